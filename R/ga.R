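#' Genetic-algorithm configuration
#'
#' @param max_features maximum subset size (the automatic model search for
#'   the BBB models capped this at 10).
#' @param population population size.
#' @param generations number of generations.
#' @param crossover crossover probability.
#' @param mutation per-gene mutation probability (default `1/n` set at run
#'   time when `NULL`).
#' @param seed integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(max_features = 10L, population = 100L,
                      generations = 200L, crossover = 0.9, mutation = NULL,
                      seed = 1L) {
  stopifnot(max_features >= 1L, population >= 4L, generations >= 1L,
            crossover >= 0, crossover <= 1,
            is.null(mutation) || (mutation >= 0 && mutation <= 1))
  structure(
    list(max_features = as.integer(max_features),
         population = as.integer(population),
         generations = as.integer(generations),
         crossover = crossover, mutation = mutation, seed = seed),
    class = "ga_config"
  )
}

#' Genetic-algorithm feature selection
#'
#' Evolves feature subsets (binary genomes) by tournament selection,
#' uniform crossover and per-gene mutation, with elitism (the best genome
#' always survives) and a repair step keeping every subset at or below
#' `max_features`. The fitness of a subset is the cross-validated balanced
#' accuracy of the package KNN classifier by default; any evaluator
#' `function(feature_indices) -> numeric` can be supplied. Fully seeded and
#' reproducible.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param positive positive class label.
#' @param config a [ga_config()].
#' @param evaluator fitness function over integer feature-index vectors;
#'   the default is 5-fold CV balanced accuracy of a k=5 Euclidean KNN.
#' @return An object of class `ga_result`: `best` (feature names),
#'   `best_fitness`, `history` (tibble per generation), `final_population`.
#' @export
ga_select <- function(x, y, positive, config = ga_config(),
                      evaluator = NULL) {
  nf <- ncol(x)
  if (config$max_features > nf) {
    stop("max_features exceeds the number of available features",
         call. = FALSE)
  }
  if (is.null(evaluator)) {
    evaluator <- function(cols) {
      cv <- suppressWarnings(cross_validate(
        x[, cols, drop = FALSE], y, positive,
        folds = 5L, seed = config$seed
      ))
      cv$pooled$balanced_accuracy
    }
  }
  mut_rate <- config$mutation %||% (1 / nf)
  cache <- new.env(parent = emptyenv())
  fitness <- function(genome) {
    cols <- which(genome)
    if (length(cols) == 0L) return(-Inf)
    key <- paste(cols, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evaluator(cols)
    cache[[key]] <- val
    val
  }
  repair <- function(genome) {
    on <- which(genome)
    if (length(on) > config$max_features) {
      genome[sample(on, length(on) - config$max_features)] <- FALSE
    }
    genome
  }

  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i) {
      g <- rep(FALSE, nf)
      g[sample.int(nf, sample.int(config$max_features, 1L))] <- TRUE
      g
    })
    fit <- vapply(pop, fitness, numeric(1))
    history <- list()
    for (gen in seq_len(config$generations)) {
      elite <- which.max(fit)
      newpop <- list(pop[[elite]])
      while (length(newpop) < config$population) {
        tournament <- function() {
          c2 <- sample.int(config$population, 2L)
          c2[which.max(fit[c2])]
        }
        p1 <- pop[[tournament()]]
        p2 <- pop[[tournament()]]
        child <- if (stats::runif(1) < config$crossover) {
          mask <- stats::runif(nf) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        flip <- stats::runif(nf) < mut_rate
        child <- xor(child, flip)
        newpop[[length(newpop) + 1L]] <- repair(child)
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      history[[gen]] <- tibble::tibble(
        generation = gen, best_fitness = max(fit), mean_fitness = mean(fit[is.finite(fit)]),
        best_size = sum(pop[[which.max(fit)]])
      )
    }
    best <- pop[[which.max(fit)]]
    structure(
      list(
        best = colnames(x)[which(best)] %||% which(best),
        best_idx = which(best),
        best_fitness = max(fit),
        history = dplyr::bind_rows(history),
        final_population = pop,
        config = config
      ),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.3f with %d features: %s\n",
              x$best_fitness, length(x$best_idx),
              paste(x$best, collapse = ", ")))
  invisible(x)
}
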