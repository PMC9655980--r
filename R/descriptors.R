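#' Atomic polarizability table
#'
#' Static atomic polarizabilities (10^-24 cm^3) for the standard atom set,
#' used by the mean-polarizability descriptor; values are scaled on carbon
#' at evaluation time. Stored as data so an alternative compilation can be
#' swapped in.
#'
#' @return A tibble with columns `element` and `polarizability`.
#' @export
polarizability_table <- function() {
  tibble::tibble(
    element = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    polarizability = c(0.667, 3.03, 1.76, 1.10, 0.802, 0.557, 3.63, 2.90,
                       2.18, 3.05, 5.35)
  )
}

#' Mean atomic polarizability, scaled on carbon
#'
#' Average atomic polarizability over all atoms including hydrogens,
#' divided by the carbon value: `Mp = (sum_i p_i / p_C) / n`. A composition
#' descriptor: independent of connectivity and of molecule size at fixed
#' composition.
#'
#' @param mol a `mol_graph`.
#' @param table polarizability lookup, as from [polarizability_table()].
#' @return Numeric; `NA` if an element is missing from the table.
#' @export
calc_mp <- function(mol, table = polarizability_table()) {
  p <- stats::setNames(table$polarizability, table$element)
  heavy <- mol$atoms$element[mol$atoms$element != "*"]
  if (!all(heavy %in% names(p))) return(NA_real_)
  n_h <- sum(mol$atoms$hcount)
  total <- sum(p[heavy]) + n_h * p[["H"]]
  n_all <- length(heavy) + n_h
  unname(total / (n_all * p[["C"]]))
}

#' Number of nitrogen atoms
#' @param mol a `mol_graph`.
#' @return Integer count, regardless of charge or aromaticity.
#' @export
calc_nn <- function(mol) sum(mol$atoms$element == "N")

#' Molecular path count of order 7 (log scale)
#'
#' Counts simple paths of exactly 7 bonds in the heavy-atom graph (each
#' undirected path once) and returns `ln(1 + count)`, so a molecule with no
#' such path scores 0.
#'
#' @param mol a `mol_graph`.
#' @return Numeric.
#' @export
calc_mpc07 <- function(mol) log1p(count_simple_paths(mol, 7L))

#' Number of quaternary ammonium cations (E-state atom type ssssN+)
#'
#' Nitrogen atoms with formal charge +1 and exactly four single bonds.
#'
#' @param mol a `mol_graph`.
#' @return Integer count.
#' @export
calc_nssssnp <- function(mol) {
  b <- mol$bonds
  sum(vapply(seq_len(n_atoms(mol)), function(a) {
    if (mol$atoms$element[a] != "N" || mol$atoms$charge[a] != 1L ||
        mol$atoms$hcount[a] != 0L) {
      return(FALSE)
    }
    rows <- which(b$from == a | b$to == a)
    length(rows) == 4L && all(b$order[rows] == 1L) && !any(b$aromatic[rows])
  }, logical(1)))
}

#' SHannon Entropy Descriptor over a pharmacophore point pair
#'
#' Collects the topological distances of every atom pair carrying the two
#' labels (distances capped at `dmax`), forms the distribution over the
#' occupied distance bins and returns `exp(H)` where `H` is its Shannon
#' entropy (natural log). Equals 1 when all pairs share one distance,
#' approaches `dmax` when all bins are uniformly occupied, and is 0 by
#' convention when no labelled pair exists.
#'
#' @param mol a `mol_graph`.
#' @param pair two labels from {"D","A","P","N","L"}, e.g. `c("D","L")`.
#' @param dmax number of distance bins (default 20); larger distances clamp
#'   into the last bin.
#' @param ppp optional precomputed [assign_ppp()] result.
#' @return Numeric in `{0} U [1, dmax]`.
#' @export
#' @examples
#' calc_shed(parse_smiles("NCC"), c("D", "L")) # single D-L pair -> 1
calc_shed <- function(mol, pair, dmax = 20L, ppp = NULL) {
  stopifnot(length(pair) == 2L)
  if (is.null(ppp)) ppp <- assign_ppp(mol)
  heavy <- heavy_idx(mol)
  dmat <- topological_distance_matrix(mol)
  xs <- ppp$atom[ppp[[pair[1L]]]]
  ys <- ppp$atom[ppp[[pair[2L]]]]
  if (length(xs) == 0L || length(ys) == 0L) return(0)
  pos <- function(a) match(a, heavy)
  seen <- character()
  dists <- integer()
  for (a in xs) {
    for (b in ys) {
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (key %in% seen) next
      seen <- c(seen, key)
      d <- dmat[pos(a), pos(b)]
      if (!is.finite(d)) next # disconnected pair: treated as absent
      dists <- c(dists, min(as.integer(d), dmax))
    }
  }
  if (length(dists) == 0L) return(0)
  p <- tabulate(dists, nbins = dmax)
  p <- p[p > 0L] / length(dists)
  exp(-sum(p * log(p)))
}

#' Carbon pairs at topological distance 9 (frequency atom pair F09[C-C])
#'
#' @param mol a `mol_graph`.
#' @return Integer: number of unordered C-C pairs at shortest-path
#'   distance 9.
#' @export
calc_f09_cc <- function(mol) {
  heavy <- heavy_idx(mol)
  cs <- which(mol$atoms$element[heavy] == "C")
  if (length(cs) < 2L) return(0L)
  dmat <- topological_distance_matrix(mol)[cs, cs, drop = FALSE]
  sum(dmat[upper.tri(dmat)] == 9) |> as.integer()
}

# closures so that collation order does not matter
DESCRIPTOR_FUNS <- list(
  "Mp" = function(mol) calc_mp(mol),
  "nN" = function(mol) as.numeric(calc_nn(mol)),
  "MPC07" = function(mol) calc_mpc07(mol),
  "NssssN+" = function(mol) as.numeric(calc_nssssnp(mol)),
  "SHED_DL" = function(mol) calc_shed(mol, c("D", "L")),
  "SHED_AN" = function(mol) calc_shed(mol, c("A", "N")),
  "F09[C-C]" = function(mol) as.numeric(calc_f09_cc(mol)),
  "TPSA(Tot)" = function(mol) calc_tpsa(mol),
  "MLOGP" = function(mol) calc_mlogp(mol),
  "MLOGP2" = function(mol) calc_mlogp(mol)^2
)

#' Names of the implemented molecular descriptors
#' @return Character vector accepted by [calc_descriptor_matrix()].
#' @export
descriptor_names <- function() names(DESCRIPTOR_FUNS)

#' Descriptor matrix for a molecule table
#'
#' One row per molecule, one column per requested descriptor. A descriptor
#' that cannot be computed for a molecule (e.g. an element missing from the
#' polarizability table) yields `NA` for that cell, never an error; failed
#' cells are listed in the `failures` attribute.
#'
#' @param table a molecule table.
#' @param names descriptor names, a subset of [descriptor_names()].
#' @return A tibble with `id` and one numeric column per descriptor.
#' @export
#' @examples
#' calc_descriptor_matrix(molecule_table(c("CCO", "c1ccncc1")),
#'                        c("nN", "TPSA(Tot)"))
calc_descriptor_matrix <- function(table, names = descriptor_names()) {
  unknown <- setdiff(names, descriptor_names())
  if (length(unknown) > 0L) {
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(id = table$id)
  failures <- list()
  for (nm in names) {
    f <- DESCRIPTOR_FUNS[[nm]]
    vals <- vapply(seq_along(table$mol), function(i) {
      v <- tryCatch(f(table$mol[[i]]), error = function(e) {
        failures[[length(failures) + 1L]] <<- tibble::tibble(
          id = table$id[i], descriptor = nm, message = conditionMessage(e)
        )
        NA_real_
      })
      if (length(v) != 1L || is.nan(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    out[[nm]] <- vals
  }
  attr(out, "failures") <- if (length(failures) > 0L) {
    dplyr::bind_rows(failures)
  } else tibble::tibble(id = integer(), descriptor = character(),
                        message = character())
  out
}
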