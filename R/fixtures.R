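#' A fixed suite of toy molecules exercising the curation machinery
#'
#' Deterministic, self-contained test material: the n-alkane homologous
#' series C1-C12, a stereoisomer pair differing in one tetrahedral centre,
#' a carbon with a missing hydrogen (unusual valence), the nitro-group
#' spelling variants, a covalently drawn sodium phenolate, a salt mixture,
#' a lone noble-gas atom and quaternary ammonium examples.
#'
#' @return A molecule table.
#' @export
toy_molecules <- function() {
  alkanes <- vapply(1:12, function(n) paste(rep("C", n), collapse = ""),
                    character(1))
  smiles <- c(
    alkanes,
    "Nc1ccn([C@@H]2CC[C@@H](CO)O2)c(=O)n1",
    "Nc1ccn([C@H]2CC[C@@H](CO)O2)c(=O)n1",
    "C=C([CH]CC)CC",
    "[O-][N+](=O)C1CCCC1",
    "O=N(=O)C1CCCC1",
    "[O-]N(=O)C1CCCC1",
    "[Na]Oc1cccc(-c2ccccc2)c1",
    "CC.[Na+]",
    "[Kr]",
    "C[N+](C)(C)C",
    "OCC[N+](C)(C)C",
    "c1ccccc1",
    "c1ccncc1"
  )
  names <- c(
    paste0("alkane_C", 1:12),
    "stereo_pair_a", "stereo_pair_b", "missing_hydrogen",
    "nitro_charged", "nitro_neutral", "nitro_anionic",
    "sodium_phenolate_covalent", "ethane_sodium_salt", "krypton",
    "tetramethylammonium", "choline", "benzene", "pyridine"
  )
  molecule_table(smiles, names)
}

#' Synthetic two-class dataset with planted informative features
#'
#' Class-conditional multivariate normal features: the informative columns
#' are shifted by `effect` standard deviations between the two classes, the
#' noise columns are identically distributed in both. All randomness flows
#' from `seed`.
#'
#' @param n_per_class molecules per class (>= 10).
#' @param n_informative number of informative features.
#' @param n_noise number of pure-noise features.
#' @param effect between-class mean shift in sd units (Cohen's d).
#' @param seed integer seed.
#' @return A list with `x` (matrix, columns `inf1..`/`noise1..`), `y`
#'   (character labels `"pos"`/`"neg"`), and `spec` (the generating
#'   parameters).
#' @export
synthetic_classification <- function(n_per_class = 200L, n_informative = 2L,
                                     n_noise = 48L, effect = 3,
                                     seed = 1L) {
  stopifnot(n_per_class >= 10L, effect >= 0, n_informative >= 1L,
            n_noise >= 0L)
  with_seed(seed, {
    n <- 2L * n_per_class
    y <- rep(c("pos", "neg"), each = n_per_class)
    shift <- ifelse(y == "pos", effect / 2, -effect / 2)
    xi <- matrix(stats::rnorm(n * n_informative), n, n_informative) + shift
    xn <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    x <- cbind(xi, xn)
    colnames(x) <- c(
      paste0("inf", seq_len(n_informative)),
      if (n_noise > 0L) paste0("noise", seq_len(n_noise))
    )
    rownames(x) <- as.character(seq_len(n))
    list(
      x = x, y = y,
      spec = list(n_per_class = n_per_class, n_informative = n_informative,
                  n_noise = n_noise, effect = effect, seed = seed)
    )
  })
}

#' Write the toy molecule suite to disk
#'
#' @param dir output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tbl <- toy_molecules()
  p1 <- file.path(dir, "toy_molecules.smi")
  p2 <- file.path(dir, "toy_molecules.sdf")
  write_molecules(tbl, p1, "smiles")
  write_molecules(tbl, p2, "sdf")
  invisible(c(p1, p2))
}
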