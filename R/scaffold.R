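#' Bemis-Murcko scaffold of one molecule
#'
#' The molecular framework: ring systems plus the linker atoms connecting
#' them, obtained by iteratively pruning terminal heavy atoms. Side chains
#' (including exocyclic terminal heteroatoms) are removed. Returns `NA` for
#' ring-free molecules.
#'
#' @param mol a `mol_graph`.
#' @return Canonical key of the framework, or `NA_character_` if the
#'   molecule has no ring.
#' @export
#' @examples
#' murcko_scaffold(parse_smiles("Cc1ccccc1")) # benzene framework
murcko_scaffold <- function(mol) {
  mol <- kekulize(mol)
  keep <- heavy_idx(mol)
  mol <- subset_mol(mol, keep)
  repeat {
    deg <- atom_degree(mol)
    drop <- which(deg <= 1L)
    if (n_atoms(mol) == 0L || length(drop) == 0L) break
    if (length(drop) == n_atoms(mol)) return(NA_character_) # acyclic
    mol <- subset_mol(mol, setdiff(seq_len(n_atoms(mol)), drop))
  }
  if (n_atoms(mol) == 0L) return(NA_character_)
  mol$atoms$hcount <- implicit_hcount(mol)
  canonical_key(mol, ignore_stereo = TRUE)
}

#' Scaffold census of a molecule table
#'
#' @param table a molecule table.
#' @return A list with `per_molecule` (tibble `id`, `scaffold`), `summary`
#'   (tibble `scaffold`, `n`, most frequent first), `n_scaffolds` and
#'   `n_ring_free` (molecules with no ring, which do not contribute a
#'   scaffold).
#' @export
scaffold_analysis <- function(table) {
  sc <- purrr::map_chr(table$mol, murcko_scaffold)
  per <- tibble::tibble(id = table$id, scaffold = sc)
  summary <- per |>
    dplyr::filter(!is.na(.data$scaffold)) |>
    dplyr::count(.data$scaffold, sort = TRUE)
  list(
    per_molecule = per,
    summary = summary,
    n_scaffolds = nrow(summary),
    n_ring_free = sum(is.na(sc))
  )
}
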