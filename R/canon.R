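# Canonical atom ranking by iterative neighbourhood refinement
# (Morgan-style), with deterministic tie-breaking. Symmetry-equivalent atoms
# share a cell until a tie-break, so the emitted string does not depend on
# the input numbering.

canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer())
  at <- mol$atoms
  deg <- atom_degree(mol)
  key <- paste(at$element, at$aromatic, deg, at$charge,
               ifelse(is.na(at$isotope), 0L, at$isotope), at$hcount,
               sep = "|")
  ranks <- match(key, sort(unique(key)))
  nb <- neighbour_list(mol)
  bond_key <- ifelse(mol$bonds$aromatic, "a", as.character(mol$bonds$order))

  refine <- function(ranks) {
    repeat {
      sig <- vapply(seq_len(n), function(i) {
        m <- nb[[i]]
        if (nrow(m) == 0L) return("")
        paste(sort(paste0(bond_key[m[, 2L]], ":", ranks[m[, 1L]])),
              collapse = ",")
      }, character(1))
      key2 <- paste(ranks, sig, sep = "#")
      new_ranks <- match(key2, sort(unique(key2)))
      if (length(unique(new_ranks)) == length(unique(ranks))) {
        return(new_ranks)
      }
      ranks <- new_ranks
    }
  }

  ranks <- refine(ranks)
  while (length(unique(ranks)) < n) {
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])[1L]
    cell <- which(ranks == tied)
    pick <- cell[1L]
    ranks <- ranks + as.integer(ranks > tied |
                                  (ranks == tied & seq_len(n) != pick))
    ranks[pick] <- tied
    ranks <- refine(ranks)
  }
  ranks
}

#' Canonical identity key of a molecule
#'
#' Produces a canonical SMILES string whose equality defines molecular
#' identity under a configurable set of ignored features. Two molecules
#' receive equal keys iff their graphs are identical once the ignored
#' features are erased; the key does not depend on input atom order.
#' Aromaticity is normalized first (kekulize, then re-perceive), so the
#' aromatic and Kekule spellings of the same molecule agree.
#'
#' @param mol a `mol_graph`.
#' @param ignore_stereo drop tetrahedral tags and bond direction marks.
#' @param ignore_charge zero all formal charges.
#' @param ignore_isotope drop isotope labels.
#' @param ignore_h_count renormalize hydrogen counts to the default
#'   implicit-hydrogen model (so valence-anomalous spellings collapse).
#' @return A character key (canonical SMILES of the normalized graph).
#' @export
#' @examples
#' canonical_key(parse_smiles("OCC")) == canonical_key(parse_smiles("CCO"))
canonical_key <- function(mol, ignore_stereo = FALSE, ignore_charge = FALSE,
                          ignore_isotope = FALSE, ignore_h_count = FALSE) {
  m <- tryCatch(aromatize(mol), error = function(e) mol)
  if (ignore_stereo) {
    m$atoms$chiral <- NA_character_
    if (nrow(m$bonds) > 0L) m$bonds$stereo <- NA_character_
  }
  if (ignore_charge) m$atoms$charge <- 0L
  if (ignore_isotope) m$atoms$isotope <- NA_integer_
  if (ignore_h_count) {
    std <- implicit_hcount(m)
    org <- m$atoms$element %in% ORGANIC_SUBSET
    m$atoms$hcount[org] <- std[org]
  }
  write_smiles(m, canonical = TRUE)
}
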