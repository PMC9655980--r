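STANDARD_ATOM_SET <- c("H", "B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ALKALI_METALS <- c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Sr", "Ba")
ELECTRONEGATIVE <- c("N", "O", "S", "F", "Cl", "Br", "I")

CHECKER_IDS <- c(
  "multiple_structures", "unusual_valence", "covalent_ionic_bond",
  "total_charge", "isotope", "charged_atom", "no_carbon",
  "nonstandard_atom_set", "aromaticity", "radical_atom"
)

# rows of single bonds between an alkali/alkaline-earth metal and an
# electronegative atom (the "covalent where it should be ionic" pattern)
covalent_ionic_rows <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(integer())
  el <- mol$atoms$element
  which(
    b$order == 1L & !b$aromatic &
      ((el[b$from] %in% ALKALI_METALS & el[b$to] %in% ELECTRONEGATIVE) |
         (el[b$to] %in% ALKALI_METALS & el[b$from] %in% ELECTRONEGATIVE))
  )
}

# per-atom used valence = incident bond orders (aromatic model) + hydrogens
used_valence <- function(mol) valence_sum(mol) + mol$atoms$hcount

atom_valence_ok <- function(mol) {
  v <- used_valence(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    el <- mol$atoms$element[i]
    if (!el %in% STANDARD_ATOM_SET || el == "H") return(TRUE)
    av <- allowed_valences(el, mol$atoms$charge[i])
    if (anyNA(av)) return(TRUE)
    any(abs(av - v[i]) < 1e-9)
  }, logical(1))
}

check_one <- function(mol, checker) {
  switch(checker,
    multiple_structures = length(mol_fragments(mol)) > 1L,
    unusual_valence = !all(atom_valence_ok(mol)),
    covalent_ionic_bond = length(covalent_ionic_rows(mol)) > 0L,
    total_charge = sum(mol$atoms$charge) != 0L,
    isotope = any(!is.na(mol$atoms$isotope)),
    charged_atom = any(mol$atoms$charge != 0L),
    no_carbon = !any(mol$atoms$element == "C"),
    nonstandard_atom_set = !all(mol$atoms$element %in% STANDARD_ATOM_SET),
    aromaticity = inherits(tryCatch(kekulize(mol), error = identity), "error"),
    radical_atom = {
      v <- used_valence(mol)
      any(vapply(seq_len(n_atoms(mol)), function(i) {
        el <- mol$atoms$element[i]
        if (!el %in% STANDARD_ATOM_SET || el == "H") return(FALSE)
        if (mol$atoms$charge[i] != 0L) return(FALSE)
        av <- allowed_valences(el, 0L)
        all(av > v[i]) # under-filled valence without a charge
      }, logical(1)))
    },
    stop("unknown checker id '", checker, "'", call. = FALSE)
  )
}

#' List the available structure checker ids
#' @return Character vector of the ten checker ids.
#' @export
checker_ids <- function() CHECKER_IDS

#' Flag structural anomalies in a molecule table
#'
#' Applies the selected checkers to every molecule and returns one logical
#' column per checker. The available checkers are: `multiple_structures`
#' (disconnected fragments), `unusual_valence` (an atom whose bond-order sum
#' plus hydrogens does not match an allowed valence for its element/charge),
#' `covalent_ionic_bond` (covalently drawn metal-heteroatom bond),
#' `total_charge` (non-zero net charge), `isotope`, `charged_atom`,
#' `no_carbon`, `nonstandard_atom_set` (element outside H, B, C, N, O, P, S,
#' F, Cl, Br, I), `aromaticity` (no valid Kekule assignment) and
#' `radical_atom` (under-filled valence without a compensating charge).
#'
#' @param table a molecule table from [read_molecules()] or [toy_molecules()].
#' @param checkers character vector of checker ids (default: all ten).
#' @return A tibble with `id` and one logical column per enabled checker,
#'   plus `any_flag`.
#' @export
#' @examples
#' tbl <- molecule_table(c("CC.[Na+]", "[Kr]", "CCO"))
#' check_structures(tbl)
check_structures <- function(table, checkers = CHECKER_IDS) {
  stopifnot(nrow(table) > 0L)
  bad <- setdiff(checkers, CHECKER_IDS)
  if (length(bad) > 0L) {
    stop("unknown checker id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(id = table$id)
  for (ck in checkers) {
    out[[ck]] <- vapply(table$mol, check_one, logical(1), checker = ck)
  }
  out$any_flag <- Reduce(`|`, out[checkers])
  out
}

#' Build a molecule table directly from SMILES strings
#'
#' Convenience constructor mirroring the shape of [read_molecules()].
#'
#' @param smiles character vector of SMILES.
#' @param name optional molecule names.
#' @param ... further equal-length columns to attach (e.g. an endpoint).
#' @return A tibble with `id`, `smiles`, `name`, `mol` and any extra columns.
#' @export
molecule_table <- function(smiles, name = rep("", length(smiles)), ...) {
  mols <- purrr::map2(smiles, name, parse_smiles)
  tibble::tibble(
    id = seq_along(smiles), smiles = smiles, name = name, mol = mols, ...
  )
}
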