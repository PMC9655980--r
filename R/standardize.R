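# Built-in structure standardizers. Each takes and returns a mol_graph and
# is deterministic; apply_standardizers() runs an ordered rule list to a
# per-rule fixed point. Order matters across different rules by design.

NITRO_NEUTRAL_SMIRKS <-
  "[N;D3:1](~[O;D1:2])(~[O;D1:3])>>[*+0;H0:1](=[*+0;H0:2])=[*+0;H0:3]"
NITRO_CHARGED_SMIRKS <-
  "[N;D3:1](~[O;D1:2])(~[O;D1:3])>>[*+1;H0:1](=[*+0;H0:2])-[*-1;H0:3]"
AZIDE_SMIRKS <-
  "[N;D2:1](~[N;D2:2])~[N;D1:3]>>[*:1]=[*+1;H0:2]=[*-1;H0:3]"
DIAZO_SMIRKS <-
  "[C:1](~[N;D2:2])~[N;D1:3]>>[*:1]=[*+1;H0:2]=[*-1;H0:3]"

std_covalent_to_ionic <- function(mol) {
  repeat {
    rows <- covalent_ionic_rows(mol)
    if (length(rows) == 0L) return(mol)
    r <- rows[1L]
    metal <- if (mol$atoms$element[mol$bonds$from[r]] %in% ALKALI_METALS) {
      mol$bonds$from[r]
    } else mol$bonds$to[r]
    other <- setdiff(c(mol$bonds$from[r], mol$bonds$to[r]), metal)
    mol$bonds <- mol$bonds[-r, , drop = FALSE]
    mol$atoms$charge[metal] <- mol$atoms$charge[metal] + 1L
    mol$atoms$charge[other] <- mol$atoms$charge[other] - 1L
  }
}

std_charge_quaternary_nitrogen <- function(mol) {
  deg <- atom_degree(mol)
  b <- mol$bonds
  four_single <- vapply(seq_len(n_atoms(mol)), function(a) {
    rows <- which(b$from == a | b$to == a)
    length(rows) == 4L && all(b$order[rows] == 1L) && !any(b$aromatic[rows])
  }, logical(1))
  sel <- mol$atoms$element == "N" & mol$atoms$charge == 0L & four_single
  mol$atoms$charge[sel] <- 1L
  mol
}

target_hcount <- function(mol) {
  v <- valence_sum(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    el <- mol$atoms$element[i]
    if (!el %in% STANDARD_ATOM_SET || el == "H") {
      return(mol$atoms$hcount[i])
    }
    av <- allowed_valences(el, mol$atoms$charge[i])
    if (anyNA(av)) return(mol$atoms$hcount[i])
    fit <- av[av >= v[i] - 1e-9]
    if (length(fit) == 0L) return(0L)
    as.integer(round(fit[1] - v[i]))
  }, integer(1))
}

std_remove_exceeding_hydrogens <- function(mol) {
  tgt <- target_hcount(mol)
  mol$atoms$hcount <- pmin(mol$atoms$hcount, tgt)
  mol
}

std_add_missing_hydrogens <- function(mol) {
  tgt <- target_hcount(mol)
  mol$atoms$hcount <- pmax(mol$atoms$hcount, tgt)
  mol
}

std_remove_monoatomic_fragments <- function(mol) {
  frags <- mol_fragments(mol)
  if (length(frags) < 2L) return(mol)
  sizes <- lengths(frags)
  if (all(sizes == 1L)) return(mol)
  keep <- unlist(frags[sizes > 1L])
  subset_mol(mol, keep)
}

std_retain_biggest_fragment <- function(mol) {
  frags <- mol_fragments(mol)
  if (length(frags) < 2L) return(mol)
  heavy <- vapply(frags, function(f) {
    sum(mol$atoms$element[f] != "H")
  }, integer(1))
  subset_mol(mol, frags[[which.max(heavy)]])
}

std_clear_isotopes <- function(mol) {
  mol$atoms$isotope <- NA_integer_
  mol
}

std_clear_chirality <- function(mol) {
  mol$atoms$chiral <- NA_character_
  mol
}

std_clear_bond_direction <- function(mol) {
  if (nrow(mol$bonds) > 0L) mol$bonds$stereo <- NA_character_
  mol
}

std_remove_radicals <- function(mol) {
  # radicals are modelled as under-filled neutral valence; repair with H
  tgt <- target_hcount(mol)
  sel <- mol$atoms$charge == 0L & mol$atoms$hcount < tgt
  mol$atoms$hcount[sel] <- tgt[sel]
  mol
}

std_remove_hydrogens <- function(mol) {
  hs <- which(mol$atoms$element == "H")
  if (length(hs) == 0L) return(mol)
  for (a in hs) {
    rows <- which(mol$bonds$from == a | mol$bonds$to == a)
    for (r in rows) {
      nbr <- setdiff(c(mol$bonds$from[r], mol$bonds$to[r]), a)
      mol$atoms$hcount[nbr] <- mol$atoms$hcount[nbr] + 1L
    }
  }
  subset_mol(mol, setdiff(seq_len(n_atoms(mol)), hs))
}

neutralize_one <- function(mol, a) {
  ch <- mol$atoms$charge[a]
  if (ch < 0L) {
    mol$atoms$hcount[a] <- mol$atoms$hcount[a] - ch
    mol$atoms$charge[a] <- 0L
  } else if (ch > 0L && mol$atoms$hcount[a] >= ch) {
    mol$atoms$hcount[a] <- mol$atoms$hcount[a] - ch
    mol$atoms$charge[a] <- 0L
  }
  mol
}

std_neutralize_atoms <- function(mol) {
  for (a in which(mol$atoms$charge != 0L)) mol <- neutralize_one(mol, a)
  mol
}

std_neutralize_molecule <- function(mol) {
  for (a in which(mol$atoms$charge != 0L)) {
    if (sum(mol$atoms$charge) == 0L) break
    mol <- neutralize_one(mol, a)
  }
  mol
}

BUILTIN_STANDARDIZERS <- list(
  covalent_to_ionic = std_covalent_to_ionic,
  charge_quaternary_nitrogen = std_charge_quaternary_nitrogen,
  remove_exceeding_hydrogens = std_remove_exceeding_hydrogens,
  add_missing_hydrogens = std_add_missing_hydrogens,
  remove_monoatomic_fragments = std_remove_monoatomic_fragments,
  retain_biggest_fragment = std_retain_biggest_fragment,
  nitro_to_neutral = function(mol) apply_smirks(mol, NITRO_NEUTRAL_SMIRKS),
  nitro_to_charged = function(mol) apply_smirks(mol, NITRO_CHARGED_SMIRKS),
  standardize_azide = function(mol) apply_smirks(mol, AZIDE_SMIRKS),
  standardize_diazo = function(mol) apply_smirks(mol, DIAZO_SMIRKS),
  clear_isotopes = std_clear_isotopes,
  clear_chirality = std_clear_chirality,
  clear_bond_direction = std_clear_bond_direction,
  remove_radicals = std_remove_radicals,
  remove_hydrogens = std_remove_hydrogens,
  neutralize_atoms = std_neutralize_atoms,
  neutralize_molecule = std_neutralize_molecule
)

#' List the built-in standardizer ids
#' @return Character vector of rule ids accepted by [apply_standardizers()].
#' @export
standardizer_ids <- function() names(BUILTIN_STANDARDIZERS)

#' Apply an ordered list of standardizer rules to every molecule
#'
#' Rules are applied in the given order; each rule runs to a fixed point on
#' a molecule before the next rule starts. A rule is either a built-in id
#' (see [standardizer_ids()]) or a custom reaction-SMARTS string containing
#' `">>"` (see [parse_smirks()]). Applying different rules in a different
#' order can legitimately give different results; a single rule list is
#' idempotent for the built-in rules.
#'
#' @param table a molecule table.
#' @param rules character vector of rule ids / reaction-SMARTS strings.
#' @return The table with transformed `mol` and refreshed `smiles` columns.
#' @export
#' @examples
#' tbl <- molecule_table("CC.[Na+]")
#' apply_standardizers(tbl, "retain_biggest_fragment")$smiles
apply_standardizers <- function(table, rules) {
  compiled <- lapply(rules, function(r) {
    if (grepl(">>", r, fixed = TRUE)) {
      rule <- parse_smirks(r) # errors name the pattern
      function(mol) apply_smirks(mol, rule)
    } else if (r %in% names(BUILTIN_STANDARDIZERS)) {
      BUILTIN_STANDARDIZERS[[r]]
    } else {
      stop("unknown standardizer '", r, "'", call. = FALSE)
    }
  })
  table$mol <- purrr::map(table$mol, function(mol) {
    for (f in compiled) mol <- f(mol)
    mol
  })
  table$smiles <- purrr::map_chr(table$mol, write_smiles)
  table
}
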