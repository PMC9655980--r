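test_that("checkers flag the documented anomaly classes", {
  tbl <- molecule_table(c(
    "C=C([CH]CC)CC",  # carbon with a missing hydrogen
    "[Kr]",           # lone noble-gas atom
    "CC.[Na+]",       # salt mixture
    "CCO",            # clean
    "[13CH4]",        # isotope label
    "[Na]OC"          # covalently drawn ionic bond
  ))
  rep <- check_structures(tbl)
  expect_true(rep$unusual_valence[1])
  expect_true(rep$radical_atom[1])
  expect_true(rep$nonstandard_atom_set[2])
  expect_true(rep$no_carbon[2])
  expect_true(all(unlist(
    rep[3, c("multiple_structures", "charged_atom", "total_charge")]
  )))
  expect_false(rep$any_flag[4])
  expect_true(rep$isotope[5])
  expect_true(rep$covalent_ionic_bond[6])
  expect_error(check_structures(tbl, "not_a_checker"), "unknown checker")
})

test_that("the custom nitro reaction-SMARTS rules match the printed
           transformations", {
  neutral <- "[N;D3:1](~[O;D1:2])(~[O;D1:3])>>[*+0;H0:1](=[*+0;H0:2])=[*+0;H0:3]"
  charged <- "[N;D3:1](~[O;D1:2])(~[O;D1:3])>>[*+1;H0:1](=[*+0;H0:2])-[*−1;H0:3]"
  tbl <- molecule_table("[O-][N+](=O)C1CCCC1")
  out <- apply_standardizers(tbl, neutral)
  expect_equal(canonical_key(out$mol[[1]]),
               canonical_key(parse_smiles("O=N(=O)C1CCCC1")))
  # typographic minus in the printed pattern is normalized to ASCII
  out2 <- apply_standardizers(molecule_table("O=N(=O)C1CCCC1"), charged)
  expect_equal(canonical_key(out2$mol[[1]]),
               canonical_key(parse_smiles("[O-][N+](=O)C1CCCC1")))
  # a broken custom pattern errors and the message names the pattern text
  expect_error(apply_standardizers(tbl, "[N:1](~[O>>broken"), "\\[N:1\\]")
  expect_error(apply_standardizers(tbl, "no_such_rule"),
               "unknown standardizer")
})

test_that("all nitro spelling variants converge under one standardizer", {
  variants <- molecule_table(c(
    "[O-][N+](=O)C1CCCC1", "O=N(=O)C1CCCC1", "[O-]N(=O)C1CCCC1"
  ))
  for (rule in c("nitro_to_neutral", "nitro_to_charged")) {
    out <- apply_standardizers(variants, rule)
    keys <- purrr::map_chr(out$mol, canonical_key)
    expect_length(unique(keys), 1L)
  }
})

test_that("standardizer order matters across rules but a fixed list is
           idempotent", {
  phenolate <- "[Na]Oc1cccc(-c2ccccc2)c1"
  a <- apply_standardizers(molecule_table(phenolate),
                           c("remove_monoatomic_fragments",
                             "covalent_to_ionic"))
  b <- apply_standardizers(molecule_table(phenolate),
                           c("covalent_to_ionic",
                             "remove_monoatomic_fragments"))
  expect_false(canonical_key(a$mol[[1]]) == canonical_key(b$mol[[1]]))
  # order A keeps the sodium counter-ion, order B drops it
  expect_equal(length(qsarkit:::mol_fragments(a$mol[[1]])), 2L)
  expect_equal(length(qsarkit:::mol_fragments(b$mol[[1]])), 1L)

  suite <- toy_molecules()
  rules <- c("covalent_to_ionic", "nitro_to_neutral",
             "charge_quaternary_nitrogen", "clear_isotopes",
             "retain_biggest_fragment")
  once <- apply_standardizers(suite, rules)
  twice <- apply_standardizers(once, rules)
  expect_equal(purrr::map_chr(twice$mol, canonical_key),
               purrr::map_chr(once$mol, canonical_key))
})

test_that("fragment and hydrogen standardizers behave as documented", {
  expect_equal(
    apply_standardizers(molecule_table("CC.[Na+]"),
                        "retain_biggest_fragment")$smiles, "CC"
  )
  fixed <- apply_standardizers(molecule_table("C=C([CH]CC)CC"),
                               "add_missing_hydrogens")
  expect_false(check_structures(fixed)$unusual_valence[1])
  neut <- apply_standardizers(molecule_table("CC([O-])=O"),
                              "neutralize_atoms")
  expect_equal(canonical_key(neut$mol[[1]]),
               canonical_key(parse_smiles("CC(O)=O")))
  quat <- apply_standardizers(molecule_table("C[N+](C)(C)C"),
                              "neutralize_atoms")
  expect_equal(quat$smiles, "C[N+](C)(C)C") # no H to remove: unchanged
})

test_that("duplicate grouping is stereo-aware and an equivalence relation", {
  tbl <- molecule_table(
    c("Nc1ccn([C@@H]2CC[C@@H](CO)O2)c(=O)n1",
      "Nc1ccn([C@H]2CC[C@@H](CO)O2)c(=O)n1",
      "CCO", "OCC", "CCO", "CCN"),
    BBB = c("BBB+", "BBB-", "BBB+", "BBB+", "BBB+", "BBB-")
  )
  strict <- find_duplicates(tbl)
  loose <- find_duplicates(tbl, ignore_stereo = TRUE)
  expect_equal(length(unique(strict$group)), 1L) # only the CCO triple
  expect_equal(sum(strict$group == 1L), 3L)
  expect_equal(length(unique(loose$group)), 2L) # stereo pair joins in
  # loosening options never shrinks any group
  for (g in unique(strict$group)) {
    ids <- strict$id[strict$group == g]
    joined <- loose$group[match(ids, loose$id)]
    expect_length(unique(joined), 1L)
  }
  # transitivity: members of a group all share one key
  expect_true(all(tapply(loose$key, loose$group,
                         function(k) length(unique(k)) == 1L)))
})

test_that("duplicate resolution removes conflicts and keeps first of
           agreeing groups", {
  tbl <- molecule_table(
    c("Nc1ccn([C@@H]2CC[C@@H](CO)O2)c(=O)n1",
      "Nc1ccn([C@H]2CC[C@@H](CO)O2)c(=O)n1",
      "CCO", "OCC", "CCN"),
    BBB = c("BBB+", "BBB-", "BBB+", "BBB+", "BBB-")
  )
  groups <- find_duplicates(tbl, ignore_stereo = TRUE)
  out <- resolve_duplicates(tbl, groups, "BBB")
  expect_equal(out$id, c(3L, 5L)) # conflict pair gone, first CCO kept
  rem <- attr(out, "removals")
  expect_setequal(rem$id, c(1L, 2L, 4L))
  # missing endpoint inside a group counts as disagreement
  tbl$BBB[4] <- NA
  out2 <- resolve_duplicates(tbl, groups, "BBB")
  expect_false(any(c(3L, 4L) %in% out2$id))
  expect_error(resolve_duplicates(tbl, groups, "nope"), "endpoint")
  # no groups: table unchanged
  clean <- molecule_table(c("CCO", "CCN"), BBB = c("BBB+", "BBB-"))
  expect_equal(
    resolve_duplicates(clean, find_duplicates(clean), "BBB")$id,
    clean$id
  )
})

test_that("Bemis-Murcko scaffolds keep rings and linkers, drop side chains", {
  benzene <- canonical_key(parse_smiles("c1ccccc1"))
  expect_equal(murcko_scaffold(parse_smiles("Cc1ccccc1")), benzene)
  expect_equal(murcko_scaffold(parse_smiles("CCc1ccc(CC(N)C)cc1")), benzene)
  expect_true(is.na(murcko_scaffold(parse_smiles("CCCCCC"))))
  biphenyl <- parse_smiles("c1ccc(cc1)-c2ccccc2")
  expect_equal(murcko_scaffold(biphenyl), canonical_key(biphenyl))
  sa <- scaffold_analysis(molecule_table(
    c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "CCCC", "CC")
  ))
  expect_equal(sa$n_scaffolds, 2L)
  expect_equal(sa$n_ring_free, 2L)
  expect_equal(sa$summary$n[1], 2L) # benzene twice
})

test_that("the BBB curation preset removes the enumerated classes and is
           idempotent", {
  tbl <- molecule_table(
    c("CC.[Na+]",        # disconnected
      "C=C([CH]CC)CC",   # unusual valence
      "[Kr]",            # single atom
      "CCO", "OCC",      # duplicate pair with conflicting labels
      "CCN", "CCC", "c1ccccc1", "CCCC", "CCCCC"),
    BBB = c("BBB+", "BBB+", "BBB-", "BBB+", "BBB-",
            "BBB+", "BBB-", "BBB+", "BBB-", "BBB+")
  )
  cur <- curate_bbb(tbl)
  # hand count: 1 disconnected + 1 valence + 1 single-atom + 2 conflicting
  # duplicates removed -> 5 survivors
  expect_equal(nrow(cur), 5L)
  expect_setequal(cur$id, c(6L, 7L, 8L, 9L, 10L))
  log <- attr(cur, "removal_log")
  expect_equal(nrow(log), 5L)
  expect_length(unique(log$reason), 4L)
  # after curation the structural flags are clean
  rep <- check_structures(cur, c("multiple_structures", "unusual_valence"))
  expect_false(any(rep$any_flag))
  expect_false(any(vapply(cur$mol,
                          function(m) length(qsarkit:::heavy_idx(m)) == 1L,
                          logical(1))))
  # re-curation removes nothing
  cur2 <- curate_bbb(cur)
  expect_equal(nrow(cur2), nrow(cur))
  expect_equal(nrow(attr(cur2, "removal_log")), 0L)
  # clean input passes through untouched
  clean <- molecule_table(c("CCO", "CCN"), BBB = c("BBB+", "BBB-"))
  expect_equal(nrow(curate_bbb(clean)), 2L)
})
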