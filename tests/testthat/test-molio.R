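test_that("SMILES files read into tidy molecule tables with error reporting", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "CCN\tethylamine"), path)
  tbl <- read_molecules(path)
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$name, c("ethanol", "ethylamine"))
  expect_s3_class(tbl$mol[[1]], "mol_graph")

  # unparseable entries are reported with their line numbers, not dropped
  writeLines(c("CCO", "C1CC", "CCN"), path)
  expect_warning(tbl <- read_molecules(path), "line")
  errs <- attr(tbl, "parse_errors")
  expect_equal(errs$line, 2L)
  expect_match(errs$message, "ring")
  expect_equal(nrow(tbl), 2L)

  writeLines("C1CC", path)
  expect_error(read_molecules(path), "no valid molecules")
  expect_error(read_molecules(tempfile()), "no such file")
})

test_that("a 28-heavy-atom azo dye SMILES parses to the right atom count", {
  m <- parse_smiles("O=C(O)c1cc(N=Nc2ccc(S(=O)(=O)Nc3ccccn3)cc2)ccc1O")
  expect_equal(length(qsarkit:::heavy_idx(m)), 28L)
})

test_that("kekulize assigns alternating bonds, is idempotent, and rejects
           anti-aromatic rings", {
  k <- kekulize(parse_smiles("c1ccccc1"))
  expect_equal(sort(k$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_true(is_kekulized(k))
  # already-kekulized input passes through unchanged
  m <- parse_smiles("C1=CC=CC=C1")
  expect_identical(kekulize(m)$bonds, m$bonds)
  expect_error(kekulize(parse_smiles("c1ccc1")), "aromatic")
  # heteroaromatics get chemically sensible assignments
  for (s in c("c1ccncc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1",
              "c1ccc2ccccc2c1")) {
    expect_true(is_kekulized(kekulize(parse_smiles(s))), label = s)
  }
})

test_that("kekulize-aromatize-kekulize is stable on representative rings", {
  for (s in c("c1ccccc1", "c1ccncc1", "c1cc[nH]c1", "c1ccoc1",
              "Cc1ccccc1", "c1ccc2ccccc2c1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")) {
    k1 <- kekulize(parse_smiles(s))
    k2 <- kekulize(aromatize(k1))
    expect_equal(canonical_key(k1), canonical_key(k2), label = s)
    expect_equal(sort(k1$bonds$order), sort(k2$bonds$order), label = s)
  }
})

test_that("topological distances match brute-force BFS on random graphs", {
  d <- topological_distance_matrix(parse_smiles("CC"))
  expect_equal(d[1, 2], 1)
  expect_equal(max(topological_distance_matrix(parse_smiles("C1CCCCC1"))), 3)
  dd <- topological_distance_matrix(parse_smiles("CCCCCCCCCC"))
  expect_equal(dd[1, 10], 9)
  # disconnected pairs carry an unreachable sentinel
  expect_true(is.infinite(topological_distance_matrix(
    parse_smiles("CC.CC")
  )[1, 3]))
  for (seed in 1:10) {
    m <- rand_mol(sample(4:12, 1), seed = seed, ring = seed %% 2 == 0)
    expect_equal(unname(topological_distance_matrix(m)), bfs_distances(m),
                 label = paste("seed", seed))
  }
})

test_that("canonical keys are invariant to atom input order", {
  pairs <- list(
    c("CCO", "OCC"),
    c("c1ccncc1", "n1ccccc1"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
    c("C1=CC=CC=C1O", "Oc1ccccc1")
  )
  for (p in pairs) {
    expect_equal(canonical_key(parse_smiles(p[1])),
                 canonical_key(parse_smiles(p[2])), label = p[1])
  }
  for (seed in 1:8) {
    m <- rand_mol(sample(4:10, 1), seed = seed + 100, ring = TRUE)
    p <- permute_mol(m, sample(nrow(m$atoms)))
    expect_equal(canonical_key(m), canonical_key(p),
                 label = paste("seed", seed))
  }
})

test_that("canonical key equality agrees with an independent
           canonicalizer on sampled pairs", {
  skip_if(Sys.which("obabel") == "", "obabel not on PATH")
  smiles <- c("CCO", "OCC", "CCN", "c1ccccc1O", "Oc1ccccc1",
              "CC(C)=O", "CC(=O)C", "N#CC", "CC#N")
  for (i in seq_along(smiles)) {
    for (j in seq_len(i - 1L)) {
      mine <- canonical_key(parse_smiles(smiles[i])) ==
        canonical_key(parse_smiles(smiles[j]))
      theirs <- obabel_canonical(smiles[i]) == obabel_canonical(smiles[j])
      expect_equal(mine, theirs, label = paste(smiles[i], "vs", smiles[j]))
    }
  }
})

test_that("stereochemistry distinguishes keys unless ignored", {
  a <- parse_smiles("Nc1ccn([C@@H]2CC[C@@H](CO)O2)c(=O)n1")
  b <- parse_smiles("Nc1ccn([C@H]2CC[C@@H](CO)O2)c(=O)n1")
  expect_false(canonical_key(a) == canonical_key(b))
  expect_equal(canonical_key(a, ignore_stereo = TRUE),
               canonical_key(b, ignore_stereo = TRUE))
  # tetrahedral tags survive a canonicalization round trip
  s <- write_smiles(parse_smiles("N[C@@H](C)C(=O)O"))
  expect_equal(write_smiles(parse_smiles(s)), s)
  expect_false(canonical_key(parse_smiles("N[C@@H](C)C(=O)O")) ==
                 canonical_key(parse_smiles("N[C@H](C)C(=O)O")))
})

test_that("charge/hydrogen ignore-options merge the corresponding spellings", {
  a <- parse_smiles("CC(=O)[O-]")
  b <- parse_smiles("CC(=O)O")
  expect_false(canonical_key(a) == canonical_key(b))
  expect_equal(
    canonical_key(a, ignore_charge = TRUE, ignore_h_count = TRUE),
    canonical_key(b, ignore_charge = TRUE, ignore_h_count = TRUE)
  )
  c1 <- parse_smiles("[13CH4]")
  c2 <- parse_smiles("C")
  expect_false(canonical_key(c1) == canonical_key(c2))
  expect_equal(canonical_key(c1, ignore_isotope = TRUE), canonical_key(c2))
})

test_that("molecule tables round-trip through SMILES and SDF files", {
  tbl <- molecule_table(
    c("CC([O-])=O", "c1ccncc1", "N[C@@H](C)C(=O)O", "[13CH4]"),
    name = c("acetate", "pyridine", "alanine", "c13"),
    endpoint = c("BBB+", "BBB-", "BBB+", "BBB-")
  )
  for (fmt in c("smiles", "sdf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_molecules(tbl, path, format = fmt)
    back <- read_molecules(path, format = fmt,
                           header = fmt == "smiles")
    expect_equal(nrow(back), nrow(tbl))
    expect_equal(purrr::map_chr(back$mol, canonical_key),
                 purrr::map_chr(tbl$mol, canonical_key),
                 label = fmt)
    expect_equal(back$endpoint, tbl$endpoint, label = fmt)
  }
})

test_that("an independent SDF reader agrees on atom and bond counts", {
  skip_if_not_installed("ChemmineR")
  tbl <- molecule_table(c("c1ccncc1", "CC(=O)O", "C1CC1"))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(tbl, path, format = "sdf")
  ref <- suppressWarnings(ChemmineR::read.SDFset(path))
  for (i in seq_len(nrow(tbl))) {
    expect_equal(nrow(ChemmineR::atomblock(ref[[i]])),
                 nrow(tbl$mol[[i]]$atoms))
    expect_equal(nrow(ChemmineR::bondblock(ref[[i]])),
                 nrow(tbl$mol[[i]]$bonds))
  }
})
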