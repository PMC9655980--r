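test_that("mean atomic polarizability matches hand evaluation and depends
           only on composition", {
  # methane: (1.76 + 4*0.667) / (5*1.76)
  expect_equal(calc_mp(parse_smiles("C")), (1.76 + 4 * 0.667) / (5 * 1.76))
  # benzene: (6*1.76 + 6*0.667) / (12*1.76)
  expect_equal(calc_mp(parse_smiles("c1ccccc1")),
               (6 * 1.76 + 6 * 0.667) / (12 * 1.76))
  # identical composition, different connectivity
  expect_equal(calc_mp(parse_smiles("CCCO")), calc_mp(parse_smiles("CC(C)O")))
  # missing element yields a missing value, not an error
  expect_true(is.na(calc_mp(parse_smiles("[Kr]"))))
})

test_that("nitrogen count ignores charge and aromaticity", {
  expect_equal(calc_nn(parse_smiles("Cn1cnc2c1c(=O)n(C)c(=O)n2C")), 4L)
  expect_equal(calc_nn(parse_smiles("CCCCCC")), 0L)
  expect_equal(calc_nn(parse_smiles("C[N+](C)(C)C")), 1L)
})

test_that("MPC07 equals ln(1 + path count) with an enumeration oracle", {
  expect_equal(calc_mpc07(parse_smiles("CCCCCCC")), 0)      # longest path 6
  expect_equal(calc_mpc07(parse_smiles("CCCCCCCC")), log(2)) # exactly one
  expect_equal(calc_mpc07(parse_smiles("C1CCCCCCC1")), log(9)) # 8-cycle: 8
  for (seed in 1:8) {
    m <- rand_mol(sample(6:10, 1), seed = seed + 50, ring = seed %% 2 == 0)
    expect_equal(qsarkit:::count_simple_paths(m, 7L),
                 igraph_path_count(m, 7L), label = paste("seed", seed))
  }
})

test_that("quaternary ammonium detection follows the ssssN+ definition", {
  expect_equal(calc_nssssnp(parse_smiles("C[N+](C)(C)C")), 1L)
  expect_equal(calc_nssssnp(parse_smiles("[nH+]1ccccc1")), 0L)
  expect_equal(calc_nssssnp(parse_smiles("OCC[N+](C)(C)C")), 1L)
  expect_equal(calc_nssssnp(parse_smiles("CN")), 0L)
})

test_that("pharmacophore typing follows the published rule set", {
  ppp <- assign_ppp(parse_smiles("CCO"))
  expect_true(ppp$D[3] && ppp$A[3])   # hydroxyl O donates and accepts
  expect_false(ppp$L[2])              # carbon bonded to the O is not L
  expect_true(ppp$L[1])               # terminal carbon is L
  acetate <- assign_ppp(parse_smiles("CC([O-])=O"))
  expect_true(all(acetate$N[3:4]))    # both carboxylate oxygens negative
  expect_true(all(acetate$A[3:4]))
  hexane <- assign_ppp(parse_smiles("CCCCCC"))
  expect_true(all(hexane$L))
  expect_false(any(hexane$D | hexane$A | hexane$N | hexane$P))
})

test_that("SHED is exp(entropy) over pair-distance bins with the stated
           conventions", {
  # a single donor-lipophilic pair at one distance
  expect_equal(calc_shed(parse_smiles("NCC"), c("D", "L")), 1)
  # no donor at all -> 0 by convention
  expect_equal(calc_shed(parse_smiles("CCCC"), c("D", "L")), 0)
  # two pairs at two distinct distances -> exp(ln 2) = 2
  expect_equal(calc_shed(parse_smiles("NCCC"), c("D", "L")), 2)
  # three pairs at three distances -> 3
  expect_equal(calc_shed(parse_smiles("NCCCC"), c("D", "L")), 3)
  # range: {0} U [1, dmax], uniform occupancy approaches dmax
  suite <- toy_molecules()
  for (m in suite$mol) {
    v <- calc_shed(m, c("D", "L"))
    expect_true(v == 0 || (v >= 1 && v <= 20))
  }
})

test_that("F09[C-C] counts carbon pairs at topological distance nine", {
  expect_equal(calc_f09_cc(parse_smiles("CCCCCCCCCC")), 1L)  # decane
  expect_equal(calc_f09_cc(parse_smiles("CCCCCCCCC")), 0L)   # nonane
  expect_equal(calc_f09_cc(parse_smiles("CCCCCCCCCCC")), 2L) # undecane
  # nitrogen at a terminus does not count
  expect_equal(calc_f09_cc(parse_smiles("NCCCCCCCCC")), 0L)
})

test_that("F09[C-C] and MPC07 are monotone under chain extension", {
  alkanes <- lapply(6:12, function(n) {
    parse_smiles(paste(rep("C", n), collapse = ""))
  })
  f09 <- vapply(alkanes, calc_f09_cc, integer(1))
  mpc <- vapply(alkanes, calc_mpc07, numeric(1))
  expect_false(is.unsorted(f09))
  expect_false(is.unsorted(mpc))
})

test_that("TPSA reproduces published fragment sums", {
  expect_equal(calc_tpsa(parse_smiles("CCCCCC")), 0)
  expect_equal(calc_tpsa(parse_smiles("c1ccncc1")), 12.89)
  # aspirin: ester (9.23 + 17.07) + carboxylic acid (17.07 + 20.23)
  expect_equal(calc_tpsa(parse_smiles("CC(=O)Oc1ccccc1C(=O)O")), 63.60)
  # charged nitro: 3.01 + 17.07 + 23.06 (independently verified value)
  expect_equal(calc_tpsa(parse_smiles("O=[N+]([O-])C1CCCC1")), 43.14)
  expect_equal(calc_tpsa(parse_smiles("CCO")), 20.23)
})

test_that("Moriguchi logP matches hand evaluation and MLOGP2 squares it", {
  # benzene: 1.244*6^0.6 - 0.145*3^0.8 - 1.041, no other terms
  expect_equal(calc_mlogp(parse_smiles("c1ccccc1")),
               1.244 * 6^0.6 - 0.145 * 3^0.8 - 1.041)
  # hexane: alkane dummy active
  expect_equal(calc_mlogp(parse_smiles("CCCCCC")),
               1.244 * 6^0.6 + 0.912 - 1.041)
  expect_equal(calc_mlogp2(parse_smiles("c1ccccc1")),
               calc_mlogp(parse_smiles("c1ccccc1"))^2)
  expect_true(calc_mlogp2(parse_smiles("CCCCCC")) >= 0)
})

test_that("all descriptors are invariant under atom reordering", {
  pairs <- list(
    c("OCC[N+](C)(C)C", "C[N+](C)(C)CCO"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
    c("NCCCCCCCCC", "C(CCCCCCCN)C")
  )
  for (p in pairs) {
    a <- molecule_table(p[1])
    b <- molecule_table(p[2])
    da <- calc_descriptor_matrix(a)
    db <- calc_descriptor_matrix(b)
    expect_equal(da[, -1], db[, -1], label = p[1])
  }
})

test_that("the descriptor matrix handles failures as missing cells", {
  tbl <- molecule_table(c("CCCC", "[Kr]", "CCO"))
  m <- calc_descriptor_matrix(tbl, c("nN", "Mp", "MPC07"))
  expect_equal(m$nN, c(0, 0, 0))
  expect_true(is.na(m$Mp[2]))
  expect_false(anyNA(m$MPC07))
  expect_error(calc_descriptor_matrix(tbl, "XLOGP"), "unknown descriptor")
  alk <- molecule_table(vapply(1:8, function(n) {
    paste(rep("C", n), collapse = "")
  }, character(1)))
  am <- calc_descriptor_matrix(alk, c("nN", "F09[C-C]", "MPC07"))
  expect_true(all(am$nN == 0))
})
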