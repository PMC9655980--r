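test_that("classification scores satisfy their identities", {
  truth <- c(rep("BBB+", 100), rep("BBB-", 100))
  est <- c(rep("BBB+", 88), rep("BBB-", 12), rep("BBB+", 34),
           rep("BBB-", 66))
  sc <- classification_scores(truth, est, positive = "BBB+")
  expect_equal(sc$sensitivity, 0.88)
  expect_equal(sc$specificity, 0.66)
  expect_equal(sc$accuracy, 0.77)
  expect_equal(sc$balanced_accuracy, (0.88 + 0.66) / 2)
  cc <- attr(sc, "confusion")
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 200L)
  # perfect predictions
  p <- classification_scores(truth, truth, "BBB+")
  expect_true(all(unlist(p[1, ]) == 1))
  # predict-all-positive: Sn 1, Sp 0
  ap <- classification_scores(truth, rep("BBB+", 200), "BBB+")
  expect_equal(ap$sensitivity, 1)
  expect_equal(ap$specificity, 0)
  # accuracy always between the class rates when both classes present
  set.seed(8)
  for (i in 1:10) {
    tr <- sample(c("BBB+", "BBB-"), 40, replace = TRUE)
    if (length(unique(tr)) < 2) next
    es <- sample(c("BBB+", "BBB-"), 40, replace = TRUE)
    s <- classification_scores(tr, es, "BBB+")
    expect_gte(s$accuracy, min(s$sensitivity, s$specificity) - 1e-12)
    expect_lte(s$accuracy, max(s$sensitivity, s$specificity) + 1e-12)
    expect_equal(s$balanced_accuracy,
                 (s$sensitivity + s$specificity) / 2)
  }
  expect_warning(classification_scores(rep("BBB+", 5), rep("BBB+", 5),
                                       "BBB+"), "absent")
})

test_that("stratified folds balance sizes and classes", {
  y <- c(rep("a", 33), rep("b", 17))
  f <- stratified_folds(y, 5, seed = 2)
  expect_equal(length(f), 50L)
  sizes <- table(f)
  expect_lte(max(sizes) - min(sizes), 2L)
  for (k in 1:5) {
    expect_true(all(c("a", "b") %in% y[f == k]))
  }
  per_class <- table(f[y == "a"])
  expect_lte(max(per_class) - min(per_class), 1L)
  expect_identical(f, stratified_folds(y, 5, seed = 2))
})

test_that("cross-validation predicts each sample once and is reproducible", {
  d <- synthetic_classification(n_per_class = 40, seed = 6)
  cv <- cross_validate(d$x, d$y, "pos", folds = 5, seed = 6)
  expect_equal(sort(cv$predictions$row), 1:80)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_true(all(table(cv$predictions$fold) %in% c(15, 16, 17)))
  cv2 <- cross_validate(d$x, d$y, "pos", folds = 5, seed = 6)
  expect_identical(cv$predictions, cv2$predictions) # bit-reproducible
  # separable informative features classify nearly perfectly
  cvi <- cross_validate(d$x[, 1:2], d$y, "pos", folds = 5, seed = 6)
  expect_gte(cvi$pooled$accuracy, 0.9)
  expect_gte(glance(cvi)$accuracy, 0.9)
  expect_equal(nrow(tidy(cvi)), 5L * 4L) # five folds, four score metrics
})

test_that("Y-randomization collapses scores to chance and keeps the
           observed model intact", {
  d <- synthetic_classification(n_per_class = 50, n_informative = 2,
                                n_noise = 3, effect = 3, seed = 10)
  yr <- y_randomization(d$x, d$y, "pos", n_iter = 12, seed = 10)
  expect_equal(nrow(yr), 12L)
  obs <- attr(yr, "observed")
  expect_gt(obs$accuracy, mean(yr$accuracy)) # degradation toward chance
  # permuted accuracy within 3 Monte-Carlo standard errors of the
  # majority-class rate (0.5 for balanced classes)
  se <- sd(yr$accuracy) / sqrt(nrow(yr))
  expect_lte(abs(mean(yr$accuracy) - 0.5), 3 * se + 0.05)
  g <- glance(yr)
  expect_equal(g$observed_accuracy, obs$accuracy)
})

test_that("leverage AD reproduces the hat-matrix closed forms", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  ad <- leverage_fit(X)
  expect_equal(sum(ad$h_train), ncol(X) + 1) # trace of the hat matrix
  expect_true(all(ad$h_train <= 1 + 1e-12))
  expect_equal(ad$threshold, 3 * (3 + 1) / 20)
  # single centred feature: h_i = 1/n + x_i^2 / sum(x^2)
  x1 <- matrix(scale(rnorm(15), scale = FALSE), ncol = 1)
  ad1 <- leverage_fit(x1)
  expect_equal(ad1$h_train,
               1 / 15 + as.numeric(x1)^2 / sum(x1^2))
  lv <- leverage_value(ad, X)
  expect_equal(lv$h, unname(ad$h_train))
  far <- leverage_value(ad, matrix(100, 1, 3))
  expect_false(far$inside)
  expect_error(leverage_fit(cbind(X, X[, 1])), "singular|variable_reduction")
})

test_that("distance AD admits ~95% of training data and rejects outliers", {
  set.seed(12)
  X <- matrix(rnorm(200), 100, 2)
  ad <- distance_ad_fit(X, "euclidean", k_ad = 5)
  expect_equal(mean(ad$dbar_train <= ad$threshold), 0.95)
  v <- distance_ad_value(ad, matrix(c(50, 50), 1, 2))
  expect_false(v$inside)
  # a training point re-queried is inside
  expect_true(distance_ad_value(ad, X[1, , drop = FALSE])$inside)
  # fingerprint metric variant
  B <- matrix(stats::runif(400) < 0.5, 20, 20) * 1
  adb <- distance_ad_fit(B, "jaccard_tanimoto", k_ad = 3)
  vb <- distance_ad_value(adb, B)
  expect_true(mean(vb$inside) >= 0.9)
})

test_that("consensus AD is the conjunction of member domains", {
  expect_true(consensus_ad(TRUE, TRUE, TRUE))
  expect_false(consensus_ad(TRUE, FALSE, TRUE))
  expect_equal(consensus_ad(c(TRUE, FALSE)), c(TRUE, FALSE)) # identity
  inside <- consensus_ad(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(inside, c(TRUE, FALSE, FALSE))
  # inside-set is a subset of every member's inside-set
  m1 <- c(TRUE, TRUE, FALSE, TRUE)
  m2 <- c(TRUE, FALSE, TRUE, TRUE)
  cj <- consensus_ad(list(m1, m2))
  expect_true(all(which(cj) %in% which(m1)))
  expect_true(all(which(cj) %in% which(m2)))
  expect_error(consensus_ad(), "at least one")
})
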