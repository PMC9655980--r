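test_that("all split methods partition the ids", {
  tbl <- tibble::tibble(id = 1:10,
                        cid = c("1", "2", "", "4", "", "6", "7", "", "9", ""))
  s1 <- split_dataset(tbl, "venetian", every_n = 5)
  expect_equal(length(s1$train_ids), 8L)
  expect_equal(length(s1$test_ids), 2L)
  s2 <- split_dataset(tbl, "by_variable", variable = "cid")
  expect_equal(s2$train_ids, c(1L, 2L, 4L, 6L, 7L, 9L))
  s3 <- split_dataset(tbl, "random", train_prop = 0.7, seed = 42)
  expect_identical(s3, split_dataset(tbl, "random", train_prop = 0.7,
                                     seed = 42))
  expect_false(identical(
    s3$train_ids,
    split_dataset(tbl, "random", train_prop = 0.7, seed = 43)$train_ids
  ))
  for (s in list(s1, s2, s3)) {
    expect_length(intersect(s$train_ids, s$test_ids), 0L)
    expect_setequal(c(s$train_ids, s$test_ids), tbl$id)
  }
})

test_that("standardization centres and scales on training parameters only", {
  x <- matrix(c(1, 2, 3), dimnames = list(NULL, "f"))
  st <- standardize_fit(x)
  expect_equal(as.numeric(standardize_apply(st, x)), c(-1, 0, 1))
  expect_equal(as.numeric(standardize_apply(st, matrix(2))), 0)
  X <- matrix(rnorm(60, 5, 3), 20, 3)
  st2 <- standardize_fit(X, train_rows = 1:12)
  Z <- standardize_apply(st2, X[1:12, ])
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-12))
  expect_error(standardize_fit(cbind(X, const = 7)), "variable_reduction")
})

test_that("variable reduction drops constants, near-constants, duplicates
           and handles missing values per policy", {
  set.seed(1)
  X <- cbind(a = rnorm(30), b = rnorm(30), const = 2,
             tiny = rnorm(30, sd = 1e-6))
  X <- cbind(X, dup = X[, "a"])
  r <- variable_reduction(X, quasi_constant_sd = 1e-3,
                          correlation_threshold = 0.95)
  expect_setequal(colnames(r), c("a", "b"))
  log <- attr(r, "reduction_log")
  expect_setequal(log$reason, c("constant", "quasi-constant",
                                "correlated with earlier feature"))
  Xna <- cbind(a = rnorm(5), b = c(1, NA, 3, 4, 5))
  rf <- variable_reduction(Xna, missing_policy = "drop_feature")
  expect_equal(colnames(rf), "a")
  rm_ <- variable_reduction(Xna, missing_policy = "drop_molecule")
  expect_equal(dim(rm_), c(4L, 2L))
  expect_error(variable_reduction(matrix(1, 5, 1)), "every feature")
})

test_that("KNN fitting validates its configuration", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(1:10, c("a", "b")))
  y <- rep(c("BBB+", "BBB-"), 5)
  expect_error(knn_fit(x, y, k = 0), "k must be")
  expect_error(knn_fit(x, y, k = 11), "k must be")
  expect_error(knn_fit(x, rep("BBB+", 10), k = 3), "two classes")
  expect_error(knn_fit(x, y, k = 3, metric = "jaccard_tanimoto"), "0/1")
  m <- knn_fit(x, y, k = 5)
  expect_s3_class(m, "knn_model")
  expect_equal(glance(m)$n_features, 2L)
  expect_true(glance(m)$standardized)
  expect_equal(sum(tidy(m)$n_train), 10L)
})

test_that("KNN predictions follow the brute-force neighbour definition and
           the deterministic tie rules", {
  x <- matrix(c(0, 1, 10), dimnames = list(1:3, NULL))
  m <- knn_fit(x, c("+", "+", "-"), k = 1, standardize = FALSE)
  expect_equal(predict(m, matrix(0.4))$.pred, "+")
  # k = n: global majority regardless of query
  m3 <- knn_fit(x, c("+", "+", "-"), k = 3, standardize = FALSE)
  expect_equal(predict(m3, matrix(1e6))$.pred, "+")
  # k=1 re-query of a training point returns its own class
  tr <- matrix(rnorm(20), 10, 2, dimnames = list(1:10, NULL))
  yy <- rep(c("a", "b"), 5)
  m1 <- knn_fit(tr, yy, k = 1)
  expect_equal(predict(m1, tr)$.pred, yy)
  # equidistant neighbours at the k-th rank: first-sorting id included
  xt <- matrix(c(0, 1, -1), dimnames = list(c("10", "2", "3"), NULL))
  mt <- knn_fit(xt, c("p", "n", "p"), k = 1, standardize = FALSE)
  nb <- predict(mt, matrix(0.0))$neighbors[[1]]
  expect_equal(nb$id, "10") # distance 0 beats the ties
  mt2 <- knn_fit(matrix(c(1, -1, 5), dimnames = list(c("5", "walnut", "9"),
                                                     NULL)),
                 c("p", "n", "p"), k = 1, standardize = FALSE)
  nb2 <- predict(mt2, matrix(0.0))$neighbors[[1]]
  expect_equal(nb2$id, "5") # "5" sorts before "walnut"
  # even-k vote tie falls back to the nearest neighbour's class
  m2 <- knn_fit(matrix(c(0, 3), dimnames = list(1:2, NULL)), c("p", "n"),
                k = 2, standardize = FALSE)
  expect_equal(predict(m2, matrix(1))$.pred, "p")
  expect_equal(predict(m2, matrix(2.5))$.pred, "n")
})

test_that("Euclidean KNN agrees with an independent implementation", {
  skip_if_not_installed("class")
  set.seed(9)
  xtr <- matrix(rnorm(100), 50, 2)
  ytr <- ifelse(xtr[, 1] + rnorm(50, sd = 0.3) > 0, "hi", "lo")
  xte <- matrix(rnorm(40), 20, 2)
  for (k in c(1L, 5L)) {
    mine <- predict(knn_fit(xtr, ytr, k = k, standardize = FALSE), xte,
                    detail = FALSE)$.pred
    ref <- as.character(class::knn(xtr, xte, ytr, k = k))
    expect_equal(mine, ref, label = paste("k =", k))
  }
})

test_that("self-exclusion changes in-sample scoring as expected", {
  set.seed(3)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(1:30, NULL))
  y <- rep(c("p", "n"), 15)
  m <- knn_fit(x, y, k = 1)
  with_self <- predict(m, x)$.pred
  expect_equal(with_self, y) # k=1 with self included is always perfect
  without <- predict(m, x, exclude_self = TRUE)$.pred
  expect_true(mean(without == y) < 1)
})

test_that("consensus majority vote and its guard rails work", {
  x <- matrix(c(0, 1, 10, 11), dimnames = list(1:4, NULL))
  y <- c("p", "p", "n", "n")
  a <- knn_fit(x, y, k = 1, standardize = FALSE)
  b <- knn_fit(x, y, k = 3, standardize = FALSE)
  cm <- consensus_model(list(A = a, B = b, C = a))
  pr <- predict(cm, matrix(c(0.2, 10.5)))
  expect_equal(pr$.pred, c("p", "n"))
  # identical members equal the member
  same <- consensus_model(list(a, a, a))
  expect_equal(predict(same, matrix(c(0.2, 10.5)))$.pred,
               predict(a, matrix(c(0.2, 10.5)))$.pred)
  expect_error(consensus_model(list(a)), "2")
  flipped <- knn_fit(x, c("x", "y", "x", "y"), k = 1, standardize = FALSE)
  expect_error(consensus_model(list(a, flipped)), "same label set")
  # even-count tie errors unless a tie member is configured
  opp <- knn_fit(x, rev(y), k = 1, standardize = FALSE)
  even <- consensus_model(list(A = a, B = opp))
  expect_error(predict(even, matrix(0.2)), "tie")
  even2 <- consensus_model(list(A = a, B = opp), tie = "A")
  expect_equal(predict(even2, matrix(0.2))$.pred, "p")
})

test_that("GA selection is seeded, elitist, and size-bounded", {
  d <- synthetic_classification(n_per_class = 30, n_informative = 2,
                                n_noise = 10, effect = 3, seed = 5)
  cfg <- ga_config(max_features = 4, population = 12, generations = 5,
                   seed = 5)
  g1 <- ga_select(d$x, d$y, "pos", cfg)
  g2 <- ga_select(d$x, d$y, "pos", cfg)
  expect_identical(g1$history, g2$history) # same seed, same trajectory
  expect_false(is.unsorted(g1$history$best_fitness)) # elitism
  expect_lte(length(g1$best_idx), 4L)
  sizes <- vapply(g1$final_population, sum, integer(1))
  expect_true(all(sizes <= 4L))
  expect_error(
    ga_select(d$x, d$y, "pos", ga_config(max_features = 99)),
    "max_features"
  )
})
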