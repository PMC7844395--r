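test_that("projections are uniform m-subsets and reproducible", {
  set.seed(1)
  expect_identical(draw_projection(5, 5), 1:5)
  expect_error(draw_projection(5, 6), "exceeds")
  set.seed(42); a <- draw_projection(100, 10)
  set.seed(42); b <- draw_projection(100, 10)
  expect_identical(a, b)
  set.seed(3)
  freq <- tabulate(replicate(5000, draw_projection(10, 2)), nbins = 10) /
    (5000 * 2)
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("stratified splits preserve classes and balance the training part", {
  y <- rep(c(0, 1), c(100, 100))
  set.seed(9)
  sp <- split_train_test(y, 2 / 3, "full")
  expect_true(all(table(y[sp$train]) %in% 66:67))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(all(sort(c(sp$train, sp$test)) == seq_along(y)))

  y2 <- rep(c(1, 0), c(50, 5000))
  set.seed(9)
  sp2 <- split_train_test(y2, 2 / 3, "balanced")
  counts <- table(y2[sp2$train])
  expect_identical(unname(counts[1]), unname(counts[2]))
  # test part keeps the natural imbalance of the held-out fraction
  expect_gt(sum(y2[sp2$test] == 0), 1000)

  set.seed(7); a <- split_train_test(y, 0.5, "full")
  set.seed(7); b <- split_train_test(y, 0.5, "full")
  expect_identical(a, b)
  expect_error(split_train_test(c(0, 1, 1), 0.5), "fewer than 2")
})

test_that("trees handle pure, separable, and degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  pure <- build_tree(X, rep(1L, 10), min_leaf = 2)
  expect_identical(pure$feature, 0L)
  expect_identical(pure$pred, 1L)

  y <- rep(c(0L, 1L), each = 10)
  Xs <- cbind(noise = rnorm(20), signal = y + rnorm(20, sd = 0.01))
  sep <- build_tree(Xs, y, min_leaf = 2)
  expect_identical(sep$feature[1], 2L)       # splits on the separating column
  expect_equal(sep$gain[1], 1, tolerance = 1e-9)  # full 1-bit entropy drop
  expect_identical(predict(sep, Xs), y)

  const <- build_tree(matrix(1, 20, 3), y, min_leaf = 2)
  expect_identical(const$feature, 0L)        # no positive gain: single leaf
  expect_identical(const$pred, 0L)           # majority tie resolved to 0
})

test_that("tree split ties break on the lowest feature index", {
  y <- rep(c(0L, 1L), each = 6)
  x <- c(rep(0, 6), rep(1, 6))
  X <- cbind(a = x, b = x)                   # identical separating features
  tr <- build_tree(X, y, min_leaf = 2)
  expect_identical(tr$feature[1], 1L)
})

test_that("weighted accuracy is the mean of per-class recalls", {
  y <- rep(c(0L, 1L), each = 10)
  X <- cbind(sig = y)
  tr <- build_tree(X, y, min_leaf = 2)
  expect_identical(weighted_accuracy(tr, X, y), 1)
  # constant predictor on a balanced test set scores 0.5
  leaf <- build_tree(matrix(0, 4, 1), rep(0L, 4), min_leaf = 2)
  expect_equal(weighted_accuracy(leaf, X, y), 0.5, tolerance = 1e-12)
  expect_error(weighted_accuracy(tr, X, rep(0L, 20)), "both classes")
})

test_that("relative importance aggregates additively over trees", {
  y <- rep(c(0L, 1L), each = 10)
  X <- cbind(sig = as.numeric(y))
  tr <- build_tree(X, y, min_leaf = 2)
  entry <- list(tree = tr, wacc = 0.9, features = 5L)
  ri <- relative_importance(list(entry), d = 6, u = 1, v = 1)
  expect_equal(ri[5], 0.9 * 1 * 1, tolerance = 1e-9)  # wAcc * IG * frac
  expect_identical(ri[-5], rep(0, 5))
  ri2 <- relative_importance(list(entry, entry), d = 6)
  expect_equal(ri2, 2 * ri, tolerance = 1e-12)
})

test_that("a full run is deterministic and finds a label-aligned feature", {
  set.seed(21)
  n <- 120; d <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[, 17] <- y + rnorm(n, sd = 0.05)
  p <- mcfs_params(s_projections = 60, t_splits = 2, seed = 31)
  r1 <- run_mcfs(X, y, p)
  r2 <- run_mcfs(X, y, p)
  expect_identical(r1, r2)
  expect_identical(r1$rank[17], 1L)
  expect_true(all(r1$RI >= 0))
})

test_that("the permutation cutoff is non-negative and flags the planted feature", {
  set.seed(4)
  n <- 100; d <- 25
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[, 3] <- y * 2 + rnorm(n, sd = 0.2)
  p <- mcfs_params(s_projections = 40, t_splits = 2, n_permutations = 10,
                   seed = 11)
  r <- mcfs_select(X, y, p)
  expect_gte(attr(r, "cutoff"), 0)
  expect_true(r$significant[r$feature_id == "f3"])
  expect_error(permutation_threshold(X, y, mcfs_params(n_permutations = 1)),
               "at least 2")
})
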