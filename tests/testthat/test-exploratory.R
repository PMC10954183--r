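test_that("PCA recovers closed-form eigenstructure", {
  # two perfectly correlated columns -> PC1 carries all variance
  set.seed(1)
  v <- rnorm(50)
  p <- fit_pca(scale(cbind(v, 2 * v + 1)))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  # hand-built 3x3 covariance via its known decomposition:
  # eigenvalues 3, 2, 1 with orthonormal eigenvectors Q
  q <- cbind(c(1, 1, 1) / sqrt(3), c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  s <- q %*% diag(c(3, 2, 1)) %*% t(q)
  # generate data with exactly this sample covariance: x = z %*% chol(s) with
  # z whitened
  set.seed(2)
  z <- matrix(rnorm(300), 100, 3)
  z <- sweep(z, 2, colMeans(z), "-")
  z <- z %*% solve(chol(cov(z)))
  x <- z %*% chol(s)
  p3 <- fit_pca(x)
  expect_equal(p3$eigenvalues, c(3, 2, 1), tolerance = 1e-8)
  expect_error(fit_pca(matrix(1, 1, 3)), "at least 2")
})

test_that("PCA invariants hold on synthetic collections", {
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 4, n = 30)))
  p <- fit_pca(gm)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(unname(crossprod(p$loadings)), diag(15), tolerance = 1e-8)
  # scores' covariance is diagonal with the eigenvalues
  expect_equal(unname(cov(p$scores)), diag(p$eigenvalues), tolerance = 1e-8)
  # deterministic sign convention: dominant loading positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  tab <- pca_table(p)
  expect_equal(tab$cumulative_pct[15], 100, tolerance = 1e-8)
})

test_that("classification tree separates separable data and counts nodes", {
  x <- matrix(c(1:10, 21:30), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  tr <- grow_tree(x, y, min_leaf = 1)
  expect_equal(tr$accuracy, 1)
  expect_equal(tr$n_nodes, 3)
  expect_equal(tr$n_decision, 1)
  expect_equal(tr$n_terminal, 2)
  expect_equal(tr$n_nodes, tr$n_decision + tr$n_terminal)
  expect_identical(predict(tr, matrix(c(0, 100), ncol = 1)), c("a", "b"))
  # single-class input -> degenerate single leaf, not an error
  tr1 <- grow_tree(x, rep("a", 20))
  expect_equal(tr1$n_nodes, 1)
  expect_equal(tr1$accuracy, 1)
  # depth-0: accuracy equals the majority-class fraction
  y3 <- rep(c("a", "b", "c"), c(10, 6, 4))
  tr0 <- grow_tree(matrix(rnorm(20), ncol = 1), y3, max_depth = 0)
  expect_equal(tr0$accuracy, 0.5)
})

test_that("tree root split matches the exhaustive split-search oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(round(rnorm(40), 1), ncol = 2)
    y <- sample(c("a", "b"), 20, replace = TRUE)
    oracle <- brute_force_split(x, y, min_leaf = 2)
    tr <- grow_tree(x, y, max_depth = 1, min_leaf = 2)
    if (is.null(oracle)) {
      expect_equal(tr$n_nodes, 1)
    } else {
      expect_equal(tr$nodes$var[1], oracle$var)
      expect_equal(tr$nodes$threshold[1], oracle$threshold)
    }
  }
})

test_that("tree training accuracy is non-decreasing in max_depth", {
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 4, n = 25, seed = 9)))
  accs <- vapply(0:4, function(d) grow_tree(gm, gm$group, max_depth = d)$accuracy,
                 numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("stratified split honours fractions, determinism and validity", {
  labels <- rep(c("a", "b", "c", "d"), each = 25)
  sp <- split_train_validation(labels, fraction = 0.75, seed = 3)
  expect_equal(length(sp$train), 75)
  expect_equal(length(sp$validation), 25)
  per_class <- table(labels[sp$train])
  expect_true(all(per_class %in% c(18, 19)))
  expect_identical(sp, split_train_validation(labels, fraction = 0.75, seed = 3))
  expect_false(identical(sp$train,
                         split_train_validation(labels, seed = 4)$train))
  expect_setequal(c(sp$train, sp$validation), seq_along(labels))
  expect_error(split_train_validation(c("a", "a", "b")), "single member.*b")
  # long-run validation membership is ~25% per grain
  hits <- integer(16)
  for (s in 1:300) {
    v <- split_train_validation(rep(c("a", "b"), each = 8), seed = s)$validation
    hits[v] <- hits[v] + 1
  }
  # 6 of 8 per class train -> every grain validates 25% of the time
  expect_true(all(abs(hits / 300 - 0.25) < 0.1))
})

test_that("confusion matrix counts, precision and margins are correct", {
  truth <- c("a", "a", "b", "b", "c", "c")
  cm <- confusion(truth, truth)
  expect_equal(sum(diag(cm$table)), 6)
  expect_true(all(cm$precision == 1))
  expect_equal(cm$accuracy, 1)
  swapped <- c("b", "b", "a", "a", "c", "c")
  cm2 <- confusion(truth, swapped)
  expect_equal(unname(cm2$precision[c("a", "b")]), c(0, 0))
  # hand tally on a 3-class fixture
  tr <- c("a", "a", "a", "b", "b", "c")
  pr <- c("a", "b", "b", "b", "c", "c")
  cm3 <- confusion(tr, pr)
  expect_equal(unname(unclass(cm3$table)["a", ]), c(1, 2, 0))
  expect_equal(unname(rowSums(cm3$table)), c(3, 2, 1))   # truth margins
  expect_equal(sum(cm3$table), 6)
  expect_equal(unname(cm3$precision["b"]), 1 / 3)
  expect_equal(unname(rowSums(cm3$normalized)), rep(1, 3))
  expect_error(confusion(tr, pr[-1]), "lengths")
  expect_error(confusion(tr, pr, groups = c("a", "b")), "outside")
})
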