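test_that("pooled covariance and distances match pencil-and-paper values", {
  # 3 groups x 2 points in 2 variables; hand calculation:
  # S_A = [[2,0],[0,0]], S_B = [[0,0],[0,2]], S_C = [[2,2],[2,2]]
  # Sigma = (S_A + S_B + S_C) / 3 = [[4/3, 2/3], [2/3, 4/3]]
  # Sigma^-1 = [[1, -1/2], [-1/2, 1]]
  x <- rbind(c(0, 0), c(2, 0), c(0, 4), c(0, 6), c(4, 4), c(6, 6))
  g <- c("A", "A", "B", "B", "C", "C")
  m <- grain_lda(x, g)
  expect_equal(m$means, rbind(A = c(1, 0), B = c(0, 5), C = c(5, 5)),
               ignore_attr = TRUE)
  expect_equal(m$cov, rbind(c(4 / 3, 2 / 3), c(2 / 3, 4 / 3)),
               ignore_attr = TRUE)
  expect_equal(m$cov_inv, rbind(c(1, -0.5), c(-0.5, 1)), ignore_attr = TRUE)
  # d2 from the origin: to A (1,0): 1; to B (0,5): 25; to C (5,5): 25
  expect_equal(unname(squared_distance(m, c(0, 0))[1, ]), c(1, 25, 25))
  expect_equal(squared_distance(m, c(0, 5), "B"), 0, ignore_attr = TRUE)
  # coef() reproduces score(x, k) = m_k' S^-1 x - 0.5 m_k' S^-1 m_k + log pi_k
  cf <- coef(m)
  xs <- c(1.5, -2)
  expect_equal(drop(cf["constant", ] + xs %*% cf[-1, ]),
               drop(predict(m, xs)$score[1, ]))
})

test_that("two-group symmetric problems place the boundary midway", {
  set.seed(5)
  x <- matrix(c(rnorm(200, 0), rnorm(200, 2)), ncol = 1)
  g <- rep(c("lo", "hi"), each = 200)
  m <- grain_lda(x, g)
  # posterior at the midpoint of the *estimated* means is exactly 0.5
  mid <- mean(m$means)
  expect_equal(unname(posteriors(m, mid)[1, ]), c(0.5, 0.5))
  # identical group means -> posteriors equal priors everywhere
  m2 <- grain_lda(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                  c("A", "A", "B", "B"))
  expect_equal(unname(posteriors(m2, c(5, -3))[1, ]), c(0.5, 0.5))
  pr <- c(A = 0.9, B = 0.1)
  m3 <- grain_lda(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                  c("A", "A", "B", "B"), prior = pr)
  expect_equal(posteriors(m3, c(5, -3))[1, ], pr)
})

test_that("squared distances equal the explicit quadratic form", {
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 3, n = 20)))
  m <- grain_lda(gm)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(15)
    d2 <- squared_distance(m, x)
    for (k in seq_along(m$levels)) {
      v <- x - m$means[k, ]
      expect_equal(unname(d2[1, k]), drop(t(v) %*% m$cov_inv %*% v),
                   tolerance = 1e-10)
    }
  }
})

test_that("posteriors match the logistic closed form in two groups", {
  set.seed(6)
  x <- matrix(rnorm(60, rep(c(0, 2), each = 30)), ncol = 1)
  g <- rep(c("A", "B"), each = 30)
  m <- grain_lda(x, g)
  xs <- matrix(seq(-2, 4, by = 0.5), ncol = 1)
  p <- posteriors(m, xs)
  sc <- predict(m, xs)$score
  expect_equal(p[, "A"], plogis(sc[, "A"] - sc[, "B"]), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(rowSums(p), rep(1, nrow(xs)), tolerance = 1e-12)
})

test_that("classification ranks coherently and recovers group means", {
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 5, n = 20)))
  m <- grain_lda(gm)
  res <- classify_grains(m, m$means, grain_id = m$levels)
  expect_identical(res$group1, m$levels)  # each mean goes to its own group
  post <- attr(classify_grains(m, gm$x), "posterior")
  expect_true(all(abs(rowSums(post) - 1) < 1e-10))
  res2 <- classify_grains(m, gm$x)
  expect_true(all(res2$prob1 >= res2$prob2))
  expect_true(all(res2$dist2_1 >= 0))
  # under equal priors the rankings agree: score vs -d2 exactly, and the
  # two reported best groups also lead the posterior ordering (posteriors
  # further down can underflow to exactly zero)
  sc <- attr(res2, "score"); d2 <- attr(res2, "d2")
  post2 <- attr(res2, "posterior")
  for (i in seq_len(nrow(sc))) {
    expect_equal(order(sc[i, ], decreasing = TRUE), order(d2[i, ]))
    so <- order(sc[i, ], decreasing = TRUE)
    expect_equal(unname(which.max(post2[i, ])), so[1])
    if (post2[i, so[2]] > 1e-300) {
      expect_equal(order(post2[i, ], decreasing = TRUE)[2], so[2])
    }
  }
})

test_that("classify agrees with brute-force Gaussian Bayes posteriors", {
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 4, n = 25)))
  m <- grain_lda(gm)
  # independent oracle: explicit pooled-covariance Gaussian densities
  set.seed(13)
  xs <- matrix(rnorm(200 * 15), ncol = 15)
  logd <- sapply(seq_along(m$levels), function(k) {
    apply(xs, 1, function(x) {
      v <- x - m$means[k, ]
      -0.5 * drop(t(v) %*% solve(m$cov) %*% v)
    })
  })
  dens <- exp(logd - apply(logd, 1, max))
  oracle_post <- dens / rowSums(dens)  # equal priors
  expect_equal(unname(posteriors(m, xs)), unname(oracle_post), tolerance = 1e-10)
})

test_that("predictions agree with an established LDA implementation", {
  skip_if_not_installed("MASS")
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 13, n = 30, seed = 3)))
  m <- grain_lda(gm)
  ml <- MASS::lda(gm$x, grouping = gm$group)
  agree <- mean(predict(m, gm$x)$class ==
                  as.character(predict(ml, gm$x)$class))
  expect_gte(agree, 0.99)
})

test_that("degenerate fits are rejected with informative errors", {
  expect_error(grain_lda(matrix(rnorm(10), ncol = 2),
                         c("a", "a", "a", "a", "b")), "fewer than 2")
  # duplicated column -> singular pooled covariance
  x <- cbind(rnorm(20), 0)
  x[, 2] <- x[, 1]
  g <- rep(c("a", "b"), 10)
  expect_error(grain_lda(x, g), "singular")
  expect_message(m <- grain_lda(x, g, ridge = 1e-6), "ridge")
  expect_true(m$ridged)
  expect_error(predict(grain_lda(matrix(rnorm(20), ncol = 2),
                                 rep(c("a", "b"), 5)),
                       matrix(1, 1, 3)), "dimension")
})

test_that("estimated group means converge at the root-n rate", {
  prof <- separated_profiles(3, 50)
  rmse_at <- function(n) {
    profs <- lapply(prof, function(p) { p$n <- n; p })
    ref <- generate_reference(profs, seed = 21)
    gm <- assemble_matrix(ref)
    # raw (unscaled) size means vs the generating lognormal mean
    err <- vapply(names(profs), function(s) {
      mu <- exp(profs[[s]]$lmax_meanlog + profs[[s]]$lmax_sdlog^2 / 2)
      mean(gm$x[gm$group == s, "l_max_um"]) - mu
    }, numeric(1))
    sqrt(mean(err^2))
  }
  r_small <- rmse_at(50)
  r_big <- rmse_at(5000)
  # 100-fold n increase -> ~10-fold RMSE drop; allow generous slack
  expect_lt(r_big, r_small / 3)
})

test_that("simulate draws from the fitted class-conditional model", {
  gm <- scale_matrix(assemble_matrix(toy_collection(k = 3, n = 30)))
  m <- grain_lda(gm)
  sim <- simulate(m, nsim = 2000, seed = 77)
  expect_equal(nrow(sim), 6000)
  for (g in m$levels) {
    mu_hat <- colMeans(sim[sim$group == g, -1])
    expect_lt(max(abs(mu_hat - m$means[g, ])), 0.15)
  }
  expect_identical(sim, simulate(m, nsim = 2000, seed = 77))
  expect_error(simulate(m, groups = "nope"), "unknown group")
})
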