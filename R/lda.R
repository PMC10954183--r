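#' Fit a pooled-covariance linear discriminant model
#'
#' From-scratch linear discriminant analysis on a (scaled) feature matrix.
#' Estimates per-group mean vectors and the pooled within-group covariance
#' `Sigma = sum_k (n_k - 1) S_k / (n - K)`, and derives for every group k the
#' linear classification function
#' `score_k(x) = m_k' Sigma^-1 x - 0.5 m_k' Sigma^-1 m_k + log(prior_k)`.
#' Classification by highest score is equivalent to lowest squared
#' Mahalanobis distance `(x - m_k)' Sigma^-1 (x - m_k)` under equal priors,
#' and posteriors are `prior_k * exp(-d2_k / 2)` renormalized (computed in
#' log space).
#'
#' @param x Numeric matrix of observations (or a `grain_matrix`, whose group
#'   labels are used when `grouping` is missing).
#' @param grouping Group label per row.
#' @param prior Per-group prior probabilities: `"equal"` (default),
#'   `"proportional"` (group frequencies), or a named numeric vector
#'   summing to 1.
#' @param ridge Ridge constant added to the pooled covariance diagonal when
#'   it is numerically singular; `0` disables the fallback and a singular
#'   covariance is an error. A message is emitted whenever ridging is
#'   applied.
#' @return A `grain_lda` object with components `levels`, `counts`, `prior`,
#'   `means` (K x p), `cov`, `cov_inv`, `coef` (p x K discriminant
#'   coefficients) and `const` (per-group constants).
#' @seealso [predict.grain_lda()], [classify_grains()], [squared_distance()]
#' @export
grain_lda <- function(x, grouping = NULL, prior = c("equal", "proportional"),
                      ridge = 0) {
  if (inherits(x, "grain_matrix")) {
    if (is.null(grouping)) grouping <- x$group
    x <- x$x
  }
  x <- as.matrix(x)
  grouping <- as.character(grouping)
  stopifnot(nrow(x) == length(grouping))
  lev <- sort(unique(grouping))
  counts <- table(factor(grouping, levels = lev))
  if (any(counts < 2)) {
    stop_domain("grain_lda: group(s) with fewer than 2 observations: %s",
                paste(lev[counts < 2], collapse = ", "))
  }
  n <- nrow(x); K <- length(lev); p <- ncol(x)
  means <- matrix(NA_real_, K, p, dimnames = list(lev, colnames(x)))
  pooled <- matrix(0, p, p)
  for (k in seq_len(K)) {
    xk <- x[grouping == lev[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    pooled <- pooled + crossprod(sweep(xk, 2, means[k, ], "-"))
  }
  pooled <- pooled / (n - K)
  dimnames(pooled) <- list(colnames(x), colnames(x))

  if (is.character(prior)) {
    prior <- match.arg(prior)
    pr <- if (prior == "equal") rep(1 / K, K) else as.numeric(counts) / n
    names(pr) <- lev
  } else {
    pr <- prior[lev]
    if (anyNA(pr) || abs(sum(pr) - 1) > 1e-8) {
      stop_domain("grain_lda: numeric prior must name every group and sum to 1")
    }
  }

  safe_inv <- function(s) {
    rc <- tryCatch(rcond(s), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) return(NULL)
    tryCatch(chol2inv(chol(s)), error = function(e) NULL)
  }
  inv <- safe_inv(pooled)
  ridged <- FALSE
  if (is.null(inv)) {
    if (ridge > 0) {
      message(sprintf("grain_lda: pooled covariance singular; applying ridge %g", ridge))
      pooled <- pooled + diag(ridge, p)
      inv <- safe_inv(pooled)
      ridged <- TRUE
    }
    if (is.null(inv)) {
      stop_domain(paste0("grain_lda: pooled covariance is singular ",
                         "(try the 'ridge' option, e.g. ridge = 1e-8)"))
    }
  }
  dimnames(inv) <- dimnames(pooled)
  coef <- inv %*% t(means)                       # p x K
  const <- -0.5 * colSums(t(means) * coef) + log(pr)
  structure(list(levels = lev, counts = as.integer(counts), n = n, p = p,
                 prior = pr, means = means, cov = pooled, cov_inv = inv,
                 coef = coef, const = const, ridged = ridged,
                 ridge = if (ridged) ridge else 0),
            class = "grain_lda")
}

#' @export
print.grain_lda <- function(x, ...) {
  cat(sprintf("Linear discriminant model: %d groups, %d variables, n = %d\n",
              length(x$levels), x$p, x$n))
  cat("Groups:", paste(sprintf("%s (%d)", x$levels, x$counts), collapse = ", "), "\n")
  cat("Priors:", if (length(unique(x$prior)) == 1) "equal" else
      paste(sprintf("%s=%.3f", x$levels, x$prior), collapse = ", "), "\n")
  if (x$ridged) cat(sprintf("Pooled covariance ridged (lambda = %g)\n", x$ridge))
  invisible(x)
}

#' @export
summary.grain_lda <- function(object, ...) {
  structure(list(model = object), class = "summary.grain_lda")
}

#' @export
print.summary.grain_lda <- function(x, ...) {
  print(x$model)
  cat("\nGroup means (first variables):\n")
  print(round(x$model$means[, seq_len(min(5, x$model$p)), drop = FALSE], 3))
  invisible(x)
}

#' Discriminant function coefficients
#'
#' @param object A `grain_lda`.
#' @param ... Unused.
#' @return Matrix with one column per group: the constant term in the first
#'   row, then the p linear coefficients of the classification function.
#' @export
coef.grain_lda <- function(object, ...) {
  rbind(constant = object$const, object$coef)
}

#' Squared Mahalanobis distance to a group centroid
#'
#' `(x - m_k)' Sigma^-1 (x - m_k)` under the pooled covariance.
#'
#' @param model A `grain_lda`.
#' @param x Numeric vector or matrix of observations.
#' @param group Group label(s); if omitted, distances to all groups.
#' @return If `group` given, numeric vector; otherwise n x K matrix.
#' @export
squared_distance <- function(model, x, group = NULL) {
  stopifnot(inherits(model, "grain_lda"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != model$p) stop_domain("squared_distance: dimension mismatch")
  d2 <- matrix(NA_real_, nrow(x), length(model$levels),
               dimnames = list(rownames(x), model$levels))
  for (k in seq_along(model$levels)) {
    d <- sweep(x, 2, model$means[k, ], "-")
    d2[, k] <- rowSums((d %*% model$cov_inv) * d)
  }
  if (!is.null(group)) {
    j <- match(group, model$levels)
    if (anyNA(j)) stop_domain("squared_distance: unknown group")
    if (length(j) == 1) d2[, j] else d2[cbind(seq_len(nrow(x)), j)]
  } else d2
}

#' Posterior group probabilities
#'
#' `prior_k * exp(-d2_k / 2)` renormalized over groups, evaluated in log
#' space for numerical stability.
#'
#' @param model A `grain_lda`.
#' @param x Numeric vector or matrix of observations.
#' @return n x K matrix of posteriors; each row sums to 1.
#' @export
posteriors <- function(model, x) {
  d2 <- squared_distance(model, x)
  lp <- sweep(-d2 / 2, 2, log(model$prior), "+")
  t(apply(lp, 1, function(r) exp(r - logsumexp(r))))
}

#' Predict from a linear discriminant model
#'
#' @param object A `grain_lda`.
#' @param newdata Numeric matrix (or `grain_matrix`) of observations.
#' @param ... Unused.
#' @return List with `class` (highest-posterior group, posterior ties broken
#'   by group name), `posterior` (n x K), `score` (n x K linear
#'   classification-function values) and `d2` (n x K squared Mahalanobis
#'   distances).
#' @export
predict.grain_lda <- function(object, newdata, ...) {
  if (inherits(newdata, "grain_matrix")) newdata <- newdata$x
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != object$p) stop_domain("predict.grain_lda: dimension mismatch")
  score <- sweep(x %*% object$coef, 2, object$const, "+")
  d2 <- squared_distance(object, x)
  post <- posteriors(object, x)
  # ranking by linear score is identical to ranking by posterior
  # (score_k = log prior_k - d2_k/2 + h(x)) but never underflows;
  # exact ties resolved by group order (lexicographic)
  cls <- object$levels[apply(score, 1, which.max)]
  list(class = cls, posterior = post, score = score, d2 = d2)
}

#' Classify grains with ranked two-best-group reporting
#'
#' Runs [predict.grain_lda()] and reports, per grain, the two highest-scoring
#' groups with their linear classification-function value, squared
#' Mahalanobis distance, and posterior probability — the standard reporting
#' layout for discriminant identification of unknowns.
#'
#' @param model A `grain_lda`.
#' @param x Observations (matrix or `grain_matrix`).
#' @param grain_id Optional ids; defaults to rownames or row numbers.
#' @return A `grain_classification` data frame with columns `grain_id`,
#'   `group1`, `value1`, `dist2_1`, `prob1`, `group2`, `value2`, `dist2_2`,
#'   `prob2`. The full posterior/score/distance matrices are kept in
#'   attributes `posterior`, `score`, `d2`.
#' @export
classify_grains <- function(model, x, grain_id = NULL) {
  if (inherits(x, "grain_matrix")) {
    if (is.null(grain_id)) grain_id <- x$grain_id
    x <- x$x
  }
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (is.null(grain_id)) grain_id <- rownames(x) %||% as.character(seq_len(nrow(x)))
  pr <- predict(model, x)
  K <- length(model$levels)
  pick <- t(apply(pr$score, 1, order, decreasing = TRUE))
  r1 <- pick[, 1]; r2 <- if (K > 1) pick[, 2] else pick[, 1]
  i <- seq_len(nrow(x))
  out <- data.frame(
    grain_id = grain_id,
    group1 = model$levels[r1],
    value1 = pr$score[cbind(i, r1)],
    dist2_1 = pr$d2[cbind(i, r1)],
    prob1 = pr$posterior[cbind(i, r1)],
    group2 = model$levels[r2],
    value2 = pr$score[cbind(i, r2)],
    dist2_2 = pr$d2[cbind(i, r2)],
    prob2 = pr$posterior[cbind(i, r2)],
    stringsAsFactors = FALSE
  )
  attr(out, "posterior") <- pr$posterior
  attr(out, "score") <- pr$score
  attr(out, "d2") <- pr$d2
  class(out) <- c("grain_classification", "data.frame")
  out
}

#' Resubstitution confusion matrix of a discriminant model
#'
#' Classifies the observations the model was fitted on (or any labelled set)
#' and tabulates predictions against the true labels.
#'
#' @param model A `grain_lda`.
#' @param x Observations.
#' @param labels True group labels.
#' @return A `grain_confusion`.
#' @export
resubstitution_confusion <- function(model, x, labels) {
  if (inherits(x, "grain_matrix")) {
    if (missing(labels) || is.null(labels)) labels <- x$group
    x <- x$x
  }
  confusion(labels, predict(model, x)$class, groups = model$levels)
}

#' Simulate observations from a fitted discriminant model
#'
#' Parametric draws from the fitted class-conditional Gaussians
#' `N(m_k, Sigma)` with the pooled covariance.
#'
#' @param object A `grain_lda`.
#' @param nsim Draws per group.
#' @param seed Optional integer seed (caller's RNG state is restored).
#' @param groups Groups to simulate; default all.
#' @param ... Unused.
#' @return Data frame with a `group` column followed by the p variables.
#' @export
simulate.grain_lda <- function(object, nsim = 1, seed = NULL, groups = NULL, ...) {
  groups <- groups %||% object$levels
  bad <- setdiff(groups, object$levels)
  if (length(bad)) stop_domain("simulate: unknown group(s): %s", paste(bad, collapse = ", "))
  cl <- chol(object$cov)
  out <- with_seed(seed, {
    do.call(rbind, lapply(groups, function(g) {
      z <- matrix(stats::rnorm(nsim * object$p), nsim, object$p) %*% cl
      data.frame(group = g, sweep(z, 2, object$means[g, ], "+"),
                 check.names = FALSE)
    }))
  })
  names(out)[-1] <- colnames(object$means)
  out
}

#' Plot group centroids of a discriminant model
#'
#' Projects the group means onto the two leading principal axes of the
#' Mahalanobis-whitened centroid configuration, so plotted distances
#' approximate pairwise Mahalanobis distances.
#'
#' @param x A `grain_lda`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grain_lda <- function(x, ...) {
  w <- x$means %*% chol(x$cov_inv)
  w <- sweep(w, 2, colMeans(w), "-")
  pc <- svd(w, nu = 2, nv = 0)$u %*% diag(svd(w)$d[1:2])
  graphics::plot(pc, type = "n", xlab = "axis 1 (Mahalanobis)",
                 ylab = "axis 2 (Mahalanobis)", ...)
  graphics::text(pc, labels = x$levels, cex = 0.8)
  invisible(x)
}
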