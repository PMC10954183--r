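#' Principal component analysis of a scaled feature matrix
#'
#' Eigendecomposition of the covariance matrix of the z-scored data (i.e. the
#' correlation matrix of the raw measurements). The sign of each component is
#' fixed so that its largest-magnitude loading is positive, making results
#' deterministic across platforms.
#'
#' @param gm A scaled `grain_matrix`, or a plain numeric matrix of z-scores.
#' @return A `grain_pca` object: `eigenvalues` (descending), `variance_fraction`
#'   (sums to 1), `loadings` (p x p orthonormal), `scores` (n x p).
#' @export
fit_pca <- function(gm) {
  x <- if (inherits(gm, "grain_matrix")) {
    if (!gm$scaled) stop_domain("fit_pca: matrix must be scaled first")
    gm$x
  } else as.matrix(gm)
  if (nrow(x) < 2) stop_domain("fit_pca: need at least 2 observations")
  s <- stats::cov(x)
  e <- eigen(s, symmetric = TRUE)
  val <- pmax(e$values, 0)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(x), paste0("PC", seq_len(ncol(vec))))
  structure(list(
    eigenvalues = val,
    variance_fraction = val / sum(val),
    loadings = vec,
    scores = sweep(x, 2, colMeans(x), "-") %*% vec
  ), class = "grain_pca")
}

#' @export
print.grain_pca <- function(x, k = 5, ...) {
  k <- min(k, length(x$eigenvalues))
  cat("Principal component analysis (correlation matrix)\n")
  tab <- data.frame(
    eigenvalue = round(x$eigenvalues[1:k], 4),
    proportion = round(100 * x$variance_fraction[1:k], 2),
    cumulative = round(100 * cumsum(x$variance_fraction)[1:k], 2)
  )
  rownames(tab) <- paste0("PC", 1:k)
  print(tab)
  invisible(x)
}

#' Eigenvalue table of a PCA
#'
#' Per-component eigenvalue, percentage of variance and cumulative
#' percentage, in the layout of a standard PCA summary table.
#'
#' @param pca A `grain_pca`.
#' @return Data frame with columns `component`, `eigenvalue`, `proportion_pct`,
#'   `cumulative_pct`.
#' @export
pca_table <- function(pca) {
  stopifnot(inherits(pca, "grain_pca"))
  data.frame(
    component = paste0("PC", seq_along(pca$eigenvalues)),
    eigenvalue = pca$eigenvalues,
    proportion_pct = 100 * pca$variance_fraction,
    cumulative_pct = 100 * cumsum(pca$variance_fraction)
  )
}

#' Stratified train/validation split
#'
#' Splits observations into a training and a validation set stratified by
#' class: each class contributes `fraction` of its members to training
#' (largest-remainder apportionment, so the overall fraction is honoured
#' exactly when attainable). Reproducible given `seed`.
#'
#' @param labels Class label per observation.
#' @param fraction Training fraction, default 0.75.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_train_validation <- function(labels, fraction = 0.75, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop_domain("split_train_validation: class(es) with a single member: %s",
                paste(names(tab)[tab < 2], collapse = ", "))
  }
  ideal <- as.numeric(tab) * fraction
  take <- floor(ideal)
  rem <- ideal - take
  short <- round(sum(ideal)) - sum(take)
  if (short > 0) {
    extra <- order(rem, decreasing = TRUE)[seq_len(short)]
    take[extra] <- take[extra] + 1
  }
  take <- pmin(pmax(take, 1), as.numeric(tab) - 1)  # keep both sides non-empty
  train <- integer(0)
  with_seed(seed, {
    for (i in seq_along(tab)) {
      idx <- which(labels == names(tab)[i])
      train <- c(train, sort(sample(idx, take[i])))
    }
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' Confusion matrix with per-group precision and recall
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels (same length; must be drawn from
#'   the union of observed groups unless `groups` is given).
#' @param groups Optional fixed group ordering.
#' @return A `grain_confusion` object: `table` (truth rows x predicted
#'   columns), `precision`, `recall` (per group), `normalized` (rows sum to 1,
#'   heatmap-ready), `accuracy`.
#' @export
confusion <- function(truth, predicted, groups = NULL) {
  if (length(truth) != length(predicted)) {
    stop_domain("confusion: 'truth' and 'predicted' lengths differ")
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(groups)) groups <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), groups)
  if (length(bad)) {
    stop_domain("confusion: label(s) outside group set: %s", paste(bad, collapse = ", "))
  }
  tab <- table(factor(truth, levels = groups), factor(predicted, levels = groups))
  names(dimnames(tab)) <- c("truth", "predicted")
  m <- unclass(tab)
  prec <- diag(m) / pmax(colSums(m), 1)
  rec <- diag(m) / pmax(rowSums(m), 1)
  norm <- sweep(m, 1, pmax(rowSums(m), 1), "/")
  structure(list(table = tab, precision = prec, recall = rec,
                 normalized = norm, accuracy = sum(diag(m)) / sum(m)),
            class = "grain_confusion")
}

#' @export
print.grain_confusion <- function(x, ...) {
  print(x$table)
  cat(sprintf("Accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' Heatmap of a confusion matrix
#'
#' Row-normalized confusion matrix drawn with [graphics::image()], truth on
#' the vertical axis.
#'
#' @param x A `grain_confusion`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.grain_confusion <- function(x, ...) {
  m <- x$normalized
  k <- nrow(m)
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "truth", ...)
  graphics::axis(1, seq_len(k), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}
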