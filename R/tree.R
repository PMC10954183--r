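#' Grow a Gini classification tree
#'
#' Greedy binary CART on the numeric-coded 15-variable matrix. At each node
#' every variable/threshold pair (thresholds are midpoints between
#' consecutive observed values) is scored by the decrease in Gini impurity;
#' ties are broken by the lowest variable index, then the lowest threshold,
#' so the tree is fully deterministic. Splitting stops at `max_depth`, when a
#' node is pure, when no admissible split (both children of size
#' `>= min_leaf`) reduces impurity, or when a node holds fewer than
#' `2 * min_leaf` observations.
#'
#' @param x Numeric matrix (or a `grain_matrix`) of predictors.
#' @param labels Class label per row.
#' @param max_depth Maximum tree depth (root = depth 0), default 6.
#' @param min_leaf Minimum observations per leaf, default 5.
#' @return A `grain_tree` object with the node table, node counts
#'   (`n_decision`, `n_terminal`), and resubstitution accuracy.
#' @export
grow_tree <- function(x, labels, max_depth = 6, min_leaf = 5) {
  if (inherits(x, "grain_matrix")) x <- x$x
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), nrow(x) > 0)
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  nodes <- list()
  new_id <- function() length(nodes) + 1L

  majority <- function(idx) {
    cnt <- tabulate(y[idx], nbins = length(classes))
    classes[which.max(cnt)]  # ties -> first (alphabetical) class
  }
  gini_counts <- function(cnt) {
    n <- sum(cnt)
    if (n == 0) return(0)
    1 - sum((cnt / n)^2)
  }

  best_split <- function(idx) {
    n <- length(idx)
    parent_cnt <- tabulate(y[idx], nbins = length(classes))
    parent_imp <- gini_counts(parent_cnt)
    best <- NULL
    best_gain <- 1e-12
    for (j in seq_len(ncol(x))) {
      v <- x[idx, j]
      o <- order(v)
      vs <- v[o]
      ys <- y[idx][o]
      # cumulative class counts after each sorted observation
      cum <- apply(diag(length(classes))[ys, , drop = FALSE], 2, cumsum)
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
      cut_ok <- which(diff(vs) > 0)  # split between distinct adjacent values
      for (i in cut_ok) {
        nl <- i
        nr <- n - i
        if (nl < min_leaf || nr < min_leaf) next
        lc <- cum[i, ]
        rc <- parent_cnt - lc
        gain <- parent_imp - (nl * gini_counts(lc) + nr * gini_counts(rc)) / n
        if (gain > best_gain) {
          best_gain <- gain
          best <- list(var = j, threshold = (vs[i] + vs[i + 1]) / 2, gain = gain)
        }
      }
    }
    best
  }

  build <- function(idx, depth) {
    id <- new_id()
    nodes[[id]] <<- list(id = id, n = length(idx), pred = majority(idx),
                         depth = depth, leaf = TRUE,
                         var = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_)
    pure <- length(unique(y[idx])) == 1
    if (!pure && depth < max_depth && length(idx) >= 2 * min_leaf) {
      sp <- best_split(idx)
      if (!is.null(sp)) {
        left_idx <- idx[x[idx, sp$var] <= sp$threshold]
        right_idx <- setdiff(idx, left_idx)
        nodes[[id]]$leaf <<- FALSE
        nodes[[id]]$var <<- sp$var
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$left <<- build(left_idx, depth + 1)
        nodes[[id]]$right <<- build(right_idx, depth + 1)
      }
    }
    id
  }
  build(seq_len(nrow(x)), 0L)

  node_df <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, n = nd$n, depth = nd$depth, leaf = nd$leaf,
               var = nd$var, threshold = nd$threshold,
               left = nd$left, right = nd$right, pred = nd$pred,
               stringsAsFactors = FALSE)
  }))
  tr <- structure(list(nodes = node_df, classes = classes,
                       var_names = colnames(x),
                       n_nodes = nrow(node_df),
                       n_decision = sum(!node_df$leaf),
                       n_terminal = sum(node_df$leaf),
                       max_depth = max_depth, min_leaf = min_leaf),
                  class = "grain_tree")
  tr$accuracy <- mean(predict(tr, x) == labels)
  tr
}

#' Predict classes from a grain_tree
#'
#' @param object A `grain_tree`.
#' @param newdata Numeric matrix (or `grain_matrix`) with the same columns.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.grain_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "grain_matrix")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  nd <- object$nodes
  vapply(seq_len(nrow(newdata)), function(i) {
    j <- 1L
    while (!nd$leaf[j]) {
      j <- if (newdata[i, nd$var[j]] <= nd$threshold[j]) nd$left[j] else nd$right[j]
    }
    nd$pred[j]
  }, character(1))
}

#' @export
print.grain_tree <- function(x, ...) {
  cat(sprintf("Gini classification tree: %d nodes (%d decision, %d terminal)\n",
              x$n_nodes, x$n_decision, x$n_terminal))
  cat(sprintf("Resubstitution accuracy: %.2f%%\n", 100 * x$accuracy))
  nd <- x$nodes
  for (i in seq_len(nrow(nd))) {
    pad <- strrep("  ", nd$depth[i])
    if (nd$leaf[i]) {
      cat(sprintf("%s[%d] leaf: %s (n=%d)\n", pad, nd$id[i], nd$pred[i], nd$n[i]))
    } else {
      cat(sprintf("%s[%d] %s <= %.4g ? (n=%d)\n", pad, nd$id[i],
                  x$var_names[nd$var[i]] %||% paste0("V", nd$var[i]),
                  nd$threshold[i], nd$n[i]))
    }
  }
  invisible(x)
}
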