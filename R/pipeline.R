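#' Filter a reference collection to its correctly self-classified core
#'
#' Fits a discriminant model on the full reference collection, classifies the
#' same grains by resubstitution, and keeps exactly those whose predicted
#' group equals their true species. The kept subset is the curated library
#' later used to identify unknowns.
#'
#' @param gm Scaled reference `grain_matrix` (or plain matrix with `labels`).
#' @param labels Species label per row (taken from `gm` when omitted).
#' @param prior,ridge Passed to [grain_lda()].
#' @return List with `kept` (integer row indices), `report` (per-species
#'   kept/discarded counts, class `subset_report`), and `model` (the
#'   full-reference `grain_lda`).
#' @export
filter_reference <- function(gm, labels = NULL, prior = "equal", ridge = 0) {
  x <- if (inherits(gm, "grain_matrix")) {
    if (is.null(labels)) labels <- gm$group
    gm$x
  } else as.matrix(gm)
  labels <- as.character(labels)
  model <- grain_lda(x, labels, prior = prior, ridge = ridge)
  pred <- predict(model, x)$class
  kept <- which(pred == labels)
  tab_in <- table(factor(labels, levels = model$levels))
  tab_kept <- table(factor(labels[kept], levels = model$levels))
  if (any(tab_kept < 2)) {
    stop_domain("filter_reference: species reduced below 2 grains: %s",
                paste(model$levels[tab_kept < 2], collapse = ", "))
  }
  report <- data.frame(
    species = model$levels,
    n_input = as.integer(tab_in),
    n_kept = as.integer(tab_kept),
    n_discarded = as.integer(tab_in) - as.integer(tab_kept),
    stringsAsFactors = FALSE
  )
  class(report) <- c("subset_report", "data.frame")
  list(kept = kept, report = report, model = model)
}

#' @export
print.subset_report <- function(x, ...) {
  cat(sprintf("Reference filtering: kept %d of %d grains (%.1f%%)\n",
              sum(x$n_kept), sum(x$n_input), 100 * sum(x$n_kept) / sum(x$n_input)))
  print.data.frame(x)
  invisible(x)
}

#' Classify unknown grains against a curated reference subset
#'
#' Refits the discriminant model on the curated reference subset pooled with
#' the unknowns, which enter as their own group `"Archeo"`. Every unknown is
#' then classified across the reference species plus the Archeo group, so an
#' unknown may match other unknowns better than any reference species. By
#' default unknowns are classified by resubstitution (each contributes to
#' the Archeo mean and pooled covariance); `method = "leave-one-out"` refits
#' the model without the grain being classified.
#'
#' @param subset_x Curated reference observations (matrix or `grain_matrix`).
#' @param subset_labels Species labels of the subset rows.
#' @param unknown_x Unknown observations (>= 2 rows).
#' @param unknown_ids Optional ids for the unknowns.
#' @param method `"resubstitution"` (default) or `"leave-one-out"`.
#' @param prior,ridge Passed to [grain_lda()].
#' @return List with `results` (a `grain_classification` over K+1 groups)
#'   and `model` (the combined-fit `grain_lda`).
#' @export
classify_unknowns <- function(subset_x, subset_labels = NULL, unknown_x,
                              unknown_ids = NULL,
                              method = c("resubstitution", "leave-one-out"),
                              prior = "equal", ridge = 0) {
  method <- match.arg(method)
  if (inherits(subset_x, "grain_matrix")) {
    if (is.null(subset_labels)) subset_labels <- subset_x$group
    subset_x <- subset_x$x
  }
  if (inherits(unknown_x, "grain_matrix")) {
    if (is.null(unknown_ids)) unknown_ids <- unknown_x$grain_id
    unknown_x <- unknown_x$x
  }
  unknown_x <- as.matrix(unknown_x)
  if (nrow(unknown_x) < 2) {
    stop_domain(paste0("classify_unknowns: at least 2 unknowns are required ",
                       "(the Archeo group needs a covariance contribution)"))
  }
  if (is.null(unknown_ids)) {
    unknown_ids <- rownames(unknown_x) %||% paste0("unknown_", seq_len(nrow(unknown_x)))
  }
  comb_x <- rbind(subset_x, unknown_x)
  comb_lab <- c(as.character(subset_labels), rep("Archeo", nrow(unknown_x)))
  model <- grain_lda(comb_x, comb_lab, prior = prior, ridge = ridge)
  if (method == "resubstitution") {
    results <- classify_grains(model, unknown_x, grain_id = unknown_ids)
  } else {
    nref <- nrow(subset_x)
    rows <- lapply(seq_len(nrow(unknown_x)), function(i) {
      m_i <- grain_lda(comb_x[-(nref + i), , drop = FALSE], comb_lab[-(nref + i)],
                       prior = prior, ridge = ridge)
      classify_grains(m_i, unknown_x[i, , drop = FALSE], grain_id = unknown_ids[i])
    })
    results <- do.call(rbind, lapply(rows, as.data.frame))
    class(results) <- c("grain_classification", "data.frame")
  }
  list(results = results, model = model)
}

#' Bin classified unknowns by posterior-probability confidence
#'
#' Partitions classification results into four confidence bins:
#' \itemize{
#'   \item `secure`: posterior > `hi` to a reference species;
#'   \item `archeo_matched`: posterior > `hi` to the Archeo group (the grain
#'     resembles other unknowns more than any reference species);
#'   \item `probable`: posterior in `[lo, hi]`;
#'   \item `unassigned`: posterior < `lo`.
#' }
#'
#' @param results A `grain_classification` (or data frame with `grain_id`,
#'   `group1`, `prob1`).
#' @param hi High-confidence threshold, default 0.90 (strict: exactly `hi`
#'   is "probable").
#' @param lo Low threshold, default 0.80 (inclusive for "probable").
#' @return A `confidence_bins` object: per-bin grain-id lists, per-bin
#'   species tallies, and `counts`.
#' @export
bin_by_confidence <- function(results, hi = 0.90, lo = 0.80) {
  if (hi <= lo) stop_domain("bin_by_confidence: 'hi' must exceed 'lo'")
  stopifnot(all(c("grain_id", "group1", "prob1") %in% names(results)))
  p <- results$prob1
  g <- results$group1
  bin <- ifelse(p > hi & g != "Archeo", "secure",
         ifelse(p > hi, "archeo_matched",
         ifelse(p >= lo, "probable", "unassigned")))
  out <- list(hi = hi, lo = lo,
              grains = split(results$grain_id, factor(bin, levels = c(
                "secure", "archeo_matched", "probable", "unassigned"))),
              species = lapply(split(g, factor(bin, levels = c(
                "secure", "archeo_matched", "probable", "unassigned"))), table),
              counts = c(secure = sum(bin == "secure"),
                         archeo_matched = sum(bin == "archeo_matched"),
                         probable = sum(bin == "probable"),
                         unassigned = sum(bin == "unassigned")))
  class(out) <- "confidence_bins"
  out
}

#' @export
print.confidence_bins <- function(x, ...) {
  cat(sprintf("Confidence bins (hi > %.2f, lo >= %.2f):\n", x$hi, x$lo))
  cat(sprintf("  secure:         %d (to %d species)\n", x$counts["secure"],
              length(x$species$secure)))
  cat(sprintf("  archeo-matched: %d\n", x$counts["archeo_matched"]))
  cat(sprintf("  probable:       %d\n", x$counts["probable"]))
  cat(sprintf("  unassigned:     %d\n", x$counts["unassigned"]))
  invisible(x)
}

#' Species-by-artifact contingency table
#'
#' Tallies classified grains per assigned species and source artifact, with
#' row and column margins.
#'
#' @param results A `grain_classification` (uses `group1` as the assignment).
#' @param artifact_map Data frame with columns `grain_id` and `artifact`
#'   mapping every classified grain to exactly one artifact.
#' @return Matrix of counts (species rows, artifact columns) with `total`
#'   margins; class `artifact_table`.
#' @export
per_artifact_table <- function(results, artifact_map) {
  stopifnot(all(c("grain_id", "artifact") %in% names(artifact_map)))
  if (nrow(results) == 0) {
    out <- matrix(0L, 1, 1, dimnames = list("total", "total"))
    class(out) <- c("artifact_table", class(out))
    return(out)
  }
  j <- match(results$grain_id, artifact_map$grain_id)
  if (anyNA(j)) {
    stop_domain("per_artifact_table: unmapped grain(s): %s",
                paste(utils::head(results$grain_id[is.na(j)], 5), collapse = ", "))
  }
  tab <- table(species = results$group1, artifact = artifact_map$artifact[j])
  m <- unclass(tab)
  m <- rbind(m, total = colSums(m))
  m <- cbind(m, total = rowSums(m))
  class(m) <- c("artifact_table", class(m))
  m
}

#' @export
print.artifact_table <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Audit ledger of microscopy screening counts
#'
#' Tracks the reduction from photographed candidate particles to measurable
#' starch grains: items discarded as non-starch (e.g. microcrystalline
#' structures), then grains unmeasurable because of damage or slide position.
#'
#' @param photographed Number of candidate items photographed.
#' @param non_starch Items discarded as not starch.
#' @param unmeasurable Starch grains that could not be fully measured.
#' @return List with `measurable` and a step-by-step `log` data frame.
#' @export
screening_ledger <- function(photographed, non_starch, unmeasurable) {
  v <- c(photographed = photographed, non_starch = non_starch,
         unmeasurable = unmeasurable)
  if (any(v < 0)) stop_domain("screening_ledger: counts must be non-negative")
  starch <- photographed - non_starch
  if (starch < 0) stop_domain("screening_ledger: non-starch exclusions exceed total")
  measurable <- starch - unmeasurable
  if (measurable < 0) stop_domain("screening_ledger: unmeasurable exclusions exceed remaining")
  list(
    measurable = measurable,
    log = data.frame(
      step = c("photographed", "discarded non-starch", "starch grains",
               "discarded unmeasurable", "measurable"),
      n = c(photographed, -non_starch, starch, -unmeasurable, measurable)
    )
  )
}

#' Two-step discriminant identification of unknown grains
#'
#' End-to-end identification pipeline: scale the reference collection, fit a
#' discriminant model, filter the reference to its correctly self-classified
#' subset, refit on the subset pooled with the unknowns as an `"Archeo"`
#' group, classify every unknown, bin assignments by posterior confidence,
#' and (when an artifact map is given) tabulate species per artifact.
#'
#' @param reference Reference grain data frame (validated; indices derived
#'   if absent).
#' @param unknowns Archaeological grain data frame (>= 2 rows).
#' @param hi,lo Confidence thresholds, defaults 0.90 / 0.80.
#' @param prior `"equal"` (default) or `"proportional"`.
#' @param scaling `"reference"` (default: scaling fitted on the reference
#'   collection and applied to unknowns) or `"pooled"` (fitted on reference
#'   and unknowns jointly).
#' @param ridge Ridge fallback for singular pooled covariances (see
#'   [grain_lda()]).
#' @param artifact_map Optional data frame (`grain_id`, `artifact`).
#' @param method Unknown-classification mode, see [classify_unknowns()].
#' @return A `starch_identification` object: `subset_report`, `results`
#'   (Table of ranked two-best assignments), `bins`, `per_artifact` (or
#'   `NULL`), and the two fitted models.
#' @export
starch_identify <- function(reference, unknowns, hi = 0.90, lo = 0.80,
                            prior = "equal", scaling = c("reference", "pooled"),
                            ridge = 0, artifact_map = NULL,
                            method = "resubstitution") {
  scaling <- match.arg(scaling)
  reference <- derive_indices(reference)
  unknowns <- derive_indices(unknowns)
  ref_gm <- assemble_matrix(reference)
  unk_gm <- assemble_matrix(unknowns)
  if (scaling == "reference") {
    ref_gm <- scale_matrix(ref_gm)
    unk_gm <- scale_matrix(unk_gm, params = scaling_params(ref_gm))
  } else {
    pooled <- rbind(ref_gm$x, unk_gm$x)
    ctr <- colMeans(pooled)
    spr <- apply(pooled, 2, stats::sd)
    pars <- list(center = ctr, scale = spr)
    ref_gm <- scale_matrix(ref_gm, params = pars)
    unk_gm <- scale_matrix(unk_gm, params = pars)
  }
  filt <- filter_reference(ref_gm, prior = prior, ridge = ridge)
  sub_x <- ref_gm$x[filt$kept, , drop = FALSE]
  sub_lab <- ref_gm$group[filt$kept]
  cls <- classify_unknowns(sub_x, sub_lab, unk_gm$x,
                           unknown_ids = unk_gm$grain_id,
                           method = method, prior = prior, ridge = ridge)
  bins <- bin_by_confidence(cls$results, hi = hi, lo = lo)
  pat <- if (!is.null(artifact_map)) {
    per_artifact_table(cls$results, artifact_map)
  } else if (any(!is.na(unk_gm$artifact))) {
    per_artifact_table(cls$results,
                       data.frame(grain_id = unk_gm$grain_id,
                                  artifact = unk_gm$artifact,
                                  stringsAsFactors = FALSE))
  } else NULL
  structure(list(subset_report = filt$report, reference_model = filt$model,
                 results = cls$results, model = cls$model, bins = bins,
                 per_artifact = pat, hi = hi, lo = lo, scaling = scaling),
            class = "starch_identification")
}

#' @export
print.starch_identification <- function(x, ...) {
  cat("Two-step discriminant identification\n")
  cat(sprintf("Reference subset: %d of %d grains kept\n",
              sum(x$subset_report$n_kept), sum(x$subset_report$n_input)))
  cat(sprintf("Unknowns classified: %d (over %d groups)\n",
              nrow(x$results), length(x$model$levels)))
  print(x$bins)
  invisible(x)
}

#' @export
summary.starch_identification <- function(object, ...) {
  cat("Subset report:\n"); print(object$subset_report)
  cat("\nAssignments (two best groups per grain):\n")
  df <- as.data.frame(object$results)
  df[sapply(df, is.numeric)] <- lapply(df[sapply(df, is.numeric)], round, 3)
  print(df, row.names = FALSE)
  print(object$bins)
  if (!is.null(object$per_artifact)) {
    cat("\nSpecies x artifact:\n"); print(object$per_artifact)
  }
  invisible(object)
}
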