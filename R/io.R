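# Grain CSV dialect: UTF-8, header mandatory, decimal point, empty = missing.

numeric_grain_columns <- function() {
  c("l_max_um", "l_min_um", "perimeter_um", "area_um2", "d_max_um", "d_min_um",
    "c_index", "e_index", "ce_index")
}

#' Read a grain table from CSV
#'
#' Reads and validates grain records. Numeric fields must use a decimal
#' point; decimal commas are rejected with the offending line number. The
#' three shape indices are derived from the primitive measurements when the
#' index columns are empty.
#'
#' @param path CSV file in the grain dialect (see [write_grains()]).
#' @return Validated grain data frame.
#' @export
read_grains <- function(path) {
  if (!file.exists(path)) stop_domain("read_grains: file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  need <- setdiff(grain_columns(), "lamellae")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_domain("read_grains: header missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (!"lamellae" %in% names(raw)) raw$lamellae <- ""
  if (nrow(raw) == 0) {
    out <- raw
    for (f in numeric_grain_columns()) out[[f]] <- numeric(0)
    return(out[, grain_columns()])
  }
  for (f in numeric_grain_columns()) {
    v <- trimws(raw[[f]])
    commas <- grepl(",", v, fixed = TRUE)
    if (any(commas)) {
      stop_domain(paste0("read_grains: decimal commas are not supported ",
                         "(line %d, field '%s'); use a decimal point"),
                  which(commas)[1] + 1L, f)
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & nzchar(v) & is.na(num)
    if (any(bad)) {
      stop_domain("read_grains: malformed number at line %d, field '%s': '%s'",
                  which(bad)[1] + 1L, f, v[which(bad)[1]])
    }
    raw[[f]] <- num
  }
  prim <- c("l_max_um", "l_min_um", "perimeter_um", "area_um2", "d_max_um", "d_min_um")
  for (f in prim) {
    if (anyNA(raw[[f]])) {
      stop_domain("read_grains: missing measurement at line %d, field '%s'",
                  which(is.na(raw[[f]]))[1] + 1L, f)
    }
  }
  if (anyNA(raw$c_index) || anyNA(raw$e_index) || anyNA(raw$ce_index)) {
    raw <- derive_indices(raw)
  }
  raw$lamellae[!nzchar(trimws(raw$lamellae))] <- NA_character_
  out <- raw[, grain_columns()]
  validate_grains(out)
  out
}

#' Write a grain table to CSV
#'
#' @param grains Grain data frame.
#' @param path Output file.
#' @export
write_grains <- function(grains, path) {
  cols <- intersect(grain_columns(), names(grains))
  utils::write.csv(grains[, cols], path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Export a scaled feature matrix to CSV with scaling provenance
#'
#' The per-variable center and spread are written as `#scaling=` comment
#' header lines so a scaled matrix is self-describing.
#'
#' @param gm A scaled `grain_matrix`.
#' @param path Output file.
#' @export
write_scaled_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "grain_matrix"), gm$scaled)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#scaling=center:%s",
                     paste(sprintf("%s=%.10g", names(gm$center), gm$center),
                           collapse = ";")), con)
  writeLines(sprintf("#scaling=scale:%s",
                     paste(sprintf("%s=%.10g", names(gm$scale), gm$scale),
                           collapse = ";")), con)
  df <- data.frame(grain_id = gm$grain_id, group = gm$group, gm$x,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys: `hi_threshold`, `lo_threshold`, `priors`
#' (`equal`/`proportional`), `scaling` (`reference`/`pooled`), `ridge`, and
#' `encoding:` (code-table overrides, see [starch_codes()]).
#'
#' @param path YAML file, or `NULL` for defaults.
#' @return List of configuration values with defaults filled in.
#' @export
read_starch_config <- function(path = NULL) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  list(
    hi_threshold = cfg$hi_threshold %||% 0.90,
    lo_threshold = cfg$lo_threshold %||% 0.80,
    priors = cfg$priors %||% "equal",
    scaling = cfg$scaling %||% "reference",
    ridge = cfg$ridge %||% 0,
    codes = starch_codes(cfg$encoding)
  )
}
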