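#' Categorical trait levels of the grain data model
#'
#' Returns the documented levels for the six qualitative variables recorded
#' per starch grain (two-dimensional outline shape, hilum type, presence of a
#' hilum fissure, fissure shape, pressure facets, and style of the extinction
#' cross), plus the optional lamellae flag. Level order defines the ordinal
#' numeric codes used downstream (see [starch_codes()]).
#'
#' @return Named list of character vectors, one per qualitative variable.
#' @export
starch_levels <- function() {
  list(
    shape_2d = c("circular", "oval", "oblong", "oblanceolate", "polyhedral",
                 "polymorphic", "bell-shaped"),
    hilum_type = c("non-visible", "closed", "open"),
    fissure_present = c("absent", "present"),
    fissure_shape = c("absent", "circular", "simple", "v-shaped", "y-shaped",
                      "elongated", "hat/square-shaped"),
    facets = c("absent", "flat", "concave", "flat multi-faceted",
               "concave multi-faceted", "mixed multi-faceted"),
    extinction_cross = c("straight", "curved", "wavy"),
    lamellae = c("absent", "present")
  )
}

# Columns a complete grain table must carry, in the canonical CSV order.
grain_columns <- function() {
  c("grain_id", "provenance_kind", "species_or_artifact",
    "l_max_um", "l_min_um", "perimeter_um", "area_um2", "d_max_um", "d_min_um",
    "c_index", "e_index", "ce_index",
    "shape_2d", "hilum_type", "fissure_present", "fissure_shape", "facets",
    "extinction_cross", "lamellae")
}

#' Compactness index of a grain outline
#'
#' Gravelius-style shape ratio `0.282 * P / sqrt(A)`: approximately 1 for a
#' circular outline and larger for elongated or irregular outlines. Digitized
#' perimeters of near-circular grains can fall slightly below 1 due to
#' pixelation, so only positivity is guaranteed.
#'
#' @param perimeter Total outline perimeter in micrometers (> 0).
#' @param area Grain area in square micrometers (> 0).
#' @return Dimensionless compactness value (vectorized).
#' @examples
#' compactness_index(2 * pi, pi)   # unit circle, ~1
#' compactness_index(4, 1)         # unit square, 1.128
#' @export
compactness_index <- function(perimeter, area) {
  if (any(!is.finite(perimeter)) || any(perimeter <= 0)) {
    stop_domain("compactness_index: 'perimeter' must be positive")
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop_domain("compactness_index: 'area' must be positive")
  }
  0.282 * perimeter / sqrt(area)
}

#' Elongation index of a grain
#'
#' Ratio of maximum to minimum grain length; 1 for equiaxial grains.
#'
#' @param l_max Maximum grain length, micrometers.
#' @param l_min Minimum grain length, micrometers (> 0, `<= l_max`).
#' @return Dimensionless elongation `l_max / l_min >= 1` (vectorized).
#' @export
elongation_index <- function(l_max, l_min) {
  if (any(!is.finite(l_min)) || any(l_min <= 0)) {
    stop_domain("elongation_index: 'l_min' must be positive")
  }
  if (any(l_max < l_min)) {
    stop_domain("elongation_index: 'l_max' < 'l_min' (inputs look swapped)")
  }
  l_max / l_min
}

#' Centricity index of the hilum
#'
#' `d_max / (d_max + d_min)` of the maximum and minimum hilum-to-edge
#' distances: 0.5 for a perfectly centric hilum, approaching 1 as the hilum
#' moves to the grain margin.
#'
#' @param d_max Maximum hilum-to-edge distance, micrometers (> 0).
#' @param d_min Minimum hilum-to-edge distance, micrometers (`0 <= d_min <= d_max`).
#' @return Centricity in `[0.5, 1]` (vectorized).
#' @export
centricity_index <- function(d_max, d_min) {
  if (any(!is.finite(d_max)) || any(!is.finite(d_min)) || any(d_min < 0)) {
    stop_domain("centricity_index: distances must be finite and 'd_min' >= 0")
  }
  if (any(d_max <= 0)) {
    stop_domain("centricity_index: 'd_max' must be positive (hilum distances both zero)")
  }
  if (any(d_max < d_min)) {
    stop_domain("centricity_index: 'd_max' < 'd_min' (inputs look swapped)")
  }
  d_max / (d_max + d_min)
}

#' Categorize a shape index value
#'
#' Maps an index value to its qualitative category. The printed category
#' bounds are two-decimal labels of contiguous intervals, so the value is
#' first rounded to two decimals (half away from zero) and then binned on
#' closed intervals:
#' \itemize{
#'   \item compactness: circular (<= 1.00), elongated (1.01-1.25), irregular (>= 1.26)
#'   \item elongation: not elongated (1.00), slightly (1.01-2.00),
#'         moderately (2.01-3.00), highly elongated (>= 3.01)
#'   \item centricity: centric (0.50-0.60), eccentric (0.61-0.70),
#'         hyperexcentric (0.71-1.00)
#' }
#'
#' @param value Index value(s).
#' @param kind One of `"compactness"`, `"elongation"`, `"centricity"`.
#' @return Character vector of category labels.
#' @examples
#' categorize_index(1.004, "compactness")  # "circular"
#' categorize_index(0.605, "centricity")   # rounds to 0.61, "eccentric"
#' @export
categorize_index <- function(value, kind = c("compactness", "elongation", "centricity")) {
  kind <- match.arg(kind)
  v <- round_half_up(value, 2)
  switch(kind,
    compactness = ifelse(v <= 1.00, "circular",
                  ifelse(v <= 1.25, "elongated", "irregular")),
    elongation = {
      if (any(v < 1 - 1e-9)) stop_domain("categorize_index: elongation values must be >= 1")
      ifelse(v <= 1.00, "not elongated",
      ifelse(v <= 2.00, "slightly elongated",
      ifelse(v <= 3.00, "moderately elongated", "highly elongated")))
    },
    centricity = {
      if (any(v < 0.5 - 1e-9 | v > 1 + 1e-9)) {
        stop_domain("categorize_index: centricity values must lie in [0.5, 1]")
      }
      ifelse(v <= 0.60, "centric",
      ifelse(v <= 0.70, "eccentric", "hyperexcentric"))
    }
  )
}

#' Derive the three shape indices for a grain table
#'
#' Populates (or re-populates) `c_index`, `e_index` and `ce_index` from the
#' primitive measurements. Idempotent: re-deriving a completed table changes
#' nothing.
#'
#' @param grains Data frame with at least the primitive measurement columns
#'   `l_max_um`, `l_min_um`, `perimeter_um`, `area_um2`, `d_max_um`, `d_min_um`.
#' @return The same data frame with the three index columns filled.
#' @export
derive_indices <- function(grains) {
  stopifnot(is.data.frame(grains))
  need <- c("l_max_um", "l_min_um", "perimeter_um", "area_um2", "d_max_um", "d_min_um")
  miss <- setdiff(need, names(grains))
  if (length(miss)) {
    stop_domain("derive_indices: missing primitive columns: %s", paste(miss, collapse = ", "))
  }
  ctx <- function(expr) {
    tryCatch(expr, error = function(e) {
      bad <- if ("grain_id" %in% names(grains)) {
        paste0(" [first grains: ", paste(utils::head(grains$grain_id, 3), collapse = ", "), "]")
      } else ""
      stop_domain("%s%s", conditionMessage(e), bad)
    })
  }
  grains$c_index <- ctx(compactness_index(grains$perimeter_um, grains$area_um2))
  grains$e_index <- ctx(elongation_index(grains$l_max_um, grains$l_min_um))
  grains$ce_index <- ctx(centricity_index(grains$d_max_um, grains$d_min_um))
  grains
}

#' Validate a grain table against the data-model invariants
#'
#' Checks measurement positivity and ordering (`l_max >= l_min`,
#' `d_max >= d_min`), index ranges (`e_index >= 1`, `ce_index` in
#' `[0.5, 1]`, `c_index > 0`), categorical levels, and the coupling between
#' fissure presence and fissure shape (`fissure_shape == "absent"` iff
#' `fissure_present == "absent"`). Lamellae, when recorded, must be a valid
#' level but never enters the analysis feature vector.
#'
#' @param grains Grain data frame (see [read_grains()] for the column dialect).
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_grains <- function(grains) {
  stopifnot(is.data.frame(grains))
  miss <- setdiff(setdiff(grain_columns(), "lamellae"), names(grains))
  if (length(miss)) {
    stop_domain("validate_grains: missing columns: %s", paste(miss, collapse = ", "))
  }
  if (nrow(grains) == 0) return(invisible(grains))
  fail <- function(rows, field, why) {
    if (any(rows)) {
      id <- grains$grain_id[which(rows)[1]]
      stop_domain("validate_grains: grain '%s', field '%s': %s", id, field, why)
    }
  }
  if (!all(grains$provenance_kind %in% c("reference", "archaeological"))) {
    fail(!grains$provenance_kind %in% c("reference", "archaeological"),
         "provenance_kind", "must be 'reference' or 'archaeological'")
  }
  num <- c("l_max_um", "l_min_um", "perimeter_um", "area_um2")
  for (f in num) fail(!is.finite(grains[[f]]) | grains[[f]] <= 0, f, "must be positive")
  fail(!is.finite(grains$d_max_um) | grains$d_max_um <= 0, "d_max_um", "must be positive")
  fail(!is.finite(grains$d_min_um) | grains$d_min_um < 0, "d_min_um", "must be non-negative")
  fail(grains$l_max_um < grains$l_min_um, "l_max_um", "l_max < l_min")
  fail(grains$d_max_um < grains$d_min_um, "d_max_um", "d_max < d_min")
  fail(grains$c_index <= 0, "c_index", "must be positive")
  fail(grains$e_index < 1 - 1e-9, "e_index", "must be >= 1")
  fail(grains$ce_index < 0.5 - 1e-9 | grains$ce_index > 1 + 1e-9,
       "ce_index", "must lie in [0.5, 1]")
  lv <- starch_levels()
  for (f in c("shape_2d", "hilum_type", "fissure_present", "fissure_shape",
              "facets", "extinction_cross")) {
    fail(!grains[[f]] %in% lv[[f]], f, "unknown category level")
  }
  if ("lamellae" %in% names(grains)) {
    ok <- is.na(grains$lamellae) | grains$lamellae %in% lv$lamellae | grains$lamellae == ""
    fail(!ok, "lamellae", "unknown category level")
  }
  fail((grains$fissure_shape == "absent") != (grains$fissure_present == "absent"),
       "fissure_shape", "must be 'absent' exactly when fissure_present is 'absent'")
  invisible(grains)
}
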