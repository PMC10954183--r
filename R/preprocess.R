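#' Ordinal numeric codes for the qualitative variables
#'
#' The analysis treats all 15 variables as numeric in a single matrix, so the
#' six qualitative traits are coded as small integers in the order the levels
#' are documented (see [starch_levels()]), with "absent" always coded 0 and
#' "non-visible" hila coded 0. Codes may be overridden through the
#' `encoding:` section of a YAML configuration (see [read_starch_config()]).
#'
#' @param overrides Optional named list of named numeric vectors replacing the
#'   code table of individual variables.
#' @return Named list of named numeric code vectors, one per variable.
#' @export
starch_codes <- function(overrides = NULL) {
  codes <- list(
    shape_2d = c("circular" = 1, "oval" = 2, "oblong" = 3, "oblanceolate" = 4,
                 "polyhedral" = 5, "polymorphic" = 6, "bell-shaped" = 7),
    hilum_type = c("non-visible" = 0, "closed" = 1, "open" = 2),
    fissure_present = c("absent" = 0, "present" = 1),
    fissure_shape = c("absent" = 0, "circular" = 1, "simple" = 2, "v-shaped" = 3,
                      "y-shaped" = 4, "elongated" = 5, "hat/square-shaped" = 6),
    facets = c("absent" = 0, "flat" = 1, "concave" = 2, "flat multi-faceted" = 3,
               "concave multi-faceted" = 4, "mixed multi-faceted" = 5),
    extinction_cross = c("straight" = 1, "curved" = 2, "wavy" = 3)
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(codes)) {
        stop_domain("starch_codes: unknown variable '%s' in encoding overrides", nm)
      }
      ov <- unlist(overrides[[nm]])
      if (!setequal(names(ov), names(codes[[nm]]))) {
        stop_domain("starch_codes: override for '%s' must cover exactly its levels", nm)
      }
      codes[[nm]] <- ov[names(codes[[nm]])]
    }
  }
  codes
}

#' Encode the qualitative traits of a grain table numerically
#'
#' @param grains Grain data frame with valid categorical levels.
#' @param codes Code tables, default [starch_codes()].
#' @return Numeric matrix with one column per qualitative variable, rows in
#'   input order.
#' @export
encode_qualitative <- function(grains, codes = starch_codes()) {
  vars <- names(codes)
  out <- matrix(NA_real_, nrow = nrow(grains), ncol = length(vars),
                dimnames = list(NULL, vars))
  for (v in vars) {
    lev <- grains[[v]]
    bad <- !lev %in% names(codes[[v]])
    if (any(bad)) {
      i <- which(bad)[1]
      id <- if ("grain_id" %in% names(grains)) grains$grain_id[i] else paste("row", i)
      stop_domain("encode_qualitative: grain '%s', field '%s': unknown level '%s'",
                  id, v, lev[i])
    }
    out[, v] <- unname(codes[[v]][lev])
  }
  out
}

#' Decode numeric trait codes back to level labels
#'
#' Inverse of [encode_qualitative()]; exact round-trip for every documented
#' level.
#'
#' @param coded Numeric matrix with qualitative-variable columns.
#' @param codes Code tables, default [starch_codes()].
#' @return Data frame of level labels.
#' @export
decode_qualitative <- function(coded, codes = starch_codes()) {
  out <- as.data.frame(matrix(NA_character_, nrow(coded), ncol(coded)),
                       stringsAsFactors = FALSE)
  names(out) <- colnames(coded)
  for (v in colnames(coded)) {
    tab <- codes[[v]]
    idx <- match(coded[, v], unname(tab))
    if (anyNA(idx)) stop_domain("decode_qualitative: code not in table for '%s'", v)
    out[[v]] <- names(tab)[idx]
  }
  out
}

# Canonical 15-variable order of the feature matrix (biplot/tree codes 1-15).
feature_names <- function() {
  c("l_max_um", "l_min_um", "e_index", "perimeter_um", "area_um2", "c_index",
    "d_max_um", "d_min_um", "ce_index",
    "shape_2d", "hilum_type", "fissure_present", "fissure_shape", "facets",
    "extinction_cross")
}

#' Assemble the 15-variable feature matrix from a grain table
#'
#' Builds the numeric observation matrix used by all downstream analyses:
#' nine quantitative variables (lengths, perimeter, area, hilum distances and
#' the three derived indices) followed by the six ordinally coded qualitative
#' traits, in the fixed canonical order. Reference grains are labelled by
#' their species; archaeological grains are pooled under the group label
#' `"Archeo"`.
#'
#' @param grains Validated grain data frame.
#' @param codes Qualitative code tables, default [starch_codes()].
#' @return A `grain_matrix` object: list with `x` (n x 15 numeric matrix),
#'   `group` (per-row label), `grain_id`, `artifact` (artifact id for
#'   archaeological rows, `NA` otherwise), and scaling state.
#' @export
assemble_matrix <- function(grains, codes = starch_codes()) {
  validate_grains(grains)
  qual <- encode_qualitative(grains, codes)
  quant <- as.matrix(grains[, c("l_max_um", "l_min_um", "e_index", "perimeter_um",
                                "area_um2", "c_index", "d_max_um", "d_min_um",
                                "ce_index")])
  if (nrow(grains) > 0 && any(!is.finite(quant))) {
    stop_domain("assemble_matrix: incomplete quantitative measurements")
  }
  x <- cbind(quant, qual)[, , drop = FALSE]
  colnames(x) <- feature_names()
  rownames(x) <- grains$grain_id
  structure(list(
    x = x,
    group = ifelse(grains$provenance_kind == "reference",
                   grains$species_or_artifact, "Archeo"),
    grain_id = grains$grain_id,
    artifact = ifelse(grains$provenance_kind == "archaeological",
                      grains$species_or_artifact, NA_character_),
    scaled = FALSE, center = NULL, scale = NULL
  ), class = "grain_matrix")
}

#' @export
print.grain_matrix <- function(x, ...) {
  cat(sprintf("Grain feature matrix: %d grains x %d variables (%s)\n",
              nrow(x$x), ncol(x$x), if (x$scaled) "scaled" else "unscaled"))
  tab <- table(x$group)
  cat("Groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Scale a feature matrix to zero mean and unit variance
#'
#' Column-wise z-scoring with the sample (n-1) standard deviation, so that
#' all 15 variables carry equal weight. When `params` is supplied (e.g. the
#' scaling fitted on the reference collection, applied to unknowns) its
#' center and spread are used verbatim and recorded. Scaling an
#' already-scaled matrix is a no-op.
#'
#' @param gm A `grain_matrix`.
#' @param params Optional list with elements `center` and `scale` (named
#'   numeric vectors over the 15 variables).
#' @return The scaled `grain_matrix`, with `scaling_params` stored.
#' @export
scale_matrix <- function(gm, params = NULL) {
  stopifnot(inherits(gm, "grain_matrix"))
  if (gm$scaled) return(gm)
  if (is.null(params)) {
    ctr <- colMeans(gm$x)
    spr <- apply(gm$x, 2, stats::sd)
    zero <- spr < 1e-12 | !is.finite(spr)
    if (any(zero)) {
      stop_domain("scale_matrix: zero-variance column(s): %s",
                  paste(colnames(gm$x)[zero], collapse = ", "))
    }
  } else {
    ctr <- params$center[colnames(gm$x)]
    spr <- params$scale[colnames(gm$x)]
    if (anyNA(ctr) || anyNA(spr)) {
      stop_domain("scale_matrix: supplied params do not cover all 15 variables")
    }
  }
  gm$x <- sweep(sweep(gm$x, 2, ctr, "-"), 2, spr, "/")
  gm$scaled <- TRUE
  gm$center <- ctr
  gm$scale <- spr
  gm$params_supplied <- !is.null(params)
  gm
}

#' Extract the scaling parameters of a scaled matrix
#' @param gm A scaled `grain_matrix`.
#' @return List with `center` and `scale`.
#' @export
scaling_params <- function(gm) {
  stopifnot(inherits(gm, "grain_matrix"), gm$scaled)
  list(center = gm$center, scale = gm$scale)
}
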