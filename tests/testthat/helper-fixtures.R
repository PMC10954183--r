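# Shared in-code fixtures for the test suite.

# A geometrically consistent grain row built from primitives; indices derived.
toy_grain <- function(id = "g1", species = "SpeciesA", l_max = 10, l_min = 10,
                      perimeter = pi * 10, area = pi * 25, d_max = 5, d_min = 5,
                      shape = "circular", hilum = "closed",
                      fissure_shape = "absent", facets = "absent",
                      cross = "straight", kind = "reference") {
  derive_indices(data.frame(
    grain_id = id, provenance_kind = kind, species_or_artifact = species,
    l_max_um = l_max, l_min_um = l_min, perimeter_um = perimeter,
    area_um2 = area, d_max_um = d_max, d_min_um = d_min,
    c_index = NA_real_, e_index = NA_real_, ce_index = NA_real_,
    shape_2d = shape, hilum_type = hilum,
    fissure_present = if (fissure_shape == "absent") "absent" else "present",
    fissure_shape = fissure_shape, facets = facets, extinction_cross = cross,
    lamellae = "absent", stringsAsFactors = FALSE))
}

# Small synthetic grain table: k species x n grains, distinct sizes.
# Categorical majorities are softened to 0.8 so that small groups retain
# within-group variance on every coded column (keeps the pooled covariance
# well conditioned at tiny n); species stay separable through the size block.
toy_collection <- function(k = 3, n = 10, seed = 42) {
  profs <- lapply(separated_profiles(k, n), function(p) {
    for (v in names(p$cat_probs)) {
      tb <- p$cat_probs[[v]]
      j <- which.max(tb)
      tb[] <- 0.2 / (length(tb) - 1)
      tb[j] <- 0.8
      p$cat_probs[[v]] <- tb
    }
    p
  })
  generate_reference(profs, seed = seed)
}

# Exhaustive-search CART oracle: best single split by Gini over all
# variable/threshold candidates, ties to lowest variable then threshold.
brute_force_split <- function(x, y, min_leaf = 1) {
  gini <- function(lab) 1 - sum((table(lab) / length(lab))^2)
  n <- nrow(x)
  best <- NULL
  best_gain <- 1e-12
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (t in (vals[-length(vals)] + vals[-1]) / 2) {
      l <- x[, j] <= t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      gain <- gini(y) - (sum(l) * gini(y[l]) + sum(!l) * gini(y[!l])) / n
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(var = j, threshold = t, gain = gain)
      }
    }
  }
  best
}
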