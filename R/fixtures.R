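#' Load the packaged published-table fixtures
#'
#' Reads the plain-text fixtures shipped with the package — the printed
#' per-grain classification of the 46 archaeological grains (two best
#' groups with linear score, squared distance and posterior), the per-artifact
#' grain counts, the grain-to-artifact map, the per-species reference and
#' curated-subset sizes, and the microscopy screening counts — and checks
#' their internal consistency (row counts, margins, cross-table totals)
#' before returning them.
#'
#' @return A `paper_fixtures` object: `table3` (46-row classification),
#'   `table4` (artifact counts), `artifact_map` (`grain_id` -> `artifact`),
#'   `reference_counts`, `subset_counts`, `screening` (named counts).
#' @export
load_fixtures <- function() {
  p <- function(f) system.file("extdata", f, package = "starchid")
  rd <- function(f) utils::read.csv(p(f), check.names = FALSE,
                                    stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  fx <- list(
    table3 = rd("table3.csv"),
    table4 = rd("table4.csv"),
    artifact_map = rd("artifact_map.csv"),
    reference_counts = rd("counts_reference.csv"),
    subset_counts = rd("counts_subset.csv"),
    screening = unlist(rd("screening.csv")[1, ])
  )
  chk <- function(ok, what) {
    if (!ok) stop_domain("load_fixtures: integrity check failed: %s", what)
  }
  chk(nrow(fx$table3) == 46, "table3 must have 46 rows")
  chk(!anyNA(fx$table3$prob1) && all(fx$table3$prob1 >= 0 & fx$table3$prob1 <= 1),
      "table3 probabilities in [0,1]")
  chk(sum(fx$table4$n_grains) == 46, "table4 grains must total 46")
  chk(nrow(fx$artifact_map) == 46, "artifact map must cover 46 grains")
  chk(setequal(fx$artifact_map$grain_id, fx$table3$grain_id),
      "artifact map ids must match table3")
  tallied <- table(fx$artifact_map$artifact)
  t4 <- fx$table4[fx$table4$n_grains > 0, ]
  chk(setequal(names(tallied), t4$artifact) &&
        all(tallied[t4$artifact] == t4$n_grains),
      "artifact map margins must match table4")
  chk(sum(fx$reference_counts$n) == 1598, "reference collection must total 1598")
  chk(sum(fx$subset_counts$n) == 1240, "curated subset must total 1240")
  chk(nrow(fx$reference_counts) == 13 && nrow(fx$subset_counts) == 13,
      "13 species expected")
  chk(all(fx$screening == c(78, 6, 26)), "screening counts 78/6/26")
  class(fx) <- "paper_fixtures"
  fx
}

#' @export
print.paper_fixtures <- function(x, ...) {
  cat("Published-table fixtures:\n")
  cat(sprintf("  table3: %d classified archaeological grains\n", nrow(x$table3)))
  cat(sprintf("  table4: %d artifacts, %d grains\n", nrow(x$table4),
              sum(x$table4$n_grains)))
  cat(sprintf("  reference: %d species, %d grains; curated subset: %d grains\n",
              nrow(x$reference_counts), sum(x$reference_counts$n),
              sum(x$subset_counts$n)))
  cat(sprintf("  screening: %d photographed - %d non-starch - %d unmeasurable = %d\n",
              x$screening["photographed"], x$screening["non_starch"],
              x$screening["unmeasurable"],
              x$screening["photographed"] - x$screening["non_starch"] -
                x$screening["unmeasurable"]))
  invisible(x)
}
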