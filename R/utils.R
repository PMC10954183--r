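# internal helpers shared across modules

# Round half away from zero at `digits` decimals. base::round() rounds half to
# even, which would put boundary index values (e.g. 0.605) in the wrong bin.
# The small epsilon absorbs binary representation error (0.605 is stored just
# below its decimal value); index magnitudes are < 1e3 so 1e-8 is safe.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-8) / m
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
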