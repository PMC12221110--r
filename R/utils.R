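# Small internal helpers shared across modules.

# Display rounding. All internal computation is full precision; rounding to
# (by default) 1 decimal happens only at the presentation layer. round() is
# IEC 60559 round-half-even, the documented convention.
round_display <- function(x, digits = 1L) {
  if (is.null(digits)) return(x)
  round(x, digits)
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so that seeded operations never perturb global reproducibility.
with_preserved_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    parameter_error("`seed` must be a single finite integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Numbers formatted for CSV output: locale-independent, deterministic,
# full precision up to 15 significant digits.
format_csv_number <- function(x) {
  vapply(x, function(v) sprintf("%.15g", v), character(1))
}
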