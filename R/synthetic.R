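#' Specification of a synthetic calibration dataset
#'
#' Describes how to synthesize a (temperature, DO2i) calibration dataset
#' emulating the kind of simulated physiological data used to calibrate the
#' quadratic taDO2i curve: a temperature grid across the hypothermia range,
#' a generating model for the mean per-m2 DO2i at each grid temperature, and
#' additive Gaussian noise.
#'
#' Defaults are the stated calibration world: grid 24--37 °C in 0.5 °C steps
#' (27 points), Q10-anchored means (the calibrated quadratic aligns closely
#' with the Q10 curve), and noise standard deviation 3.0 mL/min/m2.
#'
#' @param temp_start,temp_stop,temp_step temperature grid in °C; must lie
#'   within 24--37.
#' @param generator_model `"q10"` (default), `"linear"`, `"quadratic"`, or
#'   `"blend"` (a `blend_weight`-weighted mixture of the Q10 and linear
#'   means).
#' @param noise_sd additive Gaussian noise standard deviation, mL/min/m2
#'   (>= 0, default 3.0).
#' @param blend_weight weight of the Q10 mean when `generator_model =
#'   "blend"`, in \[0, 1\] (default 0.8, i.e. Q10-dominated).
#' @param seed integer RNG seed; required for a noisy dataset.
#' @param params model parameter bundle supplying the generating models
#'   (defaults to the canonical parameters).
#' @return An object of class `tado2i_synth_spec`.
#' @export
synthetic_spec <- function(temp_start = 24, temp_stop = 37, temp_step = 0.5,
                           generator_model = c("q10", "linear", "quadratic",
                                               "blend"),
                           noise_sd = 3.0, blend_weight = 0.8, seed = 1L,
                           params = tado2i_params()) {
  generator_model <- match.arg(generator_model)
  stopifnot_scalar_number(temp_start, "temp_start")
  stopifnot_scalar_number(temp_stop, "temp_stop")
  stopifnot_scalar_number(temp_step, "temp_step")
  if (temp_start < 24 || temp_stop > 37 || temp_start > temp_stop ||
      temp_step <= 0) {
    parameter_error("temperature grid must lie within 24-37 °C with step > 0")
  }
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) parameter_error("`noise_sd` must be >= 0")
  stopifnot_scalar_number(blend_weight, "blend_weight")
  if (blend_weight < 0 || blend_weight > 1) {
    parameter_error("`blend_weight` must lie in [0, 1]")
  }
  stopifnot_scalar_number(seed, "seed")
  structure(list(temp_start = temp_start, temp_stop = temp_stop,
                 temp_step = temp_step, generator_model = generator_model,
                 noise_sd = noise_sd, blend_weight = blend_weight,
                 seed = as.integer(seed), params = params),
            class = "tado2i_synth_spec")
}

#' @export
print.tado2i_synth_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic calibration spec: %s means on %g-%g °C by %g, noise sd %g, seed %d\n",
    x$generator_model, x$temp_start, x$temp_stop, x$temp_step, x$noise_sd,
    x$seed))
  invisible(x)
}

#' Generate a synthetic calibration dataset
#'
#' For each grid temperature the mean is the chosen generating model's
#' per-m2 prediction (for `"blend"`, `w * Q10 + (1 - w) * linear`), and
#' independent Gaussian noise with standard deviation `noise_sd` is added.
#' The same spec and seed always yield the identical dataset; the caller's
#' RNG state is preserved.
#'
#' @param spec a [synthetic_spec()].
#' @return A [calibration_dataset()] with provenance `"synthetic"` and the
#'   spec attached as attribute `"spec"`.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_spec(seed = 42))
#' fit_quadratic(d)
generate_dataset <- function(spec) {
  if (!inherits(spec, "tado2i_synth_spec")) {
    parameter_error("`spec` must be created with synthetic_spec()")
  }
  grid <- seq(spec$temp_start, spec$temp_stop, by = spec$temp_step)
  if (length(grid) == 0L) parameter_error("empty temperature grid")
  p <- spec$params
  mean_fun <- switch(spec$generator_model,
    q10 = function(tt) q10_per_m2(tt, p$q10, p$validity_range, p$extrapolate),
    linear = function(tt) linear_per_m2(tt, p$linear, p$validity_range,
                                        p$extrapolate),
    quadratic = function(tt) quadratic_per_m2(tt, p$coeffs, p$validity_range,
                                              p$extrapolate),
    blend = function(tt) {
      spec$blend_weight *
        q10_per_m2(tt, p$q10, p$validity_range, p$extrapolate) +
        (1 - spec$blend_weight) *
          linear_per_m2(tt, p$linear, p$validity_range, p$extrapolate)
    }
  )
  mu <- mean_fun(grid)
  y <- if (spec$noise_sd > 0) {
    with_preserved_seed(spec$seed,
                        mu + stats::rnorm(length(grid), sd = spec$noise_sd))
  } else {
    mu
  }
  out <- calibration_dataset(grid, y, provenance = "synthetic")
  attr(out, "spec") <- spec
  out
}
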