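#' Quadratic taDO2i coefficients
#'
#' Construct the coefficient triple \eqn{(a, b, c)} of the per-m2
#' temperature-adjusted critical DO2i curve
#' \deqn{DO_{2i}(T) = a T^2 + b T + c}
#' where \eqn{T} is core temperature in degrees Celsius and the result is in
#' mL/min/m2. `a` controls the curvature, `b` the slope, and `c` the
#' intercept (the value at \eqn{T = 0}).
#'
#' @param a curvature coefficient (mL·min⁻¹·m⁻²·°C⁻²).
#' @param b slope coefficient (mL·min⁻¹·m⁻²·°C⁻¹).
#' @param c intercept (mL·min⁻¹·m⁻²).
#' @return An object of class `tado2i_quad_coeffs`.
#' @seealso [canonical_coeffs()] for the calibrated default values,
#'   [quadratic_per_m2()] to evaluate the curve.
#' @export
#' @examples
#' quad_coeffs(0.057, 10.754, -194.245)
quad_coeffs <- function(a, b, c) {
  stopifnot_scalar_number(a, "a")
  stopifnot_scalar_number(b, "b")
  stopifnot_scalar_number(c, "c")
  structure(list(a = a, b = b, c = c), class = "tado2i_quad_coeffs")
}

#' Canonical calibrated quadratic coefficients
#'
#' The calibrated coefficient triple \eqn{(a, b, c) = (0.057, 10.754,
#' -194.245)}. Over the validity range 24--37 °C the derivative
#' \eqn{2aT + b} is strictly positive, so the curve is monotone increasing:
#' the target rises smoothly from deep hypothermia toward its normothermic
#' value of about 281.7 mL/min/m2 at 37 °C.
#'
#' @return A `tado2i_quad_coeffs` object.
#' @export
canonical_coeffs <- function() {
  quad_coeffs(a = 0.057, b = 10.754, c = -194.245)
}

#' @export
print.tado2i_quad_coeffs <- function(x, ...) {
  cat(sprintf("taDO2i quadratic coefficients: a = %g, b = %g, c = %g\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Q10 exponential-decay model of critical DO2i
#'
#' Parameterizes the exponential temperature dependence of the critical DO2i
#' threshold via the Q10 principle: metabolic rate (and hence the critical
#' oxygen-delivery threshold) changes by a fixed factor per 10 °C change in
#' core temperature. The factor is stored in the decay convention
#' (`q10` < 1, applied with exponent \eqn{(T_{ref} - T)/10} for cooling);
#' this is equivalent to the conventional Q10 > 1 form \eqn{(1/q10)} with
#' exponent \eqn{(T - T_{ref})/10}.
#'
#' @param baseline_do2i per-m2 critical DO2i at the reference temperature
#'   (mL/min/m2). Default 300, the usual normothermic critical threshold.
#' @param q10 decade decay factor, in (0, 1]. Default 0.6, the typical value
#'   under hypothermic conditions (reported range 0.5--0.6).
#' @param ref_temp reference core temperature in °C (normothermia, 37).
#' @return An object of class `tado2i_q10_model`.
#' @export
#' @examples
#' m <- q10_model()
#' q10_per_m2(28, m)  # ~189.4 mL/min/m2
q10_model <- function(baseline_do2i = 300, q10 = 0.6, ref_temp = 37) {
  stopifnot_scalar_number(baseline_do2i, "baseline_do2i")
  stopifnot_scalar_number(q10, "q10")
  stopifnot_scalar_number(ref_temp, "ref_temp")
  if (baseline_do2i <= 0) {
    parameter_error("`baseline_do2i` must be positive")
  }
  if (q10 <= 0 || q10 > 1) {
    parameter_error("`q10` must lie in (0, 1] (decay convention)")
  }
  if (ref_temp < 30 || ref_temp > 40) {
    parameter_error("`ref_temp` must lie within 30-40 °C")
  }
  structure(list(baseline_do2i = baseline_do2i, q10 = q10,
                 ref_temp = ref_temp),
            class = "tado2i_q10_model")
}

#' @export
print.tado2i_q10_model <- function(x, ...) {
  cat(sprintf("Q10 model: baseline %g mL/min/m2 at %g °C, Q10 = %g\n",
              x$baseline_do2i, x$ref_temp, x$q10))
  invisible(x)
}

#' Van't Hoff linear model of critical DO2i
#'
#' Linear approximation of metabolic suppression with cooling: the critical
#' DO2i threshold decreases by a fixed fraction of its normothermic value per
#' degree Celsius below the reference temperature (typically 6--7%/°C below
#' 37 °C).
#'
#' @param baseline_do2i per-m2 critical DO2i at the reference temperature
#'   (mL/min/m2). Default 300.
#' @param fraction_per_degree fractional decrease per °C below reference,
#'   in (0, 0.1). Default 0.06.
#' @param ref_temp reference core temperature in °C (default 37).
#' @return An object of class `tado2i_linear_model`.
#' @export
#' @examples
#' linear_per_m2(28, linear_model())  # 138 mL/min/m2
linear_model <- function(baseline_do2i = 300, fraction_per_degree = 0.06,
                         ref_temp = 37) {
  stopifnot_scalar_number(baseline_do2i, "baseline_do2i")
  stopifnot_scalar_number(fraction_per_degree, "fraction_per_degree")
  stopifnot_scalar_number(ref_temp, "ref_temp")
  if (baseline_do2i <= 0) {
    parameter_error("`baseline_do2i` must be positive")
  }
  if (fraction_per_degree <= 0 || fraction_per_degree >= 0.1) {
    parameter_error("`fraction_per_degree` must lie in (0, 0.1)")
  }
  structure(list(baseline_do2i = baseline_do2i,
                 fraction_per_degree = fraction_per_degree,
                 ref_temp = ref_temp),
            class = "tado2i_linear_model")
}

#' @export
print.tado2i_linear_model <- function(x, ...) {
  cat(sprintf(
    "Van't Hoff linear model: baseline %g mL/min/m2 at %g °C, -%g%%/°C\n",
    x$baseline_do2i, x$ref_temp, 100 * x$fraction_per_degree))
  invisible(x)
}

#' Patient description (body surface area)
#'
#' A patient is characterized, for oxygen-delivery indexing, by body surface
#' area (BSA, m2). BSA may be given directly or derived from height and
#' weight via [bsa_from_anthropometrics()].
#'
#' @param bsa body surface area in m2 (0.2--3.0), or `NULL` to derive from
#'   `height_cm` and `weight_kg`.
#' @param height_cm,weight_kg anthropometrics used when `bsa` is `NULL`.
#' @param formula BSA formula for the derivation, `"dubois"` (default) or
#'   `"mosteller"`.
#' @return An object of class `tado2i_patient` with element `bsa`.
#' @export
#' @examples
#' patient(bsa = 1.8)
#' patient(height_cm = 180, weight_kg = 75)
patient <- function(bsa = NULL, height_cm = NULL, weight_kg = NULL,
                    formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  derived <- FALSE
  if (is.null(bsa)) {
    if (is.null(height_cm) || is.null(weight_kg)) {
      parameter_error("supply `bsa` or both `height_cm` and `weight_kg`")
    }
    bsa <- bsa_from_anthropometrics(height_cm, weight_kg, formula)
    derived <- TRUE
  }
  stopifnot_scalar_number(bsa, "bsa")
  if (bsa < 0.2 || bsa > 3.0) {
    parameter_error(sprintf(
      "%sBSA %.3f m2 is outside the supported range 0.2-3.0 m2",
      if (derived) "derived " else "", bsa))
  }
  structure(list(bsa = bsa, height_cm = height_cm, weight_kg = weight_kg,
                 formula = if (derived) formula else NULL),
            class = "tado2i_patient")
}

#' @export
print.tado2i_patient <- function(x, ...) {
  cat(sprintf("Patient: BSA %.3f m2%s\n", x$bsa,
              if (!is.null(x$formula)) {
                sprintf(" (derived, %s: %g cm, %g kg)",
                        x$formula, x$height_cm, x$weight_kg)
              } else ""))
  invisible(x)
}

# Coerce a bare number to a patient for convenience in the higher layers.
as_patient <- function(x) {
  if (inherits(x, "tado2i_patient")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(patient(bsa = x))
  parameter_error("`patient` must be a tado2i_patient or a single BSA value")
}

# Validity-range gate shared by all three models. The default range 24-37 C
# is the calibration span; outside it the default is a hard error, and an
# explicit extrapolation flag downgrades this to a warning (the linear model
# goes negative below ~20.3 C and the quadratic is uncalibrated outside the
# span). Pass validity_range = NULL to disable checking entirely.
check_temp_range <- function(temp_c, validity_range = c(24, 37),
                             extrapolate = FALSE, what = "temperature") {
  if (!is.numeric(temp_c) || length(temp_c) < 1L || anyNA(temp_c) ||
      any(!is.finite(temp_c))) {
    parameter_error("`temp_c` must be finite numeric")
  }
  if (is.null(validity_range)) return(invisible(temp_c))
  out <- temp_c < validity_range[1] | temp_c > validity_range[2]
  if (any(out)) {
    msg <- sprintf(
      "%s %s °C outside the model validity range [%g, %g] °C",
      what, paste(format(temp_c[out]), collapse = ", "),
      validity_range[1], validity_range[2])
    if (extrapolate) {
      warning(paste0("extrapolating: ", msg), call. = FALSE)
    } else {
      range_error(paste0(msg, " (set extrapolate = TRUE to override)"),
                  temp_c = temp_c[out])
    }
  }
  invisible(temp_c)
}

#' Quadratic taDO2i model: per-m2 prediction
#'
#' Evaluates the calibrated quadratic curve \eqn{aT^2 + bT + c} at the given
#' core temperature(s). The value is returned unrounded; round at the
#' presentation layer only (see [comparison_table()]).
#'
#' @param temp_c core temperature(s) in °C.
#' @param coeffs a [quad_coeffs()] object; defaults to [canonical_coeffs()].
#' @param validity_range two-element numeric range of calibrated validity in
#'   °C (default `c(24, 37)`), or `NULL` to disable range checking.
#' @param extrapolate if `TRUE`, out-of-range temperatures produce a warning
#'   instead of an error.
#' @return per-m2 critical DO2i in mL/min/m2, same length as `temp_c`.
#' @export
#' @examples
#' quadratic_per_m2(30)            # 179.675
#' quadratic_per_m2(30) * 1.8      # 323.415 -> total target for BSA 1.8
quadratic_per_m2 <- function(temp_c, coeffs = canonical_coeffs(),
                             validity_range = c(24, 37),
                             extrapolate = FALSE) {
  if (!inherits(coeffs, "tado2i_quad_coeffs")) {
    parameter_error("`coeffs` must be created with quad_coeffs()")
  }
  check_temp_range(temp_c, validity_range, extrapolate)
  coeffs$a * temp_c^2 + coeffs$b * temp_c + coeffs$c
}

#' Q10 exponential model: per-m2 prediction
#'
#' Evaluates \eqn{baseline \cdot q10^{(T_{ref} - T)/10}}. At the reference
#' temperature the prediction equals the baseline exactly; for `q10 < 1` it
#' is strictly increasing in temperature.
#'
#' @inheritParams quadratic_per_m2
#' @param model a [q10_model()] object.
#' @return per-m2 critical DO2i in mL/min/m2.
#' @export
q10_per_m2 <- function(temp_c, model = q10_model(),
                       validity_range = c(24, 37), extrapolate = FALSE) {
  if (!inherits(model, "tado2i_q10_model")) {
    parameter_error("`model` must be created with q10_model()")
  }
  check_temp_range(temp_c, validity_range, extrapolate)
  model$baseline_do2i * model$q10^((model$ref_temp - temp_c) / 10)
}

#' Van't Hoff linear model: per-m2 prediction
#'
#' Evaluates \eqn{baseline \cdot (1 - f \cdot (T_{ref} - T))} with `f` the
#' fractional decrease per °C. Predictions must remain non-negative inside
#' the validity range; a parameterization that would go negative there is
#' rejected.
#'
#' @inheritParams quadratic_per_m2
#' @param model a [linear_model()] object.
#' @return per-m2 critical DO2i in mL/min/m2.
#' @export
linear_per_m2 <- function(temp_c, model = linear_model(),
                          validity_range = c(24, 37), extrapolate = FALSE) {
  if (!inherits(model, "tado2i_linear_model")) {
    parameter_error("`model` must be created with linear_model()")
  }
  check_temp_range(temp_c, validity_range, extrapolate)
  pred <- model$baseline_do2i *
    (1 - model$fraction_per_degree * (model$ref_temp - temp_c))
  in_range <- if (is.null(validity_range)) {
    rep(TRUE, length(pred))
  } else {
    temp_c >= validity_range[1] & temp_c <= validity_range[2]
  }
  if (any(pred[in_range] < 0)) {
    parameter_error(
      "linear model parameters yield a negative DO2i inside the validity range")
  }
  pred
}

#' Scale a per-m2 target by body surface area
#'
#' Converts an indexed target (mL/min/m2) into a total oxygen-delivery
#' target (mL/min) for a given patient: \eqn{taDO_{2i} = f(T) \cdot BSA}.
#' Scale the full-precision per-m2 value and round the product for display;
#' scaling an already-rounded value changes the last digit.
#'
#' @param per_m2 per-m2 DO2i value(s), mL/min/m2, non-negative.
#' @param patient a [patient()] object, or a bare BSA value in m2.
#' @return total DO2 target(s) in mL/min.
#' @export
#' @examples
#' scale_by_bsa(quadratic_per_m2(30), patient(bsa = 1.8))  # 323.415
scale_by_bsa <- function(per_m2, patient) {
  if (!is.numeric(per_m2) || anyNA(per_m2) || any(per_m2 < 0)) {
    parameter_error("`per_m2` must be non-negative numeric")
  }
  p <- as_patient(patient)
  per_m2 * p$bsa
}

#' Body surface area from height and weight
#'
#' DuBois: \eqn{0.007184 \cdot h^{0.725} \cdot w^{0.425}};
#' Mosteller: \eqn{\sqrt{h w / 3600}} (h in cm, w in kg, result in m2).
#' DuBois is the default, being the most common convention in perfusion
#' practice.
#'
#' @param height_cm height in cm (30--250).
#' @param weight_kg weight in kg (1--300).
#' @param formula `"dubois"` or `"mosteller"`.
#' @return BSA in m2.
#' @export
#' @examples
#' bsa_from_anthropometrics(180, 75)               # ~1.94
#' bsa_from_anthropometrics(180, 72, "mosteller")  # sqrt(3.6) ~ 1.897
bsa_from_anthropometrics <- function(height_cm, weight_kg,
                                     formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  stopifnot_scalar_number(height_cm, "height_cm")
  stopifnot_scalar_number(weight_kg, "weight_kg")
  if (height_cm < 30 || height_cm > 250) {
    parameter_error("`height_cm` must lie within 30-250 cm")
  }
  if (weight_kg < 1 || weight_kg > 300) {
    parameter_error("`weight_kg` must lie within 1-300 kg")
  }
  switch(formula,
    dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425,
    mosteller = sqrt(height_cm * weight_kg / 3600)
  )
}

#' Model parameter bundle
#'
#' Collects the parameters of the three models plus the validity-range
#' policy, for use by the trajectory and CLI layers. Defaults are the
#' canonical published parameters.
#'
#' @param coeffs quadratic coefficients ([canonical_coeffs()] by default).
#' @param q10 a [q10_model()].
#' @param linear a [linear_model()].
#' @param validity_range numeric range in °C, or `NULL` to disable checks.
#' @param extrapolate downgrade out-of-range errors to warnings.
#' @return An object of class `tado2i_params`.
#' @export
tado2i_params <- function(coeffs = canonical_coeffs(), q10 = q10_model(),
                          linear = linear_model(),
                          validity_range = c(24, 37), extrapolate = FALSE) {
  if (!inherits(coeffs, "tado2i_quad_coeffs")) {
    parameter_error("`coeffs` must be created with quad_coeffs()")
  }
  if (!inherits(q10, "tado2i_q10_model")) {
    parameter_error("`q10` must be created with q10_model()")
  }
  if (!inherits(linear, "tado2i_linear_model")) {
    parameter_error("`linear` must be created with linear_model()")
  }
  if (!is.null(validity_range) &&
      (!is.numeric(validity_range) || length(validity_range) != 2L ||
       validity_range[1] >= validity_range[2])) {
    parameter_error("`validity_range` must be c(lo, hi) with lo < hi, or NULL")
  }
  structure(list(coeffs = coeffs, q10 = q10, linear = linear,
                 validity_range = validity_range,
                 extrapolate = isTRUE(extrapolate)),
            class = "tado2i_params")
}
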