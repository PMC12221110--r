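#' Temperature profile of a bypass run
#'
#' Time-stamped core temperatures across the thermal phases of
#' cardiopulmonary bypass (cooling, hypothermia maintenance, rewarming).
#' Times are minutes from bypass start and must be strictly increasing;
#' temperatures are screened against a loose plausibility window of
#' 15--40 °C at read time (the tighter model validity range is enforced
#' when targets are computed).
#'
#' @param time_min numeric vector, minutes from bypass start, strictly
#'   increasing.
#' @param temp_c numeric vector of core temperatures (°C).
#' @return A data frame of class `tado2i_profile`.
#' @export
temperature_profile <- function(time_min, temp_c) {
  if (!is.numeric(time_min) || !is.numeric(temp_c) ||
      length(time_min) != length(temp_c) || length(time_min) < 1L ||
      anyNA(time_min) || anyNA(temp_c)) {
    parameter_error(
      "`time_min` and `temp_c` must be equal-length numeric without NA")
  }
  if (any(diff(time_min) <= 0)) {
    parameter_error("`time_min` must be strictly increasing")
  }
  if (any(temp_c < 15 | temp_c > 40)) {
    parameter_error("profile temperatures must lie within 15-40 °C")
  }
  structure(data.frame(time_min = as.numeric(time_min),
                       temp_c = as.numeric(temp_c)),
            class = c("tado2i_profile", "data.frame"))
}

#' Per-model DO2i target trajectory over a temperature profile
#'
#' Applies the three critical-DO2i models row-wise to a temperature profile
#' and scales the quadratic (taDO2i) prediction by the patient's BSA. No
#' interpolation is performed between samples: targets are computed at the
#' given time points only, and resampling is the caller's concern. A pure
#' function of its inputs.
#'
#' @param profile a [temperature_profile()].
#' @param patient a [patient()] object or bare BSA (m2).
#' @param params a [tado2i_params()] bundle.
#' @return A data frame of class `tado2i_trajectory` with columns
#'   `time_min`, `temp_c`, `linear_do2i`, `q10_do2i`, `tado2i_per_m2`
#'   (all mL/min/m2) and `tado2i_total` (mL/min), full precision.
#' @export
#' @examples
#' prof <- temperature_profile(c(0, 20, 60, 90), c(36, 30, 30, 36.5))
#' compute_trajectory(prof, patient(bsa = 1.8))
compute_trajectory <- function(profile, patient, params = tado2i_params()) {
  if (!inherits(profile, "tado2i_profile")) {
    parameter_error("`profile` must be created with temperature_profile()")
  }
  p <- as_patient(patient)
  tt <- profile$temp_c
  if (!is.null(params$validity_range) && !params$extrapolate) {
    out <- tt < params$validity_range[1] | tt > params$validity_range[2]
    if (any(out)) {
      i <- which(out)[1]
      range_error(sprintf(
        "profile temperature %g °C at time %g min is outside the validity range [%g, %g] °C",
        tt[i], profile$time_min[i],
        params$validity_range[1], params$validity_range[2]))
    }
  }
  per_m2 <- quadratic_per_m2(tt, params$coeffs, params$validity_range,
                             params$extrapolate)
  structure(data.frame(
    time_min = profile$time_min,
    temp_c = tt,
    linear_do2i = linear_per_m2(tt, params$linear, params$validity_range,
                                params$extrapolate),
    q10_do2i = q10_per_m2(tt, params$q10, params$validity_range,
                          params$extrapolate),
    tado2i_per_m2 = per_m2,
    tado2i_total = scale_by_bsa(pmax(per_m2, 0), p)
  ), bsa = p$bsa, class = c("tado2i_trajectory", "data.frame"))
}

#' Model comparison table at selected temperatures
#'
#' One row per temperature with the per-m2 predictions of the linear, Q10
#' and quadratic models plus the BSA-scaled total, rounded (by default to 1
#' decimal) for display. Totals are computed from the full-precision per-m2
#' values before rounding.
#'
#' @param temps numeric vector of core temperatures (°C); may be empty.
#' @param patient a [patient()] object or bare BSA (m2).
#' @param params a [tado2i_params()] bundle.
#' @param digits display rounding (default 1); `NULL` for full precision.
#' @return A data frame with columns `temp_c`, `linear_do2i`, `q10_do2i`,
#'   `tado2i_per_m2`, `tado2i_total`.
#' @export
#' @examples
#' comparison_table(c(25, 28, 30, 33, 35, 37), patient(bsa = 1.8))
comparison_table <- function(temps, patient, params = tado2i_params(),
                             digits = 1L) {
  p <- as_patient(patient)
  if (length(temps) == 0L) {
    return(data.frame(temp_c = numeric(0), linear_do2i = numeric(0),
                      q10_do2i = numeric(0), tado2i_per_m2 = numeric(0),
                      tado2i_total = numeric(0)))
  }
  per_m2 <- quadratic_per_m2(temps, params$coeffs, params$validity_range,
                             params$extrapolate)
  data.frame(
    temp_c = temps,
    linear_do2i = round_display(
      linear_per_m2(temps, params$linear, params$validity_range,
                    params$extrapolate), digits),
    q10_do2i = round_display(
      q10_per_m2(temps, params$q10, params$validity_range,
                 params$extrapolate), digits),
    tado2i_per_m2 = round_display(per_m2, digits),
    tado2i_total = round_display(scale_by_bsa(pmax(per_m2, 0), p), digits)
  )
}

#' Pump flow needed to deliver a total-DO2 target
#'
#' Utility helper, not part of the published target model: converts a total
#' oxygen-delivery target into the pump flow that achieves it at the current
#' arterial oxygen content,
#' \deqn{CaO_2 = 1.36 \cdot Hb \cdot SaO_2/100 + 0.003 \cdot PaO_2}
#' (mL O2/dL), \eqn{flow = DO_2 / (CaO_2 \times 10)} (L/min). The constants
#' 1.36 mL O2/g Hb and 0.003 mL O2/dL/mmHg are the common clinical
#' convention for hemoglobin-bound and dissolved oxygen.
#'
#' @param total_do2 total oxygen-delivery target, mL/min (>= 0).
#' @param hb_g_dl hemoglobin, g/dL (2--25).
#' @param sao2_pct arterial oxygen saturation, percent (50--100).
#' @param pao2_mmhg arterial oxygen tension, mmHg (30--700).
#' @return pump flow in L/min.
#' @export
#' @examples
#' flow_target(507, hb_g_dl = 10, sao2_pct = 100, pao2_mmhg = 150)
flow_target <- function(total_do2, hb_g_dl, sao2_pct, pao2_mmhg) {
  if (!is.numeric(total_do2) || anyNA(total_do2) || any(total_do2 < 0)) {
    parameter_error("`total_do2` must be non-negative numeric")
  }
  stopifnot_scalar_number(hb_g_dl, "hb_g_dl")
  stopifnot_scalar_number(sao2_pct, "sao2_pct")
  stopifnot_scalar_number(pao2_mmhg, "pao2_mmhg")
  if (hb_g_dl < 2 || hb_g_dl > 25) {
    parameter_error("`hb_g_dl` must lie within 2-25 g/dL")
  }
  if (sao2_pct < 50 || sao2_pct > 100) {
    parameter_error("`sao2_pct` must lie within 50-100%")
  }
  if (pao2_mmhg < 30 || pao2_mmhg > 700) {
    parameter_error("`pao2_mmhg` must lie within 30-700 mmHg")
  }
  cao2 <- 1.36 * hb_g_dl * (sao2_pct / 100) + 0.003 * pao2_mmhg
  total_do2 / (cao2 * 10)
}
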