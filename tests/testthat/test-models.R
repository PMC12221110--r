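test_that("worked examples reproduce at the printed precision", {
  # Q10 exponential at 28 C: 300 * 0.6^(9/10) ~ 189.4
  expect_equal(round(q10_per_m2(28), 1), 189.4)
  # Van't Hoff linear at 28 C: 300 * 0.46 = 138.0
  expect_equal(linear_per_m2(28), 138.0)
  # quadratic at 30 C: 0.057*900 + 10.754*30 - 194.245 = 179.675, unrounded
  expect_equal(quadratic_per_m2(30), 179.675)
  # total at BSA 1.8: 179.675 * 1.8 = 323.415 -> displayed 323.4
  expect_equal(scale_by_bsa(quadratic_per_m2(30), patient(bsa = 1.8)),
               323.415)
  expect_equal(round(scale_by_bsa(quadratic_per_m2(30), 1.8), 1), 323.4)
})

test_that("models return their baseline at the reference temperature", {
  expect_identical(q10_per_m2(37), 300)
  expect_identical(linear_per_m2(37), 300)
  # quadratic normothermic value is set by the calibrated coefficients
  expect_equal(round(quadratic_per_m2(37), 1), 281.7)
  # one full decade of cooling: exactly baseline * q10 (range check off)
  expect_equal(q10_per_m2(27, q10_model(300, 0.6, 37)), 180.0)
})

test_that("quadratic intercept and parameter overrides behave", {
  cf <- quad_coeffs(2, -3, 7)
  expect_identical(quadratic_per_m2(0, cf, validity_range = NULL), 7)
  expect_equal(quadratic_per_m2(c(1, 2), cf, validity_range = NULL),
               c(2 - 3 + 7, 8 - 6 + 7))
  expect_error(quad_coeffs(NA, 1, 2), class = "tado2i_parameter_error")
})

test_that("validity range is enforced, extrapolation downgrades to warning", {
  expect_error(quadratic_per_m2(20), class = "tado2i_range_error")
  expect_error(q10_per_m2(38.5), class = "tado2i_range_error")
  expect_error(linear_per_m2(23.9), class = "tado2i_range_error")
  expect_warning(v <- quadratic_per_m2(20, extrapolate = TRUE),
                 "extrapolating")
  expect_equal(v, 0.057 * 400 + 10.754 * 20 - 194.245)
  # disabled checking is silent
  expect_silent(q10_per_m2(15, validity_range = NULL))
})

test_that("model constructors validate their invariants", {
  expect_error(q10_model(baseline_do2i = -1), class = "tado2i_parameter_error")
  expect_error(q10_model(q10 = 1.4), class = "tado2i_parameter_error")
  expect_error(q10_model(ref_temp = 25), class = "tado2i_parameter_error")
  expect_error(linear_model(fraction_per_degree = 0.12),
               class = "tado2i_parameter_error")
  # a slope that goes negative inside the validity range is rejected at
  # evaluation time: 8%/degree crosses zero at 24.5 C
  expect_error(linear_per_m2(24, linear_model(300, 0.08, 37)),
               class = "tado2i_parameter_error")
})

test_that("BSA derivation matches the closed-form oracles", {
  # frozen oracle values: direct evaluation of the published formulas
  expect_equal(bsa_from_anthropometrics(180, 75, "dubois"), 1.9424056,
               tolerance = 1e-6)
  expect_equal(bsa_from_anthropometrics(180, 72, "mosteller"), sqrt(3.6))
  expect_identical(bsa_from_anthropometrics(100, 36, "mosteller"), 1.0)
  expect_error(bsa_from_anthropometrics(20, 70), class = "tado2i_parameter_error")
  expect_error(bsa_from_anthropometrics(170, 400), class = "tado2i_parameter_error")
  p <- patient(height_cm = 180, weight_kg = 75)
  expect_equal(p$bsa, bsa_from_anthropometrics(180, 75))
  expect_error(patient(bsa = 5), class = "tado2i_parameter_error")
  expect_error(patient(), class = "tado2i_parameter_error")
  # derived BSA must satisfy the same bounds as a direct one
  expect_error(patient(height_cm = 240, weight_kg = 250),
               class = "tado2i_parameter_error")
})

test_that("scale_by_bsa is linear in both arguments", {
  xs <- c(0, 50, 179.675, 300)
  for (b in c(0.5, 1.0, 1.4, 2.8)) {
    expect_equal(scale_by_bsa(xs, patient(bsa = b)), xs * b)
    expect_equal(scale_by_bsa(xs, patient(bsa = 2 * b / 2)),
                 scale_by_bsa(xs, b))
  }
  expect_identical(scale_by_bsa(123.4, 1.0), 123.4)
  expect_error(scale_by_bsa(-1, 1.8), class = "tado2i_parameter_error")
})

test_that("all three models are strictly increasing over 24-37 C", {
  tt <- seq(24, 37, by = 0.25)
  for (f in list(quadratic_per_m2,
                 function(x) q10_per_m2(x),
                 function(x) linear_per_m2(x))) {
    expect_true(all(diff(f(tt)) > 0))
  }
  # quadratic derivative 2aT + b stays positive across the range
  expect_true(all(2 * 0.057 * tt + 10.754 > 0))
})

test_that("model ordering below normothermia matches the published table", {
  # Both sub-normothermic per-m2 curves sit below the Q10 curve everywhere
  # in the table; the linear and quadratic curves cross between 30 and
  # 33 C: in deep/moderate hypothermia (<= 30) the linear model is the
  # lowest (it over-suppresses), while in mild hypothermia (33, 35) it
  # overshoots the quadratic. This is exactly the pattern of the published
  # comparison table, row by row.
  for (tt in c(25, 28, 30, 33, 35)) {
    expect_lt(quadratic_per_m2(tt), q10_per_m2(tt))
    expect_lt(linear_per_m2(tt), q10_per_m2(tt))
  }
  for (tt in c(25, 28, 30)) {
    expect_lt(linear_per_m2(tt), quadratic_per_m2(tt))
  }
  for (tt in c(33, 35)) {
    expect_gt(linear_per_m2(tt), quadratic_per_m2(tt))
  }
})

test_that("composing the operations reproduces every published table cell", {
  for (i in seq_len(nrow(table1))) {
    tt <- table1$temp_c[i]
    expect_equal(round(linear_per_m2(tt), 1), table1$linear_do2i[i])
    expect_equal(round(q10_per_m2(tt), 1), table1$q10_do2i[i])
    per <- quadratic_per_m2(tt)
    expect_equal(round(per, 1), table1$tado2i_per_m2[i])
    expect_equal(round(scale_by_bsa(per, table1_bsa), 1),
                 table1$tado2i_total[i])
  }
})
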