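test_that("noise-free self-fit recovers the canonical coefficients exactly", {
  fit <- fit_quadratic(noise_free_canonical())
  expect_equal(fit$coeffs$a, canonical_abc[["a"]], tolerance = 1e-11)
  expect_equal(fit$coeffs$b, canonical_abc[["b"]], tolerance = 1e-11)
  expect_equal(fit$coeffs$c, canonical_abc[["c"]], tolerance = 1e-11)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$see, 1e-9)
})

test_that("fit matches the brute-force normal-equations oracle", {
  # several seeded noisy datasets plus the printed 6-point comparison column
  cases <- lapply(1:5, function(s) {
    d <- generate_dataset(synthetic_spec(seed = s))
    list(tt = d$temp_c, y = d$do2i_per_m2)
  })
  cases <- c(cases, list(list(tt = table1$temp_c, y = table1$q10_do2i)))
  for (cs in cases) {
    fit <- fit_quadratic(calibration_dataset(cs$tt, cs$y))
    ora <- oracle_quad_fit(cs$tt, cs$y)
    expect_equal(c(a = fit$coeffs$a, b = fit$coeffs$b, c = fit$coeffs$c),
                 ora$coeffs, tolerance = 1e-8)
    expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-10)
    expect_equal(fit$see, ora$see, tolerance = 1e-8)
  }
})

test_that("the printed Q10 comparison points fit a quadratic with R^2 > 0.99", {
  fit <- fit_quadratic(calibration_dataset(table1$temp_c, table1$q10_do2i))
  expect_gt(fit$r_squared, 0.99)
})

test_that("degenerate designs are rejected as such", {
  expect_error(fit_quadratic(calibration_dataset(c(30, 30, 30), c(180, 181, 179))),
               class = "tado2i_degenerate_error")
  expect_error(fit_quadratic(calibration_dataset(c(28, 30, 32), c(150, 180, 210))),
               class = "tado2i_degenerate_error")  # n = 3 < 4
  expect_error(
    fit_quadratic(calibration_dataset(c(30, 30, 30, 30), c(180, 181, 179, 182))),
    class = "tado2i_degenerate_error")
  expect_error(calibration_dataset(c(30, 45), c(100, 100)),
               class = "tado2i_parameter_error")
  expect_error(calibration_dataset(30, -5), class = "tado2i_parameter_error")
})

test_that("r_squared is invariant under rescaling the response", {
  d <- generate_dataset(synthetic_spec(seed = 11))
  r2 <- fit_quadratic(d)$r_squared
  for (k in c(0.2, 3, 1000)) {
    r2k <- fit_quadratic(calibration_dataset(d$temp_c, k * d$do2i_per_m2))$r_squared
    expect_equal(r2k, r2, tolerance = 1e-12)
  }
})

test_that("bootstrap is seed-reproducible, seed-sensitive, and contains the fit", {
  d <- generate_dataset(synthetic_spec(seed = 42))
  b1 <- bootstrap_coefficients(d, n_resamples = 1000, seed = 42)
  b2 <- bootstrap_coefficients(d, n_resamples = 1000, seed = 42)
  expect_identical(b1$ci, b2$ci)
  # intervals bracket the full-data point estimates
  expect_true(all(b1$ci[, "lower"] <= b1$estimates))
  expect_true(all(b1$estimates <= b1$ci[, "upper"]))
  # a different seed gives different intervals that still overlap the estimate
  b3 <- bootstrap_coefficients(d, n_resamples = 1000, seed = 43)
  expect_false(identical(b1$ci, b3$ci))
  expect_true(all(b3$ci[, "lower"] <= b3$estimates &
                    b3$estimates <= b3$ci[, "upper"]))
  # the caller's RNG stream is untouched by seeded calls
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(bootstrap_coefficients(d, 200, seed = 5))
  expect_identical(rnorm(3), before)
})

test_that("bootstrap on noise-free data collapses to the true coefficients", {
  d <- noise_free_canonical(seq(24, 37, by = 1))
  b <- bootstrap_coefficients(d, n_resamples = 200, seed = 1)
  widths <- b$ci[, "upper"] - b$ci[, "lower"]
  expect_true(all(widths < 1e-6))
  expect_true(all(b$ci[, "lower"] - 1e-7 <= canonical_abc &
                    canonical_abc <= b$ci[, "upper"] + 1e-7))
})

test_that("bootstrap input validation", {
  d <- generate_dataset(synthetic_spec(seed = 1))
  small <- calibration_dataset(c(25, 27, 29, 31, 33),
                               quadratic_per_m2(c(25, 27, 29, 31, 33)))
  expect_error(bootstrap_coefficients(small, 1000, seed = 1),
               class = "tado2i_parameter_error")
  expect_error(bootstrap_coefficients(d, 50, seed = 1),
               class = "tado2i_parameter_error")
  expect_error(bootstrap_coefficients(d, 1000, confidence = 1.2, seed = 1),
               class = "tado2i_parameter_error")
  expect_error(bootstrap_coefficients(d, 1000), "seed")
})

test_that("parameter recovery: coefficients within 3 bootstrap SEs", {
  # canonical quadratic + sd-3 noise on the 27-point grid; in >= 90% of 100
  # seeded replicates each coefficient is within 3 bootstrap SEs of truth
  n_rep <- 100
  ok <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    d <- generate_dataset(synthetic_spec(generator_model = "quadratic",
                                         noise_sd = 3, seed = s))
    b <- bootstrap_coefficients(d, n_resamples = 200, seed = s + 10000)
    ok[s] <- all(abs(b$estimates - canonical_abc) <= 3 * b$se)
  }
  expect_gte(mean(ok), 0.90)
})
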