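# Shared fixtures and independent oracles.

# The published model-comparison table at BSA = 1.8 m2 (values as printed,
# 1-decimal display rounding; totals scale the unrounded per-m2 value).
table1 <- data.frame(
  temp_c        = c(25,    28,    30,    33,    35,    37),
  linear_do2i   = c(84,    138,   174,   228,   264,   300),
  q10_do2i      = c(162.5, 189.4, 209.8, 244.6, 270.9, 300),
  tado2i_per_m2 = c(110.2, 151.6, 179.7, 222.7, 252.0, 281.7),
  tado2i_total  = c(198.4, 272.8, 323.4, 400.9, 453.5, 507.0)
)

table1_bsa <- 1.8

# Independent least-squares oracle: brute-force normal equations on the
# explicit design matrix (deliberately not the QR path the package uses).
# Returns coefficients in (a, b, c) order.
oracle_quad_fit <- function(tt, y) {
  X <- cbind(1, tt, tt^2)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  list(
    coeffs = c(a = beta[3], b = beta[2], c = beta[1]),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    see = sqrt(sum(res^2) / (length(y) - 3))
  )
}

canonical_abc <- c(a = 0.057, b = 10.754, c = -194.245)

# Noise-free dataset sampled exactly from the canonical quadratic.
noise_free_canonical <- function(tt = seq(24, 37, by = 1)) {
  calibration_dataset(tt, quadratic_per_m2(tt))
}
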