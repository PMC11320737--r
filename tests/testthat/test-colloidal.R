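test_that("kD regression inverts the linear diffusion law exactly", {
  s <- make_dls_series(5e-11, -30, c(1, 5, 10, 20))$dapp
  f <- fit_kd(s)
  expect_equal(f$d0, 5e-11, tolerance = 1e-12)
  expect_equal(f$kd, -30, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  flat <- concentration_series(c(1, 5, 10), rep(4e-11, 3), "Dapp")
  expect_equal(fit_kd(flat)$kd, 0)
  same_c <- concentration_series(rep(5, 3), c(1, 2, 3) * 1e-11, "Dapp")
  expect_error(fit_kd(same_c), "singular")
})

test_that("kD point estimates equal the closed-form OLS oracle", {
  for (seed in 1:25) {
    noise <- noise_spec("gaussian", 0.02 * 5e-11, seed = seed)
    s <- make_dls_series(5e-11, -30, c(1, 2, 5, 10, 15, 20), noise = noise)$dapp
    f <- fit_kd(s)
    beta <- ols_oracle(s$concentration, s$value)
    expect_equal(f$d0, beta[1L], tolerance = 1e-10)
    expect_equal(f$kd, 1000 * beta[2L] / beta[1L], tolerance = 1e-10)
  }
})

test_that("noisy kD estimates are unbiased at the study noise level", {
  kds <- vapply(1:200, function(seed) {
    s <- make_dls_series(5e-11, -30, c(1, 2, 5, 10, 15, 20),
                         noise = noise_spec("gaussian", 0.02 * 5e-11,
                                            seed = seed))$dapp
    fit_kd(s)$kd
  }, numeric(1))
  expect_lt(abs(mean(kds) - (-30)) / 30, 0.05)
})

test_that("kD estimate is invariant to row order and dataset duplication", {
  s <- make_dls_series(4e-11, -22, c(1, 3, 8, 15, 20),
                       noise = noise_spec("gaussian", 5e-13, seed = 3L))$dapp
  f <- fit_kd(s)
  shuffled <- concentration_series(rev(s$concentration), rev(s$value), "Dapp")
  doubled <- concentration_series(rep(s$concentration, 2), rep(s$value, 2), "Dapp")
  expect_equal(fit_kd(shuffled)$kd, f$kd, tolerance = 1e-12)
  expect_equal(fit_kd(doubled)$kd, f$kd, tolerance = 1e-12)
})

test_that("attraction flag uses a strict -15 mL/g boundary", {
  mk <- function(kd) structure(list(kd = kd), class = "kd_fit")
  expect_equal(classify_kd(mk(-20)), "attractive_flag")
  expect_equal(classify_kd(mk(-15)), "pass")
  expect_equal(classify_kd(mk(5)), "pass")
})

test_that("trend fits recover both published Z-average parameter pairs", {
  for (ab in list(c(0.46, 0.87), c(0.2, 0.92))) {
    s <- make_dls_series(5e-11, -30, c(1, 2, 5, 10, 20), zave_params = ab)
    tr <- fit_trends(s$dapp, s$zave)
    expect_equal(tr$zave_log$slope, ab[1L], tolerance = 1e-10)
    expect_equal(tr$zave_log$intercept, ab[2L], tolerance = 1e-10)
    expect_equal(tr$zave_log$r_squared, 1, tolerance = 1e-12)
  }
  # constant diffusion coefficient -> zero decay rate
  d_flat <- concentration_series(c(1, 5, 10, 20), rep(4.5e-11, 4), "Dapp")
  z <- make_dls_series(5e-11, -30, c(1, 5, 10, 20))$zave
  expect_equal(fit_trends(d_flat, z)$d_exp$rate, 0, tolerance = 1e-12)
  bad <- concentration_series(c(1, 5, 10), c(1e-11, -1e-11, 1e-11), "Dapp")
  expect_error(fit_trends(bad, z), "nonpositive")
})

test_that("GSE viscosity reproduces the closed-form value for a known fluid", {
  # constant dH = 10 nm and D = 4.3611e-11 m^2/s at 298 K give ~1.00 cP
  trends <- structure(list(
    d_exp = list(amplitude = 4.3611e-11, rate = 0, r_squared = 1),
    zave_log = list(slope = 0, intercept = 1, r_squared = 1)),
    class = "trend_fits")
  g <- gse_viscosity(trends, c(1, 10, 100), temperature = 298)
  expect_true(all(abs(g$eta_theoretical - 1.00) < 0.01))
  # doubling D at fixed dH halves eta
  trends2 <- trends
  trends2$d_exp$amplitude <- 2 * 4.3611e-11
  g2 <- gse_viscosity(trends2, c(1, 10, 100))
  expect_equal(g2$eta_theoretical, g$eta_theoretical / 2, tolerance = 1e-12)
})

test_that("GSE viscosity rises once diffusion decay dominates diameter growth", {
  # d log eta / dc = rate - slope/c, positive for c > slope/rate = 15 mg/mL
  trends <- structure(list(
    d_exp = list(amplitude = 5e-11, rate = 0.02, r_squared = 1),
    zave_log = list(slope = 0.3, intercept = 1, r_squared = 1)),
    class = "trend_fits")
  g <- gse_viscosity(trends, seq(20, 180, by = 5))
  expect_true(all(diff(g$eta_theoretical) > 0))
  expect_true(all(g$eta_theoretical > 0))
})
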