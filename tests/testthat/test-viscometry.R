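make_eta_series <- function(model, params, conc, noise = noise_spec()) {
  rec <- make_viscosity_curve(model, params, conc, noise = noise)
  aggregate_records(filter_records(rec, quiet = TRUE))
}

test_that("record filtering enforces the steady-plateau and R^2 rules", {
  rec <- data.frame(concentration = rep(50, 10), shear_rate = 1000,
                    viscosity = 5,
                    pressure_fit_r2 = c(0.999, 0.997, 0.9985, 0.996, 0.9991,
                                        0.998, 0.9979, 0.9995, 1, 0.999),
                    steady = TRUE)
  kept <- suppressMessages(filter_records(rec))
  expect_equal(nrow(kept), 7L)                  # 3 of 10 fall below 0.998
  expect_true(all(kept$pressure_fit_r2 >= 0.998))
  rec$steady[1L] <- FALSE
  expect_equal(nrow(suppressMessages(filter_records(rec))), 6L)
  all_bad <- data.frame(concentration = 1, shear_rate = 1, viscosity = 1,
                        pressure_fit_r2 = 0.9, steady = TRUE)
  expect_error(suppressMessages(filter_records(all_bad)), "filtered out")
})

test_that("multi-shear records are averaged only on a Newtonian plateau", {
  rec <- make_viscosity_curve("expgrowth", expgrowth_params(1.2, 0.02),
                              c(10, 50), shear_rates = c(100, 1000, 2000))
  agg <- aggregate_records(rec)
  expect_equal(nrow(agg), 2L)
  rec$viscosity[1L] <- rec$viscosity[1L] * 1.2   # shear-thinning spread
  expect_error(aggregate_records(rec), "non-Newtonian")
})

test_that("exponential-growth fit inverts noiseless model data", {
  s <- make_eta_series("expgrowth", expgrowth_params(1.2, 0.024), seq(10, 150, 20))
  f <- fit_expgrowth(s)
  expect_equal(f$params$y0, 1.2, tolerance = 1e-8)
  expect_equal(f$params$k_rate, 0.024, tolerance = 1e-8)
  flat <- make_eta_series("expgrowth", expgrowth_params(3, 0), c(10, 50, 100))
  ff <- fit_expgrowth(flat)
  expect_equal(ff$sse, 0, tolerance = 1e-12)
})

test_that("exponential-growth SSE matches an independent grid+polish oracle", {
  for (seed in c(2L, 9L)) {
    s <- make_eta_series("expgrowth", expgrowth_params(1.2, 0.024),
                         seq(10, 150, 20),
                         noise = noise_spec("gaussian", 0.3, seed = seed))
    f <- fit_expgrowth(s)
    oracle <- expgrowth_oracle_sse(s$concentration, s$value)
    expect_lt(f$sse, oracle + 1e-8)
  }
})

test_that("Tomar fit is the exact log-linear OLS solution", {
  s <- make_eta_series("tomar", tomar_params(0.15, 0.021), seq(5, 150, 15))
  f <- fit_tomar(s)
  expect_equal(f$params$ln_a, 0.15, tolerance = 1e-10)
  expect_equal(f$params$b_slope, 0.021, tolerance = 1e-10)
  # equals the closed-form normal-equations oracle on noisy data
  sn <- make_eta_series("tomar", tomar_params(0.1, 0.02), seq(10, 150, 20),
                        noise = noise_spec("gaussian", 0.2, seed = 4L))
  fn <- fit_tomar(sn)
  beta <- ols_oracle(sn$concentration, log(sn$value / 1.13))
  expect_equal(fn$params$ln_a, beta[1L], tolerance = 1e-10)
  expect_equal(fn$params$b_slope, beta[2L], tolerance = 1e-10)
})

test_that("Ross-Minton fit recovers the identifiable parameters from clean data", {
  # k and v enter only through k/v, so the ratio and [eta] are what a fit
  # can pin down; SSE at the optimum must be numerically zero
  s <- make_eta_series("rossminton", rossminton_params(6.3, 0.37, 0.80),
                       seq(10, 150, 20))
  f <- fit_rossminton(s)
  expect_equal(f$params$eta_intrinsic, 6.3, tolerance = 1e-4)
  expect_equal(f$params$k_crowding / f$params$v_shape, 0.37 / 0.80,
               tolerance = 1e-4)
  expect_lt(f$sse, 1e-8)
})

test_that("Ross-Minton SSE never exceeds the dense-grid oracle", {
  lower <- c(1, 0.01, 0.05); upper <- c(60, 5, 5)
  for (seed in 1:5) {
    s <- make_eta_series("rossminton", rossminton_params(6.3, 0.37, 0.80),
                         seq(10, 150, 20),
                         noise = noise_spec("gaussian", 0.5, seed = seed))
    f <- fit_rossminton(s, bounds = list(lower = lower, upper = upper))
    oracle <- rm_grid_oracle(s$concentration, s$value, 1.13, lower, upper,
                             n = 25L)
    expect_lte(f$sse, oracle + 1e-9)
  }
})

test_that("interpolation evaluates each model's closed form", {
  tom <- fit_tomar(make_eta_series("tomar", tomar_params(0, 0), c(10, 50, 100)))
  expect_equal(interpolate_viscosity(tom, 80), 1.13, tolerance = 1e-10)
  eg <- fit_expgrowth(make_eta_series("expgrowth",
                                      expgrowth_params(1, log(2) / 100),
                                      c(10, 50, 100)))
  expect_equal(interpolate_viscosity(eg, 100), 2, tolerance = 1e-6)
  expect_warning(interpolate_viscosity(eg, 130), "extrapolating")
  # intercept consistency at c = 0 for all three models
  rm0 <- fit_rossminton(make_eta_series("rossminton",
                                        rossminton_params(6.3, 0.37, 0.8),
                                        seq(10, 150, 20)))
  expect_equal(interpolate_viscosity(rm0, 0), 1.13, tolerance = 1e-8)
  expect_equal(interpolate_viscosity(eg, 0), eg$params$y0, tolerance = 1e-10)
})

test_that("round-trip: generate, refit, interpolate at a generator-known point", {
  truth <- rossminton_params(10.4, 0.45, 0.9)
  s <- make_eta_series("rossminton", truth, seq(10, 150, 10))
  f <- fit_rossminton(s)
  c_test <- 125
  expect_equal(interpolate_viscosity(f, c_test),
               make_viscosity_curve("rossminton", truth, c_test)$viscosity,
               tolerance = 1e-4)
})

test_that("reduced viscosities follow the relative/specific/reduced chain", {
  s <- concentration_series(10, 2 * 1.13, "eta")    # c = 0.01 g/mL, eta = 2 eta0
  r <- reduced_viscosities(s, eta0 = 1.13)
  expect_equal(r$value, 100)                        # (2 - 1) / 0.01 g/mL
  s0 <- concentration_series(25, 1.13, "eta")
  expect_equal(reduced_viscosities(s0, 1.13)$value, 0)
  zero_c <- concentration_series(0, 2, "eta")
  expect_error(reduced_viscosities(zero_c, 1.13), "zero concentration")
})

test_that("Huggins regression inverts both published parameter pairs exactly", {
  for (p in list(c(10.42, 1.27), c(8.28, 5.30))) {
    red <- make_reduced_viscosity_series(p[1L], p[2L], c(5, 10, 20, 30, 40, 50))
    h <- fit_huggins(red)
    expect_equal(h$eta_intrinsic, p[1L], tolerance = 1e-10)
    expect_equal(h$k_huggins, p[2L], tolerance = 1e-10)
    # stored invariant: kH = slope/intercept^2 bit-exactly
    expect_identical(h$k_huggins, h$slope_x / h$eta_intrinsic^2)
  }
})

test_that("Huggins point estimates equal the closed-form OLS oracle", {
  red <- make_reduced_viscosity_series(9.5, 2.1, c(5, 10, 20, 30, 40, 50),
                                       noise = noise_spec("gaussian", 0.4,
                                                          seed = 12L))
  h <- fit_huggins(red)
  beta <- ols_oracle(red$concentration / 1000, red$value)
  expect_equal(h$eta_intrinsic, beta[1L], tolerance = 1e-10)
  expect_equal(h$slope_x, beta[2L], tolerance = 1e-10)
})

test_that("full pipeline inverts the reduced-viscosity generator", {
  # viscosity curve consistent with eta_red = [eta] + kH [eta]^2 c
  eta0 <- 1.13
  conc <- c(5, 10, 20, 30, 40, 50)
  red_true <- make_reduced_viscosity_series(10.42, 1.27, conc)
  eta <- eta0 * (1 + red_true$value * conc / 1000)
  h <- fit_huggins(reduced_viscosities(concentration_series(conc, eta, "eta"),
                                       eta0))
  expect_equal(h$eta_intrinsic, 10.42, tolerance = 1e-9)
  expect_equal(h$k_huggins, 1.27, tolerance = 1e-9)
})

test_that("zero-slope Huggins data yield kH = 0 with slope-only uncertainty", {
  red <- make_reduced_viscosity_series(8, 0, c(5, 15, 30, 45),
                                       noise = noise_spec("gaussian", 1e-6,
                                                          seed = 5L))
  h <- fit_huggins(red)
  expect_equal(h$k_huggins, 0, tolerance = 1e-4)
  expect_equal(h$sigma_kh, h$sigma_x / h$eta_intrinsic^2, tolerance = 1e-3)
  neg <- concentration_series(c(5, 10, 20), c(-1, -0.5, 0.2), "eta_red")
  expect_error(fit_huggins(neg), "intercept")
})

test_that("propagated kH uncertainty matches a Monte-Carlo oracle", {
  conc <- c(5, 10, 20, 30, 40, 50)
  sigma <- 0.3
  eta_i <- 10.42; kh <- 1.27
  mu <- make_reduced_viscosity_series(eta_i, kh, conc)$value
  X <- cbind(1, conc / 1000)
  XtXi <- solve(crossprod(X))
  n_mc <- 1e5
  set.seed(101)
  Y <- matrix(mu, length(conc), n_mc) +
    matrix(stats::rnorm(length(conc) * n_mc, 0, sigma), length(conc), n_mc)
  B <- XtXi %*% crossprod(X, Y)
  mc_sd <- stats::sd(B[2L, ] / B[1L, ]^2)
  # delta-method sigma at the true coefficients and true noise level
  V <- XtXi * sigma^2
  g <- c(-2 * kh * eta_i^2 / eta_i^3, 1 / eta_i^2)
  delta_sd <- sqrt(drop(t(g) %*% V %*% g))
  expect_lt(abs(delta_sd - mc_sd) / mc_sd, 0.10)
  # and the estimate from one realized fit sits near the same value
  h <- fit_huggins(make_reduced_viscosity_series(
    eta_i, kh, conc, noise = noise_spec("gaussian", sigma, seed = 77L)))
  expect_lt(abs(h$sigma_kh - mc_sd) / mc_sd, 0.75)
})

test_that("solvent-quality call uses a strict 0.5 boundary", {
  mk <- function(kh) structure(list(k_huggins = kh), class = "huggins_result")
  expect_equal(classify_solvent_quality(mk(1.27)), "poor_solvent")
  expect_equal(classify_solvent_quality(mk(0.5)), "good_solvent")
  expect_equal(classify_solvent_quality(mk(0.1)), "good_solvent")
})
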