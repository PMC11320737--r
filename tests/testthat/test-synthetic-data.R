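test_that("noise_spec validates its fields", {
  expect_s3_class(noise_spec(), "noise_spec")
  expect_error(noise_spec("none", sigma = 0.1), "sigma")
  expect_error(noise_spec("gaussian", sigma = 0), "sigma")
  expect_error(noise_spec("gaussian", sigma = -1), "nonnegative")
})

test_that("DLS generator evaluates the linear diffusion law and log Z-average", {
  s <- make_dls_series(5e-11, -30, c(1, 5, 10, 20))
  expect_equal(s$dapp$value, c(4.85e-11, 4.25e-11, 3.5e-11, 2.0e-11))
  # at c = 1 mg/mL the log term vanishes: Zave = 10^intercept
  z <- make_dls_series(5e-11, -10, c(1, 10), zave_params = c(0.46, 0.87))$zave
  expect_equal(z$value[1L], 10^0.87)
  expect_equal(z$value[2L], 10^(0.46 + 0.87))
  expect_error(make_dls_series(5e-11, -30, 10), "two distinct")
  expect_error(make_dls_series(5e-11, -30, c(0, 10)), "strictly positive")
})

test_that("every generator is deterministic under a fixed seed", {
  ns <- noise_spec("gaussian", 1e-12, seed = 42L)
  expect_identical(make_dls_series(5e-11, -30, c(1, 5, 10, 20), noise = ns),
                   make_dls_series(5e-11, -30, c(1, 5, 10, 20), noise = ns))
  nv <- noise_spec("gaussian", 0.05, seed = 42L)
  expect_identical(
    make_viscosity_curve("expgrowth", expgrowth_params(1.2, 0.02), 1:5, noise = nv),
    make_viscosity_curve("expgrowth", expgrowth_params(1.2, 0.02), 1:5, noise = nv))
  expect_identical(make_thermogram(list(c(65, 0.1, 2)), noise = nv),
                   make_thermogram(list(c(65, 0.1, 2)), noise = nv))
  expect_identical(make_sensorgram(1e5, 1e-3, 20, c(1e-9, 1e-8), noise = nv),
                   make_sensorgram(1e5, 1e-3, 20, c(1e-9, 1e-8), noise = nv))
  expect_identical(make_score_table(10, seed = 7L), make_score_table(10, seed = 7L))
})

test_that("viscosity-curve generator matches each model's closed form at c = 0", {
  tom <- make_viscosity_curve("tomar", tomar_params(0, 0.02), 0)
  expect_equal(tom$viscosity, 1.13)
  eg <- make_viscosity_curve("expgrowth", expgrowth_params(2, 0.01), 0)
  expect_equal(eg$viscosity, 2)
  rm0 <- make_viscosity_curve("rossminton", rossminton_params(6.3, 0.37, 0.8), 0)
  expect_equal(rm0$viscosity, 1.13)
  expect_true(all(tom$pressure_fit_r2 == 1) && all(tom$steady))
  expect_error(make_viscosity_curve("mooney", list(), 1), "'arg'")
})

test_that("reduced-viscosity generator follows the Huggins relation", {
  r <- make_reduced_viscosity_series(10.42, 1.27, c(5, 10, 20))
  expect_equal(r$value, 10.42 + 1.27 * 10.42^2 * c(5, 10, 20) / 1000)
  flat <- make_reduced_viscosity_series(8, 0, c(5, 25, 50))
  expect_true(all(flat$value == 8))
  expect_error(make_reduced_viscosity_series(-1, 1, c(5, 10)), "positive")
})

test_that("thermogram generator places derivative maxima at each Tm", {
  tg <- make_thermogram(list(c(65, 0.1, 2)), step = 0.1)
  dv <- diff(tg$ratio) / diff(tg$temperature)
  expect_equal(tg$temperature[which.max(dv)], 65, tolerance = 0.11)
  tg2 <- make_thermogram(list(c(60, 0.08, 2), c(80, 0.1, 2)), step = 0.1)
  expect_error(make_thermogram(list(c(10, 0.1, 2))), "outside ramp")
  expect_error(make_thermogram(list(c(65, 0.1, 0))), "width")
  # grid-step refinement: peak positions agree within one coarse step
  fine <- find_transitions(make_thermogram(list(c(65, 0.1, 2)), step = 0.1))
  coarse <- find_transitions(make_thermogram(list(c(65, 0.1, 2)), step = 0.5))
  expect_lt(abs(fine$tm[1L] - coarse$tm[1L]), 0.5 + 1e-9)
})

test_that("plasmon-spectrum generator peaks at the requested wavelength", {
  s <- make_plasmon_spectrum(530)
  expect_equal(s$wavelength[which.max(s$absorbance)], 530)
  expect_error(make_plasmon_spectrum(700), "outside")
})

test_that("sensorgram generator follows the 1:1 closed form", {
  KD <- 1e-3 / 1e5                       # kd/ka = 10 nM
  sg <- make_sensorgram(1e5, 1e-3, 20, c(KD, 5e-8), t_assoc = 50000, dt = 100)
  a_end <- sg[sg$phase == "association" & sg$conc == KD, ]
  # at C = KD the association plateau is Rmax/2
  expect_equal(max(a_end$response), 10, tolerance = 1e-6)
  plateau <- 20 * 5e-8 / (5e-8 + KD)
  expect_equal(max(sg$response[sg$conc == 5e-8]), plateau, tolerance = 1e-6)
  expect_error(make_sensorgram(-1, 1e-3, 20, 1e-9), "positive")
})

test_that("purity tables conserve the 100% total and honour drift", {
  pt <- make_purity_table(c(97.5, 1.5, 1.0),
                          list(`5C` = c(0, 0), `25C` = c(0.5 / 7, 0.01)),
                          days = c(7, 14, 28, 57))
  expect_true(all(abs(pt$pct_monomer + pt$pct_hmws + pt$pct_lmws - 100) < 1e-9))
  cold <- pt[pt$condition == "5C", ]
  expect_true(all(cold$pct_hmws == 1.5))
  warm <- pt[pt$condition == "25C", ]
  expect_true(all(diff(warm$pct_hmws) > 0))
  expect_error(make_purity_table(c(97, 1.5, 1.0), list(a = c(0, 0)), 7),
               "sum to 100")
})

test_that("score-table generator emits one row per candidate model", {
  st <- make_score_table(10, seed = 1L)
  expect_equal(nrow(st), 10L)
  expect_true(all(c("model_id", "packing", "rmsd_to_average") %in% names(st)))
  expect_error(make_score_table(1), "at least two")
})
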