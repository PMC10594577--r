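# Two-step irreversible inhibition kinetics and Eyring interconversion.

test_that("progress model matches its closed form and limits", {
  t <- seq(0, 1800, by = 10)
  expect_equal(simulate_progress(2, 0, t), 2 * t)
  expect_equal(simulate_progress(1, log(2), 1), 0.5 / log(2))
  # plateau v0 / k_obs at long times
  expect_equal(simulate_progress(3, 0.01, 1e7), 300, tolerance = 1e-12)
  # continuity through k_obs -> 0 (relative deviation is O(k_obs * t / 2))
  expect_equal(simulate_progress(2, 1e-12, t), 2 * t, tolerance = 1e-8)
  expect_error(simulate_progress(-1, 0.1, t), class = "fepkin_input_error")
  expect_error(simulate_progress(1, -0.1, t), class = "fepkin_input_error")
})

test_that("k_obs fit recovers noiseless curves exactly and noisy ones within SE", {
  t <- seq(10, 1800, by = 10)
  clean <- progress_curve(t, simulate_progress(2, 0.003, t), 100e-9)
  fit <- fit_kobs(clean)
  expect_equal(fit$v0, 2, tolerance = 1e-8)
  expect_equal(fit$k_obs, 0.003, tolerance = 1e-8)
  set.seed(2024)
  noisy <- progress_curve(t, pmax(simulate_progress(2, 0.003, t) +
                                    stats::rnorm(length(t), 0, 0.01 * 2 / 0.003), 0),
                          100e-9)
  nfit <- fit_kobs(noisy)
  expect_lt(abs(nfit$k_obs - 0.003), 3 * nfit$se["k_obs"])
  expect_lt(abs(nfit$v0 - 2), 3 * nfit$se["v0"])
  # flat signal: k_obs unidentifiable
  expect_error(fit_kobs(progress_curve(t, rep(5, length(t)), 1e-9)),
               class = "fepkin_fit_error")
  expect_error(fit_kobs(progress_curve(1:4, 1:4, 1e-9)), "at least 5")
})

test_that("two-step fit recovers the published constants from noiseless data", {
  truth_ki <- 8.5e-9; truth_kin <- 0.00629
  curves <- gen_progress_curves(assay_design(noise_scale = 0),
                                K_i = truth_ki, k_inact = truth_kin,
                                v0_uninhibited = 10)
  fit <- fit_two_step(curves)
  expect_true(fit$identifiable)
  expect_equal(fit$K_i, truth_ki, tolerance = 1e-8)
  expect_equal(fit$k_inact, truth_kin, tolerance = 1e-8)
  expect_equal(fit$efficiency, fit$k_inact / fit$K_i)
  expect_equal(fit$efficiency, 740000, tolerance = 1e-6)
  expect_error(fit_two_step(curves[1:3]), "4 distinct")
})

test_that("substrate competition rescales the apparent K_i", {
  # generate with K_i^app = K_i * (1 + [S]/Km), fit both conventions
  ki <- 10e-9; kin <- 0.01; s_over_km <- 1.5
  design <- assay_design(noise_scale = 0)
  t <- seq(design$interval, design$duration, by = design$interval)
  curves <- lapply(design$concentrations, function(I) {
    kobs <- kin * I / (ki * (1 + s_over_km) + I)
    progress_curve(t, simulate_progress(5, kobs, t), I,
                   substrate = 15e-6, km = 10e-6)
  })
  plain <- fit_two_step(curves)
  corr <- fit_two_step(curves, competition = TRUE)
  expect_equal(plain$K_i, ki * (1 + s_over_km), tolerance = 1e-6)
  expect_equal(corr$K_i, ki, tolerance = 1e-6)
  expect_equal(corr$k_inact, kin, tolerance = 1e-6)
})

test_that("linear-regime designs only identify the efficiency", {
  ki <- 8.5e-9; kin <- 0.00629
  design <- assay_design(concentrations = ki / 100 / 2^(4:0),
                         noise_scale = 0)
  curves <- gen_progress_curves(design, ki, kin, 10)
  expect_warning(fit <- fit_two_step(curves), "identifiable")
  expect_false(fit$identifiable)
  expect_true(is.na(fit$K_i))
  expect_equal(fit$efficiency, kin / ki, tolerance = 0.05)
})

test_that("Eyring conversions reproduce the measured-rate barriers", {
  b1 <- eyring_barrier(0.040, 298)
  b2 <- eyring_barrier(0.00629, 298)
  expect_equal(b1$barrier, 19.3, tolerance = 0.1 / 19.3)
  expect_equal(b2$barrier, 20.4, tolerance = 0.1 / 20.4)
  # prefactor identity: k = kB*T/h gives a zero barrier
  expect_equal(eyring_barrier(fepkin_constants$kB_over_h * 298, 298)$barrier, 0)
  expect_equal(eyring_rate(0, 298), fepkin_constants$kB_over_h * 298)
  # round trips to 1e-10 relative
  for (k in c(0.040, 0.00629, 1e-6, 5e3)) {
    expect_equal(eyring_rate(eyring_barrier(k, 298)$barrier, 298), k,
                 tolerance = 1e-10)
  }
  # a 25 kcal/mol reverse barrier implies a rate far too slow for a 30-min assay
  k_rev <- eyring_rate(25.0, 298)
  expect_equal(k_rev, 2.9e-6, tolerance = 0.05)
  expect_gt(log(2) / k_rev, 100 * 1800)
  expect_error(eyring_barrier(0), class = "fepkin_input_error")
  expect_error(eyring_barrier(0.1, -5), class = "fepkin_input_error")
})

test_that("barrier and rate conversions are strictly monotone", {
  ks <- 10^seq(-8, 4, length.out = 25)
  bars <- vapply(ks, function(k) eyring_barrier(k, 298)$barrier, numeric(1))
  expect_true(all(diff(bars) < 0))
  gs <- seq(0, 30, length.out = 25)
  expect_true(all(diff(eyring_rate(gs, 298)) < 0))
})

test_that("efficiency ratio matches the published table", {
  expect_equal(efficiency(0.00629, 8.5e-9), 740000, tolerance = 5e-3)
  expect_equal(efficiency(0.040, 12.00e-9), 3.3e6, tolerance = 0.02)
  expect_equal(efficiency(1, 1), 1)
  expect_error(efficiency(0.1, 0), class = "fepkin_input_error")
  expect_error(efficiency(-1, 1e-9), class = "fepkin_input_error")
})

test_that("progress curves round-trip through CSV", {
  curves <- gen_progress_curves(assay_design(noise_scale = 0.01, seed = 8),
                                8.5e-9, 0.00629, 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_progress_curves(curves, f)
  back <- read_progress_curves(f)
  expect_length(back, length(curves))
  conc_in <- sort(vapply(curves, `[[`, numeric(1), "inhibitor"))
  conc_out <- unname(sort(vapply(back, `[[`, numeric(1), "inhibitor")))
  expect_equal(conc_out, conc_in)
  ref <- curves[[3]]
  match_back <- back[[which(abs(conc_out - ref$inhibitor) < 1e-15)]]
  expect_equal(match_back$signal, ref$signal)
  expect_error(progress_curve(c(1, 2, 2), 1:3, 1e-9), "strictly increasing")
  expect_error(progress_curve(1:3, c(-1, 0, 1), 1e-9), "non-negative")
})
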