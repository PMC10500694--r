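test_that("stationary_mz evaluates the CW saturation closed form", {
  relax <- fig2_relax()
  expect_equal(stationary_mz(0, relax), 1)
  # construct (2 pi f)^2 t1 t2 = 1 -> Mz = 1/2
  f_half <- 1 / (2 * pi * sqrt(relax$t1 * relax$t2))
  expect_equal(stationary_mz(f_half, relax), 0.5)
  expect_equal(stationary_mz(11.7, relax),
               1 / (1 + (2 * pi * 11.7)^2 * 0.25), tolerance = 1e-15)
})

test_that("off-resonance steady state solves the stationary Bloch system", {
  relax <- relaxation_params(0.5, 0.3)
  expect_equal(cw_offres_steady_state(11.7, 0, relax),
               stationary_mz(11.7, relax), tolerance = 1e-12)
  expect_equal(cw_offres_steady_state(0, c(-30, 0, 70), relax), c(1, 1, 1))
  # independent closed form: Mz = (1 + (w0 t2)^2) / (1 + (w0 t2)^2 + w1^2 t1 t2)
  offs <- seq(-60, 60, by = 7.5)
  got <- cw_offres_steady_state(11.7, offs, relax)
  x <- (2 * pi * offs * relax$t2)^2
  y <- (2 * pi * 11.7)^2 * relax$t1 * relax$t2
  expect_equal(got, (1 + x) / (1 + x + y), tolerance = 1e-12)
  # saturation relaxes monotonically toward 1 with |offset|
  pos <- cw_offres_steady_state(11.7, seq(0, 500, 25), relax)
  expect_true(all(diff(pos) > 0))
})

test_that("profile_request enforces the integer module-count rule", {
  wf <- fig2_waveform(40, n_points = 100, dt_s = 1e-4)  # T = 0.01 s
  relax <- fig2_relax()
  req <- profile_request(wf, relax, seq(-50, 50, 1), relaxation_delay_s = 0.1)
  expect_identical(req$n_modules, 10L)
  expect_error(profile_request(wf, relax, seq(-50, 50, 1),
                               relaxation_delay_s = 0.015),
               class = "presatr_config_error")
  expect_error(profile_request(wf, relax, c(0, 1, 3)),
               class = "presatr_invalid_input")
  expect_error(profile_request(wf, relax, c(3, 2, 1)),
               class = "presatr_invalid_input")
})

test_that("a zero-amplitude waveform leaves magnetization at equilibrium", {
  wf <- synthesize_waveform(0, peak_rf_hz = 1, n_points = 50, dt_s = 1e-3)
  wf$w1x[] <- 0
  pr <- simulate_profile(wf, relax = fig2_relax(),
                         offset_grid_hz = seq(-20, 20, 2), n_modules = 3L)
  expect_true(all(pr$mz_final == 1))
})

test_that("symmetric site sets give symmetric profiles", {
  wf <- fig2_waveform(15, n_points = 800, dt_s = 1e-4)
  pr <- simulate_profile(wf, relax = fig2_relax(),
                         offset_grid_hz = seq(-40, 40, 1), n_modules = 5L)
  expect_lte(maxnorm(pr$mz_final, rev(pr$mz_final)), 1e-12)
})

test_that("the profile at a site recovers the per-site stationary value", {
  # delay 10 s = 20 T1; per-site RF is peak_rf/2 for a two-site pulse, and
  # the sites are far apart relative to that amplitude so the off-resonant
  # component of the pulse perturbs the site only to O((rf/sep)^2) ~ 2e-4
  relax <- fig2_relax()
  wf <- fig2_waveform(200, n_points = 2500, dt_s = 1e-4,
                      peak_rf_hz = 11.7)  # T = 0.25 s
  pr <- simulate_profile(wf, relax = relax,
                         offset_grid_hz = seq(-250, 250, 50), n_modules = 40L)
  at_site <- pr$mz_final[pr$offsets_hz == 200]
  expect_lt(abs(at_site - stationary_mz(11.7 / 2, relax)), 1e-3)
})

test_that("attenuation_percent interpolates and range-checks", {
  pr <- structure(list(offsets_hz = c(-1, 0, 1),
                       mz_final = c(1, 0.03, 1), meta = list()),
                  class = "saturation_profile")
  expect_equal(attenuation_percent(pr, 0), 97)
  expect_equal(attenuation_percent(pr, -1), 0)
  expect_equal(attenuation_percent(pr, 0.5), 100 * (1 - 0.515))
  expect_error(attenuation_percent(pr, 2), class = "presatr_invalid_input")
})

test_that("bandwidth of a constructed triangular dip is exact", {
  x <- seq(-50, 50, 1)
  pr <- structure(list(offsets_hz = x, mz_final = pmin(1, abs(x) / 20),
                       meta = list()), class = "saturation_profile")
  expect_equal(bandwidth_at_half(pr, 0), 20)
  iv <- half_reduction_intervals(pr)
  expect_identical(nrow(iv), 1L)
  expect_equal(iv$center_hz, 0)
  flat <- structure(list(offsets_hz = x, mz_final = rep(1, length(x)),
                         meta = list()), class = "saturation_profile")
  expect_identical(bandwidth_at_half(flat, 0), NA_real_)
})

test_that("simulated CW bandwidth matches the stationary closed form", {
  relax <- fig2_relax()
  f <- 11.7
  wf <- synthesize_waveform(0, peak_rf_hz = f, n_points = 2500, dt_s = 1e-4)
  pr <- simulate_profile(wf, relax = relax,
                         offset_grid_hz = seq(-25, 25, 1), n_modules = 40L)
  bw <- bandwidth_at_half(pr, 0)
  w1 <- 2 * pi * f
  bw_closed <- 2 * sqrt(w1^2 * relax$t1 * relax$t2 - 1) / relax$t2 / (2 * pi)
  expect_lt(abs(bw - bw_closed), 2)  # within 2 grid steps of 1 Hz
})

test_that("saturation deepens monotonically with RF power", {
  relax <- fig2_relax()
  prev <- Inf
  for (f in c(5.9, 11.7, 58.7)) {
    wf <- synthesize_waveform(0, peak_rf_hz = f, n_points = 1250, dt_s = 2e-4)
    pr <- simulate_profile(wf, relax = relax, offset_grid_hz = c(-1, 0, 1),
                           n_modules = 20L)
    expect_lte(pr$mz_final[2], prev)
    prev <- pr$mz_final[2]
  }
})

test_that("close sites widen the merged feature beyond the single-site width", {
  # same per-site amplitude (25 Hz); pair separation 10 Hz is well below the
  # single-site bandwidth, i.e. the interference regime
  relax <- fig2_relax()
  single <- synthesize_waveform(0, peak_rf_hz = 25, n_points = 2500,
                                dt_s = 2e-4)
  pair <- synthesize_waveform(c(-5, 5), peak_rf_hz = 50, n_points = 2500,
                              dt_s = 2e-4)
  grid <- seq(-80, 80, 1)
  bw_single <- bandwidth_at_half(
    simulate_profile(single, relax = relax, offset_grid_hz = grid,
                     n_modules = 10L), 0)
  bw_pair <- bandwidth_at_half(
    simulate_profile(pair, relax = relax, offset_grid_hz = grid,
                     n_modules = 10L), 0)
  expect_gt(bw_pair, bw_single)
})

test_that("splitting at dt/4 and oracle profiles agree on a coarse grid", {
  relax <- relaxation_params(0.4, 0.3)
  wf <- fig2_waveform(12, n_points = 60, dt_s = 1e-3)
  grid <- seq(-25, 25, 2.5)
  mz_split <- vapply(grid, function(f0)
    propagate_with_refinement(equilibrium_state(), wf, 2 * pi * f0, relax,
                              n_repeats = 2L, levels = 2L)$state$mz,
    numeric(1))
  mz_oracle <- vapply(grid, function(f0)
    oracle_propagate(equilibrium_state(), wf, 2 * pi * f0, relax,
                     n_repeats = 2L, tol = 1e-10)$mz, numeric(1))
  expect_lt(maxnorm(mz_split, mz_oracle), 1e-3)
})

test_that("profile tables and CSV files round-trip", {
  wf <- fig2_waveform(10, n_points = 50, dt_s = 1e-4)
  pr <- simulate_profile(wf, relax = fig2_relax(),
                         offset_grid_hz = c(-10, 0, 10), n_modules = 2L)
  tab <- profile_to_table(pr)
  expect_identical(names(tab), c("offset_hz", "mz_fraction"))
  expect_identical(nrow(tab), 3L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(pr, path)
  back <- read_profile_csv(path)
  expect_identical(back$offsets_hz, pr$offsets_hz)
  expect_identical(back$mz_final, pr$mz_final)
  expect_equal(back$meta$t1_s, 0.5)
  expect_error(read_profile_csv(withr::local_tempfile(lines = "x,y")),
               class = "presatr_parse_error")
})
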