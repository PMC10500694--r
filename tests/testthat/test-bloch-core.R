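test_that("rotation_matrix reproduces hand-evaluated axis-angle cases", {
  expect_equal(rotation_matrix(list(ux = 0, uy = 0, uz = 1, theta = 0)),
               diag(3))
  expect_equal(rotation_matrix(list(ux = 1, uy = 0, uz = 0, theta = pi)),
               diag(c(1, -1, -1)), tolerance = 1e-15)
  expect_equal(
    as.numeric(rotation_matrix(list(ux = 0, uy = 0, uz = 1,
                                    theta = pi / 2)) %*% c(1, 0, 0)),
    c(0, 1, 0), tolerance = 1e-15)
})

test_that("rotation_matrix agrees with an independent quaternion rotation", {
  set.seed(101)
  for (i in 1:50) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    theta <- runif(1, -4 * pi, 4 * pi)
    v <- rnorm(3)
    R <- rotation_matrix(list(ux = u[1], uy = u[2], uz = u[3], theta = theta))
    expect_lt(maxnorm(as.numeric(R %*% v), rotate_quat(u, theta, v)), 1e-12)
  }
})

test_that("rotation matrices are orthogonal with unit determinant", {
  set.seed(202)
  for (i in 1:100) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    R <- rotation_matrix(list(ux = u[1], uy = u[2], uz = u[3],
                              theta = runif(1, -10, 10)))
    expect_lte(maxnorm(crossprod(R), diag(3)), 1e-12)
    expect_lte(abs(det(R) - 1), 1e-12)
  }
})

test_that("non-unit axes with nonzero angle are rejected", {
  expect_error(rotation_matrix(list(ux = 1, uy = 1, uz = 0, theta = 1)),
               class = "presatr_invalid_input")
})

test_that("effective_field captures the Bloch torque of a slice", {
  # 3-4-5 field: the magnitude relations of the printed convention, with the
  # axis negated so that the Rodrigues matrix evolves Eq.-1-style dynamics
  spec <- effective_field(field_slice(3, 0, 1), omega0 = 4)
  expect_equal(spec$omega_eff, 5)
  expect_equal(c(spec$ux, spec$uy, spec$uz), -c(0.6, 0, 0.8))
  expect_equal(spec$theta, 5 * 1)

  # single-axis field: pi/2 nutation in 5 ms at 50 Hz
  spec <- effective_field(field_slice(2 * pi * 50, 0, 5e-3), omega0 = 0)
  expect_equal(spec$theta, pi / 2)
  expect_equal(abs(spec$ux), 1)

  # free precession: axis along z
  spec <- effective_field(field_slice(0, 0, 1e-3), omega0 = 2 * pi * 10)
  expect_equal(spec$omega_eff, 2 * pi * 10)
  expect_equal(abs(spec$uz), 1)
  expect_equal(spec$uy, 0)

  # zero effective field: identity flag
  expect_true(effective_field(field_slice(0, 0, 1e-3), omega0 = 0)$identity)
})

test_that("on-resonance +x field turns +z toward +y (Bloch sign convention)", {
  no_relax <- relaxation_params(1e9, 1e9)
  m <- propagate_slice(equilibrium_state(),
                       field_slice(2 * pi * 50, 0, 1e-3), 0, no_relax)
  expect_gt(m$my, 0)
  expect_equal(m$mx, 0, tolerance = 1e-12)
  # quarter turn: (0,0,1) -> (0,1,0)
  m <- propagate_slice(equilibrium_state(),
                       field_slice(2 * pi * 50, 0, 5e-3), 0, no_relax)
  expect_equal(state_vec(m), c(0, 1, 0), tolerance = 1e-9)
})

test_that("relaxation_step matches its closed form", {
  relax <- relaxation_params(0.3, 0.1)
  m <- magnetization_state(0.4, -0.2, 0.1)
  expect_equal(state_vec(relaxation_step(m, relax, 0)), state_vec(m))
  eq <- equilibrium_state(0.7)
  expect_equal(state_vec(relaxation_step(eq, relax, 1.23)), state_vec(eq))
  # half-life construction on mx
  dt <- 0.05
  relax2 <- relaxation_params(1, dt / log(2))
  m2 <- relaxation_step(magnetization_state(1, 0, 1), relax2, dt)
  expect_equal(m2$mx, 0.5, tolerance = 1e-14)
  expect_error(relaxation_step(m, relax, -1), class = "presatr_invalid_input")
})

test_that("propagate_slice = rotation then relaxation, in that order", {
  relax <- relaxation_params(0.2, 0.1)
  sl <- field_slice(2 * pi * 30, 2 * pi * 12, 2e-3)
  omega0 <- 2 * pi * 8
  m0 <- magnetization_state(0.1, -0.3, 0.8)
  got <- propagate_slice(m0, sl, omega0, relax)
  R <- rotation_matrix(effective_field(sl, omega0))
  rotated <- as.numeric(R %*% state_vec(m0))
  expected <- relaxation_step(magnetization_state(rotated[1], rotated[2],
                                                  rotated[3], m0$mz_eq),
                              relax, sl$dt)
  expect_lt(maxnorm(state_vec(got), state_vec(expected)), 1e-13)
  # the reversed order (relaxation first) differs: the order is observable
  relaxed <- state_vec(relaxation_step(m0, relax, sl$dt))
  wrong <- as.numeric(R %*% relaxed)
  expect_gt(maxnorm(state_vec(got), wrong), 1e-6)
})

test_that("trivial propagation fixed points hold", {
  relax0 <- relaxation_params(1e12, 1e12)
  m <- propagate_slice(equilibrium_state(), field_slice(0, 0, 1e-3), 0, relax0)
  expect_equal(state_vec(m), c(0, 0, 1), tolerance = 1e-12)
  # free precession leaves +/- z untouched even with arbitrary offset
  m <- propagate_slice(equilibrium_state(), field_slice(0, 0, 1e-3),
                       2 * pi * 123.4, relax0)
  expect_equal(state_vec(m), c(0, 0, 1))
})

test_that("propagate_waveform composes slices and repeats", {
  relax <- relaxation_params(0.4, 0.3)
  set.seed(11)
  tab <- random_slice_table(20, 1e-3)
  m1 <- propagate_waveform(equilibrium_state(), tab, 2 * pi * 5, relax, 1L)
  m_manual <- equilibrium_state()
  for (j in 1:20)
    m_manual <- propagate_slice(m_manual,
                                field_slice(tab$w1x[j], tab$w1y[j], tab$dt[j]),
                                2 * pi * 5, relax)
  expect_equal(state_vec(m1), state_vec(m_manual))
  m3 <- propagate_waveform(equilibrium_state(), tab, 2 * pi * 5, relax, 3L)
  m_seq <- equilibrium_state()
  for (r in 1:3) m_seq <- propagate_waveform(m_seq, tab, 2 * pi * 5, relax, 1L)
  expect_equal(state_vec(m3), state_vec(m_seq))
  expect_error(propagate_waveform(equilibrium_state(), list(), 0, relax),
               class = "presatr_invalid_input")
})

test_that("an all-zero waveform gives pure T1 recovery", {
  relax <- relaxation_params(0.7, 0.2)
  n <- 40; dt <- 2.5e-3
  tab <- list(w1x = rep(0, n), w1y = rep(0, n), dt = rep(dt, n))
  m0 <- magnetization_state(0, 0, 0.5)
  m <- propagate_waveform(m0, tab, 0, relax, n_repeats = 10L)
  total <- 10 * n * dt
  expect_equal(m$mz, 1 + (0.5 - 1) * exp(-total / relax$t1), tolerance = 1e-12)
})

test_that("on-resonance CW saturates toward the stationary limit", {
  relax <- fig2_relax()
  wf <- synthesize_waveform(0, peak_rf_hz = 50, n_points = 500, dt_s = 1e-3)
  m <- propagate_waveform(equilibrium_state(), wf, 0, relax, n_repeats = 10L)
  expect_lt(abs(m$mz), 1e-2)
})

test_that("refinement error estimate vanishes without relaxation and halves with it", {
  set.seed(33)
  tab <- random_slice_table(20, 1e-3)
  no_relax <- relaxation_params(1e12, 1e12)
  res <- propagate_with_refinement(equilibrium_state(), tab, 2 * pi * 10,
                                   no_relax, levels = 1L)
  expect_lt(res$error_estimate, 1e-12)

  relax <- relaxation_params(0.2, 0.15)
  est <- vapply(1:4, function(lev)
    propagate_with_refinement(equilibrium_state(), tab, 2 * pi * 10, relax,
                              levels = lev)$error_estimate, numeric(1))
  expect_true(all(est > 0))
  ratios <- est[-4] / est[-1]
  expect_true(all(ratios > 1.6 & ratios < 2.4))
})

test_that("the ODE oracle agrees with closed forms in its limits", {
  relax0 <- relaxation_params(1e12, 1e12)
  m <- oracle_propagate(equilibrium_state(), field_slice(0, 0, 1e-3), 0,
                        relax0, tol = 1e-12)
  expect_equal(state_vec(m), c(0, 0, 1), tolerance = 1e-10)

  # zero field: oracle equals the pure relaxation transformation
  relax <- relaxation_params(0.3, 0.12)
  m0 <- magnetization_state(0.5, -0.2, 0.3)
  m <- oracle_propagate(m0, field_slice(0, 0, 0.05), 0, relax, tol = 1e-12)
  expect_lt(maxnorm(state_vec(m),
                    state_vec(relaxation_step(m0, relax, 0.05))), 1e-9)

  # negligible-relaxation limit: oracle equals the pure rotation
  slow <- relaxation_params(1e9, 1e9)
  sl <- field_slice(2 * pi * 30, 2 * pi * 10, 2e-3)
  om0 <- 2 * pi * 15
  m <- oracle_propagate(equilibrium_state(), sl, om0, slow, tol = 1e-12)
  R <- rotation_matrix(effective_field(sl, om0))
  expect_lt(maxnorm(state_vec(m), as.numeric(R %*% c(0, 0, 1))), 1e-8)
})

test_that("trajectories stay inside the Bloch ball when T2 <= 2 T1", {
  set.seed(44)
  for (i in 1:10) {
    tab <- random_slice_table(80, runif(1, 2e-4, 3e-3))
    relax <- random_relax()
    tr <- propagate_trajectory(equilibrium_state(), tab,
                               2 * pi * runif(1, -50, 50), relax)
    expect_true(all(rowSums(tr^2) <= 1 + 1e-9))
  }
})

test_that("Mz is mirror-symmetric in the offset sign for w1y = 0 waveforms", {
  set.seed(55)
  for (i in 1:5) {
    n <- 60
    tab <- list(w1x = 2 * pi * runif(n, -50, 50), w1y = rep(0, n),
                dt = rep(5e-4, n))
    relax <- random_relax()
    f0 <- 2 * pi * runif(1, 1, 60)
    mp <- propagate_waveform(equilibrium_state(), tab, f0, relax, 4L)
    mm <- propagate_waveform(equilibrium_state(), tab, -f0, relax, 4L)
    expect_lte(abs(mp$mz - mm$mz), 1e-12)
  }
})

test_that("batched offset propagation is bit-identical to scalar calls", {
  set.seed(66)
  tab <- random_slice_table(50, 1e-3)
  relax <- relaxation_params(0.5, 0.4)
  offs <- 2 * pi * seq(-20, 20, by = 5)
  batch <- presatr:::propagate_batch(equilibrium_state(),
                                     presatr:::validate_slice_table(tab),
                                     offs, relax, n_repeats = 3L)
  for (i in seq_along(offs)) {
    m <- propagate_waveform(equilibrium_state(), tab, offs[i], relax, 3L)
    expect_identical(as.numeric(batch[i, ]), state_vec(m))
  }
})
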