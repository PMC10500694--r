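# Shared fixtures and independent oracles for the test suite.

maxnorm <- function(a, b = 0) max(abs(a - b))

state_vec <- function(m) c(m$mx, m$my, m$mz)

# Independent axis-angle rotation via quaternions (never touches Rodrigues):
# v' = v + 2 s (q x v) + 2 q x (q x v),  q = sin(theta/2) u, s = cos(theta/2).
rotate_quat <- function(u, theta, v) {
  s <- cos(theta / 2)
  q <- sin(theta / 2) * u
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  v + 2 * s * cr(q, v) + 2 * cr(q, cr(q, v))
}

# Random slice table (uniform dt) as the plain-list waveform representation.
random_slice_table <- function(n, dt, max_rf_hz = 60) {
  list(w1x = 2 * pi * runif(n, -max_rf_hz, max_rf_hz),
       w1y = 2 * pi * runif(n, -max_rf_hz, max_rf_hz),
       dt = rep(dt, n))
}

# Random relaxation with the Bloch-ball condition T2 <= 2 T1.
random_relax <- function(t1_range = c(0.1, 0.5)) {
  t1 <- runif(1, t1_range[1], t1_range[2])
  t2 <- min(runif(1, 0.5 * t1, 1.5 * t1), 2 * t1)
  relaxation_params(t1, t2)
}

fig2_relax <- function() relaxation_params(0.5, 0.5)

# Two-site waveform at +/- f Hz with the Fig. 2 RF level, at reduced N.
fig2_waveform <- function(f_sat_hz, n_points = 5000, dt_s = 1e-4,
                          peak_rf_hz = 50) {
  synthesize_waveform(c(-f_sat_hz, f_sat_hz), peak_rf_hz = peak_rf_hz,
                      n_points = n_points, dt_s = dt_s)
}

# Splitting deviation from the ODE oracle at refinement levels 0..levels.
splitting_devs <- function(tab, omega0, relax, levels = 4, tol = 1e-12) {
  orc <- state_vec(oracle_propagate(equilibrium_state(), tab, omega0, relax,
                                    tol = tol))
  vapply(0:levels, function(lev) {
    st <- if (lev == 0) {
      state_vec(propagate_waveform(equilibrium_state(), tab, omega0, relax))
    } else {
      state_vec(propagate_with_refinement(equilibrium_state(), tab, omega0,
                                          relax, levels = lev)$state)
    }
    maxnorm(st, orc)
  }, numeric(1))
}
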