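#' Magnetization state in the rotating frame
#'
#' A macroscopic magnetization vector (`mx`, `my`, `mz`) together with its
#' equilibrium longitudinal value `mz_eq`.  All components are dimensionless;
#' by convention `mz_eq = 1` and every result is a fraction of the equilibrium
#' magnetization.
#'
#' @param mx,my,mz Magnetization components (dimensionless).
#' @param mz_eq Equilibrium longitudinal magnetization, > 0.
#' @return An object of class `"magnetization_state"`.
#' @seealso [equilibrium_state()]
#' @export
#' @examples
#' magnetization_state(0, 0, 0.5)
magnetization_state <- function(mx, my, mz, mz_eq = 1) {
  check_scalar(mx, "mx"); check_scalar(my, "my"); check_scalar(mz, "mz")
  check_scalar(mz_eq, "mz_eq", positive = TRUE)
  structure(list(mx = mx, my = my, mz = mz, mz_eq = mz_eq),
            class = "magnetization_state")
}

#' Equilibrium magnetization state
#'
#' @param mz_eq Equilibrium longitudinal magnetization, > 0.
#' @return A `"magnetization_state"` with `(mx, my, mz) = (0, 0, mz_eq)`.
#' @export
equilibrium_state <- function(mz_eq = 1) {
  magnetization_state(0, 0, mz_eq, mz_eq)
}

#' @export
print.magnetization_state <- function(x, ...) {
  cat(sprintf("<magnetization_state> (mx, my, mz) = (%.6g, %.6g, %.6g), mz_eq = %g\n",
              x$mx, x$my, x$mz, x$mz_eq))
  invisible(x)
}

#' Longitudinal and transverse relaxation times
#'
#' @param t1 Longitudinal relaxation time, seconds (> 0).
#' @param t2 Transverse relaxation time, seconds (> 0).
#' @return An object of class `"relaxation_params"` exposing `t1`, `t2` and
#'   the derived rates `r1 = 1/t1`, `r2 = 1/t2` (1/s).
#' @export
#' @examples
#' relaxation_params(t1 = 0.5, t2 = 0.5)
relaxation_params <- function(t1, t2) {
  check_scalar(t1, "t1", positive = TRUE)
  check_scalar(t2, "t2", positive = TRUE)
  structure(list(t1 = t1, t2 = t2, r1 = 1 / t1, r2 = 1 / t2),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("<relaxation_params> T1 = %g s, T2 = %g s (R1 = %g, R2 = %g 1/s)\n",
              x$t1, x$t2, x$r1, x$r2))
  invisible(x)
}

#' One piecewise-constant RF slice
#'
#' @param w1x,w1y RF nutation components in the rotating frame, rad/s.
#' @param dt Slice duration, seconds (> 0).
#' @return An object of class `"field_slice"`.
#' @export
field_slice <- function(w1x, w1y, dt) {
  check_scalar(w1x, "w1x"); check_scalar(w1y, "w1y")
  check_scalar(dt, "dt", positive = TRUE)
  structure(list(w1x = w1x, w1y = w1y, dt = dt), class = "field_slice")
}

#' Effective-field rotation of one slice
#'
#' During a slice the magnetization evolves (relaxation apart) under
#' `dM/dt = M x Omega` with `Omega = (w1x, w1y, omega0)` — the literal
#' rotating-frame Bloch torque.  That is a rotation at angular frequency
#' `omega_eff = |Omega|` about the axis `u = -Omega/omega_eff` (the negation
#' makes [rotation_matrix()], the standard Rodrigues form, reproduce the Bloch
#' sign convention in which an on-resonance field along +x turns +z toward
#' +y).  The rotation angle over the slice is `theta = omega_eff * dt`.
#'
#' Slices with `omega_eff * dt < 1e-15` rad are flagged as identity rotations
#' (the axis is undefined at zero effective field).
#'
#' @param slice A [field_slice()].
#' @param omega0 Resonance offset (precession angular frequency), rad/s.
#' @return An object of class `"rotation_spec"` with fields `ux`, `uy`, `uz`,
#'   `theta`, `omega_eff` and logical `identity`.
#' @export
#' @examples
#' effective_field(field_slice(3, 0, 1), omega0 = 4)  # omega_eff = 5
effective_field <- function(slice, omega0) {
  stopifnot(inherits(slice, "field_slice"))
  check_scalar(omega0, "omega0")
  omega_eff <- sqrt(slice$w1x^2 + slice$w1y^2 + omega0^2)
  theta <- omega_eff * slice$dt
  if (theta < 1e-15) {
    spec <- list(ux = 0, uy = 0, uz = 1, theta = 0,
                 omega_eff = omega_eff, identity = TRUE)
  } else {
    spec <- list(ux = -slice$w1x / omega_eff,
                 uy = -slice$w1y / omega_eff,
                 uz = -omega0 / omega_eff,
                 theta = theta,
                 omega_eff = omega_eff, identity = FALSE)
  }
  structure(spec, class = "rotation_spec")
}

#' Axis-angle (Rodrigues) rotation matrix
#'
#' `R = cos(theta) I + (1 - cos(theta)) u u' + sin(theta) [u]x`, with the
#' cross-product matrix `[u]x` having first row `(0, -uz, uy)`.  The result is
#' orthogonal with determinant +1.
#'
#' @param spec A `"rotation_spec"` as returned by [effective_field()], or any
#'   list with fields `ux`, `uy`, `uz`, `theta` (and optionally `identity`).
#' @return A 3x3 numeric rotation matrix.
#' @export
#' @examples
#' rotation_matrix(list(ux = 0, uy = 0, uz = 1, theta = pi / 2)) %*% c(1, 0, 0)
rotation_matrix <- function(spec) {
  if (isTRUE(spec$identity)) return(diag(3))
  u <- c(spec$ux, spec$uy, spec$uz)
  theta <- spec$theta
  if (!all(is.finite(u)) || !is.finite(theta))
    stop_invalid("rotation axis and angle must be finite")
  nrm2 <- sum(u^2)
  if (abs(nrm2 - 1) > 1e-12) {
    if (theta != 0)
      stop_invalid(sprintf(
        "rotation axis must be a unit vector (|u|^2 = %.15g); only identity rotations may omit it",
        nrm2))
    return(diag(3))
  }
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), nrow = 3, byrow = TRUE)
  ct * diag(3) + (1 - ct) * tcrossprod(u) + st * K
}

#' Pure relaxation over an interval
#'
#' Applies the relaxation-only transformation
#' `(mx, my, mz) -> (mx e^{-R2 dt}, my e^{-R2 dt}, mz_eq + (mz - mz_eq) e^{-R1 dt})`.
#'
#' @param m A [magnetization_state()].
#' @param relax A [relaxation_params()].
#' @param dt Interval duration, seconds (>= 0).
#' @return The relaxed `"magnetization_state"`.
#' @export
relaxation_step <- function(m, relax, dt) {
  stopifnot(inherits(m, "magnetization_state"),
            inherits(relax, "relaxation_params"))
  check_scalar(dt, "dt", nonneg = TRUE)
  e2 <- exp(-relax$r2 * dt)
  e1 <- exp(-relax$r1 * dt)
  magnetization_state(m$mx * e2, m$my * e2,
                      m$mz_eq + (m$mz - m$mz_eq) * e1, m$mz_eq)
}

# Coerce the accepted waveform representations to parallel numeric vectors.
# Accepts a presat_waveform, a single field_slice, a list of field_slice, or
# a data.frame/list with components w1x, w1y, dt.
slice_table <- function(slices) {
  if (inherits(slices, "presat_waveform"))
    return(list(w1x = slices$w1x, w1y = slices$w1y,
                dt = rep(slices$dt_s, slices$n_points)))
  if (inherits(slices, "field_slice"))
    return(list(w1x = slices$w1x, w1y = slices$w1y, dt = slices$dt))
  if (is.list(slices) && length(slices) > 0 &&
      all(vapply(slices, inherits, logical(1), "field_slice"))) {
    return(list(w1x = vapply(slices, `[[`, numeric(1), "w1x"),
                w1y = vapply(slices, `[[`, numeric(1), "w1y"),
                dt  = vapply(slices, `[[`, numeric(1), "dt")))
  }
  if ((is.list(slices) || is.data.frame(slices)) &&
      all(c("w1x", "w1y", "dt") %in% names(slices))) {
    tab <- list(w1x = as.numeric(slices$w1x), w1y = as.numeric(slices$w1y),
                dt = as.numeric(slices$dt))
    if (length(tab$dt) == 1L && length(tab$w1x) > 1L)
      tab$dt <- rep(tab$dt, length(tab$w1x))
    return(tab)
  }
  stop_invalid("'slices' must be a presat_waveform, a field_slice, a list of field_slice, or a list/data.frame with w1x, w1y, dt")
}

validate_slice_table <- function(tab) {
  n <- length(tab$w1x)
  if (n == 0L) stop_invalid("waveform must contain at least one slice")
  if (length(tab$w1y) != n || length(tab$dt) != n)
    stop_invalid("w1x, w1y and dt must have equal length")
  if (!all(is.finite(tab$w1x)) || !all(is.finite(tab$w1y)))
    stop_invalid("RF components must be finite")
  if (!all(is.finite(tab$dt)) || any(tab$dt <= 0))
    stop_invalid("slice durations must be positive and finite")
  tab
}

#' Propagate through one slice (rotation, then relaxation)
#'
#' Applies the effective-field rotation of the slice and then the relaxation
#' transformation over the slice duration — the operator splitting in the
#' order rotation(`dt`)-relaxation(`dt`).
#'
#' @inheritParams relaxation_step
#' @param slice A [field_slice()].
#' @param omega0 Resonance offset, rad/s.
#' @return The propagated `"magnetization_state"`.
#' @export
propagate_slice <- function(m, slice, omega0, relax) {
  stopifnot(inherits(m, "magnetization_state"),
            inherits(relax, "relaxation_params"))
  tab <- validate_slice_table(slice_table(slice))
  check_scalar(omega0, "omega0")
  res <- bloch_propagate_cpp(c(m$mx, m$my, m$mz), m$mz_eq,
                             tab$w1x, tab$w1y, tab$dt, omega0,
                             relax$r1, relax$r2, 1L, 1L)
  magnetization_state(res[1, 1], res[1, 2], res[1, 3], m$mz_eq)
}

#' Propagate through a slice train, possibly repeated
#'
#' Applies the full slice sequence `n_repeats` times in order (the shaped
#' pulse is emitted repetitively so that the overall irradiation time equals
#' the relaxation delay).
#'
#' @inheritParams propagate_slice
#' @param slices A waveform: see [synthesize_waveform()], or any form accepted
#'   by `propagate_slice` plus lists/data frames of slices.
#' @param n_repeats Number of times the train is applied (>= 1).
#' @return The final `"magnetization_state"`.
#' @export
propagate_waveform <- function(m, slices, omega0, relax, n_repeats = 1L) {
  stopifnot(inherits(m, "magnetization_state"),
            inherits(relax, "relaxation_params"))
  tab <- validate_slice_table(slice_table(slices))
  check_scalar(omega0, "omega0")
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L || n_repeats < 1 ||
      n_repeats != round(n_repeats))
    stop_invalid("'n_repeats' must be a positive integer")
  res <- bloch_propagate_cpp(c(m$mx, m$my, m$mz), m$mz_eq,
                             tab$w1x, tab$w1y, tab$dt, omega0,
                             relax$r1, relax$r2, as.integer(n_repeats), 1L)
  magnetization_state(res[1, 1], res[1, 2], res[1, 3], m$mz_eq)
}

# Batched propagation over a vector of offsets (rad/s); returns a matrix with
# columns mx, my, mz.  Same compiled loop as the scalar path, so batched
# results are bit-identical to per-offset calls.
propagate_batch <- function(m, tab, omega0_vec, relax, n_repeats = 1L,
                            subdiv = 1L) {
  res <- bloch_propagate_cpp(c(m$mx, m$my, m$mz), m$mz_eq,
                             tab$w1x, tab$w1y, tab$dt, omega0_vec,
                             relax$r1, relax$r2, as.integer(n_repeats),
                             as.integer(subdiv))
  colnames(res) <- c("mx", "my", "mz")
  res
}

#' Per-slice trajectory through a slice train
#'
#' Like [propagate_waveform()] with `n_repeats = 1`, but returns the state
#' after every slice.  Used for trajectory-level checks such as Bloch-ball
#' containment.
#'
#' @inheritParams propagate_waveform
#' @return A matrix with one row per slice and columns `mx`, `my`, `mz`.
#' @export
propagate_trajectory <- function(m, slices, omega0, relax) {
  stopifnot(inherits(m, "magnetization_state"),
            inherits(relax, "relaxation_params"))
  tab <- validate_slice_table(slice_table(slices))
  check_scalar(omega0, "omega0")
  res <- bloch_trajectory_cpp(c(m$mx, m$my, m$mz), m$mz_eq,
                              tab$w1x, tab$w1y, tab$dt, omega0,
                              relax$r1, relax$r2)
  colnames(res) <- c("mx", "my", "mz")
  res
}

#' Propagate with slice refinement and a splitting-error estimate
#'
#' Replacing each rotation(`dt`)-relaxation(`dt`) step by two consecutive
#' rotation(`dt/2`)-relaxation(`dt/2`) steps (and so on recursively) gives a
#' practical estimate of the splitting error: the max-norm difference between
#' the results at consecutive refinement levels.  Level `k` subdivides every
#' slice into `2^k` sub-slices; level 0 is the unsplit propagation.
#'
#' @inheritParams propagate_waveform
#' @param levels Refinement level (>= 1).
#' @return A list with `state` (the `"magnetization_state"` at `levels`) and
#'   `error_estimate` (max-norm difference between levels `levels` and
#'   `levels - 1`).
#' @export
propagate_with_refinement <- function(m, slices, omega0, relax,
                                      n_repeats = 1L, levels = 1L) {
  stopifnot(inherits(m, "magnetization_state"),
            inherits(relax, "relaxation_params"))
  tab <- validate_slice_table(slice_table(slices))
  check_scalar(omega0, "omega0")
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1 ||
      levels != round(levels))
    stop_invalid("'levels' must be a positive integer")
  fine <- propagate_batch(m, tab, omega0, relax, n_repeats, 2L^levels)
  coarse <- propagate_batch(m, tab, omega0, relax, n_repeats, 2L^(levels - 1L))
  list(state = magnetization_state(fine[1, 1], fine[1, 2], fine[1, 3], m$mz_eq),
       error_estimate = max(abs(fine - coarse)))
}

#' Reference propagation by direct ODE integration
#'
#' Integrates the full rotating-frame Bloch system (precession, nutation and
#' relaxation simultaneously) over each piecewise-constant slice with a
#' controlled-accuracy integrator (`deSolve::ode`, `lsoda`).  This is the
#' ground truth against which the splitting propagator's first-order error is
#' measured; it is far slower and not meant for production profiles.
#'
#' @inheritParams propagate_waveform
#' @param tol Relative and absolute integration tolerance (> 0).
#' @return The final `"magnetization_state"`.
#' @export
oracle_propagate <- function(m, slices, omega0, relax, n_repeats = 1L,
                             tol = 1e-10) {
  stopifnot(inherits(m, "magnetization_state"),
            inherits(relax, "relaxation_params"))
  tab <- validate_slice_table(slice_table(slices))
  check_scalar(omega0, "omega0")
  check_scalar(tol, "tol", positive = TRUE)
  rhs <- function(t, y, p) {
    list(c(p$w0 * y[2] - p$w1y * y[3] - p$r2 * y[1],
           p$w1x * y[3] - p$w0 * y[1] - p$r2 * y[2],
           p$w1y * y[1] - p$w1x * y[2] - p$r1 * (y[3] - p$mzeq)))
  }
  y <- c(m$mx, m$my, m$mz)
  n <- length(tab$w1x)
  for (rep in seq_len(n_repeats)) {
    for (j in seq_len(n)) {
      p <- list(w1x = tab$w1x[j], w1y = tab$w1y[j], w0 = omega0,
                r1 = relax$r1, r2 = relax$r2, mzeq = m$mz_eq)
      sol <- deSolve::ode(y = y, times = c(0, tab$dt[j]), func = rhs,
                          parms = p, method = "lsoda",
                          rtol = tol, atol = tol)
      istate <- attr(sol, "istate")[1]
      yn <- as.numeric(sol[nrow(sol), 2:4])
      if (!is.null(istate) && istate < 0 || any(!is.finite(yn)))
        stop_numeric(sprintf(
          "ODE integration failed in slice %d of repeat %d (istate = %s)",
          j, rep, as.character(istate)))
      y <- yn
    }
  }
  magnetization_state(y[1], y[2], y[3], m$mz_eq)
}
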