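# forward / time-reversal drivers around the compiled FDTD kernel

.solver_dt <- function(medium, cfl) cfl * medium$dx / max(medium$c_map)

.nearest_col <- function(medium, xs) {
  j <- vapply(xs, function(x) which.min(abs(medium$x - x)), integer(1))
  if (any(abs(medium$x[j] - xs) > medium$dx))
    stop("sensor positions fall outside the medium grid")
  j
}

# cubic-spline resampling of a heavily oversampled solver trace onto a
# uniform output grid; the solver rate (CFL-driven, >200 MS/s) is far above
# the acoustic band so interpolation error is negligible
.resample_traces <- function(tr, t_in, t_out) {
  apply(tr, 2, function(col) spline(t_in, col, xout = t_out)$y)
}

#' Simulate forward photoacoustic propagation to the detection surface
#'
#' Integrates the 2D first-order acoustic equations (staggered grid,
#' leapfrog) from an initial pressure distribution and records the normal
#' particle velocity just inside the soft detection surface at the
#' requested sensor positions -- the observable a surface-probing laser
#' Doppler vibrometer measures. Displacement is the cumulative time
#' integral of the velocity.
#'
#' @param medium A [build_medium()] object.
#' @param p0 Initial pressure matrix (Pa), `nz x nx`.
#' @param duration Simulated time in s.
#' @param sensor_x Lateral sensor positions in m (same frame as `medium$x`).
#' @param fs_out Output sampling rate in Hz (default 65 MS/s, the
#'   acquisition rate of the I/Q digitizer).
#' @param cfl CFL number for the internal time step (`dt = cfl * dx / max c`).
#' @param sponge_strength Per-step damping strength of the lateral sponge.
#'
#' @return A `surface_record`: list with `time` (s), `x` (sensor positions,
#'   m), displacement matrix `d` and velocity matrix `u` (samples x
#'   sensors), `fs`, and solver metadata.
#' @export
simulate_forward <- function(medium, p0, duration, sensor_x,
                             fs_out = 65e6, cfl = 0.3,
                             sponge_strength = 0.05) {
  stopifnot(inherits(medium, "pa_medium"))
  if (!all(dim(p0) == c(medium$nz, medium$nx)))
    stop("p0 shape does not match the medium grid")
  if (cfl <= 0 || cfl > 1 / sqrt(2))
    stop(sprintf("unstable solver settings: CFL = %.3g exceeds the 2D limit 1/sqrt(2)", cfl))
  if (is.unsorted(sensor_x, strictly = TRUE))
    stop("sensor positions must be strictly increasing")
  dt <- .solver_dt(medium, cfl)
  nsteps <- as.integer(ceiling(duration / dt))
  jj <- .nearest_col(medium, sensor_x)

  res <- fdtd_core(medium$c_map, medium$rho_map, medium$dx, dt, nsteps, p0,
                   sensor_j = jj - 1L,
                   src_traces = matrix(0, 0, 0),
                   src_i = integer(0), src_j = integer(0),
                   snap_steps = integer(0),
                   sponge_cells = medium$sponge_cells,
                   sponge_strength = sponge_strength,
                   soft_top = medium$boundary$top == "soft",
                   soft_bottom = medium$boundary$bottom == "soft",
                   blowup_factor = 10)
  if (!res$stable)
    stop("wave solver unstable: pressure exceeded 10x the source amplitude")

  t_in <- (seq_len(nsteps) - 0.5) * dt       # vz lives on half steps
  u_in <- res$u
  d_in <- apply(u_in, 2, function(col) cumsum(col) * dt)
  t_out <- seq(0, duration, by = 1 / fs_out)
  t_out <- t_out[t_out <= max(t_in)]
  u <- .resample_traces(u_in, t_in, t_out)
  d <- .resample_traces(d_in, t_in, t_out)
  structure(list(time = t_out, x = sensor_x, d = d, u = u, fs = fs_out,
                 dt_solver = dt, max_abs_p = res$max_abs_p,
                 medium_hash = .medium_hash(medium)),
            class = "surface_record")
}

.medium_hash <- function(medium) {
  v <- c(medium$nz, medium$nx, medium$dx, sum(medium$c_map), sum(medium$rho_map))
  paste(format(v, digits = 12), collapse = "|")
}

#' @export
print.surface_record <- function(x, ...) {
  cat(sprintf("surface record: %d sensors x %d samples at %.3g MS/s (%.2f us)\n",
              length(x$x), length(x$time), x$fs / 1e6, 1e6 * max(x$time)))
  cat(sprintf("  peak |velocity| %.3g m/s, peak |displacement| %.3g m\n",
              max(abs(x$u)), max(abs(x$d))))
  invisible(x)
}

#' @export
plot.surface_record <- function(x, sensor = which.max(apply(abs(x$u), 2, max)),
                                ...) {
  graphics::plot(1e6 * x$time, 1e3 * x$u[, sensor], type = "l",
                 xlab = "time (us)", ylab = "surface velocity (mm/s)",
                 main = sprintf("sensor at x = %+0.2f mm", 1e3 * x$x[sensor]),
                 ...)
  invisible(x)
}

#' Time-reversal back-propagation of boundary pressure traces
#'
#' Re-emits the time-reversed surface pressure traces as Dirichlet pressure
#' sources at the sensor cells (one row inside the soft detection surface)
#' and integrates the same wave solver; the pressure field at the final
#' step is the estimate of the initial photoacoustic pressure.
#'
#' @param medium Reconstruction medium ([build_medium()]); typically
#'   homogeneous PDMS with an absorbing (non-soft) backside and a depth
#'   extent large enough to contain backside-mirror artifacts.
#' @param traces Pressure traces, samples x positions (Pa), on a common
#'   uniform time base.
#' @param time Time vector of `traces` in s.
#' @param sensor_x Lateral positions of the traces (m).
#' @param cfl,sponge_strength Solver controls, as in [simulate_forward()].
#'
#' @return An `nz x nx` pressure map (the final-time field).
#' @export
simulate_time_reversal <- function(medium, traces, time, sensor_x,
                                   cfl = 0.3, sponge_strength = 0.05) {
  stopifnot(inherits(medium, "pa_medium"))
  traces <- as.matrix(traces)
  if (nrow(traces) != length(time))
    stop("traces and time base have mismatched lengths")
  if (ncol(traces) != length(sensor_x))
    stop("one trace per sensor position required")
  dts <- diff(time)
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1]))
    stop("traces must share a common uniform time base")
  dt <- .solver_dt(medium, cfl)
  duration <- max(time) - min(time)
  nsteps <- as.integer(ceiling(duration / dt))
  t_solver <- min(time) + (seq_len(nsteps) - 1L) * dt
  # time-reverse, then resample onto the solver clock
  rev_traces <- traces[rev(seq_len(nrow(traces))), , drop = FALSE]
  src <- .resample_traces(rev_traces, seq(min(time), max(time),
                                          length.out = nrow(traces)), t_solver)
  src <- matrix(src, nrow = nsteps)
  jj <- .nearest_col(medium, sensor_x)
  res <- fdtd_core(medium$c_map, medium$rho_map, medium$dx, dt, nsteps,
                   matrix(0, medium$nz, medium$nx),
                   sensor_j = integer(0),
                   src_traces = src,
                   src_i = rep(1L, length(jj)), src_j = jj - 1L,
                   snap_steps = integer(0),
                   sponge_cells = medium$sponge_cells,
                   sponge_strength = sponge_strength,
                   soft_top = medium$boundary$top == "soft",
                   soft_bottom = medium$boundary$bottom == "soft",
                   blowup_factor = 200)
  if (!res$stable)
    stop("time-reversal solver unstable")
  res$p_final
}

#' Pressure-field snapshots of a forward simulation
#'
#' Runs the forward solver from an initial pressure map and returns the
#' pressure field at the requested times, used to inspect propagation
#' phenomenology (e.g. the splitting of the backside-reflected front as it
#' traverses a higher-speed channel).
#'
#' @param medium A [build_medium()] object.
#' @param p0 Initial pressure matrix.
#' @param t Snapshot time(s) in s, all within the simulated duration.
#' @param cfl,sponge_strength Solver controls.
#'
#' @return A single pressure matrix if `t` has length 1, otherwise a list
#'   of matrices named by time.
#' @export
snapshot <- function(medium, p0, t, cfl = 0.3, sponge_strength = 0.05) {
  stopifnot(inherits(medium, "pa_medium"))
  if (any(t < 0)) stop("snapshot times must be >= 0")
  if (!all(dim(p0) == c(medium$nz, medium$nx)))
    stop("p0 shape does not match the medium grid")
  ts <- sort(unique(t))
  dt <- .solver_dt(medium, cfl)
  if (ts[1] == 0 && length(ts) == 1) return(p0)
  steps <- pmax(1L, as.integer(round(ts[ts > 0] / dt)))
  nsteps <- max(steps)
  res <- fdtd_core(medium$c_map, medium$rho_map, medium$dx, dt, nsteps, p0,
                   sensor_j = integer(0),
                   src_traces = matrix(0, 0, 0),
                   src_i = integer(0), src_j = integer(0),
                   snap_steps = as.integer(steps),
                   sponge_cells = medium$sponge_cells,
                   sponge_strength = sponge_strength,
                   soft_top = medium$boundary$top == "soft",
                   soft_bottom = medium$boundary$bottom == "soft",
                   blowup_factor = 10)
  if (!res$stable) stop("wave solver unstable during snapshot run")
  out <- vector("list", length(ts))
  names(out) <- format(ts)
  k <- 1L
  for (i in seq_along(ts)) {
    if (ts[i] == 0) out[[i]] <- p0
    else { out[[i]] <- res$snapshots[[k]]; k <- k + 1L }
  }
  if (length(out) == 1) out[[1]] else out
}
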