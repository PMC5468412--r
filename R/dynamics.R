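#' Integrate the network dynamics
#'
#' Adaptive stiff-capable integration (deSolve's `lsoda`, switching between
#' Adams and BDF) of the full voltage/activity system, with the analytic
#' Jacobian supplied to the implicit solver. Output is sampled on a uniform
#' grid; the solver's internal steps are finer and error-controlled.
#'
#' @param V,s initial state.
#' @inheritParams rhs
#' @param duration simulated time (s).
#' @param sample_dt output sampling interval (s), default 0.01.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param t0 initial time (s).
#' @return An object of class `trajectory`: `times` (vector), `V` and `s`
#'   (samples x neurons matrices), `stimulus`.
#' @export
integrate_model <- function(V, s, conn, params, Vth, stim = NULL,
                            duration, sample_dt = 0.01,
                            rtol = 1e-8, atol = 1e-10, t0 = 0) {
  if (duration <= 0 || sample_dt <= 0)
    stop("duration and sample_dt must be positive")
  .check_state(V, s, conn)
  n <- length(V)
  times <- seq(t0, t0 + duration, by = sample_dt)
  func <- function(t, y, p) {
    d <- rhs(y[1:n], y[(n + 1):(2 * n)], conn, params, Vth, stim)
    list(c(d$dV, d$ds))
  }
  jacf <- function(t, y, p)
    jacobian(y[1:n], y[(n + 1):(2 * n)], conn, params, Vth, stim)
  out <- deSolve::lsoda(c(V, s), times, func, parms = NULL,
                        jacfunc = jacf, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed; last state: ",
         paste(signif(out[nrow(out), -1], 4), collapse = ", "))
  structure(list(times = out[, 1],
                 V = out[, 1 + (1:n), drop = FALSE],
                 s = out[, 1 + n + (1:n), drop = FALSE],
                 stimulus = stim),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples over [%.3g, %.3g] s, %d neurons\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              ncol(x$V)))
  invisible(x)
}

#' Extract the state at a given sample
#' @param traj a `trajectory`.
#' @param i sample index (default: last sample).
#' @return list(V, s).
#' @export
state_at <- function(traj, i = length(traj$times)) {
  list(V = as.numeric(traj$V[i, ]), s = as.numeric(traj$s[i, ]))
}

#' Restrict a trajectory to a time window
#' @param traj a `trajectory`.
#' @param from,to window bounds (s), inclusive.
#' @return a `trajectory` over the window.
#' @export
trajectory_window <- function(traj, from = -Inf, to = Inf) {
  keep <- traj$times >= from & traj$times <= to
  if (!any(keep)) stop("window contains no samples")
  structure(list(times = traj$times[keep],
                 V = traj$V[keep, , drop = FALSE],
                 s = traj$s[keep, , drop = FALSE],
                 stimulus = traj$stimulus), class = "trajectory")
}

#' Write a trajectory to a delimited text table
#' @param traj a `trajectory`.
#' @param file output path; columns time, V..., s....
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  tab <- data.frame(time = traj$times, traj$V, traj$s)
  names(tab) <- c("time", paste0("V_", seq_len(ncol(traj$V))),
                  paste0("s_", seq_len(ncol(traj$s))))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Transient convergence time under the epsilon criterion
#'
#' The smallest sampled time after which every later sample stays within
#' distance `epsilon` of the final value. Distances are Euclidean in
#' whatever coordinates are supplied -- conventionally the two projection
#' plane coordinates, with the default `epsilon = 0.004` quoted in those
#' units; full-state coordinates can be passed instead.
#'
#' @param times sample times (s), strictly increasing.
#' @param coords samples x k coordinate matrix (or a vector for k = 1).
#' @param final_value length-k coordinates of the final value.
#' @param epsilon convergence distance (default 0.004, plane units).
#' @return list with `time` (s) and `converged` (logical; `FALSE` means the
#'   trajectory never settles and the last sample time is returned).
#' @export
convergence_time <- function(times, coords, final_value, epsilon = 0.004) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (m == 0) stop("empty trajectory")
  if (length(times) != m) stop("times and coords disagree in length")
  if (epsilon <= 0) stop("epsilon must be positive")
  d <- sqrt(colSums((t(coords) - final_value)^2))
  within <- d <= epsilon
  # first index from which all later samples stay within epsilon
  ok_from <- rev(cumprod(rev(within))) > 0
  if (!ok_from[m]) return(list(time = times[m], converged = FALSE))
  list(time = times[which(ok_from)[1]], converged = TRUE)
}

#' Fundamental period of an oscillatory signal
#'
#' Autocorrelation-based period estimate: the signal (each column demeaned)
#' is autocorrelated, local maxima above a significance floor are located,
#' and among them the smallest lag whose integer multiples account for every
#' other peak is taken as the fundamental; its lag is refined by parabolic
#' interpolation through the three samples around the peak. A two-harmonic
#' signal thus yields the fundamental, not the half period.
#'
#' @param x numeric vector or samples x k matrix (k signals sharing one
#'   period, e.g. the two plane coordinates).
#' @param dt sampling interval (s).
#' @param min_corr significance floor for an autocorrelation peak.
#' @return period in seconds, or `NA` when no significant periodicity is
#'   found.
#' @export
estimate_period <- function(x, dt, min_corr = 0.2) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 8) return(NA_real_)
  xc <- sweep(x, 2, colMeans(x))
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  maxlag <- floor(m * 2 / 3)
  r <- vapply(seq_len(maxlag), function(L) {
    sum(xc[1:(m - L), , drop = FALSE] * xc[(L + 1):m, , drop = FALSE]) / denom
  }, numeric(1))
  peaks <- which(diff(sign(diff(r))) == -2) + 1L
  peaks <- peaks[r[peaks] > min_corr]
  if (!length(peaks)) return(NA_real_)
  floor_r <- 0.5 * max(r[peaks])
  cand <- peaks[r[peaks] >= floor_r]
  best <- cand[1]
  for (p in cand) {
    mult <- peaks / p
    if (all(abs(mult - round(mult)) < 0.15)) { best <- p; break }
  }
  # parabolic refinement
  if (best > 1 && best < maxlag) {
    y1 <- r[best - 1]; y2 <- r[best]; y3 <- r[best + 1]
    denom2 <- y1 - 2 * y2 + y3
    off <- if (denom2 != 0) 0.5 * (y1 - y3) / denom2 else 0
    return((best + off) * dt)
  }
  best * dt
}

#' Classify a trajectory tail as a fixed point or limit cycle
#'
#' Looks at the final `window` seconds of the trajectory. If the
#' peak-to-peak variation of *every* state variable (all neurons, voltages
#' and activities) is below `tol_fp`, the tail is a fixed point. Otherwise a
#' period is estimated from the projection-plane coordinates and the tail is
#' a limit cycle if the coordinates recur, one period apart, within
#' `tol_cycle` relative to the oscillation amplitude. Anything else is
#' reported as `"unclassified"` -- never silently labeled.
#'
#' The convergence criterion is deliberately full-state: when the
#' motorneurons sit on a fixed point (or cycle), so must the sensory and
#' interneurons.
#'
#' @param traj a `trajectory` (transient already simulated past; the last
#'   `window` seconds are analysed).
#' @param plane a [projection_plane].
#' @param window analysis window length (s), default 20.
#' @param tol_fp peak-to-peak full-state tolerance (mV and dimensionless
#'   units), default 1e-3.
#' @param tol_cycle relative recurrence tolerance for cycles, default 0.05.
#' @return An object of class `attractor_record`: `kind` in
#'   `c("fixed_point", "limit_cycle", "unclassified")`, `representative`
#'   (list(V, s): the settled point, or the cycle point farthest from the
#'   plane origin), `period` (s; `NA` unless a cycle), and
#'   `max_plane_distance`.
#' @export
classify_attractor <- function(traj, plane, window = 20,
                               tol_fp = 1e-3, tol_cycle = 0.05) {
  t_end <- traj$times[length(traj$times)]
  tail <- trajectory_window(traj, from = t_end - window)
  m <- length(tail$times)
  if (m < 4) stop("trajectory too short for the analysis window")
  coords <- project(tail, plane)
  dist <- sqrt(rowSums(coords^2))
  ptp_V <- apply(tail$V, 2, function(v) diff(range(v)))
  ptp_s <- apply(tail$s, 2, function(v) diff(range(v)))
  if (max(ptp_V, ptp_s) < tol_fp) {
    rep_state <- state_at(tail, m)
    return(structure(list(kind = "fixed_point", representative = rep_state,
                          period = NA_real_,
                          max_plane_distance = sqrt(sum(project_state(
                            rep_state$V, plane)^2))),
                     class = "attractor_record"))
  }
  dt <- tail$times[2] - tail$times[1]
  period <- estimate_period(coords, dt)
  if (is.finite(period) && period > 0 && period < window / 2) {
    lag <- round(period / dt)
    amp <- max(dist)
    rec <- sqrt(rowSums((coords[1:(m - lag), , drop = FALSE] -
                           coords[(lag + 1):m, , drop = FALSE])^2))
    if (amp > 0 && max(rec) / amp < tol_cycle) {
      i_far <- which.max(dist)
      return(structure(list(kind = "limit_cycle",
                            representative = state_at(tail, i_far),
                            period = period,
                            max_plane_distance = dist[i_far]),
                       class = "attractor_record"))
    }
  }
  structure(list(kind = "unclassified", representative = state_at(tail, m),
                 period = NA_real_, max_plane_distance = max(dist)),
            class = "attractor_record")
}

#' @export
print.attractor_record <- function(x, ...) {
  cat(sprintf("attractor: %s, plane distance %.4g%s\n", x$kind,
              x$max_plane_distance,
              if (x$kind == "limit_cycle")
                sprintf(", period %.3g s", x$period) else ""))
  invisible(x)
}
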