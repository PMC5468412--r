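#' Standard equilibrium and sigmoid thresholds
#'
#' The reference fixed point of the zero-input system, constructed by
#' requiring every neuron's activation to sit at exactly one half of its
#' sigmoid at equilibrium. With `phi = 1/2` fixed, every synaptic activity
#' equals `s* = ar/2 / (ar/2 + ad)` and the voltage balance becomes linear:
#'
#'   `(Gc + sum_j Ggap_ij + s* sum_j Gsyn_ij) V_i - sum_j Ggap_ij V_j
#'     = Gc Ecell + s* sum_j Gsyn_ij E_j`
#'
#' whose matrix is strictly diagonally dominant (the gap off-diagonals are
#' dominated by the diagonal through `Gc > 0`), hence uniquely solvable. The
#' sigmoid centers are then defined as `Vth := Veq`, which makes the
#' construction self-consistent. The standard equilibrium is defined at zero
#' external input so that distances "from standard equilibrium" are
#' comparable across stimuli.
#'
#' @param conn a [connectome].
#' @param params [model_parameters].
#' @return An object of class `standard_equilibrium` with fields `Veq` (mV),
#'   `Vth` (mV, equal to `Veq`), and `seq` (per-neuron activity).
#' @export
standard_equilibrium <- function(conn, params = model_parameters()) {
  n <- n_neurons(conn)
  s_star <- params$ar * 0.5 / (params$ar * 0.5 + params$ad)
  Ej <- .reversal(conn, params)
  A <- -conn$gap
  diag(A) <- params$Gc + rowSums(conn$gap) + s_star * rowSums(conn$syn)
  b <- params$Gc * params$Ecell + s_star * as.numeric(conn$syn %*% Ej)
  Veq <- as.numeric(solve(A, b))
  structure(list(Veq = Veq, Vth = Veq, seq = rep(s_star, n)),
            class = "standard_equilibrium")
}

#' @export
print.standard_equilibrium <- function(x, ...) {
  cat(sprintf("standard equilibrium: %d neurons, Veq in [%.3f, %.3f] mV, s = %.5f\n",
              length(x$Veq), min(x$Veq), max(x$Veq), x$seq[1]))
  invisible(x)
}

.rhs_vec <- function(V, s, conn, params, Vth, stim) {
  d <- rhs(V, s, conn, params, Vth, stim)
  c(d$dV, d$ds)
}

#' Newton solve for a fixed point
#'
#' Damped Newton iteration on the full `(V, s)` residual using the analytic
#' Jacobian. Steps that increase the residual norm are halved (up to 30
#' times) before being accepted. Divergence is reported as a failure value,
#' not an error, so sweeps can record where a branch is lost.
#'
#' @param V,s initial guess.
#' @inheritParams rhs
#' @param tol infinity-norm residual tolerance in native units (mV/s, 1/s).
#' @param max_iter Newton iteration cap.
#' @return list with `V`, `s`, `converged` (logical), `residual`
#'   (infinity norm), `iterations`.
#' @export
solve_fixed_point <- function(V, s, conn, params, Vth, stim = NULL,
                              tol = 1e-9, max_iter = 100L) {
  if (!all(is.finite(V)) || !all(is.finite(s)))
    stop("initial guess contains non-finite values")
  n <- length(V)
  x <- c(V, s)
  f <- .rhs_vec(x[1:n], x[(n + 1):(2 * n)], conn, params, Vth, stim)
  res <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (res < tol)
      return(list(V = x[1:n], s = x[(n + 1):(2 * n)], converged = TRUE,
                  residual = res, iterations = it - 1L))
    J <- jacobian(x[1:n], x[(n + 1):(2 * n)], conn, params, Vth, stim)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- tryCatch(
        .rhs_vec(xn[1:n], xn[(n + 1):(2 * n)], conn, params, Vth, stim),
        error = function(e) rep(NA_real_, 2 * n))
      rn <- suppressWarnings(max(abs(fn)))
      if (is.finite(rn) && rn < res) break
      lambda <- lambda / 2
      if (lambda < 2^-30) break
    }
    if (!is.finite(rn) || rn >= res) break   # stagnated
    x <- xn; f <- fn; res <- rn
  }
  if (res < tol)
    return(list(V = x[1:n], s = x[(n + 1):(2 * n)], converged = TRUE,
                residual = res, iterations = max_iter))
  list(V = x[1:n], s = x[(n + 1):(2 * n)], converged = FALSE,
       residual = res, iterations = max_iter)
}

#' Linear stability of a fixed point
#'
#' Eigenvalues of the analytic Jacobian at a fixed point. The point must
#' actually be a fixed point: the residual is checked against
#' `residual_tol` first.
#'
#' @inheritParams rhs
#' @param residual_tol maximal infinity-norm residual accepted (native units).
#' @return list with `stable` (all real parts negative),
#'   `leading_real_part` (1/s), and `eigenvalues`.
#' @export
stability <- function(V, s, conn, params, Vth, stim = NULL,
                      residual_tol = 1e-6) {
  res <- max(abs(.rhs_vec(V, s, conn, params, Vth, stim)))
  if (res > residual_tol)
    stop(sprintf("point is not a fixed point (residual %.3g > %.3g)",
                 res, residual_tol))
  ev <- eigen(jacobian(V, s, conn, params, Vth, stim),
              only.values = TRUE)$values
  lead <- max(Re(ev))
  list(stable = lead < 0, leading_real_part = lead, eigenvalues = ev)
}

#' Continue the fixed-point branch over an amplitude grid
#'
#' Tracks the fixed point seeded at the standard equilibrium across a
#' strictly increasing input-amplitude grid, warm-starting each Newton solve
#' from the previous amplitude's solution, and records the leading Jacobian
#' eigenvalue real part and a stability flag per amplitude. If Newton fails
#' at some amplitude the branch is truncated there and marked.
#'
#' @param conn a [connectome].
#' @param params [model_parameters].
#' @param Vth sigmoid centers from [standard_equilibrium].
#' @param direction stimulus direction vector (or neuron names).
#' @param amplitudes strictly increasing numeric grid (fA).
#' @param start optional list(V, s) initial guess for the first amplitude;
#'   defaults to the standard-equilibrium state.
#' @param baseline optional constant input vector added at every amplitude
#'   (see [stimulus]).
#' @param tol Newton residual tolerance.
#' @return An object of class `fixed_point_branch`: `amplitudes`, matrices
#'   `V` and `s` (neurons x amplitudes), `leading_real_part`, `stable`,
#'   `n_converged` (branch length before truncation).
#' @export
continue_branch <- function(conn, params, Vth, direction, amplitudes,
                            start = NULL, baseline = NULL, tol = 1e-9) {
  if (length(amplitudes) < 1 || is.unsorted(amplitudes, strictly = TRUE))
    stop("amplitudes must be strictly increasing")
  if (is.character(direction))
    direction <- stimulus(direction, 1, conn)$direction
  n <- n_neurons(conn)
  m <- length(amplitudes)
  if (is.null(start)) {
    eq <- standard_equilibrium(conn, params)
    start <- list(V = eq$Veq, s = eq$seq)
  }
  Vm <- matrix(NA_real_, n, m)
  sm <- matrix(NA_real_, n, m)
  lead <- rep(NA_real_, m)
  stab <- rep(NA, m)
  guess <- start
  k <- 0L
  for (i in seq_len(m)) {
    st <- stimulus(direction, amplitudes[i], baseline = baseline)
    fp <- solve_fixed_point(guess$V, guess$s, conn, params, Vth, st, tol = tol)
    if (!fp$converged) {
      if (i == 1L) stop("fixed-point solve failed at the first amplitude")
      break
    }
    Vm[, i] <- fp$V; sm[, i] <- fp$s
    sa <- stability(fp$V, fp$s, conn, params, Vth, st)
    lead[i] <- sa$leading_real_part
    stab[i] <- sa$stable
    guess <- list(V = fp$V, s = fp$s)
    k <- i
  }
  structure(list(amplitudes = amplitudes, V = Vm, s = sm,
                 leading_real_part = lead, stable = stab, n_converged = k,
                 direction = direction, baseline = baseline),
            class = "fixed_point_branch")
}

#' @export
print.fixed_point_branch <- function(x, ...) {
  cat(sprintf("fixed-point branch: %d/%d amplitudes converged, %d stable\n",
              x$n_converged, length(x$amplitudes),
              sum(x$stable, na.rm = TRUE)))
  invisible(x)
}

#' Export a fixed-point branch as a data frame
#'
#' @param branch a `fixed_point_branch`.
#' @param voltages include per-neuron voltage columns.
#' @return data.frame with amplitude, stability and leading real part.
#' @export
branch_table <- function(branch, voltages = FALSE) {
  d <- data.frame(amplitude = branch$amplitudes,
                  stable = branch$stable,
                  leading_real_part = branch$leading_real_part)
  if (voltages) d <- cbind(d, t(branch$V))
  d
}

#' First destabilization amplitude of the branch
#'
#' The smallest amplitude at which the continued fixed point loses
#' stability. When the model context is supplied, the crossing is refined by
#' bisection on the sign of the leading eigenvalue real part (solving the
#' fixed point at each midpoint) until the bracket's relative width is below
#' `rel_tol`; without context the coarse grid value is returned.
#'
#' @param branch a `fixed_point_branch`.
#' @param conn,params,Vth optional model context enabling refinement.
#' @param rel_tol relative bracket width for bisection.
#' @return the bifurcation amplitude (fA), or `NA` if the branch is stable
#'   wherever it converged.
#' @export
first_bifurcation_amplitude <- function(branch, conn = NULL, params = NULL,
                                        Vth = NULL, rel_tol = 1e-3) {
  k <- branch$n_converged
  if (k < 2) stop("branch must contain at least two converged points")
  st <- branch$stable[seq_len(k)]
  flip <- which(!st)[1]
  if (is.na(flip)) return(NA_real_)
  if (flip == 1L) return(branch$amplitudes[1])
  lo <- flip - 1L
  a_lo <- branch$amplitudes[lo]
  a_hi <- branch$amplitudes[flip]
  if (is.null(conn)) return(a_hi)
  guess <- list(V = branch$V[, lo], s = branch$s[, lo])
  while ((a_hi - a_lo) > rel_tol * abs(a_hi)) {
    a_mid <- (a_lo + a_hi) / 2
    st_mid <- stimulus(branch$direction, a_mid, baseline = branch$baseline)
    fp <- solve_fixed_point(guess$V, guess$s, conn, params, Vth, st_mid)
    if (!fp$converged) break   # fold hit: report the unstable edge
    sa <- stability(fp$V, fp$s, conn, params, Vth, st_mid)
    if (sa$stable) {
      a_lo <- a_mid
      guess <- list(V = fp$V, s = fp$s)
    } else a_hi <- a_mid
  }
  a_hi
}
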