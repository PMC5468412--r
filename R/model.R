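#' Model parameters
#'
#' Global scalar parameters of the graded-synapse membrane model. All neurons
#' share them; the only per-neuron heterogeneity in the model is the
#' connectivity and the excitatory/inhibitory flag. The unit system is
#' \{mV, s, pS, pF, fA\}, which is self-consistent: pS x mV = fA and
#' pF x mV / s = fA, so no hidden conversion factors appear in the equations.
#'
#' Defaults are the consolidated parameter record of the underlying model:
#' C = 1 pF, Gc = 10 pS, Ecell = -35 mV, g_unit = 100 pS, beta = 0.125 / mV,
#' ar = 1 / s, ad = 5 / s, E_exc = 0 mV, E_inh = -45 mV. Note that the source
#' literature is internally inconsistent about the sigmoid width (prose says
#' 0.25 / mV where the parameter table says 0.125 / mV); the table value is
#' the default here and `beta` is freely configurable.
#'
#' @param C membrane capacitance (pF).
#' @param Gc membrane leakage conductance (pS).
#' @param Ecell leakage potential (mV).
#' @param g_unit per-contact conductance (pS).
#' @param beta synaptic sigmoid width (1/mV).
#' @param ar synaptic rise constant (1/s).
#' @param ad synaptic decay constant (1/s).
#' @param E_exc,E_inh reversal potentials of excitatory/inhibitory
#'   presynaptic neurons (mV).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(C = 1, Gc = 10, Ecell = -35, g_unit = 100,
                             beta = 0.125, ar = 1, ad = 5,
                             E_exc = 0, E_inh = -45) {
  p <- list(C = C, Gc = Gc, Ecell = Ecell, g_unit = g_unit, beta = beta,
            ar = ar, ad = ad, E_exc = E_exc, E_inh = E_inh)
  pos <- c("C", "Gc", "g_unit", "beta", "ar", "ad")
  bad <- pos[vapply(p[pos], function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be positive and finite: ", paste(bad, collapse = ", "))
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("model parameters (units mV, s, pS, pF, fA):\n")
  for (nm in names(x)) cat(sprintf("  %-7s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Serialize / restore model parameters as key=value text
#'
#' @param params a `model_parameters` object.
#' @param file path to a flat `key=value` file.
#' @return `write_parameters` returns the path invisibly; `read_parameters`
#'   returns a `model_parameters` object.
#' @export
write_parameters <- function(params, file) {
  writeLines(sprintf("%s=%.17g", names(params), unlist(params)), file)
  invisible(file)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(file) {
  kv <- strsplit(readLines(file), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(x[2]))
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(model_parameters, vals)
}

#' Stimulus specification
#'
#' A constant-in-time external current: a fixed direction vector over neurons
#' scaled by a scalar amplitude (fA), the amplitude being the bifurcation
#' parameter of all sweeps.
#'
#' @param direction numeric vector over neurons, or a character vector of
#'   neuron names (each named neuron gets weight 1) resolved against `conn`.
#' @param amplitude scalar input amplitude (fA).
#' @param conn optional [connectome], required when `direction` is given by
#'   neuron names.
#' @param baseline optional constant input vector (fA) added on top of
#'   `amplitude * direction`; this is how a compound input with one fixed
#'   component (say, constant drive into one neuron pair while another
#'   pair's amplitude is swept) is expressed.
#' @return An object of class `stimulus` with fields `direction`,
#'   `amplitude`, `baseline`.
#' @export
stimulus <- function(direction, amplitude, conn = NULL, baseline = NULL) {
  if (is.character(direction)) {
    if (is.null(conn)) stop("a connectome is needed to resolve neuron names")
    idx <- match(direction, conn$neuron_names)
    if (anyNA(idx))
      stop("unknown neuron(s): ",
           paste(direction[is.na(idx)], collapse = ", "))
    d <- numeric(n_neurons(conn))
    d[idx] <- 1
    direction <- d
  }
  if (!is.numeric(direction) || !all(is.finite(direction)))
    stop("direction must be a finite numeric vector")
  if (amplitude != 0 && all(direction == 0))
    stop("direction must not be all-zero when amplitude is nonzero")
  if (!is.null(baseline)) {
    if (length(baseline) != length(direction) || !all(is.finite(baseline)))
      stop("baseline must be a finite vector of the direction's length")
    baseline <- as.numeric(baseline)
  }
  structure(list(direction = as.numeric(direction),
                 amplitude = as.numeric(amplitude),
                 baseline = baseline), class = "stimulus")
}

#' Logistic activation
#' @param x numeric.
#' @return 1 / (1 + exp(-x)), evaluated without clipping.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Presynaptic reversal potentials: a property of the *sending* neuron.
.reversal <- function(conn, params)
  ifelse(conn$is_inhibitory, params$E_inh, params$E_exc)

.check_state <- function(V, s, conn) {
  n <- n_neurons(conn)
  if (length(V) != n || length(s) != n)
    stop("state dimensions do not match the connectome (", n, " neurons)")
  if (!all(is.finite(V)) || !all(is.finite(s)))
    stop("state contains non-finite values")
}

#' Time derivative of the network state
#'
#' The membrane equation per neuron: capacitive voltage change balances the
#' leak current, ohmic gap-junction currents toward each coupled neighbour,
#' graded synaptic currents gated by the presynaptic activity variables, and
#' the external input. The synaptic activity rises at rate
#' `ar * phi(beta (V - Vth))` toward 1 and decays at rate `ad`.
#'
#' @param V,s numeric vectors: membrane voltages (mV) and synaptic
#'   activities (dimensionless, in \[0, 1\]).
#' @param conn a [connectome].
#' @param params [model_parameters].
#' @param Vth per-neuron sigmoid centers (mV), usually from
#'   [standard_equilibrium].
#' @param stim a [stimulus] (or `NULL` for zero input).
#' @return list with components `dV` (mV/s) and `ds` (1/s).
#' @export
rhs <- function(V, s, conn, params, Vth, stim = NULL) {
  .check_state(V, s, conn)
  if (length(Vth) != length(V)) stop("Vth length mismatch")
  Iext <- if (is.null(stim)) 0 else
    stim$amplitude * stim$direction +
      (if (is.null(stim$baseline)) 0 else stim$baseline)
  Ej <- .reversal(conn, params)
  Igap <- rowSums(conn$gap) * V - as.numeric(conn$gap %*% V)
  Isyn <- as.numeric(conn$syn %*% s) * V - as.numeric(conn$syn %*% (s * Ej))
  dV <- (-params$Gc * (V - params$Ecell) - Igap - Isyn + Iext) / params$C
  phi <- sigmoid(params$beta * (V - Vth))
  ds <- params$ar * phi * (1 - s) - params$ad * s
  list(dV = unname(dV), ds = unname(ds))
}

#' Equilibrium synaptic activity at fixed voltage
#'
#' Setting the activity equation to zero gives the rate-balance form
#' `s = ar phi / (ar phi + ad)`; algebraically this equals the shifted-sigmoid
#' closed form `phi(beta (V - Vth) + log(1 + ar/ad)) / (1 + ad/ar)`. The
#' rate-balance form is evaluated; the equivalence is checked in the tests.
#'
#' @inheritParams rhs
#' @return per-neuron equilibrium activity in (0, ar/(ar+ad)).
#' @export
synaptic_equilibrium <- function(V, params, Vth) {
  if (!all(is.finite(V))) stop("voltages must be finite")
  phi <- sigmoid(params$beta * (V - Vth))
  params$ar * phi / (params$ar * phi + params$ad)
}

#' Analytic Jacobian of the network vector field
#'
#' Partial derivatives of `(dV, ds)` with respect to `(V, s)`, as a dense
#' `2n x 2n` matrix with state ordered voltages-first. The voltage-voltage
#' block is the (negated, scaled) leak plus gap Laplacian plus the diagonal
#' total synaptic conductance; the voltage-activity block carries the driving
#' forces; both activity blocks are diagonal.
#'
#' @inheritParams rhs
#' @return a `2n x 2n` numeric matrix (units 1/s).
#' @export
jacobian <- function(V, s, conn, params, Vth, stim = NULL) {
  .check_state(V, s, conn)
  n <- length(V)
  Ej <- .reversal(conn, params)
  Jvv <- conn$gap / params$C
  diag(Jvv) <- -(params$Gc + rowSums(conn$gap) +
                   as.numeric(conn$syn %*% s)) / params$C
  Jvs <- -conn$syn * outer(V, Ej, "-") / params$C
  phi <- sigmoid(params$beta * (V - Vth))
  Jsv <- diag(params$ar * params$beta * phi * (1 - phi) * (1 - s), n)
  Jss <- diag(-(params$ar * phi + params$ad), n)
  rbind(cbind(Jvv, Jvs), cbind(Jsv, Jss))
}

#' Intrinsic timescales of the model
#'
#' The exponential decay constant of an unconnected neuron is `C/Gc`; the
#' timescale a single gap contact imposes is `C/g_unit`; and with voltages
#' frozen the synaptic activity relaxes exponentially with time constant
#' `1/(ar phi + ad)`, which over `phi` in (0, 1) spans
#' `(1/(ar + ad), 1/ad)`.
#'
#' @param params [model_parameters].
#' @return list with `tau_free`, `tau_gap` (s) and `tau_syn_range`
#'   (length-2 numeric, s).
#' @export
intrinsic_timescales <- function(params = model_parameters()) {
  list(tau_free = params$C / params$Gc,
       tau_gap = params$C / params$g_unit,
       tau_syn_range = c(1 / (params$ar + params$ad), 1 / params$ad))
}
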