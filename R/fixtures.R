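#' Deterministic test fixtures with known answers
#'
#' A small registry of hand-built networks whose behaviour is known in
#' closed form or from independent brute-force computation, so every stage
#' of the analysis pipeline can be exercised without external connectivity
#' data. Registered names:
#'
#' * `isolated_neuron` -- one unconnected neuron; standard equilibrium at
#'   the leakage potential, stable for any leak-balanced input, leading
#'   Jacobian eigenvalue `-(ar/2 + ad)`.
#' * `gap_pair` -- two neurons coupled by one gap contact; equal voltages
#'   carry zero coupling current.
#' * `excitatory_synapse_pair` -- one excitatory synapse (100 pS) from
#'   neuron 2 onto neuron 1; the postsynaptic equilibrium voltage solves
#'   `Gc (V - Ecell) + G s* V = 0` with `s* = 1/11`, giving
#'   `V = Gc Ecell / (Gc + G/11)`.
#' * `mutual_excitation_oscillator` -- a mutually coupled
#'   excitatory/inhibitory pair (500 pS each way) with the sigmoid width
#'   scaled up 40-fold, tuned by a stored search (tools/search_oscillator.R)
#'   so the standard equilibrium is an unstable focus at zero input,
#'   surrounded by a limit cycle of roughly 0.36 s period, and restabilizes
#'   as drive into the excitatory neuron crosses the declared flip range.
#'   Pure mutual excitation cannot oscillate here (its feedback loop is
#'   sign-positive, so eigenvalues cross the axis on the real line); the
#'   inhibitory partner supplies the negative feedback an oscillation
#'   needs.
#' * `random_three_class` -- a seeded 30-neuron synthetic connectome
#'   (5 sensory, 10 inter, 15 motor) used by the ensemble-versus-oracle
#'   comparisons.
#'
#' @param name one of the registered fixture names.
#' @param seed integer seed for the stochastic fixtures.
#' @return An object of class `fixture_case`: `name`, `connectome`,
#'   `params` (a [model_parameters], possibly non-default), and `expected`,
#'   a list of machine-checkable expectations.
#' @export
build_fixture <- function(name, seed = 1L) {
  registered <- c("isolated_neuron", "gap_pair", "excitatory_synapse_pair",
                  "mutual_excitation_oscillator", "random_three_class")
  if (!name %in% registered)
    stop("unknown fixture '", name, "'; registered: ",
         paste(registered, collapse = ", "))
  params <- model_parameters()
  fix <- switch(
    name,
    isolated_neuron = {
      conn <- connectome("N1", matrix(0, 1, 1), matrix(0, 1, 1),
                         "sensory", FALSE)
      list(connectome = conn, params = params,
           expected = list(
             Veq = params$Ecell,
             seq = 1 / 11,
             leading_real_part = -(params$ar / 2 + params$ad),
             tau_free = params$C / params$Gc))
    },
    gap_pair = {
      gap <- matrix(c(0, 100, 100, 0), 2, 2)
      conn <- connectome(c("N1", "N2"), gap, matrix(0, 2, 2),
                         c("sensory", "inter"), c(FALSE, FALSE))
      list(connectome = conn, params = params,
           expected = list(Veq = rep(params$Ecell, 2)))
    },
    excitatory_synapse_pair = {
      syn <- matrix(0, 2, 2)
      syn[1, 2] <- 100   # onto 1 from 2
      conn <- connectome(c("POST", "PRE"), matrix(0, 2, 2), syn,
                         c("inter", "sensory"), c(FALSE, FALSE))
      list(connectome = conn, params = params,
           expected = list(
             Veq = c(params$Gc * params$Ecell /
                       (params$Gc + 100 / 11), params$Ecell)))
    },
    mutual_excitation_oscillator = {
      # beta x40; conductances and the flip window frozen from the stored
      # search in tools/search_oscillator.R
      osc_params <- model_parameters(beta = 0.125 * 40)
      syn <- matrix(0, 2, 2)
      syn[2, 1] <- 500   # excitatory drive onto the inhibitory partner
      syn[1, 2] <- 500   # inhibitory feedback onto the driven neuron
      conn <- connectome(c("EXC", "INH"), matrix(0, 2, 2), syn,
                         c("inter", "inter"), c(FALSE, TRUE))
      list(connectome = conn, params = osc_params,
           expected = list(
             unstable_at = 0,          # unstable focus, limit cycle around it
             stable_at = 100,          # drive into EXC quenches the cycle
             flip_range = c(0, 100),   # stability boundary inside this range
             flip_bracket = c(45, 50), # from the stored independent scan
             leading_at_zero = 5.852,  # 1/s, ditto
             period = 0.3585,          # cycle period at zero input (s)
             input_neuron = "EXC"))
    },
    random_three_class = {
      conn <- generate_synthetic_connectome(
        n_sensory = 5, n_inter = 10, n_motor = 15,
        gap_density = 0.15, syn_density = 0.15,
        inhibitory_fraction = 0.3, seed = seed)
      list(connectome = conn, params = params,
           expected = list(n = 30L, n_motor = 15L))
    })
  structure(c(list(name = name), fix), class = "fixture_case")
}

#' @export
print.fixture_case <- function(x, ...) {
  cat("fixture:", x$name, "\n")
  print(x$connectome)
  invisible(x)
}
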