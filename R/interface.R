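#' Command-line entry point
#'
#' A thin dispatcher over the package's functions, used by the
#' `inst/scripts/nemodyn` Rscript. Subcommands:
#'
#' * `timescales` -- print the intrinsic timescales for the active
#'   parameters.
#' * `equilibrium` -- compute the standard equilibrium of a connectome and
#'   write it as a CSV table.
#' * `simulate` -- integrate from the standard equilibrium (optionally
#'   voltage-displaced) under a stimulus and write the trajectory.
#' * `bifurcate` -- ensemble bifurcation diagram over an amplitude grid.
#' * `basin` -- basin-of-attraction map at one stimulus.
#' * `survey` -- all-single-neuron sweeps summarized by neuron class.
#'
#' Flags are `--key value` pairs; `--fixture NAME` substitutes a registered
#' fixture for `--edges`/`--meta` connectome files. Every stochastic stage
#' takes `--seed`. Invalid usage prints the usage text and returns a
#' nonzero status rather than raising.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly: 0 on success.
#' @export
run_command <- function(argv) {
  usage <- paste(
    "usage: nemodyn <subcommand> [--key value ...]",
    "subcommands:",
    "  timescales  [--C x --Gc x --g_unit x --ar x --ad x]",
    "  equilibrium --edges F --meta F [--out F]",
    "  simulate    (--fixture NAME | --edges F --meta F) [--direction A,B]",
    "              [--amplitude x] [--duration s] [--dt s] [--displace mV]",
    "              [--out F]",
    "  bifurcate   (--fixture NAME | --edges F --meta F) --direction A,B",
    "              [--amin x --amax x --steps k] [--ensemble n] [--seed i]",
    "              [--transient s] [--window s] [--out F]",
    "  basin       (--fixture NAME | --edges F --meta F) --direction A,B",
    "              --amplitude x [--half-width x] [--resolution k]",
    "              [--seed i] [--out F]",
    "  survey      (--fixture NAME | --edges F --meta F)",
    "              [--amin x --amax x --steps k] [--ensemble n] [--seed i]",
    "              [--out F]",
    sep = "\n")
  fail <- function(msg) {
    message(msg)
    message(usage)
    invisible(1L)
  }
  if (length(argv) < 1) return(fail("no subcommand given"))
  sub <- argv[1]
  opts <- .parse_flags(argv[-1])
  if (inherits(opts, "error")) return(fail(conditionMessage(opts)))
  get_num <- function(key, default) {
    if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
  }
  res <- tryCatch(switch(
    sub,
    timescales = {
      pkeys <- intersect(names(opts),
                         c("C", "Gc", "Ecell", "g_unit", "beta", "ar", "ad"))
      params <- do.call(model_parameters,
                        lapply(opts[pkeys], as.numeric))
      ts <- intrinsic_timescales(params)
      cat(sprintf("tau_free  %g ms\n", 1000 * ts$tau_free))
      cat(sprintf("tau_gap   %g ms\n", 1000 * ts$tau_gap))
      cat(sprintf("tau_syn   (%g, %g) ms\n",
                  1000 * ts$tau_syn_range[1], 1000 * ts$tau_syn_range[2]))
      0L
    },
    equilibrium = {
      conn <- .load_conn(opts)
      eq <- standard_equilibrium(conn)
      tab <- data.frame(neuron = conn$neuron_names, Veq = eq$Veq,
                        seq = eq$seq)
      .emit_table(tab, opts$out)
      0L
    },
    simulate = {
      conn <- .load_conn(opts)
      params <- model_parameters()
      eq <- standard_equilibrium(conn, params)
      st <- .parse_stim(opts, conn)
      V <- eq$Veq + get_num("displace", 0)
      s <- synaptic_equilibrium(V, params, eq$Vth)
      traj <- integrate_model(V, s, conn, params, eq$Vth, st,
                              duration = get_num("duration", 10),
                              sample_dt = get_num("dt", 0.01))
      if (is.null(opts$out)) {
        cat(sprintf("final V: %s\n",
                    paste(signif(traj$V[nrow(traj$V), ], 6),
                          collapse = " ")))
      } else write_trajectory(traj, opts$out)
      0L
    },
    bifurcate = {
      conn <- .load_conn(opts)
      params <- .fixture_params(opts)
      eq <- standard_equilibrium(conn, params)
      dir <- .parse_stim(opts, conn, need_dir = TRUE)$direction
      amps <- seq(get_num("amin", 0), get_num("amax", 2e4),
                  length.out = get_num("steps", 11))
      plane <- .default_plane(conn, params, eq, dir, max(amps))
      ens <- ensemble_spec(get_num("ensemble", 5),
                           seed = get_num("seed", 1))
      dg <- bifurcation_diagram(conn, params, eq, dir, amps, ens, plane,
                                transient = get_num("transient", 20),
                                window = get_num("window", 10))
      .emit_table(diagram_table(dg), opts$out)
      0L
    },
    basin = {
      conn <- .load_conn(opts)
      params <- .fixture_params(opts)
      eq <- standard_equilibrium(conn, params)
      st <- .parse_stim(opts, conn, need_dir = TRUE)
      plane <- .default_plane(conn, params, eq, st$direction, st$amplitude)
      ens <- ensemble_spec(get_num("ensemble", 10),
                           seed = get_num("seed", 1))
      dg <- bifurcation_diagram(conn, params, eq, st$direction,
                                st$amplitude, ens, plane,
                                transient = get_num("transient", 20),
                                window = get_num("window", 10))
      bm <- basin_map(conn, params, eq, st, plane, dg$attractors[[1]],
                      half_width = get_num("half-width", 4e-6),
                      resolution = get_num("resolution", 5),
                      transient = get_num("transient", 20),
                      window = get_num("window", 10))
      tab <- data.frame(c1 = rep(bm$c1, times = length(bm$c2)),
                        c2 = rep(bm$c2, each = length(bm$c1)),
                        label = as.integer(bm$labels))
      .emit_table(tab, opts$out)
      0L
    },
    survey = {
      conn <- .load_conn(opts)
      params <- .fixture_params(opts)
      eq <- standard_equilibrium(conn, params)
      amps <- seq(get_num("amin", 0), get_num("amax", 2e4),
                  length.out = get_num("steps", 6))
      ens <- ensemble_spec(get_num("ensemble", 3),
                           seed = get_num("seed", 1))
      diagrams <- lapply(conn$neuron_names, function(nm) {
        dir <- stimulus(nm, 1, conn)$direction
        plane <- .default_plane(conn, params, eq, dir, max(amps))
        bifurcation_diagram(conn, params, eq, dir, amps, ens, plane,
                            transient = get_num("transient", 20),
                            window = get_num("window", 10))
      })
      names(diagrams) <- conn$neuron_names
      sm <- summarize_by_neuron_class(diagrams, conn)
      tab <- data.frame(class = rownames(sm$cumulative_unstable),
                        cycle_fraction = sm$cycle_fraction)
      .emit_table(tab, opts$out)
      0L
    },
    NULL), error = function(e) e)
  if (is.null(res)) return(fail(paste0("unknown subcommand '", sub, "'")))
  if (inherits(res, "error")) return(fail(conditionMessage(res)))
  invisible(res)
}

.parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      return(simpleError(paste("unexpected argument:", args[i])))
    if (i + 1L > length(args))
      return(simpleError(paste("flag", args[i], "needs a value")))
    opts[[substring(args[i], 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.load_conn <- function(opts) {
  if (!is.null(opts$fixture)) return(build_fixture(opts$fixture)$connectome)
  if (is.null(opts$edges) || is.null(opts$meta))
    stop("either --fixture or both --edges and --meta are required")
  read_connectome(opts$edges, opts$meta)
}

.fixture_params <- function(opts) {
  if (!is.null(opts$fixture)) build_fixture(opts$fixture)$params
  else model_parameters()
}

.parse_stim <- function(opts, conn, need_dir = FALSE) {
  amp <- if (is.null(opts$amplitude)) 0 else as.numeric(opts$amplitude)
  if (is.null(opts$direction)) {
    if (need_dir) stop("--direction is required")
    return(stimulus(rep(0, n_neurons(conn)), 0))
  }
  stimulus(strsplit(opts$direction, ",")[[1]], amp, conn)
}

# Plane fitted from a short run at the top amplitude: enough structure to
# give the sweep usable coordinates without a separate fitting step.
.default_plane <- function(conn, params, eq, direction, amplitude) {
  motor <- forward_motor_indices(conn)
  if (length(motor) < 2) motor <- seq_len(min(n_neurons(conn), 2))
  st <- stimulus(direction, amplitude)
  V <- eq$Veq
  V[motor[1]] <- V[motor[1]] + 0.1
  traj <- integrate_model(V, synaptic_equilibrium(V, params, eq$Vth),
                          conn, params, eq$Vth, st,
                          duration = 20, sample_dt = 0.02)
  fit_projection_plane(traj, motor, eq)
}

.emit_table <- function(tab, out) {
  if (is.null(out)) {
    utils::write.csv(tab, stdout(), row.names = FALSE)
  } else utils::write.csv(tab, out, row.names = FALSE)
}
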