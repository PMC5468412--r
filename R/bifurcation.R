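#' Ensemble specification for attractor searches
#'
#' Describes how random initial conditions are drawn around the standard
#' equilibrium. `"uniform_plane"` draws uniformly from a disc of radius
#' `scale` in projection-plane coordinates (displacing only motorneuron
#' voltages, with activities set to their voltage-consistent equilibria);
#' `"gaussian_full"` jitters every voltage independently with standard
#' deviation `scale` (mV).
#'
#' @param n_initial_conditions simulations per amplitude (>= 1).
#' @param perturbation_scale disc radius (plane units) or voltage sd (mV).
#' @param distribution `"uniform_plane"` or `"gaussian_full"`.
#' @param seed integer; identical seeds give identical ensembles.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_initial_conditions = 20,
                          perturbation_scale = 4e-6,
                          distribution = c("uniform_plane", "gaussian_full"),
                          seed = 1L) {
  if (n_initial_conditions < 1) stop("need at least one initial condition")
  if (perturbation_scale <= 0) stop("perturbation_scale must be positive")
  structure(list(n_initial_conditions = as.integer(n_initial_conditions),
                 perturbation_scale = perturbation_scale,
                 distribution = match.arg(distribution),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Initial condition displaced along the plane
#'
#' Standard-equilibrium voltages displaced by `c1 * mode1 + c2 * mode2` on
#' the motorneuron coordinates only; synaptic activities are set to the
#' equilibrium consistent with the displaced voltages.
#'
#' @param c1,c2 plane coordinates of the displacement.
#' @param eq a [standard_equilibrium].
#' @param plane a [projection_plane].
#' @param params [model_parameters].
#' @return list(V, s).
#' @export
plane_initial_condition <- function(c1, c2, eq, plane, params) {
  V <- eq$Veq
  V[plane$motor_indices] <- V[plane$motor_indices] +
    c1 * plane$modes[, 1] + c2 * plane$modes[, 2]
  list(V = V, s = synaptic_equilibrium(V, params, eq$Vth))
}

.draw_ensemble <- function(eq, plane, params, spec) {
  lapply(seq_len(spec$n_initial_conditions), function(i) {
    if (spec$distribution == "uniform_plane") {
      r <- spec$perturbation_scale * sqrt(stats::runif(1))
      th <- 2 * pi * stats::runif(1)
      plane_initial_condition(r * cos(th), r * sin(th), eq, plane, params)
    } else {
      V <- eq$Veq + stats::rnorm(length(eq$Veq), 0, spec$perturbation_scale)
      list(V = V, s = synaptic_equilibrium(V, params, eq$Vth))
    }
  })
}

#' Deduplicate classified attractors
#'
#' Single-linkage merging: fixed points whose representatives are closer
#' than `fp_tol` in plane coordinates join one group; limit cycles join when
#' both their periods and their furthest plane distances agree within
#' `cycle_tol` (relative). Fixed points never merge with cycles. Each merged
#' record keeps the member with the largest plane distance and gains a
#' `count` field.
#'
#' @param records list of `attractor_record`s (unclassified ones are
#'   dropped; callers count them separately).
#' @param fp_tol absolute plane-distance tolerance for fixed points.
#' @param cycle_tol relative tolerance for cycles.
#' @return list of deduplicated `attractor_record`s.
#' @export
merge_attractors <- function(records, fp_tol = 1e-4, cycle_tol = 0.05) {
  records <- Filter(function(r) r$kind != "unclassified", records)
  k <- length(records)
  if (k == 0) return(list())
  same <- function(a, b) {
    if (a$kind != b$kind) return(FALSE)
    if (a$kind == "fixed_point") {
      pa <- a$plane_coords %||% NULL
      da <- if (!is.null(pa) && !is.null(b$plane_coords))
        sqrt(sum((a$plane_coords - b$plane_coords)^2))
      else abs(a$max_plane_distance - b$max_plane_distance)
      return(da < fp_tol)
    }
    dper <- abs(a$period - b$period) / max(a$period, b$period)
    dd <- abs(a$max_plane_distance - b$max_plane_distance) /
      max(a$max_plane_distance, b$max_plane_distance, .Machine$double.eps)
    dper <= cycle_tol && dd <= cycle_tol
  }
  # connected components under the pairwise relation (single linkage)
  comp <- seq_len(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (comp[i] != comp[j] && same(records[[i]], records[[j]]))
      comp[comp == comp[j]] <- comp[i]
  }
  lapply(unique(comp), function(cid) {
    members <- records[comp == cid]
    best <- members[[which.max(vapply(members, function(r)
      r$max_plane_distance, numeric(1)))]]
    best$count <- length(members)
    best
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a record to the nearest reference attractor
#'
#' @param record an `attractor_record`.
#' @param reference list of reference `attractor_record`s.
#' @return index into `reference`, or `NA` for unclassified records or when
#'   no reference of the same kind exists.
#' @export
assign_attractor <- function(record, reference) {
  if (record$kind == "unclassified" || !length(reference)) return(NA_integer_)
  kinds <- vapply(reference, function(r) r$kind, "")
  cand <- which(kinds == record$kind)
  if (!length(cand)) return(NA_integer_)
  d <- vapply(cand, function(i) {
    r <- reference[[i]]
    if (!is.null(record$plane_coords) && !is.null(r$plane_coords))
      sqrt(sum((record$plane_coords - r$plane_coords)^2))
    else abs(record$max_plane_distance - r$max_plane_distance)
  }, numeric(1))
  cand[which.min(d)]
}

.classify_with_coords <- function(traj, plane, window, tol_fp, tol_cycle) {
  rec <- classify_attractor(traj, plane, window, tol_fp, tol_cycle)
  rec$plane_coords <- project_state(rec$representative$V, plane)
  rec
}

#' Ensemble bifurcation diagram
#'
#' For each input amplitude: draw an ensemble of initial conditions around
#' the standard equilibrium, integrate past the transient, classify each
#' tail as a fixed point or limit cycle, merge duplicates, and record each
#' attractor's furthest plane distance from the standard equilibrium. The
#' continued standard fixed-point branch, with stability flags, is attached.
#' Identical ensemble seeds give identical diagrams. This is exploratory:
#' there is no guarantee every attractor of the system is found, and
#' unclassified tails are counted, never dropped silently.
#'
#' @param conn a [connectome].
#' @param params [model_parameters].
#' @param eq a [standard_equilibrium] (supplies thresholds and the
#'   reference).
#' @param direction stimulus direction (vector or neuron names).
#' @param amplitudes strictly increasing amplitude grid (fA).
#' @param ensemble an [ensemble_spec].
#' @param plane a [projection_plane] fitted beforehand.
#' @param transient discarded lead-in per simulation (s).
#' @param window analysis window (s).
#' @param sample_dt output sampling step (s).
#' @param tol_fp,tol_cycle classification tolerances (see
#'   [classify_attractor]).
#' @param merge_fp_tol,merge_cycle_tol deduplication tolerances (see
#'   [merge_attractors]).
#' @param baseline optional constant input vector added at every
#'   amplitude (see [stimulus]).
#' @param rtol,atol solver tolerances.
#' @return An object of class `bifurcation_diagram`: `amplitudes`,
#'   `attractors` (list per amplitude of merged records),
#'   `n_unclassified` (per amplitude), `standard_branch`, `direction`.
#' @export
bifurcation_diagram <- function(conn, params, eq, direction, amplitudes,
                                ensemble, plane,
                                transient = 50, window = 20,
                                sample_dt = 0.01,
                                tol_fp = 1e-3, tol_cycle = 0.05,
                                merge_fp_tol = 1e-4, merge_cycle_tol = 0.05,
                                baseline = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(amplitudes, strictly = TRUE))
    stop("amplitudes must be strictly increasing")
  if (is.character(direction))
    direction <- stimulus(direction, 1, conn)$direction
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(ensemble$seed)
  attractors <- vector("list", length(amplitudes))
  n_uncl <- integer(length(amplitudes))
  for (i in seq_along(amplitudes)) {
    st <- stimulus(direction, amplitudes[i], baseline = baseline)
    ics <- .draw_ensemble(eq, plane, params, ensemble)
    recs <- lapply(ics, function(ic) {
      traj <- integrate_model(ic$V, ic$s, conn, params, eq$Vth, st,
                              duration = transient + window,
                              sample_dt = sample_dt,
                              rtol = rtol, atol = atol)
      .classify_with_coords(traj, plane, window, tol_fp, tol_cycle)
    })
    n_uncl[i] <- sum(vapply(recs, function(r)
      r$kind == "unclassified", logical(1)))
    attractors[[i]] <- merge_attractors(recs, merge_fp_tol, merge_cycle_tol)
  }
  branch <- tryCatch(
    continue_branch(conn, params, eq$Vth, direction, amplitudes,
                    baseline = baseline),
    error = function(e) NULL)   # branch may be lost at the first amplitude
  structure(list(amplitudes = amplitudes, attractors = attractors,
                 n_unclassified = n_uncl, standard_branch = branch,
                 direction = direction),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  kinds <- diagram_table(x)
  cat(sprintf("bifurcation diagram: %d amplitudes, %d attractor records (%d cycles)\n",
              length(x$amplitudes), nrow(kinds),
              sum(kinds$kind == "limit_cycle")))
  invisible(x)
}

#' Flatten a bifurcation diagram to a table
#'
#' @param diagram a `bifurcation_diagram`.
#' @return data.frame with amplitude, kind, max plane distance, period,
#'   ensemble count per attractor.
#' @export
diagram_table <- function(diagram) {
  rows <- lapply(seq_along(diagram$amplitudes), function(i) {
    recs <- diagram$attractors[[i]]
    if (!length(recs)) return(NULL)
    data.frame(amplitude = diagram$amplitudes[i],
               kind = vapply(recs, function(r) r$kind, ""),
               max_plane_distance = vapply(recs, function(r)
                 r$max_plane_distance, numeric(1)),
               period = vapply(recs, function(r) r$period, numeric(1)),
               count = vapply(recs, function(r) r$count %||% 1L, integer(1)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(amplitude = numeric(), kind = character(),
                      max_plane_distance = numeric(), period = numeric(),
                      count = integer())
  out
}

#' Diagram contains at least one limit cycle?
#' @param diagram a `bifurcation_diagram`.
#' @return logical.
#' @export
has_limit_cycle <- function(diagram)
  any(diagram_table(diagram)$kind == "limit_cycle")

#' Basin-of-attraction map over a custom grid runner
#'
#' The grid machinery independent of the neural model: evaluates a runner
#' at every cell of a square lattice of plane coordinates and assigns each
#' resulting record to the nearest reference attractor. This is what
#' [basin_map] plugs the connectome model into; any two-variable system can
#' be plumbed through by supplying its own runner.
#'
#' @param run function(c1, c2) returning an `attractor_record`.
#' @param reference list of reference `attractor_record`s.
#' @param half_width grid half-width (plane units), default 4e-6.
#' @param resolution cells per side.
#' @return An object of class `basin_map`: `c1`, `c2` (cell-center
#'   coordinates), `labels` (resolution x resolution integer matrix indexing
#'   `reference`, `NA` = unconverged/unmatched), `reference`.
#' @export
basin_map_grid <- function(run, reference, half_width = 4e-6,
                           resolution = 11) {
  cs <- seq(-half_width, half_width, length.out = resolution)
  labels <- matrix(NA_integer_, resolution, resolution)
  for (i in seq_len(resolution)) for (j in seq_len(resolution)) {
    rec <- run(cs[i], cs[j])
    labels[i, j] <- assign_attractor(rec, reference)
  }
  structure(list(c1 = cs, c2 = cs, labels = labels, reference = reference),
            class = "basin_map")
}

#' Basin-of-attraction map on the projection plane
#'
#' Lays a square lattice of initial conditions over the plane, each the
#' standard equilibrium displaced along the two modes (activities set to
#' their voltage-consistent equilibria), integrates every cell under the
#' given stimulus, classifies the tail, and labels the cell with the nearest
#' reference attractor. Unconverged or unmatched cells keep the `NA`
#' sentinel.
#'
#' @inheritParams bifurcation_diagram
#' @param stim the [stimulus] under which basins are mapped.
#' @param reference list of reference `attractor_record`s, typically from a
#'   [bifurcation_diagram] at this stimulus.
#' @param half_width grid half-width in plane units (default 4e-6, a small
#'   neighbourhood of the standard equilibrium).
#' @param resolution cells per side.
#' @return a `basin_map` (see [basin_map_grid]) with the stimulus attached.
#' @export
basin_map <- function(conn, params, eq, stim, plane, reference,
                      half_width = 4e-6, resolution = 11,
                      transient = 50, window = 20, sample_dt = 0.01,
                      tol_fp = 1e-3, tol_cycle = 0.05,
                      rtol = 1e-8, atol = 1e-10) {
  run <- function(c1, c2) {
    ic <- plane_initial_condition(c1, c2, eq, plane, params)
    traj <- integrate_model(ic$V, ic$s, conn, params, eq$Vth, stim,
                            duration = transient + window,
                            sample_dt = sample_dt, rtol = rtol, atol = atol)
    .classify_with_coords(traj, plane, window, tol_fp, tol_cycle)
  }
  bm <- basin_map_grid(run, reference, half_width, resolution)
  bm$stimulus <- stim
  bm
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("basin map: %d x %d cells, %d attractor labels, %d unresolved\n",
              length(x$c1), length(x$c2),
              length(unique(stats::na.omit(as.integer(x$labels)))),
              sum(is.na(x$labels))))
  invisible(x)
}

#' Summarize single-neuron input sweeps by neuron class
#'
#' Given one bifurcation diagram per single-neuron input direction (all on
#' the same amplitude grid), reports per class (sensory/inter/motor): the
#' cumulative fraction of neurons whose standard equilibrium has
#' destabilized by each grid amplitude, and the fraction of neurons whose
#' sweep contains at least one limit-cycle attractor anywhere in the range.
#'
#' @param diagrams named list of `bifurcation_diagram`s, names = neuron
#'   names; one per neuron of `conn`.
#' @param conn the [connectome] the sweeps were run on.
#' @return list with `amplitudes`, `cumulative_unstable` (class x amplitude
#'   matrix of fractions), `cycle_fraction` (named numeric, percent-free
#'   fractions in \[0, 1\]), `first_bifurcation` (named per neuron, `NA` if
#'   stable throughout).
#' @export
summarize_by_neuron_class <- function(diagrams, conn) {
  missing <- setdiff(conn$neuron_names, names(diagrams))
  if (length(missing))
    stop("missing diagrams for neuron(s): ", paste(missing, collapse = ", "))
  diagrams <- diagrams[conn$neuron_names]
  grids <- lapply(diagrams, function(d) d$amplitudes)
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1)
    stop("all diagrams must share one amplitude grid")
  amps <- grids[[1]]
  first_bif <- vapply(diagrams, function(d)
    first_bifurcation_amplitude(d$standard_branch), numeric(1))
  cyc <- vapply(diagrams, has_limit_cycle, logical(1))
  classes <- c("sensory", "inter", "motor")
  cum <- t(vapply(classes, function(cl) {
    members <- conn$neuron_class == cl
    if (!any(members)) return(rep(NA_real_, length(amps)))
    vapply(amps, function(a)
      mean(!is.na(first_bif[members]) & first_bif[members] <= a), numeric(1))
  }, numeric(length(amps))))
  cycle_fraction <- vapply(classes, function(cl) {
    members <- conn$neuron_class == cl
    if (!any(members)) return(NA_real_)
    mean(cyc[members])
  }, numeric(1))
  list(amplitudes = amps, cumulative_unstable = cum,
       cycle_fraction = cycle_fraction, first_bifurcation = first_bif)
}
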