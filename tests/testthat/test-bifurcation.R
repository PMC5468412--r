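fp_record <- function(coords, dist = sqrt(sum(coords^2))) {
  structure(list(kind = "fixed_point",
                 representative = list(V = NULL, s = NULL),
                 period = NA_real_, max_plane_distance = dist,
                 plane_coords = coords), class = "attractor_record")
}
lc_record <- function(dist, period) {
  structure(list(kind = "limit_cycle",
                 representative = list(V = NULL, s = NULL),
                 period = period, max_plane_distance = dist,
                 plane_coords = c(dist, 0)), class = "attractor_record")
}

test_that("attractor merging collapses duplicates but not kinds", {
  near <- list(fp_record(c(0.2, 0)), fp_record(c(0.2, 1e-9)))
  expect_length(merge_attractors(near, fp_tol = 1e-4), 1)
  expect_equal(merge_attractors(near, fp_tol = 1e-4)[[1]]$count, 2L)
  mixed <- list(fp_record(c(0.3, 0)), lc_record(0.3, 2))
  expect_length(merge_attractors(mixed, fp_tol = 1e-4), 2)
  cycles <- list(lc_record(1.0, 2.0), lc_record(1.001, 2.001),
                 lc_record(1.5, 2.0))
  out <- merge_attractors(cycles, cycle_tol = 0.05)
  expect_length(out, 2)
})

test_that("jittered attractor clouds merge like single-linkage clustering", {
  set.seed(17)
  centers <- list(c(0, 0), c(1, 0))
  recs <- lapply(1:50, function(i) {
    ctr <- centers[[1 + (i %% 2)]]
    fp_record(ctr + runif(2, -1e-6, 1e-6))
  })
  merged <- merge_attractors(recs, fp_tol = 1e-3)
  expect_length(merged, 2)
  # oracle: exhaustive pairwise single linkage at the same cut
  coords <- t(vapply(recs, function(r) r$plane_coords, numeric(2)))
  k <- length(unique(cutree(hclust(dist(coords), method = "single"),
                            h = 1e-3)))
  expect_equal(length(merged), k)
})

test_that("records are assigned to the nearest same-kind reference", {
  refs <- list(fp_record(c(0, 0)), fp_record(c(1, 0)), lc_record(2, 1.5))
  expect_equal(assign_attractor(fp_record(c(0.9, 0)), refs), 2L)
  expect_equal(assign_attractor(lc_record(2.1, 1.52), refs), 3L)
  uncl <- structure(list(kind = "unclassified", period = NA,
                         max_plane_distance = 1),
                    class = "attractor_record")
  expect_true(is.na(assign_attractor(uncl, refs)))
  expect_true(is.na(assign_attractor(lc_record(2, 1.5),
                                     refs[1:2])))
})

test_that("gap-only networks have a single fixed point at any drive", {
  conn <- generate_synthetic_connectome(2, 3, 5, 0.5, 0, 0, seed = 21)
  p <- model_parameters()
  eq <- standard_equilibrium(conn, p)
  motor <- forward_motor_indices(conn)
  # any non-equilibrium start gives snapshots to fit the plane
  V0 <- eq$Veq + seq(0.1, 1, length.out = 10)
  traj <- integrate_model(V0, eq$seq, conn, p, eq$Vth,
                          duration = 2, sample_dt = 0.01)
  plane <- fit_projection_plane(traj, motor, eq)
  dg <- bifurcation_diagram(conn, p, eq, c(1, rep(0, 9)),
                            amplitudes = c(0, 500, 1000),
                            ensemble = ensemble_spec(4, 1e-3, seed = 2),
                            plane = plane, transient = 5, window = 3)
  expect_true(all(lengths(dg$attractors) == 1))
  expect_true(all(vapply(dg$attractors, function(a)
    a[[1]]$kind, "") == "fixed_point"))
  expect_equal(sum(dg$n_unclassified), 0)
  expect_true(all(dg$standard_branch$stable))
})

osc_setup <- function() {
  fx <- build_fixture("mutual_excitation_oscillator")
  eq <- standard_equilibrium(fx$connectome, fx$params)
  list(fx = fx, eq = eq,
       plane = identity_plane(2, reference = eq$Veq))
}

test_that("the sweep sees the cycle die as drive quenches the focus", {
  os <- osc_setup()
  dg <- bifurcation_diagram(os$fx$connectome, os$fx$params, os$eq,
                            c(1, 0), amplitudes = c(0, 100),
                            ensemble = ensemble_spec(4, 0.5, seed = 5),
                            plane = os$plane, transient = 25, window = 10,
                            sample_dt = 0.005)
  tab <- diagram_table(dg)
  expect_equal(tab$kind[tab$amplitude == 0], "limit_cycle")
  expect_equal(tab$kind[tab$amplitude == 100], "fixed_point")
  expect_false(dg$standard_branch$stable[1])
  expect_true(dg$standard_branch$stable[2])
  expect_true(has_limit_cycle(dg))
})

test_that("identical seeds give identical diagrams; ensembles saturate", {
  os <- osc_setup()
  run <- function(n) bifurcation_diagram(
    os$fx$connectome, os$fx$params, os$eq, c(1, 0),
    amplitudes = c(0, 100), ensemble = ensemble_spec(n, 0.5, seed = 9),
    plane = os$plane, transient = 25, window = 10, sample_dt = 0.005)
  a <- run(3); b <- run(3); big <- run(6)
  expect_identical(a, b)
  kinds <- function(d) lapply(d$attractors, function(recs)
    sort(vapply(recs, function(r) r$kind, "")))
  expect_equal(kinds(a), kinds(big))
})

test_that("where the standard branch is stable the ensemble refinds it", {
  os <- osc_setup()
  dg <- bifurcation_diagram(os$fx$connectome, os$fx$params, os$eq,
                            c(1, 0), amplitudes = c(80, 100),
                            ensemble = ensemble_spec(4, 0.5, seed = 3),
                            plane = os$plane, transient = 25, window = 10,
                            sample_dt = 0.005)
  for (i in 1:2) {
    branch_coords <- project_state(dg$standard_branch$V[, i], os$plane)
    recs <- dg$attractors[[i]]
    expect_length(recs, 1)
    expect_lt(sqrt(sum((recs[[1]]$plane_coords - branch_coords)^2)), 1e-4)
  }
})

test_that("basin grid recovers the normal-form separatrix within a cell", {
  refs <- list(normal_form_record(-1, 0), normal_form_record(1, 0))
  bm <- basin_map_grid(function(c1, c2) normal_form_record(c1, c2),
                       refs, half_width = 1.5, resolution = 12)
  # analytic separatrix is x = 0: the label must equal the sign of c1
  want <- ifelse(bm$c1 < 0, 1L, 2L)
  expect_equal(bm$labels, matrix(rep(want, 12), 12, 12))
})

test_that("a monostable stimulus labels every cell identically", {
  os <- osc_setup()
  st <- stimulus(c(1, 0), 100)
  dg <- bifurcation_diagram(os$fx$connectome, os$fx$params, os$eq,
                            c(1, 0), amplitudes = 100,
                            ensemble = ensemble_spec(3, 0.5, seed = 4),
                            plane = os$plane, transient = 25, window = 10,
                            sample_dt = 0.005)
  bm <- basin_map(os$fx$connectome, os$fx$params, os$eq, st, os$plane,
                  reference = dg$attractors[[1]],
                  half_width = 0.5, resolution = 3,
                  transient = 25, window = 10, sample_dt = 0.005)
  expect_true(all(bm$labels == 1L))
})

test_that("class summaries count destabilization and cycles per class", {
  conn <- connectome(paste0("N", 1:7), matrix(0, 7, 7), matrix(0, 7, 7),
                     c(rep("sensory", 3), rep("motor", 4)),
                     rep(FALSE, 7),
                     c(rep("other", 3), "DB", "DD", "VB", "VD"))
  amps <- c(0, 100, 200)
  fake_diag <- function(flip_at, cycle) {
    stable <- if (is.na(flip_at)) rep(TRUE, 3) else amps < flip_at
    br <- structure(list(amplitudes = amps,
                         V = matrix(0, 7, 3), s = matrix(0, 7, 3),
                         leading_real_part = ifelse(stable, -1, 1),
                         stable = stable, n_converged = 3L,
                         direction = rep(0, 7)),
                    class = "fixed_point_branch")
    at <- if (cycle) list(list(lc_record(1, 2))) else
      list(list(fp_record(c(0, 0))))
    structure(list(amplitudes = amps, attractors = rep(at, 3),
                   n_unclassified = integer(3), standard_branch = br,
                   direction = rep(0, 7)),
              class = "bifurcation_diagram")
  }
  diagrams <- list(
    N1 = fake_diag(100, TRUE),  N2 = fake_diag(200, TRUE),
    N3 = fake_diag(NA, FALSE),
    N4 = fake_diag(200, TRUE),  N5 = fake_diag(NA, FALSE),
    N6 = fake_diag(NA, FALSE),  N7 = fake_diag(NA, FALSE))
  sm <- summarize_by_neuron_class(diagrams, conn)
  expect_equal(sm$cycle_fraction[["sensory"]], 2 / 3, tolerance = 1e-12)
  expect_equal(sm$cycle_fraction[["motor"]], 1 / 4)
  expect_true(is.na(sm$cycle_fraction[["inter"]]))
  # cumulative destabilized fractions at each grid amplitude
  expect_equal(sm$cumulative_unstable["sensory", ], c(0, 1 / 3, 2 / 3))
  expect_equal(sm$cumulative_unstable["motor", ], c(0, 0, 1 / 4))
  expect_error(summarize_by_neuron_class(diagrams[-1], conn), "N1")
})
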