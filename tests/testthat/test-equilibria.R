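test_that("gap-only networks rest at the leakage potential", {
  conn <- generate_synthetic_connectome(2, 3, 3, 0.5, 0, 0, seed = 4)
  eq <- standard_equilibrium(conn)
  expect_equal(eq$Veq, rep(-35, 8), tolerance = 1e-12)
  expect_equal(eq$Vth, eq$Veq)
  expect_equal(eq$seq, rep(1 / 11, 8))
})

test_that("single excitatory synapse shifts the postsynaptic equilibrium", {
  fx <- build_fixture("excitatory_synapse_pair")
  eq <- standard_equilibrium(fx$connectome, fx$params)
  # hand-solved balance: Gc(V - Ecell) + G s* V = 0, s* = 1/11
  expect_equal(eq$Veq[1], 10 * (-35) / (10 + 100 / 11), tolerance = 1e-9)
  expect_equal(eq$Veq[1], -18.3333, tolerance = 1e-4)
  expect_equal(eq$Veq[2], -35)
})

test_that("standard equilibrium zeroes the full vector field", {
  for (seed in 1:20) {
    conn <- generate_synthetic_connectome(3, 4, 5, 0.2, 0.3, 0.4,
                                          seed = seed)
    p <- model_parameters()
    eq <- standard_equilibrium(conn, p)
    d <- rhs(eq$Veq, eq$seq, conn, p, eq$Vth)
    expect_lt(max(abs(c(d$dV, d$ds))), 1e-9)
  }
})

test_that("the equilibrium linear system is strictly diagonally dominant", {
  p <- model_parameters()
  s_star <- p$ar * 0.5 / (p$ar * 0.5 + p$ad)
  for (seed in 1:100) {
    conn <- generate_synthetic_connectome(2, 3, 3, 0.4, 0.4, 0.5,
                                          seed = seed)
    A <- -conn$gap
    diag(A) <- p$Gc + rowSums(conn$gap) + s_star * rowSums(conn$syn)
    off <- rowSums(abs(A)) - abs(diag(A))
    expect_true(all(abs(diag(A)) > off))
  }
})

test_that("Newton refinds a fixed point from a perturbed guess", {
  conn <- generate_synthetic_connectome(3, 4, 5, 0.2, 0.3, 0.3, seed = 12)
  p <- model_parameters()
  eq <- standard_equilibrium(conn, p)
  st <- stimulus(c(1, rep(0, 11)), 5000)
  # long integration finds the stable fixed point independently
  traj <- integrate_model(eq$Veq, eq$seq, conn, p, eq$Vth, st,
                          duration = 40, sample_dt = 0.02)
  ref <- state_at(traj)
  set.seed(1)
  fp <- solve_fixed_point(ref$V + rnorm(12, 0, 0.1),
                          pmin(pmax(ref$s + rnorm(12, 0, 0.005), 0), 1),
                          conn, p, eq$Vth, st)
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-9)
  expect_lt(max(abs(fp$V - ref$V)), 1e-6)
  expect_error(solve_fixed_point(c(NA, ref$V[-1]), ref$s, conn, p,
                                 eq$Vth, st), "finite")
})

test_that("already-converged guesses return immediately", {
  fx <- build_fixture("gap_pair")
  eq <- standard_equilibrium(fx$connectome, fx$params)
  fp <- solve_fixed_point(eq$Veq, eq$seq, fx$connectome, fx$params, eq$Vth)
  expect_true(fp$converged)
  expect_equal(fp$iterations, 0L)
  expect_equal(fp$V, eq$Veq)
})

test_that("isolated neuron is stable with leading eigenvalue -5.5/s", {
  fx <- build_fixture("isolated_neuron")
  eq <- standard_equilibrium(fx$connectome, fx$params)
  sa <- stability(eq$Veq, eq$seq, fx$connectome, fx$params, eq$Vth)
  expect_true(sa$stable)
  expect_equal(sa$leading_real_part, -5.5)
  expect_setequal(round(Re(sa$eigenvalues), 9), c(-10, -5.5))
})

test_that("gap-only networks are stable at zero input", {
  conn <- generate_synthetic_connectome(3, 3, 4, 0.5, 0, 0, seed = 9)
  p <- model_parameters()
  eq <- standard_equilibrium(conn, p)
  sa <- stability(eq$Veq, eq$seq, conn, p, eq$Vth)
  expect_true(sa$stable)
  # the voltage block is -(Gc I + gap Laplacian)/C: negative definite
  expect_lt(sa$leading_real_part, 0)
})

test_that("stability refuses points that are not fixed points", {
  fx <- build_fixture("isolated_neuron")
  expect_error(stability(-20, 0.5, fx$connectome, fx$params, Vth = -35),
               "not a fixed point")
})

test_that("oscillator pair is unstable at rest, quenched by drive", {
  fx <- build_fixture("mutual_excitation_oscillator")
  eq <- standard_equilibrium(fx$connectome, fx$params)
  sa0 <- stability(eq$Veq, eq$seq, fx$connectome, fx$params, eq$Vth)
  expect_false(sa0$stable)
  expect_equal(sa0$leading_real_part, fx$expected$leading_at_zero,
               tolerance = 1e-3)
  expect_gt(max(abs(Im(sa0$eigenvalues))), 1)  # a genuine focus
  st <- stimulus(c(1, 0), fx$expected$stable_at)
  fp <- solve_fixed_point(eq$Veq, eq$seq, fx$connectome, fx$params,
                          eq$Vth, st)
  sa1 <- stability(fp$V, fp$s, fx$connectome, fx$params, eq$Vth, st)
  expect_true(sa1$stable)
})

test_that("continuation matches cold-start Newton along the branch", {
  conn <- generate_synthetic_connectome(3, 4, 5, 0.2, 0.3, 0.3, seed = 12)
  p <- model_parameters()
  eq <- standard_equilibrium(conn, p)
  amps <- seq(0, 1e4, length.out = 6)
  dirn <- c(1, rep(0, 11))
  br <- continue_branch(conn, p, eq$Vth, dirn, amps)
  expect_equal(br$n_converged, 6L)
  expect_equal(br$stable, br$leading_real_part < 0)
  for (i in seq_along(amps)) {
    cold <- solve_fixed_point(eq$Veq, eq$seq, conn, p, eq$Vth,
                              stimulus(dirn, amps[i]))
    expect_true(cold$converged)
    expect_lt(max(abs(cold$V - br$V[, i])), 1e-8)
  }
  expect_error(continue_branch(conn, p, eq$Vth, dirn, c(1, 1)),
               "strictly increasing")
})

test_that("zero-synapse branches are affine in the input amplitude", {
  conn <- generate_synthetic_connectome(2, 3, 3, 0.5, 0, 0, seed = 6)
  p <- model_parameters()
  eq <- standard_equilibrium(conn, p)
  dirn <- c(1, rep(0, 7))
  amps <- c(0, 250, 500, 750, 1000)
  br <- continue_branch(conn, p, eq$Vth, dirn, amps)
  expect_true(all(br$stable))
  # analytic: A V = Gc Ecell + a d, with A the leak + gap Laplacian
  A <- -conn$gap
  diag(A) <- p$Gc + rowSums(conn$gap)
  for (i in seq_along(amps)) {
    Va <- solve(A, p$Gc * p$Ecell + amps[i] * dirn)
    expect_lt(max(abs(br$V[, i] - Va)), 1e-10)
  }
})

test_that("bisection refines the stability flip to the eigen-scan value", {
  fx <- build_fixture("mutual_excitation_oscillator")
  conn <- fx$connectome; p <- fx$params
  eq <- standard_equilibrium(conn, p)
  # strong symmetric drive holds the pair stable; as the drive decays to
  # zero the focus destabilizes: sweep increasing amplitude along -(1,1)
  dirn <- c(-1, -1)
  amps <- seq(-100, -5, by = 5)
  br <- continue_branch(conn, p, eq$Vth, dirn, amps)
  expect_true(br$stable[1])
  expect_false(br$stable[br$n_converged])
  a_ref <- first_bifurcation_amplitude(br, conn, p, eq$Vth, rel_tol = 1e-4)
  # dense eigen-scan oracle: warm-started solves on a 10^4-point grid
  dense <- seq(-100, -5, length.out = 1e4)
  guess <- list(V = br$V[, 1], s = br$s[, 1])
  flip_dense <- NA_real_
  for (a in dense) {
    st <- stimulus(dirn, a)
    fp <- solve_fixed_point(guess$V, guess$s, conn, p, eq$Vth, st)
    if (!fp$converged) stop("dense-scan solve failed at amplitude ", a)
    guess <- list(V = fp$V, s = fp$s)
    lead <- max(Re(eigen(jacobian(fp$V, fp$s, conn, p, eq$Vth, st),
                         only.values = TRUE)$values))
    if (lead >= 0) { flip_dense <- a; break }
  }
  expect_false(is.na(flip_dense))
  expect_lt(abs(a_ref - flip_dense) / abs(flip_dense), 1e-3)
})

test_that("all-stable branches report no bifurcation", {
  conn <- generate_synthetic_connectome(2, 2, 2, 0.5, 0, 0, seed = 3)
  p <- model_parameters()
  eq <- standard_equilibrium(conn, p)
  br <- continue_branch(conn, p, eq$Vth, c(1, 0, 0, 0, 0, 0),
                        seq(0, 1000, length.out = 5))
  expect_true(is.na(first_bifurcation_amplitude(br)))
})
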