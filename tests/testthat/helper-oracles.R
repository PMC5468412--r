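# Shared helpers: independent oracles and small constructors used across
# the suite. Oracles here never call the code paths they check.

# Central finite-difference Jacobian of the full vector field.
fd_jacobian <- function(V, s, conn, params, Vth, stim = NULL, h = 1e-6) {
  n <- length(V)
  f <- function(x) {
    d <- rhs(x[1:n], x[(n + 1):(2 * n)], conn, params, Vth, stim)
    c(d$dV, d$ds)
  }
  x0 <- c(V, s)
  vapply(seq_len(2 * n), function(k) {
    e <- numeric(2 * n); e[k] <- h
    (f(x0 + e) - f(x0 - e)) / (2 * h)
  }, numeric(2 * n))
}

# Write a tiny connectome CSV pair into a temp dir; returns the two paths.
write_csv_fixture <- function(edges, meta, dir = tempfile("conn")) {
  dir.create(dir)
  ef <- file.path(dir, "edges.csv")
  mf <- file.path(dir, "meta.csv")
  writeLines(c("pre,post,kind,count", edges), ef)
  writeLines(c("name,class,inhibitory,subclass", meta), mf)
  list(edges = ef, meta = mf)
}

# A bare projection plane whose two modes are coordinate axes of the named
# indices; used by harness systems that live directly in plane coordinates.
identity_plane <- function(n_state, indices = 1:2, reference = c(0, 0)) {
  structure(list(motor_indices = as.integer(indices),
                 modes = diag(2),
                 singular_values = c(1, 1),
                 reference = reference,
                 variance_fraction = 1,
                 n_neurons = as.integer(n_state)),
            class = "projection_plane")
}

# Wrap plain (times x k) coordinate data as a trajectory whose "voltages"
# are the coordinates (activities identically zero), so the classification
# machinery can be driven with constructed signals.
harness_trajectory <- function(times, coords) {
  coords <- as.matrix(coords)
  structure(list(times = times, V = coords,
                 s = matrix(0, nrow(coords), ncol(coords)),
                 stimulus = NULL), class = "trajectory")
}

# Integrate the bistable normal form xdot = x - x^3, ydot = -y with deSolve
# and classify its tail through the package's own machinery.
normal_form_record <- function(x0, y0, duration = 30) {
  out <- deSolve::lsoda(c(x0, y0), seq(0, duration, by = 0.05),
                        function(t, y, p) list(c(y[1] - y[1]^3, -y[2])),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  traj <- harness_trajectory(out[, 1], out[, 2:3])
  plane <- identity_plane(2)
  rec <- classify_attractor(traj, plane, window = 10, tol_fp = 1e-6)
  rec$plane_coords <- project_state(traj$V[nrow(traj$V), ], plane)
  rec
}
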