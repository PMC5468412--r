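#' Fit the two-mode motorneuron projection plane
#'
#' Collects the forward-motion motorneuron voltage snapshots of a trajectory
#' into a matrix (neurons x times), centers each snapshot at the
#' standard-equilibrium motorneuron voltages, and takes the singular value
#' decomposition. The plane is spanned by the first two left singular
#' vectors -- the dominant orthogonal modes of motorneuron activity. Only
#' motorneuron voltages project onto the plane; sensory and interneuron
#' voltages (and all synaptic activities) lie in its null space. For sign
#' reproducibility each mode's largest-magnitude entry is made positive.
#'
#' Centering at the standard equilibrium makes plane coordinates directly
#' interpretable as displacement from the reference state, which is the
#' distance every sweep reports.
#'
#' @param traj a `trajectory` covering the oscillation to be captured.
#' @param motor_indices indices of the motorneuron subset, e.g. from
#'   [forward_motor_indices].
#' @param reference a [standard_equilibrium] (or a numeric vector of
#'   reference voltages over all neurons).
#' @return An object of class `projection_plane`: `motor_indices`, `modes`
#'   (length(motor_indices) x 2 orthonormal), `singular_values` (full
#'   spectrum), `reference` (motorneuron reference voltages),
#'   `variance_fraction` captured by the two modes, `n_neurons`.
#' @export
fit_projection_plane <- function(traj, motor_indices, reference) {
  if (length(motor_indices) < 2)
    stop("at least two motorneurons are required")
  ref_all <- if (inherits(reference, "standard_equilibrium"))
    reference$Veq else as.numeric(reference)
  ref <- ref_all[motor_indices]
  X <- t(traj$V[, motor_indices, drop = FALSE]) - ref   # neurons x times
  sv <- svd(X)
  if (sum(sv$d > max(sv$d) * 1e-12) < 2)
    stop("degenerate plane: fewer than two nonzero singular values")
  modes <- sv$u[, 1:2, drop = FALSE]
  for (k in 1:2) {
    i <- which.max(abs(modes[, k]))
    if (modes[i, k] < 0) modes[, k] <- -modes[, k]
  }
  structure(list(motor_indices = as.integer(motor_indices),
                 modes = modes,
                 singular_values = sv$d,
                 reference = ref,
                 variance_fraction = sum(sv$d[1:2]^2) / sum(sv$d^2),
                 n_neurons = ncol(traj$V)),
            class = "projection_plane")
}

#' @export
print.projection_plane <- function(x, ...) {
  cat(sprintf(
    "projection plane: %d motorneurons, two modes capture %.2f%% of variance\n",
    length(x$motor_indices), 100 * x$variance_fraction))
  invisible(x)
}

#' Project voltages onto the plane
#'
#' Coordinates are `t(modes) %*% (V[motor] - reference)`; states differing
#' only outside the motorneuron subset project identically.
#'
#' @param V full voltage vector (length `n_neurons`).
#' @param plane a [projection_plane].
#' @return length-2 numeric plane coordinates.
#' @export
project_state <- function(V, plane) {
  if (length(V) != plane$n_neurons)
    stop("state dimension does not match the plane's parent system")
  as.numeric(crossprod(plane$modes, V[plane$motor_indices] - plane$reference))
}

#' Project a trajectory (or voltage matrix) onto the plane
#'
#' @param traj a `trajectory`, or a samples x neurons voltage matrix.
#' @param plane a [projection_plane].
#' @return samples x 2 matrix of plane coordinates.
#' @export
project <- function(traj, plane) {
  Vm <- if (inherits(traj, "trajectory")) traj$V else as.matrix(traj)
  if (ncol(Vm) != plane$n_neurons)
    stop("state dimension does not match the plane's parent system")
  sweep(Vm[, plane$motor_indices, drop = FALSE], 2, plane$reference) %*%
    plane$modes
}

#' Distance from the standard equilibrium within the plane
#'
#' @inheritParams project_state
#' @return Euclidean norm of the plane coordinates.
#' @export
plane_distance <- function(V, plane) sqrt(sum(project_state(V, plane)^2))

#' Serialize / restore a projection plane as delimited text
#'
#' @param plane a [projection_plane].
#' @param file path.
#' @return `write_plane` returns the path invisibly; `read_plane` the plane.
#' @export
write_plane <- function(plane, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d variance_fraction=%.17g",
                     plane$n_neurons, plane$variance_fraction), con)
  writeLines(paste0("# singular_values=",
                    paste(sprintf("%.17g", plane$singular_values),
                          collapse = ",")), con)
  tab <- data.frame(index = plane$motor_indices,
                    reference = plane$reference,
                    mode1 = plane$modes[, 1], mode2 = plane$modes[, 2])
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_plane
#' @export
read_plane <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- function(s) as.numeric(sub(".*=", "", s))
  sv <- as.numeric(strsplit(sub("^# singular_values=", "", lines[2]),
                            ",")[[1]])
  tab <- utils::read.csv(textConnection(lines[-(1:2)]))
  structure(list(motor_indices = as.integer(tab$index),
                 modes = cbind(tab$mode1, tab$mode2),
                 singular_values = sv,
                 reference = tab$reference,
                 variance_fraction = kv(hdr[2]),
                 n_neurons = as.integer(kv(hdr[1]))),
            class = "projection_plane")
}
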