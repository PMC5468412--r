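#' Connectome objects
#'
#' A `connectome` bundles everything the dynamical model needs to know about
#' the network: the total gap-junction conductance between each unordered
#' neuron pair, the maximal chemical-synapse conductance onto each neuron from
#' each presynaptic partner, a coarse class label per neuron (sensory, inter,
#' motor), an optional forward-motion motorneuron subclass (DB, DD, VB, VD),
#' and a per-neuron flag marking inhibitory neurons (which fixes the reversal
#' potential their synapses pull towards).
#'
#' Conductances are stored in picosiemens. `gap` is symmetric with zero
#' diagonal; `syn[i, j]` is the conductance onto neuron `i` from neuron `j`
#' (zero diagonal). Both are dense base matrices: the networks of interest
#' have at most a few hundred neurons.
#'
#' @param neuron_names character vector of unique neuron identifiers.
#' @param gap n x n symmetric nonnegative matrix of gap conductances (pS).
#' @param syn n x n nonnegative matrix of synaptic conductances (pS),
#'   orientation "onto row i from column j".
#' @param neuron_class character vector, each element one of `"sensory"`,
#'   `"inter"`, `"motor"`.
#' @param is_inhibitory logical vector; `TRUE` marks an inhibitory neuron.
#' @param motor_subclass character vector with entries in
#'   `c("DB", "DD", "VB", "VD", "other")`; defaults to `"other"` everywhere.
#' @return An object of class `connectome`.
#' @export
connectome <- function(neuron_names, gap, syn, neuron_class, is_inhibitory,
                       motor_subclass = NULL) {
  n <- length(neuron_names)
  if (n < 1L) stop("a connectome needs at least one neuron")
  if (anyDuplicated(neuron_names)) stop("duplicate neuron names")
  if (is.null(motor_subclass)) motor_subclass <- rep("other", n)
  gap <- as.matrix(gap)
  syn <- as.matrix(syn)
  if (!all(dim(gap) == c(n, n)) || !all(dim(syn) == c(n, n)))
    stop("matrix dimensions must equal the number of neurons")
  if (length(neuron_class) != n || length(is_inhibitory) != n ||
      length(motor_subclass) != n)
    stop("per-neuron metadata must have one entry per neuron")
  if (!all(neuron_class %in% c("sensory", "inter", "motor")))
    stop("neuron_class entries must be 'sensory', 'inter' or 'motor'")
  if (!all(motor_subclass %in% c("DB", "DD", "VB", "VD", "other")))
    stop("motor_subclass entries must be DB, DD, VB, VD or 'other'")
  if (any(gap < 0) || any(syn < 0)) stop("conductances must be nonnegative")
  if (any(abs(gap - t(gap)) > 0)) stop("gap matrix must be symmetric")
  if (any(diag(gap) != 0) || any(diag(syn) != 0))
    stop("self-connections are not allowed (zero diagonals required)")
  dimnames(gap) <- dimnames(syn) <- list(neuron_names, neuron_names)
  structure(list(
    neuron_names  = as.character(neuron_names),
    gap           = gap,
    syn           = syn,
    neuron_class  = as.character(neuron_class),
    motor_subclass = as.character(motor_subclass),
    is_inhibitory = as.logical(is_inhibitory)
  ), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$neuron_names)
  cat(sprintf("connectome: %d neurons (%d sensory, %d inter, %d motor)\n",
              n, sum(x$neuron_class == "sensory"),
              sum(x$neuron_class == "inter"), sum(x$neuron_class == "motor")))
  cat(sprintf("  gap pairs: %d   chemical edges: %d   inhibitory: %d\n",
              sum(x$gap[upper.tri(x$gap)] > 0), sum(x$syn > 0),
              sum(x$is_inhibitory)))
  invisible(x)
}

#' Number of neurons in a connectome
#' @param conn a `connectome`.
#' @return integer count.
#' @export
n_neurons <- function(conn) length(conn$neuron_names)

#' Indices of forward-motion motorneurons
#'
#' Motorneurons whose subclass is one of DB, DD, VB, VD; these are the
#' coordinates the projection plane lives on.
#'
#' @param conn a `connectome`.
#' @return integer vector of neuron indices.
#' @export
forward_motor_indices <- function(conn) {
  which(conn$neuron_class == "motor" &
          conn$motor_subclass %in% c("DB", "DD", "VB", "VD"))
}

#' Read a connectome from edge-list and metadata files
#'
#' The edge file is comma-separated with header `pre,post,kind,count`, where
#' `kind` is `"gap"` or `"chem"` and `count` is the number of physical
#' contacts. The metadata file has header `name,class,inhibitory,subclass`;
#' neuron order follows metadata row order. Total conductances are
#' `count * g_unit`; gap counts reported in either direction for the same
#' pair are summed before symmetrization, since the gap entry is the total
#' conductance between the pair.
#'
#' @param edge_file path to the edge CSV (may contain zero edge rows).
#' @param meta_file path to the neuron metadata CSV.
#' @param g_unit conductance per contact, pS (default 100).
#' @return A [connectome].
#' @export
read_connectome <- function(edge_file, meta_file, g_unit = 100) {
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("name", "class", "inhibitory", "subclass")
  if (!all(need %in% names(meta)))
    stop("metadata file must have columns name,class,inhibitory,subclass")
  if (anyDuplicated(meta$name))
    stop("duplicate neuron name in metadata: ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "))
  names_ <- meta$name
  n <- length(names_)
  gap <- syn <- matrix(0, n, n)
  edges <- utils::read.csv(edge_file, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (!all(c("pre", "post", "kind", "count") %in% names(edges)))
      stop("edge file must have columns pre,post,kind,count")
    unknown <- setdiff(unique(c(edges$pre, edges$post)), names_)
    if (length(unknown))
      stop("edge list references unknown neuron(s): ",
           paste(unknown, collapse = ", "))
    if (any(!is.finite(edges$count)) || any(edges$count < 0))
      stop("edge counts must be finite and nonnegative")
    if (!all(edges$kind %in% c("gap", "chem")))
      stop("edge kind must be 'gap' or 'chem'")
    i <- match(edges$post, names_)   # onto
    j <- match(edges$pre, names_)    # from
    if (any(i == j)) stop("self-edges are not allowed")
    for (k in seq_len(nrow(edges))) {
      w <- edges$count[k] * g_unit
      if (edges$kind[k] == "chem") {
        syn[i[k], j[k]] <- syn[i[k], j[k]] + w
      } else {
        gap[i[k], j[k]] <- gap[i[k], j[k]] + w
        gap[j[k], i[k]] <- gap[j[k], i[k]] + w
      }
    }
  }
  inhib <- tolower(meta$inhibitory) %in% c("1", "true", "t", "yes")
  sub <- ifelse(meta$subclass %in% c("DB", "DD", "VB", "VD"),
                meta$subclass, "other")
  connectome(names_, gap, syn, meta$class, inhib, sub)
}

#' Write a connectome to the edge-list/metadata CSV dialect
#'
#' Inverse of [read_connectome] up to the per-contact unit: conductances are
#' divided by `g_unit` to recover counts. Gap pairs are emitted once (upper
#' triangle).
#'
#' @param conn a `connectome`.
#' @param edge_file,meta_file output paths.
#' @param g_unit conductance per contact, pS.
#' @return invisibly, the two paths.
#' @export
write_connectome <- function(conn, edge_file, meta_file, g_unit = 100) {
  nm <- conn$neuron_names
  meta <- data.frame(name = nm, class = conn$neuron_class,
                     inhibitory = ifelse(conn$is_inhibitory, "true", "false"),
                     subclass = conn$motor_subclass)
  utils::write.csv(meta, meta_file, row.names = FALSE, quote = FALSE)
  rows <- list()
  ut <- which(upper.tri(conn$gap) & conn$gap > 0, arr.ind = TRUE)
  if (nrow(ut))
    rows[[1]] <- data.frame(pre = nm[ut[, 1]], post = nm[ut[, 2]],
                            kind = "gap", count = conn$gap[ut] / g_unit)
  ch <- which(conn$syn > 0, arr.ind = TRUE)
  if (nrow(ch))
    rows[[2]] <- data.frame(pre = nm[ch[, 2]], post = nm[ch[, 1]],
                            kind = "chem", count = conn$syn[ch] / g_unit)
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pre = character(), post = character(),
               kind = character(), count = numeric())
  utils::write.csv(edges, edge_file, row.names = FALSE, quote = FALSE)
  invisible(c(edge_file, meta_file))
}

#' Generate a random synthetic connectome
#'
#' Draws an Erdos-Renyi-style network with the structural features the model
#' assumes: a symmetric nonnegative gap matrix (edges on unordered pairs), a
#' nonnegative directed chemical-synapse matrix (edges on ordered pairs),
#' three neuron classes in a fixed order (sensory, then inter, then motor),
#' and an independent per-neuron inhibitory flag. Each realized edge carries
#' one contact of `g_unit` pS. Motorneurons are assigned DB/DD/VB/VD
#' subclasses cyclically so a projection plane can always be built.
#'
#' @param n_sensory,n_inter,n_motor class sizes (total must be >= 1).
#' @param gap_density probability of a gap junction on each unordered pair.
#' @param syn_density probability of a chemical synapse on each ordered pair.
#' @param inhibitory_fraction probability that a neuron is inhibitory.
#' @param seed integer seed; identical seeds give identical connectomes.
#' @param g_unit conductance per contact, pS.
#' @return A [connectome].
#' @export
generate_synthetic_connectome <- function(n_sensory, n_inter, n_motor,
                                          gap_density = 0.1,
                                          syn_density = 0.1,
                                          inhibitory_fraction = 0.3,
                                          seed = 1L, g_unit = 100) {
  n <- n_sensory + n_inter + n_motor
  if (n < 1L) stop("at least one neuron is required")
  probs <- c(gap_density, syn_density, inhibitory_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("densities and inhibitory_fraction must lie in [0, 1]")
  cls <- rep(c("sensory", "inter", "motor"), c(n_sensory, n_inter, n_motor))
  nm <- sprintf("%s%03d", toupper(substr(cls, 1, 1)), seq_len(n))
  sub <- rep("other", n)
  if (n_motor > 0)
    sub[cls == "motor"] <-
      rep(c("DB", "DD", "VB", "VD"), length.out = n_motor)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gap <- matrix(0, n, n)
  if (n > 1) {
    ut <- upper.tri(gap)
    gap[ut] <- g_unit * (stats::runif(sum(ut)) < gap_density)
    gap <- gap + t(gap)
  }
  syn <- matrix(g_unit * (stats::runif(n * n) < syn_density), n, n)
  diag(syn) <- 0
  inhib <- stats::runif(n) < inhibitory_fraction
  connectome(nm, gap, syn, cls, inhib, sub)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
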