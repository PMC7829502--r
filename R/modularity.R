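## Multilayer (temporal) modularity.
##
## Quality function: for layers s with weights A_ijs, strengths k_is and
## totals 2m_s,
##
##   Q(gamma, omega) = 1/(2 mu) * sum_{ijsr} [ (A_ijs -
##       gamma * k_is k_js / (2 m_s)) * delta(s, r)
##       + delta(i, j) * omega * [|s - r| = 1] ] * delta(M_is, M_jr)
##
## with 2 mu = sum_s 2m_s + 2 * omega * N * (T - 1). Coupling is ordinal:
## a node's copies in adjacent layers are rewarded for sharing a module.
## Optimization is a generalized Louvain heuristic (see src/).

#' Multilayer modularity parameters
#'
#' @param gamma topological resolution, > 0; larger values favour more,
#'   smaller modules. Default 1.
#' @param omega inter-layer coupling, >= 0, applied between copies of the
#'   same node in adjacent layers. Default 1.
#' @param n_runs ensemble size (independent optimization restarts).
#' @param seed master seed; per-run seeds are derived from it.
#' @return a \code{modularity_params} list.
#' @export
modularity_params <- function(gamma = 1, omega = 1, n_runs = 100L,
                              seed = 1L) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  structure(list(gamma = gamma, omega = omega, n_runs = n_runs,
                 seed = as.integer(seed)), class = "modularity_params")
}

#' Assemble the multilayer graph from a dynamic connectivity stack
#'
#' Negative Fisher-z weights are set to zero before optimization: the
#' configuration null model is ill-behaved on signed matrices, and
#' zeroing is the common practice with temporal-modularity toolboxes.
#' Per-layer strengths and totals are precomputed.
#'
#' @param dg a \code{dynamic_graph} or a list of symmetric node x node
#'   weight matrices.
#' @return a \code{multilayer_graph}: list with \code{layers}
#'   (non-negative), \code{strength} (node x layer matrix),
#'   \code{two_m} (per-layer total weight), \code{n_nodes},
#'   \code{n_layers}.
#' @export
build_multilayer <- function(dg) {
  layers <- if (inherits(dg, "dynamic_graph")) dg$layers else dg
  layers <- lapply(layers, function(a) {
    a <- as.matrix(a)
    a[a < 0] <- 0
    diag(a) <- 0
    a
  })
  n <- nrow(layers[[1L]])
  T <- length(layers)
  strength <- vapply(layers, rowSums, numeric(n))
  strength <- matrix(strength, nrow = n)
  two_m <- colSums(strength)
  if (any(two_m == 0))
    stop(sprintf(
      "layer %d has no positive weights; the null model is undefined",
      which(two_m == 0)[1L]))
  structure(list(layers = layers, strength = strength, two_m = two_m,
                 n_nodes = n, n_layers = T), class = "multilayer_graph")
}

#' Normalization constant 2*mu of the multilayer quality function
#'
#' Sum of all intra-layer strengths plus the total ordinal coupling
#' weight \code{2 * omega * n_nodes * (n_layers - 1)}.
#'
#' @param mg a \code{multilayer_graph}.
#' @param params a \code{modularity_params}.
#' @return scalar 2*mu.
#' @export
two_mu <- function(mg, params) {
  sum(mg$two_m) + 2 * params$omega * mg$n_nodes * (mg$n_layers - 1L)
}

#' Evaluate multilayer modularity of a given partition
#'
#' Direct evaluation of the quality function (including the diagonal null
#' terms, as the standard toolboxes do), independent of the optimizer.
#'
#' @param mg a \code{multilayer_graph}.
#' @param labels node x layer integer matrix of module assignments.
#' @param params a \code{modularity_params} (only \code{gamma} and
#'   \code{omega} are used).
#' @return scalar modularity q.
#' @export
modularity_q <- function(mg, labels, params) {
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == mg$n_nodes, ncol(labels) == mg$n_layers)
  total <- 0
  for (s in seq_len(mg$n_layers)) {
    k <- mg$strength[, s]
    P <- mg$layers[[s]] - params$gamma * tcrossprod(k) / mg$two_m[s]
    same <- outer(labels[, s], labels[, s], "==")
    total <- total + sum(P[same])
  }
  if (mg$n_layers > 1L && params$omega > 0) {
    for (s in seq_len(mg$n_layers - 1L))
      total <- total +
        2 * params$omega * sum(labels[, s] == labels[, s + 1L])
  }
  total / two_mu(mg, params)
}

# Dense supra-modularity matrix (node-layer copies x node-layer copies).
# Kept internal: quadratic in n_nodes * n_layers.
supra_modularity_matrix <- function(mg, params) {
  n <- mg$n_nodes; T <- mg$n_layers
  nT <- n * T
  if (nT > 8000L)
    stop(sprintf(paste0(
      "%d node-layer copies exceed the dense optimizer limit (8000); ",
      "use a larger window step to reduce the layer count"), nT))
  B <- matrix(0, nT, nT)
  for (s in seq_len(T)) {
    idx <- ((s - 1L) * n + 1L):(s * n)
    k <- mg$strength[, s]
    B[idx, idx] <- mg$layers[[s]] - params$gamma * tcrossprod(k) / mg$two_m[s]
  }
  if (T > 1L && params$omega > 0) {
    for (s in seq_len(T - 1L)) {
      i <- ((s - 1L) * n + 1L):(s * n)
      j <- (s * n + 1L):((s + 1L) * n)
      B[cbind(i, j)] <- params$omega
      B[cbind(j, i)] <- params$omega
    }
  }
  B
}

#' One generalized-Louvain optimization run
#'
#' Greedy phase: node-layer copies are swept in a seeded random order and
#' moved to the neighbouring module with the largest positive modularity
#' gain (ties keep the current module, otherwise the lowest module id);
#' aggregation phase: modules are contracted and the procedure repeats on
#' the reduced structure until no move improves q by more than 1e-10.
#'
#' @param mg a \code{multilayer_graph}.
#' @param params a \code{modularity_params}.
#' @param seed integer seed for this run's sweep orders.
#' @return a \code{partition}: list with \code{labels} (node x layer
#'   integer matrix) and \code{q}.
#' @export
louvain_run <- function(mg, params, seed = params$seed) {
  B <- supra_modularity_matrix(mg, params)
  res <- .genlouvain_cpp(B, two_mu(mg, params), as.double(seed))
  structure(list(labels = matrix(res$labels, mg$n_nodes, mg$n_layers),
                 q = res$q, seed = as.integer(seed)),
            class = "partition")
}

#' Ensemble of optimization runs
#'
#' The heuristic's local optima vary with the sweep order, so the
#' partition is re-optimized \code{n_runs} times with per-run seeds
#' derived deterministically from the master seed; downstream metrics are
#' averaged over the ensemble.
#'
#' @param mg a \code{multilayer_graph}.
#' @param params a \code{modularity_params}.
#' @return a \code{partition_ensemble}: list with \code{partitions}
#'   (length \code{n_runs}), \code{q} (achieved modularities) and
#'   \code{params}.
#' @export
partition_ensemble <- function(mg, params) {
  seeds <- derive_seeds(params$seed, params$n_runs)
  parts <- lapply(seeds, function(s) louvain_run(mg, params, seed = s))
  structure(list(partitions = parts,
                 q = vapply(parts, `[[`, numeric(1L), "q"),
                 params = params),
            class = "partition_ensemble")
}

# Deterministic child-seed fan-out: a fixed counter scheme so that
# subject- or run-level parallelism cannot change results.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> %d runs, q in [%.4f, %.4f]\n",
              length(x$partitions), min(x$q), max(x$q)))
  invisible(x)
}
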