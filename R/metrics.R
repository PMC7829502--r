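## Dynamic reconfiguration metrics derived from partition ensembles.
##
## All metrics are averaged over the ensemble's optimization runs; module
## ids are arbitrary per run, and every metric is invariant to relabeling.

ens_labels <- function(ens) {
  if (inherits(ens, "partition_ensemble"))
    lapply(ens$partitions, `[[`, "labels")
  else if (inherits(ens, "partition")) list(ens$labels)
  else if (is.list(ens)) ens
  else list(as.matrix(ens))
}

#' Connection-stability (module allegiance) matrix
#'
#' For each run, the fraction of layers in which a node pair shares a
#' module; averaged over runs. The diagonal is fixed at 1 (a node is
#' always with itself).
#'
#' @param ens a \code{partition_ensemble}, a \code{partition}, or a list
#'   of node x layer label matrices.
#' @return symmetric node x node matrix with entries in [0, 1].
#' @export
connection_stability <- function(ens) {
  labs <- ens_labels(ens)
  n <- nrow(labs[[1L]])
  acc <- matrix(0, n, n)
  for (lab in labs) {
    run <- matrix(0, n, n)
    for (s in seq_len(ncol(lab)))
      run <- run + outer(lab[, s], lab[, s], "==")
    acc <- acc + run / ncol(lab)
  }
  out <- acc / length(labs)
  diag(out) <- 1
  out
}

#' Nodal flexibility
#'
#' Per run, the fraction of the T - 1 layer transitions at which a node
#' changes module; averaged over runs. 0 means the node never switches,
#' 1 means it switches at every transition.
#'
#' @inheritParams connection_stability
#' @return numeric vector, one value in [0, 1] per node.
#' @export
flexibility <- function(ens) {
  labs <- ens_labels(ens)
  T <- ncol(labs[[1L]])
  if (T < 2L) stop("flexibility needs at least 2 layers")
  per_run <- vapply(labs, function(lab) {
    rowSums(lab[, -1L, drop = FALSE] != lab[, -T, drop = FALSE]) / (T - 1L)
  }, numeric(nrow(labs[[1L]])))
  rowMeans(matrix(per_run, nrow = nrow(labs[[1L]])))
}

#' Classify module-switch events of one partition
#'
#' A node's switch at transition s -> s+1 is \emph{cohesive} when at
#' least one other node makes the same source-module to
#' destination-module move at that transition, and \emph{disjoint}
#' otherwise (including moves whose partners leave the same source for a
#' different destination).
#'
#' @param labels node x layer integer matrix (or a \code{partition}).
#' @return data frame with columns \code{transition}, \code{node},
#'   \code{from}, \code{to}, \code{kind} ("disjoint"/"cohesive") and
#'   \code{n_partners} (nodes sharing the same move, excluding self).
#' @export
change_events <- function(labels) {
  if (inherits(labels, "partition")) labels <- labels$labels
  labels <- as.matrix(labels)
  T <- ncol(labels)
  if (T < 2L) stop("change events need at least 2 layers")
  out <- vector("list", T - 1L)
  for (s in seq_len(T - 1L)) {
    moved <- which(labels[, s] != labels[, s + 1L])
    if (!length(moved)) next
    key <- paste(labels[moved, s], labels[moved, s + 1L], sep = "->")
    sz <- table(key)
    n_partners <- as.integer(sz[key]) - 1L
    out[[s]] <- data.frame(
      transition = s, node = moved,
      from = labels[moved, s], to = labels[moved, s + 1L],
      kind = ifelse(n_partners >= 1L, "cohesive", "disjoint"),
      n_partners = n_partners, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(data.frame(transition = integer(0), node = integer(0),
                      from = integer(0), to = integer(0),
                      kind = character(0), n_partners = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Nodal disjointness and cohesion strength
#'
#' Per run, disjointness of node i is the number of its disjoint switches
#' divided by T - 1 (the rate at which the node changes module alone);
#' cohesion strength is the number of partner nodes sharing the same
#' source -> destination move, summed over transitions and divided by
#' T - 1. Both are averaged over runs. Per run,
#' \code{disjoint + cohesive counts = flexibility * (T - 1)}.
#'
#' @inheritParams connection_stability
#' @return list with numeric per-node vectors \code{disjointness},
#'   \code{cohesion_strength}, and run-averaged raw counts
#'   \code{disjoint_count}, \code{cohesive_count}.
#' @export
disjointness_cohesion <- function(ens) {
  labs <- ens_labels(ens)
  n <- nrow(labs[[1L]])
  T <- ncol(labs[[1L]])
  if (T < 2L) stop("disjointness needs at least 2 layers")
  dis <- coh <- dcnt <- ccnt <- numeric(n)
  for (lab in labs) {
    ev <- change_events(lab)
    d <- c <- p <- numeric(n)
    if (nrow(ev)) {
      is_dis <- ev$kind == "disjoint"
      d <- as.numeric(tabulate(ev$node[is_dis], nbins = n))
      c <- as.numeric(tabulate(ev$node[!is_dis], nbins = n))
      if (any(!is_dis))
        p <- vapply(seq_len(n), function(i)
          sum(ev$n_partners[ev$node == i]), numeric(1L))
    }
    dis <- dis + d / (T - 1L)
    coh <- coh + p / (T - 1L)
    dcnt <- dcnt + d
    ccnt <- ccnt + c
  }
  k <- length(labs)
  list(disjointness = dis / k, cohesion_strength = coh / k,
       disjoint_count = dcnt / k, cohesive_count = ccnt / k)
}

#' Full per-subject metric table
#'
#' Bundles connection stability, flexibility, disjointness and cohesion
#' strength from one ensemble, with network-level aggregates when an
#' atlas is supplied.
#'
#' @param ens a \code{partition_ensemble}.
#' @param atlas optional \code{atlas} used for network aggregation.
#' @return a \code{metric_table}: list with \code{connection_stability}
#'   (node x node), per-node \code{flexibility}, \code{disjointness},
#'   \code{cohesion_strength}, scalar \code{global_disjointness}, and
#'   (with an atlas) \code{network_means}.
#' @export
metric_table <- function(ens, atlas = NULL) {
  cs <- connection_stability(ens)
  fl <- flexibility(ens)
  dc <- disjointness_cohesion(ens)
  mt <- structure(list(
    connection_stability = cs, flexibility = fl,
    disjointness = dc$disjointness,
    cohesion_strength = dc$cohesion_strength,
    disjoint_count = dc$disjoint_count,
    cohesive_count = dc$cohesive_count,
    global_disjointness = mean(dc$disjointness),
    network_means = NULL), class = "metric_table")
  if (!is.null(atlas)) mt$network_means <- network_aggregate(mt, atlas)
  mt
}

#' Aggregate nodal metrics to the network level
#'
#' Connection stability of a network is the mean over its within-network
#' node pairs (i < j); nodal metrics are means over member nodes. A
#' single-node network has no within pairs, so its stability is recorded
#' as missing (with a warning).
#'
#' @param mt a \code{metric_table} (network_means may be NULL).
#' @param atlas an \code{atlas} covering all nodes.
#' @return data frame with one row per network: \code{abbreviation},
#'   \code{connection_stability}, \code{flexibility},
#'   \code{disjointness}, \code{cohesion_strength}.
#' @export
network_aggregate <- function(mt, atlas) {
  stopifnot(inherits(atlas, "atlas"))
  if (length(mt$flexibility) != atlas$n_nodes)
    stop("atlas node count does not match the metric table")
  rows <- lapply(seq_len(nrow(atlas$networks)), function(k) {
    mem <- atlas$networks$members[[k]]
    if (length(mem) >= 2L) {
      sub <- mt$connection_stability[mem, mem]
      cs <- mean(sub[upper.tri(sub)])
    } else {
      warning(sprintf("network %s has a single node; stability undefined",
                      atlas$networks$abbreviation[k]))
      cs <- NA_real_
    }
    data.frame(abbreviation = atlas$networks$abbreviation[k],
               connection_stability = cs,
               flexibility = mean(mt$flexibility[mem]),
               disjointness = mean(mt$disjointness[mem]),
               cohesion_strength = mean(mt$cohesion_strength[mem]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
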