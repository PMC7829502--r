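# Independent oracles used to cross-check the package's computations.
# These are deliberately written as naive, direct implementations.

# All set partitions of n elements as restricted-growth label vectors.
all_set_partitions <- function(n) {
  parts <- list(integer(0))
  for (i in seq_len(n)) {
    parts <- unlist(lapply(parts, function(p) {
      m <- if (length(p)) max(p) else 0L
      lapply(seq_len(m + 1L), function(k) c(p, k))
    }), recursive = FALSE)
  }
  parts
}

# Supra modularity matrix of a multilayer graph, built entry by entry
# straight from the quality function's definition (non-negative layers).
oracle_supra <- function(layers, gamma, omega) {
  n <- nrow(layers[[1L]]); T <- length(layers)
  idx <- function(i, s) (s - 1L) * n + i
  B <- matrix(0, n * T, n * T)
  for (s in seq_len(T)) {
    A <- layers[[s]]
    k <- rowSums(A)
    m2 <- sum(A)
    for (i in seq_len(n))
      for (j in seq_len(n))
        B[idx(i, s), idx(j, s)] <- A[i, j] - gamma * k[i] * k[j] / m2
  }
  if (T > 1L) {
    for (s in seq_len(T))
      for (r in seq_len(T))
        if (abs(s - r) == 1L)
          for (i in seq_len(n))
            B[idx(i, s), idx(i, r)] <- B[idx(i, s), idx(i, r)] + omega
  }
  two_mu <- sum(vapply(layers, sum, numeric(1L))) + 2 * omega * n * (T - 1L)
  list(B = B, two_mu = two_mu)
}

oracle_q <- function(supra, labels_vec) {
  sum(supra$B[outer(labels_vec, labels_vec, "==")]) / supra$two_mu
}

# Exhaustive maximum of the quality function over all partitions of the
# node-layer copies.
oracle_max_q <- function(layers, gamma, omega) {
  supra <- oracle_supra(layers, gamma, omega)
  nT <- nrow(supra$B)
  best <- -Inf
  for (p in all_set_partitions(nT)) {
    q <- oracle_q(supra, p)
    if (q > best) best <- q
  }
  best
}

# Random non-negative symmetric multilayer graph (every layer has at
# least one positive edge).
random_layers <- function(n, T) {
  lapply(seq_len(T), function(s) {
    repeat {
      a <- matrix(runif(n * n), n)
      a[lower.tri(a, diag = TRUE)] <- 0
      a[a < 0.35] <- 0
      a <- a + t(a)
      if (sum(a) > 0) return(a)
    }
  })
}

# AUC by explicit pair counting (Mann-Whitney with ties counted half).
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Toy label matrices (nodes x layers) with known switch structure.
toy_labels_cohesive_disjoint <- function() {
  # T = 3; at transition 1 nodes 1,2 move 1 -> 2 together, node 3 moves
  # 1 -> 3 alone; nothing moves at transition 2.
  matrix(c(1, 1, 1,
           2, 2, 3,
           2, 2, 3), nrow = 3, byrow = FALSE)
}
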