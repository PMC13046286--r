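# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: reachability closure instead of Tarjan/igraph,
# full 3^m enumeration instead of the sampler, grid/optim search instead of
# closed-form fits.

# SCC membership via O(b^3) reachability closure: i and j share a component
# iff directed paths exist both ways
oracle_scc <- function(A) {
  b <- nrow(A)
  R <- (A > 0) | diag(b) > 0
  for (k in seq_len(b)) R <- R | (R[, k] %o% R[k, ]) > 0
  both <- R & t(R)
  memb <- integer(b)
  nxt <- 0L
  for (i in seq_len(b)) {
    if (memb[i] == 0L) {
      nxt <- nxt + 1L
      memb[both[i, ]] <- nxt
    }
  }
  memb
}

# all edge-state vectors over the allowed sets of a candidate graph
all_state_vectors <- function(graph) {
  grids <- lapply(graph$allowed, identity)
  as.matrix(rev(expand.grid(rev(grids))))
}

# brute-force pseudo-posterior over all acyclic state vectors:
# prior x profile likelihood, normalized
oracle_pseudo_posterior <- function(graph, data, spec, prior) {
  S <- all_state_vectors(graph)
  lw <- apply(S, 1L, function(s) {
    s <- as.integer(s)
    A <- states_to_adjacency(s, graph)
    if (!is_dag(A)) return(-Inf)
    prior_log_prob(s, prior) +
      graph_log_pseudo_likelihood(s, graph, data, spec)
  })
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  names(w) <- apply(S, 1L, paste, collapse = "")
  w
}

# empirical distribution of retained state vectors, keyed like the oracle
sample_frequencies <- function(samples) {
  ids <- apply(samples, 1L, paste, collapse = "")
  table(ids) / nrow(samples)
}

total_variation <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}

# grid-search maximization of the Gaussian log likelihood over
# (beta0, beta1, sigma2), with two refinement passes around the incumbent
oracle_gaussian_loglik <- function(y, x) {
  ll <- function(b0, b1, s2)
    sum(stats::dnorm(y, b0 + b1 * x, sqrt(s2), log = TRUE))
  centers <- c(0, 0, 1)
  widths <- c(3, 3, 2.5)
  best <- -Inf
  for (pass in 1:3) {
    g0 <- seq(centers[1] - widths[1], centers[1] + widths[1], length.out = 41)
    g1 <- seq(centers[2] - widths[2], centers[2] + widths[2], length.out = 41)
    g2 <- seq(max(centers[3] - widths[3], 1e-3),
              centers[3] + widths[3], length.out = 41)
    for (b0 in g0) for (b1 in g1) for (s2 in g2) {
      v <- ll(b0, b1, s2)
      if (v > best) {
        best <- v
        centers <- c(b0, b1, s2)
      }
    }
    widths <- widths / 15
  }
  best
}

# grid-search maximization of the binomial (logit link) log likelihood
oracle_binomial_loglik <- function(y, x, trials) {
  ll <- function(b0, b1)
    sum(stats::dbinom(y, trials, stats::plogis(b0 + b1 * x), log = TRUE))
  centers <- c(0, 0)
  widths <- c(4, 4)
  best <- -Inf
  for (pass in 1:3) {
    g0 <- seq(centers[1] - widths[1], centers[1] + widths[1], length.out = 61)
    g1 <- seq(centers[2] - widths[2], centers[2] + widths[2], length.out = 61)
    for (b0 in g0) for (b1 in g1) {
      v <- ll(b0, b1)
      if (v > best) {
        best <- v
        centers <- c(b0, b1)
      }
    }
    widths <- widths / 20
  }
  best
}

# brute-force Markov equivalence class: all 3^m state assignments on the
# skeleton filtered for acyclicity, full skeleton and equal v-structures
oracle_equivalence_class <- function(A_true) {
  nodes <- rownames(A_true)
  graph <- candidate_graph(nodes, skeleton_pairs(A_true))
  v0 <- v_structures(A_true)
  S <- all_state_vectors(graph)
  keep <- list()
  for (r in seq_len(nrow(S))) {
    s <- as.integer(S[r, ])
    if (any(s == 2L)) next                    # must keep the full skeleton
    B <- states_to_adjacency(s, graph)
    if (!is_dag(B)) next
    if (!identical(v_structures(B), v0)) next
    keep[[length(keep) + 1L]] <- B
  }
  keep
}

# canonical key for comparing sets of adjacency matrices
adj_key <- function(A) paste(which(A == 1L), collapse = ",")
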