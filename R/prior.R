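#' Edge-state prior
#'
#' Independent per-edge prior over the three edge states `(p0, p1, p2)`:
#' the two orientations and absence. A single shared triple or an `m x 3`
#' matrix of per-edge triples may be given; each triple must be nonnegative
#' and sum to 1 (tolerance 1e-9). For constrained edges (instrumental
#' variables), the mass of disallowed states is renormalized onto the
#' allowed states so that every edge keeps a proper distribution. The triple
#' `(1/3, 1/3, 1/3)` is the uniform prior; `(0.05, 0.05, 0.9)` is the sparse
#' prior that encodes a 90% prior belief in edge absence.
#'
#' @param graph A [candidate_graph()].
#' @param p Numeric triple, or an `m x 3` matrix with one triple per edge.
#' @return Object of class `edge_state_prior`: list with `probs` (the
#'   renormalized `m x 3` matrix, disallowed states set to 0) and
#'   `log_probs`.
#' @examples
#' g <- candidate_graph(c("T1", "T2"), rbind(c("T1", "T2")))
#' edge_state_prior(g, c(0.05, 0.05, 0.9))
#' @export
edge_state_prior <- function(graph, p = c(1 / 3, 1 / 3, 1 / 3)) {
  m <- n_edges(graph)
  if (is.matrix(p)) {
    if (nrow(p) != m || ncol(p) != 3L)
      stop("per-edge prior must be an m x 3 matrix")
    P <- p
  } else {
    if (length(p) != 3L) stop("prior must be a triple (p0, p1, p2)")
    P <- matrix(p, m, 3L, byrow = TRUE)
  }
  if (any(P < 0)) stop("prior probabilities must be nonnegative")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("each prior triple must sum to 1 (within 1e-9)")
  for (i in seq_len(m)) {
    disallowed <- setdiff(0:2, graph$allowed[[i]])
    if (length(disallowed)) {
      P[i, disallowed + 1L] <- 0
      s <- sum(P[i, ])
      if (s <= 0) stop("prior places no mass on the allowed states of edge ",
                       edge_labels(graph)[i])
      P[i, ] <- P[i, ] / s
    }
  }
  dimnames(P) <- list(edge_labels(graph), c("p0", "p1", "p2"))
  # precomputed switch machinery: per edge, the prior-weighted distribution
  # over the other allowed states for each current state
  sw_log <- array(NA_real_, c(m, 3L, 3L))   # [edge, from + 1, to + 1]
  sw_to <- vector("list", m)                # per edge, per from-state targets
  sw_w <- vector("list", m)                 # matching sampling weights
  for (i in seq_len(m)) {
    a <- graph$allowed[[i]]
    sw_to[[i]] <- vector("list", 3L)
    sw_w[[i]] <- vector("list", 3L)
    for (from in a) {
      others <- a[a != from]
      w <- P[i, others + 1L]
      tot <- sum(w)
      # degenerate prior (all alternatives at zero mass): switch uniformly;
      # the acceptance step rejects zero-prior states anyway
      w <- if (tot > 0) w / tot else rep(1 / length(others), length(others))
      sw_log[i, from + 1L, others + 1L] <- log(w)
      sw_to[[i]][[from + 1L]] <- others
      sw_w[[i]][[from + 1L]] <- w
    }
  }
  structure(list(probs = P, log_probs = log(P), switch_log = sw_log,
                 switch_to = sw_to, switch_w = sw_w),
            class = "edge_state_prior")
}

#' @export
print.edge_state_prior <- function(x, ...) {
  cat("Edge-state prior (renormalized over allowed states):\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Log prior probability of an edge-state vector
#'
#' Independent-edge prior: `sum_i log p[i, s_i]`. A state with zero prior
#' mass gives `-Inf`, which deterministically rejects any proposal
#' occupying it.
#'
#' @param states Edge-state vector.
#' @param prior An [edge_state_prior()].
#' @return Log prior probability (possibly `-Inf`).
#' @export
prior_log_prob <- function(states, prior) {
  sum(prior$log_probs[cbind(seq_along(states), as.integer(states) + 1L)])
}

#' Probability of switching an edge to a given state
#'
#' When a proposal selects an edge for a state change, the new state is
#' drawn from the remaining allowed states with probabilities proportional
#' to their prior mass. For example, with prior `(0.05, 0.05, 0.9)` an edge
#' in state 0 switches to state 1 with probability `0.05 / (0.05 + 0.9)`.
#' An edge is never allowed to stay in its current state. If every
#' alternative has zero prior mass the switch is uniform over the
#' alternatives (the acceptance step rejects zero-prior states regardless).
#'
#' @param from_state,to_state Distinct states in `allowed_states`.
#' @param prior_i Numeric triple of prior mass for this edge (any positive
#'   scaling; only ratios matter).
#' @param allowed_states Allowed states for this edge (default all three).
#' @return The switch probability.
#' @export
switch_probability <- function(from_state, to_state, prior_i,
                               allowed_states = 0:2) {
  from_state <- as.integer(from_state); to_state <- as.integer(to_state)
  if (from_state == to_state)
    stop("an edge may not remain in the same state (from == to)")
  if (!from_state %in% allowed_states || !to_state %in% allowed_states)
    stop("states must both be allowed for this edge")
  others <- allowed_states[allowed_states != from_state]
  w <- prior_i[others + 1L]
  tot <- sum(w)
  if (tot <= 0) return(1 / length(others))
  unname(w[match(to_state, others)] / tot)
}
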