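# Proposal kernel over edge-state vectors: number of edges to change is
# Binomial(m, 1/m) truncated to >= 1, changed edges are a uniform subset,
# and each selected edge switches state with the prior-weighted rule.

# truncated-binomial draw: Bin(m, 1/m) conditioned on d >= 1
rtrunc_binom <- function(m) {
  repeat {
    d <- stats::rbinom(1L, m, 1 / m)
    if (d >= 1L) return(d)
  }
}

# log pmf of the truncated proposal size
dtrunc_binom_log <- function(d, m) {
  stats::dbinom(d, m, 1 / m, log = TRUE) -
    log1p(-stats::dbinom(0L, m, 1 / m))
}

#' Propose a new edge-state vector
#'
#' Draws the number of edges to change from `Binomial(m, 1/m)` truncated to
#' at least one, selects that many distinct edges uniformly, switches each
#' with the prior-weighted rule of [switch_probability()], and then repairs
#' any directed cycles with [repair_cycles()]. The returned vector is always
#' acyclic and constraint-respecting.
#'
#' @param states Current (acyclic) edge-state vector.
#' @param graph A [candidate_graph()].
#' @param prior An [edge_state_prior()].
#' @return List with `states` (the proposal, post-repair) and `changed`
#'   (indices of edges whose state differs from the input).
#' @export
propose <- function(states, graph, prior) {
  states <- check_state_vector(states, graph)
  m <- n_edges(graph)
  d <- rtrunc_binom(m)
  sel <- if (d == m) seq_len(m) else sample.int(m, d)
  prop <- states
  for (i in sel)
    prop[i] <- sample_switch(prior, i, prop[i])
  prop <- repair_cycles(prop, graph, prior)
  list(states = as.integer(prop), changed = which(prop != states),
       repairs = attr(prop, "repairs"))
}

#' Changed-edge-only transition log probability
#'
#' Log proposal probability of moving between two edge-state vectors,
#' written purely in terms of the set `D` of edges whose states differ
#' (`d = |D|`): the truncated-binomial log mass at `d`, minus
#' `log choose(m, d)` for the uniform edge selection, plus the sum of log
#' switch probabilities over `D`. The path actually taken through cycle
#' repair does not enter: in the acceptance ratio the forward and reverse
#' path terms cancel, leaving exactly this changed-edge form, and the
#' `d`-dependent factors cancel between numerator and denominator because
#' `d` is the same in both directions.
#'
#' @param states_from,states_to Edge-state vectors on the same graph (both
#'   acyclic). If they are identical the truncated kernel assigns no direct
#'   mass to the move and `-Inf` is returned; the sampler treats such
#'   cancelled moves as no-ops and never consults this value.
#' @param graph A [candidate_graph()].
#' @param prior An [edge_state_prior()].
#' @return Log transition probability.
#' @export
transition_log_prob <- function(states_from, states_to, graph, prior) {
  states_from <- check_state_vector(states_from, graph)
  states_to <- check_state_vector(states_to, graph)
  D <- which(states_from != states_to)
  d <- length(D)
  m <- n_edges(graph)
  if (d == 0L) return(-Inf)
  dtrunc_binom_log(d, m) - lchoose(m, d) +
    sum(prior$switch_log[cbind(D, states_from[D] + 1L, states_to[D] + 1L)])
}
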