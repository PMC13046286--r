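#' Strongly connected components of a directed graph
#'
#' A strongly connected component (SCC) is a maximal node set with directed
#' paths both ways between every pair of its members. A digraph is acyclic
#' iff every SCC is a singleton, and every directed cycle lies entirely
#' inside one SCC, which is what the cycle-repair step exploits.
#'
#' @param A Binary adjacency matrix.
#' @return Integer membership vector (one component id per node), named by
#'   node when `A` has dimnames.
#' @export
strongly_connected_components <- function(A) {
  A <- validate_adjacency(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  m <- igraph::components(g, mode = "strong")$membership
  m <- as.integer(m)
  names(m) <- rownames(A)
  m
}

#' Repair directed cycles in an edge-state vector
#'
#' While the induced digraph contains a cycle, pick (uniformly) a strongly
#' connected component with at least two nodes, pick (uniformly) a present
#' candidate edge with both endpoints inside it, and resample that edge's
#' state from its other allowed states with the same prior-weighted switch
#' rule used by proposals (see [switch_probability()]). Edges outside every
#' multi-node SCC are never touched.
#'
#' @param states Edge-state vector (may induce cycles).
#' @param graph A [candidate_graph()].
#' @param prior An [edge_state_prior()] for `graph`.
#' @param max_iter Safety cap on repair steps; exceeding it signals an
#'   internal error, not bad user input.
#' @return An acyclic edge-state vector, with attribute `"repairs"` giving
#'   the number of repair steps taken.
#' @export
repair_cycles <- function(states, graph, prior, max_iter = 10000L) {
  states <- check_state_vector(states, graph)
  e <- graph$edges
  b <- length(graph$nodes)
  A <- states_to_adjacency(states, graph)
  repairs <- 0L
  while (!acyclic_int(A)) {
    if (repairs >= max_iter)
      stop("cycle repair exceeded ", max_iter,
           " steps; this indicates an internal error")
    memb <- strongly_connected_components(A)
    sizes <- tabulate(memb)
    comp_ids <- which(sizes >= 2L)
    comp <- comp_ids[sample_one(length(comp_ids))]
    inside <- which(states != 2L &
                      memb[e[, 1L]] == comp & memb[e[, 2L]] == comp)
    i <- inside[sample_one(length(inside))]
    old <- states[i]
    new <- sample_switch(prior, i, old)
    states[i] <- new
    # incremental adjacency update for the single modified edge
    j <- e[i, 1L]; k <- e[i, 2L]
    A[j, k] <- A[k, j] <- 0L
    if (new == 0L) A[j, k] <- 1L else if (new == 1L) A[k, j] <- 1L
    repairs <- repairs + 1L
  }
  attr(states, "repairs") <- repairs
  states
}

# uniform index in 1..n (sample.int is safe for n = 1 too, but keep explicit)
sample_one <- function(n) if (n == 1L) 1L else sample.int(n, 1L)

# internal: draw the new state of edge i given its current state, using the
# prior-weighted switch distribution precomputed in the edge_state_prior
sample_switch <- function(prior, i, from) {
  others <- prior$switch_to[[i]][[from + 1L]]
  if (length(others) == 1L) return(others)
  w <- prior$switch_w[[i]][[from + 1L]]
  if (stats::runif(1L) < w[1L]) others[1L] else others[2L]
}
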