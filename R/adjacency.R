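#' Convert an edge-state vector to an adjacency matrix
#'
#' State `0` of edge `i = (j, k)` (with `j < k` in node order) puts a 1 in
#' entry `[j, k]`, state `1` in entry `[k, j]`, and state `2` leaves both
#' zero. Non-candidate entries are always zero.
#'
#' @param states Integer vector over \{0, 1, 2\}, aligned with
#'   `graph$edges`.
#' @param graph A [candidate_graph()].
#' @return A `b x b` binary integer matrix with node names as dimnames.
#' @examples
#' g <- candidate_graph(c("T1", "T2", "T3"),
#'                      rbind(c("T1", "T2"), c("T2", "T3")))
#' states_to_adjacency(c(0, 0), g)
#' @export
states_to_adjacency <- function(states, graph) {
  states <- check_state_vector(states, graph)
  b <- length(graph$nodes)
  A <- matrix(0L, b, b, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges
  fwd <- states == 0L
  bwd <- states == 1L
  A[e[fwd, , drop = FALSE]] <- 1L
  A[e[bwd, c(2L, 1L), drop = FALSE]] <- 1L
  A
}

#' Convert an adjacency matrix to an edge-state vector
#'
#' Inverse of [states_to_adjacency()]. The matrix may only have support on
#' candidate pairs, and no pair may carry both directions.
#'
#' @param A Binary adjacency matrix, `A[j, k] = 1` meaning `j -> k`.
#' @param graph A [candidate_graph()].
#' @return Integer state vector aligned with `graph$edges`.
#' @export
adjacency_to_states <- function(A, graph) {
  A <- validate_adjacency(A, n = length(graph$nodes))
  e <- graph$edges
  fwd <- A[e] == 1L
  bwd <- A[e[, c(2L, 1L), drop = FALSE]] == 1L
  if (any(fwd & bwd))
    stop("both directions set for candidate edge ",
         edge_labels(graph)[which(fwd & bwd)[1L]])
  states <- rep(2L, nrow(e))
  states[fwd] <- 0L
  states[bwd] <- 1L
  # any support off the candidate pairs?
  B <- A
  B[e] <- 0L
  B[e[, c(2L, 1L), drop = FALSE]] <- 0L
  if (any(B == 1L)) {
    bad <- which(B == 1L, arr.ind = TRUE)[1L, ]
    stop("adjacency has an edge on a non-candidate pair: ",
         graph$nodes[bad[1L]], " -> ", graph$nodes[bad[2L]])
  }
  check_state_vector(states, graph)
}

# internal: basic adjacency sanity checks
validate_adjacency <- function(A, n = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (!is.null(n) && nrow(A) != n)
    stop("adjacency dimension ", nrow(A), " does not match ", n, " nodes")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  storage.mode(A) <- "integer"
  A
}

#' Test a directed graph for acyclicity
#'
#' Kahn-style peeling of zero-in-degree nodes; a digraph is acyclic iff all
#' nodes can be peeled (equivalently, all strongly connected components are
#' singletons).
#'
#' @param A Binary adjacency matrix (`A[j, k] = 1` for `j -> k`).
#' @return `TRUE` if `A` has no directed cycle.
#' @export
is_dag <- function(A) {
  A <- validate_adjacency(A)
  acyclic_int(A)
}

# internal hot-path acyclicity check (no validation)
acyclic_int <- function(A) {
  b <- nrow(A)
  indeg <- .colSums(A, b, b)
  alive <- rep(TRUE, b)
  repeat {
    z <- which(alive & indeg == 0)
    if (!length(z)) break
    alive[z] <- FALSE
    if (!any(alive)) return(TRUE)
    indeg <- indeg - .colSums(A[z, , drop = FALSE], length(z), b)
  }
  !any(alive)
}
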