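#' Candidate graph specification
#'
#' Defines the search space of the edge-state sampler: the node set, the list
#' of candidate edges (unordered node pairs), and the states each edge may
#' occupy. Every candidate edge `i` between nodes `j < k` (in node order) has
#' three possible states: `0` for `j -> k`, `1` for `k -> j`, and `2` for
#' edge absence. Declaring a node as an instrumental variable removes the
#' state that would point an edge into it, which is equivalent to
#' blacklisting that direction: under Mendelian randomization a genetic
#' variant may regulate expression but not the reverse.
#'
#' @param nodes Character vector of unique node names, in column order of the
#'   data matrix.
#' @param edges Two-column matrix or data frame of candidate edges, given as
#'   node names or integer indices. Pairs are stored with the lower-indexed
#'   node first; duplicates and self-pairs are errors.
#' @param iv_nodes Character vector of instrumental-variable nodes. Edges
#'   incident to an IV node may only point away from it (or be absent).
#'
#' @return An object of class `candidate_graph`: a list with elements
#'   `nodes`, `edges` (an `m x 2` integer matrix with `edges[i,1] <
#'   edges[i,2]`), `allowed` (a list of allowed state vectors per edge) and
#'   `iv_nodes`.
#'
#' @examples
#' g <- candidate_graph(c("T1", "T2", "T3"),
#'                      rbind(c("T1", "T2"), c("T2", "T3")))
#' g
#' @seealso [states_to_adjacency()], [edge_state_prior()], [run_sampler()]
#' @export
candidate_graph <- function(nodes, edges, iv_nodes = character()) {
  stopifnot(is.character(nodes), length(nodes) >= 1L)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (!all(iv_nodes %in% nodes)) stop("iv_nodes must be a subset of nodes")

  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (is.character(edges)) {
    idx <- matrix(match(edges, nodes), ncol = 2L)
    if (anyNA(idx)) stop("edge refers to unknown node: ",
                         paste(edges[is.na(idx)], collapse = ", "))
  } else {
    idx <- matrix(as.integer(edges), ncol = 2L)
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(nodes)))
      stop("edge index out of range")
  }
  if (any(idx[, 1L] == idx[, 2L])) stop("self-pairs are not allowed")
  # canonical order: lower node index first
  idx <- cbind(pmin(idx[, 1L], idx[, 2L]), pmax(idx[, 1L], idx[, 2L]))
  if (anyDuplicated(idx)) stop("duplicate candidate edges")

  iv <- match(iv_nodes, nodes)
  allowed <- lapply(seq_len(nrow(idx)), function(i) {
    j <- idx[i, 1L]; k <- idx[i, 2L]
    if (j %in% iv && k %in% iv)
      stop("edge between two instrumental variables (", nodes[j], ", ",
           nodes[k], ") admits no direction; remove it from the candidates")
    if (j %in% iv) c(0L, 2L) else if (k %in% iv) c(1L, 2L) else c(0L, 1L, 2L)
  })

  structure(list(nodes = nodes, edges = unname(idx), allowed = allowed,
                 iv_nodes = iv_nodes),
            class = "candidate_graph")
}

#' Number of candidate edges
#' @param graph A [candidate_graph()].
#' @return Integer edge count `m`.
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Edge labels of a candidate graph
#' @param graph A [candidate_graph()].
#' @return Character vector `"<node_j>-<node_k>"` per candidate edge.
#' @export
edge_labels <- function(graph) {
  paste(graph$nodes[graph$edges[, 1L]], graph$nodes[graph$edges[, 2L]],
        sep = "-")
}

#' @export
print.candidate_graph <- function(x, ...) {
  cat("Candidate graph:", length(x$nodes), "nodes,", n_edges(x),
      "candidate edges\n")
  if (length(x$iv_nodes))
    cat("Instrumental variables:", paste(x$iv_nodes, collapse = ", "), "\n")
  lab <- edge_labels(x)
  st <- vapply(x$allowed, function(a) paste(a, collapse = ""), "")
  cat(paste0("  ", lab, " {", st, "}"), sep = "\n")
  invisible(x)
}

#' Fully connected candidate graph
#'
#' Convenience constructor for the uninformed search space: every node pair
#' is a candidate edge.
#'
#' @inheritParams candidate_graph
#' @return A [candidate_graph()] over all `choose(b, 2)` pairs.
#' @export
full_candidate_graph <- function(nodes, iv_nodes = character()) {
  b <- length(nodes)
  if (b < 2L) stop("need at least two nodes")
  pairs <- t(utils::combn(b, 2L))
  # drop IV-IV pairs: they admit no direction
  iv <- match(iv_nodes, nodes)
  keep <- !(pairs[, 1L] %in% iv & pairs[, 2L] %in% iv)
  candidate_graph(nodes, pairs[keep, , drop = FALSE], iv_nodes = iv_nodes)
}

# internal: check that an edge-state vector conforms to the graph
check_state_vector <- function(states, graph) {
  if (length(states) != n_edges(graph))
    stop("state vector length ", length(states), " does not match the ",
         n_edges(graph), " candidate edges")
  states <- as.integer(states)
  for (i in seq_along(states))
    if (!states[i] %in% graph$allowed[[i]])
      stop("state ", states[i], " is not allowed for edge ",
           edge_labels(graph)[i])
  states
}
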