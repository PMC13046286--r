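#' Skeleton of a directed graph
#'
#' @param A Binary adjacency matrix.
#' @return Two-column integer matrix of undirected pairs `(j, k)`, `j < k`.
#' @export
skeleton_pairs <- function(A) {
  A <- validate_adjacency(A)
  und <- (A + t(A)) > 0
  idx <- which(upper.tri(und) & und, arr.ind = TRUE)
  unname(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE])
}

#' v-structures of a DAG
#'
#' A v-structure (collider) is a triple `j -> k <- l` with `j` and `l`
#' non-adjacent. Shared skeleton and shared v-structures characterize
#' Markov equivalence.
#'
#' @param A Binary adjacency matrix of a DAG.
#' @return Three-column integer matrix with rows `(j, k, l)`, `j < l`,
#'   sorted; zero rows when the DAG has no collider.
#' @export
v_structures <- function(A) {
  A <- validate_adjacency(A)
  b <- nrow(A)
  out <- matrix(0L, 0L, 3L)
  for (k in seq_len(b)) {
    pa <- which(A[, k] == 1L)
    if (length(pa) < 2L) next
    cmb <- utils::combn(pa, 2L)
    for (c2 in seq_len(ncol(cmb))) {
      j <- cmb[1L, c2]; l <- cmb[2L, c2]
      if (A[j, l] == 0L && A[l, j] == 0L)
        out <- rbind(out, c(j, k, l))
    }
  }
  out[order(out[, 1L], out[, 2L], out[, 3L]), , drop = FALSE]
}

#' Enumerate the Markov equivalence class of a DAG
#'
#' Orients the skeleton in all `2^E` ways and keeps the orientations that
#' are acyclic and reproduce the v-structure set of the input (the
#' Verma-Pearl characterization). Exact and exhaustive; intended for the
#' small graphs (up to a dozen edges) this package targets.
#'
#' @param A_true Adjacency matrix of an acyclic digraph.
#' @return List of adjacency matrices, the input's class (includes the
#'   input itself).
#' @export
enumerate_equivalence_class <- function(A_true) {
  A_true <- validate_adjacency(A_true)
  if (!acyclic_int(A_true)) stop("input graph is cyclic")
  sk <- skeleton_pairs(A_true)
  E <- nrow(sk)
  v0 <- v_structures(A_true)
  b <- nrow(A_true)
  out <- list()
  for (mask in 0:(2^E - 1)) {
    B <- matrix(0L, b, b, dimnames = dimnames(A_true))
    bit <- mask
    for (e in seq_len(E)) {
      if (bit %% 2L) B[sk[e, 2L], sk[e, 1L]] <- 1L
      else B[sk[e, 1L], sk[e, 2L]] <- 1L
      bit <- bit %/% 2L
    }
    if (acyclic_int(B) && identical(v_structures(B), v0))
      out[[length(out) + 1L]] <- B
  }
  out
}

#' True edge-state probabilities under Markov equivalence
#'
#' Ground truth for evaluating posterior edge-state estimates: for each
#' candidate edge, the relative frequency of each of the three states
#' across the members of the true graph's Markov equivalence class.
#' Skeleton edges therefore have zero probability of absence, and candidate
#' edges not in the skeleton get `(0, 0, 1)`. Frequencies are exact
#' ratios of integer counts (e.g. 2/3, printed as 0.67 or 0.66 depending on
#' rounding), stored at full precision.
#'
#' @param A_true Adjacency matrix of the true DAG.
#' @param graph A [candidate_graph()] whose candidate pairs are scored; by
#'   default the skeleton of `A_true`.
#' @return `m x 3` matrix (`p0_true`, `p1_true`, `p2_true`), rows summing
#'   to 1, rownames the edge labels.
#' @examples
#' m1 <- builtin_topology("M1")
#' true_edge_state_probabilities(m1$adjacency)
#' @export
true_edge_state_probabilities <- function(A_true, graph = NULL) {
  A_true <- validate_adjacency(A_true)
  if (is.null(graph)) {
    nodes <- rownames(A_true)
    if (is.null(nodes)) nodes <- paste0("T", seq_len(nrow(A_true)))
    graph <- candidate_graph(nodes, skeleton_pairs(A_true))
  }
  cl <- enumerate_equivalence_class(A_true)
  n_cl <- length(cl)
  e <- graph$edges
  m <- nrow(e)
  out <- matrix(0, m, 3L,
                dimnames = list(edge_labels(graph),
                                c("p0_true", "p1_true", "p2_true")))
  for (i in seq_len(m)) {
    j <- e[i, 1L]; k <- e[i, 2L]
    fwd <- sum(vapply(cl, function(B) B[j, k] == 1L, TRUE))
    bwd <- sum(vapply(cl, function(B) B[k, j] == 1L, TRUE))
    out[i, ] <- c(fwd, bwd, n_cl - fwd - bwd) / n_cl
  }
  out
}
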