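#' Built-in benchmark topologies
#'
#' The small benchmark networks used throughout the simulation machinery.
#' `M1` is the three-node mediation chain T1 -> T2 -> T3 (equivalence class
#' of size 3); `M2` the v-structure T1 -> T2 <- T3 (class of size 1); `GN4`
#' and `GN5` are four- and five-node gene-network motifs whose equivalence
#' classes (sizes 3 and 4) leave some edge directions ambiguous; `MP`
#' (multi-parent) is a pure collider with three parents; `GN8` and `GN11`
#' are larger layered networks mixing chains and colliders. M1 and M2 recur
#' as subgraphs of the larger networks. Each fixture also records a
#' conventional set of false edges (non-skeleton candidate pairs) used in
#' sparsity studies.
#'
#' @param name One of `"M1"`, `"M2"`, `"GN4"`, `"GN5"`, `"MP"`
#'   (alias `"multi-parent"`), `"GN8"`, `"GN11"` (case-insensitive).
#' @return A `topology_fixture`: list with `name`, `nodes`, `adjacency`
#'   (true DAG), `candidates` (skeleton pairs, the default candidate set),
#'   and `false_edges` (matrix of extra candidate pairs, possibly empty).
#' @examples
#' builtin_topology("M1")$adjacency
#' @export
builtin_topology <- function(name) {
  key <- toupper(name)
  if (key == "MULTI-PARENT" || key == "MULTIPARENT") key <- "MP"
  defs <- list(
    M1 = list(b = 3L,
              edges = rbind(c(1L, 2L), c(2L, 3L)),
              false = rbind(c(1L, 3L))),
    M2 = list(b = 3L,
              edges = rbind(c(1L, 2L), c(3L, 2L)),
              false = rbind(c(1L, 3L))),
    GN4 = list(b = 4L,
               edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(4L, 3L)),
               false = rbind(c(1L, 4L))),
    GN5 = list(b = 5L,
               edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 5L),
                             c(4L, 5L)),
               false = NULL),
    MP = list(b = 4L,
              edges = rbind(c(1L, 4L), c(2L, 4L), c(3L, 4L)),
              false = NULL),
    GN8 = list(b = 8L,
               edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L),
                             c(4L, 5L), c(5L, 6L), c(5L, 7L), c(6L, 8L),
                             c(7L, 8L)),
               false = NULL),
    GN11 = list(b = 11L,
                edges = rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(3L, 5L),
                              c(4L, 5L), c(5L, 6L), c(6L, 7L), c(9L, 7L),
                              c(7L, 8L), c(9L, 10L), c(10L, 11L)),
                false = rbind(c(1L, 3L), c(4L, 6L)))
  )
  def <- defs[[key]]
  if (is.null(def))
    stop("unknown topology '", name, "'; available: ",
         paste(names(defs), collapse = ", "))
  nodes <- paste0("T", seq_len(def$b))
  A <- matrix(0L, def$b, def$b, dimnames = list(nodes, nodes))
  A[def$edges] <- 1L
  stopifnot(acyclic_int(A))
  candidates <- skeleton_pairs(A)
  structure(list(name = key, nodes = nodes, adjacency = A,
                 candidates = candidates,
                 false_edges = def$false),
            class = "topology_fixture")
}

#' @export
print.topology_fixture <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  cat("Topology", x$name, ":", length(x$nodes), "nodes,", nrow(idx),
      "edges\n  ",
      paste(x$nodes[idx[, 1L]], "->", x$nodes[idx[, 2L]], collapse = ", "),
      "\n")
  if (!is.null(x$false_edges))
    cat("  false-edge set:",
        paste(x$nodes[x$false_edges[, 1L]], "-",
              x$nodes[x$false_edges[, 2L]], collapse = ", "), "\n")
  invisible(x)
}
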