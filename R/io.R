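# File formats: comma-separated UTF-8 with a mandatory header row. Node
# names must match exactly across the data, adjacency and node-spec files.

#' Read a data matrix
#'
#' @param path CSV file, one named column per node, no missing values.
#' @return Numeric matrix.
#' @export
read_data_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("non-numeric column in ", path)
  if (anyNA(m)) stop("missing values in ", path)
  m
}

#' Write a data matrix
#' @param data Matrix with column names.
#' @param path Output CSV path.
#' @export
write_data_matrix <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
}

#' Read an adjacency matrix from CSV
#'
#' Rows are sources and columns targets; entries are 0/1 and the first CSV
#' column holds the row (node) names. Symmetric 1s denote a candidate edge
#' with both directions allowed; a single 1 at `[j, k]` allows only
#' `j -> k` (or absence).
#'
#' @param path CSV file.
#' @return Binary integer matrix with node dimnames.
#' @export
read_adjacency_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  A <- as.matrix(d)
  if (!identical(rownames(A), colnames(A)))
    stop("adjacency row and column names differ in ", path)
  validate_adjacency(A)
}

#' Write an adjacency matrix to CSV
#' @param A Binary matrix with dimnames.
#' @param path Output CSV path.
#' @export
write_adjacency_matrix <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
}

#' Candidate graph from an input adjacency matrix
#'
#' Interprets an input-graph adjacency matrix as a candidate edge list:
#' any pair with at least one direction set is a candidate. A pair with
#' only `A[j, k] = 1` blacklists the reverse direction (allowed states
#' `{0, 2}`); instrumental-variable declarations add further constraints.
#'
#' @param A Binary adjacency matrix with node dimnames.
#' @param iv_nodes Instrumental-variable node names.
#' @return A [candidate_graph()].
#' @export
candidate_graph_from_adjacency <- function(A, iv_nodes = character()) {
  A <- validate_adjacency(A)
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- paste0("T", seq_len(nrow(A)))
  sk <- skeleton_pairs(A)
  if (!nrow(sk)) stop("input adjacency matrix has no candidate edges")
  g <- candidate_graph(nodes, sk, iv_nodes = iv_nodes)
  # one-directional input entries act as a blacklist of the reverse state
  for (i in seq_len(n_edges(g))) {
    j <- g$edges[i, 1L]; k <- g$edges[i, 2L]
    keep <- g$allowed[[i]]
    if (A[j, k] == 1L && A[k, j] == 0L) keep <- setdiff(keep, 1L)
    if (A[k, j] == 1L && A[j, k] == 0L) keep <- setdiff(keep, 0L)
    if (!2L %in% keep || length(keep) < 2L)
      stop("input graph and IV constraints leave no admissible state for ",
           edge_labels(g)[i])
    g$allowed[[i]] <- keep
  }
  g
}

#' Read a node model specification
#' @param path CSV with columns `node`, `family`, `trials`.
#' @return A [node_model_spec()].
#' @export
read_node_spec <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node", "family", "trials")
  if (!all(need %in% names(d)))
    stop("node spec must have columns node, family, trials")
  node_model_spec(d$node, d$family, d$trials)
}

#' Write a node model specification
#' @param spec A [node_model_spec()].
#' @param path Output CSV path.
#' @export
write_node_spec <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
}

#' Read a per-edge prior table
#' @param path CSV with columns `edge`, `p0`, `p1`, `p2`.
#' @param graph Candidate graph the rows must match (by edge label).
#' @return `m x 3` numeric matrix usable with [edge_state_prior()].
#' @export
read_prior_csv <- function(path, graph) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("edge", "p0", "p1", "p2")
  if (!all(need %in% names(d))) stop("prior file must have columns ",
                                     paste(need, collapse = ", "))
  idx <- match(edge_labels(graph), d$edge)
  if (anyNA(idx)) stop("prior file is missing edges: ",
                       paste(edge_labels(graph)[is.na(idx)], collapse = ", "))
  as.matrix(d[idx, c("p0", "p1", "p2")])
}

#' Write a posterior summary to CSV
#'
#' Columns: `edge`, `node_j`, `node_k`, `p_state0`, `p_state1`, `p_state2`.
#'
#' @param posterior A `posterior_summary` (or `m x 3` matrix plus `edges`).
#' @param path Output CSV path.
#' @param edges Optional edge data frame for bare matrices.
#' @export
write_posterior <- function(posterior, path, edges = NULL) {
  if (inherits(posterior, "posterior_summary")) {
    probs <- posterior$probabilities
    edges <- posterior$edges
  } else probs <- as.matrix(posterior)
  out <- data.frame(edge = rownames(probs), edges,
                    p_state0 = probs[, 1L], p_state1 = probs[, 2L],
                    p_state2 = probs[, 3L], row.names = NULL)
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read a posterior CSV back into a probability table
#' @param path CSV written by [write_posterior()].
#' @return List with `probabilities` (`m x 3`, rownames edge labels) and
#'   `edges`.
#' @export
read_posterior <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  probs <- as.matrix(d[, c("p_state0", "p_state1", "p_state2")])
  dimnames(probs) <- list(d$edge, c("p0", "p1", "p2"))
  list(probabilities = probs,
       edges = d[, c("node_j", "node_k"), drop = FALSE])
}

#' Write a truth table to CSV
#' @param truth `m x 3` matrix from [true_edge_state_probabilities()].
#' @param path Output CSV path.
#' @export
write_truth_table <- function(truth, path) {
  out <- data.frame(edge = rownames(truth), p0_true = truth[, 1L],
                    p1_true = truth[, 2L], p2_true = truth[, 3L],
                    row.names = NULL)
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read a truth table
#' @param path CSV written by [write_truth_table()].
#' @return `m x 3` matrix with edge rownames.
#' @export
read_truth_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  truth <- as.matrix(d[, c("p0_true", "p1_true", "p2_true")])
  rownames(truth) <- d$edge
  truth
}

# internal: write a plain key=value run manifest (inputs hashed so a run can
# be re-executed bit-identically given the same code version)
write_manifest <- function(path, inputs = character(), config = list(),
                           timing = NULL) {
  lines <- c(paste0("edgebayes_version=",
                    as.character(utils::packageVersion("edgebayes"))),
             paste0("r_version=", R.version.string))
  for (f in inputs)
    lines <- c(lines, paste0("input.", basename(f), ".md5=",
                             unname(tools::md5sum(f))))
  for (k in names(config))
    lines <- c(lines, paste0(k, "=", paste(config[[k]], collapse = " ")))
  if (!is.null(timing))
    lines <- c(lines, paste0("elapsed_sec=", round(timing, 3)))
  writeLines(lines, path)
  invisible(path)
}
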