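# Accuracy metrics comparing posterior edge-state probabilities with the
# Markov-equivalence ground truth.

# internal: align and validate a pair of m x 3 probability tables
align_tables <- function(truth, posterior) {
  if (inherits(posterior, "posterior_summary"))
    posterior <- posterior$probabilities
  truth <- as.matrix(truth); posterior <- as.matrix(posterior)
  if (!all(dim(truth) == dim(posterior)) || ncol(truth) != 3L)
    stop("truth and posterior must be m x 3 tables over the same edges")
  rt <- rownames(truth); rp <- rownames(posterior)
  if (!is.null(rt) && !is.null(rp)) {
    if (!setequal(rt, rp)) stop("edge sets differ between truth and posterior")
    posterior <- posterior[rt, , drop = FALSE]
  }
  list(truth = truth, posterior = posterior)
}

#' Edgewise mean squared error
#'
#' Per candidate edge, the mean over the three states of the squared
#' difference between the true (equivalence-averaged) and posterior state
#' probabilities. Ranges over `[0, 2/3]`; an edge whose probability mass is
#' fully misplaced between two states attains the maximum.
#'
#' @param truth `m x 3` table from [true_edge_state_probabilities()].
#' @param posterior `m x 3` posterior table or a `posterior_summary`.
#' @return Named numeric vector, one value per edge.
#' @export
edgewise_mse <- function(truth, posterior) {
  al <- align_tables(truth, posterior)
  rowMeans((al$truth - al$posterior)^2)
}

#' Graph-level MSE over the three edge states
#'
#' The edgewise MSE averaged over all candidate edges. Values below 0.1
#' generally indicate accurate recovery of both direction and probability.
#'
#' @inheritParams edgewise_mse
#' @return A single number.
#' @export
mse1 <- function(truth, posterior) mean(edgewise_mse(truth, posterior))

#' Graph-level MSE over the probabilistic adjacency matrix
#'
#' Mean squared error over the `2m` direction entries only (absence
#' excluded): the probabilities of `j -> k` and `k -> j` for every candidate
#' pair.
#'
#' @inheritParams edgewise_mse
#' @return A single number.
#' @export
mse2 <- function(truth, posterior) {
  al <- align_tables(truth, posterior)
  mean((al$truth[, 1:2, drop = FALSE] - al$posterior[, 1:2, drop = FALSE])^2)
}

#' Presence-level precision and power of a decided graph
#'
#' Compares the presence calls of [decide_edges()] (cutoff 0.5 on the
#' posterior probability of presence) with the true skeleton. A candidate
#' edge counts as a true positive when it is called present and its pair is
#' in the true skeleton, regardless of direction. With no called edges,
#' precision is undefined and reported `NA` (flagged via the
#' `"undefined_precision"` attribute).
#'
#' @param decided Data frame from [decide_edges()].
#' @param A_true True adjacency matrix, with node names matching the
#'   decision table.
#' @return Named numeric vector `c(precision, power)`.
#' @export
precision_power <- function(decided, A_true) {
  A_true <- validate_adjacency(A_true)
  nodes <- rownames(A_true)
  if (is.null(nodes)) nodes <- paste0("T", seq_len(nrow(A_true)))
  sk <- skeleton_pairs(A_true)
  true_pairs <- paste(nodes[sk[, 1L]], nodes[sk[, 2L]])
  cand_pairs <- paste(decided$node_j, decided$node_k)
  present <- decided$decision != "absent"
  tp <- sum(present & cand_pairs %in% true_pairs)
  fp <- sum(present & !cand_pairs %in% true_pairs)
  # true edges missing from the candidate set can never be recovered and
  # still count against power
  fn <- length(true_pairs) - tp
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  out <- c(precision = precision, power = tp / (tp + fn))
  attr(out, "undefined_precision") <- tp + fp == 0L
  out
}
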