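#' Simulate data from a DAG
#'
#' Generates one dataset under the node-wise generalized linear model used
#' by the sampler, visiting nodes in topological order. Gaussian nodes have
#' mean `intercept + beta * sum(parents)` and unit variance by default; all
#' parent coefficients share the same value `beta`, the signal strength
#' (the benchmark design uses beta in \{0.2, 0.5, 1\}, N in
#' \{100, 200, 600\}, variance 1 and intercept 0). Binomial nodes use a
#' logistic link with the same coefficients; a parentless binomial node is
#' drawn as `Binomial(trials, maf)`, mirroring a genotype with minor allele
#' frequency `maf`.
#'
#' @param A_true Acyclic adjacency matrix (`A[j, k] = 1` for `j -> k`).
#' @param n Sample size.
#' @param beta Signal strength shared by all edges.
#' @param spec Optional [node_model_spec()]; default all-Gaussian.
#' @param sigma Gaussian noise standard deviation (default 1).
#' @param intercept Shared intercept (default 0).
#' @param maf Success probability of a parentless binomial node
#'   (default 0.3).
#' @param seed Optional integer seed.
#' @return `n x b` numeric matrix with node names as column names.
#' @examples
#' top <- builtin_topology("M2")
#' d <- simulate_data(top$adjacency, n = 1000, beta = 1, seed = 1)
#' cor(d[, "T1"], d[, "T3"])  # parents of a collider are independent
#' @export
simulate_data <- function(A_true, n, beta, spec = NULL, sigma = 1,
                          intercept = 0, maf = 0.3, seed = NULL) {
  A_true <- validate_adjacency(A_true)
  if (!acyclic_int(A_true)) stop("A_true must be acyclic")
  b <- nrow(A_true)
  nodes <- rownames(A_true)
  if (is.null(nodes)) nodes <- paste0("T", seq_len(b))
  if (is.null(spec)) spec <- node_model_spec(nodes)
  if (!is.null(seed)) set.seed(seed)

  ord <- topological_order(A_true)
  out <- matrix(0, n, b, dimnames = list(NULL, nodes))
  for (j in ord) {
    pa <- which(A_true[, j] == 1L)
    eta <- intercept +
      if (length(pa)) beta * rowSums(out[, pa, drop = FALSE]) else 0
    if (spec$family[j] == "gaussian") {
      out[, j] <- stats::rnorm(n, mean = eta, sd = sigma)
    } else {
      tr <- spec$trials[j]
      p <- if (length(pa)) stats::plogis(eta) else rep(maf, n)
      out[, j] <- stats::rbinom(n, tr, p)
    }
  }
  out
}

# internal: a topological order of an acyclic digraph (Kahn peeling)
topological_order <- function(A) {
  b <- nrow(A)
  indeg <- .colSums(A, b, b)
  alive <- rep(TRUE, b)
  ord <- integer(0)
  while (any(alive)) {
    z <- which(alive & indeg == 0)
    if (!length(z)) stop("graph is cyclic")
    ord <- c(ord, z)
    alive[z] <- FALSE
    indeg <- indeg - .colSums(A[z, , drop = FALSE], length(z), b)
  }
  ord
}

#' Simulate replicate datasets for a benchmark topology
#'
#' Convenience wrapper over [simulate_data()] for the simulation design:
#' a number of independent replicate datasets at one `(beta, n)` setting,
#' with per-replicate seeds derived from `seed`.
#'
#' @param topology A `topology_fixture` from [builtin_topology()] or a
#'   topology name.
#' @param beta Signal strength.
#' @param n Sample size.
#' @param replicates Number of datasets (the benchmark design uses 25).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @inheritParams simulate_data
#' @return List of `n x b` data matrices, length `replicates`.
#' @export
simulate_replicates <- function(topology, beta, n, replicates = 25L,
                                seed = 1L, spec = NULL) {
  if (is.character(topology)) topology <- builtin_topology(topology)
  lapply(seq_len(replicates), function(r)
    simulate_data(topology$adjacency, n = n, beta = beta, spec = spec,
                  seed = seed + r - 1L))
}
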