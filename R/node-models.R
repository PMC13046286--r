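#' Node model specification
#'
#' Declares, per node, the conditional distribution family used in the
#' factorized graph likelihood: `gaussian` for continuous measurements
#' (linear model with Gaussian noise) or `binomial` for bounded counts with
#' a logistic link. For binomial nodes, `trials` is the number of trials
#' (2 for genotypes coded 0/1/2, 1 for binary indicators).
#'
#' @param nodes Character vector of node names.
#' @param family `"gaussian"` or `"binomial"`, recycled along nodes.
#' @param trials Positive integer trial counts, recycled; ignored (NA) for
#'   gaussian nodes.
#' @return Data frame of class `node_model_spec` with columns `node`,
#'   `family`, `trials`.
#' @export
node_model_spec <- function(nodes, family = "gaussian", trials = NA_integer_) {
  family <- rep_len(match.arg(family, c("gaussian", "binomial"),
                              several.ok = TRUE), length(nodes))
  trials <- rep_len(as.integer(trials), length(nodes))
  if (any(family == "binomial" & (is.na(trials) | trials < 1L)))
    stop("binomial nodes need a positive trial count")
  trials[family == "gaussian"] <- NA_integer_
  structure(data.frame(node = nodes, family = family, trials = trials,
                       stringsAsFactors = FALSE),
            class = c("node_model_spec", "data.frame"))
}

# variance floor guarding constant columns; the profile likelihood plugs in
# the MLE sigma^2 = RSS/N, never the unbiased estimate
.sigma2_floor <- 1e-12

#' Fit a Gaussian node by maximum likelihood
#'
#' Least squares of `y` on an intercept plus the parent columns; the plug-in
#' variance is the MLE `RSS / N` (floored at 1e-12), and the returned
#' log-likelihood is the Gaussian log-density at the MLE. A rank-deficient
#' design (collinear parents) is solved by pseudoinverse with a warning.
#'
#' @param y Numeric response vector.
#' @param X Numeric matrix of parent values (`NULL` or zero columns for a
#'   parentless node).
#' @return Object of class `fitted_node_model`: list with `coefficients`
#'   (intercept first), `sigma2`, `loglik`, `family`, `flagged`.
#' @export
fit_gaussian_node <- function(y, X = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  Xm <- cbind(`(Intercept)` = rep(1, N), X)
  flagged <- FALSE
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    warning("rank-deficient design (collinear parents); using pseudoinverse")
    beta <- as.vector(MASS::ginv(Xm) %*% y)
    flagged <- TRUE
  } else {
    beta <- qr.coef(qrX, y)
  }
  res <- y - as.vector(Xm %*% beta)
  rss <- sum(res * res)
  sigma2 <- max(rss / N, .sigma2_floor)
  ll <- -N / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
  structure(list(coefficients = unname(beta), sigma2 = sigma2, loglik = ll,
                 family = "gaussian", flagged = flagged),
            class = "fitted_node_model")
}

#' Fit a binomial node by maximum likelihood
#'
#' Logistic regression of the success counts `y` (out of `trials`) on an
#' intercept plus the parent columns, via iteratively reweighted least
#' squares (tolerance 1e-8, at most 100 iterations). On non-convergence or
#' complete separation the fit is redone with a small ridge penalty
#' (lambda = 1e-4) and flagged. The log-likelihood includes the binomial
#' coefficient term, so values are comparable across runs (the term is
#' constant across parent sets and cancels in acceptance ratios).
#'
#' @param y Integer counts in `[0, trials]`.
#' @param X Parent matrix or `NULL`.
#' @param trials Number of binomial trials per observation.
#' @return A `fitted_node_model` with elements `coefficients`, `loglik`,
#'   `family`, `flagged`.
#' @export
fit_binomial_node <- function(y, X = NULL, trials = 1L) {
  trials <- as.integer(trials)
  if (trials < 1L) stop("trials must be a positive integer")
  if (any(y != round(y)) || any(y < 0) || any(y > trials))
    stop("binomial responses must be integers in [0, trials]")
  N <- length(y)
  Xm <- cbind(`(Intercept)` = rep(1, N), X)
  fit <- suppressWarnings(
    stats::glm.fit(Xm, y / trials, weights = rep(trials, N),
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100L))
  )
  p <- fit$fitted.values
  separated <- any(p < 1e-10 | p > 1 - 1e-10)
  flagged <- FALSE
  if (!fit$converged || fit$boundary || separated || anyNA(fit$coefficients)) {
    beta <- ridge_irls(Xm, y, trials, lambda = 1e-4)
    p <- stats::plogis(as.vector(Xm %*% beta))
    flagged <- TRUE
  } else {
    beta <- fit$coefficients
  }
  ll <- sum(stats::dbinom(y, trials, p, log = TRUE))
  structure(list(coefficients = unname(beta), loglik = ll,
                 family = "binomial", trials = trials, flagged = flagged),
            class = "fitted_node_model")
}

# ridge-penalized IRLS fallback for separated or non-converged logistic fits
ridge_irls <- function(Xm, y, trials, lambda = 1e-4,
                       tol = 1e-8, maxit = 100L) {
  p_dim <- ncol(Xm)
  beta <- numeric(p_dim)
  pen <- diag(lambda, p_dim)
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xm %*% beta)
    mu <- stats::plogis(eta)
    w <- trials * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - trials * mu) / w
    XtW <- t(Xm * w)
    beta_new <- solve(XtW %*% Xm + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

#' @export
print.fitted_node_model <- function(x, ...) {
  cat("Fitted", x$family, "node model\n")
  cat("  coefficients:", signif(x$coefficients, 4), "\n")
  if (x$family == "gaussian") cat("  sigma2:", signif(x$sigma2, 4), "\n")
  cat("  log-likelihood:", x$loglik, if (x$flagged) " (flagged)" else "", "\n")
  invisible(x)
}

#' Create a fit cache
#'
#' Environment memoizing maximized per-node log-likelihoods, keyed by
#' `(node, sorted parent set)`. Caching never changes values; it only avoids
#' refitting nodes whose parent set is unchanged between graphs.
#'
#' @return An environment with hit/miss counters (`..hits`, `..misses`).
#' @export
new_fit_cache <- function() {
  cache <- new.env(parent = emptyenv())
  assign("..hits", 0L, envir = cache)
  assign("..misses", 0L, envir = cache)
  cache
}

# internal: maximized log-likelihood of node j given a parent index set
node_loglik <- function(j, parents, data, spec, cache = NULL) {
  if (!is.null(cache)) {
    key <- paste0(j, "|", paste(sort.int(parents), collapse = ","))
    val <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(val)) {
      cache$..hits <- cache$..hits + 1L
      return(val)
    }
  }
  y <- data[, j]
  X <- if (length(parents)) data[, parents, drop = FALSE] else NULL
  fit <- tryCatch(
    if (spec$family[j] == "gaussian") fit_gaussian_node(y, X)
    else fit_binomial_node(y, X, spec$trials[j]),
    error = function(e)
      stop("node model fit failed for node ", spec$node[j], ": ",
           conditionMessage(e))
  )
  val <- fit$loglik
  if (!is.null(cache)) {
    cache$..misses <- cache$..misses + 1L
    assign(key, val, envir = cache)
  }
  val
}

# internal: parent index set of node v under the state vector
node_parents <- function(v, states, graph) {
  e <- graph$edges
  c(e[e[, 2L] == v & states == 0L, 1L],
    e[e[, 1L] == v & states == 1L, 2L])
}

#' Graph log pseudo-likelihood (profile likelihood)
#'
#' The factorized likelihood of the data under the DAG induced by an
#' edge-state vector, with each node's nuisance parameters replaced by their
#' maximum likelihood estimates: the sum over nodes of the maximized
#' conditional log-likelihood given the parent set. Markov-equivalent DAGs
#' have equal values on Gaussian data.
#'
#' @param states Acyclic edge-state vector.
#' @param graph A [candidate_graph()].
#' @param data Numeric matrix or data frame, one column per node in
#'   `graph$nodes` order.
#' @param spec A [node_model_spec()] aligned with `graph$nodes`.
#' @param cache Optional [new_fit_cache()]; unchanged nodes are never refit.
#' @return The log pseudo-likelihood.
#' @export
graph_log_pseudo_likelihood <- function(states, graph, data, spec,
                                        cache = NULL) {
  states <- check_state_vector(states, graph)
  data <- as_data_matrix(data, graph)
  if (!is_dag(states_to_adjacency(states, graph)))
    stop("edge-state vector induces a directed cycle")
  sum(vapply(seq_along(graph$nodes), function(j)
    node_loglik(j, node_parents(j, states, graph), data, spec, cache),
    numeric(1)))
}

# internal: coerce data to a numeric matrix aligned with graph$nodes
as_data_matrix <- function(data, graph) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data)) stop("data must not contain missing values")
  if (!is.null(colnames(data))) {
    miss <- setdiff(graph$nodes, colnames(data))
    if (length(miss)) stop("data is missing columns: ",
                           paste(miss, collapse = ", "))
    data <- data[, graph$nodes, drop = FALSE]
  } else if (ncol(data) != length(graph$nodes)) {
    stop("data has ", ncol(data), " columns but the graph has ",
         length(graph$nodes), " nodes")
  }
  data
}
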