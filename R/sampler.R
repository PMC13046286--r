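#' Sampler configuration
#'
#' @param iterations Total Metropolis-Hastings-like iterations (30,000 is
#'   adequate for the small benchmark topologies; larger graphs use 50,000
#'   or more).
#' @param burnin Fraction of iterations discarded before retention
#'   (default 0.20).
#' @param retained Number of equally spaced post-burn-in samples used for
#'   the posterior edge-state frequencies (default 200).
#' @param prior Shared edge-state prior triple `(p0, p1, p2)`, or an
#'   `m x 3` per-edge matrix.
#' @param seed Optional integer seed; when given, the run is reproducible.
#' @param iv_nodes Instrumental-variable nodes (directions into them are
#'   blacklisted); usually set on the [candidate_graph()] instead.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(iterations = 30000L, burnin = 0.2,
                           retained = 200L,
                           prior = c(0.05, 0.05, 0.9),
                           seed = NULL, iv_nodes = character()) {
  iterations <- as.integer(iterations)
  retained <- as.integer(retained)
  if (iterations < 2L) stop("iterations must be at least 2")
  if (burnin < 0 || burnin >= 1) stop("burnin must be in [0, 1)")
  keep <- iterations - floor(burnin * iterations)
  if (retained > keep)
    stop("retained (", retained, ") exceeds the ", keep,
         " post-burn-in iterations")
  structure(list(iterations = iterations, burnin = burnin,
                 retained = retained, prior = prior, seed = seed,
                 iv_nodes = iv_nodes),
            class = "sampler_config")
}

#' Metropolis-Hastings acceptance probability
#'
#' `min(1, exp(delta_prior + delta_loglik + reverse - forward))` computed in
#' log space, where `forward`/`reverse` are the changed-edge transition log
#' probabilities of [transition_log_prob()]. A non-finite proposal
#' log-likelihood rejects (probability 0) with a warning.
#'
#' @param states_t,states_prop Current and proposed edge-state vectors.
#' @param loglik_t,loglik_prop Their plug-in log pseudo-likelihoods.
#' @param prior An [edge_state_prior()].
#' @param graph A [candidate_graph()].
#' @return Acceptance probability in `[0, 1]`.
#' @export
acceptance_probability <- function(states_t, states_prop, loglik_t,
                                   loglik_prop, prior, graph) {
  if (!is.finite(loglik_prop)) {
    warning("non-finite proposal log-likelihood; rejecting")
    return(0)
  }
  lp_t <- prior_log_prob(states_t, prior)
  lp_p <- prior_log_prob(states_prop, prior)
  if (!is.finite(lp_p)) return(0)  # zero-prior state occupied
  la <- (lp_p - lp_t) + (loglik_prop - loglik_t) +
    transition_log_prob(states_prop, states_t, graph, prior) -
    transition_log_prob(states_t, states_prop, graph, prior)
  min(1, exp(la))
}

#' Draw an initial edge-state vector
#'
#' Each edge's state is drawn independently from the
#' (constraint-renormalized) prior, then cycles are repaired; the result is
#' an acyclic DAG in the candidate graph space.
#'
#' @param graph A [candidate_graph()].
#' @param prior An [edge_state_prior()].
#' @return Acyclic edge-state vector.
#' @export
initialize_state <- function(graph, prior) {
  m <- n_edges(graph)
  states <- integer(m)
  for (i in seq_len(m)) {
    a <- graph$allowed[[i]]
    states[i] <- a[sample(length(a), 1L, prob = prior$probs[i, a + 1L])]
  }
  as.integer(repair_cycles(states, graph, prior))
}

#' Run the edge-state sampler
#'
#' The Metropolis-Hastings-like loop: at each iteration a proposal is drawn
#' with [propose()] (cycle-repaired, constraint-respecting), accepted with
#' [acceptance_probability()], and the current graph is recorded in the
#' traces. Proposals whose repairs cancel all changes are no-ops: the
#' current graph is recorded and no accept/reject step is taken. After
#' discarding the burn-in, `retained` equally spaced samples estimate the
#' per-edge posterior state probabilities as relative frequencies.
#' Nuisance parameters are never sampled: each evaluated graph uses plug-in
#' maximum likelihood fits, memoized per `(node, parent set)`.
#'
#' @param data Data matrix or data frame, one named column per node.
#' @param graph A [candidate_graph()].
#' @param spec A [node_model_spec()]; default all-Gaussian.
#' @param config A [sampler_config()].
#' @return Object of class `posterior_summary`: per-edge probability matrix
#'   `probabilities` (rows sum to 1), `samples` (retained state vectors),
#'   `trace_loglik` and `trace_graph` (per-iteration log pseudo-likelihood
#'   and graph id), `acceptance_rate`, `repair_count`, `cache_hit_rate`,
#'   plus the graph and config.
#' @examples
#' top <- builtin_topology("M1")
#' dat <- simulate_data(top$adjacency, n = 200, beta = 1, seed = 7)
#' g <- candidate_graph(top$nodes, top$candidates)
#' fit <- run_sampler(dat, g, config = sampler_config(2000, seed = 1))
#' fit$probabilities
#' @export
run_sampler <- function(data, graph, spec = NULL,
                        config = sampler_config()) {
  if (is.null(spec)) spec <- node_model_spec(graph$nodes)
  if (!identical(spec$node, graph$nodes))
    spec <- spec[match(graph$nodes, spec$node), ]
  if (anyNA(spec$node)) stop("node model spec does not cover all nodes")
  data <- as_data_matrix(data, graph)
  if (length(config$iv_nodes) && !length(graph$iv_nodes))
    graph <- candidate_graph(graph$nodes, graph$edges,
                             iv_nodes = config$iv_nodes)
  if (!is.null(config$seed)) set.seed(config$seed)

  prior <- if (inherits(config$prior, "edge_state_prior")) config$prior
           else edge_state_prior(graph, config$prior)
  m <- n_edges(graph)
  b <- length(graph$nodes)
  Tn <- config$iterations
  cache <- new_fit_cache()

  s <- initialize_state(graph, prior)
  A <- states_to_adjacency(s, graph)
  edges <- graph$edges
  lprior <- prior$log_probs
  sw_log <- prior$switch_log

  # per-node incident edges: which state of each incident edge makes the
  # other endpoint a parent (state 1 when the node is the lower endpoint,
  # state 0 when it is the higher one); a bit mask over these indicators
  # identifies the parent set, which keys the fit cache
  inc_idx <- inc_pstate <- inc_other <- inc_pow <- vector("list", b)
  for (j in seq_len(b)) {
    e1 <- which(edges[, 1L] == j); e2 <- which(edges[, 2L] == j)
    inc_idx[[j]] <- c(e1, e2)
    inc_pstate[[j]] <- c(rep(1L, length(e1)), rep(0L, length(e2)))
    inc_other[[j]] <- c(edges[e1, 2L], edges[e2, 1L])
    inc_pow[[j]] <- 2 ^ (seq_along(inc_idx[[j]]) - 1)
  }
  node_ll_for <- function(j, st) {
    isparent <- st[inc_idx[[j]]] == inc_pstate[[j]]
    key <- paste0(j, "_", sum(inc_pow[[j]][isparent]))
    val <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(val)) {
      cache$..hits <- cache$..hits + 1L
      return(val)
    }
    val <- node_loglik(j, inc_other[[j]][isparent], data, spec, cache = NULL)
    cache$..misses <- cache$..misses + 1L
    assign(key, val, envir = cache)
    val
  }
  node_ll <- vapply(seq_len(b), node_ll_for, numeric(1), st = s)
  ll <- sum(node_ll)
  lp <- prior_log_prob(s, prior)

  pow3 <- 3 ^ (seq_len(m) - 1)
  trace_ll <- numeric(Tn)
  trace_id <- numeric(Tn)
  burn <- floor(config$burnin * Tn)
  keep_idx <- unique(floor(seq(burn + 1L, Tn, length.out = config$retained)))
  samples <- matrix(NA_integer_, length(keep_idx), m)
  keep_ptr <- 1L
  accepted <- 0L; decided <- 0L; repairs_total <- 0L

  for (t in seq_len(Tn)) {
    # proposal: truncated-binomial edge count, uniform edge subset,
    # prior-weighted switches, then SCC cycle repair
    d <- rtrunc_binom(m)
    sel <- if (d == m) seq_len(m) else sample.int(m, d)
    sp <- s; Ap <- A
    for (i in sel) {
      new <- sample_switch(prior, i, sp[i])
      j <- edges[i, 1L]; k <- edges[i, 2L]
      Ap[j, k] <- Ap[k, j] <- 0L
      if (new == 0L) Ap[j, k] <- 1L else if (new == 1L) Ap[k, j] <- 1L
      sp[i] <- new
    }
    while (!acyclic_int(Ap)) {
      memb <- strongly_connected_components(Ap)
      sizes <- tabulate(memb)
      comp_ids <- which(sizes >= 2L)
      comp <- comp_ids[sample_one(length(comp_ids))]
      inside <- which(sp != 2L &
                        memb[edges[, 1L]] == comp & memb[edges[, 2L]] == comp)
      i <- inside[sample_one(length(inside))]
      new <- sample_switch(prior, i, sp[i])
      j <- edges[i, 1L]; k <- edges[i, 2L]
      Ap[j, k] <- Ap[k, j] <- 0L
      if (new == 0L) Ap[j, k] <- 1L else if (new == 1L) Ap[k, j] <- 1L
      sp[i] <- new
      repairs_total <- repairs_total + 1L
    }
    D <- which(sp != s)
    if (length(D)) {
      decided <- decided + 1L
      touched <- unique(as.vector(edges[D, , drop = FALSE]))
      new_ll <- node_ll
      for (j in touched) new_ll[j] <- node_ll_for(j, sp)
      llp <- sum(new_ll)
      lpp <- sum(lprior[cbind(D, sp[D] + 1L)]) -
        sum(lprior[cbind(D, s[D] + 1L)]) + lp
      if (!is.finite(llp)) {
        warning("non-finite proposal log-likelihood at iteration ", t,
                "; rejecting")
        alpha <- 0
      } else if (!is.finite(lpp)) {
        alpha <- 0
      } else {
        # truncated-binomial and subset-choice terms cancel (same d both
        # ways); only prior, likelihood and switch terms remain
        la <- (lpp - lp) + (llp - ll) +
          sum(sw_log[cbind(D, sp[D] + 1L, s[D] + 1L)]) -
          sum(sw_log[cbind(D, s[D] + 1L, sp[D] + 1L)])
        alpha <- if (la >= 0) 1 else exp(la)
      }
      if (alpha == 1 || stats::runif(1L) < alpha) {
        s <- sp; A <- Ap; node_ll <- new_ll; ll <- llp; lp <- lpp
        accepted <- accepted + 1L
      }
    }
    trace_ll[t] <- ll
    trace_id[t] <- sum(s * pow3)
    if (keep_ptr <= length(keep_idx) && t == keep_idx[keep_ptr]) {
      samples[keep_ptr, ] <- s
      keep_ptr <- keep_ptr + 1L
    }
  }

  probs <- t(apply(samples, 2L, function(col) tabulate(col + 1L, 3L)))
  probs <- probs / nrow(samples)
  dimnames(probs) <- list(edge_labels(graph), c("p0", "p1", "p2"))
  hits <- cache$..hits; misses <- cache$..misses
  structure(list(
    probabilities = probs,
    edges = data.frame(node_j = graph$nodes[graph$edges[, 1L]],
                       node_k = graph$nodes[graph$edges[, 2L]],
                       stringsAsFactors = FALSE),
    samples = samples,
    trace_loglik = trace_ll,
    trace_graph = trace_id,
    acceptance_rate = if (decided) accepted / decided else NA_real_,
    repair_count = repairs_total,
    cache_hit_rate = if (hits + misses) hits / (hits + misses) else NA_real_,
    graph = graph,
    config = config
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Edge-state posterior from", x$config$iterations, "iterations (",
      nrow(x$samples), "retained samples )\n")
  print(round(x$probabilities, 3))
  cat("acceptance rate:", signif(x$acceptance_rate, 3),
      "| cycle repairs:", x$repair_count,
      "| cache hit rate:", signif(x$cache_hit_rate, 3), "\n")
  invisible(x)
}

#' Average posterior summaries across runs
#'
#' Element-wise mean of the per-edge posterior probability matrices from
#' independent runs on the same candidate graph (the multi-run protocol:
#' several long chains from different random starting points, averaged for
#' final inference).
#'
#' @param ... `posterior_summary` objects, or a single list of them.
#' @return A `posterior_summary` carrying the averaged probabilities (traces
#'   and samples are dropped).
#' @export
average_posteriors <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && !inherits(runs[[1L]], "posterior_summary"))
    runs <- runs[[1L]]
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, TRUE, "posterior_summary")))
  base <- runs[[1L]]
  for (r in runs[-1L])
    if (!identical(dimnames(r$probabilities), dimnames(base$probabilities)))
      stop("runs have different edge sets")
  probs <- Reduce(`+`, lapply(runs, `[[`, "probabilities")) / length(runs)
  out <- base
  out$probabilities <- probs
  out$samples <- NULL; out$trace_loglik <- NULL; out$trace_graph <- NULL
  out$acceptance_rate <- mean(vapply(runs, `[[`, 1, "acceptance_rate"))
  out
}

#' Decide edge presence and direction from a posterior
#'
#' An edge is called present when its posterior probability of presence
#' `1 - p2` is at least `presence_cutoff` (ties go to present), and directed
#' when the absolute difference between the two direction probabilities
#' exceeds `direction_margin`; otherwise it is reported
#' undirected-present.
#'
#' @param posterior A `posterior_summary` (or a plain `m x 3` probability
#'   matrix with an `edges` data frame attached via `edges =`).
#' @param presence_cutoff Presence threshold on `1 - p2` (default 0.5).
#' @param direction_margin Margin `|p0 - p1|` required to call a direction
#'   (default 0.2).
#' @param edges Optional `node_j`/`node_k` data frame when `posterior` is a
#'   bare matrix.
#' @return Data frame with columns `node_j`, `node_k`, `p0`, `p1`, `p2`,
#'   `decision` (one of `"absent"`, `"j->k"`, `"k->j"`, `"undirected"`).
#' @export
decide_edges <- function(posterior, presence_cutoff = 0.5,
                         direction_margin = 0.2, edges = NULL) {
  if (inherits(posterior, "posterior_summary")) {
    probs <- posterior$probabilities
    edges <- posterior$edges
  } else {
    probs <- as.matrix(posterior)
    if (is.null(edges))
      edges <- data.frame(node_j = paste0("e", seq_len(nrow(probs)), ".j"),
                          node_k = paste0("e", seq_len(nrow(probs)), ".k"))
  }
  present <- (1 - probs[, 3L]) >= presence_cutoff
  directed <- abs(probs[, 1L] - probs[, 2L]) > direction_margin
  decision <- ifelse(!present, "absent",
                     ifelse(!directed, "undirected",
                            ifelse(probs[, 1L] > probs[, 2L],
                                   "j->k", "k->j")))
  data.frame(edges, p0 = probs[, 1L], p1 = probs[, 2L], p2 = probs[, 3L],
             decision = decision, row.names = NULL,
             stringsAsFactors = FALSE)
}
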