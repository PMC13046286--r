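test_that("gaussian node fit handles degenerate and parentless cases", {
  f <- fit_gaussian_node(rep(3.5, 20))
  expect_equal(f$coefficients, 3.5)
  expect_equal(f$sigma2, 1e-12)
  expect_true(is.finite(f$loglik))
  # plain sample: intercept = mean, sigma2 = MLE (denominator N)
  y <- c(1, 2, 4, 9)
  f2 <- fit_gaussian_node(y)
  expect_equal(f2$coefficients, mean(y))
  expect_equal(f2$sigma2, mean((y - mean(y))^2))
})

test_that("gaussian node fit recovers simulated coefficients", {
  set.seed(101)
  n <- 10000
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  f <- fit_gaussian_node(y, cbind(x))
  se_beta <- 1 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(f$coefficients[2] - 2), 3 * se_beta)
  expect_lt(abs(f$sigma2 - 1), 3 * sqrt(2 / n))
})

test_that("gaussian maximized log-likelihood matches the grid-search oracle", {
  set.seed(7)
  x <- round(rnorm(20), 3)
  y <- round(0.5 + 1.2 * x + rnorm(20, sd = 0.8), 3)
  f <- fit_gaussian_node(y, cbind(x))
  expect_equal(f$loglik, oracle_gaussian_loglik(y, x), tolerance = 1e-3)
})

test_that("collinear parents trigger the pseudoinverse path with a warning", {
  set.seed(8)
  x <- rnorm(50)
  y <- x + rnorm(50)
  expect_warning(f <- fit_gaussian_node(y, cbind(x, 2 * x)),
                 "rank-deficient")
  expect_true(f$flagged)
  ref <- fit_gaussian_node(y, cbind(x))
  expect_equal(f$loglik, ref$loglik, tolerance = 1e-8)
})

test_that("binomial node fit: intercept-only MLE is the success fraction", {
  y <- c(rep(2L, 3), rep(1L, 4), rep(0L, 3))  # 10 obs of Binomial(2, p)
  f <- fit_binomial_node(y, trials = 2L)
  fr <- sum(y) / 20
  expect_equal(stats::plogis(f$coefficients[1]), fr, tolerance = 1e-7)
  expect_equal(f$loglik, sum(dbinom(y, 2, fr, log = TRUE)), tolerance = 1e-7)
  expect_error(fit_binomial_node(c(0L, 3L), trials = 2L), "in \\[0, trials\\]")
})

test_that("binomial node fit recovers simulated coefficients", {
  set.seed(202)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  f <- fit_binomial_node(y, cbind(x), trials = 1L)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-5)
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_lt(abs(f$coefficients[1] - 0), 3 * se[1])
  expect_lt(abs(f$coefficients[2] - 1), 3 * se[2])
})

test_that("binomial maximized log-likelihood matches the grid-search oracle", {
  set.seed(9)
  x <- round(rnorm(30), 3)
  y <- rbinom(30, 2, plogis(0.3 + 0.9 * x))
  f <- fit_binomial_node(y, cbind(x), trials = 2L)
  expect_equal(f$loglik, oracle_binomial_loglik(y, x, 2L), tolerance = 1e-3)
})

test_that("complete separation falls back to the ridge fit and is flagged", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- as.integer(x > 0)
  f <- fit_binomial_node(y, cbind(x), trials = 1L)
  expect_true(f$flagged)
  expect_true(all(is.finite(f$coefficients)))
  expect_true(is.finite(f$loglik))
})

test_that("graph pseudo-likelihood factorizes and is cache-transparent", {
  top <- builtin_topology("GN8")
  g <- candidate_graph(top$nodes, top$candidates)
  spec <- node_model_spec(g$nodes)
  dat <- simulate_data(top$adjacency, n = 120, beta = 0.5, seed = 4)
  # all-absent graph: sum of marginal fits
  s_absent <- rep(2L, n_edges(g))
  marg <- sum(vapply(seq_len(ncol(dat)), function(j)
    fit_gaussian_node(dat[, j])$loglik, numeric(1)))
  expect_equal(graph_log_pseudo_likelihood(s_absent, g, dat, spec), marg,
               tolerance = 1e-9)
  # cached and uncached evaluations agree on random acyclic vectors
  cache <- new_fit_cache()
  set.seed(12)
  tried <- 0
  while (tried < 100) {
    s <- sample(0:2, n_edges(g), replace = TRUE)
    if (!is_dag(states_to_adjacency(s, g))) next
    tried <- tried + 1
    expect_equal(graph_log_pseudo_likelihood(s, g, dat, spec, cache),
                 graph_log_pseudo_likelihood(s, g, dat, spec),
                 tolerance = 1e-12)
  }
  expect_gt(cache$..hits, 0)
  # cyclic input is rejected
  g3 <- candidate_graph(paste0("T", 1:3),
                        rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_error(
    graph_log_pseudo_likelihood(c(0L, 0L, 1L), g3, dat[, 1:3],
                                node_model_spec(g3$nodes)),
    "cycle")
})

test_that("adding a parent never decreases the maximized log-likelihood", {
  set.seed(13)
  dat <- simulate_data(builtin_topology("M1")$adjacency, n = 80, beta = 0.5)
  base <- fit_gaussian_node(dat[, "T3"])$loglik
  one <- fit_gaussian_node(dat[, "T3"], dat[, "T2", drop = FALSE])$loglik
  two <- fit_gaussian_node(dat[, "T3"], dat[, c("T1", "T2")])$loglik
  expect_gte(one, base)
  expect_gte(two, one)
})

test_that("Markov-equivalent DAGs have equal Gaussian pseudo-likelihoods", {
  top <- builtin_topology("M1")
  g <- candidate_graph(top$nodes, top$candidates)
  spec <- node_model_spec(g$nodes)
  for (seed in 1:5) {
    dat <- simulate_data(top$adjacency, n = 100, beta = 1, seed = seed)
    chain_fwd <- graph_log_pseudo_likelihood(c(0L, 0L), g, dat, spec)
    chain_rev <- graph_log_pseudo_likelihood(c(1L, 1L), g, dat, spec)
    fork <- graph_log_pseudo_likelihood(c(1L, 0L), g, dat, spec)
    collider <- graph_log_pseudo_likelihood(c(0L, 1L), g, dat, spec)
    expect_equal(chain_fwd, chain_rev, tolerance = 1e-6)
    expect_equal(chain_fwd, fork, tolerance = 1e-6)
    # the collider encodes different independencies: not in the class
    expect_false(isTRUE(all.equal(chain_fwd, collider, tolerance = 1e-6)))
  }
})
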