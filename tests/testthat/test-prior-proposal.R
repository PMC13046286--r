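test_that("edge-state prior validates and renormalizes over allowed states", {
  g <- candidate_graph(paste0("T", 1:3), rbind(c(1, 2), c(2, 3)),
                       iv_nodes = "T1")
  expect_error(edge_state_prior(g, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(edge_state_prior(g, c(-0.1, 0.2, 0.9)), "nonnegative")
  pr <- edge_state_prior(g, c(0.05, 0.05, 0.9))
  # edge T1-T2 disallows state 1 (T1 is an IV); mass renormalized
  expect_equal(unname(pr$probs[1, ]), c(0.05, 0, 0.9) / 0.95)
  expect_equal(unname(pr$probs[2, ]), c(0.05, 0.05, 0.9))
  expect_equal(rowSums(pr$probs), c(`T1-T2` = 1, `T2-T3` = 1))
})

test_that("prior log probability is the log product over edges", {
  g4 <- candidate_graph(paste0("T", 1:5),
                        rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  unif <- edge_state_prior(g4, c(1, 1, 1) / 3)
  expect_equal(prior_log_prob(c(0L, 1L, 2L, 0L), unif), 4 * log(1 / 3))
  g5 <- candidate_graph(paste0("T", 1:6),
                        rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6)))
  sparse <- edge_state_prior(g5, c(0.05, 0.05, 0.9))
  expect_equal(prior_log_prob(rep(2L, 5), sparse), 5 * log(0.9))
  # matches a direct product for random vectors
  set.seed(3)
  for (r in 1:100) {
    s <- sample(0:2, 5, replace = TRUE)
    expect_equal(prior_log_prob(s, sparse),
                 log(prod(sparse$probs[cbind(1:5, s + 1)])))
  }
  # occupied zero-prior state gives -Inf
  pr0 <- edge_state_prior(g4, c(0, 0.5, 0.5))
  expect_identical(prior_log_prob(c(0L, 2L, 2L, 2L), pr0), -Inf)
})

test_that("switch probabilities follow the prior-weighted rule", {
  sparse <- c(0.05, 0.05, 0.9)
  expect_equal(switch_probability(0, 1, sparse), 0.05 / (0.05 + 0.9))
  expect_equal(switch_probability(0, 2, sparse), 0.9 / (0.05 + 0.9))
  expect_equal(switch_probability(1, 0, sparse), 0.05 / 0.95)
  # constrained edge with a single alternative switches with certainty
  expect_equal(switch_probability(0, 2, sparse, allowed_states = c(0, 2)), 1)
  expect_error(switch_probability(1, 1, sparse), "same state")
  expect_error(switch_probability(0, 1, sparse, allowed_states = c(0, 2)),
               "allowed")
})

test_that("proposal size follows the truncated binomial law", {
  # m = 1: the single edge must switch every time
  g1 <- candidate_graph(c("T1", "T2"), rbind(c(1, 2)))
  pr1 <- edge_state_prior(g1)
  set.seed(17)
  for (r in 1:50) {
    p <- propose(2L, g1, pr1)
    expect_length(p$changed, 1L)
  }
  # chi-square test of the internal truncated draw at m = 12
  m <- 12L
  set.seed(99)
  draws <- replicate(1e5, edgebayes:::rtrunc_binom(m))
  pmf <- dbinom(1:m, m, 1 / m) / (1 - dbinom(0, m, 1 / m))
  bins <- c(1, 2, 3, 4)  # pool the sparse upper tail
  obs <- c(sum(draws == 1), sum(draws == 2), sum(draws == 3),
           sum(draws >= 4))
  expected <- c(pmf[1], pmf[2], pmf[3], sum(pmf[4:m]))
  gof <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("proposals and initializations never occupy blacklisted states", {
  g <- candidate_graph(paste0("T", 1:3), rbind(c(1, 2), c(1, 3), c(2, 3)),
                       iv_nodes = "T1")
  pr <- edge_state_prior(g, c(0.05, 0.05, 0.9))
  set.seed(41)
  s <- initialize_state(g, pr)
  for (r in 1:20000) {
    p <- propose(s, g, pr)
    expect_false(p$states[1] == 1L || p$states[2] == 1L)
    s <- p$states
  }
  for (r in 1:200) {
    s0 <- initialize_state(g, pr)
    expect_false(s0[1] == 1L || s0[2] == 1L)
    expect_true(is_dag(states_to_adjacency(s0, g)))
  }
})

test_that("transition log probability follows the changed-edge formula", {
  # m = 1: only the switch term survives
  g1 <- candidate_graph(c("T1", "T2"), rbind(c(1, 2)))
  pr1 <- edge_state_prior(g1, c(0.05, 0.05, 0.9))
  expect_equal(transition_log_prob(0L, 2L, g1, pr1), log(0.9 / 0.95))
  # m = 3 uniform prior, one edge flipped 0 -> 1
  g3 <- candidate_graph(paste0("T", 1:4),
                        rbind(c(1, 2), c(2, 3), c(3, 4)))
  pr3 <- edge_state_prior(g3, c(1, 1, 1) / 3)
  tb1 <- dbinom(1, 3, 1 / 3) / (1 - dbinom(0, 3, 1 / 3))
  expect_equal(transition_log_prob(c(0L, 0L, 0L), c(1L, 0L, 0L), g3, pr3),
               log(tb1 * (1 / 3) * (1 / 2)))
  # identical vectors carry no direct proposal mass
  expect_identical(transition_log_prob(c(0L, 0L, 0L), c(0L, 0L, 0L),
                                       g3, pr3), -Inf)
})

test_that("transition probabilities normalize over reachable targets", {
  # tree-shaped candidate sets cannot form cycles, so every completion is
  # reachable and the changed-edge kernel must sum to one exactly
  for (spec in list(list(m = 2, pr = c(1, 1, 1) / 3),
                    list(m = 3, pr = c(0.05, 0.05, 0.9)))) {
    g <- candidate_graph(paste0("T", 1:(spec$m + 1)),
                         cbind(1:spec$m, 2:(spec$m + 1)))
    pr <- edge_state_prior(g, spec$pr)
    S <- all_state_vectors(g)
    set.seed(2)
    for (r in 1:5) {
      from <- as.integer(S[sample(nrow(S), 1), ])
      tot <- sum(apply(S, 1, function(to) {
        to <- as.integer(to)
        if (all(to == from)) 0
        else exp(transition_log_prob(from, to, g, pr))
      }))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("on cycle-free skeletons empirical proposal frequencies match the kernel", {
  # chain of three candidate edges: no orientation can close a cycle, so
  # the changed-edge formula is the exact proposal law
  g <- candidate_graph(paste0("T", 1:4), rbind(c(1, 2), c(2, 3), c(3, 4)))
  pr <- edge_state_prior(g, c(0.2, 0.3, 0.5))
  s0 <- c(0L, 2L, 1L)
  n <- 1e5
  set.seed(77)
  ids <- integer(n)
  for (r in seq_len(n)) {
    p <- propose(s0, g, pr)
    ids[r] <- sum(p$states * 3^(0:2))
  }
  freq <- table(ids) / n
  S <- all_state_vectors(g)
  for (r in seq_len(nrow(S))) {
    to <- as.integer(S[r, ])
    if (all(to == s0)) next
    thy <- exp(transition_log_prob(s0, to, g, pr))
    obs <- freq[as.character(sum(to * 3^(0:2)))]
    obs <- if (is.na(obs)) 0 else as.numeric(obs)
    se <- sqrt(thy * (1 - thy) / n)
    expect_lt(abs(obs - thy), max(3 * se, 1e-4))
  }
})
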