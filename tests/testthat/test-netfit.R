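## Two-gene toy shared by several tests: gene A has strong unique-read
## evidence (9:1), gene B is fully ambiguous, and the only edge is a1 - b1.
toy_two_gene <- function() {
  catalog <- transcript_catalog(
    gene_id = c("A", "A", "B", "B"),
    transcript_id = c("a1", "a2", "b1", "b2"),
    length = rep(100, 4)
  )
  compat <- make_compat(catalog, list(
    list(list(count = 9, q = c(`1` = 0.01)), list(count = 1, q = c(`2` = 0.01))),
    list(list(count = 10, q = c(`1` = 0.01, `2` = 0.01)))
  ))
  net <- transcript_network(rbind(c(1, 3)), catalog)
  list(catalog = catalog, compat = compat, net = net)
}

## Direct evaluation of the joint objective for the toy as a function of
## (p_a1, p_b1); an independent formula oracle, vectorized over p_b1.
toy_total <- function(pa1, pb1, lambda) {
  lC <- function(a1, a2) lgamma(a1 + a2) - lgamma(a1) - lgamma(a2)
  fl <- function(x) log(pmax(x, 1e-12))
  pi_a1 <- 10 * pa1 / 100
  pi_b1 <- 10 * pb1 / 100
  phi_a1 <- 100 * pi_b1   # a1's sole neighbor is b1
  phi_b1 <- 100 * pi_a1   # b1's sole neighbor is a1
  term_a <- lC(lambda * phi_a1 + 1, 1) + lambda * phi_a1 * fl(pa1) +
    9 * log(0.01 * pa1) + 1 * log(0.01 * (1 - pa1))
  term_b <- lC(lambda * phi_b1 + 1, 1) + lambda * phi_b1 * fl(pb1) +
    10 * log(0.01 * pb1 + 0.01 * (1 - pb1))
  term_a + term_b
}

test_that("neighborhood prior is the length-scaled neighbor mean", {
  catalog <- transcript_catalog(paste0("G", 1:3), c("t", "u", "v"),
                                c(100, 50, 80))
  net <- transcript_network(rbind(c(1, 2), c(1, 3)), catalog)
  pi <- c(0, 2, 4)
  expect_equal(neighborhood_prior(pi, net, c(100, 50, 80), 1), 300)  # 100 * mean(2, 4)
  net0 <- transcript_network(matrix(integer(0), 0, 2), catalog)
  expect_equal(neighborhood_prior(pi, net0, c(100, 50, 80), 1), 0)
  expect_equal(neighborhood_prior(c(0, 0, 0), net, c(100, 50, 80), 1), 0)
})

test_that("Dirichlet parameters are lambda * phi + 1", {
  expect_equal(dirichlet_params(300, 0.1), 31)
  expect_equal(dirichlet_params(c(5, 0), 0), c(1, 1))
  expect_equal(dirichlet_params(0, 2), 1)
  expect_error(dirichlet_params(1, -0.1), "lambda")
  expect_error(dirichlet_params(-1, 0.1), "phi")
})

test_that("posterior log-likelihood reduces to the flat-prior cases", {
  g <- gene_compat(list(list(count = 2, q = c(`1` = 0.01, `2` = 0.02))), K = 2)
  p <- c(0.3, 0.7)
  ## alpha all ones: log C = log Gamma(2) = 0
  expect_equal(gene_posterior_loglik(p, c(1, 1), g), gene_log_likelihood(p, g))
  ## no reads, K transcripts, flat prior: log Gamma(K)
  K <- 5
  g0 <- list(counts = numeric(0), Q = matrix(0, 0, K))
  expect_equal(gene_posterior_loglik(rep(1 / K, K), rep(1, K), g0), lgamma(K))
  expect_error(gene_posterior_loglik(p, c(0.5, 1), g), "alpha")
})

test_that("posterior log-likelihood matches an independent formula oracle", {
  set.seed(17)
  for (rep in 1:20) {
    g <- random_gene_instance(K = sample(2:4, 1), E = sample(3:20, 1))
    K <- ncol(g$Q)
    p <- as.vector(stats::rgamma(K, 1)); p <- p / sum(p)
    alpha <- 1 + stats::rexp(K, rate = 0.1)
    expect_equal(gene_posterior_loglik(p, alpha, g),
                 oracle_posterior(p, alpha, g$counts, g$Q), tolerance = 1e-10)
  }
})

test_that("EM with prior hits closed-form fixed points", {
  ## unique reads (6, 4) with lambda * phi = (5, 5): one M-step gives 11/20
  g <- gene_compat(list(list(count = 6, q = c(`1` = 0.01)),
                        list(count = 4, q = c(`2` = 0.01))), K = 2)
  fit <- em_with_prior(g, phi = c(5, 5), lambda = 1)
  expect_equal(fit$p, c(11 / 20, 9 / 20), tolerance = 1e-9)
  ## lambda = 0 reduces to base EM from the same start
  g2 <- random_gene_instance(K = 3, E = 20)
  expect_equal(em_with_prior(g2, phi = c(9, 9, 9), lambda = 0)$p,
               base_em_fit(g2)$p)
  ## no reads: p is the normalized prior
  g0 <- list(counts = numeric(0), Q = matrix(0, 0, 2))
  expect_equal(em_with_prior(g0, phi = c(3, 1), lambda = 1)$p, c(0.75, 0.25))
})

test_that("posterior objective is non-decreasing along prior-EM iterations", {
  set.seed(53)
  for (rep in 1:30) {
    g <- random_gene_instance()
    K <- ncol(g$Q)
    phi <- stats::rexp(K, rate = 0.05)
    lambda <- sample(c(0.01, 0.1, 1), 1)
    alpha <- dirichlet_params(phi, lambda)
    p <- rep(1 / K, K)
    obj_prev <- gene_posterior_loglik(p, alpha, g)
    for (it in 1:30) {
      p <- em_with_prior(g, phi, lambda, p0 = p, max_iter = 1)$p
      obj <- gene_posterior_loglik(p, alpha, g)
      expect_gte(obj, obj_prev - 1e-10)
      obj_prev <- obj
    }
  }
})

test_that("the closed-form M-step maximizes the expected complete objective", {
  ## one E-step fixes the responsibilities; the M-step argmax of
  ## sum_k (lambda phi_k + n_k) log p_k must match a simplex grid search
  set.seed(71)
  for (rep in 1:15) {
    K <- sample(2:3, 1)
    g <- random_gene_instance(K = K, E = sample(5:30, 1))
    phi <- stats::rexp(K, rate = 0.05)
    lambda <- 0.1
    p_cur <- as.vector(stats::rgamma(K, 1)); p_cur <- p_cur / sum(p_cur)
    mix <- as.vector(g$Q %*% p_cur)
    n_k <- p_cur * as.vector(crossprod(g$Q, g$counts / mix))
    w <- lambda * phi + n_k
    p_step <- em_with_prior(g, phi, lambda, p0 = p_cur, max_iter = 1)$p
    expect_equal(p_step, w / sum(w), tolerance = 1e-12)
    if (K == 2) {
      p_grid <- grid_argmax_2(function(p) sum(w * log(pmax(p, 1e-12))))
      expect_lt(abs(p_step[1] - p_grid), 1e-3)
    } else {
      f <- function(p) sum(w * log(pmax(p, 1e-12)))
      ## random simplex probes never beat the closed form
      probes <- matrix(stats::rgamma(3 * 500, 1), ncol = 3)
      probes <- probes / rowSums(probes)
      expect_true(all(apply(probes, 1, f) <= f(p_step) + 1e-9))
    }
  }
})

test_that("acceptance objective reduces correctly and matches brute force", {
  toy <- toy_two_gene()
  lambda <- 0.1
  p_list <- list(c(0.9, 0.1), c(0.6, 0.4))
  ## no cross-gene neighbors: acceptance equals the gene posterior
  catalog1 <- transcript_catalog(rep("G1", 2), c("t1", "t2"), c(100, 100))
  compat1 <- make_compat(catalog1, list(
    list(list(count = 4, q = c(`1` = 0.01)), list(count = 2, q = c(`2` = 0.01)))))
  net1 <- transcript_network(matrix(integer(0), 0, 2), catalog1)
  p <- c(0.7, 0.3)
  expect_equal(acceptance_loglik(p, 1, list(p), net1, compat1, lambda),
               gene_posterior_loglik(p, c(1, 1), compat1, 1))
  ## brute-force Eq-style evaluation for the toy, updating gene B
  for (pb1 in c(0.3, 0.5, 0.8)) {
    got <- acceptance_loglik(c(pb1, 1 - pb1), 2, p_list, toy$net, toy$compat,
                             lambda)
    lC <- function(a1, a2) lgamma(a1 + a2) - lgamma(a1) - lgamma(a2)
    pi_a1 <- 10 * 0.9 / 100
    pi_b1 <- 10 * pb1 / 100
    phi_b1 <- 100 * pi_a1
    phi_a1 <- 100 * pi_b1
    want <- lC(lambda * phi_b1 + 1, 1) + lambda * phi_b1 * log(pb1) +
      10 * log(0.01) +                                   # fully ambiguous reads
      lC(lambda * phi_a1 + 1, 1) + lambda * phi_a1 * log(0.9)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(acceptance_loglik(p, 5, p_list, toy$net, toy$compat, lambda),
               "out of range")
})

test_that("total pseudo-log-likelihood matches a term-by-term hand evaluation", {
  catalog <- transcript_catalog(
    gene_id = c("G1", "G1", "G2", "G3"),
    transcript_id = c("t1", "t2", "u1", "v1"),
    length = c(100, 200, 100, 400)
  )
  compat <- make_compat(catalog, list(
    list(list(count = 3, q = c(`1` = 0.01)), list(count = 1, q = c(`1` = 0.01, `2` = 0.005))),
    list(list(count = 5, q = c(`1` = 0.02))),
    NULL
  ))
  net <- transcript_network(rbind(c(1, 3), c(2, 4), c(3, 4)), catalog)
  p_list <- list(c(0.7, 0.3), 1, 1)
  lambda <- 0.1
  ## hand evaluation from the definitions
  pi <- c(4 * 0.7 / 100, 4 * 0.3 / 200, 5 * 1 / 100, 0)
  phi <- c(100 * pi[3], 200 * pi[4], 100 * mean(c(pi[1], pi[4])), 400 * mean(c(pi[2], pi[3])))
  lC <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  want <- lC(lambda * phi[1:2] + 1) + sum(lambda * phi[1:2] * log(c(0.7, 0.3))) +
    3 * log(0.01 * 0.7) + log(0.01 * 0.7 + 0.005 * 0.3) +
    lC(lambda * phi[3] + 1) + lambda * phi[3] * log(1) + 5 * log(0.02) +
    lC(lambda * phi[4] + 1) + lambda * phi[4] * log(1)
  expect_equal(total_pseudo_loglik(p_list, net, compat, lambda), want,
               tolerance = 1e-10)
  ## lambda = 0: sum of gene log-likelihoods plus the flat-prior constants
  want0 <- 3 * log(0.01 * 0.7) + log(0.01 * 0.7 + 0.005 * 0.3) + 5 * log(0.02) +
    lgamma(2)  # log Gamma(K_i) terms; K = 1 genes contribute lgamma(1) = 0
  expect_equal(total_pseudo_loglik(p_list, net, compat, 0), want0,
               tolerance = 1e-12)
})

test_that("joint fit pulls ambiguous genes toward their network neighbors", {
  toy <- toy_two_gene()
  lambda <- 0.1
  base <- net_quantify(toy$compat, net = NULL, lambda = 0)
  expect_equal(base$p[3], 0.5)  # base EM cannot break the plateau
  fit <- net_quantify(toy$compat, toy$net, lambda = lambda)
  expect_gt(fit$p[3], fit$p[4])  # prior from a1 lifts b1
  ## grid-search oracle over both free coordinates of the joint objective
  grid <- seq(0.001, 0.999, by = 0.001)
  best <- c(NA, NA); best_val <- -Inf
  for (pa1 in seq(0.85, 0.95, by = 0.001)) {
    vals <- toy_total(pa1, grid, lambda)
    i <- which.max(vals)
    if (vals[i] > best_val) { best_val <- vals[i]; best <- c(pa1, grid[i]) }
  }
  ## the ambiguous gene lands where the grid search puts it
  expect_lt(abs(fit$p[3] - best[2]), 2e-3)
  ## gene A satisfies its one-step fixed point given B's solution:
  ## p_a1 = (lambda phi_a1 + 9) / (lambda phi_a1 + 10), phi_a1 = 10 p_b1
  phi_a1 <- 10 * fit$p[3]
  expect_equal(fit$p[1], (lambda * phi_a1 + 9) / (lambda * phi_a1 + 10),
               tolerance = 1e-6)
  ## and the heuristic's objective is within a whisker of the grid optimum
  expect_gt(toy_total(fit$p[1], fit$p[3], lambda), best_val - 0.01)
})

test_that("lambda = 0 and empty networks reproduce the base EM exactly", {
  set.seed(101)
  d <- simulate_dataset(n_genes = 12, n_reads = 4000, seed = 101)
  fit0 <- net_quantify(d$compat, d$net, lambda = 0)
  fit_empty <- net_quantify(d$compat, net = NULL, lambda = 0.1)
  for (gi in seq_len(n_genes(d$catalog))) {
    if (d$compat$n_reads[gi] == 0) next
    pb <- base_em_fit(d$compat, gi)$p
    rows <- d$catalog$tx_by_gene[[gi]]
    expect_lt(max(abs(fit0$p[rows] - pb)), 1e-9)
    expect_lt(max(abs(fit_empty$p[rows] - pb)), 1e-9)
  }
})

test_that("joint fit is deterministic, simplex-valid, and monotone in its trace", {
  d <- simulate_dataset(n_genes = 10, n_reads = 3000, seed = 77)
  f1 <- net_quantify(d$compat, d$net, lambda = 0.1, init = "random", seed = 5)
  f2 <- net_quantify(d$compat, d$net, lambda = 0.1, init = "random", seed = 5)
  expect_identical(f1$p, f2$p)
  expect_identical(attr(f1, "diagnostics")$trace, attr(f2, "diagnostics")$trace)
  ## per-gene simplex and nonnegativity
  for (gi in seq_len(n_genes(d$catalog))) {
    rows <- d$catalog$tx_by_gene[[gi]]
    expect_equal(sum(f1$p[rows]), 1, tolerance = 1e-9)
    expect_equal(sum(f1$rho[rows]), 1, tolerance = 1e-9)
  }
  expect_true(all(f1$p >= 0) && all(f1$pi >= 0))
  ## the trace of accepted updates never decreases
  expect_true(all(diff(attr(f1, "diagnostics")$trace) > 0))
  ## and the incremental bookkeeping agrees with a from-scratch evaluation
  p_list <- lapply(seq_len(n_genes(d$catalog)),
                   function(gi) f1$p[d$catalog$tx_by_gene[[gi]]])
  final <- total_pseudo_loglik(p_list, d$net, d$compat, 0.1)
  expect_equal(utils::tail(attr(f1, "diagnostics")$trace, 1), final,
               tolerance = 1e-8)
})
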