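test_that("psrf handles the degenerate binary-sequence conventions", {
  const <- rep(0.3, 100)
  expect_equal(psrf(list(const, const, const)), 1)
  expect_equal(psrf(list(rep(0, 100), rep(1, 100))), Inf)
  expect_error(psrf(list(const)), "2 chains")
})

test_that("psrf matches a hand-coded split-chain transcription", {
  ref_psrf <- function(chains) {
    halves <- unlist(lapply(chains, function(x) {
      h <- length(x) %/% 2
      list(x[1:h], x[(length(x) - h + 1):length(x)])
    }), recursive = FALSE)
    n <- length(halves[[1]])
    m <- length(halves)
    means <- sapply(halves, mean)
    W <- mean(sapply(halves, var))
    B <- n * var(means)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(61)
  chains <- lapply(1:4, function(k) rnorm(1000, mean = 0.01 * k))
  expect_equal(psrf(chains), ref_psrf(chains), tolerance = 1e-12)
  expect_lt(psrf(chains), 1.01)  # i.i.d. chains look converged
  # clearly divergent chains are flagged
  bad <- lapply(1:4, function(k) rnorm(200, mean = 3 * k))
  expect_gt(psrf(bad), 1.01)
})

test_that("effective sample size tracks the chains' autocorrelation", {
  set.seed(62)
  # i.i.d.: ESS is close to the total draw count
  iid <- lapply(1:4, function(k) rnorm(1000))
  expect_equal(effective_sample_size(iid), 4000, tolerance = 0.15)
  # AR(1) with phi = 0.5: ESS/N -> (1 - phi)/(1 + phi) = 1/3
  ar <- lapply(1:4, function(k)
    as.numeric(arima.sim(list(ar = 0.5), 4000)))
  expect_equal(effective_sample_size(ar) / 16000, 1 / 3, tolerance = 0.2)
  # maximal autocorrelation: constant chains that disagree
  expect_equal(effective_sample_size(list(rep(0, 50), rep(1, 50))), 2)
  # constant and agreeing: total retained count by convention
  expect_equal(effective_sample_size(list(rep(1, 50), rep(1, 50))), 100)
})

test_that("edge probabilities are post-burnin sample fractions", {
  # build a minimal trace by hand: 2 variables, 4 iterations
  tr <- structure(list(
    variables = c("a", "b"),
    initial_parents = list(integer(0), integer(0)),
    initial_lambdas = c(5, 5),
    deltas = list(
      list(lam_j = integer(0), lam_v = numeric(0),
           par_j = 1L, par_add = 2L, par_rem = NA_integer_),  # edge 2->1 on
      list(lam_j = integer(0), lam_v = numeric(0),
           par_j = integer(0), par_add = integer(0), par_rem = integer(0)),
      list(lam_j = 1L, lam_v = 9, par_j = integer(0),
           par_add = integer(0), par_rem = integer(0)),
      list(lam_j = integer(0), lam_v = numeric(0),
           par_j = 1L, par_add = NA_integer_, par_rem = 2L)   # edge 2->1 off
    ),
    iterations = 4L,
    attempts = c(lambda = 4, add = 2, remove = 2, swap = 0),
    accepts = c(lambda = 1, add = 1, remove = 1, swap = 0),
    seed = 1L, standardized = FALSE, elapsed_seconds = 0
  ), class = "ssps_chain_trace")

  # burnin 0.5 of 4 iterations: iterations 3 and 4 retained; the edge is
  # present in exactly one of the two retained samples
  post <- edge_posterior(list(tr), burnin_fraction = 0.5)
  expect_equal(post$n_retained_per_chain, 2)
  expect_equal(post$prob["b", "a"], 0.5)
  expect_equal(post$prob["a", "b"], 0)
  expect_equal(post$lambda_summary$mean[1], mean(c(9, 9)))
})

test_that("summaries match a dense-storage oracle and ignore chain order", {
  toy <- make_toy(V = 4, seed = 63)
  traces <- run_chains(toy$data, toy$prior,
                       termination = termination_policy(max_iterations = 60),
                       n_chains = 3, base_seed = 70)
  post <- edge_posterior(traces, burnin_fraction = 0.5)

  # dense oracle: replay full states iteration by iteration
  dense_prob <- matrix(0, 4, 4)
  keep <- 31:60
  for (tr in traces) for (it in keep) {
    st <- replay_state(tr, it)
    for (j in 1:4) dense_prob[st$parents[[j]], j] <-
        dense_prob[st$parents[[j]], j] + 1
  }
  dense_prob <- dense_prob / (3 * length(keep))
  expect_equal(unname(post$prob), dense_prob, tolerance = 1e-12)

  # permuting chains changes nothing
  post_perm <- edge_posterior(traces[c(3, 1, 2)], burnin_fraction = 0.5)
  expect_equal(post_perm$prob, post$prob)
  expect_equal(post_perm$psrf, post$psrf)
  expect_equal(post_perm$neff, post$neff)
})

test_that("never-proposed edges are converged at probability zero", {
  # two tiny hand-built constant traces: no accepted move ever
  mk <- function(seed) structure(list(
    variables = c("a", "b"), initial_parents = list(integer(0), integer(0)),
    initial_lambdas = c(5, 5),
    deltas = rep(list(list(lam_j = integer(0), lam_v = numeric(0),
                           par_j = integer(0), par_add = integer(0),
                           par_rem = integer(0))), 40),
    iterations = 40L,
    attempts = c(lambda = 40, add = 40, remove = 0, swap = 0),
    accepts = c(lambda = 0, add = 0, remove = 0, swap = 0),
    seed = seed, standardized = FALSE, elapsed_seconds = 0
  ), class = "ssps_chain_trace")
  post <- edge_posterior(list(mk(1L), mk(2L)), burnin_fraction = 0.5)
  expect_true(all(post$prob == 0))
  expect_true(all(post$converged))
  expect_true(all(post$psrf == 1))
  expect_true(all(post$neff == 40))  # 2 chains x 20 retained
})

test_that("the convergence flag combines both diagnostic thresholds", {
  toy <- make_toy(V = 3, seed = 64)
  traces <- run_chains(toy$data, toy$prior,
                       termination = termination_policy(max_iterations = 40),
                       n_chains = 2, base_seed = 80)
  post <- edge_posterior(traces)
  ok <- !is.na(post$converged)
  expect_identical(post$converged[ok],
                   ((post$psrf < 1.01) & (post$neff >= 10))[ok])
})
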