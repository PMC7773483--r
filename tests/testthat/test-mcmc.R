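toy5 <- make_toy(V = 5, seed = 31)
no_std <- model_config(standardize = FALSE)

test_that("chains are deterministic and bounded by the iteration cap", {
  tr1 <- run_chain(toy5$data, toy5$prior, no_std,
                   termination = termination_policy(max_iterations = 10),
                   seed = 99)
  tr2 <- run_chain(toy5$data, toy5$prior, no_std,
                   termination = termination_policy(max_iterations = 10),
                   seed = 99)
  expect_equal(tr1$iterations, 10)
  expect_identical(tr1$deltas, tr2$deltas)
  expect_identical(tr1$initial_parents, tr2$initial_parents)
  expect_identical(tr1$initial_lambdas, tr2$initial_lambdas)
})

test_that("delta replay reconstructs the state at any iteration", {
  tr <- run_chain(toy5$data, toy5$prior, no_std,
                  termination = termination_policy(max_iterations = 40),
                  seed = 7)
  # dense per-vertex series and direct state replay must agree everywhere
  for (j in c(1, 3, 5)) {
    ser <- replay_vertex_series(tr, j)
    for (it in c(1, 17, 40)) {
      st <- replay_state(tr, it)
      z <- numeric(5); z[st$parents[[j]]] <- 1
      expect_equal(ser$z[it, ], z)
      expect_equal(ser$lambda[it], st$lambdas[j])
    }
  }
  # the initial state is untouched by replay
  st0 <- replay_state(tr, 0)
  expect_identical(st0$parents, lapply(tr$initial_parents, as.integer))
})

test_that("parent update accepts exactly per the full-posterior MH ratio", {
  toy <- make_toy(V = 3, seed = 32)
  cfg <- model_config(standardize = FALSE)
  for (seed in 101:140) {
    st <- graph_state(list(2L, c(1L, 3L), integer(0)), c(4, 7, 10))
    j <- (seed %% 3) + 1
    set.seed(seed)
    mv <- propose_parent_update(st, j, toy$prior, cfg)
    u <- runif(1)
    cand <- st
    cand$parents[[j]] <- sort(mv$parents)
    logr <- (log_posterior(toy$data, toy$prior, cand, cfg) -
               log_posterior(toy$data, toy$prior, st, cfg)) +
      mv$logq_rev - mv$logq_fwd
    set.seed(seed)
    res <- mh_update_parents(st, j, toy$data, toy$prior, cfg)
    expect_identical(res$accepted, log(u) < logr)
    if (res$accepted) {
      expect_identical(res$state$parents[[j]], sort(as.integer(mv$parents)))
    } else {
      expect_identical(res$state, st)  # rejection leaves state bit-identical
    }
  }
})

test_that("lambda update is a prior-only MH step with hard bounds", {
  toy <- make_toy(V = 3, seed = 33)
  cfg <- model_config()
  # tiny xi: proposals are near-identity, so acceptance approaches 1
  st <- graph_state(list(1L, 2L, 3L), c(8, 8, 8))
  set.seed(41)
  acc <- vapply(1:200, function(i)
    mh_update_lambda(st, 1, toy$prior, cfg, proposal_config(xi = 1e-6))$accepted,
    logical(1))
  expect_true(all(acc))
  # proposals outside the uniform support are always rejected
  st_edge <- graph_state(list(1L, 2L, 3L), c(14.999, 8, 8))
  set.seed(42)
  res <- replicate(200, {
    r <- mh_update_lambda(st_edge, 1, toy$prior, cfg, proposal_config(xi = 50))
    c(r$accepted, r$state$lambdas[1])
  })
  expect_true(all(res[2, res[1, ] == 1] <= 15 & res[2, res[1, ] == 1] >= 3))
  # acceptance ratio equals the direct prior ratio for a flat-0.5 column
  conf <- toy$prior$conf; conf[, 1] <- 0.5
  prior2 <- prior_confidences(conf, toy$prior$variables)
  for (seed in 301:320) {
    set.seed(seed)
    lam_new <- rnorm(1, 8, 3)
    u <- runif(1)
    z <- c(1, 0, 0)
    expected <- lam_new >= 3 && lam_new <= 15 &&
      log(u) < (log_prior_vertex(z, rep(0.5, 3), lam_new) -
                  log_prior_vertex(z, rep(0.5, 3), 8))
    set.seed(seed)
    res <- mh_update_lambda(st, 1, prior2, cfg, proposal_config(xi = 3))
    expect_identical(res$accepted, expected)
  }
})

test_that("stationary distribution matches exact enumeration on two vertices", {
  # fixed lambda, unstandardized data: the per-vertex posterior over the
  # four parent sets is enumerable exactly
  toy <- make_toy(V = 2, T_len = 8, M = 4, seed = 34)
  lam0 <- 4
  init <- graph_state(list(integer(0), integer(0)), c(lam0, lam0))
  traces <- lapply(1:2, function(k)
    run_chain(toy$data, toy$prior, no_std,
              proposal_config(update_lambdas = FALSE),
              termination_policy(max_iterations = 6000),
              seed = 400 + k, init = init))
  post <- edge_posterior(traces, burnin_fraction = 0.5)
  exact <- vapply(1:2, function(j)
    oracle_edge_posterior(toy$data$courses, toy$prior$conf, lam0, j),
    numeric(2))
  for (j in 1:2) for (i in 1:2) {
    band <- mc_band(post$prob[i, j], post$neff[i, j])
    expect_lt(abs(post$prob[i, j] - exact[i, j]), band)
  }
})

test_that("independent chains get distinct derived seeds and pool cleanly", {
  traces <- run_chains(toy5$data, toy5$prior, no_std,
                       termination = termination_policy(max_iterations = 30),
                       n_chains = 3, base_seed = 50)
  expect_length(traces, 3)
  expect_equal(vapply(traces, `[[`, 1L, "seed"), 51:53)
  traces2 <- run_chains(toy5$data, toy5$prior, no_std,
                        termination = termination_policy(max_iterations = 30),
                        n_chains = 3, base_seed = 50)
  expect_identical(lapply(traces, `[[`, "deltas"),
                   lapply(traces2, `[[`, "deltas"))
  post <- edge_posterior(traces)
  expect_true(all(post$prob >= 0 & post$prob <= 1))
})

test_that("sparse parent-set proposal mixes faster than a uniform toggle proposal", {
  # test-only baseline: pick a candidate parent uniformly and toggle the
  # edge (symmetric proposal), the classic uniform add/remove scheme.
  # Mixing is scored by the effective sample size of each vertex's
  # parent-count series, the quantity the size-dependent action
  # probabilities are designed to move.
  uniform_toggle_sizes <- function(data, prior, lam0, iters, seed) {
    data <- standardize_time_courses(data)
    ss <- ssps:::dbn_suffstats(data)
    V <- ss$V
    set.seed(seed)
    parents <- rep(list(integer(0)), V)
    loglik <- vapply(1:V, function(j) ssps:::loglik_vertex_stats(ss, j, integer(0)), 1)
    sizes <- matrix(0, iters, V)
    for (it in 1:iters) {
      for (j in 1:V) {
        i <- sample.int(V, 1)
        pa_new <- if (i %in% parents[[j]]) setdiff(parents[[j]], i)
                  else c(parents[[j]], i)
        ll_new <- ssps:::loglik_vertex_stats(ss, j, pa_new)
        d_pri <- if (i %in% parents[[j]]) lam0 * (1 - prior$conf[i, j])
                 else -lam0 * (1 - prior$conf[i, j])
        if (log(runif(1)) < ll_new - loglik[j] + d_pri) {
          parents[[j]] <- pa_new
          loglik[j] <- ll_new
        }
        sizes[it, j] <- length(parents[[j]])
      }
    }
    sizes
  }

  lam0 <- 4
  iters <- 600
  for (V in c(20L, 40L)) {
    inst <- simulate_instance(V = V, r = 0.1, a = 0.1, seed = 35 + V)
    init <- graph_state(rep(list(integer(0)), V), rep(lam0, V))
    traces <- lapply(1:2, function(k)
      run_chain(inst$data, inst$prior, model_config(),
                proposal_config(update_lambdas = FALSE),
                termination_policy(max_iterations = iters),
                seed = 500 + k, init = init))
    sizes_unif <- lapply(1:2, function(k)
      uniform_toggle_sizes(inst$data, inst$prior, lam0, iters, 600 + k))

    keep <- (iters / 2 + 1):iters
    sizes_ssps <- lapply(traces, function(tr) {
      m <- sapply(seq_len(V), function(j)
        rowSums(replay_vertex_series(tr, j)$z))
      m[keep, , drop = FALSE]
    })
    ess_ssps <- sum(vapply(seq_len(V), function(j)
      effective_sample_size(lapply(sizes_ssps, function(m) m[, j])), 1))
    ess_unif <- sum(vapply(seq_len(V), function(j)
      effective_sample_size(lapply(sizes_unif, function(m) m[keep, j])), 1))
    expect_gt(ess_ssps, ess_unif)
  }
})
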