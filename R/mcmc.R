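#' Termination policy for the Markov chains
#'
#' A chain stops at whichever comes first: the iteration cap or the
#' wall-clock limit (checked at iteration boundaries, so traces always hold
#' whole sweeps). Defaults mirror an overnight run: 100 000 iterations or
#' 12 hours, 4 chains, first half of each chain discarded as burnin.
#'
#' @param max_iterations Iteration cap per chain.
#' @param max_wall_seconds Wall-clock cap per chain, in seconds.
#' @param n_chains Number of chains.
#' @param burnin_fraction Fraction of each chain discarded before
#'   summarization, in (0, 1).
#' @return A list of class \code{ssps_termination}.
#' @export
termination_policy <- function(max_iterations = 100000,
                               max_wall_seconds = 43200,
                               n_chains = 4, burnin_fraction = 0.5) {
  stopifnot(max_iterations >= 1, max_wall_seconds > 0, n_chains >= 1,
            burnin_fraction > 0, burnin_fraction < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 max_wall_seconds = max_wall_seconds,
                 n_chains = as.integer(n_chains),
                 burnin_fraction = burnin_fraction),
            class = "ssps_termination")
}

#' Construct a graph state
#'
#' @param parents List of integer vectors, one parent set per vertex.
#' @param lambdas Numeric vector of per-vertex inverse temperatures.
#' @return A list of class \code{ssps_graph_state}.
#' @export
graph_state <- function(parents, lambdas) {
  stopifnot(length(parents) == length(lambdas))
  structure(list(parents = lapply(parents, as.integer),
                 lambdas = as.numeric(lambdas)),
            class = "ssps_graph_state")
}

# prior$conf reordered so its variables match the data's; errors on mismatch.
align_prior <- function(prior, variables) {
  if (identical(prior$variables, variables)) return(prior)
  idx <- match(variables, prior$variables)
  if (anyNA(idx))
    stop("prior is missing variable(s): ",
         paste(variables[is.na(idx)], collapse = ", "))
  prior_confidences(prior$conf[idx, idx, drop = FALSE], variables)
}

indicator_column <- function(pa, V) {
  z <- numeric(V)
  z[pa] <- 1
  z
}

#' Metropolis--Hastings update of one vertex's inverse temperature
#'
#' Proposes \eqn{\lambda_j' \sim N(\lambda_j, \xi^2)}. Proposals outside
#' \code{[lambda_min, lambda_max]} carry zero prior mass and are rejected
#' outright; otherwise the symmetric proposal cancels and the move is
#' accepted with probability \code{min(1, exp(delta log prior))}. The
#' likelihood does not involve \eqn{\lambda_j}, so no likelihood term enters.
#'
#' @param state A graph state (list with \code{parents}, \code{lambdas}).
#' @param j Vertex index.
#' @param prior A \code{prior_confidences}.
#' @param config A \code{model_config}.
#' @param proposal A \code{proposal_config}.
#' @return List with \code{state} (possibly updated) and \code{accepted}.
#' @export
mh_update_lambda <- function(state, j, prior, config = model_config(),
                             proposal = proposal_config()) {
  V <- length(prior$variables)
  lam <- state$lambdas[j]
  lam_new <- stats::rnorm(1L, lam, proposal$xi)
  if (lam_new < config$lambda_min || lam_new > config$lambda_max)
    return(list(state = state, accepted = FALSE))
  z <- indicator_column(state$parents[[j]], V)
  delta <- log_prior_column(z, prior$conf[, j], lam_new) -
    log_prior_column(z, prior$conf[, j], lam)
  if (log(stats::runif(1L)) < delta) {
    state$lambdas[j] <- lam_new
    list(state = state, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

#' Metropolis--Hastings update of one vertex's parent set
#'
#' Draws a move from the sparse parent-set proposal and accepts it with
#' probability \code{min(1, exp(delta loglik_j + delta logprior_j +
#' logq_rev - logq_fwd))}. Only vertex j's likelihood and prior terms are
#' recomputed; a rejected proposal leaves the state untouched.
#'
#' @inheritParams mh_update_lambda
#' @param data A \code{time_course_set} (scored as given).
#' @return List with \code{state}, \code{accepted} and \code{action}.
#' @export
mh_update_parents <- function(state, j, data, prior, config = model_config(),
                              proposal = proposal_config()) {
  ss <- dbn_suffstats(data)
  V <- ss$V
  shat <- clamp_shat(reference_sizes(prior)[j], V, proposal$shat_clamp)
  mv <- propose_parent_move(as.integer(state$parents[[j]]), j, shat, V,
                            allow_self = config$allow_self_edges)
  cvec <- prior$conf[, j]
  lam <- state$lambdas[j]
  d_lik <- loglik_vertex_stats(ss, j, mv$parents) -
    loglik_vertex_stats(ss, j, as.integer(state$parents[[j]]))
  d_pri <- prior_delta(mv, cvec, lam)
  logr <- d_lik + d_pri + mv$logq_rev - mv$logq_fwd
  if (log(stats::runif(1L)) < logr) {
    state$parents[[j]] <- sort(as.integer(mv$parents))
    list(state = state, accepted = TRUE, action = mv$action)
  } else {
    list(state = state, accepted = FALSE, action = mv$action)
  }
}

# Change in the structure-prior log mass from a single move: flipping edge
# i -> j on costs lambda * (1 - c_ij); the per-edge normalizers cancel.
prior_delta <- function(mv, cvec, lam) {
  d <- 0
  if (!is.na(mv$add)) d <- d - lam * (1 - cvec[mv$add])
  if (!is.na(mv$remove)) d <- d + lam * (1 - cvec[mv$remove])
  d
}

#' Run one Markov chain
#'
#' Initializes the state (inverse temperatures uniform on their support,
#' edges drawn from their prior Bernoulli probabilities at the initial
#' \eqn{\lambda_j}, so chains start overdispersed), then performs sweeps
#' over the vertices in ascending order; each sweep updates \eqn{\lambda_j}
#' and then the parent set of every vertex and counts as one iteration.
#' Accepted changes are delta-encoded: the trace stores the initial state
#' plus, per iteration, the accepted edge and \eqn{\lambda} changes, from
#' which any intermediate state can be replayed exactly.
#'
#' @param data A \code{time_course_set}.
#' @param prior A \code{prior_confidences} over the same variables
#'   (reconciled by name).
#' @param config A \code{model_config}; when \code{config$standardize} is
#'   \code{TRUE} the data are centered/scaled before inference.
#' @param proposal A \code{proposal_config}.
#' @param termination A \code{termination_policy}.
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   trace.
#' @param init Optional initial \code{graph_state}; default draws one as
#'   described above.
#' @param verbose Print progress every \code{log_every} iterations.
#' @param log_every Progress interval in iterations.
#' @return An object of class \code{ssps_chain_trace}.
#' @export
run_chain <- function(data, prior, config = model_config(),
                      proposal = proposal_config(),
                      termination = termination_policy(),
                      seed = 1L, init = NULL, verbose = FALSE,
                      log_every = 1000L) {
  t0 <- proc.time()[["elapsed"]]
  prior <- align_prior(prior, data$variables)
  if (config$standardize) data <- standardize_time_courses(data)
  ss <- dbn_suffstats(data)
  V <- ss$V
  conf <- prior$conf
  shat <- clamp_shat(colSums(conf), V, proposal$shat_clamp)
  pool_n <- if (config$allow_self_edges) V else V - 1L

  set.seed(as.integer(seed))

  if (is.null(init)) {
    lambdas <- stats::runif(V, config$lambda_min, config$lambda_max)
    parents <- lapply(seq_len(V), function(j) {
      p_edge <- exp(-lambdas[j]) /
        (exp(-conf[, j] * lambdas[j]) + exp(-lambdas[j]))
      if (!config$allow_self_edges) p_edge[j] <- 0
      which(stats::runif(V) < p_edge)
    })
  } else {
    lambdas <- as.numeric(init$lambdas)
    parents <- lapply(init$parents, as.integer)
    if (length(parents) != V || length(lambdas) != V)
      stop("'init' does not match the number of variables")
  }

  loglik <- vapply(seq_len(V), function(j) loglik_vertex_stats(ss, j, parents[[j]]),
                   numeric(1L))
  logpri <- vapply(seq_len(V), function(j)
    log_prior_column(indicator_column(parents[[j]], V), conf[, j], lambdas[j]),
    numeric(1L))

  initial_parents <- parents
  initial_lambdas <- lambdas

  att <- c(lambda = 0, add = 0, remove = 0, swap = 0)
  acc <- c(lambda = 0, add = 0, remove = 0, swap = 0)
  deltas <- vector("list", termination$max_iterations)
  n_done <- 0L

  for (it in seq_len(termination$max_iterations)) {
    lam_j <- integer(0); lam_v <- numeric(0)
    par_j <- integer(0); par_add <- integer(0); par_rem <- integer(0)

    for (j in seq_len(V)) {
      cvec <- conf[, j]
      if (proposal$update_lambdas) {
        att[["lambda"]] <- att[["lambda"]] + 1
        lam_new <- stats::rnorm(1L, lambdas[j], proposal$xi)
        if (lam_new >= config$lambda_min && lam_new <= config$lambda_max) {
          lp_new <- log_prior_column(indicator_column(parents[[j]], V), cvec, lam_new)
          if (log(stats::runif(1L)) < lp_new - logpri[j]) {
            lambdas[j] <- lam_new
            logpri[j] <- lp_new
            acc[["lambda"]] <- acc[["lambda"]] + 1
            lam_j <- c(lam_j, j); lam_v <- c(lam_v, lam_new)
          }
        }
      }

      mv <- propose_parent_move(parents[[j]], j, shat[j], V,
                                allow_self = config$allow_self_edges)
      att[[mv$action]] <- att[[mv$action]] + 1
      ll_new <- loglik_vertex_stats(ss, j, mv$parents)
      if (!is.finite(ll_new))
        stop(sprintf("non-finite log-likelihood at iteration %d, vertex %d", it, j))
      logr <- (ll_new - loglik[j]) + prior_delta(mv, cvec, lambdas[j]) +
        mv$logq_rev - mv$logq_fwd
      if (log(stats::runif(1L)) < logr) {
        parents[[j]] <- sort(as.integer(mv$parents))
        loglik[j] <- ll_new
        logpri[j] <- logpri[j] + prior_delta(mv, cvec, lambdas[j])
        acc[[mv$action]] <- acc[[mv$action]] + 1
        par_j <- c(par_j, j)
        par_add <- c(par_add, mv$add)
        par_rem <- c(par_rem, mv$remove)
      }
    }

    deltas[[it]] <- list(lam_j = lam_j, lam_v = lam_v,
                         par_j = par_j, par_add = par_add, par_rem = par_rem)
    n_done <- it
    if (verbose && it %% log_every == 0L) {
      rates <- ifelse(att > 0, acc / att, NA_real_)
      message(sprintf("iter %d | accept: lambda %.2f add %.2f remove %.2f swap %.2f",
                      it, rates[["lambda"]], rates[["add"]],
                      rates[["remove"]], rates[["swap"]]))
    }
    if (proc.time()[["elapsed"]] - t0 > termination$max_wall_seconds) break
  }

  structure(list(
    variables = data$variables,
    initial_parents = initial_parents,
    initial_lambdas = initial_lambdas,
    deltas = deltas[seq_len(n_done)],
    iterations = n_done,
    attempts = att, accepts = acc,
    seed = as.integer(seed),
    standardized = config$standardize,
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  ), class = "ssps_chain_trace")
}

#' @export
print.ssps_chain_trace <- function(x, ...) {
  cat(sprintf("ssps_chain_trace: %d iterations over %d variables (seed %d, %.1fs)\n",
              x$iterations, length(x$variables), x$seed, x$elapsed_seconds))
  rates <- ifelse(x$attempts > 0, x$accepts / x$attempts, NA_real_)
  cat("acceptance rates:",
      paste(sprintf("%s %.3f", names(rates), rates), collapse = ", "), "\n")
  invisible(x)
}

#' Replay a delta-encoded trace to the state after a given iteration
#'
#' @param trace An \code{ssps_chain_trace}.
#' @param iteration Iteration to stop after (0 = initial state); defaults to
#'   the final iteration.
#' @return A \code{graph_state}.
#' @export
replay_state <- function(trace, iteration = trace$iterations) {
  stopifnot(iteration >= 0, iteration <= trace$iterations)
  parents <- lapply(trace$initial_parents, as.integer)
  lambdas <- trace$initial_lambdas
  for (it in seq_len(iteration)) {
    d <- trace$deltas[[it]]
    if (length(d$lam_j)) lambdas[d$lam_j] <- d$lam_v
    for (k in seq_along(d$par_j)) {
      j <- d$par_j[k]
      pa <- parents[[j]]
      if (!is.na(d$par_rem[k])) pa <- setdiff(pa, d$par_rem[k])
      if (!is.na(d$par_add[k])) pa <- c(pa, d$par_add[k])
      parents[[j]] <- sort(pa)
    }
  }
  graph_state(parents, lambdas)
}

# Dense per-iteration series for vertex j: an iterations x V 0/1 matrix of
# its parent indicators and the lambda_j series, replayed from the deltas.
replay_vertex_series <- function(trace, j) {
  V <- length(trace$variables)
  n <- trace$iterations
  Z <- matrix(0, nrow = n, ncol = V)
  lam <- numeric(n)
  z <- indicator_column(trace$initial_parents[[j]], V)
  l <- trace$initial_lambdas[j]
  for (it in seq_len(n)) {
    d <- trace$deltas[[it]]
    hit <- which(d$lam_j == j)
    if (length(hit)) l <- d$lam_v[hit[length(hit)]]
    for (k in which(d$par_j == j)) {
      if (!is.na(d$par_rem[k])) z[d$par_rem[k]] <- 0
      if (!is.na(d$par_add[k])) z[d$par_add[k]] <- 1
    }
    Z[it, ] <- z
    lam[it] <- l
  }
  list(z = Z, lambda = lam)
}

#' Run several independent Markov chains
#'
#' Chain k is seeded with \code{base_seed + k}, so a fixed base seed yields
#' a reproducible set of chains and sequential execution is the defined
#' semantics. A chain that fails is reported as a warning and dropped; an
#' error is raised only if every chain fails.
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains (defaults to the termination policy's).
#' @param base_seed Base integer seed.
#' @return List of \code{ssps_chain_trace} objects.
#' @export
run_chains <- function(data, prior, config = model_config(),
                       proposal = proposal_config(),
                       termination = termination_policy(),
                       n_chains = termination$n_chains,
                       base_seed = 1L, verbose = FALSE, log_every = 1000L) {
  traces <- vector("list", n_chains)
  ok <- logical(n_chains)
  for (k in seq_len(n_chains)) {
    traces[[k]] <- tryCatch({
      tr <- run_chain(data, prior, config, proposal, termination,
                      seed = as.integer(base_seed) + k,
                      verbose = verbose, log_every = log_every)
      ok[k] <- TRUE
      tr
    }, error = function(e) {
      warning(sprintf("chain %d failed: %s", k, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  if (!any(ok)) stop("all chains failed")
  traces[ok]
}
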