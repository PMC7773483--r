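# Coerce per-chain sequences to a common-length matrix (iterations x chains).
as_chain_matrix <- function(chains) {
  if (is.matrix(chains)) return(chains)
  stopifnot(is.list(chains), length(chains) >= 1L)
  n <- min(lengths(chains))
  vapply(chains, function(x) as.numeric(x[seq_len(n)]), numeric(n))
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting half-chains, which also flags
#' within-chain nonstationarity. Binary edge indicators are frequently
#' constant, where the ratio is 0/0: by convention the result is 1 when all
#' half-chains are constant with equal means (nothing to mix), and
#' \code{Inf} when within-chain variance is zero but the chains disagree.
#'
#' @param chains List of equal-length numeric vectors (one per chain, at
#'   least 2), or an iterations x chains matrix.
#' @return The PSRF estimate (>= 1, possibly \code{Inf}).
#' @export
psrf <- function(chains) {
  x <- as_chain_matrix(chains)
  if (ncol(x) < 2L) stop("psrf needs at least 2 chains")
  if (nrow(x) < 4L) stop("psrf needs post-burnin chains of length >= 4")
  half <- nrow(x) %/% 2L
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[seq.int(nrow(x) - half + 1L, nrow(x)), , drop = FALSE])
  m <- ncol(splits)
  n <- nrow(splits)
  mu <- colMeans(splits)
  W <- mean(apply(splits, 2L, stats::var))
  B_over_n <- stats::var(mu)   # = B/n
  if (W <= 0) {
    if (B_over_n <= 0) return(1)
    return(Inf)
  }
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

# Within-chain autocovariances (biased, denominator n) up to lag.max,
# averaged over chains: one row per lag 0..lag.max.
mean_autocov <- function(x, lag.max) {
  n <- nrow(x)
  acvs <- apply(x, 2L, function(v)
    stats::acf(v, lag.max = lag.max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1L, 1L] * (n - 1) / n)
  rowMeans(acvs)
}

#' Multi-chain effective sample size
#'
#' Combines chains via the pooled-variance autocorrelation estimate
#' (between-chain disagreement inflates the autocorrelation, shrinking the
#' ESS) and truncates the autocorrelation sum with Geyer's initial monotone
#' positive sequence: successive lag pairs are summed, the sum stops at the
#' first non-positive pair, and the pair sums are forced non-increasing.
#' Degenerate cases follow the same convention as \code{\link{psrf}}: all
#' chains constant and equal gives ESS = total retained draws; constant but
#' disagreeing chains give ESS = the chain count (one effective draw per
#' chain).
#'
#' @inheritParams psrf
#' @return Effective number of samples.
#' @export
effective_sample_size <- function(chains) {
  x <- as_chain_matrix(chains)
  if (ncol(x) < 2L) stop("effective_sample_size needs at least 2 chains")
  if (nrow(x) < 4L) stop("effective_sample_size needs chains of length >= 4")
  m <- ncol(x)
  n <- nrow(x)
  W <- mean(apply(x, 2L, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (W <= 0) {
    if (B_over_n <= 0) return(m * n)
    return(m)
  }
  var_plus <- (n - 1) / n * W + B_over_n
  lag.max <- min(n - 1L, 400L)
  acov <- mean_autocov(x, lag.max)
  rho <- 1 - (W - acov[-1L]) / var_plus   # rho[t], t = 1..lag.max

  # Geyer pairing over (rho_{2k-1} + rho_{2k}) with rho_0 = 1 absorbed below.
  tau <- 1
  prev_pair <- Inf
  t <- 1L
  while (t <= length(rho)) {
    pair <- rho[t] + (if (t + 1L <= length(rho)) rho[t + 1L] else 0)
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2L
  }
  max(m * n / tau, 1e-12)
}

#' Summarize chains into posterior edge probabilities with diagnostics
#'
#' Replays each delta-encoded trace into dense per-edge indicator series,
#' discards the first \code{burnin_fraction} of every chain, and reports
#' the pooled sample frequency of each edge together with its split-chain
#' PSRF, effective sample size and a convergence flag
#' (\code{psrf < psrf_threshold} and \code{neff >= neff_threshold}; the
#' defaults flag failure at PSRF >= 1.01 or fewer than 10 effective
#' samples). Inverse temperatures get the same treatment per vertex. Chains
#' are truncated to a common post-burnin length; summaries are invariant to
#' chain order.
#'
#' @param traces List of \code{ssps_chain_trace} objects (>= 1).
#' @param burnin_fraction Fraction of each chain discarded (default 0.5).
#' @param psrf_threshold,neff_threshold Convergence flag cutoffs.
#' @return An object of class \code{ssps_edge_posterior}: matrices
#'   \code{prob}, \code{psrf}, \code{neff}, \code{converged} (parent rows,
#'   child columns), a \code{lambda_summary} data frame, retained sample
#'   counts and pooled acceptance statistics.
#' @export
edge_posterior <- function(traces, burnin_fraction = 0.5,
                           psrf_threshold = 1.01, neff_threshold = 10) {
  if (inherits(traces, "ssps_chain_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, burnin_fraction > 0, burnin_fraction < 1)
  vars <- traces[[1L]]$variables
  V <- length(vars)
  for (tr in traces)
    if (!identical(tr$variables, vars)) stop("traces cover different variables")

  n_keep <- vapply(traces, function(tr) {
    drop <- floor(burnin_fraction * tr$iterations)
    as.integer(tr$iterations - drop)
  }, integer(1L))
  if (any(n_keep < 1L)) stop("a chain has no post-burnin samples")
  n_ret <- min(n_keep)
  n_chains <- length(traces)
  multi <- n_chains >= 2L && n_ret >= 4L

  prob <- matrix(NA_real_, V, V, dimnames = list(vars, vars))
  rhat <- matrix(NA_real_, V, V, dimnames = list(vars, vars))
  ness <- matrix(NA_real_, V, V, dimnames = list(vars, vars))
  lam_mean <- lam_rhat <- lam_ness <- rep(NA_real_, V)

  for (j in seq_len(V)) {
    zs <- vector("list", n_chains)
    ls <- vector("list", n_chains)
    for (k in seq_len(n_chains)) {
      ser <- replay_vertex_series(traces[[k]], j)
      keep <- seq.int(traces[[k]]$iterations - n_ret + 1L, traces[[k]]$iterations)
      zs[[k]] <- ser$z[keep, , drop = FALSE]
      ls[[k]] <- ser$lambda[keep]
    }
    pooled <- do.call(rbind, zs)
    prob[, j] <- colMeans(pooled)
    lam_mean[j] <- mean(unlist(ls))
    if (multi) {
      for (i in seq_len(V)) {
        seqs <- lapply(zs, function(z) z[, i])
        rhat[i, j] <- psrf(seqs)
        ness[i, j] <- effective_sample_size(seqs)
      }
      lam_rhat[j] <- psrf(ls)
      lam_ness[j] <- effective_sample_size(ls)
    }
  }

  converged <- if (multi) (rhat < psrf_threshold) & (ness >= neff_threshold)
               else matrix(NA, V, V, dimnames = list(vars, vars))

  att <- Reduce(`+`, lapply(traces, `[[`, "attempts"))
  acc <- Reduce(`+`, lapply(traces, `[[`, "accepts"))

  structure(list(
    variables = vars,
    prob = prob, psrf = rhat, neff = ness, converged = converged,
    lambda_summary = data.frame(variable = vars, mean = lam_mean,
                                psrf = lam_rhat, neff = lam_ness),
    n_chains = n_chains, n_retained_per_chain = n_ret,
    burnin_fraction = burnin_fraction,
    psrf_threshold = psrf_threshold, neff_threshold = neff_threshold,
    attempts = att, accepts = acc
  ), class = "ssps_edge_posterior")
}

#' @export
print.ssps_edge_posterior <- function(x, ...) {
  cat(sprintf("ssps_edge_posterior: %d variables, %d chain(s), %d retained samples/chain\n",
              length(x$variables), x$n_chains, x$n_retained_per_chain))
  if (!all(is.na(x$converged))) {
    n_bad <- sum(!x$converged, na.rm = TRUE)
    cat(sprintf("edges flagged non-converged: %d of %d\n", n_bad,
                length(x$converged)))
  }
  invisible(x)
}

#' Long-format edge table of a posterior summary
#'
#' @param x An \code{ssps_edge_posterior}.
#' @param ... Unused.
#' @return Data frame with columns parent, child, probability, psrf, neff,
#'   converged.
#' @export
as.data.frame.ssps_edge_posterior <- function(x, ...) {
  V <- length(x$variables)
  idx <- expand.grid(parent = seq_len(V), child = seq_len(V))
  data.frame(
    parent = x$variables[idx$parent],
    child = x$variables[idx$child],
    probability = x$prob[cbind(idx$parent, idx$child)],
    psrf = x$psrf[cbind(idx$parent, idx$child)],
    neff = x$neff[cbind(idx$parent, idx$child)],
    converged = x$converged[cbind(idx$parent, idx$child)]
  )
}

#' Write a posterior edge table as CSV
#'
#' @param x An \code{ssps_edge_posterior}.
#' @param path Output file path.
#' @export
write_edge_posterior <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
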