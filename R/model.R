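#' Model configuration
#'
#' Bounds of the uniform prior on the per-vertex inverse temperatures
#' \eqn{\lambda_j}, plus structural switches. \eqn{\lambda_j} controls how
#' strongly the prior confidences constrain vertex j's parent set; small
#' lower bounds admit states with very many edges, so the default floor is 3.
#'
#' @param lambda_min Lower bound of the uniform \eqn{\lambda} prior (> 0).
#' @param lambda_max Upper bound (> \code{lambda_min}). The posterior is
#'   insensitive to this as long as it is comfortably large.
#' @param standardize Center/scale each variable before inference (default
#'   \code{TRUE}; recorded in run metadata).
#' @param allow_self_edges Keep the diagonal in the candidate edge set. A
#'   lagged self-edge i -> i is plain autoregression, so it is allowed by
#'   default.
#' @return A list of class \code{ssps_model_config}.
#' @export
model_config <- function(lambda_min = 3, lambda_max = 15,
                         standardize = TRUE, allow_self_edges = TRUE) {
  stopifnot(is.numeric(lambda_min), lambda_min > 0,
            is.numeric(lambda_max), lambda_max > lambda_min)
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max,
                 standardize = isTRUE(standardize),
                 allow_self_edges = isTRUE(allow_self_edges)),
            class = "ssps_model_config")
}

#' Lagged regression design for one vertex
#'
#' For vertex j with parent set pa(j), the response y stacks variable j at
#' timepoints 2..T_m of every course (courses in input order, time
#' ascending), and the design B stacks the parent columns at timepoints
#' 1..T_m - 1. With M courses of lengths T_m the stacked row count is
#' n = sum(T_m - 1).
#'
#' @param data A \code{time_course_set}.
#' @param j Vertex (column) index.
#' @param parents Integer vector of parent indices (possibly empty).
#' @return List with \code{y} (length n) and \code{B} (n x |parents|).
#' @export
build_design <- function(data, j, parents) {
  V <- n_variables(data)
  j <- as.integer(j)
  parents <- as.integer(parents)
  if (length(j) != 1L || is.na(j) || j < 1L || j > V)
    stop("vertex index out of range")
  if (length(parents) && (anyNA(parents) || any(parents < 1L | parents > V)))
    stop("parent index out of range")
  ys <- lapply(data$courses, function(cm) cm[-1L, j])
  Bs <- lapply(data$courses, function(cm)
    cm[-nrow(cm), parents, drop = FALSE])
  list(y = unlist(ys, use.names = FALSE), B = do.call(rbind, Bs))
}

# Sufficient statistics for the marginal likelihood: with Xm the stacked
# lagged predictors (n x V) and Xp the stacked responses (n x V),
#   G = Xm'Xm,  H[i, j] = Xm[, i]'Xp[, j],  yty[j] = Xp[, j]'Xp[, j].
# Every per-vertex likelihood evaluation then reduces to an s x s solve,
# independent of n and V.
dbn_suffstats <- function(data) {
  Xm <- do.call(rbind, lapply(data$courses, function(cm) cm[-nrow(cm), , drop = FALSE]))
  Xp <- do.call(rbind, lapply(data$courses, function(cm) cm[-1L, , drop = FALSE]))
  n <- nrow(Xm)
  list(V = ncol(Xm), n = n, t_eff = n + 1,
       G = crossprod(Xm), H = crossprod(Xm, Xp),
       yty = colSums(Xp^2))
}

# Minimum-norm solve of A x = b via Cholesky, falling back to the
# Moore-Penrose pseudo-inverse when A is (numerically) singular. Rank
# deficiency is legitimate here: parent sets may exceed the number of
# stacked timepoints because in-degrees are unconstrained.
solve_psd <- function(A, b) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(R)) return(backsolve(R, backsolve(R, b, transpose = TRUE)))
  sv <- svd(A)
  pos <- sv$d > max(sv$d[1L], 0) * 1e-10
  if (!any(pos)) return(rep(0, length(b)))
  sv$v[, pos, drop = FALSE] %*% ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
}

# Core of the marginalized Gaussian likelihood, from sufficient statistics.
# Up to a constant shared by all parent sets of vertex j:
#   -(s/2) log(T) - ((T-1)/2) log( y'y - ((T-1)/T) y'B bhat ),
# with T the effective timepoint count n + 1 and bhat the (minimum-norm)
# OLS coefficients. The log argument is floored at 1e-12 * y'y to guard
# cancellation when the fit interpolates.
loglik_vertex_stats <- function(ss, j, parents) {
  yty <- unname(ss$yty[j])
  if (yty <= 0) stop(sprintf("response column %d is identically zero", j))
  n <- ss$n
  t_eff <- ss$t_eff
  s <- length(parents)
  if (s == 0L) return(-(n / 2) * log(yty))
  b <- ss$H[parents, j]
  yBb <- sum(b * solve_psd(ss$G[parents, parents, drop = FALSE], b))
  arg <- max(yty - (n / t_eff) * yBb, 1e-12 * yty)
  val <- -(s / 2) * log(t_eff) - (n / 2) * log(arg)
  if (!is.finite(val))
    stop(sprintf("non-finite log-likelihood for vertex %d", j))
  val
}

#' Marginalized log-likelihood of one vertex's parent set
#'
#' The regression coefficients and noise variance of the linear-Gaussian
#' transition model for vertex j are integrated out under a g-prior-style
#' coefficient prior and the improper \eqn{1/\sigma^2} variance prior,
#' leaving a closed-form structure score. Returned up to an additive
#' constant shared by all parent sets of the same vertex, so only
#' differences across parent sets are meaningful. Multiple courses are
#' pooled: with n = sum(T_m - 1) stacked transitions the effective
#' timepoint count is n + 1, which reduces to the single-course T when
#' M = 1.
#'
#' @param data A \code{time_course_set}.
#' @param j Vertex index.
#' @param parents Integer vector of parent indices.
#' @return Log-likelihood contribution (a scalar).
#' @export
log_marginal_likelihood_vertex <- function(data, j, parents) {
  loglik_vertex_stats(dbn_suffstats(data), as.integer(j), as.integer(parents))
}

# Per-edge Bernoulli log-masses of the structure prior, vectorized over a
# column. With a = -c*lambda and b = -lambda, the normalizer is
# logsumexp(a, b); presence contributes b - logZ, absence a - logZ.
log_prior_column <- function(z_col, c_col, lambda_j) {
  a <- -c_col * lambda_j
  b <- -lambda_j
  hi <- pmax(a, b)
  logz <- hi + log(exp(a - hi) + exp(b - hi))
  sum(ifelse(z_col > 0, b - logz, a - logz))
}

#' Log prior mass of one vertex's parent-set indicators
#'
#' Each potential edge i -> j is an independent Bernoulli draw with success
#' probability \eqn{e^{-\lambda_j} / (e^{-c_{ij}\lambda_j} + e^{-\lambda_j})}.
#' When all confidences are binary this reproduces the reference-graph prior
#' that gives uniform mass to subgraphs of the reference and penalizes each
#' extra edge by \eqn{e^{-\lambda}}; fractional confidences interpolate it.
#'
#' @param z_col Indicator vector (0/1 or logical), entry i = edge i -> j.
#' @param c_col Confidence vector, entries in [0, 1].
#' @param lambda_j Inverse temperature (> 0).
#' @return Log prior mass (a scalar).
#' @export
log_prior_vertex <- function(z_col, c_col, lambda_j) {
  stopifnot(length(z_col) == length(c_col), lambda_j > 0,
            all(c_col >= 0 & c_col <= 1))
  log_prior_column(as.numeric(z_col), as.numeric(c_col), lambda_j)
}

#' Full log posterior of a graph state
#'
#' Sums the per-vertex marginal log-likelihood and structure-prior terms and
#' adds the flat \eqn{\lambda} prior: constant inside
#' \code{[lambda_min, lambda_max]}, \code{-Inf} outside. The result
#' decomposes over vertices, so editing vertex j's parents or
#' \eqn{\lambda_j} changes only term j.
#'
#' @param data A \code{time_course_set} (standardize beforehand if desired;
#'   this function scores the data it is given).
#' @param prior A \code{prior_confidences}.
#' @param state List with \code{parents} (list of integer vectors, one per
#'   vertex) and \code{lambdas} (numeric vector).
#' @param config A \code{model_config}.
#' @return Log posterior density up to a constant.
#' @export
log_posterior <- function(data, prior, state, config = model_config()) {
  V <- n_variables(data)
  if (any(state$lambdas < config$lambda_min | state$lambdas > config$lambda_max))
    return(-Inf)
  ss <- dbn_suffstats(data)
  total <- 0
  for (j in seq_len(V)) {
    pa <- as.integer(state$parents[[j]])
    z <- numeric(V)
    z[pa] <- 1
    total <- total + loglik_vertex_stats(ss, j, pa) +
      log_prior_column(z, prior$conf[, j], state$lambdas[j])
  }
  total
}
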