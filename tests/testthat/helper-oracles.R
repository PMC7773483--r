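`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles: direct, unoptimized transcriptions of the model's
# definitions, sharing no code with the implementation paths they check.

# Stack the lagged design for vertex j by hand (no build_design).
oracle_design <- function(courses, j, parents) {
  y <- unlist(lapply(courses, function(cm) cm[2:nrow(cm), j]))
  B <- do.call(rbind, lapply(courses, function(cm)
    cm[1:(nrow(cm) - 1), parents, drop = FALSE]))
  list(y = y, B = B)
}

# Marginalized structure score evaluated term by term: explicit OLS via the
# pseudo-inverse of B'B, then the closed form with effective timepoint
# count n + 1.
oracle_loglik <- function(courses, j, parents) {
  d <- oracle_design(courses, j, parents)
  n <- length(d$y)
  teff <- n + 1
  yty <- sum(d$y^2)
  if (length(parents) == 0L) return(-(n / 2) * log(yty))
  BtB <- t(d$B) %*% d$B
  sv <- svd(BtB)
  keep <- sv$d > max(sv$d) * 1e-10
  pinv <- sv$v[, keep, drop = FALSE] %*%
    diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
  beta_hat <- pinv %*% (t(d$B) %*% d$y)
  yBb <- sum(d$y * (d$B %*% beta_hat))
  -(length(parents) / 2) * log(teff) - (n / 2) * log(yty - (n / teff) * yBb)
}

# Per-edge Bernoulli log-mass, summed one edge at a time.
oracle_logprior <- function(z, cvec, lam) {
  cvec <- unname(cvec)
  total <- 0
  for (i in seq_along(z)) {
    p_edge <- exp(-lam) / (exp(-cvec[i] * lam) + exp(-lam))
    total <- total + if (z[i] == 1) log(p_edge) else log(1 - p_edge)
  }
  total
}

all_subsets <- function(V) {
  lapply(0:(2^V - 1), function(code) which(bitwAnd(code, 2^(0:(V - 1))) > 0))
}

# Exact per-vertex posterior over all 2^V parent sets at fixed lambda.
# Returns the marginal probability of each candidate parent edge.
oracle_edge_posterior <- function(courses, conf, lam, j) {
  V <- ncol(conf)
  subsets <- all_subsets(V)
  logw <- vapply(subsets, function(pa) {
    z <- numeric(V); z[pa] <- 1
    oracle_loglik(courses, j, pa) + oracle_logprior(z, conf[, j], lam)
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  vapply(seq_len(V), function(i)
    sum(w[vapply(subsets, function(pa) i %in% pa, logical(1))]), numeric(1))
}

# Small linear-Gaussian instance with a binary corrupted prior; raw
# (unstandardized) data so enumeration oracles see exactly what the
# sampler sees when standardize = FALSE. Denser and stronger-signal than
# the benchmark generator so tiny-V posteriors are informative.
make_toy <- function(V = 3, T_len = 8, M = 4, r = 0, a = 0, seed = 42,
                     p_edge = 0.5, beta_sd = 1 / sqrt(V)) {
  set.seed(seed)
  A <- matrix(rbinom(V * V, 1, p_edge), V, V)
  beta <- matrix(0, V, V)
  if (sum(A) > 0) beta[A == 1] <- rnorm(sum(A), 0, beta_sd)
  data <- simulate_time_courses(A, beta, M = M, T_len = T_len)
  prior <- corrupt_graph(A, r, a)
  dimnames(A) <- list(data$variables, data$variables)
  list(A = A, beta = beta, data = data, prior = prior)
}

# Monte-Carlo band: 3 binomial standard errors at the sampler's own
# effective sample size, floored at 0.01 to guard near-degenerate edges.
mc_band <- function(p_hat, neff) {
  pmax(3 * sqrt(pmax(p_hat * (1 - p_hat), 0) / pmax(neff, 1)), 0.01)
}
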