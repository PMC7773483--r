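#' Sample a random sparse DBN (structure and weights)
#'
#' Each adjacency entry, diagonal included, is an independent
#' Bernoulli(5/V) trial, so vertices have five parents on average
#' regardless of problem size — roughly the sparsity expected of signaling
#' pathways. Edge weights are drawn from N(0, 1/V); this scale keeps the
#' simulated linear dynamics from diverging.
#'
#' @param V Number of vertices (>= 2).
#' @return List with binary adjacency \code{A} (parent rows, child columns)
#'   and weight matrix \code{beta} (0 off the edge set).
#' @export
sample_true_dbn <- function(V) {
  stopifnot(V >= 2)
  A <- matrix(stats::rbinom(V * V, 1L, min(1, 5 / V)), V, V)
  beta <- matrix(0, V, V)
  ne <- sum(A)
  if (ne > 0) beta[A == 1L] <- stats::rnorm(ne, 0, sqrt(1 / V))
  list(A = A, beta = beta)
}

#' Simulate time courses from a linear-Gaussian DBN
#'
#' Each course starts at \code{x_1 ~ N(0, I)} and evolves by
#' \code{x_{t+1, j} = sum_i beta[i, j] * x_{t, i} + e}, with independent
#' N(0, sigma_noise^2) innovations; courses are independent replicates.
#'
#' @param A Binary adjacency (only its weighted counterpart matters here).
#' @param beta Weight matrix, same shape as \code{A}.
#' @param M Number of courses (default 4, matching typical phosphoproteomic
#'   designs).
#' @param T_len Course length in timepoints (default 8).
#' @param sigma_noise Innovation standard deviation (default 1).
#' @return A \code{time_course_set} of M courses, each T_len x V.
#' @export
simulate_time_courses <- function(A, beta, M = 4, T_len = 8, sigma_noise = 1) {
  stopifnot(M >= 1, T_len >= 2, nrow(beta) == ncol(beta))
  V <- ncol(beta)
  courses <- lapply(seq_len(M), function(m) {
    x <- matrix(0, T_len, V)
    x[1L, ] <- stats::rnorm(V)
    for (t in seq_len(T_len - 1L)) {
      x[t + 1L, ] <- as.numeric(x[t, ] %*% beta) +
        stats::rnorm(V, 0, sigma_noise)
    }
    if (!all(is.finite(x))) stop("simulated trajectory diverged")
    x
  })
  time_course_set(courses)
}

#' Corrupt a true graph into imperfect prior knowledge
#'
#' Removes \code{round(r * |E0|)} uniformly chosen true edges and adds
#' \code{round(a * |E0|)} uniformly chosen spurious edges (drawn from the
#' non-edges, diagonal included), where |E0| is the original edge count.
#' \code{r} injects false negatives and \code{a} false positives into the
#' prior. Rounding is round-half-to-even. If fewer non-edges exist than
#' requested additions, all non-edges are added with a warning.
#'
#' @param A Binary adjacency matrix.
#' @param r Fraction of true edges removed, in [0, 1].
#' @param a Fraction of |E0| added as spurious edges, in [0, 1].
#' @return A binary \code{prior_confidences}.
#' @export
corrupt_graph <- function(A, r, a) {
  stopifnot(r >= 0, r <= 1, a >= 0, a <= 1)
  P <- A
  edges <- which(A == 1L)
  e0 <- length(edges)
  if (e0 > 0) {
    n_rm <- round(r * e0)
    if (n_rm > 0)
      P[edges[sample.int(e0, n_rm)]] <- 0L
    non_edges <- which(A == 0L)
    n_add <- round(a * e0)
    if (n_add > length(non_edges)) {
      warning(sprintf("requested %d spurious edges but only %d non-edges exist; adding all",
                      n_add, length(non_edges)))
      n_add <- length(non_edges)
    }
    if (n_add > 0)
      P[non_edges[sample.int(length(non_edges), n_add)]] <- 1L
  }
  prior_confidences(P, variables = paste0("v", seq_len(ncol(A))))
}

#' Generate one simulated benchmark instance
#'
#' Draws a sparse DBN, simulates its time courses and corrupts its
#' adjacency into a binary prior, bundling everything with its parameters.
#'
#' @param V Number of variables.
#' @param r,a Corruption parameters (see \code{\link{corrupt_graph}}).
#' @param M,T_len Course count and length.
#' @param replicate Replicate identifier recorded in the output.
#' @param seed Integer seed; fully determines the instance.
#' @param sigma_noise Innovation standard deviation.
#' @return A list of class \code{ssps_sim_instance}: \code{A}, \code{beta},
#'   \code{data}, \code{prior}, \code{params} (including the original edge
#'   count \code{e0}).
#' @export
simulate_instance <- function(V, r, a, M = 4, T_len = 8, replicate = 1L,
                              seed = 1L, sigma_noise = 1) {
  set.seed(as.integer(seed))
  net <- sample_true_dbn(V)
  data <- simulate_time_courses(net$A, net$beta, M = M, T_len = T_len,
                                sigma_noise = sigma_noise)
  prior <- corrupt_graph(net$A, r, a)
  dimnames(net$A) <- list(data$variables, data$variables)
  structure(list(
    A = net$A, beta = net$beta, data = data, prior = prior,
    params = list(V = V, r = r, a = a, M = M, T_len = T_len,
                  replicate = as.integer(replicate), seed = as.integer(seed),
                  e0 = sum(net$A))
  ), class = "ssps_sim_instance")
}

#' Generate the full simulation grid to disk
#'
#' The benchmark grid crosses problem sizes \code{V} in \{40, 100, 200\}
#' with prior-corruption levels \code{r} and \code{a} each in
#' \{0.1, 0.5, 0.75, 1.0\} — 48 distinct cells — and draws K = 5 replicates
#' per cell, 240 instances in all, each with M = 4 courses of length
#' T = 8. Every instance gets a deterministic seed derived from
#' \code{base_seed} and its position, and is written as four files
#' (data CSV, dense prior CSV, truth CSV, JSON parameter sidecar) tied
#' together by a manifest CSV.
#'
#' @param out_dir Output directory (created if needed).
#' @param base_seed Base integer seed.
#' @param V_values,r_values,a_values,K,M,T_len Grid levels; defaults are the
#'   benchmark's.
#' @return The manifest data frame, invisibly; also written to
#'   \code{manifest.csv} in \code{out_dir}.
#' @export
generate_grid <- function(out_dir, base_seed = 1L,
                          V_values = c(40L, 100L, 200L),
                          r_values = c(0.1, 0.5, 0.75, 1.0),
                          a_values = c(0.1, 0.5, 0.75, 1.0),
                          K = 5L, M = 4L, T_len = 8L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- expand.grid(V = V_values, r = r_values, a = a_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (k in seq_len(K)) {
      idx <- idx + 1L
      seed <- as.integer(base_seed) + idx
      V <- cells$V[ci]; r <- cells$r[ci]; a <- cells$a[ci]
      inst <- simulate_instance(V, r, a, M = M, T_len = T_len,
                                replicate = k, seed = seed)
      stem <- sprintf("V%d_r%s_a%s_rep%d", V, r, a, k)
      data_file <- file.path(out_dir, paste0(stem, "_data.csv"))
      prior_file <- file.path(out_dir, paste0(stem, "_prior.csv"))
      truth_file <- file.path(out_dir, paste0(stem, "_truth.csv"))
      params_file <- file.path(out_dir, paste0(stem, "_params.json"))
      write_time_courses(inst$data, data_file)
      write_prior(inst$prior, prior_file)
      utils::write.csv(inst$A, truth_file, row.names = TRUE)
      jsonlite::write_json(inst$params, params_file, auto_unbox = TRUE)
      rows[[idx]] <- data.frame(V = V, r = r, a = a, replicate = k,
                                seed = seed, e0 = inst$params$e0,
                                data = basename(data_file),
                                prior = basename(prior_file),
                                truth = basename(truth_file),
                                params = basename(params_file))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
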