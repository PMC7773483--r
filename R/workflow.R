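#' Assemble a run configuration
#'
#' Collects every tunable of an inference run into one list, optionally
#' seeded from a YAML file; arguments override file values which override
#' defaults.
#'
#' @param file Optional YAML file with any of the fields below.
#' @param chains Number of Markov chains.
#' @param max_iterations,max_hours Chain termination bounds.
#' @param burnin Fraction of each chain discarded.
#' @param xi Inverse-temperature proposal standard deviation.
#' @param lambda_min,lambda_max Inverse-temperature prior bounds.
#' @param seed Base RNG seed.
#' @param standardize Center/scale variables before inference.
#' @param allow_self_edges Keep lagged self-edges in the model.
#' @return A list of class \code{ssps_config}.
#' @export
ssps_config <- function(file = NULL, chains = 4L, max_iterations = 100000L,
                        max_hours = 12, burnin = 0.5, xi = 3,
                        lambda_min = 3, lambda_max = 15, seed = 1L,
                        standardize = TRUE, allow_self_edges = TRUE) {
  cfg <- list(chains = chains, max_iterations = max_iterations,
              max_hours = max_hours, burnin = burnin, xi = xi,
              lambda_min = lambda_min, lambda_max = lambda_max, seed = seed,
              standardize = standardize, allow_self_edges = allow_self_edges)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    supplied <- names(match.call())[-1L]
    for (nm in setdiff(names(from_file), supplied))
      cfg[[nm]] <- from_file[[nm]]
  }
  structure(cfg, class = "ssps_config")
}

config_pieces <- function(cfg) {
  list(
    model = model_config(lambda_min = cfg$lambda_min,
                         lambda_max = cfg$lambda_max,
                         standardize = cfg$standardize,
                         allow_self_edges = cfg$allow_self_edges),
    proposal = proposal_config(xi = cfg$xi),
    termination = termination_policy(max_iterations = cfg$max_iterations,
                                     max_wall_seconds = cfg$max_hours * 3600,
                                     n_chains = cfg$chains,
                                     burnin_fraction = cfg$burnin)
  )
}

#' Infer posterior edge probabilities from time-course data and a prior
#'
#' End-to-end inference: reads (or accepts) the data and prior, reconciles
#' variables by name, runs the Markov chains, and summarizes them into an
#' \code{ssps_edge_posterior}. When \code{out_dir} is given, writes
#' \code{edges.csv} (long-format posterior), \code{summary.json}
#' (config echo, acceptance rates, convergence counts) and
#' \code{manifest.json} (inputs, digests, seeds, version, per-chain
#' summaries — enough to reproduce the run).
#'
#' @param data A \code{time_course_set} or path to a time-course CSV.
#' @param prior A \code{prior_confidences} or path to a prior CSV.
#' @param config An \code{ssps_config}.
#' @param out_dir Optional output directory.
#' @param verbose Print per-chain progress.
#' @return The \code{ssps_edge_posterior}, with the run manifest attached
#'   as attribute \code{"manifest"}.
#' @export
ssps_infer <- function(data, prior, config = ssps_config(), out_dir = NULL,
                       verbose = FALSE) {
  data_path <- if (is.character(data)) data else NA_character_
  prior_path <- if (is.character(prior)) prior else NA_character_
  if (is.character(data)) data <- read_time_courses(data)
  if (is.character(prior)) prior <- read_prior(prior)
  prior <- align_prior(prior, data$variables)
  pieces <- config_pieces(config)
  traces <- run_chains(data, prior, pieces$model, pieces$proposal,
                       pieces$termination, n_chains = config$chains,
                       base_seed = config$seed, verbose = verbose)
  post <- edge_posterior(traces, burnin_fraction = config$burnin)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ssps")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = list(data = data_path, prior = prior_path,
                  n_variables = length(data$variables),
                  n_courses = length(data$courses)),
    chains = lapply(traces, function(tr)
      list(seed = tr$seed, iterations = tr$iterations,
           elapsed_seconds = tr$elapsed_seconds,
           accept_rates = as.list(ifelse(tr$attempts > 0,
                                         tr$accepts / tr$attempts, NA))))
  )
  attr(post, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_posterior(post, file.path(out_dir, "edges.csv"))
    summary_json <- list(
      config = unclass(config),
      n_chains = post$n_chains,
      retained_per_chain = post$n_retained_per_chain,
      accept_rates = as.list(ifelse(post$attempts > 0,
                                    post$accepts / post$attempts, NA)),
      n_edges_nonconverged = if (all(is.na(post$converged))) NA
                             else sum(!post$converged, na.rm = TRUE),
      n_lambda_nonconverged = if (all(is.na(post$lambda_summary$psrf))) NA
        else sum(!(post$lambda_summary$psrf < post$psrf_threshold &
                   post$lambda_summary$neff >= post$neff_threshold))
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  post
}

read_truth <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}

#' Benchmark inference against the prior baseline over simulated instances
#'
#' For each manifest row (optionally a subset), runs inference on the
#' instance's data and prior, scores the posterior edge probabilities
#' against the true graph by AUCPR, and scores the prior-knowledge baseline
#' — the prior confidences reported as predictions, with no inference — the
#' same way. Emits a long-format results table and per-cell paired
#' t-statistics of the method against the baseline. Instance failures are
#' recorded and the run continues.
#'
#' @param manifest Manifest data frame from \code{\link{generate_grid}}, or
#'   the path to a manifest CSV.
#' @param dir Directory holding the instance files (defaults to the
#'   manifest's directory when a path is given).
#' @param config An \code{ssps_config}.
#' @param rows Optional integer subset of manifest rows to run.
#' @param include_diagonal Passed to \code{\link{aucpr_of_prediction}}.
#' @param verbose Progress messages.
#' @return List with \code{results} (V, r, a, replicate, method, aucpr,
#'   error) and \code{t_stats} (V, r, a, t, K) data frames.
#' @export
ssps_benchmark <- function(manifest, dir = NULL, config = ssps_config(),
                           rows = NULL, include_diagonal = TRUE,
                           verbose = FALSE) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  if (is.null(dir)) dir <- "."
  if (is.null(rows)) rows <- seq_len(nrow(manifest))
  res <- list()
  for (ri in rows) {
    row <- manifest[ri, ]
    rec <- data.frame(V = row$V, r = row$r, a = row$a,
                      replicate = row$replicate,
                      method = c("ssps", "prior"),
                      aucpr = NA_real_, error = NA_character_)
    out <- tryCatch({
      truth <- read_truth(file.path(dir, row$truth))
      prior <- read_prior(file.path(dir, row$prior))
      cfg <- config
      cfg$seed <- config$seed + row$seed  # distinct chains per instance
      post <- ssps_infer(file.path(dir, row$data), prior, cfg)
      rec$aucpr[1L] <- aucpr_of_prediction(post$prob, truth,
                                           include_diagonal = include_diagonal)
      rec$aucpr[2L] <- aucpr_of_prediction(prior$conf, truth,
                                           include_diagonal = include_diagonal)
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
    if (verbose)
      message(sprintf("instance %d/%d: V=%s r=%s a=%s rep=%s aucpr=%.3f (prior %.3f)",
                      ri, nrow(manifest), row$V, row$r, row$a, row$replicate,
                      out$aucpr[1L], out$aucpr[2L]))
    res[[length(res) + 1L]] <- out
  }
  results <- do.call(rbind, res)
  t_stats <- benchmark_t_stats(results)
  list(results = results, t_stats = t_stats)
}

#' Per-cell paired t-statistics of a benchmark results table
#'
#' @param results Long-format results as produced by
#'   \code{\link{ssps_benchmark}}.
#' @return Data frame with one row per (V, r, a) cell: the paired
#'   t-statistic of the method's AUCPR against the prior baseline's, and
#'   the number of complete pairs K.
#' @export
benchmark_t_stats <- function(results) {
  ok <- results[is.na(results$error) & !is.na(results$aucpr), ]
  cells <- unique(ok[, c("V", "r", "a")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sub <- merge(
      ok[ok$method == "ssps" & ok$V == cells$V[ci] & ok$r == cells$r[ci] &
           ok$a == cells$a[ci], c("replicate", "aucpr")],
      ok[ok$method == "prior" & ok$V == cells$V[ci] & ok$r == cells$r[ci] &
           ok$a == cells$a[ci], c("replicate", "aucpr")],
      by = "replicate", suffixes = c("_ssps", "_prior"))
    if (nrow(sub) >= 2L) {
      out[[length(out) + 1L]] <- data.frame(
        V = cells$V[ci], r = cells$r[ci], a = cells$a[ci],
        t = paired_t_statistic(sub$aucpr_ssps, sub$aucpr_prior),
        K = nrow(sub))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(V = numeric(0), r = numeric(0), a = numeric(0),
                  t = numeric(0), K = integer(0))
}

#' Score a prediction file against a truth file
#'
#' Reads a long-format prediction CSV (parent, child, probability — the
#' \code{edges.csv} layout) or a dense matrix CSV, plus a dense truth CSV,
#' and returns AUCPR.
#'
#' @param prediction_file Prediction CSV path.
#' @param truth_file Dense truth CSV path.
#' @param include_diagonal Passed to \code{\link{aucpr_of_prediction}}.
#' @return List with \code{aucpr} and the aligned matrices.
#' @export
ssps_evaluate <- function(prediction_file, truth_file,
                          include_diagonal = TRUE) {
  truth <- read_truth(truth_file)
  head_names <- names(utils::read.csv(prediction_file, nrows = 1L,
                                      check.names = FALSE))
  if (all(c("parent", "child", "probability") %in% head_names)) {
    df <- utils::read.csv(prediction_file)
    vars <- rownames(truth)
    scores <- matrix(0, nrow(truth), ncol(truth),
                     dimnames = dimnames(truth))
    pi <- match(as.character(df$parent), vars)
    ci <- match(as.character(df$child), vars)
    if (anyNA(pi) || anyNA(ci))
      stop("prediction refers to variables absent from the truth file")
    scores[cbind(pi, ci)] <- df$probability
  } else {
    scores <- read_truth(prediction_file)
    scores <- scores[rownames(truth), rownames(truth)]
  }
  list(aucpr = aucpr_of_prediction(scores, truth,
                                   include_diagonal = include_diagonal),
       scores = scores, truth = truth)
}
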