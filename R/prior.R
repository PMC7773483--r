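#' Construct a matrix of prior edge confidences
#'
#' Entry (i, j) is the prior confidence, in [0, 1], that vertex i is a parent
#' of vertex j (i.e. that the lagged edge i -> j exists). Binary confidences
#' recover a hard reference-graph prior; intermediate values interpolate it.
#'
#' @param conf A square numeric matrix with entries in [0, 1].
#' @param variables Optional character vector of variable names; defaults to
#'   the matrix dimnames or \code{v1..vV}.
#' @return An object of class \code{prior_confidences}.
#' @export
prior_confidences <- function(conf, variables = NULL) {
  conf <- as.matrix(conf)
  storage.mode(conf) <- "double"
  if (nrow(conf) != ncol(conf)) stop("'conf' must be square")
  if (!all(is.finite(conf)) || any(conf < 0) || any(conf > 1))
    stop("prior confidences must be finite and in [0, 1]")
  V <- ncol(conf)
  if (is.null(variables)) {
    variables <- colnames(conf)
    if (is.null(variables)) variables <- paste0("v", seq_len(V))
  }
  variables <- as.character(variables)
  if (length(variables) != V) stop("length of 'variables' must match matrix size")
  dimnames(conf) <- list(variables, variables)
  structure(list(conf = conf, variables = variables),
            class = "prior_confidences")
}

#' @export
print.prior_confidences <- function(x, ...) {
  cat(sprintf("prior_confidences: %d variables, %d nonzero entries, sum %.3f\n",
              length(x$variables), sum(x$conf > 0), sum(x$conf)))
  invisible(x)
}

#' Reference parent-set sizes implied by the prior
#'
#' The reference size of vertex j is the column sum \eqn{\hat{s}_j = \sum_i
#' c_{ij}}: the prior's expected-scale parent count, used to center the
#' parent-set proposal's action probabilities.
#'
#' @param prior A \code{prior_confidences}.
#' @return Named numeric vector of column sums.
#' @export
reference_sizes <- function(prior) {
  colSums(prior$conf)
}

#' Read prior edge confidences from CSV
#'
#' Two layouts are accepted and auto-detected:
#' \itemize{
#'   \item a dense |V| x |V| table whose header names the child variables and
#'     whose first column names the parent variables;
#'   \item a 3-column edge list with header \code{parent, child, confidence};
#'     pairs not listed default to confidence 0.
#' }
#'
#' @param path Path to a CSV file.
#' @param variables For the edge-list layout, the full variable set (required
#'   if some variables appear in no edge). Ignored for dense input.
#' @return A \code{prior_confidences}.
#' @export
read_prior <- function(path, variables = NULL) {
  head_names <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  is_edge_list <- length(head_names) == 3L &&
    all(tolower(head_names) %in% c("parent", "child", "confidence"))
  if (is_edge_list) {
    df <- utils::read.csv(path, check.names = FALSE)
    names(df) <- tolower(names(df))
    if (is.null(variables))
      variables <- sort(unique(c(as.character(df$parent), as.character(df$child))))
    V <- length(variables)
    conf <- matrix(0, V, V, dimnames = list(variables, variables))
    pi <- match(as.character(df$parent), variables)
    ci <- match(as.character(df$child), variables)
    if (anyNA(pi) || anyNA(ci)) {
      bad <- unique(c(df$parent[is.na(pi)], df$child[is.na(ci)]))
      stop("edge list names not in 'variables': ", paste(bad, collapse = ", "))
    }
    conf[cbind(pi, ci)] <- df$confidence
    prior_confidences(conf, variables)
  } else {
    tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    conf <- as.matrix(tab)
    if (!setequal(rownames(conf), colnames(conf)))
      stop("dense prior must have identical row and column variable names")
    conf <- conf[colnames(conf), , drop = FALSE]  # align parent order to child order
    prior_confidences(conf, colnames(conf))
  }
}

#' Write prior confidences as a dense CSV
#'
#' @param prior A \code{prior_confidences}.
#' @param path Output file path.
#' @export
write_prior <- function(prior, path) {
  utils::write.csv(prior$conf, path, row.names = TRUE)
  invisible(path)
}
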