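#' Construct a set of time courses over shared variables
#'
#' A \code{time_course_set} holds one or more replicate time courses measured
#' over the same ordered set of variables. Each course is a numeric matrix
#' with one row per timepoint and one column per variable; all courses share
#' the same columns (same variables, same order) but may differ in length.
#'
#' @param courses A list of numeric matrices, each of shape T_m x |V| with
#'   T_m >= 2, or a single matrix (treated as one course).
#' @param variables Character vector of variable names. Defaults to the
#'   column names of the first course, or \code{v1..vV} when unnamed.
#' @return An object of class \code{time_course_set} with elements
#'   \code{variables} and \code{courses}.
#' @examples
#' x <- matrix(rnorm(24), nrow = 8, ncol = 3)
#' tc <- time_course_set(list(x, x))
#' n_variables(tc)
#' @export
time_course_set <- function(courses, variables = NULL) {
  if (is.matrix(courses)) courses <- list(courses)
  if (!is.list(courses) || length(courses) == 0L)
    stop("'courses' must be a non-empty list of matrices")
  courses <- lapply(courses, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  V <- ncol(courses[[1L]])
  if (is.null(variables)) {
    variables <- colnames(courses[[1L]])
    if (is.null(variables)) variables <- paste0("v", seq_len(V))
  }
  variables <- as.character(variables)
  if (length(variables) != V) stop("length of 'variables' must match column count")
  for (m in seq_along(courses)) {
    cm <- courses[[m]]
    if (ncol(cm) != V)
      stop(sprintf("course %d has %d columns; expected %d", m, ncol(cm), V))
    if (nrow(cm) < 2L)
      stop(sprintf("course %d has fewer than 2 timepoints", m))
    if (!all(is.finite(cm)))
      stop(sprintf("course %d contains non-finite values", m))
    dimnames(courses[[m]]) <- list(NULL, variables)
  }
  structure(list(variables = variables, courses = courses),
            class = "time_course_set")
}

#' @export
print.time_course_set <- function(x, ...) {
  lens <- vapply(x$courses, nrow, integer(1L))
  cat(sprintf("time_course_set: %d variables, %d course(s), lengths %s\n",
              length(x$variables), length(x$courses),
              paste(lens, collapse = ", ")))
  invisible(x)
}

#' @rdname time_course_set
#' @param x A \code{time_course_set}.
#' @export
n_variables <- function(x) length(x$variables)

#' Pool a time-course set into a single (replicate, timepoint) data frame
#'
#' @param x A \code{time_course_set}.
#' @return A data frame with columns \code{replicate}, \code{time}, then one
#'   column per variable.
#' @export
as.data.frame.time_course_set <- function(x, ...) {
  parts <- lapply(seq_along(x$courses), function(m) {
    cm <- x$courses[[m]]
    data.frame(replicate = m, time = seq_len(nrow(cm)), cm,
               check.names = FALSE)
  })
  do.call(rbind, parts)
}

#' Read time courses from delimited text
#'
#' Expects a header row with columns: a replicate identifier, a timepoint
#' index, then one column per variable. Rows are sorted by (replicate, time)
#' before courses are assembled, so file row order does not matter.
#'
#' @param path Path to a CSV file.
#' @return A \code{time_course_set}.
#' @export
read_time_courses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L)
    stop("time-course file needs replicate, time and at least one variable column")
  rep_col <- df[[1L]]
  time_col <- df[[2L]]
  if (!is.numeric(time_col))
    stop(sprintf("column 2 ('%s') must be a numeric timepoint index", names(df)[2L]))
  vars <- names(df)[-(1:2)]
  reps <- unique(rep_col)
  courses <- lapply(reps, function(r) {
    sub <- df[rep_col == r, , drop = FALSE]
    sub <- sub[order(sub[[2L]]), , drop = FALSE]
    as.matrix(sub[, vars, drop = FALSE])
  })
  time_course_set(courses, variables = vars)
}

#' Write time courses to CSV
#'
#' @param x A \code{time_course_set}.
#' @param path Output file path.
#' @export
write_time_courses <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Center and scale each variable across all pooled timepoints
#'
#' Each variable's pooled column (all courses stacked) is centered and, when
#' its pooled standard deviation is positive, scaled to unit variance.
#' Constant columns are centered only.
#'
#' @param x A \code{time_course_set}.
#' @return A standardized \code{time_course_set}.
#' @export
standardize_time_courses <- function(x) {
  pooled <- do.call(rbind, x$courses)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- 1
  courses <- lapply(x$courses, function(cm) sweep(sweep(cm, 2L, mu), 2L, sdv, "/"))
  time_course_set(courses, variables = x$variables)
}
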