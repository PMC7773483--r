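#' Parent-set proposal configuration
#'
#' @param xi Standard deviation of the Gaussian random-walk proposal for the
#'   inverse temperatures (default 3; the sampler is insensitive to it).
#' @param shat_clamp Bounds for the reference size \eqn{\hat{s}_j} as
#'   (lower count, upper fraction of |V|). The action-probability exponent
#'   \eqn{\gamma(\hat{s}) = 1 / \log_2(|V| / \hat{s})} needs
#'   \eqn{0 < \hat{s} < |V|}, so empty or overfull prior columns are clamped
#'   to \code{[1, |V|/2]} by default.
#' @param update_lambdas Set \code{FALSE} to freeze the inverse temperatures
#'   at their initial values (useful for validation against enumeration).
#' @return A list of class \code{ssps_proposal_config}.
#' @export
proposal_config <- function(xi = 3, shat_clamp = c(1, 0.5), update_lambdas = TRUE) {
  stopifnot(xi > 0, length(shat_clamp) == 2L, shat_clamp[1L] > 0,
            shat_clamp[2L] > 0, shat_clamp[2L] < 1)
  structure(list(xi = xi, shat_clamp = as.numeric(shat_clamp),
                 update_lambdas = isTRUE(update_lambdas)),
            class = "ssps_proposal_config")
}

clamp_shat <- function(shat, V, shat_clamp = c(1, 0.5)) {
  pmin(pmax(shat, shat_clamp[1L]), shat_clamp[2L] * V)
}

#' Action probabilities of the parent-set proposal
#'
#' With current parent count s, reference size \eqn{\hat{s}} and |V|
#' vertices, let \eqn{u = (s/|V|)^{\gamma(\hat{s})}} with
#' \eqn{\gamma(\hat{s}) = 1/\log_2(|V|/\hat{s})}. The unnormalized action
#' weights are \eqn{(1-u,\ u,\ 2u(1-u))} for (add, remove, swap), normalized
#' to sum to 1. These forms are chosen for their boundary behaviour: add is
#' certain at s = 0, remove is certain at s = |V|, and all three actions are
#' equally likely at \eqn{s = \hat{s}}, which biases exploration toward
#' parent sets near the prior-implied size.
#'
#' @param s Current parent-set size (0..V).
#' @param shat Reference size (clamped internally to \code{shat_clamp}).
#' @param V Vertex count (>= 2).
#' @param shat_clamp As in \code{\link{proposal_config}}.
#' @return Named probability vector \code{c(add, remove, swap)}.
#' @examples
#' action_probabilities(0, 5, 40)   # add is certain
#' action_probabilities(5, 5, 40)   # all equal
#' @export
action_probabilities <- function(s, shat, V, shat_clamp = c(1, 0.5)) {
  s <- unname(s); shat <- unname(shat); V <- unname(V)
  stopifnot(V >= 2, s >= 0, s <= V)
  shat <- clamp_shat(shat, V, shat_clamp)
  gam <- 1 / log2(V / shat)
  u <- (s / V)^gam
  w <- c(add = 1 - u, remove = u, swap = 2 * u * (1 - u))
  w / sum(w)
}

# Sampled parent-set move together with its forward and reverse log masses.
# Action masses: an action is drawn from action_probabilities (infeasible
# actions, i.e. an empty candidate or victim pool, get weight 0), then the
# edge(s) involved are drawn uniformly. The reverse mass is the probability
# of the inverse move evaluated at the candidate state: add <-> remove, and
# swap is its own inverse with identical mass.
propose_parent_move <- function(pa, j, shat_j, V, allow_self = TRUE) {
  pool <- if (allow_self) seq_len(V) else setdiff(seq_len(V), j)
  nonpa <- setdiff(pool, pa)
  s <- length(pa)
  p <- action_probabilities(s, shat_j, V)
  if (length(nonpa) == 0L) { p[c("add", "swap")] <- 0 }
  if (s == 0L) { p[c("remove", "swap")] <- 0 }
  p <- p / sum(p)
  act <- c("add", "remove", "swap")[sample.int(3L, 1L, prob = p)]

  rev_probs <- function(s2) {
    p2 <- action_probabilities(s2, shat_j, V)
    if (s2 == length(pool)) p2[c("add", "swap")] <- 0
    if (s2 == 0L) p2[c("remove", "swap")] <- 0
    p2 / sum(p2)
  }

  if (act == "add") {
    i_add <- nonpa[sample.int(length(nonpa), 1L)]
    cand <- c(pa, i_add)
    logq_fwd <- log(p[["add"]]) - log(length(nonpa))
    logq_rev <- log(rev_probs(s + 1L)[["remove"]]) - log(s + 1L)
    list(parents = cand, add = i_add, remove = NA_integer_,
         action = "add", logq_fwd = logq_fwd, logq_rev = logq_rev)
  } else if (act == "remove") {
    i_rem <- pa[sample.int(s, 1L)]
    cand <- setdiff(pa, i_rem)
    logq_fwd <- log(p[["remove"]]) - log(s)
    logq_rev <- log(rev_probs(s - 1L)[["add"]]) - log(length(nonpa) + 1L)
    list(parents = cand, add = NA_integer_, remove = i_rem,
         action = "remove", logq_fwd = logq_fwd, logq_rev = logq_rev)
  } else {
    i_rem <- pa[sample.int(s, 1L)]
    i_add <- nonpa[sample.int(length(nonpa), 1L)]
    cand <- c(setdiff(pa, i_rem), i_add)
    logq <- log(p[["swap"]]) - log(s) - log(length(nonpa))
    list(parents = cand, add = i_add, remove = i_rem,
         action = "swap", logq_fwd = logq, logq_rev = logq)
  }
}

#' Propose a parent-set update for one vertex
#'
#' Draws one add/remove/swap move for vertex j from the sparse parent-set
#' proposal and reports its forward and reverse transition log masses, as
#' needed by the Metropolis--Hastings ratio. Uses R's global RNG.
#'
#' @param state List with \code{parents} (list of integer vectors) and
#'   \code{lambdas}.
#' @param j Vertex index.
#' @param prior A \code{prior_confidences} (supplies the reference size).
#' @param config A \code{model_config} (self-edge switch).
#' @param proposal A \code{proposal_config} (reference-size clamp).
#' @return List with \code{parents} (candidate set), \code{action},
#'   \code{add}, \code{remove}, \code{logq_fwd}, \code{logq_rev}.
#' @export
propose_parent_update <- function(state, j, prior, config = model_config(),
                                  proposal = proposal_config()) {
  V <- length(prior$variables)
  shat <- clamp_shat(reference_sizes(prior)[j], V, proposal$shat_clamp)
  propose_parent_move(as.integer(state$parents[[j]]), j, shat, V,
                      allow_self = config$allow_self_edges)
}
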