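#' @title The joint belief grid and its update rules
#' @description
#' Beliefs about a partner are a discretized joint probability table over
#' harmful-intent (rows) and self-interest (columns) bins, `NB = 9` each.
#' Every public operation returns a grid whose cells are nonnegative and sum
#' to one within 1e-10.
#' @name belief-grid
NULL

NB_DEFAULT <- 9L

# additive floor in the consistency rule; fixed, not fitted
grid_xi <- function(nb) 0.02 / nb^2

new_belief_grid <- function(probs, nb = nrow(probs)) {
  stopifnot(is.matrix(probs), nrow(probs) == nb, ncol(probs) == nb)
  structure(list(probs = probs, nb = nb), class = "attr_belief_grid")
}

#' @export
print.attr_belief_grid <- function(x, ...) {
  cat("<belief grid>", x$nb, "x", x$nb, "joint p(HI, SI); sum =",
      format(sum(x$probs)), "\n")
  invisible(x)
}

normalize_grid <- function(g) {
  s <- sum(g$probs)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate-grid: belief mass vanished", call. = FALSE)
  }
  g$probs <- g$probs / s
  g
}

#' Discretized binomial prior marginal
#'
#' A binomial pmf with `NB - 1` trials evaluated at `k = bin - 1`, raised
#' elementwise to `1/u` and renormalized. `u = 1` recovers the plain
#' binomial; `u -> Inf` flattens towards uniform.
#'
#' @param p0 Prior magnitude in (0, 1) (location of the marginal).
#' @param u Positive uncertainty; larger values flatten the marginal.
#' @param nb Number of bins (default 9).
#' @return Length-`nb` probability vector.
#' @examples
#' discretized_binomial_prior(0.5, 1)   # symmetric around the central bin
#' discretized_binomial_prior(0.5, 1e6) # ~uniform
#' @export
discretized_binomial_prior <- function(p0, u, nb = NB_DEFAULT) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("invalid-parameter: p0 must be in (0, 1)", call. = FALSE)
  }
  if (!is.finite(u) || u <= 0) {
    stop("invalid-parameter: u must be positive", call. = FALSE)
  }
  lp <- dbinom(0:(nb - 1L), size = nb - 1L, prob = p0, log = TRUE) / u
  w <- exp(lp - max(lp))
  w / sum(w)
}

#' Joint prior belief grid
#'
#' Outer product of the harmful-intent and self-interest prior marginals.
#'
#' @param params An [attr_params()] object.
#' @param nb Number of bins per dimension.
#' @return A belief grid (class `attr_belief_grid`).
#' @export
build_joint_prior <- function(params, nb = NB_DEFAULT) {
  stopifnot(inherits(params, "attr_params"))
  hi <- discretized_binomial_prior(params$pHI0, params$uPri_HI, nb)
  si <- discretized_binomial_prior(params$pSI0, params$uPri_SI, nb)
  normalize_grid(new_belief_grid(outer(hi, si), nb))
}

#' Partner policy likelihood
#'
#' The participant's internal likelihood that a partner whose character sits
#' at grid cell (HI, SI) acts unfairly:
#' `pi_gen(rew = 0; HI, SI) = sigma(w0 + wHI (HI - delta) + wSI (SI - delta))`
#' with `delta = (NB + 1)/2` the grid centre and `sigma` the logistic
#' function; the fair slice is the exact complement.
#'
#' @param w0,wHI,wSI Finite likelihood weights.
#' @param nb Number of bins per dimension.
#' @return Object of class `attr_policy_lik`: list with `unfair` and `fair`
#'   `nb x nb` matrices (`unfair + fair == 1` cellwise, entries in (0, 1)),
#'   plus `delta`.
#' @export
build_policy_likelihood <- function(w0, wHI, wSI, nb = NB_DEFAULT) {
  if (any(!is.finite(c(w0, wHI, wSI)))) {
    stop("invalid-parameter: likelihood weights must be finite", call. = FALSE)
  }
  delta <- (nb + 1) / 2
  hi <- seq_len(nb) - delta
  si <- seq_len(nb) - delta
  unfair <- plogis(outer(wHI * hi, wSI * si, `+`) + w0)
  structure(list(unfair = unfair, fair = 1 - unfair, delta = delta, nb = nb),
            class = "attr_policy_lik")
}

lik_slice <- function(lik, outcome) {
  if (outcome == 0) lik$unfair else if (outcome == 0.5) lik$fair else
    stop("invalid-record: outcome must be 0 (unfair) or 0.5 (fair)", call. = FALSE)
}

#' Bayesian belief update after a partner action
#'
#' Elementwise product of the current grid with the likelihood slice for the
#' observed outcome, renormalized.
#'
#' @param grid A belief grid.
#' @param lik An `attr_policy_lik` from [build_policy_likelihood()].
#' @param outcome `0` (partner takes all, unfair) or `0.5` (fair split).
#' @return Updated belief grid.
#' @export
bayes_update <- function(grid, lik, outcome) {
  stopifnot(inherits(grid, "attr_belief_grid"))
  grid$probs <- grid$probs * lik_slice(lik, outcome)
  normalize_grid(grid)
}

#' Consistency scaling of the posterior
#'
#' Raises every cell to `1/u_pi`, adds the floor `xi = 0.02/NB^2` and
#' renormalizes. Larger `u_pi` weakens the impact of observed actions
#' (`u_pi -> Inf` drives the grid uniform).
#'
#' @param grid A belief grid.
#' @param u_pi Positive consistency noise.
#' @param xi Additive floor; fixed at `0.02/NB^2` (overridable for tests).
#' @return Scaled belief grid.
#' @export
apply_consistency <- function(grid, u_pi, xi = grid_xi(grid$nb)) {
  stopifnot(inherits(grid, "attr_belief_grid"))
  if (!is.finite(u_pi) || u_pi <= 0) {
    stop("invalid-parameter: u_pi must be positive", call. = FALSE)
  }
  grid$probs <- grid$probs^(1 / u_pi) + xi
  normalize_grid(grid)
}

#' Change-point blending between partners
#'
#' The belief carried into a new encounter is the convex mixture
#' `(1 - eta) * baseline prior + eta * final posterior about the previous
#' partner`. `eta = 0` resets fully; `eta = 1` carries the posterior over.
#'
#' @param prior Baseline prior belief grid (the `t = 0` joint prior).
#' @param posterior_final Grid after the previous partner's final action.
#' @param eta Blending weight in `[0, 1]`.
#' @return Blended belief grid.
#' @export
partner_change_blend <- function(prior, posterior_final, eta) {
  stopifnot(inherits(prior, "attr_belief_grid"),
            inherits(posterior_final, "attr_belief_grid"))
  if (!is.finite(eta) || eta < 0 || eta > 1) {
    stop("invalid-parameter: eta must lie in [0, 1]", call. = FALSE)
  }
  prior$probs <- prior$probs * (1 - eta) + posterior_final$probs * eta
  normalize_grid(prior)
}

#' Map a 1-100 rating onto a grid bin (and back)
#'
#' Equal-width bins: `bin = ceiling(rating * NB / 100)` clamped to
#' `[1, NB]`; the inverse returns the bin centre on the 1-100 scale.
#'
#' @param rating Integer rating(s) in 1..100.
#' @param nb Number of bins.
#' @return `rating_to_bin`: integer bin index in 1..`nb`.
#' @export
rating_to_bin <- function(rating, nb = NB_DEFAULT) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 100)) {
    stop("invalid-record: ratings must lie in 1..100", call. = FALSE)
  }
  pmin(pmax(as.integer(ceiling(rating * nb / 100)), 1L), nb)
}

#' @rdname rating_to_bin
#' @param bin Integer bin index in 1..`nb`.
#' @return `bin_to_rating`: the bin-centre rating (integer in 1..100).
#' @export
bin_to_rating <- function(bin, nb = NB_DEFAULT) {
  if (any(bin < 1) || any(bin > nb)) {
    stop("invalid-record: bin out of range", call. = FALSE)
  }
  as.integer(round((bin - 0.5) * 100 / nb))
}

#' Log-likelihood of a reported attribution pair
#'
#' Log of the joint cell mass at the reported (HI, SI) bin, floored at
#' 1e-12 to guard `log(0)`.
#'
#' @param grid A belief grid.
#' @param hi_bin,si_bin Bin indices in 1..`NB`.
#' @return Scalar log-probability.
#' @export
report_loglik <- function(grid, hi_bin, si_bin) {
  stopifnot(inherits(grid, "attr_belief_grid"))
  if (hi_bin < 1 || hi_bin > grid$nb || si_bin < 1 || si_bin > grid$nb) {
    stop("invalid-record: bin out of range", call. = FALSE)
  }
  log(max(grid$probs[hi_bin, si_bin], 1e-12))
}
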