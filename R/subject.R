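#' Run the generative model over one subject's trial sequence
#'
#' Replays the full per-trial cycle of the attribution model on observed
#' data: at each partner boundary the starting belief is the change-point
#' blend of the baseline prior and the final grid from the previous partner;
#' within a trial the observed outcome drives a Bayesian update, the
#' consistency rule is applied, and the two reported attributions are scored
#' on the resulting grid.
#'
#' @param trials Data frame with one row per trial for a single subject and
#'   condition, in presentation order, with columns `partner` (grouping id),
#'   `outcome` (0 unfair / 0.5 fair), `hi_rating`, `si_rating` (1..100).
#' @param params An [attr_params()] object.
#' @param nb Number of bins per dimension.
#' @param keep_grids Keep the per-trial grids (post-consistency)?
#' @return List with `loglik` (summed report log-likelihood), `grids`
#'   (list of belief grids, one per trial, if requested) and `trace`,
#'   a tibble of per-trial report log-likelihoods and expected attributions
#'   (grid-marginal means mapped back to the 1-100 scale).
#' @export
run_subject <- function(trials, params, nb = NB_DEFAULT, keep_grids = TRUE) {
  stopifnot(inherits(params, "attr_params"))
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0) {
    stop("invalid-input: empty trial list", call. = FALSE)
  }
  req <- c("partner", "outcome", "hi_rating", "si_rating")
  if (!all(req %in% names(trials))) {
    stop("invalid-input: trials must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  hi_bin <- rating_to_bin(trials$hi_rating, nb)
  si_bin <- rating_to_bin(trials$si_rating, nb)

  prior0 <- build_joint_prior(params, nb)
  lik <- build_policy_likelihood(params$w0, params$wHI, params$wSI, nb)
  centers <- bin_to_rating(seq_len(nb), nb)

  grid <- prior0
  grids <- if (keep_grids) vector("list", nrow(trials)) else NULL
  ll_t <- e_hi <- e_si <- numeric(nrow(trials))
  total <- 0
  for (t in seq_len(nrow(trials))) {
    if (t > 1L && trials$partner[t] != trials$partner[t - 1L]) {
      grid <- partner_change_blend(prior0, grid, params$eta)
    }
    grid <- bayes_update(grid, lik, trials$outcome[t])
    grid <- apply_consistency(grid, params$u_pi)
    ll_t[t] <- report_loglik(grid, hi_bin[t], si_bin[t])
    total <- total + ll_t[t]
    e_hi[t] <- sum(rowSums(grid$probs) * centers)
    e_si[t] <- sum(colSums(grid$probs) * centers)
    if (keep_grids) grids[[t]] <- grid
  }
  list(
    loglik = total,
    grids = grids,
    trace = tibble::tibble(
      partner = trials$partner, outcome = trials$outcome,
      report_loglik = ll_t, expected_hi = e_hi, expected_si = e_si
    )
  )
}

#' Simulate attribution reports from the model
#'
#' Plays the model forward over a fixed outcome sequence; after each
#' update-and-consistency step a (HI, SI) bin pair is sampled from the joint
#' grid and converted to 1-100 ratings via bin centres. Deterministic given
#' the seed.
#'
#' @param outcomes Data frame with columns `partner` and `outcome` in
#'   presentation order (one row per trial).
#' @param params An [attr_params()] object.
#' @param seed Integer seed for the report sampling.
#' @param nb Number of bins per dimension.
#' @return A tibble: `partner`, `trial` (within-partner index), `outcome`,
#'   `hi_rating`, `si_rating`.
#' @export
simulate_reports <- function(outcomes, params, seed = 1L, nb = NB_DEFAULT) {
  stopifnot(inherits(params, "attr_params"))
  outcomes <- as.data.frame(outcomes)
  stopifnot(all(c("partner", "outcome") %in% names(outcomes)))
  n <- nrow(outcomes)
  prior0 <- build_joint_prior(params, nb)
  lik <- build_policy_likelihood(params$w0, params$wHI, params$wSI, nb)
  centers <- bin_to_rating(seq_len(nb), nb)

  hi <- si <- integer(n)
  trial <- integer(n)
  grid <- prior0
  local_rng(seed, {
    for (t in seq_len(n)) {
      if (t > 1L && outcomes$partner[t] != outcomes$partner[t - 1L]) {
        grid <- partner_change_blend(prior0, grid, params$eta)
      }
      grid <- bayes_update(grid, lik, outcomes$outcome[t])
      grid <- apply_consistency(grid, params$u_pi)
      cell <- sample.int(nb * nb, 1L, prob = as.vector(grid$probs))
      # column-major: row (HI bin) varies fastest
      hi[t] <- ((cell - 1L) %% nb) + 1L
      si[t] <- ((cell - 1L) %/% nb) + 1L
      trial[t] <- if (t == 1L || outcomes$partner[t] != outcomes$partner[t - 1L])
        1L else trial[t - 1L] + 1L
    }
  })
  tibble::tibble(
    partner = outcomes$partner, trial = trial, outcome = outcomes$outcome,
    hi_rating = centers[hi], si_rating = centers[si]
  )
}
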