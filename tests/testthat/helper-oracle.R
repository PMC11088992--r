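# Independent straight-line re-implementation of the belief model, written
# directly from the update equations with no shared code: the oracle for
# the equivalence tests. Deliberately naive (explicit loops, no helpers).
oracle_subject <- function(pHI0, pSI0, uPriHI, uPriSI, w0, wHI, wSI, u_pi, eta,
                           partner, outcome, hi_bin, si_bin, nb = 9) {
  k <- 0:(nb - 1)
  mhi <- dbinom(k, nb - 1, pHI0)^(1 / uPriHI); mhi <- mhi / sum(mhi)
  msi <- dbinom(k, nb - 1, pSI0)^(1 / uPriSI); msi <- msi / sum(msi)
  prior <- outer(mhi, msi); prior <- prior / sum(prior)
  delta <- (nb + 1) / 2
  lik0 <- matrix(0, nb, nb)
  for (i in 1:nb) for (j in 1:nb) {
    lik0[i, j] <- 1 / (1 + exp(-(w0 + wHI * (i - delta) + wSI * (j - delta))))
  }
  xi <- 0.02 / nb^2
  g <- prior
  ll <- 0
  grids <- vector("list", length(outcome))
  for (t in seq_along(outcome)) {
    if (t > 1 && partner[t] != partner[t - 1]) {
      g <- prior * (1 - eta) + g * eta
      g <- g / sum(g)
    }
    slice <- if (outcome[t] == 0) lik0 else 1 - lik0
    g <- g * slice; g <- g / sum(g)
    g <- g^(1 / u_pi) + xi; g <- g / sum(g)
    ll <- ll + log(max(g[hi_bin[t], si_bin[t]], 1e-12))
    grids[[t]] <- g
  }
  list(loglik = ll, grids = grids)
}

# random model-space parameter draw in a plausible region (seeded by caller)
random_params <- function(variant = "M3") {
  u <- exp(runif(1, -0.7, 0.7))
  w <- runif(2, -0.2, 0.9)
  attr_params(
    pHI0 = runif(1, 0.1, 0.9), pSI0 = runif(1, 0.1, 0.9),
    uPri_HI = u, uPri_SI = u,
    w0 = runif(1, -2, 0.5),
    wHI = if (variant == "M2") w[1] else w[1],
    wSI = if (variant == "M2") w[1] else w[2],
    u_pi = exp(runif(1, -0.5, 0.7)), eta = runif(1, 0.05, 0.95),
    variant = variant
  )
}

# small trial table: 3 partners x n trials, alternating-ish outcomes
toy_trials <- function(n_per = 6, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      partner = rep(1:3, each = n_per),
      trial = rep(seq_len(n_per), 3),
      outcome = sample(c(0, 0.5), 3 * n_per, replace = TRUE),
      hi_rating = sample(1:100, 3 * n_per, replace = TRUE),
      si_rating = sample(1:100, 3 * n_per, replace = TRUE)
    )
  })
}

tiny_spec <- function(n = 8, conditions = "placebo") {
  cohort_spec(n_subjects = n, conditions = conditions)
}
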