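test_that("discretized binomial prior matches direct enumeration and limits", {
  # symmetric case: mean bin equals the grid centre delta = 5
  p <- discretized_binomial_prior(0.5, 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(p * 1:9), 5, tolerance = 1e-10)
  expect_equal(p, rev(p), tolerance = 1e-12)

  # huge uncertainty flattens to uniform
  p_flat <- discretized_binomial_prior(0.5, 1e6)
  expect_true(all(abs(p_flat - 1 / 9) < 1e-3))

  # direct 9-term enumeration oracle for p0 = 0.8, u = 2
  k <- 0:8
  pmf <- (choose(8, k) * 0.8^k * 0.2^(8 - k))^(1 / 2)
  expect_equal(discretized_binomial_prior(0.8, 2), pmf / sum(pmf),
               tolerance = 1e-12)

  expect_error(discretized_binomial_prior(0, 1), "invalid-parameter")
  expect_error(discretized_binomial_prior(0.5, -1), "invalid-parameter")
})

test_that("joint prior is the outer product of its marginals", {
  par <- attr_params(0.9, 0.1, 1, 1, 0, 0, 0, 1, 0.5, variant = "M1")
  g <- build_joint_prior(par)
  expect_equal(sum(g$probs), 1, tolerance = 1e-12)
  expect_equal(rowSums(g$probs), discretized_binomial_prior(0.9, 1),
               tolerance = 1e-12)
  expect_equal(colSums(g$probs), discretized_binomial_prior(0.1, 1),
               tolerance = 1e-12)
  # modal cell sits at the marginal modes
  mode_idx <- which(g$probs == max(g$probs), arr.ind = TRUE)
  expect_equal(unname(mode_idx[1, ]),
               c(which.max(discretized_binomial_prior(0.9, 1)),
                 which.max(discretized_binomial_prior(0.1, 1))))

  # uniform limit
  par_u <- attr_params(0.5, 0.5, 1e6, 1e6, 0, 0, 0, 1, 0.5, variant = "M3")
  expect_true(all(abs(build_joint_prior(par_u)$probs - 1 / 81) < 1e-3))
})

test_that("policy likelihood is the centred sigmoid with exact complement", {
  lik <- build_policy_likelihood(0, 0, 0)
  expect_true(all(lik$unfair == 0.5))
  lik2 <- build_policy_likelihood(0, 1, 0)
  expect_equal(lik2$unfair[9, 1], plogis(4), tolerance = 1e-12)
  expect_equal(lik2$unfair[1, 5], plogis(-4), tolerance = 1e-12)
  # complement holds cellwise, exactly
  lik3 <- build_policy_likelihood(-1.3, 0.4, 0.7)
  expect_identical(lik3$unfair + lik3$fair, matrix(1, 9, 9))
  expect_true(all(lik3$unfair > 0 & lik3$unfair < 1))
})

test_that("likelihood is monotone in wHI about the grid centre", {
  l_lo <- build_policy_likelihood(0.2, 0.3, 0.5)$unfair
  l_hi <- build_policy_likelihood(0.2, 0.6, 0.5)$unfair
  expect_true(all(l_hi[6:9, ] > l_lo[6:9, ]))
  expect_true(all(l_hi[1:4, ] < l_lo[1:4, ]))
  expect_equal(l_hi[5, ], l_lo[5, ], tolerance = 1e-12)
})

test_that("bayes update composes and respects uniform/constant identities", {
  par <- attr_params(0.3, 0.6, 1, 1, -1, 0.4, 0.6, 1, 0.5, variant = "M3")
  lik <- build_policy_likelihood(par$w0, par$wHI, par$wSI)
  uni <- attributr:::new_belief_grid(matrix(1 / 81, 9, 9))

  post <- bayes_update(uni, lik, 0)
  expect_equal(post$probs, lik$unfair / sum(lik$unfair), tolerance = 1e-12)

  # two sequential updates equal one update with the product slice
  g0 <- build_joint_prior(par)
  g12 <- bayes_update(bayes_update(g0, lik, 0), lik, 0.5)
  prod_slice <- lik$unfair * lik$fair
  manual <- g0$probs * prod_slice
  manual <- manual / sum(manual)
  expect_equal(g12$probs, manual, tolerance = 1e-12)

  # constant likelihood leaves the grid unchanged
  flat <- build_policy_likelihood(0, 0, 0)
  expect_equal(bayes_update(g0, flat, 0)$probs, g0$probs, tolerance = 1e-12)
})

test_that("consistency rule: power, floor, renormalize; uniform limit", {
  par <- attr_params(0.3, 0.6, 1, 1, -1, 0.4, 0.6, 1, 0.5, variant = "M3")
  g <- build_joint_prior(par)
  expect_true(all(abs(apply_consistency(g, 1e9)$probs - 1 / 81) < 1e-6))
  # exponent-1 identity with the floor zeroed via the test hook
  expect_equal(apply_consistency(g, 1, xi = 0)$probs, g$probs, tolerance = 1e-12)
  expect_error(apply_consistency(g, 0), "invalid-parameter")
  # hand enumeration: square root, floor, renormalize
  xi <- 0.02 / 81
  out <- apply_consistency(g, 2)
  expect_equal(out$probs,
               (sqrt(g$probs) + xi) / sum(sqrt(g$probs) + xi),
               tolerance = 1e-12)
})

test_that("partner change blend endpoints and midpoint", {
  par <- attr_params(0.3, 0.6, 1, 1, -1, 0.4, 0.6, 1, 0.5, variant = "M3")
  pr <- build_joint_prior(par)
  lik <- build_policy_likelihood(par$w0, par$wHI, par$wSI)
  po <- bayes_update(pr, lik, 0)
  expect_equal(partner_change_blend(pr, po, 0)$probs, pr$probs, tolerance = 1e-15)
  expect_equal(partner_change_blend(pr, po, 1)$probs, po$probs, tolerance = 1e-15)
  expect_equal(partner_change_blend(pr, po, 0.5)$probs,
               (pr$probs + po$probs) / 2, tolerance = 1e-12)
  expect_error(partner_change_blend(pr, po, 1.2), "invalid-parameter")
})

test_that("rating-bin map covers boundaries and round-trips bin centres", {
  expect_equal(rating_to_bin(1), 1L)
  expect_equal(rating_to_bin(100), 9L)
  expect_equal(rating_to_bin(50), 5L)  # ceil(4.5)
  expect_error(rating_to_bin(0), "invalid-record")
  expect_error(rating_to_bin(101), "invalid-record")
  for (b in 1:9) expect_equal(rating_to_bin(bin_to_rating(b)), b)
})

test_that("report log-likelihood reads the indexed cell with a floor", {
  uni <- attributr:::new_belief_grid(matrix(1 / 81, 9, 9))
  expect_equal(report_loglik(uni, 3, 7), log(1 / 81), tolerance = 1e-12)
  spike <- matrix(0, 9, 9); spike[5, 5] <- 1
  g <- attributr:::new_belief_grid(spike)
  expect_equal(report_loglik(g, 5, 5), 0, tolerance = 1e-12)
  expect_equal(report_loglik(g, 1, 1), log(1e-12), tolerance = 1e-12)
})

test_that("run_subject matches the independent brute-force oracle", {
  withr::with_seed(42, {
    for (rep in 1:6) {
      par <- random_params("M3")
      tr <- toy_trials(seed = rep)
      res <- run_subject(tr, par)
      orc <- oracle_subject(par$pHI0, par$pSI0, par$uPri_HI, par$uPri_SI,
                            par$w0, par$wHI, par$wSI, par$u_pi, par$eta,
                            tr$partner, tr$outcome,
                            rating_to_bin(tr$hi_rating),
                            rating_to_bin(tr$si_rating))
      expect_equal(res$loglik, orc$loglik, tolerance = 1e-12)
      expect_equal(res$grids[[18]]$probs, orc$grids[[18]], tolerance = 1e-12)
      # every returned grid normalized
      for (g in res$grids) expect_equal(sum(g$probs), 1, tolerance = 1e-10)
    }
  })
})

test_that("compiled likelihood agrees with the R path and the oracle", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      par <- random_params("M3")
      theta <- params_to_native(par)
      tr <- toy_trials(seed = 100 + rep)
      ll_cpp <- attributr:::cpp_subject_loglik(
        theta, "M3", tr$outcome, as.integer(tr$partner),
        rating_to_bin(tr$hi_rating), rating_to_bin(tr$si_rating), 9L)
      expect_equal(ll_cpp, run_subject(tr, par)$loglik, tolerance = 1e-10)
    }
  })
})

test_that("eta = 0 resets beliefs to the raw prior at each new partner", {
  par <- attr_params(0.3, 0.6, 1, 1, -1, 0.4, 0.6, 1, eta = 0, variant = "M3")
  tr <- toy_trials(seed = 3)
  res <- run_subject(tr, par)
  # first trial of partners 2 and 3 equals the first trial of partner 1
  # whenever the observed outcome matches (same prior, same update)
  for (t0 in c(7L, 13L)) {
    same <- which(tr$outcome[c(1, 7, 13)] == tr$outcome[t0])
    ref <- c(1L, 7L, 13L)[same[1]]
    expect_equal(res$grids[[t0]]$probs, res$grids[[ref]]$probs,
                 tolerance = 1e-12)
  }
})

test_that("simulated reports are seed-deterministic and track the prior", {
  par <- attr_params(0.3, 0.6, 1, 1, -1, 0.4, 0.6, 1, 0.5, variant = "M3")
  frame <- tibble::tibble(partner = rep(1:3, each = 6),
                          outcome = rep(c(0.5, 0, 0), each = 6))
  a <- simulate_reports(frame, par, seed = 9)
  b <- simulate_reports(frame, par, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$hi_rating >= 1 & a$hi_rating <= 100))

  # higher harmful-intent prior raises first-trial HI ratings (fair partner)
  frame1 <- tibble::tibble(partner = 1L, outcome = 0.5)
  mean_first <- function(p0, seeds) {
    par <- attr_params(p0, 0.5, 1, 1, -1, 0.2, 0.2, 1, 0.5, variant = "M3")
    mean(vapply(seeds, function(s) simulate_reports(frame1, par, seed = s)$hi_rating,
                numeric(1)))
  }
  hi <- mean_first(0.9, 1:400)
  lo <- mean_first(0.1, 1:400)
  expect_gt(hi, lo + 20)
})

test_that("parameter constraints of the model variants are enforced", {
  expect_error(attr_params(0.3, 0.6, 1, 2, 0, 0.1, 0.1, 1, 0.5, variant = "M3"),
               "uPri_HI == uPri_SI")
  expect_error(attr_params(0.3, 0.6, 1, 1, 0, 0.1, 0.4, 1, 0.5, variant = "M2"),
               "wHI == wSI")
  expect_error(attr_params(1.2, 0.6, 1, 1, 0, 0.1, 0.1, 1, 0.5, variant = "M1"),
               "invalid-parameter")
  expect_equal(length(param_names("M3")), 8L)
  expect_equal(length(param_names("M1")), 9L)
})

test_that("native transforms round-trip within 1e-9", {
  withr::with_seed(11, {
    for (variant in c("M1", "M2", "M3")) {
      theta <- rnorm(length(param_names(variant)), 0, 2)
      par <- native_to_params(theta, variant)
      back <- params_to_native(par)
      expect_equal(unname(back), theta, tolerance = 1e-9)
    }
  })
})
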