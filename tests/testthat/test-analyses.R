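make_paired <- function(d, n = 28, seed = 1) {
  withr::with_seed(seed, {
    base <- rnorm(n, 0, 1)
    tibble::tibble(
      subject = rep(seq_len(n), 2),
      condition = rep(c("A", "B"), each = n),
      value = c(base + d, base)
    )
  })
}

test_that("paired contrast recovers location shifts and respects symmetry", {
  # identical pairs: zero-variance differences are flagged as degenerate
  same <- make_paired(0)
  same$value[same$condition == "A"] <- same$value[same$condition == "B"]
  expect_error(bayesian_paired_contrast(same, value, condition, subject),
               "degenerate")

  # constant shift with small noise: median difference near the shift
  df <- make_paired(0.5, seed = 2)
  df$value <- df$value + rnorm(56, 0, 0.01)
  ct <- bayesian_paired_contrast(df, value, condition, subject,
                                 order = c("A", "B"), seed = 3)
  expect_equal(ct$median_diff, 0.5, tolerance = 0.02)
  expect_true(ct$hdi_lower < ct$median_diff & ct$median_diff < ct$hdi_upper)

  # antisymmetry under swapping conditions
  ct_rev <- bayesian_paired_contrast(df, value, condition, subject,
                                     order = c("B", "A"), seed = 3)
  # antisymmetry holds in distribution; allow Monte-Carlo error
  expect_equal(ct_rev$median_diff, -ct$median_diff, tolerance = 5e-3)
  expect_equal(ct_rev$hdi_lower, -ct$hdi_upper, tolerance = 5e-3)
})

test_that("paired contrast matches the closed-form Student-t posterior", {
  withr::with_seed(4, {
    d <- rnorm(28, 0.15, 0.3)
  })
  df <- tibble::tibble(subject = rep(1:28, 2),
                       condition = rep(c("A", "B"), each = 28),
                       value = c(d, rep(0, 28)))
  ct <- bayesian_paired_contrast(df, value, condition, subject,
                                 order = c("A", "B"), n_draws = 2e5, seed = 8)
  # under the Jeffreys prior, mu | d ~ dbar + (s/sqrt(n)) t_{n-1}
  n <- 28
  q <- mean(d) + sd(d) / sqrt(n) * qt(c(0.25, 0.5, 0.75), df = n - 1)
  emp <- quantile(ct$draws$mu, c(0.25, 0.5, 0.75))
  expect_equal(unname(emp), q, tolerance = 0.005)
})

test_that("attribution precision is inverse variance with degenerate flags", {
  d <- tibble::tibble(
    subject = 1, condition = "placebo",
    partner = rep(1:3, each = 6), policy = rep("fair", 18),
    trial = rep(1:6, 3),
    outcome = 0.5,
    hi_rating = rep(c(48, 52), 9),   # variance 4 (population denominator n-1 -> 4.06)
    si_rating = 50
  )
  p <- attribution_precision(d)
  hi <- p[p$dimension == "HI", ]
  expect_equal(hi$precision, 1 / var(rep(c(48, 52), 9)), tolerance = 1e-12)
  si <- p[p$dimension == "SI", ]
  expect_true(si$degenerate)
  expect_true(is.na(si$precision))
})

test_that("precision regression recovers exact structure and ranks AIC", {
  withr::with_seed(9, {
    n <- 120
    wHI <- rnorm(n); w0 <- rnorm(n)
    prec_lin <- 2 - 1.5 * wHI                      # exactly linear in wHI
    df <- tibble::tibble(subject = 1:n, condition = "c",
                         dimension = "HI", variance = 1,
                         degenerate = FALSE, n_trials = 18,
                         precision = prec_lin)
    par <- tibble::tibble(subject = 1:n, condition = "c", wHI = wHI, w0 = w0)
    fit <- precision_regression(df, par)
    co <- fit$coefficients
    # standardized slope of a noiseless linear relation is -1
    expect_equal(co$estimate[co$term == "wHI_z"], -1, tolerance = 1e-6)
    expect_gt(summary(fit$fit)$r.squared, 0.999)

    # quadratic-w0 truth prefers the quadratic variant by AIC
    prec_q <- 2 - 1.5 * wHI - 0.8 * w0^2 + rnorm(n, 0, 0.1)
    df$precision <- prec_q
    fit_q <- precision_regression(df, par)
    expect_lt(fit_q$aic_quadratic, fit_q$aic_linear)
  })
})

test_that("permuted likelihood weights lose the precision association", {
  withr::with_seed(31, {
    n <- 100
    wHI <- rnorm(n)
    df <- tibble::tibble(subject = 1:n, condition = "c", dimension = "HI",
                         variance = 1, degenerate = FALSE, n_trials = 18,
                         precision = 2 - 1.5 * wHI + rnorm(n, 0, 0.5))
    covered <- vapply(1:60, function(i) {
      par <- tibble::tibble(subject = 1:n, condition = "c",
                            wHI = sample(wHI), w0 = rnorm(n))
      co <- precision_regression(df, par)$coefficients
      row <- co[co$term == "wHI_z", ]
      row$conf_low <= 0 && 0 <= row$conf_high
    }, logical(1))
    expect_gt(mean(covered), 0.85)
  })
})

test_that("trial-wise coupling detects independence and built-in trade-offs", {
  withr::with_seed(12, {
    n <- 40
    mk <- function(anticorrelated) {
      purrr::map_dfr(1:n, function(s) {
        pol <- rep(c("fair", "partially_fair", "unfair"), each = 6)
        base <- c(fair = 30, partially_fair = 55, unfair = 75)[pol]
        hi <- pmin(pmax(round(base + rnorm(18, 0, 12)), 1), 100)
        si <- if (anticorrelated) {
          pmin(pmax(round(2 * base - hi + rnorm(18, 0, 3)), 1), 100)
        } else {
          pmin(pmax(round(base + rnorm(18, 0, 12)), 1), 100)
        }
        tibble::tibble(subject = s, condition = "x",
                       partner = rep(1:3, each = 6), policy = pol,
                       trial = rep(1:6, 3), outcome = 0,
                       hi_rating = hi, si_rating = si)
      })
    }
    indep <- trialwise_coupling(mk(FALSE))
    expect_true(all(abs(indep$series$rho) <= 1, na.rm = TRUE))
    expect_lt(abs(indep$decay$mean_rho), 0.12)

    anti <- trialwise_coupling(mk(TRUE))
    expect_lt(anti$decay$mean_rho, -0.5)
  })
})

test_that("factor analysis recovers planted two-factor structure", {
  withr::with_seed(13, {
    n <- 200
    f1 <- rnorm(n); f2 <- rnorm(n)
    x <- cbind(a1 = f1 + rnorm(n, 0, 0.3), a2 = f1 + rnorm(n, 0, 0.3),
               a3 = f1 + rnorm(n, 0, 0.3),
               b1 = f2 + rnorm(n, 0, 0.3), b2 = f2 + rnorm(n, 0, 0.3),
               b3 = f2 + rnorm(n, 0, 0.3))
    fa <- parameter_factor_analysis(tibble::as_tibble(x), n_factors = 2)
    expect_gt(fa$eigenvalues[1], 1.5)
    expect_gt(fa$eigenvalues[2], 1.5)
    expect_lt(fa$eigenvalues[3], 1)
    L <- abs(fa$loadings)
    # block structure up to factor permutation
    fa_of_a <- which.max(colMeans(L[1:3, ]))
    fa_of_b <- which.max(colMeans(L[4:6, ]))
    expect_true(fa_of_a != fa_of_b)
    expect_true(all(L[1:3, fa_of_a] > 0.7))
    expect_true(all(L[4:6, fa_of_b] > 0.7))
    expect_lt(fa$residual_rms, 0.05)

    # cross-check against maximum-likelihood factanal on the same data
    ml <- stats::factanal(x, factors = 2, rotation = "promax",
                          scores = "regression")
    mlL <- abs(unclass(ml$loadings))
    ml_a <- which.max(colMeans(mlL[1:3, ]))
    expect_equal(unname(L[1:3, fa_of_a]), unname(mlL[1:3, ml_a]),
                 tolerance = 0.08)

    # scores separate the planted factors
    sc <- as.matrix(fa$scores[, c("F1", "F2")])
    expect_gt(max(abs(cor(sc[, fa_of_a], f1)), abs(cor(sc[, fa_of_b], f1))), 0.9)
  })
})

test_that("factor analysis flags unusable inputs", {
  withr::with_seed(14, {
    x <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = 1)
    expect_error(parameter_factor_analysis(x, 1), "constant")
    dup <- tibble::tibble(a = rnorm(30))
    dup$b <- dup$a
    dup$c <- rnorm(30)
    # duplicated column: singular correlation matrix is flagged, loadings
    # still couple the duplicates on a common factor
    fa <- parameter_factor_analysis(dup, n_factors = 1)
    expect_true(fa$singular)
    expect_equal(fa$loadings["a", 1], fa$loadings["b", 1], tolerance = 0.02)
  })
})

test_that("cross-validated discrimination spans null and separable regimes", {
  withr::with_seed(15, {
    n <- 28
    null_scores <- tibble::tibble(
      subject = rep(1:n, 2), condition = rep(c("placebo", "halo"), each = n),
      F1 = rnorm(2 * n), F2 = rnorm(2 * n)
    )
    cv0 <- drug_discrimination_cv(null_scores, seed = 6)
    expect_lt(max(cv0$solutions$mean_accuracy), 0.72)
    expect_lt(cv0$auc, 0.75)

    sep_scores <- null_scores
    sep_scores$F1 <- sep_scores$F1 + ifelse(sep_scores$condition == "halo", 6, -6)
    cv1 <- drug_discrimination_cv(sep_scores, seed = 6)
    expect_gt(cv1$solutions$mean_accuracy[1], 0.95)
    expect_gt(cv1$auc, 0.99)
    expect_gt(cv1$sensitivity, 0.9)
    gl <- glance(cv1)
    expect_equal(gl$best_n_factors, cv1$best)
  })
})

test_that("moderately separated factor scores discriminate near the analytic rate", {
  # two classes shifted by d = 1.2 on one dimension: the Bayes accuracy is
  # pnorm(d/2) ~= 0.726; logistic CV should come within binomial error
  withr::with_seed(16, {
    accs <- vapply(1:8, function(i) {
      n <- 28
      sc <- tibble::tibble(
        subject = rep(1:n, 2),
        condition = rep(c("placebo", "halo"), each = n),
        F1 = rnorm(2 * n) + ifelse(rep(c(FALSE, TRUE), each = n), 1.2, 0)
      )
      drug_discrimination_cv(sc, seed = i)$solutions$mean_accuracy[1]
    }, numeric(1))
    expect_equal(mean(accs), pnorm(0.6), tolerance = 0.06)
  })
})
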