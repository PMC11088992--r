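#' Attribution precision (inverse variance of rating series)
#'
#' Precision (`1/sigma^2`) of each subject-condition's harmful-intent and
#' self-interest rating series, across all 18 trials and, optionally,
#' within each dictator policy. Zero-variance series are flagged, never
#' returned as infinite.
#'
#' @param data Long-format trial table (see [generate_cohort_dataset()]).
#' @param within_policy Also split by dictator policy?
#' @return Tibble: `subject`, `condition`, (`policy`,) `dimension`
#'   (`"HI"`/`"SI"`), `variance`, `precision`, `degenerate`.
#' @export
attribution_precision <- function(data, within_policy = FALSE) {
  groups <- c("subject", "condition", if (within_policy) "policy")
  groups <- intersect(groups, names(data))
  long <- data |>
    tidyr::pivot_longer(c("hi_rating", "si_rating"),
                        names_to = "dimension", values_to = "rating") |>
    dplyr::mutate(dimension = ifelse(.data$dimension == "hi_rating", "HI", "SI"))
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "dimension")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      variance = var(.data$rating),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$n_trials < 2 | .data$variance < 1e-12,
      precision = ifelse(.data$degenerate, NA_real_, 1 / .data$variance)
    )
}

#' Regression of attribution precision on likelihood weights
#'
#' Fits precision on `wHI` (linear) and `w0` (quadratic by default), their
#' interaction and, when precision is computed within policies, dictator
#' policy terms. All dependent regressors are centred and scaled. The
#' linear-`w0` variant is fitted alongside for AIC comparison.
#'
#' @param precision Output of [attribution_precision()] (degenerate rows are
#'   dropped), typically the `dimension == "HI"` rows.
#' @param params Tibble with `subject`, `condition` and columns `wHI`, `w0`
#'   (native space; identity-transformed parameters).
#' @param w0_form `"quadratic"` (default) or `"linear"`.
#' @return Object of class `attr_precision_reg`: coefficient tibble with
#'   95% CIs, the fitted `lm`s, and AIC for both `w0` variants.
#' @export
precision_regression <- function(precision, params,
                                 w0_form = c("quadratic", "linear")) {
  w0_form <- match.arg(w0_form)
  df <- dplyr::inner_join(
    dplyr::filter(precision, !.data$degenerate),
    params, by = intersect(c("subject", "condition"), names(params))
  )
  if (nrow(df) < 5) stop("invalid-input: too few usable records", call. = FALSE)
  df$precision_z <- as.numeric(scale(df$precision))
  df$wHI_z <- as.numeric(scale(df$wHI))
  df$w0_z <- as.numeric(scale(df$w0))
  df$w0_q <- as.numeric(scale(df$w0^2))
  has_policy <- "policy" %in% names(df) && length(unique(df$policy)) > 1

  form <- function(w0_term) {
    rhs <- c("wHI_z", w0_term, paste0("wHI_z:", w0_term),
             if (has_policy) "policy")
    stats::as.formula(paste("precision_z ~", paste(rhs, collapse = " + ")))
  }
  fit_q <- lm(form("w0_q"), data = df)
  fit_l <- lm(form("w0_z"), data = df)
  fit <- if (w0_form == "quadratic") fit_q else fit_l
  if (any(!is.finite(coef(fit)))) stop("rank-deficient precision regression", call. = FALSE)
  ci <- confint(fit)
  coefs <- tibble::tibble(
    term = names(coef(fit)),
    estimate = unname(coef(fit)),
    conf_low = ci[, 1],
    conf_high = ci[, 2]
  )
  structure(list(
    coefficients = coefs,
    fit = fit,
    aic_quadratic = AIC(fit_q),
    aic_linear = AIC(fit_l),
    w0_form = w0_form,
    n = nrow(df)
  ), class = "attr_precision_reg")
}

#' @export
print.attr_precision_reg <- function(x, ...) {
  cat("<attr_precision_reg>", x$w0_form, "w0 term; n =", x$n, "\n")
  print(as.data.frame(x$coefficients))
  cat(sprintf("AIC: quadratic w0 = %.1f, linear w0 = %.1f\n",
              x$aic_quadratic, x$aic_linear))
  invisible(x)
}
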