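#' Trial-wise attributional coupling
#'
#' At each trial index (1..18 in presentation order), the across-subject
#' partial correlation between harmful-intent and self-interest ratings,
#' controlling for the type of dictator policy (both series are residualized
#' on policy indicators; Spearman uses ranks before residualizing). Also
#' returns a decay statistic (Pearson correlation of the per-trial
#' coefficients with trial index) per condition, and, when two conditions
#' are present, a paired Bayesian contrast of the per-trial coefficients.
#'
#' @param data Long-format trial table.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param conditions Optional length-2 vector ordering the condition
#'   contrast (difference `conditions[1] - conditions[2]`).
#' @param seed Integer seed (for the contrast posterior).
#' @return Object of class `attr_coupling`: `series` (per condition x trial
#'   index coefficient), `decay` (per condition), `contrast` (or `NULL`).
#' @export
trialwise_coupling <- function(data, method = c("spearman", "pearson"),
                               conditions = NULL, seed = 1L) {
  method <- match.arg(method)
  df <- data |>
    dplyr::mutate(trial_index = (.data$partner - 1L) * max(.data$trial) + .data$trial)

  series <- df |>
    dplyr::group_by(.data$condition, .data$trial_index) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 3) return(tibble::tibble(rho = NA_real_, flagged = TRUE))
      hi <- g$hi_rating
      si <- g$si_rating
      if (method == "spearman") { hi <- rank(hi); si <- rank(si) }
      if (sd(hi) < 1e-12 || sd(si) < 1e-12) {
        return(tibble::tibble(rho = NA_real_, flagged = TRUE))
      }
      if (length(unique(g$policy)) > 1) {
        hi <- stats::resid(lm(hi ~ factor(g$policy)))
        si <- stats::resid(lm(si ~ factor(g$policy)))
      }
      if (sd(hi) < 1e-12 || sd(si) < 1e-12) {
        return(tibble::tibble(rho = NA_real_, flagged = TRUE))
      }
      tibble::tibble(rho = cor(hi, si), flagged = FALSE)
    }) |>
    dplyr::ungroup()

  decay <- series |>
    dplyr::filter(!.data$flagged) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_rho = mean(.data$rho),
      sd_rho = sd(.data$rho),
      decay_r = if (dplyr::n() > 2) cor(.data$rho, .data$trial_index) else NA_real_,
      .groups = "drop"
    )

  contrast <- NULL
  conds <- conditions %||% unique(series$condition)
  if (length(conds) >= 2) {
    conds <- conds[1:2]
    sub <- series |>
      dplyr::filter(.data$condition %in% conds, !.data$flagged)
    wide <- tidyr::pivot_wider(sub[, c("condition", "trial_index", "rho")],
                               names_from = "condition", values_from = "rho")
    d <- wide[[conds[1]]] - wide[[conds[2]]]
    d <- d[is.finite(d)]
    if (length(d) >= 3) {
      contrast <- paired_difference_posterior(d, seed = seed, labels = conds)
    }
  }

  structure(list(series = series, decay = decay, contrast = contrast,
                 method = method), class = "attr_coupling")
}

#' @export
print.attr_coupling <- function(x, ...) {
  cat("<attr_coupling> method =", x$method, "\n")
  print(as.data.frame(x$decay))
  if (!is.null(x$contrast)) print(x$contrast)
  invisible(x)
}
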