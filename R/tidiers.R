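#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @param model Variant whose group-level posterior to tabulate (default:
#'   highest-frequency model).
#' @export
tidy.attr_hbi_fit <- function(x, model = NULL, ...) {
  model <- model %||% x$models[which.max(x$freq)]
  g <- x$group[[model]]
  tibble::tibble(
    model = model,
    parameter = param_names(model),
    group_mean = unname(g$mean),
    group_sd = unname(g$sd)
  )
}

#' @rdname tidiers
#' @export
glance.attr_hbi_fit <- function(x, ...) {
  best <- which.max(x$freq)
  tibble::tibble(
    n_subjects = length(x$subjects),
    n_models = length(x$models),
    best_model = x$models[best],
    best_frequency = unname(x$freq[best]),
    best_exceedance = unname(x$exceedance[best]),
    iterations = nrow(x$iterations),
    converged = x$converged
  )
}

#' @rdname tidiers
#' @export
tidy.attr_contrast <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$labels, collapse = " - "),
    median_diff = x$median_diff,
    hdi_lower = x$hdi_lower, hdi_upper = x$hdi_upper,
    effect_size = x$effect_size,
    effect_hdi_lower = x$effect_hdi_lower,
    effect_hdi_upper = x$effect_hdi_upper,
    n = x$n
  )
}

#' @rdname tidiers
#' @param loading_filter Absolute loading below which entries are blanked
#'   (reporting convention; default 0.4). Use 0 to keep all.
#' @export
tidy.attr_factor <- function(x, loading_filter = 0.4, ...) {
  L <- x$loadings
  tibble::as_tibble(L, rownames = "parameter") |>
    tidyr::pivot_longer(-"parameter", names_to = "factor",
                        values_to = "loading") |>
    dplyr::mutate(loading = ifelse(abs(.data$loading) < loading_filter,
                                   NA_real_, .data$loading))
}

#' @rdname tidiers
#' @export
glance.attr_factor <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    eigenvalue = list(x$eigenvalues),
    residual_rms = x$residual_rms,
    singular = x$singular
  )
}

#' @rdname tidiers
#' @export
tidy.attr_recovery <- function(x, ...) x$parameter_r

#' @rdname tidiers
#' @export
glance.attr_recovery <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    min_parameter_r = min(x$parameter_r$r, na.rm = TRUE),
    min_generative_r = min(x$generative_r$r, na.rm = TRUE),
    n_subjects = length(unique(x$truth$subject)),
    n_conditions = length(unique(x$truth$condition))
  )
}

#' @rdname tidiers
#' @export
tidy.attr_cv <- function(x, ...) x$solutions

#' @rdname tidiers
#' @export
glance.attr_cv <- function(x, ...) {
  tibble::tibble(
    best_n_factors = x$best,
    best_accuracy = max(x$solutions$mean_accuracy),
    auc = x$auc,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @rdname tidiers
#' @export
tidy.attr_precision_reg <- function(x, ...) x$coefficients
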