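#' Plot methods
#'
#' ggplot2 visualisations of the package's result objects.
#'
#' @param object A result object.
#' @param ... Unused.
#' @name plots
NULL

#' Heatmap of a joint belief grid
#'
#' @param grid A belief grid.
#' @return A ggplot.
#' @export
plot_belief_grid <- function(grid) {
  stopifnot(inherits(grid, "attr_belief_grid"))
  df <- tibble::as_tibble(grid$probs, .name_repair = ~paste0("SI", seq_len(grid$nb))) |>
    dplyr::mutate(HI = seq_len(grid$nb)) |>
    tidyr::pivot_longer(-"HI", names_to = "SI", values_to = "p") |>
    dplyr::mutate(SI = as.integer(sub("SI", "", .data$SI)))
  ggplot2::ggplot(df, ggplot2::aes(.data$SI, .data$HI, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "p(HI, SI)") +
    ggplot2::labs(x = "self-interest bin", y = "harmful-intent bin") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.attr_hbi_fit <- function(object, ...) {
  df <- tibble::tibble(
    model = rep(object$models, 2),
    quantity = rep(c("frequency", "exceedance"), each = length(object$models)),
    value = c(unname(object$freq), unname(object$exceedance))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$value, fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = NULL, x = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.attr_contrast <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(.data$mu)) +
    ggplot2::geom_density(fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$hdi_lower, object$hdi_upper),
                        linetype = 3) +
    ggplot2::labs(x = sprintf("mean difference (%s - %s)",
                              object$labels[1], object$labels[2]),
                  y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.attr_coupling <- function(object, ...) {
  df <- dplyr::filter(object$series, !.data$flagged)
  ggplot2::ggplot(df, ggplot2::aes(.data$trial_index, .data$rho,
                                   colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trial", y = "HI-SI partial correlation") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.attr_factor <- function(object, ...) {
  df <- tidy.attr_factor(object, loading_filter = 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$parameter,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.attr_cv <- function(object, ...) {
  df <- tibble::tibble(
    specificity = rev(object$roc$specificities),
    sensitivity = rev(object$roc$sensitivities)
  )
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.attr_recovery <- function(object, ...) {
  nm <- param_names(object$variant)
  joined <- dplyr::inner_join(object$truth, object$recovered,
                              by = c("subject", "condition"),
                              suffix = c("_true", "_rec"))
  df <- purrr::map_dfr(nm, function(p) {
    tibble::tibble(parameter = p,
                   true = joined[[paste0(p, "_true")]],
                   recovered = joined[[paste0(p, "_rec")]])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$true, .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generative (native space)", y = "recovered") +
    ggplot2::theme_minimal()
}
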