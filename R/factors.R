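#' Exploratory factor analysis of parameter covariation
#'
#' Principal-axis factoring on the correlation matrix of standardized
#' parameter columns (communalities initialized at squared multiple
#' correlations and iterated), followed by oblique (promax) rotation.
#' Factor scores are computed by the regression method. Eigenvalues of the
#' correlation matrix are exposed for scree inspection; the |0.4| loading
#' filter is applied only at reporting ([tidy()]), never to the solution.
#'
#' @param params Data frame with one row per subject-condition and one
#'   column per parameter (id columns `subject`/`condition` are carried
#'   through to the scores).
#' @param n_factors Number of factors to extract.
#' @param max_iter,tol Communality iteration controls.
#' @return Object of class `attr_factor`: `loadings` (pattern matrix),
#'   `structure`, `phi` (factor correlations), `eigenvalues`, `communality`,
#'   `scores` tibble, `residual_rms` (off-diagonal RMS of the reproduced
#'   correlation residuals), `n_factors`.
#' @export
parameter_factor_analysis <- function(params, n_factors = 2L,
                                      max_iter = 200L, tol = 1e-6) {
  idc <- intersect(c("subject", "condition"), names(params))
  x <- as.matrix(params[, setdiff(names(params), idc), drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!complete.cases(x))) stop("invalid-input: incomplete parameter table", call. = FALSE)
  z <- scale(x)
  constant <- attr(z, "scaled:scale") < 1e-12
  if (any(constant)) {
    stop("invalid-input: constant parameter column(s): ",
         paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  }
  R <- cor(x)
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  singular <- is.null(Rinv)
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  p <- ncol(R)
  stopifnot(n_factors >= 1, n_factors < p)

  # principal-axis factoring: iterate communalities on the reduced matrix
  h2 <- if (singular) rep(0.5, p) else 1 - 1 / diag(Rinv)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(ev), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  rownames(L) <- colnames(R)
  # orient each factor so its largest loading is positive
  for (j in seq_len(n_factors)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }

  if (n_factors > 1) {
    rot <- stats::promax(L)
    pattern <- unclass(rot$loadings)
    phi <- solve(t(rot$rotmat) %*% rot$rotmat)
  } else {
    pattern <- L
    phi <- matrix(1, 1, 1)
  }
  colnames(pattern) <- paste0("F", seq_len(n_factors))
  dimnames(phi) <- list(colnames(pattern), colnames(pattern))
  struct <- pattern %*% phi
  Rhat <- pattern %*% phi %*% t(pattern)
  resid_rms <- sqrt(mean((R - Rhat)[lower.tri(R)]^2))

  scores_mat <- if (!singular) z %*% Rinv %*% struct else matrix(NA_real_, nrow(z), n_factors)
  colnames(scores_mat) <- colnames(pattern)
  scores <- dplyr::bind_cols(params[, idc, drop = FALSE],
                             tibble::as_tibble(scores_mat))

  structure(list(
    loadings = pattern, structure = struct, phi = phi,
    eigenvalues = eigenvalues, communality = h2,
    scores = scores, residual_rms = resid_rms,
    n_factors = n_factors, singular = singular
  ), class = "attr_factor")
}

#' @export
print.attr_factor <- function(x, ...) {
  cat("<attr_factor>", x$n_factors, "factors; eigenvalues:",
      paste(round(x$eigenvalues, 2), collapse = ", "), "\n")
  print(round(x$loadings, 2))
  invisible(x)
}

# stratified fold assignment: shuffled fold labels within each class
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated drug discrimination from factor scores
#'
#' Repeated stratified k-fold cross-validation of a logistic model
#' predicting condition from the first 1..K factor-score columns; reports
#' per-solution mean CV accuracy and full-data AIC, and for the
#' best-accuracy solution a ROC curve with AUC and Youden-point
#' sensitivity/specificity.
#'
#' @param scores Tibble from `parameter_factor_analysis()$scores` (columns
#'   `condition` and `F1`, `F2`, ...).
#' @param k Folds (default 10).
#' @param repeats Repeats (default 3).
#' @param positive Condition treated as the positive class (default: last
#'   level).
#' @param seed Integer seed.
#' @return Object of class `attr_cv`: `solutions` tibble (factors, mean/sd
#'   accuracy, AIC), `best` (factor count), `auc`, `sensitivity`,
#'   `specificity`, `roc` (a `pROC::roc` object).
#' @export
drug_discrimination_cv <- function(scores, k = 10L, repeats = 3L,
                                   positive = NULL, seed = 1L) {
  fcols <- grep("^F[0-9]+$", names(scores), value = TRUE)
  stopifnot(length(fcols) >= 1, "condition" %in% names(scores))
  y <- as.character(scores$condition)
  classes <- unique(y)
  stopifnot(length(classes) == 2)
  positive <- positive %||% classes[2]
  yb <- as.integer(y == positive)
  n <- length(yb)
  if (min(table(yb)) < k) k <- max(2L, min(table(yb)))

  res <- purrr::map_dfr(seq_along(fcols), function(j) {
    cols <- fcols[seq_len(j)]
    df <- data.frame(y = yb, scores[, cols, drop = FALSE])
    full <- glm(y ~ ., data = df, family = binomial())
    acc <- local_rng(seed_stream(seed, "cv", j), {
      unlist(lapply(seq_len(repeats), function(rep) {
        fold <- stratified_folds(yb, k)
        vapply(seq_len(k), function(f) {
          tr <- df[fold != f, , drop = FALSE]
          te <- df[fold == f, , drop = FALSE]
          if (length(unique(tr$y)) < 2 || nrow(te) == 0) return(NA_real_)
          m <- suppressWarnings(glm(y ~ ., data = tr, family = binomial()))
          p <- predict(m, newdata = te, type = "response")
          mean((p > 0.5) == te$y)
        }, numeric(1))
      }))
    })
    tibble::tibble(n_factors = j, mean_accuracy = mean(acc, na.rm = TRUE),
                   sd_accuracy = sd(acc, na.rm = TRUE), aic = AIC(full))
  })
  best <- res$n_factors[which.max(res$mean_accuracy)]
  df_best <- data.frame(y = yb, scores[, fcols[seq_len(best)], drop = FALSE])
  full <- glm(y ~ ., data = df_best, family = binomial())
  roc <- pROC::roc(response = yb, predictor = fitted(full),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  youden <- pROC::coords(roc, x = "best", best.method = "youden",
                         ret = c("sensitivity", "specificity"), transpose = FALSE)
  structure(list(
    solutions = res, best = best,
    auc = as.numeric(pROC::auc(roc)),
    sensitivity = youden$sensitivity[1],
    specificity = youden$specificity[1],
    roc = roc, positive = positive,
    full_fit = full
  ), class = "attr_cv")
}

#' @export
print.attr_cv <- function(x, ...) {
  cat("<attr_cv> best solution:", x$best, "factor(s)\n")
  print(as.data.frame(x$solutions))
  cat(sprintf("AUC = %.2f; sensitivity = %.2f; specificity = %.2f\n",
              x$auc, x$sensitivity, x$specificity))
  invisible(x)
}
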