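#' Read, write and validate long-format trial tables
#'
#' The on-disk schema is a plain CSV with columns `subject`, `condition`,
#' `partner`, `policy`, `trial`, `outcome`, `hi_rating`, `si_rating`.
#'
#' @param path File path.
#' @return `read_dataset`: a tibble.
#' @export
read_dataset <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_dataset
#' @param data A trial table.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Export a belief grid as a 9 x 9 CSV for inspection
#'
#' @param grid A belief grid.
#' @param path File path.
#' @export
write_belief_grid <- function(grid, path) {
  stopifnot(inherits(grid, "attr_belief_grid"))
  m <- as.data.frame(grid$probs)
  names(m) <- paste0("SI", seq_len(grid$nb))
  readr::write_csv(dplyr::bind_cols(tibble::tibble(HI = seq_len(grid$nb)), m),
                   path, progress = FALSE)
  invisible(path)
}

#' Validate a trial table against the task schema
#'
#' Checks column presence and types, rating bounds (1..100), the two-value
#' outcome set, and completeness (each subject-condition holds 3 partners
#' of `n_trials` trials each). Violations are collected with row pointers.
#'
#' @param data A trial table or a CSV path.
#' @param n_trials Expected trials per partner (default 6).
#' @return Invisibly, the validated tibble. Errors with a report listing
#'   each violation if the table is malformed.
#' @export
validate_dataset <- function(data, n_trials = 6L) {
  if (is.character(data)) data <- read_dataset(data)
  data <- tibble::as_tibble(data)
  req <- c("subject", "condition", "partner", "policy", "trial",
           "outcome", "hi_rating", "si_rating")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("schema mismatch: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  bad <- which(!data$outcome %in% c(0, 0.5))
  if (length(bad)) {
    problems <- c(problems, paste0("row ", head(bad, 5), ": outcome not in {0, 0.5}"))
  }
  for (col in c("hi_rating", "si_rating")) {
    v <- data[[col]]
    bad <- which(!is.finite(v) | v < 1 | v > 100)
    if (length(bad)) {
      problems <- c(problems, paste0("row ", head(bad, 5), ": ", col, " outside 1..100"))
    }
  }
  bad <- which(!data$policy %in% dictator_policies()$policy)
  if (length(bad)) {
    problems <- c(problems, paste0("row ", head(bad, 5), ": unknown policy"))
  }
  counts <- data |>
    dplyr::count(.data$subject, .data$condition, .data$partner)
  bad_blocks <- counts[counts$n != n_trials, , drop = FALSE]
  if (nrow(bad_blocks)) {
    problems <- c(problems, sprintf(
      "subject %s / condition %s: partner %s has %d trials (expected %d)",
      bad_blocks$subject, bad_blocks$condition, bad_blocks$partner,
      bad_blocks$n, n_trials))
  }
  n_partners <- data |>
    dplyr::distinct(.data$subject, .data$condition, .data$partner) |>
    dplyr::count(.data$subject, .data$condition)
  bad_sc <- n_partners[n_partners$n != 3L, , drop = FALSE]
  if (nrow(bad_sc)) {
    problems <- c(problems, sprintf(
      "subject %s / condition %s: %d partner block(s), expected 3",
      bad_sc$subject, bad_sc$condition, bad_sc$n))
  }
  if (length(problems)) {
    stop("dataset validation failed:\n  ",
         paste(head(problems, 20), collapse = "\n  "), call. = FALSE)
  }
  invisible(data)
}

#' Run the full pipeline: simulate, fit, recover, analyse
#'
#' Orchestrates the package end to end on a synthetic cohort: dataset
#' generation, per-condition hierarchical fits, parameter/generative
#' recovery, paired parameter contrasts, attribution precision with its
#' regression, trial-wise coupling, factor analysis and cross-validated
#' condition discrimination. Identical config and seed give identical
#' numeric payloads.
#'
#' @param config List with optional entries `seed` (default 1), `spec` (a
#'   [cohort_spec()]; default `cohort_spec()`), `variant` (default `"M3"`),
#'   `models` (candidate set for the comparison; default the generating
#'   variant), `contrast_order` (default `c("haloperidol", "placebo")`),
#'   `n_factors` (default 2), `n_starts` (default 10), `max_iter`, `tol`
#'   (EM controls).
#' @param out_dir Optional directory: artifacts (dataset CSV, fit/recovery/
#'   analysis JSON, config echo) are written there.
#' @return A bundle (list) with elements `config`, `data`, `truth`,
#'   `recovery`, `fits`, `contrasts`, `precision_reg`, `coupling`,
#'   `factors`, `cv`, `log`.
#' @export
run_end_to_end <- function(config = list(), out_dir = NULL) {
  seed <- config$seed %||% 1L
  spec <- config$spec %||% cohort_spec()
  variant <- config$variant %||% "M3"
  models <- config$models %||% variant
  n_factors <- config$n_factors %||% 2L
  n_starts <- config$n_starts %||% 10L
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(stage, t0) {
    log[[stage]] <<- tibble::tibble(stage = stage, seconds = tic() - t0)
  }

  t0 <- tic()
  rec <- recovery_study(spec, variant = variant, seed = seed,
                        models = models, n_starts = n_starts,
                        max_iter = config$max_iter %||% 50L,
                        tol = config$tol %||% 1e-3)
  stamp("simulate_fit_recover", t0)

  conds <- names(spec$conditions)
  params_long <- rec$recovered
  contrast_order <- config$contrast_order %||%
    intersect(c("haloperidol", "placebo"), conds)
  contrasts <- NULL
  if (length(contrast_order) == 2) {
    t0 <- tic()
    contrasts <- parameter_contrasts(params_long, order = contrast_order,
                                     seed = seed_stream(seed, "contrasts"))
    stamp("contrasts", t0)
  }

  t0 <- tic()
  prec <- attribution_precision(rec$data, within_policy = TRUE)
  prec_reg <- tryCatch({
    precision_regression(
      dplyr::filter(prec, .data$dimension == "HI"),
      dplyr::select(params_long, "subject", "condition", "wHI", "w0")
    )
  }, error = function(e) NULL)
  coupling <- trialwise_coupling(rec$data, conditions = contrast_order,
                                 seed = seed_stream(seed, "coupling"))
  stamp("analyses", t0)

  factors <- NULL
  cv <- NULL
  if (length(contrast_order) == 2) {
    t0 <- tic()
    fa_input <- dplyr::filter(params_long, .data$condition %in% contrast_order)
    factors <- parameter_factor_analysis(fa_input, n_factors = n_factors)
    cv <- drug_discrimination_cv(factors$scores,
                                 positive = contrast_order[1],
                                 seed = seed_stream(seed, "cv"))
    stamp("factors_cv", t0)
  }

  bundle <- list(
    config = list(seed = seed, variant = variant, models = models,
                  n_factors = n_factors,
                  conditions = conds,
                  n_subjects = spec$n_subjects,
                  single_model = length(models) == 1L),
    data = rec$data, truth = rec$truth, recovery = rec, fits = rec$fits,
    contrasts = contrasts, precision = prec, precision_reg = prec_reg,
    coupling = coupling, factors = factors, cv = cv,
    log = dplyr::bind_rows(log)
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(bundle$data, file.path(out_dir, "dataset.csv"))
  readr::write_csv(bundle$truth, file.path(out_dir, "truth.csv"), progress = FALSE)
  jsonlite::write_json(bundle$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- list(
    parameter_recovery = bundle$recovery$parameter_r,
    generative_recovery = bundle$recovery$generative_r,
    identification = bundle$recovery$identification,
    contrasts = bundle$contrasts,
    coupling_decay = bundle$coupling$decay,
    cv_solutions = if (!is.null(bundle$cv)) bundle$cv$solutions,
    auc = if (!is.null(bundle$cv)) bundle$cv$auc
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
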