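#' Dictator policies of the Sharing Game
#'
#' The three partner types: always take half (`fair`), a 50:50 chance to
#' take half or all (`partially_fair`), always take all (`unfair`).
#'
#' @return Tibble with columns `policy` and `p_unfair`.
#' @export
dictator_policies <- function() {
  tibble::tibble(
    policy = c("fair", "partially_fair", "unfair"),
    p_unfair = c(0, 0.5, 1)
  )
}

#' Generate a partner's outcome sequence
#'
#' @param policy One of `"fair"`, `"partially_fair"`, `"unfair"`.
#' @param n_trials Number of trials (default 6).
#' @param seed Integer seed (used by the partially fair policy).
#' @param balanced If `TRUE`, the partially fair partner deals a shuffled
#'   half-and-half sequence instead of independent Bernoulli(0.5) draws.
#' @return Numeric vector of outcomes: 0 (takes all) or 0.5 (fair split).
#' @export
generate_policy_sequence <- function(policy, n_trials = 6L, seed = 1L,
                                     balanced = FALSE) {
  stopifnot(n_trials >= 1)
  pol <- dictator_policies()
  if (!policy %in% pol$policy) {
    stop("invalid-policy: unknown policy '", policy, "'", call. = FALSE)
  }
  if (policy == "fair") return(rep(0.5, n_trials))
  if (policy == "unfair") return(rep(0, n_trials))
  local_rng(seed, {
    if (balanced) {
      base <- rep(c(0, 0.5), length.out = n_trials)
      sample(base)
    } else {
      sample(c(0, 0.5), n_trials, replace = TRUE)
    }
  })
}

# native-space preset means; uPri_HI == uPri_SI in the presets so every
# variant can be generated from them
preset_means <- function(label) {
  base <- c(pHI0 = qlogis(0.3), pSI0 = qlogis(0.6),
            uPri_HI = log(0.8), uPri_SI = log(0.8),
            w0 = -1, wHI = 0.45, wSI = 0.7,
            u_pi = log(1), eta = qlogis(0.4))
  switch(label,
    placebo = base,
    ldopa = base,
    haloperidol = {
      b <- base
      # directions from the reported drug contrasts: likelihood weight on
      # harmful intent up, intercept drawn towards zero, more carry-over
      b[["wHI"]] <- 0.55
      b[["w0"]] <- -0.4
      b[["eta"]] <- qlogis(0.55)
      b
    },
    stop("unknown preset '", label, "'", call. = FALSE)
  )
}

preset_sds <- function() {
  c(pHI0 = 0.7, pSI0 = 0.7, uPri_HI = 0.5, uPri_SI = 0.5,
    w0 = 0.8, wHI = 0.25, wSI = 0.25, u_pi = 0.5, eta = 0.7)
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort with the task's structure: `n_subjects` participants,
#' each playing 3 partners (one per dictator policy) for
#' `n_trials_per_partner` trials under each listed condition. Condition
#' presets give group-level native-space means and spreads; the
#' `haloperidol`-like preset shifts `wHI`, `w0` and `eta` relative to
#' `placebo`, mirroring the reported drug contrasts.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param n_trials_per_partner Trials per partner (default 6).
#' @param conditions Character vector of condition labels (any of
#'   `"placebo"`, `"haloperidol"`, `"ldopa"`) or a named list of
#'   `list(mean = <named native vector>, sd = <named native vector>)`.
#' @param balanced_partial Balanced half-and-half partially fair sequences?
#' @return Object of class `attr_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 28L, n_trials_per_partner = 6L,
                        conditions = c("placebo", "haloperidol", "ldopa"),
                        balanced_partial = FALSE) {
  stopifnot(n_subjects >= 2, n_trials_per_partner >= 1)
  if (is.character(conditions)) {
    conditions <- setNames(
      lapply(conditions, function(l) list(mean = preset_means(l), sd = preset_sds())),
      conditions
    )
  }
  stopifnot(is.list(conditions), length(conditions) >= 1, !is.null(names(conditions)))
  for (cc in conditions) {
    stopifnot(all(param_names_full() %in% names(cc$mean)),
              all(param_names_full() %in% names(cc$sd)),
              all(cc$sd >= 0))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_partner = as.integer(n_trials_per_partner),
                 conditions = conditions,
                 balanced_partial = isTRUE(balanced_partial)),
            class = "attr_cohort_spec")
}

#' Draw per-subject generative parameters for a cohort
#'
#' Native-space vectors are drawn from each condition's Gaussian preset and
#' reported in native space (the fitting space); [native_to_params()] maps
#' them to model space.
#'
#' @param spec An [cohort_spec()] object.
#' @param variant Model variant to generate from.
#' @param seed Integer seed.
#' @return Tibble: `subject`, `condition`, then one column per free
#'   parameter of `variant` (native space).
#' @export
sample_cohort_params <- function(spec, variant = "M3", seed = 1L) {
  stopifnot(inherits(spec, "attr_cohort_spec"))
  nm <- param_names(variant)
  # map variant free names onto the full preset names
  src <- ifelse(nm == "uPri", "uPri_HI", ifelse(nm == "w", "wHI", nm))
  rows <- purrr::imap(spec$conditions, function(cc, label) {
    s <- seed_stream(seed, paste0("params-", label))
    draws <- local_rng(s, {
      vapply(seq_along(nm), function(j) {
        rnorm(spec$n_subjects, cc$mean[[src[j]]], cc$sd[[src[j]]])
      }, numeric(spec$n_subjects))
    })
    draws <- matrix(draws, nrow = spec$n_subjects)
    colnames(draws) <- nm
    dplyr::bind_cols(
      tibble::tibble(subject = seq_len(spec$n_subjects), condition = label),
      tibble::as_tibble(draws)
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate a full synthetic cohort dataset
#'
#' For each subject and condition: a randomized partner order over the three
#' dictator policies, seeded policy sequences, and attribution reports
#' sampled from the generative model. Regenerating with the same seed gives
#' an identical dataset.
#'
#' @param spec An [cohort_spec()] object.
#' @param variant Model variant to generate from.
#' @param seed Integer seed.
#' @return List with `data` (long-format tibble: `subject`, `condition`,
#'   `partner` (presentation index 1..3), `policy`, `trial` (1..6),
#'   `outcome`, `hi_rating`, `si_rating`) and `truth` (the
#'   [sample_cohort_params()] table used to generate it).
#' @export
generate_cohort_dataset <- function(spec, variant = "M3", seed = 1L) {
  stopifnot(inherits(spec, "attr_cohort_spec"))
  truth <- sample_cohort_params(spec, variant, seed)
  policies <- dictator_policies()$policy
  nt <- spec$n_trials_per_partner
  nm <- param_names(variant)

  rows <- purrr::map(
    split(truth, seq_len(nrow(truth))),
    function(row) {
      sid <- row$subject
      cond <- row$condition
      theta <- as.numeric(row[nm])
      params <- native_to_params(theta, variant)
      s_order <- seed_stream(seed, paste0("order-", cond), sid)
      order_idx <- local_rng(s_order, sample.int(3L))
      ordered_policies <- policies[order_idx]
      outcome <- unlist(lapply(seq_along(ordered_policies), function(k) {
        generate_policy_sequence(
          ordered_policies[k], nt,
          seed = seed_stream(seed, paste0("policy-", cond, "-", k), sid),
          balanced = spec$balanced_partial
        )
      }))
      frame <- tibble::tibble(
        partner = rep(seq_len(3L), each = nt),
        policy = rep(ordered_policies, each = nt),
        outcome = outcome
      )
      reps <- simulate_reports(frame, params,
                               seed = seed_stream(seed, paste0("report-", cond), sid))
      tibble::tibble(
        subject = sid, condition = cond,
        partner = frame$partner, policy = frame$policy,
        trial = reps$trial, outcome = frame$outcome,
        hi_rating = reps$hi_rating, si_rating = reps$si_rating
      )
    }
  )
  list(data = dplyr::bind_rows(rows), truth = truth)
}
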