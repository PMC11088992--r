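#' @title Hierarchical random-effects fitting of the attribution model
#' @description
#' Per-subject MAP estimation in an unconstrained native space under a broad
#' Gaussian group prior (initially mean 0, sd 6.5), Laplace-approximated
#' model evidence, and an empirical-Bayes EM over group moments and model
#' frequencies with random-effects model comparison (responsibilities,
#' Dirichlet frequency counts, exceedance probabilities). Each drug
#' condition is fitted independently.
#' @name fitting
NULL

# pack one subject's ordered trials into the vectors the compiled
# likelihood consumes
pack_subject <- function(trials, nb = NB_DEFAULT) {
  list(outcome = as.numeric(trials$outcome),
       partner = as.integer(as.factor(trials$partner)),
       hi_bin = rating_to_bin(trials$hi_rating, nb),
       si_bin = rating_to_bin(trials$si_rating, nb))
}

subject_loglik_native <- function(theta, variant, packed, nb = NB_DEFAULT) {
  cpp_subject_loglik(theta, variant, packed$outcome, packed$partner,
                     packed$hi_bin, packed$si_bin, nb)
}

# central-difference Hessian of f at x (step fixed at 1e-4)
fd_hessian <- function(f, x, step = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d)
      ei[i] <- step; ej[j] <- step
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * step^2)
      }
    }
  }
  (H + t(H)) / 2
}

# regularize a symmetric matrix to positive definite: diagonal jitter
# first, eigenvalue clamping as a fallback (the report-likelihood floor can
# put a kink under the finite-difference stencil, leaving a saddle)
make_pd <- function(H, jitter0 = 1e-6, max_tries = 12) {
  jit <- jitter0
  H0 <- H
  for (k in seq_len(max_tries)) {
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (!is.null(ch)) return(list(H = H, chol = ch, ok = TRUE))
    H <- H + diag(jit, nrow(H))
    jit <- jit * 10
  }
  e <- tryCatch(eigen(H0, symmetric = TRUE), error = function(e) NULL)
  if (is.null(e) || any(!is.finite(e$values))) {
    return(list(H = H0, chol = NULL, ok = FALSE))
  }
  lam <- pmax(abs(e$values), 1e-6)
  H <- e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
  H <- (H + t(H)) / 2
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(list(H = H, chol = NULL, ok = FALSE))
  list(H = H, chol = ch, ok = TRUE)
}

#' Laplace approximation to the log model evidence
#'
#' `log Z ~= f(theta_MAP) + (d/2) log(2 pi) - (1/2) log det(-Hessian)`,
#' where `f` is the log joint (log-likelihood plus log-prior) at the MAP.
#'
#' @param objective_at_map Log joint density at the MAP.
#' @param neg_hessian Negative Hessian of the log joint at the MAP
#'   (positive definite after regularization); a 0 x 0 matrix means no free
#'   parameters, in which case the evidence equals the objective.
#' @return Scalar log evidence (flagged `NA` if the Hessian cannot be made
#'   positive definite).
#' @export
laplace_evidence <- function(objective_at_map, neg_hessian) {
  d <- nrow(neg_hessian) %||% 0
  if (is.null(neg_hessian) || d == 0) return(objective_at_map)
  pd <- make_pd(neg_hessian)
  if (!pd$ok) return(NA_real_)
  logdet <- 2 * sum(log(diag(pd$chol)))
  objective_at_map + (d / 2) * log(2 * pi) - 0.5 * logdet
}

#' MAP-fit one subject under one model variant
#'
#' Maximizes log-likelihood plus native-space Gaussian log-prior by
#' multi-start quasi-Newton (BFGS) optimization; returns the best mode, a
#' finite-difference negative Hessian regularized to positive definite, and
#' the Laplace log evidence.
#'
#' @param trials One subject's trials (see [run_subject()] for columns), in
#'   presentation order.
#' @param variant Model variant.
#' @param prior_mean,prior_sd Native-space group prior (vectors of length
#'   `length(param_names(variant))` or scalars; defaults 0 and 6.5).
#' @param n_starts Number of optimization starts (default 10).
#' @param seed Integer seed for the random starts.
#' @param start Optional warm-start native vector (replaces one start).
#' @param nb Grid bins.
#' @return List: `theta` (native MAP), `objective` (log joint at MAP),
#'   `loglik`, `neg_hessian`, `post_var` (diagonal of the Laplace posterior
#'   covariance), `evidence`, `converged`.
#' @export
map_fit_subject <- function(trials, variant = "M3",
                            prior_mean = 0, prior_sd = 6.5,
                            n_starts = 10L, seed = 1L, start = NULL,
                            nb = NB_DEFAULT) {
  if (nrow(trials) < 1) stop("invalid-input: no trials", call. = FALSE)
  nm <- param_names(variant)
  d <- length(nm)
  mu <- rep_len(prior_mean, d)
  sdv <- rep_len(prior_sd, d)
  if (any(sdv <= 0)) stop("invalid-parameter: prior sd must be positive", call. = FALSE)
  packed <- pack_subject(trials, nb)

  negobj <- function(theta) {
    -(subject_loglik_native(theta, variant, packed, nb) +
        sum(dnorm(theta, mu, sdv, log = TRUE)))
  }
  neggrad <- function(theta) {
    cpp_subject_negobj_grad(theta, variant, packed$outcome, packed$partner,
                            packed$hi_bin, packed$si_bin, mu, sdv, nb)
  }

  starts <- list(mu)
  if (!is.null(start)) starts <- c(starts, list(rep_len(start, d)))
  n_rand <- max(0L, n_starts - length(starts))
  if (n_rand > 0) {
    jit <- pmin(sdv, 1.5)
    rand <- local_rng(seed, {
      lapply(seq_len(n_rand), function(i) mu + rnorm(d) * jit)
    })
    starts <- c(starts, rand)
  }

  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negobj, gr = neggrad, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(theta = setNames(mu, nm), objective = NA_real_,
                loglik = NA_real_, neg_hessian = NULL, post_var = rep(NA_real_, d),
                evidence = NA_real_, converged = FALSE))
  }
  theta <- setNames(best$par, nm)
  H <- fd_hessian(negobj, best$par)
  pd <- make_pd(H)
  post_var <- if (pd$ok) diag(chol2inv(pd$chol)) else rep(NA_real_, d)
  obj <- -best$value
  list(theta = theta, objective = obj,
       loglik = subject_loglik_native(best$par, variant, packed, nb),
       neg_hessian = pd$H, post_var = post_var,
       evidence = laplace_evidence(obj, pd$H),
       converged = n_ok > 0L && pd$ok)
}

#' Monte-Carlo exceedance probabilities
#'
#' Probability that each model has the largest population frequency under a
#' Dirichlet posterior over frequencies; the protected variant mixes with
#' the null of equal frequencies.
#'
#' @param dirichlet_counts Positive Dirichlet counts, one per model.
#' @param protected Mix with the equal-frequency null?
#' @param null_weight Null mixture weight for the protected variant.
#' @param n_mc Monte-Carlo sample size.
#' @param seed Integer seed.
#' @return Named numeric vector of per-model probabilities (sums to 1).
#' @export
exceedance_probabilities <- function(dirichlet_counts, protected = FALSE,
                                     null_weight = 0.5, n_mc = 10000L,
                                     seed = 1L) {
  a <- dirichlet_counts
  stopifnot(all(a > 0))
  k <- length(a)
  if (k == 1L) return(setNames(1, names(a)))
  wins <- local_rng(seed, {
    g <- matrix(rgamma(n_mc * k, shape = rep(a, each = n_mc)), nrow = n_mc)
    tabulate(max.col(g, ties.method = "random"), nbins = k)
  })
  xp <- wins / n_mc
  if (protected) xp <- (1 - null_weight) * xp + null_weight / k
  setNames(xp, names(a))
}

#' Hierarchical random-effects fit and comparison
#'
#' Empirical-Bayes EM over one condition's subjects: (a) MAP-fit each
#' subject under each candidate model with the current group priors; (b)
#' model responsibilities proportional to model frequency times
#' exp(Laplace evidence); (c) responsibility-weighted group moments (the
#' variance update includes each subject's Laplace posterior variance); (d)
#' Dirichlet count update of model frequencies. Iterates until the largest
#' change in any group mean falls below `tol` or `max_iter` is reached.
#'
#' @param data Long-format trial table for a single condition (columns
#'   `subject`, `partner`, `trial`, `outcome`, `hi_rating`, `si_rating`).
#' @param models Character vector of candidate variants.
#' @param seed Integer seed.
#' @param n_starts Optimization starts for the first EM iteration
#'   (subsequent iterations warm-start at the previous MAP).
#' @param tol Convergence tolerance on group means.
#' @param max_iter Iteration cap.
#' @param alpha0 Dirichlet prior count per model.
#' @param nu0,sigma0 Normal-inverse-chi-squared hyperprior on each group
#'   variance: `nu0` pseudo-observations at scale `sigma0` (defaults 1 and
#'   6.5, the initial broad prior scale); keeps group variances from
#'   collapsing for weakly identified parameters.
#' @param nb Grid bins.
#' @return Object of class `attr_hbi_fit`: per-model group means/variances,
#'   model frequencies, (protected) exceedance probabilities, per-subject
#'   fits and responsibilities, iteration log and convergence flag.
#' @export
hbi_fit <- function(data, models = c("M1", "M2", "M3"), seed = 1L,
                    n_starts = 10L, tol = 1e-3, max_iter = 50L,
                    alpha0 = 1, nu0 = 1, sigma0 = 2, nb = NB_DEFAULT) {
  subjects <- unique(data$subject)
  if (length(subjects) < 2) stop("invalid-input: need >= 2 subjects", call. = FALSE)
  if (length(unique(data$condition %||% "one")) > 1) {
    stop("invalid-input: hbi_fit expects a single condition; fit each separately",
         call. = FALSE)
  }
  k <- length(models)
  trials_by_subject <- lapply(subjects, function(s) {
    tr <- data[data$subject == s, , drop = FALSE]
    tr[order(tr$partner, tr$trial), , drop = FALSE]
  })
  n <- length(subjects)

  group <- lapply(models, function(m) {
    d <- length(param_names(m))
    list(mean = rep(0, d), sd = rep(6.5, d))
  })
  names(group) <- models
  freq <- rep(1 / k, k)
  fits <- vector("list", k)
  names(fits) <- models
  resp <- matrix(1 / k, n, k)
  log_iter <- list()
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    old_means <- lapply(group, `[[`, "mean")
    ev <- matrix(NA_real_, n, k)
    for (mi in seq_len(k)) {
      m <- models[mi]
      fits[[m]] <- lapply(seq_len(n), function(i) {
        warm <- if (iter > 1L) fits[[m]][[i]]$theta else NULL
        ns <- if (iter > 1L) 3L else n_starts
        map_fit_subject(trials_by_subject[[i]], m,
                        prior_mean = group[[m]]$mean,
                        prior_sd = group[[m]]$sd,
                        n_starts = ns,
                        seed = seed_stream(seed, paste0("map-", m, "-", iter), i),
                        start = warm, nb = nb)
      })
      ev[, mi] <- vapply(fits[[m]], `[[`, numeric(1), "evidence")
    }
    usable <- apply(ev, 1, function(e) all(is.finite(e)))
    if (!any(usable)) stop("all subject fits failed", call. = FALSE)
    if (any(!usable)) {
      warning(sum(!usable), " subject(s) flagged non-converged; excluded from group updates")
    }
    # responsibilities (log domain)
    lw <- sweep(ev, 2, log(freq), `+`)
    lw <- lw - apply(lw, 1, max)
    w <- exp(lw)
    resp <- w / rowSums(w)
    resp[!usable, ] <- NA_real_

    for (mi in seq_len(k)) {
      m <- models[mi]
      r <- resp[usable, mi]
      if (sum(r) < 1e-8) next  # model effectively dead; keep previous prior
      th <- do.call(rbind, lapply(fits[[m]][usable], `[[`, "theta"))
      pv <- do.call(rbind, lapply(fits[[m]][usable], `[[`, "post_var"))
      pv[!is.finite(pv)] <- 0
      mu <- colSums(th * r) / sum(r)
      v <- (nu0 * sigma0^2 + colSums((sweep(th, 2, mu)^2 + pv) * r)) /
        (nu0 + sum(r))
      group[[m]]$mean <- mu
      group[[m]]$sd <- sqrt(pmax(v, 1e-4))
    }
    alpha <- alpha0 + colSums(resp[usable, , drop = FALSE])
    freq <- alpha / sum(alpha)

    delta <- max(unlist(Map(function(a, b) max(abs(a - b)),
                            old_means, lapply(group, `[[`, "mean"))))
    log_iter[[iter]] <- tibble::tibble(iter = iter, max_mean_change = delta,
                                       freq = list(setNames(freq, models)))
    if (iter > 1L && delta < tol) { converged <- TRUE; break }
  }

  # final polish cycle: full multi-start refit of every subject at the
  # converged group prior (removes residual warm-start mode noise from the
  # reported estimates), followed by one more E/M sweep so responsibilities,
  # group moments and frequencies are consistent with the polished fits
  for (mi in seq_len(k)) {
    m <- models[mi]
    fits[[m]] <- lapply(seq_len(n), function(i) {
      refit <- map_fit_subject(trials_by_subject[[i]], m,
                               prior_mean = group[[m]]$mean,
                               prior_sd = group[[m]]$sd,
                               n_starts = n_starts,
                               seed = seed_stream(seed, paste0("polish-", m), i),
                               start = fits[[m]][[i]]$theta, nb = nb)
      if (is.finite(refit$evidence)) refit else fits[[m]][[i]]
    })
    ev[, mi] <- vapply(fits[[m]], `[[`, numeric(1), "evidence")
  }
  usable <- apply(ev, 1, function(e) all(is.finite(e)))
  lw <- sweep(ev, 2, log(freq), `+`)
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  resp <- w / rowSums(w)
  resp[!usable, ] <- NA_real_
  for (mi in seq_len(k)) {
    m <- models[mi]
    r <- resp[usable, mi]
    if (sum(r) < 1e-8) next
    th <- do.call(rbind, lapply(fits[[m]][usable], `[[`, "theta"))
    pv <- do.call(rbind, lapply(fits[[m]][usable], `[[`, "post_var"))
    pv[!is.finite(pv)] <- 0
    mu <- colSums(th * r) / sum(r)
    v <- (nu0 * sigma0^2 + colSums((sweep(th, 2, mu)^2 + pv) * r)) /
      (nu0 + sum(r))
    group[[m]]$mean <- mu
    group[[m]]$sd <- sqrt(pmax(v, 1e-4))
  }
  alpha <- alpha0 + colSums(resp[usable, , drop = FALSE])
  freq <- alpha / sum(alpha)

  alpha <- alpha0 + colSums(resp[apply(resp, 1, function(x) all(is.finite(x))), ,
                                 drop = FALSE])
  names(alpha) <- models
  xp <- exceedance_probabilities(alpha, protected = FALSE,
                                 seed = seed_stream(seed, "xp"))
  pxp <- exceedance_probabilities(alpha, protected = TRUE,
                                  seed = seed_stream(seed, "pxp"))
  structure(list(
    models = models,
    group = group,
    freq = setNames(freq, models),
    alpha = alpha,
    exceedance = xp,
    protected_exceedance = pxp,
    responsibilities = {
      rownames(resp) <- subjects; colnames(resp) <- models; resp
    },
    subject_fits = fits,
    subjects = subjects,
    evidence = {
      rownames(ev) <- subjects; colnames(ev) <- models; ev
    },
    iterations = dplyr::bind_rows(log_iter),
    converged = converged,
    seed = seed
  ), class = "attr_hbi_fit")
}

#' @export
print.attr_hbi_fit <- function(x, ...) {
  cat("<attr_hbi_fit>", length(x$subjects), "subjects;",
      nrow(x$iterations), "EM iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("model frequencies:\n")
  print(round(x$freq, 3))
  cat("exceedance probabilities:\n")
  print(round(x$exceedance, 3))
  invisible(x)
}

#' Native-space MAP estimates from a hierarchical fit
#'
#' @param fit An `attr_hbi_fit`.
#' @param model Variant to extract (default: the highest-frequency model).
#' @return Tibble: `subject` plus one column per free parameter (native
#'   space).
#' @export
fitted_params <- function(fit, model = NULL) {
  stopifnot(inherits(fit, "attr_hbi_fit"))
  model <- model %||% fit$models[which.max(fit$freq)]
  th <- do.call(rbind, lapply(fit$subject_fits[[model]], `[[`, "theta"))
  dplyr::bind_cols(tibble::tibble(subject = fit$subjects),
                   tibble::as_tibble(th))
}
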