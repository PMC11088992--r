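#' Model parameters for the attribution model
#'
#' Bundles the free parameters of the joint harmful-intent / self-interest
#' belief model and enforces the constraints of the three candidate variants:
#' `M1` (separate prior uncertainties, separate likelihood weights), `M2`
#' (shared likelihood weight `wHI == wSI`), `M3` (shared prior uncertainty
#' `uPri_HI == uPri_SI`; the winning, 8-parameter variant).
#'
#' @param pHI0,pSI0 Prior magnitudes in (0, 1): the expected level of harmful
#'   intent / self-interest attributed before any action is observed.
#' @param uPri_HI,uPri_SI Positive prior uncertainties; larger values flatten
#'   the corresponding prior marginal.
#' @param w0 Likelihood intercept: log-odds of an unfair action at the centre
#'   of the belief grid.
#' @param wHI,wSI Likelihood weights: sensitivity of the unfair-action
#'   probability to the (centred) harmful-intent / self-interest bin.
#' @param u_pi Positive consistency noise; larger values damp the impact of
#'   each observed action on beliefs.
#' @param eta Change-point blending weight in `[0, 1]`: how much of the final
#'   belief about one partner is carried into the next encounter.
#' @param variant One of `"M1"`, `"M2"`, `"M3"`.
#'
#' @return An object of class `attr_params`: a named list of the nine
#'   model-space parameter values plus the variant label.
#' @examples
#' attr_params(pHI0 = 0.3, pSI0 = 0.6, uPri_HI = 3, uPri_SI = 3,
#'             w0 = -2, wHI = 0.3, wSI = 0.4, u_pi = 3, eta = 0.4,
#'             variant = "M3")
#' @export
attr_params <- function(pHI0, pSI0, uPri_HI, uPri_SI, w0, wHI, wSI,
                        u_pi, eta, variant = c("M3", "M1", "M2")) {
  variant <- match.arg(variant)
  vals <- c(pHI0 = pHI0, pSI0 = pSI0, uPri_HI = uPri_HI, uPri_SI = uPri_SI,
            w0 = w0, wHI = wHI, wSI = wSI, u_pi = u_pi, eta = eta)
  if (any(!is.finite(vals))) {
    stop("invalid-parameter: all parameter values must be finite", call. = FALSE)
  }
  if (pHI0 <= 0 || pHI0 >= 1 || pSI0 <= 0 || pSI0 >= 1) {
    stop("invalid-parameter: pHI0 and pSI0 must lie strictly in (0, 1)", call. = FALSE)
  }
  if (uPri_HI <= 0 || uPri_SI <= 0 || u_pi <= 0) {
    stop("invalid-parameter: uncertainties uPri and u_pi must be positive", call. = FALSE)
  }
  if (eta < 0 || eta > 1) {
    stop("invalid-parameter: eta must lie in [0, 1]", call. = FALSE)
  }
  if (variant == "M2" && !isTRUE(all.equal(wHI, wSI))) {
    stop("invalid-parameter: variant M2 requires wHI == wSI", call. = FALSE)
  }
  if (variant == "M3" && !isTRUE(all.equal(uPri_HI, uPri_SI))) {
    stop("invalid-parameter: variant M3 requires uPri_HI == uPri_SI", call. = FALSE)
  }
  structure(c(as.list(vals), list(variant = variant)), class = "attr_params")
}

#' @export
print.attr_params <- function(x, ...) {
  cat("<attr_params> variant", x$variant, "\n")
  v <- unlist(x[param_names_full()])
  print(round(v, 4))
  invisible(x)
}

# canonical order of the full (expanded) parameter set
param_names_full <- function() {
  c("pHI0", "pSI0", "uPri_HI", "uPri_SI", "w0", "wHI", "wSI", "u_pi", "eta")
}

#' Free-parameter names of a model variant
#'
#' @param variant `"M1"`, `"M2"` or `"M3"`.
#' @return Character vector of free parameter names in native-vector order
#'   (9 for M1, 8 for M2 and M3).
#' @export
param_names <- function(variant = c("M3", "M1", "M2")) {
  variant <- match.arg(variant)
  switch(variant,
    M1 = c("pHI0", "pSI0", "uPri_HI", "uPri_SI", "w0", "wHI", "wSI", "u_pi", "eta"),
    M2 = c("pHI0", "pSI0", "uPri_HI", "uPri_SI", "w0", "w", "u_pi", "eta"),
    M3 = c("pHI0", "pSI0", "uPri", "w0", "wHI", "wSI", "u_pi", "eta")
  )
}

# transform class per free parameter: "logit" (native -> plogis), "log"
# (native -> exp), "id"
param_transforms <- function(variant) {
  nm <- param_names(variant)
  tr <- c(pHI0 = "logit", pSI0 = "logit", uPri_HI = "log", uPri_SI = "log",
          uPri = "log", w0 = "id", wHI = "id", wSI = "id", w = "id",
          u_pi = "log", eta = "logit")
  tr[nm]
}

# numerical guards on the model-space scale; documented in the vignette
.P_EPS <- 1e-7
.U_MIN <- 1e-3
.U_MAX <- 1e6

native_to_model_value <- function(x, kind) {
  switch(kind,
    logit = pmin(pmax(plogis(x), .P_EPS), 1 - .P_EPS),
    log   = pmin(pmax(exp(x), .U_MIN), .U_MAX),
    id    = x
  )
}

model_to_native_value <- function(x, kind) {
  switch(kind,
    logit = qlogis(pmin(pmax(x, .P_EPS), 1 - .P_EPS)),
    log   = log(pmin(pmax(x, .U_MIN), .U_MAX)),
    id    = x
  )
}

#' Convert a native-space vector to model parameters
#'
#' Fitting is carried out in an unconstrained "native" space with broad
#' Gaussian priors (mean 0, sd 6.5); monotone maps take each coordinate to
#' its model-space domain: logistic for `pHI0`, `pSI0`, `eta`; exponential
#' for `uPri` and `u_pi`; identity for the likelihood weights.
#'
#' @param theta Named or unnamed numeric vector in native space, in
#'   [param_names()] order for `variant`.
#' @param variant Model variant label.
#' @return An [attr_params()] object.
#' @export
native_to_params <- function(theta, variant = c("M3", "M1", "M2")) {
  variant <- match.arg(variant)
  nm <- param_names(variant)
  stopifnot(length(theta) == length(nm))
  if (any(!is.finite(theta))) {
    stop("invalid-parameter: non-finite native value", call. = FALSE)
  }
  tr <- param_transforms(variant)
  m <- vapply(seq_along(nm), function(i) native_to_model_value(theta[[i]], tr[[i]]),
              numeric(1))
  names(m) <- nm
  full <- switch(variant,
    M1 = m,
    M2 = c(m[c("pHI0", "pSI0", "uPri_HI", "uPri_SI", "w0")],
           wHI = unname(m[["w"]]), wSI = unname(m[["w"]]),
           m[c("u_pi", "eta")]),
    M3 = c(m[c("pHI0", "pSI0")],
           uPri_HI = unname(m[["uPri"]]), uPri_SI = unname(m[["uPri"]]),
           m[c("w0", "wHI", "wSI", "u_pi", "eta")])
  )
  full <- full[param_names_full()]
  attr_params(full[["pHI0"]], full[["pSI0"]], full[["uPri_HI"]], full[["uPri_SI"]],
              full[["w0"]], full[["wHI"]], full[["wSI"]], full[["u_pi"]],
              full[["eta"]], variant = variant)
}

#' Convert model parameters to the native-space vector
#'
#' Inverse of [native_to_params()]; round-trips to within 1e-9.
#'
#' @param params An [attr_params()] object.
#' @return Named numeric vector in native space.
#' @export
params_to_native <- function(params) {
  stopifnot(inherits(params, "attr_params"))
  variant <- params$variant
  nm <- param_names(variant)
  tr <- param_transforms(variant)
  get_model <- function(name) {
    switch(name,
      uPri = params$uPri_HI,
      w    = params$wHI,
      params[[name]]
    )
  }
  theta <- vapply(seq_along(nm),
                  function(i) model_to_native_value(get_model(nm[[i]]), tr[[i]]),
                  numeric(1))
  names(theta) <- nm
  theta
}
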