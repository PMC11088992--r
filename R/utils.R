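# Seed plumbing: every stochastic routine takes an explicit integer seed and
# evaluates under a locally-set RNG state, restoring the caller's state after.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds, namespaced by stage label and index; kept
# strictly below 2^31 so they remain valid R integer seeds.
seed_stream <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 97L + 1L))
  val <- (as.double(seed) * 48271 + h * 9973 + as.double(index) * 7919) %% 2147483629
  as.integer(val) + 1L
}

# shortest interval containing `prob` posterior mass
hdi_interval <- function(samples, prob = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2) return(c(lower = NA_real_, upper = NA_real_))
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
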