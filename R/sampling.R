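#' Sample natural frequencies for a population
#'
#' Draws the natural frequencies of one oscillator ensemble from its
#' Lorentzian law, either as seeded i.i.d. Cauchy draws (`mode = "random"`,
#' the stochastic setting of the model) or as the deterministic
#' equal-probability quantiles `k/(N+1)`, `k = 1..N`, in ascending order
#' (`mode = "quantile"`, used for reproducible comparisons against the
#' mean-field reduction). Draws are never truncated -- the heavy Cauchy
#' tails are intrinsic to the exact mean-field closure -- but draws beyond
#' 200 Hz in magnitude are reported via a message.
#'
#' @param spec A [population_spec()].
#' @param mode `"random"` or `"quantile"`.
#' @return Numeric vector of length `n_oscillators`, in Hz.
#' @examples
#' sp <- population_spec("theta", 11, lorentz_spec(6, 0.5), seed = 1)
#' sample_natural_frequencies(sp, "quantile")[6] # median = center
#' @export
sample_natural_frequencies <- function(spec, mode = c("random", "quantile")) {
  stopifnot(inherits(spec, "population_spec"))
  mode <- match.arg(mode)
  law <- spec$frequency_law
  n <- spec$n_oscillators
  if (mode == "quantile") {
    f <- qcauchy(seq_len(n) / (n + 1), location = law$center_hz,
                 scale = law$half_width_hz)
  } else {
    f <- withr_seed(spec$seed, rcauchy(n, location = law$center_hz,
                                       scale = law$half_width_hz))
  }
  nx <- sum(abs(f) > 200)
  if (nx > 0)
    message(sprintf("population '%s': %d frequency draw(s) exceed 200 Hz in magnitude",
                    spec$name, nx))
  f
}

#' Sample uniform initial phases
#'
#' Seeded i.i.d. draws from the uniform distribution on `[0, 2*pi)`,
#' emulating the desynchronized pre-stimulus state in which every
#' oscillator starts at a different phase.
#'
#' @param n Number of phases (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n` in `[0, 2*pi)`.
#' @export
sample_initial_phases <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  withr_seed(seed, runif(n, 0, 2 * pi))
}

# Evaluate `expr` under a temporary RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
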