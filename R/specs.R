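#' Lorentzian (Cauchy) natural-frequency law
#'
#' Describes the distribution of natural frequencies within one population
#' of phase oscillators: a Lorentzian with peak `center_hz` and half-width
#' at half-maximum `half_width_hz`. The heavy tails of this law are what
#' make the exact mean-field (Ott-Antonsen) closure possible, so draws are
#' never truncated.
#'
#' @param center_hz Distribution peak, in Hz. Must be positive.
#' @param half_width_hz Half-width at half-maximum, in Hz. Must be positive.
#' @return An object of class `lorentz_spec`.
#' @examples
#' lorentz_spec(6, 0.5)
#' @export
lorentz_spec <- function(center_hz, half_width_hz) {
  stopifnot(is.numeric(center_hz), length(center_hz) == 1L, is.finite(center_hz),
            is.numeric(half_width_hz), length(half_width_hz) == 1L, is.finite(half_width_hz))
  if (center_hz <= 0) stop("`center_hz` must be > 0", call. = FALSE)
  if (half_width_hz <= 0) stop("`half_width_hz` must be > 0", call. = FALSE)
  structure(list(center_hz = center_hz, half_width_hz = half_width_hz),
            class = "lorentz_spec")
}

#' @export
print.lorentz_spec <- function(x, ...) {
  cat(sprintf("Lorentzian frequency law: center %g Hz, half-width %g Hz\n",
              x$center_hz, x$half_width_hz))
  invisible(x)
}

#' One brain area as an ensemble of phase oscillators
#'
#' @param name Population label (e.g. `"thalamus"`, `"theta"`, `"alpha"`).
#' @param n_oscillators Ensemble size (at least 2).
#' @param frequency_law A [lorentz_spec()] giving the natural-frequency
#'   distribution of the ensemble.
#' @param seed Integer seed governing the random frequency draw for this
#'   population.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec("theta", 1000, lorentz_spec(6, 0.5), seed = 1)
#' @export
population_spec <- function(name, n_oscillators, frequency_law, seed = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(frequency_law, "lorentz_spec"))
  n_oscillators <- as.integer(n_oscillators)
  if (is.na(n_oscillators) || n_oscillators < 2L)
    stop("`n_oscillators` must be an integer >= 2", call. = FALSE)
  structure(list(name = name, n_oscillators = n_oscillators,
                 frequency_law = frequency_law, seed = as.integer(seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Population '%s': %d oscillators, center %g Hz, half-width %g Hz (seed %d)\n",
              x$name, x$n_oscillators, x$frequency_law$center_hz,
              x$frequency_law$half_width_hz, x$seed))
  invisible(x)
}

#' External stimulus acting on the thalamic population
#'
#' A rectangular pulse of dimensionless intensity `intensity` entering the
#' thalamic phase equations as `I(t) * cos(phi)`. The pulse is active on the
#' half-open window `[onset_ms, onset_ms + duration_ms)`.
#'
#' @param intensity Stimulus intensity (>= 0).
#' @param onset_ms Onset time, ms.
#' @param duration_ms Duration, ms (>= 0).
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(100, 0, 50)
#' @export
stimulus_spec <- function(intensity = 100, onset_ms = 0, duration_ms = 50) {
  stopifnot(is.numeric(intensity), length(intensity) == 1L,
            is.numeric(onset_ms), length(onset_ms) == 1L,
            is.numeric(duration_ms), length(duration_ms) == 1L)
  if (intensity < 0) stop("`intensity` must be >= 0", call. = FALSE)
  if (duration_ms < 0) stop("`duration_ms` must be >= 0", call. = FALSE)
  structure(list(intensity = intensity, onset_ms = onset_ms,
                 duration_ms = duration_ms),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Stimulus: I = %g on [%g, %g) ms\n", x$intensity, x$onset_ms,
              x$onset_ms + x$duration_ms))
  invisible(x)
}

#' Thalamo-cortical network of oscillator populations
#'
#' One thalamic population reciprocally coupled to one or two cortical
#' populations through their complex mean fields. `k_thal_to_cortex` holds
#' the thalamus-to-cortex coupling strength for each cortical band and
#' `k_cortex_to_thal` the feedback coupling from that band to the thalamus.
#' There is no direct cortico-cortical coupling: the bands interact only
#' through the thalamus.
#'
#' @param thalamus A [population_spec()] for the thalamic relay population.
#' @param cortical A list of one or two [population_spec()]s for the
#'   cortical frequency bands.
#' @param k_thal_to_cortex Numeric vector (one entry per cortical band) of
#'   thalamus-to-cortex coupling strengths K_T, all >= 0.
#' @param k_cortex_to_thal Numeric vector (one entry per cortical band) of
#'   cortex-to-thalamus feedback strengths K_C, all >= 0.
#' @param stimulus A [stimulus_spec()] attached to the thalamic population.
#' @return An object of class `network_spec`.
#' @seealso [two_population_network()], [three_population_network()]
#' @export
network_spec <- function(thalamus, cortical, k_thal_to_cortex,
                         k_cortex_to_thal, stimulus = stimulus_spec()) {
  stopifnot(inherits(thalamus, "population_spec"), inherits(stimulus, "stimulus_spec"))
  if (inherits(cortical, "population_spec")) cortical <- list(cortical)
  stopifnot(is.list(cortical), length(cortical) %in% c(1L, 2L),
            all(vapply(cortical, inherits, TRUE, "population_spec")))
  nb <- length(cortical)
  k_thal_to_cortex <- as.numeric(k_thal_to_cortex)
  k_cortex_to_thal <- as.numeric(k_cortex_to_thal)
  if (length(k_thal_to_cortex) != nb || length(k_cortex_to_thal) != nb)
    stop("coupling vectors must have one entry per cortical population", call. = FALSE)
  if (any(k_thal_to_cortex < 0) || any(k_cortex_to_thal < 0))
    stop("coupling strengths must be >= 0", call. = FALSE)
  nm <- c(thalamus$name, vapply(cortical, `[[`, "", "name"))
  if (anyDuplicated(nm)) stop("population names must be unique", call. = FALSE)
  structure(list(thalamus = thalamus, cortical = cortical,
                 k_thal_to_cortex = k_thal_to_cortex,
                 k_cortex_to_thal = k_cortex_to_thal,
                 stimulus = stimulus),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Thalamo-cortical network\n")
  print(x$thalamus)
  for (i in seq_along(x$cortical)) {
    print(x$cortical[[i]])
    cat(sprintf("  K_T (thalamus -> %s) = %g, K_C (%s -> thalamus) = %g\n",
                x$cortical[[i]]$name, x$k_thal_to_cortex[i],
                x$cortical[[i]]$name, x$k_cortex_to_thal[i]))
  }
  print(x$stimulus)
  invisible(x)
}

#' Population names of a network, thalamus first
#' @param net A `network_spec`.
#' @return Character vector of population names.
#' @export
population_names <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  c(net$thalamus$name, vapply(net$cortical, `[[`, "", "name"))
}

#' Minimal two-population thalamus-theta network
#'
#' Convenience constructor for the minimal model: a thalamic relay
#' population coupled to a single cortical theta-band population. Defaults
#' follow the study conditions used throughout the package: 1000
#' oscillators per population, theta center 6 Hz (half-width 1.5 Hz),
#' thalamic center 9.25 Hz (half-width 1.25 Hz), stimulus I = 100 for
#' 50 ms from t = 0. At these values the reduced system has a subcritical
#' regime: a fold of limit cycles below the Hopf point, a bistable window
#' between them, and a sustained synchronized state of amplitude ~0.6 at
#' K_T = 16, K_C = 1.2.
#'
#' @param k_tc Thalamus-to-cortex coupling K_T.
#' @param k_ct Cortex-to-thalamus feedback K_C.
#' @param n Oscillators per population.
#' @param f_thal,f_theta Population center frequencies, Hz.
#' @param w_thal,w_theta Population half-widths, Hz.
#' @param stimulus A [stimulus_spec()].
#' @param seed Base integer seed; the two populations draw frequencies from
#'   `seed` and `seed + 1`.
#' @return A `network_spec`.
#' @examples
#' net <- two_population_network(k_tc = 16, k_ct = 1.2)
#' @export
two_population_network <- function(k_tc, k_ct, n = 1000,
                                   f_thal = 9.25, f_theta = 6,
                                   w_thal = 1.25, w_theta = 1.5,
                                   stimulus = stimulus_spec(100, 0, 50),
                                   seed = 1L) {
  network_spec(
    thalamus = population_spec("thalamus", n, lorentz_spec(f_thal, w_thal),
                               seed = seed),
    cortical = list(population_spec("theta", n, lorentz_spec(f_theta, w_theta),
                                    seed = seed + 1L)),
    k_thal_to_cortex = k_tc, k_cortex_to_thal = k_ct, stimulus = stimulus)
}

#' Three-population thalamus-theta-alpha network
#'
#' The extended model: a thalamic relay population coupled to a theta-band
#' and an alpha-band cortical population (no direct cortico-cortical
#' connection). Coupling vectors are ordered (theta, alpha).
#'
#' @param k_tc Length-2 vector of thalamus-to-cortex couplings
#'   (theta, alpha). The defaults are the fixed driving couplings used in
#'   the feedback-plane scans; at these values the (K_C theta, K_C alpha)
#'   plane contains cells matching both the healthy and the patient
#'   synchronization targets.
#' @param k_ct Length-2 vector of cortex-to-thalamus feedbacks
#'   (theta, alpha).
#' @param n Oscillators per population.
#' @param f_thal,f_theta,f_alpha Center frequencies, Hz.
#' @param w_thal,w_theta,w_alpha Half-widths, Hz.
#' @param stimulus A [stimulus_spec()].
#' @param seed Base integer seed; populations draw from `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return A `network_spec`.
#' @examples
#' net <- three_population_network(k_ct = c(2, 2))
#' @export
three_population_network <- function(k_tc = c(1.35, 1.7), k_ct, n = 1000,
                                     f_thal = 9, f_theta = 6, f_alpha = 10,
                                     w_thal = 2, w_theta = 0.3, w_alpha = 1.25,
                                     stimulus = stimulus_spec(100, 0, 50),
                                     seed = 1L) {
  stopifnot(length(k_tc) == 2L, length(k_ct) == 2L)
  network_spec(
    thalamus = population_spec("thalamus", n, lorentz_spec(f_thal, w_thal),
                               seed = seed),
    cortical = list(
      population_spec("theta", n, lorentz_spec(f_theta, w_theta), seed = seed + 1L),
      population_spec("alpha", n, lorentz_spec(f_alpha, w_alpha), seed = seed + 2L)),
    k_thal_to_cortex = k_tc, k_cortex_to_thal = k_ct, stimulus = stimulus)
}
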