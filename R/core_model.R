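#' Stimulus value at a time point
#'
#' Rectangular pulse: returns `intensity` on the half-open window
#' `[onset_ms, onset_ms + duration_ms)` and 0 elsewhere. Vectorized over
#' `t_ms`.
#'
#' @param t_ms Time(s), ms.
#' @param s A [stimulus_spec()].
#' @return Numeric vector of stimulus values.
#' @examples
#' stimulus_value(c(-10, 25, 50), stimulus_spec(100, 0, 50)) # 0 100 0
#' @export
stimulus_value <- function(t_ms, s) {
  stopifnot(inherits(s, "stimulus_spec"))
  ifelse(t_ms >= s$onset_ms & t_ms < s$onset_ms + s$duration_ms, s$intensity, 0)
}

#' Complex mean field of a phase ensemble
#'
#' The order parameter `Y = R * exp(i * Theta)` of a set of phases: the
#' complex average of `exp(i * phi_k)`. `R` in `[0, 1]` measures the degree
#' of synchrony and `Theta` the collective phase.
#'
#' @param phases Numeric vector of phases (radians), non-empty.
#' @return An object of class `mean_field`: a list with elements
#'   `amplitude`, `phase` and the complex `value`.
#' @examples
#' mean_field(c(0, pi / 2))$amplitude # sqrt(2)/2
#' @export
mean_field <- function(phases) {
  if (length(phases) == 0L) stop("`phases` must be non-empty", call. = FALSE)
  z <- mean(exp(1i * phases))
  structure(list(amplitude = Mod(z), phase = Arg(z), value = z),
            class = "mean_field")
}

#' @export
print.mean_field <- function(x, ...) {
  cat(sprintf("Mean field: R = %.4f, Theta = %.4f rad\n", x$amplitude, x$phase))
  invisible(x)
}

#' Right-hand side of the full N-oscillator model
#'
#' Instantaneous phase velocities of every oscillator. Each cortical
#' oscillator in band b obeys
#' `dphi/dt = omega + K_T(b) * R_T * sin(Theta_T - phi)` and each thalamic
#' oscillator
#' `dphi/dt = omega + sum_b K_C(b) * R_b * sin(Theta_b - phi) + I(t) * cos(phi)`,
#' where `(R_a, Theta_a)` are the population mean fields of the current
#' state and all rates are converted from the Hz scale to rad/ms.
#'
#' @param phases Named list of phase vectors, thalamus first, matching
#'   `population_names(net)`.
#' @param t_ms Time, ms (for the stimulus).
#' @param net A [network_spec()].
#' @param freqs Named list of natural-frequency vectors (Hz), same shape as
#'   `phases`.
#' @return Named list of derivative vectors, rad/ms.
#' @export
full_rhs <- function(phases, t_ms, net, freqs) {
  stopifnot(inherits(net, "network_spec"), is.list(phases), is.list(freqs))
  nm <- population_names(net)
  sizes <- c(net$thalamus$n_oscillators,
             vapply(net$cortical, `[[`, 1L, "n_oscillators"))
  if (length(phases) != length(nm) || length(freqs) != length(nm))
    stop("`phases` and `freqs` must have one vector per population", call. = FALSE)
  for (a in seq_along(nm)) {
    if (length(phases[[a]]) != sizes[a] || length(freqs[[a]]) != sizes[a])
      stop(sprintf("population '%s': expected %d oscillators", nm[a], sizes[a]),
           call. = FALSE)
  }
  Y <- lapply(phases, function(p) mean_field(p)$value)
  It <- stimulus_value(t_ms, net$stimulus)
  nb <- length(net$cortical)
  d <- vector("list", nb + 1L)
  names(d) <- nm
  coup_T <- 0
  for (b in seq_len(nb)) {
    Yb <- Y[[b + 1L]]
    coup_T <- coup_T + net$k_cortex_to_thal[b] *
      (Im(Yb) * cos(phases[[1L]]) - Re(Yb) * sin(phases[[1L]]))
  }
  d[[1L]] <- .unit_scale * (freqs[[1L]] + coup_T + It * cos(phases[[1L]]))
  for (b in seq_len(nb)) {
    YT <- Y[[1L]]
    d[[b + 1L]] <- .unit_scale * (freqs[[b + 1L]] + net$k_thal_to_cortex[b] *
      (Im(YT) * cos(phases[[b + 1L]]) - Re(YT) * sin(phases[[b + 1L]])))
  }
  d
}

#' Integrate the full N-oscillator model
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the full
#' model through pre-stimulus, stimulus and post-stimulus intervals,
#' starting from seeded uniform initial phases. The run is fully
#' reproducible from `(net, seed, dt_ms)`: population seeds govern the
#' natural-frequency draws and `seed` the initial phases.
#'
#' @param net A [network_spec()].
#' @param t_span_ms Length-2 vector `(t0, t1)`, ms. The default starts
#'   100 ms before the stimulus to display the desynchronized baseline.
#' @param dt_ms Integration step, ms.
#' @param seed Integer seed for the initial phases.
#' @param freq_mode `"random"` (seeded Cauchy draws) or `"quantile"`
#'   (deterministic Lorentzian quantiles; use for comparisons against the
#'   reduced system).
#' @param thin Store every `thin`-th step (default 10, i.e. a 1 ms output
#'   grid at `dt_ms = 0.1`).
#' @param store_phases If `TRUE`, keep the per-oscillator phases (wrapped
#'   to `[0, 2*pi)`) on the output grid as well as the mean fields.
#' @param init_phases Optional list of initial-phase vectors (one per
#'   population, thalamus first) overriding the seeded uniform draw, e.g.
#'   to start from a synchronized state.
#' @return An object of class `tc_trajectory`: a list with `times_ms`, the
#'   complex mean-field matrix `Y` (rows = stored times, columns =
#'   populations, thalamus first), optional `phases` (list of matrices),
#'   and the metadata needed to reproduce the run.
#' @examples
#' net <- two_population_network(k_tc = 16, k_ct = 1.2, n = 200)
#' traj <- integrate_full(net, t_span_ms = c(-50, 300), seed = 1)
#' @export
integrate_full <- function(net, t_span_ms = c(-100, 1000), dt_ms = 0.1,
                           seed = 1L, freq_mode = c("random", "quantile"),
                           thin = 10L, store_phases = FALSE,
                           init_phases = NULL) {
  stopifnot(inherits(net, "network_spec"), length(t_span_ms) == 2L,
            t_span_ms[1] < t_span_ms[2], dt_ms > 0)
  freq_mode <- match.arg(freq_mode)
  pops <- c(list(net$thalamus), net$cortical)
  nm <- population_names(net)
  freqs <- lapply(pops, sample_natural_frequencies, mode = freq_mode)
  phi0 <- if (is.null(init_phases)) {
    lapply(seq_along(pops), function(a)
      sample_initial_phases(pops[[a]]$n_oscillators, seed = seed + a - 1L))
  } else {
    stopifnot(length(init_phases) == length(pops))
    lapply(init_phases, as.numeric)
  }
  s <- net$stimulus
  out <- .full_rk4_cpp(freqs, phi0, net$k_thal_to_cortex, net$k_cortex_to_thal,
                       s$intensity, s$onset_ms, s$duration_ms,
                       t_span_ms[1], t_span_ms[2], dt_ms, as.integer(thin),
                       isTRUE(store_phases))
  Y <- matrix(complex(real = out$Yre, imaginary = out$Yim),
              nrow = nrow(out$Yre), dimnames = list(NULL, nm))
  phases <- out$phases
  if (!is.null(phases)) names(phases) <- nm
  structure(list(times_ms = out$times_ms, Y = Y, phases = phases,
                 network = net, dt_ms = dt_ms, thin = as.integer(thin),
                 seed = as.integer(seed), freq_mode = freq_mode,
                 engine = "full"),
            class = "tc_trajectory")
}

#' @export
print.tc_trajectory <- function(x, ...) {
  cat(sprintf("Full-model trajectory: %d populations (%s), t = [%g, %g] ms, dt = %g ms\n",
              ncol(x$Y), paste(colnames(x$Y), collapse = ", "),
              min(x$times_ms), max(x$times_ms), x$dt_ms))
  cat(sprintf("  final mean-field amplitudes: %s\n",
              paste(sprintf("%s %.3f", colnames(x$Y), Mod(x$Y[nrow(x$Y), ])),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.tc_trajectory <- function(x, ...) {
  amp <- Mod(x$Y)
  graphics::matplot(x$times_ms, amp, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "mean-field amplitude R",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", colnames(x$Y), col = seq_len(ncol(amp)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Export a trajectory as a tidy data frame
#'
#' Long-format view of the population mean fields: one row per stored time
#' and population with columns `time_ms`, `population`, `R`, `Theta`.
#'
#' @param x A `tc_trajectory` or `oa_trajectory`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.tc_trajectory <- function(x, ...) {
  nm <- colnames(x$Y)
  do.call(rbind, lapply(seq_along(nm), function(a) {
    data.frame(time_ms = x$times_ms, population = nm[a],
               R = Mod(x$Y[, a]), Theta = Arg(x$Y[, a]))
  }))
}
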