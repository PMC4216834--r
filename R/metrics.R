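#' Stimulus locking index of a set of phases
#'
#' The resultant length `|mean(exp(i*phi_k))|`: 0 for uniformly spread
#' phases, 1 for perfectly aligned ones. In the model the ensemble of
#' differently initialized oscillators plays the role of the repeated
#' experimental trials, so the SLI is computed across the ensemble at a
#' single stimulation. Identical to the mean-field amplitude.
#'
#' @param phases Numeric vector of phases (radians), non-empty.
#' @return A number in `[0, 1]`.
#' @examples
#' sli(rep(1.3, 10))          # 1
#' sli(c(0, 2 * pi / 3, 4 * pi / 3)) # 0 (balanced triad)
#' @export
sli <- function(phases) {
  if (length(phases) == 0L) stop("`phases` must be non-empty", call. = FALSE)
  Mod(mean(exp(1i * phases)))
}

#' SLI time series of a trajectory
#'
#' Per population, the SLI at every stored time: the modulus of the stored
#' complex mean field (full model) or order parameter (reduced model).
#'
#' @param traj A `tc_trajectory` or `oa_trajectory`.
#' @return An object of class `sli_series`: list with `times_ms`, matrix
#'   `sli` (rows = times, columns = populations), and the stimulus carried
#'   over from the trajectory for window defaults.
#' @export
sli_timeseries <- function(traj) {
  stopifnot(inherits(traj, c("tc_trajectory", "oa_trajectory")))
  stimulus <- if (inherits(traj, "tc_trajectory")) traj$network$stimulus
              else traj$params$stimulus
  n_osc <- if (inherits(traj, "tc_trajectory")) {
    c(traj$network$thalamus$n_oscillators,
      vapply(traj$network$cortical, `[[`, 1L, "n_oscillators"))
  } else rep(Inf, ncol(traj$Y))
  structure(list(times_ms = traj$times_ms, sli = Mod(traj$Y),
                 stimulus = stimulus, n_oscillators = n_osc),
            class = "sli_series")
}

#' @export
print.sli_series <- function(x, ...) {
  cat(sprintf("SLI series: %d populations (%s), %d time points on [%g, %g] ms\n",
              ncol(x$sli), paste(colnames(x$sli), collapse = ", "),
              length(x$times_ms), min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' @export
plot.sli_series <- function(x, ...) {
  graphics::matplot(x$times_ms, x$sli, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "SLI", ylim = c(0, 1), ...)
  graphics::legend("topright", colnames(x$sli), col = seq_len(ncol(x$sli)),
                   lty = 1, bty = "n")
  invisible(x)
}

# stimulus offset of a series (end of the pulse), used as default window start
series_offset <- function(series) {
  s <- series$stimulus
  if (is.null(s)) 0 else s$onset_ms + s$duration_ms
}

#' Maximum SLI over a window
#'
#' The maximum SLI per population over a time window; by default from the
#' stimulus offset to the end of the record, the read-out used on every
#' cell of the coupling-plane scans.
#'
#' @param series An [sli_timeseries()] result.
#' @param window_ms Length-2 window `(a, b)`; default
#'   `c(stimulus offset, end of record)`.
#' @param population Optional population name or index; default all.
#' @return Named numeric vector (or single value if `population` given).
#' @export
max_sli <- function(series, window_ms = NULL, population = NULL) {
  stopifnot(inherits(series, "sli_series"))
  if (is.null(window_ms))
    window_ms <- c(series_offset(series), max(series$times_ms))
  sel <- series$times_ms >= window_ms[1] & series$times_ms <= window_ms[2]
  if (!any(sel)) stop("empty window", call. = FALSE)
  out <- apply(series$sli[sel, , drop = FALSE], 2, max)
  if (!is.null(population)) out <- out[[population]]
  out
}

#' Time-averaged SLI over a window
#'
#' The mean SLI per population over a time window, the natural read-out
#' for a sustained post-stimulus plateau (a regime-level quantity that,
#' unlike [max_sli()], ignores the brief reset transient).
#'
#' @inheritParams max_sli
#' @return Named numeric vector (or single value if `population` given).
#' @export
mean_sli <- function(series, window_ms = NULL, population = NULL) {
  stopifnot(inherits(series, "sli_series"))
  if (is.null(window_ms))
    window_ms <- c(series_offset(series), max(series$times_ms))
  sel <- series$times_ms >= window_ms[1] & series$times_ms <= window_ms[2]
  if (!any(sel)) stop("empty window", call. = FALSE)
  out <- colMeans(series$sli[sel, , drop = FALSE])
  if (!is.null(population)) out <- out[[population]]
  out
}

#' Synchronization duration after the stimulus
#'
#' Time from stimulus offset until the SLI first falls below `threshold`
#' and stays below it for at least `guard_ms`. Returns 0 for a population
#' that never exceeds the threshold after the offset; a population still
#' above threshold at the end of the record is reported censored at the
#' record length (with attribute `censored`). The default threshold is
#' `max(0.15, 3/sqrt(n))`, i.e. three times the finite-ensemble noise
#' floor but no less than 0.15.
#'
#' @param series An [sli_timeseries()] result.
#' @param threshold Detection threshold in (0, 1), or `NULL` for the
#'   default rule.
#' @param guard_ms Time the series must remain below threshold for the
#'   desynchronization to count (default 50 ms).
#' @param offset_ms Window start; default the stimulus offset.
#' @return Named numeric vector of durations (ms) with attribute
#'   `censored` (logical vector).
#' @export
sync_duration <- function(series, threshold = NULL, guard_ms = 50,
                          offset_ms = NULL) {
  stopifnot(inherits(series, "sli_series"))
  if (is.null(offset_ms)) offset_ms <- series_offset(series)
  t <- series$times_ms
  sel <- t >= offset_ms
  out <- numeric(ncol(series$sli))
  cens <- logical(ncol(series$sli))
  names(out) <- colnames(series$sli)
  for (a in seq_len(ncol(series$sli))) {
    thr <- threshold
    if (is.null(thr)) thr <- max(0.15, 3 / sqrt(series$n_oscillators[a]))
    stopifnot(thr > 0, thr < 1)
    x <- series$sli[sel, a]
    tt <- t[sel]
    if (max(x) < thr) { out[a] <- 0; next }
    ipk <- which.max(x)
    below <- x < thr
    below[seq_len(ipk)] <- FALSE   # desynchronization is after the peak
    des <- NA_real_
    idx <- which(below)
    for (i in idx) {
      g <- tt >= tt[i] & tt <= tt[i] + guard_ms
      if (all(x[g] < thr)) { des <- tt[i]; break }
    }
    if (is.na(des)) { out[a] <- max(tt) - offset_ms; cens[a] <- TRUE }
    else out[a] <- des - offset_ms
  }
  attr(out, "censored") <- cens
  out
}

#' Peak oscillation frequency of a population mean field
#'
#' Frequency (Hz) of the largest spectral peak of `Re(Y)` of one
#' population over a window: the signal is linearly detrended, Hann
#' tapered, zero-padded fourfold and transformed with the FFT; the
#' bin-center frequency of the maximal non-DC peak is returned.
#'
#' @param traj A `tc_trajectory` or `oa_trajectory` (or an object with
#'   `times_ms` and complex matrix `Y`).
#' @param population Population name or column index.
#' @param window_ms Length-2 analysis window; must span at least two
#'   nominal periods (>= 2 / `min_freq_hz`).
#' @param min_freq_hz Lower edge of the searched band (default 1 Hz,
#'   excluding the DC/trend region).
#' @param pad Zero-padding factor (default 4).
#' @return Peak frequency, Hz.
#' @examples
#' t <- seq(0, 1000, by = 1)
#' fake <- structure(list(times_ms = t,
#'   Y = cbind(osc = complex(real = cos(2 * pi * 6 * t / 1000),
#'                           imaginary = 0))), class = "oa_trajectory")
#' peak_frequency(fake, "osc", c(0, 1000)) # 6 Hz
#' @export
peak_frequency <- function(traj, population, window_ms, min_freq_hz = 1,
                           pad = 4) {
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2])
  t <- traj$times_ms
  sel <- t >= window_ms[1] & t <= window_ms[2]
  x <- Re(traj$Y[sel, population])
  n <- length(x)
  span_s <- (window_ms[2] - window_ms[1]) / 1000
  if (n < 16 || span_s < 0.1)
    stop("window too short for a spectral estimate", call. = FALSE)
  # a frequency is only searchable if the window holds >= 2 of its periods
  min_freq_hz <- max(min_freq_hz, 2 / span_s)
  dt_s <- mean(diff(t[sel])) / 1000
  tt <- seq_len(n)
  x <- x - stats::fitted(lm(x ~ tt))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xp <- c(x * w, rep(0, (pad - 1) * n))
  np <- length(xp)
  spec <- Mod(fft(xp))^2
  freqs <- (seq_len(np) - 1) / (np * dt_s)
  half <- seq_len(floor(np / 2))
  ok <- half[freqs[half] >= min_freq_hz]
  freqs[ok[which.max(spec[ok])]]
}

#' Synchronization summary of a trajectory
#'
#' One row per population: maximum post-stimulus SLI, synchronization
#' duration, and peak frequency over the phase-locked interval (from the
#' stimulus offset to the desynchronization time, or a 500 ms window if
#' the population stays locked or never locks).
#'
#' @param traj A `tc_trajectory` or `oa_trajectory`.
#' @param threshold,guard_ms Passed to [sync_duration()].
#' @return A data frame with columns `population`, `max_sli`,
#'   `sync_duration_ms`, `peak_frequency_hz`.
#' @export
sync_summary <- function(traj, threshold = NULL, guard_ms = 50) {
  ser <- sli_timeseries(traj)
  off <- series_offset(ser)
  mx <- max_sli(ser)
  dur <- sync_duration(ser, threshold = threshold, guard_ms = guard_ms)
  pk <- vapply(seq_along(mx), function(a) {
    # at least 350 ms of signal so theta-range rhythms are resolvable
    w0 <- off + 10
    w1 <- min(off + max(dur[a], 350), max(ser$times_ms))
    if (w1 - w0 < 350) w1 <- min(w0 + 350, max(ser$times_ms))
    peak_frequency(traj, a, c(w0, w1))
  }, 0)
  data.frame(population = names(mx), max_sli = unname(mx),
             sync_duration_ms = unname(dur), peak_frequency_hz = pk,
             row.names = NULL)
}
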