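#' Parameters of the Ott-Antonsen reduced system
#'
#' On the Ott-Antonsen manifold the infinite-N dynamics of each population
#' closes into a single complex ODE for its order parameter `Y_a`:
#' \deqn{dY_a/dt = (i \hat\omega_a - \Delta_a) Y_a + (H_a - H_a^* Y_a^2)/2,}
#' with driving fields `H_b = K_T(b) Y_T` for cortical bands and
#' `H_T = sum_b K_C(b) Y_b + i I(t)` for the thalamus. This constructor
#' collects the centers, half-widths, couplings and stimulus; usually built
#' from a network via [as_oa_params()].
#'
#' @param centers_hz Named numeric vector of population center frequencies
#'   (Hz), thalamus first.
#' @param widths_hz Half-widths (Hz), same order; all > 0 (analyticity in
#'   the upper half-plane requires a genuine Lorentzian).
#' @param k_tc,k_ct Coupling strengths per cortical band, as in
#'   [network_spec()].
#' @param stimulus A [stimulus_spec()].
#' @return An object of class `oa_params`.
#' @export
oa_params <- function(centers_hz, widths_hz, k_tc, k_ct,
                      stimulus = stimulus_spec()) {
  stopifnot(is.numeric(centers_hz), is.numeric(widths_hz),
            length(centers_hz) == length(widths_hz),
            length(centers_hz) >= 2L,
            length(k_tc) == length(centers_hz) - 1L,
            length(k_ct) == length(centers_hz) - 1L,
            inherits(stimulus, "stimulus_spec"))
  if (any(widths_hz <= 0)) stop("half-widths must be > 0", call. = FALSE)
  if (any(k_tc < 0) || any(k_ct < 0)) stop("couplings must be >= 0", call. = FALSE)
  if (is.null(names(centers_hz)))
    names(centers_hz) <- c("thalamus", paste0("cortex", seq_len(length(centers_hz) - 1L)))
  structure(list(centers_hz = centers_hz, widths_hz = widths_hz,
                 k_tc = as.numeric(k_tc), k_ct = as.numeric(k_ct),
                 stimulus = stimulus),
            class = "oa_params")
}

#' @export
print.oa_params <- function(x, ...) {
  cat(sprintf("OA reduced parameters (%d populations: %s)\n",
              length(x$centers_hz), paste(names(x$centers_hz), collapse = ", ")))
  cat(sprintf("  centers: %s Hz; half-widths: %s Hz\n",
              paste(x$centers_hz, collapse = ", "),
              paste(x$widths_hz, collapse = ", ")))
  cat(sprintf("  K_T: %s;  K_C: %s\n", paste(x$k_tc, collapse = ", "),
              paste(x$k_ct, collapse = ", ")))
  invisible(x)
}

#' Reduced parameters of a network
#'
#' Maps a full [network_spec()] onto the parameters of its Ott-Antonsen
#' reduction: each population is replaced by the center and half-width of
#' its Lorentzian frequency law; couplings and stimulus carry over
#' unchanged.
#'
#' @param net A [network_spec()].
#' @return An [oa_params()] object.
#' @export
as_oa_params <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  pops <- c(list(net$thalamus), net$cortical)
  centers <- vapply(pops, function(p) p$frequency_law$center_hz, 0)
  widths <- vapply(pops, function(p) p$frequency_law$half_width_hz, 0)
  names(centers) <- vapply(pops, `[[`, "", "name")
  oa_params(centers, widths, net$k_thal_to_cortex, net$k_cortex_to_thal,
            net$stimulus)
}

#' Right-hand side of the reduced system
#'
#' Complex derivatives `dY/dt` (per ms) of the order parameters under the
#' Ott-Antonsen closure.
#'
#' @param Y Complex vector of order parameters, thalamus first.
#' @param t_ms Time, ms.
#' @param p An [oa_params()] object.
#' @return Complex vector of derivatives.
#' @export
reduced_rhs <- function(Y, t_ms, p) {
  stopifnot(inherits(p, "oa_params"), length(Y) == length(p$centers_hz))
  Y <- as.complex(Y)
  It <- stimulus_value(t_ms, p$stimulus)
  P <- length(Y)
  H_T <- sum(p$k_ct * Y[-1L]) + 1i * It
  dY <- complex(P)
  dY[1L] <- (1i * p$centers_hz[1L] - p$widths_hz[1L]) * Y[1L] +
    (H_T - Conj(H_T) * Y[1L]^2) / 2
  for (b in 2:P) {
    H <- p$k_tc[b - 1L] * Y[1L]
    dY[b] <- (1i * p$centers_hz[b] - p$widths_hz[b]) * Y[b] +
      (H - Conj(H) * Y[b]^2) / 2
  }
  unname(.unit_scale * dY)
}

#' Integrate the reduced system
#'
#' Fixed-step RK4 integration of the Ott-Antonsen order-parameter ODEs,
#' with the same step size convention as [integrate_full()] so the two
#' systems can be compared directly. Integration aborts if any
#' `|Y_a|` exceeds `1 + 1e-6` (departure from the OA manifold).
#'
#' @param p An [oa_params()] object.
#' @param y0 Complex initial order parameters (default: all zero, the
#'   incoherent state); must satisfy `|Y_a| < 1`.
#' @param t_span_ms Length-2 time span, ms.
#' @param dt_ms Step, ms.
#' @param thin Store every `thin`-th step.
#' @return An object of class `oa_trajectory` with fields `times_ms`,
#'   complex matrix `Y`, amplitude matrix `R`, and metadata.
#' @examples
#' p <- as_oa_params(two_population_network(k_tc = 16, k_ct = 1.2))
#' tr <- integrate_reduced(p, t_span_ms = c(-100, 500))
#' @export
integrate_reduced <- function(p, y0 = NULL, t_span_ms = c(-100, 1000),
                              dt_ms = 0.1, thin = 10L) {
  stopifnot(inherits(p, "oa_params"), length(t_span_ms) == 2L,
            t_span_ms[1] < t_span_ms[2], dt_ms > 0)
  P <- length(p$centers_hz)
  if (is.null(y0)) y0 <- complex(P)
  y0 <- as.complex(y0)
  stopifnot(length(y0) == P)
  if (any(Mod(y0) >= 1))
    stop("initial order parameters must lie strictly inside the unit disc",
         call. = FALSE)
  s <- p$stimulus
  out <- .reduced_rk4_cpp(unname(p$centers_hz), unname(p$widths_hz),
                          p$k_tc, p$k_ct,
                          s$intensity, s$onset_ms, s$duration_ms,
                          y0, t_span_ms[1], t_span_ms[2], dt_ms,
                          as.integer(thin))
  Y <- out$Y
  colnames(Y) <- names(p$centers_hz)
  structure(list(times_ms = out$times_ms, Y = Y, R = Mod(Y), params = p,
                 dt_ms = dt_ms, thin = as.integer(thin), engine = "reduced"),
            class = "oa_trajectory")
}

#' @export
print.oa_trajectory <- function(x, ...) {
  cat(sprintf("Reduced (OA) trajectory: %d populations (%s), t = [%g, %g] ms, dt = %g ms\n",
              ncol(x$Y), paste(colnames(x$Y), collapse = ", "),
              min(x$times_ms), max(x$times_ms), x$dt_ms))
  cat(sprintf("  final |Y|: %s\n",
              paste(sprintf("%s %.3f", colnames(x$Y), Mod(x$Y[nrow(x$Y), ])),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.oa_trajectory <- function(x, ...) {
  graphics::matplot(x$times_ms, x$R, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "|Y|", ylim = c(0, 1), ...)
  graphics::legend("topright", colnames(x$Y), col = seq_len(ncol(x$Y)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.oa_trajectory <- function(x, ...) {
  nm <- colnames(x$Y)
  do.call(rbind, lapply(seq_along(nm), function(a) {
    data.frame(time_ms = x$times_ms, population = nm[a],
               re = Re(x$Y[, a]), im = Im(x$Y[, a]), R = Mod(x$Y[, a]))
  }))
}

#' Real-form state conversion
#'
#' The complex order parameters map bijectively onto a real state vector
#' `(x_1, y_1, x_2, y_2, ...)` via `Y_a = x_a + i y_a` (the 4-dimensional
#' real form in the two-population case). `to_real_system()` flattens,
#' `from_real_system()` reassembles.
#'
#' @param Y Complex vector of order parameters.
#' @return `to_real_system()`: numeric vector of length `2 * length(Y)`;
#'   `from_real_system()`: complex vector.
#' @examples
#' to_real_system(c(0.3 + 0.4i, 0 + 0i)) # c(0.3, 0.4, 0, 0)
#' @export
to_real_system <- function(Y) {
  Y <- as.complex(Y)
  as.numeric(rbind(Re(Y), Im(Y)))
}

#' @rdname to_real_system
#' @param x Numeric vector of even length.
#' @export
from_real_system <- function(x) {
  stopifnot(length(x) %% 2 == 0)
  complex(real = x[c(TRUE, FALSE)], imaginary = x[c(FALSE, TRUE)])
}
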