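#' Jacobian of the reduced system at the incoherent state
#'
#' Exact Jacobian of the real form of the reduced system at the origin
#' (all order parameters zero), with the stimulus off. In the real
#' coordinates `(x_a, y_a)` the diagonal block of population a is
#' `[[-Delta_a, -omega_a], [omega_a, -Delta_a]]` and the couplings enter
#' as `(K/2) * I2` off-diagonal blocks (the quadratic `Y^2` term has no
#' linear part). All entries are in 1/ms.
#'
#' @param p An [oa_params()] object.
#' @return A `2P x 2P` numeric matrix, populations ordered thalamus first.
#' @export
jacobian_at_origin <- function(p) {
  stopifnot(inherits(p, "oa_params"))
  P <- length(p$centers_hz)
  J <- matrix(0, 2 * P, 2 * P)
  for (a in seq_len(P)) {
    i <- 2 * a - 1
    J[i:(i + 1), i:(i + 1)] <- rbind(c(-p$widths_hz[a], -p$centers_hz[a]),
                                     c(p$centers_hz[a], -p$widths_hz[a]))
  }
  for (b in 2:P) {
    i <- 2 * b - 1
    J[1:2, i:(i + 1)] <- diag(2) * p$k_ct[b - 1] / 2
    J[i:(i + 1), 1:2] <- diag(2) * p$k_tc[b - 1] / 2
  }
  .unit_scale * J
}

# leading (largest) real part of the origin's eigenvalues, 1/ms
origin_growth_rate <- function(p) {
  max(Re(eigen(jacobian_at_origin(p), only.values = TRUE)$values))
}

# return params with one coupling replaced
set_coupling <- function(p, which = c("k_tc", "k_ct"), band = 1L, value) {
  which <- match.arg(which)
  p[[which]][band] <- value
  p
}

#' Locate the Hopf bifurcation along one coupling
#'
#' Finds the coupling value at which the leading eigenvalue pair of the
#' origin crosses the imaginary axis, by bisection on the maximal real
#' part of [jacobian_at_origin()] eigenvalues.
#'
#' @param p An [oa_params()] object (other parameters held fixed).
#' @param vary Which coupling to vary: `"k_tc"` or `"k_ct"`.
#' @param band Cortical band index of the varied coupling.
#' @param interval Search interval for the coupling.
#' @param tol Bisection tolerance on the coupling (default `1e-6`).
#' @return The critical coupling value, or `NA` if the real part does not
#'   change sign on the interval (no crossing is not an error).
#' @export
hopf_point <- function(p, vary = "k_tc", band = 1L, interval = c(0, 40),
                       tol = 1e-6) {
  g <- function(k) origin_growth_rate(set_coupling(p, vary, band, k))
  lo <- interval[1]; hi <- interval[2]
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) * glo <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Hopf locus over a coupling plane
#'
#' For each value of the fixed coupling on `grid`, locates the Hopf point
#' of the other coupling by bisection.
#'
#' @param p An [oa_params()] object.
#' @param fixed Which coupling is stepped along `grid` (`"k_ct"` steps the
#'   feedback and locates the critical `k_tc`, and vice versa).
#' @param band Cortical band index.
#' @param grid Numeric vector of values for the fixed coupling.
#' @param interval,tol Passed to [hopf_point()].
#' @return Data frame with columns `k_ct` and `k_tc` (NA rows dropped).
#' @export
hopf_locus <- function(p, fixed = "k_ct", band = 1L, grid,
                       interval = c(0, 40), tol = 1e-6) {
  vary <- if (fixed == "k_ct") "k_tc" else "k_ct"
  ks <- vapply(grid, function(v)
    hopf_point(set_coupling(p, fixed, band, v), vary = vary, band = band,
               interval = interval, tol = tol), 0)
  out <- if (fixed == "k_ct") data.frame(k_ct = grid, k_tc = ks)
         else data.frame(k_ct = ks, k_tc = grid)
  out[is.finite(out$k_tc) & is.finite(out$k_ct), , drop = FALSE]
}

# post-stimulus reset state: integrate the stimulus window from the origin
# (plus a small perturbation so a formally invariant origin cannot mask it)
reset_state <- function(p, eps = 1e-3) {
  P <- length(p$centers_hz)
  s <- p$stimulus
  tr <- integrate_reduced(p, y0 = rep(complex(real = eps), P),
                          t_span_ms = c(s$onset_ms - 1,
                                        s$onset_ms + s$duration_ms),
                          thin = 1L)
  tr$Y[nrow(tr$Y), ]
}

# does a long run from `y0` settle on a nonzero attractor of band `band`?
settles_nonzero <- function(p, y0, band = 2L, t_end = 8000, level = 0.05) {
  pq <- p
  pq$stimulus <- stimulus_spec(0, 0, 0)
  tr <- integrate_reduced(pq, y0 = y0, t_span_ms = c(0, t_end))
  tail_amp <- max(tr$R[tr$times_ms > t_end - 300, band])
  tail_amp > level
}

#' Find a periodic orbit of the reduced system
#'
#' Stable orbits are located by long-run integration and convergence of
#' successive crossings of the Poincare section `Im(Y_band) = 0` (crossing
#' upward); unstable orbits by single-shooting Newton refinement of the
#' section return map, with the map's finite-difference Jacobian supplying
#' Floquet multipliers. The stimulus is off.
#'
#' @param p An [oa_params()] object.
#' @param init Complex initial state (default: the post-stimulus reset
#'   state).
#' @param branch `"stable"` or `"unstable"`.
#' @param band Cortical band (population index) defining the section.
#' @param t_settle Settling time before crossings are collected (ms).
#' @param tol Convergence tolerance on section states.
#' @return A list of class `periodic_orbit` with `period_ms`, `x_min`,
#'   `x_max` (extrema of `Re(Y_band)` over one period), `stable`,
#'   `multipliers` (unstable branch only), `converged`, and the section
#'   `state`; or `NULL` if no orbit is found.
#' @export
find_periodic_orbit <- function(p, init = NULL, branch = c("stable", "unstable"),
                                band = 2L, t_settle = 4000, tol = 1e-6) {
  branch <- match.arg(branch)
  stopifnot(inherits(p, "oa_params"))
  pq <- p
  pq$stimulus <- stimulus_spec(0, 0, 0)
  if (is.null(init)) init <- reset_state(p)
  if (branch == "stable") {
    tr <- integrate_reduced(pq, y0 = init, t_span_ms = c(0, t_settle + 1000),
                            thin = 1L)
    t <- tr$times_ms
    sel <- t >= t_settle
    Yb <- tr$Y[sel, band]
    if (max(Mod(Yb)) < 0.02) return(NULL)   # decayed to the origin
    cr <- section_crossings(t[sel], tr$Y[sel, , drop = FALSE], band)
    if (nrow(cr$states) < 4) return(NULL)
    k <- nrow(cr$states)
    drift <- max(Mod(cr$states[k, ] - cr$states[k - 1, ]))
    per <- diff(cr$times)
    period <- mean(per[max(1, length(per) - 3):length(per)])
    # extrema over the final period
    last <- t[sel] >= cr$times[k] - period - 1 & t[sel] <= cr$times[k]
    xs <- Re(tr$Y[sel, band][last])
    structure(list(period_ms = period, x_min = min(xs), x_max = max(xs),
                   stable = TRUE, converged = drift < max(tol, 1e-4),
                   state = cr$states[k, ], band = band),
              class = "periodic_orbit")
  } else {
    # the reduced system is equivariant under a global phase rotation:
    # periodic solutions are rotating waves (constant amplitudes) or
    # modulated waves (oscillating amplitudes). Both are periodic orbits
    # of the polar system (amplitudes + phase differences), where the
    # neutral phase direction is factored out; locate the unstable one by
    # single shooting there, seeded from the basin boundary between the
    # origin and the nonzero attractor.
    bb <- basin_boundary_state(pq, init, band)
    if (is.null(bb)) return(NULL)
    # a genuinely subcritical wave shows constant amplitudes: try the
    # co-rotating-frame Newton first
    orb <- rotating_wave(pq, bb, band = band)
    if (!is.null(orb) && orb$x_max >= 0.01 && !orb$stable) return(orb)
    orb <- shoot_polar_orbit(pq, bb, band, tol = max(tol, 1e-6))
    if (!is.null(orb) && !orb$stable) return(orb)
    # weakly unstable separatrix (near-supercritical geometry): Newton has
    # no usable basin; report the bisection-tracked edge state as the
    # branch endpoint, flagged as unconverged
    edge_state_orbit(pq, init, band)
  }
}

# iterated-bisection ("edge tracking") approximation of the separatrix
# object between the origin and the nonzero attractor
edge_state_orbit <- function(p, init, band, rounds = 5, horizon = 12000,
                             advance = 400) {
  hi <- init
  lo <- 0 * init
  mid <- NULL
  for (r in seq_len(rounds)) {
    flo <- 0; fhi <- 1
    if (!settles_nonzero(p, lo + fhi * (hi - lo), band = band,
                         t_end = horizon)) return(NULL)
    for (i in 1:25) {
      f <- (flo + fhi) / 2
      if (settles_nonzero(p, lo + f * (hi - lo), band = band,
                          t_end = horizon)) fhi <- f else flo <- f
    }
    tr <- integrate_reduced(p, y0 = lo + (flo + fhi) / 2 * (hi - lo),
                            t_span_ms = c(0, advance))
    mid <- tr$Y[nrow(tr$Y), ]
    hi <- mid * 1.1
    lo <- mid * 0.9
  }
  tr <- integrate_reduced(p, y0 = mid, t_span_ms = c(0, 600), thin = 1L)
  amp <- max(Mod(tr$Y[, band]))
  if (amp < 0.01) return(NULL)
  cr <- section_crossings(tr$times_ms, tr$Y, band)
  period <- if (length(cr$times) > 1) mean(diff(cr$times)) else NA_real_
  structure(list(period_ms = period, x_min = -amp, x_max = amp,
                 stable = FALSE, multipliers = NULL, converged = FALSE,
                 state = mid, band = band),
            class = "periodic_orbit")
}

# ---------------------------------------------------------------------------
# Polar form of the reduced system: state (R_1..R_P, psi_2..psi_P) with
# psi_b = Theta_thal - Theta_b. The global phase is factored out, so
# rotating waves become fixed points and modulated waves periodic orbits.
# ---------------------------------------------------------------------------

polar_rhs <- function(u, p) {
  P <- length(p$centers_hz)
  R <- u[1:P]
  psi <- u[(P + 1):(2 * P - 1)]
  kct <- p$k_ct; ktc <- p$k_tc
  dR <- numeric(P); dTh <- numeric(P)
  # thalamus driven by all bands (stimulus off in this frame)
  sum_ct_R <- 0; sum_ct_I <- 0
  for (b in 2:P) {
    # field of band b on the thalamus: angle Theta_b - Theta_T = -psi_b
    sum_ct_R <- sum_ct_R + kct[b - 1] * R[b] * cos(-psi[b - 1])
    sum_ct_I <- sum_ct_I + kct[b - 1] * R[b] * sin(-psi[b - 1])
  }
  dR[1] <- -p$widths_hz[1] * R[1] + 0.5 * (1 - R[1]^2) * sum_ct_R
  dTh[1] <- p$centers_hz[1] +
    0.5 * (1 + R[1]^2) * sum_ct_I / max(R[1], 1e-12)
  for (b in 2:P) {
    dR[b] <- -p$widths_hz[b] * R[b] +
      0.5 * ktc[b - 1] * R[1] * (1 - R[b]^2) * cos(psi[b - 1])
    dTh[b] <- p$centers_hz[b] +
      0.5 * ktc[b - 1] * R[1] * (1 + R[b]^2) * sin(psi[b - 1]) /
        max(R[b], 1e-12)
  }
  .unit_scale * c(dR, dTh[1] - dTh[2:P])
}

polar_state <- function(Y) {
  P <- length(Y)
  c(Mod(Y), Arg(Y[1]) - Arg(Y[2:P]))
}

polar_rk4 <- function(u0, p, t_len, dt = 0.1) {
  n <- ceiling(t_len / dt)
  out <- matrix(NA_real_, n + 1, length(u0))
  out[1, ] <- u <- u0
  for (i in seq_len(n)) {
    k1 <- polar_rhs(u, p)
    k2 <- polar_rhs(u + dt / 2 * k1, p)
    k3 <- polar_rhs(u + dt / 2 * k2, p)
    k4 <- polar_rhs(u + dt * k3, p)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- u
  }
  out
}

# shooting for a periodic orbit of the polar system on the section
# R_band = level (upward crossing); unknowns: remaining polar coordinates
shoot_polar_orbit <- function(p, bb, band, tol = 1e-6, max_iter = 25) {
  P <- length(p$centers_hz)
  u0 <- polar_state(bb)
  level <- u0[band]
  # first return to the section from a state on it
  ret <- function(v) {
    # v: polar state without R_band
    u <- append(v, level, after = band - 1)
    dt <- 0.1
    tr <- polar_rk4(u, p, 2000, dt)
    x <- tr[, band]
    up <- which(x[-length(x)] < level & x[-1] >= level)
    up <- up[up > 3]
    if (!length(up)) return(NULL)
    i <- up[1]
    frac <- (level - x[i]) / (x[i + 1] - x[i])
    st <- tr[i, ] + frac * (tr[i + 1, ] - tr[i, ])
    list(state = st[-band], time = (i - 1 + frac) * dt)
  }
  v <- u0[-band]
  period <- NA_real_
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    r0 <- ret(v)
    if (is.null(r0)) return(NULL)
    res <- r0$state - v
    period <- r0$time
    if (max(abs(res)) < tol) { conv <- TRUE; break }
    m <- length(v)
    Jm <- matrix(0, m, m)
    h <- pmax(1e-5, 1e-5 * abs(v))
    for (j in seq_len(m)) {
      vp <- v; vp[j] <- vp[j] + h[j]
      rj <- ret(vp)
      if (is.null(rj)) return(NULL)
      Jm[, j] <- (rj$state - vp - res) / h[j]
    }
    dv <- tryCatch(solve(Jm, -res), error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    lam <- 1
    repeat {
      vn <- v + lam * dv
      Rn <- append(vn, level, after = band - 1)[1:P]
      if ((all(Rn > 1e-4) && all(Rn < 0.999)) || lam < 1e-4) break
      lam <- lam / 2
    }
    v <- vn
  }
  if (!conv || !is.finite(period)) return(NULL)
  # Floquet multipliers of the section map
  r0 <- ret(v)
  m <- length(v)
  Jm <- matrix(0, m, m)
  h <- pmax(1e-5, 1e-5 * abs(v))
  for (j in seq_len(m)) {
    vp <- v; vp[j] <- vp[j] + h[j]
    rj <- ret(vp)
    if (is.null(rj)) return(NULL)
    Jm[, j] <- (rj$state - r0$state) / h[j]
  }
  mult <- eigen(Jm, only.values = TRUE)$values
  u <- append(v, level, after = band - 1)
  tr <- polar_rk4(u, p, period + 1, 0.05)
  amp <- max(tr[, band])
  if (amp < 0.01) return(NULL)
  structure(list(period_ms = period, x_min = -amp, x_max = amp,
                 stable = all(Mod(mult) < 1 + 1e-6), multipliers = mult,
                 converged = TRUE, polar_state = u, band = band),
            class = "periodic_orbit")
}

# Rotating-wave Newton: solve rhs(y) = i * Omega_scaled * y with the gauge
# Im(y_band) = 0, unknowns (Re/Im of all populations except Im(y_band),
# plus Omega in Hz). Returns a periodic_orbit classified by the rotating-
# frame eigenvalues (Floquet exponents; one is always ~0, the phase mode).
rotating_wave <- function(p, y0, band = 2L, max_iter = 60, ftol = 1e-10) {
  P <- length(p$centers_hz)
  fix <- 2 * band
  # gauge-rotate the seed so Im(y0[band]) = 0, Re >= 0
  y0 <- y0 * exp(-1i * Arg(y0[band]))
  omega <- sum(p$centers_hz) / P
  pack <- function(Y, om) c(to_real_system(Y)[-fix], om)
  unpack <- function(u) {
    v <- numeric(2 * P)
    v[-fix] <- u[-length(u)]
    list(Y = from_real_system(v), om = u[length(u)])
  }
  G <- function(u) {
    s <- unpack(u)
    g <- reduced_rhs(s$Y, t_ms = -1e9, p = p) -
      1i * .unit_scale * s$om * s$Y
    # deflate the trivial root Y = 0 (a solution for every Omega) so
    # Newton cannot slide into it
    to_real_system(g) * (1 + 1 / sum(Mod(s$Y)^2))
  }
  u <- pack(y0, omega)
  m <- length(u)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    g0 <- G(u)
    if (max(abs(g0)) < ftol) { conv <- TRUE; break }
    Jm <- matrix(0, m, m)
    h <- pmax(1e-7, 1e-7 * abs(u))
    for (j in seq_len(m)) {
      up <- u; up[j] <- up[j] + h[j]
      Jm[, j] <- (G(up) - g0) / h[j]
    }
    du <- tryCatch(solve(Jm, -g0), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    # damped step: stay inside the unit polydisc and do not let the
    # residual grow
    lam <- 1
    n0 <- sqrt(sum(g0^2))
    repeat {
      un <- u + lam * du
      ok <- max(Mod(unpack(un)$Y)) < 0.999 &&
        sqrt(sum(G(un)^2)) <= (1 - 0.1 * lam) * n0
      if (ok || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6) return(NULL)   # stagnation
    u <- un
  }
  if (!conv) return(NULL)
  s <- unpack(u)
  if (s$om <= 0) return(NULL)
  period <- 1000 / s$om                   # om is in Hz
  # rotating-frame Jacobian at the wave (full 2P real coordinates)
  Frot <- function(v) {
    Y <- from_real_system(v)
    to_real_system(reduced_rhs(Y, t_ms = -1e9, p = p) -
                     1i * .unit_scale * s$om * Y)
  }
  v0 <- to_real_system(s$Y)
  g0 <- Frot(v0)
  Jr <- matrix(0, 2 * P, 2 * P)
  h <- pmax(1e-7, 1e-7 * abs(v0))
  for (j in seq_len(2 * P)) {
    vp <- v0; vp[j] <- vp[j] + h[j]
    Jr[, j] <- (Frot(vp) - g0) / h[j]
  }
  ev <- eigen(Jr, only.values = TRUE)$values
  # drop the neutral phase mode, classify by the rest
  ev <- ev[order(abs(Re(ev)))][-1]
  amp <- Mod(s$Y[band])
  structure(list(period_ms = period, x_min = -amp, x_max = amp,
                 stable = all(Re(ev) < 1e-9),
                 multipliers = exp(ev * period),
                 converged = TRUE, state = s$Y, omega_hz = s$om,
                 band = band),
            class = "periodic_orbit")
}

# bisection along the ray f * init for the boundary between decay to the
# origin and convergence to the nonzero attractor; returns a state close
# to the unstable orbit
basin_boundary_state <- function(p, init, band, t_probe = 8000, tol = 1e-4) {
  grows <- function(f) {
    tr <- integrate_reduced(p, y0 = f * init, t_span_ms = c(0, t_probe))
    max(tr$R[tr$times_ms > t_probe - 300, band]) > 0.05
  }
  lo <- 0; hi <- 1
  if (!grows(1)) return(NULL)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (grows(mid)) hi <- mid else lo <- mid
  }
  # advance a little along the flow to land near the orbit itself
  tr <- integrate_reduced(p, y0 = ((lo + hi) / 2) * init,
                          t_span_ms = c(0, 400), thin = 1L)
  cr <- section_crossings(tr$times_ms, tr$Y, band)
  if (!nrow(cr$states)) return(NULL)
  cr$states[nrow(cr$states), ]
}

# linearly interpolated upward crossings of Im(Y_band) = 0
section_crossings <- function(t, Y, band) {
  y <- Im(Y[, band])
  i <- which(y[-length(y)] < 0 & y[-1] >= 0)
  if (!length(i)) return(list(times = numeric(0),
                              states = matrix(complex(0), 0, ncol(Y))))
  frac <- -y[i] / (y[i + 1] - y[i])
  times <- t[i] + frac * (t[i + 1] - t[i])
  states <- Y[i, , drop = FALSE] + frac * (Y[i + 1, , drop = FALSE] -
                                           Y[i, , drop = FALSE])
  list(times = times, states = states)
}

# first-return map of the section Im(Y_band)=0 (upward): returns the next
# crossing state and time, integrating with a fixed step
return_map <- function(p, y0, band, t_max = 1500, dt = 0.05) {
  tr <- integrate_reduced(p, y0 = y0, t_span_ms = c(0, t_max), dt_ms = dt,
                          thin = 1L)
  # skip the initial point (it lies on the section)
  t <- tr$times_ms[-(1:4)]
  Y <- tr$Y[-(1:4), , drop = FALSE]
  cr <- section_crossings(t, Y, band)
  if (!length(cr$times)) return(NULL)
  list(state = cr$states[1, ], time = cr$times[1])
}

# single-shooting Newton on the section map; unknowns are the real
# coordinates of all populations except Im(Y_band) (fixed at 0)
shoot_orbit <- function(p, init, band, tol = 1e-6, max_iter = 30) {
  P <- length(p$centers_hz)
  fix <- 2 * band            # index of Im(Y_band) in the real vector
  pack <- function(Y) to_real_system(Y)[-fix]
  unpack <- function(u) {
    v <- numeric(2 * P)
    v[-fix] <- u
    from_real_system(v)
  }
  Fmap <- function(u) {
    r <- return_map(p, unpack(u), band)
    if (is.null(r)) return(NULL)
    list(res = pack(r$state) - u, time = r$time)
  }
  u <- pack(init)
  period <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f0 <- Fmap(u)
    if (is.null(f0)) return(NULL)
    period <- f0$time
    if (max(abs(f0$res)) < tol) { converged <- TRUE; break }
    m <- length(u)
    Jm <- matrix(0, m, m)
    # FD step must exceed the section-interpolation noise of the map
    h <- pmax(1e-4, 1e-4 * abs(u))
    for (j in seq_len(m)) {
      up <- u; up[j] <- up[j] + h[j]
      fj <- Fmap(up)
      if (is.null(fj)) return(NULL)
      Jm[, j] <- (fj$res - f0$res) / h[j]
    }
    du <- tryCatch(solve(Jm, -f0$res), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    # damped update to keep the state inside the unit polydisc
    lam <- 1
    repeat {
      un <- u + lam * du
      if (max(Mod(unpack(un))) < 0.999 || lam < 1e-3) break
      lam <- lam / 2
    }
    u <- un
  }
  if (!converged) return(NULL)
  # Floquet multipliers of the return map
  f0 <- Fmap(u)
  m <- length(u)
  Jm <- matrix(0, m, m)
  h <- pmax(1e-4, 1e-4 * abs(u))
  for (j in seq_len(m)) {
    up <- u; up[j] <- up[j] + h[j]
    fj <- Fmap(up)
    if (is.null(fj)) return(NULL)
    Jm[, j] <- (fj$res + up - (f0$res + u)) / h[j]
  }
  mult <- eigen(Jm, only.values = TRUE)$values
  # trace one period for the amplitude extrema
  tr <- integrate_reduced(p, y0 = unpack(u), t_span_ms = c(0, period),
                          dt_ms = 0.05, thin = 1L)
  xs <- Re(tr$Y[, band])
  structure(list(period_ms = period, x_min = min(xs), x_max = max(xs),
                 stable = all(Mod(mult) < 1 + 1e-6), multipliers = mult,
                 converged = TRUE, state = unpack(u), band = band),
            class = "periodic_orbit")
}

#' @export
print.periodic_orbit <- function(x, ...) {
  cat(sprintf("Periodic orbit (%s): period %.1f ms, Re(Y) in [%.3f, %.3f]\n",
              if (x$stable) "stable" else "unstable", x$period_ms,
              x$x_min, x$x_max))
  invisible(x)
}

#' Locate the fold-limit-cycle bifurcation along one coupling
#'
#' Bisection on the existence of a nonzero attractor reached from the
#' post-stimulus reset state: below the fold only the incoherent state
#' attracts, above it a stable periodic orbit exists. Because trajectories
#' linger near the orbit ghost just below the fold, existence is probed
#' with a long settling integration.
#'
#' @param p An [oa_params()] object.
#' @param vary,band Coupling being varied, as in [hopf_point()].
#' @param interval Search interval.
#' @param tol Bisection tolerance on the coupling (default `1e-4`).
#' @param band_section Population index probed for a nonzero attractor
#'   (default 2, the first cortical band).
#' @param t_end Settling time for the existence probe (ms).
#' @return Critical coupling value, or `NA` if existence does not change
#'   over the interval.
#' @export
flb_point <- function(p, vary = "k_tc", band = 1L, interval = c(0.5, 40),
                      tol = 1e-4, band_section = 2L, t_end = 20000) {
  ex <- function(k) {
    pk <- set_coupling(p, vary, band, k)
    settles_nonzero(pk, reset_state(pk), band = band_section, t_end = t_end)
  }
  lo <- interval[1]; hi <- interval[2]
  if (ex(lo) || !ex(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ex(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @rdname hopf_locus
#' @details `flb_locus()` does the same stepping for the fold of limit
#'   cycles, using [flb_point()].
#' @export
flb_locus <- function(p, fixed = "k_ct", band = 1L, grid,
                      interval = c(0.5, 40), tol = 1e-3) {
  vary <- if (fixed == "k_ct") "k_tc" else "k_ct"
  ks <- vapply(grid, function(v)
    flb_point(set_coupling(p, fixed, band, v), vary = vary, band = band,
              interval = interval, tol = tol), 0)
  out <- if (fixed == "k_ct") data.frame(k_ct = grid, k_tc = ks)
         else data.frame(k_ct = ks, k_tc = grid)
  out[is.finite(out$k_tc) & is.finite(out$k_ct), , drop = FALSE]
}

#' Classify the dynamical regime at one parameter point
#'
#' Region I: the incoherent state is stable and attracts both probe
#' states (small perturbation and post-stimulus reset) -- full
#' desynchronization. Region III: the incoherent state is unstable -- all
#' trajectories reach the stable orbit, persistent synchrony. Region II:
#' the incoherent state is locally stable but a stable orbit coexists --
#' bistability, transient synchrony possible.
#'
#' @param p An [oa_params()] object.
#' @param band Population index probed for sustained synchrony.
#' @param t_end Settling time of the probes (ms).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_region <- function(p, band = 2L, t_end = 8000) {
  if (origin_growth_rate(p) > 1e-12) return("III")
  P <- length(p$centers_hz)
  probes <- list(rep(complex(real = 1e-3), P), reset_state(p))
  for (y0 in probes)
    if (settles_nonzero(p, y0, band = band, t_end = t_end)) return("II")
  "I"
}

#' One-parameter bifurcation diagram of the reduced system
#'
#' Sweeps one coupling over a grid and records, per value: the origin's
#' leading growth rate and stability, the stable periodic orbit (extrema
#' of `Re(Y_band)`, from long-run integration continued along the sweep)
#' and, where bracketed, the located Hopf and fold points.
#'
#' @param p An [oa_params()] object.
#' @param vary,band Coupling swept, as in [hopf_point()].
#' @param grid Numeric vector of coupling values (increasing).
#' @param band_section Population whose `Re(Y)` is reported (default 2).
#' @param t_settle Settling time per point (ms).
#' @return An object of class `bifurcation_diagram`: list with the branch
#'   data frame (`k`, `origin_stable`, `growth_rate`, `orbit_x_min`,
#'   `orbit_x_max`, `orbit_period_ms`, `region`), and located `hopf_k`,
#'   `flb_k`.
#' @export
bifurcation_diagram <- function(p, vary = "k_tc", band = 1L, grid,
                                band_section = 2L, t_settle = 6000) {
  rows <- lapply(grid, function(k) {
    pk <- set_coupling(p, vary, band, k)
    gr <- origin_growth_rate(pk)
    orb <- find_periodic_orbit(pk, branch = "stable", band = band_section,
                               t_settle = t_settle)
    data.frame(k = k, origin_stable = gr < 0, growth_rate = gr,
               orbit_x_min = if (is.null(orb)) NA_real_ else orb$x_min,
               orbit_x_max = if (is.null(orb)) NA_real_ else orb$x_max,
               orbit_period_ms = if (is.null(orb)) NA_real_ else orb$period_ms,
               region = classify_region(pk, band = band_section))
  })
  branch <- do.call(rbind, rows)
  hopf_k <- hopf_point(p, vary = vary, band = band,
                       interval = range(grid))
  flb_k <- flb_point(p, vary = vary, band = band,
                     interval = c(max(min(grid), 0.1), max(grid)))
  structure(list(branch = branch, hopf_k = hopf_k, flb_k = flb_k,
                 vary = vary, band = band, params = p),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation diagram over %s[%d]: %d points on [%g, %g]\n",
              x$vary, x$band, nrow(x$branch), min(x$branch$k), max(x$branch$k)))
  cat(sprintf("  Hopf at %s, fold of limit cycles at %s\n",
              format(x$hopf_k), format(x$flb_k)))
  cat(sprintf("  regions: %s\n",
              paste(rle(x$branch$region)$values, collapse = " -> ")))
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  b <- x$branch
  graphics::plot(b$k, rep(0, nrow(b)), type = "n",
                 ylim = range(c(-0.05, 0.05, b$orbit_x_min, b$orbit_x_max),
                              na.rm = TRUE),
                 xlab = x$vary, ylab = "Re(Y) extrema", ...)
  graphics::lines(b$k[b$origin_stable], rep(0, sum(b$origin_stable)),
                  col = "red", lwd = 2)
  graphics::lines(b$k[!b$origin_stable], rep(0, sum(!b$origin_stable)),
                  col = "black", lty = 2, lwd = 2)
  graphics::points(b$k, b$orbit_x_max, col = "darkgreen", pch = 19)
  graphics::points(b$k, b$orbit_x_min, col = "darkgreen", pch = 19)
  if (is.finite(x$hopf_k)) graphics::abline(v = x$hopf_k, col = "blue")
  if (is.finite(x$flb_k)) graphics::abline(v = x$flb_k, col = "blue", lty = 3)
  invisible(x)
}
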