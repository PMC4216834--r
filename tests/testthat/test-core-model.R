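test_that("stimulus window is half-open with the printed amplitude", {
  s <- stimulus_spec(100, 0, 50)
  expect_equal(stimulus_value(25, s), 100)
  expect_equal(stimulus_value(-10, s), 0)
  expect_equal(stimulus_value(50, s), 0)   # right endpoint excluded
  expect_equal(stimulus_value(0, s), 100)  # left endpoint included
  expect_equal(stimulus_value(c(-1, 0, 49.9, 50), s), c(0, 100, 100, 0))
})

test_that("mean field is the complex average of unit phasors", {
  expect_error(mean_field(numeric(0)), "non-empty")
  mf <- mean_field(rep(1.3, 5))
  expect_equal(mf$amplitude, 1)
  expect_equal(mf$phase, 1.3)
  expect_equal(mean_field(c(0, pi))$amplitude, 0, tolerance = 1e-12)
  mf2 <- mean_field(c(0, pi / 2))
  expect_equal(mf2$amplitude, sqrt(2) / 2)
  expect_equal(mf2$phase, pi / 4)
})

test_that("full-model velocities reduce to the expected limits", {
  net <- two_population_network(k_tc = 0, k_ct = 0, n = 3,
                                stimulus = stimulus_spec(0, 0, 0))
  freqs <- list(c(9, 9.5, 10), c(5, 6, 7))
  ph <- list(c(0.1, 2, 4), c(1, 3, 5))
  d <- full_rhs(ph, 10, net, freqs)
  # uncoupled, unstimulated: every oscillator advances at its own frequency
  expect_equal(d[[1]], 2 * pi / 1000 * freqs[[1]])
  expect_equal(d[[2]], 2 * pi / 1000 * freqs[[2]])

  # stimulus term vanishes at phi = pi/2 and is attracting there
  net2 <- two_population_network(k_tc = 0, k_ct = 0, n = 2,
                                 stimulus = stimulus_spec(100, 0, 50))
  d2 <- full_rhs(list(c(pi / 2, pi / 2), c(0, 0)), 10, net2,
                 list(c(9, 9), c(6, 6)))
  expect_equal(d2[[1]], 2 * pi / 1000 * c(9, 9))
  eps <- 1e-4
  dplus <- full_rhs(list(c(pi / 2 + eps, pi / 2), c(0, 0)), 10, net2,
                    list(c(9, 9), c(6, 6)))[[1]][1]
  expect_lt(dplus, d2[[1]][1])  # restoring: d(I cos phi)/dphi < 0 at pi/2

  # perfectly synchronized thalamus at Theta = 0 exerts no torque on a
  # cortical oscillator sitting at phi = 0
  net3 <- two_population_network(k_tc = 8, k_ct = 0, n = 2,
                                 stimulus = stimulus_spec(0, 0, 0))
  d3 <- full_rhs(list(c(0, 0), c(0, pi / 3)), 10, net3,
                 list(c(9, 9), c(6, 6)))
  expect_equal(d3[[2]][1], 2 * pi / 1000 * 6)

  expect_error(full_rhs(list(1, 1), 0, net3, list(c(9, 9), c(6, 6))),
               "expected 2 oscillators")
})

test_that("uncoupled oscillators drift linearly at machine-level accuracy", {
  net <- two_population_network(0, 0, n = 2,
                                stimulus = stimulus_spec(0, 0, 0))
  phi0 <- list(c(0.3, 1.1), c(2.0, 4.2))
  tr <- integrate_full(net, c(0, 100), dt_ms = 0.1, freq_mode = "quantile",
                       init_phases = phi0, store_phases = TRUE, thin = 100L)
  f <- lapply(list(net$thalamus, net$cortical[[1]]),
              sample_natural_frequencies, mode = "quantile")
  t_end <- 100
  for (a in 1:2) {
    expected <- (phi0[[a]] + 2 * pi / 1000 * f[[a]] * t_end) %% (2 * pi)
    expect_equal(tr$phases[[a]][nrow(tr$phases[[a]]), ], expected,
                 tolerance = 1e-10)
  }
})

test_that("trajectories are reproducible and mean fields consistent", {
  net <- tiny_two_pop(n = 100)
  tr1 <- quiet(integrate_full(net, c(-20, 200), seed = 8, store_phases = TRUE))
  tr2 <- quiet(integrate_full(net, c(-20, 200), seed = 8, store_phases = TRUE))
  expect_identical(tr1$Y, tr2$Y)
  expect_identical(tr1$phases, tr2$phases)

  # mean-field amplitude bounded by 1 everywhere
  expect_true(all(Mod(tr1$Y) <= 1 + 1e-12))

  # stored mean fields recompute exactly from stored phases
  for (a in 1:2) {
    rec <- rowMeans(exp(1i * tr1$phases[[a]]))
    expect_equal(rec, unname(tr1$Y[, a]), tolerance = 1e-12)
  }
})

test_that("an initially synchronized Lorentzian ensemble dephases at rate Delta", {
  # uncoupled, unstimulated: |Y(t)| should follow the Cauchy characteristic
  # function exp(-Delta t); quantile sampling at large N tracks it closely
  w <- 1.5
  D <- 2 * pi * w / 1000
  net <- two_population_network(0, 0, n = 40000, w_theta = w,
                                stimulus = stimulus_spec(0, 0, 0))
  horizon <- 3 / D
  tr <- integrate_full(net, c(0, horizon), freq_mode = "quantile",
                       init_phases = list(rep(0, 40000), rep(0, 40000)))
  pred <- exp(-D * tr$times_ms)
  rel <- abs(Mod(tr$Y[, "theta"]) - pred) / pred
  expect_lt(max(rel), 0.02)
})

test_that("a strong stimulus resets thalamic phases to the attracting phase", {
  # with I = 100 for 50 ms and no coupling, nearly all oscillators are
  # driven to the stable zero of omega + I cos(phi), close to pi/2
  net <- two_population_network(0, 0, n = 1000,
                                stimulus = stimulus_spec(100, 0, 50))
  tr <- quiet(integrate_full(net, c(0, 50), seed = 2, store_phases = TRUE,
                             thin = 10L))
  end <- tr$phases[["thalamus"]][nrow(tr$phases[["thalamus"]]), ]
  frac <- mean(abs((end - pi / 2 + pi) %% (2 * pi) - pi) < 0.3)
  expect_gte(frac, 0.95)

  # oracle: the same 1-D ODE integrated per oscillator with deSolve
  skip_if_not_installed("deSolve")
  f <- quiet(sample_natural_frequencies(net$thalamus))
  phi0 <- sample_initial_phases(1000, seed = 2)
  idx <- seq(1, 1000, by = 50)
  for (k in idx) {
    sol <- deSolve::ode(y = c(phi = phi0[k]), times = c(0, 25, 50),
                        func = function(t, y, parms)
                          list(2 * pi / 1000 * (f[k] + 100 * cos(y))),
                        parms = NULL, method = "rk4", hini = 0.05)
    expect_equal(unname(((sol[3, "phi"] - end[k] + pi) %% (2 * pi)) - pi),
                 0, tolerance = 2e-2)
  }
})
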