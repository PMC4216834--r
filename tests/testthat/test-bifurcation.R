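test_that("the origin Jacobian has the block structure and analytic spectrum", {
  # decoupled: eigenvalues are -Delta_a +- i omega_a exactly
  p0 <- oa_params(c(thalamus = 9, theta = 6), c(1, 0.5), k_tc = 0, k_ct = 0,
                  stimulus = stimulus_spec(0, 0, 0))
  ev <- eigen(jacobian_at_origin(p0), only.values = TRUE)$values
  expected <- 2 * pi / 1000 * c(-1 + 9i, -1 - 9i, -0.5 + 6i, -0.5 - 6i)
  expect_equal(sort(Re(ev)), sort(Re(expected)), tolerance = 1e-12)
  expect_equal(sort(Im(ev)), sort(Im(expected)), tolerance = 1e-12)
})

test_that("the analytic Jacobian agrees with numerical differentiation", {
  skip_if_not_installed("pracma")
  for (p in list(minimal_params(k_tc = 5.5),
                 as_oa_params(three_population_network(k_ct = c(2, 3))))) {
    p$stimulus <- stimulus_spec(0, 0, 0)
    P <- length(p$centers_hz)
    f <- function(x) to_real_system(reduced_rhs(from_real_system(x), 0, p))
    J_fd <- pracma::jacobian(f, rep(0, 2 * P))
    expect_equal(jacobian_at_origin(p), J_fd, tolerance = 1e-6)
  }
})

test_that("the Hopf point is located and self-consistent", {
  p <- minimal_params()
  hb <- hopf_point(p, interval = c(0, 20))
  expect_true(is.finite(hb))
  expect_gt(hb, 5.5)
  expect_lte(hb, 16)
  # on the located point the leading real part vanishes
  gr <- thalcort:::origin_growth_rate(thalcort:::set_coupling(p, "k_tc", 1, hb))
  expect_lt(abs(gr), 1e-8)
  # refinement invariance
  hb2 <- hopf_point(p, interval = c(0, 20), tol = 5e-7)
  expect_lt(abs(hb - hb2), 1e-4)
  # no crossing in a range strictly below the Hopf point is not an error
  expect_true(is.na(hopf_point(p, interval = c(0, 2))))
})

test_that("the fold of limit cycles lies below the Hopf point", {
  p <- minimal_params()
  hb <- hopf_point(p, interval = c(0, 20))
  flb <- flb_point(p, interval = c(1, hb - 1e-3), tol = 1e-3)
  expect_true(is.finite(flb))
  expect_gt(flb, 1)
  expect_lt(flb, hb)

  # just below the fold only the origin attracts; just above, the reset
  # state reaches a nonzero attractor (bistability with the stable origin)
  below <- thalcort:::set_coupling(p, "k_tc", 1, flb - 0.1)
  above <- thalcort:::set_coupling(p, "k_tc", 1, flb + 0.1)
  expect_false(thalcort:::settles_nonzero(below, thalcort:::reset_state(below),
                                          t_end = 20000))
  expect_true(thalcort:::settles_nonzero(above, thalcort:::reset_state(above),
                                         t_end = 20000))

  # fold location is robust under stretching the settling horizon
  flb2 <- flb_point(p, interval = c(1, hb - 1e-3), tol = 1e-3, t_end = 30000)
  expect_lt(abs(flb - flb2) / flb, 0.01)
})

test_that("regions I, II and III are classified consistently", {
  p <- minimal_params()
  hb <- hopf_point(p, interval = c(0, 20))
  flb <- flb_point(p, interval = c(1, hb - 1e-3), tol = 1e-2)
  ks <- c(1, (flb + hb) / 2, 16)
  labs <- vapply(ks, function(k)
    classify_region(thalcort:::set_coupling(p, "k_tc", 1, k)), "")
  expect_identical(labs, c("I", "II", "III"))
})

test_that("periodic orbits exist where the diagram says they do", {
  p <- minimal_params()
  # region III: a stable orbit with the plateau amplitude
  p16 <- thalcort:::set_coupling(p, "k_tc", 1, 16)
  orb <- find_periodic_orbit(p16, branch = "stable",
                             init = c(0.5 + 0i, 0.5 + 0i))
  expect_false(is.null(orb))
  expect_gt(orb$x_max, 0.5)
  expect_true(orb$stable)
  # its period matches the locked rhythm (about 7.5 Hz here)
  expect_lt(abs(1000 / orb$period_ms - 7.5), 1)

  # region I: no orbit, the origin attracts
  p1 <- thalcort:::set_coupling(p, "k_tc", 1, 1)
  expect_null(find_periodic_orbit(p1, branch = "stable"))

  # region II: stable and unstable objects coexist; the unstable one
  # (the basin boundary) has the smaller amplitude
  p2 <- thalcort:::set_coupling(p, "k_tc", 1, 14.8)
  st <- find_periodic_orbit(p2, branch = "stable",
                            init = c(0.5 + 0i, 0.5 + 0i))
  un <- find_periodic_orbit(p2, branch = "unstable")
  expect_false(is.null(st))
  expect_false(is.null(un))
  expect_false(un$stable)
  expect_lt(un$x_max, st$x_max)
})

test_that("transients lengthen on approach to the fold from below", {
  p <- minimal_params()
  hb <- hopf_point(p, interval = c(0, 20))
  flb <- flb_point(p, interval = c(1, hb - 1e-3), tol = 1e-2)
  desync_time <- function(k) {
    pk <- thalcort:::set_coupling(p, "k_tc", 1, k)
    tr <- integrate_reduced(pk, t_span_ms = c(-100, 20000))
    a <- tr$R[, 2]; t <- tr$times_ms
    pk_i <- which.max(a * (t > 50))
    below <- t[t > t[pk_i] & a < 0.15]
    below[1]
  }
  ks <- flb - c(2, 1, 0.5, 0.2)
  times <- vapply(ks, desync_time, 0)
  expect_true(all(diff(times) > 0))
})

test_that("hopf and fold loci partition the plane like the region labels", {
  p <- minimal_params()
  grid <- c(0.8, 1.2, 1.6)
  hl <- hopf_locus(p, fixed = "k_ct", grid = grid, interval = c(0, 40))
  expect_equal(nrow(hl), 3)
  # larger feedback moves the instability to smaller drive
  expect_true(all(diff(hl$k_tc) < 0))
  # each located point is a genuine sign change
  for (i in seq_len(nrow(hl))) {
    pk <- thalcort:::set_coupling(p, "k_ct", 1, hl$k_ct[i])
    lo <- thalcort:::set_coupling(pk, "k_tc", 1, hl$k_tc[i] - 0.01)
    hi <- thalcort:::set_coupling(pk, "k_tc", 1, hl$k_tc[i] + 0.01)
    expect_lt(thalcort:::origin_growth_rate(lo), 0)
    expect_gt(thalcort:::origin_growth_rate(hi), 0)
  }
  # probe grid: region III iff above the Hopf curve at matching feedback
  for (i in seq_len(nrow(hl))) {
    pk <- thalcort:::set_coupling(p, "k_ct", 1, hl$k_ct[i])
    above <- classify_region(thalcort:::set_coupling(pk, "k_tc", 1,
                                                     hl$k_tc[i] + 0.5))
    expect_identical(above, "III")
  }
})

test_that("the one-parameter diagram assembles branches and points", {
  p <- minimal_params()
  bd <- bifurcation_diagram(p, grid = c(1, 8, 14.8, 16), t_settle = 4000)
  expect_s3_class(bd, "bifurcation_diagram")
  b <- bd$branch
  expect_identical(b$region, c("I", "I", "II", "III"))
  expect_true(all(b$origin_stable[1:3]))
  expect_false(b$origin_stable[4])
  expect_true(is.na(b$orbit_x_max[1]))
  expect_false(is.na(b$orbit_x_max[4]))
  expect_true(is.finite(bd$hopf_k) && is.finite(bd$flb_k))
  expect_lt(bd$flb_k, bd$hopf_k)
})
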