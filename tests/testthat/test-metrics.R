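test_that("sli is the resultant length with its edge cases", {
  expect_error(sli(numeric(0)), "non-empty")
  expect_equal(sli(rep(2.2, 7)), 1)
  expect_equal(sli(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(sli(c(0, 2 * pi / 3, 4 * pi / 3)), 0, tolerance = 1e-12)
})

test_that("sli is invariant under global phase shifts and matches mean_field", {
  for (s in 1:5) {
    ph <- sample_initial_phases(200, seed = s)
    shift <- runif(1, -10, 10)
    expect_equal(sli(ph + shift), sli(ph), tolerance = 1e-12)
    expect_equal(sli(ph), mean_field(ph)$amplitude)
  }
})

test_that("sli time series reproduces the noise floor and perfect locking", {
  net <- two_population_network(0, 0, n = 1000,
                                stimulus = stimulus_spec(0, 0, 0))
  tr <- quiet(integrate_full(net, c(0, 200), seed = 4))
  ser <- sli_timeseries(tr)
  expect_true(all(ser$sli >= 0 & ser$sli <= 1))
  expect_true(all(ser$sli < 0.1))   # uniform-initialized, uncoupled

  # fully synchronized artificial trajectory
  fake <- structure(list(times_ms = 0:10,
                         Y = cbind(theta = rep(1 + 0i, 11)),
                         network = net),
                    class = "tc_trajectory")
  expect_true(all(sli_timeseries(fake)$sli == 1))
})

test_that("max_sli and mean_sli respect their windows", {
  ser <- fake_series(0:1000, rep(0.42, 1001))
  expect_equal(unname(max_sli(ser)), 0.42)
  expect_equal(unname(mean_sli(ser, c(100, 500))), 0.42)
  expect_error(max_sli(ser, c(2000, 3000)), "empty window")
})

test_that("sync_duration implements the threshold-and-guard rule", {
  # step series: locked until 300 ms after offset, then silent
  t <- 0:1000
  v <- ifelse(t <= 350, 1, 0)
  ser <- fake_series(t, v, offset = 50)
  expect_equal(as.numeric(sync_duration(ser, threshold = 0.5)), 301)

  # never above threshold
  ser0 <- fake_series(t, rep(0.05, length(t)))
  expect_equal(as.numeric(sync_duration(ser0, threshold = 0.5)), 0)

  # still locked at the end of the record: censored at record length
  ser1 <- fake_series(t, rep(0.9, length(t)))
  d <- sync_duration(ser1, threshold = 0.5)
  expect_equal(as.numeric(d), 950)
  expect_true(attr(d, "censored"))

  # a dip shorter than the guard interval does not end the locked state
  v2 <- rep(0.8, length(t))
  v2[t >= 300 & t < 320] <- 0.1   # 20 ms dip, guard is 50 ms
  v2[t >= 600] <- 0.1
  ser2 <- fake_series(t, v2)
  expect_equal(as.numeric(sync_duration(ser2, threshold = 0.5)), 550)

  # monotone non-increasing in the threshold
  net <- two_population_network(5.5, 1.2)
  tr <- quiet(integrate_full(net, c(-100, 1000), seed = 1))
  ser3 <- sli_timeseries(tr)
  durs <- vapply(c(0.15, 0.25, 0.35, 0.45), function(th)
    sync_duration(ser3, threshold = th)[["theta"]], 0)
  expect_true(all(diff(durs) <= 0))
})

test_that("peak_frequency recovers pure sampled sinusoids to within a bin", {
  t <- seq(0, 2000, by = 1)
  for (f0 in c(4, 6, 9.4, 12)) {
    fake <- structure(list(times_ms = t,
                           Y = cbind(osc = complex(real = cos(2 * pi * f0 * t / 1000),
                                                   imaginary = 0))),
                      class = "oa_trajectory")
    bin <- 1000 / (4 * length(t))  # zero-padded fourfold
    est <- peak_frequency(fake, "osc", c(0, 2000))
    expect_lt(abs(est - f0), bin + 1e-9)
  }
  fake <- structure(list(times_ms = t, Y = cbind(osc = rep(0 + 0i, length(t)))),
                    class = "oa_trajectory")
  expect_error(peak_frequency(fake, "osc", c(0, 50)), "window too short")
})

test_that("sync_summary lines up populations with their read-outs", {
  net <- two_population_network(16, 1.2)
  tr <- quiet(integrate_full(net, c(-100, 1000), seed = 1,
                             freq_mode = "quantile"))
  sm <- sync_summary(tr)
  expect_identical(sm$population, c("thalamus", "theta"))
  ser <- sli_timeseries(tr)
  expect_equal(sm$max_sli, unname(max_sli(ser)))
  # persistent-synchrony regime: theta locks for the whole record
  expect_gt(sm$max_sli[2], 0.5)
  expect_gt(sm$sync_duration_ms[2], 800)
})
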