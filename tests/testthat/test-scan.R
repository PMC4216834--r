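test_that("scans evaluate every cell and are deterministic", {
  net <- two_population_network(5, 1.2, n = 200)
  ax1 <- list(coupling = "k_ct", band = 1L, values = c(1, 1.2))
  ax2 <- list(coupling = "k_tc", band = 1L, values = c(1, 5, 16))
  sg <- scan_coupling_plane(net, ax1, ax2, engine = "reduced",
                            t_end_ms = 1200)
  expect_s3_class(sg, "scan_grid")
  expect_equal(nrow(sg), 6)   # one cortical band per cell
  sg2 <- scan_coupling_plane(net, ax1, ax2, engine = "reduced",
                             t_end_ms = 1200)
  expect_identical(as.data.frame(sg), as.data.frame(sg2))

  # deep region I cells sit at the (reduced) noise floor, region III high
  low <- sg[sg$axis2 == 1, "max_sli"]
  high <- sg[sg$axis2 == 16, "max_sli"]
  expect_true(all(low < 0.2))
  expect_true(all(high > 0.6))
})

test_that("a coarse scan is a subsample of a finer one", {
  net <- two_population_network(5, 1.2)
  fine <- scan_coupling_plane(net,
                              list(coupling = "k_ct", band = 1L,
                                   values = c(1, 1.5, 2)),
                              list(coupling = "k_tc", band = 1L,
                                   values = c(2, 4, 6)),
                              engine = "reduced", t_end_ms = 1000)
  coarse <- scan_coupling_plane(net,
                                list(coupling = "k_ct", band = 1L,
                                     values = c(1, 2)),
                                list(coupling = "k_tc", band = 1L,
                                     values = c(2, 6)),
                                engine = "reduced", t_end_ms = 1000)
  f <- as.data.frame(fine); c2 <- as.data.frame(coarse)
  shared <- merge(c2, f, by = c("axis1", "axis2", "population"))
  expect_equal(shared$max_sli.x, shared$max_sli.y)
  expect_equal(shared$peak_frequency_hz.x, shared$peak_frequency_hz.y)
})

test_that("drive strength moves synchronization more than feedback does", {
  # from (K_C = 2, K_T = 5), lowering K_T to 4.5 weakens the peak response
  # more than lowering K_C to 1.1
  mx <- function(kc, kt) {
    tr <- integrate_reduced(minimal_params(k_tc = kt, k_ct = kc),
                            t_span_ms = c(-100, 1500))
    max(tr$R[tr$times_ms > 50, 2])
  }
  base <- mx(2, 5)
  drop_feedback <- base - mx(1.1, 5)
  drop_drive <- base - mx(2, 4.5)
  expect_gt(drop_drive, drop_feedback)
  expect_gt(drop_drive, 0)
})

test_that("calibration returns the mismatch-minimizing admissible cell", {
  net <- three_population_network(k_ct = c(1, 1), n = 200)
  sg <- scan_coupling_plane(net,
                            list(coupling = "k_ct", band = 1L,
                                 values = c(0.5, 4, 7.5)),
                            list(coupling = "k_ct", band = 2L,
                                 values = c(0.5, 4, 10)),
                            engine = "reduced")
  # self-consistency: a cell's own achieved values are found exactly
  cell <- as.data.frame(sg)
  own <- cell[cell$axis1 == 4 & cell$axis2 == 4, ]
  tg <- calibration_target(
    sli = setNames(own$max_sli, own$population),
    freq_lo = setNames(own$peak_frequency_hz - 1, own$population),
    freq_hi = setNames(own$peak_frequency_hz + 1, own$population),
    tol_sli = 0.005)
  cp <- calibrate(sg, tg)
  expect_true(cp$found)
  expect_equal(c(cp$axis1, cp$axis2), c(4, 4))

  # unreachable targets give an empty admissible set, not an error
  tg2 <- calibration_target(c(theta = 0.99, alpha = 0.99),
                            freq_lo = c(theta = 5, alpha = 9),
                            freq_hi = c(theta = 7, alpha = 12))
  cp2 <- calibrate(sg, tg2)
  expect_false(cp2$found)
  expect_equal(nrow(cp2$admissible), 0)
})

test_that("healthy and patient operating points exist with ordered feedback", {
  net <- three_population_network(k_ct = c(1, 1))
  ax1 <- list(coupling = "k_ct", band = 1L, values = seq(0.5, 10, by = 0.5))
  ax2 <- list(coupling = "k_ct", band = 2L, values = seq(0.5, 10, by = 0.5))
  sg <- scan_coupling_plane(net, ax1, ax2, engine = "reduced")
  cH <- calibrate(sg, healthy_targets(), label = "C")
  cP <- calibrate(sg, patient_targets(), label = "P")
  expect_true(cH$found)
  expect_true(cP$found)
  # reduced cortex-to-thalamus feedback in both bands at the patient point
  expect_lt(cP$axis1, cH$axis1)
  expect_lt(cP$axis2, cH$axis2)

  # per-band peak frequency barely moves between the two operating points
  for (b in c("theta", "alpha")) {
    fH <- cH$achieved$peak_frequency_hz[cH$achieved$population == b]
    fP <- cP$achieved$peak_frequency_hz[cP$achieved$population == b]
    expect_lt(abs(fH - fP), 1)
  }

  # along the feedback ray from C to P the locking weakens monotonically
  # (up to a small tolerance for plateau effects)
  steps <- seq(0, 1, length.out = 5)
  vals <- sapply(steps, function(s) {
    kc1 <- cH$axis1 + s * (cP$axis1 - cH$axis1)
    kc2 <- cH$axis2 + s * (cP$axis2 - cH$axis2)
    neti <- three_population_network(k_ct = c(kc1, kc2))
    tr <- integrate_reduced(as_oa_params(neti), t_span_ms = c(-100, 1500))
    apply(tr$R[tr$times_ms > 50, 2:3], 2, max)
  })
  expect_true(all(diff(t(vals)[, 1]) <= 0.02))
  expect_true(all(diff(t(vals)[, 2]) <= 0.02))
})

test_that("full-model confirmation of a cell reproduces the reduced picture", {
  net <- two_population_network(5, 1.2, n = 400)
  sg <- scan_coupling_plane(net,
                            list(coupling = "k_ct", band = 1L, values = 1.2),
                            list(coupling = "k_tc", band = 1L,
                                 values = c(1, 16)),
                            engine = "reduced+full-verify", t_end_ms = 1000)
  hi <- confirm_cell(sg, 1.2, 16, seed = 2, replicates = 2)
  lo <- confirm_cell(sg, 1.2, 1, seed = 2, replicates = 2)
  expect_gt(hi$max_sli[hi$population == "theta"], 0.6)
  expect_lt(lo$max_sli[lo$population == "theta"],
            hi$max_sli[hi$population == "theta"])
})
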