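#' Scan a coupling plane
#'
#' Runs the stimulus protocol on every cell of a two-coupling grid and
#' records, per cortical band, the maximum post-stimulus SLI and the peak
#' frequency over the phase-locked interval. Axes address couplings of
#' the template network: `"k_tc"` / `"k_ct"` with a band index, so the
#' minimal model scans `(K_C, K_T)` and the extended model the feedback
#' plane `(K_C_theta, K_C_alpha)`.
#'
#' The `"reduced"` engine integrates the Ott-Antonsen system per cell
#' (the inexpensive surrogate the reduction exists for); `"full"` runs
#' the N-oscillator model; `"reduced+full-verify"` scans with the
#' reduced system -- verification of selected cells is then done by
#' [calibrate()] or by the caller with [confirm_cell()].
#'
#' @param net Template [network_spec()]; couplings named by the axes are
#'   overwritten per cell, everything else is held fixed.
#' @param axis1,axis2 Lists `list(coupling = "k_ct"|"k_tc", band = i,
#'   values = numeric)` defining the grid axes.
#' @param engine `"reduced"`, `"full"`, or `"reduced+full-verify"`.
#' @param t_end_ms End of each run (stimulus onset at the template's
#'   stimulus time), default 1500 ms.
#' @param seed Seed for full-model runs.
#' @param freq_mode Frequency sampling for full-model runs.
#' @return An object of class `scan_grid`: a long-format data frame
#'   (`axis1`, `axis2`, `population`, `max_sli`, `sync_duration_ms`,
#'   `peak_frequency_hz`) with the scan metadata in attributes.
#' @export
scan_coupling_plane <- function(net, axis1, axis2,
                                engine = c("reduced", "full",
                                           "reduced+full-verify"),
                                t_end_ms = 1500, seed = 1L,
                                freq_mode = "quantile") {
  stopifnot(inherits(net, "network_spec"))
  engine <- match.arg(engine)
  cells <- expand.grid(a1 = axis1$values, a2 = axis2$values,
                       KEEP.OUT.ATTRS = FALSE)
  run_engine <- if (engine == "full") "full" else "reduced"
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    neti <- set_network_coupling(net, axis1, cells$a1[i])
    neti <- set_network_coupling(neti, axis2, cells$a2[i])
    sm <- if (run_engine == "full") {
      traj <- integrate_full(neti, t_span_ms = c(-100, t_end_ms),
                             seed = seed, freq_mode = freq_mode)
      sync_summary(traj)
    } else {
      traj <- integrate_reduced(as_oa_params(neti),
                                t_span_ms = c(-100, t_end_ms))
      sync_summary(traj)
    }
    sm <- sm[sm$population != neti$thalamus$name, , drop = FALSE]
    rows[[i]] <- cbind(axis1 = cells$a1[i], axis2 = cells$a2[i], sm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("scan_grid", "data.frame"),
            axis1 = axis1[c("coupling", "band")],
            axis2 = axis2[c("coupling", "band")],
            engine = engine, template = net, t_end_ms = t_end_ms,
            seed = seed, freq_mode = freq_mode)
}

# overwrite one coupling of a network according to an axis spec
set_network_coupling <- function(net, axis, value) {
  slot <- switch(axis$coupling,
                 k_tc = "k_thal_to_cortex",
                 k_ct = "k_cortex_to_thal",
                 stop("unknown coupling '", axis$coupling, "'", call. = FALSE))
  net[[slot]][axis$band] <- value
  net
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("Coupling-plane scan (%s engine): %d cells x %d band(s)\n",
              attr(x, "engine"),
              length(unique(x$axis1)) * length(unique(x$axis2)),
              length(unique(x$population))))
  NextMethod()
}

#' Calibration targets for coupling-plane scans
#'
#' Per-band target maximum SLI with an admissibility tolerance, and the
#' admissible peak-frequency interval per band (the frequency bands in
#' which the rhythms must stay, e.g. 5-7 Hz for theta and 9-12 Hz for
#' alpha).
#'
#' @param sli Named numeric vector of target max SLI per band (names =
#'   population names).
#' @param freq_lo,freq_hi Named numeric vectors (same names): admissible
#'   frequency interval per band, Hz.
#' @param tol_sli Admissibility tolerance on each band's max SLI
#'   (default 0.02, of the order of the N = 1000 ensemble noise floor).
#' @return An object of class `calibration_target`.
#' @examples
#' healthy_targets()
#' patient_targets()
#' @export
calibration_target <- function(sli, freq_lo, freq_hi, tol_sli = 0.02) {
  stopifnot(is.numeric(sli), !is.null(names(sli)),
            all(names(sli) %in% names(freq_lo)),
            all(names(sli) %in% names(freq_hi)), tol_sli > 0,
            all(freq_hi[names(sli)] > freq_lo[names(sli)]))
  structure(list(sli = sli, freq_lo = freq_lo[names(sli)],
                 freq_hi = freq_hi[names(sli)], tol_sli = tol_sli),
            class = "calibration_target")
}

#' @export
print.calibration_target <- function(x, ...) {
  for (nm in names(x$sli))
    cat(sprintf("  %s: max SLI %.2f +- %.2f, frequency in [%g, %g] Hz\n",
                nm, x$sli[[nm]], x$tol_sli, x$freq_lo[[nm]], x$freq_hi[[nm]]))
  invisible(x)
}

#' @rdname calibration_target
#' @details `healthy_targets()` and `patient_targets()` return the
#'   synchronization levels reported for healthy controls (theta 0.37,
#'   alpha 0.26) and schizophrenia patients (theta 0.30, alpha 0.19),
#'   with the 5-7 Hz theta and 9-12 Hz alpha admissible bands.
#' @export
healthy_targets <- function(tol_sli = 0.02) {
  calibration_target(c(theta = 0.37, alpha = 0.26),
                     freq_lo = c(theta = 5, alpha = 9),
                     freq_hi = c(theta = 7, alpha = 12), tol_sli = tol_sli)
}

#' @rdname calibration_target
#' @export
patient_targets <- function(tol_sli = 0.02) {
  calibration_target(c(theta = 0.30, alpha = 0.19),
                     freq_lo = c(theta = 5, alpha = 9),
                     freq_hi = c(theta = 7, alpha = 12), tol_sli = tol_sli)
}

#' Calibrate coupling strengths against SLI targets
#'
#' Filters the scan for cells whose per-band maximum SLI lies within
#' `tol_sli` of every target and whose per-band peak frequency lies in
#' the admissible interval, then reports the admissible cell minimizing
#' the total SLI mismatch. An empty admissible set is a valid outcome
#' (returned with `found = FALSE`), not an error.
#'
#' @param scan A [scan_coupling_plane()] result whose bands cover the
#'   target names.
#' @param target A [calibration_target()].
#' @param label Optional label for the point (e.g. `"C"` or `"P"`).
#' @return An object of class `calibration_point`: list with `found`,
#'   the chosen `axis1`/`axis2` coupling values, `achieved` (per-band
#'   max SLI and frequency at the chosen cell), `admissible` (data frame
#'   of all admissible cells), `label`.
#' @export
calibrate <- function(scan, target, label = NULL) {
  stopifnot(inherits(scan, "scan_grid"), inherits(target, "calibration_target"))
  bands <- names(target$sli)
  if (!all(bands %in% scan$population))
    stop("scan does not cover bands: ",
         paste(setdiff(bands, scan$population), collapse = ", "), call. = FALSE)
  df <- as.data.frame(scan)
  cells <- unique(df[, c("axis1", "axis2")])
  ok <- logical(nrow(cells))
  mismatch <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- df[df$axis1 == cells$axis1[i] & df$axis2 == cells$axis2[i], ]
    good <- TRUE; mm <- 0
    for (b in bands) {
      r <- sub[sub$population == b, ]
      dev <- abs(r$max_sli - target$sli[[b]])
      good <- good && dev <= target$tol_sli &&
        r$peak_frequency_hz >= target$freq_lo[[b]] &&
        r$peak_frequency_hz <= target$freq_hi[[b]]
      mm <- mm + dev
    }
    ok[i] <- good; mismatch[i] <- mm
  }
  adm <- cbind(cells[ok, , drop = FALSE], mismatch = mismatch[ok])
  if (!nrow(adm))
    return(structure(list(found = FALSE, admissible = adm, label = label,
                          target = target, scan_attrs = attributes(scan)[
                            c("axis1", "axis2", "engine")]),
                     class = "calibration_point"))
  best <- adm[which.min(adm$mismatch), ]
  sub <- df[df$axis1 == best$axis1 & df$axis2 == best$axis2, ]
  structure(list(found = TRUE, axis1 = best$axis1, axis2 = best$axis2,
                 achieved = sub[, c("population", "max_sli",
                                    "sync_duration_ms", "peak_frequency_hz")],
                 admissible = adm, label = label, target = target,
                 scan_attrs = attributes(scan)[c("axis1", "axis2", "engine")]),
            class = "calibration_point")
}

#' @export
print.calibration_point <- function(x, ...) {
  if (!x$found) {
    cat("Calibration: no admissible cell\n")
    return(invisible(x))
  }
  cat(sprintf("Calibration point%s: axis1 = %g, axis2 = %g (%d admissible cells)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$axis1, x$axis2, nrow(x$admissible)))
  print(x$achieved, row.names = FALSE)
  invisible(x)
}

#' Confirm a scan cell with a full-model run
#'
#' Re-runs one grid cell with the N-oscillator model and returns its
#' [sync_summary()], for verifying reduced-engine scan cells at finite
#' ensemble size. With `replicates > 1` the run is repeated with distinct
#' initial-phase seeds and per-band medians are reported, which stabilizes
#' threshold-crossing read-outs near bistable boundaries.
#'
#' @param scan A [scan_coupling_plane()] result (supplies template and
#'   axis definitions).
#' @param axis1,axis2 Coupling values of the cell.
#' @param seed Base seed.
#' @param replicates Number of initial-phase replicates (default 1).
#' @param t_end_ms Run length; default the scan's.
#' @param freq_mode Frequency sampling (default the scan's).
#' @return A `sync_summary()` data frame (medians across replicates).
#' @export
confirm_cell <- function(scan, axis1, axis2, seed = 1L, replicates = 1L,
                         t_end_ms = NULL, freq_mode = NULL) {
  stopifnot(inherits(scan, "scan_grid"))
  net <- set_network_coupling(attr(scan, "template"), attr(scan, "axis1"),
                              axis1)
  net <- set_network_coupling(net, attr(scan, "axis2"), axis2)
  if (is.null(t_end_ms)) t_end_ms <- attr(scan, "t_end_ms")
  if (is.null(freq_mode)) freq_mode <- attr(scan, "freq_mode")
  sums <- lapply(seq_len(replicates), function(r) {
    traj <- integrate_full(net, t_span_ms = c(-100, t_end_ms),
                           seed = seed + 1000L * (r - 1L),
                           freq_mode = freq_mode)
    sync_summary(traj)
  })
  out <- sums[[1]]
  if (replicates > 1L) {
    for (col in c("max_sli", "sync_duration_ms", "peak_frequency_hz"))
      out[[col]] <- apply(sapply(sums, `[[`, col), 1, stats::median)
  }
  out
}
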