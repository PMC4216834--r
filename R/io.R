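#' Read a run configuration
#'
#' A single declarative YAML file describes a run: a `populations` block
#' (thalamus plus one or two cortical bands, each with `center_hz`,
#' `half_width_hz`, `n`, optional `seed`), a `couplings` block
#' (`k_thal_to_cortex`, `k_cortex_to_thal`, one value per band), a
#' `stimulus` block (`intensity`, `onset_ms`, `duration_ms`), an
#' `integration` block (`dt_ms`, `t0_ms`, `t1_ms`, `thin`), a `task`
#' block (`name` of simulate | reduce | bifurcate | scan | calibrate plus
#' task-specific keys), and a top-level `seed`. Missing optional keys are
#' filled with defaults; the fully resolved configuration is what
#' [run_task()] writes to the metadata sidecar.
#'
#' @param path Path to a YAML config file.
#' @return A list of class `run_config` with elements `network`
#'   ([network_spec()]), `integration`, `task`, `seed`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_config
#' @param cfg A list with the same structure as the YAML file.
#' @export
as_run_config <- function(cfg) {
  for (key in c("populations", "couplings", "stimulus"))
    if (is.null(cfg[[key]]))
      stop("config error: missing required section `", key, "`", call. = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  pops <- cfg$populations
  if (is.null(pops$thalamus))
    stop("config error: `populations` must name a `thalamus`", call. = FALSE)
  mk_pop <- function(name, x, k) {
    for (f in c("center_hz", "half_width_hz"))
      if (is.null(x[[f]]))
        stop("config error: `populations.", name, ".", f, "` is missing",
             call. = FALSE)
    population_spec(name, x$n %||% 1000L,
                    lorentz_spec(x$center_hz, x$half_width_hz),
                    seed = x$seed %||% (seed + k))
  }
  cortical_names <- setdiff(names(pops), "thalamus")
  if (!length(cortical_names) || length(cortical_names) > 2L)
    stop("config error: `populations` needs 1 or 2 cortical bands",
         call. = FALSE)
  thal <- mk_pop("thalamus", pops$thalamus, 0L)
  cort <- lapply(seq_along(cortical_names), function(i)
    mk_pop(cortical_names[i], pops[[cortical_names[i]]], i))
  cp <- cfg$couplings
  for (f in c("k_thal_to_cortex", "k_cortex_to_thal"))
    if (is.null(cp[[f]]))
      stop("config error: `couplings.", f, "` is missing", call. = FALSE)
  st <- cfg$stimulus
  stim <- stimulus_spec(st$intensity %||% 100, st$onset_ms %||% 0,
                        st$duration_ms %||% 50)
  net <- network_spec(thal, cort, unlist(cp$k_thal_to_cortex),
                      unlist(cp$k_cortex_to_thal), stim)
  integ <- utils::modifyList(list(dt_ms = 0.1, t0_ms = -100, t1_ms = 1000,
                                  thin = 10L),
                             cfg$integration %||% list())
  task <- cfg$task %||% list(name = "simulate")
  if (is.null(task$name)) task$name <- "simulate"
  structure(list(network = net, integration = integ, task = task,
                 seed = seed, raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured task
#'
#' Executes the task named in the configuration and writes its artifacts
#' to `out_dir`: trajectory / scan / diagram tables as CSV, located
#' points and calibration results as JSON, plus a `metadata.json` sidecar
#' holding the fully resolved configuration and seeds so the run can be
#' reproduced exactly.
#'
#' Tasks: `simulate` (full model), `reduce` (reduced model), `bifurcate`
#' (one-parameter diagram; keys `vary`, `band`, `from`, `to`, `by`),
#' `scan` (coupling plane; keys `axis1`/`axis2` with `coupling`, `band`,
#' `from`, `to`, `by`, and `engine`), `calibrate` (a scan plus `targets:
#' healthy|patient` or explicit per-band values).
#'
#' @param config A [read_config()] result, a path to a YAML file, or a
#'   config-shaped list.
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) the task result object; artifacts on disk.
#' @export
run_task <- function(config, out_dir = tempfile("thalcort_run_")) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- config$network
  ig <- config$integration
  task <- config$task
  res <- switch(task$name,
    simulate = {
      traj <- integrate_full(net, t_span_ms = c(ig$t0_ms, ig$t1_ms),
                             dt_ms = ig$dt_ms, seed = config$seed,
                             freq_mode = task$freq_mode %||% "random",
                             thin = ig$thin)
      write.csv(as.data.frame(traj), file.path(out_dir, "trajectory.csv"),
                row.names = FALSE)
      write.csv(sync_summary(traj), file.path(out_dir, "summary.csv"),
                row.names = FALSE)
      traj
    },
    reduce = {
      traj <- integrate_reduced(as_oa_params(net),
                                t_span_ms = c(ig$t0_ms, ig$t1_ms),
                                dt_ms = ig$dt_ms, thin = ig$thin)
      write.csv(as.data.frame(traj), file.path(out_dir, "trajectory.csv"),
                row.names = FALSE)
      traj
    },
    bifurcate = {
      grid <- seq(task$from %||% 0.5, task$to %||% 20, by = task$by %||% 0.5)
      bd <- bifurcation_diagram(as_oa_params(net),
                                vary = task$vary %||% "k_tc",
                                band = task$band %||% 1L, grid = grid)
      write.csv(bd$branch, file.path(out_dir, "branches.csv"),
                row.names = FALSE)
      jsonlite::write_json(list(hopf_k = bd$hopf_k, flb_k = bd$flb_k),
                           file.path(out_dir, "points.json"),
                           auto_unbox = TRUE, digits = NA)
      bd
    },
    scan = {
      ax <- function(a) list(coupling = a$coupling, band = a$band %||% 1L,
                             values = seq(a$from %||% 0, a$to %||% 10,
                                          by = a$by %||% 0.5))
      sg <- scan_coupling_plane(net, ax(task$axis1), ax(task$axis2),
                                engine = task$engine %||% "reduced",
                                t_end_ms = task$t_end_ms %||% 1500,
                                seed = config$seed)
      write.csv(as.data.frame(sg), file.path(out_dir, "scan.csv"),
                row.names = FALSE)
      sg
    },
    calibrate = {
      ax <- function(a) list(coupling = a$coupling, band = a$band %||% 1L,
                             values = seq(a$from %||% 0, a$to %||% 10,
                                          by = a$by %||% 0.5))
      sg <- scan_coupling_plane(net, ax(task$axis1), ax(task$axis2),
                                engine = task$engine %||% "reduced",
                                t_end_ms = task$t_end_ms %||% 1500,
                                seed = config$seed)
      tg <- if (identical(task$targets, "healthy")) healthy_targets()
            else if (identical(task$targets, "patient")) patient_targets()
            else calibration_target(unlist(task$targets$sli),
                                    unlist(task$targets$freq_lo),
                                    unlist(task$targets$freq_hi),
                                    task$targets$tol_sli %||% 0.02)
      cp <- calibrate(sg, tg, label = task$label %||% NULL)
      out <- list(found = cp$found)
      if (cp$found) {
        out$axis1 <- cp$axis1; out$axis2 <- cp$axis2
        out$achieved <- cp$achieved
      }
      jsonlite::write_json(out, file.path(out_dir, "calibration.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      cp
    },
    stop("config error: unknown task `", task$name, "`", call. = FALSE)
  )
  meta <- list(package = "thalcort",
               version = as.character(utils::packageVersion("thalcort")),
               seed = config$seed, integration = ig, task = task,
               network = network_to_list(net))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# network_spec -> plain list (for metadata and write_config)
network_to_list <- function(net) {
  pops <- c(list(net$thalamus), net$cortical)
  pl <- lapply(pops, function(p)
    list(center_hz = p$frequency_law$center_hz,
         half_width_hz = p$frequency_law$half_width_hz,
         n = p$n_oscillators, seed = p$seed))
  names(pl) <- vapply(pops, `[[`, "", "name")
  list(populations = pl,
       couplings = list(k_thal_to_cortex = net$k_thal_to_cortex,
                        k_cortex_to_thal = net$k_cortex_to_thal),
       stimulus = list(intensity = net$stimulus$intensity,
                       onset_ms = net$stimulus$onset_ms,
                       duration_ms = net$stimulus$duration_ms))
}

#' Write a network to a config file
#'
#' Serializes a [network_spec()] (plus integration settings and seed) to
#' the YAML layout accepted by [read_config()].
#'
#' @param net A [network_spec()].
#' @param path Output path.
#' @param integration,task,seed Optional blocks to include.
#' @return `path`, invisibly.
#' @export
write_config <- function(net, path, integration = NULL, task = NULL,
                         seed = 1L) {
  cfg <- network_to_list(net)
  cfg$seed <- seed
  if (!is.null(integration)) cfg$integration <- integration
  if (!is.null(task)) cfg$task <- task
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Generate a seeded test fixture
#'
#' Writes small, documented fixture files consumed by tests and examples:
#' `"uniform-phases"` (seeded uniform phases, the desynchronized
#' baseline), `"synced-phases"` (all phases equal), or
#' `"quantile-freqs"` (deterministic Lorentzian quantiles).
#'
#' @param kind Fixture kind.
#' @param path Output CSV path.
#' @param n Number of values.
#' @param seed Seed (uniform phases).
#' @param center_hz,half_width_hz Lorentzian parameters (quantile
#'   frequencies).
#' @param phase Common phase value (synced phases).
#' @return `path`, invisibly; the file has a single column `value` and a
#'   `# kind:` comment header.
#' @export
generate_fixture <- function(kind = c("uniform-phases", "synced-phases",
                                      "quantile-freqs"),
                             path, n = 1000, seed = 1L,
                             center_hz = 6, half_width_hz = 0.5,
                             phase = 0) {
  kind <- match.arg(kind)
  x <- switch(kind,
    "uniform-phases" = sample_initial_phases(n, seed),
    "synced-phases" = rep(phase, n),
    "quantile-freqs" = sample_natural_frequencies(
      population_spec("fixture", n, lorentz_spec(center_hz, half_width_hz)),
      mode = "quantile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s; n: %d; seed: %d", kind, n, seed), con)
  utils::write.table(data.frame(value = x), con, row.names = FALSE,
                     sep = ",", quote = FALSE)
  invisible(path)
}
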