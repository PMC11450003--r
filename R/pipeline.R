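# end-to-end pipeline: simulate -> synthesize -> demodulate ->
# characterize -> reconstruct

#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end experiment. All
#' physical quantities are SI. The configuration serializes losslessly to
#' YAML or JSON ([write_config()] / [read_config()]).
#'
#' @param phantom A [phantom_spec()] or a plain list of its arguments.
#' @param scan A [scan_config()] or argument list.
#' @param model An [iq_model()] or argument list.
#' @param demod A [demod_config()] or argument list.
#' @param solver List with `dx`, `f_max`, `cfl`, `fluence_scale`.
#' @param reconstruction List with `dx`, `depth_factor`, `envelope_mode`.
#' @param seed Global integer seed.
#' @param out_dir Output directory for pipeline artifacts (`NULL`: keep
#'   everything in memory only).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = list(), scan = list(), model = list(),
                            demod = list(), solver = list(),
                            reconstruction = list(), seed = 1L,
                            out_dir = NULL) {
  as_args <- function(x, cls) if (inherits(x, cls)) unclass(x) else x
  cfg <- list(
    phantom = as_args(phantom, "phantom_spec"),
    scan = as_args(scan, "scan_config"),
    model = as_args(model, "iq_model"),
    demod = as_args(demod, "demod_config"),
    solver = modifyList(list(dx = 20e-6, f_max = 5e6, cfl = 0.3,
                             fluence_scale = 1e3), solver),
    reconstruction = modifyList(list(dx = 20e-6, depth_factor = 2,
                                     envelope_mode = TRUE), reconstruction),
    seed = as.integer(seed), out_dir = out_dir)
  # drop derived fields so constructors re-derive them on instantiation
  cfg$scan$positions <- NULL; cfg$scan$n_segments <- NULL
  cfg$model$radius <- NULL
  structure(cfg, class = "pipeline_config")
}

.instantiate <- function(cfg) {
  keep <- function(args, fn) args[names(args) %in% names(formals(fn))]
  list(phantom = do.call(phantom_spec, keep(cfg$phantom, phantom_spec)),
       scan = do.call(scan_config, keep(cfg$scan, scan_config)),
       model = do.call(iq_model, keep(cfg$model, iq_model)),
       demod = do.call(demod_config, keep(cfg$demod, demod_config)))
}

#' @rdname pipeline_config
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  x$phantom$channels <- lapply(x$phantom$channels, as.list)
  do.call(pipeline_config, x)
}

#' Run the full photoacoustic experiment end to end
#'
#' Executes the whole chain the package models: forward wave simulation of
#' the phantom, per-position synthesis of triggered noisy I/Q records,
#' ellipse calibration against a reference vibration, per-segment
#' demodulation and averaging to surface pressure, detector metrics (SNR
#' per position), and time-reversal image reconstruction with peak
#' localization. Deterministic under the configured seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage banners and summary lines.
#' @return List with the scan `dataset` (averaged pressure traces), the
#'   ground-truth `truth` record, `demods` (per-position `demod_result`s),
#'   `snr` per position, the `image`, located `peaks`, and the `config`.
#'   With `out_dir` set, traces, metrics and the image are also written as
#'   CSV/YAML files.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) cat(sprintf(...), "\n")
  inst <- .instantiate(config)
  set.seed(config$seed)

  say("[simulate] phantom: %d channel(s), grid dx = %.3g um",
      length(inst$phantom$channels), 1e6 * config$solver$dx)
  ds <- generate_scan_dataset(inst$phantom, inst$scan, inst$model,
                              seed = config$seed, dx = config$solver$dx,
                              f_max = config$solver$f_max,
                              fluence_scale = config$solver$fluence_scale)
  say("[simulate] solver dt = %.3g ns, %d sensor positions",
      1e9 * ds$truth$dt_solver, length(ds$positions))

  say("[calibrate] reference vibration ellipse fit")
  ref <- make_reference_vibration(inst$model, fs = ds$truth$fs,
                                  seed = config$seed + 1L)
  ell <- fit_ellipse(as.vector(ref$i), as.vector(ref$q))

  cfg_d <- inst$demod
  cfg_d$fs <- ds$truth$fs
  say("[demod] %d segments per position", inst$scan$n_segments)
  demods <- lapply(ds$records, demodulate_record, config = cfg_d,
                   ellipse = ell)
  ndrop <- sum(vapply(demods, `[[`, numeric(1), "dropouts"))
  say("[demod] total dropout samples interpolated: %d", ndrop)

  p_mat <- vapply(demods, `[[`, numeric(length(demods[[1]]$p)), "p")
  dataset <- scan_dataset(ds$positions, demods[[1]]$time, p_mat,
                          pitch = inst$scan$pitch, cutoff = cfg_d$cutoff,
                          truth = inst$phantom)

  arrival <- min(vapply(inst$phantom$channels, function(ch)
    (ch$depth - ch$diameter / 2) / 1020, numeric(1)))
  nw <- c(0.5e-6, max(1e-6, arrival - 1e-6))
  snrs <- vapply(seq_along(demods), function(k)
    snr(demods[[k]]$u, demods[[k]]$fs, nw,
        signal_window = c(arrival - 1e-6, max(demods[[k]]$time))), numeric(1))
  say("[characterize] median SNR %.2f (noise window %.1f-%.1f us)",
      median(snrs), 1e6 * nw[1], 1e6 * nw[2])

  say("[reconstruct] time reversal, %s image",
      if (config$reconstruction$envelope_mode) "envelope" else "in-phase")
  med_r <- reconstruction_medium(dataset, thickness = inst$phantom$thickness,
                                 dx = config$reconstruction$dx,
                                 depth_factor = config$reconstruction$depth_factor,
                                 f_max = config$solver$f_max)
  image <- reconstruct(dataset, med_r,
                       envelope_mode = config$reconstruction$envelope_mode)
  peaks <- localize(image, n_peaks = max(2L, length(inst$phantom$channels)))
  if (verbose && nrow(peaks) > 0) {
    say("[reconstruct] peak table:")
    for (k in seq_len(nrow(peaks)))
      say("  x = %+0.2f mm, z = %.2f mm, amplitude %.3g",
          1e3 * peaks$x[k], 1e3 * peaks$z[k], peaks$amplitude[k])
  }

  out <- list(dataset = dataset, truth = ds$truth, demods = demods,
              snr = snrs, image = image, peaks = peaks, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_traces(file.path(config$out_dir, "pressure_traces.csv"), dataset)
    write_traces(file.path(config$out_dir, "truth_velocity.csv"), ds$truth, "u")
    write.table(image$values, file.path(config$out_dir, "image.csv"),
                sep = ",", row.names = FALSE, col.names = FALSE)
    yaml::write_yaml(list(seed = config$seed, snr = as.list(snrs),
                          peaks = as.list(peaks)),
                     file.path(config$out_dir, "metrics.yaml"))
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}
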