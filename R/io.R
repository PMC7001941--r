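# number formatting for byte-reproducible CSV output
fmt9 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.9g", x) else x
}

write_csv9 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt9), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration from a YAML file
#'
#' A structured plain-text configuration describing one simulation, kernel
#' fit, calibration or reference-generation run.  The top-level \code{task}
#' key selects the command (\code{simulate}, \code{smol_fit},
#' \code{calibrate}, \code{make_reference}; default \code{simulate}).
#' Simulation keys mirror \code{\link{abm_config}} arguments; lengths accept
#' \code{"px"}/\code{"um"} suffixes.  Unknown keys are an error.
#'
#' @param path YAML file path
#' @return a list with \code{task} and task-specific fields (e.g.
#'   \code{config}, an \code{\link{abm_config}})
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) stop("empty config file: ", path)
  task <- raw$task %||% "simulate"
  raw$task <- NULL
  known_sim <- c("n_initial", "cell_diameter", "step_length",
                 "proliferation_rate", "alpha_max", "compaction", "flux",
                 "box_side", "pixel_size", "n_iterations", "seed",
                 "cancel_on_contact", "stride")
  build_abm <- function(x) {
    unknown <- setdiff(names(x), known_sim)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    args <- x[setdiff(names(x), c("flux", "box_side", "stride"))]
    if (!is.null(x$flux)) {
      fx <- x$flux
      bad <- setdiff(names(fx),
                     c("enabled", "direction", "scope", "small_threshold"))
      if (length(bad)) stop("unknown flux key(s): ", paste(bad, collapse = ", "))
      args$flux <- do.call(flux_spec, fx)
    }
    if (!is.null(x$box_side))
      args$box <- box_spec(parse_length(x$box_side,
                                        x$pixel_size %||% PIXEL_SIZE_UM))
    list(config = do.call(abm_config, args), stride = x$stride %||% 10L)
  }
  out <- switch(task,
    simulate = build_abm(raw),
    make_reference = {
      extra <- intersect(names(raw), c("replicates", "noise_sd_fraction"))
      c(build_abm(raw[setdiff(names(raw), extra)]), raw[extra])
    },
    smol_fit = {
      bad <- setdiff(names(raw), c("series_csv", "kernel", "n_initial", "kmax"))
      if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
      if (is.null(raw$series_csv)) stop("smol_fit task needs series_csv")
      raw
    },
    calibrate = {
      bad <- setdiff(names(raw),
                     c("reference_csv", "a0_grid", "kappa_grid", "flux_grid",
                       "replicates", known_sim))
      if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
      if (is.null(raw$reference_csv) || is.null(raw$a0_grid))
        stop("calibrate task needs reference_csv and a0_grid")
      extra <- c("reference_csv", "a0_grid", "kappa_grid", "flux_grid",
                 "replicates")
      c(build_abm(raw[setdiff(names(raw), extra)]),
        raw[intersect(names(raw), extra)])
    },
    stop("unknown task: ", task))
  c(list(task = task), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write trajectory snapshots as CSV
#'
#' Long format with columns \code{time_min, cell_id, x_um, y_um};
#' numbers are formatted with 9 significant digits so identical runs give
#' byte-identical files.
#'
#' @param traj an \code{abm_trajectory}
#' @param path output CSV path
#' @export
write_snapshot_csv <- function(traj, path) {
  write_csv9(as.data.frame(traj), path)
}

#' Read trajectory snapshots written by \code{\link{write_snapshot_csv}}
#'
#' @param path CSV path
#' @param config the \code{\link{abm_config}} of the run (needed to measure)
#' @return an \code{abm_trajectory}
#' @export
read_snapshot_csv <- function(path, config) {
  df <- read.csv(path)
  times <- sort(unique(df$time_min))
  snaps <- lapply(times, function(tm) {
    sub <- df[df$time_min == tm, ]
    structure(list(time = tm,
                   cells = data.frame(id = sub$cell_id, x = sub$x_um,
                                      y = sub$y_um),
                   next_id = max(sub$cell_id) + 1L),
              class = "abm_world")
  })
  structure(list(config = config, seed = NA_integer_, times = times,
                 snapshots = snaps), class = "abm_trajectory")
}

#' Write a measured time series as CSV
#' @param ts an \code{aggregate_ts}
#' @param path output CSV path
#' @export
write_timeseries_csv <- function(ts, path) {
  write_csv9(ts[, c("time_min", "n_aggregates", "normalized_n",
                    "mean_area_um2", "mean_area_px2")], path)
}

#' Write / read a reference series (CSV plus JSON provenance sidecar)
#'
#' @param ref an \code{agg_reference}
#' @param path CSV path; the provenance goes to \code{<path>.json}
#' @export
write_reference <- function(ref, path) {
  write_csv9(as.data.frame(ref)[, c("time_min", "n_norm_mean", "n_norm_sd",
                                    "area_mean_um2", "area_sd_um2")], path)
  prov <- attr(ref, "provenance")
  prov$n_initial <- attr(ref, "n_initial")
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- read.csv(path)
  sidecar <- paste0(path, ".json")
  prov <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  structure(df, class = c("agg_reference", "data.frame"),
            provenance = prov, n_initial = prov$n_initial)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run: resolved configuration, seed,
#' package version, timestamps, and an MD5 inventory of output files.
#'
#' @param path manifest path
#' @param config the resolved \code{\link{abm_config}} (or any list)
#' @param seed the seed used
#' @param outputs character vector of produced file paths
#' @param started POSIXct start time
#' @export
write_manifest <- function(path, config, seed, outputs,
                           started = Sys.time()) {
  cfg <- unclass(config)
  cfg$flux <- unclass(cfg$flux)
  cfg$box <- unclass(cfg$box)
  man <- list(package = "cellagg",
              version = as.character(utils::packageVersion("cellagg")),
              seed = seed,
              started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = cfg,
              outputs = lapply(outputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Export trajectory frames as image files
#'
#' Writes the rasterized binary masks as PNG files (one per snapshot) or a
#' single multi-page TIFF.  Requires the \pkg{png} or \pkg{tiff} package.
#'
#' @param traj an \code{abm_trajectory}
#' @param dir output directory (PNG) or file path (TIFF)
#' @param format \code{"png"} or \code{"tiff"}
#' @return invisibly, the written path(s)
#' @export
export_frames <- function(traj, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  masks <- lapply(traj$snapshots, function(w) {
    m <- rasterize(w, traj$config)
    # image origin top-left: flip rows so y increases downward
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    matrix(as.numeric(m), nrow(m), ncol(m))
  })
  if (format == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package png not available")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, sprintf("frame_t%06d.png", round(traj$times)))
    for (i in seq_along(masks)) png::writePNG(masks[[i]], paths[i])
    invisible(paths)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package tiff not available")
    tiff::writeTIFF(masks, dir)
    invisible(dir)
  }
}
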