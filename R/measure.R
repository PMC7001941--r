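#' Rasterize cell disks into the experimental viewport
#'
#' Produces a binary mask of the union of cell disks (radius d/2), sampled
#' at pixel centers under the minimal image convention.  The viewport is
#' anchored at the box origin; by default its width spans the full box
#' (1280 px for the calibrated 842.24 um box) and its height is capped at
#' 1080 px, reproducing the experimental 1280 x 1080 field of view.
#'
#' @param cells n x 2 position matrix, data.frame with x/y columns, or an
#'   \code{abm_world}
#' @param config an \code{\link{abm_config}} (supplies diameter, pixel size,
#'   box)
#' @param width_px,height_px viewport size in pixels; defaults as described
#' @return an integer 0/1 matrix of class \code{frame_mask} (rows = y,
#'   columns = x) with attributes \code{pixel_size} and \code{box_side}
#' @export
rasterize <- function(cells, config, width_px = NULL, height_px = NULL) {
  if (inherits(cells, "abm_world")) cells <- cells$cells
  pos <- cells_to_posid(cells)$pos
  L <- config$box$side_length
  ps <- config$pixel_size
  if (is.null(width_px)) width_px <- round(L / ps)
  if (is.null(height_px)) height_px <- min(round(L / ps), FIELD_HEIGHT_PX)
  m <- cpp_rasterize(pos, config$cell_diameter / 2, ps, L,
                     as.integer(width_px), as.integer(height_px))
  structure(m, class = "frame_mask", pixel_size = ps, box_side = L)
}

#' @export
print.frame_mask <- function(x, ...) {
  cat(sprintf("frame_mask: %d x %d px (%.3g um/px), %.1f%% foreground\n",
              ncol(x), nrow(x), attr(x, "pixel_size"), 100 * mean(x > 0)))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling; 8-connectivity by default (the convention
#' of Fiji-style particle analysis), switchable to 4.  For a
#' \code{frame_mask} whose viewport spans the full periodic box on an axis,
#' label connectivity wraps around that axis so a disk straddling the seam
#' stays one component; a cropped axis (like the 1080-px height of the
#' calibrated field of view) is never wrapped.  Components smaller than
#' \code{min_area} pixels can be dropped.
#'
#' @param mask binary matrix (a \code{frame_mask} or any 0/1 matrix)
#' @param connectivity 4 or 8
#' @param min_area minimum component pixel count to keep (default 0: keep all)
#' @param wrap_x,wrap_y override the periodic seam joining (default: derived
#'   from the \code{frame_mask} attributes, \code{FALSE} for plain matrices)
#' @return list with \code{labels} (integer matrix, 0 = background) and
#'   \code{sizes} (pixel count per component)
#' @export
label_components <- function(mask, connectivity = 8L, min_area = 0L,
                             wrap_x = NULL, wrap_y = NULL) {
  L <- attr(mask, "box_side")
  ps <- attr(mask, "pixel_size")
  full_span <- function(npx) !is.null(L) && npx == round(L / ps)
  if (is.null(wrap_x)) wrap_x <- full_span(ncol(mask))
  if (is.null(wrap_y)) wrap_y <- full_span(nrow(mask))
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  storage.mode(m) <- "integer"
  res <- cpp_label_mask(m, as.integer(connectivity), isTRUE(wrap_x),
                        isTRUE(wrap_y))
  if (min_area > 0L && length(res$sizes)) {
    keep <- which(res$sizes >= min_area)
    remap <- integer(length(res$sizes))
    remap[keep] <- seq_along(keep)
    lab <- res$labels
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    res <- list(labels = lab, sizes = res$sizes[keep])
  }
  res
}

#' Per-frame aggregate statistics
#'
#' The two experimental observables: the number of aggregates (connected
#' foreground components, single cells included) normalized by the initial
#' cell count, and the mean projected area.
#'
#' @param component_areas pixel counts per component (from
#'   \code{\link{label_components}})
#' @param n0 initial number of individual cells (normalization)
#' @param pixel_size um per pixel
#' @param time frame time in minutes
#' @return a one-row data.frame: \code{time_min}, \code{n_aggregates},
#'   \code{normalized_n}, \code{mean_area_px2}, \code{mean_area_um2}
#'   (\code{NA} when there are no components)
#' @export
frame_stats <- function(component_areas, n0, pixel_size = PIXEL_SIZE_UM,
                        time = NA_real_) {
  stop_unless(n0 >= 1, "n0 must be >= 1")
  k <- length(component_areas)
  mean_px <- if (k > 0) mean(component_areas) else NA_real_
  data.frame(time_min = time, n_aggregates = k, normalized_n = k / n0,
             mean_area_px2 = mean_px, mean_area_um2 = mean_px * pixel_size^2)
}

#' Aggregate count and area time series of a trajectory
#'
#' Runs the image-style measurement (rasterize, label, per-frame stats) on
#' every recorded snapshot, mirroring the analysis applied to experimental
#' time-lapse micrographs.
#'
#' @param traj an \code{abm_trajectory}
#' @param n0 normalization count; defaults to the configured N0
#' @param connectivity,min_area passed to \code{\link{label_components}}
#' @param width_px,height_px passed to \code{\link{rasterize}}
#' @return a data.frame of class \code{aggregate_ts}, one row per snapshot
#' @export
aggregate_timeseries <- function(traj, n0 = traj$config$n_initial,
                                 connectivity = 8L, min_area = 0L,
                                 width_px = NULL, height_px = NULL) {
  rows <- lapply(traj$snapshots, function(w) {
    mask <- rasterize(w, traj$config, width_px, height_px)
    comp <- label_components(mask, connectivity, min_area)
    frame_stats(comp$sizes, n0, traj$config$pixel_size, w$time)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aggregate_ts", "data.frame")
  attr(out, "n0") <- n0
  out
}

#' @export
plot.aggregate_ts <- function(x, which = c("count", "area"), ...) {
  which <- match.arg(which)
  if (which == "count")
    plot(x$time_min, x$normalized_n, type = "b", xlab = "time (min)",
         ylab = "normalized number of aggregates", ylim = c(0, 1.05), ...)
  else
    plot(x$time_min, x$mean_area_um2, type = "b", xlab = "time (min)",
         ylab = expression(paste("mean aggregate area (", mu, m^2, ")")), ...)
  invisible(x)
}

#' Circularity of large aggregates in a frame
#'
#' Rasterizes a configuration, labels components, assigns each cell to the
#' component under its center, and computes the circularity 4*pi*A/P^2 of
#' every component containing at least \code{min_cells} cells (perimeter
#' estimated from exposed 4-neighbor pixel edges).  Used for the compaction
#' contrast: compacted aggregates are rounder.
#'
#' @param world an \code{abm_world} (or cells data.frame)
#' @param config an \code{\link{abm_config}}
#' @param min_cells minimum member count of reported aggregates
#' @param connectivity component connectivity (default 8)
#' @return data.frame with per-aggregate \code{n_cells}, \code{area_px2},
#'   \code{perimeter_px}, \code{circularity}
#' @export
frame_circularity <- function(world, config, min_cells = 10L,
                              connectivity = 8L) {
  cells <- if (inherits(world, "abm_world")) world$cells else world
  mask <- rasterize(cells, config)
  comp <- label_components(mask, connectivity)
  if (length(comp$sizes) == 0L)
    return(data.frame(n_cells = integer(), area_px2 = numeric(),
                      perimeter_px = numeric(), circularity = numeric()))
  ps <- config$pixel_size
  # component under each cell center (centers may fall outside the viewport)
  ci <- floor(cells$y / ps) + 1L
  cj <- floor(cells$x / ps) + 1L
  inside <- ci >= 1L & ci <= nrow(mask) & cj >= 1L & cj <= ncol(mask)
  labs <- rep(0L, nrow(cells))
  labs[inside] <- comp$labels[cbind(ci[inside], cj[inside])]
  ncells <- tabulate(labs[labs > 0L], nbins = length(comp$sizes))
  per <- cpp_component_perimeter(comp$labels, length(comp$sizes))
  out <- data.frame(n_cells = ncells, area_px2 = comp$sizes,
                    perimeter_px = per,
                    circularity = 4 * pi * comp$sizes / per^2)
  out[out$n_cells >= min_cells, , drop = FALSE]
}

#' Unwrap per-cell tracks from a trajectory
#'
#' Accumulates minimal-image displacements between consecutive snapshots so
#' tracks live in the unbounded plane (required for MSD analysis).  Only
#' cells present in every snapshot are tracked; snapshots must be at a
#' constant stride.
#'
#' @param traj an \code{abm_trajectory}
#' @return object of class \code{track_set}: list with \code{times} and
#'   \code{x}, \code{y} (T x n matrices, one column per tracked cell)
#' @export
unwrap_tracks <- function(traj) {
  ids <- Reduce(intersect, lapply(traj$snapshots, function(w) w$cells$id))
  if (length(ids) == 0L) stop("no cell persists through the trajectory")
  Tn <- length(traj$snapshots)
  L <- traj$config$box$side_length
  x <- matrix(NA_real_, Tn, length(ids))
  y <- matrix(NA_real_, Tn, length(ids))
  for (t in seq_len(Tn)) {
    cells <- traj$snapshots[[t]]$cells
    i <- match(ids, cells$id)
    x[t, ] <- cells$x[i]
    y[t, ] <- cells$y[i]
  }
  ux <- apply(x, 2, function(col) c(col[1], col[1] + cumsum(mi_diff(diff(col), L))))
  uy <- apply(y, 2, function(col) c(col[1], col[1] + cumsum(mi_diff(diff(col), L))))
  structure(list(times = traj$times, x = ux, y = uy), class = "track_set")
}

mi_diff <- function(dx, L) dx - L * round(dx / L)

#' Mean squared displacement curve
#'
#' Time-origin-averaged MSD over all tracks at every available lag.
#'
#' @param tracks a \code{track_set}
#' @return data.frame with \code{lag_min} and \code{msd_um2}
#' @export
msd_curve <- function(tracks) {
  Tn <- nrow(tracks$x)
  if (Tn < 2L) stop("need at least two time points")
  dt <- diff(tracks$times)
  if (max(abs(dt - dt[1])) > 1e-9) stop("tracks must be evenly sampled")
  lags <- seq_len(Tn - 1L)
  msd <- vapply(lags, function(l) {
    dx <- tracks$x[(1 + l):Tn, , drop = FALSE] - tracks$x[1:(Tn - l), , drop = FALSE]
    dy <- tracks$y[(1 + l):Tn, , drop = FALSE] - tracks$y[1:(Tn - l), , drop = FALSE]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag_min = lags * dt[1], msd_um2 = msd)
}

#' Diffusion coefficient from MSD
#'
#' Least-squares slope of MSD(t) versus lag through the origin, over the
#' first half of the available lags, divided by 4 (2D diffusion:
#' MSD = 4 D t).
#'
#' @param tracks a \code{track_set}
#' @param max_lag_frac fraction of lags used in the fit (default 0.5)
#' @return diffusion coefficient in um^2/min
#' @export
msd_diffusion <- function(tracks, max_lag_frac = 0.5) {
  m <- msd_curve(tracks)
  k <- max(1L, floor(nrow(m) * max_lag_frac))
  m <- m[seq_len(k), ]
  slope <- sum(m$msd_um2 * m$lag_min) / sum(m$lag_min^2)
  slope / 4
}
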