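#' Replicate simulations with mean and SD curves
#'
#' Runs R independent simulations (seeds \code{base_seed + 0:(R-1)}) and
#' summarizes the measured normalized aggregate count and mean projected
#' area as per-time mean and standard deviation, mirroring the experimental
#' convention of averaging replicate fields with SD error bars.
#'
#' @param config an \code{\link{abm_config}}
#' @param R number of replicates (>= 2); seeds must be distinct
#' @param base_seed first replicate seed
#' @param stride snapshot interval in iterations
#' @return object of class \code{agg_replicates}: data.frame with
#'   \code{time_min}, \code{n_norm_mean}, \code{n_norm_sd},
#'   \code{area_mean_um2}, \code{area_sd_um2}, plus attributes
#'   (\code{config}, \code{R}, \code{base_seed})
#' @export
simulate_replicates <- function(config, R, base_seed = config$seed,
                                stride = 30L) {
  R <- as.integer(R)
  if (R < 2L) stop("R must be >= 2")
  seeds <- base_seed + seq_len(R) - 1L
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
  series <- lapply(seeds, function(s)
    aggregate_timeseries(run_abm(config, seed = s, stride = stride)))
  tgrid <- series[[1]]$time_min
  nmat <- vapply(series, `[[`, numeric(length(tgrid)), "normalized_n")
  amat <- vapply(series, `[[`, numeric(length(tgrid)), "mean_area_um2")
  if (length(tgrid) == 1L) { nmat <- t(nmat); amat <- t(amat) }
  out <- data.frame(time_min = tgrid,
                    n_norm_mean = rowMeans(nmat),
                    n_norm_sd = apply(nmat, 1, sd),
                    area_mean_um2 = rowMeans(amat),
                    area_sd_um2 = apply(amat, 1, sd))
  structure(out, class = c("agg_replicates", "data.frame"),
            config = config, R = R, base_seed = base_seed)
}

#' Synthetic reference curves from known parameters
#'
#' Generates a reference (stand-in for experimental mean curves) by running
#' replicate simulations at a known "true" configuration, optionally adding
#' multiplicative Gaussian noise to the means.  The provenance attribute
#' records the generating parameters, enabling parameter-recovery studies.
#'
#' @param true_config generating \code{\link{abm_config}}
#' @param R replicates (>= 3, as in triplicate experiments)
#' @param seed base seed
#' @param noise_sd_fraction SD of multiplicative noise applied to the mean
#'   curves (0 = none)
#' @param stride snapshot interval
#' @return object of class \code{agg_reference}: data.frame as in
#'   \code{\link{simulate_replicates}} with a \code{provenance} attribute
#' @export
make_synthetic_reference <- function(true_config, R = 3L, seed = 1L,
                                     noise_sd_fraction = 0, stride = 30L) {
  if (R < 3L) stop("R must be >= 3")
  rep <- simulate_replicates(true_config, R, base_seed = seed, stride = stride)
  out <- as.data.frame(rep)
  if (noise_sd_fraction > 0) {
    set.seed(seed + 10007L)  # noise stream distinct from the simulation seeds
    out$n_norm_mean <- out$n_norm_mean *
      (1 + rnorm(nrow(out), 0, noise_sd_fraction))
    out$area_mean_um2 <- out$area_mean_um2 *
      (1 + rnorm(nrow(out), 0, noise_sd_fraction))
  }
  prov <- list(source = "synthetic",
               a0_um = true_config$a0,
               proliferation_rate = true_config$proliferation_rate,
               alpha_max = true_config$alpha_max,
               flux_enabled = true_config$flux$enabled,
               n_initial = true_config$n_initial,
               cell_diameter = true_config$cell_diameter,
               box_side = true_config$box$side_length,
               n_iterations = true_config$n_iterations,
               R = R, seed = seed,
               noise_sd_fraction = noise_sd_fraction)
  structure(out, class = c("agg_reference", "data.frame"),
            provenance = prov, n_initial = true_config$n_initial)
}

#' Fit objective between simulated and reference curves
#'
#' Weighted sum of squares of the normalized-count and mean-area
#' discrepancies, the quantitative form of the visual matching used to tune
#' the step length (count curve) and the proliferation rate (late-time area
#' curve).  Simulated curves are linearly interpolated onto the reference
#' time grid; areas are scaled by the reference's initial mean area so both
#' terms are dimensionless.
#'
#' @param sim an \code{agg_replicates} (or data.frame with the same columns)
#' @param ref an \code{agg_reference} (or data.frame with the same columns)
#' @param w_n,w_a weights of the count and area terms
#' @param area_scale area normalization; defaults to the reference's initial
#'   mean area
#' @return scalar objective (>= 0)
#' @export
fit_objective <- function(sim, ref, w_n = 1, w_a = 1, area_scale = NULL) {
  if (min(ref$time_min) > max(sim$time_min) ||
      max(ref$time_min) < min(sim$time_min))
    stop("simulated and reference time ranges are disjoint")
  tt <- ref$time_min[ref$time_min >= min(sim$time_min) &
                     ref$time_min <= max(sim$time_min)]
  n_sim <- approx(sim$time_min, sim$n_norm_mean, xout = tt)$y
  a_sim <- approx(sim$time_min, sim$area_mean_um2, xout = tt)$y
  keep <- match(tt, ref$time_min)
  if (is.null(area_scale)) area_scale <- ref$area_mean_um2[1]
  w_n * sum((n_sim - ref$n_norm_mean[keep])^2) +
    w_a * sum(((a_sim - ref$area_mean_um2[keep]) / area_scale)^2)
}

#' Grid-search calibration of the agent-based model
#'
#' Exhaustively evaluates the fit objective over a grid of step lengths,
#' proliferation rates and flux settings (alpha_max, diameter and N0 stay
#' fixed: alpha_max is set from cell-pair superimposition images and N0 from
#' the first frame of the reference).  Each grid point is scored with R
#' replicate simulations.  Ties break toward smaller a0, then smaller
#' kappa, then flux off.
#'
#' @param ref an \code{agg_reference} (its \code{n_initial} attribute, or
#'   \code{n_initial} in \code{base_config}, fixes N0)
#' @param base_config template \code{\link{abm_config}} holding the fixed
#'   parameters
#' @param a0_grid step lengths to try (um, or \code{"px"} strings)
#' @param kappa_grid proliferation rates to try
#' @param flux_grid logical vector of flux settings to try
#' @param R replicates per grid point
#' @param seed base seed (each grid point reuses the same replicate seeds:
#'   common random numbers reduce comparison noise)
#' @param stride snapshot interval
#' @param w_n,w_a objective weights
#' @return object of class \code{abm_calibration}: list with \code{best}
#'   (named list a0, kappa, flux), \code{objective}, \code{grid} (full
#'   table), \code{R}, \code{seed}
#' @export
abm_calibrate <- function(ref, base_config, a0_grid,
                          kappa_grid = base_config$proliferation_rate,
                          flux_grid = base_config$flux$enabled,
                          R = 5L, seed = 1L, stride = 30L,
                          w_n = 1, w_a = 1) {
  a0_um <- unname(vapply(a0_grid, parse_length, numeric(1),
                         pixel_size = base_config$pixel_size))
  g <- expand.grid(a0 = a0_um, kappa = kappa_grid, flux = flux_grid,
                   KEEP.OUT.ATTRS = FALSE)
  if (nrow(g) == 0L) stop("empty parameter grid")
  n0 <- attr(ref, "n_initial")
  if (is.null(n0)) n0 <- base_config$n_initial
  g$objective <- NA_real_
  for (i in seq_len(nrow(g))) {
    cfg <- base_config
    cfg$n_initial <- as.integer(n0)
    cfg$a0 <- g$a0[i]
    cfg$proliferation_rate <- g$kappa[i]
    cfg$flux$enabled <- g$flux[i]
    sim <- simulate_replicates(cfg, R, base_seed = seed, stride = stride)
    g$objective[i] <- fit_objective(sim, ref, w_n, w_a)
  }
  o <- order(g$objective, g$a0, g$kappa, g$flux)
  best <- g[o[1], ]
  structure(list(best = list(a0 = best$a0, kappa = best$kappa,
                             flux = best$flux),
                 objective = best$objective, grid = g,
                 R = as.integer(R), seed = as.integer(seed)),
            class = "abm_calibration")
}

#' @export
print.abm_calibration <- function(x, ...) {
  cat("abm_calibration over", nrow(x$grid), "grid points,",
      x$R, "replicates each\n")
  cat(sprintf("  best: a0 = %.4g um, kappa = %.3g /min, flux %s (objective %.5g)\n",
              x$best$a0, x$best$kappa, if (x$best$flux) "on" else "off",
              x$objective))
  invisible(x)
}

#' @export
summary.abm_calibration <- function(object, ...) {
  g <- object$grid[order(object$grid$objective), ]
  print(object)
  cat("grid (best first):\n")
  print(utils::head(g, 10), row.names = FALSE)
  invisible(object)
}

#' @export
plot.abm_calibration <- function(x, ...) {
  g <- x$grid
  plot(g$a0, g$objective, log = "y", xlab = "a0 (um)",
       ylab = "objective (log scale)", ...)
  invisible(x)
}

#' Parameter-recovery study
#'
#' End-to-end validation of the calibration workflow: build a synthetic
#' reference at known parameters, run the grid search, and report true
#' versus recovered values with relative errors.
#'
#' @param true_config generating configuration
#' @param a0_grid,kappa_grid,flux_grid search grid (should bracket the true
#'   values)
#' @param R replicates per grid point
#' @param seed base seed; the reference uses \code{seed + 20011} so its
#'   replicates are independent of the search replicates
#' @param ref_R replicates for the reference
#' @param stride snapshot interval
#' @return data.frame with one row per fitted parameter: \code{parameter},
#'   \code{true}, \code{recovered}, \code{rel_error}
#' @export
recovery_report <- function(true_config, a0_grid,
                            kappa_grid = true_config$proliferation_rate,
                            flux_grid = true_config$flux$enabled,
                            R = 5L, seed = 1L, ref_R = 3L, stride = 30L) {
  ref <- make_synthetic_reference(true_config, R = ref_R,
                                  seed = seed + 20011L, stride = stride)
  cal <- abm_calibrate(ref, true_config, a0_grid, kappa_grid, flux_grid,
                       R = R, seed = seed, stride = stride)
  rel <- function(tr, rec) if (tr == 0) abs(rec - tr) else abs(rec - tr) / abs(tr)
  out <- data.frame(
    parameter = c("a0_um", "kappa", "flux"),
    true = c(true_config$a0, true_config$proliferation_rate,
             as.numeric(true_config$flux$enabled)),
    recovered = c(cal$best$a0, cal$best$kappa, as.numeric(cal$best$flux)))
  out$rel_error <- mapply(rel, out$true, out$recovered)
  attr(out, "calibration") <- cal
  out
}
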