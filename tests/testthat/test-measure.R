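test_that("rasterized disk area matches the analytic disk area", {
  cfg <- test_config(n_initial = 1L, box_side = 200)
  mask <- rasterize(rbind(c(100, 100)), cfg)
  a_px <- sum(mask) * cfg$pixel_size^2
  expect_equal(a_px, pi * (13.2 / 2)^2, tolerance = 0.05)
  # empty input gives an all-background image
  m0 <- rasterize(matrix(numeric(0), 0, 2), cfg)
  expect_equal(sum(m0), 0)
  # two cells at the minimal center distance form one component
  dmin <- min_center_distance(cfg)
  m2 <- rasterize(rbind(c(100, 100), c(100 + dmin, 100)), cfg)
  expect_equal(length(label_components(m2)$sizes), 1L)
})

test_that("disks wrap across the periodic seam of the viewport", {
  cfg <- test_config(n_initial = 1L, box_side = 200)
  mask <- rasterize(rbind(c(0.5, 100)), cfg)
  a_px <- sum(mask) * cfg$pixel_size^2
  expect_equal(a_px, pi * (13.2 / 2)^2, tolerance = 0.05)
})

test_that("component labeling honors the 4/8 connectivity switch", {
  # two blobs joined by a single diagonal bridge
  m <- matrix(0L, 7, 7)
  m[2:3, 2:3] <- 1L
  m[4, 4] <- 1L          # diagonal bridge pixel
  m[5:6, 5:6] <- 1L
  expect_equal(length(label_components(m, connectivity = 8)$sizes), 1L)
  expect_equal(length(label_components(m, connectivity = 4)$sizes), 3L)
  # checkerboard: fully connected under 8, isolated under 4
  cb <- outer(1:6, 1:6, function(i, j) as.integer((i + j) %% 2 == 0))
  expect_equal(length(label_components(cb, connectivity = 8)$sizes), 1L)
  expect_equal(length(label_components(cb, connectivity = 4)$sizes), sum(cb))
  # min_area filter drops small components
  expect_equal(length(label_components(m, connectivity = 4, min_area = 2)$sizes), 2L)
})

test_that("labeling agrees with the EBImage oracle under 4-connectivity", {
  set.seed(30)
  m <- matrix(rbinom(60 * 40, 1, 0.35), 60, 40)
  mine <- label_components(m, connectivity = 4)
  ref <- EBImage::bwlabel(m)
  expect_equal(length(mine$sizes), max(ref))
  expect_equal(sort(mine$sizes), sort(tabulate(ref[ref > 0])))
})

test_that("frame statistics implement the normalized count and mean area", {
  fs <- frame_stats(c(100, 300), n0 = 50, pixel_size = 0.658, time = 10)
  expect_equal(fs$n_aggregates, 2L)
  expect_equal(fs$normalized_n, 0.04)
  expect_equal(fs$mean_area_px2, 200)
  expect_equal(fs$mean_area_um2, 200 * 0.658^2)
  fs1 <- frame_stats(400, n0 = 1, time = 0)
  expect_equal(fs1$mean_area_um2, 400 * 0.658^2, tolerance = 1e-12)
  empty <- frame_stats(numeric(0), n0 = 10)
  expect_equal(empty$n_aggregates, 0L)
  expect_true(is.na(empty$mean_area_um2))
})

test_that("well-separated initial cells give normalized count 1", {
  # regular sparse grid: every cell its own component
  cfg <- test_config(n_initial = 16L, box_side = 200)
  gx <- rep(seq(25, 175, by = 50), 4)
  gy <- rep(seq(25, 175, by = 50), each = 4)
  mask <- rasterize(cbind(gx, gy), cfg)
  comp <- label_components(mask)
  fs <- frame_stats(comp$sizes, n0 = 16, cfg$pixel_size, 0)
  expect_equal(fs$normalized_n, 1)
})

test_that("raster component count equals the graph cluster count away from marginal gaps", {
  cfg <- test_config(n_initial = 9L, box_side = 300, alpha_max = 0.7)
  dmin <- min_center_distance(cfg)
  # three singletons, two pairs, one triple; clusters separated by >> 2 px
  cells <- rbind(c(30, 30), c(150, 30), c(270, 30),
                 c(30, 150), c(30 + dmin, 150),
                 c(150, 150), c(150, 150 + dmin),
                 c(250, 250), c(250 + dmin, 250), c(250 + 2 * dmin, 250))
  gl <- cluster_labels(cells, cfg$cell_diameter + 1e-6, cfg$box)
  mask <- rasterize(cells, cfg)
  comp <- label_components(mask)
  expect_equal(length(comp$sizes), length(gl$sizes))
})

test_that("mean area is translation invariant up to pixelization jitter", {
  cfg <- test_config(n_initial = 3L, box_side = 200)
  cells <- rbind(c(60, 60), c(63, 60), c(140, 150))
  base <- frame_stats(label_components(rasterize(cells, cfg))$sizes, 3,
                      cfg$pixel_size)$mean_area_um2
  set.seed(31)
  for (i in 1:10) {
    sh <- runif(2, 0, 200)
    moved <- wrap_position(sweep(cells, 2, sh, "+"), 200)
    a <- frame_stats(label_components(rasterize(moved, cfg))$sizes, 3,
                     cfg$pixel_size)$mean_area_um2
    expect_equal(a, base, tolerance = 0.05)
  }
})

test_that("the calibrated box maps to the experimental 1280 x 1080 viewport", {
  cfg <- abm_config(n_initial = 1L)  # default 842.24 um box
  mask <- rasterize(rbind(c(400, 400)), cfg)
  expect_equal(dim(mask), c(1080L, 1280L))
})

test_that("trajectory time series tracks merging and proliferation", {
  cfg <- test_config(n_initial = 60L, box_side = 250, kappa = 0,
                     n_iterations = 100L)
  traj <- run_abm(cfg, seed = 41, stride = 20L)
  ts <- aggregate_timeseries(traj)
  expect_equal(nrow(ts), length(traj$snapshots))
  # merging-only dynamics: normalized count non-increasing
  expect_true(all(diff(ts$normalized_n) <= 0))
  expect_true(all(ts$mean_area_um2 > 0))
  # constant world gives a constant series
  cfg0 <- test_config(n_initial = 20L, step_length = 0, kappa = 0,
                      n_iterations = 30L)
  ts0 <- aggregate_timeseries(run_abm(cfg0, seed = 42, stride = 10L))
  expect_equal(length(unique(ts0$n_aggregates)), 1L)
  expect_equal(length(unique(ts0$mean_area_um2)), 1L)
})

test_that("post-aggregation area growth is driven by proliferation", {
  cfg <- test_config(n_initial = 40L, box_side = 250, kappa = 5e-3,
                     n_iterations = 240L)
  slopes <- vapply(1:4, function(seed) {
    ts <- aggregate_timeseries(run_abm(cfg, seed = seed, stride = 40L))
    late <- ts[ts$time_min >= 80, ]
    unname(coef(lm(mean_area_um2 ~ time_min, late))[2])
  }, numeric(1))
  expect_gt(mean(slopes), 0)
})

test_that("MSD estimation recovers immobility and the a0 scaling", {
  cfg <- test_config(n_initial = 10L, box_side = 500, step_length = 0,
                     kappa = 0, n_iterations = 30L)
  tr <- unwrap_tracks(run_abm(cfg, seed = 50, stride = 1L))
  expect_equal(msd_diffusion(tr), 0)
  # doubling a0 quadruples D (isolated walkers, loose stochastic band)
  D <- vapply(c(1, 2), function(a0) {
    cfg <- abm_config(n_initial = 200L, cell_diameter = 13.2,
                      step_length = a0, proliferation_rate = 0,
                      alpha_max = 0.7, box = box_spec(5000),
                      n_iterations = 80L)
    msd_diffusion(unwrap_tracks(run_abm(cfg, seed = 51, stride = 1L)))
  }, numeric(1))
  expect_equal(D[2] / D[1], 4, tolerance = 0.2)
  expect_error(msd_curve(list(times = 0, x = matrix(0, 1, 1),
                              y = matrix(0, 1, 1))), "two time points")
})
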