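test_that("replicate simulation summarizes mean and sd per time point", {
  cfg <- test_config(n_initial = 30L, box_side = 200, n_iterations = 20L)
  rep2 <- simulate_replicates(cfg, R = 3L, base_seed = 1L, stride = 10L)
  expect_s3_class(rep2, "agg_replicates")
  expect_equal(rep2$time_min, c(0, 10, 20))
  expect_true(all(rep2$n_norm_sd >= 0))
  expect_error(simulate_replicates(cfg, R = 1L), ">= 2")
  # frozen dynamics: every replicate's curve is constant in time, so the
  # mean and sd columns are flat (replicates still differ in their random
  # initial placement)
  cfg0 <- test_config(n_initial = 20L, step_length = 0, kappa = 0,
                      n_iterations = 10L)
  rep0 <- simulate_replicates(cfg0, R = 3L, base_seed = 5L, stride = 5L)
  expect_true(all(diff(rep0$n_norm_mean) == 0))
  expect_true(all(diff(rep0$n_norm_sd) == 0))
  expect_true(all(diff(rep0$area_sd_um2) == 0))
})

test_that("the fit objective is zero at equality and grows with discrepancy", {
  ref <- structure(data.frame(time_min = seq(0, 100, 20),
                              n_norm_mean = seq(1, 0.5, length.out = 6),
                              n_norm_sd = 0.05,
                              area_mean_um2 = seq(150, 400, length.out = 6),
                              area_sd_um2 = 20),
                   class = c("agg_reference", "data.frame"))
  expect_equal(fit_objective(ref, ref), 0)
  off <- ref
  off$n_norm_mean[3] <- off$n_norm_mean[3] + 0.1
  expect_gt(fit_objective(off, ref), 0)
  worse <- off
  worse$n_norm_mean[5] <- worse$n_norm_mean[5] + 0.2
  expect_gt(fit_objective(worse, ref), fit_objective(off, ref))
  # weight degeneracy: w_a = 0 ignores the area channel entirely
  area_off <- ref
  area_off$area_mean_um2 <- area_off$area_mean_um2 * 3
  expect_equal(fit_objective(area_off, ref, w_a = 0), 0)
  expect_gt(fit_objective(area_off, ref), 0)
  # disjoint time ranges are an error
  late <- ref
  late$time_min <- late$time_min + 1000
  expect_error(fit_objective(late, ref), "disjoint")
})

test_that("synthetic references are reproducible and carry provenance", {
  cfg <- test_config(n_initial = 25L, box_side = 200, n_iterations = 20L,
                     kappa = 1e-3)
  r1 <- make_synthetic_reference(cfg, R = 3L, seed = 7L, stride = 10L)
  r2 <- make_synthetic_reference(cfg, R = 3L, seed = 7L, stride = 10L)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  prov <- attr(r1, "provenance")
  expect_equal(prov$a0_um, cfg$a0)
  expect_equal(prov$n_initial, 25L)
  expect_error(make_synthetic_reference(cfg, R = 2L), ">= 3")
  rn <- make_synthetic_reference(cfg, R = 3L, seed = 7L, stride = 10L,
                                 noise_sd_fraction = 0.05)
  expect_false(identical(rn$n_norm_mean, r1$n_norm_mean))
  # provenance round-trips through the CSV + JSON sidecar
  path <- file.path(tempdir(), "ref.csv")
  write_reference(r1, path)
  back <- read_reference(path)
  expect_equal(back$n_norm_mean, r1$n_norm_mean, tolerance = 1e-8)
  expect_equal(attr(back, "provenance")$a0_um, cfg$a0, tolerance = 1e-8)
  expect_equal(attr(back, "n_initial"), 25L)
  unlink(c(path, paste0(path, ".json")))
})

test_that("a single-point grid returns that point", {
  cfg <- test_config(n_initial = 25L, box_side = 200, n_iterations = 20L)
  ref <- make_synthetic_reference(cfg, R = 3L, seed = 3L, stride = 10L)
  cal <- abm_calibrate(ref, cfg, a0_grid = cfg$a0, R = 2L, seed = 11L,
                       stride = 10L)
  expect_equal(cal$best$a0, cfg$a0)
  expect_equal(nrow(cal$grid), 1L)
  expect_error(abm_calibrate(ref, cfg, a0_grid = numeric(0)), "empty")
})

test_that("grid search recovers the generating step length and flux setting", {
  cfg <- test_config(n_initial = 100L, box_side = 300, step_length = "4 px",
                     kappa = 0, n_iterations = 240L)
  ref <- make_synthetic_reference(cfg, R = 4L, seed = 101L, stride = 30L)
  cal <- abm_calibrate(ref, cfg, a0_grid = c("1 px", "4 px", "12 px"),
                       R = 3L, seed = 13L, stride = 30L)
  expect_equal(cal$best$a0, parse_length("4 px"))
  # objective landscape: both too-slow and too-fast are worse than the truth
  g <- cal$grid[order(cal$grid$a0), ]
  expect_gt(g$objective[1], g$objective[2])
  expect_gt(g$objective[3], g$objective[2])
  # flux off reference against an {off, on} grid selects off
  cal_f <- abm_calibrate(ref, cfg, a0_grid = cfg$a0,
                         flux_grid = c(FALSE, TRUE), R = 3L, seed = 17L,
                         stride = 30L)
  expect_false(cal_f$best$flux)
})

test_that("recovery_report round-trips parameters through the full workflow", {
  cfg <- test_config(n_initial = 50L, box_side = 300, step_length = "4 px",
                     kappa = 0, n_iterations = 100L)
  rec <- recovery_report(cfg, a0_grid = c("2 px", "4 px", "8 px"),
                         R = 3L, seed = 19L, ref_R = 3L, stride = 25L)
  expect_equal(rec$recovered[rec$parameter == "a0_um"],
               rec$true[rec$parameter == "a0_um"])
  expect_true(all(c("parameter", "true", "recovered", "rel_error") %in%
                  names(rec)))
})
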