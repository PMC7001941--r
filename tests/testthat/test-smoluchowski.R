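test_that("constant-kernel closed form has the right limits and half-life", {
  expect_equal(constant_kernel_total(0, 400, 1e-4), 400)
  expect_equal(constant_kernel_total(c(0, 50, 1000), 400, 0), rep(400, 3))
  K <- 3e-5; N0 <- 250
  expect_equal(constant_kernel_total(1 / (K * N0), N0, K), N0 / 2)
})

test_that("coagulation RHS matches the general gain/loss double sum", {
  set.seed(60)
  kmax <- 6
  for (rep in 1:5) {
    spec <- runif(kmax, 0, 10)
    K <- 2.5e-3
    got <- coagulation_rhs(spec, kernel_spec("constant", K))
    # the rate is defined via dN/dt = -K N^2, i.e. kernel entries 2K in the
    # gain/loss double sum
    want <- brute_coagulation_rhs(spec, matrix(2 * K, kmax, kmax))
    expect_equal(got, want, tolerance = 1e-10)
    # when no occupied pair can coagulate past the truncation, the totals
    # identity dN/dt = -K N^2 holds exactly
    spec_low <- c(runif(3, 0, 10), rep(0, 3))
    d_low <- coagulation_rhs(spec_low, kernel_spec("constant", K))
    expect_equal(sum(d_low), -K * sum(spec_low)^2, tolerance = 1e-10)
    # monomer-only kernel as a matrix: K_1j = K_j1 = K1, else 0
    K1 <- 4e-3
    Km <- matrix(0, kmax, kmax); Km[1, ] <- K1; Km[, 1] <- K1
    got_m <- coagulation_rhs(spec, kernel_spec("monomer_only", K1))
    want_m <- brute_coagulation_rhs(spec, Km)
    # sizes >= 3 and size 1 follow the double sum exactly; the dimer source
    # carries the corrected +N1^2/2 sign
    expect_equal(got_m, want_m, tolerance = 1e-10)
  }
  expect_error(coagulation_rhs(5, kernel_spec("constant", 1)), "kmax")
})

test_that("monomer-only RHS special cases", {
  # all mass in monomers: dN/dt = -K1 N1^2 / 2
  K1 <- 1e-3
  d <- coagulation_rhs(c(100, 0, 0, 0), kernel_spec("monomer_only", K1))
  expect_equal(sum(d), -0.5 * K1 * 100^2)
  # no monomers left: aggregates cannot react
  d0 <- coagulation_rhs(c(0, 5, 3, 2), kernel_spec("monomer_only", K1))
  expect_equal(d0, rep(0, 4))
})

test_that("k-resolved monomer-only derivatives telescope to the total-number equation", {
  set.seed(61)
  for (rep in 1:20) {
    kmax <- sample(50:200, 1)
    spec <- runif(kmax, 0, 5)
    spec[kmax] <- 0  # no occupancy at the truncation edge
    K1 <- 10^runif(1, -5, -2)
    d <- coagulation_rhs(spec, kernel_spec("monomer_only", K1))
    N1 <- spec[1]; N <- sum(spec)
    expect_equal(sum(d), K1 * N1 * (0.5 * N1 - N), tolerance = 1e-10)
  }
})

test_that("numerical integration reproduces the constant-kernel closed form", {
  N0 <- 150; K <- 2e-4
  tt <- seq(0, 10 / (K * N0), length.out = 25)
  kin <- integrate_kinetics(N0, kernel_spec("constant", K), tt, kmax = 256L)
  expect_lt(max(abs(kin$totals - constant_kernel_total(kin$times, N0, K)) /
                constant_kernel_total(kin$times, N0, K)), 1e-6)
})

test_that("pure coagulation conserves mass and never increases the total", {
  N0 <- 200; K1 <- 1e-4
  tt <- seq(0, 400, by = 20)
  kin <- integrate_kinetics(N0, kernel_spec("monomer_only", K1), tt,
                            kmax = 512L)
  mass <- kin$spectra %*% seq_len(kin$kmax)
  expect_equal(as.numeric(mass) / N0, rep(1, length(kin$times)),
               tolerance = 1e-6)
  expect_true(all(diff(kin$totals) <= 1e-9))
  expect_true(all(kin$spectra > -1e-8))
})

test_that("truncation-induced mass loss triggers automatic kmax doubling", {
  # tiny kmax forces mass past the truncation edge
  kin <- integrate_kinetics(100, kernel_spec("monomer_only", 5e-3),
                            seq(0, 50, 5), kmax = 4L)
  expect_gt(kin$kmax, 4L)
  expect_lte(kin$mass_loss_rel, 0.01)
})

test_that("kernel rate is recovered exactly from noise-free closed-form data", {
  N0 <- 300; K_true <- 5e-5
  tt <- seq(0, 600, by = 30)
  series <- data.frame(time = tt, count = constant_kernel_total(tt, N0, K_true))
  fit <- smol_fit(series, kernel = "constant", N0 = N0)
  expect_equal(fit$rate, K_true, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  # formula interface agrees
  fit2 <- smol_fit(count ~ time, data = series, kernel = "constant", N0 = N0)
  expect_equal(coef(fit2), coef(fit))
  expect_equal(unname(coef(fit)), fit$rate)
})

test_that("monomer-only rate is recovered from self-generated data", {
  N0 <- 200; K1_true <- 8e-5
  tt <- seq(0, 500, by = 50)
  kin <- integrate_kinetics(N0, kernel_spec("monomer_only", K1_true), tt,
                            kmax = 256L)
  series <- data.frame(time = kin$times, count = kin$totals)
  fit <- smol_fit(series, kernel = "monomer_only", N0 = N0, kmax = 256L)
  expect_equal(fit$rate, K1_true, tolerance = 1e-5)
})

test_that("rate recovery is robust to multiplicative noise", {
  N0 <- 300; K_true <- 5e-5
  tt <- seq(0, 600, by = 30)
  clean <- constant_kernel_total(tt, N0, K_true)
  set.seed(62)
  err <- vapply(1:20, function(i) {
    noisy <- clean * (1 + rnorm(length(clean), 0, 0.05))
    fit <- smol_fit(data.frame(time = tt, count = abs(noisy)),
                    kernel = "constant", N0 = N0)
    abs(fit$rate - K_true) / K_true
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("degenerate flat series yields rate zero with a warning", {
  series <- data.frame(time = seq(0, 100, 10), count = rep(50, 11))
  expect_warning(fit <- smol_fit(series, kernel = "constant", N0 = 50),
                 "rate 0|constant counts")
  expect_equal(fit$rate, 0)
})

test_that("model selection identifies the generating kernel", {
  N0 <- 200; tt <- seq(0, 600, by = 40)
  cst <- data.frame(time = tt,
                    count = constant_kernel_total(tt, N0, 6e-5))
  sel <- select_kernel(cst, N0 = N0, kmax = 128L)
  expect_equal(sel$best, "constant")
  kin <- integrate_kinetics(N0, kernel_spec("monomer_only", 6e-5), tt,
                            kmax = 128L)
  mono <- data.frame(time = kin$times, count = kin$totals)
  sel2 <- select_kernel(mono, N0 = N0, kmax = 128L)
  expect_equal(sel2$best, "monomer_only")
  expect_lt(sel2$sse[["monomer_only"]], sel2$sse[["constant"]])
})

test_that("fitted-model methods are mutually consistent", {
  N0 <- 250; K <- 4e-5
  tt <- seq(0, 500, 25)
  series <- data.frame(time = tt, count = constant_kernel_total(tt, N0, K))
  fit <- smol_fit(series, kernel = "constant", N0 = N0)
  expect_equal(fitted(fit), predict(fit), tolerance = 1e-12)
  expect_equal(residuals(fit), series$count - fitted(fit))
  expect_equal(predict(fit, newdata = data.frame(time = 0)), N0)
  expect_output(print(fit), "constant kernel")
  expect_output(summary(fit), "model comparison")
})

test_that("kernel rate unit conversions match the printed identity", {
  # 6.4e-14 m2/s is 3.84 um2/min
  expect_equal(convert_rate_units(6.4e-14, "m2_s", "um2_min"), 3.84)
  expect_equal(convert_rate_units(0, "m2_s", "um2_min"), 0)
  r <- 3.8
  round_trip <- convert_rate_units(convert_rate_units(r, "um2_min", "m2_s"),
                                   "m2_s", "um2_min")
  expect_equal(round_trip, r, tolerance = 1e-12)
  # count-space conversion scales by the field area
  fa <- field_area_um2()
  expect_equal(fa, 842.24 * 710.64, tolerance = 1e-9)
  expect_equal(convert_rate_units(2e-6, "count_min", "um2_min", fa),
               2e-6 * fa)
  expect_error(convert_rate_units(1, "m2_s", "furlongs"), "unknown unit")
})

test_that("ODE totals agree with the Gillespie stochastic oracle", {
  N0 <- 2000; K1 <- 2e-5; reps <- 100
  checkpoints <- seq(10, 100, by = 10)
  set.seed(63)
  sims <- gillespie_monomer_totals(N0, K1, checkpoints, reps)
  kin <- integrate_kinetics(N0, kernel_spec("monomer_only", K1),
                            checkpoints, kmax = 256L)
  ode <- kin$totals[match(checkpoints, kin$times)]
  mu <- colMeans(sims)
  se <- apply(sims, 2, sd) / sqrt(reps)
  expect_true(all(abs(mu - ode) <= 3 * se))
})
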