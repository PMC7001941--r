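#' Aggregation kernel specification
#'
#' Two perikinetic scenarios: a constant kernel (every pair of clusters
#' merges at the same rate K) and a monomer-only kernel (only individual
#' cells move: K_1j = K_j1 = K1 and K_ij = 0 for i, j > 1).  Rates are in
#' count space (per pair per minute); \code{\link{convert_rate_units}} maps
#' to um^2/min and m^2/s via the observed field area.  The constant-kernel
#' rate follows the classical coagulation-constant convention, defined by
#' the total-number equation dN/dt = -K N^2 (closed form
#' \code{N0/(1 + K N0 t)}); the monomer-only rate K1 enters the spectrum
#' equations directly, giving dN/dt = K1 N1 (N1/2 - N).
#'
#' @param kind \code{"constant"} or \code{"monomer_only"}
#' @param rate kernel rate, >= 0 (count space, per min)
#' @return an object of class \code{kernel_spec}
#' @export
kernel_spec <- function(kind = c("constant", "monomer_only"), rate) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("rate must be a single non-negative number")
  structure(list(kind = kind, rate = as.numeric(rate)), class = "kernel_spec")
}

#' Constant-kernel total aggregate number (closed form)
#'
#' With a constant kernel the total obeys dN/dt = -K N^2, giving
#' \code{N(t) = N0 / (1 + K N0 t)}.
#'
#' @param t time(s), same units as 1/(K N0)
#' @param N0 initial count
#' @param K kernel rate
#' @return total count at \code{t}
#' @export
constant_kernel_total <- function(t, N0, K) {
  stopifnot(K >= 0, N0 > 0, all(t >= 0))
  N0 / (1 + K * N0 * t)
}

#' Right-hand side of the coagulation equations
#'
#' The size-spectrum derivative dN_k/dt for a finite spectrum
#' \code{N_1..N_kmax}.  For the constant kernel this is the classical
#' gain/loss double sum (gain into sizes beyond kmax is dropped: truncation
#' loses mass, which \code{\link{integrate_kinetics}} monitors).  For the
#' monomer-only kernel: dN1/dt = -K1 N1 N, dN2/dt = K1 (N1^2/2 - N1 N2),
#' dNk/dt = K1 N1 (N_{k-1} - N_k) for k >= 3, whose sum telescopes to the
#' total-number equation dN/dt = K1 N1 (N1/2 - N).
#'
#' @param spectrum numeric vector \code{N_1..N_kmax} (kmax >= 2)
#' @param kernel a \code{\link{kernel_spec}}
#' @return derivative vector of the same length
#' @export
coagulation_rhs <- function(spectrum, kernel) {
  kmax <- length(spectrum)
  if (kmax < 2L) stop("spectrum needs kmax >= 2")
  N <- sum(spectrum)
  K <- kernel$rate
  if (kernel$kind == "constant") {
    # The rate K is defined by the total-number equation dN/dt = -K N^2
    # (the classical coagulation-constant convention), which corresponds to
    # kernel entries K_ij = 2K in the size-resolved gain/loss double sum.
    Keff <- 2 * K
    # gain_k = (Keff/2) sum_{i+j=k} N_i N_j via self-convolution
    conv <- convolve(spectrum, rev(spectrum), type = "open")
    gain <- c(0, 0.5 * Keff * conv[seq_len(kmax - 1L)])
    gain - Keff * spectrum * N
  } else {
    N1 <- spectrum[1]
    d <- numeric(kmax)
    d[1] <- -K * N1 * N
    d[2] <- K * (0.5 * N1^2 - N1 * spectrum[2])
    if (kmax >= 3L)
      d[3:kmax] <- K * N1 * (spectrum[2:(kmax - 1L)] - spectrum[3:kmax])
    d
  }
}

#' Integrate the coagulation equations
#'
#' Solves the finite spectrum ODE system with \code{deSolve::lsoda}
#' (rtol 1e-8) from a monodisperse start (all mass in monomers) or a given
#' spectrum.  Truncation at kmax loses the mass that would coagulate past
#' kmax; if more than \code{max_mass_loss} (relative) is lost, kmax is
#' doubled automatically and the integration rerun.
#'
#' @param N0 initial monomer count (ignored when \code{spectrum0} is given)
#' @param kernel a \code{\link{kernel_spec}}
#' @param times output time grid (minutes), starting at 0
#' @param kmax initial spectrum truncation (default 256)
#' @param spectrum0 optional initial spectrum
#' @param max_mass_loss tolerated relative mass loss (default 0.01)
#' @param rtol relative integration tolerance
#' @return object of class \code{smol_kinetics}: list with \code{times},
#'   \code{totals}, \code{spectra} (time x size matrix), \code{kernel},
#'   \code{kmax}, \code{mass_loss_rel}
#' @export
integrate_kinetics <- function(N0, kernel, times, kmax = 256L,
                               spectrum0 = NULL, max_mass_loss = 0.01,
                               rtol = 1e-8) {
  stopifnot(inherits(kernel, "kernel_spec"), all(diff(times) > 0))
  if (times[1] > 0) times <- c(0, times)
  kmax <- as.integer(kmax)
  if (kmax < 2L) stop("kmax must be >= 2")
  repeat {
    y0 <- if (is.null(spectrum0)) c(N0, numeric(kmax - 1L))
          else c(spectrum0, numeric(max(0L, kmax - length(spectrum0))))[1:kmax]
    mass0 <- sum(seq_len(kmax) * y0)
    deriv <- function(t, y, parms) list(coagulation_rhs(y, kernel))
    sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                          rtol = rtol, atol = rtol * max(mass0, 1))
    if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
    spectra <- sol[, -1, drop = FALSE]
    mass_end <- sum(seq_len(kmax) * spectra[nrow(spectra), ])
    loss <- (mass0 - mass_end) / mass0
    if (loss <= max_mass_loss || kmax >= 8192L) break
    kmax <- kmax * 2L
  }
  structure(list(times = sol[, 1], totals = rowSums(spectra),
                 spectra = spectra, kernel = kernel, kmax = kmax,
                 mass_loss_rel = loss),
            class = "smol_kinetics")
}

#' @export
print.smol_kinetics <- function(x, ...) {
  cat(sprintf("smol_kinetics (%s kernel, rate %.4g): N %g -> %.4g over %g min; kmax %d, mass loss %.2g\n",
              x$kernel$kind, x$kernel$rate, x$totals[1],
              x$totals[length(x$totals)], max(x$times), x$kmax,
              x$mass_loss_rel))
  invisible(x)
}

# predicted totals on a time grid for a given kernel rate
predict_totals <- function(times, N0, kind, rate, kmax) {
  if (kind == "constant") return(constant_kernel_total(times, N0, rate))
  kin <- integrate_kinetics(N0, kernel_spec("monomer_only", rate),
                            times, kmax = kmax)
  kin$totals[match(round(times, 9), round(kin$times, 9))]
}

# 1-parameter least squares: log-spaced bracket then golden-section refinement
fit_kernel_rate <- function(time, count, kind, N0, kmax = 256L,
                            weights = NULL) {
  stopifnot(length(time) == length(count), length(time) >= 3,
            all(count > 0), all(time >= 0))
  w <- if (is.null(weights)) rep(1, length(count)) else weights
  sse <- function(K) {
    pred <- predict_totals(time, N0, kind, K, kmax)
    sum(w * (count - pred)^2)
  }
  if (all(count == count[1])) {
    warning("constant counts: returning rate 0")
    return(list(rate = 0, sse = sse(0)))
  }
  tmax <- max(time)
  # dimensionless u = K * N0 * tmax; aggregation horizons of interest have
  # u between far-below-one (no decay) and ~1e3 (near-complete decay)
  ugrid <- 10^seq(-5, 4, by = 0.5)
  Kgrid <- ugrid / (N0 * tmax)
  vals <- vapply(Kgrid, sse, numeric(1))
  i <- which.min(vals)
  if (sse(0) <= vals[i]) {
    warning("no decay detectable: returning rate 0")
    return(list(rate = 0, sse = sse(0)))
  }
  lo <- log10(Kgrid[max(1L, i - 1L)])
  hi <- log10(Kgrid[min(length(Kgrid), i + 1L)])
  opt <- optimize(function(lk) sse(10^lk), c(lo, hi), tol = 1e-9)
  list(rate = 10^opt$minimum, sse = opt$objective)
}

#' Field area of the observed viewport
#'
#' Count-space kernel rates are converted to area units through the area of
#' the observed field: box width times viewport height
#' (842.24 um x 710.64 um for the calibrated setup).
#'
#' @param width_um,height_um viewport extent in um
#' @return area in um^2
#' @export
field_area_um2 <- function(width_um = BOX_SIDE_UM,
                           height_um = FIELD_HEIGHT_PX * PIXEL_SIZE_UM) {
  width_um * height_um
}

#' Convert a kernel rate between unit systems
#'
#' \code{count_min} (per count per minute, the model's internal unit) maps
#' to \code{um2_min} by multiplying with the observed field area;
#' \code{um2_min} and \code{m2_s} interconvert via 1 um^2 = 1e-12 m^2 and
#' 1 min = 60 s.
#'
#' @param rate rate value
#' @param from,to unit tokens: \code{"count_min"}, \code{"um2_min"},
#'   \code{"m2_s"}
#' @param field_area observed field area in um^2 (for count-space
#'   conversions)
#' @return the converted rate
#' @export
convert_rate_units <- function(rate, from, to, field_area = field_area_um2()) {
  units <- c("count_min", "um2_min", "m2_s")
  if (!(from %in% units) || !(to %in% units))
    stop("unknown unit token; use one of: ", paste(units, collapse = ", "))
  stopifnot(field_area > 0)
  # normalize to um2_min
  u <- switch(from,
              count_min = rate * field_area,
              um2_min = rate,
              m2_s = rate * 1e12 * 60)
  switch(to,
         count_min = u / field_area,
         um2_min = u,
         m2_s = u * 1e-12 / 60)
}

#' Fit a Smoluchowski kernel to an aggregate-count time series
#'
#' Least-squares fit of the kernel rate to observed total aggregate counts
#' over time.  The constant kernel uses the closed form
#' \code{N0/(1 + K N0 t)}; the monomer-only kernel integrates the spectrum
#' ODE system.  With \code{kernel = "auto"} both are fitted and the
#' lower-SSE model is selected (ties go to the constant kernel).
#'
#' @param x a data.frame with time and count columns (named \code{time} /
#'   \code{time_min} and \code{count} / \code{n_aggregates}, or the first
#'   two columns), or a formula \code{count ~ time}
#' @param data data.frame for the formula method
#' @param kernel \code{"auto"}, \code{"constant"} or \code{"monomer_only"}
#' @param N0 initial count; defaults to the count at the earliest time
#' @param kmax spectrum truncation for the monomer-only kernel
#' @param weights optional least-squares weights
#' @param field_area field area (um^2) for rate unit conversion
#' @param ... passed between methods
#' @return an object of class \code{smol_fit} with \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals} and \code{plot} methods
#' @export
smol_fit <- function(x, ...) UseMethod("smol_fit")

#' @rdname smol_fit
#' @export
smol_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  out <- smol_fit.data.frame(data.frame(time = mf[[2]], count = mf[[1]]), ...)
  out$call <- match.call()
  out
}

#' @rdname smol_fit
#' @export
smol_fit.data.frame <- function(x, kernel = c("auto", "constant",
                                              "monomer_only"),
                                N0 = NULL, kmax = 256L, weights = NULL,
                                field_area = field_area_um2(), ...) {
  kernel <- match.arg(kernel)
  tcol <- intersect(c("time", "time_min", "t"), names(x))
  ccol <- intersect(c("count", "n", "n_aggregates"), names(x))
  time <- if (length(tcol)) x[[tcol[1]]] else x[[1]]
  count <- if (length(ccol)) x[[ccol[1]]] else x[[2]]
  o <- order(time)
  time <- time[o]; count <- count[o]
  if (is.null(N0)) N0 <- count[1]
  kinds <- if (kernel == "auto") c("constant", "monomer_only") else kernel
  fits <- lapply(kinds, function(kd)
    fit_kernel_rate(time, count, kd, N0, kmax, weights))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  best <- if (length(fits) == 2L && sses[2] < sses[1]) 2L else 1L
  rate <- fits[[best]]$rate
  kind <- kinds[best]
  fitted_vals <- predict_totals(time, N0, kind, rate, kmax)
  structure(list(
    kernel = kind, rate = rate,
    rate_um2_min = convert_rate_units(rate, "count_min", "um2_min", field_area),
    rate_m2_s = convert_rate_units(rate, "count_min", "m2_s", field_area),
    sse = sses[best], N0 = N0, kmax = as.integer(kmax),
    field_area = field_area,
    data = data.frame(time = time, count = count),
    fitted = fitted_vals,
    alternatives = data.frame(kernel = kinds, rate =
                                vapply(fits, `[[`, numeric(1), "rate"),
                              sse = sses),
    tie = length(fits) == 2L && sses[1] == sses[2],
    call = match.call()), class = "smol_fit")
}

#' Select the better-fitting kernel scenario
#'
#' Fits both the constant and the monomer-only kernel and reports the one
#' with the lower residual sum of squares (a tie is reported and resolved
#' toward the constant kernel).
#'
#' @inheritParams smol_fit.data.frame
#' @param series data.frame with time and count columns
#' @return list with \code{best} (kernel kind), \code{sse} and \code{rate}
#'   (named vectors over both kernels) and \code{tie}
#' @export
select_kernel <- function(series, N0 = NULL, kmax = 256L) {
  fit <- smol_fit(series, kernel = "auto", N0 = N0, kmax = kmax)
  list(best = fit$kernel,
       sse = setNames(fit$alternatives$sse, fit$alternatives$kernel),
       rate = setNames(fit$alternatives$rate, fit$alternatives$kernel),
       tie = fit$tie)
}

#' @export
print.smol_fit <- function(x, ...) {
  cat(sprintf("smol_fit: %s kernel\n", x$kernel))
  cat(sprintf("  rate = %.6g /min (count space) = %.4g um2/min = %.4g m2/s\n",
              x$rate, x$rate_um2_min, x$rate_m2_s))
  cat(sprintf("  SSE = %.6g over %d points, N0 = %g\n",
              x$sse, nrow(x$data), x$N0))
  invisible(x)
}

#' @export
summary.smol_fit <- function(object, ...) {
  cat(sprintf("Smoluchowski kernel fit (%d points, N0 = %g)\n",
              nrow(object$data), object$N0))
  cat("model comparison (SSE):\n")
  print(object$alternatives, row.names = FALSE)
  cat(sprintf("selected: %s kernel, rate %.6g /min = %.4g um2/min = %.4g m2/s\n",
              object$kernel, object$rate, object$rate_um2_min,
              object$rate_m2_s))
  invisible(object)
}

#' @export
coef.smol_fit <- function(object, ...) {
  setNames(object$rate, if (object$kernel == "constant") "K" else "K1")
}

#' @export
fitted.smol_fit <- function(object, ...) object$fitted

#' @export
residuals.smol_fit <- function(object, ...) object$data$count - object$fitted

#' @export
predict.smol_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$data$time
           else if (is.data.frame(newdata)) newdata[[1]]
           else as.numeric(newdata)
  predict_totals(times, object$N0, object$kernel, object$rate, object$kmax)
}

#' @export
plot.smol_fit <- function(x, ...) {
  plot(x$data$time, x$data$count, xlab = "time (min)",
       ylab = "number of aggregates", ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
  lines(tt, predict(x, tt))
  invisible(x)
}
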