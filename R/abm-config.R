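#' Parse a length given in micrometers or pixel lengths
#'
#' Figure-caption parameter values are quoted in pixel lengths; internal
#' units are micrometers.  Accepts a number (um) or a string such as
#' \code{"6 px"}, \code{"3.95 um"}.
#'
#' @param x numeric (um) or string(s) with a \code{px}/\code{um} suffix;
#'   vectorized
#' @param pixel_size um per pixel (default 0.658)
#' @return length(s) in um
#' @export
parse_length <- function(x, pixel_size = PIXEL_SIZE_UM) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) stop("length must be numeric or a string")
  vapply(x, function(xi) {
    m <- regmatches(xi, regexec("^\\s*([0-9eE.+-]+)\\s*(px|um|µm)?\\s*$", xi))[[1]]
    if (length(m) == 0L || is.na(suppressWarnings(as.numeric(m[2]))))
      stop("cannot parse length: '", xi, "'")
    val <- as.numeric(m[2])
    if (identical(m[3], "px")) val * pixel_size else val
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hydrodynamic flux specification
#'
#' On non-adhesive gels a weak hydrodynamic flux biases motion: directions
#' are restricted to the half-plane around the flux direction.  The bias can
#' apply to individual cells only, to individuals and all aggregates
#' (default), or to individuals and aggregates below a size threshold.
#'
#' @param enabled logical
#' @param direction flux direction in degrees, \code{[0, 360)}
#' @param scope one of \code{"individuals_and_aggregates"},
#'   \code{"individuals_only"}, \code{"individuals_and_small_aggregates"}
#' @param small_threshold aggregate size (cells) below which the third scope
#'   applies; >= 2
#' @return an object of class \code{flux_spec}
#' @export
flux_spec <- function(enabled = FALSE, direction = 0,
                      scope = c("individuals_and_aggregates",
                                "individuals_only",
                                "individuals_and_small_aggregates"),
                      small_threshold = 10L) {
  scope <- match.arg(scope)
  if (!is.finite(direction) || direction < 0 || direction >= 360)
    stop("flux direction must lie in [0, 360)")
  small_threshold <- as.integer(small_threshold)
  if (scope == "individuals_and_small_aggregates" && small_threshold < 2L)
    stop("small_threshold must be >= 2")
  structure(list(enabled = isTRUE(enabled), direction = as.numeric(direction),
                 scope = scope, small_threshold = small_threshold),
            class = "flux_spec")
}

#' Simulator configuration
#'
#' All parameters of the agent-based model.  One iteration is one minute;
#' lengths are micrometers internally but may be given in pixel lengths
#' (strings like \code{"6 px"}, converted via \code{pixel_size}).
#'
#' @param n_initial N0, initial number of individual cells (>= 1)
#' @param cell_diameter d, cell diameter in um (13.2 for F98, 21.1 for U87)
#' @param step_length a0, per-iteration step of an isolated cell; um or
#'   \code{"px"} string
#' @param proliferation_rate kappa, division probability per cell per
#'   iteration, in \code{[0, 1]}
#' @param alpha_max maximum superimposition coefficient in \code{[0, 1)}:
#'   the minimal allowed center distance is \code{d * (1 - alpha_max)}
#' @param compaction logical; bias aggregate-member motion toward the
#'   aggregate center of mass
#' @param flux a \code{\link{flux_spec}}
#' @param box a \code{\link{box_spec}} or side length in um
#' @param pixel_size um per pixel for length parsing and rasterization
#' @param n_iterations number of 1-minute iterations
#' @param seed default RNG seed used by \code{\link{run_abm}}
#' @param cancel_on_contact if \code{TRUE}, a move that would violate the
#'   superimposition rule is cancelled outright instead of being truncated at
#'   the contact point (default \code{FALSE}: truncation, i.e. the motion is
#'   prematurely stopped and the cells adhere)
#' @return an object of class \code{abm_config}
#' @export
abm_config <- function(n_initial,
                       cell_diameter = 13.2,
                       step_length = "6 px",
                       proliferation_rate = 7e-4,
                       alpha_max = 0.7,
                       compaction = TRUE,
                       flux = flux_spec(FALSE),
                       box = box_spec(),
                       pixel_size = PIXEL_SIZE_UM,
                       n_iterations = 720L,
                       seed = 1L,
                       cancel_on_contact = FALSE) {
  if (!inherits(flux, "flux_spec")) stop("flux must be a flux_spec")
  if (!inherits(box, "box_spec")) box <- box_spec(box)
  a0 <- parse_length(step_length, pixel_size)
  d <- as.numeric(cell_diameter)
  stop_unless(is.finite(d) && d > 0, "cell_diameter must be > 0")
  stop_unless(is.finite(a0) && a0 >= 0, "step_length must be >= 0")
  stop_unless(a0 < box$side_length / 4,
              "step_length must be well below the box size")
  stop_unless(is.finite(proliferation_rate) && proliferation_rate >= 0 &&
                proliferation_rate <= 1,
              "proliferation_rate must lie in [0, 1]")
  stop_unless(is.finite(alpha_max) && alpha_max >= 0 && alpha_max < 1,
              "alpha_max must lie in [0, 1)")
  n_initial <- as.integer(n_initial)
  stop_unless(!is.na(n_initial) && n_initial >= 1L, "n_initial must be >= 1")
  n_iterations <- as.integer(n_iterations)
  stop_unless(!is.na(n_iterations) && n_iterations >= 0L,
              "n_iterations must be >= 0")
  structure(list(n_initial = n_initial, cell_diameter = d, a0 = a0,
                 pixel_size = as.numeric(pixel_size),
                 proliferation_rate = as.numeric(proliferation_rate),
                 alpha_max = as.numeric(alpha_max),
                 compaction = isTRUE(compaction), flux = flux, box = box,
                 iteration_minutes = 1,
                 n_iterations = n_iterations, seed = as.integer(seed),
                 cancel_on_contact = isTRUE(cancel_on_contact)),
            class = "abm_config")
}

stop_unless <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' @export
print.abm_config <- function(x, ...) {
  cat("abm_config\n")
  cat(sprintf("  N0 = %d cells, d = %.3g um, box = %.5g um (periodic)\n",
              x$n_initial, x$cell_diameter, x$box$side_length))
  cat(sprintf("  a0 = %.4g um (%.3g px), kappa = %.3g /min, alpha_max = %.2f\n",
              x$a0, x$a0 / x$pixel_size, x$proliferation_rate, x$alpha_max))
  cat(sprintf("  compaction %s, flux %s%s, %d iterations, seed %d\n",
              if (x$compaction) "on" else "off",
              if (x$flux$enabled) "on" else "off",
              if (x$flux$enabled) paste0(" (", x$flux$scope, ", dir ",
                                         x$flux$direction, " deg)") else "",
              x$n_iterations, x$seed))
  invisible(x)
}

#' Minimal allowed center distance between two cells
#'
#' The superimposition rule allows two disks to overlap up to a fraction
#' \code{alpha_max} of the diameter, so centers may approach down to
#' \code{d * (1 - alpha_max)}.
#'
#' @param config an \code{\link{abm_config}}
#' @return distance in um
#' @export
min_center_distance <- function(config) {
  config$cell_diameter * (1 - config$alpha_max)
}

#' Preset configurations from the calibrated experiments
#'
#' Parameter sets used for the two glioma cell lines on adhesive (PEG+PLL)
#' and non-adhesive (PEG) hydrogels.  F98: d = 13.2 um, alpha_max = 0.7,
#' kappa = 7e-4 /min; U87: d = 21.1 um, alpha_max = 0.2, kappa = 3e-4 /min.
#' Non-adhesive F98 runs have the flux bias on.
#'
#' @param name preset name
#' @param ... overrides passed to \code{\link{abm_config}}
#' @return an \code{\link{abm_config}}
#' @export
abm_preset <- function(name = c("F98-nonadhesive", "F98-adhesive",
                                "U87-nonadhesive", "U87-adhesive"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "F98-nonadhesive" = list(n_initial = 784L, cell_diameter = 13.2,
                             step_length = "6 px", proliferation_rate = 7e-4,
                             alpha_max = 0.7, flux = flux_spec(TRUE)),
    "F98-adhesive"    = list(n_initial = 484L, cell_diameter = 13.2,
                             step_length = "1.6 px", proliferation_rate = 7e-4,
                             alpha_max = 0.7, flux = flux_spec(FALSE)),
    "U87-nonadhesive" = list(n_initial = 625L, cell_diameter = 21.1,
                             step_length = "6 px", proliferation_rate = 3e-4,
                             alpha_max = 0.2, flux = flux_spec(FALSE)),
    "U87-adhesive"    = list(n_initial = 484L, cell_diameter = 21.1,
                             step_length = "2 px", proliferation_rate = 3e-4,
                             alpha_max = 0.2, flux = flux_spec(FALSE)))
  args <- utils::modifyList(base, list(...))
  do.call(abm_config, args)
}
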