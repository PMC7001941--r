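#' Square periodic simulation box
#'
#' The simulation domain is a square with periodic boundary conditions; the
#' default side length matches the experimental field of view width
#' (1280 px at 0.658 um/px = 842.24 um).
#'
#' @param side_length box side in micrometers (> 0)
#' @return an object of class \code{box_spec}
#' @export
box_spec <- function(side_length = BOX_SIDE_UM) {
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0)
    stop("side_length must be a single positive finite number")
  structure(list(side_length = as.numeric(side_length), periodic = TRUE),
            class = "box_spec")
}

box_side <- function(box) {
  if (inherits(box, "box_spec")) return(box$side_length)
  if (is.numeric(box) && length(box) == 1L && is.finite(box) && box > 0)
    return(as.numeric(box))
  stop("box must be a box_spec or a positive side length")
}

as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must have two coordinates")
    p <- matrix(as.numeric(p), 1L, 2L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("points must be n x 2")
  storage.mode(p) <- "double"
  p
}

#' Wrap positions into the periodic box
#'
#' Each coordinate is reduced modulo the box side into \code{[0, L)}.
#'
#' @param p a length-2 point or an n x 2 matrix of points (um)
#' @param box a \code{\link{box_spec}} or side length
#' @return wrapped point(s), same shape as the input
#' @export
wrap_position <- function(p, box) {
  L <- box_side(box)
  vec <- is.null(dim(p))
  out <- cpp_wrap(as_points(p), L)
  if (vec) drop(out) else out
}

#' Minimal-image displacement between two points
#'
#' Returns the shortest displacement \code{v} with \code{q == p + v} modulo
#' the box, so each component lies in \code{[-L/2, L/2]}.  The minimal-image
#' distance is \code{sqrt(sum(v^2))}.
#'
#' @param p,q length-2 points (um), wrapped
#' @inheritParams wrap_position
#' @return length-2 displacement vector (um)
#' @export
min_image_vector <- function(p, q, box) {
  L <- box_side(box)
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 2L || length(q) != 2L || any(!is.finite(c(p, q))))
    stop("p and q must be finite length-2 points")
  v <- q - p
  v - L * round(v / L)
}

#' Minimal-image distance
#' @inheritParams min_image_vector
#' @return scalar distance (um)
#' @export
min_image_distance <- function(p, q, box) {
  sqrt(sum(min_image_vector(p, q, box)^2))
}

#' Center of mass under periodic boundaries
#'
#' Per-axis circular mean: coordinates are mapped to angles on a circle of
#' circumference L, the unit vectors are averaged, and the mean angle is
#' mapped back.  For point sets of extent < L/2 on an axis this equals the
#' minimal-image arithmetic mean relative to any member.
#'
#' @param points n x 2 matrix of wrapped positions (um); n >= 1
#' @inheritParams wrap_position
#' @return length-2 point (um)
#' @export
pbc_center_of_mass <- function(points, box) {
  L <- box_side(box)
  points <- as_points(points)
  if (nrow(points) == 0L) stop("empty point set has no center of mass")
  k <- 2 * pi / L
  com <- vapply(1:2, function(ax) {
    th <- k * points[, ax]
    a <- atan2(mean(sin(th)), mean(cos(th)))
    (a / k) %% L
  }, numeric(1))
  com
}

#' Direction-sampling law
#'
#' Motion directions are drawn either uniformly on the circle, uniformly in
#' an angular sector, or in a half-plane (a sector of half-width 90 degrees,
#' used for the hydrodynamic flux bias).
#'
#' @param mode one of \code{"uniform"}, \code{"sector"}, \code{"halfplane"}
#' @param center_angle sector/half-plane center, degrees
#' @param half_width sector half-width in degrees, in (0, 180]; forced to 90
#'   for \code{"halfplane"}
#' @return an object of class \code{direction_law}
#' @export
direction_law <- function(mode = c("uniform", "sector", "halfplane"),
                          center_angle = 0, half_width = 180) {
  mode <- match.arg(mode)
  if (mode == "halfplane") half_width <- 90
  if (mode != "uniform") {
    if (!is.finite(center_angle)) stop("center_angle must be finite")
    if (!is.finite(half_width) || half_width <= 0 || half_width > 180)
      stop("half_width must lie in (0, 180]")
  }
  structure(list(mode = mode, center_angle = as.numeric(center_angle),
                 half_width = as.numeric(half_width)),
            class = "direction_law")
}

#' Sample motion directions
#'
#' @param law a \code{\link{direction_law}}
#' @param n number of draws
#' @return angles in degrees, reduced to \code{[0, 360)}
#' @export
sample_direction <- function(law, n = 1L) {
  if (!inherits(law, "direction_law")) stop("law must be a direction_law")
  if (law$mode == "uniform") return(runif(n, 0, 360))
  (law$center_angle + law$half_width * (2 * runif(n) - 1)) %% 360
}
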