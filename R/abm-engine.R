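#' Step length of a cell inside an aggregate
#'
#' Intra-aggregate motion slows with crowding: a cell with n contact
#' neighbors moves by \code{a0 / (1 + n^2)} per iteration.
#'
#' @param a0 isolated-cell step length (um)
#' @param n neighbor count (integer >= 0)
#' @return step length in um
#' @export
intra_step_length <- function(a0, n) {
  if (any(n < 0) || any(n != floor(n))) stop("n must be a non-negative integer")
  a0 / (1 + n^2)
}

#' Step length of an aggregate's collective motion
#'
#' The whole aggregate performs a random step decreasing as 1/N with the
#' number of member cells, mirroring the 1/r scaling of the diffusion
#' coefficient of a particle in a viscous medium.
#'
#' @param a0 isolated-cell step length (um)
#' @param N aggregate size in cells (>= 1)
#' @return step length in um
#' @export
aggregate_step_length <- function(a0, N) {
  if (any(N < 1)) stop("N must be >= 1")
  a0 / N
}

#' Compaction sector half-width
#'
#' Inside an aggregate of n cells, motion directions are drawn in a sector
#' of half-width \code{90 * (1 + exp(-n/40))} degrees centered on the
#' direction toward the aggregate's center of mass: small aggregates allow
#' any direction (180 at n = 0), very large ones only a +/- 90 degree
#' sector.
#'
#' @param n aggregate size in cells (>= 0)
#' @return half-width in degrees
#' @export
compaction_halfwidth_deg <- function(n) {
  if (any(n < 0)) stop("n must be >= 0")
  90 * (1 + exp(-n / 40))
}

#' Propose a motion direction for one cell
#'
#' Individual cells draw uniformly, or in the flux half-plane when the flux
#' bias is on.  Cells inside an aggregate draw in the compaction sector
#' centered on the minimal-image direction to the aggregate center of mass
#' (when compaction is enabled), or uniformly otherwise.
#'
#' @param cluster_size N, size of the cell's aggregate (1 for an individual)
#' @param position the cell position (um), needed for aggregate members
#' @param com the aggregate's center of mass; required iff
#'   \code{cluster_size >= 2}
#' @param config an \code{\link{abm_config}}
#' @param n number of draws
#' @return angle(s) in degrees
#' @export
propose_direction <- function(cluster_size, position = NULL, com = NULL,
                              config, n = 1L) {
  if (cluster_size >= 2) {
    if (!config$compaction) return(sample_direction(direction_law("uniform"), n))
    if (is.null(com) || is.null(position))
      stop("aggregate member needs its position and the aggregate com")
    v <- min_image_vector(position, com, config$box)
    center <- atan2(v[2], v[1]) * 180 / pi
    law <- direction_law("sector", center_angle = center,
                         half_width = compaction_halfwidth_deg(cluster_size))
    return(sample_direction(law, n))
  }
  if (config$flux$enabled)
    sample_direction(direction_law("halfplane",
                                   center_angle = config$flux$direction), n)
  else
    sample_direction(direction_law("uniform"), n)
}

#' Move a cell along a ray, stopping at first contact
#'
#' The cell travels at most \code{step} along the direction; if the moving
#' center would come within \code{dmin} of another center the motion is
#' prematurely stopped exactly at contact (ray-circle intersection under the
#' minimal image convention).
#'
#' @param p length-2 start position (um)
#' @param angle direction in degrees
#' @param step maximal travel (um)
#' @param others m x 2 matrix of other cell centers
#' @param dmin hard-core distance \code{d * (1 - alpha_max)} (um)
#' @param box a \code{\link{box_spec}} or side length
#' @return the wrapped end position
#' @export
truncated_move <- function(p, angle, step, others, dmin, box) {
  L <- box_side(box)
  others <- if (is.null(others) || length(others) == 0L)
    matrix(numeric(0), 0, 2) else as_points(others)
  cpp_truncated_move(as.numeric(p), angle, step, others, dmin, L)
}

#' No-detachment acceptance rule
#'
#' A move is kept only if the cell ends with at least as many contact
#' neighbors as it started with; a step that would lower the neighbor count
#' is cancelled.  Isolated cells always move.
#'
#' @param current,proposed length-2 positions (um)
#' @param others m x 2 matrix of the other cell centers
#' @param contact_dist neighbor distance (the cell diameter)
#' @inheritParams truncated_move
#' @return logical: accept the move?
#' @export
no_detach_accept <- function(current, proposed, others, contact_dist, box) {
  if (is.null(others) || length(others) == 0L) return(TRUE)
  others <- as_points(others)
  n_at <- function(p) {
    d2 <- vapply(seq_len(nrow(others)), function(j)
      sum(min_image_vector(p, others[j, ], box)^2), numeric(1))
    sum(d2 <= (contact_dist + CONTACT_TOL)^2)
  }
  nc <- n_at(current)
  if (nc == 0L) return(TRUE)
  n_at(proposed) >= nc
}

#' Attempt one cell division
#'
#' With probability \code{proliferation_rate} the cell tries to divide: a
#' daughter position is drawn at a uniformly random angle at center distance
#' d from the mother.  If the daughter would violate the superimposition
#' rule against any existing cell the division is aborted (a single
#' candidate is drawn, no retries).
#'
#' @param p mother position (um)
#' @param others m x 2 matrix of all other cell centers
#' @param config an \code{\link{abm_config}}
#' @return the daughter position, or \code{NULL} if no division happened
#' @export
attempt_division <- function(p, others, config) {
  if (runif(1) >= config$proliferation_rate) return(NULL)
  ang <- runif(1, 0, 2 * pi)
  d <- config$cell_diameter
  q <- wrap_position(p + d * c(cos(ang), sin(ang)), config$box)
  dmin <- min_center_distance(config)
  if (!is.null(others) && length(others) > 0L) {
    others <- as_points(others)
    d2 <- vapply(seq_len(nrow(others)), function(j)
      sum(min_image_vector(q, others[j, ], config$box)^2), numeric(1))
    if (any(d2 < dmin^2 - HARD_TOL)) return(NULL)
  }
  q
}

# parameter list handed to the C++ stepper
engine_par <- function(config) {
  scope_code <- match(config$flux$scope,
                      c("individuals_only", "individuals_and_aggregates",
                        "individuals_and_small_aggregates")) - 1L
  list(L = config$box$side_length, d = config$cell_diameter,
       dmin = min_center_distance(config), a0 = config$a0,
       kappa = config$proliferation_rate, compaction = config$compaction,
       flux_on = config$flux$enabled, flux_dir = config$flux$direction,
       flux_scope = scope_code, small_threshold = config$flux$small_threshold,
       cancel_mode = config$cancel_on_contact)
}

#' Initialize a world of uniformly placed cells
#'
#' Places \code{n_initial} cells i.i.d. uniformly in the box, rejection
#' sampling any candidate closer than the hard-core distance to an already
#' placed cell.  Uses the current RNG state; call \code{set.seed} first for
#' reproducibility (or use \code{\link{run_abm}}).
#'
#' @param config an \code{\link{abm_config}}
#' @param max_attempts total rejection-sampling budget
#' @return an object of class \code{abm_world}: list with \code{time} (min)
#'   and \code{cells} (data.frame id, x, y)
#' @export
init_world <- function(config, max_attempts = 1e6L) {
  pos <- cpp_init_world(config$n_initial, config$box$side_length,
                        min_center_distance(config), as.integer(max_attempts))
  structure(list(time = 0,
                 cells = data.frame(id = seq_len(config$n_initial),
                                    x = pos[, 1], y = pos[, 2]),
                 next_id = config$n_initial + 1L),
            class = "abm_world")
}

#' @export
print.abm_world <- function(x, ...) {
  cat(sprintf("abm_world: %d cells at t = %g min\n", nrow(x$cells), x$time))
  invisible(x)
}

#' Advance the world by one iteration (one minute)
#'
#' One iteration: (1) aggregates are labeled from the contact graph and each
#' aggregate of >= 2 cells performs one rigid random step of length
#' \code{a0/N} (truncated at first contact with a non-member); (2) every
#' cell, visited in a fresh random permutation, draws a direction
#' (flux/compaction rules), moves by \code{a0/(1+n^2)} truncated at contact,
#' subject to the no-detachment rule; (3) each visited cell may divide.
#' Daughters appear immediately as obstacles but are not updated in their
#' birth iteration.
#'
#' @param world an \code{abm_world}
#' @param config an \code{\link{abm_config}}
#' @return the updated \code{abm_world}, time advanced by 1 min
#' @export
step_world <- function(world, config) {
  pos <- cbind(world$cells$x, world$cells$y)
  storage.mode(pos) <- "double"
  res <- cpp_step_world(pos, as.integer(world$cells$id),
                        as.integer(world$next_id), engine_par(config))
  structure(list(time = world$time + 1,
                 cells = data.frame(id = res$ids, x = res$pos[, 1],
                                    y = res$pos[, 2]),
                 next_id = res$next_id),
            class = "abm_world")
}

#' Run an aggregation simulation
#'
#' Initializes the world and applies \code{\link{step_world}} for
#' \code{config$n_iterations} iterations, recording snapshots every
#' \code{stride} iterations (the initial and final states are always
#' recorded).  Fully reproducible: the same config and seed give a
#' bit-identical trajectory.
#'
#' @param config an \code{\link{abm_config}}
#' @param seed RNG seed; defaults to \code{config$seed}
#' @param stride snapshot interval in iterations
#' @return an object of class \code{abm_trajectory}: list with
#'   \code{config}, \code{times} and \code{snapshots} (list of
#'   \code{abm_world})
#' @export
run_abm <- function(config, seed = config$seed, stride = 10L) {
  stopifnot(inherits(config, "abm_config"))
  stride <- max(1L, as.integer(stride))
  set.seed(as.integer(seed))
  world <- init_world(config)
  snaps <- list(world)
  for (it in seq_len(config$n_iterations)) {
    world <- step_world(world, config)
    if (it %% stride == 0L || it == config$n_iterations)
      snaps[[length(snaps) + 1L]] <- world
  }
  # dedupe final snapshot when n_iterations %% stride == 0
  times <- vapply(snaps, `[[`, numeric(1), "time")
  keep <- !duplicated(times)
  structure(list(config = config, seed = as.integer(seed),
                 times = times[keep], snapshots = snaps[keep]),
            class = "abm_trajectory")
}

#' @rdname run_abm
#' @param object an \code{\link{abm_config}}
#' @param nsim number of independent trajectories
#' @param ... passed to \code{\link{run_abm}} (e.g. \code{stride})
#' @export
simulate.abm_config <- function(object, nsim = 1, seed = object$seed, ...) {
  if (nsim == 1) return(run_abm(object, seed = seed, ...))
  lapply(seq_len(nsim) - 1L, function(k) run_abm(object, seed = seed + k, ...))
}

#' @export
print.abm_trajectory <- function(x, ...) {
  n0 <- nrow(x$snapshots[[1]]$cells)
  nf <- nrow(x$snapshots[[length(x$snapshots)]]$cells)
  cat(sprintf("abm_trajectory: %d snapshots over %g min (seed %d)\n",
              length(x$snapshots), max(x$times), x$seed))
  cat(sprintf("  cells: %d -> %d\n", n0, nf))
  invisible(x)
}

#' @export
summary.abm_trajectory <- function(object, ...) {
  cfg <- object$config
  lab <- lapply(object$snapshots, function(w)
    cluster_labels(w$cells, cfg$cell_diameter + CONTACT_TOL, cfg$box))
  data.frame(time_min = object$times,
             n_cells = vapply(object$snapshots, function(w) nrow(w$cells),
                              numeric(1)),
             n_clusters = vapply(lab, function(l) length(l$sizes), numeric(1)),
             largest = vapply(lab, function(l) max(l$sizes), numeric(1)))
}

#' @export
plot.abm_trajectory <- function(x, time = max(x$times), ...) {
  i <- which.min(abs(x$times - time))
  w <- x$snapshots[[i]]
  L <- x$config$box$side_length
  r <- x$config$cell_diameter / 2
  symbols(w$cells$x, w$cells$y, circles = rep(r, nrow(w$cells)),
          inches = FALSE, xlim = c(0, L), ylim = c(0, L), asp = 1,
          xlab = "x (um)", ylab = "y (um)",
          main = sprintf("t = %g min, %d cells", w$time, nrow(w$cells)), ...)
  invisible(x)
}

#' @export
as.data.frame.abm_trajectory <- function(x, ...) {
  do.call(rbind, lapply(x$snapshots, function(w)
    data.frame(time_min = w$time, cell_id = w$cells$id,
               x_um = w$cells$x, y_um = w$cells$y)))
}
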