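#' Contact pairs between cells
#'
#' All unordered pairs of cells whose minimal-image center distance is at
#' most \code{contact_dist}.  Two cells are neighbors when their disks touch
#' or overlap, i.e. at center distance <= cell diameter (plus a 1e-6 um
#' tolerance applied by the engine).  Internally a uniform-bin spatial grid
#' is used; the result is identical to the all-pairs scan.
#'
#' @param cells an n x 2 position matrix, or a data.frame with columns
#'   \code{id}, \code{x}, \code{y}
#' @param contact_dist contact distance in um (> 0)
#' @param box a \code{\link{box_spec}} or side length
#' @return a two-column matrix of cell ids (row indices when \code{cells} has
#'   no id column)
#' @export
contact_pairs <- function(cells, contact_dist, box) {
  if (!is.numeric(contact_dist) || contact_dist <= 0)
    stop("contact_dist must be positive")
  L <- box_side(box)
  cp <- cells_to_posid(cells)
  pr <- cpp_contact_pairs(cp$pos, contact_dist, L)
  out <- cbind(i = cp$ids[pr[, 1]], j = cp$ids[pr[, 2]])
  out
}

cells_to_posid <- function(cells) {
  if (is.data.frame(cells)) {
    if (!all(c("x", "y") %in% names(cells)))
      stop("cells data.frame needs columns x and y")
    ids <- if ("id" %in% names(cells)) cells$id else seq_len(nrow(cells))
    pos <- cbind(cells$x, cells$y)
  } else {
    pos <- as_points(cells)
    ids <- seq_len(nrow(pos))
  }
  storage.mode(pos) <- "double"
  list(pos = pos, ids = as.integer(ids))
}

#' Connected components of the contact graph
#'
#' Union-find components over an edge list; isolated cells become size-1
#' clusters.  Cluster ids are 1..k in order of first appearance.
#'
#' @param pairs two-column matrix of cell ids (as from
#'   \code{\link{contact_pairs}})
#' @param ids vector of all cell ids (isolated cells included)
#' @return integer vector of cluster ids, named by cell id
#' @export
connected_components <- function(pairs, ids) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  n <- length(ids)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(setNames(seq_len(n), ids))
  }
  idx <- match(as.integer(pairs), ids)
  if (anyNA(idx)) stop("pairs refer to unknown cell ids")
  m <- matrix(idx, ncol = 2)
  lab <- cpp_components(n, m)
  setNames(as.integer(lab), ids)
}

#' Aggregate labeling of a cell configuration
#'
#' Builds the contact graph, extracts connected components (aggregates; a
#' single cell is its own size-1 cluster), and computes per-cluster sizes and
#' periodic centers of mass.
#'
#' @inheritParams contact_pairs
#' @return an object of class \code{cluster_labeling}: list with
#'   \code{labels} (cluster id per cell, named by cell id), \code{sizes}
#'   (member count per cluster) and \code{coms} (k x 2 matrix of periodic
#'   centers of mass)
#' @export
cluster_labels <- function(cells, contact_dist, box) {
  cp <- cells_to_posid(cells)
  pairs <- contact_pairs(cells, contact_dist, box)
  labels <- connected_components(pairs, cp$ids)
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  coms <- t(vapply(seq_len(k), function(cl) {
    pbc_center_of_mass(cp$pos[labels == cl, , drop = FALSE], box)
  }, numeric(2)))
  structure(list(labels = labels, sizes = sizes, coms = coms),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat("cluster_labeling:", length(x$labels), "cells in", length(x$sizes),
      "clusters (largest:", max(x$sizes), "cells)\n")
  invisible(x)
}

#' Number of contact neighbors of a cell
#'
#' @param id a cell id
#' @param pairs two-column id matrix from \code{\link{contact_pairs}}
#' @return the degree of the cell in the contact graph
#' @export
neighbor_count <- function(id, pairs) {
  if (length(id) != 1L) stop("one id at a time")
  if (is.null(pairs) || nrow(pairs) == 0L) return(0L)
  sum(pairs[, 1] == id) + sum(pairs[, 2] == id)
}
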