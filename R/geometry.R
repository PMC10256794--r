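#' Euclidean distance matrix between contacts
#'
#' Straight-line mm distances between contact coordinates. Distance is the
#' standard confound of connectivity analyses on depth electrodes (nearby
#' contacts are more connected in every modality), so this matrix is what
#' gets regressed out of edge vectors before coupling statistics.
#'
#' @param contacts a [contact_set]; all rows are used, so filter with
#'   [white_matter_contacts()] first if needed.
#' @return a [conn_matrix] with modality `"distance"`.
#' @examples
#' cs <- contact_set(c("a", "b"),
#'                   rbind(c(46, -14, -20), c(34, -4, -23)))
#' euclidean_distance_matrix(cs)$values["a", "b"]  # sqrt(253) ~ 15.906 mm
#' @export
euclidean_distance_matrix <- function(contacts) {
  xyz <- contact_coords(contacts)
  if (nrow(xyz) < 2) stop("need at least two contacts")
  d <- as.matrix(stats::dist(xyz))
  conn_matrix(d, rownames(xyz), modality = "distance")
}

# Integer voxel offsets for the three supported sphere neighborhoods:
# 7  = center + 6 face neighbors          (radius of one voxel)
# 19 = center + 6 face + 12 edge neighbors (3 mm radius at 2 mm voxels)
# 27 = full 3x3x3 cube
sphere_offsets <- function(neighborhood) {
  if (!neighborhood %in% c(7L, 19L, 27L))
    stop("neighborhood must be 7, 19 or 27 voxels")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manhattan <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "7" = manhattan <= 1,
                 "19" = manhattan <= 2,
                 "27" = rep(TRUE, nrow(g)))
  unname(g[keep, , drop = FALSE])
}

# round half away from zero, elementwise
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Voxel indices of a sphere ROI around a mm position
#'
#' Maps a mm position to its nearest voxel on a regular grid
#' (round-half-away-from-zero per axis) and returns the 1-based integer voxel
#' indices of the 7-, 19- or 27-voxel neighborhood. Voxels falling outside
#' the grid are dropped with a warning (edge contacts keep their in-grid
#' voxels).
#'
#' @param center_mm length-3 mm position.
#' @param neighborhood 7, 19 or 27.
#' @param voxel_mm isotropic voxel size in mm.
#' @param grid_origin mm position of the center of voxel (1, 1, 1).
#' @param grid_dim integer grid dimensions, or `NULL` to skip bounds
#'   checking.
#' @return integer matrix (k x 3) of voxel indices, k <= neighborhood.
#' @export
sphere_voxels <- function(center_mm, neighborhood = 19L, voxel_mm = 2,
                          grid_origin = c(0, 0, 0), grid_dim = NULL) {
  if (length(center_mm) != 3 || any(!is.finite(center_mm)))
    stop("center_mm must be a finite length-3 mm position")
  center_vox <- round_half_away((center_mm - grid_origin) / voxel_mm) + 1
  vox <- sweep(sphere_offsets(neighborhood), 2, center_vox, "+")
  if (!is.null(grid_dim)) {
    inside <- vox[, 1] >= 1 & vox[, 1] <= grid_dim[1] &
      vox[, 2] >= 1 & vox[, 2] <= grid_dim[2] &
      vox[, 3] >= 1 & vox[, 3] <= grid_dim[3]
    if (!any(inside)) stop("sphere ROI lies fully outside the grid")
    if (!all(inside)) {
      if (mean(inside) < 0.5)
        warning(sprintf("sphere ROI at (%g, %g, %g) has <50%% of voxels in-grid",
                        center_mm[1], center_mm[2], center_mm[3]))
      else
        warning("sphere ROI truncated at grid edge; out-of-grid voxels dropped")
      vox <- vox[inside, , drop = FALSE]
    }
  }
  storage.mode(vox) <- "integer"
  vox
}

# Densify a polyline so consecutive points are at most step_mm apart.
densify_polyline <- function(points, step_mm = 0.5) {
  if (nrow(points) < 2 || step_mm <= 0) return(points)
  out <- vector("list", nrow(points) - 1)
  for (k in seq_len(nrow(points) - 1)) {
    a <- points[k, ]; b <- points[k + 1, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step_mm))
    tt <- seq(0, 1, length.out = nseg + 1)[-(nseg + 1)]
    out[[k]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  rbind(do.call(rbind, out), points[nrow(points), , drop = FALSE])
}

#' Streamline-count structural connectivity between contact spheres
#'
#' Edge weight between contacts i and j is the number of streamlines with at
#' least one point within `roi_radius_mm` of contact i and at least one
#' within `roi_radius_mm` of contact j; a streamline increments every pair it
#' connects by one (pass-through convention). Polylines are densified to
#' `densify_step_mm` before the point-in-sphere test so that segments passing
#' through a sphere between stored vertices are still counted.
#'
#' @param streamlines a [streamline_set].
#' @param contacts a [contact_set] defining the nodes.
#' @param roi_radius_mm sphere radius in mm; default 2 mm, one voxel.
#' @param densify_step_mm densification step in mm; `0` disables (vertex-only
#'   test).
#' @return a [conn_matrix] with modality `"sc"` (integer counts, zero
#'   diagonal). An empty streamline set yields the zero matrix.
#' @export
count_streamline_connections <- function(streamlines, contacts,
                                         roi_radius_mm = 2,
                                         densify_step_mm = 0.5) {
  stopifnot(inherits(streamlines, "streamline_set"))
  if (roi_radius_mm <= 0) stop("roi_radius_mm must be positive")
  xyz <- contact_coords(contacts)
  n <- nrow(xyz)
  counts <- matrix(0L, n, n)
  r2 <- roi_radius_mm^2
  for (line in streamlines$streamlines) {
    pts <- if (densify_step_mm > 0) densify_polyline(line, densify_step_mm)
           else line
    hit <- vapply(seq_len(n), function(i) {
      dx <- pts[, 1] - xyz[i, 1]
      dy <- pts[, 2] - xyz[i, 2]
      dz <- pts[, 3] - xyz[i, 3]
      any(dx * dx + dy * dy + dz * dz <= r2)
    }, logical(1))
    touched <- which(hit)
    if (length(touched) >= 2) {
      pairs <- utils::combn(touched, 2)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        counts[i, j] <- counts[i, j] + 1L
        counts[j, i] <- counts[j, i] + 1L
      }
    }
  }
  conn_matrix(counts, rownames(xyz), modality = "sc")
}
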