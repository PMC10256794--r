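#' 4D BOLD volume container
#'
#' A regular isotropic grid of BOLD samples. `origin_mm` is the mm position
#' of the center of voxel (1, 1, 1); the affine is assumed diagonal (RAS mm
#' convention), which is all the sphere-ROI machinery needs.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_mm isotropic voxel size in mm.
#' @param origin_mm mm position of the first voxel center.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, voxel_mm = 2, origin_mm = c(0, 0, 0), tr = 2) {
  if (length(dim(data)) != 4) stop("data must be a 4D array (x, y, z, t)")
  if (voxel_mm <= 0 || tr <= 0) stop("voxel_mm and tr must be positive")
  if (dim(data)[4] < 2) stop("need at least two volumes")
  structure(list(data = data, voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm), tr = tr),
            class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_volume> %dx%dx%d voxels (%g mm) x %d volumes (TR %g s)\n",
              d[1], d[2], d[3], x$voxel_mm, d[4], x$tr))
  invisible(x)
}

#' Extract sphere-ROI time series at contact locations
#'
#' For each contact, averages the volume over the voxels of its 7-, 19- or
#' 27-voxel sphere neighborhood at every time point. Spheres truncated by the
#' grid edge keep their in-grid voxels (with a warning); a contact whose
#' sphere lies fully outside the grid is an error.
#'
#' @param vol a [bold_volume].
#' @param contacts a [contact_set].
#' @param neighborhood 7, 19 or 27 voxels; 19 is the 3 mm radius sphere used
#'   for the main BOLD FC analysis.
#' @return a [ts_panel] with modality `"bold"`, `fs = 1/tr`, channels in
#'   contact order.
#' @export
extract_roi_timeseries <- function(vol, contacts, neighborhood = 19L) {
  stopifnot(inherits(vol, "bold_volume"))
  xyz <- contact_coords(contacts)
  d <- dim(vol$data)
  nt <- d[4]
  flat <- matrix(vol$data, prod(d[1:3]), nt)  # voxel-major view
  out <- matrix(0, nrow(xyz), nt)
  for (i in seq_len(nrow(xyz))) {
    vox <- sphere_voxels(xyz[i, ], neighborhood, vol$voxel_mm,
                         vol$origin_mm, grid_dim = d[1:3])
    lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
    out[i, ] <- colMeans(flat[lin, , drop = FALSE])
  }
  ts_panel(out, fs = 1 / vol$tr, channel_ids = rownames(xyz),
           modality = "bold")
}

#' Discard initial volumes
#'
#' Removes the first `n` time points of a panel (scanner equilibration
#' volumes; default 5).
#'
#' @param panel a [ts_panel].
#' @param n number of initial samples to drop.
#' @return the shortened [ts_panel].
#' @export
drop_initial_volumes <- function(panel, n = 5L) {
  stopifnot(inherits(panel, "ts_panel"))
  if (n < 0) stop("n must be nonnegative")
  if (n == 0) return(panel)
  if (n >= ncol(panel$values))
    stop("cannot drop all volumes")
  ts_panel(panel$values[, -(seq_len(n)), drop = FALSE], panel$fs,
           panel$channel_ids, panel$modality)
}

#' Demean and remove linear trends
#'
#' Per channel, subtracts the least-squares line in time; the output has zero
#' mean and zero linear trend.
#'
#' @param panel a [ts_panel] with >= 3 samples.
#' @return the detrended [ts_panel].
#' @export
detrend_demean <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  nt <- ncol(panel$values)
  if (nt < 3) stop("need at least three samples to detrend")
  X <- cbind(1, seq_len(nt))
  res <- t(qr.resid(qr(X), t(panel$values)))
  ts_panel(res, panel$fs, panel$channel_ids, panel$modality)
}

#' Regress confound time series out of a panel
#'
#' Ordinary least squares of every channel on `[intercept | confounds]`;
#' returns residuals, which are orthogonal to every confound column.
#' Linearly dependent confound columns are dropped with a warning.
#'
#' @param panel a [ts_panel].
#' @param confounds numeric matrix or data frame, one row per time point,
#'   named columns (e.g. the 24 motion regressors: six estimates, their
#'   derivatives, and quadratics of both; optionally global/CSF signals).
#' @return the residual [ts_panel].
#' @export
regress_confounds <- function(panel, confounds) {
  stopifnot(inherits(panel, "ts_panel"))
  confounds <- as.matrix(confounds)
  nt <- ncol(panel$values)
  if (nrow(confounds) != nt)
    stop("confound rows must equal the number of time points")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank >= nt)
    stop("confound design saturates the time series (rank >= t)")
  if (qrX$rank < ncol(X)) {
    drop_cols <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping linearly dependent confound column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  res <- t(qr.resid(qrX, t(panel$values)))
  ts_panel(res, panel$fs, panel$channel_ids, panel$modality)
}

#' Temporal bandpass for BOLD panels
#'
#' Zero-phase Butterworth bandpass; the default 0.01-0.2 Hz passband is the
#' main analysis, 0.01-0.08 Hz the sensitivity variant.
#'
#' @param panel a [ts_panel] sampled at `1/tr` Hz.
#' @param low,high passband edges in Hz; `high` must be below Nyquist
#'   (0.25 Hz at TR = 2 s).
#' @param order filter order (per pass).
#' @return the filtered [ts_panel].
#' @export
bandpass_bold <- function(panel, low = 0.01, high = 0.2, order = 3) {
  stopifnot(inherits(panel, "ts_panel"))
  if (high >= panel$fs / 2)
    stop(sprintf("high edge %g Hz is at or above Nyquist (%g Hz)",
                 high, panel$fs / 2))
  filt <- signal::butter(order, c(low, high) / (panel$fs / 2), type = "pass")
  apply_zero_phase(panel, filt)
}
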