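#' Multichannel time-series panel
#'
#' Container for SEEG-like or BOLD ROI time series: a channels x samples
#' matrix plus sampling rate, channel identifiers and a modality tag.
#'
#' @param values numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_ids character vector of unique channel (contact) ids; row
#'   names of `values` are used when omitted.
#' @param modality `"seeg"` or `"bold"`.
#' @return An object of class `ts_panel`.
#' @examples
#' p <- ts_panel(matrix(rnorm(20), 2, 10), fs = 10,
#'               channel_ids = c("a", "b"), modality = "seeg")
#' panel_duration(p)
#' @export
ts_panel <- function(values, fs, channel_ids = rownames(values),
                     modality = c("seeg", "bold")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nrow(values)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(values))
    stop("channel_ids length must equal the number of rows of values")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (any(!is.finite(values)))
    stop("panel contains non-finite samples")
  rownames(values) <- channel_ids
  structure(list(values = values, fs = fs, channel_ids = channel_ids,
                 modality = modality),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("<ts_panel> %s: %d channels x %d samples @ %g Hz (%.4g s)\n",
              x$modality, nrow(x$values), ncol(x$values), x$fs,
              panel_duration(x)))
  invisible(x)
}

#' Panel duration in seconds
#' @param panel a [ts_panel].
#' @return duration in seconds (`n_samples / fs`).
#' @export
panel_duration <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  ncol(panel$values) / panel$fs
}

#' Subset a panel by channel id
#' @param panel a [ts_panel].
#' @param ids channel ids to keep, in the order given.
#' @return the subset [ts_panel].
#' @export
subset_panel <- function(panel, ids) {
  stopifnot(inherits(panel, "ts_panel"))
  missing_ids <- setdiff(ids, panel$channel_ids)
  if (length(missing_ids))
    stop("unknown channel ids: ", paste(missing_ids, collapse = ", "))
  ts_panel(panel$values[ids, , drop = FALSE], panel$fs, ids, panel$modality)
}

#' Crop a panel to a time window
#' @param panel a [ts_panel].
#' @param duration_s seconds to keep.
#' @param from_s start of the window in seconds (default 0).
#' @return the cropped [ts_panel].
#' @export
crop_panel <- function(panel, duration_s, from_s = 0) {
  stopifnot(inherits(panel, "ts_panel"))
  i0 <- round(from_s * panel$fs) + 1L
  i1 <- i0 + round(duration_s * panel$fs) - 1L
  if (i1 > ncol(panel$values))
    stop(sprintf("crop window ends at %.4g s but panel is %.4g s",
                 i1 / panel$fs, panel_duration(panel)))
  ts_panel(panel$values[, i0:i1, drop = FALSE], panel$fs,
           panel$channel_ids, panel$modality)
}

# Apply a per-channel function returning a vector of (possibly new) length.
panel_map <- function(panel, f, fs = panel$fs) {
  out <- lapply(seq_len(nrow(panel$values)),
                function(i) f(panel$values[i, ]))
  ts_panel(do.call(rbind, out), fs, panel$channel_ids, panel$modality)
}
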