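#' The seven SEEG analysis bands
#'
#' Delta through high-gamma bands used for band-limited SEEG functional
#' connectivity: 1-4, 4-8, 8-13, 13-30, 30-40, 40-70 and 70-170 Hz.
#'
#' @return data frame with columns `name`, `low`, `high` (Hz).
#' @export
seeg_bands <- function() {
  data.frame(
    name = c("1-4", "4-8", "8-13", "13-30", "30-40", "40-70", "70-170"),
    low  = c(1, 4, 8, 13, 30, 40, 70),
    high = c(4, 8, 13, 30, 40, 70, 170),
    stringsAsFactors = FALSE
  )
}

# zero-phase (forward-backward) application of a signal::Arma filter to all
# channels at once; numerically identical to signal::filtfilt per channel
apply_zero_phase <- function(panel, filt) {
  vals <- filtfilt_channels_cpp(filt$b, filt$a, panel$values)
  ts_panel(vals, panel$fs, panel$channel_ids, panel$modality)
}

#' Broadband Butterworth bandpass
#'
#' Third-order Butterworth bandpass, 0.5-300 Hz by default, applied zero
#' phase (forward-backward) so no inter-channel lag is introduced. Requires a
#' sampling rate comfortably above twice the upper edge.
#'
#' @param panel a [ts_panel].
#' @param low,high passband edges in Hz.
#' @param order filter order (per pass).
#' @return the filtered [ts_panel], same length.
#' @export
broadband_filter <- function(panel, low = 0.5, high = 300, order = 3) {
  stopifnot(inherits(panel, "ts_panel"))
  if (panel$fs < 620)
    stop("sampling rate too low for a 300 Hz passband (need fs >= 620 Hz)")
  filt <- signal::butter(order, c(low, high) / (panel$fs / 2), type = "pass")
  apply_zero_phase(panel, filt)
}

#' Power-line band-stop filtering
#'
#' Cascaded third-order Butterworth band-stop filters over the 50 Hz mains
#' frequency and its harmonics (49-61, 99-101, 149-151, 199-201, 249-251,
#' 299-300 Hz by default), applied zero phase.
#'
#' @param panel a [ts_panel].
#' @param stop_bands list of length-2 Hz vectors.
#' @param order filter order (per pass, per band).
#' @return the filtered [ts_panel].
#' @export
powerline_notch <- function(panel,
                            stop_bands = list(c(49, 61), c(99, 101),
                                              c(149, 151), c(199, 201),
                                              c(249, 251), c(299, 300)),
                            order = 3) {
  stopifnot(inherits(panel, "ts_panel"))
  if (panel$fs / 2 <= max(unlist(stop_bands)))
    stop("sampling rate too low for the requested stop bands")
  for (b in stop_bands) {
    filt <- signal::butter(order, b / (panel$fs / 2), type = "stop")
    panel <- apply_zero_phase(panel, filt)
  }
  panel
}

#' Band-limiting filter for one SEEG analysis band
#'
#' Zero-phase third-order Butterworth bandpass at `[low, high]` Hz.
#'
#' @param panel a [ts_panel].
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @param order filter order (per pass).
#' @return the filtered [ts_panel].
#' @export
band_filter <- function(panel, low, high, order = 3) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= panel$fs / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 high, panel$fs / 2))
  filt <- signal::butter(order, c(low, high) / (panel$fs / 2), type = "pass")
  apply_zero_phase(panel, filt)
}

#' Flag flat or excessively noisy channels
#'
#' Channels with sample variance below `flat_tol` are flagged as flat; among
#' the remaining channels, those whose log-variance has a robust z-score
#' (median/MAD) above `noise_z` are flagged as noisy. The panel is not
#' modified; exclusion is the caller's decision.
#'
#' @param panel a [ts_panel] with at least three channels.
#' @param flat_tol variance threshold for a flat line.
#' @param noise_z robust z threshold on log variance.
#' @return character vector of flagged channel ids, with a `reason`
#'   attribute (`"flat"` or `"noisy"`); empty when all channels pass.
#' @export
detect_bad_channels <- function(panel, flat_tol = 1e-10, noise_z = 5) {
  stopifnot(inherits(panel, "ts_panel"))
  if (nrow(panel$values) < 3) stop("need at least three channels")
  v <- apply(panel$values, 1, var)
  flat <- v < flat_tol
  noisy <- rep(FALSE, length(v))
  nonflat <- which(!flat)
  if (length(nonflat) >= 3) {
    lv <- log(v[nonflat])
    s <- stats::mad(lv)
    if (s > 0) {
      z <- (lv - median(lv)) / s
      noisy[nonflat[z > noise_z]] <- TRUE
    }
  }
  sel <- which(flat | noisy)
  structure(panel$channel_ids[sel],
            reason = ifelse(flat[sel], "flat", "noisy"))
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over a reference channel set from
#' every channel. With the reference set being all white-matter channels this
#' is the white-matter common average reference; by construction the mean of
#' the output over the included channels is identically zero.
#'
#' @param panel a [ts_panel].
#' @param include_ids channel ids forming the reference; defaults to all.
#' @return the re-referenced [ts_panel].
#' @export
common_average_reference <- function(panel, include_ids = panel$channel_ids) {
  stopifnot(inherits(panel, "ts_panel"))
  include_ids <- as.character(include_ids)
  if (length(include_ids) == 0) stop("reference channel set is empty")
  if (!all(include_ids %in% panel$channel_ids))
    stop("include_ids contains unknown channels")
  ref <- colMeans(panel$values[include_ids, , drop = FALSE])
  ts_panel(sweep(panel$values, 2, ref, "-"), panel$fs, panel$channel_ids,
           panel$modality)
}

#' Average consecutive segments of a panel
#'
#' Takes the first `window_s * n_segments` seconds, splits them into
#' `n_segments` consecutive non-overlapping windows and returns their
#' pointwise average per channel — the segment-averaging step that raises the
#' SEEG signal-to-noise ratio before FC estimation. Defaults reproduce the
#' main analysis (ten 6 s segments from 60 s); 4 s and 8 s windows are the
#' sensitivity variants.
#'
#' @param panel a [ts_panel].
#' @param window_s segment length in seconds.
#' @param n_segments number of segments.
#' @return a [ts_panel] of duration `window_s`.
#' @export
segment_and_average <- function(panel, window_s = 6, n_segments = 10) {
  stopifnot(inherits(panel, "ts_panel"))
  nper <- round(window_s * panel$fs)
  need <- nper * n_segments
  if (ncol(panel$values) < need)
    stop(sprintf("panel too short: need %.4g s, have %.4g s",
                 need / panel$fs, panel_duration(panel)))
  acc <- matrix(0, nrow(panel$values), nper)
  for (k in seq_len(n_segments)) {
    idx <- ((k - 1) * nper + 1):(k * nper)
    acc <- acc + panel$values[, idx, drop = FALSE]
  }
  ts_panel(acc / n_segments, panel$fs, panel$channel_ids, panel$modality)
}

#' Per-segment FC averaging (alternative to time-domain segment averaging)
#'
#' Computes Pearson FC within each consecutive segment and averages the FC
#' matrices, instead of averaging the segments in the time domain first.
#' Provided as an explicit alternative; time-domain averaging is the
#' default analysis.
#'
#' @param panel a [ts_panel] (band-filtered, conditioned).
#' @param window_s,n_segments segmentation parameters.
#' @param band optional band label for the result.
#' @return a [conn_matrix] of averaged per-segment Pearson FC.
#' @export
pearson_fc_per_segment <- function(panel, window_s = 6, n_segments = 10,
                                   band = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  nper <- round(window_s * panel$fs)
  if (ncol(panel$values) < nper * n_segments)
    stop(sprintf("panel too short: need %.4g s, have %.4g s",
                 nper * n_segments / panel$fs, panel_duration(panel)))
  acc <- NULL
  for (k in seq_len(n_segments)) {
    idx <- ((k - 1) * nper + 1):(k * nper)
    seg <- ts_panel(panel$values[, idx, drop = FALSE], panel$fs,
                    panel$channel_ids, panel$modality)
    fc <- pearson_fc(seg, band = band)
    acc <- if (is.null(acc)) fc$values else acc + fc$values
  }
  modality <- if (panel$modality == "bold") "bold_fc" else "seeg_fc"
  conn_matrix(acc / n_segments, panel$channel_ids, modality = modality,
              band = band)
}

#' Pearson functional connectivity
#'
#' Pairwise Pearson correlation between all channels over the full panel.
#' Zero-variance channels make correlations undefined; they are reported by
#' name in a warning and their entries set to `NA` rather than silently
#' propagating.
#'
#' @param panel a [ts_panel] with >= 2 channels.
#' @param band optional band label attached to the result.
#' @return a [conn_matrix] with modality `"seeg_fc"` or `"bold_fc"` per the
#'   panel modality.
#' @export
pearson_fc <- function(panel, band = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  if (nrow(panel$values) < 2) stop("need at least two channels")
  sds <- apply(panel$values, 1, sd)
  degenerate <- panel$channel_ids[sds == 0]
  if (length(degenerate))
    warning("zero-variance channel(s), FC undefined: ",
            paste(degenerate, collapse = ", "))
  r <- suppressWarnings(cor(t(panel$values)))
  modality <- if (panel$modality == "bold") "bold_fc" else "seeg_fc"
  conn_matrix(r, panel$channel_ids, modality = modality, band = band)
}

#' Band-averaged magnitude-squared coherence
#'
#' Welch estimate: Hann-tapered windows (`window_s` seconds, `overlap`
#' fractional overlap), cross-spectra averaged over windows, magnitude-squared
#' coherence per frequency bin, then the mean over bins inside `[low, high]`.
#'
#' @param panel a [ts_panel]; its duration must support at least four
#'   averaging windows.
#' @param low,high band edges in Hz.
#' @param window_s taper window length in seconds.
#' @param overlap fractional window overlap in [0, 1).
#' @return a [conn_matrix] with modality `"coherence_fc"` (values in [0, 1],
#'   unit diagonal) and band label `"low-high"`.
#' @export
coherence_fc <- function(panel, low, high, window_s = 1, overlap = 0.5) {
  stopifnot(inherits(panel, "ts_panel"))
  nwin <- round(window_s * panel$fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, ncol(panel$values) - nwin + 1L, by = hop)
  if (length(starts) < 4)
    stop("panel too short: need at least four averaging windows")
  freqs <- (seq_len(nwin) - 1) * panel$fs / nwin
  bins <- which(freqs >= low & freqs <= high & freqs <= panel$fs / 2)
  if (!length(bins))
    stop(sprintf("no frequency bins inside [%g, %g] Hz at %g s windows",
                 low, high, window_s))
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hann
  nch <- nrow(panel$values)
  # accumulate cross-spectra: for each retained bin a nch x nch matrix
  S <- array(0 + 0i, dim = c(length(bins), nch, nch))
  for (s0 in starts) {
    seg <- t(panel$values[, s0:(s0 + nwin - 1), drop = FALSE]) * taper
    F <- mvfft(seg)[bins, , drop = FALSE]
    for (b in seq_along(bins))
      S[b, , ] <- S[b, , ] + outer(F[b, ], Conj(F[b, ]))
  }
  coh <- matrix(0, nch, nch)
  for (b in seq_along(bins)) {
    Sb <- S[b, , ]
    p <- Re(diag(Sb))
    msc <- Mod(Sb)^2 / outer(p, p)
    coh <- coh + msc
  }
  coh <- coh / length(bins)
  coh <- pmin(pmax(coh, 0), 1)
  conn_matrix(coh, panel$channel_ids, modality = "coherence_fc",
              band = paste0(low, "-", high))
}

#' Polyphase resampling of a panel
#'
#' Rational-rate polyphase resampling so that recordings at either stated
#' acquisition rate (2000 or 2048 Hz) can be brought to a common rate before
#' FC estimation.
#'
#' @param panel a [ts_panel].
#' @param fs_new target sampling rate in Hz (integer, as is `panel$fs`).
#' @return the resampled [ts_panel] at `fs_new`.
#' @export
resample_panel <- function(panel, fs_new) {
  stopifnot(inherits(panel, "ts_panel"))
  if (fs_new == panel$fs) return(panel)
  fs_old <- panel$fs
  if (fs_new %% 1 != 0 || fs_old %% 1 != 0)
    stop("resampling requires integer sampling rates")
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(fs_new, fs_old)
  p <- fs_new / d; q <- fs_old / d
  panel_map(panel, function(x) as.numeric(signal::resample(x, p, q)),
            fs = fs_new)
}

#' Full SEEG conditioning chain
#'
#' Broadband bandpass, power-line band-stops, bad-channel exclusion,
#' white-matter common average reference and segment averaging, in that
#' order. Returns the conditioned panel (bad channels removed) plus the list
#' of excluded channels.
#'
#' @param panel raw SEEG [ts_panel].
#' @param window_s,n_segments segment-averaging parameters.
#' @param flat_tol,noise_z bad-channel thresholds, see
#'   [detect_bad_channels()].
#' @param reference_ids channels for the common average reference; defaults
#'   to all retained channels.
#' @return list with elements `panel` (conditioned [ts_panel]) and
#'   `bad_channels` (character).
#' @export
condition_seeg <- function(panel, window_s = 6, n_segments = 10,
                           flat_tol = 1e-10, noise_z = 5,
                           reference_ids = NULL) {
  panel <- broadband_filter(panel)
  panel <- powerline_notch(panel)
  bad <- detect_bad_channels(panel, flat_tol = flat_tol, noise_z = noise_z)
  keep <- setdiff(panel$channel_ids, bad)
  if (length(keep) < 2) stop("fewer than two channels survive exclusion")
  panel <- subset_panel(panel, keep)
  if (is.null(reference_ids)) reference_ids <- keep
  panel <- common_average_reference(panel, intersect(reference_ids, keep))
  panel <- segment_and_average(panel, window_s = window_s,
                               n_segments = n_segments)
  list(panel = panel, bad_channels = as.character(bad))
}
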