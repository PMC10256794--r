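#' Study-level configuration
#'
#' Describes a whole study: who the participants are (synthetic configs or
#' file paths), the analysis bands, BOLD passband, sphere neighborhood,
#' segment averaging, FC method and FDR level.
#'
#' @param participants either an integer (that many synthetic participants
#'   generated from `synth_template`, each with its own seed substream), a
#'   list of [synth_config] objects, or a list of named lists of file paths
#'   (`contacts`, `seeg_panel`, and `bold_panel` or `bold_volume`, plus
#'   `streamlines` or `sc`).
#' @param synth_template [synth_config] used when `participants` is a count.
#' @param bands band table (data frame `name`, `low`, `high`); defaults to
#'   the seven analysis bands of [seeg_bands()].
#' @param bold_band length-2 Hz passband for BOLD preprocessing.
#' @param roi_neighborhood 7, 19 or 27 voxels for BOLD sphere ROIs.
#' @param segment_window_s,n_segments SEEG segment averaging parameters.
#' @param fc_method `"pearson"` or `"coherence"` for SEEG FC.
#' @param alpha FDR level.
#' @param drop_volumes initial BOLD volumes to discard.
#' @param use_volumes render/consume 4D volumes and extract sphere ROIs
#'   (`TRUE`, the full pipeline) or use the node-level BOLD panel directly.
#' @param output_dir optional directory for on-disk artifacts.
#' @param seed study-level seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(participants = 2, synth_template = synth_config(),
                         bands = seeg_bands(), bold_band = c(0.01, 0.2),
                         roi_neighborhood = 19L, segment_window_s = 6,
                         n_segments = 10, fc_method = c("pearson", "coherence"),
                         alpha = 0.05, drop_volumes = 5L, use_volumes = TRUE,
                         output_dir = NULL, seed = 1) {
  fc_method <- match.arg(fc_method)
  stopifnot(is.data.frame(bands),
            all(c("name", "low", "high") %in% names(bands)))
  if (!roi_neighborhood %in% c(7L, 19L, 27L))
    stop("roi_neighborhood must be 7, 19 or 27")
  # overlap between bands is a convention warning, not an error
  ord <- order(bands$low)
  if (any(bands$high[ord][-nrow(bands)] > bands$low[ord][-1]))
    warning("analysis bands overlap")
  structure(as.list(environment()), class = "study_config")
}

# resolve the participants field into a named list of per-participant inputs
resolve_participants <- function(cfg) {
  p <- cfg$participants
  if (is.numeric(p) && length(p) == 1) {
    p <- lapply(seq_len(p), function(i) {
      tpl <- cfg$synth_template
      tpl$seed <- derive_seed(cfg$seed, paste0("participant", i))
      tpl
    })
  }
  if (!is.list(p)) stop("participants must be a count or a list")
  if (is.null(names(p)) || any(names(p) == ""))
    names(p) <- sprintf("p%02d", seq_along(p))
  p
}

# load a participant described by file paths
load_participant <- function(paths, use_volumes) {
  if (is.null(paths$contacts)) stop("participant paths need 'contacts'")
  contacts <- read_contacts(paths$contacts)
  neural <- read_panel(paths$seeg_panel, modality = "seeg")
  out <- list(contacts = contacts, neural = neural)
  if (!is.null(paths$bold_volume)) {
    out$volume <- read_volume_nifti(paths$bold_volume)
  } else if (!is.null(paths$bold_panel)) {
    out$bold <- read_panel(paths$bold_panel, modality = "bold")
  } else stop("participant paths need 'bold_volume' or 'bold_panel'")
  if (!is.null(paths$streamlines)) {
    out$streamlines <- read_streamlines(paths$streamlines)
  } else if (!is.null(paths$sc)) {
    out$sc <- read_matrix(paths$sc, modality = "sc")
  } else stop("participant paths need 'streamlines' or 'sc'")
  out
}

#' SEEG band FC pipeline for one conditioned study
#'
#' Conditions a raw SEEG panel (broadband filter, power-line band-stops,
#' bad-channel exclusion, white-matter common average reference, segment
#' averaging) and computes one FC matrix per band.
#'
#' @param panel raw SEEG [ts_panel].
#' @param bands band table (`name`, `low`, `high`).
#' @param window_s,n_segments segment averaging parameters.
#' @param fc_method `"pearson"` or `"coherence"`.
#' @return list with `fc` (named list of [conn_matrix]) and `bad_channels`.
#' @export
seeg_fc_pipeline <- function(panel, bands = seeg_bands(), window_s = 6,
                             n_segments = 10,
                             fc_method = c("pearson", "coherence")) {
  fc_method <- match.arg(fc_method)
  # select the analysis excerpt (window_s * n_segments seconds) before
  # filtering: long recordings carry the slow dynamics for other modalities
  need_s <- window_s * n_segments
  if (panel_duration(panel) > need_s) panel <- crop_panel(panel, need_s)
  cond <- condition_seeg(panel, window_s = window_s,
                         n_segments = n_segments)
  fc <- lapply(seq_len(nrow(bands)), function(b) {
    if (fc_method == "pearson") {
      pearson_fc(band_filter(cond$panel, bands$low[b], bands$high[b]),
                 band = bands$name[b])
    } else {
      coherence_fc(cond$panel, bands$low[b], bands$high[b])
    }
  })
  names(fc) <- bands$name
  list(fc = fc, bad_channels = cond$bad_channels,
       panel = cond$panel)
}

#' BOLD FC pipeline
#'
#' Sphere-ROI extraction (when a volume is supplied), initial-volume
#' dropping, demeaning/detrending, optional confound regression, temporal
#' bandpass and Pearson FC.
#'
#' @param bold a [ts_panel] with modality `"bold"`, or `NULL` when `volume`
#'   is given.
#' @param contacts a [contact_set] (needed with `volume`).
#' @param volume optional [bold_volume] to extract ROIs from.
#' @param neighborhood sphere neighborhood for extraction.
#' @param drop_volumes initial volumes to discard.
#' @param band length-2 Hz passband.
#' @param confounds optional confound matrix (rows = retained volumes).
#' @return list with `fc` (a [conn_matrix]) and `panel` (the preprocessed
#'   [ts_panel]).
#' @export
bold_fc_pipeline <- function(bold = NULL, contacts = NULL, volume = NULL,
                             neighborhood = 19L, drop_volumes = 5L,
                             band = c(0.01, 0.2), confounds = NULL) {
  if (is.null(bold)) {
    if (is.null(volume) || is.null(contacts))
      stop("need either a BOLD panel or a volume plus contacts")
    bold <- extract_roi_timeseries(volume, contacts, neighborhood)
  }
  bold <- drop_initial_volumes(bold, drop_volumes)
  bold <- detrend_demean(bold)
  if (!is.null(confounds)) bold <- regress_confounds(bold, confounds)
  bold <- bandpass_bold(bold, band[1], band[2])
  list(fc = pearson_fc(bold), panel = bold)
}

# process one participant into coupling rows
process_participant <- function(pid, part, cfg) {
  if (inherits(part, "synth_config")) {
    part <- synth_participant(part, render_volume = cfg$use_volumes)
  } else if (!is.null(part$contacts) && is.null(part$neural)) {
    part <- load_participant(part, cfg$use_volumes)
  }
  seeg <- seeg_fc_pipeline(part$neural, bands = cfg$bands,
                           window_s = cfg$segment_window_s,
                           n_segments = cfg$n_segments,
                           fc_method = cfg$fc_method)
  keep <- seeg$panel$channel_ids
  contacts <- part$contacts[part$contacts$contact_id %in% keep, ]
  class(contacts) <- c("contact_set", "data.frame")
  dist <- euclidean_distance_matrix(contacts)
  sc <- if (!is.null(part$streamlines)) {
    count_streamline_connections(part$streamlines, contacts)
  } else subset_conn(part$sc, keep)
  bold <- bold_fc_pipeline(
    bold = if (cfg$use_volumes && !is.null(part$volume)) NULL else part$bold,
    contacts = contacts,
    volume = if (cfg$use_volumes) part$volume else NULL,
    neighborhood = cfg$roi_neighborhood, drop_volumes = cfg$drop_volumes,
    band = cfg$bold_band)
  bold_fc <- subset_conn(bold$fc, keep)
  rows <- list()
  for (b in names(seeg$fc)) {
    rows[[length(rows) + 1L]] <-
      couple_fc_fc(bold_fc, seeg$fc[[b]], dist, participant = pid, band = b)
    rows[[length(rows) + 1L]] <-
      couple_sc_fc(sc, seeg$fc[[b]], dist, participant = pid, band = b,
                   comparison = "sc_vs_seeg")
  }
  rows[[length(rows) + 1L]] <-
    couple_sc_fc(sc, bold_fc, dist, participant = pid, band = "bold",
                 comparison = "sc_vs_bold")
  list(rows = do.call(rbind, rows), bad_channels = seeg$bad_channels,
       matrices = list(dist = dist, sc = sc, bold_fc = bold_fc,
                       seeg_fc = seeg$fc))
}

#' Run a whole study end to end
#'
#' For every participant: build or load contacts, distance and structural
#' matrices, condition the SEEG panel and compute seven band FC matrices,
#' preprocess BOLD and compute its FC, then evaluate the distance-residualized
#' Spearman coupling (BOLD vs SEEG per band, SC vs SEEG per band, SC vs BOLD)
#' and apply joint BH-FDR across participants and bands within each
#' comparison family. A participant whose processing fails is logged and
#' skipped; the study continues.
#'
#' @param cfg a [study_config].
#' @return list with `table` (the FDR-corrected study table), `band_summary`
#'   (per-band medians from [summarize_bands()]), `bad_channels` (per
#'   participant), and `failures` (named character of error messages).
#'   With `output_dir` set, matrices, the table and a provenance JSON are
#'   also written.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  parts <- resolve_participants(cfg)
  rows <- list()
  bad <- list()
  failures <- character(0)
  artifacts <- list()
  for (pid in names(parts)) {
    res <- tryCatch(process_participant(pid, parts[[pid]], cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[pid] <- conditionMessage(res)
      message("participant ", pid, " failed: ", conditionMessage(res))
      next
    }
    rows[[pid]] <- res$rows
    bad[[pid]] <- res$bad_channels
    artifacts[[pid]] <- res$matrices
  }
  if (!length(rows)) stop("no participant could be processed")
  table <- fdr_correct(do.call(rbind, rows), alpha = cfg$alpha)
  rownames(table) <- NULL
  summary <- summarize_bands(table)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_study_table(table, file.path(cfg$output_dir, "study_table.tsv"))
    write_study_table(summary, file.path(cfg$output_dir, "band_summary.tsv"))
    for (pid in names(artifacts)) {
      pdir <- file.path(cfg$output_dir, pid)
      dir.create(pdir, showWarnings = FALSE)
      write_matrix(artifacts[[pid]]$dist, file.path(pdir, "distance.tsv"))
      write_matrix(artifacts[[pid]]$sc, file.path(pdir, "sc.tsv"))
      write_matrix(artifacts[[pid]]$bold_fc, file.path(pdir, "bold_fc.tsv"))
      for (b in names(artifacts[[pid]]$seeg_fc))
        write_matrix(artifacts[[pid]]$seeg_fc[[b]],
                     file.path(pdir, paste0("seeg_fc_", gsub("-", "_", b),
                                            ".tsv")))
    }
    jsonlite::write_json(
      list(seed = cfg$seed, config_hash = config_hash(cfg),
           package_version = as.character(utils::packageVersion("wmcoupling")),
           r_version = R.version.string,
           n_participants = length(parts),
           failures = failures),
      file.path(cfg$output_dir, "provenance.json"), auto_unbox = TRUE)
  }
  list(table = table, band_summary = summary, bad_channels = bad,
       failures = failures)
}

# small FNV-style hash of the serialized config, for provenance records
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "output_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (ch in utf8ToInt(as.character(s)))
    h <- (h * 16777619 + ch) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
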