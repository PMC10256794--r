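# All floating-point text output uses 12 significant digits so that text
# round-trips are testable to 1e-9.
fmt_num <- function(x) sprintf("%.12g", x)

#' Write / read a connectivity matrix as TSV
#'
#' Tab-delimited with a header row of node ids and a leading `node` column;
#' values at 12 significant digits.
#'
#' @param m a [conn_matrix].
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   [conn_matrix].
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  txt <- matrix(fmt_num(m$values), nrow(m$values))
  df <- data.frame(node = m$nodes, txt, stringsAsFactors = FALSE)
  names(df) <- c("node", m$nodes)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param modality,band metadata for the matrix being read, see
#'   [conn_matrix()].
#' @export
read_matrix <- function(path, modality, band = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "node")
    stop("malformed matrix file: first column must be 'node'")
  nodes <- as.character(df$node)
  if (!identical(names(df)[-1], nodes))
    stop("matrix file id mismatch between header and node column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(vals) != ncol(vals))
    stop("matrix file dimension mismatch")
  conn_matrix(vals, nodes, modality = modality, band = band)
}

#' Write / read a contact table as TSV
#'
#' Columns `contact_id`, `x_mm`, `y_mm`, `z_mm`, `tissue`.
#'
#' @param contacts a [contact_set].
#' @param path file path.
#' @return `write_contacts` returns `path` invisibly; `read_contacts` a
#'   [contact_set].
#' @export
write_contacts <- function(contacts, path) {
  stopifnot(inherits(contacts, "contact_set"))
  df <- as.data.frame(contacts)
  df$x_mm <- fmt_num(df$x_mm); df$y_mm <- fmt_num(df$y_mm)
  df$z_mm <- fmt_num(df$z_mm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("contact_id", "x_mm", "y_mm", "z_mm", "tissue")
  if (!all(need %in% names(df)))
    stop("malformed contacts file: need columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$contact_id))
    stop("duplicate contact id in contacts file")
  contact_set(df$contact_id, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
              df$tissue)
}

#' Write / read a time-series panel as TSV
#'
#' First column `time_s`, one column per channel. The sampling rate is
#' recovered from the time column on read.
#'
#' @param panel a [ts_panel].
#' @param path file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` a
#'   [ts_panel].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ts_panel"))
  t_s <- (seq_len(ncol(panel$values)) - 1) / panel$fs
  df <- data.frame(time_s = fmt_num(t_s),
                   matrix(fmt_num(t(panel$values)), ncol(panel$values)),
                   stringsAsFactors = FALSE)
  names(df) <- c("time_s", panel$channel_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param modality modality tag for the panel being read.
#' @export
read_panel <- function(path, modality = c("seeg", "bold")) {
  modality <- match.arg(modality)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "time_s")
    stop("malformed panel file: first column must be 'time_s'")
  if (nrow(df) < 2) stop("panel file needs at least two samples")
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("panel file has a non-uniform time column")
  ts_panel(t(as.matrix(df[, -1, drop = FALSE])), fs = 1 / dt[1],
           channel_ids = names(df)[-1], modality = modality)
}

#' Write / read streamlines as plain text
#'
#' One polyline per block: rows of `x y z` (mm), blocks separated by blank
#' lines.
#'
#' @param streamlines a [streamline_set].
#' @param path file path.
#' @return `write_streamlines` returns `path` invisibly; `read_streamlines`
#'   a [streamline_set].
#' @export
write_streamlines <- function(streamlines, path) {
  stopifnot(inherits(streamlines, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in streamlines$streamlines) {
    writeLines(apply(s, 1, function(p) paste(fmt_num(p), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  lines <- readLines(path)
  blocks <- unname(split(lines, cumsum(lines == "")))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0]
  streamline_set(lapply(blocks, function(b) {
    do.call(rbind, lapply(strsplit(b, "[ \t]+"), as.numeric))
  }))
}

#' Write a study table as TSV
#'
#' Columns `participant`, `band`, `comparison`, `r`, `p`, `n_edges` and,
#' when present, `p_fdr`, `significant`.
#'
#' @param table study table data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  df <- table
  for (col in intersect(c("r", "p", "p_fdr"), names(df)))
    df[[col]] <- fmt_num(df[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write ground truth as TSV + JSON
#'
#' The streamline-count matrix goes to `<stem>_sc.tsv`, the dynamic coupling
#' matrix to `<stem>_coupling.tsv`, and scalar metadata to `<stem>.json`.
#'
#' @param truth a [ground_truth].
#' @param stem path stem (no extension).
#' @return the JSON path, invisibly.
#' @export
write_ground_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "ground_truth"))
  nodes <- rownames(truth$sc_weights)
  if (is.null(nodes)) nodes <- sprintf("c%02d", seq_len(nrow(truth$sc_weights)))
  write_matrix(conn_matrix(truth$sc_weights, nodes, "sc"),
               paste0(stem, "_sc.tsv"))
  # coupling is continuous; reuse the TSV layout via a distance-tagged matrix
  km <- truth$dynamic_coupling
  txt <- matrix(fmt_num(km), nrow(km))
  df <- data.frame(node = nodes, txt, stringsAsFactors = FALSE)
  names(df) <- c("node", nodes)
  write.table(df, paste0(stem, "_coupling.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(coupling_strength = truth$coupling_strength,
                            n_nodes = nrow(km)),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(paste0(stem, ".json"))
}

#' Export / import a BOLD volume as NIfTI-1
#'
#' Uses a diagonal affine (`voxel_mm` scaling, `origin_mm` translation) in
#' the RAS mm convention. Requires the RNifti package. Volumes whose affine
#' is not diagonal are rejected on read.
#'
#' @param vol a [bold_volume].
#' @param path `.nii` or `.nii.gz` path.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` a [bold_volume].
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  stopifnot(inherits(vol, "bold_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, c(rep(vol$voxel_mm, 3), vol$tr))
  xform <- diag(c(rep(vol$voxel_mm, 3), 1))
  xform[1:3, 4] <- vol$origin_mm
  img <- RNifti::`qform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI import")
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop("non-diagonal NIfTI affine is not supported")
  vx <- diag(rot)
  if (max(abs(vx - vx[1])) > 1e-6)
    stop("anisotropic voxels are not supported")
  tr <- RNifti::pixdim(img)[4]
  bold_volume(unclass(img)[, , , , drop = FALSE], voxel_mm = vx[1],
              origin_mm = xf[1:3, 4], tr = tr)
}

#' Read a band table from YAML
#'
#' Expects a top-level `bands:` list of `name`/`low`/`high` entries.
#'
#' @param path YAML file path.
#' @return data frame with columns `name`, `low`, `high`.
#' @export
read_bands_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$bands)) stop("YAML must contain a top-level 'bands' list")
  out <- do.call(rbind, lapply(y$bands, function(b) {
    if (is.null(b$name) || is.null(b$low) || is.null(b$high))
      stop("each band needs name, low and high")
    data.frame(name = b$name, low = as.numeric(b$low),
               high = as.numeric(b$high), stringsAsFactors = FALSE)
  }))
  if (any(out$low <= 0 | out$low >= out$high))
    stop("bands must satisfy 0 < low < high")
  out
}
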