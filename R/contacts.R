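#' Electrode contact table
#'
#' Contacts with millimetre coordinates (MNI-like frame) and a tissue label.
#' All connectivity analyses operate on the white-matter contacts; the
#' `tissue` column lets mixed tables be carried around and filtered.
#'
#' @param contact_id character vector of unique ids.
#' @param coords numeric matrix (n x 3) of mm coordinates, columns x, y, z.
#' @param tissue per-contact label: `"white"`, `"gray"` or `"excluded"`.
#' @return A `contact_set`, a data frame with columns `contact_id`, `x_mm`,
#'   `y_mm`, `z_mm`, `tissue`.
#' @examples
#' cs <- contact_set(c("A1", "A2"), rbind(c(0, 0, 0), c(10, 0, 0)))
#' contact_coords(cs)
#' @export
contact_set <- function(contact_id, coords, tissue = "white") {
  contact_id <- as.character(contact_id)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have three columns (x, y, z mm)")
  if (nrow(coords) != length(contact_id))
    stop("coords rows must match contact_id length")
  if (anyDuplicated(contact_id)) stop("duplicate contact ids")
  if (any(!is.finite(coords))) stop("non-finite contact coordinates")
  tissue <- rep_len(as.character(tissue), length(contact_id))
  if (!all(tissue %in% c("white", "gray", "excluded")))
    stop("tissue must be one of 'white', 'gray', 'excluded'")
  out <- data.frame(contact_id = contact_id,
                    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
                    tissue = tissue, stringsAsFactors = FALSE)
  class(out) <- c("contact_set", "data.frame")
  out
}

#' Coordinates of a contact set as a matrix
#' @param contacts a [contact_set].
#' @param tissue optional tissue filter, e.g. `"white"`.
#' @return n x 3 numeric matrix with contact ids as row names.
#' @export
contact_coords <- function(contacts, tissue = NULL) {
  stopifnot(inherits(contacts, "contact_set"))
  if (!is.null(tissue)) contacts <- contacts[contacts$tissue %in% tissue, ]
  m <- as.matrix(contacts[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- contacts$contact_id
  m
}

#' Keep only white-matter contacts
#' @param contacts a [contact_set].
#' @return the white-matter subset, a [contact_set].
#' @export
white_matter_contacts <- function(contacts) {
  stopifnot(inherits(contacts, "contact_set"))
  out <- contacts[contacts$tissue == "white", ]
  class(out) <- c("contact_set", "data.frame")
  out
}

#' Streamline set
#'
#' A list of polylines in mm space, each an n x 3 matrix of ordered points.
#'
#' @param streamlines list of numeric matrices, each with >= 2 rows and 3
#'   columns.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines) {
  if (!is.list(streamlines)) stop("streamlines must be a list of matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3 || nrow(s) < 2)
      stop("each streamline needs >= 2 points with 3 coordinates")
    if (any(!is.finite(s))) stop("non-finite streamline coordinates")
    unname(s)
  })
  structure(list(streamlines = streamlines), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d polylines\n", length(x$streamlines)))
  invisible(x)
}
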