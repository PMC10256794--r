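#' Node-by-node connectivity matrix
#'
#' Symmetric matrix over a fixed node (contact) order with a modality tag and
#' optional frequency-band label. Functional connectivity (`bold_fc`,
#' `seeg_fc`) lies in [-1, 1] with unit diagonal; `coherence_fc` in [0, 1]
#' with unit diagonal; `sc` is a nonnegative integer streamline count and
#' `distance` a nonnegative mm distance, both with zero diagonal.
#'
#' @param values square numeric matrix.
#' @param nodes character vector of node ids (defaults to row names).
#' @param modality one of `"bold_fc"`, `"seeg_fc"`, `"coherence_fc"`, `"sc"`,
#'   `"distance"`.
#' @param band optional band label (e.g. `"1-4"`), or `NULL`.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, nodes = rownames(values),
                        modality = c("bold_fc", "seeg_fc", "coherence_fc",
                                     "sc", "distance"),
                        band = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("connectivity matrix must be square")
  if (is.null(nodes)) nodes <- paste0("c", seq_len(n))
  nodes <- as.character(nodes)
  if (length(nodes) != n) stop("nodes length must match matrix dimension")
  if (anyDuplicated(nodes)) stop("node ids must be unique")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("connectivity matrix must be symmetric")
  values <- (values + t(values)) / 2
  # diagonal is definitional (1 for FC/coherence, 0 for SC/distance)
  diag_target <- if (modality %in% c("sc", "distance")) 0 else 1
  diag(values) <- diag_target
  rng <- range(values[row(values) != col(values)], na.rm = TRUE)
  if (modality %in% c("bold_fc", "seeg_fc") &&
      (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9))
    stop("FC values must lie in [-1, 1]")
  if (modality == "coherence_fc" && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    stop("coherence values must lie in [0, 1]")
  if (modality %in% c("sc", "distance") && rng[1] < 0)
    stop(modality, " values must be nonnegative")
  dimnames(values) <- list(nodes, nodes)
  structure(list(values = values, nodes = nodes, modality = modality,
                 band = band),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s%s: %d nodes\n", x$modality,
              if (is.null(x$band)) "" else paste0(" [", x$band, "]"),
              length(x$nodes)))
  invisible(x)
}

#' Subset a connectivity matrix by node id
#' @param m a [conn_matrix].
#' @param ids node ids to keep, in the order given.
#' @return the subset [conn_matrix].
#' @export
subset_conn <- function(m, ids) {
  stopifnot(inherits(m, "conn_matrix"))
  missing_ids <- setdiff(ids, m$nodes)
  if (length(missing_ids))
    stop("unknown node ids: ", paste(missing_ids, collapse = ", "))
  conn_matrix(m$values[ids, ids, drop = FALSE], ids, m$modality, m$band)
}
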