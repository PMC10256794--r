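#' Half-vectorize a symmetric connectivity matrix
#'
#' Flattens the upper triangle (excluding the diagonal) into an edge vector
#' in lexicographic (i, j) order, i < j: (1,2), (1,3), ..., (1,n), (2,3), ...
#' The companion [edge_to_matrix()] reconstructs the symmetric matrix.
#'
#' @param m a [conn_matrix], or a plain symmetric matrix.
#' @return An `edge_vector`: list with `values`, integer index vectors `i`
#'   and `j` (i < j), and `nodes`.
#' @examples
#' m <- conn_matrix(diag(3), letters[1:3], modality = "distance")
#' half_vectorize(m)$values  # 3 edges: (1,2), (1,3), (2,3)
#' @export
half_vectorize <- function(m) {
  vals <- if (inherits(m, "conn_matrix")) m$values else as.matrix(m)
  nodes <- if (inherits(m, "conn_matrix")) m$nodes else rownames(vals)
  n <- nrow(vals)
  if (ncol(vals) != n) stop("matrix must be square")
  if (max(abs(vals - t(vals)), na.rm = TRUE) > 1e-10)
    stop("matrix is asymmetric beyond tolerance 1e-10")
  if (is.null(nodes)) nodes <- paste0("c", seq_len(n))
  idx <- which(upper.tri(vals), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])  # lexicographic (i, j)
  idx <- idx[ord, , drop = FALSE]
  structure(list(values = vals[idx], i = unname(idx[, 1]),
                 j = unname(idx[, 2]), nodes = nodes),
            class = "edge_vector")
}

#' Rebuild a symmetric matrix from an edge vector
#' @param ev an `edge_vector` from [half_vectorize()].
#' @param diag_value value placed on the diagonal.
#' @return symmetric matrix with the edge vector's node names.
#' @export
edge_to_matrix <- function(ev, diag_value = 0) {
  stopifnot(inherits(ev, "edge_vector"))
  n <- length(ev$nodes)
  m <- matrix(diag_value * 0, n, n)
  m[cbind(ev$i, ev$j)] <- ev$values
  m[cbind(ev$j, ev$i)] <- ev$values
  diag(m) <- diag_value
  dimnames(m) <- list(ev$nodes, ev$nodes)
  m
}

# check two edge vectors share node order and pair index
check_aligned <- function(...) {
  evs <- list(...)
  ref <- evs[[1]]
  for (ev in evs[-1]) {
    if (!identical(ev$nodes, ref$nodes) || !identical(ev$i, ref$i) ||
        !identical(ev$j, ref$j))
      stop("edge vectors are not aligned (node sets or pair order differ)")
  }
  invisible(TRUE)
}

#' Regress Euclidean distance out of an edge vector
#'
#' Ordinary least-squares residual of `y` on `[intercept, d]`. The residuals
#' have zero mean and zero sample covariance with the distances, removing the
#' distance-connectivity confound before rank correlation.
#'
#' @param y an `edge_vector` of connectivity values.
#' @param d an `edge_vector` of mm distances over the same pairs.
#' @return an `edge_vector` of residuals.
#' @export
residualize_on_distance <- function(y, d) {
  stopifnot(inherits(y, "edge_vector"), inherits(d, "edge_vector"))
  check_aligned(y, d)
  if (length(y$values) < 3) stop("need at least three edges")
  if (sd(d$values) == 0)
    stop("degenerate geometry: all pairwise distances are equal, ",
         "distance cannot be regressed out")
  X <- cbind(1, d$values)
  res <- qr.resid(qr(X), y$values)
  out <- y
  out$values <- as.numeric(res)
  out
}

#' Spearman rank correlation between two edge vectors
#'
#' Pearson correlation of mid-ranks (average ranks for ties). The two-sided p
#' value uses the t approximation with n - 2 degrees of freedom; for small
#' edge counts an exact permutation p is available.
#'
#' @param x,y aligned `edge_vector`s (or plain numeric vectors) with n >= 4.
#' @param method `"t"` (default) or `"permutation"` (exact enumeration,
#'   n <= 8 only).
#' @return list with `r`, `p`, `n`.
#' @export
spearman_edges <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  if (inherits(x, "edge_vector") && inherits(y, "edge_vector"))
    check_aligned(x, y)
  xv <- if (inherits(x, "edge_vector")) x$values else as.numeric(x)
  yv <- if (inherits(y, "edge_vector")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("length mismatch")
  n <- length(xv)
  if (n < 4) stop("need at least four pairs")
  if (sd(xv) == 0 || sd(yv) == 0)
    stop("constant vector: rank correlation undefined")
  rx <- rank(xv); ry <- rank(yv)
  r <- cor(rx, ry)
  if (method == "permutation") {
    if (n > 8) stop("exact permutation p supported only for n <= 8")
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stats <- abs((matrix(rxc[perms], nrow(perms)) %*% ryc)[, 1]) / denom
    p <- mean(stats >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(r = unname(r), p = min(max(p, .Machine$double.xmin), 1), n = n)
}

# all permutations of 1:n as an n! x n matrix (n small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

# shared core: residualize two edge vectors on distance and rank-correlate
couple_core <- function(a, b, d, participant, band, comparison) {
  check_aligned(a, b, d)
  keep <- is.finite(a$values) & is.finite(b$values) & is.finite(d$values)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " edge(s) with undefined connectivity dropped")
    a$values <- a$values[keep]; b$values <- b$values[keep]
    d$values <- d$values[keep]
    a$i <- a$i[keep]; a$j <- a$j[keep]
    b$i <- b$i[keep]; b$j <- b$j[keep]
    d$i <- d$i[keep]; d$j <- d$j[keep]
  }
  if (length(a$values) < 4) stop("fewer than four usable edges")
  ra <- residualize_on_distance(a, d)
  rb <- residualize_on_distance(b, d)
  sp <- spearman_edges(ra, rb)
  data.frame(participant = participant, band = band,
             comparison = comparison, r = sp$r, p = sp$p, n_edges = sp$n,
             stringsAsFactors = FALSE)
}

#' Distance-residualized coupling between two FC matrices
#'
#' Half-vectorizes the BOLD FC, SEEG FC and distance matrices, regresses
#' distance out of both FC edge vectors, and Spearman-correlates the
#' residuals across all regional pairs.
#'
#' @param bold,seeg [conn_matrix] objects over identical node sets.
#' @param dist the distance [conn_matrix].
#' @param participant participant id for the result row.
#' @param band band label for the result row.
#' @return one-row data frame: `participant`, `band`, `comparison`
#'   (`"bold_vs_seeg"`), `r`, `p`, `n_edges`.
#' @export
couple_fc_fc <- function(bold, seeg, dist, participant = "p1",
                         band = "broadband") {
  if (!identical(bold$nodes, seeg$nodes) ||
      !identical(bold$nodes, dist$nodes))
    stop("node sets differ between matrices")
  couple_core(half_vectorize(bold), half_vectorize(seeg),
              half_vectorize(dist), participant, band, "bold_vs_seeg")
}

#' Distance-residualized coupling between SC and an FC matrix
#'
#' Restricts all edge vectors to regional pairs with nonzero structural
#' connectivity (the structural network is sparse; zero entries carry no
#' streamline evidence), residualizes SC and FC on distance within that edge
#' set, and Spearman-correlates the residuals.
#'
#' @param sc streamline-count [conn_matrix].
#' @param fc functional [conn_matrix] (BOLD or SEEG).
#' @param dist distance [conn_matrix].
#' @param participant,band labels for the result row.
#' @param comparison `"sc_vs_seeg"` or `"sc_vs_bold"`.
#' @return one-row data frame as in [couple_fc_fc()].
#' @export
couple_sc_fc <- function(sc, fc, dist, participant = "p1",
                         band = "broadband",
                         comparison = c("sc_vs_seeg", "sc_vs_bold")) {
  comparison <- match.arg(comparison)
  if (!identical(sc$nodes, fc$nodes) || !identical(sc$nodes, dist$nodes))
    stop("node sets differ between matrices")
  es <- half_vectorize(sc)
  ef <- half_vectorize(fc)
  ed <- half_vectorize(dist)
  mask <- which(es$values > 0)
  if (length(mask) < 4)
    stop("insufficient nonzero structural connections (< 4 edges)")
  for (nm in c("es", "ef", "ed")) {
    ev <- get(nm)
    ev$values <- ev$values[mask]; ev$i <- ev$i[mask]; ev$j <- ev$j[mask]
    assign(nm, ev)
  }
  couple_core(es, ef, ed, participant, band, comparison)
}

#' Benjamini-Hochberg FDR correction over a study table
#'
#' Adds BH step-up adjusted p values (`p_fdr`) and a `significant` flag.
#' Adjustment is joint over all rows within each comparison family
#' (all participants x all bands of one comparison type), matching a design
#' where multiple participants and bands are tested together.
#'
#' @param table data frame with at least `p` and `comparison` columns.
#' @param alpha FDR level (default 0.05).
#' @return the table with `p_fdr` and `significant` columns appended.
#' @export
fdr_correct <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), "p" %in% names(table))
  if (any(!is.finite(table$p) | table$p <= 0 | table$p > 1))
    stop("all p values must lie in (0, 1]")
  fam <- if ("comparison" %in% names(table)) table$comparison
         else rep("all", nrow(table))
  p_fdr <- rep(NA_real_, nrow(table))
  for (f in unique(fam)) {
    sel <- fam == f
    p_fdr[sel] <- p.adjust(table$p[sel], method = "BH")
  }
  table$p_fdr <- p_fdr
  table$significant <- p_fdr < alpha
  table
}

#' Per-band medians of coupling results
#'
#' Median Spearman r across participants for every (comparison, band) cell,
#' plus the number of participants and (when present) the count of
#' FDR-significant participants.
#'
#' @param table a study table (rows of coupling results), with or without
#'   FDR columns.
#' @return data frame with columns `comparison`, `band`, `median_r`,
#'   `n_participants` and, if available, `n_significant`.
#' @export
summarize_bands <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  key <- interaction(table$comparison, table$band, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- table[key == k, ]
    out <- data.frame(comparison = sub$comparison[1], band = sub$band[1],
                      median_r = median(sub$r),
                      n_participants = nrow(sub),
                      stringsAsFactors = FALSE)
    if ("significant" %in% names(sub))
      out$n_significant <- sum(sub$significant)
    out
  })
  do.call(rbind, rows)
}
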