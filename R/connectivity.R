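#' Fisher-z connectivity matrix from ROI time series
#'
#' Computes Pearson correlations between all pairs of ROI time courses,
#' applies the Fisher z-transform (with r clipped to +/- (1 - 1e-7) so the
#' transform stays finite), and zeroes the diagonal.
#'
#' @param timeseries numeric T x N matrix (rows = time points, columns =
#'   ROIs), with column names used as node ids.
#' @return a `connectivity_matrix`: the N x N Fisher-z matrix with node ids
#'   as dimnames, zero diagonal.
#' @export
correlation_matrix <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (!is.numeric(ts) || !all(is.finite(ts))) {
    stop("time series must be finite numeric", call. = FALSE)
  }
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("constant time series for node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- cor(ts)
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  if (is.null(colnames(ts))) {
    dimnames(z) <- list(paste0("n", seq_len(ncol(ts))),
                        paste0("n", seq_len(ncol(ts))))
  }
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            n_timepoints = nrow(ts))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Fisher-z connectivity matrix:", nrow(x), "nodes\n")
  invisible(x)
}

# Positive part of a connectivity (or plain) matrix, diagonal zeroed.
positive_weights <- function(C) {
  w <- unclass(C)
  attr(w, "n_timepoints") <- NULL
  w[w < 0] <- 0
  diag(w) <- 0
  w
}

#' Wrap a precomputed symmetric matrix as a connectivity matrix
#'
#' For cohorts that supply N x N Fisher-z matrices instead of raw time
#' series. The diagonal is zeroed; `n_timepoints` (the sample size behind the
#' correlations) is needed later by [threshold_fdr()].
#'
#' @param values symmetric numeric matrix.
#' @param n_timepoints optional sample size the correlations came from.
#' @export
as_connectivity <- function(values, n_timepoints = NULL) {
  check_square_symmetric(values, "connectivity matrix")
  diag(values) <- 0
  if (is.null(rownames(values))) {
    dimnames(values) <- list(paste0("n", seq_len(nrow(values))),
                             paste0("n", seq_len(nrow(values))))
  }
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            n_timepoints = n_timepoints)
}

#' Proportional density thresholding
#'
#' Retains the K = round(d * N(N-1)/2) strongest connections (by signed
#' value) of the upper triangle, binarizes and symmetrizes. Ties at the
#' cutoff are broken by ascending (row, column) order so the result is
#' deterministic.
#'
#' @param C a [correlation_matrix()] result or symmetric matrix.
#' @param d target density in (0, 1); the study grid is 0.02-0.10.
#' @return a `binary_graph`: list with `adjacency` (0/1 matrix), `density`
#'   and `edge_count`.
#' @export
threshold_density <- function(C, d) {
  check_square_symmetric(unclass(C), "connectivity matrix")
  if (d <= 0 || d >= 1) stop("density must be in (0, 1)", call. = FALSE)
  n <- nrow(C)
  m <- n * (n - 1) / 2
  k <- floor(d * m + 0.5) # round half up, independent of IEEE round-to-even
  if (k < 1) stop("density ", d, " keeps no edges (degenerate graph)",
                  call. = FALSE)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  vals <- unclass(C)[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  a <- matrix(0L, n, n, dimnames = dimnames(C))
  a[ut[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  structure(list(adjacency = a, density = d, edge_count = as.integer(k)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("Binary graph:", nrow(x$adjacency), "nodes,", x$edge_count,
      "edges (density", format(x$density), ")\n")
  invisible(x)
}

#' Edge-wise FDR thresholding of a connectivity matrix
#'
#' Converts each Fisher-z value to a two-sided p-value via the normal
#' approximation z * sqrt(T - 3) ~ N(0, 1), applies Benjamini-Hochberg
#' step-up at level `q` across the edges of the requested sign, and keeps the
#' surviving weights (all others set to zero).
#'
#' @param C a [correlation_matrix()] result.
#' @param q FDR level in (0, 1); default 0.05.
#' @param sign `"positive"` or `"negative"`: which edges form the family.
#' @param n_timepoints number of samples behind the correlations; taken from
#'   `C` when available.
#' @return a `signed_weighted_graph`: list with `weights`, `q`, `sign`.
#' @export
threshold_fdr <- function(C, q = 0.05, sign = c("positive", "negative"),
                          n_timepoints = attr(C, "n_timepoints")) {
  sign <- match.arg(sign)
  check_square_symmetric(unclass(C), "connectivity matrix")
  if (is.null(n_timepoints)) {
    stop("n_timepoints is required to convert Fisher-z values to p-values",
         call. = FALSE)
  }
  if (n_timepoints <= 3) stop("need more than 3 time points", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  z <- unclass(C)
  attr(z, "n_timepoints") <- NULL
  ut <- upper.tri(z)
  cand <- if (sign == "positive") ut & z > 0 else ut & z < 0
  w <- matrix(0, nrow(z), ncol(z), dimnames = dimnames(z))
  if (any(cand)) {
    p <- 2 * pnorm(-abs(z[cand]) * sqrt(n_timepoints - 3))
    keep <- p.adjust(p, method = "BH") <= q
    idx <- which(cand)
    w[idx[keep]] <- z[idx[keep]]
    w <- w + t(w)
  }
  structure(list(weights = w, q = q, sign = sign),
            class = "signed_weighted_graph")
}

#' @export
print.signed_weighted_graph <- function(x, ...) {
  cat("FDR-thresholded", x$sign, "graph:", sum(x$weights != 0) / 2,
      "surviving edges (q =", x$q, ")\n")
  invisible(x)
}

#' Read a delimited ROI time-series file
#'
#' Plain TSV, T rows x N columns, header row of node ids (the format written
#' by [sample_cohort()]).
#'
#' @param path file path.
#' @export
read_timeseries <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write a graph as an edge list
#'
#' @param g a `binary_graph` or `signed_weighted_graph`.
#' @param path CSV output path (columns node_i, node_j, weight).
#' @export
write_edge_list <- function(g, path) {
  m <- if (inherits(g, "binary_graph")) g$adjacency else g$weights
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  df <- data.frame(node_i = rownames(m)[idx[, 1]],
                   node_j = colnames(m)[idx[, 2]],
                   weight = m[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
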