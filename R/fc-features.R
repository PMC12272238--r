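#' Number of unique edges of a P-parcel connectivity matrix
#'
#' @param p Parcel count (P >= 2).
#' @return Integer, `p * (p - 1) / 2` — the length of the vectorized lower
#'   triangle. A 419-parcel matrix has 87,571 edges.
#' @export
#' @examples
#' n_edges(419)
n_edges <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 2, p == round(p))
  as.integer(p * (p - 1) / 2)
}

#' Edge index table for the canonical edge order
#'
#' The canonical edge order used throughout the package is the strict lower
#' triangle traversed row-major: edge k connects parcels (i, j) with i > j,
#' rows in increasing i and, within a row, increasing j. This is the order in
#' which [vectorize_lower_triangle()] emits edges and in which Haufe
#' importance maps are indexed.
#'
#' @param p Parcel count.
#' @return A tibble with columns `edge` (1..E), `i` (row parcel, i > j), `j`.
#' @export
edge_index <- function(p) {
  p <- as.integer(p)
  stopifnot(p >= 2)
  i <- unlist(lapply(2:p, function(r) rep.int(r, r - 1L)))
  j <- unlist(lapply(2:p, function(r) seq_len(r - 1L)))
  tibble::tibble(edge = seq_along(i), i = i, j = j)
}

check_symmetric <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("FC input must be a square matrix, got ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (nrow(m) < 2) stop("FC matrix needs at least 2 parcels", call. = FALSE)
  d <- abs(m - t(m))
  if (any(d > tol, na.rm = TRUE)) {
    w <- which(d == max(d), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "FC matrix is asymmetric beyond tolerance %g: entry (%d, %d) differs from (%d, %d) by %g",
      tol, w[1], w[2], w[2], w[1], max(d)), call. = FALSE)
  }
  invisible(m)
}

#' Vectorize the strict lower triangle of a symmetric FC matrix
#'
#' Extracts the strictly lower-triangular entries (diagonal excluded) in the
#' canonical row-major order of [edge_index()]. A 419 x 419 matrix yields a
#' vector of length 87,571.
#'
#' @param fc Symmetric numeric P x P matrix (P >= 2). Asymmetry beyond `tol`
#'   is an error; the diagonal is ignored.
#' @param tol Symmetry tolerance on `max |M - t(M)|`.
#' @return Numeric vector of length `n_edges(P)` with attribute
#'   `normalized = FALSE`.
#' @seealso [devectorize_edges()] for the inverse, [normalize_feature_vector()].
#' @export
vectorize_lower_triangle <- function(fc, tol = 1e-8) {
  check_symmetric(fc, tol)
  p <- nrow(fc)
  # row-major over rows i > j == column-major upper triangle of t(fc);
  # build explicitly from the transpose so the order is row-major by i
  v <- t(fc)[upper.tri(fc)]
  # upper.tri of t(fc) in column-major order enumerates (j < i) by column i,
  # i.e. for i = 2..P all j < i -- exactly the canonical order
  attr(v, "normalized") <- FALSE
  v
}

#' Reconstruct a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_lower_triangle()] up to the diagonal, which carries
#' no edge information and is set to `diag_value`.
#'
#' @param v Numeric vector of length `P(P-1)/2` in canonical edge order.
#' @param diag_value Value placed on the diagonal (default 1, a correlation
#'   matrix's self-similarity).
#' @return Symmetric P x P matrix.
#' @export
devectorize_edges <- function(v, diag_value = 1) {
  e <- length(v)
  p <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(p - round(p)) > 1e-9) {
    stop("edge vector length ", e, " is not P(P-1)/2 for any integer P",
         call. = FALSE)
  }
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- v
  m <- t(m)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- diag_value
  m
}

#' Normalize a feature vector to zero mean and unit L2 norm
#'
#' Subtracts the mean and divides by the L2 norm of the demeaned vector, so
#' the result has exactly zero mean and unit norm; the operation is
#' idempotent. Cross-dataset learners consume normalized vectors; this
#' normalization has no effect on correlation-kernel KRR (see
#' [correlation_kernel()]).
#'
#' @param v Numeric vector with at least 2 entries and nonzero variance.
#' @return Normalized vector with attribute `normalized = TRUE`.
#' @export
normalize_feature_vector <- function(v) {
  if (length(v) < 2) stop("feature vector needs length >= 2", call. = FALSE)
  c0 <- v - mean(v)
  nrm <- sqrt(sum(c0^2))
  if (nrm < .Machine$double.eps * length(v)) {
    stop("degenerate input: constant feature vector has zero norm after demeaning",
         call. = FALSE)
  }
  out <- c0 / nrm
  attr(out, "normalized") <- TRUE
  out
}

#' Row-wise normalization of a feature matrix
#'
#' Applies [normalize_feature_vector()] to each row of a participants x edges
#' matrix.
#'
#' @param x Numeric matrix, one participant per row.
#' @return Matrix of the same shape, each row zero-mean unit-norm.
#' @export
normalize_features <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  ctr <- x - rowMeans(x)
  nrm <- sqrt(rowSums(ctr^2))
  if (any(nrm < .Machine$double.eps * ncol(x))) {
    stop("degenerate input: constant feature row(s) ",
         paste(utils::head(which(nrm < .Machine$double.eps * ncol(x)), 3), collapse = ", "),
         call. = FALSE)
  }
  ctr / nrm
}

#' Correlation kernel between participants
#'
#' Kernel similarity between two participants is the Pearson correlation of
#' their feature vectors. Because the kernel correlates each pair of rows, it
#' is invariant to per-participant affine rescaling of the raw features —
#' which is why per-participant normalization does not change KRR.
#'
#' @param a Numeric matrix, participants x features (features >= 2).
#' @param b Optional second matrix with the same number of columns; defaults
#'   to `a`.
#' @return `nrow(a)` x `nrow(b)` matrix of Pearson correlations in \[-1, 1\].
#' @export
correlation_kernel <- function(a, b = NULL) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(b)) b <- a
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(a) != ncol(b)) {
    stop("feature length mismatch: ", ncol(a), " vs ", ncol(b), call. = FALSE)
  }
  if (ncol(a) < 2) stop("correlation kernel needs >= 2 features", call. = FALSE)
  za <- normalize_features(a)
  zb <- normalize_features(b)
  k <- tcrossprod(za, zb)
  pmin(pmax(k, -1), 1)
}
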