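#' Membership (affiliation) matrices
#'
#' The membership matrix U is c x x: row i holds the affiliation of every
#' sample to cluster i, column g the affiliations of sample g, which must be
#' in [0, 1] and sum to 1.  A \emph{hard} matrix contains only 0/1 entries
#' with exactly one 1 per column (the HCM output, or a hardened FCM output).
#'
#' @param mu numeric matrix, clusters in rows, samples in columns.
#' @return \code{mu} with class \code{"membership_matrix"}, validated.
#' @examples
#' membership_matrix(rbind(c(0.8, 0.5), c(0.2, 0.5)))
#' @export
membership_matrix <- function(mu) {
  mu <- as.matrix(mu)
  .validate_membership(mu)
  class(mu) <- c("membership_matrix", "matrix", "array")
  mu
}

.validate_membership <- function(mu, tol = 1e-9) {
  if (!is.numeric(mu) || !is.matrix(mu))
    stop("membership matrix must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(mu)))
    stop("membership matrix contains non-finite entries", call. = FALSE)
  if (any(mu < -tol) || any(mu > 1 + tol))
    stop("membership entries must lie in [0, 1]", call. = FALSE)
  cs <- colSums(mu)
  if (any(abs(cs - 1) > tol))
    stop("membership columns must each sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")", call. = FALSE)
  invisible(mu)
}

#' Test whether a membership matrix is hard (crisp)
#'
#' @param u membership matrix (c x x).
#' @return \code{TRUE} iff every entry is 0 or 1 and each column has exactly
#'   one 1.
#' @export
is_hard_membership <- function(u) {
  u <- as.matrix(u)
  all(u == 0 | u == 1) && all(colSums(u) == 1)
}

#' Harden (threshold) a fuzzy membership matrix
#'
#' Per sample, the cluster with maximal membership receives affiliation 1 and
#' all others 0; ties go to the lowest cluster index.  Idempotent on hard
#' matrices.
#'
#' @param u membership matrix (c x x).
#' @return A hard \code{\link{membership_matrix}} of the same dimensions.
#' @examples
#' harden(rbind(c(0.7, 0.5), c(0.3, 0.5)))  # ties -> cluster 1
#' @export
harden <- function(u) {
  u <- as.matrix(u)
  .validate_membership(u)
  win <- max.col(t(u), ties.method = "first")
  h <- matrix(0, nrow(u), ncol(u))
  h[cbind(win, seq_len(ncol(u)))] <- 1
  membership_matrix(h)
}

#' Label image from a membership matrix
#'
#' Hardens \code{u} if needed, then reshapes the per-sample winning cluster
#' indices (0-based, 0..c-1) to the original image dimensions in R's
#' column-major order -- the inverse of \code{\link{as_feature_set}}'s
#' flattening.
#'
#' @param u membership matrix (c x x).
#' @param shape integer vector of image dimensions with \code{prod(shape)}
#'   equal to the number of samples.
#' @return Integer array of cluster labels with \code{dim = shape} (a plain
#'   integer vector when \code{shape} has length 1).
#' @export
labels_from <- function(u, shape) {
  u <- as.matrix(u)
  .validate_membership(u)
  shape <- as.integer(shape)
  if (prod(shape) != ncol(u))
    stop("labels_from: prod(shape) [", prod(shape),
         "] must equal the sample count [", ncol(u), "]", call. = FALSE)
  lab <- max.col(t(u), ties.method = "first") - 1L
  if (length(shape) == 1L) lab else array(lab, dim = shape)
}

#' One-hot membership matrix from integer labels
#'
#' Inverse of \code{\link{labels_from}} for hard matrices: labels are 0-based
#' cluster indices.
#'
#' @param labels integer vector/array of 0-based cluster labels.
#' @param c number of clusters; defaults to \code{max(labels) + 1}.
#' @return A hard \code{\link{membership_matrix}}.
#' @export
one_hot <- function(labels, c = NULL) {
  lab <- as.integer(labels)
  if (is.null(c)) c <- max(lab) + 1L
  if (any(lab < 0L) || any(lab >= c))
    stop("one_hot: labels must lie in 0..c-1", call. = FALSE)
  h <- matrix(0, c, length(lab))
  h[cbind(lab + 1L, seq_along(lab))] <- 1
  membership_matrix(h)
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat("<membership_matrix> c =", nrow(x), " x =", ncol(x),
      if (is_hard_membership(x)) " (hard)\n" else " (fuzzy)\n")
  invisible(x)
}
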