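#' Feature sets: flattened image intensities
#'
#' A \code{feature_set} holds the sample collection handed to the clustering
#' engines: one scalar intensity per pixel/voxel (\code{values}), the original
#' image dimensions (\code{shape}) so label maps can be reconstructed, and the
#' sample count \code{x}.  Images are flattened in R's native column-major
#' order; \code{\link{labels_from}} reshapes with the same convention, so the
#' round trip is exact.
#'
#' @param values numeric vector of intensities, one per sample; must be finite.
#' @param shape integer vector of original image dimensions; defaults to
#'   \code{length(values)} (a flat 1-D set).
#' @return An object of class \code{"feature_set"}: a list with elements
#'   \code{values}, \code{shape} and \code{x}.
#' @examples
#' fs <- feature_set(c(0, 0, 10, 10), shape = c(2, 2))
#' fs$x
#' @export
feature_set <- function(values, shape = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("feature_set: 'values' must be non-empty", call. = FALSE)
  if (!all(is.finite(values)))
    stop("feature_set: 'values' must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (is.null(shape)) shape <- length(values)
  shape <- as.integer(shape)
  if (any(shape <= 0L))
    stop("feature_set: 'shape' must be positive", call. = FALSE)
  if (prod(shape) != length(values))
    stop("feature_set: prod(shape) [", prod(shape),
         "] must equal length(values) [", length(values), "]", call. = FALSE)
  structure(list(values = values, shape = shape, x = length(values)),
            class = "feature_set")
}

#' Coerce an image or vector to a feature set
#'
#' Matrices and arrays are flattened (column-major) with their dimensions
#' retained as \code{shape}; vectors become flat 1-D sets; an existing
#' \code{feature_set} passes through.
#'
#' @param x a \code{feature_set}, numeric vector, matrix or array.
#' @return A \code{\link{feature_set}}.
#' @export
as_feature_set <- function(x) {
  if (inherits(x, "feature_set")) return(x)
  if (is.array(x) || is.matrix(x)) return(feature_set(as.vector(x), dim(x)))
  feature_set(x)
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> x =", x$x, " shape =", paste(x$shape, collapse = "x"),
      " range = [", format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Fit configuration for the clustering engines
#'
#' @param c number of clusters (>= 1).
#' @param fuzzifier the FCM fuzzy-weighting exponent r (> 1); larger values
#'   smooth the memberships.  Values outside the interval (1.1, 5) are allowed
#'   but trigger a warning at fit time, since the method is characterised for
#'   that range.  Ignored by HCM (conceptually r = 1).
#' @param max_iter maximum number of update cycles (default 300).
#' @param tol convergence threshold on the maximum absolute center change
#'   (default 1e-5, intensity units).
#' @param seed RNG seed used by the \code{"random"} initializer; \code{NULL}
#'   leaves the RNG untouched.
#' @param init initialization strategy: \code{"quantile"} (deterministic,
#'   default) places centers at the (i + 0.5)/c quantiles of the distinct
#'   observed intensities (see \code{\link{init_centers}});
#'   \code{"random"} samples c distinct observed values.
#' @return An object of class \code{"fit_config"}.
#' @examples
#' fit_config(c = 3, fuzzifier = 2)
#' @export
fit_config <- function(c = 2L, fuzzifier = 2, max_iter = 300L, tol = 1e-5,
                       seed = NULL, init = c("quantile", "random")) {
  init <- match.arg(init)
  c <- as.integer(c)
  if (is.na(c) || c < 1L)
    stop("fit_config: 'c' must be a positive integer", call. = FALSE)
  if (!is.numeric(fuzzifier) || length(fuzzifier) != 1L || !is.finite(fuzzifier))
    stop("fit_config: 'fuzzifier' must be a finite scalar", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("fit_config: 'max_iter' must be a positive integer", call. = FALSE)
  if (!is.numeric(tol) || tol < 0)
    stop("fit_config: 'tol' must be non-negative", call. = FALSE)
  structure(list(c = c, fuzzifier = fuzzifier, max_iter = max_iter,
                 tol = tol, seed = seed, init = init),
            class = "fit_config")
}

# Warn once per fit when r leaves the characterised interval; error when the
# fuzzy update is undefined (r <= 1).
.check_fuzzifier <- function(r) {
  if (r <= 1)
    stop("fuzzifier r must be > 1 for fuzzy clustering (got ", r, ")",
         call. = FALSE)
  if (r <= 1.1 || r >= 5)
    warning("fuzzifier r = ", r,
            " lies outside the characterised interval (1.1, 5)",
            call. = FALSE)
  invisible(r)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
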