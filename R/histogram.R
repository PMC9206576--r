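#' Quantize an image to integer gray levels
#'
#' Images already integer-valued in 0..n_levels-1 pass through unchanged;
#' anything else is linearly min-max scaled to 0..n_levels-1 and rounded.
#' A constant image maps to level 0.
#'
#' @param image numeric matrix/array (or vector) of intensities.
#' @param n_levels number of gray levels N (>= 2).
#' @return The image with integer values in 0..n_levels-1, dimensions kept.
#' @export
quantize_image <- function(image, n_levels = 256L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L)
    stop("quantize_image: n_levels must be >= 2", call. = FALSE)
  v <- as.vector(image)
  if (!all(is.finite(v)))
    stop("quantize_image: image must be finite-valued", call. = FALSE)
  if (all(v == round(v)) && min(v) >= 0 && max(v) <= n_levels - 1L) {
    q <- round(v)
  } else {
    rng <- range(v)
    q <- if (rng[1L] == rng[2L]) rep(0, length(v))
         else round((v - rng[1L]) / (rng[2L] - rng[1L]) * (n_levels - 1L))
  }
  out <- as.integer(q)
  if (!is.null(dim(image))) dim(out) <- dim(image)
  out
}

#' Gray-level histogram of an image
#'
#' Quantizes the image to 0..n_levels-1 (\code{\link{quantize_image}}) and
#' returns the per-level probabilities h(g) = count(g) / (A x B), the basis
#' of the histogram-accelerated FCM: per-iteration work then scales with the
#' number of gray levels N instead of the pixel count.
#'
#' @inheritParams quantize_image
#' @return An object of class \code{"gray_histogram"}: list with
#'   \code{probs} (length N, sums to 1), \code{counts}, \code{levels}
#'   (0..N-1), \code{n_levels}, \code{total_pixels}, and \code{quantized}
#'   (the quantized image, kept so level memberships can be mapped back to
#'   pixels).
#' @examples
#' h <- compute_histogram(matrix(c(0, 0, 255, 255), 2), n_levels = 256)
#' h$probs[c(1, 256)]  # 0.5 at level 0 and level 255
#' @export
compute_histogram <- function(image, n_levels = 256L) {
  n_levels <- as.integer(n_levels)
  q <- quantize_image(image, n_levels)
  counts <- tabulate(as.vector(q) + 1L, nbins = n_levels)
  structure(list(probs = counts / sum(counts), counts = counts,
                 levels = seq_len(n_levels) - 1L, n_levels = n_levels,
                 total_pixels = length(q), quantized = q),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat("<gray_histogram> N =", x$n_levels, " pixels =", x$total_pixels,
      " nonempty levels =", sum(x$counts > 0L), "\n")
  invisible(x)
}

#' Histogram-domain FCM objective
#'
#' J_H(U, W) = sum_g sum_i mu_ig^r h(g) (g - w_i)^2 over gray levels g: the
#' pixel-domain FCM objective with each level's term weighted by its
#' probability of occurrence, so J_H equals the pixel-domain objective of the
#' expanded image divided by the pixel count.
#'
#' @param hist a \code{"gray_histogram"}.
#' @param u level membership matrix (c x N).
#' @param centers numeric vector of c centers (gray-level units), or a
#'   \code{"cluster_model"}.
#' @param r fuzzifier (> 1); defaults to the model's when a model is given.
#' @return The scalar objective value.
#' @export
histogram_objective <- function(hist, u, centers, r = NULL) {
  if (inherits(centers, "cluster_model")) {
    if (is.null(r)) r <- centers$fuzzifier
    centers <- centers$centers
  }
  if (is.null(r))
    stop("histogram_objective: supply r", call. = FALSE)
  u <- as.matrix(u)
  if (ncol(u) != hist$n_levels)
    stop("histogram_objective: u must have one column per gray level",
         call. = FALSE)
  .fcm_objective_w(as.numeric(hist$levels), u, as.numeric(centers), r,
                   w = hist$probs)
}

#' Fit FCM over the gray-level histogram
#'
#' The accelerated variant: alternates the fuzzy membership update over the N
#' gray levels with the frequency-weighted center update
#' w_i = sum_g h(g) mu_ig^r g / sum_g h(g) mu_ig^r.  Because a pixel's
#' membership depends only on its gray value, this reproduces the
#' pixel-domain \code{\link{fcm_fit}} on the quantized image exactly (same
#' initialization), at per-iteration cost O(N c) instead of O(x c).
#'
#' @param hist a \code{"gray_histogram"} (from \code{\link{compute_histogram}}).
#' @param config a \code{\link{fit_config}}.
#' @param centers optional initial centers (gray-level units).
#' @return A list with \code{u} (c x N level \code{\link{membership_matrix}})
#'   and \code{model} (a \code{"cluster_model"}; its objective trace is the
#'   histogram objective, i.e. pixel objective / pixel count).
#' @examples
#' h <- compute_histogram(c(0, 0, 0, 10, 10, 10), n_levels = 11)
#' histogram_fcm_fit(h, fit_config(c = 2))$model$centers
#' @export
histogram_fcm_fit <- function(hist, config, centers = NULL) {
  if (!inherits(hist, "gray_histogram"))
    stop("histogram_fcm_fit: 'hist' must come from compute_histogram()",
         call. = FALSE)
  .check_fuzzifier(config$fuzzifier)
  nonempty <- hist$counts > 0L
  if (sum(nonempty) < config$c)
    stop("histogram_fcm_fit: only ", sum(nonempty), " nonempty gray levels ",
         "but c = ", config$c, "; input is degenerate", call. = FALSE)
  if (is.null(centers))
    centers <- .init_centers_support(as.numeric(hist$levels[nonempty]),
                                     config)
  centers <- as.numeric(centers)
  if (length(centers) != config$c)
    stop("histogram_fcm_fit: length(centers) must equal config$c",
         call. = FALSE)
  res <- .fcm_engine(as.numeric(hist$levels), centers, config, w = hist$probs)
  model <- new_cluster_model(centers = res$centers,
                             fuzzifier = config$fuzzifier,
                             objective_trace = res$trace,
                             iterations = res$iterations,
                             converged = res$converged, method = "fcm-hist")
  list(u = membership_matrix(res$u), model = model)
}

#' Map gray-level memberships back to pixels
#'
#' Each pixel inherits the membership column of its gray level, turning a
#' c x N level matrix into the c x x pixel matrix the hardening and label
#' reconstruction steps expect.
#'
#' @param image integer-valued image already quantized to 0..N-1 (e.g.
#'   \code{hist$quantized}).
#' @param level_u level membership matrix (c x N).
#' @return A pixel \code{\link{membership_matrix}} (c x prod(dim(image))).
#' @export
pixel_memberships_from_levels <- function(image, level_u) {
  level_u <- as.matrix(level_u)
  g <- as.vector(image)
  if (any(g != round(g)) || min(g) < 0 || max(g) > ncol(level_u) - 1L)
    stop("pixel_memberships_from_levels: image must be integer-valued in ",
         "0..N-1 (N = ", ncol(level_u), "); quantize it first", call. = FALSE)
  membership_matrix(level_u[, g + 1L, drop = FALSE])
}
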