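#' Specification of a synthetic multi-tissue phantom
#'
#' Describes a piecewise-constant 2-D or 3-D image built from nested ellipses
#' (ellipsoids in 3-D): background, an organ, and a lesion strictly inside
#' the organ -- the minimal geometry echoing a cystic lesion on a pelvic MRI
#' slice.  On top of the clean image the generator applies optional additive
#' Gaussian noise and impulse ("salt-and-pepper") corruption of a configurable
#' pixel fraction, then rounds to integer gray levels on
#' \code{intensity_range}.
#'
#' @param shape image dimensions (length 2 or 3); default 256 x 256.
#' @param tissue_means per-class intensities (background, organ, lesion),
#'   pairwise distinct; default 30/120/200 on the 0-255 scale --
#'   well-separated but not trivially so.
#' @param organ_center,organ_axes center and semi-axes of the organ ellipse,
#'   in pixels; defaults: image center, 0.35 x shape.
#' @param lesion_center,lesion_axes center and semi-axes of the lesion
#'   ellipse; defaults: offset a quarter of the organ semi-axes from the
#'   organ center, 0.1 x shape.
#' @param gaussian_sigma standard deviation of the additive Gaussian noise
#'   (intensity units; 0 disables it).
#' @param impulse_fraction fraction of pixels replaced by impulse noise, in
#'   [0, 1]: exactly \code{round(impulse_fraction * x)} pixels are corrupted,
#'   half to the minimum and half to the maximum of \code{intensity_range}.
#' @param intensity_range the representable gray range, default c(0, 255);
#'   noisy images are clamped to it before rounding.
#' @param seed RNG seed making the noise draw reproducible.
#' @return An object of class \code{"phantom_spec"}.
#' @examples
#' spec <- phantom_spec(shape = c(64, 64), gaussian_sigma = 0, seed = 1)
#' @export
phantom_spec <- function(shape = c(256L, 256L),
                         tissue_means = c(30, 120, 200),
                         organ_center = NULL, organ_axes = NULL,
                         lesion_center = NULL, lesion_axes = NULL,
                         gaussian_sigma = 5, impulse_fraction = 0,
                         intensity_range = c(0, 255), seed = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L) || any(shape < 8L))
    stop("phantom_spec: shape must be 2-D or 3-D with each dimension >= 8",
         call. = FALSE)
  if (length(tissue_means) != 3L || anyDuplicated(tissue_means))
    stop("phantom_spec: tissue_means must be 3 pairwise-distinct values ",
         "(background, organ, lesion)", call. = FALSE)
  if (impulse_fraction < 0 || impulse_fraction > 1)
    stop("phantom_spec: impulse_fraction must lie in [0, 1]", call. = FALSE)
  if (gaussian_sigma < 0)
    stop("phantom_spec: gaussian_sigma must be non-negative", call. = FALSE)
  if (length(intensity_range) != 2L || diff(intensity_range) <= 0)
    stop("phantom_spec: intensity_range must be an increasing pair",
         call. = FALSE)
  if (is.null(organ_center)) organ_center <- (shape + 1) / 2
  if (is.null(organ_axes)) organ_axes <- 0.35 * shape
  if (is.null(lesion_center)) lesion_center <- organ_center + organ_axes / 4
  if (is.null(lesion_axes)) lesion_axes <- 0.1 * shape
  stopifnot(length(organ_center) == nd, length(organ_axes) == nd,
            length(lesion_center) == nd, length(lesion_axes) == nd)
  structure(list(shape = shape, tissue_means = as.numeric(tissue_means),
                 organ_center = organ_center, organ_axes = organ_axes,
                 lesion_center = lesion_center, lesion_axes = lesion_axes,
                 gaussian_sigma = gaussian_sigma,
                 impulse_fraction = impulse_fraction,
                 intensity_range = as.numeric(intensity_range), seed = seed),
            class = "phantom_spec")
}

# Logical mask of the (filled) ellipse/ellipsoid with given center/semi-axes.
.ellipse_mask <- function(shape, center, axes) {
  sq <- lapply(seq_along(shape), function(k)
    ((seq_len(shape[k]) - center[k]) / axes[k])^2)
  total <- if (length(shape) == 2L) outer(sq[[1L]], sq[[2L]], `+`)
           else outer(outer(sq[[1L]], sq[[2L]], `+`), sq[[3L]], `+`)
  total <= 1
}

#' Generate a synthetic phantom image with ground truth
#'
#' Renders the piecewise-constant tissue image of a \code{\link{phantom_spec}}
#' (labels 0 = background, 1 = organ, 2 = lesion), then adds Gaussian noise,
#' corrupts exactly \code{round(impulse_fraction * x)} distinct pixels
#' (\code{floor(n/2)} to the range minimum, the rest to the maximum), clamps
#' to \code{intensity_range}, and rounds to integer gray levels.  The truth
#' label map and lesion mask are untouched by noise, and the result is
#' deterministic for a given seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{"phantom"}: list with \code{image}
#'   (numeric array of integer gray values), \code{truth} (integer label
#'   array), \code{lesion} (logical lesion mask) and \code{spec}.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64), gaussian_sigma = 0,
#'                                     seed = 1))
#' table(ph$truth)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("generate_phantom: 'spec' must be a phantom_spec", call. = FALSE)
  organ <- .ellipse_mask(spec$shape, spec$organ_center, spec$organ_axes)
  lesion <- .ellipse_mask(spec$shape, spec$lesion_center, spec$lesion_axes)
  if (any(lesion & !organ))
    stop("generate_phantom: lesion ellipse is not strictly inside the organ",
         call. = FALSE)
  truth <- array(0L, dim = spec$shape)
  truth[organ] <- 1L
  truth[lesion] <- 2L
  if (any(tabulate(as.vector(truth) + 1L, nbins = 3L) == 0L))
    stop("generate_phantom: geometry leaves a tissue class empty",
         call. = FALSE)

  img <- spec$tissue_means[truth + 1L]
  x <- length(img)
  img <- .with_seed(spec$seed, {
    if (spec$gaussian_sigma > 0)
      img <- img + stats::rnorm(x, sd = spec$gaussian_sigma)
    n_imp <- round(spec$impulse_fraction * x)
    if (n_imp > 0) {
      idx <- sample.int(x, n_imp)
      n_pepper <- floor(n_imp / 2)
      if (n_pepper > 0) img[idx[seq_len(n_pepper)]] <- spec$intensity_range[1L]
      img[idx[seq.int(n_pepper + 1L, n_imp)]] <- spec$intensity_range[2L]
    }
    img
  })
  img <- round(pmin(pmax(img, spec$intensity_range[1L]),
                    spec$intensity_range[2L]))
  dim(img) <- spec$shape
  structure(list(image = img, truth = truth, lesion = lesion, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", paste(x$spec$shape, collapse = "x"),
      " classes: bg/organ/lesion =",
      paste(tabulate(as.vector(x$truth) + 1L, 3L), collapse = "/"),
      " impulse =", x$spec$impulse_fraction, "\n")
  invisible(x)
}

#' Generate a noise sweep of phantoms
#'
#' One phantom per impulse fraction, identical in every other respect
#' (geometry, means, Gaussian component, seed), sharing one truth map -- the
#' input grid for noise-robustness benchmarks (canonically fractions 0, 0.01,
#' ..., 0.05).
#'
#' @param base a \code{\link{phantom_spec}} providing everything but the
#'   impulse fraction.
#' @param fractions numeric vector of impulse fractions, each in [0, 1].
#' @return A list of \code{"phantom"} objects, one per fraction (possibly
#'   empty).
#' @export
noise_sweep <- function(base, fractions = seq(0, 0.05, by = 0.01)) {
  if (!inherits(base, "phantom_spec"))
    stop("noise_sweep: 'base' must be a phantom_spec", call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("noise_sweep: fractions must lie in [0, 1]", call. = FALSE)
  lapply(fractions, function(f) {
    s <- base
    s$impulse_fraction <- f
    generate_phantom(s)
  })
}
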