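#' Region masks for lesion-overlap evaluation
#'
#' Pairs the true lesion region A with the predicted lesion region C on a
#' common grid; their complements B and D (true and predicted background) are
#' derived, so A/B and C/D each tile the grid exactly.
#'
#' @param truth_lesion logical array: the true lesion mask A.
#' @param pred_lesion logical array of the same shape: the predicted mask C.
#' @return An object of class \code{"region_masks"}: list with logical arrays
#'   \code{A}, \code{B}, \code{C}, \code{D} and the grid \code{shape}.
#' @export
region_masks <- function(truth_lesion, pred_lesion) {
  A <- as.logical(truth_lesion)
  C <- as.logical(pred_lesion)
  if (anyNA(A) || anyNA(C))
    stop("region_masks: masks must not contain NA", call. = FALSE)
  dA <- if (is.null(dim(truth_lesion))) length(A) else dim(truth_lesion)
  dC <- if (is.null(dim(pred_lesion))) length(C) else dim(pred_lesion)
  if (!identical(as.integer(dA), as.integer(dC)))
    stop("region_masks: truth and prediction shapes differ (",
         paste(dA, collapse = "x"), " vs ", paste(dC, collapse = "x"), ")",
         call. = FALSE)
  structure(list(A = A, B = !A, C = C, D = !C, shape = as.integer(dA)),
            class = "region_masks")
}

.as_region_masks <- function(masks) {
  if (inherits(masks, "region_masks")) masks
  else stop("expected a 'region_masks' object (see region_masks())",
            call. = FALSE)
}

#' Dice overlap coefficient
#'
#' Dice = |A intersect C| / ((|A| + |C|) / 2): the symmetric overlap between
#' the true and predicted lesion regions, 1 for perfect agreement and 0 for
#' disjoint regions.
#'
#' @param masks a \code{\link{region_masks}} object.
#' @return Scalar in [0, 1].
#' @examples
#' m <- region_masks(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' dice(m)  # 2*1/(2+1)
#' @export
dice <- function(masks) {
  m <- .as_region_masks(masks)
  denom <- sum(m$A) + sum(m$C)
  if (denom == 0)
    stop("dice: undefined when both the true and predicted lesion regions ",
         "are empty", call. = FALSE)
  2 * sum(m$A & m$C) / denom
}

#' Segmentation sensitivity (lesion recall)
#'
#' Sensitivity = |A intersect C| / |A|: the fraction of the true lesion
#' covered by the prediction.
#'
#' @inheritParams dice
#' @return Scalar in [0, 1].
#' @export
sensitivity <- function(masks) {
  m <- .as_region_masks(masks)
  if (sum(m$A) == 0)
    stop("sensitivity: undefined for an empty true lesion region",
         call. = FALSE)
  sum(m$A & m$C) / sum(m$A)
}

#' Segmentation specificity (background recall)
#'
#' Specificity = |B intersect D| / |B|: the fraction of the true background
#' predicted as background.
#'
#' @inheritParams dice
#' @return Scalar in [0, 1].
#' @export
specificity <- function(masks) {
  m <- .as_region_masks(masks)
  if (sum(m$B) == 0)
    stop("specificity: undefined for an empty true background region",
         call. = FALSE)
  sum(m$B & m$D) / sum(m$B)
}
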