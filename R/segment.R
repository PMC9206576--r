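#' Segment an image by HCM, FCM, or histogram-accelerated FCM
#'
#' One-call pipeline: flatten the image, fit the requested clustering, harden
#' the memberships, and reshape to a label map.  With a ground-truth lesion
#' mask the overlap metrics (Dice, sensitivity, specificity) are computed for
#' the predicted lesion cluster -- chosen by maximal Dice against the truth
#' unless \code{lesion_cluster} pins it explicitly.  For HCM the validity
#' indices are reported from the \code{\link{soft_membership}} relaxation at
#' the fitted centers (a hard partition trivially scores PC = 1, PE = 0);
#' the hard values are available via \code{validity_report(fit$u)}.
#'
#' @param image numeric matrix/array of intensities.
#' @param algorithm one of \code{"hcm"}, \code{"fcm"}, \code{"fcm-hist"}.
#' @param config a \code{\link{fit_config}}.
#' @param n_levels gray levels for \code{"fcm-hist"} (default 256).
#' @param truth optional logical array: ground-truth lesion mask.
#' @param lesion_cluster optional 0-based cluster index to treat as lesion.
#' @return A list of class \code{"segmentation"}: \code{labels} (integer
#'   array, 0..c-1), \code{u} (pixel \code{\link{membership_matrix}}),
#'   \code{model} (\code{"cluster_model"}), \code{algorithm}, and
#'   \code{metrics} (flat named list: validity indices, iterations, final
#'   objective, and overlap metrics when truth is supplied).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64), seed = 1))
#' seg <- segment_image(ph$image, "fcm", fit_config(c = 3), truth = ph$lesion)
#' seg$metrics$dice
#' @export
segment_image <- function(image, algorithm = c("fcm", "hcm", "fcm-hist"),
                          config = fit_config(), n_levels = 256L,
                          truth = NULL, lesion_cluster = NULL) {
  algorithm <- match.arg(algorithm)
  attr(image, "nifti_reference") <- NULL
  fs <- as_feature_set(image)

  if (algorithm == "hcm") {
    fit <- hcm_fit(fs, config)
    u_pixel <- fit$u
    u_validity <- soft_membership(fs, fit$model, r = 2)
  } else if (algorithm == "fcm") {
    fit <- fcm_fit(fs, config)
    u_pixel <- fit$u
    u_validity <- fit$u
  } else {
    h <- compute_histogram(image, n_levels)
    fit <- histogram_fcm_fit(h, config)
    u_pixel <- pixel_memberships_from_levels(h$quantized, fit$u)
    u_validity <- u_pixel
  }

  labels <- labels_from(u_pixel, fs$shape)
  metrics <- list(
    algorithm = algorithm,
    c = config$c,
    fuzzifier = if (algorithm == "hcm") 1 else config$fuzzifier,
    iterations = fit$model$iterations,
    converged = fit$model$converged,
    objective = if (length(fit$model$objective_trace))
      fit$model$objective_trace[length(fit$model$objective_trace)] else NA_real_,
    partition_coefficient = partition_coefficient(u_validity),
    partition_entropy = partition_entropy(u_validity))

  if (!is.null(truth)) {
    truth <- as.logical(truth)
    if (length(truth) != fs$x)
      stop("segment_image: truth mask shape does not match the image",
           call. = FALSE)
    if (is.null(lesion_cluster)) {
      dices <- vapply(seq_len(config$c) - 1L, function(k) {
        pred <- as.vector(labels) == k
        if (!any(pred) && !any(truth)) return(0)
        dice(region_masks(truth, pred))
      }, numeric(1))
      lesion_cluster <- which.max(dices) - 1L
    }
    masks <- region_masks(truth, as.vector(labels) == lesion_cluster)
    metrics$lesion_cluster <- as.integer(lesion_cluster)
    metrics$dice <- dice(masks)
    metrics$sensitivity <- sensitivity(masks)
    metrics$specificity <- specificity(masks)
  }

  structure(list(labels = labels, u = u_pixel, model = fit$model,
                 algorithm = algorithm, metrics = metrics),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation:", x$algorithm, "> c =", length(x$model$centers),
      " iterations =", x$model$iterations, "\n")
  cat("  centers:", paste(format(x$model$centers, digits = 6),
                          collapse = ", "), "\n")
  m <- x$metrics
  cat("  PC =", format(m$partition_coefficient),
      " PE =", format(m$partition_entropy), "\n")
  if (!is.null(m$dice))
    cat("  Dice =", format(m$dice), " sensitivity =", format(m$sensitivity),
        " specificity =", format(m$specificity),
        " (lesion cluster ", m$lesion_cluster, ")\n", sep = "")
  invisible(x)
}

#' Segment an image file and write label map + metrics
#'
#' The file-level counterpart of \code{\link{segment_image}}: reads the
#' image (and optional truth mask) with \code{\link{read_image}}, segments
#' it, writes the hardened label map next to \code{output_dir} in the input's
#' format, and a flat JSON metrics record.
#'
#' @param input path to the image (NIfTI/PNG/TIFF).
#' @param output_dir output directory (created if missing).
#' @param algorithm,config,n_levels,lesion_cluster as in
#'   \code{\link{segment_image}}.
#' @param truth optional path to a ground-truth lesion mask (same format
#'   family; nonzero pixels = lesion).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with \code{labels_path}, \code{metrics_path} and
#'   the \code{"segmentation"} object.
#' @export
segment_command <- function(input, output_dir = ".",
                            algorithm = c("fcm", "hcm", "fcm-hist"),
                            config = fit_config(), n_levels = 256L,
                            truth = NULL, lesion_cluster = NULL,
                            quiet = FALSE) {
  algorithm <- match.arg(algorithm)
  img <- read_image(input)
  truth_mask <- NULL
  if (!is.null(truth)) {
    tm <- read_image(truth)
    if (!identical(dim(tm), dim(img)))
      stop("segment_command: truth mask shape (",
           paste(dim(tm), collapse = "x"), ") does not match the image (",
           paste(dim(img), collapse = "x"), ")", call. = FALSE)
    truth_mask <- tm > 0
  }

  seg <- segment_image(img, algorithm, config, n_levels = n_levels,
                       truth = truth_mask, lesion_cluster = lesion_cluster)

  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  stem <- sub("\\.nii\\.gz$", "", basename(input), ignore.case = TRUE)
  stem <- tools::file_path_sans_ext(stem)
  ext <- if (grepl("\\.nii\\.gz$", input, ignore.case = TRUE)) "nii.gz"
         else tolower(tools::file_ext(input))
  labels_path <- file.path(output_dir, paste0(stem, "_labels.", ext))
  lab <- seg$labels
  storage.mode(lab) <- "double"
  write_image(lab, labels_path,
              reference = attr(img, "nifti_reference", exact = TRUE))

  metrics_path <- file.path(output_dir, paste0(stem, "_metrics.json"))
  record <- c(list(input = basename(input), seed = config$seed,
                   n_levels = if (algorithm == "fcm-hist") n_levels else NULL,
                   centers = seg$model$centers),
              seg$metrics)
  jsonlite::write_json(record, metrics_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!quiet)
    message("segment: ", algorithm, " c=", config$c, " converged in ",
            seg$model$iterations, " iterations; final objective ",
            format(seg$metrics$objective), "; wrote ", labels_path,
            " and ", metrics_path)
  invisible(list(labels_path = labels_path, metrics_path = metrics_path,
                 segmentation = seg))
}
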