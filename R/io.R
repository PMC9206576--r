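#' Read a single-channel intensity image
#'
#' Supported formats: NIfTI-1 (\code{.nii}, \code{.nii.gz}) for 2-D/3-D
#' volumes, PNG and TIFF for 2-D slices.  PNG/TIFF pixels are returned as
#' integer gray values on the file's stored scale (0..255 for 8-bit, 0..65535
#' for 16-bit), so a \code{\link{write_image}} / \code{read_image} round trip
#' is exact for integer data.  Multichannel (e.g. RGB) inputs are rejected:
#' convert to grayscale first.
#'
#' @param path path to the image file.
#' @return A numeric matrix/array of intensities.  NIfTI reads carry the
#'   source \code{niftiImage} in attribute \code{"nifti_reference"} so
#'   spacing/affine survive write-back.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("read_image: file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    nim <- RNifti::readNifti(path)
    img <- as.array(nim)
    if (length(dim(img)) > 3L) {
      if (all(dim(img)[-(1:3)] == 1L)) {
        dim(img) <- dim(img)[1:3]
      } else {
        stop("read_image: ", path, " has ", length(dim(img)),
             " dimensions; only scalar 2-D/3-D images are supported",
             call. = FALSE)
      }
    }
    attr(img, "nifti_reference") <- nim
    return(img)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      p <- png::readPNG(path, info = TRUE)
      depth <- attr(p, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      round(p * (2^depth - 1))
    },
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop("read_image: unsupported extension '.", ext,
         "'; use .nii/.nii.gz, .png or .tif(f)", call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) {
      dim(img) <- dim(img)[1:2]
    } else {
      stop("read_image: ", path, " has ", dim(img)[3L], " channels; ",
           "convert it to single-channel grayscale first", call. = FALSE)
    }
  }
  storage.mode(img) <- "double"
  img
}

#' Write a single-channel intensity or label image
#'
#' Format follows the file extension: NIfTI-1 for 2-D/3-D arrays (spacing and
#' affine taken from \code{reference} or the array's
#' \code{"nifti_reference"} attribute when present), 8-bit PNG for integer
#' 2-D images in 0..255, 16-bit TIFF for integer 2-D images in 0..65535.
#' Writes are idempotent: the same array always produces the same bytes.
#'
#' @param image numeric matrix/array.
#' @param path destination path (\code{.nii}, \code{.nii.gz}, \code{.png},
#'   \code{.tif}, \code{.tiff}).
#' @param reference optional \code{niftiImage} template for NIfTI metadata.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path, reference = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (is.null(reference))
      reference <- attr(image, "nifti_reference", exact = TRUE)
    attr(image, "nifti_reference") <- NULL
    nim <- if (is.null(reference)) RNifti::asNifti(image)
           else RNifti::asNifti(unclass(image), reference = reference)
    RNifti::writeNifti(nim, path)
    return(invisible(path))
  }
  ext <- tolower(tools::file_ext(path))
  v <- as.vector(image)
  if (length(dim(image)) != 2L)
    stop("write_image: PNG/TIFF output requires a 2-D image; ",
         "use NIfTI for volumes", call. = FALSE)
  if (any(v != round(v)))
    stop("write_image: PNG/TIFF output requires integer gray values",
         call. = FALSE)
  if (ext == "png") {
    if (min(v) < 0 || max(v) > 255)
      stop("write_image: PNG output covers integers 0..255; ",
           "use TIFF (0..65535) or NIfTI for deeper data", call. = FALSE)
    png::writePNG(image / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (min(v) < 0 || max(v) > 65535)
      stop("write_image: 16-bit TIFF output covers integers 0..65535; ",
           "use NIfTI for deeper data", call. = FALSE)
    tiff::writeTIFF(image / 65535, where = path, bits.per.sample = 16L)
  } else {
    stop("write_image: unsupported extension '.", ext,
         "'; use .nii/.nii.gz, .png or .tif(f)", call. = FALSE)
  }
  invisible(path)
}
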