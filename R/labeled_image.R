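#' Intensity image with a per-cell label mask
#'
#' The basic container consumed by the puncta and translocation modules: a
#' single-channel fluorescence intensity grid together with an integer label
#' grid of identical dimensions, where 0 marks background and `k > 0` marks
#' the pixels of cell `k`. Segmentation itself is out of scope: label masks
#' come from an external segmentation step or from the synthetic generators.
#'
#' @param intensity Numeric matrix of nonnegative fluorescence intensities
#'   (arbitrary units).
#' @param labels Integer matrix of the same dimensions; 0 = background.
#' @param pixel_size_um Optional pixel size in micrometers per pixel.
#' @return An object of class `labeled_image`: a list with elements
#'   `intensity`, `labels` and `pixel_size_um`.
#' @examples
#' lab <- matrix(0L, 8, 8); lab[3:6, 3:6] <- 1L
#' img <- labeled_image(matrix(100, 8, 8), lab)
#' cell_ids(img)
#' @export
labeled_image <- function(intensity, labels, pixel_size_um = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  }
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop("`labels` must be an integer matrix", call. = FALSE)
  }
  if (!identical(dim(intensity), dim(labels))) {
    stop("`intensity` and `labels` must have identical dimensions",
         call. = FALSE)
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  if (!is.null(pixel_size_um)) {
    check_scalar(pixel_size_um, "pixel_size_um", lower = 0,
                 strict_lower = TRUE)
  }
  structure(
    list(intensity = intensity,
         labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
         pixel_size_um = pixel_size_um),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %d x %d px, %d cells",
              nrow(x$intensity), ncol(x$intensity), length(cell_ids(x))))
  if (!is.null(x$pixel_size_um)) {
    cat(sprintf(", %.3g um/px", x$pixel_size_um))
  }
  cat("\n")
  invisible(x)
}

#' Cell labels present in a labeled image
#'
#' @param img A [labeled_image].
#' @return Sorted integer vector of nonzero labels.
#' @export
cell_ids <- function(img) {
  stopifnot(inherits(img, "labeled_image"))
  sort(unique(img$labels[img$labels > 0L]))
}

# logical mask for one cell
cell_mask <- function(img, cell_id) {
  m <- img$labels == cell_id
  if (!any(m)) {
    stop(sprintf("cell %s has no pixels in the label mask", cell_id),
         call. = FALSE)
  }
  m
}

#' Read an intensity TIFF plus a label-mask TIFF
#'
#' Images are stored as 16-bit single-channel TIFFs; intensities are
#' recovered on the original 0..65535 scale, label values are rounded back
#' to integers.
#'
#' @param image_path Path to the intensity TIFF.
#' @param labels_path Path to the label-mask TIFF.
#' @param pixel_size_um Optional pixel size in micrometers per pixel.
#' @return A [labeled_image].
#' @export
read_labeled_image <- function(image_path, labels_path,
                               pixel_size_um = NULL) {
  intensity <- tiff::readTIFF(image_path) * 65535
  labels <- round(tiff::readTIFF(labels_path) * 65535)
  labeled_image(intensity, labels, pixel_size_um = pixel_size_um)
}

#' Write a labeled image as a pair of 16-bit TIFFs
#'
#' @param img A [labeled_image]. Intensities must fit in 0..65535.
#' @param image_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeled_image <- function(img, image_path, labels_path) {
  stopifnot(inherits(img, "labeled_image"))
  if (max(img$intensity) > 65535) {
    stop("intensities exceed the 16-bit range", call. = FALSE)
  }
  tiff::writeTIFF(img$intensity / 65535, image_path, bits.per.sample = 16L)
  tiff::writeTIFF(img$labels / 65535, labels_path, bits.per.sample = 16L)
  invisible(c(image_path, labels_path))
}
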