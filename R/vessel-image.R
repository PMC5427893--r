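#' Grayscale vessel image with physical pixel size
#'
#' A thin wrapper around a numeric matrix: intensities in `[0, 1]`, rows =
#' image rows (origin top-left), with the physical pixel size attached.
#'
#' @param data numeric matrix of intensities in `[0, 1]`.
#' @param pixel_size_um physical edge length of one pixel, in micrometers.
#' @return A `vessel_image` object.
#' @export
vessel_image <- function(data, pixel_size_um) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_config("data must be a numeric matrix")
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  structure(data, pixel_size_um = pixel_size_um,
            class = c("vessel_image", "matrix", "array"))
}

#' @export
print.vessel_image <- function(x, ...) {
  cat(sprintf("<vessel_image> %d x %d px, %.3g um/px, intensity [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

#' Pixel size accessor
#' @param x an object carrying a `pixel_size_um` attribute.
#' @return Pixel edge length in micrometers.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel_size_um attribute")
  ps
}

#' Write a vessel image as 16-bit grayscale TIFF
#'
#' The pixel size is stored in the TIFF X/Y resolution fields
#' (pixels per centimeter).
#'
#' @param image a [vessel_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vessel_tiff <- function(image, path) {
  ps <- pixel_size(image)
  m <- pmin(pmax(unclass(image), 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L,
                  reduce = TRUE)
  invisible(path)
}

#' Read a grayscale TIFF as a vessel image
#'
#' @param path TIFF file path.
#' @param pixel_size_um physical pixel size to attach (TIFF resolution tags
#'   are not assumed trustworthy for microscopy exports).
#' @return A [vessel_image()].
#' @export
read_vessel_tiff <- function(path, pixel_size_um) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # drop extra channels
  vessel_image(m, pixel_size_um)
}
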