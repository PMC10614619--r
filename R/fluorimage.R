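#' Fluorescence image with physical pixel size
#'
#' The unit every stage of the pipeline consumes: a single 2D fluorescence
#' channel stored as a numeric matrix (rows = y, columns = x; coordinates are
#' 0-based and pixel-centred) together with the physical pixel edge length in
#' nanometres.  Pixel values are fluorescence units integrated over the pixel
#' footprint and are never rescaled on load, because the calibration algebra
#' (see [estimate_rho0()], [estimate_radius()]) depends on raw units.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size_nm physical pixel edge length in nm (> 0).
#' @param channel channel label, e.g. `"lipid"` or `"protein"`.
#' @return A `fluor_image` object (matrix with `pixel_size_nm` and `channel`
#'   attributes).
#' @export
fluor_image <- function(pixels, pixel_size_nm, channel = "lipid") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  if (any(!is.finite(pixels)))
    stop("pixels must be finite")
  if (any(pixels < 0))
    stop("pixels must be non-negative")
  structure(pixels,
            pixel_size_nm = as.numeric(pixel_size_nm),
            channel = as.character(channel)[1L],
            class = c("fluor_image", "matrix", "array"))
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %d x %d px, %.3g nm/px, channel '%s'\n",
              nrow(x), ncol(x), pixel_size(x), attr(x, "channel")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Pixel size accessor
#' @param image a [fluor_image()] or label map.
#' @return pixel edge length in nm.
#' @export
pixel_size <- function(image) {
  ps <- attr(image, "pixel_size_nm")
  if (is.null(ps)) stop("object carries no pixel_size_nm attribute")
  ps
}

as_matrix <- function(image) {
  x <- unclass(image)
  attr(x, "pixel_size_nm") <- NULL
  attr(x, "channel") <- NULL
  x
}

stopifnot_image <- function(image) {
  if (!inherits(image, "fluor_image"))
    stop("expected a fluor_image (see fluor_image())")
  invisible(image)
}
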