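#' Read an image file as intensities in [0,1]
#'
#' Supports 8- and 16-bit PNG (and TIFF when the `tiff` package is
#' available). Grayscale files — and RGB files whose channels are all
#' equal — are returned as a matrix; color files as an `h x w x 3` array.
#' An alpha channel, if present, is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Matrix or `h x w x 3` array in `[0,1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_io("TIFF support requires the 'tiff' package: ", path)
    tiff::readTIFF(path)
  } else {
    stop_io("unsupported image format '", ext, "': ", path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 4L) img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[3L] == 1L) return(img[, , 1L])
    if (all(img[, , 1L] == img[, , 2L]) && all(img[, , 2L] == img[, , 3L]))
      return(img[, , 1L])
    img
  } else {
    img
  }
}

#' Write an image to an 8-bit PNG file
#'
#' Intensities are clipped to `[0,1]` and quantized to 8 bits
#' (`round(255 * x)`); reading the file back reproduces the quantized
#' values exactly.
#'
#' @param img Matrix or `h x w x 3` array in `[0,1]`.
#' @param path Output path (`.png`).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  v <- round(255 * pmin(pmax(img, 0), 1)) / 255
  ok <- tryCatch({ png::writePNG(v, target = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io("could not write image: ", path)
  invisible(path)
}
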