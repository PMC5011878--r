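#' RGB raster images
#'
#' Images are stored as integer arrays of dimension `height x width x 3`
#' (channels R, G, B) with 8-bit values in `[0, 255]`, plus a `scale` attribute
#' giving the imaging resolution in mm per pixel (0.13 mm px^-1 for the
#' platform's root camera by default).
#'
#' @param x numeric or integer array, `h x w x 3`, values in `[0, 255]`.
#' @param scale imaging resolution, mm per pixel.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(x, scale = 0.13) {
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("rgb_image requires an h x w x 3 array", call. = FALSE)
  if (any(x < 0) || any(x > 255))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  if (any(dim(x)[1:2] < 1L)) stop("image dimensions must be positive", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, scale = scale, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("rgb_image: %d x %d px, scale %.4g mm/px\n", d[1], d[2], attr(x, "scale")))
  invisible(x)
}

#' @rdname rgb_image
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

#' Read an RGB image from PNG or TIFF
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`, `.tiff`).
#' @param scale mm per pixel to attach to the image.
#' @return An [rgb_image].
#' @export
read_image <- function(path, scale = 0.13) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))  # greyscale
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]         # drop alpha
  rgb_image(round(raw * 255), scale = scale)
}

#' Write an RGB image to PNG or TIFF
#'
#' @param img an [rgb_image].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is_rgb_image(img))
  arr <- unclass(img) / 255
  attributes(arr) <- list(dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to write TIFF files", call. = FALSE)
      tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Binary masks
#'
#' A `binary_mask` is an integer matrix with values in `{0, 1}`, the output of
#' the segmentation operations.
#'
#' @param m matrix of 0/1 (or logical) values.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(m) {
  if (is.logical(m)) m <- m * 1L
  if (!is.matrix(m) || !all(m %in% c(0L, 1L)))
    stop("binary_mask requires a matrix of 0/1 values", call. = FALSE)
  storage.mode(m) <- "integer"
  structure(m, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %d foreground\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
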