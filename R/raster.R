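#' Create an in-memory 24-bit raster
#'
#' A raster is a `height x width x 3` integer array of 8-bit RGB values plus
#' optional physical resolution metadata in dots per inch (DPI). DPI is what
#' converts foreground pixel counts to physical areas; rasters from cameras
#' (rather than scanners) usually have none, and then only percentage
#' coverage is meaningful.
#'
#' @param pixels Either a `height x width x 3` numeric array, or a single
#'   color (to make a uniform raster, together with `width`/`height`).
#' @param dpi Optional positive resolution in dots per inch.
#' @param width,height Dimensions, only used when `pixels` is a single color.
#' @return A `coverage_raster` object.
#' @examples
#' img <- raster_rgb("#FFFFFF", width = 4, height = 3)
#' dim(img$pixels)
#' @export
raster_rgb <- function(pixels, dpi = NULL, width = NULL, height = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    col <- as_color(pixels)
    if (is.null(width) || is.null(height))
      stop("width and height are required for a uniform raster", call. = FALSE)
    pixels <- array(rep(as.integer(col), each = height * width),
                    dim = c(height, width, 3L))
  }
  d <- dim(pixels)
  if (d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop("pixels must be a height x width x 3 array", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L))
    stop("pixel channel values must lie in [0, 255]", call. = FALSE)
  if (!is.null(dpi)) {
    if (!is.numeric(dpi) || length(dpi) != 1L || is.na(dpi) || dpi <= 0)
      stop("dpi must be a single positive number", call. = FALSE)
    dpi <- as.numeric(dpi)
  }
  structure(list(pixels = pixels, dpi = dpi), class = "coverage_raster")
}

#' @export
print.coverage_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<coverage_raster> %d x %d px, dpi = %s\n", d[2], d[1],
              if (is.null(x$dpi)) "unset" else format(x$dpi)))
  invisible(x)
}

#' @export
dim.coverage_raster <- function(x) dim(x$pixels)[c(1L, 2L)]

.check_raster <- function(img) {
  if (!inherits(img, "coverage_raster"))
    stop("expected a coverage_raster (see raster_rgb(), read_raster())",
         call. = FALSE)
  img
}

#' Define a rectangular pixel region
#'
#' Coordinates are 0-based and half-open: the region covers columns
#' `[x0, x1)` and rows `[y0, y1)` with the origin at the top-left corner,
#' x growing rightward and y downward. This mirrors the CLI string format
#' `"x0,y0,x1,y1"`.
#'
#' @param x0,y0 Top-left corner (inclusive).
#' @param x1,y1 Bottom-right corner (exclusive).
#' @return A `region_spec` object.
#' @export
region_spec <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (anyNA(v) || any(v != round(v)) || any(v < 0))
    stop("region coordinates must be non-negative integers", call. = FALSE)
  v <- stats::setNames(as.integer(v), names(v))
  if (v[["x0"]] >= v[["x1"]] || v[["y0"]] >= v[["y1"]])
    stop("empty region: need x0 < x1 and y0 < y1", call. = FALSE)
  structure(as.list(v), class = "region_spec")
}

.check_region <- function(region, img) {
  if (!inherits(region, "region_spec")) {
    if (is.numeric(region) && length(region) == 4L)
      region <- region_spec(region[1], region[2], region[3], region[4])
    else stop("expected a region_spec or numeric c(x0, y0, x1, y1)",
              call. = FALSE)
  }
  d <- dim(img$pixels)
  if (region$x1 > d[2] || region$y1 > d[1])
    stop(sprintf("region [%d,%d)x[%d,%d) exceeds image extent %d x %d",
                 region$x0, region$x1, region$y0, region$y1, d[2], d[1]),
         call. = FALSE)
  region
}

#' Read the color of one pixel
#'
#' The scripted analogue of mouse-clicking a shade in the image to sample it
#' into a selection channel. Coordinates are 0-based from the top-left.
#'
#' @param img A `coverage_raster`.
#' @param x Column, `0 <= x < width`.
#' @param y Row, `0 <= y < height`.
#' @return The stored color as a named integer `c(r, g, b)`.
#' @export
sample_pixel <- function(img, x, y) {
  .check_raster(img)
  d <- dim(img$pixels)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      is.na(x) || is.na(y) || x != round(x) || y != round(y))
    stop("x and y must be single integer coordinates", call. = FALSE)
  if (x < 0 || x >= d[2] || y < 0 || y >= d[1])
    stop(sprintf("pixel (%d, %d) outside image extent %d x %d (0-based)",
                 as.integer(x), as.integer(y), d[2], d[1]), call. = FALSE)
  v <- img$pixels[y + 1L, x + 1L, ]
  names(v) <- c("r", "g", "b")
  v
}

#' Overwrite a region with a solid color ("blanking")
#'
#' Blanking is the batch analogue of the interactive eraser brush: artifacts
#' whose colors resemble the measured object (rulers, margin lines, stray
#' background) are overwritten with a color that is either sampled as an
#' ignore channel (pink is traditional) or left as background, before
#' classification.
#'
#' @param img A `coverage_raster`.
#' @param region A [region_spec()] (or `c(x0, y0, x1, y1)`).
#' @param fill The fill color.
#' @return A new raster with the region overwritten; dimensions and dpi
#'   unchanged.
#' @export
blank_region <- function(img, region, fill) {
  .check_raster(img)
  region <- .check_region(region, img)
  fill <- as_color(fill)
  px <- img$pixels
  rows <- (region$y0 + 1L):region$y1
  cols <- (region$x0 + 1L):region$x1
  for (k in 1:3) px[rows, cols, k] <- fill[[k]]
  raster_rgb(px, dpi = img$dpi)
}

#' Blank every pixel flagged by a mask image
#'
#' Any pixel of `mask` that is not pure black (all channels zero) is
#' overwritten with `fill` in `img`. This supports irregular blanking shapes
#' the rectangle spec cannot express.
#'
#' @param img,mask `coverage_raster`s with identical dimensions.
#' @param fill The fill color.
#' @return A new raster.
#' @export
blank_by_mask <- function(img, mask, fill) {
  .check_raster(img); .check_raster(mask)
  if (!identical(dim(img$pixels)[1:2], dim(mask$pixels)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  fill <- as_color(fill)
  hit <- (mask$pixels[, , 1] | mask$pixels[, , 2] | mask$pixels[, , 3])
  px <- img$pixels
  for (k in 1:3) {
    plane <- px[, , k]
    plane[hit] <- fill[[k]]
    px[, , k] <- plane
  }
  raster_rgb(px, dpi = img$dpi)
}

#' Crop a raster to a rectangular region
#'
#' Used to standardize a photographed set to a common scale (e.g. cropping
#' every image to the petri-dish borderline) before classification. The dpi
#' metadata is carried over unchanged.
#'
#' @param img A `coverage_raster`.
#' @param region A [region_spec()] (or `c(x0, y0, x1, y1)`).
#' @return The cropped raster, `(x1 - x0) x (y1 - y0)` pixels.
#' @export
crop_raster <- function(img, region) {
  .check_raster(img)
  region <- .check_region(region, img)
  px <- img$pixels[(region$y0 + 1L):region$y1,
                   (region$x0 + 1L):region$x1, , drop = FALSE]
  raster_rgb(px, dpi = img$dpi)
}
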