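#' Construct or coerce an 8-bit RGB color
#'
#' Colors are plain named integer vectors `c(r =, g =, b =)` with each channel
#' in `[0, 255]`. Accepted inputs are a length-3 numeric vector, a hex string
#' `"#RRGGBB"`, or an already-valid color.
#'
#' @param x A length-3 numeric vector, or a single `"#RRGGBB"` string.
#' @return A named integer vector of length 3 with names `r`, `g`, `b`.
#' @examples
#' as_color("#FF8000")
#' as_color(c(10, 20, 30))
#' @export
as_color <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^#?[0-9a-fA-F]{6}$", x))
      stop("hex color must be a single \"#RRGGBB\" string, got: ",
           paste(x, collapse = ", "), call. = FALSE)
    h <- sub("^#", "", x)
    x <- strtoi(substring(h, c(1L, 3L, 5L), c(2L, 4L, 6L)), base = 16L)
  }
  if (!is.numeric(x) || length(x) != 3L || anyNA(x))
    stop("a color is 3 numeric channel values (r, g, b)", call. = FALSE)
  v <- as.integer(round(x))
  if (any(v < 0L) || any(v > 255L))
    stop("color channels must lie in [0, 255], got (",
         paste(v, collapse = ", "), ")", call. = FALSE)
  names(v) <- c("r", "g", "b")
  v
}

#' Squared Euclidean RGB distance between two colors
#'
#' The RGB similarity measure: `(r1-r2)^2 + (g1-g2)^2 + (b1-b2)^2`.
#' A pixel is "near" a reference color when this measure is strictly below
#' the squared tolerance (see [is_near()]).
#'
#' @param a,b Colors (anything [as_color()] accepts).
#' @return A non-negative number; `0` iff `a == b`.
#' @examples
#' rgb_distance_sq(c(10, 20, 30), c(13, 24, 18)) # 9 + 16 + 144 = 169
#' @export
rgb_distance_sq <- function(a, b) {
  a <- as_color(a); b <- as_color(b)
  sum((as.numeric(a) - as.numeric(b))^2)
}

# Full-range ITU-R BT.601 (JPEG convention) RGB -> YCbCr. Components stay
# real (no rounding) and are clamped to [0, 255] only at the end.
# Vectorised conversion: m is an n x 3 numeric matrix of RGB rows. Written
# as explicit elementwise expressions (not a BLAS matrix product) so scalar
# and vectorized paths agree bit-for-bit.
.rgb_to_ycbcr_mat <- function(m) {
  y  <- 0.299 * m[, 1] + 0.587 * m[, 2] + 0.114 * m[, 3]
  cb <- 128 - 0.168736 * m[, 1] - 0.331264 * m[, 2] + 0.5 * m[, 3]
  cr <- 128 + 0.5 * m[, 1] - 0.418688 * m[, 2] - 0.081312 * m[, 3]
  out <- cbind(y = y, cb = cb, cr = cr)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Convert an RGB color to YCbCr
#'
#' Uses the full-range ITU-R BT.601 transform (the JPEG convention), keeping
#' components as reals and clamping to `[0, 255]`. Gray inputs (`r == g == b`)
#' map to `cb == cr == 128`. `y` is luminance; `cb`/`cr` carry the hue.
#'
#' @param a A color (anything [as_color()] accepts).
#' @return A named numeric vector with components `y`, `cb`, `cr`.
#' @examples
#' rgb_to_ycbcr(c(0, 0, 0))       # y = 0, cb = cr = 128
#' rgb_to_ycbcr(c(255, 0, 0))     # cr clamps at 255
#' @export
rgb_to_ycbcr <- function(a) {
  a <- as_color(a)
  drop(.rgb_to_ycbcr_mat(matrix(as.numeric(a), nrow = 1L)))[c("y", "cb", "cr")]
}

#' YCbCr similarity measure between two colors
#'
#' `(cb1-cb2)^2 + (cr1-cr2)^2 + (y1-y2)^2 / 9`: the luminance difference is
#' down-weighted by a factor of 9, so the measure concentrates on hue and
#' deemphasizes brightness. Inputs may be RGB colors (converted first via
#' [rgb_to_ycbcr()]) or already-converted named `y`/`cb`/`cr` vectors.
#'
#' @param a,b Colors, or named numeric vectors with components `y`, `cb`, `cr`.
#' @return A non-negative number.
#' @examples
#' # same hue, brightness differs by 30: 30^2 / 9 = 100
#' ycbcr_distance_measure(c(100, 100, 100), c(130, 130, 130))
#' @export
ycbcr_distance_measure <- function(a, b) {
  a <- .as_ycbcr(a); b <- .as_ycbcr(b)
  (a[["cb"]] - b[["cb"]])^2 + (a[["cr"]] - b[["cr"]])^2 +
    (a[["y"]] - b[["y"]])^2 / 9
}

.as_ycbcr <- function(x) {
  if (is.numeric(x) && !is.null(names(x)) && all(c("y", "cb", "cr") %in% names(x))) {
    if (any(x < 0) || any(x > 255))
      stop("YCbCr components must lie in [0, 255]", call. = FALSE)
    return(x)
  }
  rgb_to_ycbcr(x)
}

#' Is one color within tolerance of another?
#'
#' True iff the chosen metric's squared measure is *strictly* less than
#' `tolerance^2`. The boundary case (measure exactly equal to the squared
#' tolerance) is excluded. Note that the RGB metric typically requires higher
#' tolerances than YCbCr for the same visual "closeness".
#'
#' @param a,b Colors (anything [as_color()] accepts).
#' @param tolerance Non-negative number, shared by every channel of a
#'   selection.
#' @param metric `"rgb"` or `"ycbcr"`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_near(c(10, 10, 10), c(10, 10, 45), tolerance = 35, metric = "rgb")
#' # FALSE: distance^2 == 35^2 exactly, and the inequality is strict
#' @export
is_near <- function(a, b, tolerance, metric = c("rgb", "ycbcr")) {
  metric <- match.arg(metric)
  tolerance <- .check_tolerance(tolerance)
  m <- switch(metric,
    rgb = rgb_distance_sq(a, b),
    ycbcr = ycbcr_distance_measure(a, b)
  )
  m < tolerance^2
}

.check_tolerance <- function(tolerance) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || is.na(tolerance) ||
      tolerance < 0)
    stop("tolerance must be a single non-negative number", call. = FALSE)
  as.numeric(tolerance)
}
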