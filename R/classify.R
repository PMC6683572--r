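## Per-pixel three-way labeling. Label codes are fixed:
## 1 = foreground (C), 2 = ignored (I), 3 = background (B).

.LABELS <- c(foreground = 1L, ignored = 2L, background = 3L)

# Minimum squared measure from every pixel row of `px` (n x 3 RGB, numeric)
# to the nearest channel in `chans` (k x 3). Inf when there are no channels.
# For the ycbcr metric both sides are converted first and the luma term is
# divided by 9.
.min_measure <- function(px, chans, metric) {
  n <- nrow(px)
  if (is.null(chans) || nrow(chans) == 0L) return(rep(Inf, n))
  best <- rep(Inf, n)
  if (metric == "ycbcr") {
    px <- .rgb_to_ycbcr_mat(px)       # columns: y, cb, cr
    chans <- .rgb_to_ycbcr_mat(matrix(as.numeric(chans), ncol = 3L))
    for (j in seq_len(nrow(chans))) {
      d <- (px[, 2] - chans[j, 2])^2 + (px[, 3] - chans[j, 3])^2 +
           (px[, 1] - chans[j, 1])^2 / 9
      best <- pmin(best, d)
    }
  } else {
    for (j in seq_len(nrow(chans))) {
      d <- (px[, 1] - chans[j, 1])^2 + (px[, 2] - chans[j, 2])^2 +
           (px[, 3] - chans[j, 3])^2
      best <- pmin(best, d)
    }
  }
  best
}

.label_from_measures <- function(d_inc, d_ign, tol, conflict) {
  t2 <- tol^2
  near_inc <- d_inc < t2
  near_ign <- d_ign < t2
  fg <- switch(conflict,
    nearest = near_inc & (!near_ign | d_inc < d_ign),  # ties -> ignored
    "ignore-wins" = near_inc & !near_ign,
    "include-wins" = near_inc,
    stop("unknown conflict policy: ", conflict, call. = FALSE))
  ig <- near_ign & !fg
  lab <- rep(.LABELS[["background"]], length(d_inc))
  lab[ig] <- .LABELS[["ignored"]]
  lab[fg] <- .LABELS[["foreground"]]
  lab
}

#' Classify a single pixel color
#'
#' A pixel is *foreground* when it lies strictly within tolerance of at least
#' one include channel (and, if it is also within tolerance of an ignore
#' channel, closer to the nearest include channel than to the nearest ignore
#' channel under the selection's metric); *ignored* when within tolerance of
#' an ignore channel and not foreground; *background* otherwise. A pixel
#' equidistant from both roles resolves to ignored under the default
#' `"nearest"` policy — the conservative choice, since it never inflates
#' coverage. The published description never defines the both-roles case, so
#' the policy is switchable: `"ignore-wins"` (any ignore match wins) or
#' `"include-wins"` (any include match wins).
#'
#' @param px The pixel color.
#' @param sel A [selection()].
#' @param conflict `"nearest"`, `"ignore-wins"` or `"include-wins"`.
#' @return One of `"foreground"`, `"ignored"`, `"background"`.
#' @export
classify_pixel <- function(px, sel,
                           conflict = c("nearest", "ignore-wins",
                                        "include-wins")) {
  conflict <- match.arg(conflict)
  .check_selection(sel)
  m <- matrix(as.numeric(as_color(px)), nrow = 1L)
  lab <- .label_from_measures(.min_measure(m, sel$include, sel$metric),
                              .min_measure(m, sel$ignore, sel$metric),
                              sel$tolerance, conflict)
  names(.LABELS)[lab]
}

#' Classify every pixel of a raster
#'
#' Applies [classify_pixel()] semantics to the whole image in one vectorized
#' pass and tallies the label counts: `n` total pixels, `c` foreground, `i`
#' ignored, `b` background, with `c + i + b == n` always.
#'
#' @param img A `coverage_raster`.
#' @param sel A [selection()].
#' @param conflict Conflict policy, see [classify_pixel()].
#' @return A list of class `coverage_classification` with elements `mask`
#'   (a `label_mask`: integer matrix, 1 = foreground, 2 = ignored,
#'   3 = background) and `counts` (a `label_counts` list).
#' @export
classify_image <- function(img, sel,
                           conflict = c("nearest", "ignore-wins",
                                        "include-wins")) {
  conflict <- match.arg(conflict)
  .check_raster(img)
  .check_selection(sel)
  d <- dim(img$pixels)
  px <- matrix(as.numeric(img$pixels), ncol = 3L)  # column-major: r, g, b
  lab <- .label_from_measures(.min_measure(px, sel$include, sel$metric),
                              .min_measure(px, sel$ignore, sel$metric),
                              sel$tolerance, conflict)
  mask <- matrix(lab, nrow = d[1], ncol = d[2])
  class(mask) <- c("label_mask", class(mask))
  counts <- label_counts(n = length(lab),
                         c = sum(lab == .LABELS[["foreground"]]),
                         i = sum(lab == .LABELS[["ignored"]]))
  structure(list(mask = mask, counts = counts),
            class = "coverage_classification")
}

#' Label counts for one classified image
#'
#' The substrate of every coverage formula: `n` pixels split into foreground
#' `c`, ignored `i` and background `b = n - c - i`.
#'
#' @param n Total pixel count.
#' @param c Foreground count.
#' @param i Ignored count.
#' @param b Background count; derived as `n - c - i` when omitted.
#' @return A `label_counts` list.
#' @export
label_counts <- function(n, c, i, b = NULL) {
  n <- as.numeric(n); c <- as.numeric(c); i <- as.numeric(i)
  if (is.null(b)) b <- n - c - i else b <- as.numeric(b)
  vals <- c(n = n, c = c, i = i, b = b)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("label counts must be non-negative integers", call. = FALSE)
  if (c + i + b != n)
    stop(sprintf("inconsistent label counts: c + i + b = %g but n = %g",
                 c + i + b, n), call. = FALSE)
  structure(list(n = n, c = c, i = i, b = b), class = "label_counts")
}

#' @export
print.label_counts <- function(x, ...) {
  cat(sprintf("<label_counts> n = %g: foreground %g, ignored %g, background %g\n",
              x$n, x$c, x$i, x$b))
  invisible(x)
}

#' Render a QC overlay of a classification
#'
#' Foreground pixels keep their original color; ignored and background pixels
#' are replaced by flat palette colors. Inspecting this overlay at a few
#' candidate tolerances is how a tolerance is chosen: too low leaves object
#' pixels unpainted (under-segmentation), too high bleeds into the
#' background.
#'
#' @param img The classified `coverage_raster`.
#' @param mask The `label_mask` from [classify_image()].
#' @param palette Named list with replacement colors for `ignored` and
#'   `background`.
#' @return A `coverage_raster` overlay.
#' @export
render_mask_overlay <- function(img, mask,
                                palette = list(ignored = "#FF69B4",
                                               background = "#000000")) {
  .check_raster(img)
  d <- dim(img$pixels)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  ign_col <- as_color(palette$ignored)
  bg_col <- as_color(palette$background)
  px <- img$pixels
  is_ign <- unclass(mask) == .LABELS[["ignored"]]
  is_bg <- unclass(mask) == .LABELS[["background"]]
  for (k in 1:3) {
    plane <- px[, , k]
    plane[is_ign] <- ign_col[[k]]
    plane[is_bg] <- bg_col[[k]]
    px[, , k] <- plane
  }
  raster_rgb(px, dpi = img$dpi)
}
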