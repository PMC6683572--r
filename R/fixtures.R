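## Synthetic fixtures with exact ground truth.
##
## Every generator returns a coverage_fixture: a raster plus a truth record
## whose per-class pixel counts are exact by construction. Class palettes are
## flat base shades, optionally perturbed by integer per-channel jitter of
## amplitude `noise`; ground truth stays well-defined at the fixture's stated
## tolerance t whenever sqrt(3)*noise < t < D - sqrt(3)*noise, where D is the
## minimum RGB distance between base shades of different classes. That window
## is asserted at generation time.

# Run expr under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Integer jitter in [-a, a] per channel, clamped to [0, 255]. base: n x 3.
.jitter_colors <- function(base, a) {
  if (a == 0) return(base)
  j <- matrix(sample.int(2L * a + 1L, length(base), replace = TRUE) - a - 1L,
              nrow = nrow(base))
  out <- base + j
  out[out < 0L] <- 0L
  out[out > 255L] <- 255L
  out
}

# Assemble a raster from a class matrix (h x w integers indexing `classes`),
# a list of per-class shade palettes (k x 3 matrices) and optional per-class
# shade probabilities. Returns the pixel array (no jitter yet).
.paint_classes <- function(cls, palettes, probs = NULL) {
  h <- nrow(cls); w <- ncol(cls)
  base <- matrix(0L, nrow = h * w, ncol = 3L)
  for (ci in seq_along(palettes)) {
    idx <- which(cls == ci)
    if (!length(idx)) next
    pal <- palettes[[ci]]
    p <- if (is.null(probs)) NULL else probs[[ci]]
    pick <- sample.int(nrow(pal), length(idx), replace = TRUE, prob = p)
    base[idx, ] <- pal[pick, , drop = FALSE]
  }
  base
}

.finish_fixture <- function(cls, palettes, probs, noise, dpi, truth) {
  h <- nrow(cls); w <- ncol(cls)
  base <- .paint_classes(cls, palettes, probs)
  px <- .jitter_colors(base, noise)
  arr <- array(0L, dim = c(h, w, 3L))
  arr[, , 1] <- px[, 1]; arr[, , 2] <- px[, 2]; arr[, , 3] <- px[, 3]
  truth$noise <- noise
  truth$palette <- palettes
  truth$min_class_distance <- .min_class_distance(palettes)
  .assert_noise_window(truth)
  structure(list(raster = raster_rgb(arr, dpi = dpi), truth = truth),
            class = "coverage_fixture")
}

.min_class_distance <- function(palettes) {
  nms <- names(palettes)
  dmin <- Inf
  for (i in seq_along(palettes)) for (j in seq_along(palettes)) {
    if (i >= j) next
    a <- palettes[[i]]; b <- palettes[[j]]
    for (r in seq_len(nrow(a)))
      dmin <- min(dmin, sqrt(colSums((t(b) - as.numeric(a[r, ]))^2)))
  }
  dmin
}

.assert_noise_window <- function(truth) {
  a <- truth$noise; t <- truth$tolerance; D <- truth$min_class_distance
  lo <- sqrt(3) * a
  if (!(lo < t && t < D - lo))
    stop(sprintf(
      "fixture noise window violated: need sqrt(3)*%g = %.2f < tolerance %g < D - sqrt(3)*a = %.2f",
      a, lo, t, D - lo), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.coverage_fixture <- function(x, ...) {
  d <- dim(x$raster$pixels)
  cat(sprintf("<coverage_fixture> %s: %d x %d px, noise %g, tolerance %g (%s)\n",
              x$truth$kind, d[2], d[1], x$truth$noise, x$truth$tolerance,
              x$truth$metric))
  invisible(x)
}

#' Build a selection from a fixture's ground-truth palette
#'
#' Convenience for tests and examples: the base shades of the named truth
#' classes become the channels, with the fixture's stated tolerance and
#' metric (overridable).
#'
#' @param fx A `coverage_fixture`.
#' @param include,ignore Character vectors of class names in
#'   `fx$truth$palette`.
#' @param name Selection name.
#' @param tolerance,metric Override the fixture's stated values.
#' @return A [selection()].
#' @export
fixture_selection <- function(fx, include, ignore = NULL,
                              name = paste0(fx$truth$kind, "-selection"),
                              tolerance = fx$truth$tolerance,
                              metric = fx$truth$metric) {
  stopifnot(inherits(fx, "coverage_fixture"))
  pal <- fx$truth$palette
  pick <- function(classes) {
    if (is.null(classes)) return(NULL)
    bad <- setdiff(classes, names(pal))
    if (length(bad)) stop("unknown fixture class(es): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    do.call(rbind, pal[classes])
  }
  selection(name, include = pick(include), ignore = pick(ignore),
            metric = metric, tolerance = tolerance)
}

# Connected blob with an exact pixel count: per-row widths follow a smoothed
# multiplicative random walk (rescaled and pixel-adjusted to sum exactly to
# `target`), row start offsets a small additive walk. Non-convex for any
# non-trivial walk; exact count by construction.
.blob_pixels <- function(target) {
  target <- as.integer(target)
  stopifnot(target >= 1L)
  R <- max(2L, as.integer(round(sqrt(target))))
  if (target < 4L) R <- 1L
  shape <- exp(cumsum(stats::rnorm(R, 0, 0.06)))
  shape <- shape / mean(shape)
  w <- pmax(1L, as.integer(round(shape * target / R)))
  d <- target - sum(w)
  while (d != 0L) {
    i <- sample.int(R, 1L)
    if (d > 0L) { w[i] <- w[i] + 1L; d <- d - 1L }
    else if (w[i] > 1L) { w[i] <- w[i] - 1L; d <- d + 1L }
  }
  off <- cumsum(sample(-3:3, R, replace = TRUE))
  off <- off - min(off)
  rows <- rep(seq_len(R), times = w)
  cols <- unlist(lapply(seq_len(R), function(r) off[r] + seq_len(w[r])),
                 use.names = FALSE)
  list(rows = rows, cols = cols, height = R, width = max(off + w))
}

#' Calibration sheet: an array of squares of known physical size
#'
#' Emulates the square-pattern quality-control sheet: dark squares of
#' `square_cm` side on a white page at a known scanner DPI. With the default
#' 254 DPI a 0.5 cm square is exactly 50 px, so a 2 x 2 array is exactly
#' 10000 dark pixels = 1 cm² — the canonical self-check of the area formula.
#'
#' @param dpi Scanner resolution (default 254, giving 100 px per cm).
#' @param array_dim Squares grid, `c(rows, cols)` (default `c(2, 2)`).
#' @param square_cm Square side in cm (default 0.5).
#' @param noise Jitter amplitude (default 5).
#' @param seed RNG seed.
#' @return A `coverage_fixture`; truth records the exact dark-pixel count and
#'   the intended physical area.
#' @export
make_calibration_grid <- function(dpi = 254, array_dim = c(2L, 2L),
                                  square_cm = 0.5, noise = 5L, seed = 1L) {
  side <- round(square_cm * dpi / 2.54)
  if (side < 1) stop("degenerate sub-pixel squares: increase dpi or square_cm",
                     call. = FALSE)
  .with_seed(seed, {
    nr <- as.integer(array_dim[1]); nc <- as.integer(array_dim[2])
    gap <- side; margin <- side
    h <- 2L * margin + nr * side + (nr - 1L) * gap
    w <- 2L * margin + nc * side + (nc - 1L) * gap
    cls <- matrix(2L, nrow = h, ncol = w)  # 1 = square, 2 = paper
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      y0 <- margin + (i - 1L) * (side + gap)
      x0 <- margin + (j - 1L) * (side + gap)
      cls[(y0 + 1L):(y0 + side), (x0 + 1L):(x0 + side)] <- 1L
    }
    dark <- sum(cls == 1L)
    truth <- list(
      kind = "calibration_grid", dpi = dpi, tolerance = 35, metric = "rgb",
      counts = list(square = dark, paper = h * w - dark),
      area_cm2_true = dark / (dpi / 2.54)^2,
      intended_area_cm2 = nr * nc * square_cm^2,
      side_px = side
    )
    .finish_fixture(cls,
                    palettes = list(square = .as_channel_matrix("#3C3C3C"),
                                    paper = .as_channel_matrix("#FFFFFF")),
                    probs = NULL, noise = noise, dpi = dpi, truth = truth)
  })
}

#' Calibration object: a non-convex blob of exactly known area
#'
#' Emulates the second quality-control step: a complex (non-convex) object
#' whose true area is known. The foreground pixel count is exactly
#' `round(target_cm2 * (dpi / 2.54)^2)`; the silhouette varies with the seed
#' but the count never does.
#'
#' @param dpi Scanner resolution (default 254).
#' @param target_cm2 True object area (default 4).
#' @param noise Jitter amplitude (default 5).
#' @param seed RNG seed.
#' @return A `coverage_fixture`.
#' @export
make_complex_calibration <- function(dpi = 254, target_cm2 = 4,
                                     noise = 5L, seed = 1L) {
  target <- round(target_cm2 * (dpi / 2.54)^2)
  if (target < 1) stop("target area smaller than one pixel at this dpi",
                       call. = FALSE)
  .with_seed(seed, {
    blob <- .blob_pixels(target)
    margin <- 20L
    h <- blob$height + 2L * margin
    w <- blob$width + 2L * margin
    cls <- matrix(2L, nrow = h, ncol = w)
    cls[cbind(blob$rows + margin, blob$cols + margin)] <- 1L
    stopifnot(sum(cls == 1L) == target)
    truth <- list(
      kind = "complex_calibration", dpi = dpi, tolerance = 35, metric = "rgb",
      counts = list(object = target, paper = h * w - target),
      area_cm2_true = target / (dpi / 2.54)^2,
      intended_area_cm2 = target_cm2
    )
    .finish_fixture(cls,
                    palettes = list(object = .as_channel_matrix("#3C3C3C"),
                                    paper = .as_channel_matrix("#FFFFFF")),
                    probs = NULL, noise = noise, dpi = dpi, truth = truth)
  })
}

#' Two-phase plant: green and senescent (yellow-brown) tissue
#'
#' Emulates the senescence and tissue-culture workflows: one plant-shaped
#' blob of exactly `budget` pixels on a white (or pink) background, split
#' between green tissue and yellow-brown tissue. The yellow-brown pixels are
#' the bottom `budget - round(budget * green_fraction)` of the blob in row
#' order (senescence progresses from the lower leaves), so both phase counts
#' are exact.
#'
#' @param green_fraction Fraction of plant pixels that are green, in
#'   `[0, 1]`.
#' @param budget Total plant pixel count (default 10000).
#' @param noise Jitter amplitude (default 6).
#' @param seed RNG seed.
#' @param background `"white"` or `"pink"` (pink emulates blanked regions).
#' @return A `coverage_fixture`; truth records both phase counts and the true
#'   yellow-brown/total ratio.
#' @export
make_two_phase_plant <- function(green_fraction, budget = 10000L,
                                 noise = 6L, seed = 1L,
                                 background = c("white", "pink")) {
  background <- match.arg(background)
  if (!is.numeric(green_fraction) || green_fraction < 0 || green_fraction > 1)
    stop("green_fraction must lie in [0, 1]", call. = FALSE)
  .with_seed(seed, {
    blob <- .blob_pixels(budget)
    margin <- 15L
    h <- blob$height + 2L * margin
    w <- blob$width + 2L * margin
    cls <- matrix(3L, nrow = h, ncol = w)  # 1 green, 2 yellow-brown, 3 bg
    n_green <- round(budget * green_fraction)
    phase <- rep(2L, budget)
    if (n_green > 0) phase[seq_len(n_green)] <- 1L  # blob pixels are in row order
    cls[cbind(blob$rows + margin, blob$cols + margin)] <- phase
    bg_col <- if (background == "white") "#FFFFFF" else "#FF69B4"
    truth <- list(
      kind = "two_phase_plant", dpi = NULL, tolerance = 30, metric = "rgb",
      counts = list(green = n_green, yellow_brown = budget - n_green,
                    background = h * w - budget),
      green_fraction = green_fraction,
      ratio_yellow_brown_true = (budget - n_green) / budget,
      background_kind = background
    )
    .finish_fixture(cls,
                    palettes = list(
                      green = .as_channel_matrix(c("#287828", "#3C9137")),
                      yellow_brown = .as_channel_matrix(c("#C8A828", "#B47D20")),
                      background = .as_channel_matrix(bg_col)),
                    probs = NULL, noise = noise, dpi = NULL, truth = truth)
  })
}

#' Canopy plot: green cover over soil, with optional artifacts
#'
#' Emulates a vertical photograph of a field plot: soil-toned background,
#' green canopy patches occupying an exact fraction of the non-artifact
#' pixels, and optionally netting stripes (white/orange) and a plot label
#' (black/white) in the ignore palette. One soil shade (dry litter) sits
#' deliberately closer to the canopy greens than the plain browns do, so a
#' tolerance sweep reproduces the under/over-segmentation regimes: too-low
#' tolerances miss noisy canopy pixels, the calibrated tolerance (30, RGB)
#' is truth-faithful, and tolerances of 40+ start absorbing litter-toned
#' soil into the canopy.
#'
#' @param cover_fraction Canopy fraction of non-artifact pixels, in `[0, 1]`.
#' @param artifacts Character subset of `c("netting", "label")`.
#' @param noise Jitter amplitude (default 10).
#' @param seed RNG seed.
#' @param width,height Image dimensions in px.
#' @return A `coverage_fixture`; truth records all class counts and the true
#'   coverage percentage `c * 100 / (n - i)`.
#' @export
make_canopy_plot <- function(cover_fraction, artifacts = character(),
                             noise = 10L, seed = 1L,
                             width = 320L, height = 240L) {
  if (!is.numeric(cover_fraction) || cover_fraction < 0 || cover_fraction > 1)
    stop("cover_fraction must lie in [0, 1]", call. = FALSE)
  stopifnot(all(artifacts %in% c("netting", "label")))
  .with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    art <- matrix(0L, nrow = h, ncol = w)  # 0 none, 1 white, 2 orange, 3 black
    if ("netting" %in% artifacts) {
      vx <- seq(20L, w - 5L, by = 80L)
      hy <- seq(30L, h - 5L, by = 80L)
      for (k in seq_along(vx))
        art[, vx[k]:(vx[k] + 2L)] <- if (k %% 2L) 1L else 2L
      for (k in seq_along(hy))
        art[hy[k]:(hy[k] + 2L), ] <- if (k %% 2L) 2L else 1L
    }
    if ("label" %in% artifacts) {
      art[9:26, 9:38] <- 3L
      art[13:22, 15:32] <- 1L  # white "number" field on the black tag
    }
    free <- art == 0L
    k <- round(cover_fraction * sum(free))
    canopy <- matrix(FALSE, nrow = h, ncol = w)
    if (k > 0) {
      if (k < 0.85 * sum(free)) {
        tries <- 0L
        while (sum(canopy & free) < k && tries < 5000L) {
          cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
          rx <- stats::runif(1, 6, 26); ry <- stats::runif(1, 6, 26)
          xs <- max(1L, floor(cx - rx)):min(w, ceiling(cx + rx))
          ys <- max(1L, floor(cy - ry)):min(h, ceiling(cy + ry))
          inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
          canopy[ys, xs] <- canopy[ys, xs] | inside
          tries <- tries + 1L
        }
      } else canopy[] <- TRUE
      idx <- which(canopy & free)
      if (length(idx) > k) canopy[sample(idx, length(idx) - k)] <- FALSE
      else if (length(idx) < k) {
        pool <- which(free & !canopy)
        canopy[sample(pool, k - length(idx))] <- TRUE
      }
    }
    # class codes: 1 canopy, 2 soil, 3 net-white, 4 net-orange, 5 label-black
    cls <- matrix(2L, nrow = h, ncol = w)
    cls[canopy & free] <- 1L
    cls[art == 1L] <- 3L
    cls[art == 2L] <- 4L
    cls[art == 3L] <- 5L
    n <- h * w
    i_count <- sum(art != 0L)
    truth <- list(
      kind = "canopy_plot", dpi = NULL, tolerance = 30, metric = "rgb",
      calibrated_tolerance = 30,
      counts = list(canopy = k, soil = n - k - i_count, artifact = i_count),
      cover_fraction = cover_fraction,
      coverage_pct_true = if (n == i_count) NA_real_ else
        k * 100 / (n - i_count)
    )
    .finish_fixture(cls,
                    palettes = list(
                      canopy = .as_channel_matrix(c("#3C7D37", "#509448")),
                      soil = .as_channel_matrix(c("#966E4B", "#84603C",
                                                  "#80944E")),
                      net_white = .as_channel_matrix("#FAFAFA"),
                      net_orange = .as_channel_matrix("#F5961E"),
                      label_black = .as_channel_matrix("#141414")),
                    probs = list(NULL, c(0.45, 0.35, 0.20), NULL, NULL, NULL),
                    noise = noise, dpi = NULL, truth = truth)
  })
}

#' Write a fixture to disk as BMP plus truth JSON
#'
#' @param fx A `coverage_fixture`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to the fixture kind.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_fixture <- function(fx, dir, stem = fx$truth$kind) {
  stopifnot(inherits(fx, "coverage_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".bmp"))
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  write_raster(fx$raster, img_path)
  truth <- fx$truth
  truth$palette <- lapply(truth$palette, function(m)
    unname(apply(m, 1L, identity, simplify = FALSE)))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(c(image = img_path, truth = truth_path))
}
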