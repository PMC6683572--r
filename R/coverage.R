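#' Coverage percentage of a classification
#'
#' `coverage = c * 100 / (n - i)`: the share of *non-ignored* pixels that are
#' foreground. Since `b = n - c - i`, this is identically
#' `c * 100 / (c + b)`; both forms are evaluated and asserted equal on every
#' call. When every pixel is ignored (`n == i`) the value is undefined and
#' returned as `NA` carrying a `reason` attribute — an explicit flag, never a
#' silent zero — so one pathological image cannot abort a batch.
#'
#' @param counts A [label_counts()].
#' @return The percentage in `[0, 100]`, or flagged `NA`.
#' @examples
#' coverage_percent(label_counts(n = 100, c = 40, i = 20)) # 50
#' @export
coverage_percent <- function(counts) {
  counts <- .check_counts(counts)
  if (counts$n == counts$i)
    return(structure(NA_real_, reason = "all pixels ignored (n == i)"))
  v1 <- counts$c * 100 / (counts$n - counts$i)
  v2 <- counts$c * 100 / (counts$c + counts$b)
  stopifnot(identical(v1, v2))  # the two printed forms are the same number
  v1
}

.check_counts <- function(counts) {
  if (inherits(counts, "coverage_classification")) counts <- counts$counts
  if (!inherits(counts, "label_counts"))
    stop("expected label_counts (see classify_image())", call. = FALSE)
  counts
}

#' Physical foreground area from a pixel count
#'
#' `area = c / (dpi / 2.54)^2` cm²: each pixel is a square of side
#' `2.54 / dpi` cm, valid when the raster carries correct embedded scanner
#' resolution. Photographs without DPI metadata have no physical scale; only
#' percentage coverage is meaningful for them, and this function refuses
#' rather than guessing.
#'
#' @param c Foreground pixel count (or a [label_counts()] /
#'   classification, whose `c` is used).
#' @param dpi Positive resolution in dots per inch.
#' @return Area in cm².
#' @examples
#' area_cm2(10000, dpi = 254) # exactly 1 cm^2: 254 dpi puts 100 px per cm
#' @export
area_cm2 <- function(c, dpi) {
  if (inherits(c, "coverage_classification") || inherits(c, "label_counts"))
    c <- .check_counts(c)$c
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0)
    stop("c must be a single non-negative pixel count", call. = FALSE)
  if (is.null(dpi) || !is.numeric(dpi) || length(dpi) != 1L || is.na(dpi) ||
      dpi <= 0)
    stop("area unavailable: no positive DPI. Scanned BMPs embed it; ",
         "otherwise pass an explicit dpi (CLI: --dpi).", call. = FALSE)
  c / (dpi / 2.54)^2
}

#' Analyze one image with one selection
#'
#' Classifies the image and assembles the standard per-image record:
#' label counts, coverage percentage, physical area when DPI is available,
#' and full provenance (selection name + hash, tolerance, metric, conflict
#' policy) so the result is reproducible and provably uniform across a
#' batch.
#'
#' @param img A `coverage_raster`.
#' @param sel A [selection()].
#' @param id Image identifier recorded in the result (defaults to `"image"`).
#' @param conflict Conflict policy, see [classify_pixel()].
#' @param require_area When `TRUE`, a missing DPI is reported as status
#'   `"no-dpi"` instead of a silent `NA` area.
#' @return A `coverage_result` list; see the CSV columns of [run_batch()].
#' @export
analyze_image <- function(img, sel, id = "image",
                          conflict = c("nearest", "ignore-wins",
                                       "include-wins"),
                          require_area = FALSE) {
  conflict <- match.arg(conflict)
  .check_raster(img)
  cls <- classify_image(img, sel, conflict = conflict)
  cov <- coverage_percent(cls$counts)
  area <- if (!is.null(img$dpi)) area_cm2(cls$counts$c, img$dpi) else NA_real_
  status <- "ok"
  if (is.na(cov)) status <- "all-ignored"
  else if (require_area && is.null(img$dpi)) status <- "no-dpi"
  structure(list(
    image = id, counts = cls$counts, coverage_pct = as.numeric(cov),
    area_cm2 = area, dpi = if (is.null(img$dpi)) NA_real_ else img$dpi,
    selection = sel$name, selection_hash = selection_hash(sel),
    tolerance = sel$tolerance, metric = sel$metric, conflict = conflict,
    status = status
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %s: coverage %s%%, area %s cm^2 [%s]\n",
              x$image,
              if (is.na(x$coverage_pct)) "NA" else sprintf("%.2f", x$coverage_pct),
              if (is.na(x$area_cm2)) "NA" else sprintf("%.2f", x$area_cm2),
              x$status))
  invisible(x)
}

#' Ratio of two selections applied to the same image
#'
#' The two-pass workflow behind senescence ratios (yellow-brown / total
#' plant) and transformation escape rates (green / total tissue): the image
#' is classified once with the *total* selection (all phases of the object)
#' and once with the *subset* selection (one phase only), and the ratio of
#' the two coverage percentages is reported. Both selections must share one
#' metric and one tolerance — the uniformity rule — or the call errors. The
#' subset selection is an independent sampling, not necessarily a literal
#' subset of the total's channels; the ratio is only guaranteed in `[0, 1]`
#' when every subset-matched pixel is also total-matched.
#'
#' @param img A `coverage_raster`.
#' @param total_sel Selection covering the whole object.
#' @param subset_sel Selection covering the phase of interest.
#' @param id Image identifier.
#' @param conflict Conflict policy.
#' @return A `ratio_result` list: `image`, `subset_pct`, `total_pct`,
#'   `ratio` (`NA` with a `reason` when total coverage is 0 or undefined).
#' @export
selection_ratio <- function(img, total_sel, subset_sel, id = "image",
                            conflict = c("nearest", "ignore-wins",
                                         "include-wins")) {
  conflict <- match.arg(conflict)
  .check_selection(total_sel); .check_selection(subset_sel)
  if (!identical(total_sel$metric, subset_sel$metric) ||
      !identical(total_sel$tolerance, subset_sel$tolerance))
    stop("uniformity violation: total and subset selections must share one ",
         "metric and one tolerance (got ",
         sprintf("%s/%g vs %s/%g", total_sel$metric, total_sel$tolerance,
                 subset_sel$metric, subset_sel$tolerance), ")", call. = FALSE)
  tot <- coverage_percent(classify_image(img, total_sel, conflict = conflict))
  sub <- coverage_percent(classify_image(img, subset_sel, conflict = conflict))
  ratio <- if (is.na(tot) || is.na(sub))
    structure(NA_real_, reason = "coverage undefined (all pixels ignored)")
  else if (tot == 0)
    structure(NA_real_, reason = "total coverage is zero")
  else as.numeric(sub) / as.numeric(tot)
  structure(list(image = id, subset_pct = as.numeric(sub),
                 total_pct = as.numeric(tot), ratio = ratio,
                 subset_selection = subset_sel$name,
                 total_selection = total_sel$name),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> %s: subset %.2f%% / total %.2f%% = %s\n",
              x$image, x$subset_pct, x$total_pct,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Change in a phase ratio between two imaging dates
#'
#' For senescence scoring: the increase of the yellow-brown/total ratio
#' between an early and a late imaging date of the same plant. A negative
#' delta (apparent "greening") is returned as-is but with a warning, since
#' senescence is expected to be non-decreasing.
#'
#' @param early,late `ratio_result`s (or bare ratios) for the same plant.
#' @return `late - early`, or flagged `NA` when either input is undefined.
#' @export
senescence_delta <- function(early, late) {
  r <- function(x) if (inherits(x, "ratio_result")) x$ratio else x
  e <- r(early); l <- r(late)
  if (is.na(e) || is.na(l)) {
    why <- c(attr(e, "reason"), attr(l, "reason"), "input ratio undefined")[1]
    return(structure(NA_real_, reason = why))
  }
  d <- as.numeric(l) - as.numeric(e)
  if (d < 0)
    warning(sprintf("negative senescence delta (%.4f): late ratio below early",
                    d), call. = FALSE)
  d
}
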