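#' Apply one selection uniformly to an image set
#'
#' The central methodological discipline: every image of a batch is
#' classified with the *same* selection, tolerance, metric and pre-processing
#' spec, so segmentation error is uniform and between-image comparisons stay
#' valid. Each result row records the selection hash as proof. Per-image
#' failures (unreadable file, missing DPI when area was requested, all
#' pixels ignored) are recorded in the `status` column without aborting the
#' run; rows are ordered by path so repeated runs are byte-identical.
#'
#' @param paths Character vector of image paths (24-bit BMP).
#' @param sel A [selection()] or a selection file path.
#' @param tolerance,metric Optional overrides of the selection's stored
#'   values.
#' @param dpi Optional DPI override applied to every image.
#' @param crop Optional [region_spec()] applied identically to every image.
#' @param blank Optional list of `list(region =, fill =)` blanking specs
#'   applied identically to every image.
#' @param manifest Optional data frame with columns `path`, `x0`, `y0`,
#'   `x1`, `y1`, `fill` giving per-image blanking (for sets where artifact
#'   position varies between pots/plots).
#' @param conflict Conflict policy, see [classify_pixel()].
#' @param require_area When `TRUE`, images without DPI get status `"no-dpi"`.
#' @param save_masks Optional directory; QC overlays are written there as
#'   `<image stem>_mask.bmp`.
#' @return A data frame with columns `image`, `n`, `c`, `i`, `b`,
#'   `coverage_pct`, `area_cm2`, `dpi`, `selection`, `selection_hash`,
#'   `tolerance`, `metric`, `status`.
#' @export
run_batch <- function(paths, sel, tolerance = NULL, metric = NULL,
                      dpi = NULL, crop = NULL, blank = NULL, manifest = NULL,
                      conflict = c("nearest", "ignore-wins", "include-wins"),
                      require_area = FALSE, save_masks = NULL) {
  conflict <- match.arg(conflict)
  if (is.character(sel)) sel <- load_selection(sel)
  sel <- .apply_overrides(sel, tolerance, metric)
  .check_selection(sel)
  if (length(paths) < 1L) stop("empty input set", call. = FALSE)
  paths <- sort(paths)
  if (!is.null(save_masks))
    dir.create(save_masks, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(paths, function(p) {
    tryCatch({
      img <- read_raster(p, dpi = dpi)
      img <- .preprocess(img, crop, blank, manifest, p)
      res <- analyze_image(img, sel, id = p, conflict = conflict,
                           require_area = require_area)
      if (!is.null(save_masks)) {
        cls <- classify_image(img, sel, conflict = conflict)
        stem <- tools::file_path_sans_ext(basename(p))
        write_raster(render_mask_overlay(img, cls$mask),
                     file.path(save_masks, paste0(stem, "_mask.bmp")))
      }
      .result_row(res)
    }, error = function(e) {
      data.frame(image = p, n = NA_real_, c = NA_real_, i = NA_real_,
                 b = NA_real_, coverage_pct = NA_real_, area_cm2 = NA_real_,
                 dpi = NA_real_, selection = sel$name,
                 selection_hash = selection_hash(sel),
                 tolerance = sel$tolerance, metric = sel$metric,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

.apply_overrides <- function(sel, tolerance, metric) {
  if (!is.null(tolerance)) sel$tolerance <- .check_tolerance(tolerance)
  if (!is.null(metric)) sel$metric <- match.arg(metric, c("rgb", "ycbcr"))
  sel
}

.preprocess <- function(img, crop, blank, manifest, path) {
  if (!is.null(crop)) img <- crop_raster(img, crop)
  for (b in blank %||% list())
    img <- blank_region(img, b$region, b$fill)
  if (!is.null(manifest)) {
    hits <- manifest[manifest$path == path, , drop = FALSE]
    for (r in seq_len(nrow(hits)))
      img <- blank_region(img,
                          region_spec(hits$x0[r], hits$y0[r], hits$x1[r],
                                      hits$y1[r]),
                          hits$fill[r])
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.result_row <- function(res) {
  data.frame(image = res$image, n = res$counts$n, c = res$counts$c,
             i = res$counts$i, b = res$counts$b,
             coverage_pct = res$coverage_pct, area_cm2 = res$area_cm2,
             dpi = res$dpi, selection = res$selection,
             selection_hash = res$selection_hash, tolerance = res$tolerance,
             metric = res$metric, status = res$status,
             stringsAsFactors = FALSE)
}

#' Two-selection ratio over an image set, optionally paired across dates
#'
#' Single-set mode (`late = NULL`): every image in `paths` gets a
#' subset/total coverage ratio row (e.g. green/total per petri plate).
#' Paired mode: `paths` are the early date and `late` the late date; rows
#' are joined by plant id (file stem by default) and the senescence delta
#' `late_ratio - early_ratio` is appended. Unpairable ids are flagged, not
#' fatal.
#'
#' @param paths Image paths (single set, or the early date in paired mode).
#' @param total_sel,subset_sel Selections (objects or file paths) sharing
#'   one metric and tolerance.
#' @param late Optional late-date image paths for paired mode.
#' @param ids,late_ids Plant ids; default is the file stem.
#' @param tolerance,metric Optional overrides, applied to both selections.
#' @param dpi,crop,blank,manifest,conflict As in [run_batch()].
#' @return A data frame; paired mode has one row per plant id with
#'   `early_ratio`, `late_ratio`, `delta`, `status`.
#' @export
run_ratio_batch <- function(paths, total_sel, subset_sel, late = NULL,
                            ids = NULL, late_ids = NULL,
                            tolerance = NULL, metric = NULL, dpi = NULL,
                            crop = NULL, blank = NULL, manifest = NULL,
                            conflict = c("nearest", "ignore-wins",
                                         "include-wins")) {
  conflict <- match.arg(conflict)
  if (is.character(total_sel)) total_sel <- load_selection(total_sel)
  if (is.character(subset_sel)) subset_sel <- load_selection(subset_sel)
  total_sel <- .apply_overrides(total_sel, tolerance, metric)
  subset_sel <- .apply_overrides(subset_sel, tolerance, metric)
  if (length(paths) < 1L) stop("empty input set", call. = FALSE)

  one_set <- function(pp, pids) {
    ord <- order(pp)
    pp <- pp[ord]; pids <- pids[ord]
    rows <- mapply(function(p, id) {
      tryCatch({
        img <- read_raster(p, dpi = dpi)
        img <- .preprocess(img, crop, blank, manifest, p)
        rr <- selection_ratio(img, total_sel, subset_sel, id = id,
                              conflict = conflict)
        data.frame(id = id, image = p, subset_pct = rr$subset_pct,
                   total_pct = rr$total_pct, ratio = as.numeric(rr$ratio),
                   status = if (is.na(rr$ratio))
                     attr(rr$ratio, "reason") %||% "undefined" else "ok",
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(id = id, image = p, subset_pct = NA_real_,
                   total_pct = NA_real_, ratio = NA_real_,
                   status = paste0("error: ", conditionMessage(e)),
                   stringsAsFactors = FALSE))
    }, pp, pids, SIMPLIFY = FALSE)
    do.call(rbind, rows)
  }

  ids <- ids %||% tools::file_path_sans_ext(basename(paths))
  early_tab <- one_set(paths, ids)
  attr(early_tab, "selection_hash") <-
    c(total = selection_hash(total_sel), subset = selection_hash(subset_sel))
  if (is.null(late)) {
    rownames(early_tab) <- NULL
    return(early_tab)
  }

  late_ids <- late_ids %||% tools::file_path_sans_ext(basename(late))
  late_tab <- one_set(late, late_ids)
  all_ids <- sort(union(early_tab$id, late_tab$id))
  rows <- lapply(all_ids, function(id) {
    e <- early_tab[early_tab$id == id, , drop = FALSE]
    l <- late_tab[late_tab$id == id, , drop = FALSE]
    if (nrow(e) != 1L || nrow(l) != 1L)
      return(data.frame(id = id, early_ratio = NA_real_,
                        late_ratio = NA_real_, delta = NA_real_,
                        status = "unpaired", stringsAsFactors = FALSE))
    d <- if (is.na(e$ratio) || is.na(l$ratio)) NA_real_
         else suppressWarnings(senescence_delta(e$ratio, l$ratio))
    data.frame(id = id, early_ratio = e$ratio, late_ratio = l$ratio,
               delta = d,
               status = if (is.na(d)) "undefined-ratio"
                        else if (d < 0) "negative-delta" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a results table as a stable CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator, fixed column
#' order; percentages, areas and ratios are printed to 2 decimals (full
#' precision stays in the returned data frames). Identical inputs produce
#' byte-identical files.
#'
#' @param df A data frame from [run_batch()] or [run_ratio_batch()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path) {
  out <- df
  two_dp <- intersect(c("coverage_pct", "area_cm2", "subset_pct", "total_pct",
                        "ratio", "early_ratio", "late_ratio", "delta"),
                      names(out))
  for (col in two_dp)
    out[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.2f", df[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
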