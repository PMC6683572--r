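#' Build a color selection
#'
#' A selection is the unit of uniform analysis: a named set of up to 10
#' *include* channels (shades of the measured object), up to 10 *ignore*
#' channels (foreign objects such as netting, labels or blanked regions),
#' one similarity metric, and one global tolerance. The same selection,
#' tolerance and metric must be applied to every image of a dataset so that
#' any segmentation error is at least uniform, keeping between-image
#' comparisons meaningful.
#'
#' @param name Text label, also recorded in result tables.
#' @param include Include channels: a list of colors, an `n x 3` matrix, or a
#'   character vector of `"#RRGGBB"` strings. At least one is required before
#'   classification.
#' @param ignore Ignore channels, same forms as `include`; may be empty.
#' @param metric `"rgb"` or `"ycbcr"`.
#' @param tolerance Global tolerance, shared by all channels (default 35, a
#'   typical starting point for the RGB metric).
#' @param max_channels Per-role channel limit. The published tool allows 10;
#'   raising this is an explicit deviation.
#' @return A `color_selection` object.
#' @examples
#' sel <- selection("leaf", include = c("#3C8C3C", "#649650"),
#'                  ignore = "#FFFFFF", metric = "rgb", tolerance = 35)
#' @export
selection <- function(name, include = NULL, ignore = NULL,
                      metric = c("rgb", "ycbcr"), tolerance = 35,
                      max_channels = 10L) {
  metric <- match.arg(metric)
  tolerance <- .check_tolerance(tolerance)
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name))
    stop("selection name must be a non-empty string", call. = FALSE)
  max_channels <- as.integer(max_channels)
  inc <- .as_channel_matrix(include)
  ign <- .as_channel_matrix(ignore)
  if (nrow(inc) > max_channels || nrow(ign) > max_channels)
    stop(sprintf("at most %d channels per role (got %d include, %d ignore)",
                 max_channels, nrow(inc), nrow(ign)), call. = FALSE)
  structure(list(name = name, include = inc, ignore = ign, metric = metric,
                 tolerance = tolerance, max_channels = max_channels),
            class = "color_selection")
}

.as_channel_matrix <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0L))
    return(matrix(integer(), ncol = 3L,
                  dimnames = list(NULL, c("r", "g", "b"))))
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  else if (is.character(x)) x <- as.list(x)
  else if (is.numeric(x)) x <- list(x)
  else if (!is.list(x))
    stop("channels must be colors, a matrix, or hex strings", call. = FALSE)
  m <- do.call(rbind, lapply(x, as_color))
  colnames(m) <- c("r", "g", "b")
  m
}

#' @export
print.color_selection <- function(x, ...) {
  cat(sprintf("<color_selection> \"%s\": %d include + %d ignore channels, %s metric, tolerance %g\n",
              x$name, nrow(x$include), nrow(x$ignore), x$metric, x$tolerance))
  invisible(x)
}

.check_selection <- function(sel, need_include = TRUE) {
  if (!inherits(sel, "color_selection"))
    stop("expected a color_selection (see selection())", call. = FALSE)
  if (need_include && nrow(sel$include) == 0L)
    stop("selection has no include channels; sample at least one foreground shade",
         call. = FALSE)
  sel
}

#' Append a sampled color to a selection
#'
#' The scripted analogue of clicking a pixel in the image: the color (often
#' from [sample_pixel()]) is appended to the include or ignore channel list.
#' Adding a duplicate color to the same role is accepted with a warning;
#' classification is a union over channels so duplicates cannot change
#' results.
#'
#' @param sel A `color_selection`.
#' @param color The color to append.
#' @param role `"include"` or `"ignore"`.
#' @return The extended selection.
#' @export
add_channel <- function(sel, color, role = c("include", "ignore")) {
  .check_selection(sel, need_include = FALSE)
  role <- match.arg(role)
  color <- as_color(color)
  m <- sel[[role]]
  if (nrow(m) >= sel$max_channels)
    stop(sprintf("%s channel list is full (limit %d)", role, sel$max_channels),
         call. = FALSE)
  if (nrow(m) > 0L && any(m[, 1] == color[[1]] & m[, 2] == color[[2]] &
                          m[, 3] == color[[3]]))
    warning(sprintf("duplicate %s channel (%d, %d, %d); classification is unchanged",
                    role, color[[1]], color[[2]], color[[3]]), call. = FALSE)
  sel[[role]] <- rbind(m, color)
  rownames(sel[[role]]) <- NULL
  sel
}

.SELECTION_SCHEMA <- 1L

#' Save or load a selection file
#'
#' Selections persist as small UTF-8 JSON documents
#' (`{schema_version, name, metric, tolerance, include, ignore}`) so that one
#' optimized selection can be applied to an entire dataset, diffed, and
#' version-controlled. `load_selection(save_selection(sel, path))` reproduces
#' the selection exactly, channels in order.
#'
#' @param sel A `color_selection`.
#' @param path File path.
#' @return `save_selection`: `path`, invisibly. `load_selection`: the
#'   selection.
#' @export
save_selection <- function(sel, path) {
  .check_selection(sel, need_include = FALSE)
  doc <- list(
    schema_version = .SELECTION_SCHEMA,
    name = sel$name,
    metric = sel$metric,
    tolerance = sel$tolerance,
    include = unname(apply(sel$include, 1L, identity, simplify = FALSE)),
    ignore = unname(apply(sel$ignore, 1L, identity, simplify = FALSE))
  )
  # digits = I(17): exact IEEE round-trip for the tolerance
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_selection
#' @param max_channels Channel limit enforced on load (default 10).
#' @export
load_selection <- function(path, max_channels = 10L) {
  if (!file.exists(path)) stop("selection file not found: ", path,
                               call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse selection file ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  need <- c("schema_version", "name", "metric", "tolerance", "include",
            "ignore")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("selection file ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(as.integer(doc$schema_version), .SELECTION_SCHEMA))
    stop("unknown selection schema_version ", doc$schema_version,
         " (this build reads version ", .SELECTION_SCHEMA, ")", call. = FALSE)
  if (!is.character(doc$metric) || !doc$metric %in% c("rgb", "ycbcr"))
    stop("unknown metric \"", doc$metric,
         "\" in selection file (must be \"rgb\" or \"ycbcr\")", call. = FALSE)
  chans <- function(field)
    lapply(doc[[field]], function(ch) unlist(ch, use.names = FALSE))
  selection(doc$name, include = chans("include"), ignore = chans("ignore"),
            metric = doc$metric, tolerance = doc$tolerance,
            max_channels = max_channels)
}

#' Content hash of a selection
#'
#' MD5 over the canonical serialized form (channels in order, metric,
#' tolerance, name). Every row of a batch run records this hash, so a results
#' table proves that one identical selection was applied uniformly.
#'
#' @param sel A `color_selection`.
#' @return A 32-character hex string.
#' @export
selection_hash <- function(sel) {
  .check_selection(sel, need_include = FALSE)
  canon <- paste(
    sel$name, sel$metric, format(sel$tolerance, digits = 17),
    paste(as.vector(t(sel$include)), collapse = ","),
    paste(as.vector(t(sel$ignore)), collapse = ","),
    sep = "|")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(canon, tmp, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}
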