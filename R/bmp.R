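## 24-bit BMP (BI_RGB) reader/writer.
##
## BMP is the canonical input: scanners embed physical resolution as integer
## pixels-per-meter in the BITMAPINFOHEADER, which is what the cm^2 area
## formula relies on. dpi = ppm * 0.0254; the integer ppm quantization bounds
## the round-trip error at |delta dpi| <= 0.0127.

.PPM_PER_DPI <- 1 / 0.0254  # 300 dpi -> 11811 ppm

.read_u16 <- function(con) readBin(con, "integer", size = 2L, endian = "little",
                                   signed = FALSE)
.read_i32 <- function(con) readBin(con, "integer", size = 4L, endian = "little")

#' Read a 24-bit BMP (or any supported raster) from disk
#'
#' Only uncompressed 24-bit BMP files are decodable; other formats or bit
#' depths raise an error with a conversion hint (open the image and re-save
#' it as 24-bit BMP, e.g. with MSPaint or ImageMagick). Embedded
#' pixels-per-meter resolution is converted to DPI (`dpi = ppm * 0.0254`);
#' an explicit `dpi` argument always wins, and zero/absent metadata leaves
#' dpi unset. An anisotropic embedded resolution (horizontal and vertical
#' differing by more than 0.5% relative) is an error unless overridden.
#'
#' @param path File path.
#' @param dpi Optional override for the embedded resolution.
#' @return A `coverage_raster`.
#' @export
read_raster <- function(path, dpi = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  if (!identical(rawToChar(magic), "BM"))
    stop("not a BMP file: ", path,
         " (only 24-bit BMP is decodable; convert other formats to 24-bit ",
         "BMP first)", call. = FALSE)
  .read_i32(con)            # file size (unreliable in the wild; ignored)
  .read_i32(con)            # reserved
  data_offset <- .read_i32(con)
  hdr_size <- .read_i32(con)
  if (hdr_size < 40L)
    stop("unsupported BMP header (BITMAPCOREHEADER); re-save as 24-bit BMP",
         call. = FALSE)
  width <- .read_i32(con)
  height <- .read_i32(con)
  top_down <- height < 0L
  height <- abs(height)
  .read_u16(con)            # planes
  bitcount <- .read_u16(con)
  compression <- .read_i32(con)
  .read_i32(con)            # biSizeImage
  xppm <- .read_i32(con)
  yppm <- .read_i32(con)
  if (bitcount != 24L || compression != 0L)
    stop(sprintf(
      "unsupported BMP variant (%d-bit, compression %d): convert to ",
      bitcount, compression),
      "uncompressed 24-bit BMP (e.g. re-save from MSPaint/ImageMagick)",
      call. = FALSE)
  if (width < 1L || height < 1L) stop("degenerate BMP dimensions", call. = FALSE)

  embedded <- NULL
  if (xppm > 0L || yppm > 0L) {
    if (xppm > 0L && yppm > 0L &&
        abs(xppm - yppm) / xppm > 0.005 && is.null(dpi))
      stop(sprintf(
        "anisotropic embedded resolution (%d x %d ppm): pass an explicit dpi",
        xppm, yppm), call. = FALSE)
    # horizontal axis is authoritative when both are present
    embedded <- (if (xppm > 0L) xppm else yppm) * 0.0254
  }
  use_dpi <- if (!is.null(dpi)) dpi else embedded

  seek(con, data_offset)
  row_bytes <- 3L * width
  stride <- row_bytes + (4L - row_bytes %% 4L) %% 4L
  dat <- readBin(con, "raw", n = stride * height)
  if (length(dat) < stride * height)
    stop("truncated BMP pixel data: ", path, call. = FALSE)
  m <- matrix(as.integer(dat), nrow = stride, ncol = height)  # column = row
  if (!top_down) m <- m[, height:1, drop = FALSE]             # bottom-up file
  b <- t(m[seq(1L, row_bytes, by = 3L), , drop = FALSE])
  g <- t(m[seq(2L, row_bytes, by = 3L), , drop = FALSE])
  r <- t(m[seq(3L, row_bytes, by = 3L), , drop = FALSE])
  px <- array(0L, dim = c(height, width, 3L))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  raster_rgb(px, dpi = use_dpi)
}

#' Write a raster as an uncompressed 24-bit BMP
#'
#' Pixels round-trip exactly; dpi is stored as integer pixels-per-meter
#' (`round(dpi / 0.0254)`), so a re-read dpi can differ by at most the ppm
#' quantization (0.0127 dpi). An unset dpi is written as zero resolution
#' fields and comes back unset.
#'
#' @param img A `coverage_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  .check_raster(img)
  d <- dim(img$pixels)
  height <- d[1]; width <- d[2]
  row_bytes <- 3L * width
  pad <- (4L - row_bytes %% 4L) %% 4L
  stride <- row_bytes + pad
  ppm <- if (is.null(img$dpi)) 0L else as.integer(round(img$dpi * .PPM_PER_DPI))

  # pixel block: one column per image row, bottom-up, BGR within a row
  m <- matrix(0L, nrow = stride, ncol = height)
  rev_rows <- height:1
  m[seq(3L, row_bytes, by = 3L), ] <- t(img$pixels[rev_rows, , 1, drop = TRUE])
  m[seq(2L, row_bytes, by = 3L), ] <- t(img$pixels[rev_rows, , 2, drop = TRUE])
  m[seq(1L, row_bytes, by = 3L), ] <- t(img$pixels[rev_rows, , 3, drop = TRUE])

  img_size <- stride * height
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32(54L + img_size)   # file size
  w32(0L)               # reserved
  w32(54L)              # pixel data offset
  w32(40L)              # BITMAPINFOHEADER
  w32(width); w32(height)
  w16(1L); w16(24L)
  w32(0L)               # BI_RGB
  w32(img_size)
  w32(ppm); w32(ppm)
  w32(0L); w32(0L)
  writeBin(as.raw(m), con)
  invisible(path)
}
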