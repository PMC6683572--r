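test_that("BMP write/read round-trips pixels losslessly, padding included", {
  set.seed(21)
  # widths 1..5 exercise every 4-byte row-padding case
  for (w in 1:5) for (h in c(1, 3)) {
    img <- random_raster(w, h)
    path <- withr::local_tempfile(fileext = ".bmp")
    write_raster(img, path)
    back <- read_raster(path)
    expect_identical(back$pixels, img$pixels)
    expect_null(back$dpi)
  }
  img <- random_raster(16, 16, dpi = 300)
  path <- withr::local_tempfile(fileext = ".bmp")
  write_raster(img, path)
  expect_identical(read_raster(path)$pixels, img$pixels)
  # reading twice is deterministic
  expect_identical(read_raster(path)$pixels, read_raster(path)$pixels)
})

test_that("DPI metadata round-trips within the ppm integer quantization", {
  path <- withr::local_tempfile(fileext = ".bmp")
  for (dpi in c(300, 254, 600, 72.5)) {
    write_raster(random_raster(4, 4, dpi = dpi), path)
    back <- read_raster(path)
    expect_lte(abs(back$dpi - dpi), 0.0127)
  }
  # 300 dpi stores as ppm 11811 and comes back as 299.9994
  write_raster(random_raster(2, 2, dpi = 300), path)
  expect_equal(read_raster(path)$dpi, 11811 * 0.0254)
  # unset dpi writes zero resolution fields and stays unset
  write_raster(random_raster(2, 2), path)
  expect_null(read_raster(path)$dpi)
  # an explicit override always wins
  expect_equal(read_raster(path, dpi = 96)$dpi, 96)
  write_raster(random_raster(2, 2, dpi = 300), path)
  expect_equal(read_raster(path, dpi = 150)$dpi, 150)
})

test_that("unsupported or anisotropic BMPs error with actionable messages", {
  path <- withr::local_tempfile(fileext = ".bmp")
  write_raster(random_raster(4, 4, dpi = 300), path)

  patch <- function(path, offset, value) {
    con <- file(path, "r+b")
    on.exit(close(con))
    seek(con, offset, rw = "write")
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  # biYPelsPerMeter at byte offset 42: make it 2% off the horizontal value
  patch(path, 42L, round(11811 * 1.02))
  expect_error(read_raster(path), "anisotropic")
  expect_equal(read_raster(path, dpi = 300)$dpi, 300)  # override rescues it

  # 8-bit palettized input: bit depth word at offset 28
  write_raster(random_raster(4, 4), path)
  con <- file(path, "r+b"); seek(con, 28L, rw = "write")
  writeBin(8L, con, size = 2L, endian = "little"); close(con)
  expect_error(read_raster(path), "24-bit")

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", txt)
  expect_error(read_raster(txt), "not a BMP")
  expect_error(read_raster("/nonexistent.bmp"), "not found")
})

test_that("written BMPs decode identically under an independent reader (Pillow)", {
  img <- random_raster(7, 5, dpi = 254)   # width 7 forces row padding
  path <- withr::local_tempfile(fileext = ".bmp")
  write_raster(img, path)
  script <- paste(
    "import sys, numpy as np",
    "from PIL import Image",
    "im = Image.open(sys.argv[1])",
    "a = np.asarray(im.convert('RGB'))",
    "print(a.shape[0], a.shape[1])",
    "print(' '.join(map(str, a.flatten())))",
    "print(round(im.info.get('dpi', (0, 0))[0]))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, path), stdout = TRUE)
  dims <- as.integer(strsplit(out[1], " ")[[1]])
  expect_equal(dims, c(5L, 7L))
  flat <- as.integer(strsplit(out[2], " ")[[1]])
  # PIL flattens row-major with the channel axis fastest
  expect_identical(as.integer(aperm(img$pixels, c(3, 2, 1))), flat)
  expect_equal(as.integer(out[3]), 254L)
})

test_that("crop copies the region and carries dpi", {
  img <- random_raster(100, 80, dpi = 300)
  full <- crop_raster(img, region_spec(0, 0, 100, 80))
  expect_identical(full$pixels, img$pixels)
  expect_equal(full$dpi, 300)

  sub <- crop_raster(img, region_spec(10, 20, 20, 30))
  expect_equal(dim(sub), c(10L, 10L))
  expect_equal(sub$dpi, 300)
  expect_identical(sub$pixels[1, 1, ], img$pixels[21, 11, ])
  expect_identical(sub$pixels[10, 10, ], img$pixels[30, 20, ])

  expect_error(crop_raster(img, region_spec(0, 0, 101, 10)), "exceeds")
  expect_error(region_spec(5, 0, 5, 10), "empty region")
})

test_that("blank_region overwrites exactly the region", {
  img <- random_raster(4, 4)
  pink <- as_color("#FF69B4")
  all_pink <- blank_region(img, region_spec(0, 0, 4, 4), pink)
  expect_true(all(all_pink$pixels[, , 1] == pink[["r"]]))
  expect_true(all(all_pink$pixels[, , 2] == pink[["g"]]))
  expect_true(all(all_pink$pixels[, , 3] == pink[["b"]]))

  part <- blank_region(img, region_spec(0, 0, 2, 2), pink)
  expect_identical(part$pixels[1:2, 1:2, 1], matrix(255L, 2, 2))
  expect_identical(part$pixels[3:4, , ], img$pixels[3:4, , ])
  expect_identical(part$pixels[, 3:4, ], img$pixels[, 3:4, ])
  expect_error(blank_region(img, region_spec(0, 0, 5, 2), pink), "exceeds")
})

test_that("blank and crop never touch pixels they should not (random regions)", {
  set.seed(31)
  img <- random_raster(20, 15, dpi = 254)
  for (k in 1:15) {
    x0 <- sample(0:19, 1); x1 <- x0 + sample.int(20 - x0, 1)
    y0 <- sample(0:14, 1); y1 <- y0 + sample.int(15 - y0, 1)
    rg <- region_spec(x0, y0, x1, y1)
    fill <- random_color()
    b <- blank_region(img, rg, fill)
    inside <- b$pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
    expect_true(all(inside[, , 1] == fill[1] & inside[, , 2] == fill[2] &
                    inside[, , 3] == fill[3]))
    # restore the region from the original: everything else must be untouched
    restored <- b$pixels
    restored[(y0 + 1):y1, (x0 + 1):x1, ] <- img$pixels[(y0 + 1):y1,
                                                       (x0 + 1):x1, ]
    expect_identical(restored, img$pixels)
    expect_equal(b$dpi, img$dpi)

    cr <- crop_raster(img, rg)
    expect_equal(dim(cr), c(y1 - y0, x1 - x0))
    expect_identical(cr$pixels,
                     img$pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE])
  }
})

test_that("blank_by_mask fills exactly the nonzero mask pixels", {
  img <- random_raster(6, 6)
  mask_px <- array(0L, dim = c(6, 6, 3))
  mask_px[2, 3, 1] <- 255L
  mask_px[5, 5, 2] <- 1L
  mask <- raster_rgb(mask_px)
  out <- blank_by_mask(img, mask, "#FF69B4")
  expect_identical(out$pixels[2, 3, ], unname(as_color("#FF69B4")))
  expect_identical(out$pixels[5, 5, ], unname(as_color("#FF69B4")))
  restored <- out$pixels
  restored[2, 3, ] <- img$pixels[2, 3, ]
  restored[5, 5, ] <- img$pixels[5, 5, ]
  expect_identical(restored, img$pixels)
  expect_error(blank_by_mask(img, random_raster(5, 5), "#FF0000"),
               "dimensions")
})
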