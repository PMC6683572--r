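# Build a small on-disk image set once per file: three canopy plots plus a
# calibration sheet (the only one with DPI metadata).
local_image_set <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  for (s in 1:3)
    write_raster(make_canopy_plot(0.2 + 0.1 * s, seed = s)$raster,
                 file.path(dir, sprintf("plot_%d.bmp", s)))
  write_raster(make_calibration_grid(seed = 4)$raster,
               file.path(dir, "sheet.bmp"))
  dir
}

canopy_selection <- function(tolerance = 30, metric = "rgb") {
  fx <- make_canopy_plot(0.3, seed = 1)
  fixture_selection(fx, include = "canopy",
                    ignore = c("net_white", "net_orange", "label_black"),
                    name = "canopy", tolerance = tolerance, metric = metric)
}

test_that("run_batch stamps one selection hash on every row, sorted by path", {
  dir <- local_image_set()
  paths <- list.files(dir, pattern = "plot_", full.names = TRUE)
  tab <- run_batch(paths, canopy_selection())
  expect_equal(nrow(tab), 3L)
  expect_equal(length(unique(tab$selection_hash)), 1L)
  expect_equal(tab$image, sort(paths))
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$c + tab$i + tab$b == tab$n))
  # measured coverage tracks the constructed cover fractions
  expect_equal(tab$coverage_pct,
               vapply(1:3, function(s)
                 make_canopy_plot(0.2 + 0.1 * s,
                                  seed = s)$truth$coverage_pct_true,
                 numeric(1)))
})

test_that("batch equals the single-image API and is byte-stable on disk", {
  dir <- local_image_set()
  paths <- list.files(dir, pattern = "\\.bmp$", full.names = TRUE)
  sel <- canopy_selection()
  tab <- run_batch(paths, sel)
  one <- analyze_image(read_raster(paths[2]), sel, id = paths[2])
  expect_equal(tab$coverage_pct[2], one$coverage_pct)
  expect_equal(tab$c[2], one$counts$c)
  expect_equal(tab$selection_hash[2], one$selection_hash)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(run_batch(paths, sel), f1)
  write_results_csv(run_batch(paths, sel), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("per-image faults are isolated in the status column", {
  dir <- local_image_set()
  bad <- file.path(dir, "broken.bmp")
  writeLines("junk", bad)
  paths <- list.files(dir, pattern = "\\.bmp$", full.names = TRUE)
  tab <- run_batch(paths, canopy_selection(), require_area = TRUE)
  expect_equal(nrow(tab), 5L)
  expect_match(tab$status[tab$image == bad], "error")
  # canopy plots carry no DPI: area requested -> flagged, not fatal
  plot_rows <- grepl("plot_", tab$image)
  expect_true(all(tab$status[plot_rows] == "no-dpi"))
  expect_true(all(is.na(tab$area_cm2[plot_rows])))
  # the sheet has embedded DPI and still succeeds
  sheet <- tab[grepl("sheet", tab$image), ]
  expect_equal(sheet$status, "ok")
  expect_false(is.na(sheet$area_cm2))
})

test_that("shared crop and blank specs apply to every image", {
  dir <- withr::local_tempdir()
  img <- make_canopy_plot(0.5, seed = 8)$raster
  p <- file.path(dir, "one.bmp")
  write_raster(img, p)
  sel <- canopy_selection()
  rg <- region_spec(0, 0, 100, 100)
  tab <- run_batch(p, sel, crop = rg)
  expect_equal(tab$n, 100 * 100)
  # blank everything with a color sampled as ignore: all pixels ignored
  white <- list(region = region_spec(0, 0, 320, 240), fill = "#FAFAFA")
  tab2 <- run_batch(p, sel, blank = list(white))
  expect_equal(tab2$i, 320 * 240)
  expect_equal(tab2$status, "all-ignored")
  expect_true(is.na(tab2$coverage_pct))
})

test_that("a manifest applies per-image blanking only to its own image", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.bmp"); p2 <- file.path(dir, "b.bmp")
  img <- make_canopy_plot(0.4, seed = 12)$raster
  write_raster(img, p1); write_raster(img, p2)
  sel <- canopy_selection()
  # blank a 50x50 patch with an ignored color in image a only
  manifest <- data.frame(path = p1, x0 = 0, y0 = 0, x1 = 50, y1 = 50,
                         fill = "#FAFAFA", stringsAsFactors = FALSE)
  tab <- run_batch(c(p1, p2), sel, manifest = manifest)
  expect_gte(tab$i[tab$image == p1], 2500)
  expect_lt(tab$i[tab$image == p2], 2500)
  expect_equal(tab$n[1], tab$n[2])
})

test_that("a JSON config mirrors CLI flags and explicit flags win", {
  dir <- withr::local_tempdir()
  fx <- make_calibration_grid(seed = 2)
  bmp <- file.path(dir, "sheet.bmp")
  write_raster(fx$raster, bmp)
  selfile <- file.path(dir, "sel.json")
  save_selection(selection("squares", include = "#3C3C3C",
                           ignore = "#FFFFFF", tolerance = 35), selfile)
  out_csv <- file.path(dir, "out.csv")
  cfg <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(selection = selfile, out = out_csv,
                            images = list(bmp)),
                       cfg, auto_unbox = TRUE)
  suppressMessages(coverage_cli(c("classify", "--config", cfg)))
  expect_equal(utils::read.csv(out_csv)$c, 10000)
  # an explicit flag overrides the config value
  suppressMessages(coverage_cli(c("classify", "--config", cfg,
                                  "--tolerance", "0")))
  expect_equal(utils::read.csv(out_csv)$c, 0)
})

test_that("run_ratio_batch pairs by id and appends the senescence delta", {
  dir <- withr::local_tempdir()
  early <- file.path(dir, "early"); late <- file.path(dir, "late")
  dir.create(early); dir.create(late)
  # plant ratios by construction: early 0.10 / late 0.35 (plant_a),
  # early 0.20 / late 0.20 (plant_b); plant_c only has an early image
  write_raster(make_two_phase_plant(0.90, seed = 1)$raster,
               file.path(early, "plant_a.bmp"))
  write_raster(make_two_phase_plant(0.65, seed = 2)$raster,
               file.path(late, "plant_a.bmp"))
  write_raster(make_two_phase_plant(0.80, seed = 3)$raster,
               file.path(early, "plant_b.bmp"))
  write_raster(make_two_phase_plant(0.80, seed = 4)$raster,
               file.path(late, "plant_b.bmp"))
  write_raster(make_two_phase_plant(0.50, seed = 5)$raster,
               file.path(early, "plant_c.bmp"))

  fx <- make_two_phase_plant(0.5, seed = 1)
  total <- fixture_selection(fx, include = c("green", "yellow_brown"),
                             name = "total")
  subset <- fixture_selection(fx, include = "yellow_brown", name = "yb")

  single <- run_ratio_batch(list.files(early, full.names = TRUE),
                            total, subset)
  expect_equal(nrow(single), 3L)
  expect_equal(single$ratio[single$id == "plant_a"], 0.10)
  expect_equal(single$ratio[single$id == "plant_c"], 0.50)

  paired <- run_ratio_batch(list.files(early, full.names = TRUE),
                            total, subset,
                            late = list.files(late, full.names = TRUE))
  expect_equal(paired$id, c("plant_a", "plant_b", "plant_c"))
  a <- paired[paired$id == "plant_a", ]
  expect_equal(a$delta, 0.25)
  expect_equal(a$status, "ok")
  expect_equal(paired$delta[paired$id == "plant_b"], 0)
  expect_equal(paired$status[paired$id == "plant_c"], "unpaired")
})

test_that("the CLI drives fixtures, classify, ratio and inspect end-to-end", {
  dir <- withr::local_tempdir()
  fdir <- file.path(dir, "fx")
  suppressMessages(coverage_cli(c("fixtures", "--kind", "calibration_grid",
                                  "--seed", "5", "--out", fdir)))
  bmp <- file.path(fdir, "calibration_grid.bmp")
  expect_true(file.exists(bmp))
  expect_true(file.exists(file.path(fdir, "calibration_grid_truth.json")))

  selfile <- file.path(dir, "sel.json")
  save_selection(selection("squares", include = "#3C3C3C",
                           ignore = "#FFFFFF", tolerance = 35), selfile)
  out_csv <- file.path(dir, "res.csv")
  suppressMessages(coverage_cli(c("classify", "--selection", selfile,
                                  "--out", out_csv, bmp)))
  tab <- utils::read.csv(out_csv)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$c, 10000)
  expect_equal(tab$area_cm2, 1)

  # tolerance override propagates: at tolerance 0 nothing is classified
  suppressMessages(coverage_cli(c("classify", "--selection", selfile,
                                  "--tolerance", "0", "--out", out_csv, bmp)))
  expect_equal(utils::read.csv(out_csv)$c, 0)

  txt <- capture.output(coverage_cli(c("inspect", "--selection", selfile, bmp)))
  expect_match(paste(txt, collapse = "\n"), "C\\*100/\\(N-I\\)")
  expect_match(paste(txt, collapse = "\n"), "1.00 cm")

  expect_error(coverage_cli(c("nonsense")), "unknown command")
  expect_output(coverage_cli(character()), "usage:")
})
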