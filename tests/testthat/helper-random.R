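# Programmatic fixtures for property-style tests.

random_raster <- function(width, height, dpi = NULL) {
  raster_rgb(array(sample(0:255, height * width * 3L, replace = TRUE),
                   dim = c(height, width, 3L)),
             dpi = dpi)
}

random_color <- function() sample(0:255, 3L)

random_selection <- function(metric = sample(c("rgb", "ycbcr"), 1L),
                             tolerance = stats::runif(1, 0, 100),
                             n_include = sample(1:10, 1L),
                             n_ignore = sample(0:10, 1L)) {
  selection(paste0("rand-", paste(sample(letters, 6L), collapse = "")),
            include = replicate(n_include, random_color(), simplify = FALSE),
            ignore = if (n_ignore > 0)
              replicate(n_ignore, random_color(), simplify = FALSE),
            metric = metric, tolerance = tolerance)
}

mask_counts <- function(mask) {
  m <- unclass(mask)
  list(n = length(m), c = sum(m == 1L), i = sum(m == 2L), b = sum(m == 3L))
}
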