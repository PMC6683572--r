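# Independent brute-force classification oracle: a naive per-pixel double
# loop written from the defining formulas, deliberately sharing no code with
# the package's vectorized path.

oracle_ycc <- function(v) {
  y  <- 0.299 * v[1] + 0.587 * v[2] + 0.114 * v[3]
  cb <- 128 - 0.168736 * v[1] - 0.331264 * v[2] + 0.5 * v[3]
  cr <- 128 + 0.5 * v[1] - 0.418688 * v[2] - 0.081312 * v[3]
  out <- c(y, cb, cr)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

# Per-pixel minimum squared measures to the include and ignore channel sets.
# Returns h x w matrices di and dg (Inf where a channel set is empty).
oracle_measures <- function(img, sel) {
  d <- dim(img$pixels)
  h <- d[1]; w <- d[2]
  inc <- sel$include; ign <- sel$ignore
  if (sel$metric == "ycbcr") {
    inc_c <- lapply(seq_len(nrow(inc)), function(j) oracle_ycc(as.numeric(inc[j, ])))
    ign_c <- lapply(seq_len(nrow(ign)), function(j) oracle_ycc(as.numeric(ign[j, ])))
  }
  di <- matrix(Inf, h, w)
  dg <- matrix(Inf, h, w)
  for (yy in seq_len(h)) for (xx in seq_len(w)) {
    p <- as.numeric(img$pixels[yy, xx, ])
    if (sel$metric == "rgb") {
      for (j in seq_len(nrow(inc))) {
        m <- (p[1] - inc[j, 1])^2 + (p[2] - inc[j, 2])^2 + (p[3] - inc[j, 3])^2
        if (m < di[yy, xx]) di[yy, xx] <- m
      }
      for (j in seq_len(nrow(ign))) {
        m <- (p[1] - ign[j, 1])^2 + (p[2] - ign[j, 2])^2 + (p[3] - ign[j, 3])^2
        if (m < dg[yy, xx]) dg[yy, xx] <- m
      }
    } else {
      pc <- oracle_ycc(p)
      for (q in inc_c) {
        m <- (pc[2] - q[2])^2 + (pc[3] - q[3])^2 + (pc[1] - q[1])^2 / 9
        if (m < di[yy, xx]) di[yy, xx] <- m
      }
      for (q in ign_c) {
        m <- (pc[2] - q[2])^2 + (pc[3] - q[3])^2 + (pc[1] - q[1])^2 / 9
        if (m < dg[yy, xx]) dg[yy, xx] <- m
      }
    }
  }
  list(di = di, dg = dg)
}

# Labels from oracle measures: 1 foreground, 2 ignored, 3 background.
oracle_labels <- function(meas, tolerance, conflict = "nearest") {
  t2 <- tolerance^2
  ni <- meas$di < t2
  ng <- meas$dg < t2
  fg <- switch(conflict,
    nearest = ni & (!ng | meas$di < meas$dg),
    "ignore-wins" = ni & !ng,
    "include-wins" = ni)
  lab <- matrix(3L, nrow(meas$di), ncol(meas$di))
  lab[ng & !fg] <- 2L
  lab[fg] <- 1L
  lab
}

oracle_classify <- function(img, sel, conflict = "nearest") {
  oracle_labels(oracle_measures(img, sel), sel$tolerance, conflict)
}
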