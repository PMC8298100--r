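# Independent oracles and fixture builders shared across tests.

# rasterize a disc: pixel center (r, c) is foreground iff within radius
raster_disc <- function(radius, size = ceiling(2 * radius) + 8, center = NULL) {
  center <- center %||% ((size + 1) / 2 + 0.3)  # off-lattice center
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  (rr - center)^2 + (cc - center)^2 <= radius^2
}

raster_square <- function(side, pad = 10) {
  m <- matrix(FALSE, side + 2 * pad, side + 2 * pad)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# regular n-gon approximating an ellipse with semi-axes a, b
ellipse_polygon <- function(a, b, n = 360, rotate = 0, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(th); y0 <- b * sin(th)
  x <- center[1] + x0 * cos(rotate) - y0 * sin(rotate)
  y <- center[2] + x0 * sin(rotate) + y0 * cos(rotate)
  list(x = x, y = y)
}

# straight track at speed v along angle theta, n_steps steps of dt minutes
straight_track <- function(v = 1, dt = 1, n_steps = 10, theta = 0) {
  t <- seq(0, by = dt, length.out = n_steps + 1)
  data.frame(t = t, x = v * t * cos(theta), y = v * t * sin(theta))
}

# adjusted Rand index (closed form from the pair-counting contingency table)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# plain percentile bootstrap interval replicating the BCa resampling stream
with_seed_boot_percentile <- function(g, ctrl, n_boot, seed, level = 0.95) {
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  bg <- colMeans(matrix(sample(g, length(g) * n_boot, replace = TRUE), length(g)))
  bc <- colMeans(matrix(sample(ctrl, length(ctrl) * n_boot, replace = TRUE), length(ctrl)))
  quantile(bg - bc, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
}

# brute-force spatiotemporal variance: explicit loops, no shared code path
brute_st_variance <- function(arr, rois) {
  means <- sapply(seq_len(dim(arr)[3]), function(t) mean(arr[, , t]))
  norm <- arr
  for (t in seq_len(dim(arr)[3])) norm[, , t] <- arr[, , t] / means[t]
  vals <- c()
  for (r in rois) {
    for (row in (r[["y"]] + 1):(r[["y"]] + r[["height"]])) {
      for (col in (r[["x"]] + 1):(r[["x"]] + r[["width"]])) {
        vals <- c(vals, var(norm[row, col, ]))
      }
    }
  }
  mean(vals)
}
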