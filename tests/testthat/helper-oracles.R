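# Independent brute-force oracles used to cross-check the package's
# vectorized implementations on small instances.

# pooled-variance two-sample t by the textbook formula
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tval, p = 2 * pt(abs(tval), df, lower.tail = FALSE), df = df)
}

# Benjamini-Hochberg step-up by explicit enumeration over all ranks
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# trapezoidal area at unit spacing
oracle_trapz <- function(v) sum((v[-1] + v[-length(v)]) / 2)

# direct (non-separable) normalized 3D Gaussian convolution with the
# same per-axis truncation and normalization conventions as the package
oracle_smooth3d <- function(arr, fwhm_mm, voxel_size, mask) {
  sigma <- fwhm_mm / voxel_size / (2 * sqrt(2 * log(2)))
  k1 <- lapply(sigma, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- dnorm(-r:r, sd = s)
    k / sum(k)
  })
  r <- vapply(k1, function(k) (length(k) - 1L) %/% 2L, 0L)
  d <- dim(arr)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    num <- 0; den <- 0
    for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      w <- k1[[1]][di + r[1] + 1] * k1[[2]][dj + r[2] + 1] *
        k1[[3]][dk + r[3] + 1]
      if (mask[ii, jj, kk]) {
        num <- num + w * arr[ii, jj, kk]
        den <- den + w
      }
    }
    out[i, j, k] <- num / den
  }
  out
}

# small test geometry: 8x8x4 grid with three disjoint box regions
tiny_geometry <- function() {
  phantom_geometry(
    grid_dims = c(8L, 8L, 4L), voxel_size = c(0.5, 0.5, 1),
    regions = data.frame(
      region = c("R1", "R2", "R3"),
      x0 = c(2, 6, 2), x1 = c(3, 7, 3),
      y0 = c(2, 2, 6), y1 = c(3, 3, 7),
      z0 = c(2, 2, 2), z1 = c(3, 3, 3),
      hemisphere = c("midline", "right", "left"),
      stringsAsFactors = FALSE))
}

tiny_timeline <- function() bold_timeline(n_volumes = 30L, baseline = c(3L, 10L),
                                          activation = c(20L, 30L),
                                          injection_after = 10L)

tiny_cohort <- function(n_subjects = 2L, sigma_frac = 0.01, base_seed = 7L,
                        a = c(0.05, 0.03), regions = c("R1", "R2")) {
  cohort_spec("TINY", n_subjects,
              response_spec(regions, a = a, b = 0.8, c = 22),
              noise = noise_spec(sigma_frac = sigma_frac),
              timeline = tiny_timeline(), geometry = tiny_geometry(),
              base_seed = base_seed)
}

# forward-generate a noiseless/noisy ROI series from the sigmoid model
forward_series <- function(a, b, c, n = 65, d = 1, sd = 0) {
  y <- sigmoid_response(seq_len(n), a, b, c, d = d)
  if (sd > 0) y <- y + rnorm(n, sd = sd)
  y
}

make_run <- function(data, voxel_size = c(1, 1, 1)) {
  bold_run(data, voxel_size)
}
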