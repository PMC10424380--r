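#' Baseline normalization of a BOLD run
#'
#' `percent_change()` expresses every voxel time series as percent
#' change from its baseline-window mean `B`:
#' `out[v, t] = 100 * (S[v, t] - B[v]) / B[v]`. `ratio_normalize()`
#' divides by the baseline instead (`out = S / B`), so the two scales
#' are related exactly by `ratio = 1 + percent / 100`. The baseline is
#' the per-voxel mean intensity over the timeline's baseline window
#' (scans 5-25 by default).
#'
#' @param run A [bold_run()].
#' @param timeline A [bold_timeline()].
#' @param mask Optional 3D logical array; voxels outside it are set to
#'   `NA` and excluded from all downstream statistics. The baseline must
#'   be strictly positive at every in-mask voxel.
#' @return An object of class `normalized_run`: list with `data`
#'   (4D array on the requested scale), `scale` (`"percent"` or
#'   `"ratio"`), `baseline_map` (3D array of per-voxel baselines),
#'   `mask`, `timeline`, `voxel_size` and the run's metadata.
#' @export
percent_change <- function(run, timeline = default_timeline(), mask = NULL) {
  normalize_run(run, timeline, mask, scale = "percent")
}

#' @rdname percent_change
#' @export
ratio_normalize <- function(run, timeline = default_timeline(), mask = NULL) {
  normalize_run(run, timeline, mask, scale = "ratio")
}

normalize_run <- function(run, timeline, mask, scale) {
  stopifnot(inherits(run, "bold_run"), inherits(timeline, "bold_timeline"))
  d <- dim(run$data)
  if (d[4] != timeline$n_volumes)
    stop("run has ", d[4], " volumes but timeline expects ",
         timeline$n_volumes)
  mask <- check_mask(mask, d[1:3])
  nvox <- prod(d[1:3])
  m <- matrix(run$data, nvox, d[4])
  B <- rowMeans(m[, window_indices(timeline, "baseline"), drop = FALSE])
  bad <- mask & (B <= 0 | !is.finite(B))
  if (any(bad))
    stop(sum(bad), " in-mask voxel(s) have non-positive baseline mean")
  out <- if (scale == "percent") 100 * (m - B) / B else m / B
  out[!mask, ] <- NA_real_
  structure(list(data = array(out, d), scale = scale,
                 baseline_map = array(B, d[1:3]),
                 mask = array(mask, d[1:3]), timeline = timeline,
                 voxel_size = run$voxel_size, subject = run$subject,
                 condition = run$condition, genotype = run$genotype),
            class = "normalized_run")
}

#' Convert a normalized run between percent and ratio scales
#'
#' The conversion is the exact algebraic identity
#' `ratio = 1 + percent / 100`.
#'
#' @param norm A `normalized_run`.
#' @param to Target scale, `"percent"` or `"ratio"`.
#' @return A `normalized_run` on the target scale.
#' @export
convert_scale <- function(norm, to = c("percent", "ratio")) {
  stopifnot(inherits(norm, "normalized_run"))
  to <- match.arg(to)
  if (norm$scale == to) return(norm)
  norm$data <- if (to == "ratio") 1 + norm$data / 100 else
    100 * (norm$data - 1)
  norm$scale <- to
  norm
}

#' @export
print.normalized_run <- function(x, ...) {
  cat(sprintf("<normalized_run> %s; scale %s; subject %s, condition %s\n",
              paste(dim(x$data), collapse = "x"), x$scale, x$subject,
              x$condition))
  invisible(x)
}

#' Mask-aware Gaussian spatial smoothing
#'
#' Smooths each volume with a separable 3D Gaussian kernel of the given
#' full width at half maximum (`sigma = FWHM / (2 sqrt(2 ln 2))` per
#' axis, kernel truncated at 4 sigma). Smoothing is mask-aware
#' (normalized convolution: the smoothed signal is divided by the
#' smoothed mask), so constant fields are preserved exactly even at
#' mask edges and no out-of-mask intensity bleeds in. `fwhm_mm = 0` on
#' an axis is the identity along that axis. The conventional kernel
#' width for this pipeline is twice the voxel size per axis, the
#' default when `fwhm_mm = NULL`.
#'
#' @param x A [bold_run()], `normalized_run`, or plain 3D/4D array.
#' @param fwhm_mm Full width at half maximum per axis, in mm (length 1
#'   or 3). `NULL` means twice the voxel size (objects only).
#' @param mask Optional 3D logical array; defaults to the run's stored
#'   mask or, failing that, the whole grid.
#' @param voxel_size Voxel dimensions in mm, required for plain arrays.
#' @return An object of the same type as `x`, smoothed volume by
#'   volume. Out-of-mask voxels are `NA`.
#' @export
smooth_fwhm <- function(x, fwhm_mm = NULL, mask = NULL, voxel_size = NULL) {
  if (inherits(x, "bold_run")) {
    if (is.null(fwhm_mm)) fwhm_mm <- 2 * x$voxel_size
    x$data <- gauss_smooth(x$data, fwhm_mm, x$voxel_size,
                           check_mask(mask, dim(x$data)[1:3]))
    return(x)
  }
  if (inherits(x, "normalized_run")) {
    if (is.null(fwhm_mm)) fwhm_mm <- 2 * x$voxel_size
    if (is.null(mask)) mask <- x$mask
    x$data <- gauss_smooth(x$data, fwhm_mm, x$voxel_size,
                           check_mask(mask, dim(x$data)[1:3]))
    return(x)
  }
  if (is.array(x)) {
    if (is.null(voxel_size))
      stop("'voxel_size' is required when smoothing a plain array")
    if (is.null(fwhm_mm))
      stop("'fwhm_mm' is required when smoothing a plain array")
    nd <- length(dim(x))
    if (!nd %in% c(3L, 4L)) stop("array must be 3D or 4D")
    sp <- dim(x)[1:3]
    return(gauss_smooth(x, fwhm_mm, voxel_size, check_mask(mask, sp)))
  }
  stop("cannot smooth object of class ", paste(class(x), collapse = "/"))
}

check_mask <- function(mask, spatial_dims) {
  if (is.null(mask)) return(array(TRUE, spatial_dims))
  if (!is.array(mask) || !identical(dim(mask), as.integer(spatial_dims)))
    stop("mask dims (", paste(dim(mask), collapse = "x"),
         ") do not match spatial dims (",
         paste(spatial_dims, collapse = "x"), ")")
  array(mask != 0 & !is.na(mask), spatial_dims)
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# banded convolution matrix with zero padding at the edges
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- seq.int(max(1L, i - r), min(n, i + r))
    K[i, j] <- kernel[j - i + r + 1L]
  }
  K
}

conv_axis <- function(arr, K, axis) {
  d <- dim(arr); nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

gauss_smooth <- function(arr, fwhm_mm, voxel_size, mask) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0))
    stop("'fwhm_mm' must be non-negative")
  if (all(fwhm_mm == 0)) {
    out <- arr
    if (!all(mask)) {
      if (length(dim(arr)) == 4L) {
        m <- matrix(out, prod(dim(arr)[1:3]), dim(arr)[4])
        m[!mask, ] <- NA_real_
        out <- array(m, dim(arr))
      } else out[!mask] <- NA_real_
    }
    return(out)
  }
  sigma <- fwhm_mm / voxel_size / (2 * sqrt(2 * log(2)))
  Ks <- lapply(1:3, function(ax) {
    if (sigma[ax] > 0) conv_matrix(dim(arr)[ax], gauss_kernel(sigma[ax]))
    else NULL
  })
  conv3 <- function(a) {
    for (ax in 1:3) if (!is.null(Ks[[ax]])) a <- conv_axis(a, Ks[[ax]], ax)
    a
  }
  w <- array(as.numeric(mask), dim(mask))
  den <- conv3(w)
  nd <- length(dim(arr))
  if (nd == 3L) {
    a0 <- arr; a0[!mask] <- 0
    out <- conv3(a0) / den
    out[!mask] <- NA_real_
    return(out)
  }
  nt <- dim(arr)[4]
  m <- matrix(arr, prod(dim(arr)[1:3]), nt)
  m[!mask, ] <- 0
  num <- conv3(array(m, dim(arr)))
  out <- num / array(rep(den, nt), dim(arr))
  m <- matrix(out, prod(dim(arr)[1:3]), nt)
  m[!mask, ] <- NA_real_
  array(m, dim(arr))
}

#' Flag out-of-mask voxels of a run
#'
#' Sets every voxel outside the brain mask to `NA` across all volumes,
#' so that downstream statistics are computed over in-mask voxels only.
#' In-mask values are untouched.
#'
#' @param run A [bold_run()] or `normalized_run`.
#' @param mask 3D logical array matching the run's spatial dims.
#' @return An object of the same class with out-of-mask voxels `NA`;
#'   `normalized_run` objects also store the mask.
#' @export
apply_brain_mask <- function(run, mask) {
  data <- if (inherits(run, "bold_run") || inherits(run, "normalized_run"))
    run$data else stop("'run' must be a bold_run or normalized_run")
  mask <- check_mask(mask, dim(data)[1:3])
  m <- matrix(data, prod(dim(data)[1:3]), dim(data)[4])
  m[!mask, ] <- NA_real_
  run$data <- array(m, dim(data))
  if (inherits(run, "normalized_run")) run$mask <- run$mask & mask
  else attr(run, "mask") <- mask
  run
}
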