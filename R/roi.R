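#' Extract the mean time course of an atlas region
#'
#' Unweighted mean over the region's in-mask voxels at every volume.
#'
#' @param norm A `normalized_run` (see [percent_change()]).
#' @param atlas A `phantom_atlas`.
#' @param region Region name present in the atlas table.
#' @return An object of class `roi_timecourse`: list with `region`,
#'   `values` (length `n_volumes`), `scale`, `subject`, `condition`,
#'   `genotype`, `n_voxels`, `timeline`.
#' @export
extract_roi_timecourse <- function(norm, atlas, region) {
  stopifnot(inherits(norm, "normalized_run"), inherits(atlas, "phantom_atlas"))
  d <- dim(norm$data)
  if (!identical(d[1:3], dim(atlas$labels)))
    stop("run dims (", paste(d[1:3], collapse = "x"),
         ") do not match atlas dims (",
         paste(dim(atlas$labels), collapse = "x"), ")")
  vox <- region_voxels(atlas, region)
  vox <- vox[norm$mask[vox]]
  if (!length(vox))
    stop("region '", region, "' has no in-mask voxels")
  m <- matrix(norm$data, prod(d[1:3]), d[4])
  structure(list(region = region, values = colMeans(m[vox, , drop = FALSE]),
                 scale = norm$scale, subject = norm$subject,
                 condition = norm$condition, genotype = norm$genotype,
                 n_voxels = length(vox), timeline = norm$timeline),
            class = "roi_timecourse")
}

#' @export
print.roi_timecourse <- function(x, ...) {
  cat(sprintf("<roi_timecourse> %s (%d voxels); %d volumes on %s scale\n",
              x$region, x$n_voxels, length(x$values), x$scale))
  invisible(x)
}

#' Fit the sigmoid response model to an ROI time course
#'
#' Least-squares fit of `f(x) = d + a / (1 + exp(b (c - x)))` over
#' `x = 1..n_volumes`, with the offset `d` fixed by the scale (1 on the
#' ratio scale, 0 on the percent scale) unless `free_offset = TRUE`.
#' The rate `b` is constrained positive, so the sign of the response is
#' carried entirely by the increase value `a`. The fit uses all volumes
#' (the pre-injection plateau anchors the offset). Starting values:
#' `a0` = activation-window mean minus baseline-window mean, `c0` = the
#' first scan where the series crosses `d + a0/2` (falling back to the
#' midpoint between injection and the activation window), `b0 = 1`.
#'
#' Because the percent and ratio scales are related by an exact affine
#' map, the fitted increase value satisfies
#' `a_percent = 100 * a_ratio`.
#'
#' @param tc A `roi_timecourse`, or a numeric vector of values (then
#'   `scale` must be given).
#' @param timeline A [bold_timeline()]; defaults to the time course's.
#' @param scale `"ratio"` or `"percent"`; only used for numeric input.
#' @param free_offset Also estimate the offset `d` (default fixed).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `sigmoid_fit`: `a`, `b`, `c`, `d`, `rss`,
#'   `converged`, `n_points`, `scale`, `region`, `subject`,
#'   `condition`, `message`, and `fitted` values. Non-convergence is
#'   reported via `converged = FALSE`, never as silent `NaN`.
#' @export
fit_sigmoid <- function(tc, timeline = NULL, scale = NULL,
                        free_offset = FALSE, max_iter = 200L) {
  if (inherits(tc, "roi_timecourse")) {
    y <- tc$values
    if (is.null(scale)) scale <- tc$scale
    if (is.null(timeline)) timeline <- tc$timeline
    region <- tc$region; subject <- tc$subject; condition <- tc$condition
  } else if (is.numeric(tc)) {
    y <- as.numeric(tc)
    if (is.null(scale)) stop("'scale' is required for numeric input")
    region <- NA_character_; subject <- NA; condition <- NA_character_
  } else stop("'tc' must be a roi_timecourse or numeric vector")
  scale <- match.arg(scale, c("ratio", "percent"))
  if (is.null(timeline)) timeline <- default_timeline()
  n <- length(y)
  if (n < 6L) stop("need at least 6 time points to fit the sigmoid")
  if (n != timeline$n_volumes)
    stop("series length ", n, " does not match timeline n_volumes ",
         timeline$n_volumes)
  if (any(!is.finite(y))) stop("time course contains non-finite values")
  x <- seq_len(n)
  d0 <- if (scale == "ratio") 1 else 0

  a0 <- mean(y[window_indices(timeline, "activation")]) -
    mean(y[window_indices(timeline, "baseline")])
  dstart <- if (free_offset) mean(y[window_indices(timeline, "baseline")])
            else d0
  half <- dstart + a0 / 2
  # the response can only start after the injection, so search the
  # half-rise crossing there; noise before it would fool the search
  post <- x[x > timeline$injection_after]
  c0 <- if (a0 > 0) post[which(y[post] >= half)[1]] else
    post[which(y[post] <= half)[1]]
  c_fallback <- (timeline$injection_after + timeline$activation[1]) / 2
  if (is.na(c0)) c0 <- c_fallback

  out <- list(a = NA_real_, b = NA_real_, c = NA_real_, d = dstart,
              rss = NA_real_, converged = FALSE, n_points = n,
              scale = scale, region = region, subject = subject,
              condition = condition, message = "", fitted = NULL)

  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    # flat series: the rise is unidentifiable, amplitude is zero
    out$a <- 0; out$b <- 1; out$c <- c0
    out$d <- if (free_offset) mean(y) else d0
    out$rss <- sum((y - out$d)^2)
    out$converged <- TRUE
    out$message <- "degenerate flat series"
    out$fitted <- rep(out$d, n)
    return(structure(out, class = "sigmoid_fit"))
  }

  df <- data.frame(x = x, y = y)
  try_fit <- function(b_start, c_start) tryCatch({
    if (free_offset)
      minpack.lm::nlsLM(
        y ~ d + a / (1 + exp(b * (cc - x))), data = df,
        start = list(a = a0, b = b_start, cc = c_start, d = dstart),
        lower = c(a = -Inf, b = 1e-6, cc = -Inf, d = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = max_iter))
    else
      minpack.lm::nlsLM(
        y - d0 ~ a / (1 + exp(b * (cc - x))), data = df,
        start = list(a = a0, b = b_start, cc = c_start),
        lower = c(a = -Inf, b = 1e-6, cc = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = max_iter))
  }, error = function(e) e)
  # degenerate starts can make the initial Jacobian singular; fall back
  # to coarser rate/midpoint guesses before reporting failure
  fit <- try_fit(1, c0)
  if (inherits(fit, "error")) fit <- try_fit(1, c_fallback)
  if (inherits(fit, "error")) fit <- try_fit(0.5, c_fallback)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(structure(out, class = "sigmoid_fit"))
  }
  cf <- stats::coef(fit)
  out$a <- unname(cf["a"]); out$b <- unname(cf["b"])
  out$c <- unname(cf["cc"])
  out$d <- if (free_offset) unname(cf["d"]) else d0
  out$fitted <- out$d + out$a / (1 + exp(out$b * (out$c - x)))
  out$rss <- sum((y - out$fitted)^2)
  out$converged <- isTRUE(fit$convInfo$isConv) &&
    all(is.finite(c(out$a, out$b, out$c, out$d)))
  out$message <- fit$convInfo$stopMessage %||% ""
  structure(out, class = "sigmoid_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> %s [%s]: a=%.5g b=%.4g c=%.4g d=%g rss=%.3g (%s)\n",
    x$region, x$scale, x$a, x$b, x$c, x$d, x$rss,
    if (x$converged) "converged" else paste("NOT converged:", x$message)))
  invisible(x)
}

#' Pairwise comparison matrix of increase values
#'
#' Two-sided pooled-variance two-sample t-tests on the fitted increase
#' values of every unordered pair of regions, as used to rank regional
#' response amplitudes. Significance stars mark p < 0.05 (`*`) and
#' p < 0.01 (`**`); no multiplicity correction is applied by default.
#'
#' @param values_by_region Named list: region -> numeric vector of
#'   increase values across subjects (>= 2 each).
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] over the upper triangle (default `"none"`).
#' @return An object of class `comparison_matrix`: `regions`, square
#'   matrices `t` and `p` (diagonal `NA`), `stars` (character matrix),
#'   `mean_increase`, `n`.
#' @export
comparison_matrix <- function(values_by_region, p_adjust = "none") {
  if (!is.list(values_by_region) || is.null(names(values_by_region)) ||
      any(names(values_by_region) == ""))
    stop("'values_by_region' must be a named list of numeric vectors")
  regions <- names(values_by_region)
  for (r in regions) {
    v <- values_by_region[[r]]
    if (!is.numeric(v) || sum(is.finite(v)) < 2L)
      stop("region '", r, "' has fewer than 2 increase values")
  }
  k <- length(regions)
  tmat <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  pmat <- tmat
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        tt <- stats::t.test(values_by_region[[i]], values_by_region[[j]],
                            var.equal = TRUE)
        tmat[i, j] <- unname(tt$statistic); tmat[j, i] <- -tmat[i, j]
        pmat[i, j] <- pmat[j, i] <- tt$p.value
      }
    }
    if (p_adjust != "none") {
      up <- upper.tri(pmat)
      pmat[up] <- stats::p.adjust(pmat[up], method = p_adjust)
      pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    }
  }
  stars <- matrix("", k, k, dimnames = list(regions, regions))
  stars[!is.na(pmat) & pmat < 0.05] <- "*"
  stars[!is.na(pmat) & pmat < 0.01] <- "**"
  structure(list(regions = regions, t = tmat, p = pmat, stars = stars,
                 mean_increase = vapply(values_by_region, mean, 0),
                 n = vapply(values_by_region, length, 0L),
                 p_adjust = p_adjust),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat("<comparison_matrix> mean increase values:\n")
  print(round(x$mean_increase, digits))
  cat("pairwise two-sided p-values (*: p<0.05, **: p<0.01):\n")
  pp <- format(round(x$p, digits))
  pp[] <- paste0(pp, x$stars)
  diag(pp) <- "-"
  print(pp, quote = FALSE)
  invisible(x)
}

#' Compare one region's increase values between two experiments
#'
#' Two-sided two-sample t-test on fitted increase values for the same
#' region under two different stimulations (e.g. dopaminergic vs
#' CamKII cohorts). Positive t means group A > group B.
#'
#' @param values_a,values_b Numeric vectors of increase values (>= 2
#'   each).
#' @param var_equal Pooled variance (default `TRUE`).
#' @return A list with `t`, `p`, `df`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
compare_conditions_increase <- function(values_a, values_b,
                                        var_equal = TRUE) {
  if (sum(is.finite(values_a)) < 2L || sum(is.finite(values_b)) < 2L)
    stop("each group needs >= 2 increase values")
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(values_a),
       mean_b = mean(values_b), n_a = length(values_a),
       n_b = length(values_b))
}

#' Heatmap of a comparison matrix
#'
#' Base-graphics rendering of the pairwise p-value matrix on a
#' -log10 color scale (warmer = more significant), mirroring the usual
#' presentation of regional increase-value comparisons.
#'
#' @param x A `comparison_matrix`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot_comparison_matrix <- function(x, ...) {
  stopifnot(inherits(x, "comparison_matrix"))
  k <- length(x$regions)
  z <- -log10(x$p)
  z[!is.finite(z)] <- NA
  graphics::image(seq_len(k), seq_len(k), z, axes = FALSE,
                  xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  graphics::axis(1, at = seq_len(k), labels = x$regions, las = 2)
  graphics::axis(2, at = seq_len(k), labels = x$regions, las = 2)
  graphics::box()
  invisible(x)
}
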