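#' Activation-phase AUC map
#'
#' Collapses a baseline-normalized run to a single 3D statistic per
#' voxel: the area under the time course over the activation-phase
#' window (volumes 45-65 by default), computed with the trapezoid rule
#' at unit scan spacing (21 samples, 20 intervals). A plain-sum
#' alternative is available. On the percent scale the units are
#' percent x scan.
#'
#' @param norm A `normalized_run` (see [percent_change()]).
#' @param timeline A [bold_timeline()]; defaults to the run's own.
#' @param rule Integration rule, `"trapezoid"` (default) or `"sum"`.
#' @return An object of class `auc_map`: list with `data` (3D array,
#'   `NA` out-of-mask), `rule`, `subject`, `condition`, `genotype`,
#'   `timeline`, `voxel_size`.
#' @export
auc_activation <- function(norm, timeline = NULL,
                           rule = c("trapezoid", "sum")) {
  stopifnot(inherits(norm, "normalized_run"))
  rule <- match.arg(rule)
  if (is.null(timeline)) timeline <- norm$timeline
  idx <- window_indices(timeline, "activation")
  d <- dim(norm$data)
  if (max(idx) > d[4])
    stop("activation window exceeds run length ", d[4])
  if (rule == "trapezoid" && length(idx) < 2L)
    stop("trapezoid rule needs an activation window of >= 2 volumes")
  m <- matrix(norm$data, prod(d[1:3]), d[4])[, idx, drop = FALSE]
  auc <- if (rule == "trapezoid")
    rowSums(m) - (m[, 1] + m[, ncol(m)]) / 2 else rowSums(m)
  structure(list(data = array(auc, d[1:3]), rule = rule,
                 subject = norm$subject, condition = norm$condition,
                 genotype = norm$genotype, timeline = timeline,
                 voxel_size = norm$voxel_size),
            class = "auc_map")
}

#' @export
print.auc_map <- function(x, ...) {
  cat(sprintf("<auc_map> %s; rule %s; subject %s, condition %s\n",
              paste(dim(x$data), collapse = "x"), x$rule, x$subject,
              x$condition))
  invisible(x)
}

maps_to_matrix <- function(maps) {
  arrs <- lapply(maps, function(m) {
    if (inherits(m, "auc_map")) m$data
    else if (is.array(m) && length(dim(m)) == 3L) m
    else stop("group maps must be auc_map objects or 3D arrays")
  })
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d))
    stop("group maps have mismatched dims")
  list(m = matrix(unlist(lapply(arrs, as.vector)), nrow = prod(d)),
       dims = d)
}

#' Voxel-wise two-sample t-test between groups of maps
#'
#' Compares group A (e.g. CNO) against group B (e.g. saline) voxel by
#' voxel. The default is the classical pooled-variance two-sample
#' t-test with `df = n_A + n_B - 2` and two-sided p-values; Welch and
#' paired (one-sample on A - B differences) designs are available.
#' Positive t means A > B. Voxels with zero pooled variance get `NA`
#' statistics; their count is reported, not raised as an error.
#'
#' @param maps_a,maps_b Lists of `auc_map` objects or 3D arrays; groups
#'   need >= 2 maps each, and paired designs equal lengths.
#' @param paired One-sample test on paired differences A - B.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @return An object of class `group_stat_map`: `t`, `p` (3D arrays),
#'   `df` (scalar, or 3D array for Welch), `n_a`, `n_b`,
#'   `n_zero_variance`, `paired`, `var_equal`, `voxel_size`.
#' @export
group_ttest <- function(maps_a, maps_b, paired = FALSE, var_equal = TRUE) {
  A <- maps_to_matrix(maps_a); B <- maps_to_matrix(maps_b)
  if (!identical(A$dims, B$dims)) stop("group maps have mismatched dims")
  na <- ncol(A$m); nb <- ncol(B$m)
  if (paired && na != nb) stop("paired design needs equal group sizes")
  if (na < 2L || nb < 2L) stop("each group needs >= 2 maps")
  vox <- if (inherits(maps_a[[1]], "auc_map")) maps_a[[1]]$voxel_size else NULL
  if (paired) {
    D <- A$m - B$m
    mD <- rowMeans(D)
    vD <- rowSums((D - mD)^2) / (na - 1)
    zero <- is.finite(vD) & vD == 0
    se <- sqrt(vD / na)
    tval <- mD / se
    df <- na - 1
  } else {
    mA <- rowMeans(A$m); mB <- rowMeans(B$m)
    vA <- rowSums((A$m - mA)^2) / (na - 1)
    vB <- rowSums((B$m - mB)^2) / (nb - 1)
    if (var_equal) {
      sp2 <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
      zero <- is.finite(sp2) & sp2 == 0
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se2 <- vA / na + vB / nb
      zero <- is.finite(se2) & se2 == 0
      se <- sqrt(se2)
      df <- se2^2 / ((vA / na)^2 / (na - 1) + (vB / nb)^2 / (nb - 1))
    }
    tval <- (mA - mB) / se
  }
  tval[zero] <- NA_real_
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  dfout <- if (length(df) > 1L) array(df, A$dims) else df
  structure(list(t = array(tval, A$dims), p = array(p, A$dims),
                 df = dfout, n_a = na, n_b = nb,
                 n_zero_variance = sum(zero), paired = paired,
                 var_equal = var_equal, voxel_size = vox),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf(
    "<group_stat_map> %s; n=%d vs %d (%s%s); %d zero-variance voxel(s)\n",
    paste(dim(x$t), collapse = "x"), x$n_a, x$n_b,
    if (x$paired) "paired" else "unpaired",
    if (x$var_equal) ", pooled" else ", Welch", x$n_zero_variance))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment of a collection of p-values:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, with rejection
#' where `q <= alpha`. `NA` p-values (out-of-mask or zero-variance
#' voxels) are excluded from the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values in [0, 1] (may contain `NA`).
#' @param alpha FDR level in (0, 1).
#' @return A list with `q` (adjusted p-values, same length/order as
#'   `p`), `reject` (logical), `alpha`, and `m` (family size).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  ok <- !is.na(p)
  if (!any(ok)) stop("empty p-value collection")
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha, alpha = alpha, m = sum(ok))
}

new_threshold_mask <- function(data, rule, level, extra = list()) {
  structure(c(list(data = data, rule = rule, level = level), extra),
            class = "threshold_mask")
}

#' Threshold a group map by FDR-corrected q-values
#'
#' Applies [bh_fdr()] over the in-mask voxels of a [group_ttest()] map
#' and marks voxels with `q <= alpha` (by default only those with
#' positive t, matching activation maps that report positive
#' responses).
#'
#' @param stat A `group_stat_map`.
#' @param alpha FDR level (default 0.05).
#' @param mask Optional 3D logical brain mask restricting the family of
#'   tests.
#' @param positive_only Keep only voxels with t > 0 (default `TRUE`).
#' @return An object of class `threshold_mask` with fields `data`
#'   (3D logical), `rule = "fdr"`, `level`, and `q` (3D array of
#'   q-values, `NA` outside the family).
#' @export
threshold_fdr <- function(stat, alpha = 0.05, mask = NULL,
                          positive_only = TRUE) {
  stopifnot(inherits(stat, "group_stat_map"))
  mask <- check_mask(mask, dim(stat$p))
  p <- as.vector(stat$p)
  p[!mask] <- NA_real_
  if (!any(!is.na(p))) stop("empty mask: no voxels to test")
  fdr <- bh_fdr(p, alpha)
  sel <- fdr$reject
  if (positive_only) sel <- sel & !is.na(stat$t) & as.vector(stat$t) > 0
  new_threshold_mask(array(sel, dim(stat$p)), "fdr", alpha,
                     list(q = array(fdr$q, dim(stat$p)),
                          positive_only = positive_only))
}

#' Threshold a group map at an uncorrected p-value
#'
#' Marks voxels with two-sided `p < p_level` (strict) and, by default,
#' positive t.
#'
#' @param stat A `group_stat_map`.
#' @param p_level Uncorrected threshold in (0, 1) (default 0.001).
#' @param mask Optional 3D logical brain mask.
#' @param positive_only Keep only voxels with t > 0 (default `TRUE`).
#' @return A `threshold_mask` with `rule = "uncorrected"`.
#' @export
threshold_uncorrected <- function(stat, p_level = 0.001, mask = NULL,
                                  positive_only = TRUE) {
  stopifnot(inherits(stat, "group_stat_map"))
  if (!is.finite(p_level) || p_level <= 0 || p_level >= 1)
    stop("'p_level' must lie in (0, 1)")
  mask <- check_mask(mask, dim(stat$p))
  sel <- !is.na(stat$p) & stat$p < p_level & mask
  if (positive_only) sel <- sel & !is.na(stat$t) & stat$t > 0
  new_threshold_mask(array(sel, dim(stat$p)), "uncorrected", p_level,
                     list(positive_only = positive_only))
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("<threshold_mask> rule %s at %g; %d voxel(s) marked\n",
              x$rule, x$level, sum(x$data)))
  invisible(x)
}

#' Per-region summary of a thresholded map
#'
#' Counts, for every atlas region, how many of its voxels are marked
#' significant and what fraction of the region that represents.
#'
#' @param mask A `threshold_mask` (or 3D logical array).
#' @param atlas A `phantom_atlas`.
#' @return A data frame with columns `region`, `n_voxels_region`,
#'   `n_significant`, `fraction_of_region`.
#' @export
summarize_regions <- function(mask, atlas) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  sel <- if (inherits(mask, "threshold_mask")) mask$data else mask
  if (!is.array(sel) || !identical(dim(sel), dim(atlas$labels)))
    stop("mask dims (", paste(dim(sel), collapse = "x"),
         ") do not match atlas dims (",
         paste(dim(atlas$labels), collapse = "x"), ")")
  tab <- atlas$table
  out <- data.frame(region = tab$region_name,
                    n_voxels_region = NA_integer_,
                    n_significant = NA_integer_,
                    fraction_of_region = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    vox <- atlas$labels == tab$label[i]
    out$n_voxels_region[i] <- sum(vox)
    out$n_significant[i] <- sum(sel[vox], na.rm = TRUE)
    out$fraction_of_region[i] <- out$n_significant[i] / out$n_voxels_region[i]
  }
  out
}
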