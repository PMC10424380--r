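#' Configuration for the end-to-end pipeline
#'
#' Validates and bundles all analysis knobs: the scan timeline,
#' smoothing, the AUC integration rule, the group-test design, the
#' corrected and uncorrected thresholds, the scale used for sigmoid
#' fitting, which thresholded map feeds the conjunction, the two
#' cohorts to simulate (or `NULL` to analyze existing cohort
#' directories), the output directory and the master seed. All levels
#' are validated before any computation runs.
#'
#' @param out_dir Output directory for all written artifacts.
#' @param seed Master integer seed; every source of randomness in the
#'   pipeline derives from it.
#' @param cohort_a,cohort_b [cohort_spec()]s to simulate; defaults are
#'   the dopaminergic-like and CamKII-like cohorts.
#' @param smooth Apply spatial smoothing before the AUC map.
#' @param fwhm_factor Kernel FWHM as a multiple of the voxel size.
#' @param auc_rule `"trapezoid"` or `"sum"`.
#' @param paired Paired CNO-vs-saline group test (default unpaired).
#' @param var_equal Pooled variance (default) or Welch.
#' @param alpha_fdr FDR-corrected map level, in (0, 1).
#' @param p_uncorrected Uncorrected map level, in (0, 1).
#' @param fit_scale Scale for sigmoid fitting, `"ratio"` or
#'   `"percent"`.
#' @param conjunction_rule Which mask feeds the conjunction:
#'   `"uncorrected"` (default) or `"fdr"`.
#' @param roi_min_fraction Minimum significant fraction of a region
#'   (in the uncorrected map) for it to enter the ROI fitting stage.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cohort_a = NULL, cohort_b = NULL,
                            smooth = TRUE, fwhm_factor = 2,
                            auc_rule = c("trapezoid", "sum"),
                            paired = FALSE, var_equal = TRUE,
                            alpha_fdr = 0.05, p_uncorrected = 0.001,
                            fit_scale = c("ratio", "percent"),
                            conjunction_rule = c("uncorrected", "fdr"),
                            roi_min_fraction = 0.5) {
  auc_rule <- match.arg(auc_rule)
  fit_scale <- match.arg(fit_scale)
  conjunction_rule <- match.arg(conjunction_rule)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  for (lv in c(alpha_fdr = alpha_fdr, p_uncorrected = p_uncorrected)) {
    if (!is.finite(lv) || lv <= 0 || lv >= 1)
      stop("significance levels must lie in (0, 1)")
  }
  if (!is.finite(fwhm_factor) || fwhm_factor < 0)
    stop("'fwhm_factor' must be >= 0")
  if (!is.finite(roi_min_fraction) || roi_min_fraction < 0 ||
      roi_min_fraction > 1)
    stop("'roi_min_fraction' must lie in [0, 1]")
  if (is.null(cohort_a)) cohort_a <- dat_cohort_spec(base_seed = seed)
  if (is.null(cohort_b)) cohort_b <- camkii_cohort_spec(base_seed = seed)
  stopifnot(inherits(cohort_a, "cohort_spec"),
            inherits(cohort_b, "cohort_spec"))
  structure(list(out_dir = out_dir, seed = seed, cohort_a = cohort_a,
                 cohort_b = cohort_b, smooth = smooth,
                 fwhm_factor = fwhm_factor, auc_rule = auc_rule,
                 paired = paired, var_equal = var_equal,
                 alpha_fdr = alpha_fdr, p_uncorrected = p_uncorrected,
                 fit_scale = fit_scale,
                 conjunction_rule = conjunction_rule,
                 roi_min_fraction = roi_min_fraction),
            class = "pipeline_config")
}

analyze_cohort <- function(cohort, config, atlas, dir) {
  tl <- cohort$timeline
  mask <- atlas$mask
  fwhm <- config$fwhm_factor * cohort$geometry$voxel_size
  gen <- generate_cohort(cohort, dir)
  auc_by_cond <- list(CNO = list(), saline = list())
  roi_tc <- list()
  for (i in seq_len(nrow(gen$runs))) {
    rec <- gen$runs[i, ]
    run <- read_run(rec$file, subject = rec$subject,
                    condition = rec$condition, genotype = rec$genotype)
    norm <- percent_change(run, tl, mask = mask)
    if (config$smooth && config$fwhm_factor > 0)
      norm <- smooth_fwhm(norm, fwhm_mm = fwhm)
    auc_by_cond[[rec$condition]][[length(auc_by_cond[[rec$condition]]) + 1L]] <-
      auc_activation(norm, tl, rule = config$auc_rule)
    if (rec$condition == "CNO")
      roi_tc[[as.character(rec$subject)]] <-
        convert_scale(norm, config$fit_scale)
  }
  stat <- group_ttest(auc_by_cond$CNO, auc_by_cond$saline,
                      paired = config$paired, var_equal = config$var_equal)
  fdr_mask <- threshold_fdr(stat, config$alpha_fdr, mask = mask)
  unc_mask <- threshold_uncorrected(stat, config$p_uncorrected, mask = mask)
  summary_unc <- summarize_regions(unc_mask, atlas)
  summary_fdr <- summarize_regions(fdr_mask, atlas)

  active <- summary_unc$region[
    summary_unc$fraction_of_region >= config$roi_min_fraction]
  fits <- list()
  for (region in active) {
    for (sub in names(roi_tc)) {
      tc <- extract_roi_timecourse(roi_tc[[sub]], atlas, region)
      ft <- fit_sigmoid(tc)
      fits[[length(fits) + 1L]] <- data.frame(
        genotype = cohort$genotype, subject = as.integer(sub),
        region = region, a = ft$a, b = ft$b, c = ft$c, d = ft$d,
        rss = ft$rss, converged = ft$converged, n_voxels = tc$n_voxels,
        stringsAsFactors = FALSE)
    }
  }
  fits <- if (length(fits)) do.call(rbind, fits) else NULL
  cmp <- NULL
  if (!is.null(fits) && length(active) >= 2L) {
    vals <- split(fits$a, fits$region)[active]
    cmp <- comparison_matrix(vals)
  }
  list(genotype = cohort$genotype, manifest = gen$runs, truth = gen$truth,
       stat = stat, fdr_mask = fdr_mask, unc_mask = unc_mask,
       summary_fdr = summary_fdr, summary_unc = summary_unc,
       active_regions = active, fits = fits, comparison = cmp)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> activation map -> ROI response ->
#' conjunction -> report for the two cohorts of a
#' [pipeline_config()]: generates the phantom cohorts, normalizes and
#' (optionally) smooths every run, builds per-subject AUC maps, tests
#' CNO vs saline voxel-wise, thresholds the maps (FDR-corrected and
#' uncorrected), summarizes per-region significance, fits the sigmoid
#' response to the active ROIs of each CNO run, builds the pairwise
#' comparison matrices, compares increase values across the two
#' cohorts for co-activated regions, and computes the conjunction map
#' with its region overlap report. Everything is deterministic given
#' the config and its seed; results and TSV/NIfTI artifacts are
#' written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a report list with per-cohort results (`a`,
#'   `b`), the `conjunction` map, `overlap_report`, `cross_genotype`
#'   increase-value comparisons, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  if (!identical(config$cohort_a$geometry$grid_dims,
                 config$cohort_b$geometry$grid_dims))
    stop("the two cohorts must share one grid geometry")
  atlas <- build_phantom_atlas(config$cohort_a$geometry)

  res_a <- analyze_cohort(config$cohort_a, config, atlas,
                          file.path(out, config$cohort_a$genotype))
  res_b <- analyze_cohort(config$cohort_b, config, atlas,
                          file.path(out, config$cohort_b$genotype))

  pick <- function(res) if (config$conjunction_rule == "fdr")
    res$fdr_mask else res$unc_mask
  conj <- conjunction(pick(res_a), pick(res_b),
                      label_a = res_a$genotype, label_b = res_b$genotype)
  overlap <- region_overlap_report(conj, atlas)

  cross <- NULL
  co_regions <- overlap$region[overlap$coactive]
  co_regions <- intersect(intersect(co_regions, res_a$active_regions),
                          res_b$active_regions)
  if (length(co_regions)) {
    rows <- lapply(co_regions, function(region) {
      va <- res_a$fits$a[res_a$fits$region == region]
      vb <- res_b$fits$a[res_b$fits$region == region]
      cc <- compare_conditions_increase(va, vb)
      data.frame(region = region, t = cc$t, p = cc$p, df = cc$df,
                 mean_a = cc$mean_a, mean_b = cc$mean_b,
                 n_a = cc$n_a, n_b = cc$n_b, stringsAsFactors = FALSE)
    })
    cross <- do.call(rbind, rows)
  }

  vox <- atlas$voxel_size
  for (res in list(res_a, res_b)) {
    g <- res$genotype
    write_map(res$stat$t, vox, file.path(out, paste0(g, "_tmap.nii.gz")))
    write_map(res$stat$p, vox, file.path(out, paste0(g, "_pmap.nii.gz")))
    write_map(res$fdr_mask$q, vox, file.path(out, paste0(g, "_qmap.nii.gz")))
    write_map(res$fdr_mask$data, vox,
              file.path(out, paste0(g, "_mask_fdr.nii.gz")))
    write_map(res$unc_mask$data, vox,
              file.path(out, paste0(g, "_mask_uncorrected.nii.gz")))
    write_tsv(res$summary_unc,
              file.path(out, paste0(g, "_regions_uncorrected.tsv")))
    write_tsv(res$summary_fdr, file.path(out, paste0(g, "_regions_fdr.tsv")))
    if (!is.null(res$fits))
      write_tsv(res$fits, file.path(out, paste0(g, "_fits.tsv")))
    if (!is.null(res$comparison)) {
      pm <- as.data.frame(res$comparison$p)
      pm <- cbind(region = rownames(pm), pm)
      write_tsv(pm, file.path(out, paste0(g, "_comparison_p.tsv")))
    }
  }
  write_map(conj$data, vox, file.path(out, "conjunction.nii.gz"))
  write_tsv(overlap, file.path(out, "overlap_report.tsv"))
  if (!is.null(cross)) write_tsv(cross, file.path(out, "cross_genotype.tsv"))
  jsonlite::write_json(config_log(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(a = res_a, b = res_b, conjunction = conj,
                 overlap_report = overlap, cross_genotype = cross,
                 atlas = atlas, config = config))
}

config_log <- function(config) {
  sum_cohort <- function(ch) list(
    genotype = ch$genotype, n_subjects = ch$n_subjects,
    base_seed = ch$base_seed, b0 = ch$b0,
    responses = ch$responses,
    noise = unclass(ch$noise),
    timeline = unclass(ch$timeline),
    grid_dims = ch$geometry$grid_dims,
    voxel_size = ch$geometry$voxel_size)
  list(seed = config$seed, smooth = config$smooth,
       fwhm_factor = config$fwhm_factor, auc_rule = config$auc_rule,
       paired = config$paired, var_equal = config$var_equal,
       alpha_fdr = config$alpha_fdr, p_uncorrected = config$p_uncorrected,
       fit_scale = config$fit_scale,
       conjunction_rule = config$conjunction_rule,
       roi_min_fraction = config$roi_min_fraction,
       cohort_a = sum_cohort(config$cohort_a),
       cohort_b = sum_cohort(config$cohort_b))
}
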