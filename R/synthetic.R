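#' Noise model for phantom runs
#'
#' Additive Gaussian voxel noise with optional linear scanner drift and
#' AR(1) temporal autocorrelation. `sigma_frac` is the noise standard
#' deviation as a fraction of the baseline intensity; `drift_frac` is
#' the linear drift amplitude accumulated over the full run, also as a
#' fraction of baseline; `ar1_rho` filters the noise to a stationary
#' AR(1) process with unit marginal variance.
#'
#' @param sigma_frac Noise SD / baseline intensity, >= 0.
#' @param drift_frac Linear drift over the whole run / baseline intensity.
#' @param ar1_rho AR(1) coefficient, |rho| < 1 (0 = white noise).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_frac = 0.01, drift_frac = 0, ar1_rho = 0) {
  if (!is.finite(sigma_frac) || sigma_frac < 0)
    stop("'sigma_frac' must be >= 0")
  if (!is.finite(drift_frac))
    stop("'drift_frac' must be finite")
  if (!is.finite(ar1_rho) || abs(ar1_rho) >= 1)
    stop("'ar1_rho' must satisfy |rho| < 1")
  structure(list(sigma_frac = sigma_frac, drift_frac = drift_frac,
                 ar1_rho = ar1_rho),
            class = "noise_spec")
}

#' Per-region true response parameters
#'
#' One row per responsive region of the sigmoid response planted under
#' the active (CNO) condition: plateau amplitude `a` (fraction of
#' baseline), rate `b` (per scan, > 0) and midpoint `c` (scan index).
#'
#' @param region Region names (character).
#' @param a,b,c Response parameters, recycled to `length(region)`.
#' @return A data frame with columns `region`, `a`, `b`, `c`.
#' @export
response_spec <- function(region, a, b = 0.8, c = 38) {
  df <- data.frame(region = as.character(region), a = a, b = b, c = c,
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$a)) || any(df$a < -1))
    stop("'a' must be finite and >= -1")
  if (any(!is.finite(df$b)) || any(df$b <= 0))
    stop("'b' must be > 0")
  if (any(!is.finite(df$c)))
    stop("'c' must be finite")
  df
}

#' Specification of one phantom cohort
#'
#' Describes a genotype cohort to simulate: number of subjects (each
#' scanned under both CNO and saline), the set of responsive regions
#' with their true sigmoid parameters, the noise model, the scan
#' timeline, the grid geometry and a base seed from which every run's
#' seed is derived deterministically.
#'
#' @param genotype Cohort label, e.g. `"DAT"`.
#' @param n_subjects Number of subjects, >= 2.
#' @param responses Data frame from [response_spec()].
#' @param noise A [noise_spec()].
#' @param timeline A [bold_timeline()].
#' @param geometry A [phantom_geometry()].
#' @param base_seed Integer base seed.
#' @param b0 Baseline signal intensity in arbitrary units (> 0).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(genotype, n_subjects, responses,
                        noise = noise_spec(),
                        timeline = default_timeline(),
                        geometry = default_phantom_geometry(),
                        base_seed = 1L, b0 = 1000) {
  stopifnot(inherits(noise, "noise_spec"),
            inherits(timeline, "bold_timeline"),
            inherits(geometry, "phantom_geometry"))
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("'n_subjects' must be >= 2 (group tests need at least 2 per group)")
  if (!is.finite(b0) || b0 <= 0)
    stop("'b0' must be a positive baseline intensity")
  missing_r <- setdiff(responses$region, geometry$regions$region)
  if (length(missing_r))
    stop("responsive regions not in geometry: ",
         paste(missing_r, collapse = ", "))
  if (any(responses$c < 1) || any(responses$c > timeline$n_volumes))
    stop("'c' midpoints must lie within [1, n_volumes]")
  structure(list(genotype = as.character(genotype), n_subjects = n_subjects,
                 conditions = c("CNO", "saline"), responses = responses,
                 noise = noise, timeline = timeline, geometry = geometry,
                 base_seed = as.integer(base_seed), b0 = b0),
            class = "cohort_spec")
}

#' Default phantom cohorts for the two stimulation experiments
#'
#' `dat_cohort_spec()` emulates the dopaminergic-stimulation cohort
#' (n = 5): responses planted in VTA, mPFC, Cg and Septum with the VTA
#' amplitude largest. `camkii_cohort_spec()` emulates the
#' CamKII-stimulation cohort (n = 4): responses planted in ten regions,
#' with Cg among the largest and the shared four regions (VTA, mPFC,
#' Cg, Septum) stronger than under dopaminergic stimulation except VTA,
#' which is equal. The planted overlap of the two cohorts is therefore
#' {VTA, mPFC, Cg, Septum}.
#'
#' @param n_subjects Number of subjects.
#' @param base_seed Integer base seed.
#' @param noise A [noise_spec()].
#' @return A `cohort_spec`.
#' @export
dat_cohort_spec <- function(n_subjects = 5L, base_seed = 1L,
                            noise = noise_spec()) {
  cohort_spec("DAT", n_subjects,
              response_spec(c("VTA", "Cg", "mPFC", "Septum"),
                            a = c(0.05, 0.03, 0.02, 0.02)),
              noise = noise, base_seed = base_seed)
}

#' @rdname dat_cohort_spec
#' @export
camkii_cohort_spec <- function(n_subjects = 4L, base_seed = 1L,
                               noise = noise_spec()) {
  cohort_spec("CamKII", n_subjects,
              response_spec(c("VTA", "Cg", "mPFC", "Septum", "Insula",
                              "MC_R", "Hipp", "TH_R", "PtA_R", "ViC_R"),
                            a = c(0.05, 0.05, 0.04, 0.04, 0.03,
                                  0.03, 0.03, 0.03, 0.03, 0.03)),
              noise = noise, base_seed = base_seed)
}

#' Deterministic per-run seed
#'
#' Hashes (genotype, subject, condition) into a 31-bit offset combined
#' with the base seed, so that adding subjects or cohorts never
#' reshuffles the seeds of existing runs.
#'
#' @param base_seed Integer base seed.
#' @param genotype,subject,condition Run identity.
#' @return A single integer seed in [0, 2^31 - 2].
#' @export
run_seed <- function(base_seed, genotype, subject, condition) {
  key <- paste(genotype, subject, condition, sep = "|")
  m <- 2147483647  # 2^31 - 1; all arithmetic stays exact in doubles
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer((((base_seed %% m) * 2654435) %% m + h) %% m)
}

#' Generate one phantom BOLD run
#'
#' Simulates a 4D run for one subject and condition of a cohort: every
#' voxel holds the baseline intensity `b0`; under CNO, voxels inside
#' each responsive region are multiplied by the sigmoid response
#' [sigmoid_response()] with that region's true parameters (under
#' saline no response is applied); then linear drift and Gaussian noise
#' (SD `sigma_frac * b0`, optionally AR(1)-filtered) are added. The
#' same `(spec, subject, condition, seed)` always produces bit-identical
#' output.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index in `1:n_subjects`.
#' @param condition `"CNO"` or `"saline"`.
#' @param seed Integer seed; defaults to [run_seed()] of the run identity.
#' @return A list with elements `run` (a [bold_run()]), `truth` (data
#'   frame of the spec's per-region true parameters with the condition
#'   under which they were applied) and `seed`.
#' @export
generate_run <- function(spec, subject, condition, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!condition %in% c("CNO", "saline"))
    stop("'condition' must be \"CNO\" or \"saline\"")
  subject <- as.integer(subject)
  if (is.na(subject) || subject < 1L || subject > spec$n_subjects)
    stop("'subject' must be in 1:n_subjects")
  if (is.null(seed))
    seed <- run_seed(spec$base_seed, spec$genotype, subject, condition)
  geom <- spec$geometry
  tl <- spec$timeline
  d <- geom$grid_dims
  nt <- tl$n_volumes
  nvox <- prod(d)

  arr <- array(spec$b0, dim = c(d, nt))
  if (condition == "CNO" && nrow(spec$responses) > 0L) {
    for (i in seq_len(nrow(spec$responses))) {
      r <- spec$responses[i, ]
      box <- geom$regions[geom$regions$region == r$region, ]
      if (nrow(box) != 1L)
        stop("unknown responsive region '", r$region, "'")
      mult <- sigmoid_response(seq_len(nt), r$a, r$b, r$c)
      blk <- arr[box$x0:box$x1, box$y0:box$y1, box$z0:box$z1, , drop = FALSE]
      nb <- prod(dim(blk)[1:3])
      arr[box$x0:box$x1, box$y0:box$y1, box$z0:box$z1, ] <-
        blk * rep(mult, each = nb)
    }
  }
  ns <- spec$noise
  if (ns$drift_frac != 0) {
    drift <- spec$b0 * ns$drift_frac * (seq_len(nt) - 1) / (nt - 1)
    arr <- arr + rep(drift, each = nvox)
  }
  if (ns$sigma_frac > 0) {
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    eps <- matrix(stats::rnorm(nvox * nt), nvox, nt)
    if (ns$ar1_rho != 0) {
      rho <- ns$ar1_rho
      sc <- sqrt(1 - rho^2)
      for (t in seq.int(2L, nt))
        eps[, t] <- rho * eps[, t - 1L] + sc * eps[, t]
    }
    arr <- arr + ns$sigma_frac * spec$b0 * array(eps, dim = c(d, nt))
  }
  truth <- spec$responses
  truth$applied <- condition == "CNO"
  names(truth) <- c("region", "a_true", "b_true", "c_true", "applied")
  list(run = bold_run(arr, geom$voxel_size, subject = subject,
                      condition = condition, genotype = spec$genotype),
       truth = truth, seed = seed)
}

#' Generate a phantom cohort on disk
#'
#' Writes one NIfTI run per subject and condition, the atlas label
#' volume, brain mask and region table of the cohort geometry, and a
#' ground-truth manifest. Image files are written before the manifest,
#' so a partial failure never leaves a manifest claiming missing files.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with `runs` (manifest data frame: genotype,
#'   subject, condition, file, seed, noise summary), `truth` (long data
#'   frame of per-run true region parameters), `atlas` (the
#'   `phantom_atlas`), and `dir`.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atlas <- build_phantom_atlas(spec$geometry)
  runs <- list(); truths <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (cond in spec$conditions) {
      gr <- generate_run(spec, s, cond)
      file <- file.path(dir, sprintf("%s_sub%02d_%s.nii.gz",
                                     spec$genotype, s, cond))
      write_run(gr$run, file)
      runs[[length(runs) + 1L]] <- data.frame(
        genotype = spec$genotype, subject = s, condition = cond,
        file = file, seed = gr$seed, sigma_frac = spec$noise$sigma_frac,
        drift_frac = spec$noise$drift_frac, ar1_rho = spec$noise$ar1_rho,
        stringsAsFactors = FALSE)
      tr <- gr$truth
      if (nrow(tr)) {
        tr$genotype <- spec$genotype; tr$subject <- s; tr$condition <- cond
        truths[[length(truths) + 1L]] <- tr
      }
    }
  }
  runs <- do.call(rbind, runs)
  truth <- if (length(truths)) do.call(rbind, truths) else
    data.frame(region = character(), a_true = numeric(), b_true = numeric(),
               c_true = numeric(), applied = logical(), genotype = character(),
               subject = integer(), condition = character())
  if (anyDuplicated(runs$seed))
    stop("derived per-run seeds collide; choose a different base_seed")
  write_atlas(atlas, dir)
  write_tsv(runs, file.path(dir, "manifest.tsv"))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(list(runs = runs, truth = truth, atlas = atlas, dir = dir))
}
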