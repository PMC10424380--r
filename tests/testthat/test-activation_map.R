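norm_from_matrix <- function(m, tl) {
  # wrap a voxel x time matrix as a percent-scale normalized run
  d <- c(nrow(m), 1L, 1L, ncol(m))
  structure(list(data = array(m, d), scale = "percent",
                 baseline_map = array(0, d[1:3]),
                 mask = array(TRUE, d[1:3]), timeline = tl,
                 voxel_size = c(1, 1, 1), subject = NA,
                 condition = NA_character_, genotype = NA_character_),
            class = "normalized_run")
}

test_that("activation AUC follows the trapezoid rule with unit spacing", {
  tl <- default_timeline()
  m <- matrix(0, 3, 65)
  m[1, 45:65] <- 1                       # constant 1 -> (n-1) * value
  m[3, 45:65] <- 0:20                    # linear ramp -> 10 * 20
  am <- auc_activation(norm_from_matrix(m, tl))
  expect_equal(as.vector(am$data), c(20, 0, 200))

  s <- auc_activation(norm_from_matrix(m, tl), rule = "sum")
  expect_equal(as.vector(s$data), c(21, 0, 210))

  # linearity of the statistic
  set.seed(4)
  m1 <- matrix(rnorm(5 * 65), 5); m2 <- matrix(rnorm(5 * 65), 5)
  a1 <- auc_activation(norm_from_matrix(m1, tl))$data
  a2 <- auc_activation(norm_from_matrix(m2, tl))$data
  a12 <- auc_activation(norm_from_matrix(2 * m1 - 0.5 * m2, tl))$data
  expect_equal(a12, 2 * a1 - 0.5 * a2, tolerance = 1e-12)

  # a 1-volume window cannot support the trapezoid rule
  tl1 <- bold_timeline(65, c(5, 25), c(65, 65), 25)
  expect_error(auc_activation(norm_from_matrix(m, tl1), timeline = tl1),
               ">= 2")
})

test_that("voxel-wise group t-test matches hand computation and t.test", {
  tl <- tiny_timeline()
  to_map <- function(v) array(v, c(length(v), 1, 1))
  # hand-computed pooled example: groups {0..4} vs {2..6} at one voxel
  A <- lapply(0:4, function(v) to_map(v))
  B <- lapply(2:6, function(v) to_map(v))
  stat <- group_ttest(A, B)
  expect_equal(stat$t[1, 1, 1], -2)
  expect_equal(stat$df, 8)
  expect_equal(stat$p[1, 1, 1], 2 * pt(-2, 8), tolerance = 1e-15)

  # identical groups: t = 0, p = 1 wherever variance is nonzero
  s0 <- group_ttest(A, A)
  expect_equal(s0$t[1, 1, 1], 0)
  expect_equal(s0$p[1, 1, 1], 1)

  # antisymmetry under group swap
  sw <- group_ttest(B, A)
  expect_equal(sw$t, -stat$t)
  expect_equal(sw$p, stat$p)

  # zero-variance voxels are reported, not raised
  C <- lapply(1:3, function(i) to_map(5))
  sz <- group_ttest(C, C)
  expect_true(is.na(sz$t[1, 1, 1]))
  expect_equal(sz$n_zero_variance, 1L)
})

test_that("pooled, Welch and paired designs agree with stats::t.test", {
  set.seed(21)
  nvox <- 10
  A <- lapply(1:4, function(i) array(rnorm(nvox), c(nvox, 1, 1)))
  B <- lapply(1:4, function(i) array(rnorm(nvox, 0.5), c(nvox, 1, 1)))
  Am <- sapply(A, as.vector); Bm <- sapply(B, as.vector)

  pooled <- group_ttest(A, B)
  welch <- group_ttest(A, B, var_equal = FALSE)
  paired <- group_ttest(A, B, paired = TRUE)
  for (v in seq_len(nvox)) {
    tp <- t.test(Am[v, ], Bm[v, ], var.equal = TRUE)
    tw <- t.test(Am[v, ], Bm[v, ])
    tpair <- t.test(Am[v, ], Bm[v, ], paired = TRUE)
    expect_equal(pooled$t[v, 1, 1], unname(tp$statistic), tolerance = 1e-12)
    expect_equal(pooled$p[v, 1, 1], tp$p.value, tolerance = 1e-12)
    expect_equal(welch$t[v, 1, 1], unname(tw$statistic), tolerance = 1e-12)
    expect_equal(welch$p[v, 1, 1], tw$p.value, tolerance = 1e-12)
    expect_equal(welch$df[v, 1, 1], unname(tw$parameter), tolerance = 1e-12)
    expect_equal(paired$t[v, 1, 1], unname(tpair$statistic),
                 tolerance = 1e-12)
    expect_equal(paired$p[v, 1, 1], tpair$p.value, tolerance = 1e-12)
  }
})

test_that("BH step-up matches the rank enumeration oracle", {
  single <- bh_fdr(0.01, alpha = 0.05)
  expect_equal(single$q, 0.01)
  expect_true(single$reject)

  p4 <- c(0.01, 0.02, 0.5, 0.9)
  res <- bh_fdr(p4, alpha = 0.05)
  expect_equal(res$q, c(0.04, 0.04, 2 / 3, 0.9), tolerance = 1e-12)
  expect_equal(sum(res$reject), 2L)
  expect_equal(res$q, oracle_bh(p4), tolerance = 1e-15)

  all1 <- bh_fdr(rep(1, 20), alpha = 0.05)
  expect_false(any(all1$reject))

  set.seed(9)
  pr <- runif(200)^2
  expect_equal(bh_fdr(pr)$q, oracle_bh(pr), tolerance = 1e-12)

  # NA p-values are excluded from the family
  pna <- c(0.01, NA, 0.04)
  rna <- bh_fdr(pna)
  expect_equal(rna$m, 2L)
  expect_true(is.na(rna$q[2]))

  expect_error(bh_fdr(c(NA_real_, NA_real_)), "empty")
  expect_error(bh_fdr(c(0.1, 2)), "0, 1|\\[0, 1\\]")
  expect_error(bh_fdr(0.1, alpha = 1.2), "alpha")
})

test_that("uncorrected thresholding is strict and positive-only by default", {
  d <- c(4, 1, 1)
  stat <- structure(list(
    t = array(c(3, -3, 3, 1), d),
    p = array(c(0.0005, 0.0005, 0.001, 0.3), d),
    df = 8, n_a = 5, n_b = 5, n_zero_variance = 0L,
    paired = FALSE, var_equal = TRUE, voxel_size = NULL),
    class = "group_stat_map")
  msk <- threshold_uncorrected(stat, 0.001)
  # strict <: the voxel exactly at the level is excluded; negative t too
  expect_equal(as.vector(msk$data), c(TRUE, FALSE, FALSE, FALSE))
  signed <- threshold_uncorrected(stat, 0.001, positive_only = FALSE)
  expect_equal(as.vector(signed$data), c(TRUE, TRUE, FALSE, FALSE))
  none <- threshold_uncorrected(
    structure(modifyList(unclass(stat), list(p = array(0.5, d))),
              class = "group_stat_map"), 0.001)
  expect_equal(sum(none$data), 0L)
})

test_that("region summaries count voxels by atlas label", {
  atlas <- build_phantom_atlas(tiny_geometry())
  empty <- array(FALSE, dim(atlas$labels))
  s0 <- summarize_regions(empty, atlas)
  expect_true(all(s0$n_significant == 0))
  expect_true(all(s0$fraction_of_region == 0))

  full_r1 <- atlas$labels == 1L
  s1 <- summarize_regions(full_r1, atlas)
  expect_equal(s1$fraction_of_region[s1$region == "R1"], 1)
  expect_true(all(s1$n_significant[s1$region != "R1"] == 0))

  # hand-enumerated partial mask
  m <- array(FALSE, dim(atlas$labels))
  m[2, 2, 2] <- TRUE   # inside R1 (box 2:3, 2:3, 2:3)
  m[6, 2, 2] <- TRUE   # inside R2 (box 6:7, 2:3, 2:3)
  m[1, 1, 1] <- TRUE   # background
  s2 <- summarize_regions(m, atlas)
  expect_equal(s2$n_significant[s2$region == "R1"], 1L)
  expect_equal(s2$n_significant[s2$region == "R2"], 1L)
  expect_equal(s2$n_significant[s2$region == "R3"], 0L)
  expect_equal(s2$n_voxels_region, rep(8L, 3))

  expect_error(summarize_regions(array(FALSE, c(2, 2, 2)), atlas), "dims")
})
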