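test_that("sigmoid response has the right landmarks and saturates safely", {
  # midpoint is exactly half-rise
  expect_equal(sigmoid_response(40, a = 0.2, b = 1, c = 40), 1.10)
  # zero amplitude is the identity
  expect_equal(sigmoid_response(c(-5, 0, 17, 1e3), a = 0, b = 2, c = 10),
               rep(1, 4))
  # asymptotes
  expect_equal(sigmoid_response(1e6, a = 0.05, b = 1, c = 38), 1.05)
  expect_equal(sigmoid_response(-1e6, a = 0.05, b = 1, c = 38), 1)
  # extreme exponents saturate instead of producing NaN/Inf
  v <- sigmoid_response(c(-1e9, 1e9), a = -0.3, b = 50, c = 0)
  expect_true(all(is.finite(v)))
  expect_equal(v, c(1, 0.7))
  # strictly monotone when a != 0, b > 0
  y <- sigmoid_response(1:65, a = 0.05, b = 0.8, c = 38)
  expect_true(all(diff(y) > 0))
})

test_that("phantom atlas rasterizes boxes with consecutive labels", {
  one <- phantom_geometry(c(6L, 6L, 6L), c(1, 1, 1),
                          data.frame(region = "A", x0 = 2, x1 = 3, y0 = 2,
                                     y1 = 3, z0 = 2, z1 = 3,
                                     hemisphere = "midline"))
  atlas <- build_phantom_atlas(one)
  expect_equal(sum(atlas$labels == 1L), 8L)
  expect_true(all(atlas$mask[atlas$labels > 0]))

  none <- phantom_geometry(c(6L, 6L, 6L), c(1, 1, 1),
                           data.frame(region = character(), x0 = integer(),
                                      x1 = integer(), y0 = integer(),
                                      y1 = integer(), z0 = integer(),
                                      z1 = integer(),
                                      hemisphere = character()))
  a0 <- build_phantom_atlas(none)
  expect_equal(sum(a0$labels), 0L)
  expect_gt(sum(a0$mask), 0L)

  atlas10 <- build_phantom_atlas(default_phantom_geometry())
  counts <- table(atlas10$labels[atlas10$labels > 0])
  expect_equal(sort(as.integer(names(counts))), 1:10)
  expect_true(all(counts >= 1))
  expect_equal(nrow(atlas10$table), 10L)
})

test_that("overlapping region boxes are rejected with both names", {
  bad <- data.frame(region = c("P", "Q"),
                    x0 = c(2, 3), x1 = c(4, 5), y0 = c(2, 3), y1 = c(4, 5),
                    z0 = c(2, 3), z1 = c(4, 5),
                    hemisphere = c("midline", "midline"))
  expect_error(phantom_geometry(c(8L, 8L, 8L), c(1, 1, 1), bad),
               "P.*Q|Q.*P")
})

test_that("generated runs follow the forward model exactly when noiseless", {
  spec <- tiny_cohort(sigma_frac = 0)
  sal <- generate_run(spec, 1, "saline")$run
  expect_true(all(sal$data == 1000))

  cno <- generate_run(spec, 1, "CNO")$run
  geom <- tiny_geometry()
  b1 <- geom$regions[geom$regions$region == "R1", ]
  v_last <- cno$data[b1$x0, b1$y0, b1$z0, 30]
  expect_equal(v_last, 1000 * sigmoid_response(30, 0.05, 0.8, 22),
               tolerance = 1e-12)
  # the last-volume value reaches the plateau up to the sigmoid tail
  expect_lt(abs(v_last / 1000 - 1.05) / 1.05, 0.05 * exp(-0.8 * (30 - 22)))
  # region voxels follow a non-decreasing ramp; background is flat
  ramp <- cno$data[b1$x0, b1$y0, b1$z0, ]
  expect_true(all(diff(ramp) >= 0))
  expect_true(all(cno$data[1, 1, 1, ] == 1000))
})

test_that("noise-free window means match the analytic sigmoid means", {
  spec <- tiny_cohort(sigma_frac = 0)
  tl <- spec$timeline
  cno <- generate_run(spec, 2, "CNO")$run
  geom <- tiny_geometry()
  b1 <- geom$regions[geom$regions$region == "R1", ]
  series <- cno$data[b1$x1, b1$y1, b1$z1, ]
  emp <- mean(series[window_indices(tl, "activation")]) /
    mean(series[window_indices(tl, "baseline")])
  ana <- mean(sigmoid_response(window_indices(tl, "activation"), 0.05, 0.8, 22)) /
    mean(sigmoid_response(window_indices(tl, "baseline"), 0.05, 0.8, 22))
  expect_equal(emp, ana, tolerance = 1e-10)
})

test_that("run generation is a pure function of spec and seed", {
  spec <- tiny_cohort()
  r1 <- generate_run(spec, 1, "CNO")
  r2 <- generate_run(spec, 1, "CNO")
  expect_identical(r1$run$data, r2$run$data)
  expect_identical(r1$seed, r2$seed)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  f1 <- file.path(d1, "TINY_sub01_CNO.nii.gz")
  f2 <- file.path(d2, "TINY_sub01_CNO.nii.gz")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  d3 <- withr::local_tempdir()
  generate_cohort(tiny_cohort(base_seed = 8L), d3)
  f3 <- file.path(d3, "TINY_sub01_CNO.nii.gz")
  expect_false(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3)))
})

test_that("cohort generation writes one run and manifest row per subject x condition", {
  spec <- tiny_cohort(n_subjects = 2L)
  d <- withr::local_tempdir()
  gen <- generate_cohort(spec, d)
  expect_equal(nrow(gen$runs), 4L)
  expect_true(all(file.exists(gen$runs$file)))
  expect_equal(anyDuplicated(gen$runs$seed), 0L)
  # ground-truth amplitudes pass through unchanged
  cno_truth <- gen$truth[gen$truth$condition == "CNO" & gen$truth$subject == 1, ]
  expect_equal(cno_truth$a_true[match(spec$responses$region, cno_truth$region)],
               spec$responses$a)
  # manifest is readable back with full precision
  man <- read_tsv(file.path(d, "manifest.tsv"))
  expect_equal(man$seed, gen$runs$seed)
})

test_that("null regions have the same distribution under CNO and saline", {
  spec <- tiny_cohort(sigma_frac = 0.02)
  atlas <- build_phantom_atlas(spec$geometry)
  cno <- generate_run(spec, 1, "CNO")$run
  sal <- generate_run(spec, 1, "saline")$run
  null_vox <- which(atlas$labels == 0)[1:40]
  x <- as.vector(matrix(cno$data, prod(dim(cno$data)[1:3]),
                        dim(cno$data)[4])[null_vox, ])
  y <- as.vector(matrix(sal$data, prod(dim(sal$data)[1:3]),
                        dim(sal$data)[4])[null_vox, ])
  # different noise draws (condition enters the seed) ...
  expect_false(identical(x, y))
  # ... but indistinguishable distributions
  expect_gt(suppressWarnings(ks.test(x, y))$p.value, 0.001)
  # means agree within 5 standard errors of the noise
  expect_lt(abs(mean(x) - mean(y)), 5 * 20 / sqrt(length(x)))
})

test_that("generator rejects invalid inputs", {
  expect_error(cohort_spec("G", 1L, response_spec("R1", 0.05),
                           geometry = tiny_geometry(),
                           timeline = tiny_timeline()),
               ">= 2")
  expect_error(cohort_spec("G", 2L, response_spec("nope", 0.05),
                           geometry = tiny_geometry(),
                           timeline = tiny_timeline()),
               "nope")
  expect_error(cohort_spec("G", 2L, response_spec("R1", 0.05),
                           geometry = tiny_geometry(),
                           timeline = tiny_timeline(), b0 = 0),
               "positive")
  expect_error(generate_run(tiny_cohort(), 1, "vehicle"), "CNO")
  expect_error(noise_spec(sigma_frac = -1), ">= 0")
  expect_error(noise_spec(ar1_rho = 1), "rho")
})
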