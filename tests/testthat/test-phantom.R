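test_that("template is a binary ellipsoid with an interior class region", {
  tpl <- make_template(24L)
  expect_equal(max(tpl), 1)
  expect_equal(min(tpl), 0)
  region <- attr(tpl, "region_idx")
  tissue <- attr(tpl, "tissue_idx")
  expect_true(all(region %in% tissue))  # strictly inside the ellipsoid
  # voxelized tissue volume close to (4/3) pi a b c
  axes_vox <- c(0.82, 0.90, 0.75) * 24 / 2
  analytic <- 4 / 3 * pi * prod(axes_vox)
  expect_lt(abs(length(tissue) - analytic) / analytic, 0.10)
  expect_error(make_template(4L), ">= 8")
})

test_that("rendering honors the null-effect and seeding contracts", {
  co <- fixture_cohort(sizes = 2L, seed = 8L)
  co$label <- c(0L, 1L)
  co$age_years <- c(65, 65)
  tpl <- make_template(16L)
  null_spec <- phantom_spec(grid_size = 16L, class_effect_size = 0,
                            center_gain_sd = 0, bias_field_amplitude = 0,
                            noise_sd_by_vendor = c(Siemens = 0, GE = 0, Philips = 0))
  v0 <- render_participant(co[1, ], tpl, null_spec)
  v1 <- render_participant(co[2, ], tpl, null_spec)
  expect_identical(v0$intensities, v1$intensities)

  spec <- phantom_spec(grid_size = 16L, master_seed = 3L)
  a <- render_participant(co[1, ], tpl, spec)
  b <- render_participant(co[1, ], tpl, spec)
  expect_identical(a$intensities, b$intensities)

  bad <- co[1, ]; bad$vendor <- "Toshiba"
  expect_error(render_participant(bad, tpl, spec), "vendor")
})

test_that("class region dims by (1 - effect) for disease volumes", {
  eff <- 0.1
  spec <- phantom_spec(grid_size = 16L, class_effect_size = eff,
                       age_effect_slope = 0, center_gain_sd = 0.05,
                       bias_field_amplitude = 0.2,
                       noise_sd_by_vendor = c(Siemens = 0, GE = 0, Philips = 0),
                       master_seed = 12L)
  tpl <- make_template(16L)
  region <- attr(tpl, "region_idx")
  co <- fixture_cohort(sizes = rep(2L, 50), seed = 13L)  # 100 records
  co$age_years <- 65
  co$label <- rep(c(0L, 1L), 50)
  ratios <- vapply(seq(1, 99, by = 2), function(i) {
    m0 <- mean(render_participant(co[i, ], tpl, spec)$intensities[region])
    m1 <- mean(render_participant(co[i + 1, ], tpl, spec)$intensities[region])
    m1 / m0  # same center, so gain/bias cancel
  }, numeric(1))
  expect_equal(mean(ratios), 1 - eff, tolerance = 1e-3)
})

test_that("center effects are deterministic, stream-independent, and calibrated", {
  spec0 <- phantom_spec(grid_size = 16L, center_gain_sd = 0, master_seed = 1L)
  expect_equal(center_effect_params("anywhere", spec0)$gain, 1)

  spec <- phantom_spec(grid_size = 16L, center_gain_sd = 0.1, master_seed = 1L)
  a <- center_effect_params("center_a", spec)
  b <- center_effect_params("center_b", spec)
  expect_false(a$gain == b$gain)
  expect_identical(a, center_effect_params("center_a", spec))

  gains <- vapply(1:1000, function(i) {
    center_effect_params(paste0("mc_", i), spec)$gain
  }, numeric(1))
  expect_lt(abs(sd(gains) - 0.1) / 0.1, 0.10)
  expect_equal(mean(gains), 1, tolerance = 0.02)
})

test_that("separability increases with class effect size (threshold classifier dial)", {
  tpl <- make_template(16L)
  region <- attr(tpl, "region_idx")
  co <- fixture_cohort(sizes = rep(10L, 20), seed = 21L)  # 200 records
  co$label <- rep(c(0L, 1L), 100)
  aucs <- vapply(c(0, 0.05, 0.15, 0.4), function(eff) {
    spec <- phantom_spec(grid_size = 16L, class_effect_size = eff,
                         master_seed = 31L)
    vs <- render_cohort(co, spec, tpl)
    # threshold classifier: disease region darker => score by -mean intensity
    xz <- scale(vs$x)
    auroc(-colMeans(xz[region, ]), vs$labels)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(aucs[1], 0.6)   # no effect: near chance
})

test_that("volumes round-trip through NIfTI export/import", {
  skip_if_not_installed("RNifti")
  co <- fixture_cohort(sizes = 2L, seed = 19L)
  vs <- fixture_volumes(co)
  dir <- file.path(tempdir(), "nifti_rt")
  write_volumes_nifti(vs, dir)
  expect_setequal(list.files(dir), paste0(co$participant_id, ".nii.gz"))
  back <- read_volumes_nifti(co, dir)
  expect_equal(back$x, vs$x, tolerance = 1e-6)  # NIfTI stores float32
  expect_equal(back$grid, vs$grid)
})

test_that("between-center variance of volume means grows with center_gain_sd", {
  co <- fixture_cohort(sizes = rep(5L, 30), seed = 22L)
  vars <- vapply(c(0, 0.05, 0.15), function(g) {
    spec <- phantom_spec(grid_size = 16L, center_gain_sd = g,
                         bias_field_amplitude = 0,
                         noise_sd_by_vendor = c(Siemens = 0.01, GE = 0.01, Philips = 0.01),
                         master_seed = 17L)
    vs <- render_cohort(co, spec)
    center_means <- tapply(colMeans(vs$x), co$center_id, mean)
    var(as.numeric(center_means))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})
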