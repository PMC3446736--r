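test_that("generators are deterministic and use independent substreams", {
  cfg <- sim_config(n_subjects = 40, seed = 3, grid_dims = c(6, 6, 6))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(simulate_items(a, cfg), simulate_items(a, cfg))
  expect_identical(simulate_roi_volumes(a, cfg), simulate_roi_volumes(a, cfg))
  s1 <- simulate_voxel_maps(a, cfg, "GM")
  expect_identical(s1$data, simulate_voxel_maps(a, cfg, "GM")$data)
  # GM and WM stacks come from distinct substreams
  expect_false(identical(s1$data, simulate_voxel_maps(a, cfg, "WM")$data))
  # regenerating one object does not disturb another generated later
  set.seed(999); invisible(stats::rnorm(13))
  expect_identical(simulate_roi_volumes(a, cfg), simulate_roi_volumes(a, cfg))
})

test_that("empty cohort keeps the full column schema", {
  cfg <- sim_config(n_subjects = 0, seed = 1)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 0)
  expect_true(all(c("subject_id", "age", "education", "race_minority",
                    "hypertension", "diabetes", "handedness", "is_control",
                    "icv", "engagement", "quality_flag_mri",
                    "missing_engagement") %in% names(coh)))
  expect_identical(levels(coh$education), education_levels())
})

test_that("cohort margins converge to the configured targets", {
  cfg <- sim_config(n_subjects = 348, seed = 11)
  coh <- simulate_cohort(cfg)
  n <- nrow(coh)
  within3se <- function(phat, p) {
    abs(phat - p) <= 3 * sqrt(p * (1 - p) / n)
  }
  expect_true(within3se(mean(1 - coh$race_minority), 0.905))
  expect_true(within3se(mean(coh$hypertension), 0.517))
  expect_true(within3se(mean(coh$diabetes), 0.155))
  expect_true(within3se(mean(coh$is_control), 0.124))
  expect_lt(abs(mean(coh$age) - 65.2), 3 * 7.9 / sqrt(n))
  expect_lt(abs(sd(coh$engagement) - 0.33), 0.08)
  # large-n law-of-large-numbers check on the age margin
  big <- simulate_cohort(sim_config(n_subjects = 50000, seed = 12))
  expect_lt(abs(mean(big$age) - 65.2), 0.1)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(covariate_margins = list(p_diabetes = 1.4)),
               "p_diabetes")
  expect_error(sim_config(item_loadings = rep(1.2, 8)), "item_loadings")
  expect_error(sim_config(item_loadings = rep(0.5, 7)), "item_loadings")
  expect_error(sim_config(roi_effects = c(Thalamus = 0.1)),
               "Thalamus")
  expect_error(sim_config(grid_dims = c(8, 0, 8)), "grid_dims")
  expect_error(sim_config(
    grid_dims = c(8, 8, 8),
    blob_spec = list(list(center = c(4, 4, 4), radius = 2, amplitude = 1,
                          tissue = "GM"),
                     list(center = c(9, 4, 4), radius = 2, amplitude = 1,
                          tissue = "GM"))),
    "blob 2")
})

test_that("item responses follow the one-factor graded scheme", {
  cfg0 <- sim_config(n_subjects = 5000, seed = 21, item_loadings = rep(0, 8))
  coh <- simulate_cohort(cfg0)
  it0 <- simulate_items(coh, cfg0)
  cors <- vapply(engagement_items()$item,
                 function(j) cor(it0[[j]], coh$engagement), numeric(1))
  # loadings 0: item-latent correlations indistinguishable from 0
  expect_true(all(abs(cors) < 4 / sqrt(5000)))

  cfg9 <- sim_config(n_subjects = 5000, seed = 22, item_loadings = rep(0.9, 8))
  coh9 <- simulate_cohort(cfg9)
  it9 <- simulate_items(coh9, cfg9)
  sumscore <- rowSums(it9[, engagement_items()$item])
  expect_gt(cor(sumscore, coh9$engagement), 0.8)

  expect_equal(sum(names(it9) != "subject_id"), 8)
  # ordinal ranges respected
  expect_true(all(it9$contact_friends %in% 0:7))
  expect_true(all(it9$shopping %in% 0:4))
  # missingness injection
  cfgm <- sim_config(n_subjects = 2000, seed = 23, item_missing_rate = 0.1)
  itm <- simulate_items(simulate_cohort(cfgm), cfgm)
  rate <- mean(is.na(as.matrix(itm[, -1])))
  expect_lt(abs(rate - 0.1), 0.02)
})

test_that("region volumes hit the configured means, effects and degenerate cases", {
  cfg <- sim_config(n_subjects = 348, seed = 31)
  vols <- simulate_roi_volumes(simulate_cohort(cfg), cfg)
  tb <- vols$volume_t2[vols$roi == "Total brain volume"]
  se <- sd(tb) / sqrt(length(tb))
  expect_lt(abs(mean(tb) - 1137.96), 3 * se)
  expect_true(all(vols$volume_t2 > 0))
  expect_true(all(vols$volume_t1 > 0))
  expect_equal(vols$delta, vols$volume_t2 - vols$volume_t1)

  # degenerate: no noise, no effects, no covariate couplings -> exact means
  cfg0 <- sim_config(n_subjects = 10, seed = 32, roi_cv = 0,
                     roi_covariate_coupling = 0, delta_sd_frac = 0,
                     roi_effects = c())
  v0 <- simulate_roi_volumes(simulate_cohort(cfg0), cfg0)
  mu <- roi_inventory()$mean_cc[match(v0$roi, roi_inventory()$roi)]
  expect_equal(v0$volume_t2, mu, tolerance = 1e-12)
})

test_that("voxel maps embed blobs, respect degenerate settings, and cap at the largest reported extent", {
  # no signal, no noise, no subject scaling -> identical maps
  cfg0 <- sim_config(n_subjects = 5, seed = 41, grid_dims = c(8, 8, 8),
                     voxel_noise_sd = 0, voxel_covariate_coupling = 0)
  stk0 <- simulate_voxel_maps(simulate_cohort(cfg0), cfg0, "GM")
  expect_true(all(apply(stk0$data, 2, function(col) max(col) - min(col)) == 0))
  expect_true(all(stk0$data > 0))

  # a ~4581-voxel spherical support (largest reported cluster extent)
  r <- (3 * 4581 / (4 * pi))^(1 / 3)
  cfgL <- sim_config(n_subjects = 4, seed = 42, grid_dims = c(32, 32, 32),
                     blob_spec = list(list(center = c(16, 16, 16), radius = r,
                                           amplitude = 1, tissue = "GM")))
  expect_silent(stkL <- simulate_voxel_maps(simulate_cohort(cfgL), cfgL, "GM"))
  sup <- blob_support(c(32, 32, 32), c(16, 16, 16), r)
  expect_lt(abs(length(sup) - 4581) / 4581, 0.05)

  # blob intensity scales with standardized engagement
  cfgB <- sim_config(n_subjects = 30, seed = 43, grid_dims = c(10, 10, 10),
                     voxel_noise_sd = 0, voxel_covariate_coupling = 0,
                     blob_spec = list(list(center = c(5, 5, 5), radius = 2,
                                           amplitude = 2, tissue = "GM")))
  cohB <- simulate_cohort(cfgB)
  stkB <- simulate_voxel_maps(cohB, cfgB, "GM")
  ctr <- blob_support(c(10, 10, 10), c(5, 5, 5), 2)[1]
  base <- simulate_voxel_maps(cohB, sim_config(
    n_subjects = 30, seed = 43, grid_dims = c(10, 10, 10),
    voxel_noise_sd = 0, voxel_covariate_coupling = 0), "GM")
  lift <- stkB$data[, ctr] - base$data[, ctr]
  expect_equal(lift, 2 * cohB$engagement / 0.33, tolerance = 1e-8)
})

test_that("with no effects the voxel t-statistic is Student-t distributed", {
  # 500 simulated null datasets on a desk-scale grid; cohort and design fixed
  cfg <- sim_config(n_subjects = 348, seed = 51, grid_dims = c(8, 8, 8),
                    noise_fwhm_vox = 0)
  coh <- simulate_cohort(cfg)
  design <- suppressWarnings(build_design_matrix(coh))
  eng <- setNames(coh$engagement, coh$subject_id)
  vox <- 100L
  tvals <- vapply(seq_len(500), function(b) {
    cfg_b <- sim_config(n_subjects = 348, seed = 51 + b,
                        grid_dims = c(8, 8, 8), noise_fwhm_vox = 0)
    stk <- simulate_voxel_maps(coh, cfg_b, "GM")
    map <- fit_voxel_glm(stk, design, eng)
    map$t[vox]
  }, numeric(1))
  df <- 348 - ncol(design) - 1
  ks <- suppressWarnings(stats::ks.test(tvals, function(q) stats::pt(q, df)))
  expect_gt(ks$p.value, 0.01)
})
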