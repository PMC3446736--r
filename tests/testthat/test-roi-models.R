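make_volume_table <- function(ids, roi, v2, v1 = v2) {
  data.frame(subject_id = ids, roi = roi, volume_t1 = v1, volume_t2 = v2,
             delta = v2 - v1, stringsAsFactors = FALSE)
}

test_that("forward models match the normal-equations oracle", {
  fx <- make_fixture(n = 40, seed = 81)
  vols <- simulate_roi_volumes(fx$cohort, fx$cfg)
  res <- fit_roi_models(vols, fx$design, fx$engagement)
  expect_equal(res$roi, roi_inventory()$roi)
  for (roi in c("Total brain volume", "Hippocampus", "Occipital GM")) {
    y <- vols$volume_t2[vols$roi == roi][
      match(rownames(fx$design), vols$subject_id[vols$roi == roi])]
    X <- cbind(fx$design, engagement = unname(fx$engagement))
    o <- ols_oracle(X, y)
    row <- res[res$roi == roi, ]
    expect_equal(row$b, unname(o$b["engagement"]), tolerance = 1e-8)
    expect_equal(row$se, unname(o$se["engagement"]), tolerance = 1e-8)
    expect_equal(row$t, unname(o$t["engagement"]), tolerance = 1e-8)
    expect_equal(row$p, unname(o$p["engagement"]), tolerance = 1e-8)
    expect_equal(row$beta_std,
                 unname(o$b["engagement"]) * sd(fx$engagement) / sd(y),
                 tolerance = 1e-10)
  }
})

test_that("a noiseless engagement-equal outcome gives standardized coefficient 1", {
  n <- 30
  ids <- sprintf("Q%02d", 1:n)
  set.seed(5)
  eng <- rnorm(n)
  X <- cbind(`(Intercept)` = rep(1, n))
  rownames(X) <- ids
  vols <- make_volume_table(ids, "Total brain volume", eng)
  # lm warns about the essentially perfect fit; that is the point here
  res <- suppressWarnings(fit_roi_models(vols, X, setNames(eng, ids)))
  expect_equal(res$beta_std, 1.0, tolerance = 1e-10)
  expect_lt(res$p, 1e-10)
})

test_that("standardized results are invariant to volume rescaling", {
  fx <- make_fixture(n = 50, seed = 82)
  vols <- simulate_roi_volumes(fx$cohort, fx$cfg)
  vols_sub <- vols[vols$roi == "Temporal GM", ]
  r1 <- fit_roi_models(vols_sub, fx$design, fx$engagement)
  vols_scaled <- vols_sub
  for (cl in c("volume_t1", "volume_t2", "delta"))
    vols_scaled[[cl]] <- vols_scaled[[cl]] * 1000
  r2 <- fit_roi_models(vols_scaled, fx$design, fx$engagement)
  expect_equal(r1$beta_std, r2$beta_std, tolerance = 1e-10)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r2$b, r1$b * 1000, tolerance = 1e-6)
})

test_that("under a true null the engagement p-value is uniform", {
  cfg0 <- sim_config(n_subjects = 120, seed = 83, roi_effects = c())
  coh <- simulate_cohort(cfg0)
  design <- suppressWarnings(build_design_matrix(coh))
  eng <- setNames(coh$engagement, coh$subject_id)
  pvals <- vapply(seq_len(500), function(b) {
    cfg_b <- sim_config(n_subjects = 120, seed = 83 + b, roi_effects = c())
    vols <- simulate_roi_volumes(coh, cfg_b)
    fit_roi_models(vols[vols$roi == "Total gray matter (GM)", ],
                   design, eng)$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("reversed models regress engagement on volume change", {
  # null coupling: standardized coefficient centered on zero
  cfg <- sim_config(n_subjects = 300, seed = 84)
  coh <- simulate_cohort(cfg)
  design <- suppressWarnings(build_design_matrix(coh))
  eng <- setNames(coh$engagement, coh$subject_id)
  betas <- vapply(seq_len(60), function(b) {
    cfg_b <- sim_config(n_subjects = 300, seed = 84 + b)
    vols <- simulate_roi_volumes(coh, cfg_b)
    fit_reversed_models(vols[vols$roi == "Total brain volume", ],
                        design, eng)$beta_std
  }, numeric(1))
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)) + 0.005)

  # configured coupling 0.1 is recovered
  betas_c <- vapply(seq_len(60), function(b) {
    cfg_b <- sim_config(n_subjects = 500, seed = 984 + b,
                        delta_engagement_coupling = 0.1)
    coh_b <- simulate_cohort(cfg_b)
    des_b <- suppressWarnings(build_design_matrix(coh_b))
    vols <- simulate_roi_volumes(coh_b, cfg_b)
    fit_reversed_models(vols[vols$roi == "Total brain volume", ],
                        des_b, setNames(coh_b$engagement, coh_b$subject_id))$beta_std
  }, numeric(1))
  mc_se <- sd(betas_c) / sqrt(length(betas_c))
  expect_lt(abs(mean(betas_c) - 0.1), 3 * mc_se)

  # full output covers all 20 regions and is tagged
  vols <- simulate_roi_volumes(coh, cfg)
  rev <- fit_reversed_models(vols, design, eng)
  expect_equal(nrow(rev), 20L)
  expect_true(all(rev$direction == "reversed"))

  # missing first-timepoint volumes are an error naming subjects
  vols$volume_t1[vols$subject_id == coh$subject_id[2]] <- NA
  expect_error(fit_reversed_models(vols, design, eng), coh$subject_id[2])
})

test_that("effect-modification tests cover the five modifier sets and are calibrated", {
  fx <- make_fixture(n = 150, seed = 85)
  vols <- simulate_roi_volumes(fx$cohort, fx$cfg)
  one <- vols[vols$roi == "Total brain volume", ]
  mods <- c("age", "education", "race", "cvd_risk", "control")
  res <- lapply(mods, function(m)
    test_effect_modification(one, fx$design, fx$engagement, m))
  expect_length(res, 5L)
  # education block is a joint test over its indicator columns
  expect_equal(res[[2]]$df1, sum(grepl("^edu_", colnames(fx$design))))
  expect_error(
    test_effect_modification(one, fx$design, fx$engagement, "nonexistent"),
    "modifier")
  Xc <- cbind(fx$design, const = 1 * (fx$design[, "age_c"] > Inf))
  expect_error(
    test_effect_modification(one, Xc, fx$engagement, "const"),
    "zero variance")

  # type-I calibration at alpha = 0.05 under no interaction
  coh <- fx$cohort; design <- fx$design; eng <- fx$engagement
  n_rep <- 2000L
  rej <- vapply(seq_len(n_rep), function(b) {
    cfg_b <- sim_config(n_subjects = 150, seed = 50000 + b)
    vols_b <- simulate_roi_volumes(coh, cfg_b)
    p <- test_effect_modification(
      vols_b[vols_b$roi == "Total brain volume", ], design, eng, "age")$p
    p <= 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 2 * mc_se)
})

test_that("a collinear design is rejected with the offending column named", {
  fx <- make_fixture(n = 40, seed = 86)
  X <- cbind(fx$design, dup_age = fx$design[, "age_c"])
  vols <- simulate_roi_volumes(fx$cohort, fx$cfg)
  expect_error(
    fit_roi_models(vols[vols$roi == "Insula", ], X, fx$engagement),
    "collinear")
})
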