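small_config <- function(...) {
  cohort_config(n_patients = 12, n_controls = 10, seed = 21,
                prop_missing_items = 0, ...)
}

test_that("config validation enforces the documented invariants", {
  expect_error(cohort_config(n_patients = 1), "at least 2")
  expect_error(cohort_config(roi_labels = paste0("r", 1:48)), "callosal")
  expect_error(cohort_config(latent_loadings_x = rep(0, 10)), "length 48")
  expect_error(cohort_config(item_thresholds = c(1, 2, 2, 3)), "increasing")
  cfg <- cohort_config()
  expect_identical(length(cfg$roi_labels), 48L)
  expect_true(all(cfg$fa_baseline > 0.4 & cfg$fa_baseline < 0.8))
})

test_that("identical config and seed reproduce the cohort bit-for-bit", {
  c1 <- generate_cohort(small_config())
  c2 <- generate_cohort(small_config())
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(cohort_config(n_patients = 12, n_controls = 10,
                                      seed = 22, prop_missing_items = 0))
  expect_false(identical(c1$roi_fa, c3$roi_fa))
})

test_that("all generated FA values are strictly inside (0, 1)", {
  co <- generate_cohort(small_config())
  vals <- as.matrix(co$roi_fa[, -1])
  expect_true(all(vals > 0 & vals < 1))
})

test_that("planted group FA deficit is recovered within Monte-Carlo error", {
  diffs <- sapply(1:10, function(i) {
    cfg <- cohort_config(n_patients = 150, n_controls = 150, seed = 100 + i,
                         group_fa_deficit = 0.013,
                         latent_loadings_x = rep(0, 48),
                         covariate_betas = c(age = 0, sex = 0,
                                             abs_motion = 0, rel_motion = 0),
                         prop_missing_items = 0)
    co <- generate_cohort(cfg)
    d <- derive_fa(co$roi_fa)
    pat <- co$covariates$group == "patient"
    mean(d$global_fa[pat]) - mean(d$global_fa[!pat])
  })
  # per-replicate SE of the difference is dominated by the per-subject global
  # offset: 0.012 * sqrt(2/150) ~ 0.0014, so the 10-replicate mean has
  # SE ~ 0.00044; bound at ~3 SE
  expect_lt(abs(mean(diffs) - (-0.013)), 0.0015)
})

test_that("questionnaire generator saturates, stays in range and is calibrated", {
  thr <- c(-1.5, -0.5, 0.5, 1.5)
  expect_true(all(generate_questionnaire(50, thr, seed = 1) == 5L))
  expect_true(all(generate_questionnaire(-50, thr, seed = 1) == 1L))
  expect_error(generate_questionnaire(0, c(0, -1, 1, 2)), "increasing")
  # symmetric thresholds at latent 0: item mean 3 by symmetry
  set.seed(2)
  draws <- replicate(10000, generate_questionnaire(0, thr)[["item_a"]])
  expect_true(all(draws %in% 1:5))
  expect_equal(mean(draws), 3, tolerance = 0.05)
  # monotone in the latent score (in expectation)
  set.seed(3)
  lo <- mean(replicate(2000, sum(generate_questionnaire(-1, thr))))
  hi <- mean(replicate(2000, sum(generate_questionnaire(1, thr))))
  expect_gt(hi, lo)
})

test_that("actigraphy generator is seeded, non-negative and latent-monotone", {
  d <- test_rest()
  r1 <- generate_actigraphy(0.3, d, seed = 5)
  r2 <- generate_actigraphy(0.3, d, seed = 5)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(r1$counts >= 0))
  expect_identical(length(r1$counts), 1440L)
  # latent -> -Inf: every in-bed epoch silent
  quiet <- generate_actigraphy(-60, d, seed = 6)
  t0 <- as.numeric(quiet$epoch_start)
  in_bed <- t0 >= as.numeric(d$bed_time) & t0 < as.numeric(d$rise_time)
  expect_true(all(quiet$counts[in_bed] == 0))
  expect_error(generate_actigraphy(0, list(bad = 1)), "rest_interval")
  # WASO ordering between high and low latent scores (n = 200 each)
  waso_at <- function(z, seeds) sapply(seeds, function(s)
    actigraphy_summary(generate_actigraphy(z, d, seed = s))$waso)
  expect_gt(mean(waso_at(1.5, 1:200)), mean(waso_at(-1.5, 1:200)))
})

test_that("null-loading cohorts carry no FA-sleep association beyond covariates", {
  cfg <- cohort_config(n_patients = 150, n_controls = 150, seed = 77,
                       latent_loadings_x = rep(0, 48),
                       latent_loadings_y = c(dsi = 0, awi = 0, tst = 0,
                                             se = 0, sfi = 0, waso = 0),
                       prop_missing_items = 0)
  co <- generate_cohort(cfg)
  idx <- sleep_indices(co$ksq)
  idx <- idx[idx$period == "last_4_weeks", ]
  d <- derive_fa(co$roi_fa)
  tab <- merge(merge(co$covariates, d, by = "subject_id"), idx,
               by = "subject_id")
  r <- partial_correlation(tab$callosal_fa, tab$dsi,
                           tab[, c("age", "sex", "abs_motion", "rel_motion")],
                           B = 0)
  expect_gt(r$p_value, 0.001)
  expect_lt(abs(r$r), 0.2)
})

test_that("planted X-direction is recovered through the full measurement chain", {
  cfg <- cohort_config(n_patients = 100, n_controls = 100, seed = 31,
                       prop_missing_items = 0)
  co <- generate_cohort(cfg)
  sleep <- sleep_indices(co$ksq)
  sleep <- sleep[sleep$period == "last_4_weeks", ]
  acti <- do.call(rbind, lapply(names(co$actigraphy), function(id) {
    s <- actigraphy_summary(co$actigraphy[[id]])
    data.frame(subject_id = id, tst = s$tst, se = s$se, sfi = s$sfi,
               waso = s$waso)
  }))
  tab <- merge(merge(co$covariates, sleep, by = "subject_id"), acti,
               by = "subject_id")
  stopifnot(!anyNA(tab))
  X <- as.matrix(co$roi_fa[match(tab$subject_id, co$roi_fa$subject_id), -1])
  Y <- as.matrix(tab[, c("dsi", "awi", "tst", "se", "sfi", "waso")])
  Xr <- residualize_block(X, tab[, c("age", "sex", "abs_motion", "rel_motion")])
  Yr <- residualize_block(Y, tab[, c("age", "sex", "abs_motion", "rel_motion")])
  fit <- fit_plsc(Xr, Yr)
  expect_gte(cosine_sim(fit$x_saliences[, 1], cfg$latent_loadings_x), 0.9)
})

test_that("written cohort files round-trip through read_cohort", {
  co <- generate_cohort(small_config())
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("covariates.csv", "roi_fa.csv",
                                               "ksq.csv", "diary.csv",
                                               "actigraphy.csv",
                                               "truth.json")))))
  back <- read_cohort(dir)
  expect_identical(back$covariates$subject_id, co$covariates$subject_id)
  expect_equal(as.matrix(back$roi_fa[, -1]), as.matrix(co$roi_fa[, -1]),
               tolerance = 1e-12)
  expect_identical(back$actigraphy[["S001"]]$counts,
                   co$actigraphy[["S001"]]$counts)
})
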