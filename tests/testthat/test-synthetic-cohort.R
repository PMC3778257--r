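test_that("spec and effect validation names the offending field", {
  expect_error(cohort_spec(grid_shape = c(4, 16, 16)), "grid_shape")
  expect_error(cohort_spec(n_positive = 1), "n_positive")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(baseline = 1.5), "baseline")
  expect_error(planted_effect(c(2, 2), 2, "left", 0.1), "center")
  expect_error(planted_effect(c(2, 2, 2), 0.5, "left", 0.1), "radius")
  # center on the left but sphere crossing the midline of a 16-grid
  expect_error(
    cohort_spec(effects = list(planted_effect(c(8, 8, 8), 2, "left", 0.1))),
    "midline")
  # effect center outside the grid
  expect_error(
    cohort_spec(effects = list(planted_effect(c(20, 8, 8), 1, "right", 0.1))),
    "outside")
})

test_that("cohort generation is bit-identical under a fixed seed", {
  spec <- cohort_spec(grid_shape = c(16, 16, 16), n_positive = 10,
                      n_negative = 10, noise_sd = 0.05,
                      effects = list(planted_effect(c(12, 8, 8), 2,
                                                    "right", 0.15)),
                      seed = 1)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  for (i in seq_along(a$volumes)) {
    expect_identical(a$volumes[[i]]$data, b$volumes[[i]]$data)
  }
  expect_identical(a$clinical, b$clinical)
})

test_that("noiseless limit plants exactly delta inside the effect, zero outside", {
  eff <- planted_effect(c(4, 6, 6), 2, "left", 0.2)
  spec <- cohort_spec(grid_shape = c(12, 12, 12), n_positive = 2,
                      n_negative = 2, baseline = 0.4, noise_sd = 1e-12,
                      effects = list(eff), smooth_fwhm_mm = 0, seed = 3)
  coh <- generate_cohort(spec)
  labs <- vapply(coh$volumes, function(v) v$label, numeric(1))
  pos_mean <- Reduce(`+`, lapply(coh$volumes[labs == 1],
                                 function(v) v$data)) / 2
  neg_mean <- Reduce(`+`, lapply(coh$volumes[labs == -1],
                                 function(v) v$data)) / 2
  diff <- pos_mean - neg_mean
  inside <- wmpredict:::effect_mask(eff, spec$grid_shape)
  expect_equal(unname(diff[inside]), rep(0.2, sum(inside)), tolerance = 1e-6)
  expect_equal(max(abs(diff[!inside])), 0, tolerance = 1e-6)
})

test_that("null cohorts show only chance-level voxelwise class differences", {
  spec <- cohort_spec(grid_shape = c(16, 16, 16), n_positive = 10,
                      n_negative = 10, noise_sd = 0.05, effects = list(),
                      smooth_fwhm_mm = 0, seed = 11)
  coh <- generate_cohort(spec)
  labs <- vapply(coh$volumes, function(v) v$label, numeric(1))
  X <- t(vapply(coh$volumes, function(v) as.vector(v$data),
                numeric(16^3)))
  tcrit <- qt(0.975, df = 18)
  tstat <- apply(X, 2, function(v) {
    t.test(v[labs == 1], v[labs == -1], var.equal = TRUE)$statistic
  })
  frac <- mean(abs(tstat) > tcrit)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.075)
})

test_that("smoothed planted mass stays within the dilated effect region", {
  eff <- planted_effect(c(12, 8, 8), 3, "right", 0.2)
  spec <- cohort_spec(grid_shape = c(16, 16, 16), n_positive = 2,
                      n_negative = 2, baseline = 0.4, noise_sd = 1e-9,
                      effects = list(eff), smooth_fwhm_mm = 3, seed = 5)
  coh <- generate_cohort(spec)
  labs <- vapply(coh$volumes, function(v) v$label, numeric(1))
  diff <- abs(Reduce(`+`, lapply(coh$volumes[labs == 1],
                                 function(v) v$data)) / 2 -
              Reduce(`+`, lapply(coh$volumes[labs == -1],
                                 function(v) v$data)) / 2)
  sigma <- 3 / (2 * sqrt(2 * log(2)))  # 3 mm FWHM at 1 mm voxels
  dil <- dilate_mask(wmpredict:::effect_mask(eff, spec$grid_shape),
                     ceiling(2 * sigma))
  expect_gte(sum(diff[dil]) / sum(diff), 0.99)
})

test_that("Fisher scores on null cohorts match their label-permuted distribution", {
  ok <- 0L
  for (seed in 1:10) {
    # unsmoothed: the KS test assumes independent voxels, which smoothing
    # would violate (it does not change the per-voxel null distribution)
    spec <- cohort_spec(grid_shape = c(12, 12, 12), n_positive = 8,
                        n_negative = 8, noise_sd = 0.05, effects = list(),
                        smooth_fwhm_mm = 0, seed = 100 + seed)
    coh <- generate_cohort(spec)
    labs <- vapply(coh$volumes, function(v) v$label, numeric(1))
    X <- t(vapply(coh$volumes, function(v) as.vector(v$data),
                  numeric(12^3)))[, 1:1000]
    s_true <- fisher_scores(X, labs)$scores
    perm <- withr::with_seed(seed, sample(labs))
    s_perm <- fisher_scores(X, perm)$scores
    p <- suppressWarnings(ks.test(s_true, s_perm)$p.value)
    if (p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("clinical tables satisfy the record invariants and are controllable", {
  tab <- generate_clinical_table(11, 8, seed = 2)
  expect_equal(nrow(tab), 19)
  expect_true(all(tab$age_at_surgery >= tab$age_at_mri))
  expect_true(all(tab$age_at_mri >= tab$age_at_onset))
  expect_true(all(tab$age_at_onset >= 0))
  expect_true(all(tab$followup_months >= 12))
  expect_true(all(tab$febrile %in% c(0, 1)))
  expect_identical(tab, generate_clinical_table(11, 8, seed = 2))

  # location parameters steer the simulated medians: FO onset median lands
  # inside the configured uniform range
  med <- median(tab$age_at_onset[tab$label == 1])
  expect_gte(med, 18 - 12)
  expect_lte(med, 18 + 12)

  # degenerate distributions give an exact constant table
  const <- generate_clinical_table(
    2, 2, seed = 1, median_onset = c(pos = 10, neg = 10), onset_spread = 0,
    median_mri_age = c(pos = 30, neg = 30), mri_spread = 0,
    febrile_prob = c(pos = 0, neg = 0), freq_meanlog = log(4),
    freq_sdlog = 0, followup_median = 24, followup_spread = 0,
    surgery_delay_prob = 0)
  expect_equal(unique(const$age_at_onset), 10)
  expect_equal(unique(const$age_at_mri), 30)
  expect_equal(unique(const$age_at_surgery), 30)
  expect_equal(unique(const$seizure_freq_per_month), 4)
  expect_equal(unique(const$followup_months), 24)
  expect_equal(unique(const$febrile), 0)

  expect_error(generate_clinical_table(1, 8), "counts")
  expect_error(generate_clinical_table(5, 5, febrile_prob = c(pos = 2, neg = 0)),
               "febrile_prob")
})
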