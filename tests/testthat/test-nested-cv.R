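make_noise_dataset <- function(n_pos, n_neg, n_feat, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n_feat * (n_pos + n_neg)), n_pos + n_neg, n_feat)
  y <- c(rep(1, n_pos), rep(-1, n_neg))
  list(X = X, y = y)
}

test_that("grid validation enforces ordered positive values", {
  expect_error(hyper_grid(C_values = c(1, 0.1)), "C_values")
  expect_error(hyper_grid(C_values = numeric(0)), "C_values")
  expect_error(hyper_grid(k_values = c(10, 10)), "k_values")
  expect_error(hyper_grid(k_values = c(0, 5)), "k_values")
})

test_that("a single grid cell is returned without search", {
  d <- make_noise_dataset(3, 3, 20, 1)
  g <- hyper_grid(C_values = 1, k_values = 5L)
  sel <- inner_select(d$X, d$y, g)
  expect_equal(sel$C, 1)
  expect_equal(sel$k, 5L)
})

test_that("a perfectly separating column wins the k tie-break at k = 1", {
  set.seed(3)
  n <- 12
  y <- rep(c(1, -1), each = 6)
  X <- matrix(rnorm(n * 10, sd = 0.3), n, 10)
  X[, 4] <- y * 2  # one clean separator
  g <- hyper_grid(C_values = 1, k_values = c(1L, 10L))
  sel <- inner_select(X, y, g)
  expect_equal(sel$k, 1L)
  expect_equal(sel$inner_balanced_accuracy, 1)
})

test_that("inner selection is deterministic and value-based", {
  d <- make_noise_dataset(5, 5, 30, 7)
  g <- small_grid()
  s1 <- inner_select(d$X, d$y, g)
  s2 <- inner_select(d$X, d$y, g)
  expect_identical(s1, s2)
  # grid k values exceeding the feature count are dropped, not fatal
  g2 <- hyper_grid(C_values = 1, k_values = c(10L, 1000L))
  expect_equal(inner_select(d$X, d$y, g2)$k, 10L)
  expect_error(inner_select(d$X, d$y,
                            hyper_grid(C_values = 1, k_values = 1000L)),
               "exceed")
})

test_that("outer LOSO yields exactly one out-of-fold prediction per subject", {
  coh <- generate_cohort(null_spec(1))
  ds <- build_dataset(coh$volumes, clinical = coh$clinical)
  g <- hyper_grid(C_values = 1, k_values = c(5L, 20L))
  cv <- outer_loso(ds, g)
  expect_equal(nrow(cv$subjects), 12)
  expect_setequal(cv$subjects$id, ds$subject_ids)
  expect_equal(length(cv$folds), 12)
  for (f in cv$folds) {
    expect_equal(length(f$columns), f$k)
    expect_true(all(f$columns >= 1 & f$columns <= ncol(ds$X)))
  }
  expect_error(outer_loso(structure(list(X = ds$X[1:3, ], y = c(1, 1, -1)),
                                    class = "cohort_dataset"), g),
               "N >= 4")
})

test_that("a strong planted signal is classified perfectly out of fold", {
  coh <- generate_cohort(strong_signal_spec(42))  # delta = 3 * noise_sd
  ds <- build_dataset(coh$volumes, clinical = coh$clinical)
  cv <- outer_loso(ds, small_grid())
  cs <- confusion_from_decisions(cv$subjects$actual, cv$subjects$decision)
  expect_equal(cs$balanced_accuracy, 1)
})

test_that("held-out subjects cannot leak into fold-level selection", {
  coh <- generate_cohort(null_spec(5))
  ds <- build_dataset(coh$volumes, clinical = coh$clinical)
  g <- hyper_grid(C_values = c(0.1, 1), k_values = c(5L, 15L))
  cv <- outer_loso(ds, g)
  for (i in c(1L, 7L)) {
    ds2 <- ds
    set.seed(1000 + i)
    ds2$X[i, ] <- runif(ncol(ds$X), -10, 10)  # arbitrary junk row
    cv2 <- outer_loso(ds2, g)
    expect_identical(cv2$folds[[i]]$C, cv$folds[[i]]$C)
    expect_identical(cv2$folds[[i]]$k, cv$folds[[i]]$k)
    expect_identical(cv2$folds[[i]]$columns, cv$folds[[i]]$columns)
    expect_identical(cv2$folds[[i]]$w, cv$folds[[i]]$w)
  }
})

test_that("the full-cohort refit is deterministic and recovers planted voxels", {
  coh <- generate_cohort(strong_signal_spec(43))
  ds <- build_dataset(coh$volumes, clinical = coh$clinical)
  g <- small_grid()
  fm1 <- final_model(ds, g)
  fm2 <- final_model(ds, g)
  expect_identical(fm1$columns, fm2$columns)
  expect_equal(fm1$model$w, fm2$model$w)

  # selected voxels fall inside the (smoothing-dilated) planted region
  eff <- strong_signal_spec(43)$effects[[1]]
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  dil <- dilate_mask(wmpredict:::effect_mask(eff, ds$grid_shape),
                     ceiling(2 * sigma))
  hits <- dil[ds$voxel_index_map[fm1$columns, , drop = FALSE]]
  expect_gte(mean(hits), 0.8)

  # single grid cell refits deterministically without search
  fm3 <- final_model(ds, hyper_grid(C_values = 1, k_values = 10L))
  expect_equal(fm3$k, 10L)
  expect_equal(length(fm3$model$w), 10L)
})

test_that("cv results write a per-patient CSV plus fold sidecar", {
  coh <- generate_cohort(null_spec(2))
  ds <- build_dataset(coh$volumes, clinical = coh$clinical)
  cv <- outer_loso(ds, hyper_grid(C_values = 1, k_values = 5L))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_cv_result(cv, csv, js)
  got <- read.csv(csv)
  expect_equal(got$decision, cv$subjects$decision)
  folds <- jsonlite::read_json(js)
  expect_equal(length(folds), 12)
  unlink(c(csv, js))
})
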