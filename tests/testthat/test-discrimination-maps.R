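make_map <- function(volume) {
  structure(list(volume = volume, grid_shape = dim(volume),
                 provenance = "final_refit"),
            class = "discrimination_map")
}

test_that("weights land on their voxels and read back exactly", {
  model <- structure(list(w = 0.5, selected_columns = 1L),
                     class = "svm_model")
  vim <- matrix(c(2, 3, 4), 1, 3)
  map <- weights_to_volume(model, vim, c(8, 8, 8))
  expect_equal(map$volume[2, 3, 4], 0.5)
  expect_equal(sum(map$volume != 0), 1)

  set.seed(6)
  w <- rnorm(12)
  vim2 <- unique(cbind(sample(8, 12, TRUE), sample(8, 12, TRUE),
                       sample(8, 12, TRUE)))
  w <- w[seq_len(nrow(vim2))]
  model2 <- structure(list(w = w,
                           selected_columns = seq_len(nrow(vim2))),
                      class = "svm_model")
  map2 <- weights_to_volume(model2, vim2, c(8, 8, 8))
  expect_equal(map2$volume[vim2], w)
  expect_error(weights_to_volume(model, matrix(c(9, 1, 1), 1, 3),
                                 c(8, 8, 8)), "outside")
})

test_that("a mirrored map is exactly symmetric under the lateralization tests", {
  set.seed(44)
  d <- c(10, 9, 9)
  vol <- array(0, dim = d)
  # left half random, right half its mirror across the first axis
  left <- array(0, dim = d)
  left[1:5, , ][sample(5 * 81, 40)] <- rnorm(40)
  vol <- left + left[10:1, , ]
  map <- make_map(vol)
  ls <- lateralization_summary(map)
  expect_equal(ls$tests$statistic[ls$tests$comparison == "left_vs_right"], 0)
  expect_equal(ls$tests$p[ls$tests$comparison == "left_vs_right"], 1)

  # mirror flip swaps hemisphere summaries and keeps all p-values
  asym <- array(0, dim = d)
  asym[cbind(sample(10, 30, TRUE), sample(9, 30, TRUE),
             sample(9, 30, TRUE))] <- rnorm(30)
  m1 <- lateralization_summary(make_map(asym))
  m2 <- lateralization_summary(make_map(asym[10:1, , ]))
  t1 <- m1$table
  t2 <- m2$table
  for (s in c("positive", "negative")) {
    expect_equal(t1$n_voxels[t1$hemisphere == "left" & t1$sign == s],
                 t2$n_voxels[t2$hemisphere == "right" & t2$sign == s])
    expect_equal(t1$sum_abs_weight[t1$hemisphere == "left" & t1$sign == s],
                 t2$sum_abs_weight[t2$hemisphere == "right" & t2$sign == s])
  }
  expect_equal(m1$tests$p, m2$tests$p)
  expect_equal(sum(t1$n_voxels), sum(asym != 0))
})

test_that("fully lateralized maps give the closed-form chi-square", {
  d <- c(10, 10, 10)
  vol <- array(0, dim = d)
  vol[6:10, 1:4, 1:5] <- 1  # 100 voxels, all right hemisphere
  expect_equal(sum(vol != 0), 100)
  ls <- lateralization_summary(make_map(vol))
  lr <- ls$tests[ls$tests$comparison == "left_vs_right", ]
  expect_equal(lr$statistic, 100)  # (100-50)^2/50 * 2
  expect_lt(lr$p, 1e-22)
  expect_error(lateralization_summary(make_map(array(0, dim = d))),
               "all-zero")
})

test_that("weight-sum units are available and recorded", {
  d <- c(8, 8, 8)
  vol <- array(0, dim = d)
  vol[5:8, 1, 1] <- c(2, 2, 2, 2)   # right, positive, heavy
  vol[1, 1, 1:2] <- c(-0.1, 0.1)    # left, light
  ls_c <- lateralization_summary(make_map(vol), unit = "count")
  ls_w <- lateralization_summary(make_map(vol), unit = "weight")
  expect_equal(ls_c$unit, "count")
  expect_equal(ls_w$unit, "weight")
  # counts 2 vs 4; weight 0.2 vs 8 - the two units disagree on the statistic
  stat_c <- ls_c$tests$statistic[1]
  stat_w <- ls_w$tests$statistic[1]
  expect_equal(stat_c, (2 - 3)^2 / 3 + (4 - 3)^2 / 3)
  expect_equal(stat_w, (0.2 - 4.1)^2 / 4.1 + (8 - 4.1)^2 / 4.1)
})

test_that("a lateralized planted effect yields a lateralized recovered map", {
  coh <- generate_cohort(strong_signal_spec(46))  # right-hemisphere effect
  ds <- build_dataset(coh$volumes, clinical = coh$clinical)
  # 30 selected voxels: enough count for the chi-square to resolve p < 1e-3
  fm <- final_model(ds, hyper_grid(C_values = c(0.1, 1, 10), k_values = 30L))
  map <- weights_to_volume(fm$model, ds$voxel_index_map, ds$grid_shape)
  ls <- lateralization_summary(map)
  expect_lt(ls$tests$p[ls$tests$comparison == "left_vs_right"], 0.001)
  right <- sum(ls$table$n_voxels[ls$table$hemisphere == "right"])
  expect_gt(right, sum(ls$table$n_voxels) / 2)

  # >= 80% of |weight| mass inside the dilated planted region
  eff <- strong_signal_spec(46)$effects[[1]]
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  dil <- dilate_mask(wmpredict:::effect_mask(eff, ds$grid_shape),
                     ceiling(2 * sigma))
  expect_gte(sum(abs(map$volume[dil])) / sum(abs(map$volume)), 0.8)

  # fold-averaged alternative shares the lateralization
  cv <- outer_loso(ds, hyper_grid(C_values = 1, k_values = 30L))
  fa <- fold_average_map(cv, ds$voxel_index_map, ds$grid_shape)
  expect_equal(fa$provenance, "fold_average")
  ls_fa <- lateralization_summary(fa)
  expect_lt(ls_fa$tests$p[ls_fa$tests$comparison == "left_vs_right"], 0.001)
})
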