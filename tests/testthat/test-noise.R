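test_that("clone statistics match hand values and are scale-consistent", {
  cs <- clone_stats(c(1, 2, 3), "a")
  expect_equal(cs$mean, 2)
  expect_equal(cs$sd, 1)       # sample sd, n - 1 denominator
  expect_equal(cs$cv2, 0.25)
  eq <- clone_stats(rep(5, 10), "b")
  expect_equal(eq$sd, 0)
  expect_equal(eq$cv2, 0)
  # doubling all cells doubles mean and sd, cv2 unchanged
  cs2 <- clone_stats(2 * c(1, 2, 3), "a")
  expect_equal(cs2$mean, 4)
  expect_equal(cs2$sd, 2)
  expect_equal(cs2$cv2, cs$cv2)
  expect_error(clone_stats(1, "x"), class = "insertionfate_insufficient_data")
  expect_true(is.na(clone_stats(c(0, 0), "z")$cv2))
})

test_that("noise-scaling fit recovers exact proportionality and plants a unique outlier", {
  set.seed(12)
  means <- runif(50, 10, 500)
  jitter <- runif(50, 0.95, 1.05)
  st <- data.frame(clone_id = sprintf("c%02d", 1:50), mean = means,
                   sd = 0.2 * means * jitter, n_cells = 100, copy_number = 1)
  fit <- fit_noise_scaling(st)
  expect_equal(fit$slope_c, 0.2, tolerance = 0.02)
  expect_length(fit$outlier_ids, 0)
  # exact proportionality: c exact, no outliers
  exact <- st; exact$sd <- 0.2 * exact$mean
  expect_equal(fit_noise_scaling(exact)$slope_c, 0.2)
  # one steep clone sd = 1.0 * mean is the unique flagged outlier
  steep <- rbind(st, data.frame(clone_id = "steep", mean = 100, sd = 100,
                                n_cells = 100, copy_number = 1))
  expect_identical(fit_noise_scaling(steep)$outlier_ids, "steep")
  expect_error(fit_noise_scaling(st[1:4, ]), class = "insertionfate_insufficient_data")
})

test_that("outlier classification is invariant under cohort-wide rescaling", {
  set.seed(13)
  means <- runif(40, 20, 200)
  st <- data.frame(clone_id = sprintf("c%02d", 1:40), mean = means,
                   sd = 0.25 * means * runif(40, 0.97, 1.03),
                   n_cells = 100, copy_number = 1)
  st$sd[7] <- st$mean[7] * 0.9
  f1 <- fit_noise_scaling(st)
  scaled <- st; scaled$mean <- scaled$mean * 37; scaled$sd <- scaled$sd * 37
  f2 <- fit_noise_scaling(scaled)
  expect_identical(f1$outlier_ids, f2$outlier_ids)
  expect_equal(f1$slope_c, f2$slope_c)
})

test_that("copy-number normalization of summary stats rescales but keeps cv2", {
  st <- clone_stats(c(27, 30, 33), "m", copy_number = 3)
  norm <- normalize_by_copy_number(st)
  expect_equal(norm$mean, st$mean / 3)
  expect_equal(norm$sd, st$sd / 3)
  expect_equal(norm$cv2, st$cv2)
  expect_equal(norm$copy_number, 1L)
  one <- clone_stats(c(10, 12), "o", copy_number = 1)
  expect_equal(normalize_by_copy_number(one)$mean, one$mean)
  bad <- one; bad$copy_number <- 0L
  expect_error(normalize_by_copy_number(bad), class = "insertionfate_validation_error")
})

test_that("multi-insertion clones are steep-noise outliers removed by per-cell normalization", {
  cfg <- synth_config()
  recs <- c(lapply(1:40, function(i) toy_clone(sprintf("s%02d", i), k = 1)),
            lapply(1:3, function(i) toy_clone(sprintf("m2_%d", i), k = 2)),
            lapply(1:3, function(i) toy_clone(sprintf("m3_%d", i), k = 3)))
  clones <- lapply(seq_along(recs), function(i) {
    sample_cell_expression(recs[[i]], 600, "fast", cfg, seed = 400 + i)
  })
  st <- cohort_stats(clones)
  fit <- fit_noise_scaling(st)
  multi <- grep("^m", st$clone_id, value = TRUE)
  expect_setequal(fit$outlier_ids, multi)
  # stats-level normalization cannot change sd/mean, so outliers persist
  fit_stats <- fit_noise_scaling(normalize_by_copy_number(st))
  expect_setequal(fit_stats$outlier_ids, multi)
  # per-cell normalization removes the cassette-count variance component
  norm <- lapply(clones, normalize_expression_by_copy_number)
  expect_length(fit_noise_scaling(cohort_stats(norm))$outlier_ids, 0)
})

test_that("growth trend slope and label match hand computations", {
  expect_equal(growth_trend(c(0.5, 1), c(10, 20))$slope, 20)
  expect_equal(growth_trend(c(0.5, 1), c(10, 20))$label, "increasing")
  dec <- growth_trend(c(0.5, 1), c(20, 10))
  expect_equal(dec$slope, -20)
  expect_equal(dec$label, "decreasing")
  expect_equal(growth_trend(c(0.5, 1, 1.5), c(12, 12, 12))$label, "flat")
  expect_error(growth_trend(c(1, 1), c(5, 6)), class = "insertionfate_validation_error")
})
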