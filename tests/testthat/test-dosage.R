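test_that("closed-form copy number matches hand values and is monotone", {
  p <- dosage_params(40, 20, 30)
  expect_equal(mean_copy_number(0, p), 4)               # 2^((40+20)/30)
  expect_equal(mean_copy_number(1, p), 2^(2 / 3))
  expect_equal(mean_copy_number(0.5, dosage_params(0, 0, 45)), 1)
  m <- seq(0, 1, by = 0.05)
  expect_true(all(diff(mean_copy_number(m, p)) < 0))    # non-increasing for C > 0
  expect_equal(mean_copy_number(0, p), 2^((p$C_min + p$D_min) / p$tau_min))
})

test_that("fork simulator agrees with the closed form at every decile", {
  m <- seq(0, 1, by = 0.1)
  for (prm in list(dosage_params(40, 20, 30), dosage_params(40, 20, 60),
                   dosage_params(0, 0, 30))) {
    fk <- simulate_copy_number_fork(m, prm, n_cells = 2e4, seed = 7)
    closed <- mean_copy_number(m, prm)
    expect_true(all(abs(fk$mean - closed) <= pmax(3 * fk$se, 1e-12)))
  }
})

test_that("dosage profile is flat without replication lag, ori-peaked and symmetric", {
  g <- genome_spec(100000, 20000)
  expect_true(all(dosage_profile(g, dosage_params(0, 0, 30), 50)$values == 1))
  prof <- dosage_profile(g, dosage_params(40, 20, 30), 50)
  at_ori <- which.min(abs(prof$centers - 20000))
  at_ter <- which.min(abs(prof$centers - 70000))
  expect_gt(prof$values[at_ori], prof$values[at_ter])
  # antipodal ter: mirror bins about ori carry equal dosage
  m <- locus_relative_position(prof$centers, g)
  mirror <- locus_relative_position((2 * 20000 - prof$centers) %% 100000, g)
  expect_equal(mean_copy_number(m, dosage_params(40, 20, 30)),
               mean_copy_number(mirror, dosage_params(40, 20, 30)))
})

test_that("exponent fit recovers exact log-linear relations and is scale-invariant", {
  g <- genome_spec(100000, 0)
  pred <- dosage_profile(g, dosage_params(40, 20, 30), 40)
  obs_eq <- coverage_profile(pred$centers, pred$values, pred$window_bp, pred$step_bp)
  expect_silent(fit_eq <- fit_dosage_exponent(obs_eq, pred))
  expect_equal(fit_eq$alpha, 1, tolerance = 1e-9)
  obs_cube <- coverage_profile(pred$centers, pred$values^3, pred$window_bp, pred$step_bp)
  fit3 <- fit_dosage_exponent(obs_cube, pred)
  expect_equal(fit3$alpha, 3, tolerance = 1e-6)
  # scale invariance: multiplying either profile by a constant leaves alpha
  obs_scaled <- coverage_profile(pred$centers, 7.3 * pred$values^3,
                                 pred$window_bp, pred$step_bp)
  expect_equal(fit_dosage_exponent(obs_scaled, pred)$alpha, fit3$alpha)
  # zero bins are dropped and counted
  vals <- pred$values^2; vals[c(3, 8)] <- 0
  fit0 <- fit_dosage_exponent(coverage_profile(pred$centers, vals,
                                               pred$window_bp, pred$step_bp), pred)
  expect_equal(fit0$n_dropped, 2)
  expect_equal(fit0$n_bins, 38)
  few <- coverage_profile(pred$centers, c(rep(0, 38), 1, 2), pred$window_bp, pred$step_bp)
  expect_error(fit_dosage_exponent(few, pred), class = "insertionfate_insufficient_data")
})

test_that("age-structured simulator reproduces the dosage profile at beta = 0", {
  g <- genome_spec(500000, 100000, 350000)
  p <- dosage_params(40, 20, 30)
  expect_length(simulate_age_structured_insertions(g, p, n = 0, seed = 1), 0)
  ins <- simulate_age_structured_insertions(g, p, time_rate_model(0), n = 4e4, seed = 3)
  m <- locus_relative_position(ins$positions, g)
  br <- seq(0, 1, by = 0.1)
  h <- as.numeric(table(cut(m, br)))
  e <- vapply(seq_len(10), function(i) {
    stats::integrate(function(x) mean_copy_number(x, p), br[i], br[i + 1])$value
  }, numeric(1))
  e <- e / sum(e) * length(m)
  chi <- sum((h - e)^2 / e)
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.01)
})

test_that("rate growth strictly and monotonically steepens the ori/ter density ratio", {
  g <- genome_spec(500000, 100000, 350000)
  p <- dosage_params(40, 20, 30)
  for (s in c(5, 6)) {
    ratios <- vapply(c(0, 1, 2), function(beta) {
      ins <- simulate_age_structured_insertions(g, p, time_rate_model(beta),
                                                n = 2e4, seed = s)
      m <- locus_relative_position(ins$positions, g)
      sum(m < 0.2) / sum(m > 0.8)
    }, numeric(1))
    expect_true(all(diff(ratios) > 0))
  }
})
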