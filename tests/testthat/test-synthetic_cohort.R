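test_that("default configuration reproduces the study design", {
  cfg <- cohort_config(seed = 1)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$dogs), 44)
  expect_equal(sum(sim$dogs$diagnosis == "HD"), 14)
  expect_true(all(sim$dogs$pathological_side[sim$dogs$diagnosis == "HD"]
                  %in% c("left", "right")))
  expect_true(all(sim$dogs$pathological_side[sim$dogs$diagnosis == "healthy"]
                  == "none"))
  # visit schedule: monthly 84-196 d, bimonthly to 436 d, all within 450 d
  expect_equal(sort(unique(sim$runs$age_days)),
               c(84L, 112L, 140L, 168L, 196L, 256L, 316L, 376L, 436L))
  expect_true(all(sim$runs$run_index %in% 1:3))
  # runs parse through the documented dialect unchanged
  path <- write_temp_csv(sim$runs)
  expect_equal(nrow(read_runs(path)), nrow(sim$runs))
})

test_that("a fixed seed gives identical output, different seeds differ", {
  a <- simulate_cohort(cohort_config(seed = 9))
  b <- simulate_cohort(cohort_config(seed = 9))
  c <- simulate_cohort(cohort_config(seed = 10))
  expect_identical(a$runs, b$runs)
  expect_identical(a$dogs, b$dogs)
  expect_false(identical(a$runs$value, c$runs$value))
})

test_that("invalid configurations are rejected before generation", {
  expect_error(cohort_config(n_dogs = 10, n_hd = 11),
               class = "gv_config_error")
  expect_error(cohort_config(schedule_days = c(84, 500)),
               class = "gv_config_error")
  expect_error(cohort_config(runs_per_day = 4), class = "gv_config_error")
  expect_error(cohort_config(implausible_rate = 1.2),
               class = "gv_config_error")
  fp <- default_feature_params()
  fp$sigma_hd <- fp$sigma_healthy * 0.5
  expect_error(cohort_config(feature_params = fp),
               class = "gv_config_error")
})

test_that("injection rate 0 is the identity, rate 1 hits every dog-day", {
  cfg0 <- cohort_config(n_dogs = 6, n_hd = 2, features = tiny_catalogue(),
                        feature_params = tiny_params(),
                        implausible_rate = 0, seed = 4)
  sim0 <- simulate_cohort(cfg0)
  expect_equal(nrow(sim0$truth), 0)

  cfg1 <- cohort_config(n_dogs = 6, n_hd = 2, features = tiny_catalogue(),
                        feature_params = tiny_params(),
                        implausible_rate = 1, seed = 4)
  sim1 <- simulate_cohort(cfg1)
  n_days <- dplyr::n_distinct(paste(sim1$runs$dog_id, sim1$runs$age_days))
  expect_equal(nrow(sim1$truth), n_days)
  # injected step lengths echo the 2 m anomaly and violate the 0.6 m bound
  sl <- sim1$truth[grepl("len", sim1$truth$feature_id), ]
  expect_true(all(sl$injected_value == 2.0))
  expect_true(all(sl$injected_value > 0.6))
  # downstream, preprocessing must exclude every day
  pre <- preprocess_runs(sim1$runs, sim1$features)
  expect_equal(nrow(pre$series), 0)
})

test_that("expected MSE from the truth report matches Monte-Carlo pipeline output", {
  feat <- tiny_catalogue()[3:5, ]   # angle_r, angle_l, axial_sym
  fp <- tibble::tibble(feature_id = feat$feature_id,
                       intercept = c(20, 20, 100), slope = c(0.02, 0.02, 0),
                       run_sd = c(0.4, 0.4, 0.8),
                       sigma_healthy = c(1, 1, 2), sigma_hd = c(1.6, 1.6, 3))
  reps <- 300
  means <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    cfg <- cohort_config(n_dogs = 10, n_hd = 4, features = feat,
                         feature_params = fp, seed = 5000 + r)
    sim <- simulate_cohort(cfg)
    pre <- preprocess_runs(sim$runs, sim$features)
    tab <- build_instability_table(pre$series, sim$dogs, sim$features)
    keep <- tab$feature_id == "angle_r"
    means[r, 1] <- mean(tab$mse[keep & tab$diagnosis == "healthy"])
    means[r, 2] <- mean(tab$mse[keep & tab$diagnosis == "HD"])
  }
  tr <- truth_report(cohort_config(n_dogs = 10, n_hd = 4, features = feat,
                                   feature_params = fp, seed = 1))
  exp_h <- tr$expected_mse$expected_mse[
    tr$expected_mse$feature_id == "angle_r" &
      tr$expected_mse$group == "healthy"]
  exp_d <- tr$expected_mse$expected_mse[
    tr$expected_mse$feature_id == "angle_r" &
      tr$expected_mse$group == "HD"]
  for (g in 1:2) {
    obs <- mean(means[, g])
    se <- sd(means[, g]) / sqrt(reps)
    expect_lt(abs(obs - c(exp_h, exp_d)[g]), 3 * se)
  }
})

test_that("an OLS on n visits keeps (n-2)/n of the noise variance", {
  cfg <- cohort_config(seed = 1)
  tr <- truth_report(cfg)
  # with 9 visits the shrinkage factor is 7/9; run noise adds
  # run_sd^2 * E[1/m] with E[1/m] = 11/18 for m uniform on {1,2,3}
  fp <- cfg$feature_params
  i <- match("extension_r", fp$feature_id)
  expected <- (fp$sigma_healthy[i]^2 + fp$run_sd[i]^2 * (11 / 18)) * 7 / 9
  got <- tr$expected_mse$expected_mse[
    tr$expected_mse$feature_id == "extension_r" &
      tr$expected_mse$group == "healthy"]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("dispersion inflation at ratio 1.5 is detected in most seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- null_config(seed = 4000 + s, sigma_hd = 1.5)
    sim <- simulate_cohort(cfg)
    res <- run_gait_analysis(sim$runs, sim$dogs, sim$features)
    res$comparisons$p_value[1] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.6)
})
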