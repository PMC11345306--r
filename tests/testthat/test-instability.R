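test_that("linear trend fit matches hand-derived solutions", {
  # collinear points: exact fit
  fit <- fit_linear_trend(c(84, 112, 140), c(10, 12, 14))
  expect_equal(fit$slope, 1 / 14)
  expect_equal(fit$intercept, 4)
  expect_equal(fit$residuals, c(0, 0, 0))
  expect_equal(fit$mse, 0)

  # constant series
  fit <- fit_linear_trend(c(84, 112, 140), c(5, 5, 5))
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 5)

  # normal-equations hand calculation
  fit <- fit_linear_trend(c(0, 1, 2), c(0, 1, 0))
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 1 / 3)
  expect_equal(fit$residuals, c(-1 / 3, 2 / 3, -1 / 3))
  expect_equal(mse_score(fit), 2 / 9)
})

test_that("degenerate series are refused", {
  expect_error(fit_linear_trend(c(84, 112), c(1, 2)),
               class = "gv_degenerate_error")
  expect_error(fit_linear_trend(c(84, 84, 84), c(1, 2, 3)),
               class = "gv_degenerate_error")
})

test_that("mse divisor is the visit count (n - 2 behind a flag)", {
  fit <- fit_linear_trend(c(0, 1, 2, 3), c(0, 2, 1, 4))
  expect_equal(mse_score(fit), sum(fit$residuals^2) / 4)
  expect_equal(mse_score(fit, df_correct = TRUE), sum(fit$residuals^2) / 2)
  expect_equal(mse_score(fit) * 4, mse_score(fit, df_correct = TRUE) * 2)
})

test_that("OLS agrees with an independent normal-equations solver", {
  # oracle: solve (X'X) b = X'y explicitly
  ne_solve <- function(x, y) {
    X <- cbind(1, x)
    solve(t(X) %*% X, t(X) %*% y)
  }
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    x <- sort(sample(60:460, n))
    y <- rnorm(n, sd = runif(1, 0.1, 10))
    fit <- fit_linear_trend(x, y)
    b <- ne_solve(x, y)
    expect_equal(fit$intercept, b[1], tolerance = 1e-10)
    expect_equal(fit$slope, b[2], tolerance = 1e-10)
    # residuals of an intercept fit sum to zero
    expect_lt(abs(sum(fit$residuals)), 1e-8)
  }
})

test_that("mse is invariant under adding an affine function of age", {
  set.seed(8)
  x <- c(84, 112, 140, 196, 256, 316)
  y <- rnorm(6, 10, 2)
  base <- fit_linear_trend(x, y)$mse
  for (i in 1:20) {
    a <- rnorm(1, sd = 5); b <- rnorm(1, sd = 0.1)
    expect_equal(fit_linear_trend(x, y + a + b * x)$mse, base,
                 tolerance = 1e-8)
  }
})

test_that("alignment mirrors non-axial features and is an involution", {
  cat <- tiny_catalogue()
  dogs <- tiny_dogs()
  # left-pathological dog: lateral and symmetry features swap sides
  expect_equal(align_to_pathological_side("angle_r", "left", cat), "angle_l")
  expect_equal(align_to_pathological_side("len_r", "left", cat), "len_l")
  # axial features never move
  expect_equal(align_to_pathological_side("axial_sym", "left", cat),
               "axial_sym")
  # right-pathological dog with right reference: identity
  expect_equal(align_to_pathological_side("angle_r", "right", cat),
               "angle_r")
  # healthy dogs adopt the configured reference side, so they map
  # identically whichever side is the convention
  expect_equal(align_to_pathological_side("angle_r", "none", cat), "angle_r")
  expect_equal(align_to_pathological_side("angle_r", "none", cat,
                                          reference_side = "left"),
               "angle_r")
  # under a left reference the right-pathological dog is the one mirrored
  expect_equal(align_to_pathological_side("angle_r", "right", cat,
                                          reference_side = "left"),
               "angle_l")
  # involution: mirroring twice returns the original feature
  for (f in cat$feature_id[cat$feature_id != "energy_r"]) {
    once <- align_to_pathological_side(f, "left", cat)
    expect_equal(align_to_pathological_side(once, "left", cat), f)
  }
  # lateralized feature without a counterpart
  expect_error(align_to_pathological_side("energy_r", "left", cat),
               class = "gv_catalogue_error")
  expect_error(align_to_pathological_side("nope", "left", cat),
               class = "gv_catalogue_error")
})

test_that("default-catalogue mirroring matches the printed symmetry pairs", {
  cat <- default_feature_catalogue()
  expect_equal(
    align_to_pathological_side("maxacc_sym_fr_hl", "left", cat),
    "maxacc_sym_fl_hr"
  )
  expect_equal(
    align_to_pathological_side("sym_pr_lumbar", "left", cat),
    "sym_pr_lumbar"
  )
})

test_that("instability table has one row per dog and aligned feature", {
  series <- dplyr::bind_rows(
    tibble::tibble(dog_id = "d1", feature_id = "angle_r",
                   age_days = c(84L, 112L, 140L, 168L), value = c(1, 2, 4, 3)),
    tibble::tibble(dog_id = "d1", feature_id = "axial_sym",
                   age_days = c(84L, 112L, 140L, 168L), value = c(5, 6, 7, 9)),
    tibble::tibble(dog_id = "d2", feature_id = "angle_r",
                   age_days = c(84L, 112L, 140L), value = c(2, 2, 3)),
    # two-point series: must be skipped, not fatal
    tibble::tibble(dog_id = "d2", feature_id = "axial_sym",
                   age_days = c(84L, 112L), value = c(1, 2))
  )
  tab <- build_instability_table(series, tiny_dogs(), tiny_catalogue())
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$mse >= 0))
  skipped <- attr(tab, "skipped")
  expect_equal(skipped$dog_id, "d2")
  expect_equal(skipped$reason, "too_few_days")
  # d2 is left-pathological: its angle_r rows align to angle_l
  expect_equal(tab$feature_id[tab$dog_id == "d2"], "angle_l")
  expect_equal(tab$diagnosis[tab$dog_id == "d2"], "HD")
})

test_that("a noise-free cohort yields zero instability everywhere", {
  feat <- tiny_catalogue()[3:5, ]
  fp <- tibble::tibble(feature_id = feat$feature_id,
                       intercept = c(20, 20, 100), slope = c(0.02, 0.02, 0),
                       run_sd = 0, sigma_healthy = 1e-12, sigma_hd = 1e-12)
  cfg <- cohort_config(n_dogs = 6, n_hd = 2, features = feat,
                       feature_params = fp, seed = 3)
  sim <- simulate_cohort(cfg)
  pre <- preprocess_runs(sim$runs, sim$features)
  tab <- build_instability_table(pre$series, sim$dogs, sim$features)
  expect_equal(nrow(tab), 6 * 3)
  expect_true(all(tab$mse < 1e-18))
})
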