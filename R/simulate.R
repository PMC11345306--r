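#' Default simulator parameters per feature
#'
#' Per-feature trend and noise parameters used by [simulate_cohort()]:
#' intercept and slope of the linear growth trend (value units, units/day),
#' the within-day run-repeat noise SD, and the between-visit noise SD per
#' diagnosis group. Visit-level dispersion is calibrated so that the
#' pipeline's MSE instability scores land near the reference study's
#' printed group means: with n scheduled visits and m runs per day uniform
#' on the configured set, E\[MSE\] = (sigma_visit^2 + run_sd^2 E\[1/m\])
#' (n-2)/n, which is inverted for sigma_visit given a target mean MSE and
#' run_sd fixed at 25% of the target's scale. The trends themselves are
#' plausible stand-ins (the study did not publish per-feature trend
#' magnitudes). The step-length features deliberately carry a much smaller
#' dispersion than the printed MSE would imply, because the printed value
#' is incompatible with the (0.1 m, 0.6 m] plausibility band; their
#' healthy:HD dispersion ratio is preserved.
#'
#' @param catalogue Feature catalogue the parameters must cover.
#' @param n_visits Number of scheduled visits used in the calibration.
#' @param runs_per_day Integer set of possible runs per day.
#' @return Tibble: `feature_id`, `intercept`, `slope`, `run_sd`,
#'   `sigma_healthy`, `sigma_hd`.
#' @export
default_feature_params <- function(catalogue = default_feature_catalogue(),
                                   n_visits = 9, runs_per_day = 1:3) {
  ref <- reference_group_summaries()
  # target mean MSE per canonical feature and group
  target <- tibble::tibble(
    feature_id = ref$feature_id,
    mse_healthy = ref$mean_healthy,
    mse_hd = ref$mean_hd
  )
  # printed step-length dispersion would constantly violate the
  # plausibility band; scale down, keep the HD/healthy ratio of 2
  sl <- target$feature_id == "step_length_r"
  target$mse_healthy[sl] <- 4e-4
  target$mse_hd[sl] <- 8e-4

  trends <- tibble::tibble(
    feature_id = c("extension_r", "step_length_r", "max_acc_amp_r",
                   "ventral_acc_r", "max_gyr_amp_r", "acc_sd_r",
                   "ext_sym_fl_hr", "maxacc_sym_fr_fl", "maxacc_sym_fr_hl",
                   "maxacc_sym_fl_hr", "norm_sl_sym_fr_hl", "sl_sym_fr_hl",
                   "sym_pr_lumbar"),
    intercept = c(18, 0.27, 8, 40, 3, 1.5,
                  100, 100, 100, 100, 100, 100, 100),
    slope = c(0.02, 0.00035, 0.012, 0.15, 0.004, 0.003,
              0, 0, 0, 0, 0, 0, 0)
  )
  params <- dplyr::inner_join(target, trends, by = "feature_id")
  shrink <- (n_visits - 2) / n_visits
  e_inv_m <- mean(1 / runs_per_day)
  sig2 <- function(target_mse, run_sd) {
    pmax(target_mse / shrink - run_sd^2 * e_inv_m, 1e-12)
  }
  params$run_sd <- 0.25 * sqrt(params$mse_healthy / shrink)
  params$sigma_healthy <- sqrt(sig2(params$mse_healthy, params$run_sd))
  params$sigma_hd <- sqrt(sig2(params$mse_hd, params$run_sd))
  params <- params[, c("feature_id", "intercept", "slope", "run_sd",
                       "sigma_healthy", "sigma_hd")]
  # mirrored counterparts inherit the canonical side's parameters
  pair <- catalogue$symmetry_pair[match(params$feature_id,
                                        catalogue$feature_id)]
  mirrored <- params[!is.na(pair), ]
  mirrored$feature_id <- pair[!is.na(pair)]
  mirrored <- mirrored[!(mirrored$feature_id %in% params$feature_id), ]
  out <- dplyr::bind_rows(params, mirrored)
  missing <- setdiff(catalogue$feature_id, out$feature_id)
  if (length(missing) > 0) {
    gv_abort(paste0("no simulator parameters for feature(s): ",
                    paste(missing, collapse = ", ")), "gv_config_error")
  }
  out[match(catalogue$feature_id, out$feature_id), ]
}

#' Simulator configuration
#'
#' Assembles and validates the configuration of the synthetic-cohort
#' simulator. The defaults reproduce the reference study's design: 44
#' dogs of which 14 HD, breed mix 37:11:6 (Australian Shepherd : Golden
#' Retriever : Rottweiler), monthly visits from 84 to 196 days of age then
#' bimonthly to 436 days, 1-3 walking trials per examination day.
#'
#' @param n_dogs Total number of dogs (default 44).
#' @param n_hd Number of HD-diagnosed dogs (default 14).
#' @param breed_mix Named numeric vector of breed weights.
#' @param schedule_days Integer vector of scheduled visit ages (days).
#' @param visit_jitter_days Uniform +/- jitter applied to each scheduled
#'   visit (default 0 = deterministic schedule).
#' @param runs_per_day Integer set from which the number of runs of each
#'   dog-day is drawn uniformly (default `1:3`).
#' @param features Feature catalogue to simulate.
#' @param feature_params Per-feature parameters
#'   ([default_feature_params()]).
#' @param implausible_rate Probability that a dog-day receives one
#'   injected out-of-bounds value (default 0).
#' @param seed Integer seed; every stochastic draw of the simulator is
#'   governed by it.
#' @return A validated `cohort_config` object (list).
#' @export
cohort_config <- function(n_dogs = 44, n_hd = 14,
                          breed_mix = c("Australian Shepherd" = 37,
                                        "Golden Retriever" = 11,
                                        "Rottweiler" = 6),
                          schedule_days = c(84L, 112L, 140L, 168L, 196L,
                                            256L, 316L, 376L, 436L),
                          visit_jitter_days = 0,
                          runs_per_day = 1:3,
                          features = default_feature_catalogue(),
                          feature_params = NULL,
                          implausible_rate = 0,
                          seed = 1L) {
  if (n_hd > n_dogs) {
    gv_abort("n_hd cannot exceed n_dogs", "gv_config_error")
  }
  if (n_dogs < 1) gv_abort("n_dogs must be >= 1", "gv_config_error")
  if (is.null(names(breed_mix)) || any(breed_mix < 0) ||
      sum(breed_mix) == 0) {
    gv_abort("breed_mix must be a named non-negative vector", "gv_config_error")
  }
  if (any(schedule_days <= 0) || anyDuplicated(schedule_days) ||
      is.unsorted(schedule_days)) {
    gv_abort("schedule_days must be positive, sorted, distinct",
             "gv_config_error")
  }
  if (any(schedule_days > 450)) {
    gv_abort("scheduled visits must not exceed 450 days of age",
             "gv_config_error")
  }
  if (!all(runs_per_day %in% 1:3) || length(runs_per_day) == 0) {
    gv_abort("runs_per_day must be a subset of 1:3", "gv_config_error")
  }
  if (implausible_rate < 0 || implausible_rate > 1) {
    gv_abort("implausible_rate must be in [0, 1]", "gv_config_error")
  }
  validate_features(features)
  if (is.null(feature_params)) {
    feature_params <- default_feature_params(
      catalogue = features, n_visits = length(schedule_days),
      runs_per_day = runs_per_day
    )
  }
  req <- c("feature_id", "intercept", "slope", "run_sd", "sigma_healthy",
           "sigma_hd")
  if (!all(req %in% names(feature_params)) ||
      !all(features$feature_id %in% feature_params$feature_id)) {
    gv_abort("feature_params must cover every catalogue feature",
             "gv_config_error")
  }
  if (any(feature_params$sigma_healthy <= 0) ||
      any(feature_params$sigma_hd < feature_params$sigma_healthy)) {
    gv_abort("need sigma_hd >= sigma_healthy > 0", "gv_config_error")
  }
  structure(
    list(n_dogs = as.integer(n_dogs), n_hd = as.integer(n_hd),
         breed_mix = breed_mix,
         schedule_days = as.integer(schedule_days),
         visit_jitter_days = visit_jitter_days,
         runs_per_day = as.integer(runs_per_day),
         features = features, feature_params = feature_params,
         implausible_rate = implausible_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a longitudinal gait cohort
#'
#' Generates run-level gait measurements with the study's longitudinal
#' structure. Each value is
#' `intercept + breed_offset + dog_offset + slope * age + visit_noise +
#' run_noise`; visit noise is Gaussian with a per-group SD — for HD dogs
#' the features of the pathological side (and axial features) draw from
#' the inflated `sigma_hd`, everything else from `sigma_healthy`.
#' Pathological sides are assigned left/right with equal probability.
#' A fixed seed makes the output fully reproducible.
#'
#' @param config A [cohort_config()].
#' @return A list: `runs` (run table), `dogs` (metadata), `features`
#'   (the catalogue), `truth` (injected-anomaly locations from
#'   [inject_implausibles()]; zero rows when `implausible_rate = 0`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_dogs
  dog_id <- sprintf("dog%03d", seq_len(n))
  breed <- sample(names(config$breed_mix), n, replace = TRUE,
                  prob = config$breed_mix / sum(config$breed_mix))
  hd <- dog_id %in% sample(dog_id, config$n_hd)
  side <- ifelse(hd, sample(c("left", "right"), n, replace = TRUE), "none")
  dogs <- tibble::tibble(
    dog_id = dog_id, breed = breed,
    diagnosis = ifelse(hd, "HD", "healthy"),
    pathological_side = side
  )

  fp <- config$feature_params
  fid <- config$features$feature_id
  lat <- config$features$laterality[match(fid, config$features$feature_id)]
  n_day <- length(config$schedule_days)

  # dog-day grid with per-day run counts and (optionally jittered) ages
  dd <- tidyr::expand_grid(dog_id = dog_id,
                           visit = seq_len(n_day))
  dd$age_days <- config$schedule_days[dd$visit]
  if (config$visit_jitter_days > 0) {
    dd$age_days <- dd$age_days +
      sample(-config$visit_jitter_days:config$visit_jitter_days,
             nrow(dd), replace = TRUE)
  }
  dd$m <- sample(config$runs_per_day, nrow(dd), replace = TRUE)

  # visit level: dog-day x feature
  vis <- tidyr::expand_grid(
    dd[, c("dog_id", "age_days", "m")],
    feature_id = fid
  )
  i <- match(vis$feature_id, fp$feature_id)
  d <- match(vis$dog_id, dogs$dog_id)
  f_lat <- lat[match(vis$feature_id, fid)]
  inflated <- dogs$diagnosis[d] == "HD" &
    (f_lat == "axial" | f_lat == dogs$pathological_side[d])
  sigma <- ifelse(inflated, fp$sigma_hd[i], fp$sigma_healthy[i])

  # dog-level offsets (absorbed by the per-dog intercept downstream)
  breed_lvl <- match(dogs$breed[d], names(config$breed_mix))
  breed_off <- (breed_lvl - mean(seq_along(config$breed_mix))) * 0.5 *
    fp$sigma_healthy[i]
  dog_off_tbl <- matrix(rnorm(n * nrow(fp), sd = rep(fp$sigma_healthy,
                                                     each = n)),
                        nrow = n)
  dog_off <- dog_off_tbl[cbind(d, i)]

  vis$mu <- fp$intercept[i] + breed_off + dog_off +
    fp$slope[i] * vis$age_days +
    rnorm(nrow(vis), sd = sigma)
  vis$run_sd <- fp$run_sd[i]

  # expand to runs
  runs <- vis[rep(seq_len(nrow(vis)), vis$m), ]
  runs$run_index <- unlist(lapply(vis$m, seq_len), use.names = FALSE)
  runs$value <- runs$mu + rnorm(nrow(runs), sd = runs$run_sd)
  runs <- tibble::tibble(
    dog_id = runs$dog_id,
    age_days = as.integer(runs$age_days),
    run_index = as.integer(runs$run_index),
    feature_id = runs$feature_id,
    value = runs$value
  )
  runs <- dplyr::arrange(runs, .data$dog_id, .data$age_days,
                         .data$run_index, .data$feature_id)

  inj <- inject_implausibles(runs, config)
  list(runs = inj$runs, dogs = dogs, features = config$features,
       truth = inj$truth)
}

#' Inject implausible values into a run table
#'
#' Emulates the anomalies the upstream feature extraction occasionally
#' produces (e.g. step lengths of 2 m from doubly recorded frequencies).
#' Each dog-day independently receives, with probability
#' `config$implausible_rate`, one value replaced by a canonical
#' out-of-bounds value of its feature's category (step length 2 m, energy
#' 400, withers 1 m). Injection sites are returned as a truth table so
#' that the plausibility filter can be audited.
#'
#' @param runs Run table.
#' @param config A [cohort_config()]; only `implausible_rate` and the
#'   catalogue are used. Draws depend on the current RNG state (the
#'   simulator seeds it).
#' @return List with the modified `runs` and the `truth` tibble
#'   (`dog_id`, `age_days`, `run_index`, `feature_id`, `injected_value`,
#'   `reason`).
#' @export
inject_implausibles <- function(runs, config) {
  truth0 <- tibble::tibble(dog_id = character(), age_days = integer(),
                           run_index = integer(), feature_id = character(),
                           injected_value = double(), reason = character())
  rate <- config$implausible_rate
  if (rate == 0 || nrow(runs) == 0) {
    return(list(runs = runs, truth = truth0))
  }
  cat_of <- config$features$exclusion_category[
    match(runs$feature_id, config$features$feature_id)]
  bounded <- which(cat_of != "none")
  if (length(bounded) == 0) {
    gv_abort("implausible_rate > 0 but no catalogue feature has a bounded category",
             "gv_config_error")
  }
  canonical <- c(step_length = 2.0, energy = 400, withers = 1.0)
  day_key <- paste(runs$dog_id, runs$age_days)
  days <- unique(day_key)
  hit_days <- days[runif(length(days)) < rate]
  # one bounded-category run per hit day; days whose bounded rows are
  # absent (possible with partial catalogues) fall back to no injection
  idx <- bounded[!duplicated(day_key[bounded])]
  idx <- idx[day_key[idx] %in% hit_days]
  if (length(idx) == 0) {
    return(list(runs = runs, truth = truth0))
  }
  injected_value <- canonical[cat_of[idx]]
  runs$value[idx] <- injected_value
  truth <- tibble::tibble(
    dog_id = runs$dog_id[idx],
    age_days = runs$age_days[idx],
    run_index = runs$run_index[idx],
    feature_id = runs$feature_id[idx],
    injected_value = unname(injected_value),
    reason = paste0(cat_of[idx], "_bounds")
  )
  list(runs = runs, truth = truth)
}

#' Expected pipeline outcomes for a simulated cohort
#'
#' Closed-form expectations used as test oracles. For ordinary least
#' squares with an intercept on n visits, the residual mean square loses
#' two degrees of freedom: E\[MSE\] = (n-2)/n times the per-visit noise
#' variance, where the per-visit variance is sigma_visit^2 plus the
#' run-averaging contribution run_sd^2 E\[1/m\] (m uniform on the
#' configured runs-per-day set, independent of age, so the expectation
#' factorises exactly). Group expectations are reported per aligned
#' feature: under right-reference alignment the reference-side and axial
#' features of HD dogs carry the inflated dispersion. When a truth table
#' of injected anomalies is supplied, per-dog surviving day counts and the
#' dogs the minimum-days rule must remove are also predicted.
#'
#' @param config A [cohort_config()].
#' @param truth Optional injected-anomaly truth table from
#'   [simulate_cohort()].
#' @param min_days Minimum-days rule used for the removal prediction.
#' @param reference_side Alignment convention (default `"right"`).
#' @return List: `expected_mse` (tibble `feature_id`, `group`,
#'   `expected_mse`), `n_visits`, `surviving_days` (tibble `dog_id`,
#'   `n_days`; requires dog ids to appear in `truth` — dogs without
#'   injections survive with the full schedule), `removed_dogs`.
#' @export
truth_report <- function(config, truth = NULL, min_days = 4,
                         reference_side = "right") {
  stopifnot(inherits(config, "cohort_config"))
  n_vis <- length(config$schedule_days)
  e_inv_m <- mean(1 / config$runs_per_day)
  shrink <- (n_vis - 2) / n_vis
  fp <- config$feature_params
  lat <- config$features$laterality[match(fp$feature_id,
                                          config$features$feature_id)]
  hd_inflated <- lat == "axial" | lat == reference_side
  per_visit_h <- fp$sigma_healthy^2 + fp$run_sd^2 * e_inv_m
  per_visit_d <- ifelse(hd_inflated, fp$sigma_hd^2, fp$sigma_healthy^2) +
    fp$run_sd^2 * e_inv_m
  expected_mse <- dplyr::bind_rows(
    tibble::tibble(feature_id = fp$feature_id, group = "healthy",
                   expected_mse = per_visit_h * shrink),
    tibble::tibble(feature_id = fp$feature_id, group = "HD",
                   expected_mse = per_visit_d * shrink)
  )
  dog_id <- sprintf("dog%03d", seq_len(config$n_dogs))
  lost <- integer(length(dog_id))
  names(lost) <- dog_id
  if (!is.null(truth) && nrow(truth) > 0) {
    lost_tbl <- table(truth$dog_id[!duplicated(paste(truth$dog_id,
                                                     truth$age_days))])
    lost[names(lost_tbl)] <- as.integer(lost_tbl)
  }
  surviving <- tibble::tibble(dog_id = dog_id,
                              n_days = n_vis - unname(lost))
  list(expected_mse = expected_mse, n_visits = n_vis,
       surviving_days = surviving,
       removed_dogs = surviving$dog_id[surviving$n_days < min_days])
}
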