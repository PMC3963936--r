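# Seeded synthetic cohort generators.  Defaults reproduce the statistical
# structure of the study cohorts: group %ID means/SDs per injected activity,
# a 1 h uptake peak with mono-exponential washout sampled at 1/3/7 h, a 22 Gy
# stunning threshold with mean changes -3.95%/-17.5%, and recovery to 100% of
# baseline by day 4.

#' Configuration for a synthetic imaging cohort
#'
#' @param groups Data frame with one row per injected-activity group:
#'   `injected_MBq`, `n`, `pid_mean` (%ID), `pid_sd` (%ID).  Defaults to the
#'   four study groups (10/25/100/150 MBq with n = 4/9/9/29 and %ID
#'   2.84+-0.63 / 2.60+-0.35 / 2.67+-0.33 / 2.63+-0.47).
#' @param peak_time_h Uptake peak time (default 1 h).
#' @param lambda_eff_median Median effective washout rate (1/h).  Default
#'   0.256/h, calibrated so the population-mean 150 MBq animal (peak 3.945
#'   MBq) accumulates the reported 28.4 Gy mean dose under the default
#'   S-value; this is a free model parameter, not a measured value.
#' @param lambda_eff_gsd Geometric SD of the log-normal washout rate
#'   (default 1.15).
#' @param sample_times_h Imaging times (default 1, 3, 7 h; strictly
#'   increasing).
#' @param measurement_cv Multiplicative log-normal measurement noise CV
#'   (default 0.05).
#' @param seed RNG seed.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(groups = data.frame(
                            injected_MBq = c(10, 25, 100, 150),
                            n = c(4L, 9L, 9L, 29L),
                            pid_mean = c(2.84, 2.60, 2.67, 2.63),
                            pid_sd = c(0.63, 0.35, 0.33, 0.47)),
                          peak_time_h = 1,
                          lambda_eff_median = 0.256,
                          lambda_eff_gsd = 1.15,
                          sample_times_h = c(1, 3, 7),
                          measurement_cv = 0.05,
                          seed = 20140324) {
  cfg <- list(groups = groups, peak_time_h = peak_time_h,
              lambda_eff_median = lambda_eff_median,
              lambda_eff_gsd = lambda_eff_gsd,
              sample_times_h = sample_times_h,
              measurement_cv = measurement_cv, seed = seed)
  problems <- character(0)
  if (!is.data.frame(groups) ||
      !all(c("injected_MBq", "n", "pid_mean", "pid_sd") %in% names(groups)))
    problems <- c(problems, "groups must have columns injected_MBq, n, pid_mean, pid_sd")
  else {
    if (any(groups$n < 1)) problems <- c(problems, "all group n must be >= 1")
    if (any(groups$pid_sd < 0)) problems <- c(problems, "pid_sd must be >= 0")
    if (any(groups$pid_mean <= 0)) problems <- c(problems, "pid_mean must be > 0")
  }
  if (peak_time_h <= 0) problems <- c(problems, "peak_time_h must be > 0")
  if (lambda_eff_median <= 0) problems <- c(problems, "lambda_eff_median must be > 0")
  if (lambda_eff_gsd < 1) problems <- c(problems, "lambda_eff_gsd must be >= 1")
  if (any(diff(sample_times_h) <= 0)) problems <- c(problems, "sample_times_h must be strictly increasing")
  if (measurement_cv < 0) problems <- c(problems, "measurement_cv must be >= 0")
  if (length(problems))
    stop(paste0("invalid cohort config:\n  - ", paste(problems, collapse = "\n  - ")),
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Normal draw truncated at 0 by redraw (keeps the upper tail unbiased).
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Mean-1 multiplicative log-normal noise of coefficient of variation cv.
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic time-activity cohort
#'
#' For each animal: draw %ID from a truncated normal per group, convert to
#' the peak activity, draw a log-normal effective washout rate, and emit
#' activities at the configured sample times from the piecewise
#' (linear-uptake / mono-exponential washout) curve with multiplicative
#' log-normal measurement noise.  Deterministic under the config seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `animal_id`, `time_h`, `activity_MBq`,
#'   `injected_MBq` plus per-animal truth columns `true_pid`,
#'   `true_lambda_eff` (useful for parameter-recovery checks).
#' @export
synth_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    out <- list()
    for (g in seq_len(nrow(config$groups))) {
      grp <- config$groups[g, ]
      pid <- rnorm_pos(grp$n, grp$pid_mean, grp$pid_sd)
      lam <- config$lambda_eff_median *
        exp(rnorm(grp$n, 0, log(config$lambda_eff_gsd)))
      for (i in seq_len(grp$n)) {
        peak <- pid[i] * grp$injected_MBq / 100
        t <- config$sample_times_h
        a <- ifelse(t <= config$peak_time_h, peak * t / config$peak_time_h,
                    peak * exp(-lam[i] * (t - config$peak_time_h)))
        a <- a * lnorm_noise(length(t), config$measurement_cv)
        out[[length(out) + 1L]] <- data.frame(
          animal_id = sprintf("mbq%03d_%02d", grp$injected_MBq, i),
          time_h = t, activity_MBq = a, injected_MBq = grp$injected_MBq,
          true_pid = pid[i], true_lambda_eff = lam[i],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Configuration for synthetic stunning and recovery cohorts
#'
#' @param threshold_Gy True stunning dose threshold (default 22 Gy).
#' @param mean_change_below Mean percent uptake change below the threshold
#'   (default -3.95).
#' @param mean_change_above Mean percent change above (default -17.5); must
#'   not exceed `mean_change_below` for a stunning scenario.
#' @param change_sd SD of percent change (default 5).
#' @param baseline_mean,baseline_sd Baseline uptake distribution (%ID;
#'   defaults 2.63 and 0.47, the 150 MBq group).
#' @param recovery_by_day Named vector: mean uptake as percent of the day-0
#'   value per follow-up day.  Default `c("1"=55, "2"=70, "4"=100, "8"=100)`:
#'   a 45% day-1 reduction, partial day-2 recovery, full recovery from day 4.
#' @param recovery_sd SD of the per-day percent-of-baseline draws (default 8).
#' @param seed RNG seed.
#' @return A `stunning_config` list, validated.
#' @export
stunning_config <- function(threshold_Gy = 22,
                            mean_change_below = -3.95,
                            mean_change_above = -17.5,
                            change_sd = 5,
                            baseline_mean = 2.63, baseline_sd = 0.47,
                            recovery_by_day = c("1" = 55, "2" = 70,
                                                "4" = 100, "8" = 100),
                            recovery_sd = 8,
                            seed = 20140324) {
  problems <- character(0)
  if (threshold_Gy <= 0) problems <- c(problems, "threshold_Gy must be > 0")
  if (!(mean_change_above <= mean_change_below))
    problems <- c(problems, "mean_change_above must be <= mean_change_below (stunning scenario)")
  if (change_sd < 0) problems <- c(problems, "change_sd must be >= 0")
  if (any(recovery_by_day <= 0)) problems <- c(problems, "recovery means must be > 0")
  if (recovery_sd < 0) problems <- c(problems, "recovery_sd must be >= 0")
  if (length(problems))
    stop(paste0("invalid stunning config:\n  - ", paste(problems, collapse = "\n  - ")),
         call. = FALSE)
  structure(list(threshold_Gy = threshold_Gy,
                 mean_change_below = mean_change_below,
                 mean_change_above = mean_change_above,
                 change_sd = change_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 recovery_by_day = recovery_by_day,
                 recovery_sd = recovery_sd, seed = seed),
            class = "stunning_config")
}

#' Generate synthetic stunning-rechallenge records
#'
#' Each record gets a baseline uptake draw and a percent change drawn from
#' the below- or above-threshold normal distribution according to its dose;
#' the rechallenge uptake is derived from the two.
#'
#' @param config A [stunning_config()].
#' @param doses_Gy Non-empty vector of initial absorbed doses (Gy).
#' @param day Day of the rechallenge scan (default 1).
#' @return Data frame: `animal_id`, `initial_dose_Gy`, `baseline_uptake`,
#'   `rechallenge_uptake`, `day`, `percent_change`.
#' @export
synth_stunning <- function(config = stunning_config(), doses_Gy, day = 1L) {
  stopifnot(inherits(config, "stunning_config"))
  if (missing(doses_Gy) || length(doses_Gy) == 0)
    stop("doses_Gy must be non-empty", call. = FALSE)
  with_seed(config$seed, {
    n <- length(doses_Gy)
    base <- rnorm_pos(n, config$baseline_mean, config$baseline_sd)
    mu <- ifelse(doses_Gy > config$threshold_Gy,
                 config$mean_change_above, config$mean_change_below)
    pc <- rnorm(n, mu, config$change_sd)
    rech <- base * (1 + pc / 100)
    data.frame(animal_id = sprintf("stun_%02d", seq_len(n)),
               initial_dose_Gy = doses_Gy,
               baseline_uptake = base,
               rechallenge_uptake = rech,
               day = as.integer(day),
               percent_change = percent_change(base, rech),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic longitudinal recovery cohort
#'
#' Draws day-0 baseline uptakes and, for each follow-up day in the config's
#' `recovery_by_day`, per-animal uptakes at the configured mean percent of
#' baseline with normal noise `recovery_sd`.
#'
#' @param config A [stunning_config()].
#' @param n_per_day Animals per follow-up day (default 3, the study design).
#' @return List with `records` (data frame `animal_id`, `day`, `uptake`) and
#'   `day0_values` (data frame `animal_id`, `uptake`), ready for
#'   [recovery_profile()].
#' @export
synth_recovery <- function(config = stunning_config(), n_per_day = 3L) {
  stopifnot(inherits(config, "stunning_config"))
  with_seed(config$seed, {
    days <- as.integer(names(config$recovery_by_day))
    recs <- list(); d0 <- list()
    for (k in seq_along(days)) {
      ids <- sprintf("rec_d%d_%02d", days[k], seq_len(n_per_day))
      base <- rnorm_pos(n_per_day, config$baseline_mean, config$baseline_sd)
      relp <- rnorm_pos(n_per_day, config$recovery_by_day[k], config$recovery_sd)
      recs[[k]] <- data.frame(animal_id = ids, day = days[k],
                              uptake = base * relp / 100,
                              stringsAsFactors = FALSE)
      d0[[k]] <- data.frame(animal_id = ids, uptake = base,
                            stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, recs), day0_values = do.call(rbind, d0))
  })
}

#' Generate a synthetic comparative-Ct qPCR table
#'
#' Reference-gene Ct values are drawn around `ct_reference_mean`; target-gene
#' Ct values are the reference plus the group's configured delta-Ct plus
#' normal noise `sd`.  Group ratios of [relative_expression()] therefore
#' equal the configured fold changes in expectation (exactly when `sd = 0`).
#'
#' @param n_per_group Samples per group (default 4).
#' @param delta_ct_means Named vector of group delta-Ct means.  Default
#'   encodes no change at 5 Gy and 2.5-/12-fold downregulation at 20/30 Gy
#'   relative to control.
#' @param sd SD of the delta-Ct noise (default 0.3; `0` for exact ratios).
#' @param seed RNG seed.
#' @param ct_reference_mean,ct_reference_sd Reference-gene Ct distribution
#'   (defaults 17 and 0.5; cancels out of the expression ratios).
#' @return Data frame: `sample_id`, `group`, `ct_target`, `ct_reference`.
#' @export
synth_qpcr <- function(n_per_group = 4L,
                       delta_ct_means = c(control = 3,
                                          gy5 = 3,
                                          gy20 = 3 + log2(2.5),
                                          gy30 = 3 + log2(12)),
                       sd = 0.3, seed = 20140324,
                       ct_reference_mean = 17, ct_reference_sd = 0.5) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (is.null(names(delta_ct_means)) || any(!nzchar(names(delta_ct_means))))
    stop("delta_ct_means must be a named vector", call. = FALSE)
  with_seed(seed, {
    out <- lapply(names(delta_ct_means), function(gname) {
      ctr <- rnorm(n_per_group, ct_reference_mean, ct_reference_sd)
      ctt <- ctr + delta_ct_means[[gname]] + rnorm(n_per_group, 0, sd)
      data.frame(sample_id = sprintf("%s_%02d", gname, seq_len(n_per_group)),
                 group = gname, ct_target = ctt, ct_reference = ctr,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
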