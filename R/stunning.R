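#' Percent change in uptake between two scans
#'
#' Signed percent change `100 * (rechallenge - baseline) / baseline`;
#' negative values indicate stunning.  Uses raw (not decay-corrected) uptake
#' consistently on both scans, so units cancel.
#'
#' @param baseline Baseline uptake (> 0; %ID or MBq).
#' @param rechallenge Rechallenge uptake, same unit.
#' @return Percent change (vectorized).
#' @examples
#' percent_change(2.6, 1.43)  # -45%
#' @export
percent_change <- function(baseline, rechallenge) {
  if (any(baseline <= 0)) stop("baseline uptake must be > 0", call. = FALSE)
  100 * (rechallenge - baseline) / baseline
}

#' Dose-threshold scan for stunning
#'
#' Searches for the initial absorbed dose above which rechallenge uptake is
#' significantly reduced.  Candidate thresholds are midpoints between
#' consecutive distinct observed doses (restricted to splits leaving at least
#' `min_per_side` records on each side); each candidate is evaluated with a
#' two-sided two-sample Student's t-test (equal variances by default; Welch
#' via `var_equal = FALSE`) comparing percent change below vs above.
#'
#' Selection rule: `"min_p"` (default) returns the candidate with the
#' smallest p-value (the maximally selected split, which localizes a true
#' change point); `"smallest_significant"` returns the lowest-dose candidate
#' with p below `alpha`.  No multiple-testing correction is applied across
#' candidates; the returned p-value is the unadjusted per-split p (see the
#' `note` field).
#'
#' @param records Data frame with columns `initial_dose_Gy` and
#'   `percent_change` (e.g. from [synth_stunning()] or [read_stunning_csv()]).
#' @param alpha Significance level (default 0.05).
#' @param rule Candidate selection rule, see above.
#' @param var_equal Use the classical equal-variance t-test (default TRUE).
#' @param min_per_side Minimum records on each side of a candidate (default 3).
#' @return An object of class `threshold_result`: list with `threshold_Gy`,
#'   `p_value`, `significant`, `mean_below`, `mean_above`, `n_below`,
#'   `n_above`, `alpha`, `candidates` (per-candidate table) and `note`.
#' @export
threshold_scan <- function(records, alpha = 0.05,
                           rule = c("min_p", "smallest_significant"),
                           var_equal = TRUE, min_per_side = 3) {
  rule <- match.arg(rule)
  if (!is.data.frame(records) ||
      !all(c("initial_dose_Gy", "percent_change") %in% names(records)))
    stop("records must have columns initial_dose_Gy and percent_change", call. = FALSE)
  d <- records$initial_dose_Gy; pc <- records$percent_change
  du <- sort(unique(d))
  if (length(du) < 2L) stop("all doses identical: no candidate thresholds", call. = FALSE)

  mids <- (du[-length(du)] + du[-1]) / 2
  cand <- lapply(mids, function(m) {
    lo <- pc[d < m]; hi <- pc[d > m]
    if (length(lo) < min_per_side || length(hi) < min_per_side) return(NULL)
    tt <- t.test(lo, hi, var.equal = var_equal)
    data.frame(threshold_Gy = m, p_value = tt$p.value,
               mean_below = mean(lo), mean_above = mean(hi),
               n_below = length(lo), n_above = length(hi))
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L)
    stop(sprintf("no candidate split leaves >= %d records on each side", min_per_side),
         call. = FALSE)

  sig <- cand[cand$p_value < alpha, , drop = FALSE]
  if (nrow(sig) > 0L) {
    pick <- if (rule == "min_p") sig[which.min(sig$p_value), ] else sig[1L, ]
    significant <- TRUE
  } else {
    pick <- cand[which.min(cand$p_value), ]
    significant <- FALSE
  }

  structure(list(
    threshold_Gy = pick$threshold_Gy,
    p_value = pick$p_value,
    significant = significant,
    mean_below = pick$mean_below,
    mean_above = pick$mean_above,
    n_below = pick$n_below,
    n_above = pick$n_above,
    alpha = alpha,
    rule = rule,
    candidates = cand,
    note = "p-values are per-split Student t-tests, unadjusted for the threshold search"
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> threshold %.2f Gy, p = %.4f (%s at alpha %.2f)\n",
              x$threshold_Gy, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  cat(sprintf("  below: mean %.2f%% (n=%d) | above: mean %.2f%% (n=%d)\n",
              x$mean_below, x$n_below, x$mean_above, x$n_above))
  invisible(x)
}

#' Longitudinal recovery profile
#'
#' Normalizes follow-up uptake to each animal's day-0 value (percent of
#' baseline), summarizes per day (mean, SD, n), tests each day against 100%
#' (one-sample two-sided t-test) and across days (one-way ANOVA).  A day is
#' flagged `recovered` when its mean is not significantly different from
#' 100% at `alpha`; the descriptive flag `within_1sd` (mean within one
#' sample SD of 100%) is also reported.  With one animal per day the SD and
#' p-value are reported as `NA`.
#'
#' @param records Data frame with columns `animal_id`, `day` (integer >= 1)
#'   and `uptake`.
#' @param day0_values Data frame with columns `animal_id` and `uptake`
#'   (day-0 scan of the same animal).
#' @param alpha Significance level for the per-day test (default 0.05).
#' @return An object of class `recovery_profile`: list with `per_day` (data
#'   frame `day`, `mean_percent`, `sd_percent`, `n`, `p_value`, `recovered`,
#'   `within_1sd`) and `anova_p` (NA when not estimable).
#' @export
recovery_profile <- function(records, day0_values, alpha = 0.05) {
  need <- c("animal_id", "day", "uptake")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must have columns animal_id, day, uptake", call. = FALSE)
  if (!is.data.frame(day0_values) || !all(c("animal_id", "uptake") %in% names(day0_values)))
    stop("day0_values must have columns animal_id, uptake", call. = FALSE)
  if (any(records$day < 1)) stop("day must be >= 1", call. = FALSE)

  m <- match(records$animal_id, day0_values$animal_id)
  if (anyNA(m)) {
    missing <- unique(records$animal_id[is.na(m)])
    stop(sprintf("no day-0 value for animal(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  base <- day0_values$uptake[m]
  if (any(base <= 0)) stop("day-0 uptake must be > 0", call. = FALSE)
  rel <- 100 * records$uptake / base

  days <- sort(unique(records$day))
  per_day <- do.call(rbind, lapply(days, function(dd) {
    v <- rel[records$day == dd]
    n <- length(v)
    s <- if (n > 1) sd(v) else NA_real_
    p <- if (n > 1 && isTRUE(s > 0)) t.test(v, mu = 100)$p.value
         else if (n > 1 && isTRUE(s == 0)) as.numeric(all(v == 100))
         else NA_real_
    data.frame(day = dd, mean_percent = mean(v), sd_percent = s, n = n,
               p_value = p,
               recovered = if (is.na(p)) NA else p >= alpha,
               within_1sd = if (is.na(s)) NA else abs(mean(v) - 100) <= s)
  }))
  anova_p <- if (length(days) > 1 && nrow(records) > length(days)) {
    af <- aov(rel ~ factor(records$day))
    summary(af)[[1]][["Pr(>F)"]][1]
  } else NA_real_

  structure(list(per_day = per_day, anova_p = anova_p, alpha = alpha),
            class = "recovery_profile")
}

#' @export
print.recovery_profile <- function(x, ...) {
  cat("<recovery_profile>\n")
  print(x$per_day, row.names = FALSE)
  cat(sprintf("  one-way ANOVA across days: p = %s\n", format(x$anova_p)))
  invisible(x)
}

#' Relative expression by the comparative Ct method
#'
#' `2^-(Ct_target - Ct_reference)`, the standard single-reference relative
#' expression measure (reference gene here: beta-actin; target: NIS).
#'
#' @param ct_target Target-gene cycle threshold (vectorized, finite).
#' @param ct_reference Reference-gene cycle threshold.
#' @return Relative expression (dimensionless).
#' @examples
#' relative_expression(20, 20)  # 1
#' relative_expression(21, 20)  # 0.5
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  2^(-(ct_target - ct_reference))
}
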