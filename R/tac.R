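#' Physical decay and decay correction
#'
#' `decay()` returns the activity remaining after `elapsed_h` hours of
#' physical decay; `decay_correct()` is its inverse (corrects a measured
#' activity back to the reference time).
#'
#' @param activity_MBq Activity in MBq (vectorized, >= 0).
#' @param elapsed_h Elapsed time in hours.  Negative values are an error for
#'   `decay()`; `decay_correct()` accepts any sign.
#' @param half_life_h Physical half-life in hours (> 0); defaults to the
#'   Tc-99m value 6.0067 h.
#' @return Activity in MBq.
#' @examples
#' decay(150, 72)          # three days of decay, ~12 half-lives -> 0.04 MBq
#' decay_correct(decay(150, 5), 5)  # identity
#' @export
decay <- function(activity_MBq, elapsed_h, half_life_h = TC99M_HALF_LIFE_H) {
  if (any(half_life_h <= 0)) stop("half_life_h must be > 0", call. = FALSE)
  if (any(activity_MBq < 0)) stop("activity must be >= 0", call. = FALSE)
  if (any(elapsed_h < 0)) stop("elapsed_h must be >= 0 (use decay_correct for back-correction)", call. = FALSE)
  activity_MBq * 2^(-elapsed_h / half_life_h)
}

#' @rdname decay
#' @export
decay_correct <- function(activity_MBq, elapsed_h, half_life_h = TC99M_HALF_LIFE_H) {
  if (any(half_life_h <= 0)) stop("half_life_h must be > 0", call. = FALSE)
  if (any(activity_MBq < 0)) stop("activity must be >= 0", call. = FALSE)
  activity_MBq * 2^(elapsed_h / half_life_h)
}

#' Fit a thyroid time-activity curve
#'
#' Piecewise model of the (not decay-corrected) thyroid time-activity curve:
#' a straight uptake line through the origin reaching the peak activity at
#' the peak time, followed by mono-exponential washout
#' \eqn{A(t) = A_{peak} e^{-\lambda_{eff}(t - t_{peak})}} fitted by least
#' squares on log-activity of the post-peak samples (exact for two post-peak
#' points).  No activity is assumed at t = 0.
#'
#' @param samples Data frame with columns `time_h` (strictly increasing) and
#'   `activity_MBq`; optionally `injected_MBq`.
#' @param peak_time_mode `"fixed"` (default): the peak is the first measured
#'   sample, matching a 1 h uptake maximum; `"free"`: the peak is the sample
#'   with maximal activity.
#' @param half_life_h Physical half-life used only to warn when the fitted
#'   effective washout is slower than physical decay.
#' @return An object of class `tac_fit`: list with `peak_time_h`,
#'   `peak_activity_MBq`, `uptake_slope_MBq_h`, `lambda_eff_per_h`, `rss`,
#'   `n_washout`.
#' @examples
#' s <- data.frame(time_h = c(1, 3, 7),
#'                 activity_MBq = 3.5 * exp(-0.4 * c(0, 2, 6)))
#' fit_tac(s)$lambda_eff_per_h  # 0.4 recovered exactly
#' @export
fit_tac <- function(samples, peak_time_mode = c("fixed", "free"),
                    half_life_h = TC99M_HALF_LIFE_H) {
  peak_time_mode <- match.arg(peak_time_mode)
  if (!is.data.frame(samples) || !all(c("time_h", "activity_MBq") %in% names(samples)))
    stop("samples must be a data frame with columns time_h and activity_MBq", call. = FALSE)
  t <- samples$time_h; a <- samples$activity_MBq
  if (any(!is.finite(t)) || any(!is.finite(a)))
    stop("non-finite sample values", call. = FALSE)
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  if (any(t < 0) || any(a < 0)) stop("times and activities must be >= 0", call. = FALSE)
  if ("injected_MBq" %in% names(samples) && any(a > samples$injected_MBq))
    stop("activity exceeds injected activity", call. = FALSE)

  i_peak <- if (peak_time_mode == "fixed") 1L else which.max(a)
  t_peak <- t[i_peak]; a_peak <- a[i_peak]
  if (t_peak <= 0) stop("peak time must be > 0", call. = FALSE)
  if (a_peak <= 0) stop("peak activity must be > 0", call. = FALSE)

  post <- which(t > t_peak)
  if (length(post) < 2L)
    stop(sprintf("need >= 2 post-peak samples for the washout fit, found %d",
                 length(post)), call. = FALSE)
  if (any(a[post] <= 0))
    stop("non-positive post-peak activity: log-linear washout fit undefined", call. = FALSE)

  fit <- lm(log(a[post]) ~ t[post])
  lambda <- -unname(coef(fit)[2])
  if (lambda <= 0)
    stop("washout fit produced non-positive lambda_eff (activity not decreasing)", call. = FALSE)
  lambda_phys <- log(2) / half_life_h
  if (lambda < lambda_phys)
    warning(sprintf("lambda_eff (%.4f /h) slower than physical decay (%.4f /h): washout is empirical but check the data",
                    lambda, lambda_phys), call. = FALSE)

  pred <- ifelse(t <= t_peak, a_peak * t / t_peak,
                 a_peak * exp(-lambda * (t - t_peak)))
  structure(list(
    peak_time_h = t_peak,
    peak_activity_MBq = a_peak,
    uptake_slope_MBq_h = a_peak / t_peak,
    lambda_eff_per_h = lambda,
    rss = sum((a - pred)^2),
    n_washout = length(post)
  ), class = "tac_fit")
}

#' Predict a fitted time-activity curve
#'
#' @param object A [fit_tac()] object.
#' @param t_h Times (hours) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Activities in MBq.
#' @export
predict.tac_fit <- function(object, t_h, ...) {
  ifelse(t_h <= object$peak_time_h,
         object$peak_activity_MBq * t_h / object$peak_time_h,
         object$peak_activity_MBq *
           exp(-object$lambda_eff_per_h * (t_h - object$peak_time_h)))
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit> peak %.3f MBq at %.2f h, lambda_eff %.4f /h (T1/2,eff %.2f h), rss %.3g\n",
              x$peak_activity_MBq, x$peak_time_h, x$lambda_eff_per_h,
              log(2) / x$lambda_eff_per_h, x$rss))
  invisible(x)
}

#' Cumulated activity of a fitted time-activity curve
#'
#' Closed-form time integral of the piecewise (linear uptake then
#' mono-exponential washout) curve from 0 to `t_end_h`:
#' \deqn{\tilde A = \tfrac12 A_{peak} t_{peak} +
#'   \frac{A_{peak}}{\lambda_{eff}}\left(1 - e^{-\lambda_{eff}(t_{end} - t_{peak})}\right)}
#' converted to Bq s.
#'
#' @param fit A [fit_tac()] object.
#' @param t_end_h Integration endpoint in hours (default 24); must exceed the
#'   peak time.
#' @return List with `value_Bq_s` and `t_end_h`.
#' @export
cumulated_activity <- function(fit, t_end_h = 24) {
  stopifnot(inherits(fit, "tac_fit"))
  stopifnot_scalar(t_end_h, "t_end_h", positive = TRUE)
  if (t_end_h <= fit$peak_time_h)
    stop("t_end_h must exceed the peak time", call. = FALSE)
  a <- fit$peak_activity_MBq; tp <- fit$peak_time_h; l <- fit$lambda_eff_per_h
  mbq_h <- 0.5 * a * tp + (a / l) * (1 - exp(-l * (t_end_h - tp)))
  list(value_Bq_s = mbq_h * 1e6 * 3600, t_end_h = t_end_h)
}

#' Percent injected dose
#'
#' Thyroid uptake as a percentage of the injected activity, optionally after
#' correcting the measured activity for physical decay since injection.
#'
#' @param activity_MBq Measured activity (MBq).
#' @param injected_MBq Injected activity (MBq, > 0).
#' @param elapsed_h Time since injection (hours); used only when
#'   `decay_correct = TRUE`.
#' @param half_life_h Physical half-life (hours).
#' @param decay_correct Apply decay correction (default FALSE).
#' @return Percent of injected dose.
#' @export
percent_id <- function(activity_MBq, injected_MBq, elapsed_h = 0,
                       half_life_h = TC99M_HALF_LIFE_H, decay_correct = FALSE) {
  if (any(injected_MBq <= 0)) stop("injected_MBq must be > 0", call. = FALSE)
  a <- if (decay_correct) activity_MBq * 2^(elapsed_h / half_life_h) else activity_MBq
  100 * a / injected_MBq
}
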