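#' Akaike information criterion for a least-squares fit
#'
#' The least-squares form \eqn{AIC = n \ln(RSS/n) + 2k}, with \eqn{n} the
#' number of fitted frames and \eqn{k} the free-parameter count of the
#' model order (1TCM = 2, 2TCM = 4, 3TCM = 6). A perfect fit (RSS = 0) has
#' no finite log-likelihood and is returned as `-Inf`, the perfect-fit
#' sentinel that always wins model selection.
#'
#' @param rss residual sum of squares, >= 0 (or a `kinetic_fit`).
#' @param n number of frames; must exceed `k`.
#' @param k number of free parameters.
#' @return The AIC value.
#' @export
compute_aic <- function(rss, n, k) {
  if (inherits(rss, "kinetic_fit")) {
    fit <- rss; rss <- fit$rss; n <- fit$n; k <- fit$npar
  }
  if (rss < 0) stop("RSS must be non-negative")
  if (n <= k) stop("need more frames than free parameters")
  if (rss == 0) return(-Inf)
  n * log(rss / n) + 2 * k
}

#' Select the most suitable model order by lowest AIC
#'
#' The fit with the lowest AIC wins; ties are broken toward fewer
#' parameters (parsimony). All fits must be of the same observed curve.
#'
#' @param fits list of `kinetic_fit`s of one curve.
#' @return The selected model order (integer).
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  if (length(fits) > 1) {
    y0 <- fits[[1]]$observed
    same <- vapply(fits, function(f) isTRUE(all.equal(f$observed, y0)),
                   logical(1))
    if (!all(same)) stop("fits were made on different observed curves")
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ords <- vapply(fits, `[[`, integer(1), "order")
  unname(ords[order(aics, ords)[1]])
}

#' Endpoint SUV: mean of the final 20-min frame (60-80 min)
#'
#' The SUV_mean endpoint metric is the ROI-mean SUV of the frame spanning
#' the final 20 minutes of the acquisition, allowing the standard 60-min
#' circulation time after injection.
#'
#' @param suv_tac a `tac` in SUV units.
#' @param window endpoint window in minutes, default `c(60, 80)`.
#' @return The endpoint frame's value.
#' @export
suv_mean_endpoint <- function(suv_tac, window = c(60, 80)) {
  stopifnot(inherits(suv_tac, "tac"))
  sch <- suv_tac$schedule
  hit <- which(abs(sch$start_s - window[1] * 60) < 1e-6 &
                 abs(sch$start_s + sch$duration_s - window[2] * 60) < 1e-6)
  if (length(hit) != 1)
    stop("schedule has no frame spanning ", window[1], "-", window[2],
         " min")
  suv_tac$values[hit]
}

#' Tumor-to-background ratio
#'
#' Ratio of a tumor metric to the same metric in contralateral normal
#' brain.
#'
#' @param tumor_metric,contralateral_metric scalar metrics on the same
#'   scale; the contralateral value must be positive.
#' @return `tumor_metric / contralateral_metric`.
#' @export
tbr <- function(tumor_metric, contralateral_metric) {
  if (!is.finite(contralateral_metric) || contralateral_metric <= 0)
    stop("contralateral metric must be positive")
  tumor_metric / contralateral_metric
}

#' Longitudinal change between imaging sessions
#'
#' Day-7 minus day-4 value of a metric (e.g. k1 TBR). A missing session is
#' a flagged `NA`, excluded from downstream comparisons rather than
#' imputed.
#'
#' @param metric_day4,metric_day7 scalar metrics; `NA` marks a missing
#'   session.
#' @return `metric_day7 - metric_day4`, or `NA` if either is missing.
#' @export
longitudinal_delta <- function(metric_day4, metric_day7) {
  if (is.na(metric_day4) || is.na(metric_day7)) return(NA_real_)
  metric_day7 - metric_day4
}

#' Classify immunotherapy response from a bioluminescence series
#'
#' Responder if the total-flux increase from baseline at (approximately)
#' one month is strictly less than 20%:
#' `(signal_day30 - baseline) / baseline < 0.20`. The day-30 reading is the
#' measurement nearest day 30 within `+/- day_window` days.
#'
#' @param days measurement days (baseline must be present at `baseline_day`).
#' @param flux total flux (photons/s) per day.
#' @param baseline_day baseline day (default 0).
#' @param followup_day nominal response day (default 30).
#' @param day_window tolerance around `followup_day` (default 3 days).
#' @param threshold fractional-increase threshold (default 0.20).
#' @return `"responder"` or `"non-responder"`.
#' @export
classify_response <- function(days, flux, baseline_day = 0,
                              followup_day = 30, day_window = 3,
                              threshold = 0.20) {
  stopifnot(length(days) == length(flux))
  b <- which(days == baseline_day)
  if (length(b) != 1) stop("no baseline measurement at day ", baseline_day)
  near <- which(abs(days - followup_day) <= day_window)
  if (length(near) == 0)
    stop("no measurement within ", day_window, " days of day ",
         followup_day)
  d30 <- near[which.min(abs(days[near] - followup_day))]
  if (flux[b] <= 0) stop("baseline flux must be positive")
  frac <- (flux[d30] - flux[b]) / flux[b]
  if (frac < threshold) "responder" else "non-responder"
}
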