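#' Product-limit survival estimation and censoring weights
#'
#' Kaplan-Meier estimation, reverse-KM median follow-up, and inverse
#' probability of censoring weights (IPCW) at a fixed horizon. Tied event and
#' censoring times follow the standard convention: events are processed before
#' censorings.
#'
#' @name survival-tools
NULL

#' Kaplan-Meier estimator
#'
#' @param times positive follow-up times.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return A `step_survival` object: ascending unique times with the
#'   right-continuous survival estimate, numbers at risk, events and
#'   censorings.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) stop_lny("kaplan_meier: empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  structure(list(time = fit$time, survival = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor),
            class = "step_survival")
}

#' Evaluate a step survival curve
#'
#' @param curve a `step_survival`.
#' @param t times at which to evaluate.
#' @param left if `TRUE`, return the left limit S(t-) instead of the
#'   right-continuous value S(t).
#' @return Numeric vector of survival probabilities.
#' @export
surv_at <- function(curve, t, left = FALSE) {
  s <- c(1, curve$survival)
  idx <- findInterval(t, curve$time, left.open = left)
  s[idx + 1]
}

#' @export
print.step_survival <- function(x, ...) {
  cat(sprintf("<step_survival> %d time points, final S = %.4f\n",
              length(x$time), x$survival[length(x$survival)]))
  invisible(x)
}

#' Export a survival curve as two-column CSV
#' @param curve a `step_survival`.
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time = curve$time, survival = curve$survival),
                   path, row.names = FALSE)
  invisible(path)
}

#' Median potential follow-up by the reverse Kaplan-Meier method
#'
#' Applies the product-limit estimator with the censoring indicator as the
#' event, which estimates follow-up duration without the downward bias of
#' taking a naive median over death-terminated times. The confidence interval
#' uses the log-log transformed Greenwood band.
#'
#' @inheritParams kaplan_meier
#' @return List with `median` (years) and `ci` (95\% interval; may be `NA`
#'   when the band is undefined).
#' @export
reverse_km_median_followup <- function(times, events) {
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  if (all(events == 1)) {
    stop_lny("reverse_km_median_followup: all observations are events; median follow-up is undefined")
  }
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1,
                           conf.type = "log-log")
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  if (is.na(med)) {
    stop_lny("reverse_km_median_followup: censoring survival never reaches 0.5; median undefined")
  }
  list(median = med, ci = c(unname(q$lower), unname(q$upper)))
}

# Internal product-limit estimator of the censoring distribution G, returned
# as sorted censoring-event times and the step values. At tied times the
# censorings (the "events" of this estimator) are processed first, so a death
# at time t is still in the risk set of a censoring at t - the standard
# reverse-KM convention, mirroring events-before-censorings of the event KM.
# Used in tight loops (bootstrap weight recomputation); survfit on the
# flipped indicator is the independent oracle in the test suite.
censoring_km <- function(times, events) {
  ord <- order(times, events)  # at a tie: censorings (events = 0) first
  t <- times[ord]
  cens <- events[ord] == 0
  n <- length(t)
  at_risk <- n - (seq_len(n) - 1L)
  ct <- t[cens]
  risk <- at_risk[cens]
  if (!length(ct)) return(list(time = numeric(0), surv = numeric(0)))
  # sequential one-at-a-time factors within a tie multiply to the usual
  # simultaneous factor (1 - d/n)
  g <- cumprod(1 - 1 / risk)
  keep <- !duplicated(ct, fromLast = TRUE)
  list(time = ct[keep], surv = g[keep])
}

# Evaluate G at x (right-continuous) or G(x-) (left limit).
censoring_surv_at <- function(G, x, left = FALSE) {
  s <- c(1, G$surv)
  s[findInterval(x, G$time, left.open = left) + 1]
}

#' Inverse probability of censoring weights at a horizon
#'
#' Builds the weights used by the IPCW binomial risk models and the
#' censoring-adjusted AUC. Let G be the Kaplan-Meier estimate of the censoring
#' distribution (per stratum when `strata` is given). A patient dying at or
#' before the horizon receives weight 1/G(T-); a patient followed to or beyond
#' the horizon receives 1/G(horizon-); a patient censored strictly before the
#' horizon has unknown status at the horizon and receives weight 0. The left
#' limit prevents a subject's own censoring from informing its weight at tied
#' times.
#'
#' @inheritParams kaplan_meier
#' @param horizon positive horizon in years.
#' @param strata optional vector of stratum labels (e.g. center), so the
#'   censoring distribution is estimated within each stratum.
#' @return An `ipcw_weights` object with fields `horizon`, `weights`,
#'   `strata_label`.
#' @export
ipcw_weights <- function(times, events, horizon, strata = NULL) {
  stopifnot(length(times) == length(events), horizon > 0,
            all(events %in% c(0, 1)))
  n <- length(times)
  w <- numeric(n)
  strata_vec <- if (is.null(strata)) rep("all", n) else as.character(strata)
  stopifnot(length(strata_vec) == n)
  for (s in unique(strata_vec)) {
    idx <- strata_vec == s
    t <- times[idx]; e <- events[idx]
    G <- censoring_km(t, e)
    case <- e == 1 & t <= horizon
    beyond <- t >= horizon & !case
    ws <- numeric(length(t))
    g_case <- censoring_surv_at(G, t[case], left = TRUE)
    g_h <- censoring_surv_at(G, horizon, left = TRUE)
    if (any(g_case <= 0) || (any(beyond) && g_h <= 0)) {
      stop_lny(sprintf(
        "ipcw_weights: censoring survival reaches 0 before a needed time in stratum '%s'", s))
    }
    ws[case] <- 1 / g_case
    ws[beyond] <- 1 / g_h
    w[idx] <- ws
  }
  structure(list(horizon = horizon, weights = w,
                 strata_label = if (is.null(strata)) NULL else strata_vec),
            class = "ipcw_weights")
}

#' @export
print.ipcw_weights <- function(x, ...) {
  cat(sprintf("<ipcw_weights> horizon %g y: %d weighted, %d censored (weight 0), mean weight %.3f\n",
              x$horizon, sum(x$weights > 0), sum(x$weights == 0),
              mean(x$weights[x$weights > 0])))
  invisible(x)
}
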