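#' Censoring-adjusted time-dependent AUC
#'
#' Estimates the probability that a randomly chosen patient dying by the
#' horizon receives a higher risk score than one surviving past it, using
#' IPCW weights so that patients censored before the horizon (status unknown)
#' contribute zero weight rather than being imputed. Cases are deaths by the
#' horizon; controls are patients followed to or beyond it. Ties in scores
#' contribute 1/2 (Mann-Whitney convention), so with no censoring the
#' estimator reduces exactly to the classical Mann-Whitney AUC.
#'
#' @param scores finite risk scores (higher = higher predicted risk).
#' @param times follow-up times.
#' @param events binary death indicators.
#' @param horizon years.
#' @param weights optional [ipcw_weights()] at the same horizon; computed from
#'   `times`/`events` when omitted.
#' @param model_label,cohort_label optional labels stored on the result.
#' @return An `auc_result`: `auc`, `n_cases`, `n_controls`, `horizon`, and a
#'   `roc` data.frame of weighted TPR/FPR points.
#' @export
ipcw_auc <- function(scores, times, events, horizon, weights = NULL,
                     model_label = NA_character_, cohort_label = NA_character_) {
  stopifnot(all(is.finite(scores)), length(scores) == length(times))
  if (is.null(weights)) weights <- ipcw_weights(times, events, horizon)
  stopifnot(inherits(weights, "ipcw_weights"))
  if (!isTRUE(all.equal(weights$horizon, horizon))) {
    stop_lny("ipcw_auc: weights were computed at a different horizon")
  }
  w <- weights$weights
  case <- events == 1 & times <= horizon & w > 0
  control <- w > 0 & !case
  if (!any(case) || !any(control)) {
    stop_lny("ipcw_auc: need at least one case and one control with positive weight")
  }
  si <- scores[case]; wi <- w[case]
  sj <- scores[control]; wj <- w[control]
  cmp <- outer(si, sj, function(a, b) (a > b) + 0.5 * (a == b))
  wprod <- outer(wi, wj)
  auc <- sum(wprod * cmp) / sum(wprod)
  # weighted ROC: classify positive when score >= threshold
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(ct) sum(wi[si >= ct]) / sum(wi), 0)
  fpr <- vapply(thr, function(ct) sum(wj[sj >= ct]) / sum(wj), 0)
  structure(list(horizon = horizon, auc = auc,
                 n_cases = sum(case), n_controls = sum(control),
                 model_label = model_label, cohort_label = cohort_label,
                 roc = data.frame(threshold = c(Inf, thr),
                                  tpr = c(0, tpr), fpr = c(0, fpr))),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC = %.3f at %g y (%d cases / %d controls)%s\n",
              x$auc, x$horizon, x$n_cases, x$n_controls,
              if (!is.na(x$model_label)) paste0(" [", x$model_label, "]") else ""))
  invisible(x)
}

auc_row <- function(a, stratum = NA_character_) {
  data.frame(stratum = stratum, horizon = a$horizon,
             model_label = a$model_label, cohort_label = a$cohort_label,
             auc = a$auc, n_cases = a$n_cases, n_controls = a$n_controls,
             stringsAsFactors = FALSE)
}

#' Marker-added AUC within UICC-stage by laterality strata
#'
#' Within each of the four strata defined by UICC stage group (I-II vs
#' III-IV) and neck-dissection laterality, fits a within-stratum IPCW risk
#' score with and without the LNY marker and reports the paired AUCs at each
#' horizon, so the marker's added discrimination can be read off per stratum.
#' The operating point of the >= 18 LNY classifier (weighted TPR/FPR of
#' `lny >= 18`) is reported alongside each stratum so it can be marked on the
#' ROC curve.
#'
#' Strata without at least one case and one control at a horizon, or where a
#' model cannot be fitted, are skipped with a warning.
#'
#' @param data an `lny_cohort` (typically pooled across centers).
#' @param horizons numeric horizons in years.
#' @param marker how LNY enters the with-marker model: `"continuous"` or
#'   `"binary18"`.
#' @param base_terms covariates of the marker-free within-stratum score.
#' @param ... passed to [fit_weighted_binomial()] (e.g. `penalized = TRUE`).
#' @return Data.frame with one row per stratum x horizon x model state.
#' @export
stratified_marker_auc <- function(data, horizons = c(3, 5),
                                  marker = c("continuous", "binary18"),
                                  base_terms = c("age", "sex", "crt", "ene"),
                                  ...) {
  marker <- match.arg(marker)
  p <- if (inherits(data, "lny_cohort")) data$patients else as.data.frame(data)
  spec0 <- term_spec(base_terms, lny_mode = "none")
  spec1 <- term_spec(base_terms, lny_mode = marker)
  out <- list()
  for (grp in lny_levels$uicc_group) {
    for (lat in lny_levels$laterality) {
      stratum <- sprintf("%s/%s", grp, lat)
      ps <- p[p$uicc_group == grp & p$laterality == lat, , drop = FALSE]
      for (h in horizons) {
        res <- tryCatch({
          w <- ipcw_weights(ps$followup_years, ps$death, h)
          wv <- w$weights
          n_case <- sum(ps$death == 1 & ps$followup_years <= h & wv > 0)
          n_ctrl <- sum(wv > 0) - n_case
          if (n_case < 1 || n_ctrl < 1) {
            stop_lny(sprintf("stratum %s has %d cases / %d controls at %g y",
                             stratum, n_case, n_ctrl, h))
          }
          rows <- list(no_lny = spec0)
          rows[[paste0("lny_", marker)]] <- spec1
          # operating point of the binary >= 18 classifier within the stratum
          case_idx <- ps$death == 1 & ps$followup_years <= h & wv > 0
          ctrl_idx <- wv > 0 & !case_idx
          op_tpr <- sum(wv[case_idx & ps$lny >= 18]) / sum(wv[case_idx])
          op_fpr <- sum(wv[ctrl_idx & ps$lny >= 18]) / sum(wv[ctrl_idx])
          recs <- lapply(names(rows), function(lbl) {
            fit <- fit_risk_model(ps, rows[[lbl]], horizon = h, ...)
            d <- build_design(ps, rows[[lbl]], coding = fit$coding)
            risks <- predict_risk(fit, d$X)
            a <- ipcw_auc(risks, ps$followup_years[d$rows], ps$death[d$rows], h,
                          weights = ipcw_weights(ps$followup_years[d$rows],
                                                 ps$death[d$rows], h),
                          model_label = lbl, cohort_label = stratum)
            cbind(auc_row(a, stratum = stratum),
                  op18_tpr = op_tpr, op18_fpr = op_fpr)
          })
          do.call(rbind, recs)
        }, error = function(e) {
          warning(sprintf("skipping stratum %s at %g y: %s",
                          stratum, h, conditionMessage(e)))
          NULL
        })
        if (!is.null(res)) out[[length(out) + 1]] <- res
      }
    }
  }
  if (!length(out)) stop_lny("stratified_marker_auc: no stratum could be evaluated")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-cohort external validation of LNY risk models
#'
#' Trains three equally adjusted IPCW binomial mortality models on the
#' training cohort - differing only in how LNY enters (continuous, the >= 18
#' dichotomy, or not at all) - then predicts risks in each held-out cohort and
#' evaluates the censoring-adjusted AUC there, using each test cohort's own
#' censoring distribution for the weights. A categorical level present in a
#' test cohort but unseen in training raises an error naming the level.
#'
#' @param train an `lny_cohort` used for fitting.
#' @param tests list of `lny_cohort` objects held out for validation.
#' @param horizons numeric horizons in years (default 3 and 5).
#' @param adjust confounder adjustment set shared by all three models.
#' @param ... passed to [fit_weighted_binomial()] (e.g. `penalized = TRUE`).
#' @return Data.frame of `3 * length(horizons) * length(tests)` AUC rows.
#' @export
cross_validate <- function(train, tests, horizons = c(3, 5),
                           adjust = c("age", "sex", "crt", "uicc_group",
                                      "ene", "laterality"), ...) {
  if (inherits(tests, "lny_cohort")) tests <- list(tests)
  modes <- c(no_lny = "none", lny_continuous = "continuous", lny18 = "binary18")
  out <- list()
  for (h in horizons) {
    fits <- lapply(modes, function(m) {
      fit_risk_model(train, term_spec(adjust, lny_mode = m), horizon = h, ...)
    })
    for (te in tests) {
      pte <- te$patients
      wte <- NULL
      for (lbl in names(fits)) {
        fit <- fits[[lbl]]
        d <- build_design(pte, fit$term_spec, coding = fit$coding)
        risks <- predict_risk(fit, d$X)
        tt <- pte$followup_years[d$rows]; ee <- pte$death[d$rows]
        a <- ipcw_auc(risks, tt, ee, h,
                      weights = ipcw_weights(tt, ee, h),
                      model_label = lbl, cohort_label = te$name)
        out[[length(out) + 1]] <- auc_row(a)[, -1]
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
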