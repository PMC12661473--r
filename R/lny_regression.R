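#' Multivariable linear model of lymph node yield
#'
#' Ordinary least squares of the nodal yield on study center, age (reported
#' per 10-year increase), sex, and the UICC stage by neck-dissection
#' laterality interaction, so that per-laterality stage contrasts (stage II,
#' III, IVa, IVb each versus stage I, separately for ipsilateral and
#' bilateral dissections) can be read off directly - the layout in which such
#' models are conventionally reported. Reference levels: the `reference_center`
#' (default `"heidelberg"`), female, ipsilateral, UICC stage I.
#'
#' Requires complete cases on center, UICC stage (five levels I, II, III,
#' IVa, IVb), laterality, age and sex; incomplete records are dropped and
#' counted. Wald 95\% confidence intervals and two-sided p-values use the
#' t-distribution on the residual degrees of freedom. Heteroscedasticity-
#' consistent (HC3) standard errors are available behind `robust = TRUE`.
#'
#' @param data pooled `lny_cohort` or patient data.frame.
#' @param reference_center center used as the baseline.
#' @param robust use sandwich (HC3) standard errors instead of classical.
#' @return An `lny_fit`: a coefficient `table` (term, estimate, ci_low,
#'   ci_high, p), `residual_sd`, `n_used`, `n_dropped`, and the underlying
#'   `lm` fit.
#' @export
fit_lny_model <- function(data, reference_center = "heidelberg",
                          robust = FALSE) {
  p <- if (inherits(data, "lny_cohort")) data$patients else as.data.frame(data)
  need <- c("center", "uicc_stage", "laterality", "age_at_surgery", "sex", "lny")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop_lny(sprintf("fit_lny_model: missing columns: %s",
                                     paste(miss, collapse = ", ")))
  cc <- stats::complete.cases(p[, need])
  n_dropped <- sum(!cc)
  p <- p[cc, , drop = FALSE]
  if (!nrow(p)) stop_lny("fit_lny_model: no complete cases")
  centers <- unique(p$center)
  if (!reference_center %in% centers) reference_center <- sort(centers)[1]
  mf <- data.frame(
    lny = p$lny,
    center = factor(p$center, levels = c(reference_center,
                                         sort(setdiff(centers, reference_center)))),
    age_decade = p$age_at_surgery / 10,
    sex = factor(p$sex, levels = lny_levels$sex),
    stage = factor(p$uicc_stage, levels = lny_levels$uicc_stage),
    laterality = factor(p$laterality, levels = lny_levels$laterality)
  )
  fit <- stats::lm(lny ~ center + age_decade + sex + stage * laterality,
                   data = mf)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop_lny(sprintf("fit_lny_model: rank-deficient design; aliased term(s): %s",
                     paste(names(beta)[is.na(beta)], collapse = ", ")),
             class = "lnyield_rank_error")
  }
  V <- if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      stop_lny("fit_lny_model: robust = TRUE requires the sandwich package")
    }
    sandwich::vcovHC(fit, type = "HC3")
  } else {
    stats::vcov(fit)
  }
  df <- fit$df.residual
  contrast <- function(lab, L) {
    est <- drop(L %*% beta)
    se <- sqrt(drop(L %*% V %*% L))
    tval <- est / se
    pval <- 2 * stats::pt(-abs(tval), df)
    half <- stats::qt(0.975, df) * se
    data.frame(term = lab, estimate = est, ci_low = est - half,
               ci_high = est + half, p = pval, row.names = NULL)
  }
  unit <- function(name) { L <- numeric(length(beta)); names(L) <- names(beta)
                           L[name] <- 1; L }
  rows <- list()
  for (ctr in levels(mf$center)[-1]) {
    rows[[length(rows) + 1]] <- contrast(paste0("center_", ctr),
                                         unit(paste0("center", ctr)))
  }
  rows[[length(rows) + 1]] <- contrast("age_per_decade", unit("age_decade"))
  rows[[length(rows) + 1]] <- contrast("male", unit("sexmale"))
  rows[[length(rows) + 1]] <- contrast("bilateral_at_stage_I",
                                       unit("lateralitybilateral"))
  for (st in levels(mf$stage)[-1]) {
    rows[[length(rows) + 1]] <- contrast(sprintf("ipsilateral_%s_vs_I", st),
                                         unit(paste0("stage", st)))
  }
  for (st in levels(mf$stage)[-1]) {
    L <- unit(paste0("stage", st))
    L[paste0("stage", st, ":lateralitybilateral")] <- 1
    rows[[length(rows) + 1]] <- contrast(sprintf("bilateral_%s_vs_I", st), L)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, residual_sd = stats::sigma(fit),
                 n_used = nrow(p), n_dropped = n_dropped, fit = fit,
                 robust = robust),
            class = "lny_fit")
}

#' @export
print.lny_fit <- function(x, ...) {
  cat(sprintf("<lny_fit> OLS of LNY, n = %d (%d dropped), residual SD %.2f%s\n",
              x$n_used, x$n_dropped, x$residual_sd,
              if (x$robust) ", HC3 SEs" else ""))
  y <- x$table
  y[-1] <- lapply(y[-1], round, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write the LNY coefficient table to CSV
#' @param x an `lny_fit`.
#' @param path output path.
#' @export
write_lny_fit_csv <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
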