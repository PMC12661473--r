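#' LNY range categories and G-computation treatment effects
#'
#' The exposure of the population-average analysis is the lymph node yield
#' grouped into five ranges of approximately equal size. Intervals are
#' left-closed/right-open except the last, which is closed: \[2,17), \[17,25),
#' \[25,33), \[33,44), \[44,119\]. The 33-44 range serves as reference so both
#' lower and higher yields can be compared against it.
#'
#' @name gcomputation
NULL

#' Default LNY category boundaries
#' @return Numeric vector of interval boundaries `c(2, 17, 25, 33, 44, 119)`.
#' @export
lny_default_breaks <- function() c(2, 17, 25, 33, 44, 119)

#' Labels for a set of LNY boundaries
#' @param breaks boundaries as in [lny_default_breaks()].
#' @export
lny_break_labels <- function(breaks = lny_default_breaks()) {
  k <- length(breaks) - 1
  paste(breaks[seq_len(k)], breaks[seq_len(k) + 1], sep = "-")
}

#' Assign LNY counts to range categories
#'
#' @param lny integer nodal yields.
#' @param breaks interval boundaries; intervals are left-closed/right-open
#'   except the last, which includes its upper bound (so 17 falls in 17-25
#'   and 44 in 44-119).
#' @return Factor of category labels (reference ordering is set by the model
#'   builder, not here).
#' @export
categorize_lny <- function(lny, breaks = lny_default_breaks()) {
  stopifnot(length(breaks) >= 3, !is.unsorted(breaks, strictly = TRUE))
  k <- length(breaks) - 1
  bad <- lny < breaks[1] | lny > breaks[k + 1]
  if (any(bad)) {
    stop_lny(sprintf("categorize_lny: value(s) outside [%g, %g]: %s",
                     breaks[1], breaks[k + 1],
                     paste(utils::head(unique(lny[bad]), 5), collapse = ", ")))
  }
  idx <- findInterval(lny, breaks, rightmost.closed = TRUE)
  factor(lny_break_labels(breaks)[idx], levels = lny_break_labels(breaks))
}

#' Derive balanced integer quintile boundaries from observed yields
#'
#' Searches integer cut points near the empirical quantiles and returns the
#' combination minimizing the largest deviation of any category size from
#' n/5, which is how "approximately equal groups" are formed from an
#' integer-valued yield with heavy ties.
#'
#' @param lny integer nodal yields of the pooled cohort.
#' @param k number of groups (default 5).
#' @param window half-width of the integer search window around each naive
#'   quantile.
#' @return Boundaries suitable for [categorize_lny()] (length `k + 1`,
#'   starting at `min(lny)` and ending at `max(lny)`).
#' @export
quintile_lny_breaks <- function(lny, k = 5, window = 6) {
  stopifnot(is_count(lny), length(lny) >= k * 2)
  n <- length(lny)
  target <- n / k
  lo <- min(lny); hi <- max(lny)
  naive <- stats::quantile(lny, probs = seq_len(k - 1) / k, type = 1, names = FALSE)
  cand <- lapply(naive, function(q) {
    v <- (q - window):(q + window)
    v[v > lo & v <= hi]
  })
  sorted <- sort(lny)
  cum_below <- function(b) findInterval(b - 0.5, sorted)  # #(lny < b), integer data
  grids <- lapply(cand, function(v) stats::setNames(cum_below(v), v))
  combos <- expand.grid(lapply(grids, function(g) seq_along(g)))
  best <- NULL; best_obj <- Inf
  for (r in seq_len(nrow(combos))) {
    cuts <- vapply(seq_len(k - 1), function(j) grids[[j]][[combos[r, j]]], 0)
    bvals <- vapply(seq_len(k - 1), function(j) as.numeric(names(grids[[j]])[combos[r, j]]), 0)
    if (is.unsorted(bvals, strictly = TRUE)) next
    sizes <- diff(c(0, cuts, n))
    obj <- max(abs(sizes - target))
    if (obj < best_obj) { best_obj <- obj; best <- bvals }
  }
  if (is.null(best)) stop_lny("quintile_lny_breaks: no valid boundary combination in the search window")
  c(lo, best, hi)
}

# Build the ATE design for a patient table with a fixed LNY category column,
# dropping terms that are constant in the subgroup (with a note) and design
# columns that are identically zero (empty study-by-category cells).
ate_design <- function(p, lny_cat, coding = NULL, keep_cols = NULL,
                       quiet = FALSE) {
  mf <- data.frame(
    age = p$age_at_surgery, sex = p$sex, lny_cat = as.character(lny_cat),
    ene = p$ene, uicc_group = p$uicc_group, laterality = p$laterality,
    crt = p$crt, center = p$center, stringsAsFactors = FALSE
  )
  cat_terms <- setdiff(names(mf), "age")
  if (is.null(coding)) {
    coding <- list()
    dropped_terms <- character(0)
    refs <- design_reference_levels()
    for (term in cat_terms) {
      obs <- unique(mf[[term]])
      if (length(obs) < 2) {
        dropped_terms <- c(dropped_terms, term)
        next
      }
      lev <- switch(term,
        lny_cat = attr(lny_cat, "level_order"),
        # largest study as reference so sparse-cell effects sit in the
        # better-identified interaction columns
        center = names(sort(table(mf$center), decreasing = TRUE)),
        intersect(refs[[term]], obs))
      lev <- c(lev, setdiff(obs, lev))
      coding[[term]] <- lev
    }
    attr(coding, "dropped_terms") <- dropped_terms
    if (length(dropped_terms) && !quiet) {
      warning(sprintf("ate: term(s) constant within the subgroup, dropped: %s",
                      paste(dropped_terms, collapse = ", ")))
    }
  }
  dropped_terms <- attr(coding, "dropped_terms") %||% character(0)
  active <- setdiff(cat_terms, dropped_terms)
  for (term in active) mf[[term]] <- factor(mf[[term]], levels = coding[[term]])
  pairs <- list(c("center", "uicc_group"), c("center", "laterality"),
                c("center", "lny_cat"), c("center", "crt"),
                c("uicc_group", "laterality"), c("laterality", "lny_cat"))
  pairs <- Filter(function(pr) all(pr %in% active), pairs)
  rhs <- c("age", active, vapply(pairs, paste, "", collapse = ":"))
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(form, data = mf)
  if (is.null(keep_cols)) {
    zero <- colSums(abs(X)) == 0
    if (any(zero) && !quiet) {
      warning(sprintf("ate: empty design cell(s); dropping column(s): %s",
                      paste(colnames(X)[zero], collapse = ", ")))
    }
    keep_cols <- colnames(X)[!zero]
    # empty study-by-category cells can also surface as exact collinearity
    # (e.g. a category observed in all but the reference study); drop the
    # aliased columns found by pivoted QR
    qrX <- qr(X[, keep_cols, drop = FALSE])
    if (qrX$rank < length(keep_cols)) {
      aliased <- keep_cols[qrX$pivot[(qrX$rank + 1):length(keep_cols)]]
      if (!quiet) {
        warning(sprintf("ate: aliased design column(s) dropped: %s",
                        paste(aliased, collapse = ", ")))
      }
      keep_cols <- setdiff(keep_cols, aliased)
    }
  }
  list(X = X[, keep_cols, drop = FALSE], coding = coding, keep_cols = keep_cols)
}

#' Population-average treatment effect of LNY range on 3-year mortality
#'
#' G-computation (standardization): an IPCW binomial model of death by the
#' horizon is fitted once within the pN subgroup - adjusted for age, sex, LNY
#' category, ENE, UICC stage group, laterality, chemoradiotherapy and study,
#' plus the six center/stage/laterality/LNY/CRT interaction terms - then each
#' patient's LNY category is set to each range in turn (all other covariates
#' fixed), individual risks are predicted and averaged over the subgroup's
#' empirical covariate distribution. Risk ratios are taken against the 33-44
#' reference range; confidence intervals come from a percentile bootstrap
#' resampling patients within study, with censoring weights and model refitted
#' in every replicate.
#'
#' Terms that are constant within the subgroup (UICC stage group is constant
#' among pN-positive patients, who are all stage III-IV) are dropped with a
#' warning, as are design columns for study-by-category cells that are empty.
#' Bootstrap replicates that fail to converge are discarded and counted; more
#' than 5\% discarded is an error.
#'
#' @param data pooled `lny_cohort` across studies.
#' @param subgroup `"pN_negative"` or `"pN_positive"`.
#' @param horizon years (default 3).
#' @param breaks LNY category boundaries.
#' @param reference reference category label (default `"33-44"`).
#' @param n_boot bootstrap replicates (0 skips the bootstrap).
#' @param seed seed governing the bootstrap; results are reproducible
#'   bit-for-bit for a given seed.
#' @param conf_level confidence level of the percentile interval.
#' @param penalized passed to [fit_weighted_binomial()]: apply a weak ridge
#'   penalty so sparse study-by-category cells with all (or no) deaths do not
#'   abort the fit with a separation error.
#' @return An `ate_result` with standardized risks per category, risk ratios
#'   with bootstrap CIs, and bookkeeping fields.
#' @export
estimate_ate <- function(data, subgroup = c("pN_negative", "pN_positive"),
                         horizon = 3, breaks = lny_default_breaks(),
                         reference = "33-44", n_boot = 1000, seed = 1,
                         conf_level = 0.95, penalized = FALSE) {
  subgroup <- match.arg(subgroup)
  p <- if (inherits(data, "lny_cohort")) data$patients else as.data.frame(data)
  sel <- if (subgroup == "pN_positive") p$pn_positive_count > 0 else p$pn_positive_count == 0
  p <- p[sel, , drop = FALSE]
  if (!nrow(p)) stop_lny(sprintf("estimate_ate: subgroup %s is empty", subgroup))
  need <- c("age_at_surgery", "sex", "ene", "uicc_group", "laterality", "crt",
            "center", "lny", "followup_years", "death")
  p <- p[stats::complete.cases(p[, need]), , drop = FALSE]
  labs <- lny_break_labels(breaks)
  if (!reference %in% labs) stop_lny("estimate_ate: reference is not a category label")
  level_order <- c(reference, setdiff(labs, reference))
  obs_cat <- categorize_lny(p$lny, breaks)
  make_cat <- function(v) structure(as.character(v), level_order = level_order)
  d <- ate_design(p, make_cat(obs_cat))
  cf <- lapply(labs, function(g) {
    ate_design(p, make_cat(rep(g, nrow(p))), coding = d$coding,
               keep_cols = d$keep_cols, quiet = TRUE)$X
  })
  names(cf) <- labs
  fit_once <- function(idx, quiet = TRUE) {
    t <- p$followup_years[idx]; e <- p$death[idx]
    w <- ipcw_weights(t, e, horizon, strata = p$center[idx])
    y <- as.integer(e == 1 & t <= horizon)
    Xi <- d$X[idx, , drop = FALSE]
    # cells empty among the status-known (weight > 0) rows - possible both in
    # the full subgroup and after resampling - make their columns unidentified;
    # select an identified column set by pivoted QR on the rows the fit uses
    used <- w$weights > 0
    sel <- colSums(abs(Xi[used, , drop = FALSE])) > 0
    qri <- qr(Xi[used, sel, drop = FALSE])
    if (qri$rank < sum(sel)) {
      aliased <- colnames(Xi)[sel][qri$pivot[(qri$rank + 1):sum(sel)]]
      sel[match(aliased, colnames(Xi))] <- FALSE
    }
    if (!all(sel) && !quiet) {
      warning(sprintf("ate: unidentified design column(s) dropped from the fit: %s",
                      paste(colnames(Xi)[!sel], collapse = ", ")))
    }
    fit <- fit_weighted_binomial(Xi[, sel, drop = FALSE], y, w,
                                 penalized = penalized)
    indiv <- vapply(labs, function(g) {
      stats::plogis(drop(cf[[g]][idx, sel, drop = FALSE] %*% fit$coefficients))
    }, numeric(length(idx)))
    structure(colMeans(indiv), indiv = indiv, coefficients = fit$coefficients,
              fitted = stats::plogis(drop(Xi[, sel, drop = FALSE] %*% fit$coefficients)))
  }
  all_idx <- seq_len(nrow(p))
  full <- fit_once(all_idx, quiet = FALSE)
  risks <- as.numeric(full)
  names(risks) <- labs
  rr <- risks / risks[reference]
  ci <- matrix(NA_real_, nrow = length(labs), ncol = 2,
               dimnames = list(labs, c("lo", "hi")))
  n_bad <- 0L
  if (n_boot > 0) {
    set.seed(seed)
    by_center <- split(all_idx, p$center)
    boot_rr <- matrix(NA_real_, nrow = n_boot, ncol = length(labs),
                      dimnames = list(NULL, labs))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(by_center, function(ii) sample(ii, length(ii),
                                                          replace = TRUE)),
                    use.names = FALSE)
      rb <- tryCatch(fit_once(idx), error = function(e) NULL)
      if (is.null(rb)) { n_bad <- n_bad + 1L; next }
      boot_rr[b, ] <- rb / rb[reference]
    }
    if (n_bad > 0.05 * n_boot) {
      stop_lny(sprintf("estimate_ate: %d of %d bootstrap replicates failed (> 5%%)",
                       n_bad, n_boot))
    }
    alpha <- (1 - conf_level) / 2
    for (g in setdiff(labs, reference)) {
      ci[g, ] <- stats::quantile(boot_rr[, g], c(alpha, 1 - alpha),
                                 na.rm = TRUE, names = FALSE)
    }
    ci[reference, ] <- c(1, 1)
  }
  rr_tab <- data.frame(category = labs, standardized_risk = unname(risks),
                       risk_ratio = unname(rr), ci_low = ci[, "lo"],
                       ci_high = ci[, "hi"],
                       reference = labs == reference, row.names = NULL)
  structure(list(subgroup = subgroup, horizon = horizon,
                 reference = reference, breaks = breaks,
                 risks = risks, rr = rr_tab, n = nrow(p),
                 n_boot = n_boot, n_discarded = n_bad, seed = seed,
                 dropped_terms = attr(d$coding, "dropped_terms"),
                 design_columns = d$keep_cols,
                 coefficients = attr(full, "coefficients"),
                 individual_risks = attr(full, "indiv"),
                 fitted_risks = attr(full, "fitted"),
                 observed_category = as.character(obs_cat),
                 coding = d$coding),
            class = "ate_result")
}

#' @export
print.ate_result <- function(x, ...) {
  cat(sprintf("<ate_result> %s, %g-year mortality, n = %d, reference %s, %d bootstrap reps\n",
              x$subgroup, x$horizon, x$n, x$reference, x$n_boot))
  y <- x$rr
  y$standardized_risk <- round(y$standardized_risk, 4)
  y[c("risk_ratio", "ci_low", "ci_high")] <-
    lapply(y[c("risk_ratio", "ci_low", "ci_high")], round, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write an ATE result as a forest-plot-ready CSV
#' @param x an `ate_result`.
#' @param path output path.
#' @export
write_ate_csv <- function(x, path) {
  utils::write.csv(x$rr, path, row.names = FALSE)
  invisible(path)
}

#' Write an ATE result as JSON
#' @param x an `ate_result`.
#' @param path output path.
#' @export
write_ate_json <- function(x, path) {
  jsonlite::write_json(list(
    subgroup = x$subgroup, horizon = x$horizon, reference = x$reference,
    n = x$n, n_boot = x$n_boot, n_discarded = x$n_discarded, seed = x$seed,
    standardized_risk = as.list(x$risks),
    risk_ratio = x$rr
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
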