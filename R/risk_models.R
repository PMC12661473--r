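#' Term specification for mortality risk models
#'
#' Defines which covariates (and pairwise interactions) enter a t-year
#' mortality model, and how lymph node yield enters: not at all (`none`), as a
#' continuous count (`continuous`), dichotomized at the >= 18 cut-off
#' (`binary18`), or as the five-range category used by the treatment-effect
#' analysis (`category5`).
#'
#' @param main_terms character vector of covariate names. Recognized names:
#'   `age`, `sex`, `center`, `uicc_group`, `uicc_stage`, `pt_stage`,
#'   `laterality`, `ene`, `crt`, and `lny` (included automatically when
#'   `lny_mode != "none"`).
#' @param interactions list of length-2 character vectors; each member must
#'   also be a main term (or `lny` when an LNY mode is active).
#' @param lny_mode one of `"none"`, `"continuous"`, `"binary18"`,
#'   `"category5"`.
#' @return A `term_spec` object.
#' @export
term_spec <- function(main_terms,
                      interactions = list(),
                      lny_mode = c("none", "continuous", "binary18", "category5")) {
  lny_mode <- match.arg(lny_mode)
  main_terms <- setdiff(unique(main_terms), "lny")
  all_terms <- c(main_terms, if (lny_mode != "none") "lny")
  for (ia in interactions) {
    if (length(ia) != 2) stop_lny("interactions must be pairs of term names")
    bad <- setdiff(ia, all_terms)
    if (length(bad)) {
      stop_lny(sprintf("interaction member(s) not among main terms: %s",
                       paste(bad, collapse = ", ")))
    }
  }
  structure(list(main_terms = main_terms, interactions = interactions,
                 lny_mode = lny_mode),
            class = "term_spec")
}

# Reference levels used for dummy coding (first level = reference).
design_reference_levels <- function() {
  c(lny_levels[c("sex", "uicc_group", "uicc_stage", "pt_stage",
                 "laterality", "ene", "crt")],
    list(lny18 = c("<18", ">=18")))
}

# Build the model variable for one term from a patient table.
design_variable <- function(p, term, lny_mode, breaks) {
  switch(term,
    age = p$age_at_surgery,
    sex = p$sex,
    center = p$center,
    uicc_group = p$uicc_group,
    uicc_stage = p$uicc_stage,
    pt_stage = p$pt_stage,
    laterality = p$laterality,
    ene = p$ene,
    crt = p$crt,
    lny = switch(lny_mode,
      continuous = p$lny,
      binary18 = ifelse(p$lny >= 18, ">=18", "<18"),
      category5 = as.character(categorize_lny(p$lny, breaks)),
      stop_lny("term 'lny' requires lny_mode != 'none'")),
    stop_lny(sprintf("unknown model term '%s'", term))
  )
}

#' Build a design matrix
#'
#' Dummy-codes categorical terms against fixed, documented reference levels
#' (female, I-II, ipsilateral, ENE no, CRT not received, LNY < 18; for
#' `center` the reference is the first level of the supplied coding, or the
#' alphabetically first observed center). Interactions are products of the
#' coded columns. Column order is deterministic: intercept, main terms in the
#' order given, then interactions.
#'
#' @param data an `lny_cohort` or patient data.frame.
#' @param spec a [term_spec()].
#' @param coding optional coding map from a previous call (e.g. the training
#'   design); observed values outside the coded levels raise an error naming
#'   the offending level, so external validation fails loudly.
#' @param lny_breaks category boundaries when `lny_mode == "category5"`.
#' @param lny_reference reference category when `lny_mode == "category5"`.
#' @return List with `X` (numeric matrix with intercept), `coding` (per-term
#'   factor levels), and `rows` (row indices of `data` used; complete cases).
#' @export
build_design <- function(data, spec, coding = NULL,
                         lny_breaks = lny_default_breaks(),
                         lny_reference = NULL) {
  p <- if (inherits(data, "lny_cohort")) data$patients else as.data.frame(data)
  stopifnot(inherits(spec, "term_spec"))
  terms <- c(spec$main_terms, if (spec$lny_mode != "none") "lny")
  vars <- lapply(terms, design_variable, p = p, lny_mode = spec$lny_mode,
                 breaks = lny_breaks)
  names(vars) <- terms
  mf <- as.data.frame(vars, optional = TRUE)
  names(mf) <- terms
  rows <- stats::complete.cases(mf)
  mf <- mf[rows, , drop = FALSE]
  if (!nrow(mf)) stop_lny("build_design: no complete cases for the requested terms")
  refs <- design_reference_levels()
  new_coding <- list()
  for (term in terms) {
    v <- mf[[term]]
    if (is.numeric(v)) next
    if (!is.null(coding)) {
      if (is.null(coding[[term]])) {
        stop_lny(sprintf("build_design: term '%s' missing from supplied coding", term))
      }
      lev <- coding[[term]]
      unseen <- setdiff(unique(v), lev)
      if (length(unseen)) {
        stop_lny(sprintf("build_design: term '%s' has level(s) unseen in the model coding: %s",
                         term, paste(unseen, collapse = ", ")),
                 class = "lnyield_unseen_level_error")
      }
    } else {
      lev <- if (term == "lny" && spec$lny_mode == "binary18") {
        refs$lny18
      } else if (term == "lny" && spec$lny_mode == "category5") {
        labs <- lny_break_labels(lny_breaks)
        ref <- lny_reference %||% (if ("33-44" %in% labs) "33-44" else labs[1])
        c(ref, setdiff(labs, ref))
      } else if (term %in% names(refs)) {
        intersect(refs[[term]], unique(v))
      } else {
        sort(unique(v))
      }
      lev <- c(lev, setdiff(unique(v), lev))
      if (length(lev) < 2) {
        stop_lny(sprintf("build_design: categorical term '%s' has a single observed level ('%s'); the column would be constant",
                         term, lev),
                 class = "lnyield_constant_term_error")
      }
    }
    mf[[term]] <- factor(v, levels = lev)
    new_coding[[term]] <- lev
  }
  rhs <- c(terms, vapply(spec$interactions, paste, "", collapse = ":"))
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(form, data = mf)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  list(X = X, coding = if (is.null(coding)) new_coding else coding,
       rows = which(rows))
}

#' Fit a weighted binomial (logistic) model by IRLS
#'
#' Maximizes the weight-multiplied binomial log-likelihood with a logit link
#' using Newton iterations with step halving, so the weighted deviance is
#' non-increasing across iterations. Convergence is declared when the maximum
#' absolute score falls below `1e-8` or the relative deviance change below
#' `1e-10` (at most 100 iterations). Weights are internally normalized to
#' mean 1, so rescaling all weights by a constant leaves the fit unchanged.
#'
#' Rows with weight 0 (status unknown at the horizon) are excluded before
#' fitting. Rank deficiency raises an error naming the collinear columns. A
#' coefficient exceeding 15 in absolute value at convergence is treated as
#' (quasi-)separation; set `penalized = TRUE` to refit with a weak ridge
#' penalty instead.
#'
#' @param X design matrix from [build_design()].
#' @param y binary outcome (death by the horizon).
#' @param weights an [ipcw_weights()] object or numeric vector.
#' @param penalized if `TRUE`, apply a ridge penalty (`lambda` times the sum
#'   of squared non-intercept coefficients) guaranteeing finite estimates.
#' @param lambda ridge penalty used when `penalized = TRUE`.
#' @param term_spec_used optional [term_spec()] stored on the result.
#' @param coding optional coding map stored on the result.
#' @return A `risk_model` object with `coefficients`, `converged`, `n_used`,
#'   `deviance`, `horizon`, `link = "logit"`.
#' @export
fit_weighted_binomial <- function(X, y, weights, penalized = FALSE,
                                  lambda = 1e-3, term_spec_used = NULL,
                                  coding = NULL) {
  horizon <- NA_real_
  if (inherits(weights, "ipcw_weights")) {
    horizon <- weights$horizon
    weights <- weights$weights
  }
  stopifnot(nrow(X) == length(y), length(weights) == length(y),
            all(weights >= 0), all(y %in% c(0, 1)))
  keep <- weights > 0
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  w <- weights[keep]
  w <- w / mean(w)
  n <- nrow(X); pdim <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < pdim) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):pdim]]
    stop_lny(sprintf("fit_weighted_binomial: design is rank deficient; collinear column(s): %s",
                     paste(bad, collapse = ", ")),
             class = "lnyield_rank_error")
  }
  # per-observation ridge: the penalty grows with the effective sample size,
  # so duplicating every row (or rescaling weights) leaves the fit unchanged
  pen <- if (penalized) rep(lambda * n, pdim) else rep(0, pdim)
  if (penalized && colnames(X)[1] == "(Intercept)") pen[1] <- 0
  devfun <- function(beta) {
    eta <- drop(X %*% beta)
    # numerically safe weighted binomial deviance
    -2 * sum(w * (y * stats::plogis(eta, log.p = TRUE) +
                  (1 - y) * stats::plogis(-eta, log.p = TRUE))) +
      sum(pen * beta^2)
  }
  beta <- rep(0, pdim)
  dev <- devfun(beta)
  converged <- FALSE
  for (iter in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, w * (y - mu))) - pen * beta
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    info <- crossprod(X, X * (w * mu * (1 - mu)))
    diag(info) <- diag(info) + pen
    delta <- tryCatch(solve(info, score), error = function(e) {
      stop_lny("fit_weighted_binomial: singular information matrix (separation or collinearity)",
               class = "lnyield_separation_error")
    })
    step <- 1
    repeat {
      cand <- beta + step * delta
      dev_new <- devfun(cand)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { dev_new <- dev; cand <- beta; break }
    }
    rel_change <- abs(dev - dev_new) / (abs(dev) + 0.1)
    beta <- cand
    dev <- dev_new
    if (rel_change < 1e-10) { converged <- TRUE; break }
  }
  if (!converged) {
    stop_lny("fit_weighted_binomial: IRLS did not converge within 100 iterations",
             class = "lnyield_convergence_error")
  }
  if (!penalized && any(abs(beta) > 15)) {
    stop_lny(sprintf(
      "fit_weighted_binomial: |coefficient| > 15 on the logit scale (%s); likely separation - consider penalized = TRUE",
      paste(colnames(X)[abs(beta) > 15], collapse = ", ")),
      class = "lnyield_separation_error")
  }
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, link = "logit", horizon = horizon,
                 converged = converged, n_used = n, deviance = dev,
                 term_spec = term_spec_used, coding = coding,
                 penalized = penalized),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> logit link, horizon %s y, n = %d, deviance %.2f\n",
              format(x$horizon), x$n_used, x$deviance))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict t-year mortality risk
#'
#' @param model a `risk_model`.
#' @param X design matrix whose columns match the model's exactly.
#' @return Numeric vector of risks in \[0, 1\].
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "risk_model"))
  have <- colnames(X)
  want <- names(model$coefficients)
  if (!identical(have, want)) {
    stop_lny(sprintf(
      "predict_risk: design columns do not match the model. Missing: [%s]; unexpected: [%s]",
      paste(setdiff(want, have), collapse = ", "),
      paste(setdiff(have, want), collapse = ", ")))
  }
  stats::plogis(drop(X %*% model$coefficients))
}

#' Fit a t-year mortality risk model on a cohort
#'
#' Convenience wrapper: computes IPCW weights at the horizon, builds the
#' design for the given term specification, and fits the weighted binomial
#' model. The death-by-horizon indicator uses the convention that an event at
#' exactly the horizon counts as a death by the horizon.
#'
#' @param data an `lny_cohort`.
#' @param spec a [term_spec()].
#' @param horizon years.
#' @param strata optional censoring-KM strata (e.g. center labels).
#' @param ... passed to [fit_weighted_binomial()].
#' @return A `risk_model` carrying the coding map for later prediction.
#' @export
fit_risk_model <- function(data, spec, horizon, strata = NULL, ...) {
  p <- if (inherits(data, "lny_cohort")) data$patients else as.data.frame(data)
  d <- build_design(p, spec)
  p <- p[d$rows, , drop = FALSE]
  X <- d$X
  strata_used <- if (!is.null(strata)) strata[d$rows] else NULL
  w <- ipcw_weights(p$followup_years, p$death, horizon, strata = strata_used)
  y <- as.integer(p$death == 1 & p$followup_years <= horizon)
  fit_weighted_binomial(X, y, w, term_spec_used = spec, coding = d$coding, ...)
}

#' Serialize a fitted risk model to JSON
#' @param model a `risk_model`.
#' @param path output path.
#' @export
write_risk_model_json <- function(model, path) {
  jsonlite::write_json(list(
    link = model$link, horizon = model$horizon,
    coefficients = as.list(model$coefficients),
    n_used = model$n_used, deviance = model$deviance,
    term_spec = unclass(model$term_spec), coding = model$coding
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted risk model from JSON
#' @param path path written by [write_risk_model_json()].
#' @return A `risk_model`.
#' @export
read_risk_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- if (!is.null(j$term_spec)) {
    term_spec(j$term_spec$main_terms,
              lapply(j$term_spec$interactions, identity),
              j$term_spec$lny_mode)
  }
  structure(list(coefficients = unlist(j$coefficients), link = j$link,
                 horizon = j$horizon, converged = TRUE, n_used = j$n_used,
                 deviance = j$deviance, term_spec = ts,
                 coding = lapply(j$coding, unlist), penalized = FALSE),
            class = "risk_model")
}
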