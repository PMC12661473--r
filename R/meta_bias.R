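#' Study-level effect table for small-study bias diagnostics
#'
#' Holds one row per published study: a log hazard ratio comparing survival
#' above versus below an LNY cut-off, its standard error, and the study size.
#'
#' @param study_label character labels.
#' @param log_hr log hazard ratios.
#' @param se standard errors (> 0).
#' @param n study sizes.
#' @return An `effect_table` data.frame.
#' @export
effect_table <- function(study_label, log_hr, se, n = NA_integer_) {
  stopifnot(length(study_label) >= 1,
            length(log_hr) == length(study_label),
            length(se) == length(study_label))
  if (any(!is.finite(se) | se <= 0)) stop_lny("effect_table: se must be finite and > 0")
  out <- data.frame(study_label = as.character(study_label),
                    log_hr = as.numeric(log_hr), se = as.numeric(se),
                    n = as.integer(n), stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Read an effect table from CSV
#' @param path CSV with columns study_label, log_hr, se, n.
#' @export
read_effect_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("study_label", "log_hr", "se"), names(d))
  if (length(miss)) stop_lny(sprintf("read_effect_table: missing columns: %s",
                                     paste(miss, collapse = ", ")))
  effect_table(d$study_label, d$log_hr, d$se, d$n %||% NA_integer_)
}

# Restricted log-likelihood of the normal-normal random-effects model at
# heterogeneity variance tau2.
reml_loglik <- function(tau2, y, v) {
  wi <- 1 / (v + tau2)
  mu <- sum(wi * y) / sum(wi)
  -0.5 * (sum(log(v + tau2)) + log(sum(wi)) + sum(wi * (y - mu)^2))
}

#' Random-effects pooling by restricted maximum likelihood
#'
#' Estimates the between-study heterogeneity variance tau^2 by maximizing the
#' restricted log-likelihood of the normal-normal model over a bounded
#' one-dimensional search (tolerance 1e-10, boundary at 0 checked
#' explicitly), then pools with inverse-variance weights 1/(se^2 + tau^2).
#' The confidence interval for the pooled mean is the normal Wald interval.
#'
#' @param tab an [effect_table()].
#' @param conf_level confidence level.
#' @return List with `mu`, `se_mu`, `tau2`, `ci`, `k`. A single-row table
#'   returns that effect with `tau2 = 0` and a warning.
#' @export
pool_random_effects <- function(tab, conf_level = 0.95) {
  stopifnot(inherits(tab, "effect_table") || is.data.frame(tab))
  y <- tab$log_hr; v <- tab$se^2; k <- length(y)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (k == 1) {
    warning("pool_random_effects: single study; tau2 fixed at 0")
    return(list(mu = y, se_mu = tab$se, tau2 = 0,
                ci = c(y - z * tab$se, y + z * tab$se), k = 1L))
  }
  upper <- max(10 * stats::var(y), 10 * max(v), 1e-3)
  opt <- stats::optimize(reml_loglik, interval = c(0, upper), y = y, v = v,
                         maximum = TRUE, tol = 1e-10)
  tau2 <- if (reml_loglik(0, y, v) >= opt$objective) 0 else opt$maximum
  wi <- 1 / (v + tau2)
  mu <- sum(wi * y) / sum(wi)
  se_mu <- sqrt(1 / sum(wi))
  list(mu = mu, se_mu = se_mu, tau2 = tau2,
       ci = c(mu - z * se_mu, mu + z * se_mu), k = as.integer(k))
}

#' Egger's regression test of funnel-plot asymmetry
#'
#' Regresses the standardized effect (log HR divided by its SE) on precision
#' (1/SE); the intercept of this regression estimates small-study asymmetry
#' and is tested against zero with the t-distribution on k - 2 degrees of
#' freedom. Equivalent to weighted regression of the effect on its SE with
#' weights 1/SE^2.
#'
#' @param tab an [effect_table()] with at least 3 rows.
#' @return List with `intercept`, `se`, `p` (two-sided).
#' @export
egger_test <- function(tab) {
  stopifnot(inherits(tab, "effect_table") || is.data.frame(tab))
  k <- nrow(tab)
  if (k < 3) stop_lny("egger_test: at least 3 studies required")
  z <- tab$log_hr / tab$se
  prec <- 1 / tab$se
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)$coefficients
  list(intercept = unname(sm["(Intercept)", "Estimate"]),
       se = unname(sm["(Intercept)", "Std. Error"]),
       p = unname(sm["(Intercept)", "Pr(>|t|)"]))
}

#' Funnel-plot coordinates with pseudo-confidence contours
#'
#' @param tab an [effect_table()].
#' @param mu pooled mean effect (e.g. from [pool_random_effects()]).
#' @param n_grid number of contour grid points over the SE range.
#' @return List with `points` (effect, se per study) and `contours`
#'   (se, lower = mu - 1.96 se, mid = mu, upper = mu + 1.96 se).
#' @export
funnel_data <- function(tab, mu, n_grid = 50) {
  se_grid <- seq(0, max(tab$se) * 1.05, length.out = n_grid)
  list(points = data.frame(effect = tab$log_hr, se = tab$se,
                           study_label = tab$study_label),
       contours = data.frame(se = se_grid,
                             lower = mu - 1.96 * se_grid,
                             mid = mu,
                             upper = mu + 1.96 * se_grid))
}
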