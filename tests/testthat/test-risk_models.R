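make_2x2 <- function(a, b, c, d) {
  # x = 1: a deaths, b survivors; x = 0: c deaths, d survivors
  data.frame(x = rep(c(1, 1, 0, 0), c(a, b, c, d)),
             y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

test_that("weighted binomial slope equals the closed-form 2x2 log odds ratio", {
  dat <- make_2x2(12, 5, 7, 20)
  X <- cbind("(Intercept)" = 1, x = dat$x)
  fit <- fit_weighted_binomial(X, dat$y, rep(1, nrow(dat)))
  expect_equal(unname(fit$coefficients["x"]), log(12 * 20 / (5 * 7)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(7 / 20),
               tolerance = 1e-8)
  # saturated model: predicted risks equal the cell frequencies
  risks <- predict_risk(fit, X)
  expect_equal(unique(round(risks[dat$x == 1], 10)), 12 / 17)
  expect_equal(unique(round(risks[dat$x == 0], 10)), 7 / 27)
})

test_that("rescaling all weights by a constant leaves the fit unchanged", {
  dat <- make_2x2(8, 9, 10, 11)
  X <- cbind(1, dat$x)
  colnames(X) <- c("(Intercept)", "x")
  f1 <- fit_weighted_binomial(X, dat$y, rep(1, nrow(dat)))
  f2 <- fit_weighted_binomial(X, dat$y, rep(7.3, nrow(dat)))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("IRLS agrees with an independent maximizer on unweighted data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 2] - 0.5 * X[, 3]))
    fit <- fit_weighted_binomial(X, y, rep(1, n))
    oracle <- stats::glm.fit(X, y, family = stats::binomial())
    expect_equal(fit$coefficients, coef(oracle), tolerance = 1e-6)
  }
})

test_that("degenerate outcomes and separation are rejected", {
  X <- cbind("(Intercept)" = 1, x = rep(c(0, 1), 10))
  expect_error(fit_weighted_binomial(X, rep(0, 20), rep(1, 20)),
               class = "lnyield_separation_error")
  # perfectly separating covariate
  y <- rep(c(0, 1), 10)
  expect_error(fit_weighted_binomial(X, y, rep(1, 20)),
               class = "lnyield_separation_error")
  # penalized refit yields finite coefficients
  fit <- fit_weighted_binomial(X, y, rep(1, 20), penalized = TRUE)
  expect_true(all(is.finite(fit$coefficients)))
  # rank deficiency names the collinear column
  X2 <- cbind(X, x_dup = X[, "x"])
  y2 <- rbinom(20, 1, 0.5); y2[1:2] <- c(0, 1)
  expect_error(fit_weighted_binomial(X2, y2, rep(1, 20)), "x_dup",
               class = "lnyield_rank_error")
})

test_that("design construction codes categories against fixed references", {
  co <- toy_cohort(20)
  sp <- term_spec(c("age", "sex", "laterality"), lny_mode = "binary18")
  d <- build_design(co, sp)
  expect_true(all(c("(Intercept)", "age", "sexmale",
                    "lateralitybilateral", "lny>=18") %in% colnames(d$X)))
  # the >= 18 cut-off is closed on the left: exactly 18 codes as 1
  p <- co$patients
  p$lny[1] <- 18L
  d2 <- build_design(p, sp)
  expect_equal(unname(d2$X[1, "lny>=18"]), 1)
  p$lny[1] <- 17L
  d3 <- build_design(p, sp)
  expect_equal(unname(d3$X[1, "lny>=18"]), 0)
  # three centers yield two dummy columns against the reference
  cohorts <- generate_cohorts(small_config(seed = 5))
  pool <- pool_cohorts(cohorts)
  dc <- build_design(pool, term_spec(c("center"), lny_mode = "none"))
  expect_equal(sum(startsWith(colnames(dc$X), "center")), 2)
})

test_that("single-level and unseen categorical levels fail loudly", {
  co <- toy_cohort(10)
  co$patients$sex <- "male"
  expect_error(build_design(co, term_spec(c("age", "sex"))),
               class = "lnyield_constant_term_error")
  # interaction members must be main terms
  expect_error(term_spec(c("age"), interactions = list(c("age", "sex"))),
               "not among main terms")
  # a level absent from the training coding fails loudly at validation time
  tr <- toy_cohort(14, seed = 1)
  tr$patients$ene <- rep(c("no", "yes"), 7)
  sp <- term_spec(c("age", "ene"))
  d <- build_design(tr, sp)
  te <- toy_cohort(10, seed = 2)
  te$patients$ene <- rep("no", 10)
  te$patients$ene[2] <- "unknown"
  expect_error(build_design(te, sp, coding = d$coding), "unknown",
               class = "lnyield_unseen_level_error")
  # a test cohort observing only a subset of trained levels is fine
  te$patients$ene[2] <- "yes"
  d2 <- build_design(te, sp, coding = d$coding)
  expect_identical(colnames(d2$X), colnames(d$X))
})

test_that("predictions are invariant to affine recoding of a covariate", {
  co <- toy_cohort(30, seed = 4)
  sp <- term_spec(c("age", "sex"), lny_mode = "continuous")
  fit <- fit_risk_model(co, sp, horizon = 3)
  d <- build_design(co, sp, coding = fit$coding)
  r1 <- predict_risk(fit, d$X)
  co2 <- co
  co2$patients$age_at_surgery <- (co2$patients$age_at_surgery - 50) / 10
  fit2 <- fit_risk_model(co2, sp, horizon = 3)
  d2 <- build_design(co2, sp, coding = fit2$coding)
  expect_equal(predict_risk(fit2, d2$X), r1, tolerance = 1e-6)
})

test_that("prediction rejects mismatched design columns", {
  co <- toy_cohort(20)
  sp <- term_spec(c("age", "sex"))
  fit <- fit_risk_model(co, sp, horizon = 3, penalized = TRUE)
  d <- build_design(co, term_spec(c("age", "sex", "crt")))
  expect_error(predict_risk(fit, d$X), "crt")
  # trivial closed forms
  m <- fit
  m$coefficients[] <- 0
  d0 <- build_design(co, sp, coding = fit$coding)
  expect_true(all(predict_risk(m, d0$X) == 0.5))
})

test_that("risk models survive a JSON round trip", {
  co <- toy_cohort(30, seed = 8)
  sp <- term_spec(c("age", "sex"), lny_mode = "binary18")
  fit <- fit_risk_model(co, sp, horizon = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_risk_model_json(fit, f)
  fit2 <- read_risk_model_json(f)
  d <- build_design(co, fit2$term_spec, coding = fit2$coding)
  expect_equal(predict_risk(fit2, d$X),
               predict_risk(fit, d$X), tolerance = 1e-12)
})
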