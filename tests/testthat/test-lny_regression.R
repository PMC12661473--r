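# Deterministic patient table whose yield follows the generator's mean model
# exactly (no noise, no rounding), so the fit must recover the coefficients
# to numerical precision.
noiseless_lny_data <- function(n = 400, seed = 61) {
  set.seed(seed)
  co <- default_lny_coefficients()
  centers <- sample(c("heidelberg", "cork", "brescia"), n, replace = TRUE)
  stage <- sample(c("I", "II", "III", "IVa", "IVb"), n, replace = TRUE)
  bilat <- sample(c(TRUE, FALSE), n, replace = TRUE)
  male <- sample(c(TRUE, FALSE), n, replace = TRUE)
  age <- runif(n, 35, 90)
  offset <- ifelse(centers == "cork", co["center_cork"],
            ifelse(centers == "brescia", co["center_brescia"], 0))
  stage_eff <- ifelse(stage == "I", 0,
                      co[paste0(ifelse(bilat, "bilateral_", "ipsilateral_"), stage)])
  lny <- co["intercept"] + offset + co["age_per_decade"] * age / 10 +
    co["male"] * male + co["bilateral"] * bilat + stage_eff
  data.frame(center = centers, uicc_stage = stage,
             laterality = ifelse(bilat, "bilateral", "ipsilateral"),
             age_at_surgery = age, sex = ifelse(male, "male", "female"),
             lny = unname(lny))
}

test_that("a noiseless mean-model table is recovered to numerical precision", {
  d <- noiseless_lny_data()
  fit <- fit_lny_model(d)
  tab <- fit$table
  get <- function(term) tab$estimate[tab$term == term]
  expect_equal(get("center_brescia"), 23.6, tolerance = 1e-8)
  expect_equal(get("center_cork"), 13.1, tolerance = 1e-8)
  expect_equal(get("age_per_decade"), -0.9, tolerance = 1e-8)
  expect_equal(get("male"), 4.0, tolerance = 1e-8)
  expect_equal(get("ipsilateral_IVa_vs_I"), 6.8, tolerance = 1e-8)
  expect_equal(get("ipsilateral_IVb_vs_I"), 9.3, tolerance = 1e-8)
  expect_equal(get("bilateral_IVa_vs_I"), 4.0, tolerance = 1e-8)
  expect_equal(get("bilateral_IVb_vs_I"), 6.0, tolerance = 1e-8)
  expect_equal(get("bilateral_III_vs_I"), -0.3, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("estimates agree with hand-solved normal equations", {
  d <- noiseless_lny_data(n = 40, seed = 62)
  set.seed(63)
  d$lny <- d$lny + rnorm(40, 0, 5)
  fit <- fit_lny_model(d)
  # independent path: explicit design and (X'X)^{-1} X'y
  X <- stats::model.matrix(
    ~ center + I(age_at_surgery / 10) + sex + uicc_stage * laterality,
    transform(d,
      center = factor(center, c("heidelberg", "brescia", "cork")),
      sex = factor(sex, c("female", "male")),
      uicc_stage = factor(uicc_stage, c("I", "II", "III", "IVa", "IVb")),
      laterality = factor(laterality, c("ipsilateral", "bilateral"))))
  beta <- solve(crossprod(X), crossprod(X, d$lny))
  tab <- fit$table
  expect_equal(tab$estimate[tab$term == "age_per_decade"],
               unname(beta["I(age_at_surgery/10)", 1]), tolerance = 1e-8)
  expect_equal(tab$estimate[tab$term == "male"], unname(beta["sexmale", 1]),
               tolerance = 1e-8)
  expect_equal(tab$estimate[tab$term == "center_brescia"],
               unname(beta["centerbrescia", 1]), tolerance = 1e-8)
  expect_equal(tab$estimate[tab$term == "bilateral_IVa_vs_I"],
               unname(beta["uicc_stageIVa", 1] +
                 beta["uicc_stageIVa:lateralitybilateral", 1]),
               tolerance = 1e-8)
})

test_that("residuals are orthogonal to the design and contrasts reconstruct", {
  pool <- pool_cohorts(generate_cohorts(simulation_config(seed = 64)))
  fit <- fit_lny_model(pool)
  X <- stats::model.matrix(fit$fit)
  r <- stats::residuals(fit$fit)
  expect_lt(max(abs(crossprod(X, r))) / nrow(X), 1e-8)
  # reported per-laterality contrasts are exact combinations of raw coefficients
  b <- coef(fit$fit)
  tab <- fit$table
  expect_equal(tab$estimate[tab$term == "bilateral_II_vs_I"],
               unname(b["stageII"] + b["stageII:lateralitybilateral"]))
  expect_equal(tab$estimate[tab$term == "ipsilateral_III_vs_I"],
               unname(b["stageIII"]))
})

test_that("generated cohorts recover the published center offsets", {
  cfg <- simulation_config(center_sizes = c(heidelberg = 2324, cork = 1044,
                                            brescia = 952), seed = 65)
  pool <- pool_cohorts(generate_cohorts(cfg))
  fit <- fit_lny_model(pool)
  tab <- fit$table
  se <- (tab$ci_high - tab$ci_low) / (2 * stats::qt(0.975, fit$fit$df.residual))
  for (term in c("center_brescia", "center_cork", "male")) {
    truth <- c(center_brescia = 23.6, center_cork = 13.1, male = 4.0)[term]
    expect_lt(abs(tab$estimate[tab$term == term] - truth),
              3 * se[tab$term == term])
  }
})

test_that("robust standard errors are available and classical CIs cover estimates", {
  d <- noiseless_lny_data(n = 120, seed = 66)
  set.seed(67)
  d$lny <- d$lny + rnorm(120, 0, 4)
  f1 <- fit_lny_model(d)
  f2 <- fit_lny_model(d, robust = TRUE)
  expect_equal(f1$table$estimate, f2$table$estimate)
  expect_false(isTRUE(all.equal(f1$table$ci_low, f2$table$ci_low)))
  expect_true(all(f1$table$ci_low <= f1$table$estimate &
                  f1$table$ci_high >= f1$table$estimate))
})
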