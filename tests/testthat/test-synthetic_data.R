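# Closed-form expected death fraction of the generator, by enumeration over
# the discrete covariate mix, Gauss-Legendre quadrature over age, and numeric
# integration of P(T < C) for exponential event times against the
# uniform-administrative x exponential-dropout censoring distribution.
# Independent of the generator's sampling path.
expected_death_fraction <- function(cfg) {
  cens <- cfg$censoring
  s_admin <- function(t) ifelse(t < cens$admin_min, 1,
                         ifelse(t > cens$admin_horizon_years, 0,
                           (cens$admin_horizon_years - t) /
                           (cens$admin_horizon_years - cens$admin_min)))
  p_death_given_rate <- function(lam) {
    stats::integrate(function(t) lam * exp(-lam * t) *
                       exp(-cens$dropout_rate * t) * s_admin(t),
                     0, cens$admin_horizon_years, rel.tol = 1e-10)$value
  }
  # Gauss-Legendre nodes on the truncated-normal age distribution
  gl <- function(k, a, b) {
    # nodes/weights via eigen-decomposition of the Jacobi matrix
    i <- seq_len(k - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, k, k)
    J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
  }
  q <- gl(40, cfg$age$min, cfg$age$max)
  zconst <- diff(stats::pnorm(c(cfg$age$min, cfg$age$max), cfg$age$mean, cfg$age$sd))
  age_w <- q$w * stats::dnorm(q$x, cfg$age$mean, cfg$age$sd) / zconst
  hc <- cfg$log_hazard_coefficients
  stopifnot(hc[["lny"]] == 0)  # enumeration ignores the yield under the null
  total <- 0
  n_all <- sum(cfg$center_sizes)
  for (ctr in names(cfg$center_sizes)) {
    w_ctr <- cfg$center_sizes[[ctr]] / n_all
    p34 <- cfg$stage34_prob_by_center[[ctr]]
    for (g34 in c(0, 1)) {
      w_g <- if (g34 == 1) p34 else 1 - p34
      p_pn <- cfg$pnpos_prob_given_stage[[if (g34 == 1) "III-IV" else "I-II"]]
      # ENE yes requires pN+, then survives the independent unknown overwrite
      p_ene <- p_pn * cfg$ene_prob_given_pnpos * (1 - cfg$ene_unknown_prob)
      for (ene in c(0, 1)) {
        w_e <- if (ene == 1) p_ene else 1 - p_ene
        for (male in c(0, 1)) {
          w_m <- if (male == 1) cfg$male_prob else 1 - cfg$male_prob
          lp_base <- hc[["uicc_34"]] * g34 + hc[["male"]] * male +
            hc[["ene_yes"]] * ene
          p_age <- sum(age_w * vapply(q$x, function(a) {
            lam <- cfg$baseline_hazard *
              exp(lp_base + hc[["age_per_decade"]] * (a - 64) / 10)
            p_death_given_rate(lam)
          }, 0))
          total <- total + w_ctr * w_g * w_e * w_m * p_age
        }
      }
    }
  }
  total
}

test_that("the generator is reproducible and passes validation", {
  cfg <- small_config(seed = 21)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(lapply(a, function(x) x$patients),
                   lapply(b, function(x) x$patients))
  for (co in a) expect_silent(validate_cohort(co))
  # each center stream is independent of the others' sizes
  cfg2 <- small_config(seed = 21)
  cfg2$center_sizes[["cork"]] <- 45
  c2 <- generate_cohorts(cfg2)
  expect_identical(c2$heidelberg$patients, a$heidelberg$patients)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(baseline_hazard = 0), "degenerate")
  expect_error(simulation_config(lny_noise_sd = -1), "lny_noise_sd")
  expect_error(simulation_config(male_prob = 1.2), "probabilities")
  expect_error(simulation_config(center_sizes = c(a = 0)), "positive")
})

test_that("default yield-model coefficients expose the published effects", {
  expect_equal(default_lny_coefficients("center_brescia"), 23.6)
  expect_equal(default_lny_coefficients("center_cork"), 13.1)
  expect_equal(default_lny_coefficients("male"), 4.0)
  expect_equal(default_lny_coefficients("age_per_decade"), -0.9)
  expect_equal(default_lny_coefficients("ipsilateral_IVb"), 9.3)
  expect_error(default_lny_coefficients("center_B"), "unknown term")
})

test_that("observed death fraction matches the closed-form expectation", {
  cfg <- simulation_config()
  p_expected <- expected_death_fraction(cfg)
  # 12 replicates of the full 1080-patient population
  fr <- vapply(1:12, function(s) {
    pool <- pool_cohorts(generate_cohorts(simulation_config(seed = 300 + s)))
    mean(pool$patients$death)
  }, 0)
  mc_se <- sqrt(p_expected * (1 - p_expected) / (1080 * 12))
  expect_lt(abs(mean(fr) - p_expected), 4 * mc_se)
})

test_that("with a null yield effect LNY carries no residual hazard signal", {
  cfg <- simulation_config(center_sizes = c(heidelberg = 5810, cork = 2610,
                                            brescia = 2380), seed = 77)
  pool <- pool_cohorts(generate_cohorts(cfg))
  p <- pool$patients
  fit <- survival::coxph(
    survival::Surv(followup_years, death) ~ lny + age_at_surgery + sex +
      uicc_group + ene + center, data = p)
  z <- coef(fit)["lny"] / sqrt(diag(vcov(fit))["lny"])
  expect_lt(abs(z), 4)
})

test_that("YAML configuration round trip regenerates identical cohorts", {
  cfg <- small_config(seed = 13)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_identical(lapply(generate_cohorts(cfg2), function(x) x$patients),
                   lapply(generate_cohorts(cfg), function(x) x$patients))
})
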