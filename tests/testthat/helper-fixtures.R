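# Fixtures are constructed in code from the published per-center margins:
# cohort sizes 581/261/238; deaths 127/137/90 with 103/84/62 by 3 years and
# 112/106/74 by 5 years; person-years 1888/1147/965; pN-positive 192/116/113;
# LNY >= 18 in 417/208/232; total nodal yield 35,248.

table1_margins <- function() {
  list(
    heidelberg = list(n = 581, deaths = 127, d3 = 103, d5 = 112, py = 1888,
                      pnpos = 192, ge18 = 417, lny_sum = 15600),
    cork = list(n = 261, deaths = 137, d3 = 84, d5 = 106, py = 1147,
                pnpos = 116, ge18 = 208, lny_sum = 8600),
    brescia = list(n = 238, deaths = 90, d3 = 62, d5 = 74, py = 965,
                   pnpos = 113, ge18 = 232, lny_sum = 11048)
  )
}

# Build one patient-level cohort reproducing a margin set exactly: deaths by
# 3y at t = 2, deaths in (3, 5] at t = 4, later deaths at t = 6; censored
# patients share the remaining person-years equally.
make_margin_cohort <- function(name, m) {
  n <- m$n
  death <- c(rep(1, m$deaths), rep(0, n - m$deaths))
  fu <- numeric(n)
  fu[seq_len(m$d3)] <- 2
  if (m$d5 > m$d3) fu[(m$d3 + 1):m$d5] <- 4
  if (m$deaths > m$d5) fu[(m$d5 + 1):m$deaths] <- 6
  death_py <- sum(fu)
  fu[death == 0] <- (m$py - death_py) / (n - m$deaths)
  n_lt18 <- n - m$ge18
  rest <- m$lny_sum - 10 * n_lt18
  base <- rest %/% m$ge18
  rem <- rest - base * m$ge18
  lny <- c(rep(10, n_lt18), rep(base + 1, rem), rep(base, m$ge18 - rem))
  stopifnot(sum(lny) == m$lny_sum, sum(lny >= 18) == m$ge18,
            all(lny[lny >= 18] <= 119))
  pnpos <- seq_len(n) <= m$pnpos
  cohort(data.frame(
    patient_id = sprintf("%s_%04d", name, seq_len(n)),
    center = name,
    age_at_surgery = 64,
    sex = "male",
    tumor_site = "tongue",
    pt_stage = "II",
    uicc_stage = ifelse(pnpos, "IVa", "I"),
    pn_stage = ifelse(pnpos, "pN2b", "pN0"),
    pn_positive_count = ifelse(pnpos, 2L, 0L),
    uicc_group = ifelse(pnpos, "III-IV", "I-II"),
    laterality = "ipsilateral",
    ene = "no",
    crt = "not_received",
    m_stage = "M0",
    lny = lny,
    followup_years = fu,
    death = death,
    stringsAsFactors = FALSE
  ), name = name)
}

make_table1_fixture <- function() {
  ms <- table1_margins()
  lapply(names(ms), function(nm) make_margin_cohort(nm, ms[[nm]])) |>
    stats::setNames(names(ms))
}

# Small hand-made cohort used across unit tests.
toy_cohort <- function(n = 12, name = "toy", seed = 99) {
  set.seed(seed)
  pnpos <- rep(c(TRUE, FALSE), length.out = n)
  lny <- sample(5:40, n, replace = TRUE)
  cohort(data.frame(
    patient_id = sprintf("p%02d", seq_len(n)),
    center = rep(c("a", "b"), length.out = n),
    age_at_surgery = round(runif(n, 45, 80), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    tumor_site = "tongue",
    pt_stage = sample(c("I", "II", "III"), n, replace = TRUE),
    uicc_stage = ifelse(pnpos, "IVa", "II"),
    pn_stage = ifelse(pnpos, "pN1", "pN0"),
    pn_positive_count = ifelse(pnpos, 1L, 0L),
    uicc_group = ifelse(pnpos, "III-IV", "I-II"),
    laterality = sample(c("ipsilateral", "bilateral"), n, replace = TRUE),
    ene = "no",
    crt = sample(c("received", "not_received"), n, replace = TRUE),
    m_stage = "M0",
    lny = pmax(lny, 2L),
    followup_years = round(runif(n, 0.5, 8), 3),
    death = rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE
  ), name = name)
}

# Reduced-size generator configuration for fast tests.
small_config <- function(seed = 1, ...) {
  simulation_config(center_sizes = c(heidelberg = 140, cork = 70, brescia = 60),
                    seed = seed, ...)
}
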