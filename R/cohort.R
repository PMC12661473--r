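#' Patient-level cohort container
#'
#' A cohort is a named, ordered collection of patient records from one or more
#' centers. Records carry the covariates used throughout the package: age at
#' neck dissection, sex, tumor site, pathological T and N stage, UICC stage
#' group, neck-dissection laterality, extranodal extension (ENE),
#' chemoradiotherapy, M stage, lymph node yield (LNY), number of pathologically
#' positive nodes, and right-censored follow-up.
#'
#' @name cohort
NULL

# Canonical factor levels; reference level first.
lny_levels <- list(
  sex        = c("female", "male"),
  pt_stage   = c("I", "II", "III", "IV"),
  pn_stage   = c("pN0", "pN1", "pN2a", "pN2b", "pN2c", "pN3a", "pN3b"),
  uicc_stage = c("I", "II", "III", "IVa", "IVb"),
  uicc_group = c("I-II", "III-IV"),
  laterality = c("ipsilateral", "bilateral"),
  ene        = c("no", "yes", "unknown"),
  crt        = c("not_received", "received"),
  m_stage    = c("M0", "M1")
)

# Required and optional columns of the cohort CSV dialect.
cohort_required_cols <- c(
  "patient_id", "center", "age_at_surgery", "sex", "pt_stage", "pn_stage",
  "pn_positive_count", "uicc_group", "laterality", "ene", "crt", "m_stage",
  "lny", "followup_years", "death"
)
cohort_optional_cols <- c("tumor_site", "uicc_stage")
cohort_numeric_cols <- c("age_at_surgery", "pn_positive_count", "lny",
                         "followup_years", "death")

#' Construct a validated cohort
#'
#' @param patients data.frame with one row per patient (see
#'   [cohort_csv_columns()] for the column contract).
#' @param name cohort label, typically the center name.
#' @param role one of `"train"`, `"validate"`, `"pooled"`.
#' @return An object of class `lny_cohort`.
#' @export
cohort <- function(patients, name, role = c("pooled", "train", "validate")) {
  role <- match.arg(role)
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(patients))
  if (length(missing_cols)) {
    stop_lny(sprintf("cohort '%s' is missing required columns: %s",
                     name, paste(missing_cols, collapse = ", ")),
             class = "lnyield_schema_error")
  }
  for (opt in cohort_optional_cols) {
    if (!opt %in% names(patients)) patients[[opt]] <- NA_character_
  }
  patients <- patients[, c(cohort_required_cols, cohort_optional_cols)]
  for (col in names(lny_levels)) {
    if (col %in% names(patients)) {
      patients[[col]] <- as.character(patients[[col]])
    }
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$center <- as.character(patients$center)
  out <- structure(list(name = name, role = role, patients = patients),
                   class = "lny_cohort")
  validate_cohort(out)
  out
}

#' Validate cohort invariants
#'
#' Checks field domains and the clinical consistency rules: positive-node
#' count never exceeds LNY; pN0 if and only if zero positive nodes; any
#' pN-positive patient is UICC stage III-IV; follow-up is non-negative.
#' Violations raise an error listing the offending patient ids.
#'
#' @param x an `lny_cohort`.
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "lny_cohort"))
  p <- x$patients
  fail <- function(msg, ids) {
    stop_lny(sprintf("cohort '%s': %s [patient_id: %s]", x$name, msg,
                     paste(utils::head(ids, 10), collapse = ", ")),
             class = "lnyield_validation_error")
  }
  if (anyDuplicated(p$patient_id)) {
    fail("duplicate patient_id", p$patient_id[duplicated(p$patient_id)])
  }
  for (col in cohort_numeric_cols) {
    if (!is.numeric(p[[col]])) fail(sprintf("column '%s' is not numeric", col),
                                    p$patient_id[!is.finite(suppressWarnings(as.numeric(p[[col]])))])
  }
  for (col in names(lny_levels)) {
    vals <- p[[col]]
    ok <- is.na(vals) | vals %in% lny_levels[[col]]
    if (col %in% cohort_required_cols) ok <- ok & !is.na(vals)
    if (!all(ok)) fail(sprintf("column '%s' outside allowed levels {%s}", col,
                               paste(lny_levels[[col]], collapse = ", ")),
                       p$patient_id[!ok])
  }
  bad <- !is.finite(p$age_at_surgery) | p$age_at_surgery <= 0
  if (any(bad)) fail("age_at_surgery must be > 0", p$patient_id[bad])
  bad <- !is_count(p$lny)
  if (bad) fail("lny must be a non-negative integer",
                p$patient_id[!(p$lny >= 0 & p$lny == round(p$lny))])
  bad <- !is_count(p$pn_positive_count)
  if (bad) fail("pn_positive_count must be a non-negative integer",
                p$patient_id[!(p$pn_positive_count >= 0 & p$pn_positive_count == round(p$pn_positive_count))])
  bad <- p$pn_positive_count > p$lny
  if (any(bad)) fail("pn_positive_count exceeds lny", p$patient_id[bad])
  bad <- (p$pn_stage == "pN0") != (p$pn_positive_count == 0)
  if (any(bad)) fail("pn_stage pN0 must coincide with pn_positive_count == 0",
                     p$patient_id[bad])
  bad <- p$pn_positive_count > 0 & p$uicc_group != "III-IV"
  if (any(bad)) fail("pN-positive patients must be UICC stage III-IV",
                     p$patient_id[bad])
  has_stage <- !is.na(p$uicc_stage)
  grp <- ifelse(p$uicc_stage %in% c("I", "II"), "I-II", "III-IV")
  bad <- has_stage & grp != p$uicc_group
  if (any(bad)) fail("uicc_stage inconsistent with uicc_group", p$patient_id[bad])
  bad <- !is.finite(p$followup_years) | p$followup_years < 0
  if (any(bad)) fail("followup_years must be finite and >= 0", p$patient_id[bad])
  bad <- !p$death %in% c(0, 1)
  if (any(bad)) fail("death must be 0 or 1", p$patient_id[bad])
  invisible(x)
}

#' @export
print.lny_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<lny_cohort> '%s' (role: %s)\n", x$name, x$role))
  cat(sprintf("  %d patients, %d deaths, %.1f person-years, median LNY %s\n",
              nrow(p), sum(p$death), sum(p$followup_years),
              if (nrow(p)) stats::median(p$lny) else NA))
  invisible(x)
}

#' @export
as.data.frame.lny_cohort <- function(x, ...) x$patients

#' Number of patients in a cohort
#' @param x an `lny_cohort`.
#' @export
n_patients <- function(x) nrow(x$patients)

#' Cohort CSV column contract
#'
#' @return Character vector of column names of the cohort CSV dialect
#'   (UTF-8, comma-separated, header row, one patient per row).
#' @export
cohort_csv_columns <- function() c(cohort_required_cols, cohort_optional_cols)

#' Read a cohort from CSV
#'
#' @param path file path to a cohort CSV.
#' @param name cohort label; defaults to the file name without extension.
#' @param role cohort role, see [cohort()].
#' @return An `lny_cohort`. Malformed rows raise an error naming the row
#'   number and field; invariant violations raise a validation error listing
#'   offending patient ids.
#' @export
read_cohort_csv <- function(path, name = NULL,
                            role = c("pooled", "train", "validate")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop_lny(sprintf("no such file: %s", path))
  name <- name %||% sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols)) {
    stop_lny(sprintf("%s: missing required columns: %s", path,
                     paste(missing_cols, collapse = ", ")),
             class = "lnyield_schema_error")
  }
  for (col in cohort_numeric_cols) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(num) & !(is.na(raw[[col]]) | raw[[col]] == "")
    if (any(bad)) {
      stop_lny(sprintf("%s: row %d, field '%s': cannot parse value '%s'",
                       path, which(bad)[1], col, raw[[col]][which(bad)[1]]),
               class = "lnyield_parse_error")
    }
    raw[[col]] <- num
  }
  for (col in intersect(cohort_optional_cols, names(raw))) {
    raw[[col]][raw[[col]] == ""] <- NA
  }
  cohort(raw, name = name, role = role)
}

#' Write a cohort to CSV
#'
#' Produces the same dialect that [read_cohort_csv()] consumes, so a
#' read-write-read round trip is lossless.
#'
#' @param x an `lny_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "lny_cohort"))
  utils::write.csv(x$patients, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Apply eligibility criteria
#'
#' Removes patients with distant metastases (M1) at diagnosis and patients
#' with zero follow-up, mirroring the inclusion rules of a survival analysis
#' that requires strictly positive observation time. Idempotent.
#'
#' @param x an `lny_cohort`.
#' @return A list with `cohort` (the filtered cohort) and `exclusions`
#'   (named integer vector of removal counts by reason).
#' @export
apply_eligibility <- function(x) {
  stopifnot(inherits(x, "lny_cohort"))
  p <- x$patients
  m1 <- p$m_stage == "M1"
  nofu <- !m1 & p$followup_years <= 0
  keep <- !(m1 | nofu)
  out <- x
  out$patients <- p[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  if (!nrow(out$patients)) {
    warning(sprintf("cohort '%s' is empty after eligibility filtering", x$name))
  }
  list(cohort = out,
       exclusions = c(M1 = sum(m1), zero_followup = sum(nofu)))
}

#' Descriptive cohort summaries
#'
#' Computes per-cohort and pooled summaries: patient count, deaths overall and
#' by horizon (a death at exactly the horizon counts as a death by that
#' horizon), person-years of follow-up, pN-positive and LNY >= 18 counts,
#' total nodal yield, and median potential follow-up by the reverse
#' Kaplan-Meier method with a log-log confidence interval. The pooled row is
#' the field-wise sum of the per-cohort rows, except the median, which is
#' re-estimated on the pooled data.
#'
#' @param cohorts a single `lny_cohort` or list of them.
#' @param horizons numeric vector of year horizons (default `c(3, 5)`).
#' @return A data.frame with one row per cohort plus a `pooled` row, of class
#'   `lny_summary`.
#' @export
summarize_cohorts <- function(cohorts, horizons = c(3, 5)) {
  if (inherits(cohorts, "lny_cohort")) cohorts <- list(cohorts)
  stopifnot(length(horizons) == 2)
  one <- function(p, label) {
    if (!nrow(p)) {
      warning(sprintf("cohort '%s' is empty; summary is all zeros", label))
      return(data.frame(cohort = label, n = 0L, deaths_total = 0L,
                        deaths_h1 = 0L, deaths_h2 = 0L, person_years = 0,
                        pn_positive_n = 0L, lny_ge18_n = 0L, lny_total = 0L,
                        median_followup = NA_real_, median_followup_lo = NA_real_,
                        median_followup_hi = NA_real_))
    }
    med <- tryCatch(
      reverse_km_median_followup(p$followup_years, p$death),
      error = function(e) list(median = NA_real_, ci = c(NA_real_, NA_real_))
    )
    data.frame(
      cohort = label,
      n = nrow(p),
      deaths_total = sum(p$death),
      deaths_h1 = sum(p$death == 1 & p$followup_years <= horizons[1]),
      deaths_h2 = sum(p$death == 1 & p$followup_years <= horizons[2]),
      person_years = sum(p$followup_years),
      pn_positive_n = sum(p$pn_positive_count > 0),
      lny_ge18_n = sum(p$lny >= 18),
      lny_total = sum(p$lny),
      median_followup = med$median,
      median_followup_lo = med$ci[1],
      median_followup_hi = med$ci[2]
    )
  }
  rows <- do.call(rbind, lapply(cohorts, function(co) one(co$patients, co$name)))
  pooled_p <- do.call(rbind, lapply(cohorts, function(co) co$patients))
  pooled <- one(pooled_p, "pooled")
  # pooled counts must equal the column sums of the per-cohort rows
  for (col in c("n", "deaths_total", "deaths_h1", "deaths_h2", "person_years",
                "pn_positive_n", "lny_ge18_n", "lny_total")) {
    pooled[[col]] <- sum(rows[[col]])
  }
  out <- rbind(rows, pooled)
  names(out)[names(out) == "deaths_h1"] <- sprintf("deaths_%gy", horizons[1])
  names(out)[names(out) == "deaths_h2"] <- sprintf("deaths_%gy", horizons[2])
  rownames(out) <- NULL
  class(out) <- c("lny_summary", "data.frame")
  out
}

#' @export
print.lny_summary <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, 2))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write a cohort summary to CSV
#' @param x an `lny_summary`.
#' @param path output path.
#' @export
write_summary_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Pool several cohorts into one
#'
#' @param cohorts list of `lny_cohort` objects.
#' @param name label for the pooled cohort.
#' @return An `lny_cohort` with role `"pooled"`. Patient ids are prefixed by
#'   cohort name when needed to stay unique.
#' @export
pool_cohorts <- function(cohorts, name = "pooled") {
  stopifnot(length(cohorts) >= 1)
  tabs <- lapply(cohorts, function(co) co$patients)
  ids <- unlist(lapply(tabs, `[[`, "patient_id"))
  if (anyDuplicated(ids)) {
    tabs <- lapply(cohorts, function(co) {
      p <- co$patients
      p$patient_id <- paste(co$name, p$patient_id, sep = ":")
      p
    })
  }
  cohort(do.call(rbind, tabs), name = name, role = "pooled")
}
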