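# Cohort construction from EMR tables.
#
# Pipeline: identify_diabetes() finds the diabetes base population (two
# outpatient diagnoses plus a qualifying outpatient lab, age >= 50);
# build_progression_cohorts() derives the three overlapping progression
# cohorts and their index dates; extract_covariates() assembles one analysis
# row per subject per cohort using the 12-month "most proximal" lab window
# and the 3-to-15-month change window; exclude_incomplete() applies the
# complete-case rule for continuous covariates.

MONTHS_12_DAYS <- 12 * DAYS_PER_MONTH   # 365.25
MONTHS_3_DAYS  <- 3 * DAYS_PER_MONTH    # 91.3125
MONTHS_15_DAYS <- 15 * DAYS_PER_MONTH   # 456.5625

ANALYSIS_CONTINUOUS <- c("age", "weight", "weight_change_pct", "peak_bmi",
                         "hba1c", "hba1c_change", "creatinine", "cholesterol",
                         "bilirubin", "bilirubin_change_pct", "rbc",
                         "rbc_change_pct")

#' Identify the diabetes base population
#'
#' A subject qualifies with (a) at least two outpatient diabetes diagnoses
#' and (b) at least one qualifying outpatient lab: HbA1c >= 6.5%, fasting
#' glucose >= 126 mg/dL, or random glucose >= 200 mg/dL.  Labs drawn during
#' hospitalization or emergency care are excluded.  Age at first evidence
#' must be >= 50; first evidence is the earliest date among the diabetes
#' diagnoses and qualifying labs.
#'
#' @param emr A `raw_emr` bundle (see [generate_population()] / [read_emr()]).
#' @return A `data.table` with columns `id`, `first_dm_date`, `age_at_dm`.
#' @export
identify_diabetes <- function(emr) {
  id <- date <- condition <- setting <- analyte <- value <- inpatient <-
    n_dx <- first_dx <- first_lab <- first_dm_date <- age_at_dm <-
    birth_date <- NULL
  dx <- emr$diagnoses[condition == "diabetes" & setting == "outpatient"]
  cnt <- dx[, list(n_dx = .N, first_dx = min(date)), by = id][n_dx >= 2L]
  ql <- emr$labs[inpatient == FALSE &
                   ((analyte == "hba1c" & value >= 6.5) |
                      (analyte == "glucose_fasting" & value >= 126) |
                      (analyte == "glucose_random" & value >= 200))]
  ql <- ql[, list(first_lab = min(date)), by = id]
  m <- merge(cnt, ql, by = "id")
  m[, first_dm_date := pmin(first_dx, first_lab)]
  m <- merge(m, emr$patients[, list(id, birth_date)], by = "id")
  m[, age_at_dm := as.numeric(first_dm_date - birth_date) / 365.25]
  out <- m[age_at_dm >= 50, list(id, first_dm_date, age_at_dm)]
  data.table::setkey(out, id)
  out[]
}

#' Derive the three diabetes-progression cohorts
#'
#' Index dates: (i) `insulin_init` — first insulin prescription;
#' (ii) `combo_oral` — first day on which two distinct oral hypoglycemic
#' classes are prescribed simultaneously after a spell on exactly one class;
#' (iii) `hba1c_rise` — first outpatient HbA1c >= 8.0 that exceeds some
#' earlier HbA1c within 15 months by >= 1.0.  Subjects whose index falls
#' within 90 days after first diabetes evidence are excluded; a subject may
#' belong to several cohorts.
#'
#' @param emr A `raw_emr` bundle.
#' @param diabetics Output of [identify_diabetes()].
#' @param combo_grace_days "Simultaneous" window for the two oral classes;
#'   0 (default) means the same calendar day.
#' @return A `data.table` with columns `id`, `cohort`, `index_date`,
#'   `first_dm_date`.
#' @export
build_progression_cohorts <- function(emr, diabetics, combo_grace_days = 0L) {
  id <- date <- drug_class <- analyte <- value <- inpatient <- index_date <-
    first_dm_date <- cohort <- NULL
  g <- as.integer(combo_grace_days)

  ins <- emr$prescriptions[drug_class == "insulin",
                           list(index_date = min(date)), by = id]
  ins[, cohort := "insulin_init"]

  orx <- emr$prescriptions[drug_class %in% ORAL_CLASSES]
  cmb <- orx[, {
    d <- as.numeric(date); cl <- drug_class
    ud <- sort(unique(d)); idx <- NA_real_
    for (dd in ud) {
      inwin <- d >= dd - g & d <= dd
      if (length(unique(cl[inwin])) >= 2L &&
          length(unique(cl[d < dd - g])) == 1L) {
        idx <- dd
        break
      }
    }
    list(index_date = as.Date(idx, origin = "1970-01-01"))
  }, by = id][!is.na(index_date)]
  cmb[, cohort := "combo_oral"]

  hb <- emr$labs[analyte == "hba1c" & inpatient == FALSE]
  data.table::setorder(hb, id, date)
  ris <- hb[, {
    d <- as.numeric(date); v <- value; idx <- NA_real_
    for (i in seq_along(d)) {
      if (v[i] >= 8.0 &&
          any(d < d[i] & d >= d[i] - MONTHS_15_DAYS & v <= v[i] - 1.0)) {
        idx <- d[i]
        break
      }
    }
    list(index_date = as.Date(idx, origin = "1970-01-01"))
  }, by = id][!is.na(index_date)]
  ris[, cohort := "hba1c_rise"]

  out <- data.table::rbindlist(list(ins, cmb, ris), use.names = TRUE)
  out <- merge(out, diabetics[, list(id, first_dm_date)], by = "id")
  out <- out[as.numeric(index_date - first_dm_date) > 90]
  data.table::setorder(out, cohort, id)
  out[, list(id, cohort, index_date, first_dm_date)][]
}

# closest record at or before index within `win_days`; returns value and date
closest_before <- function(DT, rows, win_days, by_extra = "analyte") {
  id <- date <- gap <- NULL
  M <- merge(rows, DT, by = "id", allow.cartesian = TRUE)
  M[, gap := as.numeric(index_date - date)]
  M <- M[gap >= 0 & gap <= win_days]
  data.table::setorder(M, id, cohort, gap, date)
  M[, utils::head(.SD, 1L), by = c("id", "cohort", by_extra)]
}

# prior record in the 3-to-15-month window before `cdate`, closest to 12
# months; ties broken toward the earlier test
prior_in_window <- function(DT, cur, by_extra = "analyte") {
  id <- date <- gapc <- cdate <- NULL
  M <- merge(cur, DT, by = c("id", by_extra), allow.cartesian = TRUE,
             suffixes = c(".cur", ""))
  M[, gapc := as.numeric(cdate - date)]
  M <- M[gapc >= MONTHS_3_DAYS & gapc <= MONTHS_15_DAYS]
  data.table::setorder(M, id, cohort)
  M <- M[order(id, cohort, abs(gapc - MONTHS_12_DAYS), -gapc)]
  M[, utils::head(.SD, 1L), by = c("id", "cohort", by_extra)]
}

#' Assemble per-subject, per-cohort analysis rows
#'
#' Applies the covariate windows: the current value of each lab is the one
#' most proximal to (and not after) the index date within the previous 12
#' months; percent (or, for HbA1c, absolute) changes compare it with the
#' value closest to 12 months earlier inside a 3-to-15-month window.  Weight
#' is restricted to 75-500 lbs and height to 48-84 inches before use; peak
#' BMI uses the highest plausible weight ever recorded up to the index.
#' Condition and drug indicators carry the lag (months) from their first
#' record to the index; a history of both acute and chronic pancreatitis is
#' classified as chronic.  Missing smoking/drinking become explicit
#' `"missing"` categories.
#'
#' @param emr A `raw_emr` bundle.
#' @param cohort_rows Output of [build_progression_cohorts()].
#' @param conditions,drugs Names of binary history covariates to extract.
#' @return An `analysis_dataset` data frame, one row per subject x cohort,
#'   with follow-up `time` (months) and `event` flag.  Rows with
#'   non-positive follow-up are dropped (count in attribute
#'   `n_nonpositive_followup`).
#' @export
extract_covariates <- function(emr, cohort_rows,
                               conditions = CONDITION_NAMES,
                               drugs = c("ppi", "statin", "biguanide",
                                         "dpp4_inhibitor")) {
  id <- date <- analyte <- value <- inpatient <- weight_lbs <- height_in <-
    condition <- drug_class <- index_date <- cohort <- pdac <- NULL
  rows <- data.table::as.data.table(cohort_rows)[, list(id, cohort, index_date)]
  if (!all(rows$id %in% emr$outcomes$id)) {
    stop("data-integrity error: subject(s) without an outcomes row: ",
         paste(utils::head(setdiff(rows$id, emr$outcomes$id), 5L),
               collapse = ", "))
  }

  labs <- emr$labs[inpatient == FALSE &
                     analyte %in% c("hba1c", "creatinine", "cholesterol",
                                    "bilirubin", "rbc")]
  cur <- closest_before(labs, rows, MONTHS_12_DAYS)
  cur_slim <- cur[, list(id, cohort, analyte, cdate = date, cur = value)]
  pri <- prior_in_window(labs, cur_slim)
  pri_slim <- pri[, list(id, cohort, analyte, prior = value)]
  lab_wide <- data.table::dcast(
    merge(cur_slim, pri_slim, by = c("id", "cohort", "analyte"), all.x = TRUE),
    id + cohort ~ analyte, value.var = c("cur", "prior"))

  # vitals: plausibility filter before any use
  vw <- emr$vitals[!is.na(weight_lbs)][weight_lbs >= 75 & weight_lbs <= 500,
                                       list(id, date, value = weight_lbs)]
  vh <- emr$vitals[!is.na(height_in)][height_in >= 48 & height_in <= 84,
                                      list(id, date, value = height_in)]
  vw[, analyte := "weight"]
  wcur <- closest_before(vw, rows, MONTHS_12_DAYS)
  wcur_slim <- wcur[, list(id, cohort, analyte, cdate = date, wcur = value)]
  wpri <- prior_in_window(vw, wcur_slim)
  wpri_slim <- wpri[, list(id, cohort, wprior = value)]
  # height: latest plausible measurement on/before index
  hm <- merge(rows, vh, by = "id", allow.cartesian = TRUE)
  hm <- hm[date <= index_date]
  data.table::setorder(hm, id, cohort, -date)
  hgt <- hm[, utils::head(.SD, 1L), by = c("id", "cohort")][
    , list(id, cohort, height = value)]
  # peak weight: highest plausible weight ever recorded on/before index
  pw <- merge(rows, vw, by = "id", allow.cartesian = TRUE)
  pw <- pw[date <= index_date]
  pw <- if (nrow(pw)) {
    pw[, list(peak_weight = max(value)), by = c("id", "cohort")]
  } else {
    data.table::data.table(id = character(), cohort = character(),
                           peak_weight = numeric())
  }

  out <- merge(rows, emr$patients, by = "id")
  out <- merge(out, lab_wide, by = c("id", "cohort"), all.x = TRUE)
  out <- merge(out, wcur_slim[, list(id, cohort, weight = wcur)],
               by = c("id", "cohort"), all.x = TRUE)
  out <- merge(out, wpri_slim, by = c("id", "cohort"), all.x = TRUE)
  out <- merge(out, hgt, by = c("id", "cohort"), all.x = TRUE)
  out <- merge(out, pw, by = c("id", "cohort"), all.x = TRUE)

  grab <- function(nm) if (nm %in% names(out)) out[[nm]] else NA_real_
  out[, `:=`(
    age = as.numeric(index_date - birth_date) / 365.25,
    hba1c = grab("cur_hba1c"),
    hba1c_change = grab("cur_hba1c") - grab("prior_hba1c"),
    creatinine = grab("cur_creatinine"),
    cholesterol = grab("cur_cholesterol"),
    bilirubin = grab("cur_bilirubin"),
    bilirubin_change_pct = 100 * (grab("cur_bilirubin") - grab("prior_bilirubin")) /
      grab("prior_bilirubin"),
    rbc = grab("cur_rbc"),
    rbc_change_pct = 100 * (grab("cur_rbc") - grab("prior_rbc")) /
      grab("prior_rbc"),
    weight_change_pct = 100 * (out$weight - out$wprior) / out$wprior,
    peak_bmi = 703 * out$peak_weight / out$height^2
  )]

  # condition and drug indicators with months-since-first-record lags
  add_history <- function(out, events, names_wanted, value_col) {
    first <- if (nrow(events)) {
      events[, list(first_date = min(date)), by = c("id", value_col)]
    } else {
      x <- events[, c("id", value_col), with = FALSE]
      x$first_date <- events$date
      x
    }
    M <- merge(rows, first, by = "id", allow.cartesian = TRUE)
    M <- M[first_date <= index_date]
    for (nm in names_wanted) {
      sub <- M[M[[value_col]] == nm,
               list(id, cohort,
                    lag = as.numeric(index_date - first_date) / DAYS_PER_MONTH)]
      data.table::setnames(sub, "lag", paste0(nm, "_lag"))
      out <- merge(out, sub, by = c("id", "cohort"), all.x = TRUE)
      out[[nm]] <- as.integer(!is.na(out[[paste0(nm, "_lag")]]))
    }
    out
  }
  out <- add_history(out, emr$diagnoses[condition %in% conditions],
                     conditions, "condition")
  out <- add_history(out, emr$prescriptions[drug_class %in% drugs],
                     drugs, "drug_class")
  if (all(c("acute_pancreatitis", "chronic_pancreatitis") %in% names(out))) {
    both <- out$acute_pancreatitis == 1L & out$chronic_pancreatitis == 1L
    out$acute_pancreatitis[both] <- 0L
    out$acute_pancreatitis_lag[both] <- NA_real_
  }

  out <- merge(out, emr$outcomes[, list(id, odate = date, event = pdac)],
               by = "id")
  out[, time := as.numeric(odate - index_date) / DAYS_PER_MONTH]
  n_bad <- sum(out$time <= 0)
  out <- out[time > 0]
  out$smoking[is.na(out$smoking)] <- "missing"
  out$drinking[is.na(out$drinking)] <- "missing"

  keep <- c("id", "cohort", "sex", "index_date", "age", "race", "ethnicity",
            "smoking", "drinking",
            ANALYSIS_CONTINUOUS[ANALYSIS_CONTINUOUS != "age"],
            as.vector(rbind(conditions, paste0(conditions, "_lag"))),
            as.vector(rbind(drugs, paste0(drugs, "_lag"))),
            "time", "event")
  res <- as.data.frame(out[, intersect(keep, names(out)), with = FALSE])
  attr(res, "n_nonpositive_followup") <- n_bad
  class(res) <- c("analysis_dataset", "data.frame")
  res
}

#' Complete-case filter for continuous covariates
#'
#' Removes rows with any missing continuous covariate and reports
#' per-covariate missingness.  A warning (not an error) is raised when more
#' than 10% of rows are lost, the ceiling the complete-case design assumes.
#'
#' @param dataset An `analysis_dataset`.
#' @param continuous Continuous covariate columns to require.
#' @return A list with `data` (retained rows) and `report` (a data frame of
#'   per-covariate missing counts plus the excluded fraction).
#' @export
exclude_incomplete <- function(dataset, continuous = ANALYSIS_CONTINUOUS) {
  continuous <- intersect(continuous, names(dataset))
  miss <- vapply(dataset[continuous], function(z) sum(is.na(z)), integer(1))
  bad <- rowSums(is.na(dataset[continuous])) > 0
  frac <- mean(bad)
  if (frac > 0.10) {
    warning(sprintf("%.1f%% of rows have incomplete continuous covariates ",
                    100 * frac),
            "(above the 10% ceiling the complete-case design assumes)")
  }
  list(
    data = dataset[!bad, , drop = FALSE],
    report = data.frame(covariate = c(continuous, "(total rows excluded)"),
                        n_missing = c(miss, sum(bad)),
                        fraction = c(miss / nrow(dataset), frac))
  )
}

#' One-call cohort construction from an EMR bundle
#'
#' Runs [identify_diabetes()], [build_progression_cohorts()],
#' [extract_covariates()] and [exclude_incomplete()].
#'
#' @inheritParams build_progression_cohorts
#' @inheritParams extract_covariates
#' @param apply_exclusions Drop incomplete rows (default `TRUE`).
#' @return A list with `data` (the analysis dataset), `cohorts` (membership
#'   and index dates), `diabetics`, and `exclusion_report`.
#' @export
build_analysis_dataset <- function(emr, combo_grace_days = 0L,
                                   conditions = CONDITION_NAMES,
                                   drugs = c("ppi", "statin", "biguanide",
                                             "dpp4_inhibitor"),
                                   apply_exclusions = TRUE) {
  diab <- identify_diabetes(emr)
  coh <- build_progression_cohorts(emr, diab, combo_grace_days)
  ds <- extract_covariates(emr, coh, conditions, drugs)
  if (apply_exclusions) {
    ex <- exclude_incomplete(ds)
    list(data = ex$data, cohorts = coh, diabetics = diab,
         exclusion_report = ex$report)
  } else {
    list(data = ds, cohorts = coh, diabetics = diab, exclusion_report = NULL)
  }
}
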