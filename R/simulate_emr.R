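# Synthetic EMR generator.
#
# generate_population() draws ground truth first (cohort qualification, index
# dates, covariate values, condition histories, the true linear predictor and
# the event/censoring time), then lays down relational EMR tables from which
# the cohort builder can reconstruct everything.  The truth is returned as a
# side table so tests never re-derive it from the generator's internals.
#
# Record-placement rules that make cohort membership exactly recoverable:
#   * HbA1c values of subjects who must NOT qualify for the HbA1c-rise
#     definition stay within a +/-0.45 band around a subject-level base, so
#     no pair of their tests can show a >=1 rise; qualifying subjects get one
#     crafted (prior, current) pair with current >= 8 and rise >= 1.
#   * Oral hypoglycemic classes of non-combo subjects never share a calendar
#     day; combo initiators hold exactly one prior class and receive two
#     distinct classes on the index day.
#   * Insulin appears only for insulin initiators, first on the index day.

rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rtnorm_d <- function(n, d) rtnorm(n, d$mean, d$sd, d$min, d$max)

as_day <- function(x) SIM_EPOCH + as.integer(round(x))

#' Simulate event and censoring times under a proportional-hazards Weibull law
#'
#' Inverse-transform sampling from S(t) = exp(-(t/scale)^shape * exp(lp)).
#' Decay terms contribute `beta1 * exp(-beta2 * lag)` to the log hazard,
#' held fixed at their index-date value (covariates are assessed at baseline
#' and do not update during follow-up).  The observed time is the minimum of
#' the event time, an exponential dropout time, and administrative censoring.
#'
#' @param linear_predictor Numeric vector of per-subject log hazard offsets.
#' @param decay_terms Optional list; each element is a list with components
#'   `effect` (a [decay_effect()]) and `lag` (months, scalar or vector).
#' @param shape,scale Weibull baseline parameters (time in months).
#' @param dropout_rate Per-month hazard of loss to follow-up (0 = none).
#' @param admin_censor_months Administrative censoring time.
#' @return A data frame with columns `time` (months) and `event` (0/1).
#' @export
simulate_event_time <- function(linear_predictor, decay_terms = NULL,
                                shape = 1, scale, dropout_rate = 0,
                                admin_censor_months) {
  lp <- linear_predictor
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  n <- length(lp)
  for (term in decay_terms) {
    de <- term$effect
    stopifnot(inherits(de, "decay_effect"))
    lag <- rep_len(term$lag, n)
    if (any(lag < 0)) stop("decay-term lag must be >= 0")
    lp <- lp + de$beta1 * exp(-de$beta2 * lag)
  }
  tev <- scale * (stats::rexp(n) * exp(-lp))^(1 / shape)
  tdrop <- if (dropout_rate > 0) stats::rexp(n, dropout_rate) else rep(Inf, n)
  time <- pmin(tev, tdrop, admin_censor_months)
  data.frame(time = time, event = as.integer(tev <= pmin(tdrop, admin_censor_months)))
}

empty_emr <- function(config) {
  dt <- data.table::data.table
  emr <- list(
    patients = dt(id = character(), sex = character(),
                  birth_date = as.Date(character()), race = character(),
                  ethnicity = character(), smoking = character(),
                  drinking = character()),
    diagnoses = dt(id = character(), date = as.Date(character()),
                   condition = character(), setting = character()),
    prescriptions = dt(id = character(), date = as.Date(character()),
                       drug_class = character()),
    labs = dt(id = character(), date = as.Date(character()),
              analyte = character(), value = numeric(),
              inpatient = logical()),
    vitals = dt(id = character(), date = as.Date(character()),
                weight_lbs = numeric(), height_in = numeric()),
    outcomes = dt(id = character(), date = as.Date(character()),
                  pdac = integer()),
    truth = dt(id = character())
  )
  attr(emr, "config") <- config
  class(emr) <- "raw_emr"
  emr
}

#' Generate a synthetic EMR population with known ground truth
#'
#' @param config A [sim_config()].
#' @return A list of class `raw_emr` with `data.table` elements `patients`,
#'   `diagnoses`, `prescriptions`, `labs`, `vitals`, `outcomes`, and a
#'   ground-truth side table `truth` (cohort membership flags, index dates,
#'   true covariates, true linear predictor, simulated follow-up).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  if (n == 0L) return(empty_emr(config))
  dists <- config$covariate_dists
  dt <- data.table::data.table

  id <- sprintf("S%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age_dm <- rtnorm_d(n, dists$age)
  first_dm <- sample.int(1095L, n, replace = TRUE) + 365L
  birth <- first_dm - as.integer(round(age_dm * 365.25))
  race <- sample(names(dists$race), n, replace = TRUE, prob = dists$race)
  ethnicity <- ifelse(stats::runif(n) < dists$hispanic_fraction,
                      "hispanic", "non_hispanic")
  smoking <- sample(names(dists$smoking), n, replace = TRUE,
                    prob = dists$smoking)
  drinking <- sample(names(dists$drinking), n, replace = TRUE,
                     prob = dists$drinking)
  diabetic <- stats::runif(n) >= config$frac_nondiabetic

  # cohort qualification and index dates (a fraction of qualifiers gets an
  # index close to first diabetes evidence, exercising the 90-day rule)
  qual <- matrix(FALSE, n, 3, dimnames = list(NULL, COHORT_KINDS))
  index_day <- matrix(NA_integer_, n, 3, dimnames = list(NULL, COHORT_KINDS))
  for (k in COHORT_KINDS) {
    qual[, k] <- diabetic & stats::runif(n) < config$cohort_mix[[k]]
    early <- stats::runif(n) < config$frac_early_progressor
    gap <- ifelse(early, sample(10:90, n, replace = TRUE),
                  sample(91:1095, n, replace = TRUE))
    index_day[qual[, k], k] <- first_dm[qual[, k]] + gap[qual[, k]]
  }

  # HbA1c truth: qualifying rise pair for the hba1c_rise cohort; for everyone
  # else all HbA1c values stay within a +/-0.45 band around a subject base
  is_rise <- qual[, "hba1c_rise"]
  hb_rise_cur <- rtnorm_d(n, dists$hba1c_rise_current)
  hb_rise_del <- rtnorm_d(n, dists$hba1c_rise_delta)
  hb_base <- rtnorm_d(n, dists$hba1c)            # band center for non-risers
  hb_chg_band <- rtnorm_d(n, dists$hba1c_change) # |.| <= 0.9 by construction
  hba1c <- ifelse(is_rise, hb_rise_cur, hb_base + hb_chg_band / 2)
  hba1c_change <- ifelse(is_rise, hb_rise_del, hb_chg_band)
  hb_prior_level <- ifelse(is_rise, hb_rise_cur - hb_rise_del,
                           hb_base - hb_chg_band / 2)

  # lab-draw schedule per cohort, fixed before membership so the effective
  # first diabetes evidence (earliest qualifying element among the emitted
  # records) can be derived; banded HbA1c priors may legitimately predate the
  # first diagnosis and move first evidence earlier
  lab_u <- lab_gap <- hb_extra_delta <- matrix(NA_integer_, n, 3,
                                               dimnames = list(NULL, COHORT_KINDS))
  for (k in COHORT_KINDS) {
    lab_u[, k] <- sample(0:300, n, replace = TRUE)
    lab_gap[, k] <- as.integer(round(rtnorm(n, 365, 45, 120, 440)))
    hb_extra_delta[, k] <- rtnorm(n, 0, 0.2, -0.44, 0.44)
  }
  eff_first <- first_dm
  for (k in COHORT_KINDS) {
    rows <- which(qual[, k])
    if (!length(rows)) next
    if (k == "hba1c_rise") {
      cur_day <- index_day[rows, k]
      pri_day <- cur_day - lab_gap[rows, k]
      cur_v <- round(hb_rise_cur[rows], 3)
      pri_v <- round(hb_rise_cur[rows] - hb_rise_del[rows], 3)
    } else {
      cur_day <- index_day[rows, k] - lab_u[rows, k]
      pri_day <- cur_day - lab_gap[rows, k]
      base_k <- ifelse(is_rise[rows], hb_prior_level[rows], hb_base[rows])
      delta <- ifelse(is_rise[rows], hb_extra_delta[rows, k],
                      hb_chg_band[rows])
      # risers' banded pairs sit at the pre-rise level: they can neither
      # qualify on their own (rise < 1 within the band) nor pre-empt the
      # crafted index (values after it leave the first qualifying date alone)
      cur_v <- round(base_k + delta / 2, 3)
      pri_v <- round(base_k - delta / 2, 3)
    }
    q_cur <- !is.na(cur_day) & cur_v >= 6.5
    q_pri <- !is.na(pri_day) & pri_v >= 6.5
    eff_first[rows][q_cur] <- pmin(eff_first[rows][q_cur], cur_day[q_cur])
    eff_first[rows][q_pri] <- pmin(eff_first[rows][q_pri], pri_day[q_pri])
  }

  # membership: the definitions applied to the emitted records -- age >= 50 at
  # effective first evidence, index more than 90 days past it
  diab_ok <- diabetic & (eff_first - birth) / 365.25 >= 50
  member <- qual
  for (k in COHORT_KINDS) {
    member[, k] <- qual[, k] & diab_ok &
      !is.na(index_day[, k]) & (index_day[, k] - eff_first) > 90
  }
  nonprog <- diab_ok & !member[, 1] & !member[, 2] & !member[, 3]
  midx <- ifelse(member, index_day, NA_integer_)
  anchor <- suppressWarnings(apply(midx, 1L, min, na.rm = TRUE))
  has_any <- rowSums(member) > 0
  anchor[!has_any] <- first_dm[!has_any]
  first_cohort <- rep(NA_character_, n)
  for (k in COHORT_KINDS) {
    hit <- member[, k] & is.na(first_cohort) & !is.na(index_day[, k]) &
      index_day[, k] == anchor
    first_cohort[hit] <- k
  }

  # subject-level covariate truth -------------------------------------------
  male <- sex == "male"
  weight <- numeric(n)
  weight[male] <- rtnorm(sum(male), dists$weight_m$mean, dists$weight_m$sd,
                         dists$weight_m$min, dists$weight_m$max)
  weight[!male] <- rtnorm(sum(!male), dists$weight_f$mean, dists$weight_f$sd,
                          dists$weight_f$min, dists$weight_f$max)
  height <- numeric(n)
  height[male] <- rtnorm(sum(male), dists$height_m$mean, dists$height_m$sd,
                         dists$height_m$min, dists$height_m$max)
  height[!male] <- rtnorm(sum(!male), dists$height_f$mean, dists$height_f$sd,
                          dists$height_f$min, dists$height_f$max)
  wchg <- rtnorm_d(n, dists$weight_change_pct)
  weight_prior <- pmin(pmax(weight / (1 + wchg / 100), 80), 490)
  wchg <- 100 * (weight - weight_prior) / weight_prior
  peak_weight <- pmin(pmax(weight, weight_prior) *
                        (1 + stats::runif(n, 0, 0.12)), 495)
  peak_bmi <- 703 * peak_weight / height^2

  labval <- list(
    creatinine = rtnorm_d(n, dists$creatinine),
    cholesterol = rtnorm_d(n, dists$cholesterol),
    bilirubin = rtnorm_d(n, dists$bilirubin),
    hemoglobin = rtnorm_d(n, dists$hemoglobin),
    rbc = rtnorm_d(n, dists$rbc)
  )
  labchg <- list(
    bilirubin = rtnorm_d(n, dists$bilirubin_change_pct),
    rbc = rtnorm_d(n, dists$rbc_change_pct)
  )
  labprior <- list()
  for (a in names(labval)) {
    ch <- if (a %in% names(labchg)) labchg[[a]] else rep(0, n)
    pri <- labval[[a]] / (1 + ch / 100)
    d <- dists[[a]]
    labprior[[a]] <- pmin(pmax(pri, d$min), d$max)
    labchg[[a]] <- 100 * (labval[[a]] - labprior[[a]]) / labprior[[a]]
  }

  cond_ind <- sapply(CONDITION_NAMES, function(cn)
    stats::runif(n) < config$condition_prevalences[[cn]])
  # history of both acute and chronic pancreatitis counts as chronic
  both <- cond_ind[, "acute_pancreatitis"] & cond_ind[, "chronic_pancreatitis"]
  cond_class <- cond_ind
  cond_class[both, "acute_pancreatitis"] <- FALSE
  # condition/prescription history may predate diabetes evidence (and the
  # date epoch); lags are measured to the subject's earliest index date
  cond_lag <- matrix(pmax(stats::rlnorm(n * length(CONDITION_NAMES),
                                        config$onset_lag_meanlog,
                                        config$onset_lag_sdlog), 0.5),
                     n, length(CONDITION_NAMES),
                     dimnames = list(NULL, CONDITION_NAMES))

  drug_ind <- sapply(names(config$drug_prevalences), function(dn)
    stats::runif(n) < config$drug_prevalences[[dn]])
  drug_ind[member[, "combo_oral"], "biguanide"] <- TRUE
  drug_lag_day <- matrix(
    as.integer(round(pmax(stats::rlnorm(n * ncol(drug_ind),
                                        config$onset_lag_meanlog,
                                        config$onset_lag_sdlog),
                          0.5) * DAYS_PER_MONTH)),
    n, ncol(drug_ind), dimnames = list(NULL, colnames(drug_ind)))

  # true linear predictor ----------------------------------------------------
  age_anchor <- (anchor - birth) / 365.25
  covs <- list(age = age_anchor, weight = weight, weight_change_pct = wchg,
               peak_bmi = peak_bmi, hba1c = hba1c,
               hba1c_change = hba1c_change,
               creatinine = labval$creatinine,
               cholesterol = labval$cholesterol,
               bilirubin = labval$bilirubin,
               bilirubin_change_pct = labchg$bilirubin,
               rbc = labval$rbc, rbc_change_pct = labchg$rbc,
               smoking_current = as.numeric(smoking == "current"))
  lp <- numeric(n)
  for (nm in names(config$effects)) {
    ef <- config$effects[[nm]]
    if (inherits(ef, "linear_effect")) {
      val <- if (nm %in% names(covs)) covs[[nm]] else
        if (nm %in% CONDITION_NAMES) as.numeric(cond_class[, nm]) else
          stop("configuration error in 'effects': unknown covariate '", nm, "'")
      lp <- lp + ef$beta * (val - ef$center)
    } else if (inherits(ef, "decay_effect")) {
      if (!nm %in% CONDITION_NAMES) {
        stop("configuration error in 'effects': decay effect for unknown ",
             "condition '", nm, "'")
      }
      lp <- lp + cond_class[, nm] * ef$beta1 * exp(-ef$beta2 * cond_lag[, nm])
    } else {
      stop("configuration error in 'effects': entry '", nm,
           "' is neither linear_effect nor decay_effect")
    }
  }
  # progression-stage effect: a subject in several cohorts carries the
  # highest-risk stage they reached (insulin initiation dominates)
  stage_loghr <- apply(member, 1L, function(mm)
    if (any(mm)) max(config$cohort_loghr[COHORT_KINDS][mm]) else NA_real_)
  lp <- lp + ifelse(has_any, stage_loghr,
                    ifelse(nonprog, config$nonprogressor_loghr, 0))

  scale_infl <- config$baseline_scale /
    config$event_inflation^(1 / config$baseline_shape)
  st <- simulate_event_time(lp, shape = config$baseline_shape,
                            scale = scale_infl,
                            dropout_rate = config$dropout_rate,
                            admin_censor_months = config$admin_censor_months)
  outcome_day <- anchor + as.integer(round(st$time * DAYS_PER_MONTH))

  # tables -------------------------------------------------------------------
  patients <- dt(id = id, sex = sex, birth_date = as_day(birth),
                 race = race, ethnicity = ethnicity, smoking = smoking,
                 drinking = drinking)

  dx <- list()
  dx[[1]] <- dt(id = id, date = as_day(first_dm), condition = "diabetes",
                setting = "outpatient")
  second <- diabetic
  dx[[2]] <- dt(id = id[second],
                date = as_day(first_dm[second] +
                                sample(30:300, sum(second), replace = TRUE)),
                condition = "diabetes", setting = "outpatient")
  for (cn in CONDITION_NAMES) {
    # emit the recorded history: both acute and chronic rows are written when
    # both were drawn; the builder applies the chronic-overrides-acute rule
    hit <- which(cond_ind[, cn])
    if (length(hit)) {
      ddate <- anchor[hit] -
        as.integer(round(cond_lag[hit, cn] * DAYS_PER_MONTH))
      dx[[length(dx) + 1L]] <- dt(id = id[hit], date = as_day(ddate),
                                  condition = cn, setting = "outpatient")
    }
  }
  diagnoses <- data.table::rbindlist(dx)

  rx <- list()
  ins <- which(member[, "insulin_init"] | qual[, "insulin_init"])
  if (length(ins)) {
    rx[[length(rx) + 1L]] <- dt(id = id[ins],
                                date = as_day(index_day[ins, "insulin_init"]),
                                drug_class = "insulin")
  }
  cmb <- which(member[, "combo_oral"] | qual[, "combo_oral"])
  if (length(cmb)) {
    mono_start <- index_day[cmb, "combo_oral"] -
      sample(200:1000, length(cmb), replace = TRUE)
    second_class <- ifelse(drug_ind[cmb, "dpp4_inhibitor"],
                           "dpp4_inhibitor", "sulfonylurea")
    rx[[length(rx) + 1L]] <- dt(id = id[cmb], date = as_day(mono_start),
                                drug_class = "biguanide")
    rx[[length(rx) + 1L]] <- dt(id = id[cmb],
                                date = as_day(index_day[cmb, "combo_oral"]),
                                drug_class = "biguanide")
    rx[[length(rx) + 1L]] <- dt(id = id[cmb],
                                date = as_day(index_day[cmb, "combo_oral"]),
                                drug_class = second_class)
  }
  noncmb <- which(!(member[, "combo_oral"] | qual[, "combo_oral"]))
  for (dn in colnames(drug_ind)) {
    hit <- intersect(which(drug_ind[, dn]), noncmb)
    if (dn == "dpp4_inhibitor" && length(hit)) {
      # keep oral-class start dates distinct so no spurious same-day pair
      dday <- anchor[hit] - drug_lag_day[hit, dn]
      clash <- drug_ind[hit, "biguanide"] &
        dday == anchor[hit] - drug_lag_day[hit, "biguanide"]
      dday[clash] <- dday[clash] + 1L
      rx[[length(rx) + 1L]] <- dt(id = id[hit], date = as_day(dday),
                                  drug_class = dn)
    } else if (length(hit)) {
      rx[[length(rx) + 1L]] <- dt(id = id[hit],
                                  date = as_day(anchor[hit] -
                                                  drug_lag_day[hit, dn]),
                                  drug_class = dn)
    }
  }
  # ppi/statin for combo subjects too (non-oral classes are unconstrained)
  for (dn in c("ppi", "statin")) {
    hit <- intersect(which(drug_ind[, dn]), cmb)
    if (length(hit)) {
      rx[[length(rx) + 1L]] <- dt(id = id[hit],
                                  date = as_day(anchor[hit] -
                                                  drug_lag_day[hit, dn]),
                                  drug_class = dn)
    }
  }
  prescriptions <- if (length(rx)) data.table::rbindlist(rx) else
    empty_emr(config)$prescriptions

  # labs ---------------------------------------------------------------------
  lab <- list()
  gl <- ifelse(diabetic, rtnorm(n, 160, 30, 127, 300), 110)
  lab[[1]] <- dt(id = id, date = as_day(first_dm), analyte = "glucose_fasting",
                 value = round(gl, 1), inpatient = FALSE)
  plant_pair <- function(ids, cur_day, pri_day, analyte, cur, pri) {
    list(dt(id = ids, date = as_day(cur_day), analyte = analyte,
            value = round(cur, 3), inpatient = FALSE),
         dt(id = ids, date = as_day(pri_day), analyte = analyte,
            value = round(pri, 3), inpatient = FALSE))
  }
  for (k in COHORT_KINDS) {
    rows <- which(qual[, k])
    if (!length(rows)) next
    idx <- index_day[rows, k]
    gap <- lab_gap[rows, k]
    # HbA1c: crafted qualifying pair at the rise index; banded pairs
    # elsewhere (dates and values fixed by the pre-membership schedule)
    if (k == "hba1c_rise") {
      cur_day <- idx
      pri_day <- idx - gap
      lab <- c(lab, plant_pair(id[rows], cur_day, pri_day, "hba1c",
                               hb_rise_cur[rows],
                               hb_rise_cur[rows] - hb_rise_del[rows]))
    } else {
      cur_day <- idx - lab_u[rows, k]
      pri_day <- cur_day - gap
      delta <- ifelse(is_rise[rows], hb_extra_delta[rows, k],
                      hb_chg_band[rows])
      base_k <- ifelse(is_rise[rows], hb_prior_level[rows], hb_base[rows])
      cur_v <- base_k + delta / 2
      pri_v <- base_k - delta / 2
      lab <- c(lab, plant_pair(id[rows], cur_day, pri_day,
                               "hba1c", cur_v, pri_v))
    }
    for (a in names(labval)) {
      miss <- a %in% c("cholesterol", "rbc", "bilirubin") &
        stats::runif(length(rows)) < config$missing_lab_rate
      keep <- !miss
      if (any(keep)) {
        lab <- c(lab, plant_pair(id[rows][keep], cur_day[keep], pri_day[keep],
                                 a, labval[[a]][rows][keep],
                                 labprior[[a]][rows][keep]))
      }
    }
  }
  # extreme inpatient labs that must be ignored downstream
  ipt <- which(stats::runif(n) < config$inpatient_lab_rate)
  if (length(ipt)) {
    iday <- anchor[ipt] - sample(30:300, length(ipt), replace = TRUE)
    lab[[length(lab) + 1L]] <- dt(id = id[ipt], date = as_day(iday),
                                  analyte = "glucose_random",
                                  value = round(stats::runif(length(ipt), 210, 400), 1),
                                  inpatient = TRUE)
    lab[[length(lab) + 1L]] <- dt(id = id[ipt], date = as_day(iday),
                                  analyte = "hba1c",
                                  value = round(stats::runif(length(ipt), 10, 14), 2),
                                  inpatient = TRUE)
  }
  labs <- data.table::rbindlist(lab)

  # vitals -------------------------------------------------------------------
  vt <- list()
  vt[[1]] <- dt(id = id, date = as_day(first_dm),
                weight_lbs = round(peak_weight, 1),
                height_in = round(height, 1))
  for (k in COHORT_KINDS) {
    rows <- which(qual[, k])
    if (!length(rows)) next
    idx <- index_day[rows, k]
    u <- sample(0:300, length(rows), replace = TRUE)
    gap <- as.integer(round(rtnorm(length(rows), 365, 45, 120, 440)))
    vt[[length(vt) + 1L]] <- dt(id = id[rows], date = as_day(idx - u),
                                weight_lbs = round(weight[rows], 1),
                                height_in = NA_real_)
    vt[[length(vt) + 1L]] <- dt(id = id[rows], date = as_day(idx - u - gap),
                                weight_lbs = round(weight_prior[rows], 1),
                                height_in = NA_real_)
  }
  bogus <- which(stats::runif(n) < config$implausible_vital_rate)
  if (length(bogus)) {
    vt[[length(vt) + 1L]] <- dt(id = id[bogus],
                                date = as_day(anchor[bogus] -
                                                sample(10:200, length(bogus),
                                                       replace = TRUE)),
                                weight_lbs = round(stats::runif(length(bogus),
                                                                505, 600), 1),
                                height_in = NA_real_)
  }
  vitals <- data.table::rbindlist(vt)

  outcomes <- dt(id = id, date = as_day(outcome_day),
                 pdac = st$event)

  truth <- dt(id = id, sex = sex, diabetic = diabetic,
              nonprogressor = nonprog,
              member_insulin_init = member[, "insulin_init"],
              index_insulin_init = as_day(index_day[, "insulin_init"]),
              member_combo_oral = member[, "combo_oral"],
              index_combo_oral = as_day(index_day[, "combo_oral"]),
              member_hba1c_rise = member[, "hba1c_rise"],
              index_hba1c_rise = as_day(index_day[, "hba1c_rise"]),
              first_cohort = first_cohort,
              anchor_date = as_day(anchor),
              age = age_anchor, weight = weight,
              weight_change_pct = wchg, peak_bmi = peak_bmi,
              hba1c = hba1c, hba1c_change = hba1c_change,
              creatinine = labval$creatinine,
              cholesterol = labval$cholesterol,
              bilirubin = labval$bilirubin,
              bilirubin_change_pct = labchg$bilirubin,
              rbc = labval$rbc, rbc_change_pct = labchg$rbc,
              smoking = smoking, drinking = drinking,
              lp = lp, time_months = st$time, event = st$event)
  for (cn in CONDITION_NAMES) {
    truth[[cn]] <- as.integer(cond_class[, cn])
    truth[[paste0(cn, "_lag")]] <-
      ifelse(cond_ind[, cn], cond_lag[, cn], NA_real_)
  }
  # index dates of early-excluded qualifiers are not part of the truth
  for (k in COHORT_KINDS) {
    data.table::set(truth, i = which(!member[, k]),
                    j = paste0("index_", k), value = as.Date(NA))
  }

  emr <- list(patients = patients, diagnoses = diagnoses,
              prescriptions = prescriptions, labs = labs, vitals = vitals,
              outcomes = outcomes, truth = truth)
  attr(emr, "config") <- config
  class(emr) <- "raw_emr"
  emr
}

#' @export
print.raw_emr <- function(x, ...) {
  cat("raw_emr:", nrow(x$patients), "patients;",
      nrow(x$diagnoses), "diagnoses;", nrow(x$prescriptions),
      "prescriptions;", nrow(x$labs), "labs;", nrow(x$vitals), "vitals\n")
  if (nrow(x$outcomes)) {
    cat("  PDAC events:", sum(x$outcomes$pdac), "/", nrow(x$outcomes), "\n")
  }
  invisible(x)
}

#' Write / read an EMR bundle as delimited text
#'
#' One comma-separated file per table (ISO-8601 dates) plus `config.yaml`
#' recording the generating configuration and seed.
#'
#' @param emr A `raw_emr` object.
#' @param dir Output directory (created if needed).
#' @export
write_emr <- function(emr, dir) {
  stopifnot(inherits(emr, "raw_emr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "diagnoses", "prescriptions", "labs", "vitals",
               "outcomes", "truth")) {
    data.table::fwrite(emr[[nm]], file.path(dir, paste0(nm, ".csv")),
                       dateTimeAs = "ISO")
  }
  cfg <- attr(emr, "config")
  if (!is.null(cfg)) {
    plain <- rapply(unclass(cfg), function(z) {
      if (inherits(z, c("linear_effect", "decay_effect"))) unclass(z) else z
    }, how = "replace")
    yaml::write_yaml(plain, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_emr
#' @export
read_emr <- function(dir) {
  emr <- list()
  for (nm in c("patients", "diagnoses", "prescriptions", "labs", "vitals",
               "outcomes", "truth")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f) && nm == "truth") next
    emr[[nm]] <- data.table::fread(f)
    for (cl in names(emr[[nm]])) {
      if (grepl("date$|^date$", cl)) {
        data.table::set(emr[[nm]], j = cl, value = as.Date(emr[[nm]][[cl]]))
      }
    }
  }
  class(emr) <- "raw_emr"
  emr
}
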