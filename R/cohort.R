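#' Synthetic cohort specification
#'
#' Describes the intensive-care study design the generator emulates: 37
#' adults, 65% male, heights and total body weights drawn from truncated
#' normals calibrated to the cohort's median and 5-95% quantiles, mixed
#' oral/intravenous dosing (about two thirds oral), guideline dosing
#' (loading 10-20 mg/kg, maintenance 1-4 mg/kg, 12-hourly), treatment
#' durations lognormal around a 16-day median, and trough therapeutic drug
#' monitoring on a Monday/Wednesday/Friday cadence with doses rounded to
#' 50 mg.
#'
#' Continuous distributions are given as `list(median, q05, q95)`; the SD is
#' back-calculated from the 5-95% span (a point mass when the span is zero,
#' which is how the degenerate "typical patient" design is expressed).
#'
#' @param n_patients Number of patients.
#' @param sex_fraction_male Probability a patient is male.
#' @param height_dist,tbw_dist Truncated-normal summaries (cm, kg).
#' @param oral_fraction Per-dose probability of the oral route.
#' @param loading_mg_per_kg,maintenance_mg_per_kg Dose ranges (mg/kg of
#'   total body weight).
#' @param dosing_interval Maintenance interval (h).
#' @param treatment_days_dist Lognormal summary of treatment duration (days).
#' @param tdm_weekdays Sampling weekdays (1 = Monday ... 7 = Sunday).
#' @param dose_rounding Dose granularity (mg).
#' @param lq,uq Lower/upper limit of quantification (mg/L).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 37, sex_fraction_male = 0.65,
                        height_dist = list(median = 173, q05 = 161, q95 = 187.5),
                        tbw_dist = list(median = 78.5, q05 = 51.7, q95 = 93.3),
                        oral_fraction = 0.66,
                        loading_mg_per_kg = c(10, 20),
                        maintenance_mg_per_kg = c(1, 4),
                        dosing_interval = 12,
                        treatment_days_dist = list(median = 16, q05 = 2, q95 = 61),
                        tdm_weekdays = c(1, 3, 5),
                        dose_rounding = 50, lq = 0.6, uq = 150) {
  stopifnot(n_patients >= 1, sex_fraction_male >= 0, sex_fraction_male <= 1,
            oral_fraction >= 0, oral_fraction <= 1,
            all(loading_mg_per_kg > 0), diff(loading_mg_per_kg) >= 0,
            all(maintenance_mg_per_kg > 0), diff(maintenance_mg_per_kg) >= 0,
            dosing_interval > 0, dose_rounding > 0, lq > 0, uq > lq,
            all(tdm_weekdays %in% 1:7))
  structure(as.list(environment()), class = "cohort_spec")
}

# Inverse-CDF draw from a normal given (median, q05, q95), truncated to
# [lo, hi]; degenerate span -> point mass at the median.
rtrunc_summary <- function(n, dist, lo, hi) {
  sdv <- (dist$q95 - dist$q05) / (2 * qnorm(0.95))
  if (sdv <= 0) return(rep(dist$median, n))
  plo <- pnorm(lo, dist$median, sdv)
  phi <- pnorm(hi, dist$median, sdv)
  qnorm(runif(n, plo, phi), dist$median, sdv)
}

# Lognormal analogue on the log scale (median = exp(meanlog)).
rtrunc_lnorm_summary <- function(n, dist, lo, hi) {
  if (dist$q95 <= dist$q05) return(rep(dist$median, n))
  ldist <- list(median = log(dist$median), q05 = log(dist$q05),
                q95 = log(dist$q95))
  exp(rtrunc_summary(n, ldist, log(lo), log(hi)))
}

#' Sample a patient from the cohort specification
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (`NULL`: current RNG stream).
#' @param id Patient identifier.
#' @return A [patient()].
#' @export
sample_patient <- function(spec, seed = NULL, id = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    sex <- if (runif(1) < spec$sex_fraction_male) "male" else "female"
    height <- rtrunc_summary(1, spec$height_dist, 140, 210)
    tbw <- rtrunc_summary(1, spec$tbw_dist, 35, 140)
    patient(id = id, sex = sex, height_cm = height, tbw = tbw)
  })
}

#' Sample a guideline dosing history
#'
#' One loading dose at t = 0 drawn uniformly from the loading range (mg/kg of
#' total body weight), then a per-patient maintenance dose every
#' `dosing_interval` hours from t = 12 h until the end of the drawn treatment
#' duration. Doses are rounded to the spec's granularity and each dose's
#' route is drawn independently (oral with probability `oral_fraction`).
#'
#' @param spec A [cohort_spec()].
#' @param patient A [patient()] with `tbw`.
#' @param seed Integer seed.
#' @return A [regimen()] with attribute `duration_h`.
#' @export
sample_regimen <- function(spec, patient, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), !is.na(patient$tbw))
  with_seed(seed, {
    gran <- spec$dose_rounding
    round_dose <- function(mg) pmax(round(mg / gran) * gran, gran)
    loading <- round_dose(runif(1, spec$loading_mg_per_kg[1],
                                spec$loading_mg_per_kg[2]) * patient$tbw)
    maint <- round_dose(runif(1, spec$maintenance_mg_per_kg[1],
                              spec$maintenance_mg_per_kg[2]) * patient$tbw)
    days <- max(1, round(rtrunc_lnorm_summary(1, spec$treatment_days_dist,
                                              1, 120)))
    mt <- seq(spec$dosing_interval, days * 24, by = spec$dosing_interval)
    times <- c(0, mt)
    amounts <- c(loading, rep(maint, length(mt)))
    routes <- ifelse(runif(length(times)) < spec$oral_fraction, "oral", "iv")
    r <- regimen(time = times, amount = amounts, route = routes,
                 schedule_h = spec$dosing_interval)
    attr(r, "duration_h") <- days * 24
    r
  })
}

# Trough sampling times (h) for a treatment starting at 08:00 on
# `start_weekday` (1 = Monday): the pre-dose trough at 08:00 of every
# cadence day during treatment, starting the day after the first dose.
tdm_sample_times <- function(start_weekday, duration_h, tdm_weekdays) {
  days <- seq_len(floor(duration_h / 24))
  days <- days[((start_weekday - 1 + days) %% 7 + 1) %in% tdm_weekdays]
  24 * days
}

#' Simulate a synthetic trough-monitoring dataset
#'
#' Generates the full study emulation: patients, dosing histories, individual
#' parameter realizations with occasions cut at the trough sampling times
#' (the first occasion runs from the first dose to the first sample), exact
#' concentrations at the pre-dose sampling times, proportional assay error
#' `y = c (1 + eps)`, and quantification-range flagging. Each patient's
#' treatment starts on a uniformly random weekday.
#'
#' @param spec A [cohort_spec()].
#' @param model A [population_model()].
#' @param seed Integer master seed; every patient derives an independent
#'   sub-seed, so generation is bit-reproducible.
#' @return A `tdm_dataset`: a NONMEM-style event-record `data.frame` (see
#'   [as_tdm_dataset()]) with one row per dose and per observation.
#' @export
simulate_tdm_dataset <- function(spec, model, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "population_model"))
  seeds <- derive_seeds(seed, 2 * spec$n_patients + 1)
  rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pat <- sample_patient(spec, seed = seeds[2 * i - 1], id = i)
    rows[[i]] <- with_seed(seeds[2 * i], {
      reg <- sample_regimen(spec, pat, seed = NULL)
      start_wd <- sample.int(7, 1)
      st <- tdm_sample_times(start_wd, attr(reg, "duration_h"),
                             spec$tdm_weekdays)
      n_occ <- max(length(st), 1L)
      ind <- realize_individual(model, pat, n_occasions = n_occ,
                                occasion_boundaries = head(st, -1))
      conc <- if (length(st)) concentration_profile(ind, reg, st) else numeric()
      y <- conc * (1 + rnorm(length(st), 0, model$sigma_prop))
      flag <- ifelse(y < spec$lq, "BLQ", ifelse(y > spec$uq, "ALQ", ""))
      occ_obs <- seq_along(st)
      occ_dose <- 1L + vapply(reg$time,
                              function(t) sum(st <= t + 1e-9), integer(1))
      dose_rows <- data.frame(
        ID = i, TIME = reg$time, EVID = 1L, AMT = reg$amount,
        ROUTE = reg$route, DUR = reg$dur, DV = NA_real_, MDV = 1L,
        OCC = pmin(occ_dose, n_occ + 1L), FLAG = "",
        stringsAsFactors = FALSE)
      obs_rows <- if (length(st)) data.frame(
        ID = i, TIME = st, EVID = 0L, AMT = NA_real_, ROUTE = "",
        DUR = NA_real_, DV = y, MDV = as.integer(flag != ""), OCC = occ_obs,
        FLAG = flag, stringsAsFactors = FALSE) else NULL
      out <- rbind(dose_rows, obs_rows)
      # a trough observation precedes a dose scheduled at the same time
      out <- out[order(out$TIME, out$EVID), ]
      out$SEX <- pat$sex
      out$HT <- pat$height_cm
      out$TBW <- pat$tbw
      out$IBW <- pat$ibw
      out
    })
  }
  as_tdm_dataset(do.call(rbind, rows))
}
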