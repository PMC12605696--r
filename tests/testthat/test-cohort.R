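test_that("degenerate point-mass spec reproduces the median patient and the
           guideline dose arithmetic", {
  spec <- cohort_spec(
    sex_fraction_male = 1,
    height_dist = list(median = 173, q05 = 173, q95 = 173),
    tbw_dist = list(median = 78.5, q05 = 78.5, q95 = 78.5),
    loading_mg_per_kg = c(12.7, 12.7),
    maintenance_mg_per_kg = c(2.55, 2.55),
    treatment_days_dist = list(median = 1, q05 = 1, q95 = 1))
  pat <- sample_patient(spec, seed = 1)
  expect_equal(pat$sex, "male")
  expect_equal(pat$ibw, 50 + 0.91 * 20.6)   # Brower at 173 cm
  reg <- sample_regimen(spec, pat, seed = 1)
  # 12.7 mg/kg x 78.5 kg = 996.95 -> 1000 at 50 mg granularity
  expect_equal(reg$amount[1], 1000)
  # 2.55 mg/kg x 78.5 kg = 200.175 -> 200, the cohort's median dose
  expect_equal(unique(reg$amount[-1]), 200)
  # one treatment day at a 12-h interval: exactly two maintenance doses
  expect_equal(sum(reg$time > 0), 2L)
  expect_equal(reg$time, c(0, 12, 24))
})

test_that("sampled covariates match the cohort summaries", {
  spec <- cohort_spec()
  set.seed(42)
  heights <- vapply(1:3000, function(i) sample_patient(spec)$height_cm,
                    numeric(1))
  expect_lt(abs(median(heights) - 173), 1)
  spec_m <- cohort_spec(sex_fraction_male = 1)
  sexes <- vapply(1:50, function(i) sample_patient(spec_m)$sex, character(1))
  expect_true(all(sexes == "male"))
})

test_that("trough sampling follows the Mon/Wed/Fri cadence with 48/72-h
           gaps and a realistic samples-per-patient count", {
  m <- population_model()
  spec <- cohort_spec()
  med_samp <- integer(3)
  for (s in 1:3) {
    ds <- simulate_tdm_dataset(spec, m, seed = s)
    obs <- ds[ds$EVID == 0L, ]
    gaps <- unlist(lapply(split(obs$TIME, obs$ID), diff))
    expect_true(all(gaps %in% c(48, 72)))
    med_samp[s] <- median(table(factor(obs$ID, levels = unique(ds$ID))))
  }
  expect_true(all(med_samp >= 4 & med_samp <= 9))
})

test_that("occasion indices increment exactly at the sampling times", {
  ds <- simulate_tdm_dataset(cohort_spec(n_patients = 8),
                             population_model(), seed = 2)
  for (d in split(as.data.frame(ds), ds$ID)) {
    obs <- d[d$EVID == 0L, ]
    if (!nrow(obs)) next
    expect_equal(obs$OCC, seq_len(nrow(obs)))
    # a dose between samples k and k+1 carries occasion k+1
    for (j in seq_len(nrow(d))) {
      if (d$EVID[j] == 1L)
        expect_equal(d$OCC[j], 1L + sum(obs$TIME <= d$TIME[j] + 1e-9))
    }
  }
})

test_that("generation is bit-reproducible and round-trips through the io
           layer", {
  spec <- cohort_spec(n_patients = 6)
  m <- population_model()
  d1 <- simulate_tdm_dataset(spec, m, seed = 7)
  d2 <- simulate_tdm_dataset(spec, m, seed = 7)
  expect_identical(d1, d2)
  path <- tempfile(fileext = ".csv")
  write_tdm_dataset(d1, path)
  back <- read_tdm_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(d1), tolerance = 1e-9)
})

test_that("noise-free generation returns the model predictions exactly", {
  spec <- cohort_spec(n_patients = 5)
  m0 <- det_model()
  ds <- simulate_tdm_dataset(spec, m0, seed = 3)
  for (d in split(as.data.frame(ds), ds$ID)) {
    obs <- d[d$EVID == 0L, ]
    if (!nrow(obs)) next
    doses <- d[d$EVID == 1L, ]
    ind <- realize_individual(m0, patient(d$ID[1], d$SEX[1], ibw = d$IBW[1]),
                              n_occasions = nrow(obs),
                              occasion_boundaries = head(obs$TIME, -1))
    pred <- concentration_profile(
      ind, data.frame(time = doses$TIME, amount = doses$AMT,
                      route = doses$ROUTE,
                      dur = ifelse(doses$ROUTE == "iv", doses$DUR, 0)),
      obs$TIME)
    expect_equal(obs$DV, pred, tolerance = 1e-10)
  }
})

test_that("observations outside the quantification range are flagged and
           excluded from estimation", {
  # shrink the quantification window so flags must occur
  spec <- cohort_spec(n_patients = 10, lq = 25, uq = 45)
  ds <- simulate_tdm_dataset(spec, population_model(), seed = 12)
  obs <- ds[ds$EVID == 0L, ]
  expect_true(any(obs$FLAG != ""))
  expect_true(all(obs$MDV[obs$FLAG != ""] == 1L))
  expect_true(all(obs$DV[obs$FLAG == "BLQ"] < 25))
  expect_true(all(obs$DV[obs$FLAG == "ALQ"] > 45))
  expect_true(all(obs$MDV[obs$FLAG == ""] == 0L))
})
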