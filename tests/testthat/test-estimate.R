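test_that("lognormal CV conversion", {
  expect_equal(cv_from_sd(0), 0)
  expect_equal(cv_from_sd(0.02), 2, tolerance = 1e-3)    # small-sd limit
  expect_equal(cv_from_sd(0.71), 80.9626, tolerance = 1e-4)
  expect_error(cv_from_sd(-0.1), "non-negative")
})

test_that("degenerate OFV (no random effects) equals the closed-form
           proportional-error sum and is scale invariant", {
  m0 <- det_model(sigma_prop = 0.1)
  ind <- realize_individual(m0, typical_patient())
  reg <- regimen(0, 400, "oral")
  tt <- c(12, 24, 48)
  pred <- concentration_profile(ind, reg, tt)
  y <- pred * c(1.05, 0.92, 1.1)
  ds <- as_tdm_dataset(event_df(1, reg, tt, y, ibw = 68.8))
  expected <- sum(log(2 * pi * (0.1 * pred)^2) + (y - pred)^2 / (0.1 * pred)^2)
  expect_equal(ofv(m0, ds, method = "laplace"), expected, tolerance = 1e-8)
  # scaling doses and observations by 10 shifts the OFV by the deterministic
  # jacobian term only: standardized residuals are unchanged
  reg10 <- regimen(0, 4000, "oral")
  ds10 <- as_tdm_dataset(event_df(1, reg10, tt, 10 * y, ibw = 68.8))
  expect_equal(ofv(m0, ds10, method = "laplace") - ofv(m0, ds, method = "laplace"),
               2 * 3 * log(10), tolerance = 1e-8)
})

test_that("adaptive Gauss-Hermite OFV matches dense brute-force quadrature", {
  # one random effect (clearance), one observation
  m1 <- population_model(omega_V = 0, gamma_CL = 0)
  reg <- regimen(0, 500, "iv")
  ds1 <- as_tdm_dataset(event_df(1, reg, 24, 10.5, ibw = 68.8))
  dense_1d <- local({
    typ <- covariate_scale(m1, 68.8)
    f <- function(e) {
      ind <- realize_individual(m1, typical_patient(), eta = list(eta_CL = e))
      c24 <- concentration_profile(ind, reg, 24)
      dnorm(10.5, c24, m1$sigma_prop * c24) * dnorm(e, 0, m1$omega_CL)
    }
    g <- seq(-3, 3, length.out = 20001)
    -2 * log(sum(vapply(g, f, numeric(1))) * diff(g)[1])
  })
  expect_equal(ofv(m1, ds1, method = "agq", n_nodes = 41), dense_1d,
               tolerance = 1e-3)

  # two random effects (V and CL), two observations
  m2 <- population_model(gamma_CL = 0)
  ds2 <- as_tdm_dataset(event_df(1, reg, c(2, 24), c(13.1, 10.2),
                                 ibw = 68.8))
  dense_2d <- local({
    f <- function(ev, ec) {
      ind <- realize_individual(m2, typical_patient(),
                                eta = list(eta_V = ev, eta_CL = ec))
      cc <- concentration_profile(ind, reg, c(2, 24))
      prod(dnorm(c(13.1, 10.2), cc, m2$sigma_prop * cc)) *
        dnorm(ev, 0, m2$omega_V) * dnorm(ec, 0, m2$omega_CL)
    }
    gv <- seq(-3.5, 3.5, length.out = 301)
    gc <- seq(-2, 2, length.out = 301)
    tot <- 0
    for (ev in gv) tot <- tot + sum(vapply(gc, function(ec) f(ev, ec),
                                           numeric(1)))
    -2 * log(tot * diff(gv)[1] * diff(gc)[1])
  })
  expect_equal(ofv(m2, ds2, method = "agq", n_nodes = 31), dense_2d,
               tolerance = 1e-3)
})

test_that("noise-free data with variances fixed at zero recovers the fixed
           effects to at least four significant digits", {
  gen <- det_model(theta_V = 31, theta_CL = 0.45, F_oral = 0.9)
  spec <- cohort_spec(n_patients = 12)
  ds <- simulate_tdm_dataset(spec, gen, seed = 6)
  # sigma is fixed near zero so the marginal-likelihood optimum coincides
  # with the deterministic least-squares limit (with proportional error the
  # ML optimum sits a relative sigma^2 below the data)
  fit <- fit_population(ds, list(
    fix = list(omega_V = 0, omega_CL = 0, gamma_CL = 0, sigma_prop = 0.005),
    med_IBW = 68.8))
  co <- coef(fit)
  expect_equal(unname(co["theta_V"]), 31, tolerance = 1e-4)
  expect_equal(unname(co["theta_CL"]), 0.45, tolerance = 1e-4)
  expect_equal(unname(co["F"]), 0.9, tolerance = 1e-4)
})

test_that("fitting is deterministic and invariant to patient ordering", {
  ds <- simulate_tdm_dataset(cohort_spec(n_patients = 10),
                             population_model(), seed = 8)
  cfg <- list(saem_burn = 120L, saem_iter = 80L, saem_mh = 2L)
  f1 <- fit_population(ds, cfg)
  f2 <- fit_population(ds, cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$ofv, f2$ofv)
  df <- as.data.frame(ds)
  shuffled <- do.call(rbind, rev(split(df, df$ID)))
  f3 <- fit_population(as_tdm_dataset(shuffled), cfg)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-10)
})

test_that("estimating F from oral-only data is refused as non-identifiable", {
  reg <- regimen(c(0, 12), c(200, 200), "oral")
  ds <- as_tdm_dataset(event_df(1, reg, 24, 15, ibw = 68.8))
  expect_error(fit_population(ds), "identifiable")
})

test_that("MAP estimation: prior mode without data, near-exact recovery from
           noise-free troughs, and shrinkage", {
  m <- population_model()
  pat <- typical_patient(70)
  ind0 <- map_individual(m, pat, NULL)
  expect_equal(ind0$eta_V, 0)
  expect_equal(ind0$eta_CL, 0)
  expect_equal(ind0$V_i, covariate_scale(m, 70)$V_typ)

  # a known individual sampled at an informative peak/trough pair
  m2 <- population_model(gamma_CL = 0, sigma_prop = 1e-3)
  truth <- realize_individual(m2, pat, seed = 42)
  reg <- regimen(0, 1000, "iv")
  cvals <- concentration_profile(truth, reg, c(1, 24))
  ds <- as_tdm_dataset(event_df(1, reg, c(1, 24), cvals, occ = 1:2,
                                ibw = 70))
  mp <- map_individual(m2, pat, ds)
  expect_lt(abs(mp$V_i / truth$V_i - 1), 0.01)
  expect_lt(abs(mp$CL_i_by_occasion[1] / truth$CL_i_by_occasion[1] - 1),
            0.01)

  # with realistic noise the MAP deviate is shrunk relative to the
  # unpenalized (flat-prior) fit
  m3 <- population_model(gamma_CL = 0)
  yobs <- cvals * c(1.2, 1.25)
  ds3 <- as_tdm_dataset(event_df(1, reg, c(1, 24), yobs, occ = 1:2,
                                 ibw = 70))
  mp3 <- map_individual(m3, pat, ds3)
  flat <- m3
  flat$omega_V <- 50
  flat$omega_CL <- 50
  mp_flat <- map_individual(flat, pat, ds3)
  expect_lt(abs(mp3$eta_V), abs(mp_flat$eta_V) + 1e-8)
  expect_lt(abs(mp3$eta_CL), abs(mp_flat$eta_CL) + 1e-8)
})

test_that("bootstrap-based uncertainty brackets the generating values", {
  m <- population_model()
  ds <- simulate_tdm_dataset(cohort_spec(n_patients = 25), m, seed = 18)
  fit <- fit_population(ds, list(compute_rse = TRUE, rse_boot = 12L,
                                 saem_burn = 200L, saem_iter = 120L,
                                 saem_mh = 3L))
  co <- fit$coefficients
  expect_true(all(is.finite(co$rse)) && all(co$rse > 0))
  expect_true(all(co$lo95 <= co$estimate & co$estimate <= co$hi95))
  truth <- c(F = 0.96, theta_V = 34.3, theta_CL = 0.38, omega_V = 0.71,
             omega_CL = 0.40, gamma_CL = 0.36, sigma_prop = 0.082)
  inside <- truth[co$parameter] >= co$lo95 & truth[co$parameter] <= co$hi95
  expect_gte(sum(inside), 5L)
})

test_that("stepwise selection honors the 3.84 / 10.83 thresholds exactly", {
  mk_stub <- function(fwd_drop, bwd_raise) {
    # one candidate X: forward delta = fwd_drop, backward raise = bwd_raise
    function(dataset, covariates, config) {
      has_x <- any(vapply(covariates, function(e) e$cov == "X", logical(1)))
      list(ofv = if (has_x) 100 - fwd_drop else 100)
    }
  }
  cand <- list(covariate_effect("X", "CL", "power"))
  run <- function(drop) {
    st <- stepwise_covariates(data.frame(), cand,
                              config = list(fit_fun = mk_stub(drop, drop)))
    list(steps = st, kept = length(attr(st, "selected")) > 0)
  }
  expect_false(run(3.83)$kept)                       # below forward cut
  expect_false(run(3.84)$kept)                       # included, removed
  st384 <- run(3.84)$steps
  expect_equal(st384$decision, c("included", "removed"))
  expect_true(run(10.84)$kept)                       # survives backward
  st1083 <- run(10.83)$steps
  expect_equal(st1083$decision[2], "removed")        # 10.83 is not > 10.83
  # empty candidate list
  empty <- stepwise_covariates(data.frame(), list())
  expect_equal(nrow(empty), 0L)
})

test_that("forward inclusion is greedy on the largest OFV drop", {
  stub <- function(dataset, covariates, config) {
    key <- paste(sort(vapply(covariates, function(e) e$cov, character(1))),
                 collapse = "+")
    ofvs <- c(100, 80, 90, 66)
    names(ofvs) <- c("base", "A", "B", "A+B")
    list(ofv = unname(ofvs[if (key == "") "base" else key]))
  }
  cands <- list(covariate_effect("A", "CL", "power"),
                covariate_effect("B", "V", "power"))
  st <- stepwise_covariates(data.frame(), cands, config = list(fit_fun = stub))
  fwd <- st[st$stage == "forward" & st$decision == "included", ]
  expect_equal(fwd$cov[1], "A")    # drop of 20 beats 10
  sel <- vapply(attr(st, "selected"), `[[`, character(1), "cov")
  expect_setequal(sel, c("A", "B"))
})

test_that("bootstrap reproduces the original fit under a forced identity
           resample and keeps percentile order", {
  ds <- simulate_tdm_dataset(cohort_spec(n_patients = 8),
                             population_model(), seed = 14)
  cfg <- list(saem_burn = 100L, saem_iter = 60L, saem_mh = 2L)
  orig <- fit_population(ds, cfg)
  ids <- unique(ds$ID)
  bt <- bootstrap_fit(ds, cfg, n_reps = 1, resample_ids = list(ids))
  expect_equal(bt$summary$median, unname(coef(orig)), tolerance = 1e-10)
  bt3 <- bootstrap_fit(ds, cfg, n_reps = 3, seed = 5)
  expect_true(all(bt3$summary$lo95 <= bt3$summary$median + 1e-12))
  expect_true(all(bt3$summary$median <= bt3$summary$hi95 + 1e-12))
  expect_equal(bt3$n_failed, 0L)
})

test_that("diagnostics: identity line on deterministic data and calibrated
           predictive bands on well-specified data", {
  gen <- det_model()
  ds0 <- simulate_tdm_dataset(cohort_spec(n_patients = 6), gen, seed = 4)
  fit0 <- fit_population(ds0, list(
    fix = list(omega_V = 0, omega_CL = 0, gamma_CL = 0, sigma_prop = 0.005),
    med_IBW = 68.8))
  dg0 <- diagnostics(fit0, ds0, n_sim = 10, seed = 1)
  expect_equal(dg0$gof$PRED, dg0$gof$DV, tolerance = 5e-3)
  expect_equal(dg0$gof$IPRED, dg0$gof$DV, tolerance = 5e-3)

  ds <- simulate_tdm_dataset(cohort_spec(n_patients = 25),
                             population_model(), seed = 5)
  fit <- fit_population(ds, list(saem_burn = 200L, saem_iter = 120L,
                                 saem_mh = 3L))
  dg <- diagnostics(fit, ds, n_sim = 80, n_bins = 5, seed = 2)
  slope <- unname(coef(lm(DV ~ IPRED, data = dg$gof))[2])
  expect_equal(slope, 1, tolerance = 0.1)
  inside <- with(dg$vpc, obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi)
  expect_gte(sum(inside), 4L)   # observed medians inside simulated bands
})
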