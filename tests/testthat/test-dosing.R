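test_that("target attainment fractions are coherent probabilities", {
  m <- population_model()
  r0 <- simulate_pta(m, 70, 0, "iv", "loading", n_sim = 500, seed = 1)
  expect_equal(r0$pta, 0)                 # no drug, trough below the window
  expect_equal(r0$below, 1)
  wide <- target_window(1e-9, 1e9, 1e10)
  r1 <- simulate_pta(m, 70, 500, "iv", "loading", n_sim = 500, seed = 1,
                     target = wide)
  expect_equal(r1$pta, 1)                 # any positive dose attains (0, Inf)
  r <- simulate_pta(m, 60, 1000, "oral", "loading", n_sim = 2000, seed = 3)
  expect_equal(r$pta + r$toxic + r$below + r$above, 1)
  expect_true(all(c(r$pta, r$toxic, r$below, r$above) >= 0))
})

test_that("zero-variability attainment is the indicator of the
           deterministic trough", {
  m0 <- det_model()
  tw <- target_window()
  for (dose in c(50, 150, 300, 500)) {
    sim <- simulate_pta(m0, 70, dose, "oral", "maintenance", schedule_h = 12,
                        n_sim = 10, seed = 1, loading_dose = 1100,
                        loading_route = "oral")
    cmin <- superposition_cmin(m0, 70, 1100, dose, "oral", 12, 336)
    expect_equal(sim$pta,
                 as.numeric(cmin >= tw$lower & cmin <= tw$upper))
    expect_equal(sim$cmin[1], cmin, tolerance = 1e-8)
  }
})

test_that("grid optimization is deterministic, honors single-point grids and
           breaks ties toward the lowest dose", {
  m <- population_model()
  o1 <- optimize_dose(m, 70, "iv", "loading", grid = 700, n_sim = 200,
                      seed = 2)
  expect_equal(o1$optimal_dose, 700)
  o2 <- optimize_dose(m, 70, "iv", "loading", grid = seq(800, 1400, 200),
                      n_sim = 2000, seed = 5)
  o3 <- optimize_dose(m, 70, "iv", "loading", grid = seq(800, 1400, 200),
                      n_sim = 2000, seed = 5)
  expect_identical(o2$grid, o3$grid)
  expect_identical(o2$optimal_dose, o3$optimal_dose)
  # deterministic model, very wide window: every dose attains, lowest wins
  m0 <- det_model()
  o4 <- optimize_dose(m0, 70, "iv", "loading", grid = seq(600, 1200, 200),
                      n_sim = 5, seed = 1,
                      target = target_window(0.1, 500, 600))
  expect_equal(o4$optimal_dose, 600)
  expect_true(all(o4$grid$pta == 1))
})

test_that("the dosing table refuses extrapolation and is monotone under the
           deterministic model", {
  m <- population_model()
  expect_error(dosing_table(m, ibw_list = c(50, 60)), "range")
  expect_error(dosing_table(m, ibw_list = 90), "range")
  m0 <- det_model()
  tab <- dosing_table(m0, c(55, 65, 75), n_sim_loading = 5,
                      n_sim_maintenance = 5, seed = 1)
  expect_true(all(diff(tab$loading_iv) >= 0))
  expect_true(all(diff(tab$maintenance_iv) >= 0))
  # deterministic optimum matches a closed-form grid search on the trough
  tw <- target_window()
  grid <- seq(50, 500, 50)
  for (i in seq_len(nrow(tab))) {
    cmins <- vapply(grid, function(d)
      superposition_cmin(m0, tab$ibw[i], tab$loading_iv[i], d, "iv", 12, 336),
      numeric(1))
    inside <- cmins >= tw$lower & cmins <= tw$upper
    expect_equal(tab$maintenance_iv[i], min(grid[inside]))
  }
})

test_that("24-h dosing shows at least the peak-trough fluctuation of 12-h
           dosing, matching the closed-form ratio without variability", {
  m <- population_model()
  cmp <- compare_schedules(m, 70, route = "oral", n_sim = 1200, seed = 7)
  expect_equal(cmp$schedule_h, c(12, 24))
  expect_gte(cmp$fluctuation[2], cmp$fluctuation[1])
  expect_gte(cmp$loading[2], cmp$loading[1])

  m0 <- det_model()
  cmp0 <- compare_schedules(m0, 70, route = "oral", n_sim = 3, seed = 1)
  typ <- covariate_scale(m0, 70)
  ke <- typ$CL_typ / typ$V_typ
  css <- function(t, tau) {  # steady-state oral profile, arbitrary dose scale
    m0$ka / (m0$ka - ke) *
      (exp(-ke * t) / (1 - exp(-ke * tau)) -
       exp(-m0$ka * t) / (1 - exp(-m0$ka * tau)))
  }
  for (k in 1:2) {
    tau <- cmp0$schedule_h[k]
    prof <- vapply(seq(0, tau, length.out = 25), css, numeric(1), tau = tau)
    expect_equal(cmp0$fluctuation[k], max(prof) / min(prof),
                 tolerance = 0.02)
  }
})

test_that("replicate attainment estimates agree within Monte Carlo error", {
  m <- population_model()
  p1 <- simulate_pta(m, 70, 1100, "iv", "loading", n_sim = 20000,
                     seed = 101)$pta
  p2 <- simulate_pta(m, 70, 1100, "iv", "loading", n_sim = 20000,
                     seed = 202)$pta
  expect_lt(abs(p1 - p2), 0.015)   # ~3 binomial SDs at n = 2e4
})

test_that("individual dose recommendation follows the MAP clearance", {
  m <- population_model()
  pat <- typical_patient(70)
  typical <- map_individual(m, pat, NULL)
  rec <- recommend_individual_dose(m, typical, route = "oral")
  expect_equal(rec$dose, 150)      # the population optimum for 70 kg
  expect_true(rec$in_window)
  # doubling clearance doubles the recommended dose (nearest grid step)
  fast <- realize_individual(m, pat, eta = list(eta_CL = log(2)))
  rec2 <- recommend_individual_dose(m, fast, route = "oral")
  expect_equal(rec2$dose, 300)
  # unreachable window: nearest achievable dose, flagged
  slow <- realize_individual(m, pat, eta = list(eta_CL = -3))
  rec3 <- recommend_individual_dose(m, slow, route = "oral",
                                    grid = seq(50, 500, 50))
  expect_false(rec3$in_window)
  expect_equal(rec3$dose, 50)
})
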