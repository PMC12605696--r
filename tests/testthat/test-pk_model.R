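test_that("ideal body weight follows the Brower formula", {
  expect_equal(ideal_body_weight("male", 152.4), 50)
  expect_equal(ideal_body_weight("female", 152.4), 45.5)
  expect_equal(ideal_body_weight("male", 173), 50 + 0.91 * 20.6)
  expect_equal(ideal_body_weight(c("male", "female"), c(180, 160)),
               c(50 + 0.91 * 27.6, 45.5 + 0.91 * 7.6))
  # very short patients are clamped at the configurable floor
  expect_equal(ideal_body_weight("female", 100, floor_kg = 30), 30)
  expect_error(ideal_body_weight("other", 170), "male")
  expect_error(ideal_body_weight("male", -1), "positive")
})

test_that("allometric covariate scaling is centered at the median IBW", {
  m <- population_model()
  at_med <- covariate_scale(m, 68.8)
  expect_equal(at_med$V_typ, 34.3)
  expect_equal(at_med$CL_typ, 0.38)
  # exponent 1 on V: doubling IBW doubles volume
  expect_equal(covariate_scale(m, 2 * 68.8)$V_typ, 68.6)
  sc <- covariate_scale(m, 55)
  expect_equal(sc$V_typ, 27.42006, tolerance = 1e-6)
  expect_equal(sc$CL_typ, 0.3212656, tolerance = 1e-6)
  expect_error(covariate_scale(m, 0), "positive")
})

test_that("half-life arithmetic", {
  expect_equal(half_life(1, log(2)), 1)
  expect_equal(half_life(34.3, 0.76), half_life(34.3, 0.38) / 2)
  expect_error(half_life(-1, 1), "positive")
})

test_that("individual realization reduces to the typical patient without
           variability and is seed-reproducible", {
  m0 <- det_model()
  ind <- realize_individual(m0, typical_patient(55), n_occasions = 5)
  sc <- covariate_scale(m0, 55)
  expect_equal(ind$V_i, sc$V_typ)
  expect_equal(ind$CL_i_by_occasion, rep(sc$CL_typ, 5))
  # IOV collapse: gamma 0 gives identical clearance across occasions
  m1 <- population_model(gamma_CL = 0)
  ind1 <- realize_individual(m1, typical_patient(), n_occasions = 5, seed = 3)
  expect_length(unique(ind1$CL_i_by_occasion), 1L)
  # bit-reproducible under a fixed seed
  a <- realize_individual(population_model(), typical_patient(), 4, seed = 9)
  b <- realize_individual(population_model(), typical_patient(), 4, seed = 9)
  expect_identical(a, b)
})

test_that("sampled interindividual deviates have the nominal lognormal SD", {
  m <- population_model()
  set.seed(21)
  logs <- replicate(30000,
    log(realize_individual(m, typical_patient())$V_i))
  expect_equal(sd(logs), 0.71, tolerance = 0.015)
  expect_equal(mean(logs), log(34.3), tolerance = 0.02)
})

test_that("concentration profile matches closed forms for single doses", {
  m0 <- det_model()
  ind <- realize_individual(m0, typical_patient())
  # nothing in the system before the first dose
  expect_equal(concentration_profile(ind, regimen(10, 200, "oral"),
                                     c(0, 5, 9.99)), c(0, 0, 0))
  # single oral dose at the one-compartment closed form
  co <- concentration_profile(ind, regimen(0, 200, "oral"), c(12, 24))
  expect_equal(co, oral_closed_form(0.96, 200, 1.9, 34.3, 0.38, c(12, 24)),
               tolerance = 1e-10)
  expect_equal(co[1], 4.9296, tolerance = 1e-4)
  # end of a 5-min 1100 mg infusion at the zero-order input closed form
  ke <- 0.38 / 34.3
  civ <- concentration_profile(ind, regimen(0, 1100, "iv"), 1 / 12)
  expect_equal(civ, (1100 * 12) / 0.38 * (1 - exp(-ke / 12)),
               tolerance = 1e-10)
  expect_equal(civ, 32.055, tolerance = 1e-3)
})

test_that("profile is linear in dose amounts and merges simultaneous doses", {
  m0 <- det_model()
  ind <- realize_individual(m0, typical_patient(60), n_occasions = 3,
                            occasion_boundaries = c(24, 60))
  tt <- c(2, 12, 30, 70)
  r1 <- regimen(c(0, 12, 24), c(500, 150, 200), c("iv", "oral", "oral"))
  c1 <- concentration_profile(ind, r1, tt)
  r2 <- regimen(c(0, 12, 24), 2 * c(500, 150, 200), c("iv", "oral", "oral"))
  expect_equal(concentration_profile(ind, r2, tt), 2 * c1, tolerance = 1e-12)
  # two 100 mg oral doses at the same time behave as one 200 mg dose
  rm1 <- regimen(c(0, 0), c(100, 100), "oral")
  expect_equal(nrow(rm1), 1L)
  expect_equal(rm1$amount, 200)
})

test_that("mass is conserved when clearance is zero", {
  m0 <- det_model(theta_CL = 1e-30)  # effectively no elimination
  ind <- realize_individual(m0, typical_patient())
  reg <- regimen(c(0, 12, 24), c(400, 200, 300), c("oral", "iv", "oral"))
  conc <- concentration_profile(ind, reg, 2000)
  delivered <- 0.96 * (400 + 300) + 200
  expect_equal(conc * ind$V_i, delivered, tolerance = 1e-6)
})

test_that("profile is continuous across occasion boundaries and infusion
           ends, and troughs are evaluated pre-dose", {
  m <- population_model()
  ind <- realize_individual(m, typical_patient(), n_occasions = 3,
                            occasion_boundaries = c(48, 96), seed = 5)
  reg <- regimen(c(0, 12, 24, 48), c(1000, 150, 150, 150),
                 c("iv", "oral", "oral", "iv"))
  eps <- 1e-8
  around <- function(t) concentration_profile(ind, reg, c(t - eps, t + eps))
  for (t in c(48 - 1e-3, 96, 1 / 12)) {  # boundary & infusion end
    cc <- around(t)
    expect_equal(cc[1], cc[2], tolerance = 1e-6)
  }
  # a dose scheduled at the requested time does not contribute (pre-dose)
  with_dose <- concentration_profile(ind, reg, 48)
  without <- concentration_profile(ind, reg[reg$time < 48, ], 48)
  expect_equal(with_dose, without, tolerance = 1e-12)
})

test_that("input validation rejects unsorted or negative times", {
  ind <- realize_individual(det_model(), typical_patient())
  reg <- regimen(0, 100, "oral")
  expect_error(concentration_profile(ind, reg, c(5, 2)), "sorted")
  expect_error(concentration_profile(ind, reg, -1), "non-negative")
  bad <- data.frame(time = c(10, 0), amount = c(1, 1), route = "oral",
                    dur = 0)
  expect_error(concentration_profile(ind, bad, 1), "sorted")
})

test_that("analytic engine agrees with adaptive ODE integration on random
           mixed-route regimens", {
  skip_if_not_installed("deSolve")
  set.seed(77)
  worst <- 0
  for (k in 1:12) {
    cs <- random_regimen_case()
    a <- concentration_profile(cs$ind, cs$reg, cs$times)
    b <- ode_profile(cs$ind, cs$reg, cs$times)
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-6)
})
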