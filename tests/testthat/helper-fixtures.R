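# Shared fixtures: all data are built in code at test time.

# Deterministic model without random effects or residual error; any
# component can still be overridden.
det_model <- function(...) {
  args <- utils::modifyList(list(omega_V = 0, omega_CL = 0, gamma_CL = 0,
                                 sigma_prop = 0), list(...))
  do.call(population_model, args)
}

typical_patient <- function(ibw = 68.8) patient(1, "male", ibw = ibw)

# Event-record data.frame for one patient from a regimen plus observations.
event_df <- function(id, reg, obs_t, dv, occ = seq_along(obs_t),
                     sex = "male", ht = 173, tbw = 78.5,
                     ibw = ideal_body_weight(sex, ht), mdv = 0L, flag = "") {
  doses <- data.frame(ID = id, TIME = reg$time, EVID = 1L, AMT = reg$amount,
                      ROUTE = reg$route, DUR = reg$dur, DV = NA_real_,
                      MDV = 1L, OCC = 1L, FLAG = "", SEX = sex, HT = ht,
                      TBW = tbw, IBW = ibw, stringsAsFactors = FALSE)
  obs <- if (length(obs_t)) data.frame(ID = id, TIME = obs_t, EVID = 0L,
                                       AMT = NA_real_, ROUTE = "",
                                       DUR = NA_real_, DV = dv, MDV = mdv,
                                       OCC = occ, FLAG = flag, SEX = sex,
                                       HT = ht, TBW = tbw, IBW = ibw,
                                       stringsAsFactors = FALSE) else NULL
  out <- rbind(doses, obs)
  out[order(out$TIME, out$EVID), ]
}

# Numeric ODE oracle: adaptive lsoda integration of the gut/central system,
# segment-by-segment across dose events, infusion ends and occasion
# boundaries, independent of the package's analytic propagation.
ode_profile <- function(realization, doses, times) {
  ka <- realization$ka
  F_oral <- realization$F_oral
  V <- realization$V_i
  CL_occ <- realization$CL_i_by_occasion
  occ_b <- realization$occasion_boundaries
  inf_end <- doses$time + ifelse(doses$route == "iv", doses$dur, 0)
  bp <- sort(unique(c(0, doses$time, inf_end[doses$route == "iv"], occ_b,
                      times)))
  state <- c(gut = 0, central = 0)
  out <- numeric(length(times))
  t_cur <- 0
  record <- function(t, state) {
    hit <- which(abs(times - t) < 1e-9)
    if (length(hit)) out[hit] <<- state[["central"]] / V
  }
  record(0, state)
  for (t1 in bp[bp > 1e-12]) {
    if (t1 - t_cur < 1e-9) next
    occ <- min(sum(occ_b < t1 - 1e-9) + 1, length(CL_occ))
    ke <- CL_occ[occ] / V
    R <- sum(doses$amount[doses$route == "iv" & doses$time <= t_cur + 1e-9 &
                          inf_end >= t1 - 1e-9] /
             doses$dur[doses$route == "iv" & doses$time <= t_cur + 1e-9 &
                       inf_end >= t1 - 1e-9])
    rhs <- function(t, y, p) list(c(-ka * y[1], ka * y[1] + R - ke * y[2]))
    sol <- deSolve::lsoda(state, c(t_cur, t1), rhs, NULL,
                          rtol = 1e-11, atol = 1e-11)
    state <- c(gut = unname(sol[nrow(sol), 2]),
               central = unname(sol[nrow(sol), 3]))
    record(t1, state)   # pre-dose at t1
    bolus <- doses$route == "oral" & abs(doses$time - t1) < 1e-9
    if (any(bolus)) state[["gut"]] <- state[["gut"]] +
        F_oral * sum(doses$amount[bolus])
    t_cur <- t1
  }
  out
}

# Random mixed-route regimen with occasion-varying clearance for oracle
# equivalence testing; draws use the current RNG stream.
random_regimen_case <- function(model = population_model()) {
  n_d <- sample(1:20, 1)
  dt <- sort(round(runif(n_d, 0, 200), 3))
  reg <- regimen(time = dt, amount = round(runif(n_d, 50, 1500)),
                 route = sample(c("oral", "iv"), n_d, replace = TRUE),
                 dur = 1 / 12)
  n_occ <- sample(1:5, 1)
  ob <- sort(runif(max(n_occ - 1, 0), 1, 220))
  ind <- realize_individual(model, typical_patient(runif(1, 55, 85)),
                            n_occasions = n_occ, occasion_boundaries = ob)
  times <- sort(c(runif(8, 0, 240), dt[1] + 1e-4))
  list(ind = ind, reg = reg, times = times)
}

# Closed-form concentration after a single oral dose (one-compartment,
# first-order absorption) -- independent arithmetic for engine checks.
oral_closed_form <- function(F_oral, D, ka, V, CL, t) {
  ke <- CL / V
  F_oral * D * ka / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# Closed-form trough at t_eval for a loading dose plus q-tau maintenance
# regimen, by superposition of single-dose solutions (oral) or infusion
# solutions (iv).
superposition_cmin <- function(model, ibw, loading, maintenance, route,
                               tau, t_eval) {
  typ <- covariate_scale(model, ibw)
  ke <- typ$CL_typ / typ$V_typ
  one <- function(D, t) {
    if (t <= 0) return(0)
    if (route == "oral") {
      oral_closed_form(model$F_oral, D, model$ka, typ$V_typ, typ$CL_typ, t)
    } else {
      dur <- 1 / 12
      R0 <- D / dur
      if (t <= dur) R0 / typ$CL_typ * (1 - exp(-ke * t))
      else R0 / typ$CL_typ * (1 - exp(-ke * dur)) * exp(-ke * (t - dur))
    }
  }
  dose_t <- c(0, seq(tau, t_eval, by = tau))
  amts <- c(loading, rep(maintenance, length(dose_t) - 1))
  sum(mapply(function(D, td) one(D, t_eval - td), amts, dose_t))
}
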