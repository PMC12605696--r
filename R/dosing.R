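#' Therapeutic target window
#'
#' Trough concentrations of 18-40 mg/L are targeted for seizure control in
#' superrefractory status epilepticus; concentrations above 70 mg/L are
#' associated with toxicity.
#'
#' @param lower,upper Target bounds (mg/L).
#' @param toxic Toxicity threshold (mg/L).
#' @return A `target_window` list.
#' @export
target_window <- function(lower = 18, upper = 40, toxic = 70) {
  stopifnot(0 < lower, lower < upper, upper < toxic)
  structure(list(lower = lower, upper = upper, toxic = toxic),
            class = "target_window")
}

# Shared regimen construction for the two simulation phases. Loading:
# a single dose at t = 0, trough read at t = schedule_h. Maintenance: the
# loading dose at t = 0 then maintenance doses every schedule_h from
# t = schedule_h, trough read pre-dose at t = 336 h (steady state, about
# five half-lives).
pta_design <- function(dose, route, phase, schedule_h, loading_dose,
                       loading_route, eval_h, infusion_dur) {
  if (phase == "loading") {
    eval_h <- eval_h %||% schedule_h
    reg <- regimen(time = 0, amount = dose, route = route, dur = infusion_dur)
  } else {
    eval_h <- eval_h %||% 336
    if (is.null(loading_dose))
      stop("maintenance simulations need a loading_dose", call. = FALSE)
    mt <- seq(schedule_h, eval_h, by = schedule_h)
    reg <- regimen(time = c(0, mt),
                   amount = c(loading_dose, rep(dose, length(mt))),
                   route = c(loading_route, rep(route, length(mt))),
                   dur = infusion_dur, schedule_h = schedule_h)
  }
  list(regimen = reg, eval_h = eval_h)
}

#' Monte Carlo trough simulation and probability of target attainment
#'
#' Draws `n_sim` virtual patients at the given ideal body weight from the
#' population model — lognormal interindividual variability on V and CL and
#' interoccasion variability on CL redrawn every 48 h, with no residual
#' (assay) error, so the attainment probability describes true
#' concentrations — doses them, and reads the trough. For the loading phase
#' a single dose is given at t = 0 and the concentration is read at
#' t = `schedule_h`; for the maintenance phase the loading dose is followed
#' by maintenance doses every `schedule_h` h and the pre-dose trough is read
#' at t = 336 h.
#'
#' @param model A [population_model()].
#' @param ibw Ideal body weight (kg).
#' @param dose Dose amount (mg).
#' @param route `"iv"` or `"oral"`.
#' @param phase `"loading"` or `"maintenance"`.
#' @param schedule_h Dosing interval: 12 or 24 h.
#' @param n_sim Number of virtual patients.
#' @param seed Integer seed.
#' @param target A [target_window()].
#' @param loading_dose,loading_route Initial dose for the maintenance phase.
#' @param eval_h Override of the trough read-out time (h).
#' @param iov_window_h Occasion length for interoccasion redraws (h).
#' @param infusion_dur IV infusion duration (h); default 5 min.
#' @return A list with `pta`, `toxic`, `below`, `above` (fractions summing
#'   to 1 with `pta`), `cmin` (the simulated troughs), and the design.
#' @export
simulate_pta <- function(model, ibw, dose, route = c("iv", "oral"),
                         phase = c("loading", "maintenance"), schedule_h = 12,
                         n_sim = 10000, seed = 1L, target = target_window(),
                         loading_dose = NULL, loading_route = NULL,
                         eval_h = NULL, iov_window_h = 48,
                         infusion_dur = 1 / 12) {
  route <- match.arg(route)
  phase <- match.arg(phase)
  stopifnot(dose >= 0, schedule_h %in% c(12, 24), n_sim >= 1)
  loading_route <- loading_route %||% route
  des <- pta_design(dose, route, phase, schedule_h, loading_dose,
                    loading_route, eval_h, infusion_dur)
  typ <- covariate_scale(model, ibw)
  n_occ <- max(ceiling(des$eval_h / iov_window_h), 1)
  occ_b <- iov_window_h * seq_len(n_occ - 1)
  cmin <- with_seed(seed, {
    eta_V <- rnorm(n_sim, 0, model$omega_V)
    eta_CL <- rnorm(n_sim, 0, model$omega_CL)
    kappa <- matrix(rnorm(n_sim * n_occ, 0, model$gamma_CL), n_sim, n_occ)
    Vs <- typ$V_typ * exp(eta_V)
    CLm <- typ$CL_typ * exp(eta_CL + kappa)
    reg <- des$regimen
    as.numeric(cpp_profile_multi(Vs, CLm, occ_b, model$ka, model$F_oral,
                                 reg$time, reg$amount,
                                 as.integer(reg$route == "oral"),
                                 pmax(reg$dur, 1e-12), des$eval_h))
  })
  list(pta = mean(cmin >= target$lower & cmin <= target$upper),
       toxic = mean(cmin > target$toxic),
       below = mean(cmin < target$lower),
       above = mean(cmin > target$upper & cmin <= target$toxic),
       cmin = cmin, dose = dose, route = route, phase = phase,
       schedule_h = schedule_h, eval_h = des$eval_h, ibw = ibw,
       n_sim = n_sim, seed = seed)
}

#' Optimal dose by grid search
#'
#' Runs [simulate_pta()] for every dose on the grid (each with an
#' independently derived sub-seed) and returns the dose maximizing the
#' probability of target attainment; ties break toward the lowest dose.
#'
#' @inheritParams simulate_pta
#' @param grid Candidate doses (mg).
#' @return A `pta_result`: list with `optimal_dose`, the per-dose `grid`
#'   data.frame (dose, pta, toxic, below, above), and the design fields.
#' @export
optimize_dose <- function(model, ibw, route = c("iv", "oral"),
                          phase = c("loading", "maintenance"),
                          grid = seq(100, 2500, by = 100), schedule_h = 12,
                          n_sim = 10000, seed = 1L, target = target_window(),
                          loading_dose = NULL, loading_route = NULL, ...) {
  route <- match.arg(route)
  phase <- match.arg(phase)
  stopifnot(length(grid) >= 1)
  seeds <- derive_seeds(seed, length(grid))
  cells <- lapply(seq_along(grid), function(i)
    simulate_pta(model, ibw, grid[i], route, phase, schedule_h, n_sim,
                 seed = seeds[i], target = target, loading_dose = loading_dose,
                 loading_route = loading_route, ...))
  tab <- data.frame(dose = grid,
                    pta = vapply(cells, `[[`, numeric(1), "pta"),
                    toxic = vapply(cells, `[[`, numeric(1), "toxic"),
                    below = vapply(cells, `[[`, numeric(1), "below"),
                    above = vapply(cells, `[[`, numeric(1), "above"))
  best <- which.max(tab$pta)  # which.max takes the first (lowest-dose) tie
  structure(list(optimal_dose = grid[best], pta = tab$pta[best],
                 grid = tab, ibw = ibw, route = route, phase = phase,
                 schedule_h = schedule_h, n_sim = n_sim, seed = seed),
            class = "pta_result")
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf("PTA grid (%s %s, IBW %g kg, q%gh, n_sim %d): optimal %g mg (PTA %.3f)\n",
              x$route, x$phase, x$ibw, x$schedule_h, x$n_sim,
              x$optimal_dose, x$pta))
  invisible(x)
}

#' Optimal dosing table across ideal body weights
#'
#' For each IBW, selects the optimal intravenous and oral loading dose
#' (trough at t = `schedule_h` after a single dose) and then the optimal
#' maintenance dose per route, with the route-matched optimal loading dose
#' applied as the initial dose of the maintenance simulations. IBWs outside
#' the supported 52.4-82.4 kg cohort range are refused rather than
#' extrapolated.
#'
#' @inheritParams simulate_pta
#' @param ibw_list IBWs (kg) to tabulate.
#' @param loading_grid,maintenance_grid Dose grids (mg).
#' @param n_sim_loading,n_sim_maintenance Simulations per grid cell.
#' @param ibw_range Supported IBW range (kg).
#' @return A data.frame (`ibw`, `loading_iv`, `loading_oral`,
#'   `maintenance_iv`, `maintenance_oral`) with the full per-cell PTA grids
#'   in attribute `details`.
#' @export
dosing_table <- function(model, ibw_list = seq(55, 80, by = 5),
                         loading_grid = seq(100, 2500, by = 100),
                         maintenance_grid = seq(50, 500, by = 50),
                         schedule_h = 12, n_sim_loading = 10000,
                         n_sim_maintenance = 10000, seed = 1L,
                         target = target_window(),
                         ibw_range = c(52.4, 82.4)) {
  if (any(ibw_list < ibw_range[1] | ibw_list > ibw_range[2]))
    stop("IBW outside the supported range ", ibw_range[1], "-", ibw_range[2],
         " kg; extrapolation is not supported", call. = FALSE)
  seeds <- derive_seeds(seed, 4 * length(ibw_list))
  details <- list()
  rows <- lapply(seq_along(ibw_list), function(i) {
    ibw <- ibw_list[i]
    s <- seeds[(4 * i - 3):(4 * i)]
    ld_iv <- optimize_dose(model, ibw, "iv", "loading", loading_grid,
                           schedule_h, n_sim_loading, s[1], target)
    ld_po <- optimize_dose(model, ibw, "oral", "loading", loading_grid,
                           schedule_h, n_sim_loading, s[2], target)
    mt_iv <- optimize_dose(model, ibw, "iv", "maintenance", maintenance_grid,
                           schedule_h, n_sim_maintenance, s[3], target,
                           loading_dose = ld_iv$optimal_dose,
                           loading_route = "iv")
    mt_po <- optimize_dose(model, ibw, "oral", "maintenance", maintenance_grid,
                           schedule_h, n_sim_maintenance, s[4], target,
                           loading_dose = ld_po$optimal_dose,
                           loading_route = "oral")
    details[[as.character(ibw)]] <<- list(loading_iv = ld_iv,
                                          loading_oral = ld_po,
                                          maintenance_iv = mt_iv,
                                          maintenance_oral = mt_po)
    data.frame(ibw = ibw, loading_iv = ld_iv$optimal_dose,
               loading_oral = ld_po$optimal_dose,
               maintenance_iv = mt_iv$optimal_dose,
               maintenance_oral = mt_po$optimal_dose)
  })
  structure(do.call(rbind, rows), details = details, schedule_h = schedule_h,
            class = c("dosing_table", "data.frame"))
}

#' Compare 12-h and 24-h dosing schedules
#'
#' Optimizes loading and maintenance doses under each schedule, simulates
#' the optimal regimen to steady state, and summarizes the peak-trough
#' fluctuation of the median concentration profile over the final dosing
#' interval together with the fraction of virtual patients whose
#' concentration exceeds the toxicity threshold there. Longer intervals need
#' larger doses and show larger swings.
#'
#' @inheritParams dosing_table
#' @param ibw Ideal body weight (kg).
#' @param route Administration route used for all doses.
#' @param schedules Schedules to compare (h).
#' @return A data.frame with one row per schedule: optimal doses, median
#'   peak and trough over the last interval, `fluctuation`
#'   (peak/trough ratio of the median profile) and `toxic_fraction`.
#' @export
compare_schedules <- function(model, ibw, route = "iv", n_sim = 2000,
                              seed = 1L, schedules = c(12, 24),
                              loading_grid = seq(100, 2500, by = 100),
                              maintenance_grid = seq(50, 500, by = 50),
                              target = target_window()) {
  seeds <- derive_seeds(seed, 2 * length(schedules))
  rows <- lapply(seq_along(schedules), function(k) {
    sch <- schedules[k]
    ld <- optimize_dose(model, ibw, route, "loading", loading_grid, sch,
                        n_sim, seeds[2 * k - 1], target)
    mt <- optimize_dose(model, ibw, route, "maintenance", maintenance_grid,
                        sch, n_sim, seeds[2 * k], target,
                        loading_dose = ld$optimal_dose, loading_route = route)
    prof <- simulate_profile(model, ibw, ld$optimal_dose, mt$optimal_dose,
                             route, sch, n_sim, seed = seeds[2 * k],
                             times = seq(336 - sch, 336, length.out = 25))
    med <- apply(prof, 2, median)
    peak_patient <- apply(prof, 1, max)
    data.frame(schedule_h = sch, loading = ld$optimal_dose,
               maintenance = mt$optimal_dose,
               median_peak = max(med), median_trough = min(med),
               fluctuation = max(med) / min(med),
               toxic_fraction = mean(peak_patient > target$toxic))
  })
  do.call(rbind, rows)
}

#' Simulate population concentration profiles for a regimen
#'
#' Virtual-patient concentration matrix (rows = patients) for a loading +
#' maintenance regimen; used for profile percentile plots and schedule
#' comparisons.
#'
#' @inheritParams simulate_pta
#' @param loading,maintenance Dose amounts (mg).
#' @param times Output times (h).
#' @return An `n_sim` x `length(times)` matrix of concentrations (mg/L).
#' @export
simulate_profile <- function(model, ibw, loading, maintenance, route = "iv",
                             schedule_h = 12, n_sim = 1000, seed = 1L,
                             times = seq(0, 336, by = 4), iov_window_h = 48,
                             infusion_dur = 1 / 12) {
  mt <- seq(schedule_h, max(times), by = schedule_h)
  reg <- regimen(time = c(0, mt),
                 amount = c(loading, rep(maintenance, length(mt))),
                 route = route, dur = infusion_dur, schedule_h = schedule_h)
  typ <- covariate_scale(model, ibw)
  n_occ <- max(ceiling(max(times) / iov_window_h), 1)
  occ_b <- iov_window_h * seq_len(n_occ - 1)
  with_seed(seed, {
    eta_V <- rnorm(n_sim, 0, model$omega_V)
    eta_CL <- rnorm(n_sim, 0, model$omega_CL)
    kappa <- matrix(rnorm(n_sim * n_occ, 0, model$gamma_CL), n_sim, n_occ)
    cpp_profile_multi(typ$V_typ * exp(eta_V),
                      typ$CL_typ * exp(eta_CL + kappa), occ_b, model$ka,
                      model$F_oral, reg$time, reg$amount,
                      as.integer(reg$route == "oral"),
                      pmax(reg$dur, 1e-12), times)
  })
}

#' Individualized maintenance dose recommendation
#'
#' Model-informed precision dosing: given a patient's MAP realization (from
#' [map_individual()]; with no TDM data this is the covariate-scaled typical
#' patient), selects the grid dose whose predicted individual steady-state
#' trough lies inside the target window and closest to its midpoint.
#' Interoccasion deviates are not projected forward — the individual
#' clearance uses the interindividual level only. If no grid dose reaches
#' the window, the nearest achievable dose is reported with
#' `in_window = FALSE`.
#'
#' @param model A [population_model()].
#' @param realization An `individual_realization`.
#' @param target A [target_window()].
#' @param schedule_h Dosing interval (h).
#' @param route `"oral"` or `"iv"`.
#' @param grid Candidate maintenance doses (mg).
#' @return A list with `dose` (mg), `cmin_pred` (mg/L) and `in_window`.
#' @export
recommend_individual_dose <- function(model, realization,
                                      target = target_window(),
                                      schedule_h = 12, route = "oral",
                                      grid = seq(50, 500, by = 50)) {
  stopifnot(inherits(realization, "individual_realization"))
  typ <- covariate_scale(model, realization$ibw)
  V_i <- typ$V_typ * exp(realization$eta_V)
  CL_i <- typ$CL_typ * exp(realization$eta_CL)
  cmin <- vapply(grid, function(d)
    steady_state_cmin(V_i, CL_i, d, schedule_h, route, model$ka,
                      model$F_oral), numeric(1))
  mid <- (target$lower + target$upper) / 2
  inside <- cmin >= target$lower & cmin <= target$upper
  if (any(inside)) {
    cand <- which(inside)
    best <- cand[which.min(abs(cmin[cand] - mid))]
    list(dose = grid[best], cmin_pred = cmin[best], in_window = TRUE)
  } else {
    dist <- pmax(target$lower - cmin, cmin - target$upper, 0)
    best <- which.min(dist)
    list(dose = grid[best], cmin_pred = cmin[best], in_window = FALSE)
  }
}
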