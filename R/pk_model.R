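#' Population pharmacokinetic model of phenobarbital
#'
#' Container for the fixed effects, variance components and covariate-scaling
#' constants of the hierarchical one-compartment model with first-order
#' absorption and elimination. Defaults are the final population estimates
#' for critically ill adults with refractory/superrefractory status
#' epilepticus: oral bioavailability `F` 0.96, absorption rate `ka` fixed at
#' 1.9/h, typical volume 34.3 L and clearance 0.38 L/h at the centering ideal
#' body weight of 68.8 kg, lognormal interindividual SDs 0.71 (V) and 0.40
#' (CL), interoccasion SD 0.36 (CL), and proportional residual SD 0.082.
#'
#' Volume scales allometrically with ideal body weight with exponent
#' `exp_V` (default 1) and clearance with `exp_CL` (default 0.75).
#'
#' @param F_oral Oral bioavailability fraction, in (0, 1]. Intravenous doses
#'   are always fully available.
#' @param ka First-order absorption rate constant (1/h).
#' @param theta_V Typical volume of distribution (L) at `med_IBW`.
#' @param theta_CL Typical clearance (L/h) at `med_IBW`.
#' @param omega_V,omega_CL Lognormal interindividual SDs on V and CL.
#' @param gamma_CL Lognormal interoccasion SD on CL.
#' @param sigma_prop Proportional residual error SD.
#' @param exp_V,exp_CL Allometric exponents on V and CL.
#' @param med_IBW Centering ideal body weight (kg).
#' @param tlag Optional absorption lag time (h); the final model has none.
#' @return An object of class `population_model`.
#' @examples
#' m <- population_model()
#' covariate_scale(m, 55)
#' half_life(m$theta_V, m$theta_CL)
#' @export
population_model <- function(F_oral = 0.96, ka = 1.9, theta_V = 34.3,
                             theta_CL = 0.38, omega_V = 0.71, omega_CL = 0.40,
                             gamma_CL = 0.36, sigma_prop = 0.082,
                             exp_V = 1, exp_CL = 0.75, med_IBW = 68.8,
                             tlag = 0) {
  stopifnot(F_oral > 0, F_oral <= 1, ka > 0, theta_V > 0, theta_CL > 0,
            omega_V >= 0, omega_CL >= 0, gamma_CL >= 0, sigma_prop >= 0,
            med_IBW > 0, tlag >= 0)
  structure(list(F_oral = F_oral, ka = ka, theta_V = theta_V,
                 theta_CL = theta_CL, omega_V = omega_V, omega_CL = omega_CL,
                 gamma_CL = gamma_CL, sigma_prop = sigma_prop,
                 exp_V = exp_V, exp_CL = exp_CL, med_IBW = med_IBW,
                 tlag = tlag),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (1-cpt, first-order absorption/elimination)\n")
  cat(sprintf("  F %.3g | ka %.3g /h | V %.4g L | CL %.4g L/h (at IBW %.4g kg)\n",
              x$F_oral, x$ka, x$theta_V, x$theta_CL, x$med_IBW))
  cat(sprintf("  IIV SD: V %.3g, CL %.3g | IOV SD: CL %.3g | prop. RUV SD %.3g\n",
              x$omega_V, x$omega_CL, x$gamma_CL, x$sigma_prop))
  cat(sprintf("  allometric exponents: V %.3g, CL %.3g | half-life %.1f h\n",
              x$exp_V, x$exp_CL, half_life(x$theta_V, x$theta_CL)))
  invisible(x)
}

#' Ideal body weight (Brower formula)
#'
#' IBW in kg from sex and height: `50 + 0.91 * (height - 152.4)` for males and
#' `45.5 + 0.91 * (height - 152.4)` for females.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param height_cm Height in cm, positive.
#' @param floor_kg Lower clamp for very short patients (kg).
#' @return Ideal body weight (kg).
#' @examples
#' ideal_body_weight("male", 173)
#' @export
ideal_body_weight <- function(sex, height_cm, floor_kg = 20) {
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (any(height_cm <= 0)) stop("height_cm must be positive", call. = FALSE)
  stopifnot(floor_kg > 0)
  base <- ifelse(sex == "male", 50, 45.5)
  pmax(base + 0.91 * (height_cm - 152.4), floor_kg)
}

#' Patient covariates
#'
#' @param id Identifier.
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height (cm); may be `NA` if `ibw` is given directly.
#' @param tbw Total body weight (kg), optional (used for mg/kg dosing).
#' @param ibw Ideal body weight (kg); computed from `sex` and `height_cm`
#'   via [ideal_body_weight()] when omitted.
#' @return An object of class `pk_patient`.
#' @export
patient <- function(id, sex, height_cm = NA_real_, tbw = NA_real_,
                    ibw = NULL) {
  if (is.null(ibw)) {
    if (is.na(height_cm))
      stop("either ibw or (sex, height_cm) is required", call. = FALSE)
    ibw <- ideal_body_weight(sex, height_cm)
  }
  stopifnot(ibw > 0)
  structure(list(id = id, sex = sex, height_cm = height_cm, tbw = tbw,
                 ibw = ibw),
            class = "pk_patient")
}

#' Covariate-scaled typical parameters
#'
#' Allometric ideal-body-weight scaling of the typical volume and clearance,
#' centered at the population median IBW:
#' `V_typ = theta_V * (ibw/med_IBW)^exp_V`,
#' `CL_typ = theta_CL * (ibw/med_IBW)^exp_CL`.
#'
#' @param model A [population_model()].
#' @param ibw Ideal body weight (kg), positive (vectorized).
#' @return Named list with `V_typ` (L) and `CL_typ` (L/h).
#' @export
covariate_scale <- function(model, ibw) {
  stopifnot(inherits(model, "population_model"))
  if (any(ibw <= 0)) stop("ibw must be positive", call. = FALSE)
  r <- ibw / model$med_IBW
  list(V_typ = model$theta_V * r^model$exp_V,
       CL_typ = model$theta_CL * r^model$exp_CL)
}

#' Elimination half-life
#'
#' `ln(2) * V / CL`; at the typical values 34.3 L and 0.38 L/h this is 62.6 h.
#'
#' @param V Volume of distribution (L).
#' @param CL Clearance (L/h).
#' @return Half-life (h).
#' @export
half_life <- function(V, CL) {
  if (any(V <= 0) || any(CL <= 0))
    stop("V and CL must be positive", call. = FALSE)
  log(2) * V / CL
}

#' Dosing regimen
#'
#' An ordered table of dose events. Intravenous doses are zero-order
#' infusions (default duration 5 min = 1/12 h); oral doses enter the
#' absorption depot scaled by bioavailability. Doses sharing a time and route
#' are merged by summation.
#'
#' @param time Dose times (h, non-negative).
#' @param amount Dose amounts (mg, non-negative).
#' @param route `"oral"` or `"iv"` (recycled).
#' @param dur Infusion duration (h) for iv doses; ignored for oral.
#' @param schedule_h Optional schedule metadata (h between maintenance doses).
#' @return A `data.frame` of class `pk_regimen` with columns
#'   `time`, `amount`, `route`, `dur`.
#' @examples
#' regimen(time = c(0, 12, 24), amount = c(1100, 150, 150),
#'         route = c("iv", "oral", "oral"))
#' @export
regimen <- function(time, amount, route = "oral", dur = 1 / 12,
                    schedule_h = NA_real_) {
  n <- length(time)
  route <- rep_len(route, n)
  dur <- rep_len(dur, n)
  amount <- rep_len(amount, n)
  if (!all(route %in% c("oral", "iv")))
    stop("route must be 'oral' or 'iv'", call. = FALSE)
  stopifnot(all(amount >= 0), all(time >= 0), all(dur[route == "iv"] > 0))
  o <- order(time, route)
  d <- data.frame(time = time[o], amount = amount[o], route = route[o],
                  dur = ifelse(route[o] == "iv", dur[o], 0),
                  stringsAsFactors = FALSE)
  # merge simultaneous same-route events
  key <- paste(format(d$time, digits = 12), d$route, format(d$dur, digits = 12))
  if (anyDuplicated(key)) {
    d <- do.call(rbind, lapply(split(d, factor(key, levels = unique(key))),
                               function(g) {
                                 g$amount[1] <- sum(g$amount); g[1, ]
                               }))
    d <- d[order(d$time, d$route), ]
    rownames(d) <- NULL
  }
  structure(d, class = c("pk_regimen", "data.frame"), schedule_h = schedule_h)
}

#' Realize an individual from the population model
#'
#' Draws the lognormal random effects of one subject: `eta_V ~ N(0, omega_V^2)`
#' and `eta_CL ~ N(0, omega_CL^2)` (interindividual), plus one independent
#' `kappa ~ N(0, gamma_CL^2)` per occasion (interoccasion, on clearance only).
#' The individual volume is `V_typ * exp(eta_V)`; clearance on occasion k is
#' `CL_typ * exp(eta_CL + kappa_k)`.
#'
#' @param model A [population_model()].
#' @param patient A [patient()] (its `ibw` drives the allometric scaling).
#' @param n_occasions Number of occasions (>= 1).
#' @param occasion_boundaries Times (h) at which the active occasion changes;
#'   length `n_occasions - 1`. Defaults to a 48-h grid.
#' @param seed Integer seed for reproducible draws; `NULL` uses the current
#'   RNG stream.
#' @param eta Optional list with fixed `eta_V`, `eta_CL`, `kappa_CL` to build
#'   a deterministic realization (no sampling).
#' @return An object of class `individual_realization`.
#' @export
realize_individual <- function(model, patient, n_occasions = 1,
                               occasion_boundaries = NULL, seed = NULL,
                               eta = NULL) {
  stopifnot(inherits(model, "population_model"), n_occasions >= 1)
  if (is.null(occasion_boundaries))
    occasion_boundaries <- 48 * seq_len(n_occasions - 1)
  stopifnot(length(occasion_boundaries) == n_occasions - 1)
  typ <- covariate_scale(model, patient$ibw)
  if (is.null(eta)) {
    draws <- with_seed(seed, list(
      eta_V = rnorm(1, 0, model$omega_V),
      eta_CL = rnorm(1, 0, model$omega_CL),
      kappa_CL = rnorm(n_occasions, 0, model$gamma_CL)))
  } else {
    draws <- list(eta_V = eta$eta_V %||% 0, eta_CL = eta$eta_CL %||% 0,
                  kappa_CL = rep_len(eta$kappa_CL %||% 0, n_occasions))
  }
  structure(list(
    eta_V = draws$eta_V, eta_CL = draws$eta_CL, kappa_CL = draws$kappa_CL,
    occasion_boundaries = as.numeric(occasion_boundaries),
    V_i = typ$V_typ * exp(draws$eta_V),
    CL_i_by_occasion = typ$CL_typ * exp(draws$eta_CL + draws$kappa_CL),
    ka = model$ka, F_oral = model$F_oral, tlag = model$tlag,
    ibw = patient$ibw),
    class = "individual_realization")
}

#' Concentration-time profile
#'
#' Exact piecewise-analytic solution of the one-compartment system
#' `dA_gut/dt = -ka A_gut`, `dA_central/dt = ka A_gut + R(t) - (CL/V) A_central`
#' under an arbitrary sequence of oral boluses (scaled by bioavailability)
#' and zero-order intravenous infusions, with clearance piecewise constant
#' across occasions. The state is carried across every dose event, infusion
#' end and occasion boundary, so the profile is continuous and superposition
#' in dose amounts holds exactly. A time at which a dose is also scheduled is
#' evaluated immediately pre-dose (trough convention).
#'
#' @param realization An [realize_individual()] result.
#' @param doses A [regimen()] (or data.frame with its columns).
#' @param times Sorted, non-negative times (h) at which to report
#'   concentration.
#' @return Concentrations (mg/L) at `times`.
#' @export
concentration_profile <- function(realization, doses, times) {
  stopifnot(inherits(realization, "individual_realization"))
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(doses$time)) stop("doses must be sorted", call. = FALSE)
  tlag <- realization$tlag %||% 0
  d_time <- doses$time + ifelse(doses$route == "oral", tlag, 0)
  as.numeric(cpp_profile(
    realization$V_i, realization$CL_i_by_occasion,
    realization$occasion_boundaries, realization$ka, realization$F_oral,
    d_time, doses$amount, as.integer(doses$route == "oral"),
    pmax(doses$dur, 1e-12), times))
}

# Closed-form steady-state trough (pre-dose) for a constant regimen of `dose`
# every `tau` h: oral first-order input or iv infusion of duration `dur`.
# Used for deterministic dose selection and as an independent check on the
# simulation engine at zero variability.
steady_state_cmin <- function(V, CL, dose, tau, route = "oral", ka = 1.9,
                              F_oral = 0.96, dur = 1 / 12) {
  ke <- CL / V
  if (route == "oral") {
    F_oral * dose * ka / (V * (ka - ke)) *
      (exp(-ke * tau) / (1 - exp(-ke * tau)) -
       exp(-ka * tau) / (1 - exp(-ka * tau)))
  } else {
    R0 <- dose / dur
    # end-of-infusion ss peak decayed to the next pre-dose trough
    R0 / CL * (1 - exp(-ke * dur)) * exp(-ke * (tau - dur)) /
      (1 - exp(-ke * tau))
  }
}
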