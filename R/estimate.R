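#' Lognormal coefficient of variation from an SD
#'
#' `CV% = 100 * sqrt(exp(sd^2) - 1)`, the exact CV of a lognormal random
#' effect with log-scale SD `sd`; for small `sd` this approaches `100 * sd`.
#'
#' @param sd Log-scale standard deviation, non-negative.
#' @return CV in percent.
#' @export
cv_from_sd <- function(sd) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  100 * sqrt(exp(sd^2) - 1)
}

# ---- covariate effects -----------------------------------------------------

#' Covariate effect specification
#'
#' Functional forms for covariate testing on the typical parameters:
#' `power` multiplies by `(x/ref)^beta`, `proportional` by
#' `1 + beta (x - ref)/ref`, `exponential` by `exp(beta (x - ref))`,
#' `proportional_shift` by `1 + beta x` (categorical), and `additive_shift`
#' adds `beta x` to the typical value. `beta = NULL` means the coefficient is
#' estimated; a numeric fixes it (e.g. fixed allometric exponents 1 and
#' 0.75 on V and CL).
#'
#' @param cov Covariate column name (`"IBW"`, `"TBW"`, ...).
#' @param param `"V"` or `"CL"`.
#' @param form Functional form (see above).
#' @param beta Fixed coefficient, or `NULL` to estimate.
#' @param ref Centering value; `NULL` centers at the dataset median.
#' @param init Starting value when estimated.
#' @return A `covariate_effect` list.
#' @export
covariate_effect <- function(cov, param = c("CL", "V"),
                             form = c("power", "proportional", "exponential",
                                      "proportional_shift", "additive_shift"),
                             beta = NULL, ref = NULL, init = 0.1) {
  structure(list(cov = cov, param = match.arg(param), form = match.arg(form),
                 beta = beta, ref = ref, init = init),
            class = "covariate_effect")
}

# The study's final covariate model: fixed allometric IBW scaling.
allometric_ibw_effects <- function(exp_V = 1, exp_CL = 0.75) {
  list(covariate_effect("IBW", "V", "power", beta = exp_V),
       covariate_effect("IBW", "CL", "power", beta = exp_CL))
}

cov_multiplier <- function(form, x, ref, beta) {
  switch(form,
         power = (x / ref)^beta,
         proportional = pmax(1 + beta * (x - ref) / ref, 1e-3),
         exponential = exp(beta * (x - ref)),
         proportional_shift = pmax(1 + beta * x, 1e-3),
         additive_shift = 1)  # handled additively
}

# Typical V / CL per patient under a set of covariate effects.
typical_values <- function(theta_V, theta_CL, effects, covs) {
  V <- rep(theta_V, nrow(covs))
  CL <- rep(theta_CL, nrow(covs))
  for (e in effects) {
    x <- covs[[e$cov]]
    if (e$form == "additive_shift") {
      add <- e$beta * x
      if (e$param == "V") V <- pmax(V + add, 1e-6) else
        CL <- pmax(CL + add, 1e-6)
    } else {
      m <- cov_multiplier(e$form, x, e$ref, e$beta)
      if (e$param == "V") V <- V * m else CL <- CL * m
    }
  }
  list(V = V, CL = CL)
}

# Patient covariate table (one row per patient, imputed by the population
# median where missing) plus per-patient references for centering.
patient_covariates <- function(plist) {
  covs <- data.frame(IBW = vapply(plist, `[[`, numeric(1), "ibw"),
                     TBW = vapply(plist, `[[`, numeric(1), "tbw"),
                     HT = vapply(plist, `[[`, numeric(1), "ht"))
  for (cn in names(covs)) {
    med <- median(covs[[cn]], na.rm = TRUE)
    covs[[cn]][is.na(covs[[cn]])] <- med
  }
  covs$SEXM <- as.numeric(vapply(plist, `[[`, character(1), "sex") == "male")
  covs
}

resolve_refs <- function(effects, covs) {
  lapply(effects, function(e) {
    if (is.null(e$ref)) e$ref <- median(covs[[e$cov]])
    e
  })
}

# ---- marginal likelihood ---------------------------------------------------

#' Objective function value (-2 log marginal likelihood)
#'
#' Integrates the conditional likelihood
#' `y ~ N(c_pred, (sigma_prop * c_pred)^2)` over the lognormal random effects
#' (interindividual on V and CL, interoccasion on CL) for every patient and
#' sums `-2 log` of the marginals. The default is a Laplace approximation
#' with the mode found by damped Newton per patient; `method = "agq"` uses
#' adaptive Gauss-Hermite quadrature (available for up to two random effects
#' per patient, e.g. when `gamma_CL = 0`), which converges to the exact
#' integral as `n_nodes` grows.
#'
#' @param model A [population_model()] supplying all parameters.
#' @param dataset A `tdm_dataset` with at least one usable observation.
#' @param method `"is"` (importance sampling, the default used for
#'   estimation), `"laplace"`, or `"agq"`.
#' @param n_nodes Quadrature nodes per dimension for `"agq"`, or antithetic
#'   node pairs per patient for `"is"`.
#' @param is_seed Seed of the common-random-number node stream for `"is"`.
#' @return The OFV (a scalar).
#' @export
ofv <- function(model, dataset, method = c("is", "laplace", "agq"),
                n_nodes = NULL, is_seed = 1L) {
  method <- match.arg(method)
  plist <- split_patients(dataset)
  plist <- Filter(function(p) length(p$obs_t) > 0, plist)
  if (!length(plist)) stop("dataset has no usable observations", call. = FALSE)
  covs <- patient_covariates(plist)
  r <- covs$IBW / model$med_IBW
  Vtyp <- model$theta_V * r^model$exp_V
  CLtyp <- model$theta_CL * r^model$exp_CL
  if (method %in% c("laplace", "is")) {
    n_is <- if (method == "is") n_nodes %||% 500L else 0L
    res <- cpp_laplace_ofv(plist, Vtyp, CLtyp, model$F_oral, model$ka,
                           model$omega_V, model$omega_CL, model$gamma_CL,
                           model$sigma_prop, n_is = as.integer(n_is),
                           is_seed = as.integer(is_seed))
    return(res$ofv)
  }
  sum(vapply(seq_along(plist), function(i)
    ofv_agq_patient(plist[[i]], Vtyp[i], CLtyp[i], model, n_nodes %||% 21),
    numeric(1)))
}

# AGQ marginal -2 log-likelihood for one patient, d <= 2 random effects.
ofv_agq_patient <- function(p, Vtyp, CLtyp, model, n_nodes) {
  useV <- model$omega_V > 1e-8
  useCL <- model$omega_CL > 1e-8
  if (model$gamma_CL > 1e-8)
    stop("agq supports at most 2 random effects (set gamma_CL = 0)",
         call. = FALSE)
  sds <- c(if (useV) model$omega_V, if (useCL) model$omega_CL)
  d <- length(sds)
  cond <- function(etaV, etaCL) {
    cpp_cond_neg2ll(Vtyp * exp(etaV), rep(CLtyp * exp(etaCL), p$n_occ),
                    p$occ_b, model$ka, model$F_oral, model$sigma_prop,
                    p$d_time, p$d_amt, p$d_oral, p$d_dur, p$obs_t, p$obs_y)
  }
  if (d == 0) return(cond(0, 0))
  f <- function(b) {  # penalized -2 log joint
    eta <- c(0, 0)
    eta[which(c(useV, useCL))] <- b
    cond(eta[1], eta[2]) + sum(b^2 / sds^2) + sum(log(2 * pi * sds^2))
  }
  opt <- nlminb(rep(0, d), f)
  bhat <- opt$par
  H <- pracma::hessian(f, bhat)
  Sigma <- solve(H / 2)
  A <- t(chol(Sigma)) * sqrt(2)
  gh <- pracma::gaussHermite(n_nodes)
  if (d == 1) {
    z <- matrix(gh$x, ncol = 1); w <- gh$w
  } else {
    z <- as.matrix(expand.grid(gh$x, gh$x))
    w <- as.vector(outer(gh$w, gh$w))
  }
  vals <- vapply(seq_len(nrow(z)), function(k) {
    b <- bhat + as.vector(A %*% z[k, ])
    exp(-0.5 * (f(b) - opt$objective)) * exp(sum(z[k, ]^2))
  }, numeric(1))
  integral <- abs(det(A)) * sum(w * vals)
  opt$objective - 2 * log(integral)
}

# ---- population fit --------------------------------------------------------

# Parameter transforms keeping the optimizer unconstrained.
.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Fit the population model by maximum marginal likelihood
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' effects (oral bioavailability on a logit scale, typical V and CL on a log
#' scale), the lognormal variance-component SDs and the proportional
#' residual SD, plus any estimated covariate coefficients. `ka` stays fixed
#' (trough-only sampling carries no absorption information). Returns the
#' estimates, the OFV, per-patient empirical Bayes modes, and (optionally)
#' relative standard errors with 95% confidence intervals from a
#' nonparametric bootstrap (`compute_rse = TRUE`; `rse_boot` replicates).
#'
#' @param dataset A `tdm_dataset` (both routes are needed to estimate F).
#' @param config Optional list: `covariates` (list of [covariate_effect()];
#'   default fixed allometric IBW scaling), `fix` (named values among
#'   `F`, `theta_V`, `theta_CL`, `omega_V`, `omega_CL`, `gamma_CL`,
#'   `sigma_prop` to hold fixed), `start` (named starting values),
#'   `med_IBW` (centering value; default the dataset median IBW),
#'   `compute_rse` (default `FALSE`), `control` passed to [nlminb()].
#' @return A `pk_fit` object.
#' @export
fit_population <- function(dataset, config = list()) {
  plist <- split_patients(dataset)
  plist <- Filter(function(p) length(p$obs_t) > 0, plist)
  if (!length(plist)) stop("dataset has no usable observations", call. = FALSE)
  covs <- patient_covariates(plist)
  effects <- config$covariates %||% allometric_ibw_effects()
  if (!is.null(config$med_IBW))
    effects <- lapply(effects, function(e) {
      if (e$cov == "IBW" && is.null(e$ref)) e$ref <- config$med_IBW
      e
    })
  effects <- resolve_refs(effects, covs)

  fix <- config$fix %||% list()
  est_F <- !("F" %in% names(fix))
  if (est_F && !any(unlist(lapply(plist, function(p) p$d_oral == 0L))))
    stop("F is not identifiable from oral-only data; fix F or add iv doses",
         call. = FALSE)

  start <- utils::modifyList(
    list(F = 0.9, theta_V = 30, theta_CL = 0.5, omega_V = 0.3,
         omega_CL = 0.3, gamma_CL = 0.3, sigma_prop = 0.15),
    config$start %||% list())
  pnames <- c("F", "theta_V", "theta_CL", "omega_V", "omega_CL", "gamma_CL",
              "sigma_prop")
  est_mask <- !(pnames %in% names(fix))
  est_beta <- vapply(effects, function(e) is.null(e$beta), logical(1))

  trans <- function(name, value) {
    if (name == "F") .logit(value) else log(value)
  }
  untrans <- function(name, x) {
    if (name == "F") .inv_logit(x) else exp(x)
  }
  par0 <- c(vapply(pnames[est_mask], function(n) trans(n, start[[n]]),
                   numeric(1)),
            vapply(effects[est_beta], function(e) e$init, numeric(1)))

  unpack <- function(par) {
    vals <- setNames(numeric(length(pnames)), pnames)
    i <- 0
    for (n in pnames) {
      if (n %in% names(fix)) vals[n] <- fix[[n]]
      else { i <- i + 1; vals[n] <- untrans(n, par[i]) }
    }
    eff <- effects
    for (j in which(est_beta)) { i <- i + 1; eff[[j]]$beta <- par[i] }
    list(vals = vals, effects = eff)
  }

  method <- config$method %||% "saem"
  no_re <- all(c(fix$omega_V %||% 1, fix$omega_CL %||% 1,
                 fix$gamma_CL %||% 1) == 0)
  if (method == "saem" && no_re)
    method <- "laplace"  # no random effects: the marginal is exact
  n_is_final <- as.integer(config$mc_pairs %||% 300L)
  is_seed <- as.integer(config$is_seed %||% 1L)
  warm_env <- new.env(parent = emptyenv())
  warm_env$ebe <- NULL
  objective_with <- function(n_is, use_warm = TRUE) function(par) {
    u <- unpack(par)
    v <- u$vals
    typ <- typical_values(v["theta_V"], v["theta_CL"], u$effects, covs)
    res <- cpp_laplace_ofv(plist, typ$V, typ$CL, v["F"], model_ka(config),
                           v["omega_V"], v["omega_CL"], v["gamma_CL"],
                           v["sigma_prop"],
                           warm = if (use_warm) warm_env$ebe,
                           n_is = n_is, is_seed = is_seed)
    if (use_warm) warm_env$ebe <- res$ebe
    if (!is.finite(res$ofv)) 1e10 else res$ofv
  }

  control <- utils::modifyList(list(iter.max = 400, eval.max = 800,
                                    rel.tol = 1e-9), config$control %||% list())
  if (!length(par0) && method != "saem")
    stop("no free parameters to estimate", call. = FALSE)
  if (method == "saem") {
    sa <- saem_fit(plist, covs, effects, est_beta, start, fix,
                   model_ka(config), config)
    v <- sa$vals
    eff_out <- sa$effects
    opt <- list(par = NULL, convergence = 0L,
                message = "SAEM completed", iterations = sa$n_iter)
    objective <- objective_with(n_is_final)
    u <- list(vals = v, effects = eff_out)
    # transformed-parameter vector at the SAEM solution (for optional RSEs)
    opt$par <- c(vapply(pnames[est_mask], function(nm) trans(nm, v[[nm]]),
                        numeric(1)),
                 vapply(eff_out[est_beta], function(e) e$beta, numeric(1)))
  } else {
    # stage 1: Laplace (fast, deterministic) to get close to the optimum;
    # restarts polish flat ridges (e.g. the F / theta_V trade-off)
    obj0 <- objective_with(0L)
    opt <- nlminb(par0, obj0, control = control)
    for (r in 1:3) {
      opt2 <- nlminb(opt$par, obj0, control = control)
      improved <- opt$objective - opt2$objective > 1e-10
      opt <- opt2
      if (!improved) break
    }
    if (method == "isml") {
      # stage 2: refine under the importance-sampled marginal likelihood,
      # which reduces the curvature bias of the pure Laplace objective
      objective <- objective_with(n_is_final)
      opt <- nlminb(opt$par, objective, control = control)
    } else {
      objective <- objective_with(0L)
    }
    u <- unpack(opt$par)
  }
  v <- u$vals
  typ <- typical_values(v["theta_V"], v["theta_CL"], u$effects, covs)
  # reported OFV: "is" for the stochastic fits, "agq" (exact, <= 2 random
  # effects) when likelihood-ratio decisions need it, "laplace" otherwise
  ofv_method <- config$ofv_method %||%
    (if (method %in% c("saem", "isml")) "is" else "laplace")
  final <- cpp_laplace_ofv(plist, typ$V, typ$CL, v["F"], model_ka(config),
                           v["omega_V"], v["omega_CL"], v["gamma_CL"],
                           v["sigma_prop"], warm = warm_env$ebe,
                           return_ebe = TRUE,
                           n_is = if (ofv_method == "is") n_is_final else 0L,
                           is_seed = is_seed)
  if (ofv_method == "agq") {
    pseudo <- list(omega_V = unname(v["omega_V"]),
                   omega_CL = unname(v["omega_CL"]),
                   gamma_CL = unname(v["gamma_CL"]),
                   sigma_prop = unname(v["sigma_prop"]),
                   F_oral = unname(v["F"]), ka = model_ka(config))
    final$ofv <- sum(vapply(seq_along(plist), function(i)
      ofv_agq_patient(plist[[i]], typ$V[i], typ$CL[i], pseudo,
                      config$agq_nodes %||% 15), numeric(1)))
  }

  est_names <- c(pnames[est_mask],
                 vapply(effects[est_beta], function(e)
                   paste0("beta_", e$cov, "_", e$param), character(1)))
  coefs <- data.frame(parameter = est_names,
                      estimate = c(v[pnames[est_mask]],
                                   vapply(u$effects[est_beta], `[[`,
                                          numeric(1), "beta")),
                      rse = NA_real_, lo95 = NA_real_, hi95 = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
  if (isTRUE(config$compute_rse)) {
    # nonparametric bootstrap uncertainty (the OFV surface of the
    # stochastic fits is not smooth enough for a reliable numeric Hessian)
    boot_cfg <- config
    boot_cfg$compute_rse <- NULL
    bt <- bootstrap_fit(dataset, boot_cfg,
                        n_reps = config$rse_boot %||% 50L,
                        seed = config$rse_seed %||% 1L)
    idx <- match(coefs$parameter, colnames(bt$estimates))
    for (j in seq_len(nrow(coefs))) {
      if (is.na(idx[j])) next
      reps <- bt$estimates[, idx[j]]
      se <- sd(reps)
      coefs$rse[j] <- 100 * se / abs(coefs$estimate[j])
      if (length(reps) >= 40) {
        coefs$lo95[j] <- quantile(reps, 0.025, names = FALSE)
        coefs$hi95[j] <- quantile(reps, 0.975, names = FALSE)
      } else {
        coefs$lo95[j] <- coefs$estimate[j] - 1.96 * se
        coefs$hi95[j] <- coefs$estimate[j] + 1.96 * se
      }
    }
  }

  ibw_eff <- function(param) {
    for (e in u$effects)
      if (e$cov == "IBW" && e$param == param && e$form == "power")
        return(list(exp = e$beta, ref = e$ref))
    NULL
  }
  eV <- ibw_eff("V") %||% list(exp = 0, ref = median(covs$IBW))
  eCL <- ibw_eff("CL") %||% list(exp = 0, ref = median(covs$IBW))
  v <- setNames(unname(v), names(v))
  fitted_model <- population_model(
    F_oral = unname(v["F"]), ka = model_ka(config),
    theta_V = unname(v["theta_V"]), theta_CL = unname(v["theta_CL"]),
    omega_V = unname(v["omega_V"]), omega_CL = unname(v["omega_CL"]),
    gamma_CL = unname(v["gamma_CL"]),
    sigma_prop = max(unname(v["sigma_prop"]), 1e-12),
    exp_V = eV$exp, exp_CL = eCL$exp, med_IBW = eV$ref)

  structure(list(
    coefficients = coefs, model = fitted_model, effects = u$effects,
    ofv = final$ofv,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations),
    ebe = final$ebe, ids = vapply(plist, `[[`, numeric(1), "id"),
    patients = plist, covs = covs, config = config),
    class = "pk_fit")
}

model_ka <- function(config) config$ka %||% 1.9

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: OFV %.3f (%d patients, convergence %d)\n",
              x$ofv, length(x$patients), x$convergence$code))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$parameter)
}

# SAEM front-end: builds the log-scale linear covariate designs (power and
# exponential forms are linear in log space), fixed-coefficient offsets, and
# the initial vector, then runs the C++ stochastic EM.
saem_fit <- function(plist, covs, effects, est_beta, start, fix, ka, config) {
  n <- length(plist)
  block <- function(param, theta_name) {
    free_int <- !(theta_name %in% names(fix))
    X <- if (free_int) matrix(1, n, 1) else matrix(0, n, 0)
    off <- rep(if (free_int) 0 else log(fix[[theta_name]]), n)
    idx_map <- integer()   # which effect index each free column came from
    for (j in seq_along(effects)) {
      e <- effects[[j]]
      if (e$param != param) next
      x <- switch(e$form,
                  power = log(covs[[e$cov]] / e$ref),
                  exponential = covs[[e$cov]] - e$ref,
                  stop("covariate form '", e$form,
                       "' is not supported by the SAEM fitter; use method ",
                       "'isml' or 'laplace'", call. = FALSE))
      if (is.null(e$beta)) {
        X <- cbind(X, x)
        idx_map <- c(idx_map, j)
      } else {
        off <- off + e$beta * x
      }
    }
    list(X = X, off = off, free_int = free_int, idx_map = idx_map,
         init = c(if (free_int) log(start[[theta_name]]),
                  vapply(effects[idx_map], `[[`, numeric(1), "init")))
  }
  bV <- block("V", "theta_V")
  bCL <- block("CL", "theta_CL")
  val_or_start <- function(nm) fix[[nm]] %||% start[[nm]]
  init <- c(bV$init, bCL$init, val_or_start("omega_V"),
            val_or_start("omega_CL"), val_or_start("gamma_CL"),
            val_or_start("sigma_prop"), val_or_start("F"))
  est <- function(nm) !(nm %in% names(fix))
  res <- cpp_saem(plist,
                  lapply(seq_len(n), function(i) as.numeric(bV$X[i, ])),
                  lapply(seq_len(n), function(i) as.numeric(bCL$X[i, ])),
                  bV$off, bCL$off, ka, init, ncol(bV$X), ncol(bCL$X),
                  est("omega_V"), est("omega_CL"), est("gamma_CL"),
                  est("sigma_prop"), est("F"),
                  as.integer(config$saem_burn %||% 600L),
                  as.integer(config$saem_iter %||% 400L),
                  as.integer(config$saem_mh %||% 6L),
                  as.integer(config$saem_seed %||% 1L))
  par <- res$par
  i <- 0
  take <- function() { i <<- i + 1; par[i] }
  thV <- if (bV$free_int) exp(take()) else fix$theta_V
  beta_V <- vapply(seq_along(bV$idx_map), function(k) take(), numeric(1))
  thCL <- if (bCL$free_int) exp(take()) else fix$theta_CL
  beta_CL <- vapply(seq_along(bCL$idx_map), function(k) take(), numeric(1))
  vals <- c(F = val_or_start("F"), theta_V = thV, theta_CL = thCL,
            omega_V = take(), omega_CL = take(), gamma_CL = take(),
            sigma_prop = take())
  vals["F"] <- take()
  eff_out <- effects
  for (k in seq_along(bV$idx_map)) eff_out[[bV$idx_map[k]]]$beta <- beta_V[k]
  for (k in seq_along(bCL$idx_map)) eff_out[[bCL$idx_map[k]]]$beta <- beta_CL[k]
  for (nm in names(fix)) vals[nm] <- fix[[nm]]
  list(vals = vals, effects = eff_out,
       n_iter = (config$saem_burn %||% 600L) + (config$saem_iter %||% 400L))
}

# ---- stepwise covariate modeling -------------------------------------------

#' Stepwise covariate selection
#'
#' Greedy forward inclusion followed by backward elimination on the
#' chi-squared(1) thresholds used in sparse-data pharmacokinetic modelling:
#' a candidate enters if it lowers the OFV by at least 3.84 (p < .05; the
#' largest drop wins each round) and is retained only if removing it raises
#' the OFV by more than 10.83 (p < .001).
#'
#' @param dataset A `tdm_dataset`.
#' @param candidates List of [covariate_effect()] candidates (coefficients
#'   estimated).
#' @param config Fit configuration as in [fit_population()]; additionally
#'   `fit_fun(dataset, covariates, config)` may override the fitter (it must
#'   return a list with an `ofv` element) — used to unit-test the thresholds
#'   with stubbed OFVs — and `base_covariates` sets the structural covariate
#'   set of the base model (default none).
#' @param forward_threshold,backward_threshold OFV thresholds (3.84, 10.83).
#' @return A data.frame of tested steps (`stage`, `cov`, `param`, `form`,
#'   `delta_ofv`, `decision`) with the final covariate set as attribute
#'   `selected`.
#' @export
stepwise_covariates <- function(dataset, candidates, config = list(),
                                forward_threshold = 3.84,
                                backward_threshold = 10.83) {
  if (!length(candidates))
    return(structure(data.frame(stage = character(), cov = character(),
                                param = character(), form = character(),
                                delta_ofv = numeric(), decision = character(),
                                stringsAsFactors = FALSE),
                     selected = list()))
  fit_fun <- config$fit_fun %||% function(dataset, covariates, config) {
    cfg <- config
    cfg$covariates <- covariates
    cfg$fit_fun <- NULL
    fit_population(dataset, cfg)
  }
  base <- config$base_covariates %||% list()
  safe_ofv <- function(covariates) {
    tryCatch(fit_fun(dataset, covariates, config)$ofv,
             error = function(e) {
               warning("candidate fit failed: ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  }
  steps <- list()
  note <- function(stage, e, d, decision)
    steps[[length(steps) + 1]] <<- data.frame(
      stage = stage, cov = e$cov, param = e$param, form = e$form,
      delta_ofv = d, decision = decision, stringsAsFactors = FALSE)

  selected <- list()
  remaining <- candidates
  ofv_cur <- safe_ofv(base)
  repeat {
    if (!length(remaining)) break
    deltas <- vapply(remaining, function(e)
      ofv_cur - safe_ofv(c(base, selected, list(e))), numeric(1))
    ok <- which(!is.na(deltas) & deltas >= forward_threshold)
    if (!length(ok)) {
      for (j in seq_along(remaining))
        note("forward", remaining[[j]], deltas[j], "not included")
      break
    }
    best <- ok[which.max(deltas[ok])]
    note("forward", remaining[[best]], deltas[best], "included")
    selected <- c(selected, list(remaining[[best]]))
    ofv_cur <- ofv_cur - deltas[best]
    remaining <- remaining[-best]
  }
  # backward elimination, most recently included first
  for (j in rev(seq_along(selected))) {
    e <- selected[[j]]
    without <- selected[-j]
    d <- safe_ofv(c(base, without)) - ofv_cur
    if (is.na(d) || d > backward_threshold) {
      note("backward", e, d, "retained")
    } else {
      note("backward", e, d, "removed")
      selected <- without
      ofv_cur <- ofv_cur + d
    }
  }
  structure(do.call(rbind, steps), selected = selected)
}

# ---- bootstrap -------------------------------------------------------------

#' Nonparametric bootstrap of the population fit
#'
#' Resamples patients with replacement, refits each replicate, and reports
#' the per-parameter median and 2.5/97.5 percentile confidence bounds.
#' Non-convergent replicates are dropped and counted.
#'
#' @param dataset A `tdm_dataset`.
#' @param config Fit configuration ([fit_population()]).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer master seed.
#' @param resample_ids Optional list of ID vectors, one per replicate
#'   (overrides resampling; used to force the identity replicate in tests).
#' @return A list with `summary` (data.frame: parameter, median, lo95, hi95),
#'   `estimates` (replicate-by-parameter matrix) and `n_failed`.
#' @export
bootstrap_fit <- function(dataset, config = list(), n_reps = 100, seed = 1L,
                          resample_ids = NULL) {
  stopifnot(n_reps >= 1)
  dataset <- as_tdm_dataset(as.data.frame(dataset))
  ids <- unique(dataset$ID)
  draws <- resample_ids %||% with_seed(seed, lapply(seq_len(n_reps),
    function(i) sample(ids, length(ids), replace = TRUE)))
  per_id <- split(as.data.frame(dataset), dataset$ID)
  reps <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    pieces <- lapply(seq_along(draws[[r]]), function(k) {
      d <- per_id[[as.character(draws[[r]][k])]]
      d$ID <- k
      d
    })
    boot_ds <- as_tdm_dataset(do.call(rbind, pieces))
    fit <- tryCatch(fit_population(boot_ds, config), error = function(e) NULL)
    if (is.null(fit) || fit$convergence$code != 0 || !is.finite(fit$ofv)) {
      n_failed <- n_failed + 1L
    } else {
      reps[[r]] <- coef(fit)
    }
  }
  reps <- Filter(Negate(is.null), reps)
  if (!length(reps)) stop("no bootstrap replicate converged", call. = FALSE)
  est <- do.call(rbind, reps)
  qs <- apply(est, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  list(summary = data.frame(parameter = colnames(est), median = qs[1, ],
                            lo95 = qs[2, ], hi95 = qs[3, ],
                            row.names = NULL, stringsAsFactors = FALSE),
       estimates = est, n_failed = n_failed)
}

# ---- MAP individual estimation ---------------------------------------------

#' Bayesian MAP estimate of an individual's parameters
#'
#' Maximizes the posterior of the random effects (eta_V, eta_CL, one kappa
#' per observed occasion) given a patient's dosing history and trough
#' observations, with the population model as prior. With no observations
#' the posterior mode is the prior mode: all deviates zero, i.e. the
#' covariate-scaled typical patient. This is the updating step of
#' model-informed precision dosing.
#'
#' @param model A [population_model()] (held fixed).
#' @param patient A [patient()].
#' @param tdm_records A `tdm_dataset` holding the patient's dose and
#'   observation rows, or `NULL` for a data-free prior-mode estimate.
#' @return An `individual_realization` with the MAP deviates.
#' @export
map_individual <- function(model, patient, tdm_records = NULL) {
  stopifnot(inherits(model, "population_model"))
  typ <- covariate_scale(model, patient$ibw)
  has_obs <- !is.null(tdm_records) &&
    any(tdm_records$EVID == 0L & tdm_records$MDV == 0L)
  if (!has_obs) {
    return(realize_individual(model, patient, n_occasions = 1,
                              eta = list(eta_V = 0, eta_CL = 0,
                                         kappa_CL = 0)))
  }
  p <- split_patients(tdm_records)[[1]]
  res <- cpp_map_individual(p, typ$V_typ, typ$CL_typ, model$F_oral, model$ka,
                            model$omega_V, model$omega_CL, model$gamma_CL,
                            model$sigma_prop)
  b <- res$b
  i <- 0
  eta_V <- if (res$useV) { i <- i + 1; b[i] } else 0
  eta_CL <- if (res$useCL) { i <- i + 1; b[i] } else 0
  kappa <- if (res$useK) b[(i + 1):(i + p$n_occ)] else rep(0, p$n_occ)
  realize_individual(model, patient, n_occasions = p$n_occ,
                     occasion_boundaries = p$occ_b,
                     eta = list(eta_V = eta_V, eta_CL = eta_CL,
                                kappa_CL = kappa))
}

# ---- diagnostics -----------------------------------------------------------

#' Goodness-of-fit and visual predictive check tables
#'
#' `gof` pairs each retained observation with its population prediction
#' (all random effects zero) and individual prediction (empirical Bayes
#' mode). `vpc` is a plain percentile visual predictive check: observed
#' 5/50/95th concentration percentiles per time bin overlaid on the 5-95%
#' band of the same percentiles across `n_sim` datasets simulated from the
#' fitted model (with interindividual, interoccasion and residual
#' variability) on the observed design.
#'
#' @param fit A `pk_fit`.
#' @param dataset The `tdm_dataset` that was fitted.
#' @param n_sim Number of simulated replicate datasets.
#' @param n_bins Number of time bins (quantile-spaced).
#' @param seed Integer seed for the simulation.
#' @return A list with `gof` and `vpc` data.frames.
#' @export
diagnostics <- function(fit, dataset, n_sim = 100, n_bins = 5, seed = 1L) {
  stopifnot(inherits(fit, "pk_fit"))
  m <- fit$model
  plist <- fit$patients
  covs <- fit$covs
  typ <- typical_values(m$theta_V, m$theta_CL, fit$effects, covs)

  profile_at <- function(p, V, CL_occ) {
    as.numeric(cpp_profile(V, CL_occ, p$occ_b, m$ka, m$F_oral, p$d_time,
                           p$d_amt, p$d_oral, p$d_dur, p$obs_t))
  }
  gof <- do.call(rbind, lapply(seq_along(plist), function(i) {
    p <- plist[[i]]
    pred <- profile_at(p, typ$V[i], rep(typ$CL[i], p$n_occ))
    b <- fit$ebe[[i]]
    useV <- m$omega_V > 1e-8; useCL <- m$omega_CL > 1e-8
    useK <- m$gamma_CL > 1e-8
    j <- 0
    eV <- if (useV) { j <- j + 1; b[j] } else 0
    eCL <- if (useCL) { j <- j + 1; b[j] } else 0
    kap <- if (useK) b[(j + 1):(j + p$n_occ)] else rep(0, p$n_occ)
    ipred <- profile_at(p, typ$V[i] * exp(eV), typ$CL[i] * exp(eCL + kap))
    data.frame(ID = p$id, TIME = p$obs_t, DV = p$obs_y, PRED = pred,
               IPRED = ipred)
  }))

  obs_all <- data.frame(TIME = gof$TIME, DV = gof$DV)
  brk <- unique(quantile(obs_all$TIME, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 2) brk <- range(obs_all$TIME) + c(-1, 1)
  bin <- cut(obs_all$TIME, brk, include.lowest = TRUE)
  pct <- function(x) quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  obs_pct <- t(vapply(split(obs_all$DV, bin), pct, numeric(3)))

  sim_pct <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(n_sim, nlevels(bin), 3))
    for (s in seq_len(n_sim)) {
      sim_dv <- unlist(lapply(seq_along(plist), function(i) {
        p <- plist[[i]]
        eV <- rnorm(1, 0, m$omega_V)
        eCL <- rnorm(1, 0, m$omega_CL)
        kap <- rnorm(p$n_occ, 0, m$gamma_CL)
        c_true <- profile_at(p, typ$V[i] * exp(eV),
                             typ$CL[i] * exp(eCL + kap))
        c_true * (1 + rnorm(length(c_true), 0, m$sigma_prop))
      }))
      sp <- vapply(split(sim_dv, bin), pct, numeric(3))
      arr[s, , ] <- t(sp)
    }
    arr
  })
  band <- function(k, prob) apply(sim_pct[, , k, drop = FALSE], 2, quantile,
                                  probs = prob, na.rm = TRUE)
  vpc <- data.frame(
    bin = levels(bin),
    t_mid = vapply(split(obs_all$TIME, bin), median, numeric(1)),
    n_obs = as.integer(table(bin)),
    obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p95 = obs_pct[, 3],
    sim_p5_lo = band(1, 0.05), sim_p5_hi = band(1, 0.95),
    sim_p50_lo = band(2, 0.05), sim_p50_hi = band(2, 0.95),
    sim_p95_lo = band(3, 0.05), sim_p95_hi = band(3, 0.95),
    row.names = NULL, stringsAsFactors = FALSE)
  list(gof = gof, vpc = vpc)
}
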