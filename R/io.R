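#' Event-record dataset (NONMEM-style)
#'
#' The estimation input format: one row per dose (`EVID = 1`, `AMT` in mg,
#' `ROUTE`, infusion `DUR` in h) or observation (`EVID = 0`, `DV` in mg/L,
#' `MDV = 1` when the value is excluded from estimation, e.g. outside the
#' 0.6-150 mg/L quantification range, with the reason in `FLAG`). `OCC`
#' indexes the interoccasion interval, `TIME` is in decimal hours, and the
#' covariate columns `SEX`, `HT` (cm), `TBW`, `IBW` (kg) are constant within
#' a patient.
#'
#' @param df A data.frame with the columns above.
#' @return The validated `tdm_dataset`.
#' @export
as_tdm_dataset <- function(df) {
  req <- c("ID", "TIME", "EVID", "AMT", "ROUTE", "DUR", "DV", "MDV", "OCC")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("FLAG", "SEX")) if (is.null(df[[col]])) df[[col]] <- ""
  for (col in c("HT", "TBW", "IBW")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  bad <- function(rows, what) {
    if (any(rows))
      stop(what, " (row ", paste(which(rows), collapse = ", "), ")",
           call. = FALSE)
  }
  bad(!df$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  is_dose <- df$EVID == 1L
  bad(is_dose & !(df$AMT > 0), "dose rows must have AMT > 0")
  bad(is_dose & !is.na(df$DV), "dose rows must not carry DV")
  bad(!is_dose & is.na(df$DV), "observation rows must have DV")
  bad(!is_dose & !is.na(df$DV) & df$DV < 0, "DV must be non-negative")
  bad(!is_dose & !is.na(df$AMT), "observation rows must have empty AMT")
  bad(is_dose & !df$ROUTE %in% c("oral", "iv"), "ROUTE must be oral or iv")
  for (id in unique(df$ID)) {
    tt <- df$TIME[df$ID == id]
    if (is.unsorted(tt))
      stop("TIME not non-decreasing within ID ", id, call. = FALSE)
    occ <- df$OCC[df$ID == id & df$EVID == 0L]
    if (length(occ) && is.unsorted(occ))
      stop("OCC not non-decreasing within ID ", id, call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("tdm_dataset", "data.frame")
  df
}

.tdm_columns <- c("ID", "TIME", "EVID", "AMT", "ROUTE", "DUR", "DV", "MDV",
                  "OCC", "FLAG", "SEX", "HT", "TBW", "IBW")

#' Read an event-record dataset
#'
#' Parses and validates a NONMEM-style CSV; `RATE` coding of infusions is
#' converted to `DUR`. Violations are rejected with the offending row
#' numbers.
#'
#' @param path CSV file with a header.
#' @return A `tdm_dataset`.
#' @export
read_tdm_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$RATE) && is.null(df$DUR))
    df$DUR <- ifelse(!is.na(df$AMT) & !is.na(df$RATE) & df$RATE > 0,
                     df$AMT / df$RATE, NA_real_)
  for (col in c("ROUTE", "FLAG", "SEX"))
    if (!is.null(df[[col]])) df[[col]][is.na(df[[col]])] <- ""
  as_tdm_dataset(df[, intersect(.tdm_columns, names(df)), drop = FALSE])
}

#' Write an event-record dataset
#'
#' Deterministic column order and fixed decimal formatting, so repeated
#' writes are byte-identical and `read_tdm_dataset()` round-trips losslessly.
#'
#' @param dataset A `tdm_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tdm_dataset <- function(dataset, path) {
  dataset <- as_tdm_dataset(as.data.frame(dataset))
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  cols <- .tdm_columns
  lines <- paste(cols, collapse = ",")
  if (nrow(dataset)) {
    body <- vapply(seq_len(nrow(dataset)), function(i) {
      r <- dataset[i, ]
      paste(c(r$ID, fmt_num(r$TIME), r$EVID, fmt_num(r$AMT), r$ROUTE,
              fmt_num(r$DUR), fmt_num(r$DV), r$MDV, r$OCC, r$FLAG, r$SEX,
              fmt_num(r$HT), fmt_num(r$TBW), fmt_num(r$IBW)),
            collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

# Split a tdm_dataset into the per-patient event lists the estimation
# engine consumes. Occasion boundaries are the TDM sampling times (all
# samples, flagged or not); n_occ is the number of samples; only MDV == 0
# observations enter the likelihood.
split_patients <- function(dataset) {
  dataset <- as_tdm_dataset(as.data.frame(dataset))
  lapply(split(dataset, dataset$ID), function(d) {
    doses <- d[d$EVID == 1L, ]
    obs_all <- d[d$EVID == 0L, ]
    obs <- obs_all[obs_all$MDV == 0L, ]
    n_occ <- max(nrow(obs_all), 1L)
    list(id = d$ID[1],
         d_time = doses$TIME, d_amt = doses$AMT,
         d_oral = as.integer(doses$ROUTE == "oral"),
         d_dur = ifelse(doses$ROUTE == "iv", pmax(doses$DUR, 1e-12,
                                                  na.rm = TRUE), 1e-12),
         occ_b = head(obs_all$TIME, -1),
         obs_t = obs$TIME, obs_y = obs$DV,
         n_occ = n_occ,
         ibw = d$IBW[1], sex = d$SEX[1], ht = d$HT[1], tbw = d$TBW[1])
  })
}

#' Read / write a model configuration
#'
#' Plain-text YAML with nested sections (`model`, `simulation`); the packaged
#' default at `system.file("extdata/default_model.yaml", package =
#' "phenodose")` carries the final population estimates and the standard
#' simulation settings. Parse -> serialize -> parse is the identity.
#'
#' @param path YAML file.
#' @return `read_config()`: a named list with a `model` entry convertible by
#'   [config_model()]. `write_config()`: `path`, invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_model.yaml",
                          package = "phenodose"))
}

#' @rdname read_config
#' @export
config_model <- function(config) {
  m <- config$model
  population_model(F_oral = m$F, ka = m$ka, theta_V = m$theta_V,
                   theta_CL = m$theta_CL, omega_V = m$omega_V,
                   omega_CL = m$omega_CL, gamma_CL = m$gamma_CL,
                   sigma_prop = m$sigma_prop, exp_V = m$exp_V %||% 1,
                   exp_CL = m$exp_CL %||% 0.75,
                   med_IBW = m$med_IBW, tlag = m$tlag %||% 0)
}
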