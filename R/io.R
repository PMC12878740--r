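# Flat key=value configuration contract and CSV writers.

.config_keys <- c("Vs", "Vr", "VN", "VTtot", "VI0", "sigma0", "n",
                  "phiD", "gamma", "mu1", "mu_1", "k1", "k_1", "phi",
                  "xi1", "xi2", "xi3", "C_hom", "C_hyp", "C_sev",
                  "rho", "renal_fraction")

.param_keys <- c("Vs", "Vr", "VN", "VTtot", "phiD", "gamma", "mu1",
                 "mu_1", "k1", "k_1", "phi", "xi1", "xi2", "xi3",
                 "C_hom", "C_hyp", "C_sev")

#' Load a run configuration from a flat key=value file
#'
#' Parses a plain-text configuration with one `key = value` pair per line
#' (`#` starts a comment; blank lines ignored). Recognised keys are the
#' physiological parameters (`Vs, Vr, VN, VTtot, phiD, gamma, mu1, mu_1,
#' k1, k_1, phi, xi1, xi2, xi3, C_hom, C_hyp, C_sev`), the implant
#' specification (`n, sigma0, VI0`) and the intervention settings
#' (`rho, renal_fraction`). Missing keys fall back to the published
#' healthy-adult defaults; unknown keys are an error. When `verbose`,
#' every defaulted key is reported.
#'
#' The returned configuration carries renal-adjusted parameters: the
#' `renal_fraction` key is applied through [renal_adjust()].
#'
#' @param path Path to the configuration file.
#' @param scenario Scenario name attached to the configuration.
#' @param verbose Report defaults and derived quantities via `message()`.
#' @return An object of class `run_config`: list with `scenario`,
#'   `params`, `implant`, `intervention` and the raw `values`.
#' @export
load_config <- function(path, scenario = "standard", verbose = FALSE) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config parse failure, expected 'key = value': '", ln, "'",
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% .config_keys)
      stop("unknown configuration key '", key, "'", call. = FALSE)
    if (key %in% names(vals))
      stop("duplicate configuration key '", key, "'", call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop("value for key '", key, "' is not numeric: '", val, "'",
           call. = FALSE)
    vals[[key]] <- num
  }
  build_run_config(vals, scenario = scenario, verbose = verbose)
}

#' Build a run configuration from a named list of overrides
#'
#' Programmatic counterpart of [load_config()]; `vals` holds any subset
#' of the configuration keys.
#'
#' @param vals Named list of numeric overrides.
#' @param scenario Scenario name.
#' @param verbose Report defaults applied.
#' @return A `run_config` object.
#' @export
build_run_config <- function(vals = list(), scenario = "standard",
                             verbose = FALSE) {
  bad <- setdiff(names(vals), .config_keys)
  if (length(bad))
    stop("unknown configuration key '", bad[1L], "'", call. = FALSE)
  defaults <- c(as.list(formals(physiology_params)),
                list(VI0 = 0.00527, sigma0 = 0.05, n = 1,
                     rho = 1, renal_fraction = 1))
  if (verbose) {
    missing <- setdiff(.config_keys, names(vals))
    if (length(missing))
      message("using defaults for: ", paste(missing, collapse = ", "))
  }
  full <- defaults
  full[names(vals)] <- vals
  params <- do.call(physiology_params, full[.param_keys])
  params <- renal_adjust(params, full$renal_fraction)
  implant <- scale_implants(full$n, full$sigma0, full$VI0, params)
  intervention <- intervention_config(full$rho, full$renal_fraction)
  structure(list(scenario = scenario, params = params, implant = implant,
                 intervention = intervention,
                 values = full[.config_keys]),
            class = "run_config")
}

#' Write a run configuration back to the flat key=value format
#'
#' Inverse of [load_config()]: the written file loads back to an
#' identical configuration.
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config", call. = FALSE)
  lines <- vapply(.config_keys, function(k)
    sprintf("%s = %.17g", k, config$values[[k]]), character(1))
  writeLines(lines, path)
  invisible(path)
}

# Format a numeric data frame for full-precision, locale-independent CSV.
.write_csv_full <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  for (j in which(is_num)) df[[j]] <- sprintf("%.17g", df[[j]])
  con <- if (identical(path, "-")) stdout() else file(path, "w")
  if (!identical(path, "-")) on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Writes the trajectory with the exact header
#' `t_days,Cs,CN,CT,CI,Cs_star,CN_star,CT_star,CI_star` at full double
#' precision (round-trippable), no row names. `path = "-"` streams to
#' standard output.
#'
#' @param trajectory A `pbpk_trajectory` from [simulate_pbpk()].
#' @param path Output path or `"-"`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  cols <- c("t_days", "Cs", "CN", "CT", "CI",
            "Cs_star", "CN_star", "CT_star", "CI_star")
  if (!all(cols %in% names(trajectory)))
    stop("'trajectory' is missing required columns", call. = FALSE)
  .write_csv_full(as.data.frame(trajectory)[, cols], path)
}

#' Derived-quantity report
#'
#' Collects the closed-form derived quantities for a parameterization:
#' the local and systemic buildup time points, the critical release rate,
#' the hypermagnesemia onset time for the configured implant load, the
#' per-compartment contribution shares to the systemic time, the minimum
#' implant count reaching hypermagnesemia, and the homeostasis-preserving
#' intake factor.
#'
#' @inheritParams time_scales
#' @return Data frame with columns `quantity`, `value`, `units`.
#' @export
derived_report <- function(params = physiology_params(),
                           implant = scale_implants(params = params)) {
  ts <- time_scales(params, implant)
  sh <- sigma_hyp(params, implant)
  th <- t_hyp(params, implant)
  rho_h <- rho_for_target(params, implant, "homeostasis")
  nmin <- min_implants_hyper(params, implant$sigma0, implant$VI0)
  data.frame(
    quantity = c("T1", "TMg", "sigma_hyp", "T_hyp",
                 "share_serum", "share_rbc", "share_bone", "share_tissue",
                 "min_implants", "rho_homeostasis"),
    value = c(ts$T1, ts$TMg, sh, th, unname(ts$shares), nmin,
              rho_h$rho_raw),
    units = c("days", "days", "mmol/day", "days",
              "-", "-", "-", "-", "count", "-"))
}

#' Write a quantity/value/units table as CSV
#'
#' @param report A data frame with columns `quantity`, `value`, `units`
#'   (e.g. from [derived_report()]).
#' @param path Output path or `"-"` for standard output.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  .write_csv_full(report, path)
}
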