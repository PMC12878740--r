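#' Named scenario specifications
#'
#' Builds a scenario specification reproducing the model's benchmark
#' experiments. Built-in presets:
#'
#' * `"standard"`: a single 3.2 x 32 mm screw (`sigma = 0.05` mmol/day),
#'   healthy physiology, normal diet.
#' * `"multi_implant"`: sweep over implant counts `n = 1, 5, 10, 20, 29,
#'   50`, bracketing the hypermagnesemia threshold count `n = 29`.
#' * `"plate"`: a large plate releasing 10 mmol/day into about 1.2 L of
#'   tissue (`xi ~ 0.023`), the human-scaled analogue of a subcutaneous
#'   rat-plate experiment.
#' * `"diet_control"`: severely reduced kidney function
#'   (`gamma = gamma0 / 3`) with `n = 20` implants, sweeping the external
#'   intake factor `rho` over 1, 0.833 (the homeostasis-preserving value
#'   `1 - sigma/phiD` for healthy intake), 0.5 (the value highlighted for
#'   this renal state) and 0.
#' * `"renal_sweep"`: steady-state and one-year serum levels against the
#'   kidney-function parameter `Gamma = gamma/k1` (see [sweep_renal()]).
#' * `"thyp_curve"`: hypermagnesemia onset time against release rate for
#'   several renal states (see [sweep_thyp()]).
#'
#' @param name Preset name (see above).
#' @param params Base [physiology_params()].
#' @param t_grid Time grid for trajectory presets.
#' @param sigma0,VI0 Per-implant reference values.
#' @param method Solution path passed to [simulate_pbpk()].
#' @param ... Preset-specific overrides: `n_values` (multi_implant),
#'   `rho_values` (diet_control), `renal_fraction` (diet_control),
#'   `Gamma_grid`/`implant_counts` (renal_sweep), `sigma_grid`/
#'   `renal_fractions` (thyp_curve).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("standard", "multi_implant", "plate",
                                   "diet_control", "renal_sweep",
                                   "thyp_curve"),
                          params = physiology_params(),
                          t_grid = default_time_grid(),
                          sigma0 = 0.05, VI0 = 0.00527,
                          method = c("numeric", "closed_form"), ...) {
  name <- match.arg(name)
  method <- match.arg(method)
  validate_params(params)
  extra <- list(...)
  spec <- list(name = name, params = params, t_grid = t_grid,
               sigma0 = sigma0, VI0 = VI0, method = method,
               options = extra)
  class(spec) <- "scenario_spec"
  spec
}

# Expand a scenario spec into a list of (label, sweep_var, sweep_value,
# params, implant, rho) runs.
.scenario_runs <- function(spec) {
  p <- spec$params
  opt <- spec$options
  switch(spec$name,
    standard = list(list(sweep_var = "n", sweep_value = 1,
                         params = p,
                         implant = scale_implants(1, spec$sigma0, spec$VI0, p),
                         rho = 1)),
    multi_implant = {
      ns <- opt$n_values %||% c(1, 5, 10, 20, 29, 50)
      lapply(ns, function(n)
        list(sweep_var = "n", sweep_value = n, params = p,
             implant = scale_implants(n, spec$sigma0, spec$VI0, p),
             rho = 1))
    },
    plate = list(list(sweep_var = "sigma", sweep_value = 10, params = p,
                      implant = scale_implants(1, 10, 1.2, p),
                      rho = 1)),
    diet_control = {
      rf <- opt$renal_fraction %||% (1 / 3)
      n <- opt$n %||% 20
      rhos <- opt$rho_values %||% c(1, 1 - n * spec$sigma0 / p$phiD, 0.5, 0)
      padj <- renal_adjust(p, rf)
      lapply(rhos, function(r)
        list(sweep_var = "rho", sweep_value = r, params = padj,
             implant = scale_implants(n, spec$sigma0, spec$VI0, padj),
             rho = r))
    },
    stop("preset '", spec$name, "' is a derived-value sweep; ",
         "run_scenario() dispatches it directly", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named scenario
#'
#' Executes the scenario and returns a tidy long-format table. Trajectory
#' presets (`standard`, `multi_implant`, `plate`, `diet_control`) return
#' one row per (sweep value, time point, compartment) with both absolute
#' and normalized concentrations. Derived-value presets (`renal_sweep`,
#' `thyp_curve`) return the corresponding sweep table reshaped to
#' `scenario, renal_fraction_or_Gamma, n_or_sigma, quantity, value`.
#' Output is deterministic given the spec.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame (long format).
#' @examples
#' tab <- run_scenario(scenario_spec("standard",
#'                                   t_grid = default_time_grid(n = 60),
#'                                   method = "closed_form"))
#' subset(tab, compartment == "Cs" & t_days == max(t_days))
#' @export
run_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec"))
    stop("'spec' must be a scenario_spec", call. = FALSE)
  if (spec$name == "renal_sweep") {
    opt <- spec$options
    tab <- sweep_renal(spec$params,
                       implant_counts = opt$implant_counts %||%
                         c(1, 5, 10, 15, 20, 29),
                       Gamma_grid = opt$Gamma_grid,
                       sigma0 = spec$sigma0, VI0 = spec$VI0)
    long <- rbind(
      data.frame(scenario = spec$name,
                 renal_fraction_or_Gamma = tab$Gamma, n_or_sigma = tab$n,
                 quantity = "Cs_inf_star", value = tab$Cs_inf_star),
      data.frame(scenario = spec$name,
                 renal_fraction_or_Gamma = tab$Gamma, n_or_sigma = tab$n,
                 quantity = "Cs_star_1yr", value = tab$Cs_star_1yr))
    return(long[order(long$renal_fraction_or_Gamma, long$n_or_sigma), ])
  }
  if (spec$name == "thyp_curve") {
    opt <- spec$options
    tab <- sweep_thyp(spec$params,
                      sigma_grid = opt$sigma_grid %||%
                        seq(0.05, 5, by = 0.05),
                      renal_fractions = opt$renal_fractions %||%
                        c(1, 2 / 3, 1 / 3),
                      sigma0 = spec$sigma0, VI0 = spec$VI0)
    return(data.frame(scenario = spec$name,
                      renal_fraction_or_Gamma = tab$renal_fraction,
                      n_or_sigma = tab$sigma,
                      quantity = "T_hyp", value = tab$T_hyp))
  }
  runs <- .scenario_runs(spec)
  comp <- c("Cs", "CN", "CT", "CI")
  out <- lapply(runs, function(r) {
    tr <- simulate_pbpk(r$params, r$implant, r$rho,
                        t_grid = spec$t_grid, method = spec$method)
    nt <- nrow(tr)
    data.frame(scenario = spec$name,
               sweep_var = r$sweep_var,
               sweep_value = r$sweep_value,
               t_days = rep(tr$t_days, times = 4L),
               compartment = rep(comp, each = nt),
               C_mmol_per_L = c(tr$Cs, tr$CN, tr$CT, tr$CI),
               C_star = c(tr$Cs_star, tr$CN_star, tr$CT_star, tr$CI_star))
  })
  do.call(rbind, out)
}

#' Renal-function sweep of steady-state and one-year serum levels
#'
#' Evaluates, over a grid of the kidney-function parameter
#' `Gamma = gamma/k1`, the long-run normalized serum concentration
#' (exact steady state `1 + sigma/phiD`) and the level one year after
#' implantation (single-exponential approximation evaluated at 365 days)
#' for several implant counts. Each `Gamma` point is realised by
#' [renal_adjust()], so the dietary intake covaries with the excretion
#' rate and the pre-implant state stays at homeostasis; this is why the
#' serum burden rises as `Gamma` falls.
#'
#' @param params Healthy-reference [physiology_params()].
#' @param implant_counts Integer vector of implant counts (0 allowed:
#'   no implant).
#' @param Gamma_grid Grid of `Gamma` values in `(0, Gamma0]`; default 21
#'   log-spaced points from `Gamma0/10` to `Gamma0`.
#' @param sigma0,VI0 Per-implant reference values.
#' @return Data frame with columns `Gamma`, `renal_fraction`, `n`,
#'   `Cs_inf_star`, `Cs_star_1yr`.
#' @export
sweep_renal <- function(params = physiology_params(),
                        implant_counts = c(1, 5, 10, 15, 20, 29),
                        Gamma_grid = NULL,
                        sigma0 = 0.05, VI0 = 0.00527) {
  validate_params(params)
  G0 <- Gamma_ratio(params)
  if (is.null(Gamma_grid))
    Gamma_grid <- G0 * exp(seq(log(0.1), 0, length.out = 21))
  if (any(Gamma_grid <= 0))
    stop("'Gamma_grid' values must be > 0", call. = FALSE)
  if (any(Gamma_grid > G0 * (1 + 1e-12)))
    stop("'Gamma_grid' values must not exceed the healthy Gamma0 = ",
         format(G0), call. = FALSE)
  rows <- list()
  for (G in Gamma_grid) {
    frac <- min(1, G / G0)
    padj <- renal_adjust(params, frac)
    for (n in implant_counts) {
      if (n == 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(Gamma = G, renal_fraction = frac, n = 0,
                     Cs_inf_star = 1, Cs_star_1yr = 1)
        next
      }
      impl <- scale_implants(n, sigma0, VI0, padj)
      ss <- steady_state(padj, impl, rho = 1)
      ap <- approx_trajectory(padj, impl, rho = 1, t_grid = c(0, 365))
      rows[[length(rows) + 1L]] <-
        data.frame(Gamma = G, renal_fraction = frac, n = n,
                   Cs_inf_star = unname(ss["Cs_star"]),
                   Cs_star_1yr = ap$Cs_star[2L])
    }
  }
  do.call(rbind, rows)
}

#' Hypermagnesemia onset-time sweep
#'
#' Tabulates the onset time [t_hyp()] against the total implant release
#' rate for several renal states. Renal adjustment scales both `gamma`
#' and `phiD`, entering both the systemic time point `TMg` and the
#' critical rate [sigma_hyp()]. Release rates at or below the critical
#' rate report `Inf` (hypermagnesemia never reached).
#'
#' @param params Healthy-reference [physiology_params()].
#' @param sigma_grid Total release rates (mmol/day), e.g. 0.05-5
#'   corresponding to 1-100 standard screws.
#' @param renal_fractions Fractions of healthy excretion capacity.
#' @param sigma0,VI0 Per-implant reference values (set the implant-zone
#'   volume scaling `VI = sigma/sigma0 * VI0`).
#' @return Data frame with columns `renal_fraction`, `sigma`,
#'   `sigma_hyp`, `T_hyp`.
#' @export
sweep_thyp <- function(params = physiology_params(),
                       sigma_grid = seq(0.05, 5, by = 0.05),
                       renal_fractions = c(1, 2 / 3, 1 / 3),
                       sigma0 = 0.05, VI0 = 0.00527) {
  validate_params(params)
  if (any(sigma_grid <= 0))
    stop("'sigma_grid' values must be > 0", call. = FALSE)
  rows <- list()
  for (rf in renal_fractions) {
    padj <- renal_adjust(params, rf)
    for (sg in sigma_grid) {
      impl <- scale_implants(sg / sigma0, sigma0, VI0, padj)
      sh <- sigma_hyp(padj, impl)
      rows[[length(rows) + 1L]] <-
        data.frame(renal_fraction = rf, sigma = sg, sigma_hyp = sh,
                   T_hyp = t_hyp(padj, impl, sigma = sg))
    }
  }
  do.call(rbind, rows)
}
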