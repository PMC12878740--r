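#' Characteristic buildup time scales
#'
#' Computes the two characteristic "time points" (63.2%-of-change times)
#' of the model:
#'
#' * `T1 = V_T (1 + xi3) / k_1`, the fast local buildup of Mg in the
#'   tissue surrounding the implant (about 6 days at defaults), where
#'   `V_T = (1 - xi) VTtot` is the bulk tissue volume;
#' * `TMg = (1/gamma) * ((1 + xi1) Vs + xi2 Vr + (mu1/mu_1) phi VN +
#'   (1 + xi3) (k1/k_1) VTtot)`, the slow systemic rise toward the new
#'   steady state (about 104 days at defaults).
#'
#' `TMg` is a volume-weighted Mg storage capacity divided by the excretion
#' rate; it is independent of the implant release rate. The fractional
#' contribution of each capacity term (serum, RBC, bone, tissue) is
#' returned in `shares`: at default parameters tissue holds ~74% and bone
#' ~25% of the systemic buildup time.
#'
#' @param params A [physiology_params()] object.
#' @param implant A [scale_implants()] configuration (supplies `xi`).
#' @return An object of class `time_scales`: list with `T1`, `TMg` (days)
#'   and `shares` (named fractions summing to 1).
#' @export
time_scales <- function(params = physiology_params(),
                        implant = scale_implants(params = params)) {
  validate_params(params)
  xi <- implant$xi
  T1 <- (1 - xi) * params$VTtot * (1 + params$xi3) / params$k_1
  terms <- c(serum = (1 + params$xi1) * params$Vs,
             rbc = params$xi2 * params$Vr,
             bone = params$mu1 / params$mu_1 * params$phi * params$VN,
             tissue = (1 + params$xi3) * params$k1 / params$k_1 *
               params$VTtot)
  structure(list(T1 = T1,
                 TMg = sum(terms) / params$gamma,
                 shares = terms / sum(terms)),
            class = "time_scales")
}

#' @export
print.time_scales <- function(x, ...) {
  cat(sprintf("Local buildup time point   T1  = %.3g days\n", x$T1))
  cat(sprintf("Systemic buildup time point TMg = %.4g days\n", x$TMg))
  cat("Contributions to TMg:",
      paste(sprintf("%s %.1f%%", names(x$shares), 100 * x$shares),
            collapse = ", "), "\n")
  invisible(x)
}

#' Critical implant release rate for hypermagnesemia
#'
#' The total release rate above which the long-run serum concentration
#' exceeds the hypermagnesemia threshold:
#' `sigma_hyp = phiD * (C_hyp/C_hom - 1) * (1 - xi)`. At default
#' parameters this is about 1.41 mmol/day, roughly 28 standard screws.
#'
#' @inheritParams time_scales
#' @return Critical release rate (mmol/day).
#' @export
sigma_hyp <- function(params = physiology_params(),
                      implant = scale_implants(params = params)) {
  validate_params(params)
  Chyp_star <- params$C_hyp / params$C_hom
  if (Chyp_star <= 1)
    stop("hypermagnesemia threshold C_hyp must exceed C_hom", call. = FALSE)
  params$phiD * (Chyp_star - 1) * (1 - implant$xi)
}

#' Hypermagnesemia onset time
#'
#' For a release rate `sigma` above the critical rate [sigma_hyp()], the
#' serum concentration crosses the hypermagnesemia threshold at
#' approximately `T_hyp = TMg * log(sigma / (sigma - sigma_hyp))`. When
#' `sigma <= sigma_hyp` the threshold is never reached and `Inf` is
#' returned (not an error): hypermagnesemia does not occur.
#'
#' @inheritParams time_scales
#' @param sigma Total Mg release rate (mmol/day); defaults to the
#'   configured implant total.
#' @return Onset time in days, or `Inf` if never reached.
#' @export
t_hyp <- function(params = physiology_params(),
                  implant = scale_implants(params = params),
                  sigma = implant$sigma) {
  sh <- sigma_hyp(params, implant)
  if (sigma <= sh) return(Inf)
  ts <- time_scales(params, implant)
  ts$TMg * log(sigma / (sigma - sh))
}

#' Closed-form approximate trajectory (normalized)
#'
#' Two-exponential approximation valid for small implant-zone fraction
#' `xi`. Serum, bone and bulk tissue share a single systemic exponential
#' with time point `TMg`:
#' `C* ~ 1 + (rho - 1 + sigma / ((1 - xi) phiD)) (1 - exp(-t/TMg))`,
#' which reduces to the standard result at `rho = 1`. The implant zone
#' adds the fast local term
#' `(sigma gamma / (k1 phiD)) (V_T / V_I) (1 - exp(-t/T1))`.
#' At `t -> Inf` the systemic level converges to the exact steady state
#' up to O(xi).
#'
#' @inheritParams time_scales
#' @param rho External intake factor in `[0, 1]`.
#' @param t_grid Time grid (days).
#' @return Data frame with `t_days` and normalized `Cs_star`, `CN_star`,
#'   `CT_star`, `CI_star`.
#' @export
approx_trajectory <- function(params = physiology_params(),
                              implant = scale_implants(params = params),
                              rho = 1,
                              t_grid = default_time_grid()) {
  validate_params(params)
  if (implant$xi > 0.05)
    warning("approximation assumes xi << 1; xi = ",
            format(implant$xi), call. = FALSE)
  ts <- time_scales(params, implant)
  S <- implant$sigma / ((1 - implant$xi) * params$phiD)
  VT <- (1 - implant$xi) * params$VTtot
  L <- implant$sigma * params$gamma / (params$k1 * params$phiD) *
    VT / implant$VI
  systemic <- 1 + (rho - 1 + S) * (1 - exp(-t_grid / ts$TMg))
  CI <- systemic + L * (1 - exp(-t_grid / ts$T1))
  data.frame(t_days = t_grid,
             Cs_star = systemic, CN_star = systemic, CT_star = systemic,
             CI_star = CI)
}

#' Minimum normalized serum level under intake reduction
#'
#' When external Mg intake is reduced to a fraction `rho` at `t = 0`, the
#' serum concentration dips on a fast time scale to the quasi-steady level
#' `Cs_min* = 1 + (rho - 1) * gamma / k1`
#' before the slow reserve dynamics take over: tissue and bone stores
#' buffer the serum. At default parameters and zero intake (`rho = 0`)
#' the maximal drop is `gamma / k1` (about 8%), comfortably above the
#' hypomagnesemia range (normalized ~0.76-0.88).
#'
#' This value describes the early dip. It is the trajectory minimum only
#' when the long-run steady state (`rho + sigma/phiD`) lies above it, so
#' that the serum rebounds; otherwise the trajectory continues to fall
#' slowly past the dip as the stores deplete.
#'
#' @param params A [physiology_params()] object.
#' @param rho External intake factor in `[0, 1]`.
#' @return Normalized serum concentration (dimensionless).
#' @export
min_serum_normalized <- function(params = physiology_params(), rho = 1) {
  validate_params(params)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("'rho' must lie in [0, 1]", call. = FALSE)
  1 + (rho - 1) * params$gamma / params$k1
}

#' Dietary intake factor for a clinical target
#'
#' Solves the long-run steady state for the intake factor `rho` that
#' achieves a target serum level:
#' * `"homeostasis"`: `rho = 1 - sigma/phiD`, keeping long-run serum at
#'   the homeostatic level;
#' * `"avoid_hyper"`: `rho = C_hyp* - sigma/phiD`, the largest intake that
#'   still avoids hypermagnesemia.
#'
#' A negative raw value means the target cannot be met by dietary control
#' alone (the implant release already exceeds the budget); this is
#' reported through the `feasible` flag, with `rho` clamped into `[0, 1]`.
#'
#' @inheritParams time_scales
#' @param target `"homeostasis"` or `"avoid_hyper"`.
#' @return List with `target`, `rho_raw`, `rho` (clamped), `feasible`.
#' @export
rho_for_target <- function(params = physiology_params(),
                           implant = scale_implants(params = params),
                           target = c("homeostasis", "avoid_hyper")) {
  validate_params(params)
  target <- match.arg(target)
  raw <- switch(target,
                homeostasis = 1 - implant$sigma / params$phiD,
                avoid_hyper = params$C_hyp / params$C_hom -
                  implant$sigma / params$phiD)
  list(target = target,
       rho_raw = raw,
       rho = min(1, max(0, raw)),
       feasible = raw >= 0)
}

#' Minimum implant count causing hypermagnesemia
#'
#' Scans the implant count upward and returns the smallest `n` whose
#' long-run normalized serum level `1 + n sigma0 / phiD` reaches the
#' hypermagnesemia threshold `C_hyp/C_hom`. The scan stops at the
#' non-overlap bound `n VI0 < VTtot`. At default parameters the answer
#' is 29 standard screws.
#'
#' @param params A [physiology_params()] object.
#' @param sigma0 Per-implant release rate (mmol/day).
#' @param VI0 Per-implant affected-tissue volume (L).
#' @return Integer count.
#' @export
min_implants_hyper <- function(params = physiology_params(),
                               sigma0 = 0.05, VI0 = 0.00527) {
  validate_params(params)
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 <= 0)
    stop("'sigma0' must be > 0", call. = FALSE)
  Chyp_star <- params$C_hyp / params$C_hom
  n_max <- floor(params$VTtot / VI0)
  for (n in seq_len(n_max)) {
    if (n * VI0 >= params$VTtot) break
    if (1 + n * sigma0 / params$phiD >= Chyp_star) return(n)
  }
  stop("hypermagnesemia not reachable before implant zones overlap ",
       "the whole tissue volume", call. = FALSE)
}
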