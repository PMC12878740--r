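#' Physiological parameters of the magnesium PBPK model
#'
#' Constructs the set of physiological constants driving the four-compartment
#' magnesium model: compartment volumes, exchange rate constants between
#' serum and the bone/tissue stores, the urinary excretion rate constant,
#' the dietary intake rate after intestinal absorption, the equilibrium
#' ratio constants absorbing the non-exchangeable ("unexposed") Mg pools,
#' and the clinical serum thresholds. Defaults are the published estimates
#' for a healthy adult.
#'
#' Units are fixed throughout the package: volumes in litres, rates in
#' mmol/day, rate constants in L/day, concentrations in mmol/L, time in days.
#'
#' @param Vs Serum compartment volume (L).
#' @param Vr Red-blood-cell volume (L).
#' @param VN Bone volume (L).
#' @param VTtot Total soft-tissue volume (L).
#' @param phiD Dietary Mg intake rate after intestinal absorption (mmol/day).
#' @param gamma Urinary excretion rate constant (L/day).
#' @param mu1,mu_1 Serum-to-bone and bone-to-serum exchange rate constants
#'   (L/day).
#' @param k1,k_1 Serum-to-tissue and tissue-to-serum exchange rate constants
#'   (L/day).
#' @param phi Volume fraction of exchangeable Mg in bone (dimensionless,
#'   in (0, 1]).
#' @param xi1 Equilibrium ratio of unexposed to exposed Mg in serum.
#' @param xi2 Equilibrium ratio of exposed RBC to exposed serum Mg.
#' @param xi3 Equilibrium ratio of unexposed to exposed Mg in tissue.
#' @param C_hom Homeostatic total serum Mg concentration (mmol/L).
#' @param C_hyp Hypermagnesemia threshold, total serum Mg (mmol/L).
#' @param C_sev Severe-symptom threshold, total serum Mg (mmol/L).
#'
#' @return An object of class `physiology_params` (a validated named list).
#' @seealso [validate_params()], [homeostatic_state()], [renal_adjust()]
#' @examples
#' p <- physiology_params()
#' homeostatic_state(p)
#' @export
physiology_params <- function(Vs = 3, Vr = 2, VN = 12.3, VTtot = 52.7,
                              phiD = 6, gamma = 10.9,
                              mu1 = 6.05, mu_1 = 0.0775,
                              k1 = 138, k_1 = 34.7,
                              phi = 0.3,
                              xi1 = 0.538, xi2 = 0.452, xi3 = 3.00,
                              C_hom = 0.85, C_hyp = 1.05, C_sev = 2.9) {
  p <- list(Vs = Vs, Vr = Vr, VN = VN, VTtot = VTtot,
            phiD = phiD, gamma = gamma,
            mu1 = mu1, mu_1 = mu_1, k1 = k1, k_1 = k_1,
            phi = phi, xi1 = xi1, xi2 = xi2, xi3 = xi3,
            C_hom = C_hom, C_hyp = C_hyp, C_sev = C_sev)
  class(p) <- "physiology_params"
  validate_params(p)
}

#' Validate a physiological parameter set
#'
#' Checks the structural invariants of the model parameters: strict
#' positivity of volumes, rate constants and the intake rate, `phi` in
#' (0, 1], non-negative equilibrium ratio constants, and the clinical
#' threshold ordering `C_hom < C_hyp < C_sev`. The first violated
#' invariant is reported by name.
#'
#' @param p A `physiology_params` object (or a compatible named list).
#' @return `p`, unchanged, invisibly classed as `physiology_params`.
#' @export
validate_params <- function(p) {
  if (!is.list(p)) stop("params must be a list", call. = FALSE)
  needed <- c("Vs", "Vr", "VN", "VTtot", "phiD", "gamma", "mu1", "mu_1",
              "k1", "k_1", "phi", "xi1", "xi2", "xi3",
              "C_hom", "C_hyp", "C_sev")
  miss <- setdiff(needed, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in needed) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  pos <- c("Vs", "Vr", "VN", "VTtot", "phiD", "gamma", "mu1", "mu_1",
           "k1", "k_1", "C_hom", "C_hyp", "C_sev")
  for (nm in pos) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ",
           format(p[[nm]]), ")", call. = FALSE)
  }
  if (p$phi <= 0 || p$phi > 1)
    stop("parameter 'phi' must lie in (0, 1] (got ", format(p$phi), ")",
         call. = FALSE)
  for (nm in c("xi1", "xi2", "xi3")) {
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$C_hyp <= p$C_hom)
    stop("threshold ordering violated: C_hyp (", format(p$C_hyp),
         ") must exceed C_hom (", format(p$C_hom), ")", call. = FALSE)
  if (p$C_sev <= p$C_hyp)
    stop("threshold ordering violated: C_sev (", format(p$C_sev),
         ") must exceed C_hyp (", format(p$C_hyp), ")", call. = FALSE)
  class(p) <- "physiology_params"
  invisible(p)
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("Mg PBPK physiological parameters\n")
  cat(sprintf("  volumes (L): Vs=%g Vr=%g VN=%g VTtot=%g\n",
              x$Vs, x$Vr, x$VN, x$VTtot))
  cat(sprintf("  intake/excretion: phiD=%g mmol/day, gamma=%g L/day\n",
              x$phiD, x$gamma))
  cat(sprintf("  exchange (L/day): mu1=%g mu_1=%g k1=%g k_1=%g\n",
              x$mu1, x$mu_1, x$k1, x$k_1))
  cat(sprintf("  pools: phi=%g xi1=%g xi2=%g xi3=%g\n",
              x$phi, x$xi1, x$xi2, x$xi3))
  cat(sprintf("  thresholds (mmol/L): C_hom=%g C_hyp=%g C_sev=%g\n",
              x$C_hom, x$C_hyp, x$C_sev))
  invisible(x)
}

#' Implant configuration and multi-implant scaling
#'
#' Scales the per-implant Mg release rate `sigma0` and affected-tissue
#' volume `VI0` to `n` identical implants: the total release rate is
#' `sigma = n * sigma0`, the total implant-zone volume `VI = n * VI0`, and
#' the implant-zone fraction of tissue `xi = VI / VTtot`. The implant zones
#' are assumed not to overlap, which requires `xi < 1`. Non-integer `n`
#' is accepted to represent a single larger or porous implant with `n`
#' times the surface area of the reference screw.
#'
#' The defaults describe a standard 3.2 x 32 mm screw: release rate
#' 0.05 mmol/day into roughly 5.3 mL of surrounding tissue.
#'
#' @param n Number of implants (>= minimal positive count; may be
#'   non-integer for an equivalent larger device).
#' @param sigma0 Per-implant Mg(II) release rate (mmol/day).
#' @param VI0 Per-implant affected-tissue volume (L).
#' @param params A [physiology_params()] object supplying `VTtot`.
#' @return An object of class `implant_config` with fields `n`, `sigma0`,
#'   `VI0`, `sigma`, `VI`, `xi`.
#' @examples
#' scale_implants(n = 20)
#' @export
scale_implants <- function(n = 1, sigma0 = 0.05, VI0 = 0.00527,
                           params = physiology_params()) {
  validate_params(params)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("implant count 'n' must be a single number >= 1", call. = FALSE)
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 < 0)
    stop("per-implant release rate 'sigma0' must be >= 0 (0 = inert implant)",
         call. = FALSE)
  if (!is.numeric(VI0) || length(VI0) != 1L || VI0 <= 0)
    stop("per-implant zone volume 'VI0' must be > 0", call. = FALSE)
  VI <- n * VI0
  xi <- VI / params$VTtot
  if (xi >= 1)
    stop("implant zones would overlap the whole tissue compartment: ",
         "n*VI0 = ", format(VI), " L >= VTtot = ", format(params$VTtot),
         " L (xi >= 1)", call. = FALSE)
  structure(list(n = n, sigma0 = sigma0, VI0 = VI0,
                 sigma = n * sigma0, VI = VI, xi = xi),
            class = "implant_config")
}

#' @export
print.implant_config <- function(x, ...) {
  cat(sprintf(
    "Implant config: n=%g, sigma0=%g mmol/day, VI0=%g L -> sigma=%g mmol/day, VI=%g L, xi=%.3g\n",
    x$n, x$sigma0, x$VI0, x$sigma, x$VI, x$xi))
  invisible(x)
}

#' Intervention settings: dietary intake factor and renal function
#'
#' Bundles the two clinical intervention handles of the model: `rho`, the
#' multiplicative factor on external (dietary/drug) Mg intake (1 = normal
#' diet, 0 = zero external intake), and `renal_fraction`, the kidney
#' excretion capacity relative to healthy (`gamma / gamma0`; 1 = healthy).
#'
#' @param rho External Mg intake factor, in `[0, 1]`.
#' @param renal_fraction Fraction of healthy urinary excretion capacity,
#'   in `(0, 1]`.
#' @return An object of class `intervention_config`.
#' @export
intervention_config <- function(rho = 1, renal_fraction = 1) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("'rho' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(renal_fraction) || length(renal_fraction) != 1L ||
      renal_fraction <= 0 || renal_fraction > 1)
    stop("'renal_fraction' must lie in (0, 1]", call. = FALSE)
  structure(list(rho = rho, renal_fraction = renal_fraction),
            class = "intervention_config")
}

#' Adjust parameters for reduced kidney function
#'
#' Reduced kidney function is modelled by scaling the urinary excretion
#' rate constant `gamma` by `renal_fraction`, with the dietary intake rate
#' `phiD` reduced by the same factor so that the pre-implant homeostatic
#' serum concentration `phiD / gamma` is unchanged. This covariation
#' mirrors the clinical situation in which intake is managed so that a
#' renally impaired patient is still at Mg homeostasis before implantation.
#'
#' @param params A [physiology_params()] object.
#' @param renal_fraction Fraction of healthy excretion capacity, in
#'   `(0, 1]`.
#' @return A `physiology_params` object with `gamma` and `phiD` scaled.
#' @examples
#' renal_adjust(physiology_params(), 1 / 3)
#' @export
renal_adjust <- function(params, renal_fraction) {
  validate_params(params)
  if (!is.numeric(renal_fraction) || length(renal_fraction) != 1L ||
      !is.finite(renal_fraction) || renal_fraction <= 0)
    stop("'renal_fraction' must be a single number > 0", call. = FALSE)
  if (renal_fraction > 1)
    stop("'renal_fraction' must be <= 1 (healthy kidneys)", call. = FALSE)
  params$gamma <- renal_fraction * params$gamma
  params$phiD <- renal_fraction * params$phiD
  validate_params(params)
  params
}

#' Homeostatic (pre-implant) equilibrium state
#'
#' The homeostatic exposed concentrations are the steady state of the model
#' without an implant: serum `Cse = phiD / gamma`, bone
#' `CNe = (mu1 / mu_1) * Cse`, tissue `CTe = (k1 / k_1) * Cse`. The
#' implant-zone compartment starts at the tissue level `CTe`. The clinical
#' thresholds are also returned on the normalized scale,
#' `Chyp_star = C_hyp / C_hom` and `Csev_star = C_sev / C_hom`.
#'
#' @param params A [physiology_params()] object.
#' @return An object of class `homeostatic_state` with fields `Cse`, `CNe`,
#'   `CTe` (mmol/L) and `Chyp_star`, `Csev_star` (dimensionless).
#' @export
homeostatic_state <- function(params) {
  validate_params(params)
  Cse <- params$phiD / params$gamma
  structure(list(Cse = Cse,
                 CNe = params$mu1 / params$mu_1 * Cse,
                 CTe = params$k1 / params$k_1 * Cse,
                 Chyp_star = params$C_hyp / params$C_hom,
                 Csev_star = params$C_sev / params$C_hom),
            class = "homeostatic_state")
}

#' @export
print.homeostatic_state <- function(x, ...) {
  cat(sprintf(
    "Homeostatic exposed Mg (mmol/L): serum %.4g, bone %.4g, tissue %.4g\n",
    x$Cse, x$CNe, x$CTe))
  cat(sprintf("Normalized thresholds: C_hyp* = %.4g, C_sev* = %.4g\n",
              x$Chyp_star, x$Csev_star))
  invisible(x)
}

#' Dimensionless kidney-function parameter
#'
#' Returns `Gamma = gamma / k1`, the ratio of urinary excretion to
#' serum-to-tissue exchange. The healthy value at the default parameters
#' is about 0.079. `Gamma` is read-only: renal interventions are expressed
#' through [renal_adjust()] so that `gamma` and `phiD` always covary.
#'
#' @param params A [physiology_params()] object.
#' @return A single dimensionless number.
#' @export
Gamma_ratio <- function(params) {
  validate_params(params)
  params$gamma / params$k1
}
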