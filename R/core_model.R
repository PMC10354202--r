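#' Thermal context for rate calculations
#'
#' Bundles the absolute temperature with the thermal energy \code{kT} in the
#' units used throughout (pN nm). At the default 298 K, \code{kT} is about
#' 4.114 pN nm.
#'
#' @param temperature_K Absolute temperature in kelvin (> 0).
#' @return An object of class \code{thermal_context} with fields
#'   \code{temperature_K} and \code{kT_pN_nm}.
#' @examples
#' th <- thermal_context()
#' th$kT_pN_nm
#' @export
thermal_context <- function(temperature_K = 298) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  kB <- 1.380649e-2  # pN nm / K
  structure(list(temperature_K = temperature_K,
                 kT_pN_nm = kB * temperature_K),
            class = "thermal_context")
}

#' Bell-Evans rate-law parameters
#'
#' A force-dependent first-order rate law k(F) = k0 exp(+/- F x / kT).
#' Force-accelerated transitions (unfolding, unbinding) take the plus sign;
#' force-suppressed transitions (folding, binding) the minus sign.
#'
#' @param k0_per_s Intrinsic (zero-force) rate in 1/s (> 0).
#' @param x_dagger_nm Distance to the transition state in nm (>= 0).
#' @param sense \code{"force_accelerated"} or \code{"force_suppressed"}.
#' @return An object of class \code{bell_evans_params}.
#' @examples
#' flv_unbind <- bell_evans_params(6.6e-3, 0.72, "force_accelerated")
#' @export
bell_evans_params <- function(k0_per_s, x_dagger_nm,
                              sense = c("force_accelerated", "force_suppressed")) {
  sense <- match.arg(sense)
  stopifnot(is.numeric(k0_per_s), length(k0_per_s) == 1L,
            is.finite(k0_per_s), k0_per_s > 0,
            is.numeric(x_dagger_nm), length(x_dagger_nm) == 1L,
            is.finite(x_dagger_nm), x_dagger_nm >= 0)
  structure(list(k0_per_s = k0_per_s, x_dagger_nm = x_dagger_nm, sense = sense),
            class = "bell_evans_params")
}

#' @export
print.bell_evans_params <- function(x, ...) {
  cat(sprintf("Bell-Evans rate law: k0 = %.4g /s, x-dagger = %.3g nm (%s)\n",
              x$k0_per_s, x$x_dagger_nm, x$sense))
  invisible(x)
}

#' Talin folding/unfolding parameter pair
#'
#' Two Bell-Evans branches for the talin rod domain: a force-accelerated
#' unfolding branch and a force-suppressed folding branch.
#'
#' @param unfold,fold \code{bell_evans_params} for the two branches.
#' @return An object of class \code{talin_folding_params}.
#' @export
talin_folding_params <- function(unfold, fold) {
  stopifnot(inherits(unfold, "bell_evans_params"),
            inherits(fold, "bell_evans_params"))
  if (unfold$sense != "force_accelerated")
    stop("unfold branch must be force_accelerated")
  if (fold$sense != "force_suppressed")
    stop("fold branch must be force_suppressed")
  structure(list(unfold = unfold, fold = fold), class = "talin_folding_params")
}

#' Default talin R3(IVVI) folding parameters
#'
#' Placeholder defaults, not taken from a printed table: both branches use a
#' 10 nm distance to the transition state and are calibrated so folding and
#' unfolding exchange at 0.5 /s at a 9 pN coexistence force, the regime where
#' the IVVI-stabilised R3 domain hops in equilibrium. Override with measured
#' values whenever available.
#'
#' @param therm A \code{thermal_context}.
#' @param f_half Coexistence force in pN.
#' @param rate_at_half Common rate at the coexistence force, 1/s.
#' @param x_unfold_nm,x_fold_nm Transition-state distances in nm.
#' @return A \code{talin_folding_params} object.
#' @export
default_talin_params <- function(therm = thermal_context(), f_half = 9,
                                 rate_at_half = 0.5,
                                 x_unfold_nm = 10, x_fold_nm = 10) {
  kT <- therm$kT_pN_nm
  talin_folding_params(
    unfold = bell_evans_params(rate_at_half * exp(-f_half * x_unfold_nm / kT),
                               x_unfold_nm, "force_accelerated"),
    fold = bell_evans_params(rate_at_half * exp(f_half * x_fold_nm / kT),
                             x_fold_nm, "force_suppressed"))
}

#' Biphasic binding-model parameters
#'
#' Couples the vinculin binding branch (force-suppressed Bell-Evans) to talin
#' folding/unfolding so that the observed binding rate is
#' r_B(F) = k_B(F) P_U(F), where P_U is the talin unfolding probability that
#' exposes the cryptic binding sites. Rates refer to the stated vinculin
#' concentration.
#'
#' @param bind \code{bell_evans_params}, sense \code{force_suppressed}.
#' @param talin A \code{talin_folding_params}.
#' @param concentration_nM Vinculin concentration in nM (> 0); the tweezers
#'   experiments use 20 nM.
#' @return An object of class \code{binding_model_params}.
#' @export
binding_model_params <- function(bind, talin, concentration_nM = 20) {
  stopifnot(inherits(bind, "bell_evans_params"),
            inherits(talin, "talin_folding_params"),
            is.numeric(concentration_nM), length(concentration_nM) == 1L,
            is.finite(concentration_nM), concentration_nM > 0)
  if (bind$sense != "force_suppressed")
    stop("binding branch must be force_suppressed")
  structure(list(bind = bind, talin = talin,
                 concentration_nM = concentration_nM),
            class = "binding_model_params")
}

.check_force <- function(force) {
  if (!is.numeric(force) || any(!is.finite(force)))
    stop("force must be finite numeric (pN)")
  if (any(force < 0)) stop("force must be >= 0 pN")
  invisible(force)
}

#' Evaluate a Bell-Evans rate at force
#'
#' k(F) = k0 exp(+F x/kT) for force-accelerated transitions and
#' k0 exp(-F x/kT) for force-suppressed ones. Vectorised over force.
#'
#' @param params A \code{bell_evans_params}.
#' @param force Force in pN (>= 0, finite).
#' @param therm A \code{thermal_context}.
#' @return Rate(s) in 1/s.
#' @examples
#' bell_evans_rate(bell_evans_params(6.6e-3, 0.72, "force_accelerated"), 40)
#' @export
bell_evans_rate <- function(params, force, therm = thermal_context()) {
  stopifnot(inherits(params, "bell_evans_params"),
            inherits(therm, "thermal_context"))
  .check_force(force)
  sgn <- if (params$sense == "force_accelerated") 1 else -1
  params$k0_per_s * exp(sgn * force * params$x_dagger_nm / therm$kT_pN_nm)
}

#' Talin unfolding probability under force
#'
#' P_U(F) = r_U(F) / (r_U(F) + r_F(F)), the equilibrium probability that the
#' talin rod domain is unfolded (binding sites exposed) at force F.
#'
#' @param talin A \code{talin_folding_params}.
#' @param force Force in pN.
#' @param therm A \code{thermal_context}.
#' @return Probability in [0, 1], vectorised over force.
#' @export
unfolding_probability <- function(talin, force, therm = thermal_context()) {
  stopifnot(inherits(talin, "talin_folding_params"))
  rU <- bell_evans_rate(talin$unfold, force, therm)
  rF <- bell_evans_rate(talin$fold, force, therm)
  rU / (rU + rF)
}

#' Biphasic vinculin binding rate
#'
#' r_B(F) = k_B(F) P_U(F): the force-suppressed binding branch times the talin
#' unfolding probability. Increases at low force (site exposure), decreases at
#' high force (the coil-to-helix contraction on binding becomes unfavourable),
#' giving a single interior maximum.
#'
#' @param model A \code{binding_model_params}.
#' @param force Force in pN.
#' @param therm A \code{thermal_context}.
#' @return Rate(s) in 1/s at the model's concentration.
#' @export
binding_rate <- function(model, force, therm = thermal_context()) {
  stopifnot(inherits(model, "binding_model_params"))
  bell_evans_rate(model$bind, force, therm) *
    unfolding_probability(model$talin, force, therm)
}

#' Force-dependent dissociation constant
#'
#' K_d(F) = r_Ub(F) / (r_B(F) / C): the off-rate over the per-concentration
#' on-rate, in the same concentration units as the model (nM).
#'
#' @param model A \code{binding_model_params} (carries the concentration C).
#' @param unbind \code{bell_evans_params} for the unbinding branch.
#' @param force Force in pN.
#' @param therm A \code{thermal_context}.
#' @return Dissociation constant in nM.
#' @export
dissociation_constant <- function(model, unbind, force,
                                  therm = thermal_context()) {
  rB <- binding_rate(model, force, therm)
  if (any(rB <= 0)) stop("binding rate is zero; dissociation constant undefined")
  rUb <- bell_evans_rate(unbind, force, therm)
  rUb * model$concentration_nM / rB
}

#' Crossover force where an unbinding law matches a competing rate
#'
#' Solves k0 exp(F x/kT) = r for F. Used to find the force below which a
#' competing process (e.g. maturation at rate 1/tau) outruns force-induced
#' unbinding. If the competing rate is at or below k0 the crossover would be
#' non-positive; 0 is returned with a warning and attribute
#' \code{below_zero = TRUE}.
#'
#' @param unbind \code{bell_evans_params}, sense \code{force_accelerated},
#'   with \code{x_dagger_nm > 0}.
#' @param competing_rate Competing rate in 1/s (> 0).
#' @param therm A \code{thermal_context}.
#' @return Crossover force in pN.
#' @examples
#' crossover_force(bell_evans_params(6.6e-3, 0.72, "force_accelerated"), 1 / 37)
#' @export
crossover_force <- function(unbind, competing_rate, therm = thermal_context()) {
  stopifnot(inherits(unbind, "bell_evans_params"),
            is.numeric(competing_rate), length(competing_rate) == 1L,
            is.finite(competing_rate), competing_rate > 0)
  if (unbind$sense != "force_accelerated")
    stop("crossover is defined for force-accelerated unbinding laws")
  if (unbind$x_dagger_nm <= 0)
    stop("x_dagger must be > 0 for a unique crossover")
  f <- therm$kT_pN_nm / unbind$x_dagger_nm *
    log(competing_rate / unbind$k0_per_s)
  if (f <= 0) {
    warning("competing rate <= k0: crossover force would be <= 0; returning 0")
    return(structure(0, below_zero = TRUE))
  }
  f
}
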