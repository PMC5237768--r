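#' Simulation configuration
#'
#' Collects every scalar constant of the remodeling method plus the
#' parametric domain definitions. Defaults reproduce the reference femur
#' experiment: daily updates with recycling rate `c = 0.02`, cortical
#' density cap 1.8 g/cm3, density-modulus law `E = 2315 * rho^3` (MPa),
#' and convergence declared when no element density moves by 0.001 g/cm3
#' in a day.
#'
#' @param c Recycling control rate: fraction of the predicted density
#'   change applied per day (dimensionless, default 0.02).
#' @param rho_max Maximum apparent density, the cortical cap (g/cm3).
#' @param rho_min Lower density floor kept strictly positive so the
#'   stiffness matrix stays nonsingular (g/cm3).
#' @param convergence_tol Daily max density change below which the field
#'   is considered converged (g/cm3).
#' @param step_days Iteration step length in days (the method is posed at
#'   1-day resolution).
#' @param density_modulus_coeff,density_modulus_exp Coefficients of the
#'   apparent-density to elastic-modulus power law `E = coeff * rho^exp`
#'   with E in MPa and rho in g/cm3.
#' @param poisson Poisson's ratio used for all elements.
#' @param modulus_floor Minimum element modulus (MPa) so near-void
#'   elements do not make the system singular.
#' @param oc_eta Damping exponent of the optimality-criteria update.
#' @param oc_move Move limit per inner optimality-criteria iteration
#'   (fraction of the current density).
#' @param oc_tol Inner fixed-point tolerance of the optimality-criteria
#'   iteration (g/cm3).
#' @param oc_max_iter Cap on inner optimality-criteria iterations.
#' @param mass_tol Relative tolerance on the mass constraint enforced by
#'   the Lagrange-multiplier bisection.
#' @param new_bone_theta New-bone classification threshold: a defect
#'   element counts as new bone once its bone-attributable density reaches
#'   this fraction of its pre-defect baseline density.
#' @param refill_threshold_frac Refilled-area threshold as a fraction of
#'   the implant's initial equivalent density.
#' @param max_iter Iteration cap for baseline adaptation runs.
#' @param max_days Day cap for defect/implant runs.
#' @param thickness_cm Out-of-plane thickness assumed for element volumes
#'   and the plane-stress solve (cm).
#' @param femur,rat,plate Named lists of domain-generator parameters; see
#'   [generate_femur_domain()], [generate_rat_domain()],
#'   [generate_plate_fixture()]. Entries given here override the defaults.
#'
#' @return A list of class `remodel_config`.
#' @export
remodel_config <- function(c = 0.02,
                           rho_max = 1.8,
                           rho_min = 0.01,
                           convergence_tol = 0.001,
                           step_days = 1,
                           density_modulus_coeff = 2315,
                           density_modulus_exp = 3,
                           poisson = 0.3,
                           modulus_floor = 0.01,
                           oc_eta = 0.25,
                           oc_move = 0.2,
                           oc_tol = 1e-6,
                           oc_max_iter = 200,
                           mass_tol = 1e-10,
                           new_bone_theta = 0.9,
                           refill_threshold_frac = 0.5,
                           max_iter = 2000,
                           max_days = 1000,
                           thickness_cm = 1,
                           femur = list(),
                           rat = list(),
                           plate = list()) {
  stopifnot(
    c >= 0, rho_max > 0, rho_min > 0, rho_min < rho_max,
    convergence_tol > 0, step_days > 0,
    density_modulus_coeff > 0, density_modulus_exp > 0,
    poisson >= 0, poisson < 0.5, modulus_floor > 0,
    oc_eta > 0, oc_eta <= 1, oc_move > 0, oc_move < 1,
    oc_tol > 0, oc_max_iter >= 1, mass_tol > 0,
    new_bone_theta > 0, refill_threshold_frac >= 0,
    max_iter >= 1, max_days >= 1, thickness_cm > 0
  )
  cfg <- list(
    c = c, rho_max = rho_max, rho_min = rho_min,
    convergence_tol = convergence_tol, step_days = step_days,
    density_modulus_coeff = density_modulus_coeff,
    density_modulus_exp = density_modulus_exp,
    poisson = poisson, modulus_floor = modulus_floor,
    oc_eta = oc_eta, oc_move = oc_move, oc_tol = oc_tol,
    oc_max_iter = oc_max_iter, mass_tol = mass_tol,
    new_bone_theta = new_bone_theta,
    refill_threshold_frac = refill_threshold_frac,
    max_iter = max_iter, max_days = max_days,
    thickness_cm = thickness_cm,
    femur = utils::modifyList(femur_domain_defaults(), femur),
    rat = utils::modifyList(rat_domain_defaults(), rat),
    plate = utils::modifyList(plate_domain_defaults(), plate)
  )
  structure(cfg, class = "remodel_config")
}

#' @export
print.remodel_config <- function(x, ...) {
  cat("<remodel_config>\n")
  cat(sprintf("  recycling rate c        : %g /day\n", x$c))
  cat(sprintf("  density bounds          : (%g, %g] g/cm3\n", x$rho_min, x$rho_max))
  cat(sprintf("  density-modulus law     : E = %g * rho^%g MPa\n",
              x$density_modulus_coeff, x$density_modulus_exp))
  cat(sprintf("  convergence tolerance   : %g g/cm3 per day\n", x$convergence_tol))
  cat(sprintf("  new-bone threshold theta: %g of baseline\n", x$new_bone_theta))
  invisible(x)
}

#' Convert apparent density to elastic modulus
#'
#' The cubic density-modulus power law `E = 2315 * rho^3` (E in MPa, rho in
#' g/cm3) relating apparent bone density to isotropic elastic modulus.
#'
#' @param rho Apparent density (g/cm3), strictly positive.
#' @param config A [remodel_config()] supplying the law's coefficients.
#' @return Elastic modulus in MPa, same length as `rho`.
#' @export
#' @examples
#' density_to_modulus(1.0) # 2315 MPa
density_to_modulus <- function(rho, config = remodel_config()) {
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("`rho` must be strictly positive and finite", call. = FALSE)
  }
  config$density_modulus_coeff * rho^config$density_modulus_exp
}

#' Convert elastic modulus back to apparent density
#'
#' Inverse of [density_to_modulus()]: `rho = (E / 2315)^(1/3)` under the
#' default law.
#'
#' @param E Elastic modulus (MPa), strictly positive.
#' @inheritParams density_to_modulus
#' @return Apparent density in g/cm3.
#' @export
modulus_to_density <- function(E, config = remodel_config()) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("`E` must be strictly positive and finite", call. = FALSE)
  }
  (E / config$density_modulus_coeff)^(1 / config$density_modulus_exp)
}
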