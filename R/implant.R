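# Biodegradable implant bookkeeping: the implant loses mechanical modulus
# by a square-root law E1(t) = (1 - t/T)^0.5 * E1_0 and loses mass by a
# quadratic law r(t) = rho_implant_0 * (t/T)^2 (slow early, fast late).
# The two laws are the literature's separate empirical descriptions and
# are not mutually consistent through E = 2315 rho^3; the modulus law
# drives the osteogenesis score, the mass law drives the density
# bookkeeping.

#' Define a biodegradable implant
#'
#' @param E1_0 Initial implant elastic modulus (MPa), > 0.
#' @param T_days Degradation period (days) after which the implant has no
#'   mechanical contribution, > 0.
#' @param config A [remodel_config()] supplying the density-modulus law
#'   used to express the implant as an equivalent apparent density.
#' @return Object of class `implant_state` with fields `E1_0`, `T_days`
#'   and `rho_implant_0 = (E1_0 / 2315)^(1/3)` (g/cm3).
#' @export
#' @examples
#' imp <- implant_state(1000, 20)
#' remaining_modulus(10, imp) # 1000 * sqrt(0.5)
implant_state <- function(E1_0, T_days, config = remodel_config()) {
  if (!is.finite(E1_0) || E1_0 <= 0) abort("`E1_0` must be > 0")
  if (!is.finite(T_days) || T_days <= 0) abort("`T_days` must be > 0")
  structure(
    list(
      E1_0 = E1_0,
      T_days = T_days,
      rho_implant_0 = implant_initial_density(E1_0, config)
    ),
    class = "implant_state"
  )
}

#' @export
print.implant_state <- function(x, ...) {
  cat(sprintf("<implant_state> E1_0 = %g MPa, T = %g days, rho_implant_0 = %.4f g/cm3\n",
              x$E1_0, x$T_days, x$rho_implant_0))
  invisible(x)
}

#' Implant-equivalent initial apparent density
#'
#' Inverts the density-modulus law to express the implant's initial
#' modulus as an apparent density: `(E1_0 / 2315)^(1/3)` by default.
#'
#' @inheritParams implant_state
#' @return Density in g/cm3.
#' @export
implant_initial_density <- function(E1_0, config = remodel_config()) {
  if (any(!is.finite(E1_0)) || any(E1_0 <= 0)) abort("`E1_0` must be > 0")
  modulus_to_density(E1_0, config)
}

#' Remaining implant modulus
#'
#' Square-root degradation law `E1(t) = (1 - t/T)^0.5 * E1_0` for
#' `t < T`, and 0 from the end of the degradation period on.
#'
#' @param t Day (>= 0); vectorized.
#' @param implant An [implant_state()].
#' @return Modulus in MPa.
#' @export
remaining_modulus <- function(t, implant) {
  if (any(!is.finite(t)) || any(t < 0)) abort("`t` must be >= 0")
  sqrt(pmax(0, 1 - t / implant$T_days)) * implant$E1_0
}

#' Cumulative degraded implant density
#'
#' Quadratic (second-order) mass-degradation law
#' `r(t) = rho_implant_0 * (t/T)^2` for `t <= T`, saturating at full
#' degradation `rho_implant_0` afterwards. The per-day loss
#' `r(t+1) - r(t)` increases with t: degradation is slow at early time
#' points and more rapid as time passes.
#'
#' @inheritParams remaining_modulus
#' @return Density in g/cm3.
#' @export
degraded_density <- function(t, implant) {
  if (any(!is.finite(t)) || any(t < 0)) abort("`t` must be >= 0")
  r0 <- implant$rho_implant_0
  ifelse(t >= implant$T_days, r0, r0 * (t / implant$T_days)^2)
}

defect_indices <- function(mesh) {
  idx <- mesh$element_sets$defect
  if (is.null(idx) || length(idx) == 0L) {
    abort("mesh has no (non-empty) 'defect' element set")
  }
  idx
}

#' Osteogenesis score
#'
#' Mean bone-attributable modulus over the implanted (defect) elements:
#' `mean(max(0, 2315 rho_j^3 - E1(t)))` in MPa. At implantation the total
#' element modulus equals the implant modulus, so the score starts at 0;
#' once the implant is fully degraded the score is the mean pure-bone
#' modulus of the regrown defect.
#'
#' @param state A [material_state()].
#' @param implant An [implant_state()].
#' @param t Day.
#' @param mesh A [bone_mesh()] providing the `defect` element set.
#' @param config A [remodel_config()].
#' @return Score in MPa.
#' @export
osteogenesis_score <- function(state, implant, t, mesh,
                               config = remodel_config()) {
  idx <- defect_indices(mesh)
  E1 <- remaining_modulus(t, implant)
  mean(pmax(0, density_to_modulus(state$density[idx], config) - E1))
}

#' New-bone fraction of the defect
#'
#' Fraction (as a percentage) of defect elements whose bone-attributable
#' density, `rho_j(t) - max(rho_implant_0 - r(t), 0)`, has reached
#' `new_bone_theta` times the element's pre-defect baseline density: the
#' element has regrown to (nearly) what the site carried before injury.
#'
#' @inheritParams osteogenesis_score
#' @param baseline Per-element baseline density field of the converged
#'   pre-defect state (full mesh length or one value per defect element).
#' @return Percentage in `[0, 100]`.
#' @export
new_bone_fraction <- function(state, implant, baseline, t, mesh,
                              config = remodel_config()) {
  idx <- defect_indices(mesh)
  if (is.null(baseline)) abort("`baseline` densities are required")
  base <- if (length(baseline) == length(state$density)) baseline[idx]
          else baseline
  if (length(base) != length(idx)) {
    abort("`baseline` must cover the defect elements")
  }
  implant_left <- max(implant$rho_implant_0 - degraded_density(t, implant), 0)
  bone_rho <- state$density[idx] - implant_left
  100 * mean(bone_rho >= config$new_bone_theta * base)
}

#' Refilled defect area
#'
#' Area (mm2) of defect elements whose total apparent density is at or
#' above a radio-visibility threshold: the region still occupied by dense
#' material (remaining implant plus new bone), comparable to the
#' refilled-defect cross-section measured on micro-CT.
#'
#' @inheritParams osteogenesis_score
#' @param threshold Density threshold (g/cm3); defaults to
#'   `refill_threshold_frac` times the implant's initial equivalent
#'   density.
#' @return Area in mm2.
#' @export
refilled_area <- function(state, implant, mesh, t = NULL, threshold = NULL,
                          config = remodel_config()) {
  idx <- defect_indices(mesh)
  if (is.null(threshold)) {
    threshold <- config$refill_threshold_frac * implant$rho_implant_0
  }
  above <- state$density[idx] >= threshold
  sum(mesh$element_area[idx][above]) * 100  # cm2 -> mm2
}
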