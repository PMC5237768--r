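# Remodeling core: predict the density field that minimizes total strain
# energy at fixed total mass and bounded densities, then apply the damped
# daily update.
#
# The prediction holds the current stress field fixed. Because element
# compliance scales as 1/E = 1/(coeff * rho^exp), the strain energy of
# element j at trial density x_j is U_j * (rho_j / x_j)^exp, so the
# constrained minimization is separable:
#
#   minimize   sum_j U_j (rho_j / x_j)^exp
#   subject to sum_j x_j v_j = mass_reference,  rho_min <= x_j <= rho_max
#
# solved by the optimality-criteria (OC) fixed point: x_j is scaled by
# (sensitivity / (lambda v_j))^eta under a move limit, with the Lagrange
# multiplier lambda found by bisection on the mass constraint. At the
# fixed point the energy sensitivity per unit mass, (exp * U_j rho_j^exp
# / x_j^(exp+1)) / v_j, is equal across all elements strictly inside the
# bounds (the KKT condition).

#' Predict the strain-energy-optimal density field
#'
#' Solves the mass-constrained, bound-constrained strain-energy
#' minimization for the next-day target density field by an
#' optimality-criteria iteration (damped multiplicative update with move
#' limit; Lagrange multiplier by bisection on the mass constraint).
#'
#' @param mesh A [bone_mesh()].
#' @param state A [material_state()]; `state$mass_reference` is the mass
#'   the prediction must preserve.
#' @param energies Per-element strain energies (N*mm) from the current
#'   elasticity solve (e.g. `combined_energy()$element_energy`).
#' @param config A [remodel_config()].
#' @return Numeric vector of predicted densities (g/cm3) satisfying the
#'   mass constraint to `config$mass_tol` relative and the bounds
#'   `[rho_min, rho_max]`.
#' @export
predict_density <- function(mesh, state, energies, config = remodel_config()) {
  ne <- n_elements(mesh)
  stopifnot(length(energies) == ne)
  rho <- state$density
  v <- state$volume
  M <- state$mass_reference
  pexp <- config$density_modulus_exp

  mass_max <- sum(config$rho_max * v)
  mass_min <- sum(config$rho_min * v)
  if (M > mass_max * (1 + 1e-12)) {
    abort(sprintf("infeasible mass constraint: reference mass %.6g g exceeds the maximum attainable %.6g g", M, mass_max))
  }
  if (M < mass_min * (1 - 1e-12)) {
    abort(sprintf("infeasible mass constraint: reference mass %.6g g is below the minimum attainable %.6g g", M, mass_min))
  }

  U <- pmax(energies, 0)
  if (all(U <= 0)) {
    # zero stimulus everywhere: the objective is flat, keep the field
    return(rho)
  }

  eta <- config$oc_eta
  zeta <- config$oc_move
  x <- rho
  numer <- pexp * U * rho^pexp  # sensitivity numerator, fixed during inner loop

  for (iter in seq_len(config$oc_max_iter)) {
    # base_j = x_j * (-dPhi/dx_j / v_j)^eta, so candidate(lambda) scales
    # as lambda^-eta under the move-limit and bound clips
    base <- x * (numer / (x^(pexp + 1) * v))^eta
    lower <- pmax(x * (1 - zeta), config$rho_min)
    upper <- pmin(x * (1 + zeta), config$rho_max)
    candidate <- function(lambda) pmin(upper, pmax(lower, base * lambda^-eta))
    mass_of <- function(lambda) sum(candidate(lambda) * v)
    # bracket lambda: mass(lambda) is non-increasing
    lo <- 1; hi <- 1
    it <- 0L
    while (mass_of(lo) < M && it < 600L) { lo <- lo / 10; it <- it + 1L }
    it <- 0L
    while (mass_of(hi) > M && it < 600L) { hi <- hi * 10; it <- it + 1L }
    if (mass_of(lo) < M) {
      # mass unreachable from below even as lambda -> 0: take the upper
      # clip and let later iterations expand the move window
      x_new <- candidate(lo)
    } else if (mass_of(hi) > M) {
      x_new <- candidate(hi)
    } else {
      m_lo <- mass_of(lo)
      for (b in seq_len(300L)) {
        if (abs(m_lo - M) <= config$mass_tol * M || hi / lo - 1 < 1e-15) break
        mid <- sqrt(lo * hi)
        m_mid <- mass_of(mid)
        if (m_mid >= M) { lo <- mid; m_lo <- m_mid } else hi <- mid
      }
      x_new <- candidate(lo)
    }
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < config$oc_tol && abs(sum(x * v) - M) <= 1e-8 * M) break
  }
  if (abs(sum(x * v) - M) > 1e-8 * M) {
    abort(sprintf(paste0(
      "optimality-criteria bisection did not meet the mass constraint: ",
      "target %.8g g, achieved %.8g g after %d iterations"),
      M, sum(x * v), config$oc_max_iter))
  }
  x
}

#' Apply the daily density update
#'
#' Moves every element a fraction `c` of the way toward its predicted
#' density and, on implant elements, additionally removes the day's
#' degraded implant density:
#' `rho <- rho + c * (rho_hat - rho) - implant_loss`. The result is
#' clipped to `[rho_min, rho_max]` and moduli are refreshed through the
#' density-modulus law.
#'
#' @param state A [material_state()].
#' @param rho_hat Predicted density field from [predict_density()].
#' @param implant_loss Per-element density removed by implant degradation
#'   this step (g/cm3); must be zero on non-implant elements. Scalar 0
#'   allowed.
#' @param config A [remodel_config()].
#' @return A new [material_state()] with updated density, moduli and
#'   `mass_reference`.
#' @export
apply_update <- function(state, rho_hat, implant_loss = 0,
                         config = remodel_config()) {
  ne <- length(state$density)
  stopifnot(length(rho_hat) == ne)
  implant_loss <- rep_len(implant_loss, ne)
  if (any(implant_loss[!state$is_implant] != 0)) {
    abort("`implant_loss` must be zero on non-implant elements")
  }
  delta <- config$c * (rho_hat - state$density) - implant_loss
  rho_new <- pmin(config$rho_max, pmax(config$rho_min, state$density + delta))
  update_state_density(state, rho_new, config)
}

#' Daily convergence check
#'
#' The adaptation is converged once no element density changes by the
#' configured tolerance (default 0.001 g/cm3) between consecutive days.
#'
#' @param prev,next_ Density fields of consecutive days (equal length).
#' @param config A [remodel_config()].
#' @return `TRUE` iff `max |next_ - prev| < config$convergence_tol`.
#' @export
check_convergence <- function(prev, next_, config = remodel_config()) {
  if (length(prev) != length(next_)) {
    abort("density fields have different lengths")
  }
  max(abs(next_ - prev)) < config$convergence_tol
}
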