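#' @importFrom dplyr bind_rows mutate arrange
#' @importFrom purrr map map2
NULL

new_simulation_trace <- function(days, density, metrics, mesh,
                                 implant = NULL, baseline = NULL) {
  structure(
    list(days = days, density = density, metrics = metrics,
         implant = implant, baseline = baseline,
         element_area = mesh$element_area,
         defect = mesh$element_sets$defect),
    class = "simulation_trace"
  )
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("<simulation_trace> %d days (%g..%g), %d elements\n",
              length(x$days), min(x$days), max(x$days), nrow(x$density)))
  print(utils::tail(x$metrics, 3))
  invisible(x)
}

#' Tidy a simulation trace
#'
#' @param x A `simulation_trace`.
#' @param ... Unused.
#' @return The per-day metrics as a tibble, one row per day.
#' @export
tidy.simulation_trace <- function(x, ...) x$metrics

#' @rdname tidy.simulation_trace
#' @return For `glance()`: a one-row tibble with the final day's metrics
#'   and run length.
#' @export
glance.simulation_trace <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  dplyr::mutate(last, n_days = length(x$days), .before = 1)
}

# ---- baseline adaptation ----------------------------------------------------

#' Run baseline bone adaptation to convergence
#'
#' Iterates the daily remodeling loop (elastic solve, optimal-density
#' prediction at fixed total mass, damped update) on an intact mesh from a
#' uniform initial density until no element changes by more than the
#' convergence tolerance in a day. This produces the load-adapted baseline
#' density distribution (dense cortical shell, low-density interior) used
#' as the pre-defect reference.
#'
#' @param mesh A [bone_mesh()].
#' @param loads Load groups, e.g. [femur_load_cases()].
#' @param config A [remodel_config()].
#' @param init_density Initial uniform apparent density (g/cm3).
#' @param state Optional [material_state()] to continue from (overrides
#'   `init_density`).
#' @return List with `state` (converged [material_state()]) and `trace`
#'   (a `simulation_trace` of per-day metrics).
#' @export
run_baseline <- function(mesh, loads, config = remodel_config(),
                         init_density = 1.0, state = NULL) {
  if (is.null(state)) {
    state <- material_state(mesh, init_density, config,
                            is_implant = rep(FALSE, n_elements(mesh)))
  }
  metrics <- vector("list", config$max_iter)
  days <- integer(0)
  converged <- FALSE
  residuals <- numeric(0)
  for (iter in seq_len(config$max_iter)) {
    en <- combined_energy(mesh, state, loads, config)
    rho_hat <- predict_density(mesh, state, en$element_energy, config)
    new_state <- apply_update(state, rho_hat, 0, config)
    delta <- max(abs(new_state$density - state$density))
    residuals <- c(residuals, delta)
    metrics[[iter]] <- tibble(
      day = iter * config$step_days,
      total_energy = en$total_energy,
      total_mass = new_state$mass_reference,
      max_delta_rho = delta
    )
    days <- c(days, iter * config$step_days)
    converged <- check_convergence(state$density, new_state$density, config)
    state <- new_state
    if (converged) break
  }
  if (!converged) {
    abort(
      sprintf("baseline adaptation did not converge within %d iterations (last max |delta rho| = %.3g g/cm3)",
              config$max_iter, residuals[length(residuals)]),
      class = "osteosim_no_convergence",
      residuals = residuals
    )
  }
  trace <- new_simulation_trace(
    days = days,
    density = matrix(state$density, ncol = 1,
                     dimnames = list(NULL, as.character(max(days)))),
    metrics = bind_rows(metrics[!vapply(metrics, is.null, logical(1))]),
    mesh = mesh
  )
  list(state = state, trace = trace)
}

# ---- defect + implant experiment --------------------------------------------

#' Run a defect-implant remodeling experiment
#'
#' Inserts a biodegradable implant into the defect of a converged
#' baseline state (defect densities set to the implant-equivalent density)
#' and runs the daily coupled loop: elastic solve with density-derived
#' moduli, optimal-density prediction at the current total mass, damped
#' update with the day's implant mass loss `r(t) - r(t-1)` removed from
#' implant elements. Per-day osteogenesis metrics are recorded.
#'
#' @param mesh A [bone_mesh()] with a non-empty `defect` element set.
#' @param baseline A [material_state()] holding the converged pre-defect
#'   densities (from [run_baseline()]), or the result list of
#'   [run_baseline()] itself.
#' @param implant An [implant_state()].
#' @param loads Load groups.
#' @param config A [remodel_config()].
#' @param stop_day Optional fixed final day; by default the run continues
#'   until the degradation period has elapsed and the density field has
#'   converged (capped at `config$max_days`).
#' @return A `simulation_trace`: per-day density fields and metrics
#'   (`total_energy`, `total_mass`, `max_delta_rho`, `E1_t`,
#'   `osteo_score`, `new_bone_fraction`, `refilled_area_mm2`).
#' @export
run_defect_experiment <- function(mesh, baseline, implant, loads,
                                  config = remodel_config(),
                                  stop_day = NULL) {
  if (is.list(baseline) && !inherits(baseline, "material_state") &&
      !is.null(baseline$state)) {
    baseline <- baseline$state
  }
  stopifnot(inherits(baseline, "material_state"),
            inherits(implant, "implant_state"))
  idx <- defect_indices(mesh)
  baseline_rho <- baseline$density

  rho0 <- baseline_rho
  rho0[idx] <- implant$rho_implant_0
  state <- material_state(mesh, rho0, config)

  limit <- if (is.null(stop_day)) config$max_days else stop_day
  record <- function(t, state, energy, delta) {
    tibble(
      day = t,
      total_energy = energy,
      total_mass = state$mass_reference,
      max_delta_rho = delta,
      E1_t = remaining_modulus(t, implant),
      osteo_score = osteogenesis_score(state, implant, t, mesh, config),
      new_bone_fraction = new_bone_fraction(state, implant, baseline_rho,
                                            t, mesh, config),
      refilled_area_mm2 = refilled_area(state, implant, mesh, t,
                                        config = config)
    )
  }

  density <- matrix(NA_real_, n_elements(mesh), limit + 1L)
  density[, 1L] <- state$density
  metrics <- vector("list", limit + 1L)
  metrics[[1L]] <- record(0, state, NA_real_, NA_real_)
  days <- 0
  finished <- FALSE
  for (t in seq_len(limit)) {
    en <- combined_energy(mesh, state, loads, config)
    rho_hat <- predict_density(mesh, state, en$element_energy, config)
    loss <- numeric(n_elements(mesh))
    loss[idx] <- degraded_density(t, implant) -
      degraded_density(t - 1, implant)
    new_state <- apply_update(state, rho_hat, loss, config)
    delta <- max(abs(new_state$density - state$density))
    converged <- check_convergence(state$density, new_state$density, config)
    state <- new_state
    density[, t + 1L] <- state$density
    metrics[[t + 1L]] <- record(t, state, en$total_energy, delta)
    days <- c(days, t)
    if (!is.null(stop_day)) {
      if (t >= stop_day) { finished <- TRUE; break }
    } else if (t >= implant$T_days && converged) {
      finished <- TRUE
      break
    }
  }
  if (!finished) {
    abort(
      sprintf("defect experiment did not converge within %d days", limit),
      class = "osteosim_no_convergence",
      residuals = vapply(metrics[!vapply(metrics, is.null, logical(1))],
                         function(m) m$max_delta_rho, numeric(1))
    )
  }
  keep <- seq_along(days)
  new_simulation_trace(
    days = days,
    density = density[, keep, drop = FALSE],
    metrics = bind_rows(metrics[keep]),
    mesh = mesh,
    implant = implant,
    baseline = baseline_rho
  )
}

# ---- parameter sweep --------------------------------------------------------

#' Sweep implant modulus and degradation period
#'
#' Full factorial of defect experiments over initial implant moduli and
#' degradation periods, collecting the per-day metrics in one tidy table
#' and summarizing each cell by its final osteogenesis score.
#'
#' Each cell is observed over its own degradation period plus a fixed
#' follow-up window (`follow_up_days`), so all cells are compared at the
#' same healing time after full degradation. (Running every cell to
#' per-element convergence instead is possible via
#' `follow_up_days = NULL`, but the late free-remodeling tail is governed
#' by the load regime, not the implant, and converges very slowly.)
#'
#' @inheritParams run_defect_experiment
#' @param E1_0_list Initial implant moduli (MPa), non-empty.
#' @param T_list Degradation periods (days), non-empty.
#' @param follow_up_days Observation window after the end of each cell's
#'   degradation period (days); `NULL` runs each cell to convergence.
#' @param out_csv Optional path; if given, the tidy per-day table is
#'   written there as CSV.
#' @return List of class `sweep_result`: `results` (tibble with columns
#'   `E1_0`, `T_days`, `day`, and the metric columns) and `summary`
#'   (one row per cell with `final_day` and `final_score`).
#' @export
run_sweep <- function(mesh, baseline, E1_0_list, T_list, loads,
                      config = remodel_config(), follow_up_days = 20,
                      out_csv = NULL) {
  if (length(E1_0_list) == 0L || length(T_list) == 0L) {
    abort("`E1_0_list` and `T_list` must be non-empty")
  }
  grid <- tidyr::expand_grid(E1_0 = E1_0_list, T_days = T_list)
  cells <- purrr::pmap(grid, function(E1_0, T_days) {
    trace <- tryCatch(
      run_defect_experiment(mesh, baseline,
                            implant_state(E1_0, T_days, config),
                            loads, config,
                            stop_day = if (!is.null(follow_up_days))
                              T_days + follow_up_days),
      error = function(e) {
        abort(sprintf("sweep cell E1_0 = %g MPa, T = %g days failed: %s",
                      E1_0, T_days, conditionMessage(e)),
              parent = e)
      }
    )
    mutate(tidy(trace), E1_0 = E1_0, T_days = T_days, .before = 1)
  })
  results <- bind_rows(cells)
  summary <- results |>
    dplyr::group_by(E1_0, T_days) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select(E1_0, T_days, final_day = day, final_score = osteo_score)
  if (!is.null(out_csv)) readr::write_csv(results, out_csv)
  structure(list(results = results, summary = summary),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$summary)
  best <- x$summary[which.max(x$summary$final_score), ]
  cat(sprintf("best final osteogenesis score %.4g MPa at E1_0 = %g MPa, T = %g days\n",
              best$final_score, best$E1_0, best$T_days))
  invisible(x)
}

#' @rdname tidy.simulation_trace
#' @export
tidy.sweep_result <- function(x, ...) x$results

#' @rdname tidy.simulation_trace
#' @export
glance.sweep_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$final_score), ]
  tibble(
    n_cells = nrow(x$summary),
    best_E1_0 = best$E1_0,
    best_T_days = best$T_days,
    best_final_score = best$final_score
  )
}

# ---- rat experiment ---------------------------------------------------------

#' Run the rat metaphysis defect experiment
#'
#' Builds the rat-metaphysis domain, initializes densities from the
#' regional in-vivo moduli (7000 / 2000 MPa cortex, 900 MPa cancellous),
#' remodels the intact domain to convergence under the 0.65 N joint load
#' (so the pre-defect state is an equilibrium of the adaptation
#' dynamics), then implants the calcium-sulfate cement plug (800 MPa) in
#' the 3 mm defect and runs the daily coupled loop for the degradation
#' period. The refilled defect area (mm2) is recorded daily.
#'
#' @param config A [remodel_config()].
#' @param implant An [implant_state()]; defaults to the 800 MPa cement
#'   with a 28-day degradation period (within the 4-8 week in-vivo range).
#' @param stop_day Final simulated day (default: the degradation period).
#' @return A `simulation_trace`.
#' @export
run_rat_experiment <- function(config = remodel_config(),
                               implant = NULL, stop_day = NULL) {
  mesh <- generate_rat_domain(config)
  if (is.null(implant)) {
    implant <- implant_state(config$rat$moduli[["implant"]], 28, config)
  }
  if (is.null(stop_day)) stop_day <- implant$T_days
  init_rho <- modulus_to_density(mesh$pre_defect_modulus, config)
  baseline <- run_baseline(
    mesh, rat_load_cases(), config,
    state = material_state(mesh, init_rho, config,
                           is_implant = rep(FALSE, n_elements(mesh)))
  )
  run_defect_experiment(mesh, baseline$state, implant, rat_load_cases(),
                        config, stop_day = stop_day)
}
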