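#' @importFrom Matrix sparseMatrix
NULL

# Units: mesh coordinates are cm externally and converted to mm here, so
# forces in N and moduli in MPa (= N/mm2) are consistent; displacements
# come out in mm and energies in N*mm. Element volumes for mass
# bookkeeping stay in cm3 (density is g/cm3).
MM_PER_CM <- 10

# bilinear quad shape-function derivatives wrt natural coords (2 x 4)
quad_dshape <- function(xi, eta) {
  rbind(
    c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
    c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
  )
}

plane_stress_D <- function(E, mu) {
  E / (1 - mu^2) * matrix(c(1, mu, 0, mu, 1, 0, 0, 0, (1 - mu) / 2), 3, 3)
}

#' Plane-stress bilinear quadrilateral element stiffness
#'
#' 8x8 stiffness matrix of a 4-node isoparametric quadrilateral under
#' plane stress, integrated with 2x2 Gauss quadrature. The constitutive
#' matrix is the inverse of the plane-stress compliance
#' `S = [[1/E, -mu/E, 0], [-mu/E, 1/E, 0], [0, 0, 2(1+mu)/E]]`.
#'
#' @param coords 4x2 matrix of node coordinates (mm), counter-clockwise.
#' @param E Elastic modulus (MPa), > 0.
#' @param mu Poisson's ratio, in `[0, 0.5)`.
#' @param thickness Out-of-plane thickness (mm).
#' @return Symmetric positive-semidefinite 8x8 matrix (N/mm) with exactly
#'   three rigid-body zero-energy modes.
#' @export
element_stiffness <- function(coords, E, mu, thickness = 10) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 2L)
  if (!is.finite(E) || E <= 0) abort("`E` must be > 0")
  if (mu < 0 || mu >= 0.5) abort("`mu` must be in [0, 0.5)")
  D <- plane_stress_D(E, mu)
  gp <- 1 / sqrt(3)
  K <- matrix(0, 8, 8)
  for (eta in c(-gp, gp)) {
    for (xi in c(-gp, gp)) {
      dN <- quad_dshape(xi, eta)
      J <- dN %*% coords
      detJ <- det(J)
      if (detJ <= 0) abort("inverted element: non-positive Jacobian")
      dNxy <- solve(J, dN)
      B <- matrix(0, 3, 8)
      B[1, seq(1, 8, 2)] <- dNxy[1, ]
      B[2, seq(2, 8, 2)] <- dNxy[2, ]
      B[3, seq(1, 8, 2)] <- dNxy[2, ]
      B[3, seq(2, 8, 2)] <- dNxy[1, ]
      K <- K + crossprod(B, D %*% B) * detJ * thickness
    }
  }
  K
}

# precompute geometry-dependent factors: unit-modulus element stiffnesses,
# mean stress-recovery matrices, assembly index vectors. Cached on the mesh.
fem_model <- function(mesh, config = remodel_config()) {
  key <- sprintf("fem_model_%g_%g", config$poisson, config$thickness_cm)
  cached <- mesh$cache[[key]]
  if (!is.null(cached)) return(cached)
  mu <- config$poisson
  th <- config$thickness_cm * MM_PER_CM
  conn <- as.matrix(mesh$elements[, c("n1", "n2", "n3", "n4")])
  ne <- nrow(conn)
  xs <- matrix(mesh$nodes$x[conn], ncol = 4L) * MM_PER_CM
  ys <- matrix(mesh$nodes$y[conn], ncol = 4L) * MM_PER_CM
  kem <- matrix(0, 64, ne)
  smat <- matrix(0, 24, ne)
  D1 <- plane_stress_D(1, mu)
  gp <- 1 / sqrt(3)
  gps <- expand.grid(xi = c(-gp, gp), eta = c(-gp, gp))
  for (e in seq_len(ne)) {
    coords <- cbind(xs[e, ], ys[e, ])
    K <- matrix(0, 8, 8)
    SB <- matrix(0, 3, 8)
    for (g in 1:4) {
      dN <- quad_dshape(gps$xi[g], gps$eta[g])
      J <- dN %*% coords
      detJ <- det(J)
      if (detJ <= 0) {
        abort(sprintf("inverted element %d: non-positive Jacobian", e))
      }
      dNxy <- solve(J, dN)
      B <- matrix(0, 3, 8)
      B[1, seq(1, 8, 2)] <- dNxy[1, ]
      B[2, seq(2, 8, 2)] <- dNxy[2, ]
      B[3, seq(1, 8, 2)] <- dNxy[2, ]
      B[3, seq(2, 8, 2)] <- dNxy[1, ]
      K <- K + crossprod(B, D1 %*% B) * detJ * th
      SB <- SB + D1 %*% B / 4
    }
    kem[, e] <- as.vector(K)
    smat[, e] <- as.vector(SB)
  }
  edof <- matrix(0L, 8, ne)
  edof[seq(1, 8, 2), ] <- t(2L * conn - 1L)
  edof[seq(2, 8, 2), ] <- t(2L * conn)
  iK <- edof[rep(1:8, times = 8), ]
  jK <- edof[rep(1:8, each = 8), ]
  model <- list(
    kem = kem, smat = smat, edof = edof,
    iK = as.vector(iK), jK = as.vector(jK),
    n_dof = 2L * nrow(mesh$nodes), ne = ne
  )
  mesh$cache[[key]] <- model
  model
}

# ---- loads ------------------------------------------------------------------

#' Define a point-force load case
#'
#' A force of `magnitude` newtons at `angle` degrees from the horizontal,
#' divided equally among the nodes of `node_set` and decomposed as
#' `(|f| cos(angle), -|f| sin(angle))`; with `flip = TRUE` the force is
#' reversed to `(-|f| cos(angle), +|f| sin(angle))` (used for upward
#' muscle tension such as the hip abductor on the greater trochanter).
#'
#' @param magnitude Force magnitude (N), >= 0.
#' @param angle Angle from horizontal, degrees in `[0, 360)`.
#' @param node_set Name of the mesh node set the force acts on.
#' @param weight Relative weight when averaging energies over load cases.
#' @param flip Reverse the force direction (muscle pull vs joint push).
#' @return An object of class `load_case`.
#' @export
load_case <- function(magnitude, angle, node_set, weight = 1, flip = FALSE) {
  if (!is.finite(magnitude) || magnitude < 0) abort("`magnitude` must be >= 0")
  if (!is.finite(angle) || angle < 0 || angle >= 360) {
    abort("`angle` must be in [0, 360) degrees")
  }
  structure(
    list(magnitude = magnitude, angle = angle, node_set = node_set,
         weight = weight, flip = flip),
    class = "load_case"
  )
}

#' Reference femur load cases
#'
#' The three loading configurations of the proximal femur model: hip joint
#' reaction force on the femoral head together with the abductor (greater
#' trochanter) tension, applied as alternating daily load cases whose
#' element strain energies are averaged with equal weight.
#'
#' | case | joint force (N) | angle | trochanter force (N) | angle |
#' |------|-----------------|-------|----------------------|-------|
#' | 1    | 1700            | 25    | 576                  | 35    |
#' | 2    | 2271            | 66    | 703                  | 62    |
#' | 3    | 1049            | 15    | 248                  | 8     |
#'
#' @return List of three load groups; each group is a list of two
#'   [load_case()] objects applied simultaneously.
#' @export
femur_load_cases <- function() {
  rows <- list(c(1700, 25, 576, 35), c(2271, 66, 703, 62), c(1049, 15, 248, 8))
  lapply(rows, function(r) {
    list(
      load_case(r[1], r[2], "head_load"),
      load_case(r[3], r[4], "troch_load", flip = TRUE)
    )
  })
}

#' Rat joint load
#'
#' Single load case for the rat metaphysis: a 0.65 N joint force (about a
#' third of mean rat body weight) applied vertically downward on the
#' central top-edge nodes.
#' @return List with one load group.
#' @export
rat_load_cases <- function() {
  list(list(load_case(0.65, 90, "joint_load")))
}

# one group = load cases applied simultaneously
as_load_group <- function(load) {
  if (inherits(load, "load_case")) return(list(load))
  if (is.list(load) && length(load) > 0L &&
      all(vapply(load, inherits, logical(1), "load_case"))) {
    return(load)
  }
  abort("expected a load_case or a list of load_case objects")
}

# normalize loads to a list of groups (each group = list of load_case)
as_load_groups <- function(loads) {
  if (inherits(loads, "load_case")) return(list(list(loads)))
  if (!is.list(loads) || length(loads) == 0L) {
    abort("`loads` must be a load_case or a non-empty list of load cases")
  }
  if (all(vapply(loads, inherits, logical(1), "load_case"))) {
    # a bare list of cases: alternate load cases, one group each
    return(lapply(loads, list))
  }
  lapply(loads, as_load_group)
}

assemble_force <- function(mesh, group, n_dof) {
  f <- numeric(n_dof)
  for (lc in group) {
    nodes <- mesh$node_sets[[lc$node_set]]
    if (is.null(nodes) || length(nodes) == 0L) {
      abort(sprintf("load targets unknown or empty node set '%s'", lc$node_set))
    }
    th <- lc$angle * pi / 180
    s <- if (isTRUE(lc$flip)) -1 else 1
    fx <- s * lc$magnitude * cos(th) / length(nodes)
    fy <- -s * lc$magnitude * sin(th) / length(nodes)
    f[2L * nodes - 1L] <- f[2L * nodes - 1L] + fx
    f[2L * nodes] <- f[2L * nodes] + fy
  }
  f
}

# ---- material state ---------------------------------------------------------

#' Per-element material state
#'
#' Bundles the apparent density field with the derived elastic moduli
#' (`E = 2315 rho^3`, floored at `config$modulus_floor`), the implant
#' element flags, and the current total mass `sum(rho * v)` used as the
#' reference for the mass-constrained density prediction.
#'
#' @param mesh A [bone_mesh()].
#' @param density Per-element apparent density (g/cm3); scalar is recycled.
#' @param config A [remodel_config()].
#' @param is_implant Logical per-element flag marking implant (defect)
#'   elements; defaults to the mesh `defect` element set.
#' @return Object of class `material_state` with fields `density`,
#'   `modulus`, `poisson`, `is_implant`, `volume` (cm3) and
#'   `mass_reference` (g).
#' @export
material_state <- function(mesh, density = 1.0, config = remodel_config(),
                           is_implant = NULL) {
  ne <- n_elements(mesh)
  density <- rep_len(density, ne)
  if (any(density <= 0) || any(density > config$rho_max + 1e-12)) {
    abort(sprintf("densities must lie in (0, %g]", config$rho_max))
  }
  if (is.null(is_implant)) {
    is_implant <- rep(FALSE, ne)
    if (!is.null(mesh$element_sets$defect)) {
      is_implant[mesh$element_sets$defect] <- TRUE
    }
  }
  volume <- mesh$element_area * config$thickness_cm
  structure(
    list(
      density = density,
      modulus = pmax(density_to_modulus(density, config), config$modulus_floor),
      poisson = config$poisson,
      is_implant = is_implant,
      volume = volume,
      mass_reference = sum(density * volume)
    ),
    class = "material_state"
  )
}

# refresh derived fields after a density change
update_state_density <- function(state, density, config) {
  state$density <- density
  state$modulus <- pmax(density_to_modulus(density, config),
                        config$modulus_floor)
  state$mass_reference <- sum(density * state$volume)
  state
}

# ---- linear solve -----------------------------------------------------------

#' Solve the plane-stress elasticity problem
#'
#' Assembles the global stiffness from the per-element moduli, applies the
#' clamped boundary (the mesh's `fixed_set`, optionally with prescribed
#' non-zero displacements), and solves for displacements under one load
#' group. Per-element strain energy is `U_j = 1/2 sigma' S sigma * v_j`,
#' evaluated by Gauss quadrature (identically `1/2 u_e' K_e u_e`), and the
#' total strain energy is their sum.
#'
#' @param mesh A [bone_mesh()].
#' @param state A [material_state()].
#' @param load A [load_case()] or list of load cases applied together.
#' @param config A [remodel_config()].
#' @param prescribed Optional list `list(nodes =, ux =, uy =)` of prescribed
#'   displacements (mm) imposed instead of the fixed set (e.g. for patch
#'   tests).
#' @return Object of class `elastic_field`: `displacements` (n_nodes x 2,
#'   mm), `element_stress` (tibble sxx, syy, txy in MPa, mean over
#'   quadrature points), `element_energy` (N*mm), `total_energy` (N*mm).
#' @export
solve_elastic <- function(mesh, state, load, config = remodel_config(),
                          prescribed = NULL) {
  model <- fem_model(mesh, config)
  E <- state$modulus
  if (any(!is.finite(E)) || any(E <= 0)) {
    abort("non-positive element modulus")
  }
  f <- assemble_force(mesh, as_load_group(load), model$n_dof)

  vals <- as.vector(model$kem * rep(E, each = 64L))
  u <- numeric(model$n_dof)
  if (is.null(prescribed)) {
    # fast path: pre-reduced assembly on the free dofs with a cached
    # symbolic Cholesky factorization (the sparsity pattern is fixed)
    fixed_nodes <- mesh$node_sets[[mesh$fixed_set %||% ""]]
    if (is.null(fixed_nodes) || length(fixed_nodes) == 0L) {
      abort("mesh has no fixed node set: rigid-body modes unconstrained")
    }
    cons <- sort(c(2L * fixed_nodes - 1L, 2L * fixed_nodes))
    if (length(cons) < 3L) {
      abort("fewer than 3 constrained degrees of freedom: rigid-body translation/rotation unconstrained")
    }
    rkey <- sprintf("reduced_%s_%g_%g", mesh$fixed_set, config$poisson,
                    config$thickness_cm)
    red <- mesh$cache[[rkey]]
    if (is.null(red)) {
      free <- setdiff(seq_len(model$n_dof), cons)
      map <- integer(model$n_dof)
      map[free] <- seq_along(free)
      keep <- which(map[model$iK] > 0L & map[model$jK] > 0L)
      red <- list(free = free, keep = keep,
                  ri = map[model$iK[keep]], rj = map[model$jK[keep]])
      mesh$cache[[rkey]] <- red
    }
    K <- sparseMatrix(i = red$ri, j = red$rj, x = vals[red$keep],
                      dims = c(length(red$free), length(red$free)))
    Ks <- Matrix::forceSymmetric(K)
    sol <- tryCatch({
      ckey <- paste0(rkey, "_chol")
      ch <- mesh$cache[[ckey]]
      if (is.null(ch)) {
        ch <- Matrix::Cholesky(Ks, LDL = FALSE)
        mesh$cache[[ckey]] <- ch
      } else {
        ch <- Matrix::update(ch, Ks)
      }
      Matrix::solve(ch, f[red$free])
    },
    error = function(e) {
      abort(paste0("singular stiffness system (unconstrained modes?): ",
                   conditionMessage(e)))
    })
    u[red$free] <- as.vector(sol)
  } else {
    K <- sparseMatrix(i = model$iK, j = model$jK, x = vals,
                      dims = c(model$n_dof, model$n_dof))
    cons <- sort(c(2L * prescribed$nodes - 1L, 2L * prescribed$nodes))
    u[2L * prescribed$nodes - 1L] <- prescribed$ux
    u[2L * prescribed$nodes] <- prescribed$uy
    if (length(cons) < 3L) {
      abort("fewer than 3 constrained degrees of freedom: rigid-body translation/rotation unconstrained")
    }
    free <- setdiff(seq_len(model$n_dof), cons)
    rhs <- f[free] - as.vector(K[free, cons, drop = FALSE] %*% u[cons])
    sol <- tryCatch(
      Matrix::solve(K[free, free, drop = FALSE], rhs),
      error = function(e) {
        abort(paste0("singular stiffness system (unconstrained modes?): ",
                     conditionMessage(e)))
      }
    )
    u[free] <- as.vector(sol)
  }

  U8 <- matrix(u[model$edof], nrow = 8L)
  W <- matrix(0, 8L, model$ne)
  for (i in 1:8) {
    acc <- numeric(model$ne)
    for (j in 1:8) {
      acc <- acc + model$kem[(j - 1L) * 8L + i, ] * U8[j, ]
    }
    W[i, ] <- acc
  }
  energy <- 0.5 * E * colSums(U8 * W)
  sig <- matrix(0, 3L, model$ne)
  for (i in 1:3) {
    acc <- numeric(model$ne)
    for (j in 1:8) {
      acc <- acc + model$smat[(j - 1L) * 3L + i, ] * U8[j, ]
    }
    sig[i, ] <- E * acc
  }
  structure(
    list(
      displacements = matrix(u, ncol = 2L, byrow = TRUE),
      element_stress = tibble(sxx = sig[1, ], syy = sig[2, ], txy = sig[3, ]),
      element_energy = energy,
      total_energy = sum(energy)
    ),
    class = "elastic_field"
  )
}

#' @export
print.elastic_field <- function(x, ...) {
  cat(sprintf("<elastic_field> %d nodes, %d elements, total strain energy %.6g N*mm\n",
              nrow(x$displacements), length(x$element_energy), x$total_energy))
  invisible(x)
}

#' Load-case-averaged strain energy
#'
#' Solves each load group independently and returns the weighted average
#' of the per-element strain energies (equal weights by default), the
#' remodeling stimulus when several habitual loading configurations
#' alternate.
#'
#' @inheritParams solve_elastic
#' @param loads Non-empty list of load groups (each a [load_case()] or a
#'   list of cases applied together), e.g. [femur_load_cases()].
#' @param weights Optional numeric weights, one per group; defaults to the
#'   weight of each group's first load case.
#' @return List with `element_energy` (weighted mean, N*mm),
#'   `total_energy`, and `fields` (the per-group `elastic_field`s).
#' @export
combined_energy <- function(mesh, state, loads, config = remodel_config(),
                            weights = NULL) {
  groups <- as_load_groups(loads)
  if (length(groups) == 0L) abort("empty load list")
  if (is.null(weights)) {
    weights <- vapply(groups, function(g) g[[1L]]$weight %||% 1, numeric(1))
  }
  stopifnot(length(weights) == length(groups), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)
  fields <- lapply(groups, function(g) solve_elastic(mesh, state, g, config))
  energy <- Reduce(`+`, Map(function(f, w) w * f$element_energy,
                            fields, weights))
  list(
    element_energy = energy,
    total_energy = sum(energy),
    fields = fields
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
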