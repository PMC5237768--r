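unit_square_mm <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10),
                         ncol = 2, byrow = TRUE)

test_that("element stiffness is symmetric with exactly 3 rigid-body modes", {
  for (pars in list(c(1, 0.3), c(2315, 0), c(500, 0.45))) {
    K <- element_stiffness(unit_square_mm, pars[1], pars[2])
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < max(ev) * 1e-10), 3L)
    expect_true(all(ev > -max(ev) * 1e-10))
    # rigid translations produce zero force
    tx <- rep(c(1, 0), 4); ty <- rep(c(0, 1), 4)
    expect_equal(as.vector(K %*% tx), rep(0, 8), tolerance = 1e-9)
    expect_equal(as.vector(K %*% ty), rep(0, 8), tolerance = 1e-9)
  }
})

test_that("element stiffness scales exactly linearly in the modulus", {
  K1 <- element_stiffness(unit_square_mm, 1, 0.3)
  K7 <- element_stiffness(unit_square_mm, 7.5, 0.3)
  expect_equal(K7, 7.5 * K1, tolerance = 1e-14)
})

test_that("element stiffness matches an independent quadrature oracle", {
  # 2x2 Gauss is exact for the rectangular element, and the oracle uses
  # a fine Simpson grid instead of Gauss points
  K <- element_stiffness(unit_square_mm, 1, 0.3)
  K_oracle <- oracle_element_stiffness(unit_square_mm, 1, 0.3)
  expect_equal(K, K_oracle, tolerance = 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev_o <- eigen(K_oracle, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, ev_o, tolerance = 1e-10)
})

test_that("degenerate elements and invalid materials are rejected", {
  bad <- unit_square_mm[c(1, 4, 3, 2), ]  # clockwise: inverted
  expect_error(element_stiffness(bad, 1, 0.3), "[Ii]nverted")
  expect_error(element_stiffness(unit_square_mm, -1, 0.3), "E")
  expect_error(element_stiffness(unit_square_mm, 1, 0.5), "mu")
})

test_that("zero load produces zero displacement and zero energy", {
  mesh <- generate_plate_fixture(2, 2)
  st <- material_state(mesh, 1.0)
  f <- solve_elastic(mesh, st, load_case(0, 0, "right"))
  expect_equal(f$total_energy, 0)
  expect_equal(max(abs(f$displacements)), 0)
})

test_that("fixed nodes have exactly zero displacement", {
  mesh <- generate_plate_fixture(3, 2)
  st <- material_state(mesh, 1.0)
  f <- solve_elastic(mesh, st, load_case(100, 30, "right"))
  expect_identical(f$displacements[mesh$node_sets$left, ],
                   matrix(0, length(mesh$node_sets$left), 2))
  expect_gt(max(abs(f$displacements)), 0)
})

test_that("single-element uniaxial load matches the closed form", {
  cfg <- uniaxial_config()
  mesh <- generate_plate_fixture(1, 1, elem_cm = 0.5)
  rho <- 1.0
  st <- material_state(mesh, rho, cfg)
  E <- density_to_modulus(rho, cfg)
  Fmag <- 100  # N, pulling along +x
  f <- solve_elastic(mesh, st, load_case(Fmag, 0, "right"), cfg)
  A <- 5 * 10  # mm2 cross-section (0.5 cm edge x 1 cm thickness)
  sigma <- Fmag / A
  expect_equal(f$element_stress$sxx, sigma, tolerance = 1e-8)
  expect_equal(f$element_stress$syy, 0, tolerance = 1e-8 * sigma)
  expect_equal(f$element_stress$txy, 0, tolerance = 1e-8 * sigma)
  vol <- 5 * 5 * 10  # mm3
  expect_equal(f$total_energy, sigma^2 / (2 * E) * vol, tolerance = 1e-8)
})

test_that("patch test: linear boundary displacements give constant stress", {
  # distorted 2x2 mesh (interior node moved off-grid)
  nodes <- tibble::tibble(
    x = c(0, 0.5, 1, 0, 0.58, 1, 0, 0.5, 1),
    y = c(0, 0, 0, 0.5, 0.46, 0.5, 1, 1, 1)
  )
  elements <- tibble::tibble(
    n1 = c(1L, 2L, 4L, 5L), n2 = c(2L, 3L, 5L, 6L),
    n3 = c(5L, 6L, 8L, 9L), n4 = c(4L, 5L, 7L, 8L)
  )
  mesh <- bone_mesh(nodes, elements,
                    node_sets = list(boundary = c(1:4, 6:9)))
  st <- material_state(mesh, 1.0)
  # impose u = a + b x + c y on the boundary (coordinates in mm)
  xy <- as.matrix(nodes) * 10
  ux <- 1e-3 * (2 + 0.3 * xy[, 1] + 0.1 * xy[, 2])
  uy <- 1e-3 * (-1 + 0.05 * xy[, 1] - 0.2 * xy[, 2])
  b <- mesh$node_sets$boundary
  f <- solve_elastic(mesh, st, load_case(0, 0, "boundary"),
                     prescribed = list(nodes = b, ux = ux[b], uy = uy[b]))
  # interior node recovers the linear field
  expect_equal(f$displacements[5, 1], ux[5], tolerance = 1e-8)
  expect_equal(f$displacements[5, 2], uy[5], tolerance = 1e-8)
  # constant strain -> identical stress in all elements
  for (col in c("sxx", "syy", "txy")) {
    s <- f$element_stress[[col]]
    expect_equal(s, rep(s[1], 4), tolerance = 1e-8)
  }
})

test_that("compliance-form element energies sum to the displacement-form total", {
  mesh <- generate_plate_fixture(4, 3)
  st <- material_state(mesh, seq(0.4, 1.6, length.out = 12))
  f <- solve_elastic(mesh, st, load_case(250, 40, "right"))
  # for a linear solve, 1/2 u'Ku = 1/2 u'f
  nodes <- mesh$node_sets$right
  th <- 40 * pi / 180
  fx <- 250 * cos(th) / length(nodes); fy <- -250 * sin(th) / length(nodes)
  work <- 0.5 * sum(f$displacements[nodes, 1] * fx +
                    f$displacements[nodes, 2] * fy)
  expect_equal(f$total_energy, work, tolerance = 1e-8)
  expect_equal(f$total_energy, sum(f$element_energy), tolerance = 1e-12)
})

test_that("doubling the load quadruples the strain energy exactly", {
  mesh <- generate_plate_fixture(3, 3)
  st <- material_state(mesh, 1.0)
  f1 <- solve_elastic(mesh, st, load_case(100, 15, "right"))
  f2 <- solve_elastic(mesh, st, load_case(200, 15, "right"))
  expect_equal(f2$total_energy, 4 * f1$total_energy, tolerance = 1e-12)
})

test_that("mesh refinement converges monotonically for the tip-loaded plate", {
  cfg <- remodel_config()
  energies <- vapply(c(2, 4, 8), function(n) {
    mesh <- generate_plate_fixture(4 * n, n, elem_cm = 2 / n)
    st <- material_state(mesh, 1.0, cfg)
    solve_elastic(mesh, st, load_case(50, 90, "right"), cfg)$total_energy
  }, numeric(1))
  # softening sequence: energy increases toward the exact value
  expect_true(all(diff(energies) > 0))
  # successive increments shrink (convergence)
  expect_lt(energies[3] - energies[2], energies[2] - energies[1])
})

test_that("combined energy reduces to a single solve and averages cases", {
  mesh <- generate_plate_fixture(3, 2)
  st <- material_state(mesh, 1.0)
  lc1 <- load_case(100, 0, "right")
  lc2 <- load_case(80, 60, "right")
  single <- solve_elastic(mesh, st, lc1)
  one <- combined_energy(mesh, st, list(lc1))
  expect_equal(one$element_energy, single$element_energy)
  dup <- combined_energy(mesh, st, list(lc1, lc1))
  expect_equal(dup$element_energy, single$element_energy, tolerance = 1e-12)
  two <- combined_energy(mesh, st, list(lc1, lc2))
  f2 <- solve_elastic(mesh, st, lc2)
  expect_equal(two$element_energy,
               0.5 * (single$element_energy + f2$element_energy),
               tolerance = 1e-12)
  expect_error(combined_energy(mesh, st, list()), "empty")
})

test_that("load cases validate magnitude, angle, and node set", {
  expect_error(load_case(-1, 0, "right"), "magnitude")
  expect_error(load_case(1, 360, "right"), "angle")
  mesh <- generate_plate_fixture(2, 2)
  st <- material_state(mesh, 1.0)
  expect_error(solve_elastic(mesh, st, load_case(1, 0, "nope")), "node set")
})
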