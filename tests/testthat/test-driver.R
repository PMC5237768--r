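plate_loads <- function() list(load_case(100, 0, "right"))

test_that("uniform plate under uniform axial load converges immediately", {
  cfg <- uniaxial_config()
  # single element row: the two-node end load is a consistent uniform
  # traction, so the stress state is exactly uniaxial
  mesh <- generate_plate_fixture(4, 1)
  bl <- run_baseline(mesh, plate_loads(), cfg)
  expect_equal(bl$state$density, rep(1, 4), tolerance = 1e-9)
  expect_equal(nrow(bl$trace$metrics), 1L)
  # wider plate: equal nodal splitting only approximates the traction,
  # so the converged field is near-uniform
  mesh2 <- generate_plate_fixture(4, 2)
  bl2 <- run_baseline(mesh2, plate_loads(), cfg)
  expect_equal(bl2$state$density, rep(1, 8), tolerance = 1e-2)
})

test_that("a converged baseline re-run terminates in one step", {
  cfg <- remodel_config()
  mesh <- generate_plate_fixture(5, 3)
  bl <- run_baseline(mesh, plate_loads(), cfg)
  again <- run_baseline(mesh, plate_loads(), cfg, state = bl$state)
  expect_equal(nrow(again$trace$metrics), 1L)
  expect_equal(again$state$density, bl$state$density, tolerance = 2e-3)
})

test_that("baseline errors at the iteration cap with residual history", {
  cfg <- remodel_config(max_iter = 3)
  mesh <- generate_plate_fixture(6, 3)
  err <- tryCatch(
    run_baseline(mesh, list(load_case(150, 90, "right")), cfg),
    error = function(e) e
  )
  expect_s3_class(err, "osteosim_no_convergence")
  expect_length(err$residuals, 3L)
})

test_that("defect runs are deterministic and their traces round-trip", {
  cfg <- remodel_config()
  mesh <- plate_with_defect(4, 3, defect = c(2L, 6L, 10L))
  bl <- run_baseline(mesh, plate_loads(), cfg)
  imp <- implant_state(1000, 10, cfg)
  tr1 <- run_defect_experiment(mesh, bl$state, imp, plate_loads(), cfg,
                               stop_day = 12)
  tr2 <- run_defect_experiment(mesh, bl$state, imp, plate_loads(), cfg,
                               stop_day = 12)
  expect_identical(tr1$density, tr2$density)
  expect_identical(tr1$metrics, tr2$metrics)

  # days advance strictly by the 1-day step
  expect_identical(diff(tr1$days), rep(1, length(tr1$days) - 1))

  # every stored metric row is recomputable from the stored field
  for (k in seq_along(tr1$days)) {
    t <- tr1$days[k]
    st <- material_state(mesh, tr1$density[, k], cfg)
    expect_equal(tr1$metrics$osteo_score[k],
                 osteogenesis_score(st, imp, t, mesh, cfg))
    expect_equal(tr1$metrics$new_bone_fraction[k],
                 new_bone_fraction(st, imp, tr1$baseline, t, mesh, cfg))
    expect_equal(tr1$metrics$refilled_area_mm2[k],
                 refilled_area(st, imp, mesh, t, config = cfg))
    expect_equal(tr1$metrics$total_mass[k], sum(st$density * st$volume))
  }
})

test_that("defect-run mass bookkeeping tracks the degraded implant mass", {
  # interior densities and a gentle load: no bound clipping anywhere
  cfg <- remodel_config()
  mesh <- plate_with_defect(4, 2, defect = c(2L, 6L))
  bl_state <- material_state(mesh, 0.9, cfg,
                             is_implant = rep(FALSE, n_elements(mesh)))
  imp <- implant_state(1000, 15, cfg)
  tr <- run_defect_experiment(mesh, bl_state, imp, plate_loads(), cfg,
                              stop_day = 10)
  v <- mesh$element_area * cfg$thickness_cm
  defect <- mesh$element_sets$defect
  mass0 <- tr$metrics$total_mass[1]
  for (k in 2:length(tr$days)) {
    t <- tr$days[k]
    clipped <- any(tr$density[, k] <= cfg$rho_min + 1e-12) ||
      any(tr$density[, k] >= cfg$rho_max - 1e-12)
    if (!clipped) {
      expect_equal(tr$metrics$total_mass[k],
                   mass0 - degraded_density(t, imp) * sum(v[defect]),
                   tolerance = 1e-10)
    }
  }
})

test_that("a 1x1 sweep reproduces the single defect experiment", {
  cfg <- remodel_config()
  mesh <- plate_with_defect(4, 3, defect = c(2L, 6L, 10L))
  bl <- run_baseline(mesh, plate_loads(), cfg)
  sw <- run_sweep(mesh, bl$state, 1000, 10, plate_loads(), cfg,
                  follow_up_days = 5)
  single <- run_defect_experiment(mesh, bl$state,
                                  implant_state(1000, 10, cfg),
                                  plate_loads(), cfg, stop_day = 15)
  expect_equal(nrow(sw$summary), 1L)
  expect_equal(sw$summary$final_score,
               single$metrics$osteo_score[nrow(single$metrics)])
  expect_equal(sw$results$osteo_score, single$metrics$osteo_score)
  expect_error(run_sweep(mesh, bl$state, numeric(0), 10, plate_loads(), cfg),
               "non-empty")
})

test_that("tidy and glance summarize traces and sweeps", {
  cfg <- remodel_config()
  mesh <- plate_with_defect(3, 2, defect = 2L)
  bl <- run_baseline(mesh, plate_loads(), cfg)
  tr <- run_defect_experiment(mesh, bl$state, implant_state(500, 5, cfg),
                              plate_loads(), cfg, stop_day = 6)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("day", "osteo_score", "refilled_area_mm2") %in% names(td)))
  g <- glance(tr)
  expect_equal(nrow(g), 1L)
  expect_equal(g$day, max(tr$days))
  sw <- run_sweep(mesh, bl$state, c(500, 1000), 5, plate_loads(), cfg,
                  follow_up_days = 2)
  expect_equal(nrow(glance(sw)), 1L)
  expect_true(all(c("E1_0", "T_days") %in% names(tidy(sw))))
})

test_that("field export round-trips bit-exactly and emits valid VTU", {
  cfg <- remodel_config()
  mesh <- plate_with_defect(2, 2, defect = 1L)
  bl <- run_baseline(mesh, plate_loads(), cfg)
  tr <- run_defect_experiment(mesh, bl$state, implant_state(800, 4, cfg),
                              plate_loads(), cfg, stop_day = 4)
  dir <- withr::local_tempdir()
  paths <- write_fields(mesh, tr, dir, format = "both")
  tab <- read_fields(file.path(dir, "fields.csv"))
  expect_equal(nrow(tab), n_elements(mesh) * length(tr$days))
  one_day <- tab[tab$day == tr$days[2], ]
  expect_identical(one_day$density, tr$density[, 2])

  skip_if_not_installed("xml2")
  vtu <- file.path(dir, sprintf("fields_day%04d.vtu", tr$days[1]))
  doc <- xml2::read_xml(vtu)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               n_elements(mesh))
  arrays <- xml2::xml_find_all(doc, ".//CellData/DataArray")
  expect_setequal(xml2::xml_attr(arrays, "Name"),
                  c("density", "remaining_implant_modulus", "osteo_score"))
  conn <- xml2::xml_find_first(doc, ".//DataArray[@Name='connectivity']")
  ids <- as.integer(strsplit(trimws(xml2::xml_text(conn)), "\\s+")[[1]])
  expect_length(ids, 4L * n_elements(mesh))
  expect_true(all(ids >= 0 & ids < n_nodes(mesh)))
  expect_true(file.exists(file.path(dir, "fields.pvd")))
})

test_that("field export validates element counts", {
  mesh <- generate_plate_fixture(2, 2)
  bad_trace <- structure(
    list(days = 0, density = matrix(1, 3, 1),
         metrics = tibble::tibble(day = 0), implant = NULL,
         baseline = NULL, defect = integer(0)),
    class = "simulation_trace"
  )
  expect_error(write_fields(mesh, bad_trace, withr::local_tempdir()),
               "elements")
})
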