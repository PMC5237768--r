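# Shared fixtures. The femur baseline adaptation is expensive (minutes),
# so it is computed once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

femur_fixture <- function() {
  memo("femur", {
    cfg <- remodel_config()
    mesh <- generate_femur_domain(cfg)
    bl <- run_baseline(mesh, femur_load_cases(), cfg)
    list(cfg = cfg, mesh = mesh, baseline = bl$state, trace = bl$trace)
  })
}

femur_reference_trace <- function() {
  memo("femur_trace", {
    fx <- femur_fixture()
    implant <- implant_state(1000, 20, fx$cfg)
    run_defect_experiment(fx$mesh, fx$baseline, implant, femur_load_cases(),
                          fx$cfg, stop_day = 21)
  })
}

# small plate with a hand-labeled defect column, mid-range densities, used
# for bookkeeping identities where nothing hits the density bounds
plate_with_defect <- function(nx = 4, ny = 2, defect = c(2L, 6L)) {
  mesh <- generate_plate_fixture(nx, ny)
  body <- setdiff(seq_len(n_elements(mesh)), defect)
  mesh$element_sets <- list(body = body, defect = defect)
  mesh$elements$region[defect] <- "defect"
  mesh
}

uniaxial_config <- function(...) {
  remodel_config(poisson = 0, ...)
}
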