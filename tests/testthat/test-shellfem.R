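test_that("plane-stress von Mises identities hold", {
  expect_equal(von_mises_plane(100e3, 0, 0), 100e3)
  expect_equal(von_mises_plane(100e3, 100e3, 0), 100e3)
  expect_equal(von_mises_plane(0, 0, 100e3), sqrt(3) * 100e3)
})

test_that("boundary-condition scheme fixes the outlet and slides the inlet", {
  mesh <- make_test_tube(h = 3e-3)
  bc <- apply_boundary_conditions(mesh)
  n_in <- length(mesh$tags$inlet_ring)
  n_out <- length(mesh$tags$outlet_ring)
  expect_length(bc$fixed, 6 * n_out + 2 * n_in)
  # every outlet DOF constrained
  out_dofs <- as.vector(outer(1:6, (mesh$tags$outlet_ring - 1L) * 6L, `+`))
  expect_true(all(out_dofs %in% bc$fixed))
  # inlet axial translation and rotations free
  ax_dofs <- (mesh$tags$inlet_ring - 1L) * 6L + 3L
  expect_false(any(ax_dofs %in% bc$fixed))
  mesh$tags$inlet_ring <- NULL
  expect_error(apply_boundary_conditions(mesh), "tags")
})

test_that("pressurized tube reproduces thin-wall membrane closed forms", {
  mesh <- make_test_tube(h = 2e-3, L = 0.06)
  ctx <- fem_context(mesh)
  p <- mmHg_to_pa(25)
  sol <- solve_stage(ctx, pressure = p, n_increments = 3)
  st <- sol$state
  r_mid <- 0.0095; t <- 1e-3; E <- 0.75e6
  zc <- (mesh$nodes[mesh$tri[, 1], 3] + mesh$nodes[mesh$tri[, 2], 3] +
         mesh$nodes[mesh$tri[, 3], 3]) / 3
  mid <- zc > 0.02 & zc < 0.04
  # hoop von Mises ~ p r / t away from the ends
  expect_lt(abs(mean(st$element_von_mises[mid]) - p * r_mid / t) /
              (p * r_mid / t), 0.05)
  # radial expansion ~ p r^2 / (E t)
  rad <- sqrt(rowSums(sol$ctx$x[, 1:2]^2)) -
    sqrt(rowSums(mesh$nodes[, 1:2]^2))
  nid <- mesh$nodes[, 3] > 0.02 & mesh$nodes[, 3] < 0.04
  expect_lt(abs(mean(rad[nid]) - p * r_mid^2 / (E * t)) /
              (p * r_mid^2 / (E * t)), 0.05)
  # reactions balance the applied load
  expect_lt(max(abs(load_balance(st))), 0.005)
  assign("tube25", sol, envir = .fixture_cache)
})

test_that("response is linear in pressure in the small-strain limit", {
  mesh <- make_test_tube(h = 3e-3, L = 0.06)
  umax <- vapply(c(0.25, 0.5), function(pm) {
    sol <- solve_stage(fem_context(mesh), pressure = mmHg_to_pa(pm),
                       n_increments = 1)
    max(abs(sol$state$displacements))
  }, numeric(1))
  expect_equal(umax[2] / umax[1], 2, tolerance = 0.02)
})

test_that("unloaded body stays at rest; refinement moves displacements < 3%", {
  mesh <- make_test_tube(h = 3e-3, L = 0.06)
  sol0 <- solve_stage(fem_context(mesh), pressure = 0, n_increments = 1)
  expect_equal(max(abs(sol0$state$displacements)), 0)
  expect_equal(max(sol0$state$element_von_mises), 0)
  u <- vapply(c(3e-3, 1.5e-3), function(h) {
    m <- make_test_tube(h = h, L = 0.06)
    s <- solve_stage(fem_context(m), pressure = mmHg_to_pa(25),
                     n_increments = 2)
    max(abs(s$state$displacements[, 1:3]))
  }, numeric(1))
  expect_lt(abs(u[2] - u[1]) / u[2], 0.03)
})

test_that("simply supported plate matches the Kirchhoff series deflection", {
  nn <- 12; a <- 1; tpl <- 0.01; Epl <- 1e9; nupl <- 0.3; q <- 1
  pmesh <- make_plate_mesh(nn = nn, a = a, thickness = tpl)
  ctx <- fem_context(pmesh, artery_material = plate_material(Epl, nupl, tpl))
  bN <- which(pmesh$nodes[, 1] %in% c(0, a) | pmesh$nodes[, 2] %in% c(0, a))
  ctx$bc <- list(fixed = sort(unique(c(
    (bN - 1L) * 6L + 3L,
    as.vector(outer(c(1L, 2L, 6L), (seq_len(nrow(pmesh$nodes)) - 1L) * 6L,
                    `+`))))))
  sol <- solve_stage(ctx, pressure = q, n_increments = 1)
  D <- Epl * tpl^3 / 12 / (1 - nupl^2)
  wmax <- max(abs(sol$state$displacements[, 3]))
  expect_equal(wmax / (0.00406 * q * a^4 / D), 1, tolerance = 0.02)
})

test_that("higher post-operative pressure enlarges the throat more", {
  spec <- vessel_spec(stenosis_fraction = 0.7, mesh_edge_length = 3.5e-3)
  mesh <- build_stenosed_tube(spec)
  throat <- vapply(c(25, 45), function(pm) {
    sol <- solve_stage(fem_context(mesh), pressure = mmHg_to_pa(pm),
                       n_increments = 4)
    min(extract_centerline(current_mesh(sol$ctx), n_samples = 21)$areas)
  }, numeric(1))
  expect_gt(throat[2], throat[1])
})

test_that("residual prestress stores the inflated membrane stress state", {
  mesh <- make_test_tube(h = 2.5e-3, L = 0.06)
  rp <- residual_prestress(fem_context(mesh))
  # hoop stress ~ p r / t at 5 mmHg
  p <- mmHg_to_pa(5)
  zc <- (mesh$nodes[mesh$tri[, 1], 3] + mesh$nodes[mesh$tri[, 2], 3] +
         mesh$nodes[mesh$tri[, 3], 3]) / 3
  mid <- zc > 0.02 & zc < 0.04
  vm <- von_mises_plane(rp$sig0[mid, 1], rp$sig0[mid, 2], rp$sig0[mid, 3])
  expect_lt(abs(mean(vm) - p * 0.0095 / 1e-3) / (p * 0.0095 / 1e-3), 0.05)
  expect_error(apply_residual_stress(fem_context(make_test_tube(h = 3e-3)),
                                     rp$sig0), "elements")
})
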