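test_that("centerline of a straight cylinder is the axis with constant area", {
  mesh <- make_test_tube(h = 2e-3, L = 0.06)
  prof <- extract_centerline(mesh, n_samples = 21)
  expect_lt(max(sqrt(prof$points[, 1]^2 + prof$points[, 2]^2)), 1e-5)
  a0 <- pi * 0.009^2
  expect_lt(max(abs(prof$areas - a0) / a0), 0.01)
  expect_equal(residual_stenosis(prof), 0, tolerance = 1)
  expect_true(all(diff(prof$arclength) > 0))
  expect_equal(min(prof$local_stenosis_pct), 0)
})

test_that("pre-operative profile recovers the constructed stenosis level", {
  spec <- vessel_spec(stenosis_fraction = 0.7, mesh_edge_length = 2.5e-3)
  mesh <- build_stenosed_tube(spec)
  prof <- extract_centerline(mesh, n_samples = 41)
  expect_equal(residual_stenosis(prof), 70, tolerance = 2)
  expect_equal(centerline_offset(prof), 0, tolerance = 1e-4)
  # invariant to a rigid-body transform
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes %*% t(R) + rep(c(0.01, -0.02, 0.005),
                                           each = nrow(mesh$nodes))
  # rotate about z keeps slicing planes valid for the tube axis
  prof2 <- extract_centerline(mesh2, n_samples = 41)
  expect_equal(residual_stenosis(prof2), residual_stenosis(prof),
               tolerance = 0.5)
})

test_that("stress summaries aggregate von Mises per region", {
  mesh <- make_test_tube(h = 3e-3, L = 0.06)
  st <- structure(list(element_von_mises = rep(123, nrow(mesh$tri))),
                  class = "fem_state")
  ss <- stress_summary(st, mesh, "artery")
  expect_equal(unname(ss["max"]), unname(ss["mean"]))
  expect_equal(unname(ss["max"]), 123)
  expect_error(stress_summary(st, mesh, "patch"), "no elements")
})

test_that("suture stress jump matches a two-material strip closed form", {
  # flat strip, artery half and patch half bonded at x = 0.5
  pm <- make_plate_mesh(nn = 4, a = 1)
  cent <- (pm$nodes[pm$tri[, 1], 1] + pm$nodes[pm$tri[, 2], 1] +
           pm$nodes[pm$tri[, 3], 1]) / 3
  pm$region <- ifelse(cent > 0.5, "patch", "artery")
  pm$tags$suture_line <- which(abs(pm$nodes[, 1] - 0.5) < 1e-9)
  vm <- ifelse(pm$region == "patch", 150e3, 100e3)
  st <- structure(list(element_von_mises = vm), class = "fem_state")
  expect_equal(suture_stress_jump(st, pm), 50e3)
  # identical stress on both sides: no mismatch
  st0 <- structure(list(element_von_mises = rep(80e3, nrow(pm$tri))),
                   class = "fem_state")
  expect_equal(suture_stress_jump(st0, pm), 0)
  pm$tags$suture_line <- integer(0)
  expect_error(suture_stress_jump(st, pm), "suture_line")
})

test_that("profile table and stenosis plot export run", {
  mesh <- make_test_tube(h = 3e-3, L = 0.06)
  prof <- extract_centerline(mesh, n_samples = 11)
  tb <- profile_table(prof)
  expect_named(tb, c("s_mm", "area_mm2", "stenosis_pct", "offset_mm"))
  expect_equal(nrow(tb), 11)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot_stenosis_profiles(list(pre = prof, post = prof)))
})
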