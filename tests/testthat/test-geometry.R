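test_that("vessel spec validates its invariants", {
  expect_error(vessel_spec(stenosis_fraction = 1.2), "stenosis_fraction")
  expect_error(vessel_spec(stenosis_length = 0.2, total_length = 0.1),
               "stenosis_length")
  expect_error(vessel_spec(wall_thickness = 0.006), "wall_thickness")
  expect_silent(validate_vessel_spec(vessel_spec(stenosis_fraction = 0.7)))
})

test_that("analytic area profile matches the area-stenosis definition", {
  a0 <- pi * 0.009^2
  spec70 <- vessel_spec(stenosis_fraction = 0.7)
  prof <- analytic_area_profile(spec70, 201)
  # throat: (1 - s) of the inlet area (76.3 mm^2 for 70%)
  expect_equal(min(prof$area), 0.3 * a0, tolerance = 1e-6)
  expect_equal(min(prof$area) * 1e6, 76.3, tolerance = 1e-3)
  # 80%: 50.9 mm^2
  spec80 <- vessel_spec(stenosis_fraction = 0.8)
  expect_equal(min(analytic_area_profile(spec80, 201)$area) * 1e6, 50.9,
               tolerance = 1e-3)
  # healthy vessel: flat at 254.5 mm^2
  spec0 <- vessel_spec(stenosis_fraction = 0)
  prof0 <- analytic_area_profile(spec0, 11)
  expect_true(all(abs(prof0$area - a0) < 1e-12))
  # cosine bump vanishes at the ends of the stenosed span
  expect_equal(lumen_radius(spec70, spec70$stenosis_center +
                              c(-1, 1) * spec70$stenosis_length / 2),
               rep(0.009, 2), tolerance = 1e-9)
  expect_error(analytic_area_profile(spec70, 1), "axial_samples")
})

test_that("generated tube is a valid, axisymmetric, mirror-symmetric mesh", {
  spec <- vessel_spec(stenosis_fraction = 0.7, mesh_edge_length = 2.5e-3)
  mesh <- build_stenosed_tube(spec)
  expect_silent(validate_shell_mesh(mesh))
  # outward normals: dot(normal, radial) > 0 away from the end rings
  nrm <- vpatch:::triangle_normals(mesh)
  cent <- (mesh$nodes[mesh$tri[, 1], ] + mesh$nodes[mesh$tri[, 2], ] +
           mesh$nodes[mesh$tri[, 3], ]) / 3
  rad <- cbind(cent[, 1], cent[, 2], 0)
  expect_true(all(rowSums(nrm * rad) > 0))
  # mirror symmetry about the stenosis mid-plane: reflected node set maps
  # onto the node set
  refl <- mesh$nodes
  refl[, 3] <- 2 * spec$stenosis_center - refl[, 3]
  nn <- nrow(refl)
  d <- vapply(sample(nn, 200), function(i) {
    min(sqrt(rowSums((mesh$nodes - rep(refl[i, ], each = nn))^2)))
  }, numeric(1))
  expect_lt(max(d), spec$mesh_edge_length / 10)
  # inlet/outlet ring tags sit at the axial extremes
  expect_true(all(mesh$nodes[mesh$tags$inlet_ring, 3] == 0))
  expect_true(all(abs(mesh$nodes[mesh$tags$outlet_ring, 3] -
                        spec$total_length) < 1e-12))
})

test_that("sliced mesh areas agree with the analytic profile", {
  spec <- vessel_spec(stenosis_fraction = 0.7, mesh_edge_length = 2e-3)
  mesh <- build_stenosed_tube(spec)
  prof <- extract_centerline(mesh, n_samples = 31)
  ana <- pi * lumen_radius(spec, prof$points[, 3])^2
  expect_lt(max(abs(prof$areas - ana) / ana), 0.02)
  # refinement convergence: halving the edge length moves the sliced
  # throat area by < 0.5%
  throat <- function(h) {
    m <- build_stenosed_tube(vessel_spec(stenosis_fraction = 0.7,
                                         mesh_edge_length = h))
    min(extract_centerline(m, n_samples = 31)$areas)
  }
  expect_lt(abs(throat(3e-3) - throat(1.5e-3)) / throat(1.5e-3), 0.005)
})

test_that("mesh export and import round-trip", {
  mesh <- make_test_tube(h = 3e-3)
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  vtk <- tempfile(fileext = ".vtk")
  write_stl(mesh, stl)
  write_ply(mesh, ply)
  write_vtk(mesh, vtk, cell_data = list(vm = seq_len(nrow(mesh$tri)) * 1.0))
  m2 <- read_surface_mesh(stl)
  expect_equal(nrow(m2$nodes), nrow(mesh$nodes))
  expect_equal(nrow(m2$tri), nrow(mesh$tri))
  expect_equal(sort(vpatch:::triangle_areas(m2)),
               sort(vpatch:::triangle_areas(mesh)), tolerance = 1e-5)
  m3 <- read_surface_mesh(ply)
  expect_equal(m3$nodes, mesh$nodes, tolerance = 1e-6)
  expect_equal(m3$tri, mesh$tri)
  expect_gt(file.size(vtk), 0)
  # binary STL writes the same facet count
  stlb <- tempfile(fileext = ".stl")
  write_stl(mesh, stlb, binary = TRUE)
  expect_equal(file.size(stlb), 84 + 50 * nrow(mesh$tri))
})
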