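test_that("incision spec enforces its invariants", {
  expect_error(incision_spec("double", angular_positions = c(0, 1)),
               "separated by pi")
  spec <- vessel_spec(stenosis_fraction = 0.7)
  expect_error(validate_incision(incision_spec(cut_length = 0.2), spec),
               "cut_length")
  expect_error(validate_incision(
    incision_spec(target_gap_width = 0.03), spec), "target_gap_width")
})

test_that("traced incision paths match the requested geometry", {
  spec <- vessel_spec(stenosis_fraction = 0.7, mesh_edge_length = 2.5e-3)
  mesh <- build_stenosed_tube(spec)
  # straight 50 mm: arclength within 1 mm, azimuth constant
  p <- trace_incision(mesh, incision_spec("straight", cut_length = 0.05))[[1]]
  len <- sum(sqrt(rowSums(diff(mesh$nodes[p, ])^2)))
  expect_lt(abs(len - 0.05), 1e-3)
  az <- atan2(mesh$nodes[p, 2], mesh$nodes[p, 1])
  expect_lt(max(abs(az - az[1])), 1e-9)
  # oblique 5 degrees on a straight cylinder: azimuthal sweep ~ L tan(a)/r
  spec0 <- vessel_spec(stenosis_fraction = 0, total_length = 0.1,
                       stenosis_length = 0.05, mesh_edge_length = 2.5e-3)
  mesh0 <- build_stenosed_tube(spec0)
  po <- trace_incision(mesh0, incision_spec("oblique", cut_length = 0.05,
                                            helix_angle = 5))[[1]]
  azo <- atan2(mesh0$nodes[po, 2], mesh0$nodes[po, 1])
  sweep <- sum(diff((azo + 2 * pi) %% (2 * pi)))
  expect_equal(sweep, 0.05 * tan(5 * pi / 180) / 0.0095, tolerance = 0.15)
  # double cut: two disjoint paths
  pd <- trace_incision(mesh, incision_spec("double", cut_length = 0.05))
  expect_length(pd, 2)
  expect_length(intersect(pd[[1]], pd[[2]]), 0)
})

test_that("cut_slit duplicates interior path nodes into a zero-gap slit", {
  cv <- make_cut_vessel()
  k <- length(cv$paths[[1]])
  expect_equal(nrow(cv$cut_mesh$nodes), nrow(cv$mesh$nodes) + k - 2)
  expect_silent(validate_shell_mesh(cv$cut_mesh))
  ctx <- fem_context(cv$cut_mesh)
  expect_equal(max(slit_gap(ctx, "max")), 0)
  # both lips have the same node count
  cut <- cv$cut_mesh$cuts[[1]]
  expect_length(cut$right, length(cut$left))
  # path touching a boundary ring is rejected
  na <- attr(cv$mesh, "na")
  bad <- seq(1, by = na, length.out = 5)
  expect_error(cut_slit(cv$mesh, bad), "rings")
  # unloaded slit body is in equilibrium with zero displacement
  sol <- solve_stage(ctx, pressure = 0, n_increments = 1)
  expect_equal(max(abs(sol$state$displacements)), 0)
})

test_that("residual-stress release opens the slit slightly", {
  cv <- make_cut_vessel(h = 3.5e-3)
  rp <- residual_prestress(fem_context(cv$mesh))
  ctx <- fem_context(cv$cut_mesh)
  rel <- release_residual_stress(ctx, rp$sig0)
  g <- slit_gap(rel$ctx, "max")
  expect_gt(g, 0)
  expect_lt(g, 1e-3)  # "slightly": well under a millimetre
})

test_that("open_gap with a zero target is the identity control", {
  cv <- make_cut_vessel(h = 3.5e-3)
  ctx <- fem_context(cv$cut_mesh)
  og <- open_gap(ctx, 0)
  expect_equal(og$traction, 0)
  expect_equal(max(abs(og$ctx$x - ctx$x)), 0)
})

test_that("traction-controlled opening is monotone and hits the target", {
  cv <- make_cut_vessel(h = 3.5e-3)
  rp <- residual_prestress(fem_context(cv$mesh))
  ctx <- fem_context(cv$cut_mesh)
  ctx <- release_residual_stress(ctx, rp$sig0)$ctx
  og <- open_gap(ctx, 6e-3, method = "traction", gap_at = "max")
  expect_lt(abs(slit_gap(og$ctx, "max") - 6e-3) / 6e-3, 0.01)
  expect_gt(og$traction, 0)
  # gap grows monotonically along the recorded control trace
  tr <- og$trace[order(og$trace[, "traction"]), , drop = FALSE]
  expect_true(all(diff(tr[, "gap"]) > -1e-9))
})

test_that("retractor opening reaches 16 mm and is azimuthally symmetric", {
  bo <- baseline_opened()
  expect_lt(abs(slit_gap(bo$ctx) - 0.016) / 0.016, 0.01)
  expect_gt(bo$og$traction, 0)
  # mirror symmetry about the plane of the vessel axis and slit mid-normal
  cut <- bo$ctx$mesh$cuts[[1]]
  yL <- bo$ctx$x[cut$pairs[, 1], 2]
  yR <- bo$ctx$x[cut$pairs[, 2], 2]
  widths_ok <- abs(yL + yR) / max(abs(yL)) # lips mirrored in y
  expect_lt(stats::median(widths_ok), 0.05)
  gapL <- abs(yL); gapR <- abs(yR)
  expect_lt(stats::median(abs(gapL - gapR) / pmax(gapL, 1e-6)), 0.05)
})

test_that("tangent patch spans the opening with tangent continuity", {
  bo <- baseline_opened()
  patch <- bo$patches[[1]]
  # flat-lens lower bound for a 50 x 16 mm opening: 2/3 * 50 * 16 mm^2
  expect_gt(patch$mid_surface_area, 533e-6)
  # boundary nodes are artery lip nodes
  expect_setequal(stats::na.omit(patch$boundary_map),
                  unique(c(patch$cut$left, patch$cut$right)))
  # surface normals near the boundary agree with the artery within 10 deg
  cm <- current_mesh(bo$ctx)
  nrm_a <- vpatch:::triangle_normals(cm)
  nrm_p <- vpatch:::triangle_normals(patch[c("nodes", "tri")])
  # compare means around the left lip mid-node
  iL <- ceiling(length(patch$cut$left) / 2)
  els_a <- bo$ctx$mesh$cuts[[1]]$sides[[1]]$node_elems[[iL]]
  bme <- which(patch$tri[, 1] %in% which(patch$boundary_map ==
                                           patch$cut$left[iL]) |
               patch$tri[, 2] %in% which(patch$boundary_map ==
                                           patch$cut$left[iL]) |
               patch$tri[, 3] %in% which(patch$boundary_map ==
                                           patch$cut$left[iL]))
  va <- colMeans(nrm_a[els_a, , drop = FALSE])
  vp <- colMeans(nrm_p[bme, , drop = FALSE])
  ang <- acos(sum(va * vp) / sqrt(sum(va^2) * sum(vp^2))) * 180 / pi
  expect_lt(ang, 10)
})

test_that("suturing yields a manifold mesh with the expected bookkeeping", {
  bo <- baseline_opened()
  cm <- current_mesh(bo$ctx)
  cut <- bo$ctx$mesh$cuts[[1]]
  sm <- suture(cm, bo$patches)
  expect_silent(validate_shell_mesh(sm))
  # free edges only at the inlet/outlet rings
  et <- vpatch:::mesh_edge_table(sm)
  bnd <- et[et$count == 1, ]
  ring <- c(sm$tags$inlet_ring, sm$tags$outlet_ring)
  expect_true(all(bnd$a %in% ring & bnd$b %in% ring))
  # suture line = former cut-edge node set; cut tags cleared
  expect_setequal(sm$tags$suture_line, unique(c(cut$left, cut$right)))
  expect_length(sm$tags$cut_edge_left, 0)
  # patch elements keep their material bookkeeping
  expect_equal(sum(sm$region == "patch"), nrow(bo$patches[[1]]$tri))
  expect_true(all(sm$thickness[sm$region == "patch"] ==
                    bo$patches[[1]]$thickness))
})

test_that("double cut produces two patches of equal area", {
  dd <- fixture("double_opened", function()
    open_case(cut_length = 0.05, shape = "double"))
  areas <- vapply(dd$patches, `[[`, numeric(1), "mid_surface_area")
  expect_length(areas, 2)
  # symmetry up to the mesh quantization of the two diametrically
  # opposed incision paths
  expect_lt(abs(diff(areas)) / mean(areas), 0.025)
})
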