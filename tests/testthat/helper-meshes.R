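# Shared fixture builders: everything is generated in code at test time.

# flat rectangular plate mesh in the xy-plane (structured right triangles)
make_plate_mesh <- function(nn = 8, a = 1, thickness = 0.01) {
  xs <- seq(0, a, length.out = nn + 1)
  nodes <- cbind(as.matrix(expand.grid(x = xs, y = xs)), 0)
  id <- function(i, j) (j - 1) * (nn + 1) + i
  tri <- NULL
  for (j in 1:nn) for (i in 1:nn) {
    tri <- rbind(tri,
                 c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  structure(list(nodes = unname(nodes), tri = tri,
                 region = rep("artery", nrow(tri)),
                 thickness = rep(thickness, nrow(tri)),
                 tags = list(inlet_ring = integer(0),
                             outlet_ring = integer(0))),
            class = "shell_mesh")
}

plate_material <- function(E = 1e9, nu = 0.3, t = 0.01) {
  structure(list(name = "plate", youngs_modulus = E, poissons_ratio = nu,
                 thickness = t), class = "material_model")
}

# short healthy tube for solver oracles
make_test_tube <- function(h = 2e-3, L = 0.06, s = 0) {
  spec <- vessel_spec(stenosis_fraction = s, total_length = L,
                      stenosis_length = L / 2, mesh_edge_length = h)
  build_stenosed_tube(spec)
}

# coarse stenosed vessel + straight cut, shared by surgery tests
make_cut_vessel <- function(h = 2.5e-3, s = 0.7, cut = 0.05) {
  spec <- vessel_spec(stenosis_fraction = s, mesh_edge_length = h)
  mesh <- build_stenosed_tube(spec)
  paths <- trace_incision(mesh, incision_spec("straight", cut_length = cut))
  list(spec = spec, mesh = mesh, paths = paths,
       cut_mesh = cut_slit(mesh, paths))
}
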