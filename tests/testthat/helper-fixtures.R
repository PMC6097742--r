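# Heavy simulation fixtures are built once per test session and shared
# across test files (opening a slit to 16 mm is the expensive stage; the
# post-operative branches re-use it).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# baseline 70% vessel, 50 mm straight cut, opened to 16 mm, patch built
baseline_opened <- function() fixture("baseline_opened", function() {
  open_case(cut_length = 0.05, stenosis = 0.7)
})

open_case <- function(cut_length, stenosis = 0.7, shape = "straight",
                      gap = 0.016, h = 2.5e-3) {
  spec <- vessel_spec(stenosis_fraction = stenosis, mesh_edge_length = h)
  mesh <- build_stenosed_tube(spec)
  inc <- incision_spec(shape, cut_length = cut_length,
                       target_gap_width = gap)
  paths <- trace_incision(mesh, inc)
  rp <- residual_prestress(fem_context(mesh, end_cap = TRUE))
  mesh2 <- cut_slit(mesh, paths)
  ctx <- fem_context(mesh2, end_cap = TRUE)
  rel <- release_residual_stress(ctx, rp$sig0)
  og <- open_gap(rel$ctx, gap)
  patches <- generate_tangent_patch(og$ctx, "PTFE")
  list(spec = spec, mesh = mesh, paths = paths, ctx = og$ctx, og = og,
       patches = patches, release_state = rel$state)
}

# suture a given material onto an opened case and pressurize
postop_case <- function(opened, material = "PTFE", p_mmHg = 25,
                        from_ctx = NULL) {
  mat <- material_lookup(material)
  patches <- lapply(opened$patches, function(p) {
    p$material_name <- mat$name
    p$thickness <- mat$thickness
    p
  })
  ctx2 <- if (is.null(from_ctx)) suture_context(opened$ctx, patches, mat)
          else from_ctx
  po <- solve_stage(ctx2, pressure = mmHg_to_pa(p_mmHg), traction_mag = 0,
                    n_increments = max(6, ceiling(p_mmHg / 4)))
  cm <- current_mesh(po$ctx)
  prof <- extract_centerline(cm, n_samples = 41)
  list(ctx = po$ctx, state = po$state, mesh = cm, profile = prof,
       patches = patches)
}

baseline_postop25 <- function() fixture("baseline_postop25", function() {
  postop_case(baseline_opened(), "PTFE", 25)
})

# small fast scenario for the runner tests
cheap_scenario <- function() {
  list(name = "Cheap",
       vessel = list(inner_diameter_mm = 18, wall_thickness_mm = 1,
                     stenosis_pct = 50, stenosis_length_mm = 50,
                     total_length_mm = 100),
       incision = list(shape = "straight", cut_length_mm = 30,
                       helix_angle_deg = 0, gap_mm = 8),
       patch_material = "PTFE",
       stages = list(residual_mmHg = 5, postop_mmHg = 25),
       flow = list(rate_lpm = 4, density = 1060, viscosity = 3.5e-3),
       mesh = list(edge_mm = 3.5))
}

default_scenario_for_tests <- cheap_scenario
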