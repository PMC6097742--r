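#' Scenario configuration
#'
#' A scenario bundles the vessel, incision, patch material, load stages and
#' flow conditions of one virtual patch-reconstruction case.  Scenarios are
#' plain lists (usually read from a YAML file) with blocks `vessel`,
#' `incision`, `patch_material`, `stages`, `flow` and `mesh`; units in the
#' config are clinical (mm, mmHg, L/min), converted to SI internally.
#'
#' @param path YAML file with either a single scenario or a `cases:` list.
#' @return a scenario list, or a named list of scenarios.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$cases)) {
    out <- lapply(cfg$cases, function(cs)
      utils::modifyList(cfg[setdiff(names(cfg), "cases")], cs))
    names(out) <- vapply(out, function(cs) cs$name, character(1))
    out
  } else cfg
}

default_scenario <- function() {
  list(
    name = "Baseline",
    vessel = list(inner_diameter_mm = 18, wall_thickness_mm = 1,
                  stenosis_pct = 70, stenosis_length_mm = 50,
                  total_length_mm = 100),
    incision = list(shape = "straight", cut_length_mm = 50,
                    helix_angle_deg = 0, gap_mm = 16),
    patch_material = "PTFE",
    stages = list(residual_mmHg = 5, postop_mmHg = 25),
    flow = list(rate_lpm = 4, density = 1060, viscosity = 3.5e-3),
    mesh = list(edge_mm = 2.5))
}

validate_scenario <- function(cfg) {
  cfg <- utils::modifyList(default_scenario(), cfg)
  need <- c("vessel", "incision", "patch_material", "stages", "flow", "mesh")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("scenario config missing blocks: ",
                         paste(miss, collapse = ", "))
  material_lookup(cfg$patch_material)  # errors early on unknown material
  if (!cfg$incision$shape %in% c("straight", "oblique", "double"))
    stop("unknown incision shape: ", cfg$incision$shape)
  cfg
}

scenario_vessel_spec <- function(cfg) {
  v <- cfg$vessel
  vessel_spec(inner_diameter = v$inner_diameter_mm * 1e-3,
              wall_thickness = v$wall_thickness_mm * 1e-3,
              total_length = v$total_length_mm * 1e-3,
              stenosis_fraction = v$stenosis_pct / 100,
              stenosis_length = v$stenosis_length_mm * 1e-3,
              mesh_edge_length = cfg$mesh$edge_mm * 1e-3)
}

#' Run one virtual-surgery scenario end to end
#'
#' Executes the full sequence — stenosed-vessel generation, residual
#' prestress, incision, residual-stress release, gap opening, tangent-patch
#' synthesis, suturing, post-operative pressurization — then the
#' biomechanical indices (centerline area profile, residual stenosis,
#' centerline offset, stress summaries, suture-line stress jump) and the
#' reduced-order hemodynamics.  Deterministic given the configuration.
#'
#' @param cfg a scenario list (see [read_scenario()]); missing fields take
#'   the baseline defaults.
#' @param keep_fem also return the final context/state/profile objects.
#' @param out_dir if non-NULL, stage meshes (VTK) and the profile table are
#'   written there.
#' @return a `scenario_report` list; see Details.
#' @details Report fields (clinical units): `patch_area_mm2` (sum over
#'   patches), `postop_stenosis_pct`, `max_arterial_stress_kPa`,
#'   `max_patch_stress_kPa`, `avg_patch_stress_kPa`,
#'   `suture_stress_jump_kPa`, `centerline_offset_mm`,
#'   `intraop_max_stress_kPa` (artery, opened state), `reynolds_max`,
#'   `delta_p_mmHg`, `traction_N_per_m`, plus `stages` metadata.
#' @export
run_case <- function(cfg, keep_fem = FALSE, out_dir = NULL) {
  cfg <- validate_scenario(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  spec <- scenario_vessel_spec(cfg)
  mesh <- stage("geometry", build_stenosed_tube(spec))
  inc <- incision_spec(cfg$incision$shape,
                       cut_length = cfg$incision$cut_length_mm * 1e-3,
                       helix_angle = cfg$incision$helix_angle_deg,
                       target_gap_width = cfg$incision$gap_mm * 1e-3)
  paths <- stage("incision", trace_incision(mesh, inc))
  p_res <- mmHg_to_pa(cfg$stages$residual_mmHg)
  rp <- stage("residual_prestress", residual_prestress(fem_context(mesh, end_cap = TRUE),
                                                       p_res))
  mesh2 <- stage("cut", cut_slit(mesh, paths))
  ctx <- fem_context(mesh2, end_cap = TRUE)
  rel <- stage("slit_release", release_residual_stress(ctx, rp$sig0))
  ctx <- rel$ctx
  og <- stage("open_gap", open_gap(ctx, inc$target_gap_width))
  ctx <- og$ctx
  patches <- stage("tangent_patch",
                   generate_tangent_patch(ctx, cfg$patch_material))
  pmat <- material_lookup(cfg$patch_material)
  intraop <- stress_summary(og$state, current_mesh(ctx), "artery")
  ctx2 <- stage("suture", suture_context(ctx, patches, pmat))
  p_post <- mmHg_to_pa(cfg$stages$postop_mmHg)
  po <- stage("postop_pressure",
              solve_stage(ctx2, pressure = p_post, traction_mag = 0,
                          n_increments = max(6, ceiling(
                            cfg$stages$postop_mmHg / 4))))
  cm <- current_mesh(po$ctx)
  prof <- stage("centerline", extract_centerline(cm, n_samples = 41))
  flow <- flow_spec(flow_rate = cfg$flow$rate_lpm / 60000,
                    density = cfg$flow$density,
                    viscosity = cfg$flow$viscosity)
  re <- reynolds_profile(prof, flow)
  ss_a <- stress_summary(po$state, cm, "artery")
  ss_p <- stress_summary(po$state, cm, "patch")
  rep <- structure(list(
    case_name = cfg$name,
    patch_area_mm2 = 1e6 * sum(vapply(patches, `[[`, numeric(1),
                                      "mid_surface_area")),
    postop_stenosis_pct = residual_stenosis(prof),
    max_arterial_stress_kPa = ss_a[["max"]] / 1e3,
    max_patch_stress_kPa = ss_p[["max"]] / 1e3,
    avg_patch_stress_kPa = ss_p[["mean"]] / 1e3,
    suture_stress_jump_kPa = suture_stress_jump(po$state, cm) / 1e3,
    centerline_offset_mm = 1e3 * centerline_offset(prof),
    intraop_max_stress_kPa = intraop[["max"]] / 1e3,
    intraop_mean_stress_kPa = intraop[["mean"]] / 1e3,
    reynolds_max = attr(re, "max_Re"),
    delta_p_mmHg = pa_to_mmHg(pressure_drop_estimate(prof, flow)),
    traction_N_per_m = og$traction,
    stages = list(open_trace = og$trace)), class = "scenario_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk(cm, file.path(out_dir, paste0(cfg$name, "_postop.vtk")),
              cell_data = list(von_mises = po$state$element_von_mises))
    utils::write.csv(profile_table(prof),
                     file.path(out_dir, paste0(cfg$name, "_profile.csv")),
                     row.names = FALSE)
  }
  if (keep_fem) {
    rep$fem <- list(ctx = po$ctx, state = po$state, profile = prof,
                    patches = patches, opened_ctx = ctx,
                    opened_state = og$state)
  }
  rep
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf(
    paste0("case %s: patch %.0f mm^2, post-op stenosis %.1f%%, ",
           "max artery %.0f kPa, max patch %.0f kPa, offset %.1f mm\n"),
    x$case_name, x$patch_area_mm2, x$postop_stenosis_pct,
    x$max_arterial_stress_kPa, x$max_patch_stress_kPa,
    x$centerline_offset_mm))
  invisible(x)
}

#' Run a matrix of scenarios
#'
#' Runs each case with [run_case()]; per-case failures are recorded and the
#' matrix continues.
#'
#' @param cfgs named list of scenario configs (e.g. from [read_scenario()]
#'   on a file with a `cases:` block).
#' @param out_dir optional directory for the report table and per-case
#'   exports.
#' @return a data frame, one row per case, columns in the order of the
#'   performance table (patch area, post-operative stenosis, stress
#'   summaries), plus an `error` column for failed cases.
#' @export
run_matrix <- function(cfgs, out_dir = NULL) {
  if (!length(cfgs)) stop("empty scenario list")
  rows <- lapply(cfgs, function(cfg) {
    r <- tryCatch(run_case(cfg, out_dir = out_dir),
                  error = function(e) conditionMessage(e))
    if (is.character(r))
      return(data.frame(case_name = cfg$name %||% "?", patch_area_mm2 = NA,
                        postop_stenosis_pct = NA,
                        max_arterial_stress_kPa = NA,
                        max_patch_stress_kPa = NA, avg_patch_stress_kPa = NA,
                        centerline_offset_mm = NA, reynolds_max = NA,
                        delta_p_mmHg = NA, error = r))
    data.frame(case_name = r$case_name, patch_area_mm2 = r$patch_area_mm2,
               postop_stenosis_pct = r$postop_stenosis_pct,
               max_arterial_stress_kPa = r$max_arterial_stress_kPa,
               max_patch_stress_kPa = r$max_patch_stress_kPa,
               avg_patch_stress_kPa = r$avg_patch_stress_kPa,
               centerline_offset_mm = r$centerline_offset_mm,
               reynolds_max = r$reynolds_max,
               delta_p_mmHg = r$delta_p_mmHg, error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the bundled ten-case scenario matrix
#'
#' The parametric study shipped with the package: baseline plus length,
#' shape, stenosis-level, material and pressure variations.
#'
#' @return file path of the YAML config.
#' @export
cases_table1 <- function() {
  system.file("extdata", "cases_table1.yaml", package = "vpatch",
              mustWork = TRUE)
}
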