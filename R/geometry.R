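#' Parametric description of a stenosed vessel
#'
#' Describes an axisymmetric tube with a smooth (raised-cosine) area stenosis,
#' dimensioned by default for a 9-year-old main pulmonary artery: 18 mm inner
#' diameter, 1 mm uniform wall thickness.  `stenosis_fraction` is the fraction
#' of cross-sectional *area* removed at the throat, so a 70% stenosis leaves
#' 30% of the inlet lumen area.
#'
#' @param inner_diameter lumen diameter away from the stenosis (m).
#' @param wall_thickness uniform wall thickness (m).
#' @param total_length vessel length (m).  Default twice the stenosis length.
#' @param stenosis_fraction fraction of lumen area removed at the throat,
#'   in (0, 1).  Use 0 for a healthy cylinder.
#' @param stenosis_length axial extent of the stenosed segment (m).
#' @param stenosis_center axial position of the throat (m); default mid-vessel.
#' @param profile_kind axial profile of the narrowing; only `"cosine"` (a
#'   raised-cosine bump, smooth and symmetric) is implemented.
#' @param mesh_edge_length target triangle edge length for meshing (m).
#' @return an object of class `vessel_spec`.
#' @export
#' @examples
#' spec <- vessel_spec(stenosis_fraction = 0.7)
#' analytic_area_profile(spec, 5)
vessel_spec <- function(inner_diameter = 0.018,
                        wall_thickness = 0.001,
                        total_length = 2 * stenosis_length,
                        stenosis_fraction = 0.7,
                        stenosis_length = 0.050,
                        stenosis_center = total_length / 2,
                        profile_kind = "cosine",
                        mesh_edge_length = 5e-4) {
  spec <- structure(list(
    inner_diameter = inner_diameter, wall_thickness = wall_thickness,
    total_length = total_length, stenosis_fraction = stenosis_fraction,
    stenosis_length = stenosis_length, stenosis_center = stenosis_center,
    profile_kind = match.arg(profile_kind, "cosine"),
    mesh_edge_length = mesh_edge_length), class = "vessel_spec")
  validate_vessel_spec(spec)
  spec
}

validate_vessel_spec <- function(spec) {
  if (!(spec$stenosis_fraction >= 0 && spec$stenosis_fraction < 1))
    stop("vessel_spec invariant violated: 0 <= stenosis_fraction < 1")
  if (spec$stenosis_length > spec$total_length)
    stop("vessel_spec invariant violated: stenosis_length <= total_length")
  if (spec$wall_thickness >= spec$inner_diameter / 4)
    stop("vessel_spec invariant violated: wall_thickness < inner_diameter/4")
  if (spec$inner_diameter <= 0 || spec$total_length <= 0 ||
      spec$mesh_edge_length <= 0)
    stop("vessel_spec invariant violated: all lengths must be positive")
  invisible(spec)
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf(
    "vessel_spec: D=%.1f mm, t=%.2f mm, L=%.0f mm, %g%% area stenosis over %.0f mm\n",
    1e3 * x$inner_diameter, 1e3 * x$wall_thickness, 1e3 * x$total_length,
    100 * x$stenosis_fraction, 1e3 * x$stenosis_length))
  invisible(x)
}

# Raised-cosine stenosis weight: 1 at the throat, 0 outside the stenosed span.
stenosis_bump <- function(spec, z) {
  w <- numeric(length(z))
  dz <- z - spec$stenosis_center
  inside <- abs(dz) <= spec$stenosis_length / 2
  w[inside] <- 0.5 * (1 + cos(2 * pi * dz[inside] / spec$stenosis_length))
  w
}

#' Lumen radius and analytic lumen-area profile
#'
#' Closed-form profile of the generated vessel: at axial position `z` the
#' lumen radius is `r0 * sqrt(1 - stenosis_fraction * w(z))` with `w` the
#' raised-cosine bump, so the lumen *area* at the throat is exactly
#' `(1 - stenosis_fraction)` times the inlet area.
#'
#' @param spec a [vessel_spec()].
#' @param z axial positions (m).
#' @return `lumen_radius`: radii (m). `analytic_area_profile`: a data frame
#'   with columns `z` (m) and `area` (m^2) at `axial_samples` equispaced
#'   stations.
#' @export
lumen_radius <- function(spec, z) {
  r0 <- spec$inner_diameter / 2
  r0 * sqrt(1 - spec$stenosis_fraction * stenosis_bump(spec, z))
}

#' @rdname lumen_radius
#' @param axial_samples number of equispaced axial stations (>= 2).
#' @export
analytic_area_profile <- function(spec, axial_samples = 101) {
  validate_vessel_spec(spec)
  if (axial_samples < 2) stop("axial_samples must be >= 2")
  z <- seq(0, spec$total_length, length.out = axial_samples)
  data.frame(z = z, area = pi * lumen_radius(spec, z)^2)
}

#' Build the triangulated mid-surface mesh of a stenosed tube
#'
#' The shell idealization places a single mid-surface at
#' `r_lumen(z) + wall_thickness/2`, with the thickness carried as a
#' per-element attribute.  The mesh is a structured cylindrical grid of
#' consistently wound triangles (outward normals), with the inlet ring at
#' `z = 0` and the outlet ring at `z = total_length`.
#'
#' @param spec a [vessel_spec()]; `mesh_edge_length` must not exceed
#'   `stenosis_length / 10` when a stenosis is present.
#' @return a `shell_mesh`: list with `nodes` (n x 3, m), `tri` (m x 3,
#'   1-based), `region` (per-element, `"artery"`/`"patch"`),
#'   `thickness` (per-element, m), `tags` (named node-index sets).
#' @export
build_stenosed_tube <- function(spec) {
  validate_vessel_spec(spec)
  h <- spec$mesh_edge_length
  if (spec$stenosis_fraction > 0 && h > spec$stenosis_length / 10)
    stop("mesh_edge_length must be <= stenosis_length/10")
  r_mid0 <- spec$inner_diameter / 2 + spec$wall_thickness / 2
  na <- max(12L, as.integer(round(2 * pi * r_mid0 / h)))
  nz <- max(4L, as.integer(round(spec$total_length / h)))
  z <- seq(0, spec$total_length, length.out = nz + 1)
  theta <- 2 * pi * (seq_len(na) - 1) / na
  r_mid <- lumen_radius(spec, z) + spec$wall_thickness / 2
  nodes <- cbind(
    x = rep(r_mid, each = na) * cos(theta),
    y = rep(r_mid, each = na) * sin(theta),
    z = rep(z, each = na))
  # quad cell (ring r, azimuth a) -> two outward-wound triangles
  a <- rep(seq_len(na), nz)
  r <- rep(seq_len(nz) - 1L, each = na)
  ap1 <- ifelse(a == na, 1L, a + 1L)
  A <- r * na + a
  B <- r * na + ap1
  C <- (r + 1L) * na + a
  D <- (r + 1L) * na + ap1
  tri <- rbind(cbind(A, B, C), cbind(B, D, C))
  mesh <- structure(list(
    nodes = unname(nodes),
    tri = unname(tri),
    region = rep("artery", nrow(tri)),
    thickness = rep(spec$wall_thickness, nrow(tri)),
    tags = list(inlet_ring = seq_len(na),
                outlet_ring = nz * na + seq_len(na))),
    class = "shell_mesh",
    na = na, nz = nz, spec = spec)
  mesh
}

#' @export
print.shell_mesh <- function(x, ...) {
  cat(sprintf("shell_mesh: %d nodes, %d triangles (%s)\n",
              nrow(x$nodes), nrow(x$tri),
              paste(sprintf("%s: %d", names(table(x$region)),
                            table(x$region)), collapse = ", ")))
  if (length(x$tags))
    cat("  tags:", paste(sprintf("%s[%d]", names(x$tags),
                                 lengths(x$tags)), collapse = ", "), "\n")
  invisible(x)
}

#' Mesh queries: edges, triangle areas and normals
#'
#' @param mesh a `shell_mesh`.
#' @return `mesh_edge_table`: data frame of unique edges with the number of
#'   incident triangles (`count`); `triangle_areas` / `triangle_normals`:
#'   per-element areas (m^2) / outward unit normals.
#' @keywords internal
mesh_edge_table <- function(mesh) {
  tr <- mesh$tri
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  data.frame(a = as.integer(ij[, 1]), b = as.integer(ij[, 2]),
             count = as.integer(tab))
}

triangle_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

triangle_normals <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cr / sqrt(rowSums(cr^2))
}

#' Validate shell-mesh invariants
#'
#' Checks positive triangle areas and edge manifoldness: every edge must be
#' shared by exactly two triangles except boundary edges (inlet/outlet rings
#' and, on a slit mesh, the cut edges), which are shared by one.
#'
#' @param mesh a `shell_mesh`.
#' @return invisibly `TRUE`; errors on violation.
#' @export
validate_shell_mesh <- function(mesh) {
  if (any(triangle_areas(mesh) <= 0))
    stop("shell_mesh invariant violated: all triangle areas > 0")
  et <- mesh_edge_table(mesh)
  if (any(et$count > 2))
    stop("shell_mesh invariant violated: non-manifold edge (shared by >2 triangles)")
  bnd <- et[et$count == 1, , drop = FALSE]
  allowed <- unique(unlist(mesh$tags[c("inlet_ring", "outlet_ring",
                                       "cut_edge_left", "cut_edge_right")]))
  bad <- setdiff(unique(c(bnd$a, bnd$b)), allowed)
  if (length(bad))
    stop("shell_mesh invariant violated: free edge not on a tagged boundary (nodes ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  invisible(TRUE)
}

# Nodes on free (boundary) edges.
boundary_nodes <- function(mesh) {
  et <- mesh_edge_table(mesh)
  bnd <- et[et$count == 1, , drop = FALSE]
  sort(unique(c(bnd$a, bnd$b)))
}
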