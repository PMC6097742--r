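#' Incision specification
#'
#' Describes the arteriotomy: a straight axial cut, an oblique (helical)
#' cut, or a pair of diametrically opposed straight cuts, centered axially
#' on the stenosis.
#'
#' @param shape `"straight"`, `"oblique"` or `"double"`.
#' @param cut_length geodesic incision length (m).
#' @param helix_angle helix angle from the axial direction (deg); 0 for
#'   straight, typically 5 for oblique.
#' @param target_gap_width intra-operative slit stretch: target maximum gap
#'   opening (m).
#' @param angular_positions azimuth(s) of the cut(s) (rad); `"double"`
#'   requires exactly two separated by pi.
#' @return an `incision_spec`.
#' @export
incision_spec <- function(shape = c("straight", "oblique", "double"),
                          cut_length = 0.050,
                          helix_angle = if (shape == "oblique") 5 else 0,
                          target_gap_width = 0.016,
                          angular_positions = if (shape == "double") c(0, pi)
                                              else 0) {
  shape <- match.arg(shape)
  if (shape == "double") {
    if (length(angular_positions) != 2 ||
        abs(abs(diff(angular_positions)) - pi) > 1e-9)
      stop("incision invariant violated: double cut needs two azimuths separated by pi")
  }
  structure(list(shape = shape, cut_length = cut_length,
                 helix_angle = helix_angle,
                 target_gap_width = target_gap_width,
                 angular_positions = angular_positions),
            class = "incision_spec")
}

validate_incision <- function(inc, spec) {
  if (inc$cut_length > spec$total_length)
    stop("incision invariant violated: cut_length <= vessel total_length")
  if (inc$target_gap_width >= pi * spec$inner_diameter / 2)
    stop("incision invariant violated: target_gap_width < pi*inner_diameter/2")
  invisible(inc)
}

# Ring/azimuth helpers for the structured generator mesh.
mesh_grid_info <- function(mesh) {
  na <- attr(mesh, "na"); nz <- attr(mesh, "nz")
  if (is.null(na)) stop("incision tracing requires a generator (structured) mesh")
  list(na = na, nz = nz)
}

#' Trace an incision path on the vessel surface
#'
#' Snaps the ideal straight or helical incision curve, centered axially on
#' the stenosis, to mesh vertices.  The axial extent is chosen so the
#' geodesic (along-surface) path length matches `cut_length` as closely as
#' the mesh spacing permits.
#'
#' @param mesh an intact tube from [build_stenosed_tube()].
#' @param inc an [incision_spec()].
#' @return a list of node-index paths (one per cut), ordered from low to
#'   high z.
#' @export
trace_incision <- function(mesh, inc) {
  spec <- attr(mesh, "spec")
  validate_incision(inc, spec)
  g <- mesh_grid_info(mesh)
  if (length(mesh$tags$cut_edge_left))
    stop("mesh already has a slit")
  azimuths <- switch(inc$shape,
                     straight = inc$angular_positions[1],
                     oblique = inc$angular_positions[1],
                     double = inc$angular_positions)
  paths <- lapply(azimuths, function(th0)
    trace_one_path(mesh, spec, g, th0, inc$cut_length,
                   if (inc$shape == "oblique") inc$helix_angle else 0))
  if (length(paths) == 2 && length(intersect(paths[[1]], paths[[2]])))
    stop("double incision paths overlap")
  paths
}

trace_one_path <- function(mesh, spec, g, theta0, cut_length, helix_deg) {
  na <- g$na; nz <- g$nz
  z <- mesh$nodes[seq(1, nrow(mesh$nodes), by = na), 3]
  a0 <- (round(theta0 / (2 * pi) * na) %% na) + 1L
  node_at <- function(ring, a) (ring - 1L) * na + ((a - 1L) %% na) + 1L
  rc <- which.min(abs(z - spec$stenosis_center))
  if (helix_deg == 0) {
    # choose ring extents (lo, hi) minimizing |geodesic length - cut_length|
    seglen <- sqrt(diff(mesh$nodes[node_at(seq_len(nz + 1), a0), 3])^2 +
                   diff(sqrt(mesh$nodes[node_at(seq_len(nz + 1), a0), 1]^2 +
                             mesh$nodes[node_at(seq_len(nz + 1), a0), 2]^2))^2)
    cum <- c(0, cumsum(seglen))  # arclength at each ring along the azimuth line
    best <- NULL
    for (lo in 2:(rc)) {
      tgt <- cum[lo] + cut_length
      hi <- which.min(abs(cum - tgt))
      if (hi > nz) hi <- nz  # keep off the outlet ring
      if (hi <= lo + 1) next
      err <- abs((cum[hi] - cum[lo]) - cut_length) +
        0.1 * abs((cum[lo] + cum[hi]) / 2 - cum[rc])  # prefer centered
      if (is.null(best) || err < best$err) best <- list(lo = lo, hi = hi, err = err)
    }
    if (is.null(best)) stop("incision path exits mesh bounds")
    path <- node_at(best$lo:best$hi, a0)
  } else {
    # helical walk: azimuth advances at tan(helix)/r per unit z
    alpha <- helix_deg * pi / 180
    lz <- cut_length * cos(alpha)
    lo <- which.min(abs(z - (spec$stenosis_center - lz / 2)))
    hi <- which.min(abs(z - (spec$stenosis_center + lz / 2)))
    lo <- max(lo, 2L); hi <- min(hi, nz)
    if (hi <= lo + 1) stop("incision path exits mesh bounds")
    rings <- lo:hi
    th <- numeric(length(rings)); th[1] <- 2 * pi * (a0 - 1) / na
    for (k in seq_along(rings)[-1]) {
      zm <- (z[rings[k]] + z[rings[k - 1]]) / 2
      rm <- lumen_radius(spec, zm) + spec$wall_thickness / 2
      th[k] <- th[k - 1] + tan(alpha) * (z[rings[k]] - z[rings[k - 1]]) / rm
    }
    ai <- (round(th / (2 * pi) * na) %% na) + 1L
    path <- node_at(rings, ai)
    if (any(duplicated(path))) stop("oblique path self-intersects on this mesh")
  }
  len <- sum(sqrt(rowSums((mesh$nodes[path[-1], , drop = FALSE] -
                           mesh$nodes[path[-length(path)], , drop = FALSE])^2)))
  if (abs(len - cut_length) / cut_length > 0.05)
    warning(sprintf("traced path length %.1f mm vs requested %.1f mm",
                    1e3 * len, 1e3 * cut_length))
  path
}

#' Convert an incision path to a zero-gap slit
#'
#' Duplicates every interior node of the path and reconnects the triangles
#' on one side to the copies, producing two coincident free edges
#' (`cut_edge_left`, the original nodes; `cut_edge_right`, the copies) that
#' share the two tip nodes.  The gap width is exactly zero until a solve
#' releases the residual stress.
#'
#' @param mesh a `shell_mesh`.
#' @param paths one node path or a list of paths from [trace_incision()].
#' @return the slit `shell_mesh`, with cut bookkeeping in `mesh$cuts`.
#' @export
cut_slit <- function(mesh, paths) {
  if (!is.list(paths)) paths <- list(paths)
  for (path in paths) mesh <- cut_one_slit(mesh, path)
  mesh
}

cut_one_slit <- function(mesh, path) {
  k <- length(path)
  if (k < 3) stop("incision path must have >= 3 nodes")
  if (any(duplicated(path))) stop("incision path must be simple")
  ring_nodes <- c(mesh$tags$inlet_ring, mesh$tags$outlet_ring)
  if (any(path %in% ring_nodes))
    stop("incision path must not touch the inlet/outlet rings")
  et <- mesh_edge_table(mesh)
  if (any(et$count > 2)) stop("cut_slit requires a manifold mesh")

  tri <- mesh$tri
  n0 <- nrow(mesh$nodes)
  interior <- path[2:(k - 1)]
  new_ids <- n0 + seq_along(interior)
  nodes <- rbind(mesh$nodes, mesh$nodes[interior, , drop = FALSE])

  for (ii in seq_along(interior)) {
    vi <- interior[ii]
    vprev <- path[ii]; vnext <- path[ii + 2]
    inc <- which(tri[, 1] == vi | tri[, 2] == vi | tri[, 3] == vi)
    # ordered link cycle around vi from the winding: tri (vi, b, c) -> b -> c
    nxt <- integer(0); frm <- integer(0); tri_of <- integer(0)
    for (e in inc) {
      v <- tri[e, ]
      pos <- which(v == vi)
      b <- v[pos %% 3 + 1]; cc <- v[(pos + 1) %% 3 + 1]
      frm <- c(frm, b); nxt <- c(nxt, cc); tri_of <- c(tri_of, e)
    }
    succ <- setNames(nxt, frm)
    etri <- setNames(tri_of, frm)
    # walk the link starting at vprev; once the previous path node has been
    # duplicated the link is an open chain (it ends at the duplicate),
    # otherwise a closed cycle
    cyc <- vprev; closed <- TRUE
    repeat {
      key <- as.character(cyc[length(cyc)])
      if (!key %in% names(succ)) { closed <- FALSE; break }
      nx <- succ[[key]]
      if (nx == vprev) break
      cyc <- c(cyc, nx)
      if (length(cyc) > length(inc) + 1) stop("non-manifold fan around path node")
    }
    q <- match(vnext, cyc)
    if (is.na(q)) stop("path nodes are not mesh neighbors")
    # triangles on the far side of the path: link entries from vnext onward
    sideB_from <- if (closed) cyc[q:length(cyc)] else cyc[q:(length(cyc) - 1)]
    eB <- unname(etri[as.character(sideB_from)])
    for (e in eB) tri[e, tri[e, ] == vi] <- new_ids[ii]
  }

  right_path <- c(path[1], new_ids, path[k])
  mesh$nodes <- nodes
  mesh$tri <- tri
  cut <- list(
    left = path, right = right_path,
    pairs = cbind(left = interior, right = new_ids))
  cut$sides <- lapply(list(left = path, right = right_path), function(p)
    side_info(mesh, p))
  cut$sides$left$partner <- right_path
  cut$sides$right$partner <- path
  mesh$cuts <- c(mesh$cuts, list(cut))
  mesh$tags$cut_edge_left <- c(mesh$tags$cut_edge_left, path)
  mesh$tags$cut_edge_right <- c(mesh$tags$cut_edge_right, right_path)
  validate_shell_mesh(mesh)
  mesh
}

# Per-node incident elements and a reference "toward own material" direction
# for one lip of a slit.  Precomputes the restricted element set so the
# traction force (and its finite-difference Jacobian) can be evaluated
# touching only slit-adjacent elements.
side_info <- function(mesh, p) {
  node_elems <- lapply(p, function(v)
    which(mesh$tri[, 1] == v | mesh$tri[, 2] == v | mesh$tri[, 3] == v))
  own_dir <- t(vapply(seq_along(p), function(i) {
    els <- node_elems[[i]]
    cent <- colMeans(matrix(mesh$nodes[t(mesh$tri[els, , drop = FALSE]), ],
                            ncol = 3))
    v <- cent - mesh$nodes[p[i], ]
    v / max(sqrt(sum(v^2)), 1e-30)
  }, numeric(3)))
  els_unique <- sort(unique(unlist(node_elems)))
  list(path = p, node_elems = node_elems, own_dir = own_dir,
       els_unique = els_unique,
       node_elem_rows = lapply(node_elems, match, els_unique),
       support_nodes = sort(unique(c(p, as.vector(
         mesh$tri[els_unique, , drop = FALSE])))))
}

# Register slit traction machinery on a context built from a slit mesh.
register_cuts <- function(ctx) {
  if (length(ctx$mesh$cuts))
    ctx$traction <- list(sides = unlist(lapply(ctx$mesh$cuts,
                                               function(ct) ct$sides),
                                        recursive = FALSE, use.names = FALSE))
  ctx
}

#' Slit gap width
#'
#' Euclidean distance between corresponding duplicated node pairs of each
#' cut: either the maximum over the slit, or the width at the mid-slit
#' pair (the stenosis throat for a cut centered on the stenosis, which is
#' where the patch has to pass and where the surgeon gauges the opening).
#'
#' @param ctx a `fem_context` with cuts.
#' @param at `"center"` (mid-slit pair) or `"max"`.
#' @return numeric vector, one gap per cut (m).
#' @export
slit_gap <- function(ctx, at = c("center", "max")) {
  at <- match.arg(at)
  vapply(ctx$mesh$cuts, function(cut) {
    d <- ctx$x[cut$pairs[, 1], , drop = FALSE] -
      ctx$x[cut$pairs[, 2], , drop = FALSE]
    w <- sqrt(rowSums(d^2))
    if (at == "center") w[ceiling(length(w) / 2)] else max(w)
  }, numeric(1))
}

#' Open the slit to a target gap width
#'
#' Stretches the slit until the opening width at the mid-slit (`gap_at =
#' "center"`, where the surgeon gauges the clearance for the patch)
#' reaches `target_gap` within `tol_rel`.
#'
#' Two control modes are available.  `"retractor"` (default) prescribes
#' the motion of a retractor jaw — the lip nodes within `span` of the
#' mid-slit — apart along the opening direction, in equilibrium steps:
#' displacement control traverses the limit points the opening shell
#' passes through, exactly the way the surgeon imposes the slit stretch;
#' the work-conjugate jaw reaction is reported as the equivalent edge
#' traction.  `"traction"` ramps a uniform distributed traction, normal to
#' the cut faces (follower, recomputed on the deformed lips), with a
#' damped secant loop on its magnitude; it is the natural load-control
#' formulation but cannot pass limit points, so it is limited to moderate
#' openings.
#'
#' @param ctx a `fem_context` with a slit (after residual-stress release).
#' @param target_gap target opening width (m).
#' @param pressure lumen pressure held during the stage (Pa; defaults to
#'   the pressure already in the context, typically 0 intra-operatively).
#' @param tol_rel relative tolerance on the achieved gap (default 1%).
#' @param max_outer control-loop iteration budget.
#' @param gap_at gap metric, see [slit_gap()].
#' @param method `"retractor"` or `"traction"`.
#' @param span axial extent of the retractor jaw (m); default the central
#'   half of the slit, the region the surgeon holds open for implantation.
#' @return list with updated `ctx`, the converged `fem_state`, the
#'   equivalent `traction` magnitude (N/m) and the `trace` of
#'   (traction or jaw opening, gap) pairs.
#' @export
open_gap <- function(ctx, target_gap, pressure = NULL, tol_rel = 0.01,
                     max_outer = 15, gap_at = c("center", "max"),
                     method = c("retractor", "traction"), span = NULL) {
  gap_at <- match.arg(gap_at)
  method <- match.arg(method)
  if (!length(ctx$mesh$cuts)) stop("mesh has no slit to open")
  ctx <- register_cuts(ctx)
  if (is.null(pressure)) pressure <- ctx$pressure
  # stage 1: bring any held pressure in with no stretch
  if (pressure != ctx$pressure)
    ctx <- solve_stage(ctx, pressure = pressure, n_increments = 4)$ctx
  gap0 <- max(slit_gap(ctx, gap_at))
  trace <- cbind(traction = 0, gap = gap0)
  if (target_gap <= gap0 * (1 + tol_rel))
    return(list(ctx = ctx, state = fem_state(ctx), traction = 0,
                trace = trace))
  if (method == "retractor")
    return(open_gap_retractor(ctx, target_gap, tol_rel, max_outer, gap_at,
                              span, trace))
  # local linearized gap-vs-traction rate at the current state
  n <- nrow(ctx$x)
  free <- setdiff(seq_len(6 * n), ctx$bc$fixed)
  asm <- fem_assemble(ctx, ctx$pressure)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                            dims = c(6 * n, 6 * n))
  ft <- traction_unit_forces(ctx)
  d <- numeric(6 * n)
  d[free] <- as.numeric(Matrix::solve(K[free, free], ft[free]))
  du <- matrix(d[rep(0:(n - 1) * 6, each = 3) + 1:3], ncol = 3, byrow = TRUE)
  ctx_lin <- ctx; ctx_lin$x <- ctx$x + du
  rate <- max(slit_gap(ctx_lin, gap_at)) - gap0
  if (rate <= 0) stop("slit does not open under traction; check cut tagging")
  # stage 2: traction march from below: the gap stiffens/softens
  # nonlinearly, so use damped secant updates with capped growth, aiming
  # at the target from the safe side
  tmag <- 0.6 * (target_gap - gap0) / rate
  t_prev <- 0; g_prev <- gap0
  sol <- solve_stage(ctx, pressure = pressure, traction_mag = tmag,
                     n_increments = 4)
  ctx <- sol$ctx
  for (it in seq_len(max_outer)) {
    g <- max(slit_gap(ctx, gap_at))
    trace <- rbind(trace, cbind(traction = tmag, gap = g))
    if (abs(g - target_gap) / target_gap < tol_rel)
      return(list(ctx = ctx, state = fem_state(ctx), traction = tmag,
                  trace = trace))
    slope <- (g - g_prev) / (tmag - t_prev)
    if (!is.finite(slope) || slope <= 0) slope <- rate
    step <- (target_gap - g) / slope
    t_new <- if (g < target_gap) min(tmag + 0.9 * step, 1.5 * tmag)
             else max(tmag + step, 0.5 * tmag)
    t_prev <- tmag; g_prev <- g
    tmag <- t_new
    sol <- solve_stage(ctx, pressure = pressure, traction_mag = tmag,
                       n_increments = 2)
    ctx <- sol$ctx
  }
  stop(sprintf(
    "gap control loop did not converge: last traction %.3g N/m gave %.2f mm (target %.2f mm)",
    t_prev, 1e3 * g_prev, 1e3 * target_gap))
}

# Displacement-controlled slit stretch: the lip nodes within `span` of the
# mid-slit form a rigid retractor jaw that is driven apart along the
# azimuthal axis of the cut, in equilibrium sub-steps with automatic
# halving.  The jaw DOFs stay constrained in the returned context (the
# retractor holds the gap until the patch is sutured); rebuilding the
# boundary conditions, as suturing does, releases them.
open_gap_retractor <- function(ctx, target_gap, tol_rel, max_outer, gap_at,
                               span, trace) {
  pressure <- ctx$pressure
  jaws <- lapply(ctx$mesh$cuts, function(cut) {
    pz <- ctx$mesh$nodes[cut$pairs[, 1], 3]
    mid <- pz[ceiling(length(pz) / 2)]
    if (is.null(span)) {
      pth <- ctx$mesh$nodes[cut$left, 3]
      span_c <- (max(pth) - min(pth)) / 2  # central half of the slit
    } else span_c <- span
    sel <- which(abs(pz - mid) <= span_c / 2)
    midnode <- cut$pairs[ceiling(nrow(cut$pairs) / 2), 1]
    iL <- match(midnode, cut$sides[[1]]$path)
    dL <- cut$sides[[1]]$own_dir[iL, ]
    axis <- which.max(abs(dL[1:2]))  # azimuthal pull axis (x or y)
    list(left = cut$pairs[sel, 1], right = cut$pairs[sel, 2],
         axis = axis, sgnL = sign(dL[axis]))
  })
  jaw_dofs <- unlist(lapply(jaws, function(j)
    (c(j$left, j$right) - 1L) * 6L + j$axis))
  ctx$bc$fixed <- sort(union(ctx$bc$fixed, jaw_dofs))
  ctx$retractor <- list(dofs = jaw_dofs)
  g <- max(slit_gap(ctx, gap_at))
  step_max <- 1.5e-3
  for (it in seq_len(max_outer)) {
    need <- target_gap - g
    if (abs(need) / target_gap < tol_rel) break
    remaining <- need
    while (abs(remaining) > 1e-9) {
      mv <- sign(remaining) * min(abs(remaining), step_max)
      xtry <- ctx$x
      for (j in jaws) {
        xtry[j$left, j$axis] <- xtry[j$left, j$axis] + j$sgnL * mv / 2
        xtry[j$right, j$axis] <- xtry[j$right, j$axis] - j$sgnL * mv / 2
      }
      ctx_try <- ctx; ctx_try$x <- xtry
      res <- fem_newton(ctx_try, pressure, max_iter = 60)
      if (res$converged) {
        ctx <- res$ctx
        remaining <- remaining - mv
      } else {
        step_max <- step_max / 2
        if (step_max < 2e-5)
          stop(sprintf(
            "retractor opening failed to converge at gap %.2f mm (target %.2f mm)",
            1e3 * g, 1e3 * target_gap))
      }
    }
    g <- max(slit_gap(ctx, gap_at))
    trace <- rbind(trace, cbind(traction = NA, gap = g))
  }
  if (abs(g - target_gap) / target_gap >= tol_rel)
    stop(sprintf("retractor control did not reach the target gap (%.2f of %.2f mm)",
                 1e3 * g, 1e3 * target_gap))
  st <- fem_state(ctx)
  # equivalent uniform traction: jaw reaction per unit jaw length
  react <- numeric(length(st$f_ext))
  react[st$fixed_dofs] <- st$reactions
  f_jaw <- sum(abs(react[jaws[[1]]$left * 6L - 6L + jaws[[1]]$axis]))
  len_jaw <- sum(sqrt(rowSums(diff(ctx$x[jaws[[1]]$left, , drop = FALSE])^2)))
  tr_eq <- f_jaw / max(len_jaw, 1e-9)
  trace[nrow(trace), 1] <- tr_eq
  list(ctx = ctx, state = st, traction = tr_eq, trace = trace)
}

#' Generate tangent patch(es) over the opened slit(s)
#'
#' For every cut, builds a cubic (Hermite) surface spanning the opened
#' boundary loop: each cross-curve runs from a left-lip node to its right
#' counterpart, leaving/arriving tangent to the adjacent artery surface, so
#' the patch matches the local curvature of the surrounding native tissue
#' ("tangent patch").  The patch inherits its thickness and material from
#' the library entry.
#'
#' @param ctx the opened `fem_context` from [open_gap()].
#' @param material_name a key of [material_library()].
#' @param edge_length target patch element size (m); defaults to the artery
#'   mesh spacing.
#' @return list of `patch_surface` objects with fields `nodes`, `tri`,
#'   `boundary_map` (patch node -> artery node id, `NA` for interior),
#'   `mid_surface_area` (m^2), `material_name`, `thickness`.
#' @export
generate_tangent_patch <- function(ctx, material_name, edge_length = NULL) {
  mat <- material_lookup(material_name)
  if (is.null(edge_length)) {
    spec <- attr(ctx$mesh, "spec")
    edge_length <- if (!is.null(spec)) spec$mesh_edge_length else 1.5e-3
  }
  lapply(ctx$mesh$cuts, function(cut)
    build_patch(ctx, cut, mat, edge_length))
}

hermite_row <- function(pL, pR, mL, mR, nu) {
  # sampling graded toward the lips (uniform/cosine blend): the first
  # secant then follows the end tangent closely without making the
  # boundary elements needle-thin
  uu <- seq(0, 1, length.out = nu)
  u <- 0.35 * uu + 0.65 * (1 - cos(pi * uu)) / 2
  h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
  cbind(h00 %o% pL + h01 %o% pR + h10 %o% mL + h11 %o% mR)
}

build_patch <- function(ctx, cut, mat, h) {
  nrm_all <- triangle_normals(list(nodes = ctx$x, tri = ctx$mesh$tri))
  edge_dirs <- function(side) {
    p <- ctx$x[side$path, , drop = FALSE]
    k <- nrow(p)
    tang <- rbind(p[2, ] - p[1, ],
                  (p[3:k, , drop = FALSE] - p[1:(k - 2), , drop = FALSE]) / 2,
                  p[k, ] - p[k - 1, ])
    t(vapply(seq_len(k), function(i) {
      nn <- colMeans(nrm_all[side$node_elems[[i]], , drop = FALSE])
      d <- c(nn[2] * tang[i, 3] - nn[3] * tang[i, 2],
             nn[3] * tang[i, 1] - nn[1] * tang[i, 3],
             nn[1] * tang[i, 2] - nn[2] * tang[i, 1])
      d <- d / sqrt(sum(d^2))
      if (sum(d * side$own_dir[i, ]) < 0) d <- -d
      d
    }, numeric(3)))
  }
  dL <- edge_dirs(cut$sides[[1]]); dR <- edge_dirs(cut$sides[[2]])
  pathL <- cut$sides[[1]]$path; pathR <- cut$sides[[2]]$path
  k <- length(pathL)
  rows <- vector("list", k); rowmap <- vector("list", k)
  for (j in seq_len(k)) {
    pL <- ctx$x[pathL[j], ]; pR <- ctx$x[pathR[j], ]
    ch <- sqrt(sum((pR - pL)^2))
    if (ch < h / 4) {  # slit tip (or nearly closed): single shared point
      rows[[j]] <- matrix(pL, 1, 3)
      rowmap[[j]] <- pathL[j]
    } else {
      nu <- max(3L, as.integer(round(1.3 * ch / h)) + 1L)
      # leave the left lip along -pull direction (into the gap), arrive at
      # the right lip along its +pull direction: tangent-plane continuity
      rows[[j]] <- hermite_row(pL, pR, -dL[j, ] * ch, dR[j, ] * ch, nu)
      rowmap[[j]] <- c(pathL[j], rep(NA_integer_, nu - 2L), pathR[j])
    }
  }
  # assemble local nodes; boundary points reuse artery ids via boundary_map
  nodes <- do.call(rbind, rows)
  bmap <- unlist(rowmap)
  offs <- cumsum(c(0, vapply(rows, nrow, integer(1))))
  tri <- NULL
  for (j in seq_len(k - 1)) {
    ia <- offs[j] + seq_len(nrow(rows[[j]]))
    ib <- offs[j + 1] + seq_len(nrow(rows[[j + 1]]))
    tri <- rbind(tri, ladder_triangulate(nodes, ia, ib))
  }
  # smooth the fill: Taubin lambda/mu passes knock down local bulges at
  # the tail rows without shrinking the surface.  The boundary AND its
  # first interior ring stay fixed so the tangent-plane continuity with
  # the artery along the suture line survives the smoothing.
  fixed <- !is.na(bmap)
  bedge <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ring1 <- unique(c(bedge[fixed[bedge[, 1]], 2],
                    bedge[fixed[bedge[, 2]], 1]))
  fixed[ring1] <- TRUE
  nodes <- taubin_smooth(nodes, tri, fixed = fixed,
                         n_pass = 10, lambda = 0.5, mu = -0.53)
  # orient patch normals outward (same sense as the surrounding artery)
  pm <- list(nodes = nodes, tri = tri)
  nr <- triangle_normals(pm)
  cent <- colMeans(nodes)
  axis_out <- cent - c(0, 0, cent[3])  # radially outward from the vessel axis
  flip <- sum(colMeans(nr) * axis_out)
  if (is.finite(flip) && flip < 0) tri <- tri[, c(1, 3, 2)]
  pm$tri <- tri
  structure(list(nodes = nodes, tri = tri, boundary_map = bmap,
                 mid_surface_area = sum(triangle_areas(pm)),
                 material_name = mat$name, thickness = mat$thickness,
                 cut = cut), class = "patch_surface")
}

# Laplacian smoothing with Taubin's shrink-compensating second pass.
taubin_smooth <- function(nodes, tri, fixed, n_pass = 10, lambda = 0.5,
                          mu = -0.53) {
  n <- nrow(nodes)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  adj <- lapply(adj, unique)
  idx <- as.integer(names(adj))
  move <- which(!fixed)
  for (pass in seq_len(n_pass)) {
    for (fac in c(lambda, mu)) {
      mns <- nodes
      for (v in move) {
        nb <- adj[[match(v, idx)]]
        mns[v, ] <- colMeans(nodes[nb, , drop = FALSE])
      }
      nodes[move, ] <- nodes[move, , drop = FALSE] +
        fac * (mns[move, , drop = FALSE] - nodes[move, , drop = FALSE])
    }
  }
  nodes
}

# Triangulate the strip between two polyline rows by greedy shortest
# diagonal; works for unequal row lengths (including single-point tips).
ladder_triangulate <- function(nodes, ia, ib) {
  i <- 1L; j <- 1L
  na <- length(ia); nb <- length(ib)
  tri <- matrix(0L, 0, 3)
  while (i < na || j < nb) {
    adv_a <- FALSE
    if (i < na && j < nb) {
      dA <- sum((nodes[ia[i + 1], ] - nodes[ib[j], ])^2)
      dB <- sum((nodes[ib[j + 1], ] - nodes[ia[i], ])^2)
      adv_a <- dA <= dB
    } else if (i < na) adv_a <- TRUE
    if (adv_a) {
      tri <- rbind(tri, c(ia[i], ia[i + 1], ib[j]))
      i <- i + 1L
    } else {
      tri <- rbind(tri, c(ia[i], ib[j + 1], ib[j]))
      j <- j + 1L
    }
  }
  tri
}

#' Suture a patch onto the artery (mesh-level)
#'
#' Merges the patch boundary nodes with the corresponding slit-edge nodes
#' (a bonded tie: shared degrees of freedom, no relative motion).  The
#' merged nodes are tagged `suture_line`; the combined mesh is manifold
#' with free edges only at the inlet/outlet rings once every cut is
#' patched.
#'
#' @param mesh the opened artery `shell_mesh` *in the same coordinates the
#'   patch was built in* (use [current_mesh()] on the opened context).
#' @param patch a `patch_surface` (or list of them).
#' @return the combined `shell_mesh`.
#' @export
suture <- function(mesh, patch) {
  patches <- if (inherits(patch, "patch_surface")) list(patch) else patch
  for (p in patches) mesh <- suture_one(mesh, p)
  if (length(mesh$cuts) == 0) validate_shell_mesh(mesh)
  mesh
}

suture_one <- function(mesh, patch) {
  interior <- which(is.na(patch$boundary_map))
  n0 <- nrow(mesh$nodes)
  id_map <- patch$boundary_map
  id_map[interior] <- n0 + seq_along(interior)
  if (any(id_map[!is.na(patch$boundary_map)] > n0))
    stop("patch boundary references nodes outside the artery mesh")
  mesh$nodes <- rbind(mesh$nodes, patch$nodes[interior, , drop = FALSE])
  tri_new <- matrix(id_map[patch$tri], ncol = 3)
  mesh$tri <- rbind(mesh$tri, tri_new)
  mesh$region <- c(mesh$region, rep("patch", nrow(tri_new)))
  mesh$thickness <- c(mesh$thickness, rep(patch$thickness, nrow(tri_new)))
  sl <- unique(c(patch$cut$left, patch$cut$right))
  mesh$tags$suture_line <- unique(c(mesh$tags$suture_line, sl))
  mesh$tags$cut_edge_left <- setdiff(mesh$tags$cut_edge_left, patch$cut$left)
  mesh$tags$cut_edge_right <- setdiff(mesh$tags$cut_edge_right,
                                      patch$cut$right)
  keep <- !vapply(mesh$cuts, function(ct)
    identical(ct$left, patch$cut$left), logical(1))
  mesh$cuts <- mesh$cuts[keep]
  mesh
}

#' Snapshot of the deformed mesh
#'
#' Returns the context's mesh with nodes replaced by the current (deformed)
#' coordinates, e.g. for export or for mesh-level suturing.
#'
#' @param ctx a `fem_context`.
#' @return a `shell_mesh`.
#' @export
current_mesh <- function(ctx) {
  m <- ctx$mesh
  m$nodes <- ctx$x
  m
}

#' Suture patches into a finite-element context
#'
#' Extends the opened context with the patch elements: patch boundary DOFs
#' are the artery slit-edge DOFs (bonded), the patch reference (stress-free)
#' configuration is its as-built shape, and the patch is born stress-free at
#' the moment of suturing.
#'
#' @param ctx the opened `fem_context`.
#' @param patches list of `patch_surface` from [generate_tangent_patch()].
#' @param patch_material a `material_model` for the patch elements.
#' @return the combined `fem_context` (cut traction machinery retained so
#'   the hold can be released during post-op pressurization).
#' @export
suture_context <- function(ctx, patches, patch_material) {
  validate_material(patch_material)
  for (patch in patches) {
    interior <- which(is.na(patch$boundary_map))
    n0 <- nrow(ctx$x)
    id_map <- patch$boundary_map
    id_map[interior] <- n0 + seq_along(interior)
    tri_new <- matrix(id_map[patch$tri], ncol = 3)
    mp <- nrow(tri_new)
    # current + reference state of new nodes = as-built patch
    ctx$x <- rbind(ctx$x, patch$nodes[interior, , drop = FALSE])
    ctx$x0_nodes <- rbind(if (is.null(ctx$x0_nodes)) ctx$mesh$nodes
                          else ctx$x0_nodes,
                          patch$nodes[interior, , drop = FALSE])
    eye <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = length(interior)),
                  nrow = length(interior))
    ctx$Rt <- rbind(ctx$Rt, eye)
    # element reference geometry: as-built patch triangle coords
    ref_new <- cbind(patch$nodes[patch$tri[, 1], , drop = FALSE],
                     patch$nodes[patch$tri[, 2], , drop = FALSE],
                     patch$nodes[patch$tri[, 3], , drop = FALSE])
    # reference nodal triads: the nodal rotation at suturing time
    R0_new <- matrix(0, mp, 27)
    for (a in 1:3) {
      ids <- id_map[patch$tri[, a]]
      R0_new[, (a - 1) * 9 + 1:9] <- ctx$Rt[ids, , drop = FALSE]
    }
    ctx$elem_ref <- rbind(ctx$elem_ref, ref_new)
    ctx$elem_R0 <- rbind(ctx$elem_R0, R0_new)
    ctx$E <- c(ctx$E, rep(patch_material$youngs_modulus, mp))
    ctx$nu <- c(ctx$nu, rep(patch_material$poissons_ratio, mp))
    ctx$th <- c(ctx$th, rep(patch$thickness, mp))
    ctx$sig0 <- rbind(ctx$sig0, matrix(0, mp, 3))  # patch born stress-free
    # mesh bookkeeping (reference-coordinate mesh gains the as-built nodes)
    ctx$mesh$nodes <- rbind(ctx$mesh$nodes,
                            patch$nodes[interior, , drop = FALSE])
    ctx$mesh$tri <- rbind(ctx$mesh$tri, tri_new)
    ctx$mesh$region <- c(ctx$mesh$region, rep("patch", mp))
    ctx$mesh$thickness <- c(ctx$mesh$thickness, rep(patch$thickness, mp))
    sl <- unique(c(patch$cut$left, patch$cut$right))
    ctx$mesh$tags$suture_line <- unique(c(ctx$mesh$tags$suture_line, sl))
    ctx$mesh$tags$cut_edge_left <- setdiff(ctx$mesh$tags$cut_edge_left,
                                           patch$cut$left)
    ctx$mesh$tags$cut_edge_right <- setdiff(ctx$mesh$tags$cut_edge_right,
                                            patch$cut$right)
  }
  ctx$bc <- apply_boundary_conditions(ctx$mesh)
  ctx
}
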