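#' Boundary conditions for the virtual-surgery stages
#'
#' The outlet ring (closest to the outflow tract) is fully fixed in all six
#' degrees of freedom; the inlet ring keeps radial and circumferential
#' translation fixed but is free to move axially and to rotate.  Fully
#' fixing both ends is known to produce unrealistic patch deformation, so
#' the axial-sliding inlet replicates the intra-operative state.
#'
#' @param mesh a tagged `shell_mesh` (needs `inlet_ring`, `outlet_ring`).
#' @return list with `fixed` (sorted global DOF indices, 6 per node ordered
#'   ux, uy, uz, rx, ry, rz) and per-ring breakdown.
#' @export
apply_boundary_conditions <- function(mesh) {
  tg <- mesh$tags
  if (is.null(tg$inlet_ring) || is.null(tg$outlet_ring))
    stop("mesh is missing inlet_ring/outlet_ring tags")
  dof <- function(nodes, comps)
    as.vector(outer(comps, (nodes - 1L) * 6L, `+`))
  outlet <- dof(tg$outlet_ring, 1:6)
  inlet <- dof(tg$inlet_ring, 1:2)  # x,y translation = radial + circumferential
  list(fixed = sort(unique(c(outlet, inlet))),
       outlet_dofs = outlet, inlet_dofs = inlet)
}

#' Build a finite-element context from a shell mesh
#'
#' Packs per-element reference geometry, reference nodal triads, material
#' constants and boundary conditions for the corotational shell solver.
#' Each element stores its own stress-free reference triangle, so meshes
#' assembled from parts born at different stages (native artery vs
#' freshly sutured patch) are handled uniformly.
#'
#' @param mesh a tagged `shell_mesh`.
#' @param artery_material,patch_material `material_model`s supplying E and
#'   nu per region (element thickness always comes from `mesh$thickness`).
#' @param end_cap if `TRUE`, the axially sliding inlet ring carries the
#'   capped-end axial tension `p * pi * r_lumen^2` of a pressurized vessel
#'   segment (the tether to the rest of the vasculature).  An open free
#'   end has zero axial tension and can collapse axially under pressure;
#'   the surgery pipeline enables this, the textbook open-tube membrane
#'   solutions keep it off.
#' @return a `fem_context`.
#' @export
fem_context <- function(mesh,
                        artery_material = material_lookup("MPA artery 9yr"),
                        patch_material = NULL, end_cap = FALSE) {
  validate_material(artery_material)
  m <- nrow(mesh$tri)
  E <- numeric(m); nu <- numeric(m)
  is_patch <- mesh$region == "patch"
  E[!is_patch] <- artery_material$youngs_modulus
  nu[!is_patch] <- artery_material$poissons_ratio
  if (any(is_patch)) {
    if (is.null(patch_material))
      stop("mesh has patch elements but no patch_material given")
    validate_material(patch_material)
    E[is_patch] <- patch_material$youngs_modulus
    nu[is_patch] <- patch_material$poissons_ratio
  }
  elem_ref <- cbind(mesh$nodes[mesh$tri[, 1], , drop = FALSE],
                    mesh$nodes[mesh$tri[, 2], , drop = FALSE],
                    mesh$nodes[mesh$tri[, 3], , drop = FALSE])
  Rt <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(mesh$nodes)),
               nrow = nrow(mesh$nodes))
  elem_R0 <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = m), nrow = m)
  elem_R0 <- cbind(elem_R0, elem_R0, elem_R0)
  structure(list(
    mesh = mesh, elem_ref = elem_ref, elem_R0 = elem_R0,
    x = mesh$nodes, Rt = Rt,
    E = E, nu = nu, th = mesh$thickness,
    sig0 = matrix(0, m, 3),
    bc = apply_boundary_conditions(mesh),
    end_cap = end_cap,
    cap_thickness = artery_material$thickness,
    traction = NULL, pressure = 0), class = "fem_context")
}

# Distributed follower traction on the cut edges: per-node in-plane
# direction normal to the cut path, pointing away from the opposite lip
# (i.e. into the node's own side), recomputed from the current geometry.
# Returns the nodal force vector for unit traction magnitude; only
# slit-adjacent elements are touched.
traction_unit_forces <- function(ctx, x = ctx$x) {
  n <- nrow(x)
  f <- numeric(6 * n)
  tr <- ctx$traction
  if (is.null(tr)) return(f)
  for (side in tr$sides) {
    path <- side$path
    p <- x[path, , drop = FALSE]
    k <- length(path)
    nrm <- triangle_normals(list(
      nodes = x, tri = ctx$mesh$tri[side$els_unique, , drop = FALSE]))
    tang <- rbind(p[2, ] - p[1, ],
                  (p[3:k, , drop = FALSE] - p[1:(k - 2), , drop = FALSE]) / 2,
                  p[k, ] - p[k - 1, ])
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-k, , drop = FALSE])^2))
    wlen <- c(seg / 2, 0) + c(0, seg / 2)  # tributary length per node
    wlen[c(1, k)] <- 0  # slit tips are shared between the lips: no pull
    for (i in seq_len(k)) {
      nn <- colMeans(nrm[side$node_elem_rows[[i]], , drop = FALSE])
      d <- c(nn[2] * tang[i, 3] - nn[3] * tang[i, 2],
             nn[3] * tang[i, 1] - nn[1] * tang[i, 3],
             nn[1] * tang[i, 2] - nn[2] * tang[i, 1])
      d <- d / sqrt(sum(d^2))
      # orient away from the opposite lip; at (near-)zero gap fall back to
      # the cut-time "toward own material" direction
      s <- p[i, ] - x[side$partner[i], ]
      ref <- if (sum(s^2) > 1e-10) s else side$own_dir[i, ]
      if (sum(d * ref) < 0) d <- -d
      j <- (path[i] - 1L) * 6L
      f[j + 1:3] <- f[j + 1:3] + wlen[i] * d
    }
  }
  f
}

# Sparse finite-difference Jacobian of the unit traction force with respect
# to the nodal coordinates (support = slit nodes + their one-ring).
traction_jacobian <- function(ctx, eps = 1e-9) {
  tr <- ctx$traction
  if (is.null(tr)) return(NULL)
  n <- nrow(ctx$x)
  support <- sort(unique(unlist(lapply(tr$sides, `[[`, "support_nodes"))))
  rowidx <- sort(unique(unlist(lapply(tr$sides, function(s)
    rep((s$path - 1L) * 6L, each = 3) + 1:3))))
  f0 <- traction_unit_forces(ctx)[rowidx]
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  x <- ctx$x
  for (v in support) for (k in 1:3) {
    x[v, k] <- x[v, k] + eps
    dv <- (traction_unit_forces(ctx, x)[rowidx] - f0) / eps
    x[v, k] <- x[v, k] - eps
    nz <- which(dv != 0)
    if (length(nz)) {
      ti <- c(ti, rowidx[nz])
      tj <- c(tj, rep((v - 1L) * 6L + k, length(nz)))
      tv <- c(tv, dv[nz])
    }
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(6 * n, 6 * n))
}

# Capped-end axial tension on the sliding inlet ring: the pressure load a
# vessel segment transmits through its tether, p * pi * r_lumen^2 pulling
# the free ring axially outward.  Follower in pressure and ring radius.
cap_forces <- function(ctx, pressure, x = ctx$x) {
  n <- nrow(x)
  f <- numeric(6 * n)
  if (!isTRUE(ctx$end_cap) || pressure == 0) return(f)
  ring <- ctx$mesh$tags$inlet_ring
  if (!length(ring)) return(f)
  r_lumen <- mean(sqrt(rowSums(x[ring, 1:2, drop = FALSE]^2))) -
    ctx$cap_thickness / 2
  Ftot <- -pressure * pi * r_lumen^2  # inlet at min z: outward is -z
  f[(ring - 1L) * 6L + 3L] <- Ftot / length(ring)
  f
}

fem_assemble <- function(ctx, pressure, with_stress = FALSE,
                         with_tangent = TRUE) {
  cpp_shell_assemble(ctx$elem_ref, ctx$elem_R0,
                     ctx$mesh$tri - 1L, ctx$x, ctx$Rt,
                     ctx$E, ctx$nu, ctx$th, pressure, ctx$sig0, with_stress,
                     with_tangent)
}

# Newton iteration at fixed load level, with a trust-region cap on the
# translation increment and a backtracking line search on the residual
# norm (the structure can pass close to limit points while the slit
# opens).  Returns updated context plus convergence info; ctx is
# unchanged on failure.
fem_newton <- function(ctx, pressure, traction_mag = 0, tol = 1e-6,
                       max_iter = 50, dmax = 5e-3, spring_beta = 0,
                       anchor = NULL) {
  n <- nrow(ctx$x)
  free <- setdiff(seq_len(6 * n), ctx$bc$fixed)
  x <- ctx$x; Rt <- ctx$Rt
  work <- ctx
  ref_load <- NA_real_
  tidx <- rep(0:(n - 1) * 6, each = 3) + 1:3
  ridx <- rep(0:(n - 1) * 6, each = 3) + 4:6
  kspring <- NULL  # grounded stabilization springs (snap-through traversal)
  # the edge traction follows the deformed lips, but its direction field is
  # frozen during each Newton pass (dead load => consistent tangent) and
  # refreshed between passes until self-consistent
  alpha <- 0  # adaptive Levenberg-Marquardt damping for wrinkling modes
  for (it in seq_len(max_iter)) {
    work$x <- x; work$Rt <- Rt
    f_unit <- if (traction_mag != 0) traction_unit_forces(work) else
      numeric(6 * n)
    asm <- fem_assemble(work, pressure)
    f_trac <- traction_mag * f_unit
    f_ext <- asm$f_pres + f_trac + cap_forces(work, pressure)
    r <- f_ext - asm$f_int
    if (spring_beta > 0) {
      if (is.null(kspring)) {
        K0 <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                                   dims = c(6 * n, 6 * n))
        kspring <- spring_beta * pmax(abs(Matrix::diag(K0)), 1e-30)
      }
      xvec <- numeric(6 * n); avec <- numeric(6 * n)
      xvec[tidx] <- as.vector(t(x)); avec[tidx] <- as.vector(t(anchor))
      r <- r - kspring * (xvec - avec)
    }
    load_norm <- sqrt(sum(f_ext[free]^2))
    # at zero external load (residual-stress release) scale by the initial
    # out-of-balance force instead
    if (it == 1) ref_load <- max(load_norm, sqrt(sum(r[free]^2)), 1e-12)
    res <- sqrt(sum(r[free]^2)) / ref_load
    if (res < tol) {
      ctx$x <- x; ctx$Rt <- Rt; ctx$pressure <- pressure
      return(list(ctx = ctx, converged = TRUE, iterations = it,
                  residual = res))
    }
    K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                              dims = c(6 * n, 6 * n))
    if (traction_mag != 0)
      K <- K - traction_mag * traction_jacobian(work)
    if (!is.null(kspring)) K <- K + Matrix::Diagonal(x = kspring)
    Kff <- K[free, free]
    if (alpha > 0)
      Kff <- Kff + alpha * Matrix::Diagonal(x = pmax(abs(Matrix::diag(Kff)),
                                                     1e-30))
    d <- numeric(6 * n)
    sol <- tryCatch(Matrix::solve(Kff, r[free]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      alpha <- if (alpha == 0) 1e-4 else 10 * alpha
      if (alpha > 1e2) break
      next
    }
    d[free] <- as.numeric(sol)
    du <- matrix(d[tidx], ncol = 3, byrow = TRUE)
    dr <- matrix(d[ridx], ncol = 3, byrow = TRUE)
    cap <- min(1, dmax / max(sqrt(rowSums(du^2)), 1e-30),
               0.3 / max(sqrt(rowSums(dr^2)), 1e-30))
    resfun <- function(step) {
      work$x <<- x + step * du
      work$Rt <<- cpp_rotate_update(Rt, step * dr)
      asm2 <- fem_assemble(work, pressure, with_tangent = FALSE)
      f2 <- asm2$f_pres + traction_mag * f_unit +
        cap_forces(work, pressure)
      r2 <- f2 - asm2$f_int
      if (!is.null(kspring)) {
        xv <- numeric(6 * n); av <- numeric(6 * n)
        xv[tidx] <- as.vector(t(work$x)); av[tidx] <- as.vector(t(anchor))
        r2 <- r2 - kspring * (xv - av)
      }
      sqrt(sum(r2[free]^2)) / ref_load
    }
    # nonmonotone acceptance: Newton legitimately overshoots the residual
    # on its way into the quadratic basin, so only a large increase
    # triggers backtracking
    step <- cap
    best <- c(step, Inf)
    for (ls in 1:6) {
      res2 <- resfun(step)
      if (res2 < best[2]) best <- c(step, res2)
      if (res2 < 10 * res) break
      step <- step / 2
    }
    step <- best[1]
    # damping control: raise it when the step made no progress at all
    # (indefinite tangent near wrinkling), relax it otherwise
    alpha <- if (best[2] >= res) max(10 * alpha, 1e-4) else alpha / 5
    if (alpha < 1e-8) alpha <- 0
    x <- x + step * du
    Rt <- cpp_rotate_update(Rt, step * dr)
  }
  list(ctx = ctx, converged = FALSE, iterations = max_iter, residual = NA)
}

# Incremental loading with automatic increment halving (floor 1/64 of the
# initial step).  Ramps pressure and traction magnitude together.
fem_ramp <- function(ctx, p_from, p_to, t_from = 0, t_to = 0,
                     n_increments = 10, tol = 1e-6, max_iter = 80) {
  lam <- 0; dlam <- 1 / n_increments
  hist <- list()
  while (lam < 1 - 1e-12) {
    dl <- min(dlam, 1 - lam)
    p <- p_from + (lam + dl) * (p_to - p_from)
    tm <- t_from + (lam + dl) * (t_to - t_from)
    res <- fem_newton(ctx, p, tm, tol = tol, max_iter = max_iter)
    if (res$converged) {
      ctx <- res$ctx
      lam <- lam + dl
      hist[[length(hist) + 1]] <- c(lambda = lam, iterations = res$iterations,
                                    residual = res$residual)
    } else {
      dlam <- dlam / 2
      if (dlam < 1 / (8 * n_increments)) {
        # limit point in the load path (e.g. the stenosed arch snapping
        # through): pseudo-transient continuation with grounded springs,
        # re-anchored after every equilibrium, until the motion stops;
        # the final solve is spring-free
        p_full <- p_from + min(lam + 1 / n_increments, 1) * (p_to - p_from)
        t_full <- t_from + min(lam + 1 / n_increments, 1) * (t_to - t_from)
        stab <- ctx
        beta <- 1e-2
        ok <- FALSE
        for (pass in seq_len(40)) {
          res <- fem_newton(stab, p_full, t_full, tol = 100 * tol,
                            max_iter = max_iter,
                            spring_beta = beta, anchor = stab$x)
          if (!res$converged) {
            beta <- beta * 10
            if (beta > 1) break
            next
          }
          moved <- max(abs(res$ctx$x - stab$x))
          stab <- res$ctx
          if (moved < 1e-7) { ok <- TRUE; break }
        }
        if (ok) {
          res <- fem_newton(stab, p_full, t_full, tol = tol,
                            max_iter = max_iter)
          ok <- res$converged
        }
        if (!ok)
          stop(sprintf(
            "shell solver failed to converge (stalled at load fraction %.3f)",
            lam))
        ctx <- res$ctx
        lam <- min(lam + 1 / n_increments, 1)
        hist[[length(hist) + 1]] <- c(lambda = lam,
                                      iterations = res$iterations,
                                      residual = res$residual)
        dlam <- 1 / n_increments
      }
    }
  }
  list(ctx = ctx, history = do.call(rbind, hist))
}

#' Solve one quasi-static load stage
#'
#' Executes one stage of the virtual-surgery sequence by incremental
#' follower loading with Newton iterations (direct sparse solves, relative
#' residual tolerance `1e-6`, automatic increment halving to 1/64 of the
#' initial step).  Pressure acts along the deformed outward mid-surface
#' normal; cut-edge traction acts along the deformed in-plane normal of the
#' cut path.
#'
#' @param ctx a [fem_context()] (carries the state left by prior stages).
#' @param pressure target intramural pressure (Pa).
#' @param traction_mag target cut-edge traction magnitude (N/m), if the
#'   context has cut edges registered.
#' @param n_increments load increments for the ramp.
#' @param tol relative residual tolerance.
#' @return list with the updated `ctx` and a `fem_state` (see
#'   [fem_state()]).
#' @export
solve_stage <- function(ctx, pressure, traction_mag = 0, n_increments = 5,
                        tol = 1e-6) {
  out <- fem_ramp(ctx, ctx$pressure, pressure,
                  if (is.null(ctx$traction_mag)) 0 else ctx$traction_mag,
                  traction_mag, n_increments = n_increments, tol = tol)
  ctx <- out$ctx
  ctx$traction_mag <- traction_mag
  list(ctx = ctx, state = fem_state(ctx, history = out$history))
}

#' Converged finite-element state
#'
#' Evaluates displacements, element stress resultants, the mid-surface
#' von Mises field and reaction forces for the current configuration of a
#' context.
#'
#' @param ctx a `fem_context` at equilibrium.
#' @param history optional increment history from the ramp.
#' @return a `fem_state`: `displacements` (n x 3, m), `rotations`
#'   (nodal triads), `element_stress` (membrane stress and bending moment
#'   resultants), `element_von_mises` (Pa, mid-surface),
#'   `element_von_mises_surface` (Pa, worst fiber), `reactions`
#'   (per-fixed-DOF force), `f_ext` (assembled load), `converged`.
#' @export
fem_state <- function(ctx, history = NULL) {
  asm <- fem_assemble(ctx, ctx$pressure, with_stress = TRUE)
  tmag <- if (is.null(ctx$traction_mag)) 0 else ctx$traction_mag
  f_trac <- if (tmag != 0) tmag * traction_unit_forces(ctx) else
    numeric(length(asm$f_int))
  f_ext <- asm$f_pres + f_trac + cap_forces(ctx, ctx$pressure)
  s <- asm$stress
  th <- ctx$th
  vm_mid <- von_mises_plane(s[, 1], s[, 2], s[, 3])
  bend <- 6 / th^2  # surface stress from bending moment resultant
  vm_top <- von_mises_plane(s[, 1] + bend * s[, 4], s[, 2] + bend * s[, 5],
                            s[, 3] + bend * s[, 6])
  vm_bot <- von_mises_plane(s[, 1] - bend * s[, 4], s[, 2] - bend * s[, 5],
                            s[, 3] - bend * s[, 6])
  u0 <- if (!is.null(ctx$x0_nodes)) ctx$x0_nodes else ctx$mesh$nodes
  structure(list(
    displacements = ctx$x - u0,
    rotations = ctx$Rt,
    element_stress = s,
    element_von_mises = vm_mid,
    element_von_mises_surface = pmax(vm_top, vm_bot),
    reactions = (asm$f_int - f_ext)[ctx$bc$fixed],
    fixed_dofs = ctx$bc$fixed,
    f_ext = f_ext,
    pressure = ctx$pressure,
    converged = TRUE,
    increment_history = history), class = "fem_state")
}

#' Plane-stress von Mises stress
#'
#' `sqrt(sx^2 - sx*sy + sy^2 + 3*txy^2)`.
#'
#' @param sx,sy,txy plane-stress components (Pa).
#' @return equivalent stress (Pa).
#' @export
von_mises_plane <- function(sx, sy, txy) sqrt(sx^2 - sx * sy + sy^2 + 3 * txy^2)

#' @rdname von_mises_plane
#' @param state a `fem_state`.
#' @export
von_mises_field <- function(state) state$element_von_mises

#' Pressure-equivalent residual stress
#'
#' Arterial residual stress is represented by the membrane stress state of
#' the unloaded configuration inflated with a small intramural pressure
#' (default 5 mmHg).  `residual_prestress` solves that inflation and also
#' returns the per-element membrane stress field `sig0`; embedding it with
#' [apply_residual_stress()] makes the body carry residual stress at zero
#' external load (the cardiopulmonary-bypass state), so a slit mesh
#' re-solved at zero pressure opens slightly — the residual-stress release
#' of the incision.
#'
#' @param ctx a `fem_context` in its unloaded configuration.
#' @param p_res residual-stress-equivalent pressure (Pa; default 5 mmHg).
#' @param n_increments ramp increments.
#' @return list with the inflated `ctx`, the converged `fem_state`, and
#'   `sig0` (per-element membrane stress, element-local frame, Pa).
#' @export
residual_prestress <- function(ctx, p_res = mmHg_to_pa(5), n_increments = 2) {
  out <- solve_stage(ctx, pressure = p_res, n_increments = n_increments)
  out$sig0 <- out$state$element_stress[, 1:3, drop = FALSE]
  out
}

#' @rdname residual_prestress
#' @param sig0 per-element membrane prestress, as returned by
#'   `residual_prestress` on a mesh with identical element ordering (the
#'   slit mesh preserves it).
#' @export
apply_residual_stress <- function(ctx, sig0) {
  if (nrow(sig0) != nrow(ctx$sig0))
    stop("sig0 has ", nrow(sig0), " rows; context has ", nrow(ctx$sig0),
         " elements")
  ctx$sig0 <- sig0
  ctx
}

#' @rdname residual_prestress
#' @param n_increments increments over which the stored stress is scaled in.
#' @details `release_residual_stress` embeds the prestress gradually
#'   (scaling `sig0` from 0 to 1 with equilibrium solves) so the slit lips
#'   separate smoothly from the coincident zero-gap state.
#' @export
release_residual_stress <- function(ctx, sig0, n_increments = 5) {
  if (nrow(sig0) != nrow(ctx$sig0))
    stop("sig0 has ", nrow(sig0), " rows; context has ", nrow(ctx$sig0),
         " elements")
  lam <- 0; dlam <- 1 / n_increments
  while (lam < 1 - 1e-12) {
    dl <- min(dlam, 1 - lam)
    ctx$sig0 <- (lam + dl) * sig0
    res <- fem_newton(ctx, ctx$pressure, max_iter = 80)
    if (res$converged) {
      res$ctx$sig0 <- ctx$sig0
      ctx <- res$ctx
      lam <- lam + dl
    } else {
      dlam <- dlam / 2
      if (dlam < 1 / (64 * n_increments))
        stop("residual-stress release failed to converge")
    }
  }
  list(ctx = ctx, state = fem_state(ctx))
}

#' Check equilibrium load balance of a state
#'
#' Sums applied loads and reactions per global direction; at equilibrium
#' they cancel.
#'
#' @param state a `fem_state`.
#' @return named vector: net residual force per axis over the total applied
#'   load magnitude.
#' @export
load_balance <- function(state) {
  n <- length(state$f_ext) / 6
  comp <- function(v, k) sum(v[(0:(n - 1)) * 6 + k])
  react <- numeric(6 * n)
  react[state$fixed_dofs] <- state$reactions
  tot <- vapply(1:3, function(k) comp(state$f_ext, k) + comp(react, k),
                numeric(1))
  scale <- max(sqrt(sum(vapply(1:3, function(k) comp(abs(state$f_ext), k),
                               numeric(1))^2)), 1e-12)
  setNames(tot / scale, c("x", "y", "z"))
}
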