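# Cross-section slicing.
#
# A slice is identified by the mesh edges it crosses, so the section
# polygon chains robustly: each crossing edge joins exactly the two
# segments contributed by its adjacent triangles.

slice_section <- function(mesh, origin, normal) {
  nv <- normal / sqrt(sum(normal^2))
  d <- as.numeric(mesh$nodes %*% nv) - sum(origin * nv)
  d[d == 0] <- 1e-13
  npos <- (d[mesh$tri[, 1]] > 0) + (d[mesh$tri[, 2]] > 0) +
    (d[mesh$tri[, 3]] > 0)
  crossing <- which(npos >= 1 & npos <= 2)
  if (!length(crossing)) return(NULL)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  nseg <- length(crossing)
  key1 <- character(nseg); key2 <- character(nseg)
  pt_of <- new.env()
  for (ii in seq_len(nseg)) {
    v <- mesh$tri[crossing[ii], ]
    keys <- character(0)
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- v[pair[1]]; b <- v[pair[2]]
      if (sign(d[a]) != sign(d[b])) {
        t <- d[a] / (d[a] - d[b])
        k <- edge_key(a, b)
        assign(k, mesh$nodes[a, ] + t * (mesh$nodes[b, ] - mesh$nodes[a, ]),
               pt_of)
        keys <- c(keys, k)
      }
    }
    key1[ii] <- keys[1]; key2[ii] <- keys[2]
  }
  # chain segments (= sliced triangles) into loops via shared crossing edges
  adj <- split(rep(seq_len(nseg), 2), c(key1, key2))
  used <- logical(nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    members <- integer(0)
    loop_keys <- character(0)
    cur <- start; enter <- key1[start]
    repeat {
      used[cur] <- TRUE
      members <- c(members, cur)
      exit <- if (key1[cur] == enter) key2[cur] else key1[cur]
      loop_keys <- c(loop_keys, exit)
      nxt <- adj[[exit]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      cur <- nxt[1]; enter <- exit
    }
    pts <- do.call(rbind, lapply(loop_keys, function(k) get(k, pt_of)))
    loops[[length(loops) + 1]] <- list(points = pts,
                                       elems = crossing[members])
  }
  # open chains (slices grazing a boundary ring) are not lumen contours
  loops <- Filter(function(lp) nrow(lp$points) > 3, loops)
  if (!length(loops)) return(NULL)
  attr(loops, "normal") <- nv
  loops
}

polygon_area_3d <- function(pts, nv) {
  # project onto the plane basis, shoelace
  e1 <- pts[2, ] - pts[1, ]
  e1 <- e1 - sum(e1 * nv) * nv; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
          nv[3] * e1[1] - nv[1] * e1[3],
          nv[1] * e1[2] - nv[2] * e1[1])
  u <- as.numeric((pts - rep(pts[1, ], each = nrow(pts))) %*% e1)
  v <- as.numeric((pts - rep(pts[1, ], each = nrow(pts))) %*% e2)
  n <- length(u)
  abs(sum(u * v[c(2:n, 1)] - u[c(2:n, 1)] * v)) / 2
}

polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  sum(sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2)))
}

polygon_centroid_3d <- function(pts) colMeans(pts)

#' Extract the lumen centerline and area profile of a tube mesh
#'
#' Iteratively slices the (possibly deformed) tube with planes normal to
#' the running axis estimate, takes section-contour centroids, refits a
#' smoothing spline through them and re-slices, until the centroids move
#' less than 1% of the vessel radius.  Lumen areas are recovered from the
#' mid-surface contour by an inward half-thickness offset
#' (`A - P*t/2 + pi*t^2/4` with the mean local wall thickness).
#'
#' The local stenosis reference is the largest cross-section of the
#' *native* (non-patched) vessel: sections whose contour crosses patch
#' elements can exceed it, giving negative local stenosis (dilation) at a
#' bulging patch.  On an unpatched mesh this reference coincides with the
#' profile maximum.
#'
#' @param mesh a manifold tube `shell_mesh` (deformed coordinates), open
#'   only at the inlet/outlet rings.
#' @param n_samples number of axial stations.
#' @param margin fraction of the axial span excluded at each end.
#' @param max_iter maximum centerline refinement iterations.
#' @return a `centerline_profile`: `arclength` (m), `points` (n x 3
#'   centroids), `areas` (lumen, m^2), `has_patch` (per sample),
#'   `reference_area` (m^2), `local_stenosis_pct`
#'   (`100*(1 - area/reference_area)`), `throat_index`.
#' @export
extract_centerline <- function(mesh, n_samples = 41, margin = 0.03,
                               max_iter = 5) {
  zr <- range(mesh$nodes[, 3])
  zspan <- diff(zr)
  z <- seq(zr[1] + margin * zspan, zr[2] - margin * zspan,
           length.out = n_samples)
  r0 <- sqrt(max(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2))
  cent <- cbind(0, 0, z)
  tang <- matrix(rep(c(0, 0, 1), each = n_samples), ncol = 3)
  areas <- numeric(n_samples)
  has_patch <- logical(n_samples)
  for (iter in seq_len(max_iter)) {
    newc <- cent
    for (i in seq_len(n_samples)) {
      loops <- slice_section(mesh, cent[i, ], tang[i, ])
      if (is.null(loops) || !length(loops))
        stop(sprintf("no section contour at z = %.1f mm", 1e3 * z[i]))
      if (length(loops) > 1)
        stop(sprintf("pinched lumen: %d contours at z = %.1f mm",
                     length(loops), 1e3 * z[i]))
      lp <- loops[[1]]
      nv <- attr(loops, "normal")
      a_mid <- polygon_area_3d(lp$points, nv)
      per <- polygon_perimeter(lp$points)
      tbar <- mean(mesh$thickness[lp$elems])
      areas[i] <- a_mid - per * tbar / 2 + pi * tbar^2 / 4
      has_patch[i] <- any(mesh$region[lp$elems] == "patch")
      newc[i, ] <- polygon_centroid_3d(lp$points)
    }
    move <- max(sqrt(rowSums((newc - cent)^2)))
    cent <- newc
    if (n_samples >= 8) {
      sx <- stats::smooth.spline(cent[, 3], cent[, 1], df = min(8, n_samples - 2))
      sy <- stats::smooth.spline(cent[, 3], cent[, 2], df = min(8, n_samples - 2))
      dx <- stats::predict(sx, cent[, 3], deriv = 1)$y
      dy <- stats::predict(sy, cent[, 3], deriv = 1)$y
      tang <- cbind(dx, dy, 1)
      tang <- tang / sqrt(rowSums(tang^2))
    }
    if (iter > 1 && move < 0.01 * r0) break
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(cent)^2))))
  ref <- if (any(!has_patch)) max(areas[!has_patch]) else max(areas)
  pct <- 100 * (1 - areas / ref)
  structure(list(arclength = s, points = cent, areas = areas,
                 has_patch = has_patch, reference_area = ref,
                 local_stenosis_pct = pct,
                 throat_index = which.max(pct), z = z),
            class = "centerline_profile")
}

#' @export
print.centerline_profile <- function(x, ...) {
  cat(sprintf(
    "centerline_profile: %d samples, throat %.1f%% local stenosis at s = %.1f mm\n",
    length(x$arclength), max(x$local_stenosis_pct),
    1e3 * x$arclength[x$throat_index]))
  invisible(x)
}

#' Residual percent stenosis at the throat
#'
#' Local stenosis (area relative to the largest native cross-section of
#' the model) at the throat, the sample of maximum local stenosis.
#'
#' @param profile a `centerline_profile`.
#' @return percent stenosis at the throat.
#' @export
residual_stenosis <- function(profile) {
  profile$local_stenosis_pct[profile$throat_index]
}

#' Centerline offset (tortuosity) at the throat
#'
#' Distance between the post-operative centerline and the initial vessel
#' pathway at the throat location.
#'
#' @param profile a `centerline_profile` of the post-operative vessel.
#' @param reference either `NULL` (the generator's straight axis x = y = 0)
#'   or a pre-operative `centerline_profile` sampled over the same span.
#' @return offset distance (m).
#' @export
centerline_offset <- function(profile, reference = NULL) {
  p <- unname(profile$points[profile$throat_index, ])
  if (is.null(reference)) return(sqrt(p[1]^2 + p[2]^2))
  rx <- stats::approx(reference$points[, 3], reference$points[, 1], p[3],
                      rule = 2)$y
  ry <- stats::approx(reference$points[, 3], reference$points[, 2], p[3],
                      rule = 2)$y
  unname(sqrt((p[1] - rx)^2 + (p[2] - ry)^2))
}

#' Regional stress summary
#'
#' Maximum and area-weighted mean mid-surface von Mises stress over the
#' elements of one region.
#'
#' @param state a `fem_state`.
#' @param mesh the matching `shell_mesh`.
#' @param region `"artery"` or `"patch"`.
#' @return named vector `c(max, mean)` (Pa).
#' @export
stress_summary <- function(state, mesh, region = c("artery", "patch")) {
  region <- match.arg(region)
  sel <- mesh$region == region
  if (!any(sel)) stop("no elements in region '", region, "'")
  vm <- state$element_von_mises[sel]
  w <- triangle_areas(mesh)[sel]
  c(max = max(vm), mean = sum(vm * w) / sum(w))
}

#' Suture-line stress mismatch
#'
#' For each suture node, the absolute difference between the maximum
#' von Mises stress of its adjacent patch elements and of its adjacent
#' artery elements; returns the maximum over the suture line.  Material
#' mismatch across the bonded connection drives this jump.
#'
#' @param state a `fem_state`.
#' @param mesh the sutured `shell_mesh`.
#' @return stress jump (Pa).
#' @export
suture_stress_jump <- function(state, mesh) {
  sl <- mesh$tags$suture_line
  if (!length(sl)) stop("mesh has no suture_line tag")
  vm <- state$element_von_mises
  jump <- vapply(sl, function(v) {
    els <- which(mesh$tri[, 1] == v | mesh$tri[, 2] == v | mesh$tri[, 3] == v)
    pa <- vm[els[mesh$region[els] == "patch"]]
    ar <- vm[els[mesh$region[els] == "artery"]]
    if (!length(pa) || !length(ar)) return(NA_real_)
    abs(max(pa) - max(ar))
  }, numeric(1))
  max(jump, na.rm = TRUE)
}

#' Tabulate / plot centerline profiles
#'
#' `profile_table` exports the profile as a data frame in report units
#' (mm, mm^2, %); `plot_stenosis_profiles` draws the local-stenosis curves
#' of several cases against arclength, the standard way of comparing
#' pre-operative and post-operative lumen recovery.
#'
#' @param profile a `centerline_profile`.
#' @return a data frame with columns `s_mm`, `area_mm2`, `stenosis_pct`,
#'   `offset_mm`.
#' @export
profile_table <- function(profile) {
  data.frame(s_mm = 1e3 * profile$arclength,
             area_mm2 = 1e6 * profile$areas,
             stenosis_pct = profile$local_stenosis_pct,
             offset_mm = 1e3 * sqrt(profile$points[, 1]^2 +
                                    profile$points[, 2]^2))
}

#' @rdname profile_table
#' @param profiles named list of `centerline_profile`s.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_stenosis_profiles <- function(profiles, ...) {
  s <- lapply(profiles, function(p) 1e3 * p$arclength)
  y <- lapply(profiles, function(p) p$local_stenosis_pct)
  graphics::matplot(do.call(cbind, s), do.call(cbind, y), type = "l",
                    xlab = "centerline arclength (mm)",
                    ylab = "local stenosis (%)", ...)
  graphics::legend("topright", legend = names(profiles),
                   col = seq_along(profiles), lty = seq_along(profiles))
  invisible(NULL)
}
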