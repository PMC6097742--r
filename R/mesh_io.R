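#' Export a shell mesh to STL, PLY or legacy VTK
#'
#' Minimal writers for downstream CAD / 3-D printing / visualization
#' workflows.  `write_vtk` embeds per-element region, thickness and (when
#' supplied) von Mises stress as CELL_DATA, and per-node displacement
#' magnitude as POINT_DATA.
#'
#' @param mesh a `shell_mesh`.
#' @param path output file path.
#' @param binary for STL, write the 80-byte-header binary variant instead of
#'   ASCII.
#' @param cell_data optional named list of per-element numeric vectors
#'   (VTK only).
#' @param point_data optional named list of per-node numeric vectors
#'   (VTK only).
#' @return invisibly `path`.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  nrm <- triangle_normals(mesh)
  v <- lapply(1:3, function(k) mesh$nodes[mesh$tri[, k], , drop = FALSE])
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(mesh$tri)), con, size = 4, endian = "little")
    for (e in seq_len(nrow(mesh$tri))) {
      writeBin(as.numeric(c(nrm[e, ], v[[1]][e, ], v[[2]][e, ], v[[3]][e, ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vpatch", con)
    for (e in seq_len(nrow(mesh$tri))) {
      writeLines(c(
        sprintf("facet normal %.9g %.9g %.9g", nrm[e, 1], nrm[e, 2], nrm[e, 3]),
        "  outer loop",
        sprintf("    vertex %.9g %.9g %.9g",
                c(v[[1]][e, 1], v[[2]][e, 1], v[[3]][e, 1]),
                c(v[[1]][e, 2], v[[2]][e, 2], v[[3]][e, 2]),
                c(v[[1]][e, 3], v[[2]][e, 3], v[[3]][e, 3])),
        "  endloop", "endfacet"), con)
    }
    writeLines("endsolid vpatch", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$nodes)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$tri)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
write_vtk <- function(mesh, path, cell_data = NULL, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0", "vpatch shell mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  cd <- c(list(region = as.numeric(factor(mesh$region,
                                          c("artery", "patch"))),
               thickness = mesh$thickness), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cd)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.9g", cd[[nm]]), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a triangulated surface from ASCII STL or PLY
#'
#' Accepts an externally supplied vessel surface in place of the parametric
#' generator.  Duplicate vertices (STL repeats them per facet) are merged.
#'
#' @param path file path; format inferred from the extension.
#' @param thickness wall thickness to attach to every element (m).
#' @return a `shell_mesh` (untagged; tag inlet/outlet rings before solving).
#' @export
read_surface_mesh <- function(path, thickness = 0.001) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    key <- apply(round(xyz, 12), 1, paste, collapse = ",")
    uid <- !duplicated(key)
    nodes <- xyz[uid, , drop = FALSE]
    idx <- match(key, key[uid])
    tri <- matrix(idx, ncol = 3, byrow = TRUE)
  } else if (ext == "ply") {
    txt <- readLines(path)
    hend <- which(txt == "end_header")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", txt, value = TRUE)))
    nodes <- do.call(rbind, lapply(strsplit(txt[hend + seq_len(nv)], "\\s+"),
                                   function(p) as.numeric(p[1:3])))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", txt, value = TRUE)))
    tri <- do.call(rbind, lapply(strsplit(txt[hend + nv + seq_len(nf)], "\\s+"),
                                 function(p) as.integer(p[2:4]) + 1L))
  } else stop("unsupported mesh format: ", ext)
  structure(list(nodes = nodes, tri = tri,
                 region = rep("artery", nrow(tri)),
                 thickness = rep(thickness, nrow(tri)), tags = list()),
            class = "shell_mesh")
}
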