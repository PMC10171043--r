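# Mesh export/import: binary STL, legacy-ASCII VTK, Abaqus INP.
# All writers are little-endian / plain-text and unit-agnostic (mm here).

#' Write a mesh to binary STL
#'
#' Exports the midsurface as a binary little-endian STL.  With
#' `solid = TRUE` the midsurface is offset by half the thickness along the
#' area-weighted vertex normals on both sides and closed with side walls
#' along the boundary loop, producing a watertight solid (every edge shared
#' by exactly two facets).  If the offset would locally self-intersect
#' (thickness comparable to the smallest element), a warning is emitted and
#' the midsurface alone is written.
#'
#' @param mesh A `membrane_mesh` or `leaflet_mesh`.
#' @param path Output file path.
#' @param solid Write a watertight offset solid (`TRUE`) or the open
#'   midsurface (`FALSE`, default).
#' @param positions Optional N x 3 matrix of deformed node positions to
#'   export instead of the reference coordinates.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, solid = FALSE, positions = NULL) {
  nodes <- if (is.null(positions)) mesh$nodes else as.matrix(positions)
  if (!all(is.finite(nodes))) stop("non-finite node coordinates", call. = FALSE)
  tris <- mesh$triangles

  if (solid) {
    nrm <- vertex_normals(nodes, tris)
    h <- mesh$thickness / 2
    top <- nodes + h * nrm
    bot <- nodes - h * nrm
    # offset is invalid where it inverts a facet (local self-intersection)
    flip <- function(shifted) {
      any(rowSums(facet_normals(shifted, tris) *
                    facet_normals(nodes, tris)) <= 0)
    }
    if (flip(top) || flip(bot)) {
      warning("thickness ", mesh$thickness,
              " mm: offset solid would self-intersect; ",
              "falling back to midsurface export")
      solid <- FALSE
    }
  }

  if (!solid) {
    v1 <- nodes[tris[, 1L], , drop = FALSE]
    v2 <- nodes[tris[, 2L], , drop = FALSE]
    v3 <- nodes[tris[, 3L], , drop = FALSE]
  } else {
    n <- nrow(nodes)
    all_nodes <- rbind(top, bot)         # bottom ids offset by n
    t_top <- tris
    t_bot <- tris[, c(1L, 3L, 2L), drop = FALSE] + n
    be <- boundary_edges(tris)           # directed a -> b in top winding
    walls <- NULL
    if (nrow(be) > 0L) {
      a <- be[, 1L]; b <- be[, 2L]
      walls <- rbind(cbind(b, a, a + n), cbind(b, a + n, b + n))
    }
    t_all <- rbind(t_top, t_bot, walls)
    v1 <- all_nodes[t_all[, 1L], , drop = FALSE]
    v2 <- all_nodes[t_all[, 2L], , drop = FALSE]
    v3 <- all_nodes[t_all[, 3L], , drop = FALSE]
  }

  e1 <- v2 - v1
  e2 <- v3 - v1
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  m <- length(nx)

  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  header <- charToRaw(sprintf("valvegen leaflet midsurface (%d facets)", m))
  writeBin(c(header, raw(80L - length(header))), con)
  writeBin(as.integer(m), con, size = 4L, endian = "little")
  # 12 float32 per facet (normal + 3 vertices) + uint16 attribute count
  dat <- rbind(t(cbind(nx / len, ny / len, nz / len)), t(v1), t(v2), t(v3))
  buf <- writeBin(as.numeric(dat), raw(), size = 4L, endian = "little")
  buf <- matrix(buf, nrow = 48L)
  zero2 <- writeBin(0L, raw(), size = 2L)
  out <- rbind(buf, matrix(rep(zero2, m), nrow = 2L))
  writeBin(as.vector(out), con)
  invisible(path)
}

# Unnormalised facet normals (cross product of the edge vectors).
facet_normals <- function(nodes, tris) {
  p1 <- nodes[tris[, 1L], , drop = FALSE]
  e1 <- nodes[tris[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tris[, 3L], , drop = FALSE] - p1
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

# Area-weighted unit vertex normals.
vertex_normals <- function(nodes, tris) {
  fn <- facet_normals(nodes, tris)
  vn <- matrix(0, nrow(nodes), 3L)
  idx <- c(tris[, 1L], tris[, 2L], tris[, 3L])
  acc <- rowsum(rbind(fn, fn, fn), idx)
  vn[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Read a binary STL file
#'
#' @param path Path to a binary STL file.
#' @return A list with `v1`, `v2`, `v3` (M x 3 facet vertex matrices),
#'   `normal` (M x 3) and `n_facets`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), n = 80L))
  m <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  rec <- matrix(NA_real_, m, 12L)
  for (i in seq_len(m)) {
    rec[i, ] <- readBin(con, numeric(), n = 12L, size = 4L, endian = "little")
    invisible(readBin(con, raw(), n = 2L))
  }
  list(normal = rec[, 1:3, drop = FALSE], v1 = rec[, 4:6, drop = FALSE],
       v2 = rec[, 7:9, drop = FALSE], v3 = rec[, 10:12, drop = FALSE],
       n_facets = m)
}

#' Check an STL file for watertightness
#'
#' Reconstructs shared vertices from facet coordinates and counts edge
#' incidences: a watertight solid has every edge shared by exactly two
#' facets (zero boundary edges).
#'
#' @param path Path to a binary STL file.
#' @return A list with `watertight` (logical), `n_boundary_edges` and
#'   `n_facets`.
#' @export
stl_is_watertight <- function(path) {
  s <- read_stl(path)
  verts <- rbind(s$v1, s$v2, s$v3)
  key <- apply(signif(verts, 7L), 1L, paste, collapse = ",")
  id <- match(key, unique(key))
  m <- s$n_facets
  tris <- cbind(id[seq_len(m)], id[m + seq_len(m)], id[2L * m + seq_len(m)])
  inc <- edge_incidence(tris)
  nb <- sum(inc$count != 2L)
  list(watertight = nb == 0L, n_boundary_edges = sum(inc$count == 1L),
       n_facets = m)
}

#' Write a mesh with fields to a legacy-ASCII VTK file
#'
#' Writes an unstructured triangle grid with optional point displacements
#' and a per-cell scalar (typically the von Mises stress), readable by
#' ParaView and similar tools.
#'
#' @param mesh A `membrane_mesh`.
#' @param path Output path.
#' @param positions Optional deformed N x 3 positions (default: reference).
#' @param point_displacement Optional N x 3 displacement field.
#' @param cell_scalar Optional per-triangle numeric vector.
#' @param cell_scalar_name Name for the cell scalar (default
#'   `"von_mises_mpa"`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, positions = NULL,
                      point_displacement = NULL, cell_scalar = NULL,
                      cell_scalar_name = "von_mises_mpa") {
  nodes <- if (is.null(positions)) mesh$nodes else as.matrix(positions)
  tris <- mesh$triangles
  n <- nrow(nodes); m <- nrow(tris)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("valvegen membrane field output")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(sprintf("%.9g %.9g %.9g", nodes[, 1L], nodes[, 2L], nodes[, 3L]),
             con)
  w("CELLS %d %d", m, 4L * m)
  writeLines(sprintf("3 %d %d %d", tris[, 1L] - 1L, tris[, 2L] - 1L,
                     tris[, 3L] - 1L), con)
  w("CELL_TYPES %d", m)
  writeLines(rep("5", m), con)
  if (!is.null(point_displacement)) {
    d <- as.matrix(point_displacement)
    w("POINT_DATA %d", n)
    w("VECTORS displacement_mm double")
    writeLines(sprintf("%.9g %.9g %.9g", d[, 1L], d[, 2L], d[, 3L]), con)
  }
  if (!is.null(cell_scalar)) {
    w("CELL_DATA %d", m)
    w("SCALARS %s double 1", cell_scalar_name)
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.9g", cell_scalar), con)
  }
  invisible(path)
}

#' Write a mesh to an Abaqus-style INP file
#'
#' Nodes, M3D3 membrane triangles, and the pinned attachment edge as node
#' set `F3_FIXED`, for interoperability with general finite-element tools.
#'
#' @param mesh A `membrane_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("valvegen leaflet midsurface, units mm", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
             con)
  writeLines("*ELEMENT, TYPE=M3D3, ELSET=LEAFLET", con)
  writeLines(sprintf("%d, %d, %d, %d", seq_len(nrow(mesh$triangles)),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), con)
  writeLines("*NSET, NSET=F3_FIXED", con)
  ids <- mesh$attachment_nodes
  for (i in seq(1L, length(ids), by = 8L)) {
    writeLines(paste(ids[i:min(i + 7L, length(ids))], collapse = ", "), con)
  }
  invisible(path)
}
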