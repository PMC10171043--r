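# Parametric leaflet surface and triangulated midsurface meshes.
#
# Coordinate convention: the valve axis is +z and points toward the aorta,
# the base plane of the valve is z = 0, and the single modelled leaflet is
# centred on the polar angle theta = 0.  All lengths are millimetres.

# Closed-form midsurface point for parameter pair (u, theta).
#   u     in [0, 1]: 0 = attachment scallop, 1 = free edge.
#   theta in [-Sec/2, Sec/2] degrees: circumferential parameter.
# Attachment curve: on the cylinder r = Rin with a cosine scallop, low at
# the leaflet belly (theta = 0) and rising to H1 at the commissures.
# Free edge: runs along the coaptation lines of the closed valve (the two
# sector-boundary radii), at distance Rin*|theta|/(Sec/2) from the axis and
# height H1 - tan(phi)*(Rin - r); the interior is a linear Cartesian blend,
# with an axial "dome sag" bubble of maximum depth 0.25*Rin at R = 100 %.
leaflet_surface <- function(params, u, theta) {
  half <- params$Sec / 2
  phir <- params$phi * pi / 180
  thr <- theta * pi / 180

  ax <- params$Rin * cos(thr)
  ay <- params$Rin * sin(thr)
  az <- params$H1 * (1 - cos(pi * theta / half)) / 2

  rf <- params$Rin * abs(theta) / half
  angf <- sign(theta) * half * pi / 180
  fx <- rf * cos(angf)
  fy <- rf * sin(angf)
  fz <- params$H1 - tan(phir) * (params$Rin - rf)

  x <- (1 - u) * ax + u * fx
  y <- (1 - u) * ay + u * fy
  z <- (1 - u) * az + u * fz
  z <- z - (params$R / 100) * 0.25 * params$Rin * sin(pi * u) *
    cos(pi * theta / params$Sec)
  cbind(x, y, z)
}

#' Generate a triangulated leaflet midsurface
#'
#' Builds a structured-grid point cloud from the six design parameters and
#' links it into a single triangulated surface.  The grid runs from the
#' attachment scallop (`u = 0`, fixed to the valve frame) to the free edge
#' (`u = 1`) and circumferentially across the leaflet's angular span.  The
#' attachment and free edge meet at the two commissure tips, where the grid
#' columns are welded into single nodes, so the mesh is a proper manifold
#' with `nu * (ntheta - 2) + 2` nodes and `2 * (nu - 1) * (ntheta - 2)`
#' triangles.  Triangles are wound counter-clockwise when viewed from the
#' aortic (+z) side.
#'
#' @param params A [leaflet_params()] object.
#' @param nu Number of grid rows from attachment to free edge (>= 3).
#' @param ntheta Number of circumferential grid columns (>= 5, odd, so that
#'   the leaflet centreline `theta = 0` is sampled).
#'
#' @return An object of class `leaflet_mesh` (also `membrane_mesh`): a list
#'   with `nodes` (N x 3, mm), `triangles` (M x 3 node indices),
#'   `thickness` (mm), `attachment_nodes` (indices of the fixed scallop,
#'   surface F3), `free_edge_nodes`, `grid_shape = c(nu, ntheta)` and
#'   `params`.
#' @examples
#' p <- leaflet_params(H1 = 15.22, phi = 5.17, R = 40, Rin = 9.38, T = 0.14)
#' m <- generate_leaflet_mesh(p, nu = 11, ntheta = 21)
#' nrow(m$nodes); nrow(m$triangles)
#' @export
generate_leaflet_mesh <- function(params, nu = 11, ntheta = 21) {
  if (!inherits(params, "leaflet_params")) {
    params <- do.call(leaflet_params, as.list(params))
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 3) {
    stop("nu must be a single integer >= 3", call. = FALSE)
  }
  if (!is.numeric(ntheta) || length(ntheta) != 1L || !is.finite(ntheta) ||
      ntheta < 5) {
    stop("ntheta must be a single integer >= 5", call. = FALSE)
  }
  nu <- as.integer(nu)
  ntheta <- as.integer(ntheta)
  if (ntheta %% 2L == 0L) {
    stop("ntheta must be odd so the leaflet centreline theta = 0 is sampled",
         call. = FALSE)
  }

  half <- params$Sec / 2
  u <- seq(0, 1, length.out = nu)
  theta <- seq(-half, half, length.out = ntheta)

  # Node ids: the two end columns (theta = -/+ Sec/2) collapse to the
  # commissure tips and are welded into nodes 1 and 2.
  nid <- function(i, j) {
    len <- max(length(i), length(j))
    i <- rep_len(as.integer(i), len)
    j <- rep_len(as.integer(j), len)
    out <- 2L + (j - 2L) * nu + i
    out[j == 1L] <- 1L
    out[j == ntheta] <- 2L
    out
  }
  n_nodes <- 2L + (ntheta - 2L) * nu
  nodes <- matrix(NA_real_, n_nodes, 3L)
  nodes[1L, ] <- leaflet_surface(params, 0, -half)
  nodes[2L, ] <- leaflet_surface(params, 0, half)
  for (j in 2:(ntheta - 1L)) {
    nodes[nid(seq_len(nu), j), ] <- leaflet_surface(params, u, theta[j])
  }

  tris <- matrix(0L, 2L * (nu - 1L) * (ntheta - 2L), 3L)
  k <- 0L
  for (j in seq_len(ntheta - 1L)) {
    for (i in seq_len(nu - 1L)) {
      a <- nid(i, j); b <- nid(i, j + 1L)
      c_ <- nid(i + 1L, j); d <- nid(i + 1L, j + 1L)
      if (j == 1L) {              # left commissure fan (a == c_)
        k <- k + 1L; tris[k, ] <- c(a, b, d)
      } else if (j == ntheta - 1L) { # right commissure fan (b == d)
        k <- k + 1L; tris[k, ] <- c(a, d, c_)
      } else {
        k <- k + 1L; tris[k, ] <- c(a, b, d)
        k <- k + 1L; tris[k, ] <- c(a, d, c_)
      }
    }
  }

  mesh <- structure(
    list(nodes = nodes, triangles = tris, thickness = params$T,
         attachment_nodes = c(1L, nid(1L, 2:(ntheta - 1L)), 2L),
         free_edge_nodes = c(1L, nid(nu, 2:(ntheta - 1L)), 2L),
         grid_shape = c(nu, ntheta), params = params),
    class = c("leaflet_mesh", "membrane_mesh"))

  areas <- triangle_areas(mesh$nodes, mesh$triangles)
  if (any(areas <= 1e-9)) {
    stop("degenerate leaflet mesh: triangle area <= 1e-9 mm^2 at resolution nu=",
         nu, ", ntheta=", ntheta, call. = FALSE)
  }
  mesh
}

#' General triangulated membrane mesh
#'
#' Low-level constructor used for verification geometries (see
#' [disc_mesh()]) and tests; [generate_leaflet_mesh()] produces the
#' leaflet-specific subclass.
#'
#' @param nodes N x 3 numeric matrix of coordinates (mm).
#' @param triangles M x 3 integer matrix of node indices.
#' @param thickness Membrane thickness (mm).
#' @param fixed_nodes Indices of pinned nodes (zero displacement).
#' @return An object of class `membrane_mesh`.
#' @export
membrane_mesh <- function(nodes, triangles, thickness,
                          fixed_nodes = integer(0)) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L || !all(is.finite(nodes))) {
    stop("nodes must be a finite N x 3 matrix", call. = FALSE)
  }
  if (ncol(triangles) != 3L || any(triangles < 1L) ||
      any(triangles > nrow(nodes))) {
    stop("triangles must index rows of nodes", call. = FALSE)
  }
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("thickness must be > 0", call. = FALSE)
  }
  structure(list(nodes = nodes, triangles = triangles, thickness = thickness,
                 attachment_nodes = as.integer(fixed_nodes)),
            class = "membrane_mesh")
}

#' Flat circular membrane mesh
#'
#' A flat disc in the plane z = 0, meshed with a centre fan and structured
#' rings, with the outer rim pinned.  Used as the analytic verification
#' geometry for the membrane solver (uniformly loaded circular membrane).
#'
#' @param radius Disc radius (mm).
#' @param nr Number of rings (>= 2).
#' @param nseg Number of circumferential segments (>= 6).
#' @param thickness Membrane thickness (mm).
#' @return A `membrane_mesh` whose `attachment_nodes` are the rim nodes.
#' @export
disc_mesh <- function(radius, nr = 8, nseg = 28, thickness = 0.1) {
  stopifnot(radius > 0, nr >= 2, nseg >= 6)
  nr <- as.integer(nr); nseg <- as.integer(nseg)
  ang <- 2 * pi * (seq_len(nseg) - 1L) / nseg
  nodes <- matrix(0, 1L + nr * nseg, 3L)
  for (i in seq_len(nr)) {
    r <- radius * i / nr
    idx <- 1L + (i - 1L) * nseg + seq_len(nseg)
    nodes[idx, 1L] <- r * cos(ang)
    nodes[idx, 2L] <- r * sin(ang)
  }
  nid <- function(i, k) 1L + (i - 1L) * nseg + ((k - 1L) %% nseg) + 1L
  tris <- matrix(0L, nseg + 2L * (nr - 1L) * nseg, 3L)
  m <- 0L
  for (k in seq_len(nseg)) {      # centre fan, CCW from +z
    m <- m + 1L; tris[m, ] <- c(1L, nid(1L, k), nid(1L, k + 1L))
  }
  for (i in seq_len(nr - 1L)) {
    for (k in seq_len(nseg)) {
      a <- nid(i, k); b <- nid(i, k + 1L)
      c_ <- nid(i + 1L, k); d <- nid(i + 1L, k + 1L)
      m <- m + 1L; tris[m, ] <- c(a, d, b)
      m <- m + 1L; tris[m, ] <- c(a, c_, d)
    }
  }
  rim <- 1L + (nr - 1L) * nseg + seq_len(nseg)
  membrane_mesh(nodes, tris, thickness, fixed_nodes = rim)
}

# Unsigned triangle areas (mm^2) for 3D node coordinates.
triangle_areas <- function(nodes, triangles) {
  p1 <- nodes[triangles[, 1L], , drop = FALSE]
  e1 <- nodes[triangles[, 2L], , drop = FALSE] - p1
  e2 <- nodes[triangles[, 3L], , drop = FALSE] - p1
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Undirected edge incidence counts.  Returns a data.frame with node pair
# (a < b) and the number of triangles sharing the edge.
edge_incidence <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(3L, 1L)])
  a <- pmin(e[, 1L], e[, 2L])
  b <- pmax(e[, 1L], e[, 2L])
  key <- paste(a, b)
  cnt <- table(key)
  ab <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  data.frame(a = as.integer(ab[, 1L]), b = as.integer(ab[, 2L]),
             count = as.integer(cnt))
}

# Directed boundary edges (each appearing in exactly one triangle), in
# triangle winding order.
boundary_edges <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  e[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Validate mesh invariants
#'
#' Checks that a mesh is a usable membrane midsurface: finite coordinates,
#' all triangle areas above 1e-9 mm^2, and edge-manifoldness (every edge
#' shared by at most two triangles).  For a `leaflet_mesh` additionally
#' checks that all nodes lie within the prosthesis cylinder
#' (`r <= Rin + 1e-6`) and that attachment nodes lie on it (within 1e-6 mm).
#'
#' @param mesh A `membrane_mesh` or `leaflet_mesh`.
#' @return `TRUE` (invisibly); errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  if (!all(is.finite(mesh$nodes))) stop("non-finite node coordinates")
  areas <- triangle_areas(mesh$nodes, mesh$triangles)
  if (any(areas <= 1e-9)) stop("triangle area <= 1e-9 mm^2")
  inc <- edge_incidence(mesh$triangles)
  if (any(inc$count > 2L)) stop("non-manifold edge (shared by > 2 triangles)")
  if (inherits(mesh, "leaflet_mesh")) {
    r <- sqrt(mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2)
    if (any(r > mesh$params$Rin + 1e-6)) {
      stop("node outside the prosthesis cylinder r = Rin")
    }
    ra <- r[mesh$attachment_nodes]
    if (any(abs(ra - mesh$params$Rin) > 1e-6)) {
      stop("attachment node off the cylinder r = Rin")
    }
  }
  invisible(TRUE)
}

#' Reference orifice area of one leaflet
#'
#' The area occupied by one leaflet of a tri-leaflet valve in the valve
#' cross-section: one third of the circle of radius `Rin`.  This is the
#' denominator of the degree-of-opening metric and is by convention
#' independent of the leaflet's angular span.
#'
#' @param Rin Prosthesis radius (mm), >= 0.
#' @return Area in mm^2: `pi * Rin^2 / 3`.
#' @examples
#' sector_area(10) # 104.7198
#' @export
sector_area <- function(Rin) {
  if (!is.numeric(Rin) || length(Rin) != 1L || !is.finite(Rin) || Rin < 0) {
    stop("Rin must be a single finite number >= 0", call. = FALSE)
  }
  pi * Rin^2 / 3
}

#' Projected covered area of a membrane in the valve cross-section
#'
#' Area of the union of the XY-projections of all triangles, clipped to the
#' disc `r <= Rin`, computed by rasterisation at the given resolution.
#' Used to measure how much of the orifice a (deformed) leaflet still
#' obstructs when viewed along the valve axis.
#'
#' @param x A `membrane_mesh`/`leaflet_mesh`, or an N x 3 matrix of node
#'   coordinates (in which case `triangles` must be given).
#' @param Rin Clipping disc radius (mm).
#' @param resolution Raster pixel size (mm/pixel), default 0.05.
#' @param triangles M x 3 index matrix when `x` is a bare coordinate matrix.
#' @return Covered area in mm^2.
#' @export
projected_covered_area <- function(x, Rin, resolution = 0.05,
                                   triangles = NULL) {
  if (inherits(x, "membrane_mesh")) {
    nodes <- x$nodes
    triangles <- x$triangles
  } else {
    nodes <- as.matrix(x)
    if (is.null(triangles)) {
      stop("triangles must be supplied with a bare coordinate matrix",
           call. = FALSE)
    }
  }
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0) {
    stop("resolution must be a single number > 0", call. = FALSE)
  }
  if (!all(is.finite(nodes))) stop("non-finite node coordinates", call. = FALSE)
  if (Rin <= 0) return(0)

  n <- as.integer(ceiling(2 * Rin / resolution))
  g0 <- -Rin + resolution / 2
  g <- g0 + resolution * (seq_len(n) - 1L)
  covered <- logical(n * n)

  px <- nodes[, 1L]; py <- nodes[, 2L]
  t1 <- triangles[, 1L]; t2 <- triangles[, 2L]; t3 <- triangles[, 3L]
  for (m in seq_len(nrow(triangles))) {
    x1 <- px[t1[m]]; y1 <- py[t1[m]]
    x2 <- px[t2[m]]; y2 <- py[t2[m]]
    x3 <- px[t3[m]]; y3 <- py[t3[m]]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-12) next   # edge-on projection covers no area
    ilo <- max(1L, as.integer(floor((min(x1, x2, x3) - g0) / resolution)) + 1L)
    ihi <- min(n, as.integer(ceiling((max(x1, x2, x3) - g0) / resolution)) + 1L)
    jlo <- max(1L, as.integer(floor((min(y1, y2, y3) - g0) / resolution)) + 1L)
    jhi <- min(n, as.integer(ceiling((max(y1, y2, y3) - g0) / resolution)) + 1L)
    if (ilo > ihi || jlo > jhi) next
    gx <- g[ilo:ihi]; gy <- g[jlo:jhi]
    lx <- length(gx); ly <- length(gy)
    xx <- rep(gx, times = ly); yy <- rep(gy, each = lx)
    l1 <- ((y2 - y3) * (xx - x3) + (x3 - x2) * (yy - y3)) / det
    l2 <- ((y3 - y1) * (xx - x3) + (x1 - x3) * (yy - y3)) / det
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & (1 - l1 - l2) >= -1e-9
    if (any(inside)) {
      ii <- rep(ilo:ihi, times = ly)
      jj <- rep(jlo:jhi, each = lx)
      covered[(jj[inside] - 1L) * n + ii[inside]] <- TRUE
    }
  }
  dx <- rep(g, times = n)
  dy <- rep(g, each = n)
  in_disc <- dx * dx + dy * dy <= Rin * Rin
  resolution^2 * sum(covered & in_disc)
}

#' @export
print.membrane_mesh <- function(x, ...) {
  cat(sprintf("%s: %d nodes, %d triangles, thickness %.3f mm, %d pinned nodes\n",
              if (inherits(x, "leaflet_mesh")) "Leaflet mesh" else "Membrane mesh",
              nrow(x$nodes), nrow(x$triangles), x$thickness,
              length(x$attachment_nodes)))
  if (!is.null(x$grid_shape)) {
    cat(sprintf("  structured grid %d x %d (attachment -> free edge x span)\n",
                x$grid_shape[1L], x$grid_shape[2L]))
  }
  invisible(x)
}

#' Plot a membrane mesh (top view)
#'
#' Draws the XY projection of the mesh wireframe; for a `leaflet_mesh` the
#' prosthesis circle `r = Rin` is overlaid.
#'
#' @param x A `membrane_mesh`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.membrane_mesh <- function(x, ...) {
  nd <- x$nodes
  lim <- range(nd[, 1L:2L])
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  tr <- x$triangles
  for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
    graphics::segments(nd[tr[, e[1L]], 1L], nd[tr[, e[1L]], 2L],
                       nd[tr[, e[2L]], 1L], nd[tr[, e[2L]], 2L],
                       col = "grey40")
  }
  if (inherits(x, "leaflet_mesh")) {
    a <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(x$params$Rin * cos(a), x$params$Rin * sin(a),
                    col = "red3", lty = 2)
  }
  invisible(x)
}
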