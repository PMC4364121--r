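# Axisymmetric meridian mesh of cornea + limbus + scleral cap.
#
# The outer (anterior) meridian is: the anterior conic over the corneal
# aperture, a Hermite blend across the limbus, then the scleral sphere
# down to its equator. Through-thickness node lines run along the inward
# normal of the outer surface. Local element coordinate xi follows the
# meridian (this direction carries the meridional fiber family), eta the
# thickness.

# 9-node Lagrange shape functions, tensor ordering k = 3*j + i + 1
.shape9 <- function(xi, eta) {
  L <- c(0.5 * xi * (xi - 1), 1 - xi^2, 0.5 * xi * (xi + 1))
  dL <- c(xi - 0.5, -2 * xi, xi + 0.5)
  M <- c(0.5 * eta * (eta - 1), 1 - eta^2, 0.5 * eta * (eta + 1))
  dM <- c(eta - 0.5, -2 * eta, eta + 0.5)
  list(N = as.vector(outer(L, M)),
       dxi = as.vector(outer(dL, M)),
       deta = as.vector(outer(L, dM)))
}

.gauss3 <- list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)

# outer meridian description: stations, points, inward normals, thickness
.meridian <- function(geometry, nm_cornea, nm_limbus, nm_sclera) {
  rc <- geometry$diameter / 2
  w <- geometry$limbus_width
  r7 <- rc + w
  Rs <- geometry$sclera_diameter / 2
  ant <- geometry$anterior
  z6 <- conic_sag(rc, ant); m6 <- .conic_slope(rc, ant)
  # scleral sphere through (r7, z7s); z7s from the anterior conic when its
  # domain allows, otherwise by tangent extrapolation
  z7s <- if (ant$R^2 - (1 + ant$Q) * r7^2 > 0) conic_sag(r7, ant) else
    z6 + m6 * (r7 - rc)
  zc <- z7s + sqrt(Rs^2 - r7^2)
  m7 <- r7 / sqrt(Rs^2 - r7^2)
  phi7 <- asin(r7 / Rs)

  herm <- function(r) {
    t <- (r - rc) / w
    h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2;    h11 <- t^3 - t^2
    list(z = h00 * z6 + h10 * w * m6 + h01 * z7s + h11 * w * m7,
         dz = (6 * t^2 - 6 * t) * z6 / w + (3 * t^2 - 4 * t + 1) * m6 +
              (-6 * t^2 + 6 * t) * z7s / w + (3 * t^2 - 2 * t) * m7)
  }

  # thickness of the cornea at the limbus junction (excludes the offset)
  t6 <- .normal_thickness(rc, geometry)
  ts <- if (is.null(geometry$sclera_thickness)) t6 else
    geometry$sclera_thickness
  off <- geometry$thickness_offset * 1e-3

  # one station: s in [0,1] cornea (linear in r), [1,2] limbus, [2,3] sclera
  station <- function(s) {
    if (s <= 1) {
      r <- s * rc
      z <- conic_sag(r, ant)
      sl <- .conic_slope(r, ant)
      tn <- sqrt(1 + sl^2)
      nr <- -sl / tn; nz <- 1 / tn
      th <- .normal_thickness(r, geometry) + off
    } else if (s <= 2) {
      r <- rc + (s - 1) * w
      hh <- herm(r)
      z <- hh$z; sl <- hh$dz
      tn <- sqrt(1 + sl^2)
      nr <- -sl / tn; nz <- 1 / tn
      b <- 1 - .smoothstep(s - 1)           # 1 at cornea side, 0 at sclera
      th <- (1 - b) * ts + b * t6 + b * off
    } else {
      phi <- phi7 + (s - 2) * (pi / 2 - phi7)
      r <- Rs * sin(phi); z <- zc - Rs * cos(phi)
      nr <- -sin(phi); nz <- cos(phi)
      th <- ts
    }
    c(r = r, z = z, nr = nr, nz = nz, th = th)
  }

  ss <- c(seq(0, 1, length.out = 2 * nm_cornea + 1),
          seq(1, 2, length.out = 2 * nm_limbus + 1)[-1],
          seq(2, 3, length.out = 2 * nm_sclera + 1)[-1])
  st <- t(vapply(ss, station, numeric(5)))
  list(stations = st, s = ss, zc = zc, Rs = Rs)
}

.smoothstep <- function(t) ifelse(t <= 0, 0, ifelse(t >= 1, 1, 3 * t^2 - 2 * t^3))

#' Generate the axisymmetric finite-element mesh
#'
#' Discretizes a corneal geometry (cornea, limbus ring, scleral cap down to
#' the scleral equator) into 9-node Lagrangian quadrilaterals in the
#' meridian section. The interior (posterior) surface, the anterior
#' surface, the axis and the scleral equatorial cut are tagged; boundary
#' conditions restrain radial displacement on the axis and axial
#' displacement on the scleral base.
#'
#' @param geometry a \code{corneal_geometry}.
#' @param n_meridian total elements along the meridian (>= 20); split
#'   roughly 60/10/30 between cornea, limbus, sclera.
#' @param n_thickness elements through the thickness (>= 2).
#' @return an object of class \code{meridian_mesh}.
#' @export
generate_mesh <- function(geometry, n_meridian = 40, n_thickness = 3) {
  stopifnot(inherits(geometry, "corneal_geometry"),
            n_meridian >= 20, n_thickness >= 2)
  nm_c <- as.integer(max(12, round(0.55 * n_meridian)))
  nm_l <- as.integer(max(2, round(0.10 * n_meridian)))
  nm_s <- as.integer(max(6, n_meridian - nm_c - nm_l))
  nm <- nm_c + nm_l + nm_s
  nt <- as.integer(n_thickness)
  mer <- .meridian(geometry, nm_c, nm_l, nm_s)
  st <- mer$stations
  ncol_ <- 2L * nm + 1L
  nrow_ <- 2L * nt + 1L
  zeta <- seq(0, 1, length.out = nrow_)
  nodes <- matrix(0, ncol_ * nrow_, 2)
  idx <- function(k, l) (l - 1L) * ncol_ + k
  for (l in seq_len(nrow_)) {
    nodes[idx(seq_len(ncol_), l), 1] <- st[, "r"] + zeta[l] * st[, "th"] * st[, "nr"]
    nodes[idx(seq_len(ncol_), l), 2] <- st[, "z"] + zeta[l] * st[, "th"] * st[, "nz"]
  }
  nodes[idx(1, seq_len(nrow_)), 1] <- 0   # snap axis column exactly

  ne <- nm * nt
  elems <- matrix(0L, ne, 9)
  region <- integer(ne)
  e <- 0L
  for (j in seq_len(nt)) {
    for (i in seq_len(nm)) {
      e <- e + 1L
      loc <- 1L
      for (j0 in 0:2) for (i0 in 0:2) {
        elems[e, loc] <- idx(2L * (i - 1L) + i0 + 1L, 2L * (j - 1L) + j0 + 1L)
        loc <- loc + 1L
      }
      region[e] <- if (i <= nm_c) 1L else if (i <= nm_c + nm_l) 2L else 3L
    }
  }

  edge_row <- function(l) {
    t(vapply(seq_len(nm), function(i)
      idx(c(2L * i - 1L, 2L * i, 2L * i + 1L), l), integer(3)))
  }
  edges_interior <- edge_row(nrow_)
  edges_anterior <- edge_row(1L)[seq_len(nm_c + nm_l), , drop = FALSE]

  tags <- list(
    anterior = idx(seq_len(ncol_), 1L),
    posterior = idx(seq_len(ncol_), nrow_),
    axis = idx(1L, seq_len(nrow_)),
    scleral_base = idx(ncol_, seq_len(nrow_)))
  fixed <- c(2L * tags$axis - 1L,        # u_r = 0 on the axis
             2L * tags$scleral_base)     # u_z = 0 on the scleral base
  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region,
    region_labels = c("cornea", "limbus", "sclera"),
    edges_interior = edges_interior, edges_anterior = edges_anterior,
    tags = tags, fixed_dofs = sort(unique(fixed)),
    nm = c(cornea = nm_c, limbus = nm_l, sclera = nm_s),
    nt = nt, geometry = geometry),
    class = "meridian_mesh")
  if (min_jacobian(mesh) <= 0)
    stop("meshing error: tangled elements (non-positive Jacobian)")
  mesh
}

#' Minimum reference Jacobian of a mesh
#'
#' @param mesh a \code{meridian_mesh}, or its node matrix via
#'   \code{nodes}.
#' @param nodes optional replacement node coordinates.
#' @return smallest Jacobian determinant over all Gauss points.
#' @export
min_jacobian <- function(mesh, nodes = NULL) {
  if (is.null(nodes)) nodes <- mesh$nodes
  cpp_min_jacobian(nodes, mesh$elems - 1L)
}

#' Local fiber frames at the integration points
#'
#' Meridional and circumferential unit vectors at each Gauss point,
#' computed from the reference geometry: the meridional direction follows
#' the element xi axis, the circumferential direction is e_theta. The two
#' orthogonal corneal collagen families of the 3D eye map onto these two
#' directions in the axisymmetric reduction.
#'
#' @param mesh a \code{meridian_mesh}.
#' @return list with \code{meridional} (ne*9 x 3) and
#'   \code{circumferential} (ne*9 x 3) matrices of unit vectors in the
#'   (R, Z, Theta) basis.
#' @export
fiber_frames <- function(mesh) {
  g <- .gauss3$x
  ne <- nrow(mesh$elems)
  mer <- matrix(0, ne * 9, 3)
  row <- 0L
  for (e in seq_len(ne)) {
    Xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (b in 1:3) for (a in 1:3) {
      sh <- .shape9(g[a], g[b])
      tr <- sum(sh$dxi * Xe[, 1]); tz <- sum(sh$dxi * Xe[, 2])
      tn <- sqrt(tr^2 + tz^2)
      row <- row + 1L
      mer[row, ] <- c(tr / tn, tz / tn, 0)
    }
  }
  circ <- matrix(rep(c(0, 0, 1), each = ne * 9), ne * 9, 3)
  list(meridional = mer, circumferential = circ)
}

#' Meridian-section area of a mesh region
#'
#' Area of the (r, z) section covered by the elements of one region,
#' computed by Gauss quadrature. Used for mesh-convergence checks.
#'
#' @param mesh a \code{meridian_mesh}.
#' @param region region label ("cornea", "limbus", "sclera") or NULL for
#'   the whole section.
#' @return area in mm^2.
#' @export
mesh_section_area <- function(mesh, region = "cornea") {
  keep <- if (is.null(region)) seq_len(nrow(mesh$elems)) else
    which(mesh$region == match(region, mesh$region_labels))
  g <- .gauss3
  area <- 0
  for (e in keep) {
    Xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (b in 1:3) for (a in 1:3) {
      sh <- .shape9(g$x[a], g$x[b])
      dj <- sum(sh$dxi * Xe[, 1]) * sum(sh$deta * Xe[, 2]) -
            sum(sh$dxi * Xe[, 2]) * sum(sh$deta * Xe[, 1])
      area <- area + dj * g$w[a] * g$w[b]
    }
  }
  area
}

#' @export
print.meridian_mesh <- function(x, ...) {
  cat("Axisymmetric meridian mesh\n")
  cat(sprintf("  %d nodes, %d biquadratic elements (%d+%d+%d meridian x %d thickness)\n",
              nrow(x$nodes), nrow(x$elems),
              x$nm[1], x$nm[2], x$nm[3], x$nt))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s=%d", x$region_labels, tabulate(x$region, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Export a mesh (with optional fields) in legacy VTK format
#'
#' Writes an ASCII legacy VTK unstructured grid with biquadratic
#' quadrilateral cells, for inspection in ParaView-like viewers. The
#' axisymmetric section is written in the (r, z) plane.
#'
#' @param mesh a \code{meridian_mesh}.
#' @param file output path.
#' @param point_data optional named list of per-node numeric vectors.
#' @param displacement optional n x 2 displacement field, written as a
#'   3-component vector field.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = NULL, displacement = NULL) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  # VTK biquadratic quad ordering: corners, edge midpoints, centre
  ord <- c(1, 3, 9, 7, 2, 6, 8, 4, 5)
  con <- mesh$elems[, ord, drop = FALSE] - 1L
  lines <- c("# vtk DataFile Version 3.0", "tonosim meridian mesh", "ASCII",
             "DATASET UNSTRUCTURED_GRID",
             sprintf("POINTS %d double", n),
             paste(mesh$nodes[, 1], mesh$nodes[, 2], 0),
             sprintf("CELLS %d %d", ne, ne * 10),
             apply(con, 1, function(z) paste(c(9L, z), collapse = " ")),
             sprintf("CELL_TYPES %d", ne),
             rep("28", ne),
             sprintf("CELL_DATA %d", ne),
             "SCALARS region int 1", "LOOKUP_TABLE default",
             as.character(mesh$region))
  pd <- character(0)
  if (!is.null(displacement) || length(point_data)) {
    pd <- sprintf("POINT_DATA %d", n)
    if (!is.null(displacement))
      pd <- c(pd, "VECTORS displacement double",
              paste(displacement[, 1], displacement[, 2], 0))
    for (nm in names(point_data))
      pd <- c(pd, sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
              as.character(point_data[[nm]]))
  }
  writeLines(c(lines, pd), file)
  invisible(file)
}
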