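#' Conic surface of revolution
#'
#' Corneal surfaces are described by an apical radius of curvature \code{R}
#' (mm) and an asphericity \code{Q} (Q = 0 sphere, Q < 0 prolate), the
#' parameterization corneal topographers report.
#'
#' @param R apical radius of curvature (mm), positive.
#' @param Q asphericity (dimensionless).
#' @return an object of class \code{conic_surface}.
#' @export
conic_surface <- function(R, Q = 0) {
  stopifnot(R > 0, is.finite(Q))
  structure(list(R = R, Q = Q), class = "conic_surface")
}

#' Sag of a conic surface
#'
#' Axial sag \code{z = r^2 / (R + sqrt(R^2 - (1+Q) r^2))} of a conic of
#' revolution at radial coordinate \code{r}; the apical curvature radius
#' equals \code{R}.
#'
#' @param r radial coordinates (mm).
#' @param surface a \code{conic_surface}.
#' @return sag values (mm).
#' @export
conic_sag <- function(r, surface) {
  R <- surface$R; Q <- surface$Q
  disc <- R^2 - (1 + Q) * r^2
  if (any(disc < 0))
    stop("aperture exceeds the conic surface domain")
  r^2 / (R + sqrt(disc))
}

# d sag / d r
.conic_slope <- function(r, surface) {
  R <- surface$R; Q <- surface$Q
  disc <- R^2 - (1 + Q) * r^2
  if (any(disc < 0)) stop("aperture exceeds the conic surface domain")
  r / sqrt(disc)
}

#' Corneal geometry
#'
#' Axisymmetric bi-conic corneal geometry plus limbus ring and scleral cap.
#' Coordinates: optical axis = z, apex at the origin, z positive
#' posteriorly; lengths in mm internally, thickness quoted in microns at
#' the interface. The posterior surface is placed so that the central
#' corneal thickness equals \code{cct + thickness_offset} exactly;
#' \code{thickness_offset} perturbs the thickness normal to the anterior
#' surface, leaving the anterior shape (what a topographer images)
#' unchanged.
#'
#' @param anterior,posterior \code{conic_surface} objects.
#' @param cct central corneal thickness (microns).
#' @param diameter corneal aperture diameter (mm).
#' @param limbus_width limbus ring width (mm).
#' @param sclera_diameter scleral sphere diameter (mm).
#' @param sclera_thickness scleral wall thickness (mm); default NULL means
#'   "equal to the local limbal thickness".
#' @param thickness_offset uniform corneal thickness perturbation
#'   (microns), tapered to zero across the limbus.
#' @return an object of class \code{corneal_geometry}.
#' @export
corneal_geometry <- function(anterior = conic_surface(8.08, -0.22),
                             posterior = conic_surface(6.64, -0.12),
                             cct = 585, diameter = 12, limbus_width = 1.0,
                             sclera_diameter = 25, sclera_thickness = NULL,
                             thickness_offset = 0) {
  stopifnot(inherits(anterior, "conic_surface"),
            inherits(posterior, "conic_surface"),
            cct > 0, diameter > 0, limbus_width > 0,
            sclera_diameter > diameter + 2 * limbus_width)
  g <- structure(list(anterior = anterior, posterior = posterior,
                      cct = cct, diameter = diameter,
                      limbus_width = limbus_width,
                      sclera_diameter = sclera_diameter,
                      sclera_thickness = sclera_thickness,
                      thickness_offset = thickness_offset),
                 class = "corneal_geometry")
  tt <- corneal_thickness(seq(0, diameter / 2, length.out = 41), g)
  if (any(tt <= 0))
    stop("geometry error: non-positive corneal thickness on the aperture")
  g
}

#' Central corneal thickness of a geometry
#'
#' @param geometry a \code{corneal_geometry}.
#' @return CCT in microns, including the thickness offset.
#' @export
central_thickness <- function(geometry) {
  geometry$cct + geometry$thickness_offset
}

#' Corneal thickness profile
#'
#' Thickness measured from the anterior surface along its inward normal to
#' the posterior conic, plus the uniform thickness offset.
#'
#' @param r radial coordinates on the anterior surface (mm).
#' @param geometry a \code{corneal_geometry}.
#' @return thickness values (mm... see Details) in mm.
#' @export
corneal_thickness <- function(r, geometry) {
  vapply(r, function(ri) .normal_thickness(ri, geometry), numeric(1)) +
    geometry$thickness_offset * 1e-3
}

# distance from anterior point at radius r, along the inward anterior
# normal, to the posterior conic surface (mm); excludes the offset
.normal_thickness <- function(r, geometry) {
  cct_mm <- geometry$cct * 1e-3
  za <- conic_sag(r, geometry$anterior)
  sl <- .conic_slope(r, geometry$anterior)
  tn <- sqrt(1 + sl^2)
  nr <- -sl / tn; nz <- 1 / tn          # inward (posterior) unit normal
  f <- function(d) {
    (za + d * nz) - (cct_mm + conic_sag(r + d * nr, geometry$posterior))
  }
  stats::uniroot(f, c(1e-4, 3), tol = 1e-12, extendInt = "upX")$root
}

#' @export
print.corneal_geometry <- function(x, ...) {
  cat("Corneal geometry (axisymmetric)\n")
  cat(sprintf("  anterior:  R = %g mm, Q = %g\n", x$anterior$R, x$anterior$Q))
  cat(sprintf("  posterior: R = %g mm, Q = %g\n", x$posterior$R, x$posterior$Q))
  cat(sprintf("  CCT = %g um (offset %+g um), aperture %g mm\n",
              central_thickness(x), x$thickness_offset, x$diameter))
  cat(sprintf("  limbus %g mm, sclera diameter %g mm\n",
              x$limbus_width, x$sclera_diameter))
  invisible(x)
}

#' Geometry presets
#'
#' The baseline geometry shipped with the package (anterior radius 8.08 mm,
#' asphericity -0.22; posterior radius 6.64 mm, asphericity -0.12; CCT
#' 585 microns; corneal diameter 12 mm; scleral sphere 25 mm).
#'
#' @param name preset name ("baseline").
#' @param cct optional target central thickness (microns); implemented as a
#'   thickness offset so both conic surfaces stay unchanged.
#' @return a \code{corneal_geometry}.
#' @export
geometry_preset <- function(name = "baseline", cct = NULL) {
  cfg <- .load_presets()$geometry
  if (!name %in% names(cfg)) stop("unknown geometry preset: ", name)
  p <- cfg[[name]]
  off <- if (is.null(cct)) 0 else cct - p$cct
  corneal_geometry(anterior = conic_surface(as.numeric(p$anterior_radius),
                                            as.numeric(p$anterior_asphericity)),
                   posterior = conic_surface(as.numeric(p$posterior_radius),
                                             as.numeric(p$posterior_asphericity)),
                   cct = as.numeric(p$cct), diameter = as.numeric(p$diameter),
                   limbus_width = as.numeric(p$limbus_width),
                   sclera_diameter = as.numeric(p$sclera_diameter),
                   thickness_offset = as.numeric(off))
}
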