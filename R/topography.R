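#' Synthesize a corneal topography export
#'
#' Emulates a topographer export for an axisymmetric cornea: a Cartesian
#' grid of anterior-surface elevation points plus a pachymetry map, with
#' optional Gaussian measurement noise. Output is reproducible for a fixed
#' seed.
#'
#' @param geometry a \code{corneal_geometry}.
#' @param noise_sd measurement noise standard deviation (microns), applied
#'   to both elevation and pachymetry.
#' @param seed integer RNG seed (NULL leaves the RNG state alone).
#' @param spacing grid spacing (mm).
#' @param aperture sampled diameter (mm); default the corneal aperture.
#' @return an object of class \code{topography_cloud}: a data.frame with
#'   columns \code{x_mm}, \code{y_mm}, \code{elevation_mm},
#'   \code{pachymetry_um} and attributes \code{noise_sd}, \code{seed}.
#' @export
synthesize_topography <- function(geometry, noise_sd = 0, seed = NULL,
                                  spacing = 0.25, aperture = NULL) {
  stopifnot(noise_sd >= 0, spacing > 0)
  if (is.null(aperture)) aperture <- geometry$diameter
  half <- aperture / 2
  gx <- seq(-half, half, by = spacing)
  pts <- expand.grid(x_mm = gx, y_mm = gx)
  r <- sqrt(pts$x_mm^2 + pts$y_mm^2)
  keep <- r <= half
  pts <- pts[keep, , drop = FALSE]
  r <- r[keep]
  elev <- conic_sag(r, geometry$anterior)
  pachy <- corneal_thickness(r, geometry) * 1e3
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (noise_sd > 0) {
    elev <- elev + stats::rnorm(length(r), sd = noise_sd * 1e-3)
    pachy <- pachy + stats::rnorm(length(r), sd = noise_sd)
  }
  out <- data.frame(x_mm = pts$x_mm, y_mm = pts$y_mm,
                    elevation_mm = elev, pachymetry_um = pachy)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("topography_cloud", "data.frame")
  out
}

#' Read / write topography clouds as CSV
#'
#' Plain CSV with columns \code{x_mm}, \code{y_mm}, \code{elevation_mm},
#' \code{pachymetry_um}.
#'
#' @param cloud a \code{topography_cloud} (or compatible data.frame).
#' @param file path.
#' @return \code{read_topography} returns a \code{topography_cloud}.
#' @export
write_topography <- function(cloud, file) {
  utils::write.csv(as.data.frame(cloud)[, c("x_mm", "y_mm", "elevation_mm",
                                            "pachymetry_um")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_topography
#' @export
read_topography <- function(file) {
  out <- utils::read.csv(file)
  need <- c("x_mm", "y_mm", "elevation_mm", "pachymetry_um")
  if (!all(need %in% names(out)))
    stop("topography file lacks columns: ",
         paste(setdiff(need, names(out)), collapse = ", "))
  class(out) <- c("topography_cloud", "data.frame")
  out
}

#' Recover conic parameters from a topography cloud
#'
#' Least-squares fit of the anterior conic (radius and asphericity) and the
#' central thickness from an elevation + pachymetry cloud. The conic sag
#' relation is linear in the parameters after rearrangement,
#' \code{r^2 = 2 R z - (1 + Q) z^2}, so the fit is an ordinary linear least
#' squares; the CCT is the intercept of a quadratic-in-r^2 fit of the
#' pachymetry map. Noise-free input is recovered exactly (to numerical
#' precision).
#'
#' @param cloud a \code{topography_cloud}.
#' @return list with \code{anterior} (a \code{conic_surface}), \code{cct}
#'   (microns) and the fit RMS (mm).
#' @export
recover_geometry <- function(cloud) {
  if (nrow(cloud) < 100)
    stop("too few points for a stable fit (need >= 100)")
  r2 <- cloud$x_mm^2 + cloud$y_mm^2
  z <- cloud$elevation_mm
  use <- z > 1e-9
  if (sum(use) < 50) stop("degenerate cloud: no off-axis elevation")
  X <- cbind(2 * z[use], -z[use]^2)
  qrX <- qr(X)
  if (qrX$rank < 2) stop("degenerate cloud: rank-deficient conic fit")
  cf <- qr.coef(qrX, r2[use])
  R <- cf[1]; Q <- cf[2] - 1
  if (!is.finite(R) || R <= 0) stop("degenerate cloud: non-physical radius")
  surf <- conic_surface(R = unname(R), Q = unname(Q))
  rms <- sqrt(mean((conic_sag(sqrt(r2), surf) - z)^2))
  # CCT from a central quadratic-in-r^2 fit: the global thickness profile
  # is not polynomial, so the intercept is taken from the central 2 mm
  ctr <- r2 <= 4
  if (sum(ctr) < 20) ctr <- rank(r2) <= max(20, 0.2 * length(r2))
  pfit <- stats::lm(cloud$pachymetry_um[ctr] ~ r2[ctr] + I(r2[ctr]^2))
  list(anterior = surf, cct = unname(stats::coef(pfit)[1]), rms = rms)
}
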