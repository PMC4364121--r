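#' Gasser-Holzapfel-Ogden material parameters
#'
#' Parameter container for the anisotropic hyperelastic strain-energy
#' function used for cornea and limbus: an isotropic neo-Hookean ground
#' matrix of modulus \code{C10}, a volumetric term controlled by \code{D}
#' (with \code{D = 0} meaning incompressible, enforced through a volumetric
#' penalty of bulk modulus \code{bulk_factor * C10}), and \code{N} dispersed
#' collagen fiber families of stiffness \code{k1}, exponential coefficient
#' \code{k2} and dispersion \code{kappa}. The fiber strain is
#' \code{E = kappa*(I1bar - 3) + (1 - 3*kappa)*(I4bar - 1)} and enters the
#' energy only through its Macaulay bracket \code{<E> = max(E, 0)}: fibers
#' carry tension only. \code{kappa = 0} means perfectly aligned fibers,
#' \code{kappa = 1/3} an isotropic fiber distribution. All families share
#' the same \code{k1}, \code{k2}, \code{kappa}.
#'
#' @param C10 ground-matrix shear-like modulus (MPa), positive.
#' @param D compressibility parameter (1/MPa); 0 selects the incompressible
#'   penalty treatment.
#' @param k1 fiber stiffness (MPa), non-negative.
#' @param k2 fiber exponential coefficient (dimensionless), positive.
#' @param kappa fiber dispersion, in [0, 1/3].
#' @param fiber_directions N x 3 matrix of unit reference fiber directions
#'   (default: two orthogonal in-plane families along e1 and e2).
#' @param bulk_factor penalty bulk modulus as a multiple of \code{C10} used
#'   when \code{D = 0} (default 1000).
#' @param cap overflow guard: an error is raised when \code{k2*<E>^2}
#'   exceeds this value (default 50).
#' @return an object of class \code{gho_params}.
#' @export
gho_params <- function(C10, D = 0, k1 = 0, k2 = 1, kappa = 0,
                       fiber_directions = rbind(c(1, 0, 0), c(0, 1, 0)),
                       bulk_factor = 1000, cap = .default_cap) {
  stopifnot(C10 > 0, k1 >= 0, k2 > 0, kappa >= 0, kappa <= 1 / 3 + 1e-12,
            D >= 0, bulk_factor > 0)
  fiber_directions <- rbind(fiber_directions)
  nrm <- sqrt(rowSums(fiber_directions^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("fiber directions must be unit vectors")
  structure(list(C10 = C10, D = D, k1 = k1, k2 = k2, kappa = kappa,
                 fiber_directions = fiber_directions,
                 bulk_factor = bulk_factor, cap = cap),
            class = "gho_params")
}

#' Yeoh material parameters (sclera)
#'
#' Isotropic hyperelastic reduced-polynomial model
#' \code{U = sum_i Ci0 (I1bar - 3)^i + sum_i (1/Di) (Jel - 1)^(2i)}.
#' When all \code{Di} are zero the volumetric part is replaced by a penalty
#' of bulk modulus \code{bulk_factor * C10}.
#'
#' @param C10,C20,C30 isotropic coefficients (MPa); \code{C10} positive.
#' @param D1,D2,D3 compressibility coefficients (1/MPa).
#' @param bulk_factor penalty bulk multiple of \code{C10} when all Di = 0.
#' @return an object of class \code{yeoh_params}.
#' @export
yeoh_params <- function(C10, C20 = 0, C30 = 0, D1 = 0, D2 = 0, D3 = 0,
                        bulk_factor = 1000) {
  stopifnot(C10 > 0, D1 >= 0, D2 >= 0, D3 >= 0)
  structure(list(C10 = C10, C20 = C20, C30 = C30,
                 D1 = D1, D2 = D2, D3 = D3, bulk_factor = bulk_factor),
            class = "yeoh_params")
}

#' @export
print.gho_params <- function(x, ...) {
  cat("Gasser-Holzapfel-Ogden material\n")
  cat(sprintf("  C10 = %g MPa, D = %g 1/MPa%s\n", x$C10, x$D,
              if (x$D == 0) sprintf(" (incompressible, penalty bulk %g MPa)",
                                    x$bulk_factor * x$C10) else ""))
  cat(sprintf("  k1 = %g MPa, k2 = %g, kappa = %g, %d fiber families\n",
              x$k1, x$k2, x$kappa, nrow(x$fiber_directions)))
  invisible(x)
}

#' @export
print.yeoh_params <- function(x, ...) {
  cat("Yeoh material\n")
  cat(sprintf("  Ci0 = (%g, %g, %g) MPa, Di = (%g, %g, %g) 1/MPa\n",
              x$C10, x$C20, x$C30, x$D1, x$D2, x$D3))
  invisible(x)
}

# pack a parameter object into the (model, par, fibered) form the C++
# kernels consume
.mat_pack <- function(params) {
  if (inherits(params, "gho_params")) {
    list(model = 1L,
         par = c(params$C10, params$k1, params$k2, params$kappa, params$D,
                 if (params$D == 0) params$bulk_factor * params$C10 else 0),
         fibered = 1L, cap = params$cap)
  } else if (inherits(params, "yeoh_params")) {
    list(model = 2L,
         par = c(params$C10, params$C20, params$C30,
                 params$D1, params$D2, params$D3,
                 if (params$D1 == 0 && params$D2 == 0 && params$D3 == 0)
                   params$bulk_factor * params$C10 else 0),
         fibered = 0L, cap = .default_cap)
  } else stop("unknown material parameter class")
}

#' Named material presets
#'
#' Returns the corneal material parameter sets shipped with the package.
#' Presets "A", "B" and "C" are the low, intermediate and large stiffness
#' corneal materials (they differ only in the fiber stiffness k1); preset
#' "sclera" is a Yeoh set. The corneal presets are read from the
#' declarative config at \code{system.file("extdata", "presets.yaml",
#' package = "tonosim")}. The scleral coefficients are representative
#' literature-range values, not patient-matched; they are configurable and
#' should be treated as a modelling default.
#'
#' @param name one of "A", "B", "C", "sclera".
#' @return a \code{gho_params} or \code{yeoh_params} object.
#' @export
material_preset <- function(name) {
  cfg <- .load_presets()$materials
  if (!name %in% names(cfg))
    stop("unknown material preset: ", name)
  m <- cfg[[name]]
  if (identical(m$type, "gho")) {
    gho_params(C10 = m$C10, D = m$D, k1 = m$k1, k2 = m$k2, kappa = m$kappa)
  } else {
    yeoh_params(C10 = m$C10, C20 = m$C20, C30 = m$C30,
                D1 = m$D1, D2 = m$D2, D3 = m$D3)
  }
}

.presets_cache <- new.env(parent = emptyenv())

.load_presets <- function() {
  if (is.null(.presets_cache$cfg)) {
    path <- system.file("extdata", "presets.yaml", package = "tonosim")
    .presets_cache$cfg <- yaml::read_yaml(path)
  }
  .presets_cache$cfg
}

#' Kinematic state of a material point
#'
#' Builds the deformation state consumed by the strain-energy functions:
#' the elastic volume ratio \code{J = det F}, the first modified invariant
#' \code{I1bar = tr(J^(-2/3) F'F)} and, per fiber family a, the modified
#' pseudo-invariant \code{I4bar = a' (J^(-2/3) F'F) a} (the squared fiber
#' stretch of the isochoric deformation).
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param fiber_directions N x 3 unit reference fiber directions.
#' @return an object of class \code{deformation_state}.
#' @export
deformation_state <- function(F,
                              fiber_directions = rbind(c(1, 0, 0),
                                                       c(0, 1, 0))) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("singular deformation: det F must be positive")
  fiber_directions <- rbind(fiber_directions)
  C <- crossprod(F)
  Cb <- J^(-2 / 3) * C
  I4 <- apply(fiber_directions, 1, function(a) drop(a %*% Cb %*% a))
  structure(list(F = F, J_el = J, I1_bar = sum(diag(Cb)),
                 I4_bar = as.numeric(I4),
                 fiber_directions = fiber_directions),
            class = "deformation_state")
}

#' Tension-only fiber strain
#'
#' The strain measure driving one fiber family,
#' \code{E = kappa*(I1bar - 3) + (1 - 3*kappa)*(I4bar - 1)}, together with
#' its Macaulay bracket \code{<E> = max(E, 0)}. The anisotropic energy
#' contribution vanishes whenever \code{E <= 0}: collagen fibers buckle
#' under compression and only support tension.
#'
#' @param state a \code{deformation_state}.
#' @param params a \code{gho_params} object.
#' @param family fiber family index.
#' @return list with \code{value} (the bracketed strain) and \code{raw}.
#' @export
fiber_strain <- function(state, params, family = 1) {
  if (family < 1 || family > length(state$I4_bar))
    stop("fiber family index out of range")
  E <- params$kappa * (state$I1_bar - 3) +
    (1 - 3 * params$kappa) * (state$I4_bar[family] - 1)
  list(value = max(E, 0), raw = E)
}

.state_point <- function(state, params, part = 0L, want_tangent = FALSE) {
  pk <- .mat_pack(params)
  fib <- if (pk$fibered)
    state$fiber_directions else matrix(0, 0, 3)
  cpp_material_point(state$F, pk$model, pk$par, fib, as.integer(part),
                     pk$cap, want_tangent)
}

#' Strain-energy density of the G-H-O model
#'
#' @inheritParams fiber_strain
#' @return energy density (MPa); zero at the reference configuration.
#' @export
gho_energy <- function(state, params) {
  stopifnot(inherits(params, "gho_params"))
  .state_point(state, params)$energy
}

#' Stress of the G-H-O model
#'
#' Second Piola-Kirchhoff stress \code{S = 2 dU/dC} evaluated analytically,
#' and the Cauchy stress \code{sigma = F S F' / J}.
#'
#' @inheritParams fiber_strain
#' @return an object of class \code{stress_result} with fields
#'   \code{cauchy}, \code{pk2}, \code{energy} (all in MPa).
#' @export
gho_stress <- function(state, params) {
  stopifnot(inherits(params, "gho_params"))
  r <- .state_point(state, params)
  structure(list(cauchy = r$cauchy, pk2 = r$pk2, energy = r$energy),
            class = "stress_result")
}

#' Material tangent of the G-H-O model
#'
#' Fourth-order tangent \code{CC = 2 dS/dC} in 6x6 Voigt form, order
#' (11, 22, 33, 12, 13, 23); column entries multiply Green-Lagrange strain
#' increments with engineering shear. Possesses major symmetry.
#'
#' @inheritParams fiber_strain
#' @return 6x6 matrix (MPa).
#' @export
gho_tangent <- function(state, params) {
  stopifnot(inherits(params, "gho_params"))
  .state_point(state, params, want_tangent = TRUE)$tangent
}

#' Energy and stress of the Yeoh model
#'
#' @param state a \code{deformation_state}.
#' @param params a \code{yeoh_params} object.
#' @return an object of class \code{stress_result}.
#' @export
yeoh_energy_stress <- function(state, params) {
  stopifnot(inherits(params, "yeoh_params"))
  r <- .state_point(state, params)
  structure(list(cauchy = r$cauchy, pk2 = r$pk2, energy = r$energy),
            class = "stress_result")
}

#' Yeoh material tangent
#'
#' @inheritParams yeoh_energy_stress
#' @return 6x6 Voigt tangent (same convention as \code{\link{gho_tangent}}).
#' @export
yeoh_tangent <- function(state, params) {
  stopifnot(inherits(params, "yeoh_params"))
  .state_point(state, params, want_tangent = TRUE)$tangent
}

# deviatoric Cauchy stress under exact incompressibility (J = 1 enforced by
# the caller); pressure is eliminated by the caller's traction conditions
.incomp_cauchy <- function(F, params) {
  st <- deformation_state(F, params$fiber_directions)
  .state_point(st, params, part = 1L)$cauchy
}

#' Uniaxial stress-stretch response
#'
#' Incompressible uniaxial extension along the first fiber direction: for
#' each axial stretch the two transverse stretches are solved from
#' incompressibility and zero lateral traction, and the axial Cauchy stress
#' is returned. Stretches below 1 are admitted (fibers then deactivate
#' through the Macaulay bracket).
#'
#' @param params a \code{gho_params} object.
#' @param stretch vector of axial stretches.
#' @return data.frame with columns \code{stretch}, \code{stress} (MPa,
#'   Cauchy) and \code{lateral} (the solved in-plane transverse stretch).
#' @export
uniaxial_response <- function(params, stretch = seq(1, 1.1, by = 0.005)) {
  stopifnot(inherits(params, "gho_params"))
  res <- vapply(stretch, function(lam) {
    resid <- function(l2) {
      F <- diag(c(lam, l2, 1 / (lam * l2)))
      s <- .incomp_cauchy(F, params)
      s[2, 2] - s[3, 3]
    }
    safe <- function(l2) tryCatch(resid(l2), error = function(e) NA_real_)
    # bracket the lateral stretch near the symmetric guess; the stiff
    # exponential fibers overflow far from it, so scan outward cautiously
    l0 <- lam^(-0.5)
    grid <- l0 * seq(0.93, 1.08, by = 0.005)
    vals <- vapply(grid, safe, numeric(1))
    ok <- which(is.finite(vals))
    sgn <- which(diff(sign(vals[ok])) != 0)
    if (!length(sgn)) {
      root_at <- which(vals[ok] == 0)
      if (length(root_at)) sgn <- root_at[1]
      else stop("lateral-stretch solve failed at stretch ", signif(lam, 6),
                ": no sign change in the bracket")
    }
    i <- ok[sgn[1]]
    sol <- stats::uniroot(resid, c(grid[i], grid[ok[sgn[1] + 1]]),
                          tol = 1e-12)
    l2 <- sol$root
    F <- diag(c(lam, l2, 1 / (lam * l2)))
    s <- .incomp_cauchy(F, params)
    c(s[1, 1] - s[3, 3], l2)
  }, numeric(2))
  data.frame(stretch = stretch, stress = res[1, ], lateral = res[2, ])
}

#' Spherical membrane inflation (apical rise curve)
#'
#' Uniform-stretch thin-membrane model of a corneal inflation test: a
#' spherical cap of radius \code{R_ref} and thickness \code{t_ref}, clamped
#' at a ring of radius \code{ring_radius}, is inflated. At equibiaxial
#' stretch \code{lambda} the cap area scales by \code{lambda^2} and the
#' thickness by \code{1/lambda^2} (incompressibility); the deformed cap
#' through the fixed ring gives the apex height, and the Laplace relation
#' \code{P = 2 sigma t / rho} links pressure to the equibiaxial Cauchy
#' stress of the material. For each requested pressure the stretch is
#' solved and the apical rise (apex height change, mm) returned.
#'
#' @param params a \code{gho_params} object.
#' @param R_ref reference cap radius of curvature (mm).
#' @param t_ref reference thickness (mm).
#' @param pressure_mmhg pressures (mmHg).
#' @param ring_radius clamped ring radius (mm).
#' @return data.frame with columns \code{pressure_mmhg}, \code{stretch},
#'   \code{rise_mm}.
#' @export
membrane_inflation <- function(params, R_ref = 8.08, t_ref = 0.585,
                               pressure_mmhg = seq(0, 30, by = 2),
                               ring_radius = 5.66) {
  stopifnot(inherits(params, "gho_params"), R_ref > ring_radius)
  if (t_ref / R_ref >= 0.15)
    warning("thickness/radius ratio outside the thin-shell regime")
  a <- ring_radius
  h0 <- R_ref - sqrt(R_ref^2 - a^2)
  A0 <- pi * (a^2 + h0^2)  # spherical cap area = 2 pi rho h = pi (a^2 + h^2)
  geom <- function(lam) {
    h <- sqrt(max(lam^2 * A0 / pi - a^2, 0))
    rho <- (a^2 + h^2) / (2 * h)
    c(h = h, rho = rho)
  }
  sig_eq <- function(lam) {
    F <- diag(c(lam, lam, lam^-2))
    s <- .incomp_cauchy(F, params)
    s[1, 1] - s[3, 3]
  }
  Pfun <- function(lam) {
    g <- geom(lam)
    2 * sig_eq(lam) * (t_ref / lam^2) / g["rho"]
  }
  out <- vapply(pressure_mmhg, function(p_mmhg) {
    p <- mmhg_to_mpa(p_mmhg)
    if (p <= 0) return(c(1, 0))
    hi <- 1.0005
    while (Pfun(hi) < p) {
      hi <- hi * 1.02
      if (hi > 2) stop("membrane inflation: no equilibrium below stretch 2 ",
                       "(material instability pressure exceeded)")
    }
    lam <- stats::uniroot(function(l) Pfun(l) - p, c(1 + 1e-12, hi),
                          tol = 1e-12)$root
    c(lam, geom(lam)[["h"]] - h0)
  }, numeric(2))
  data.frame(pressure_mmhg = pressure_mmhg, stretch = out[1, ],
             rise_mm = out[2, ])
}
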