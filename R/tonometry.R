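#' Air-puff load profile
#'
#' Parametric model of the metered collimated air pulse of a non-contact
#' tonometer: a temporal pulse of given peak pressure and duration, and a
#' radially symmetric spatial footprint. The default temporal shape is
#' \code{sin^2(pi t / duration)}; the default spatial shape is a flat-top
#' super-Gaussian \code{exp(-(r/r0)^m)} with \code{r0} calibrated so that
#' the region at >= 90 percent of the instantaneous peak has exactly the
#' footprint diameter.
#'
#' @param peak_pressure peak jet pressure (Pa), default 25000.
#' @param duration pulse duration (ms), default 30.
#' @param footprint_diameter diameter (mm) of the >= 90-percent-of-peak
#'   region, default 3.
#' @param temporal_shape currently "sin2".
#' @param spatial_shape currently "supergaussian".
#' @param spatial_exponent super-Gaussian exponent m (m = 2 is a Gaussian,
#'   larger m a flatter top), default 8.
#' @return an object of class \code{air_puff_profile}.
#' @export
air_puff_profile <- function(peak_pressure = 25000, duration = 30,
                             footprint_diameter = 3,
                             temporal_shape = "sin2",
                             spatial_shape = "supergaussian",
                             spatial_exponent = 8) {
  stopifnot(peak_pressure >= 0, duration > 0, footprint_diameter > 0,
            spatial_exponent > 0)
  temporal_shape <- match.arg(temporal_shape, "sin2")
  spatial_shape <- match.arg(spatial_shape, "supergaussian")
  r0 <- (footprint_diameter / 2) / (-log(0.9))^(1 / spatial_exponent)
  structure(list(peak_pressure = peak_pressure, duration = duration,
                 footprint_diameter = footprint_diameter,
                 temporal_shape = temporal_shape,
                 spatial_shape = spatial_shape,
                 spatial_exponent = spatial_exponent, r0 = r0),
            class = "air_puff_profile")
}

#' @export
print.air_puff_profile <- function(x, ...) {
  cat(sprintf("Air puff: peak %g Pa, duration %g ms, %g mm footprint (%s / %s)\n",
              x$peak_pressure, x$duration, x$footprint_diameter,
              x$temporal_shape, x$spatial_shape))
  invisible(x)
}

#' Temporal pressure of the puff
#'
#' Smooth (C1) pulse, zero at t = 0 and t = duration, attaining the peak
#' pressure at mid-pulse. Times outside the support return zero with a
#' warning.
#'
#' @param t time (ms).
#' @param profile an \code{air_puff_profile}.
#' @return pressure (Pa).
#' @export
temporal_pressure <- function(t, profile = air_puff_profile()) {
  out <- numeric(length(t))
  inside <- t >= 0 & t <= profile$duration
  if (any(!inside))
    warning("time outside the pulse support; returning zero pressure")
  out[inside] <- profile$peak_pressure *
    sin(pi * t[inside] / profile$duration)^2
  out
}

#' Spatial pressure fraction of the puff
#'
#' Radially symmetric footprint as a fraction of the instantaneous peak:
#' 1 at the apex, monotone non-increasing in r, and >= 0.9 exactly on the
#' footprint diameter.
#'
#' @param r radial coordinate (mm), non-negative.
#' @param profile an \code{air_puff_profile}.
#' @return fraction in [0, 1].
#' @export
spatial_pressure <- function(r, profile = air_puff_profile()) {
  .spatial_shape(r, profile)$value
}

# value and radial derivative of the spatial footprint (vectorized)
.spatial_shape <- function(r, profile) {
  m <- profile$spatial_exponent
  r0 <- profile$r0
  v <- exp(-(abs(r) / r0)^m)
  list(value = v, deriv = -m * abs(r)^(m - 1) / r0^m * v)
}

#' Simulate a non-contact tonometry test
#'
#' End-to-end pipeline: recover the stress-free configuration from the
#' imaged geometry at the given IOP, pressurize it back to the IOP (the
#' pre-puff state a device camera sees), then traverse the rising half of
#' the air pulse quasi-statically up to the peak, recording the apical
#' displacement, apex stress-stretch paths and applanation. Only the
#' rising phase is traversed: the quantity of interest is the maximum
#' apical displacement, and the elastic model makes the unloading path a
#' mirror image.
#'
#' @param geometry a \code{corneal_geometry}.
#' @param material corneal material: a \code{gho_params} or a preset name
#'   ("A", "B", "C"). The limbus uses the same material.
#' @param iop_mmhg intraocular pressure (mmHg).
#' @param profile an \code{air_puff_profile}.
#' @param settings a \code{solver_settings}.
#' @param sclera scleral material (a \code{yeoh_params}).
#' @param n_meridian,n_thickness mesh densities.
#' @param n_puff_steps number of time steps over the rising phase.
#' @param prestress run the zero-pressure algorithm first (default TRUE).
#' @param prestress_epsilon tolerance of the zero-pressure algorithm (mm).
#' @param cache optional environment used to reuse prestress results
#'   across runs sharing (geometry, material, IOP, mesh).
#' @return an object of class \code{tonometry_result}.
#' @export
simulate_tonometry <- function(geometry = geometry_preset("baseline"),
                               material = "B", iop_mmhg = 12,
                               profile = air_puff_profile(),
                               settings = solver_settings(),
                               sclera = material_preset("sclera"),
                               n_meridian = 40, n_thickness = 3,
                               n_puff_steps = 24, prestress = TRUE,
                               prestress_epsilon = 1e-4, cache = NULL) {
  mat_name <- if (is.character(material)) material else "custom"
  if (is.character(material)) material <- material_preset(material)
  stopifnot(inherits(material, "gho_params"), inherits(sclera, "yeoh_params"))
  materials <- list(cornea = material, limbus = material, sclera = sclera)
  mesh <- generate_mesh(geometry, n_meridian, n_thickness)

  pre <- NULL
  if (prestress) {
    key <- NULL
    if (is.environment(cache)) {
      key <- paste(collapse = "|", c(
        vapply(unlist(geometry[c("cct", "diameter", "limbus_width",
                                 "sclera_diameter", "thickness_offset")]),
               format, character(1)),
        format(unlist(geometry$anterior)), format(unlist(geometry$posterior)),
        mat_name, format(material$k1), format(iop_mmhg),
        n_meridian, n_thickness))
      pre <- cache[[key]]
    }
    if (is.null(pre)) {
      pre <- prestress_mesh(mesh, materials, iop_mmhg, settings,
                            epsilon = prestress_epsilon)
      if (!is.null(key)) cache[[key]] <- pre
    }
    mesh_sim <- pre$mesh_init
    state0 <- pre$solution
  } else {
    mesh_sim <- mesh
    state0 <- solve_static(mesh, materials, load_case(iop_mmhg = iop_mmhg),
                           settings)
  }

  # rising phase of the pulse, ending at the peak
  tgrid <- seq(0, profile$duration / 2, length.out = n_puff_steps + 1)
  qgrid <- ifelse(tgrid == 0, 0, temporal_pressure(tgrid, profile))
  loads <- lapply(qgrid[-1], function(q)
    load_case(iop_mmhg = iop_mmhg, puff_pa = q, profile = profile))
  sols <- c(list(state0),
            solve_path(mesh_sim, materials, loads, settings, state = state0))

  apex0 <- probe(state0, "anterior_apex")
  disp <- vapply(sols, function(s)
    probe(s, "anterior_apex")$displacement[2] - apex0$displacement[2],
    numeric(1))
  pa <- lapply(sols, probe, location = "anterior_apex")
  pp <- lapply(sols, probe, location = "posterior_apex")
  paths <- data.frame(
    time_ms = tgrid, puff_pa = qgrid,
    apex_displacement_mm = disp,
    anterior_sigma_MPa = vapply(pa, `[[`, numeric(1), "sigma_merid"),
    anterior_lambda = vapply(pa, `[[`, numeric(1), "lambda_merid"),
    posterior_sigma_MPa = vapply(pp, `[[`, numeric(1), "sigma_merid"),
    posterior_lambda = vapply(pp, `[[`, numeric(1), "lambda_merid"))
  kappa <- vapply(sols, function(s) .apex_curvature(mesh_sim, s$U), numeric(1))

  res <- structure(list(
    time_ms = tgrid, puff_pa = qgrid, apex_displacement_mm = disp,
    max_apical_displacement = max(disp),
    apex_curvature = kappa,
    apex_paths = paths,
    material = mat_name, material_params = material,
    iop_mmhg = iop_mmhg, profile = profile,
    geometry = geometry, mesh = mesh_sim,
    prestress = if (prestress) pre$result else NULL,
    solutions = sols),
    class = "tonometry_result")
  res$first_applanation_time <- detect_applanation(res)
  ia <- attr(res$first_applanation_time, "step")
  res$snapshots <- list(
    first_applanation = if (!is.na(res$first_applanation_time))
      sols[[ia]] else NULL,
    max_displacement = sols[[which.max(disp)]])
  res
}

# meridional curvature (1/mm) of the deformed anterior surface at the
# apex: even quadratic fit over the central region
.apex_curvature <- function(mesh, U, radius = 0.75) {
  ids <- mesh$tags$anterior
  r <- mesh$nodes[ids, 1] + U[ids, 1]
  z <- mesh$nodes[ids, 2] + U[ids, 2]
  keep <- abs(r) <= radius
  if (sum(keep) < 3) stop("too few anterior nodes for a curvature fit")
  cf <- stats::lsfit(r[keep]^2, z[keep])$coefficients
  2 * unname(cf[2])
}

#' First applanation time
#'
#' The earliest time at which the deformed anterior surface is flat at the
#' apex: the meridional curvature of the central anterior surface crosses
#' zero (tolerance 1e-3 1/mm). Returns NA (with no error) if the cornea
#' never applanates; the crossing time is interpolated linearly between
#' the stored time steps.
#'
#' @param result a \code{tonometry_result}.
#' @param tol curvature tolerance (1/mm).
#' @return applanation time (ms) with attribute \code{step} (index of the
#'   first stored step at or past applanation), or NA.
#' @export
detect_applanation <- function(result, tol = 1e-3) {
  k <- result$apex_curvature
  t <- result$time_ms
  idx <- which(k <= tol)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1 || k[i] >= 0) {
    out <- t[i]
  } else {
    # linear interpolation of the zero crossing
    out <- t[i - 1] + (t[i] - t[i - 1]) * (k[i - 1] - 0) / (k[i - 1] - k[i])
  }
  attr(out, "step") <- i
  out
}

#' Apex stress-stretch paths
#'
#' Trajectories of the normal Cauchy stress vs stretch along the
#' meridional direction for the anterior apex point and its posterior
#' mirror, from the pre-puff state to the pulse peak.
#'
#' @param result a \code{tonometry_result}.
#' @return data.frame with one row per stored time step.
#' @export
extract_apex_paths <- function(result) {
  if (is.null(result$apex_paths)) stop("no probe history stored")
  result$apex_paths
}

#' Write a tonometry run as CSV
#'
#' Fixed schema: time_ms, apex_displacement_mm, anterior_sigma_MPa,
#' anterior_lambda, posterior_sigma_MPa, posterior_lambda.
#'
#' @param result a \code{tonometry_result}.
#' @param file path.
#' @export
write_tonometry <- function(result, file) {
  utils::write.csv(result$apex_paths[, c(
    "time_ms", "apex_displacement_mm", "anterior_sigma_MPa",
    "anterior_lambda", "posterior_sigma_MPa", "posterior_lambda")],
    file, row.names = FALSE)
  invisible(file)
}

#' @export
print.tonometry_result <- function(x, ...) {
  cat("Non-contact tonometry simulation\n")
  cat(sprintf("  material %s, IOP %g mmHg, CCT %g um\n",
              x$material, x$iop_mmhg, central_thickness(x$geometry)))
  cat(sprintf("  max apical displacement: %.4f mm\n",
              x$max_apical_displacement))
  if (!is.na(x$first_applanation_time))
    cat(sprintf("  first applanation at %.2f ms\n",
                as.numeric(x$first_applanation_time)))
  else cat("  no applanation\n")
  invisible(x)
}

#' @export
summary.tonometry_result <- function(object, ...) {
  pp <- object$apex_paths
  n <- nrow(pp)
  cat("Non-contact tonometry simulation\n")
  cat(sprintf("  material %s, IOP %g mmHg, CCT %g um, puff peak %g Pa\n",
              object$material, object$iop_mmhg,
              central_thickness(object$geometry),
              object$profile$peak_pressure))
  cat(sprintf("  max apical displacement %.4f mm at t = %.1f ms\n",
              object$max_apical_displacement,
              object$time_ms[which.max(object$apex_displacement_mm)]))
  cat(sprintf("  first applanation: %s\n",
              if (is.na(object$first_applanation_time)) "none" else
                sprintf("%.2f ms", as.numeric(object$first_applanation_time))))
  cat(sprintf("  pre-puff apex:  anterior sigma %+.4f MPa (lambda %.4f), posterior %+.4f MPa (lambda %.4f)\n",
              pp$anterior_sigma_MPa[1], pp$anterior_lambda[1],
              pp$posterior_sigma_MPa[1], pp$posterior_lambda[1]))
  cat(sprintf("  peak-puff apex: anterior sigma %+.4f MPa (lambda %.4f), posterior %+.4f MPa (lambda %.4f)\n",
              pp$anterior_sigma_MPa[n], pp$anterior_lambda[n],
              pp$posterior_sigma_MPa[n], pp$posterior_lambda[n]))
  invisible(object)
}

#' Plot a tonometry result
#'
#' Two panels: apical displacement vs time over the rising pulse, and the
#' apex stress-stretch paths (anterior and posterior points).
#'
#' @param x a \code{tonometry_result}.
#' @param ... passed to \code{plot}.
#' @export
plot.tonometry_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_ms, x$apex_displacement_mm, type = "b", pch = 19,
                 xlab = "time (ms)", ylab = "apex displacement (mm)",
                 main = sprintf("material %s, IOP %g mmHg", x$material,
                                x$iop_mmhg), ...)
  if (!is.na(x$first_applanation_time))
    graphics::abline(v = as.numeric(x$first_applanation_time), lty = 2)
  pp <- x$apex_paths
  rngx <- range(pp$anterior_lambda, pp$posterior_lambda)
  rngy <- range(pp$anterior_sigma_MPa, pp$posterior_sigma_MPa)
  graphics::plot(pp$anterior_lambda, pp$anterior_sigma_MPa, type = "b",
                 pch = 6, xlim = rngx, ylim = rngy,
                 xlab = "meridional stretch", ylab = "Cauchy stress (MPa)",
                 main = "apex paths")
  graphics::lines(pp$posterior_lambda, pp$posterior_sigma_MPa, type = "b",
                  pch = 0)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", pch = c(6, 0), bty = "n",
                   legend = c("anterior apex", "posterior apex"))
  invisible(x)
}
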