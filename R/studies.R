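#' Parametric study grid
#'
#' Defines a set of tonometry runs over IOP levels, materials and central
#' corneal thickness values. Two named grids reproduce the study design:
#' \describe{
#'   \item{"iop_study"}{IOP in \{10, 12, 19, 28\} mmHg for materials A, B,
#'     C at the baseline CCT (585 um).}
#'   \item{"cct_study"}{CCT from 300 to 600 um in 50 um steps, for
#'     material C at IOP \{10, 19, 28\} mmHg and for materials A and B at
#'     IOP 19 mmHg.}
#' }
#'
#' @param preset optional named grid ("iop_study", "cct_study").
#' @param iop_levels IOP values (mmHg).
#' @param materials material preset names.
#' @param cct_levels CCT values (microns).
#' @param geometry geometry preset name.
#' @param combos optional explicit data.frame(material, iop_mmhg, cct_um)
#'   overriding the factorial expansion.
#' @return an object of class \code{study_grid}.
#' @export
study_grid <- function(preset = NULL, iop_levels = 12, materials = "B",
                       cct_levels = 585, geometry = "baseline",
                       combos = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("iop_study", "cct_study"))
    if (preset == "iop_study") {
      combos <- expand.grid(material = c("A", "B", "C"),
                            iop_mmhg = c(10, 12, 19, 28),
                            cct_um = 585, stringsAsFactors = FALSE)
    } else {
      curves <- rbind(
        data.frame(material = "C", iop_mmhg = c(10, 19, 28)),
        data.frame(material = c("A", "B"), iop_mmhg = 19))
      combos <- merge(curves, data.frame(cct_um = seq(300, 600, by = 50)))
    }
  }
  if (is.null(combos)) {
    stopifnot(length(iop_levels) > 0, length(materials) > 0,
              length(cct_levels) > 0)
    combos <- expand.grid(material = materials, iop_mmhg = iop_levels,
                          cct_um = cct_levels, stringsAsFactors = FALSE)
  }
  combos <- combos[order(combos$material, combos$iop_mmhg, combos$cct_um), ]
  rownames(combos) <- NULL
  structure(list(combos = combos, geometry = geometry),
            class = "study_grid")
}

#' @export
print.study_grid <- function(x, ...) {
  cat(sprintf("Study grid: %d runs on geometry '%s'\n",
              nrow(x$combos), x$geometry))
  print(utils::head(x$combos, 10))
  if (nrow(x$combos) > 10) cat("  ...\n")
  invisible(x)
}

#' Run a study grid
#'
#' Executes one tonometry simulation per grid point and collects summary
#' rows. Failures are recorded per row (status column), not fatal. Output
#' is deterministic for a fixed configuration. Prestress results are
#' cached across rows sharing (geometry, material, IOP, mesh).
#'
#' @param grid a \code{study_grid}.
#' @param profile an \code{air_puff_profile}.
#' @param settings a \code{solver_settings}.
#' @param n_meridian,n_thickness,n_puff_steps passed to
#'   \code{\link{simulate_tonometry}}.
#' @param progress print one line per completed run.
#' @return data.frame with one row per run: the parameter echo, the
#'   maximum apical displacement (mm), first applanation time (ms),
#'   prestress iterations and status.
#' @export
run_grid <- function(grid, profile = air_puff_profile(),
                     settings = solver_settings(),
                     n_meridian = 40, n_thickness = 3, n_puff_steps = 24,
                     progress = FALSE) {
  stopifnot(inherits(grid, "study_grid"), nrow(grid$combos) > 0)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(grid$combos)), function(i) {
    cb <- grid$combos[i, ]
    out <- data.frame(material = cb$material, iop_mmhg = cb$iop_mmhg,
                      cct_um = cb$cct_um,
                      peak_pressure_pa = profile$peak_pressure,
                      duration_ms = profile$duration,
                      max_displacement_mm = NA_real_,
                      first_applanation_ms = NA_real_,
                      prestress_iterations = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch(
      simulate_tonometry(geometry_preset(grid$geometry, cct = cb$cct_um),
                         material = cb$material, iop_mmhg = cb$iop_mmhg,
                         profile = profile, settings = settings,
                         n_meridian = n_meridian,
                         n_thickness = n_thickness,
                         n_puff_steps = n_puff_steps, cache = cache),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- conditionMessage(res)
    } else {
      out$max_displacement_mm <- res$max_apical_displacement
      out$first_applanation_ms <- as.numeric(res$first_applanation_time)
      out$prestress_iterations <- res$prestress$iterations
    }
    if (progress)
      message(sprintf("  [%d/%d] %s IOP %g CCT %g -> %.4f mm", i,
                      nrow(grid$combos), cb$material, cb$iop_mmhg,
                      cb$cct_um, out$max_displacement_mm))
    out
  })
  do.call(rbind, rows)
}

# polynomial least squares with the shared fit-report contract
.fit_poly <- function(x, y, degree) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) <= degree)
    stop("degenerate design: need more distinct x values than the degree")
  if (stats::var(y) == 0) {
    # zero-variance target: slope(s) 0 and R^2 defined as 0 by convention
    coefs <- c(mean(y), rep(0, degree))
    return(structure(list(form = if (degree == 1) "linear" else
                            paste0("degree-", degree),
                          degree = degree, coefficients = coefs,
                          r_squared = 0, residuals = rep(0, length(y)),
                          fitted = rep(mean(y), length(y))),
                     class = "fit_report"))
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  res <- unname(stats::residuals(fit))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(form = if (degree == 1) "linear" else
                   paste0("degree-", degree),
                 degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = r2,
                 residuals = res,
                 fitted = unname(stats::fitted(fit))),
            class = "fit_report")
}

#' Linear fit of displacement vs IOP
#'
#' Ordinary least squares \code{y = b0 + b1 x}; on grid outputs the slope
#' is expected negative (displacement decreases with IOP). For a
#' zero-variance response the slope is 0 and R^2 is defined as 0.
#'
#' @param x predictor (e.g. IOP, mmHg); at least 3 points.
#' @param y response (e.g. maximum apical displacement, mm).
#' @return an object of class \code{fit_report} with coefficients
#'   (intercept first), \code{r_squared} and residuals.
#' @export
fit_linear <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  .fit_poly(x, y, 1)
}

#' Cubic fit of displacement vs CCT
#'
#' Degree-3 least-squares polynomial (intercept first in the coefficient
#' vector), with R^2.
#'
#' @param x predictor (e.g. CCT, microns); at least 5 points.
#' @param y response.
#' @return an object of class \code{fit_report}.
#' @export
fit_cubic <- function(x, y) {
  if (length(x) < 5) stop("need at least 5 points")
  .fit_poly(x, y, 3)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("%s least-squares fit: R^2 = %.6f\n", x$form, x$r_squared))
  cat("  coefficients (ascending powers):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Displacement-interval overlap across materials
#'
#' For each material, the interval [min, max] of maximum apical
#' displacement spanned over the IOP range, and the lengths of the
#' pairwise interval intersections. A non-empty A-B intersection means a
#' soft cornea at high IOP and a stiffer one at low IOP can produce the
#' same deformation amplitude, so a single puff test cannot separate
#' stiffness from IOP.
#'
#' @param results a \code{run_grid} results table (columns material,
#'   max_displacement_mm).
#' @param materials materials to analyse.
#' @return list with \code{intervals} (data.frame) and
#'   \code{intersections} (data.frame of pairs with intersection bounds
#'   and length).
#' @export
overlap_analysis <- function(results, materials = c("A", "B", "C")) {
  missing_m <- setdiff(materials, unique(results$material))
  if (length(missing_m))
    stop("results lack materials: ", paste(missing_m, collapse = ", "))
  iv <- do.call(rbind, lapply(materials, function(m) {
    d <- results$max_displacement_mm[results$material == m]
    d <- d[is.finite(d)]
    if (!length(d)) stop("no finite displacements for material ", m)
    data.frame(material = m, lo = min(d), hi = max(d))
  }))
  prs <- utils::combn(materials, 2, simplify = FALSE)
  inter <- do.call(rbind, lapply(prs, function(p) {
    a <- iv[iv$material == p[1], ]; b <- iv[iv$material == p[2], ]
    lo <- max(a$lo, b$lo); hi <- min(a$hi, b$hi)
    data.frame(pair = paste(p, collapse = "-"), lo = lo, hi = hi,
               length = max(0, hi - lo))
  }))
  list(intervals = iv, intersections = inter)
}
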