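#' Solver settings
#'
#' @param newton_tol relative residual tolerance of the Newton loop.
#' @param max_newton maximum Newton iterations per load level.
#' @param n_load_steps default number of load increments when ramping a
#'   load from scratch.
#' @param line_search backtracking line search on the residual norm.
#' @param max_bisect maximum recursive bisections of a failed increment.
#' @param step_cap trust-region-like cap (mm) on the largest nodal
#'   displacement increment of one Newton step; tames the near-singular
#'   tangent met while the central cornea snaps through applanation.
#' @param verbose print per-iteration diagnostics.
#' @return an object of class \code{solver_settings}.
#' @export
solver_settings <- function(newton_tol = 1e-8, max_newton = 60,
                            n_load_steps = 10, line_search = TRUE,
                            max_bisect = 10, step_cap = 0.4,
                            verbose = FALSE) {
  stopifnot(newton_tol > 0, max_newton >= 1, n_load_steps >= 1,
            step_cap > 0)
  structure(list(newton_tol = newton_tol, max_newton = max_newton,
                 n_load_steps = n_load_steps, line_search = line_search,
                 max_bisect = max_bisect, step_cap = step_cap,
                 verbose = verbose),
            class = "solver_settings")
}

#' Load case
#'
#' Loads applied to the eye model: the intraocular pressure acting as a
#' follower pressure on the whole interior (posterior) surface including
#' the sclera, and the air-puff jet acting on the anterior corneal surface
#' as a collimated axial traction with the spatial footprint of the puff
#' profile.
#'
#' @param iop_mmhg intraocular pressure (mmHg), non-negative.
#' @param puff_pa instantaneous jet peak pressure (Pa) at the apex.
#' @param profile an \code{air_puff_profile} providing the spatial shape.
#' @return an object of class \code{load_case}.
#' @export
load_case <- function(iop_mmhg = 0, puff_pa = 0, profile = NULL) {
  stopifnot(iop_mmhg >= 0)
  if (puff_pa != 0 && is.null(profile)) profile <- air_puff_profile()
  structure(list(iop_mmhg = iop_mmhg, puff_pa = puff_pa, profile = profile),
            class = "load_case")
}

# resolve region materials into packed kernel form
.pack_materials <- function(mesh, materials) {
  labs <- mesh$region_labels
  if (!all(labs %in% names(materials)))
    stop("materials must be supplied for regions: ",
         paste(setdiff(labs, names(materials)), collapse = ", "))
  pk <- lapply(labs, function(l) .mat_pack(materials[[l]]))
  list(models = vapply(pk, `[[`, integer(1), "model"),
       params = lapply(pk, `[[`, "par"),
       fibered = vapply(pk, `[[`, integer(1), "fibered"),
       cap = max(vapply(pk, `[[`, numeric(1), "cap")))
}

# straight-line interpolation between two load cases
.interp_load <- function(l0, l1, lam) {
  load_case(iop_mmhg = l0$iop_mmhg + lam * (l1$iop_mmhg - l0$iop_mmhg),
            puff_pa = l0$puff_pa + lam * (l1$puff_pa - l0$puff_pa),
            profile = if (is.null(l1$profile)) l0$profile else l1$profile)
}

# external force and load-stiffness triplets for a load case
.external_load <- function(mesh, U, load) {
  n <- nrow(mesh$nodes)
  f <- numeric(2 * n)
  ki <- kj <- kv <- numeric(0)
  p_iop <- mmhg_to_mpa(load$iop_mmhg)
  if (p_iop != 0) {
    ed <- mesh$edges_interior - 1L
    pg <- matrix(p_iop, nrow(ed), 3)
    r <- cpp_edge_load(mesh$nodes, U, ed, 1L, pg, pg * 0)
    f <- f + r$f
    ki <- c(ki, r$ki); kj <- c(kj, r$kj); kv <- c(kv, r$kv)
  }
  q0 <- load$puff_pa * 1e-6   # Pa -> MPa
  if (q0 != 0) {
    ed <- mesh$edges_anterior - 1L
    rgp <- cpp_edge_gp_r(mesh$nodes, U, ed)
    qq <- .spatial_shape(rgp, load$profile)
    pg <- q0 * qq$value
    dpg <- q0 * qq$deriv
    r <- cpp_edge_load(mesh$nodes, U, ed, 2L, pg, dpg)
    f <- f + r$f
    ki <- c(ki, r$ki); kj <- c(kj, r$kj); kv <- c(kv, r$kv)
  }
  list(f = f, ki = ki, kj = kj, kv = kv)
}

.residual_norm <- function(v) sqrt(sum(v^2))

# Newton iteration at a fixed load; throws a condition on failure
.newton_at <- function(mesh, pk, load, U, settings) {
  n <- nrow(mesh$nodes)
  free <- setdiff(seq_len(2 * n), mesh$fixed_dofs)
  elems0 <- mesh$elems - 1L
  region0 <- mesh$region - 1L
  resid_of <- function(U) {
    a <- cpp_assemble(mesh$nodes, U, elems0, region0, pk$models, pk$params,
                      pk$fibered, pk$cap, FALSE)
    ext <- .external_load(mesh, U, load)
    (a$f - ext$f)[free]
  }
  for (it in seq_len(settings$max_newton)) {
    a <- cpp_assemble(mesh$nodes, U, elems0, region0, pk$models, pk$params,
                      pk$fibered, pk$cap, TRUE)
    ext <- .external_load(mesh, U, load)
    res <- a$f - ext$f
    denom <- max(.residual_norm(ext$f[free]), .residual_norm(a$f[free]), 1e-10)
    rn <- .residual_norm(res[free])
    if (settings$verbose)
      message(sprintf("    newton %d: |res| = %.3e (rel %.3e)", it, rn, rn / denom))
    if (rn / denom <= settings$newton_tol || rn < 1e-10)
      return(list(U = U, iterations = it, rel_residual = rn / denom))
    K <- Matrix::sparseMatrix(
      i = c(a$ki, ext$ki), j = c(a$kj, ext$kj), x = c(a$kv, -ext$kv),
      dims = c(2 * n, 2 * n))
    du <- numeric(2 * n)
    du[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                         -res[free]))
    dumax <- max(abs(du))
    if (dumax > settings$step_cap) du <- du * (settings$step_cap / dumax)
    # non-monotone acceptance: exponential fiber stiffening produces a
    # large transient residual hump that full Newton steps cross in a few
    # iterations; backtrack only on inadmissible states (element
    # inversion, material overflow) or an outright blow-up. If half the
    # iteration budget is spent, fall back to strict monotone damping.
    strict <- it > settings$max_newton %/% 2
    alpha <- 1
    ok <- FALSE
    for (ls in 1:8) {
      rn_try <- tryCatch(.residual_norm(resid_of(U + alpha *
                           matrix(du, n, 2, byrow = TRUE))),
                         error = function(e) Inf)
      accept <- is.finite(rn_try) &&
        (!settings$line_search ||
           (if (strict) rn_try < rn else
              rn_try < max(1e4 * rn, 1e3 * denom)))
      if (accept) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok)
      stop("newton: step leads to an inadmissible state")
    U <- U + alpha * matrix(du, n, 2, byrow = TRUE)
  }
  stop("newton: no convergence within max_newton iterations")
}

# advance along the interpolated load path from factor lam0 (converged
# state U) to lam1, bisecting the increment on failure
.advance <- function(mesh, pk, loadfun, lam0, lam1, U, settings, depth = 0) {
  out <- tryCatch(.newton_at(mesh, pk, loadfun(lam1), U, settings),
                  error = function(e) e)
  if (!inherits(out, "error")) return(out)
  if (depth >= settings$max_bisect)
    stop(sprintf("nonconvergence: load factor %.4f unreachable (last converged %.4f): %s",
                 lam1, lam0, conditionMessage(out)))
  mid <- (lam0 + lam1) / 2
  half <- .advance(mesh, pk, loadfun, lam0, mid, U, settings, depth + 1)
  .advance(mesh, pk, loadfun, mid, lam1, half$U, settings, depth + 1)
}

#' Static equilibrium solve
#'
#' Solves the geometrically nonlinear equilibrium of the meshed eye under a
#' load case, ramping the load in increments from zero (or from a supplied
#' converged state) with Newton iteration, line search and adaptive
#' bisection of failed increments. Pressures follow the deforming surfaces.
#'
#' @param mesh a \code{meridian_mesh}.
#' @param materials named list of material parameters per region
#'   (\code{cornea}, \code{limbus}, \code{sclera}).
#' @param load a \code{load_case}.
#' @param settings a \code{solver_settings}.
#' @param state optional previously converged \code{fe_solution} at the
#'   same mesh whose displacement seeds the solve; its load is taken as the
#'   starting load factor along the straight-line path to \code{load}.
#' @return an object of class \code{fe_solution} with fields \code{U}
#'   (n x 2 nodal displacements, mm), \code{converged},
#'   \code{rel_residual}, \code{load}, and references to mesh/materials for
#'   post-processing.
#' @export
solve_static <- function(mesh, materials, load, settings = solver_settings(),
                         state = NULL) {
  pk <- .pack_materials(mesh, materials)
  n <- nrow(mesh$nodes)
  U <- if (is.null(state)) matrix(0, n, 2) else state$U
  load0 <- if (is.null(state)) load_case(0, 0) else state$load
  loadfun <- function(lam) .interp_load(load0, load, lam)
  # warm starts take a single increment (bisected on demand); cold starts
  # ramp. A failed warm start falls back to a cold ramp from zero: the
  # seed displacement may be inconsistent with the current geometry
  # (e.g. across zero-pressure iterates)
  if (!is.null(state)) {
    res <- tryCatch(.advance(mesh, pk, loadfun, 0, 1, U, settings),
                    error = function(e) NULL)
    if (!is.null(res)) {
      return(structure(list(U = res$U, converged = TRUE,
                            rel_residual = res$rel_residual,
                            iterations = res$iterations, load = load,
                            mesh = mesh, materials = materials),
                       class = "fe_solution"))
    }
    U <- matrix(0, n, 2)
    load0 <- load_case(0, 0)
    loadfun <- function(lam) .interp_load(load0, load, lam)
  }
  lams <- seq(0, 1, length.out = settings$n_load_steps + 1)[-1]
  res <- NULL
  lam0 <- 0
  for (lam in lams) {
    res <- .advance(mesh, pk, loadfun, lam0, lam, U, settings)
    U <- res$U
    lam0 <- lam
  }
  structure(list(U = res$U, converged = TRUE,
                 rel_residual = res$rel_residual,
                 iterations = res$iterations, load = load,
                 mesh = mesh, materials = materials),
            class = "fe_solution")
}

#' Solve a sequence of load cases
#'
#' Traverses an ordered load path quasi-statically: each step restarts from
#' the previous converged state, with adaptive sub-stepping on failure.
#'
#' @param mesh,materials,settings as in \code{\link{solve_static}}.
#' @param loads list of \code{load_case} objects, ordered.
#' @param state optional starting \code{fe_solution}.
#' @return list of \code{fe_solution} objects, one per load case.
#' @export
solve_path <- function(mesh, materials, loads, settings = solver_settings(),
                       state = NULL) {
  out <- vector("list", length(loads))
  for (i in seq_along(loads)) {
    sol <- tryCatch(
      solve_static(mesh, materials, loads[[i]], settings, state = state),
      error = function(e)
        stop(sprintf("load path failed at step %d/%d: %s", i, length(loads),
                     conditionMessage(e))))
    out[[i]] <- sol
    state <- sol
  }
  out
}

#' @export
print.fe_solution <- function(x, ...) {
  cat("FE solution\n")
  cat(sprintf("  load: IOP %g mmHg, puff %g Pa\n",
              x$load$iop_mmhg, x$load$puff_pa))
  cat(sprintf("  converged, relative residual %.2e\n", x$rel_residual))
  cat(sprintf("  max |u| = %.4f mm\n", max(abs(x$U))))
  invisible(x)
}

#' Integration-point field table
#'
#' Per-Gauss-point kinematics and Cauchy stresses of a converged solution:
#' reference and deformed positions, volume ratio, meridional and
#' circumferential (hoop) stretches, the normal Cauchy stress along the
#' deformed meridional direction, hoop stress, logarithmic hoop strain and
#' the Cauchy components in the (R, Z, Theta) basis.
#'
#' @param solution an \code{fe_solution}.
#' @return data.frame, one row per integration point.
#' @export
field_table <- function(solution) {
  mesh <- solution$mesh
  pk <- .pack_materials(mesh, solution$materials)
  m <- cpp_field(mesh$nodes, solution$U, mesh$elems - 1L, mesh$region - 1L,
                 pk$models, pk$params, pk$fibered, pk$cap)
  out <- as.data.frame(m)
  names(out) <- c("elem", "R", "Z", "r", "z", "J", "lambda_merid",
                  "lambda_hoop", "sigma_merid", "sigma_hoop",
                  "log_hoop_strain", "s_rr", "s_zz", "s_tt", "s_rz",
                  "energy", "region")
  out$region <- mesh$region_labels[out$region]
  out
}

# deformation gradient and local frame at a local point of one element
.eval_F <- function(mesh, U, e, xi, eta) {
  Xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
  Ue <- U[mesh$elems[e, ], , drop = FALSE]
  sh <- .shape9(xi, eta)
  J2 <- rbind(c(sum(sh$dxi * Xe[, 1]), sum(sh$dxi * Xe[, 2])),
              c(sum(sh$deta * Xe[, 1]), sum(sh$deta * Xe[, 2])))
  iJ <- solve(J2)
  dNR <- iJ[1, 1] * sh$dxi + iJ[1, 2] * sh$deta
  dNZ <- iJ[2, 1] * sh$dxi + iJ[2, 2] * sh$deta
  Rg <- sum(sh$N * Xe[, 1])
  ur <- sum(sh$N * Ue[, 1])
  F11 <- 1 + sum(dNR * Ue[, 1]); F12 <- sum(dNZ * Ue[, 1])
  F21 <- sum(dNR * Ue[, 2]); F22 <- 1 + sum(dNZ * Ue[, 2])
  F33 <- if (Rg > 1e-9) 1 + ur / Rg else F11   # axis limit: u_r/R -> du_r/dR
  tmer <- c(J2[1, 1], J2[1, 2])
  tmer <- tmer / sqrt(sum(tmer^2))
  list(F = rbind(c(F11, F12, 0), c(F21, F22, 0), c(0, 0, F33)),
       R = Rg, Z = sum(sh$N * Xe[, 2]),
       u = c(ur, sum(sh$N * Ue[, 2])),
       a_merid = c(tmer, 0))
}

# locate the element and local coordinates of a reference point
.locate_point <- function(mesh, p) {
  for (e in seq_len(nrow(mesh$elems))) {
    Xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    mrg <- 0.3 * max(diff(range(Xe[, 1])), diff(range(Xe[, 2])))
    if (p[1] < min(Xe[, 1]) - mrg || p[1] > max(Xe[, 1]) + mrg ||
        p[2] < min(Xe[, 2]) - mrg || p[2] > max(Xe[, 2]) + mrg) next
    loc <- c(0, 0)
    for (it in 1:30) {
      sh <- .shape9(loc[1], loc[2])
      g <- c(sum(sh$N * Xe[, 1]) - p[1], sum(sh$N * Xe[, 2]) - p[2])
      if (max(abs(g)) < 1e-11) break
      J2 <- rbind(c(sum(sh$dxi * Xe[, 1]), sum(sh$deta * Xe[, 1])),
                  c(sum(sh$dxi * Xe[, 2]), sum(sh$deta * Xe[, 2])))
      loc <- loc - solve(J2, g)
      if (any(abs(loc) > 3)) break
    }
    if (all(abs(loc) <= 1 + 1e-7) && max(abs(g)) < 1e-8)
      return(list(elem = e, xi = loc[1], eta = loc[2]))
  }
  stop("probe point outside the mesh")
}

#' Probe a solution at a point
#'
#' Interpolated displacement, stretches and normal Cauchy stresses along
#' the meridional and circumferential directions at a named point
#' ("anterior_apex", "posterior_apex") or an arbitrary reference-frame
#' location \code{c(r, z)}.
#'
#' @param solution an \code{fe_solution}.
#' @param location probe location.
#' @return list with \code{displacement} (mm), \code{lambda_merid},
#'   \code{lambda_hoop}, \code{sigma_merid}, \code{sigma_hoop} (MPa,
#'   Cauchy, along the deformed directions), and the reference position.
#' @export
probe <- function(solution, location = "anterior_apex") {
  mesh <- solution$mesh
  if (is.character(location)) {
    loc <- switch(location,
      anterior_apex = list(elem = 1L, xi = -1, eta = -1),
      posterior_apex = list(elem = (mesh$nt - 1L) * sum(mesh$nm) + 1L,
                            xi = -1, eta = 1),
      stop("unknown probe location: ", location))
  } else {
    loc <- .locate_point(mesh, location)
  }
  ev <- .eval_F(mesh, solution$U, loc$elem, loc$xi, loc$eta)
  # sample stress at the nearest superconvergent (2x2 Gauss) point: corner
  # values of penalty elements oscillate, Gauss values are reliable
  gs <- 1 / sqrt(3)
  evs <- .eval_F(mesh, solution$U, loc$elem,
                 sign(loc$xi) * min(abs(loc$xi), gs),
                 sign(loc$eta) * min(abs(loc$eta), gs))
  reg <- mesh$region[loc$elem]
  mat <- solution$materials[[mesh$region_labels[reg]]]
  pk <- .mat_pack(mat)
  fib <- if (pk$fibered) rbind(evs$a_merid, c(0, 0, 1)) else matrix(0, 0, 3)
  r <- cpp_material_point(evs$F, pk$model, pk$par, fib, 0L, pk$cap, FALSE)
  md <- evs$F %*% evs$a_merid
  lamM <- sqrt(sum(md^2))
  md <- md / lamM
  list(position = c(r = ev$R, z = ev$Z), displacement = ev$u,
       lambda_merid = lamM, lambda_hoop = evs$F[3, 3],
       sigma_merid = drop(t(md) %*% r$cauchy %*% md),
       sigma_hoop = r$cauchy[3, 3])
}
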