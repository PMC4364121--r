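#' Iterative zero-pressure (stress-free configuration) algorithm
#'
#' The imaged corneal geometry is acquired while the eye is loaded by the
#' IOP, so it is not stress-free. This fixed-point iteration recovers the
#' unloaded configuration: starting from the imaged coordinates, each
#' iterate \code{X_init} is pressurized with the forward solver to give a
#' deformed configuration \code{x_def}; the error \code{E = x_def - X_ref}
#' is computed, and while its infinity norm exceeds \code{epsilon} the
#' initial configuration is updated as \code{X_init <- X_init - E}
#' (optionally damped). On convergence, pressurizing \code{X_init} to the
#' IOP reproduces the imaged geometry within \code{epsilon}.
#'
#' @param forward function \code{(X, iop)} returning the deformed
#'   configuration of the same shape as \code{X}.
#' @param X_ref reference (imaged) coordinates: numeric vector or matrix.
#' @param iop intraocular pressure passed through to \code{forward} (mmHg).
#' @param epsilon convergence tolerance on the infinity norm of the error
#'   (mm).
#' @param max_iter maximum number of outer iterations.
#' @param damping update damping factor in (0, 1]; 1 (default) is the
#'   undamped rule.
#' @param free_mask logical array of the shape of \code{X_ref}; FALSE
#'   entries (restrained coordinates) are excluded from both the update
#'   and the error norm. Default: all free.
#' @param guard optional admissibility predicate on a candidate
#'   \code{X_init} (e.g. an element-inversion check); when it fails, the
#'   update step is bisected and retried.
#' @return an object of class \code{zero_pressure_result} with
#'   \code{X_init}, \code{iterations}, \code{error_history} (mm),
#'   \code{converged}, and \code{x_def} (the final pressurized
#'   configuration).
#' @export
find_stress_free <- function(forward, X_ref, iop, epsilon = 1e-4,
                             max_iter = 50, damping = 1,
                             free_mask = NULL, guard = NULL) {
  stopifnot(epsilon > 0, max_iter >= 1, damping > 0, damping <= 1)
  if (is.null(free_mask)) free_mask <- rep(TRUE, length(X_ref))
  X <- X_ref
  hist <- numeric(0)
  xdef <- NULL
  for (k in seq_len(max_iter)) {
    xdef <- forward(X, iop)
    E <- xdef - X_ref
    E[!free_mask] <- 0
    e <- max(abs(E))
    hist <- c(hist, e)
    if (e < epsilon) {
      return(structure(list(X_init = X, iterations = k,
                            error_history = hist, converged = TRUE,
                            x_def = xdef),
                       class = "zero_pressure_result"))
    }
    step <- damping
    repeat {
      Xnew <- X - step * E
      if (is.null(guard) || isTRUE(guard(Xnew))) break
      step <- step / 2
      if (step < damping / 256)
        stop("zero-pressure update produced an inadmissible configuration ",
             "even after step bisection")
    }
    X <- Xnew
  }
  structure(list(X_init = X, iterations = max_iter, error_history = hist,
                 converged = FALSE, x_def = xdef),
            class = "zero_pressure_result")
}

#' @export
print.zero_pressure_result <- function(x, ...) {
  cat("Zero-pressure (stress-free) recovery\n")
  cat(sprintf("  %s in %d iteration(s); final |E|_inf = %.3g mm\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, utils::tail(x$error_history, 1)))
  invisible(x)
}

#' Write the zero-pressure error history as CSV
#'
#' @param result a \code{zero_pressure_result}.
#' @param file output path.
#' @export
write_zero_pressure <- function(result, file) {
  utils::write.csv(data.frame(iteration = seq_along(result$error_history),
                              error_inf_mm = result$error_history),
                   file, row.names = FALSE)
  invisible(file)
}

#' Stress-free recovery for a meshed eye
#'
#' Applies \code{\link{find_stress_free}} to a meridian mesh: the forward
#' model pressurizes candidate nodal coordinates to the IOP with
#' \code{\link{solve_static}} (warm-started across iterations), restrained
#' coordinates (axis, scleral base) are excluded from the update, and an
#' element-inversion guard bisects updates that would tangle the mesh.
#'
#' @param mesh a \code{meridian_mesh} holding the imaged (reference)
#'   coordinates.
#' @param materials named region material list.
#' @param iop_mmhg intraocular pressure (mmHg).
#' @param settings a \code{solver_settings}.
#' @param epsilon,max_iter,damping as in \code{\link{find_stress_free}}.
#' @return list with \code{result} (a \code{zero_pressure_result}),
#'   \code{mesh_init} (mesh with stress-free coordinates) and
#'   \code{solution} (the converged FE state of \code{mesh_init} at the
#'   IOP, ready to seed a tonometry simulation).
#' @export
prestress_mesh <- function(mesh, materials, iop_mmhg,
                           settings = solver_settings(),
                           epsilon = 1e-4, max_iter = 50, damping = 1) {
  n <- nrow(mesh$nodes)
  mask <- matrix(TRUE, n, 2)
  fr <- mesh$fixed_dofs[mesh$fixed_dofs %% 2L == 1L]   # u_r restrained
  fz <- mesh$fixed_dofs[mesh$fixed_dofs %% 2L == 0L]   # u_z restrained
  mask[(fr + 1L) %/% 2L, 1] <- FALSE
  mask[fz %/% 2L, 2] <- FALSE
  env <- new.env(parent = emptyenv())
  env$warm <- NULL
  env$last <- NULL
  fwd <- function(X, iop) {
    m2 <- mesh
    m2$nodes <- X
    sol <- solve_static(m2, materials, load_case(iop_mmhg = iop),
                        settings, state = env$warm)
    env$warm <- sol
    env$last <- sol
    X + sol$U
  }
  res <- find_stress_free(fwd, mesh$nodes, iop_mmhg, epsilon = epsilon,
                          max_iter = max_iter, damping = damping,
                          free_mask = mask,
                          guard = function(X) min_jacobian(mesh, X) > 0)
  if (!res$converged)
    warning("zero-pressure algorithm did not reach epsilon within max_iter")
  mesh_init <- mesh
  mesh_init$nodes <- res$X_init
  sol <- env$last
  sol$mesh <- mesh_init
  list(result = res, mesh_init = mesh_init, solution = sol)
}
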