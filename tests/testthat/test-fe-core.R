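# Nonlinear axisymmetric FE engine, validated against closed forms.

test_that("zero load gives the undeformed, stress-free state", {
  m <- shell_mesh(7.9, 8.1, nm = 12, nt = 2)
  sol <- solve_static(m, list(shell = neo_hookean()), load_case(0, 0),
                      solver_settings(n_load_steps = 1))
  expect_true(sol$converged)
  expect_equal(max(abs(sol$U)), 0)
  ft <- field_table(sol)
  expect_lt(max(abs(ft$sigma_merid)), 1e-12)
})

test_that("thin pressurized shell matches the linear membrane solution", {
  m <- shell_mesh(7.95, 8.05, nm = 24, nt = 2)
  P <- 1e-4  # MPa; small enough for the linear regime
  sol <- solve_static(m, list(shell = neo_hookean(0.05)),
                      load_case(iop_mmhg = mpa_to_mmhg(P)),
                      solver_settings(n_load_steps = 4))
  mu <- 0.1; R <- 8; t <- 0.1
  # linear elasticity of a pressurized sphere, nu = 1/2:
  # delta = P R^2 (1 - nu) / (2 t E) with E = 3 mu
  delta <- P * R^2 * 0.5 / (2 * t * 3 * mu)
  pr <- probe(sol, "posterior_apex")
  expect_equal(abs(pr$displacement[2]), delta, tolerance = 0.05)
  # membrane state: Laplace stress in both directions on both surfaces
  for (loc in c("anterior_apex", "posterior_apex")) {
    p <- probe(sol, loc)
    expect_equal(p$sigma_merid, P * R / (2 * t), tolerance = 0.05)
    expect_equal(p$sigma_hoop, P * R / (2 * t), tolerance = 0.05)
  }
})

test_that("thick incompressible sphere matches the closed-form inflation", {
  a <- 8; b <- 10; mu <- 0.1
  P_of <- function(la) {
    f <- function(R) {
      r <- (R^3 + a^3 * (la^3 - 1))^(1 / 3)
      lam <- r / R
      2 * mu * (lam^2 - lam^-4) / r * (R / r)^2
    }
    stats::integrate(f, a, b, rel.tol = 1e-10)$value
  }
  P <- 0.005
  la_exact <- stats::uniroot(function(l) P_of(l) - P, c(1, 1.5),
                             tol = 1e-12)$root
  m <- shell_mesh(a, b, nm = 20, nt = 3)
  sol <- solve_static(m, list(shell = neo_hookean(0.05)),
                      load_case(iop_mmhg = mpa_to_mmhg(P)),
                      solver_settings(n_load_steps = 6))
  la_fe <- (a + abs(probe(sol, "posterior_apex")$displacement[2])) / a
  expect_equal(la_fe, la_exact, tolerance = 0.01 * (la_exact - 1))
})

test_that("the solution is path independent and fully reversible", {
  m <- shell_mesh(7.95, 8.05, nm = 16, nt = 2)
  mats <- list(shell = neo_hookean())
  s5 <- solve_static(m, mats, load_case(iop_mmhg = 6),
                     solver_settings(n_load_steps = 5))
  s20 <- solve_static(m, mats, load_case(iop_mmhg = 6),
                      solver_settings(n_load_steps = 20))
  expect_lt(max(abs(s5$U - s20$U)), 1e-8)
  # constant path: identical solutions at every step
  path <- solve_path(m, mats, rep(list(load_case(iop_mmhg = 6)), 3),
                     solver_settings(n_load_steps = 5))
  expect_equal(path[[1]]$U, path[[3]]$U, tolerance = 1e-12)
  # reversal: hyperelasticity stores no history
  back <- solve_static(m, mats, load_case(0, 0), solver_settings(),
                       state = s5)
  expect_lt(max(abs(back$U)), 1e-10)
})

test_that("converged residuals honor the tolerance and reactions balance", {
  m <- shell_mesh(7.9, 8.1, nm = 16, nt = 2)
  mats <- list(shell = neo_hookean())
  st <- solver_settings(newton_tol = 1e-9)
  P <- 1e-3
  sol <- solve_static(m, mats, load_case(iop_mmhg = mpa_to_mmhg(P)), st)
  expect_lte(sol$rel_residual, st$newton_tol)
  # follower-load check: axial reaction = pressure x projected deformed
  # area of the interior surface
  pk <- tonosim:::.pack_materials(m, mats)
  a <- tonosim:::cpp_assemble(m$nodes, sol$U, m$elems - 1L, m$region - 1L,
                              pk$models, pk$params, pk$fibered, pk$cap,
                              FALSE)
  ext <- tonosim:::.external_load(m, sol$U, sol$load)
  reac <- sum((a$f - ext$f)[2L * m$tags$scleral_base])
  eq_in <- m$tags$posterior[length(m$tags$posterior)]
  rin <- m$nodes[eq_in, 1] + sol$U[eq_in, 1]
  expect_equal(reac, P * pi * rin^2, tolerance = 0.005)
})

test_that("probes interpolate continuously and fail outside the mesh", {
  m <- shell_mesh(7.9, 8.1, nm = 16, nt = 2)
  sol <- solve_static(m, list(shell = neo_hookean()),
                      load_case(iop_mmhg = 5), solver_settings())
  # points just either side of an element boundary (phi = 2 * pi/2/16)
  phi <- 2 * (pi / 2) / 16
  rad <- 8.0
  p1 <- probe(sol, rad * c(sin(phi - 1e-4), -cos(phi - 1e-4)))
  p2 <- probe(sol, rad * c(sin(phi + 1e-4), -cos(phi + 1e-4)))
  expect_equal(p1$displacement, p2$displacement, tolerance = 5e-3)
  expect_equal(p1$sigma_merid, p2$sigma_merid, tolerance = 0.05)
  expect_error(probe(sol, c(20, 0)), "outside")
})

test_that("the eye under IOP alone is in a pure membrane (tension) state", {
  g <- geometry_preset("baseline")
  mesh <- generate_mesh(g, 40, 3)
  mB <- material_preset("B")
  mats <- list(cornea = mB, limbus = mB, sclera = material_preset("sclera"))
  sol <- solve_static(mesh, mats, load_case(iop_mmhg = 19),
                      solver_settings())
  for (loc in c("anterior_apex", "posterior_apex")) {
    p <- probe(sol, loc)
    expect_gt(p$sigma_merid, 0)
    expect_gt(p$sigma_hoop, 0)
    expect_gt(p$lambda_merid, 1)
  }
})

test_that("apical displacement and peak stress converge under mesh refinement", {
  g <- geometry_preset("baseline")
  mC <- material_preset("C")
  mats <- list(cornea = mC, limbus = mC, sclera = material_preset("sclera"))
  res <- lapply(list(c(20, 2), c(40, 3), c(80, 5)), function(nn) {
    mesh <- generate_mesh(g, nn[1], nn[2])
    s <- solve_static(mesh, mats, load_case(iop_mmhg = 19),
                      solver_settings())
    ft <- field_table(s)
    c(u = probe(s, "anterior_apex")$displacement[2],
      smax = max(principal_stress(ft[ft$region == "cornea", ])))
  })
  v <- do.call(rbind, res)
  du_coarse <- abs(v[2, 1] - v[1, 1]) / abs(v[3, 1])
  du_fine <- abs(v[3, 1] - v[2, 1]) / abs(v[3, 1])
  ds_coarse <- abs(v[2, 2] - v[1, 2]) / abs(v[3, 2])
  ds_fine <- abs(v[3, 2] - v[2, 2]) / abs(v[3, 2])
  expect_lt(du_fine, 0.005)          # < 0.5 % on the apical displacement
  expect_lt(du_fine, du_coarse)      # changes shrink under refinement
  expect_lt(ds_fine, ds_coarse)
})

test_that("nonconvergence reports the last reachable load factor", {
  # a thin neo-Hookean balloon has a limit-point pressure (~11.6 mmHg for
  # these dimensions); asking for more must fail loudly, carrying the
  # last converged load factor
  m <- shell_mesh(7.95, 8.05, nm = 12, nt = 2)
  err <- tryCatch(
    solve_static(m, list(shell = neo_hookean()), load_case(iop_mmhg = 19),
                 solver_settings(max_bisect = 4)),
    error = function(e) conditionMessage(e))
  expect_match(err, "nonconvergence|unreachable")
  expect_match(err, "last converged")
})
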