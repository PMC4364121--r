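# Constitutive layer: kinematics, energies, stresses, tangents.

test_that("deformation state reproduces the modified invariants", {
  st <- deformation_state(diag(3))
  expect_equal(st$J_el, 1)
  expect_equal(st$I1_bar, 3)
  expect_equal(st$I4_bar, c(1, 1))

  lam <- 1.1
  st <- deformation_state(diag(c(lam, lam^-0.5, lam^-0.5)),
                          fiber_directions = c(1, 0, 0))
  expect_equal(st$J_el, 1)
  expect_equal(st$I1_bar, lam^2 + 2 / lam)   # 3.0281818...
  expect_equal(st$I4_bar, lam^2)

  st <- deformation_state(2 * diag(3))
  expect_equal(st$J_el, 8)
  expect_equal(st$I1_bar, 3)   # pure dilation: isochoric part is identity

  expect_error(deformation_state(diag(c(-1, 1, 1))), "singular")
})

test_that("fiber strain applies the Macaulay bracket and dispersion", {
  mk_state <- function(I1b, I4) structure(
    list(F = diag(3), J_el = 1, I1_bar = I1b, I4_bar = I4,
         fiber_directions = rbind(c(1, 0, 0))),
    class = "deformation_state")

  # compressed perfectly-aligned fiber carries nothing
  p0 <- gho_params(C10 = 0.05, k1 = 1, k2 = 1, kappa = 0)
  fs <- fiber_strain(mk_state(3, 0.9), p0, 1)
  expect_equal(fs$value, 0)
  expect_lt(fs$raw, 0)

  # isotropic-dispersion limit: E independent of I4
  p13 <- gho_params(C10 = 0.05, k1 = 1, k2 = 1, kappa = 1 / 3)
  e1 <- fiber_strain(mk_state(3.1, 0.8), p13, 1)$value
  e2 <- fiber_strain(mk_state(3.1, 1.3), p13, 1)$value
  expect_equal(e1, (3.1 - 3) / 3)
  expect_equal(e1, e2)

  # near-isotropic dispersion of the corneal presets, carried exactly
  pA <- material_preset("A")
  fs <- fiber_strain(mk_state(3.05, 1.08), pA, 1)
  expect_equal(fs$raw, 0.33329 * 0.05 + (1 - 3 * 0.33329) * 0.08)

  expect_error(fiber_strain(mk_state(3, 1), pA, 5), "out of range")
})

test_that("strain energy matches an independent evaluation and is zero at rest", {
  pA <- material_preset("A")
  expect_identical(gho_energy(deformation_state(diag(3)), pA), 0)

  lam <- 1.02
  st <- deformation_state(diag(c(lam, lam^-0.5, lam^-0.5)))
  expect_equal(gho_energy(st, pA), gho_energy_oracle(lam, pA),
               tolerance = 1e-12)

  # kappa = 1/3: energy insensitive to fiber orientation
  p13 <- gho_params(C10 = 0.05, k1 = 25, k2 = 2490, kappa = 1 / 3)
  c45 <- cos(pi / 4)
  rot <- gho_params(C10 = 0.05, k1 = 25, k2 = 2490, kappa = 1 / 3,
                    fiber_directions = rbind(c(c45, c45, 0),
                                             c(-c45, c45, 0)))
  F <- diag(c(1.03, 0.99, 1 / (1.03 * 0.99)))
  expect_equal(gho_energy(deformation_state(F, p13$fiber_directions), p13),
               gho_energy(deformation_state(F, rot$fiber_directions), rot),
               tolerance = 1e-12)
})

test_that("stress and tangent are the exact derivatives of the energy", {
  set.seed(42)
  mats <- list(material_preset("A"), material_preset("C"),
               material_preset("sclera"),
               gho_params(C10 = 0.08, D = 2, k1 = 10, k2 = 50, kappa = 0.1))
  for (params in mats) {
    is_gho <- inherits(params, "gho_params")
    en <- function(F) {
      s <- deformation_state(F)
      if (is_gho) gho_energy(s, params) else
        yeoh_energy_stress(s, params)$energy
    }
    pk2 <- function(F) {
      s <- deformation_state(F)
      if (is_gho) gho_stress(s, params)$pk2 else
        yeoh_energy_stress(s, params)$pk2
    }
    for (rep in 1:15) {
      F <- random_F()
      st <- deformation_state(F)
      S <- pk2(F)
      # PK1 from energy differences vs F S
      h <- 1e-6
      P <- F %*% S
      Pnum <- matrix(0, 3, 3)
      for (a in 1:3) for (b in 1:3) {
        Fp <- F; Fp[a, b] <- Fp[a, b] + h
        Fm <- F; Fm[a, b] <- Fm[a, b] - h
        Pnum[a, b] <- (en(Fp) - en(Fm)) / (2 * h)
      }
      expect_equal(P, Pnum, tolerance = 1e-4)
      # tangent: directional derivative of S
      CC <- if (is_gho) gho_tangent(st, params) else
        yeoh_tangent(st, params)
      expect_equal(CC, t(CC), tolerance = 1e-10)   # major symmetry
      dF <- matrix(rnorm(9), 3, 3)
      dSn <- (pk2(F + h * dF) - pk2(F - h * dF)) / (2 * h)
      dE <- 0.5 * (t(dF) %*% F + t(F) %*% dF)
      dEv <- c(diag(dE), 2 * dE[1, 2], 2 * dE[1, 3], 2 * dE[2, 3])
      v <- CC %*% dEv
      dS <- matrix(c(v[1], v[4], v[5], v[4], v[2], v[6],
                     v[5], v[6], v[3]), 3, 3)
      expect_equal(dS, dSn, tolerance = 1e-4)
    }
  }
})

test_that("reference state is stress free and Cauchy stress is symmetric", {
  pA <- material_preset("A")
  s0 <- gho_stress(deformation_state(diag(3)), pA)
  expect_equal(s0$cauchy, matrix(0, 3, 3))
  expect_equal(s0$pk2, matrix(0, 3, 3))
  set.seed(7)
  s <- gho_stress(deformation_state(random_F()), pA)
  expect_equal(s$cauchy, t(s$cauchy), tolerance = 1e-12)
})

test_that("a compressed fiber family contributes nothing to the stress", {
  # uniaxial compression along e1 with perfectly aligned fibers: both
  # families inactive (E < 0), so the response equals the fiber-free one
  p_fib <- gho_params(C10 = 0.05, k1 = 40, k2 = 100, kappa = 0,
                      fiber_directions = rbind(c(1, 0, 0)))
  p_nofib <- gho_params(C10 = 0.05, k1 = 0, k2 = 100, kappa = 0,
                        fiber_directions = rbind(c(1, 0, 0)))
  lam <- 0.95
  F <- diag(c(lam, lam^-0.5, lam^-0.5))
  s1 <- gho_stress(deformation_state(F, c(1, 0, 0)), p_fib)
  s2 <- gho_stress(deformation_state(F, c(1, 0, 0)), p_nofib)
  expect_equal(s1$pk2, s2$pk2, tolerance = 1e-14)
  expect_equal(s1$energy, s2$energy, tolerance = 1e-14)
})

test_that("frame indifference holds under superposed rotations", {
  set.seed(11)
  pC <- material_preset("C")
  for (rep in 1:8) {
    F <- random_F()
    Q <- random_rotation()
    u1 <- gho_energy(deformation_state(F), pC)
    u2 <- gho_energy(deformation_state(Q %*% F), pC)
    expect_equal(u1, u2, tolerance = 1e-12)
  }
})

test_that("isotropy at kappa = 1/3 extends to stresses and tangents", {
  set.seed(13)
  F <- random_F()
  base <- gho_params(C10 = 0.05, k1 = 60, k2 = 2490, kappa = 1 / 3)
  Q <- random_rotation()
  rot <- gho_params(C10 = 0.05, k1 = 60, k2 = 2490, kappa = 1 / 3,
                    fiber_directions = base$fiber_directions %*% t(Q))
  s1 <- gho_stress(deformation_state(F, base$fiber_directions), base)
  s2 <- gho_stress(deformation_state(F, rot$fiber_directions), rot)
  expect_equal(s1$cauchy, s2$cauchy, tolerance = 1e-12)
  t1 <- gho_tangent(deformation_state(F, base$fiber_directions), base)
  t2 <- gho_tangent(deformation_state(F, rot$fiber_directions), rot)
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("neo-Hookean limit reproduces linear elasticity at the reference", {
  C10 <- 0.05
  p <- neo_hookean(C10)
  CC <- gho_tangent(deformation_state(diag(3)), p)
  mu <- 2 * C10
  kv <- p$bulk_factor * C10
  lam_L <- kv - 2 * mu / 3
  ref <- matrix(0, 6, 6)
  ref[1:3, 1:3] <- lam_L
  diag(ref)[1:3] <- lam_L + 2 * mu
  diag(ref)[4:6] <- mu
  expect_equal(CC, ref, tolerance = 1e-10)
})

test_that("Yeoh degenerates to the fiber-free model and overflow is guarded", {
  y <- yeoh_params(C10 = 0.05)
  g <- neo_hookean(0.05)
  set.seed(3)
  F <- random_F()
  sy <- yeoh_energy_stress(deformation_state(F), y)
  sg <- gho_stress(deformation_state(F), g)
  expect_equal(sy$pk2, sg$pk2, tolerance = 1e-12)
  expect_equal(sy$energy, sg$energy, tolerance = 1e-12)

  pC <- material_preset("C")
  big <- deformation_state(diag(c(2, 2^-0.5, 2^-0.5)))
  expect_error(gho_energy(big, pC), "exceeds cap")
})

test_that("uniaxial response is incompressible, ordered, and closed-form in the NH limit", {
  nh <- neo_hookean(0.05)
  u <- uniaxial_response(nh, c(1, 1.02, 1.05, 1.08))
  expect_equal(u$stress[1], 0, tolerance = 1e-10)
  expect_equal(u$stress, 2 * 0.05 * (u$stretch^2 - 1 / u$stretch),
               tolerance = 1e-8)
  expect_equal(u$lateral, u$stretch^-0.5, tolerance = 1e-8)

  s <- vapply(c("A", "B", "C"), function(m)
    uniaxial_response(material_preset(m), 1.05)$stress, numeric(1))
  expect_lt(s[["A"]], s[["B"]])
  expect_lt(s[["B"]], s[["C"]])

  # strictly increasing over [1, 1.1]
  uu <- uniaxial_response(material_preset("B"), seq(1, 1.1, by = 0.01))
  expect_true(all(diff(uu$stress) > 0))
})

test_that("membrane inflation orders the materials and linearizes correctly", {
  grids <- lapply(c("A", "B", "C"), function(m)
    membrane_inflation(material_preset(m), pressure_mmhg = c(0, 5, 15, 30)))
  names(grids) <- c("A", "B", "C")
  expect_equal(grids$A$rise_mm[1], 0)
  for (i in 2:4) {
    expect_gt(grids$A$rise_mm[i], grids$B$rise_mm[i])
    expect_gt(grids$B$rise_mm[i], grids$C$rise_mm[i])
  }

  # small-pressure limit vs an independent series expansion: equibiaxial
  # modulus from energy differences + linearized cap geometry
  p <- material_preset("B")
  R0 <- 8.08; t0 <- 0.585; a <- 5.66
  eps <- 1e-4
  sig <- function(lam) {
    st <- deformation_state(diag(c(lam, lam, lam^-2)))
    s <- tonosim:::.state_point(st, p, part = 1L)$cauchy
    s[1, 1] - s[3, 3]
  }
  M <- (sig(1 + eps) - sig(1 - eps)) / (2 * eps)  # d sigma / d lambda at 1
  h0 <- R0 - sqrt(R0^2 - a^2)
  A0 <- pi * (a^2 + h0^2)
  hfun <- function(lam) sqrt(lam^2 * A0 / pi - a^2)
  rho0 <- (a^2 + h0^2) / (2 * h0)
  dhdlam <- (hfun(1 + eps) - hfun(1 - eps)) / (2 * eps)
  # P ~ (2 t0 M / rho0) (lam - 1); rise ~ dh/dlam (lam - 1)
  p_small <- 0.2  # mmHg
  lam_lin <- 1 + mmhg_to_mpa(p_small) * rho0 / (2 * t0 * M)
  rise_lin <- dhdlam * (lam_lin - 1)
  out <- membrane_inflation(p, R_ref = R0, t_ref = t0,
                            pressure_mmhg = p_small, ring_radius = a)
  expect_equal(out$rise_mm, rise_lin, tolerance = 0.02)
})
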