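# Air-puff load model and the end-to-end tonometry pipeline.

test_that("the temporal pulse spans the duration and peaks at 25 kPa", {
  pr <- air_puff_profile()
  expect_equal(temporal_pressure(0, pr), 0)
  expect_equal(temporal_pressure(30, pr), 0, tolerance = 1e-12)
  tt <- seq(0, 30, by = 0.01)
  expect_equal(max(temporal_pressure(tt, pr)), 25000)
  expect_equal(temporal_pressure(15, pr), 25000)
  expect_warning(out <- temporal_pressure(31, pr), "support")
  expect_equal(out, 0)
})

test_that("the spatial footprint is calibrated to 3 mm at 90 percent of peak", {
  pr <- air_puff_profile()
  expect_equal(spatial_pressure(0, pr), 1)
  expect_equal(spatial_pressure(1.5, pr), 0.9, tolerance = 1e-12)
  rr <- seq(0, 8, by = 0.05)
  v <- spatial_pressure(rr, pr)
  expect_true(all(diff(v) <= 0))            # monotone non-increasing
  expect_equal(2 * max(rr[v >= 0.9]), 3, tolerance = 0.1)
  expect_lt(spatial_pressure(6, pr), 0.01)
  # the analytic radial derivative matches finite differences
  h <- 1e-6
  num <- (spatial_pressure(2 + h, pr) - spatial_pressure(2 - h, pr)) / (2 * h)
  expect_equal(tonosim:::.spatial_shape(2, pr)$deriv, num, tolerance = 1e-6)
})

test_that("a zero-strength puff produces no motion and no applanation", {
  res <- simulate_tonometry(material = "B", iop_mmhg = 12,
                            profile = air_puff_profile(peak_pressure = 0),
                            n_meridian = 20, n_thickness = 2,
                            n_puff_steps = 3)
  expect_equal(res$max_apical_displacement, 0, tolerance = 1e-9)
  expect_true(is.na(res$first_applanation_time))
  pp <- extract_apex_paths(res)
  expect_lt(diff(range(pp$anterior_lambda)), 1e-9)   # single-point path
  expect_lt(diff(range(pp$posterior_sigma_MPa)), 1e-9)
})

test_that("the baseline run shows the bending sequence of a puff test", {
  res <- std_run("C", 19, 585)
  pp <- extract_apex_paths(res)
  n <- nrow(pp)

  # pre-puff: pure membrane tension at both apex points
  expect_gt(pp$anterior_sigma_MPa[1], 0)
  expect_gt(pp$posterior_sigma_MPa[1], 0)
  expect_gt(pp$anterior_lambda[1], 1)
  expect_gt(pp$posterior_lambda[1], 1)

  # peak puff: anterior in compression, posterior in increased tension
  expect_lt(pp$anterior_sigma_MPa[n], 0)
  expect_lt(pp$anterior_lambda[n], 1)
  expect_gt(pp$posterior_sigma_MPa[n], pp$posterior_sigma_MPa[1])
  expect_gt(pp$posterior_lambda[n], 1)

  # applanation exists, happens strictly before the displacement maximum,
  # and the interpolated curvature there is flat within tolerance
  ta <- res$first_applanation_time
  expect_false(is.na(ta))
  tmax <- res$time_ms[which.max(res$apex_displacement_mm)]
  expect_lt(as.numeric(ta), tmax)
  kap_at <- stats::approx(res$time_ms, res$apex_curvature,
                          xout = as.numeric(ta))$y
  expect_lt(abs(kap_at), 1e-3)

  # displacement series is consistent with its reported maximum
  expect_equal(res$max_apical_displacement,
               max(res$apex_displacement_mm))
  expect_gte(min(res$apex_displacement_mm), 0)
})

test_that("snapshot fields show the bending signature of the deformed cornea", {
  res <- std_run("C", 19, 585)
  snap <- res$snapshots$max_displacement
  ft <- field_table(snap)
  mesh <- res$mesh
  nm_tot <- sum(mesh$nm)
  # first element layer is anterior, last is posterior
  lay <- (ft$elem - 1) %/% nm_tot
  central <- ft$R < 1.5 & ft$region == "cornea"
  ant <- central & lay == 0
  post <- central & lay == mesh$nt - 1
  expect_lt(mean(ft$log_hoop_strain[ant]), 0)
  expect_gt(mean(ft$log_hoop_strain[post]), 0)
})

test_that("displacement decreases with IOP and with stiffness", {
  coarse <- list(n_meridian = 24, n_thickness = 2, n_puff_steps = 10)
  r_lo <- do.call(simulate_tonometry,
                  c(list(material = "C", iop_mmhg = 10), coarse))
  r_hi <- do.call(simulate_tonometry,
                  c(list(material = "C", iop_mmhg = 28), coarse))
  expect_gt(r_lo$max_apical_displacement, r_hi$max_apical_displacement)
  r_A <- do.call(simulate_tonometry,
                 c(list(material = "A", iop_mmhg = 19), coarse))
  r_C <- do.call(simulate_tonometry,
                 c(list(material = "C", iop_mmhg = 19), coarse))
  expect_gt(r_A$max_apical_displacement, r_C$max_apical_displacement)
})

test_that("compressed fibers carry no load at the peak-puff anterior apex", {
  # Take the simulated peak-puff state at the anterior apex: both fiber
  # directions are shortened (I4bar < 1). For aligned fibers (kappa = 0)
  # the tension-only bracket then removes the anisotropic term exactly,
  # so zeroing k1 cannot change the stress. (At the study's dispersion
  # kappa = 0.33329 the fiber term stays weakly active through the
  # isotropic part kappa*(I1bar - 3), which is never negative, so full
  # fiber independence holds only in the aligned limit.)
  res <- std_run("C", 19, 585)
  peak <- res$snapshots$max_displacement
  ev <- tonosim:::.eval_F(res$mesh, peak$U, 1L, -1 / sqrt(3), -1 / sqrt(3))
  st <- deformation_state(ev$F, rbind(ev$a_merid, c(0, 0, 1)))
  expect_true(all(st$I4_bar < 1))         # both families compressed
  mC <- material_preset("C")
  aligned <- gho_params(C10 = mC$C10, k1 = mC$k1, k2 = mC$k2, kappa = 0)
  no_fib <- gho_params(C10 = mC$C10, k1 = 0, k2 = mC$k2, kappa = 0)
  s_fib <- gho_stress(st, aligned)$cauchy
  s_0 <- gho_stress(st, no_fib)$cauchy
  expect_equal(s_fib, s_0, tolerance = 1e-12)
  md <- ev$F %*% ev$a_merid
  md <- md / sqrt(sum(md^2))
  expect_lt(drop(t(md) %*% s_fib %*% md), 0)   # genuinely compressive
})

test_that("tonometry results serialize with the fixed CSV schema", {
  res <- std_run("C", 19, 585)
  f <- tempfile(fileext = ".csv")
  write_tonometry(res, f)
  back <- utils::read.csv(f)
  expect_identical(names(back),
                   c("time_ms", "apex_displacement_mm",
                     "anterior_sigma_MPa", "anterior_lambda",
                     "posterior_sigma_MPa", "posterior_lambda"))
  expect_equal(back$apex_displacement_mm, res$apex_displacement_mm,
               tolerance = 1e-9)
  unlink(f)
})
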