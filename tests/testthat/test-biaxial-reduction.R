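test_that("marker-quad deformation gradient recovery is exact and robust", {
  ref <- marker_quad(cbind(c(-2.5, 2.5, 2.5, -2.5), c(-2.5, -2.5, 2.5, 2.5)))
  # identity and pure dilation
  expect_equal(stretches_from_markers(ref, ref)$lambda_x, 1)
  dil <- unclass(ref) * 1.04
  st <- stretches_from_markers(ref, dil)
  expect_equal(c(st$lambda_x, st$lambda_y), c(1.04, 1.04), tolerance = 1e-12)
  # anisotropic map plus 1 um zero-mean jitter: recovered within 1e-3
  set.seed(5)
  for (i in 1:20) {
    cur <- unclass(ref) %*% diag(c(1.06, 1.02))
    jit <- matrix(rnorm(8, sd = 1e-3), 4, 2) # mm
    jit <- sweep(jit, 2, colMeans(jit))
    st <- stretches_from_markers(ref, cur + jit)
    expect_equal(st$lambda_x, 1.06, tolerance = 1e-3)
    expect_equal(st$lambda_y, 1.02, tolerance = 1e-3)
  }
  # rigid translation leaves stretches unchanged
  st2 <- stretches_from_markers(ref, sweep(dil, 2, c(12.3, -4.5), "+"))
  expect_equal(c(st2$lambda_x, st2$lambda_y), c(1.04, 1.04), tolerance = 1e-12)
  # degenerate quads are rejected
  expect_error(marker_quad(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               class = "gohbiax_domain_error")
})

test_that("log strain and load-to-stress conversion follow their definitions", {
  expect_equal(log_strain(1), 0)
  expect_equal(log_strain(exp(1)), 1)
  expect_equal(log_strain(1.05), 0.04879016, tolerance = 1e-7)
  expect_error(log_strain(0), class = "gohbiax_domain_error")

  geom <- specimen_geometry()
  expect_equal(cauchy_stress_from_load(0, "x", geom, 1.05, 1.05), 0)
  # 70 gf at lambda = 1.05 over a 15 mm x 1 mm section
  s70 <- cauchy_stress_from_load(70, "x", geom, 1.05, 1.05)
  expect_equal(s70, 70 * 9.80665e-3 * 1.05 / 15e-6 / 1000, tolerance = 1e-12)
  expect_equal(s70, 48.05, tolerance = 1e-3)
  # linear in load; inverse in thickness and width
  expect_equal(cauchy_stress_from_load(140, "x", geom, 1.05, 1.05), 2 * s70)
  expect_equal(cauchy_stress_from_load(70, "x", specimen_geometry(t0 = 2), 1.05, 1.05),
               s70 / 2)
  expect_equal(cauchy_stress_from_load(70, "y", specimen_geometry(L0x = 30), 1.05, 1.05),
               s70 / 2)
})

test_that("reduction round-trips noise-free synthetic records", {
  p <- scenario_params("aligned_0.1")
  proto <- scenario_protocol("aligned_0.1", n_frames = 20)
  rec <- generate_raw_records(p, proto)
  gt <- attr(rec, "ground_truth")
  red <- reduce_experiment(rec, proto$geometry)
  expect_equal(red$x$strain, gt$curves$x$strain, tolerance = 1e-12)
  expect_equal(red$x$stress_kPa, gt$curves$x$stress_kPa, tolerance = 1e-10)
  expect_equal(red$y$stress_kPa, gt$curves$y$stress_kPa, tolerance = 1e-10)
  # off-diagonal deformation-gradient components are pure QC noise here
  expect_lt(max(abs(red$frames$F_xy)), 1e-12)
})

test_that("only the loading branch survives an unloading half-cycle", {
  p <- scenario_params("nonaligned_0.03")
  proto <- scenario_protocol("nonaligned_0.03", n_frames = 12)
  rec <- generate_raw_records(p, proto)
  # append the reversed frames (unloading) with continuing time stamps
  unload <- rec[rev(seq_len(nrow(rec) - 1)), ]
  unload$time_s <- max(rec$time_s) + 10 * seq_len(nrow(unload))
  both <- as_biaxial_records(rbind(as.data.frame(rec), as.data.frame(unload)))
  red <- reduce_experiment(both, proto$geometry)
  expect_equal(nrow(red$x), 12L)
  expect_equal(max(red$frames$frame), 12L)
  expect_true(all(diff(red$x$strain) > 0))
})

test_that("reference-policy choice shifts strains by a constant log stretch", {
  p <- scenario_params("nonaligned_0.1")
  proto <- scenario_protocol("nonaligned_0.1", n_frames = 10)
  rec <- generate_raw_records(p, proto)
  # prepend a slack frame before the preload (smaller marker square, no load)
  slack <- rec[1, ]
  slack$time_s <- -10
  lam0 <- 0.995
  mcols <- c("m1x", "m1y", "m2x", "m2y", "m3x", "m3y", "m4x", "m4y")
  slack[mcols] <- as.numeric(slack[mcols]) * lam0
  slack[c("load_x_g", "load_y_g")] <- 0
  full <- as_biaxial_records(rbind(slack, as.data.frame(rec)))
  red_pre <- reduce_experiment(full, proto$geometry, ref_policy = "preload")
  red_first <- reduce_experiment(full, proto$geometry, ref_policy = "first_frame")
  shift <- red_first$x$strain[-1] - red_pre$x$strain
  expect_equal(shift, rep(-log(lam0), length(shift)), tolerance = 1e-12)
  # and the preload policy errors when no frame is near the preload
  rec2 <- as.data.frame(rec)
  rec2$load_x_g <- rec2$load_x_g + 10
  rec2$load_y_g <- rec2$load_y_g + 10
  err <- expect_error(reduce_experiment(as_biaxial_records(rec2), proto$geometry),
                      class = "gohbiax_domain_error")
  expect_match(conditionMessage(err), "preload")
})

test_that("tangent modulus applies the 0.5 slope convention", {
  eps <- seq(0, 0.06, length.out = 25)
  # linear curve: sigma = 100 eps -> E_t = 50 everywhere
  lin <- stress_strain_curve(eps, 100 * eps, "x")
  et <- tangent_modulus(lin)
  expect_equal(et$Et_kPa, rep(50, 25), tolerance = 1e-10)
  expect_equal(tangent_modulus(lin, raw_slope = TRUE)$Et_kPa, rep(100, 25),
               tolerance = 1e-10)
  # quadratic: sigma = eps^2 -> E_t = eps (central differences are exact);
  # at eps = 0.1 the tangent modulus is 0.1
  eq <- seq(0, 0.2, length.out = 41)
  etq <- tangent_modulus(stress_strain_curve(eq, eq^2, "x"))
  expect_equal(etq$Et_kPa[21], 0.1, tolerance = 1e-10)
  expect_equal(etq$Et_kPa[2:40], eq[2:40], tolerance = 1e-10)
  # GOH forward curves have increasing tangent modulus
  for (scen in c("nonaligned_0.03", "aligned_0.25")) {
    cv <- equibiaxial_curve(scenario_params(scen), seq(1, 1.05, length.out = 30))
    ets <- tangent_modulus(cv$x)
    expect_true(all(diff(ets$Et_kPa) > 0))
  }
  expect_error(tangent_modulus(stress_strain_curve(c(0, 0.1), c(0, 1), "x")),
               class = "gohbiax_domain_error")
  # smoothing leaves an exactly linear curve alone where windows are complete
  expect_equal(tangent_modulus(lin, smoothing_window = 5)$Et_kPa[4:22],
               rep(50, 19), tolerance = 1e-10)
})

test_that("tangent-modulus averaging interpolates onto the common grid", {
  eps <- seq(0, 0.05, length.out = 11)
  c40 <- structure(data.frame(strain = eps, Et_kPa = rep(40, 11)),
                   class = c("tangent_modulus_curve", "data.frame"))
  c60 <- structure(data.frame(strain = eps, Et_kPa = rep(60, 11)),
                   class = c("tangent_modulus_curve", "data.frame"))
  grid <- seq(0.005, 0.045, length.out = 21)
  avg <- average_tangent_modulus(list(c40, c60), grid)
  expect_equal(avg$Et_kPa, rep(50, 21))
  expect_equal(avg$sd_kPa, rep(stats::sd(c(40, 60)), 21))
  # identical curves average to themselves; linear interpolation is exact
  lin <- structure(data.frame(strain = eps, Et_kPa = 10 + 300 * eps),
                   class = c("tangent_modulus_curve", "data.frame"))
  avg2 <- average_tangent_modulus(list(lin, lin), grid)
  expect_equal(avg2$Et_kPa, 10 + 300 * grid, tolerance = 1e-12)
  expect_error(average_tangent_modulus(list(c40), seq(0, 0.1, 0.01)),
               class = "gohbiax_domain_error")
})
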