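test_that("parameter validation enforces the physical ranges", {
  expect_error(material_params(C10 = -1), class = "gohbiax_domain_error")
  expect_error(material_params(C10 = 1, k1 = 5, k2 = 0),
               class = "gohbiax_domain_error")
  expect_error(material_params(C10 = 1, kappa = 0.4),
               class = "gohbiax_domain_error")
  expect_error(material_params(C10 = 1, gamma = 95),
               class = "gohbiax_domain_error")
  expect_error(material_params(C10 = 1, D = 0.1),
               class = "gohbiax_domain_error")
  p <- material_params(C10 = 11, k1 = 21000, k2 = 600, gamma = 45, kappa = 0.333)
  expect_s3_class(p, "material_params")
  d <- planar_deformation(1.05, 1.02)
  expect_equal(d$lambda_x * d$lambda_y * d$lambda_z, 1)
})

test_that("dispersion integral recovers the closed-form limits", {
  # uniform density: isotropy
  expect_equal(kappa_from_density(function(t) rep(1, length(t))), 1 / 3,
               tolerance = 1e-8)
  # narrow peak at theta0: kappa -> sin^2(theta0)/2 up to O(width^2)
  expect_lt(abs(kappa_from_density(peaked_density(pi / 2)) - 0.5), 2e-4)
  expect_lt(abs(kappa_from_density(peaked_density(0.6)) - sin(0.6)^2 / 2), 2e-4)
  # perfect alignment (peak collapsing onto the mean direction): kappa -> 0
  expect_lt(kappa_from_density(peaked_density(0.02)), 1e-3)
  # invalid densities are rejected
  expect_error(kappa_from_density(function(t) rep(2, length(t))),
               class = "gohbiax_domain_error")
  expect_error(kappa_from_density(function(t) cos(t)),
               class = "gohbiax_domain_error")
})

test_that("kappa of random valid mixture densities stays in [0, 1/2]", {
  set.seed(11)
  for (i in 1:25) {
    t0 <- runif(2, 0.1, pi - 0.1)
    w <- runif(1)
    d1 <- peaked_density(t0[1], width = runif(1, 0.05, 0.5))
    d2 <- peaked_density(t0[2], width = runif(1, 0.05, 0.5))
    mix <- function(t) w * d1(t) + (1 - w) * d2(t)
    k <- kappa_from_density(mix)
    expect_gte(k, 0)
    expect_lte(k, 0.5 + 1e-10)
  }
})

test_that("fiber strain state follows the dispersed-strain definition", {
  # identity: undeformed, fibers inactive
  p <- material_params(C10 = 10, k1 = 100, k2 = 10, gamma = 30, kappa = 0.2)
  st <- fiber_state(p, planar_deformation(1, 1))
  expect_equal(st$I1_bar, 3)
  expect_equal(unname(st$I4_bar), c(1, 1))
  expect_equal(unname(st$E_bar), c(0, 0))
  expect_false(any(st$active))
  # equibiaxial: every in-plane direction stretches by lambda
  st2 <- fiber_state(p, planar_deformation(1.04, 1.04))
  expect_equal(unname(st2$I4_bar), rep(1.04^2, 2), tolerance = 1e-12)
  # direct substitution at kappa = 0, gamma = 0
  p0 <- material_params(C10 = 10, k1 = 100, k2 = 10, gamma = 0, kappa = 0)
  st3 <- fiber_state(p0, planar_deformation(1.05, 1))
  expect_equal(unname(st3$E_bar), rep(1.05^2 - 1, 2), tolerance = 1e-12)
  expect_equal(unname(st3$E_bar)[1], 0.1025, tolerance = 1e-10)
})

test_that("strain energy matches the brute-force tensor oracle", {
  # identity deformation stores no energy
  p <- scenario_params("nonaligned_0.03")
  expect_equal(strain_energy(p, planar_deformation(1, 1)), 0)
  # neo-Hookean closed form when the fiber term is off
  nh <- material_params(C10 = 7)
  lam <- 1.04
  expect_equal(strain_energy(nh, planar_deformation(lam, lam)),
               7 * (2 * lam^2 + lam^-4 - 3), tolerance = 1e-12)
  # fitted parameter sets against explicit tensor algebra, with shear
  set.seed(21)
  for (scen in c("nonaligned_0.03", "aligned_0.25")) {
    sp <- scenario_params(scen)
    for (i in 1:10) {
      lx <- runif(1, 1, 1.05)
      ly <- runif(1, 1, 1.05)
      sh <- runif(1, -0.03, 0.03)
      expect_equal(strain_energy(sp, planar_deformation(lx, ly, sh), exp_cap = Inf),
                   oracle_energy(sp, lx, ly, sh), tolerance = 1e-10)
    }
  }
  # frozen spot value: nonaligned 0.03% set at an equibiaxial stretch of 1.05
  expect_equal(strain_energy(scenario_params("nonaligned_0.03"),
                             planar_deformation(1.05, 1.05), exp_cap = Inf),
               oracle_energy(scenario_params("nonaligned_0.03"), 1.05, 1.05),
               tolerance = 1e-12)
})

test_that("the overflow guard names the runaway fiber family", {
  p <- material_params(C10 = 1, k1 = 100, k2 = 1150, gamma = 0, kappa = 0)
  err <- expect_error(strain_energy(p, planar_deformation(1.5, 1)),
                      class = "gohbiax_range_error")
  expect_match(conditionMessage(err), "fiber family")
  expect_error(cauchy_stress_biaxial(p, 1.5, 1), class = "gohbiax_range_error")
  # raising the cap admits the state
  expect_silent(strain_energy(p, planar_deformation(1.5, 1), exp_cap = Inf))
})

test_that("biaxial stresses reduce to the incompressible neo-Hookean closed forms", {
  p <- material_params(C10 = 0.5)
  lam <- seq(1, 1.2, length.out = 7)
  s <- cauchy_stress_biaxial(p, lam, lam)
  expect_equal(s$sigma_xx, 2 * 0.5 * (lam^2 - lam^-4), tolerance = 1e-12)
  expect_equal(s$sigma_yy, s$sigma_xx, tolerance = 1e-12)
  expect_equal(unname(cauchy_stress_biaxial(p, 1, 1)$sigma_xx), 0)
  # simple shear: tau = 2 C10 s, antisymmetric
  sh <- seq(-0.2, 0.2, length.out = 9)
  expect_equal(simple_shear_stress(p, sh), 2 * 0.5 * sh, tolerance = 1e-12)
})

test_that("stress components equal finite-difference energy derivatives", {
  set.seed(7)
  for (i in 1:60) {
    p <- random_params()
    lx <- runif(1, 1, 1.06)
    ly <- runif(1, 1, 1.06)
    s <- cauchy_stress_biaxial(p, lx, ly, exp_cap = Inf)
    fd <- fd_stress(p, lx, ly)
    expect_rel_equal(s$sigma_xx, fd["sigma_xx"], 1e-6)
    expect_rel_equal(s$sigma_yy, fd["sigma_yy"], 1e-6)
    sh <- runif(1, -0.05, 0.05)
    sxy <- cauchy_stress_planar(p, planar_deformation(lx, ly, sh),
                                exp_cap = Inf)[["sigma_xy"]]
    expect_equal(sxy, unname(fd_stress(p, lx, ly, sh)["sigma_xy"]),
                 tolerance = 1e-5)
  }
})

test_that("kappa = 1/3 makes the response isotropic for any fiber angle", {
  set.seed(13)
  lam <- 1.05
  for (i in 1:100) {
    p <- material_params(C10 = 5, k1 = 2000, k2 = 300,
                         gamma = runif(1, 0, 90), kappa = 1 / 3)
    s <- cauchy_stress_biaxial(p, lam, lam, exp_cap = Inf)
    expect_equal(s$sigma_xx, s$sigma_yy, tolerance = 1e-12)
  }
  # and simple shear is antisymmetric there
  p <- material_params(C10 = 5, k1 = 2000, k2 = 300, gamma = 30, kappa = 1 / 3)
  expect_equal(simple_shear_stress(p, -0.04, exp_cap = Inf),
               -simple_shear_stress(p, 0.04, exp_cap = Inf), tolerance = 1e-12)
})

test_that("compressed fiber families carry no load", {
  # x-aligned families, no dispersion: stretching y at lambda_x <= 1 keeps
  # E <= 0, so the response is exactly the fiber-free matrix
  p <- material_params(C10 = 4, k1 = 5000, k2 = 500, gamma = 0, kappa = 0)
  nh <- material_params(C10 = 4)
  for (ly in c(1.02, 1.05, 1.1)) {
    st <- fiber_state(p, planar_deformation(0.98, ly))
    expect_true(all(st$E_bar <= 0))
    expect_false(any(st$active))
    s <- cauchy_stress_biaxial(p, 0.98, ly)
    s0 <- cauchy_stress_biaxial(nh, 0.98, ly)
    expect_equal(s$sigma_yy, s0$sigma_yy, tolerance = 1e-12)
    expect_equal(s$sigma_xx, s0$sigma_xx, tolerance = 1e-12)
  }
})

test_that("equibiaxial curve sweep validates its grid and matches closed forms", {
  p <- material_params(C10 = 2)
  expect_error(equibiaxial_curve(p, c(1.02, 1.05)), class = "gohbiax_domain_error")
  expect_error(equibiaxial_curve(p, c(1, 1.05, 1.03)), class = "gohbiax_domain_error")
  one <- equibiaxial_curve(p, 1)
  expect_equal(nrow(one$x), 1L)
  expect_equal(one$x$stress_kPa, 0)
  expect_equal(one$x$strain, 0)
  grid <- seq(1, 1.3, length.out = 20)
  cv <- equibiaxial_curve(p, grid)
  expect_equal(cv$x$stress_kPa, 2 * 2 * (grid^2 - grid^-4), tolerance = 1e-12)
  expect_equal(cv$x$strain, log(grid))
  # aligned fitted set: parallel axis stiffer at every positive strain
  av <- equibiaxial_curve(scenario_params("aligned_0.03"),
                          seq(1, 1.05, length.out = 15))
  expect_true(all(av$x$stress_kPa[-1] > av$y$stress_kPa[-1]))
})

test_that("small-strain moduli give the ideal-network 3:1 ratio", {
  p <- material_params(C10 = 0.5)
  m <- small_strain_moduli(p)
  expect_equal(m$E0, 6 * 0.5, tolerance = 1e-6)
  expect_equal(m$G0, 2 * 0.5, tolerance = 1e-8)
  expect_equal(m$E0 / m$G0, 3, tolerance = 1e-6)
  # isotropic limit holds with the fiber term active
  pf <- material_params(C10 = 2, k1 = 3000, k2 = 400, gamma = 30, kappa = 1 / 3)
  mf <- small_strain_moduli(pf)
  expect_equal(mf$E0 / mf$G0, 3, tolerance = 1e-4)
})
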