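# Independent oracles used across the suite. These deliberately avoid the
# package's invariant shortcuts: energies come from explicit 3x3 tensor
# algebra, stresses from finite differences of the energy under the
# incompressibility constraint.

# Brute-force strain energy from the deformation gradient
# F = [[lx, s, 0], [0, ly, 0], [0, 0, 1/(lx ly)]]: build C = F^T F, take
# I1 = tr(C), I4 = a . C a for unit fiber directions at +/-gamma, then apply
# the energy formula directly.
oracle_energy <- function(params, lx, ly, shear = 0) {
  FF <- matrix(c(lx, 0, 0,
                 shear, ly, 0,
                 0, 0, 1 / (lx * ly)), 3, 3)
  C <- t(FF) %*% FF
  I1 <- sum(diag(C))
  g <- params$gamma * pi / 180
  U <- params$C10 * (I1 - 3)
  if (params$k1 > 0) {
    for (sgn in c(1, -1)) {
      a <- c(cos(g), sgn * sin(g), 0)
      I4 <- drop(a %*% C %*% a)
      E <- params$kappa * (I1 - 3) + (1 - 3 * params$kappa) * (I4 - 1)
      U <- U + params$k1 / (2 * params$k2) * (exp(params$k2 * max(E, 0)^2) - 1)
    }
  }
  U
}

# Central-difference Cauchy stresses from the constrained energy:
# sigma_ii = lambda_i dU/dlambda_i (lambda_z eliminated, plane stress),
# sigma_xy = lambda_y dU/dshear.
fd_stress <- function(params, lx, ly, shear = 0, h = 1e-6) {
  U <- function(a, b, s) strain_energy(params, planar_deformation(a, b, s),
                                       exp_cap = Inf)
  c(sigma_xx = lx * (U(lx * (1 + h), ly, shear) - U(lx * (1 - h), ly, shear)) /
      (2 * h * lx),
    sigma_yy = ly * (U(lx, ly * (1 + h), shear) - U(lx, ly * (1 - h), shear)) /
      (2 * h * ly),
    sigma_xy = ly * (U(lx, ly, shear + h) - U(lx, ly, shear - h)) / (2 * h))
}

# Random admissible parameter set within the fitted magnitude range
random_params <- function() {
  material_params(C10 = stats::runif(1, 1, 20),
                  k1 = 10^stats::runif(1, 2, 4.7),
                  k2 = stats::runif(1, 50, 1200),
                  gamma = stats::runif(1, 0, 90),
                  kappa = stats::runif(1, 0, 1 / 3))
}

# Narrow normalized Gaussian bump at theta0: numerically close to a delta
# density; its kappa has the closed form sin^2(theta0) / 2. Normalized on a
# fine trapezoid grid so narrow peaks are captured reliably.
peaked_density <- function(theta0, width = 0.01) {
  raw <- function(t) exp(-0.5 * ((t - theta0) / width)^2)
  g <- seq(0, pi, length.out = 200001)
  nrm <- sum(raw(g) * sin(g)) * (pi / 200000) / 2
  function(t) raw(t) / nrm
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
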