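#' GOH material parameters
#'
#' Constructs and validates the parameter set of the Gasser-Ogden-Holzapfel
#' (GOH) strain-energy function for a membrane reinforced by two symmetric,
#' dispersed fiber families,
#' \deqn{U = C_{10}(\bar I_1 - 3) + \frac{k_1}{2k_2}\sum_{\alpha=1}^{N}
#'   \left\{\exp\!\left[k_2\langle\bar E_\alpha\rangle^2\right]-1\right\},}
#' with \eqn{\bar E_\alpha = \kappa(\bar I_1-3) + (1-3\kappa)(\bar I_4^{(\alpha\alpha)}-1)}
#' and \eqn{\langle x\rangle = \max(x, 0)} (Macauley bracket: fibers carry load
#' only in extension). The material is treated as exactly incompressible
#' (\eqn{D = 0}, \eqn{J = 1}), so the volumetric term is dropped and the
#' reaction pressure is eliminated through the plane-stress condition
#' \eqn{\sigma_{zz} = 0}.
#'
#' @param C10 matrix stiffness parameter, kPa; must be > 0.
#' @param k1 fiber stress-like parameter, kPa; must be >= 0.
#' @param k2 dimensionless fiber exponent; must be > 0 whenever `k1 > 0`.
#' @param gamma mean fiber angle measured from the x (stiff) loading axis,
#'   degrees, in \[0, 90\]. The two families lie in-plane at +gamma and -gamma.
#' @param kappa fiber dispersion parameter, dimensionless, in \[0, 1/3\]:
#'   0 is perfect alignment, 1/3 an isotropic 3-D orientation distribution.
#' @param D inverse bulk modulus, kPa^-1. Only `D = 0` (incompressible) is
#'   supported.
#' @param n_families number of fiber families; fixed at 2.
#' @return An object of class `material_params`.
#' @examples
#' material_params(C10 = 11, k1 = 21000, k2 = 600, gamma = 45, kappa = 0.333)
#' @export
material_params <- function(C10, k1 = 0, k2 = 1, gamma = 45, kappa = 1 / 3,
                            D = 0, n_families = 2) {
  check_scalar(C10, "C10", positive = TRUE)
  check_scalar(k1, "k1", nonneg = TRUE)
  check_scalar(k2, "k2")
  if (k1 > 0 && k2 <= 0) abort_domain("'k2' must be > 0 when k1 > 0 (got %g)", k2)
  check_scalar(gamma, "gamma")
  if (gamma < 0 || gamma > 90) abort_domain("'gamma' must lie in [0, 90] degrees (got %g)", gamma)
  check_scalar(kappa, "kappa")
  if (kappa < 0 || kappa > 1 / 3 + 1e-12) {
    abort_domain("'kappa' must lie in [0, 1/3] (got %g)", kappa)
  }
  check_scalar(D, "D", nonneg = TRUE)
  if (D != 0) abort_domain("only the incompressible model (D = 0) is supported")
  if (!identical(as.integer(n_families), 2L)) {
    abort_domain("only n_families = 2 (symmetric families at +/-gamma) is supported")
  }
  structure(
    list(C10 = C10, k1 = k1, k2 = k2, gamma = gamma,
         kappa = min(kappa, 1 / 3), D = 0, n_families = 2L),
    class = "material_params"
  )
}

#' @export
print.material_params <- function(x, ...) {
  cat("GOH material parameters (incompressible, 2 fiber families at +/-gamma)\n")
  cat(sprintf("  C10   = %g kPa\n  k1    = %g kPa\n  k2    = %g\n", x$C10, x$k1, x$k2))
  cat(sprintf("  gamma = %g deg\n  kappa = %g\n", x$gamma, x$kappa))
  invisible(x)
}

#' Planar deformation state of an incompressible membrane
#'
#' In-plane principal stretches plus an optional in-plane simple-shear amount.
#' The thickness stretch is derived from exact incompressibility,
#' `lambda_z = 1/(lambda_x * lambda_y)`, so `J = 1` always. The deformation
#' gradient represented is
#' `F = [[lambda_x, shear, 0], [0, lambda_y, 0], [0, 0, lambda_z]]`.
#'
#' @param lambda_x,lambda_y in-plane stretches (> 0), dimensionless.
#' @param shear in-plane simple-shear amount (0 for biaxial states).
#' @return An object of class `planar_deformation` with the derived
#'   `lambda_z`.
#' @export
planar_deformation <- function(lambda_x, lambda_y, shear = 0) {
  check_scalar(lambda_x, "lambda_x", positive = TRUE)
  check_scalar(lambda_y, "lambda_y", positive = TRUE)
  check_scalar(shear, "shear")
  structure(
    list(lambda_x = lambda_x, lambda_y = lambda_y,
         lambda_z = 1 / (lambda_x * lambda_y), shear = shear),
    class = "planar_deformation"
  )
}

# Vectorized kinematics + fiber-term core shared by all model operations.
# lx, ly, shear may be equal-length vectors. Returns invariants, per-family
# dispersed fiber strains E (Macauley-bracketed separately by callers), and
# the in-plane push-forward components of the two unit fiber directions.
goh_core <- function(params, lx, ly, shear = 0) {
  lz <- 1 / (lx * ly)
  I1 <- lx^2 + ly^2 + shear^2 + lz^2
  g <- params$gamma * pi / 180
  cg <- cos(g)
  sg <- sin(g)
  # m = F a0 for a0 = (cos g, +/- sin g, 0)
  mpx <- lx * cg + shear * sg
  mpy <- ly * sg
  mmx <- lx * cg - shear * sg
  mmy <- -ly * sg
  I4p <- mpx^2 + mpy^2
  I4m <- mmx^2 + mmy^2
  k <- params$kappa
  Ep <- k * (I1 - 3) + (1 - 3 * k) * (I4p - 1)
  Em <- k * (I1 - 3) + (1 - 3 * k) * (I4m - 1)
  list(lz = lz, I1 = I1, I4p = I4p, I4m = I4m, Ep = Ep, Em = Em,
       mpx = mpx, mpy = mpy, mmx = mmx, mmy = mmy)
}

# Guard against runaway exponents exp(k2 <E>^2); errs naming the family.
check_exponent <- function(params, Ep, Em, exp_cap) {
  if (params$k1 <= 0 || !is.finite(exp_cap)) return(invisible(NULL))
  ap <- params$k2 * pmax(Ep, 0)^2
  am <- params$k2 * pmax(Em, 0)^2
  if (any(ap > exp_cap)) {
    abort_range("fiber family at +%g deg: k2*<E>^2 = %.4g exceeds the overflow bound %g",
                params$gamma, max(ap), exp_cap)
  }
  if (any(am > exp_cap)) {
    abort_range("fiber family at -%g deg: k2*<E>^2 = %.4g exceeds the overflow bound %g",
                params$gamma, max(am), exp_cap)
  }
  invisible(NULL)
}

#' Dispersed fiber strain state
#'
#' Evaluates the invariants and per-family dispersed fiber strains
#' \eqn{\bar E_\alpha = \kappa(\bar I_1-3)+(1-3\kappa)(\bar I_4^{(\alpha\alpha)}-1)}
#' for the two families at +/-gamma. A family is *active* (contributes stress)
#' iff \eqn{\bar E_\alpha > 0}.
#'
#' @param params a [material_params()] object.
#' @param def a [planar_deformation()] object.
#' @return A list of class `fiber_strain_state` with `I1_bar`, `I4_bar`
#'   (length 2: families +gamma, -gamma), `E_bar` (length 2) and `active`
#'   (logical, length 2).
#' @export
fiber_state <- function(params, def) {
  stopifnot(inherits(params, "material_params"), inherits(def, "planar_deformation"))
  co <- goh_core(params, def$lambda_x, def$lambda_y, def$shear)
  structure(
    list(I1_bar = co$I1,
         I4_bar = c(plus = co$I4p, minus = co$I4m),
         E_bar = c(plus = co$Ep, minus = co$Em),
         active = c(plus = co$Ep > 0, minus = co$Em > 0)),
    class = "fiber_strain_state"
  )
}

#' Dispersion parameter from an orientation density
#'
#' Computes \eqn{\kappa = \tfrac14\int_0^\pi \rho(\Theta)\sin^3\Theta\,
#' d\Theta} by adaptive quadrature. The density must satisfy the normalization
#' \eqn{\tfrac12\int_0^\pi \rho(\Theta)\sin\Theta\, d\Theta = 1} and be
#' non-negative; the uniform density \eqn{\rho \equiv 1} gives
#' \eqn{\kappa = 1/3} (isotropy), a density concentrated on the mean direction
#' gives 0, and any valid density gives a value in \[0, 1/2\].
#'
#' @param rho vectorized function of the polar angle Theta in \[0, pi\]
#'   returning the orientation density.
#' @param norm_tol tolerance on the normalization check.
#' @param n_quad number of composite-Simpson panels (made even internally).
#'   The fixed fine grid is deliberate: sharply peaked (near-delta) densities
#'   are legitimate inputs and must not be missed by adaptive subdivision.
#' @return kappa, dimensionless.
#' @examples
#' kappa_from_density(function(th) rep(1, length(th))) # 1/3
#' @export
kappa_from_density <- function(rho, norm_tol = 1e-6, n_quad = 20000L) {
  if (!is.function(rho)) abort_domain("'rho' must be a function of Theta")
  n <- as.integer(n_quad)
  if (n < 10L) abort_domain("'n_quad' must be at least 10")
  if (n %% 2L == 1L) n <- n + 1L
  grid <- seq(0, pi, length.out = n + 1L)
  vals <- rho(grid)
  if (length(vals) != length(grid) || any(!is.finite(vals))) {
    abort_domain("'rho' must return finite values over [0, pi]")
  }
  if (min(vals) < -1e-10) abort_domain("orientation density must be non-negative")
  h <- pi / n
  simpson <- function(f) {
    w <- rep(c(4, 2), length.out = n - 1L)
    h / 3 * (f[1] + sum(w * f[2:n]) + f[n + 1L])
  }
  nrm <- 0.5 * simpson(vals * sin(grid))
  if (abs(nrm - 1) > norm_tol) {
    abort_domain("orientation density is not normalized: (1/2) int rho sin = %.8g (expected 1)", nrm)
  }
  0.25 * simpson(vals * sin(grid)^3)
}

#' GOH strain-energy density
#'
#' Evaluates \eqn{U = C_{10}(\bar I_1-3) + \frac{k_1}{2k_2}\sum_\alpha
#' [\exp(k_2\langle\bar E_\alpha\rangle^2)-1]} for an incompressible planar
#' deformation (the volumetric term vanishes identically at `J = 1`).
#'
#' @inheritParams fiber_state
#' @param exp_cap overflow guard: an error of class `gohbiax_range_error` is
#'   raised if `k2 * <E>^2` exceeds this bound for either family. Table-1-sized
#'   exponents (k2 up to 1150) make the fiber term explosive outside the
#'   fitted strain range, so the guard is deliberately conservative.
#' @return energy density, kPa.
#' @export
strain_energy <- function(params, def, exp_cap = getOption("gohbiax.exp_cap", 50)) {
  stopifnot(inherits(params, "material_params"), inherits(def, "planar_deformation"))
  co <- goh_core(params, def$lambda_x, def$lambda_y, def$shear)
  iso <- params$C10 * (co$I1 - 3)
  if (params$k1 <= 0) return(iso)
  check_exponent(params, co$Ep, co$Em, exp_cap)
  Ep <- max(co$Ep, 0)
  Em <- max(co$Em, 0)
  fib <- params$k1 / (2 * params$k2) *
    ((exp(params$k2 * Ep^2) - 1) + (exp(params$k2 * Em^2) - 1))
  iso + fib
}

# Vectorized full in-plane Cauchy stress (sigma_xx, sigma_yy, sigma_xy), kPa.
# Plane stress: the incompressibility pressure is p = 2 U1 lambda_z^2 so that
# sigma_zz = 0 (both fiber families are in-plane). Fibers with E <= 0 are
# inactive and contribute nothing.
cauchy_stress_core <- function(params, lx, ly, shear = 0,
                               exp_cap = getOption("gohbiax.exp_cap", 50)) {
  co <- goh_core(params, lx, ly, shear)
  check_exponent(params, co$Ep, co$Em, exp_cap)
  Ep <- pmax(co$Ep, 0)
  Em <- pmax(co$Em, 0)
  # dU/dE per family (zero when inactive), and the invariant derivatives
  # dE/dI1 = kappa, dE/dI4 = 1 - 3 kappa
  if (params$k1 > 0) {
    fp <- params$k1 * Ep * exp(params$k2 * Ep^2)
    fm <- params$k1 * Em * exp(params$k2 * Em^2)
  } else {
    fp <- fm <- 0 * Ep
  }
  U1 <- params$C10 + params$kappa * (fp + fm)
  U4p <- (1 - 3 * params$kappa) * fp
  U4m <- (1 - 3 * params$kappa) * fm
  lz2 <- co$lz^2
  sxx <- 2 * U1 * (lx^2 + shear^2 - lz2) + 2 * (U4p * co$mpx^2 + U4m * co$mmx^2)
  syy <- 2 * U1 * (ly^2 - lz2) + 2 * (U4p * co$mpy^2 + U4m * co$mmy^2)
  sxy <- 2 * U1 * shear * ly + 2 * (U4p * co$mpx * co$mpy + U4m * co$mmx * co$mmy)
  list(sigma_xx = sxx, sigma_yy = syy, sigma_xy = sxy)
}

#' Cauchy stresses for an axis-aligned biaxial stretch
#'
#' Exact plane-stress Cauchy stresses of the incompressible GOH membrane under
#' in-plane stretches `(lambda_x, lambda_y)` with `lambda_z = 1/(lambda_x
#' lambda_y)`. The reaction pressure is chosen so `sigma_zz = 0`; the shear
#' stress vanishes by the +/-gamma family symmetry. Vectorized over
#' equal-length stretch vectors.
#'
#' @inheritParams strain_energy
#' @param lambda_x,lambda_y in-plane stretches (> 0); equal-length vectors.
#' @return list with numeric vectors `sigma_xx`, `sigma_yy` (kPa).
#' @export
cauchy_stress_biaxial <- function(params, lambda_x, lambda_y,
                                  exp_cap = getOption("gohbiax.exp_cap", 50)) {
  stopifnot(inherits(params, "material_params"))
  if (length(lambda_x) != length(lambda_y)) {
    abort_domain("lambda_x and lambda_y must have equal length")
  }
  if (any(!is.finite(lambda_x)) || any(!is.finite(lambda_y)) ||
      any(lambda_x <= 0) || any(lambda_y <= 0)) {
    abort_domain("stretches must be finite and > 0")
  }
  s <- cauchy_stress_core(params, lambda_x, lambda_y, 0, exp_cap)
  list(sigma_xx = s$sigma_xx, sigma_yy = s$sigma_yy)
}

#' Full in-plane Cauchy stress of a planar deformation
#'
#' As [cauchy_stress_biaxial()] but for a general [planar_deformation()]
#' including in-plane simple shear; returns the shear component as well.
#'
#' @inheritParams strain_energy
#' @return named numeric vector `c(sigma_xx, sigma_yy, sigma_xy)`, kPa.
#' @export
cauchy_stress_planar <- function(params, def,
                                 exp_cap = getOption("gohbiax.exp_cap", 50)) {
  stopifnot(inherits(params, "material_params"), inherits(def, "planar_deformation"))
  s <- cauchy_stress_core(params, def$lambda_x, def$lambda_y, def$shear, exp_cap)
  c(sigma_xx = s$sigma_xx, sigma_yy = s$sigma_yy, sigma_xy = s$sigma_xy)
}

#' Cauchy shear stress under simple shear
#'
#' In-plane simple shear of the incompressible GOH membrane
#' (`F = I + shear e_x (x) e_y`): returns `sigma_xy`. For `k1 = 0` this is the
#' neo-Hookean result `2 * C10 * shear` exactly.
#'
#' @inheritParams strain_energy
#' @param shear shear amount(s); vectorized.
#' @return shear stress, kPa.
#' @export
simple_shear_stress <- function(params, shear,
                                exp_cap = getOption("gohbiax.exp_cap", 50)) {
  stopifnot(inherits(params, "material_params"))
  if (any(!is.finite(shear))) abort_domain("'shear' must be finite")
  one <- rep(1, length(shear))
  cauchy_stress_core(params, one, one, shear, exp_cap)$sigma_xy
}

#' Forward equibiaxial stress-strain curves
#'
#' Sweeps the model over an equibiaxial stretch grid and returns per-axis
#' Cauchy stress versus logarithmic strain tables (the forward model behind
#' simulated equibiaxial tests).
#'
#' @inheritParams strain_energy
#' @param stretch_grid numeric vector of stretches, strictly increasing and
#'   starting at 1 (a single value of 1 is allowed).
#' @return A `biaxial_curves` list with elements `x` and `y`, each a
#'   [stress_strain_curve()].
#' @export
equibiaxial_curve <- function(params, stretch_grid,
                              exp_cap = getOption("gohbiax.exp_cap", 50)) {
  stopifnot(inherits(params, "material_params"))
  if (length(stretch_grid) < 1L || any(!is.finite(stretch_grid))) {
    abort_domain("'stretch_grid' must be a non-empty finite numeric vector")
  }
  if (abs(stretch_grid[1] - 1) > 1e-12) {
    abort_domain("'stretch_grid' must start at 1 (got %g)", stretch_grid[1])
  }
  if (length(stretch_grid) > 1L && any(diff(stretch_grid) <= 0)) {
    abort_domain("'stretch_grid' must be strictly increasing")
  }
  s <- cauchy_stress_biaxial(params, stretch_grid, stretch_grid, exp_cap)
  eps <- log(stretch_grid)
  biaxial_curves(
    stress_strain_curve(eps, s$sigma_xx, axis = "x"),
    stress_strain_curve(eps, s$sigma_yy, axis = "y")
  )
}

# sigma_xx under incompressible uniaxial extension along x: lambda_y solved so
# that sigma_yy = 0 (sigma_zz = 0 holds by construction).
uniaxial_stress_x <- function(params, lambda, exp_cap = Inf) {
  f <- function(ly) cauchy_stress_core(params, lambda, ly, 0, exp_cap)$sigma_yy
  ly <- stats::uniroot(f, interval = c(0.5, 1.5), extendInt = "upX",
                       tol = 1e-14)$root
  cauchy_stress_core(params, lambda, ly, 0, exp_cap)$sigma_xx
}

#' Small-strain tensile and shear moduli
#'
#' Numerical small-strain Young's modulus `E0` (slope of the uniaxial
#' incompressible Cauchy stress with both lateral stresses zero, at
#' `lambda -> 1`) and shear modulus `G0` (slope of the simple-shear stress at
#' zero shear), by central differences. For the fiber-free matrix (`k1 = 0`)
#' the exact incompressible neo-Hookean values are `E0 = 6 C10`,
#' `G0 = 2 C10`, ratio 3 — the ideal elastic-network baseline against which
#' the much larger experimental tensile-to-shear ratios of hydrated gels are
#' judged.
#'
#' @inheritParams strain_energy
#' @param step central-difference step on log strain / shear amount.
#' @return list with `E0` and `G0`, kPa.
#' @export
small_strain_moduli <- function(params, step = 1e-4) {
  stopifnot(inherits(params, "material_params"))
  check_scalar(step, "step", positive = TRUE)
  E0 <- (uniaxial_stress_x(params, exp(step)) -
           uniaxial_stress_x(params, exp(-step))) / (2 * step)
  G0 <- (simple_shear_stress(params, step, exp_cap = Inf) -
           simple_shear_stress(params, -step, exp_cap = Inf)) / (2 * step)
  list(E0 = E0, G0 = G0)
}
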