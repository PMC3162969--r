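#' Synthetic equibiaxial experiment protocol
#'
#' Conditions for the simulated load-controlled equibiaxial test of an
#' incompressible membrane: maximum per-axis load, frame count, specimen
#' geometry, preload, and noise levels. Defaults mirror the collagen-gel
#' protocol: 15 mm x 15 mm x 1 mm specimen, 2 g preload, maximum loads of
#' 70-100 g, markers on a central 5 mm square.
#'
#' All stochastic draws of the generators flow from `seed` in a documented
#' order (per-frame stress noise for x then y, then marker jitter frame by
#' frame), so outputs are stable across runs.
#'
#' @param max_load_g maximum axial load, grams-force.
#' @param n_frames number of acquired frames (>= 3).
#' @param geometry a [specimen_geometry()].
#' @param preload_g suture-straightening preload, grams-force; the preloaded
#'   frame is the strain reference.
#' @param noise_stress_sd multiplicative stress/load noise sd (0 = exact).
#' @param marker_jitter_sd_mm isotropic Gaussian marker-position jitter sd, mm.
#' @param seed RNG seed for all noise draws.
#' @param stretch_max optional: bypass load-control inversion and sweep
#'   stretches on \[1, `stretch_max`\] directly (used for fitting fixtures).
#' @param marker_square_mm side of the reference marker square, mm.
#' @return list of class `experiment_protocol`.
#' @export
experiment_protocol <- function(max_load_g = 70, n_frames = 30,
                                geometry = specimen_geometry(),
                                preload_g = 2,
                                noise_stress_sd = 0,
                                marker_jitter_sd_mm = 0,
                                seed = 1,
                                stretch_max = NULL,
                                marker_square_mm = 5) {
  check_scalar(max_load_g, "max_load_g", positive = TRUE)
  check_scalar(preload_g, "preload_g", nonneg = TRUE)
  if (max_load_g <= preload_g) abort_domain("max_load_g must exceed preload_g")
  if (!is.numeric(n_frames) || n_frames < 3) abort_domain("n_frames must be >= 3")
  stopifnot(inherits(geometry, "specimen_geometry"))
  check_scalar(noise_stress_sd, "noise_stress_sd", nonneg = TRUE)
  check_scalar(marker_jitter_sd_mm, "marker_jitter_sd_mm", nonneg = TRUE)
  if (!is.null(stretch_max)) check_scalar(stretch_max, "stretch_max", positive = TRUE)
  check_scalar(marker_square_mm, "marker_square_mm", positive = TRUE)
  structure(list(max_load_g = max_load_g, n_frames = as.integer(n_frames),
                 geometry = geometry, preload_g = preload_g,
                 noise_stress_sd = noise_stress_sd,
                 marker_jitter_sd_mm = marker_jitter_sd_mm, seed = seed,
                 stretch_max = stretch_max,
                 marker_square_mm = marker_square_mm),
            class = "experiment_protocol")
}

# grams-force recorded on one axis at equibiaxial stretch lam, including the
# preload offset carried at the reference state: load = preload + sigma*A0/lam
load_from_stress <- function(sigma_kPa, lam, L0_perp_mm, t0_mm, preload_g) {
  area_m2 <- L0_perp_mm * t0_mm * 1e-6
  preload_g + sigma_kPa * 1000 * area_m2 / lam / GF_TO_N
}

# Equibiaxial stretch grid for a protocol: either the explicit stretch sweep
# or the load-control grid whose final frame reaches max_load_g on the
# stiffer axis (root of the monotone load-stretch map).
protocol_stretch_grid <- function(params, protocol, stretch_bound = 2) {
  if (!is.null(protocol$stretch_max)) {
    return(seq(1, protocol$stretch_max, length.out = protocol$n_frames))
  }
  geom <- protocol$geometry
  peak_load <- function(lam) {
    s <- cauchy_stress_biaxial(params, lam, lam, exp_cap = Inf)
    max(load_from_stress(s$sigma_xx, lam, geom$L0y, geom$t0, protocol$preload_g),
        load_from_stress(s$sigma_yy, lam, geom$L0x, geom$t0, protocol$preload_g))
  }
  if (peak_load(stretch_bound) < protocol$max_load_g) {
    abort_domain("max_load_g = %g g is unreachable below stretch %g",
                 protocol$max_load_g, stretch_bound)
  }
  lam_max <- stats::uniroot(function(l) peak_load(l) - protocol$max_load_g,
                            interval = c(1 + 1e-9, stretch_bound),
                            tol = 1e-12)$root
  seq(1, lam_max, length.out = protocol$n_frames)
}

#' Generate synthetic equibiaxial stress-strain curves
#'
#' Forward-model sweep under the protocol: the stretch grid is chosen so the
#' stiffer axis reaches the load equivalent of `max_load_g` (or is the
#' explicit `stretch_max` grid), and optional multiplicative Gaussian noise
#' is applied to the stresses. At zero noise the output equals
#' [equibiaxial_curve()] on the same grid exactly.
#'
#' @param params generating [material_params()].
#' @param protocol an [experiment_protocol()].
#' @return [biaxial_curves()] pair with a `stretch_grid` attribute.
#' @export
generate_curves <- function(params, protocol = experiment_protocol()) {
  stopifnot(inherits(params, "material_params"),
            inherits(protocol, "experiment_protocol"))
  grid <- protocol_stretch_grid(params, protocol)
  curves <- equibiaxial_curve(params, grid, exp_cap = Inf)
  if (protocol$noise_stress_sd > 0) {
    n <- length(grid)
    curves <- with_preserved_seed(protocol$seed, {
      fx <- 1 + stats::rnorm(n, sd = protocol$noise_stress_sd)
      fy <- 1 + stats::rnorm(n, sd = protocol$noise_stress_sd)
      biaxial_curves(
        stress_strain_curve(curves$x$strain, pmax(curves$x$stress_kPa * fx, 0), "x"),
        stress_strain_curve(curves$y$strain, pmax(curves$y$stress_kPa * fy, 0), "y"))
    })
  }
  attr(curves, "stretch_grid") <- grid
  curves
}

#' Generate raw synthetic biaxial records
#'
#' Emulates the acquisition pipeline: per frame, the marker quad is the
#' reference square mapped by the imposed equibiaxial stretch (plus optional
#' jitter), and the recorded loads are inverted from the model Cauchy
#' stresses, `load = preload + sigma * L0 * t0 / lambda` in grams-force, so
#' the first frame sits exactly at the preload. [reduce_experiment()] applied
#' to zero-noise output reproduces [generate_curves()] to numerical
#' precision.
#'
#' @inheritParams generate_curves
#' @return `biaxial_records` data.frame with a `ground_truth` attribute
#'   (generating parameters, stretch grid, noise-free curves).
#' @export
generate_raw_records <- function(params, protocol = experiment_protocol()) {
  stopifnot(inherits(params, "material_params"),
            inherits(protocol, "experiment_protocol"))
  grid <- protocol_stretch_grid(params, protocol)
  n <- length(grid)
  geom <- protocol$geometry
  s <- cauchy_stress_biaxial(params, grid, grid, exp_cap = Inf)
  load_x <- load_from_stress(s$sigma_xx, grid, geom$L0y, geom$t0, protocol$preload_g)
  load_y <- load_from_stress(s$sigma_yy, grid, geom$L0x, geom$t0, protocol$preload_g)

  base <- unclass(reference_marker_square(protocol$marker_square_mm))
  quads <- lapply(grid, function(l) base %*% diag(c(l, l)))

  if (protocol$noise_stress_sd > 0 || protocol$marker_jitter_sd_mm > 0) {
    noisy <- with_preserved_seed(protocol$seed, {
      if (protocol$noise_stress_sd > 0) {
        load_x <- protocol$preload_g +
          (load_x - protocol$preload_g) * (1 + stats::rnorm(n, sd = protocol$noise_stress_sd))
        load_y <- protocol$preload_g +
          (load_y - protocol$preload_g) * (1 + stats::rnorm(n, sd = protocol$noise_stress_sd))
      }
      if (protocol$marker_jitter_sd_mm > 0) {
        quads <- lapply(quads, function(q) {
          q + matrix(stats::rnorm(8, sd = protocol$marker_jitter_sd_mm), 4, 2)
        })
      }
      list(load_x = load_x, load_y = load_y, quads = quads)
    })
    load_x <- noisy$load_x
    load_y <- noisy$load_y
    quads <- noisy$quads
  }

  m <- t(vapply(quads, function(q) as.numeric(t(q)), numeric(8)))
  records <- data.frame(
    time_s = 10 * (seq_len(n) - 1),
    m1x = m[, 1], m1y = m[, 2], m2x = m[, 3], m2y = m[, 4],
    m3x = m[, 5], m3y = m[, 6], m4x = m[, 7], m4y = m[, 8],
    load_x_g = pmax(load_x, 0), load_y_g = pmax(load_y, 0)
  )
  records <- as_biaxial_records(records)
  attr(records, "ground_truth") <- list(
    params = params, stretch_grid = grid,
    curves = equibiaxial_curve(params, grid, exp_cap = Inf)
  )
  records
}

#' Generate a synthetic oscillatory sweep
#'
#' Emulates parallel-plate rheometry trends for collagen gels: the storage
#' modulus follows a weak power law in frequency (`G' = base * f^slope`, f in
#' Hz) and the loss modulus is `ratio_loss * G'`, optionally shaped with a
#' dip-then-rise factor across the frequency window (`loss_dip`). In strain
#' mode the storage modulus decreases slightly and the loss modulus rises
#' slightly with amplitude. Noise is multiplicative and seeded.
#'
#' @param base_G_storage storage modulus at the reference abscissa (1 Hz /
#'   smallest amplitude), Pa.
#' @param ratio_loss loss-to-storage ratio in (0, 1); collagen gels sit near
#'   0.1.
#' @param trend_coeffs list with any of `storage_slope` (frequency power-law
#'   exponent, default 0.05), `loss_dip` (fractional mid-window dip of G'',
#'   default 0 = constant ratio), `strain_storage_drop` (default 0.05),
#'   `strain_loss_rise` (default 0.1).
#' @param mode `"frequency"` (0.1-10 Hz, log-spaced) or `"strain"`
#'   (0.1-10 percent, linear, evaluated at a fixed 5 Hz).
#' @param noise_sd multiplicative noise sd on both moduli.
#' @param seed RNG seed.
#' @param n_points rows in the sweep.
#' @param metadata passed to [oscillatory_sweep()].
#' @return an [oscillatory_sweep()].
#' @export
generate_sweep <- function(base_G_storage = 100, ratio_loss = 0.1,
                           trend_coeffs = list(), mode = c("frequency", "strain"),
                           noise_sd = 0, seed = 1, n_points = 20,
                           metadata = list()) {
  mode <- match.arg(mode)
  check_scalar(base_G_storage, "base_G_storage", positive = TRUE)
  check_scalar(ratio_loss, "ratio_loss", positive = TRUE)
  if (ratio_loss >= 1) abort_domain("'ratio_loss' must lie in (0, 1)")
  tc <- utils::modifyList(list(storage_slope = 0.05, loss_dip = 0,
                               strain_storage_drop = 0.05,
                               strain_loss_rise = 0.1), trend_coeffs)
  if (mode == "frequency") {
    f <- 10^seq(log10(0.1), log10(10), length.out = n_points)
    Gp <- base_G_storage * f^tc$storage_slope
    u <- (log10(f) - mean(range(log10(f)))) / (diff(range(log10(f))) / 2)
    shape <- (1 - tc$loss_dip) + tc$loss_dip * u^2
    Gpp <- ratio_loss * Gp * shape
    x <- f
  } else {
    x <- seq(0.1, 10, length.out = n_points)
    u <- (x - x[1]) / (x[n_points] - x[1])
    Gp <- base_G_storage * (1 - tc$strain_storage_drop * u)
    Gpp <- ratio_loss * base_G_storage * (1 + tc$strain_loss_rise * u)
  }
  if (noise_sd > 0) {
    noisy <- with_preserved_seed(seed, {
      list(Gp = Gp * (1 + stats::rnorm(n_points, sd = noise_sd)),
           Gpp = Gpp * (1 + stats::rnorm(n_points, sd = noise_sd)))
    })
    Gp <- noisy$Gp
    Gpp <- noisy$Gpp
  }
  oscillatory_sweep(x, pmax(Gp, 1e-6), pmax(Gpp, 1e-6), mode = mode,
                    metadata = metadata)
}

#' Table of packaged scaffold scenarios
#'
#' The six fitted parameter sets (nonaligned and aligned scaffolds at 0.03,
#' 0.1 and 0.25 percent genipin), shipped as a JSON fixture, plus the maximum
#' equibiaxial load used when simulating each scenario (70 g for the softest
#' gel, 100 g otherwise).
#'
#' @return data.frame with columns `name`, `group`, `GP_pct`, `C10_kPa`,
#'   `k1_kPa`, `k2`, `gamma_deg`, `kappa`, `max_load_g`.
#' @export
gel_scenarios <- function() {
  path <- system.file("extdata", "table1_parameters.json", package = "gohbiax",
                      mustWork = TRUE)
  tab <- jsonlite::fromJSON(path)
  tab$max_load_g <- ifelse(tab$GP_pct <= 0.03, 70, 100)
  tab
}

#' Material parameters of a packaged scenario
#'
#' @param name scenario name, e.g. `"nonaligned_0.03"` or `"aligned_0.25"`.
#' @return a [material_params()].
#' @export
scenario_params <- function(name) {
  tab <- gel_scenarios()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    abort_domain("unknown scenario '%s'; available: %s", name,
                 paste(tab$name, collapse = ", "))
  }
  material_params(C10 = row$C10_kPa, k1 = row$k1_kPa, k2 = row$k2,
                  gamma = row$gamma_deg, kappa = row$kappa)
}

#' Default simulation protocol of a packaged scenario
#'
#' @inheritParams scenario_params
#' @param ... overrides passed to [experiment_protocol()].
#' @return an [experiment_protocol()] with the scenario's maximum load.
#' @export
scenario_protocol <- function(name, ...) {
  tab <- gel_scenarios()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) abort_domain("unknown scenario '%s'", name)
  args <- utils::modifyList(list(max_load_g = row$max_load_g), list(...))
  do.call(experiment_protocol, args)
}
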