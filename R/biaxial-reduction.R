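#' Specimen geometry for a planar biaxial test
#'
#' Unloaded (reference-state) edge lengths between the loading bars and the
#' specimen thickness. Defaults are the nominal collagen-gel dimensions:
#' a 15 mm x 15 mm membrane about 1 mm thick.
#'
#' @param L0x,L0y edge lengths between loading bars, mm.
#' @param t0 thickness, mm.
#' @return object of class `specimen_geometry`.
#' @export
specimen_geometry <- function(L0x = 15, L0y = 15, t0 = 1) {
  check_scalar(L0x, "L0x", positive = TRUE)
  check_scalar(L0y, "L0y", positive = TRUE)
  check_scalar(t0, "t0", positive = TRUE)
  structure(list(L0x = L0x, L0y = L0y, t0 = t0), class = "specimen_geometry")
}

#' Fiducial marker quad
#'
#' Four (x, y) marker positions in mm, ordered counterclockwise from the
#' lower-left corner. The reference configuration is nominally a 5 mm x 5 mm
#' square placed at the specimen center.
#'
#' @param xy 4 x 2 numeric matrix of marker coordinates, mm.
#' @return object of class `marker_quad` (a 4 x 2 matrix).
#' @export
marker_quad <- function(xy) {
  xy <- as.matrix(xy)
  if (!is.numeric(xy) || !identical(dim(xy), c(4L, 2L)) || any(!is.finite(xy))) {
    abort_domain("a marker quad must be a finite 4 x 2 numeric matrix")
  }
  if (quad_area(xy) < 1e-9) {
    abort_domain("degenerate marker quad (area ~ 0); markers must span a polygon")
  }
  structure(xy, class = c("marker_quad", "matrix"))
}

# Shoelace area (positive for counterclockwise ordering), mm^2
quad_area <- function(xy) {
  i2 <- c(2L, 3L, 4L, 1L)
  0.5 * abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]))
}

# Reference 5 mm marker square centered at the origin, counterclockwise from
# the lower-left corner.
reference_marker_square <- function(side_mm = 5) {
  h <- side_mm / 2
  marker_quad(cbind(c(-h, h, h, -h), c(-h, -h, h, h)))
}

#' Stretches from marker motion
#'
#' Best-fit homogeneous 2-D deformation gradient F mapping the centered
#' reference marker coordinates to the centered current ones, by least squares
#' over all four markers; returns the axial stretches (diagonal of F) with the
#' off-diagonal components reported for quality control. Centering makes the
#' result invariant to rigid translation of the marker field.
#'
#' @param ref,cur [marker_quad()] objects (or 4 x 2 matrices), mm.
#' @return list with `lambda_x`, `lambda_y`, and the full 2 x 2 matrix `F`.
#' @export
stretches_from_markers <- function(ref, cur) {
  ref <- marker_quad(unclass(ref))
  cur <- marker_quad(unclass(cur))
  R <- sweep(unclass(ref), 2, colMeans(ref))
  C <- sweep(unclass(cur), 2, colMeans(cur))
  G <- crossprod(R) # t(R) %*% R, 2 x 2
  if (abs(det(G)) < 1e-12) {
    abort_domain("degenerate reference quad: markers are collinear")
  }
  # minimize ||C - R t(F)||_F  =>  t(F) = solve(t(R) R) t(R) C
  FF <- t(solve(G, crossprod(R, C)))
  list(lambda_x = FF[1, 1], lambda_y = FF[2, 2], F = FF)
}

#' Logarithmic strain
#'
#' `epsilon = log(lambda)`, the true (Hencky) strain used throughout the
#' biaxial reduction.
#'
#' @param lambda stretch(es), > 0.
#' @return log strain, dimensionless.
#' @export
log_strain <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort_domain("stretch must be finite and > 0 for a log strain")
  }
  log(lambda)
}

#' Cauchy stress from an axial load
#'
#' Converts a measured axial load (grams-force) to Cauchy (true) stress: the
#' force is divided by the *current* cross-section, which for a homogeneous
#' incompressible deformation is the reference cross-section divided by the
#' axial stretch, e.g. `sigma_xx = f_x * lambda_x / (L0y * t0)`.
#'
#' @param load_gf axial load(s), grams-force.
#' @param axis `"x"` or `"y"`.
#' @param geom a [specimen_geometry()].
#' @param lambda_x,lambda_y axial stretches.
#' @return Cauchy stress, kPa.
#' @examples
#' # 70 g on a 15 mm x 1 mm section at lambda = 1.05: about 48 kPa
#' cauchy_stress_from_load(70, "x", specimen_geometry(), 1.05, 1.05)
#' @export
cauchy_stress_from_load <- function(load_gf, axis = c("x", "y"), geom,
                                    lambda_x, lambda_y) {
  axis <- match.arg(axis)
  stopifnot(inherits(geom, "specimen_geometry"))
  if (any(!is.finite(load_gf))) abort_domain("loads must be finite")
  if (any(lambda_x <= 0) || any(lambda_y <= 0)) {
    abort_domain("stretches must be > 0")
  }
  f_N <- load_gf * GF_TO_N
  if (axis == "x") {
    area_m2 <- geom$L0y * geom$t0 * 1e-6
    f_N * lambda_x / area_m2 / 1000
  } else {
    area_m2 <- geom$L0x * geom$t0 * 1e-6
    f_N * lambda_y / area_m2 / 1000
  }
}

#' Stress-strain curve container
#'
#' Paired Cauchy stress / logarithmic strain rows for one loading axis.
#'
#' @param strain log strains (dimensionless).
#' @param stress_kPa Cauchy stresses, kPa.
#' @param axis axis label, e.g. `"x"`.
#' @return data.frame of class `stress_strain_curve` with columns `strain`,
#'   `stress_kPa` and an `axis` attribute.
#' @export
stress_strain_curve <- function(strain, stress_kPa, axis = "x") {
  if (length(strain) != length(stress_kPa)) {
    abort_domain("strain and stress must have equal length")
  }
  if (any(!is.finite(strain)) || any(!is.finite(stress_kPa))) {
    abort_domain("strain and stress must be finite")
  }
  structure(
    data.frame(strain = as.numeric(strain), stress_kPa = as.numeric(stress_kPa)),
    axis = axis,
    class = c("stress_strain_curve", "data.frame")
  )
}

#' Pair of per-axis stress-strain curves
#'
#' @param x,y [stress_strain_curve()] objects for the x and y loading axes.
#' @return list of class `biaxial_curves`.
#' @export
biaxial_curves <- function(x, y) {
  stopifnot(inherits(x, "stress_strain_curve"), inherits(y, "stress_strain_curve"))
  structure(list(x = x, y = y), class = "biaxial_curves")
}

#' Reduce a raw biaxial experiment to stress-strain curves
#'
#' Selects the reference frame (by default the frame whose loads are nearest
#' the nominal preload, mirroring the convention that the preloaded state is
#' the strain reference), extracts the loading branch, and converts marker
#' motion and loads to per-axis Cauchy stress versus log strain.
#'
#' A frame belongs to the loading branch if it is at or after the reference
#' frame, not after the peak-load frame, and both axial loads are
#' non-decreasing within `branch_tol_frac` of the maximum load. With
#' `subtract_preload = TRUE` (default) the reference-frame load is treated as
#' suture-straightening tension and subtracted before computing stress.
#'
#' @param records a `biaxial_records` data.frame (see [as_biaxial_records()]).
#' @param geom a [specimen_geometry()] describing the reference state.
#' @param ref_policy `"preload"` (frame with loads nearest `preload_g`) or
#'   `"first_frame"`.
#' @param preload_g nominal preload, grams-force.
#' @param preload_tol_g maximum allowed distance from `preload_g` for the
#'   reference frame under the `"preload"` policy.
#' @param subtract_preload subtract the reference-frame load before computing
#'   stresses.
#' @param branch_tol_frac loading-branch monotonicity tolerance, as a fraction
#'   of the maximum load.
#' @return list of class `biaxial_reduction` with elements `x`, `y`
#'   ([stress_strain_curve()]s), `frames` (per-frame QC table: stretches and
#'   off-diagonal F components) and `ref_frame`.
#' @export
reduce_experiment <- function(records, geom = specimen_geometry(),
                              ref_policy = c("preload", "first_frame"),
                              preload_g = 2, preload_tol_g = 0.5,
                              subtract_preload = TRUE,
                              branch_tol_frac = 0.005) {
  records <- as_biaxial_records(records)
  ref_policy <- match.arg(ref_policy)
  n <- nrow(records)
  if (ref_policy == "preload") {
    dist <- pmax(abs(records$load_x_g - preload_g), abs(records$load_y_g - preload_g))
    iref <- which.min(dist)
    if (dist[iref] > preload_tol_g) {
      abort_domain(paste0("ref_policy = 'preload': no frame has both loads within ",
                          "%g g of the %g g preload (closest is %.3g g away)"),
                   preload_tol_g, preload_g, dist[iref])
    }
  } else {
    iref <- 1L
  }
  quad_of <- function(i) {
    matrix(as.numeric(records[i, c("m1x", "m1y", "m2x", "m2y",
                                   "m3x", "m3y", "m4x", "m4y")]),
           nrow = 4, ncol = 2, byrow = TRUE)
  }
  ref_quad <- quad_of(iref)

  # loading branch: frames iref..peak with both loads non-decreasing (tol)
  tol <- branch_tol_frac * max(records$load_x_g + records$load_y_g) / 2
  cand <- iref:n
  ipeak <- cand[which.max(records$load_x_g[cand] + records$load_y_g[cand])]
  keep <- integer(0)
  run_x <- -Inf
  run_y <- -Inf
  for (i in iref:ipeak) {
    if (records$load_x_g[i] >= run_x - tol && records$load_y_g[i] >= run_y - tol) {
      keep <- c(keep, i)
      run_x <- max(run_x, records$load_x_g[i])
      run_y <- max(run_y, records$load_y_g[i])
    }
  }

  lam <- vapply(keep, function(i) {
    st <- stretches_from_markers(ref_quad, quad_of(i))
    c(st$lambda_x, st$lambda_y, st$F[1, 2], st$F[2, 1])
  }, numeric(4))
  off_x <- if (subtract_preload) records$load_x_g[iref] else 0
  off_y <- if (subtract_preload) records$load_y_g[iref] else 0
  sx <- cauchy_stress_from_load(records$load_x_g[keep] - off_x, "x", geom,
                                lam[1, ], lam[2, ])
  sy <- cauchy_stress_from_load(records$load_y_g[keep] - off_y, "y", geom,
                                lam[1, ], lam[2, ])
  structure(
    list(
      x = stress_strain_curve(log_strain(lam[1, ]), sx, axis = "x"),
      y = stress_strain_curve(log_strain(lam[2, ]), sy, axis = "y"),
      frames = data.frame(frame = keep, time_s = records$time_s[keep],
                          lambda_x = lam[1, ], lambda_y = lam[2, ],
                          F_xy = lam[3, ], F_yx = lam[4, ]),
      ref_frame = iref
    ),
    class = "biaxial_reduction"
  )
}

#' Validate a table of raw biaxial records
#'
#' One row per acquired frame: `time_s`, the four marker positions
#' `m1x, m1y, ..., m4y` (mm, counterclockwise from lower-left), and the axial
#' loads `load_x_g`, `load_y_g` (grams-force, >= 0). Frames must be
#' time-ordered.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame with class `biaxial_records`.
#' @export
as_biaxial_records <- function(df) {
  req <- c("time_s", "m1x", "m1y", "m2x", "m2y", "m3x", "m3y", "m4x", "m4y",
           "load_x_g", "load_y_g")
  if (!is.data.frame(df)) abort_format("biaxial records must be a data.frame")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort_format("biaxial records lack required columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) < 1L) abort_format("biaxial records must contain at least one frame")
  num <- vapply(df[req], is.numeric, logical(1))
  if (!all(num)) abort_format("non-numeric biaxial record columns: %s",
                              paste(req[!num], collapse = ", "))
  if (any(!is.finite(as.matrix(df[req])))) {
    abort_format("biaxial records contain non-finite values")
  }
  if (any(df$load_x_g < 0) || any(df$load_y_g < 0)) {
    abort_domain("loads must be >= 0 grams-force")
  }
  if (is.unsorted(df$time_s)) abort_domain("frames must be time-ordered")
  class(df) <- unique(c("biaxial_records", class(df)))
  df
}

#' Tangent-modulus curve from a stress-strain curve
#'
#' Differentiates a (optionally moving-average smoothed) stress-strain curve
#' by central differences (one-sided at the ends) and applies the reporting
#' convention `E_t = 0.5 * dsigma/depsilon`; set `raw_slope = TRUE` for the
#' unscaled slope.
#'
#' @param curve a [stress_strain_curve()] with at least 3 rows.
#' @param smoothing_window odd moving-average window length applied to the
#'   stress column before differencing; 1 disables smoothing. Edge values are
#'   averaged over the available (shrunken) window.
#' @param raw_slope if `TRUE`, return `dsigma/depsilon` without the 0.5
#'   factor.
#' @return data.frame of class `tangent_modulus_curve` with columns `strain`,
#'   `Et_kPa`.
#' @export
tangent_modulus <- function(curve, smoothing_window = 1, raw_slope = FALSE) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  n <- nrow(curve)
  if (n < 3L) abort_domain("tangent modulus needs at least 3 rows (got %d)", n)
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) abort_domain("'smoothing_window' must be odd and >= 1")
  eps <- curve$strain
  sig <- curve$stress_kPa
  if (w > 1L) {
    h <- (w - 1L) %/% 2L
    sig <- vapply(seq_len(n), function(i) {
      j <- max(1L, i - h):min(n, i + h)
      mean(curve$stress_kPa[j])
    }, numeric(1))
  }
  slope <- numeric(n)
  slope[1] <- (sig[2] - sig[1]) / (eps[2] - eps[1])
  slope[n] <- (sig[n] - sig[n - 1]) / (eps[n] - eps[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    slope[i] <- (sig[i + 1] - sig[i - 1]) / (eps[i + 1] - eps[i - 1])
  }
  et <- if (raw_slope) slope else 0.5 * slope
  structure(data.frame(strain = eps, Et_kPa = et),
            axis = attr(curve, "axis"),
            class = c("tangent_modulus_curve", "data.frame"))
}

#' Average tangent-modulus curves on a common strain grid
#'
#' Linearly interpolates each curve onto `strain_grid` and returns the
#' pointwise mean with the pointwise standard deviation as spread.
#'
#' @param curves list of `tangent_modulus_curve` objects.
#' @param strain_grid strains at which to average; must lie within every
#'   curve's span.
#' @return `tangent_modulus_curve` with columns `strain`, `Et_kPa`, `sd_kPa`,
#'   `n`.
#' @export
average_tangent_modulus <- function(curves, strain_grid) {
  if (length(curves) < 1L) abort_domain("need at least one tangent-modulus curve")
  vals <- vapply(seq_along(curves), function(k) {
    cu <- curves[[k]]
    stopifnot(inherits(cu, "tangent_modulus_curve"))
    if (min(strain_grid) < min(cu$strain) - 1e-12 ||
        max(strain_grid) > max(cu$strain) + 1e-12) {
      abort_domain("strain grid [%g, %g] lies outside the span of curve %d [%g, %g]",
                   min(strain_grid), max(strain_grid), k, min(cu$strain), max(cu$strain))
    }
    stats::approx(cu$strain, cu$Et_kPa, xout = strain_grid, rule = 1)$y
  }, numeric(length(strain_grid)))
  vals <- matrix(vals, nrow = length(strain_grid))
  structure(
    data.frame(strain = strain_grid,
               Et_kPa = rowMeans(vals),
               sd_kPa = apply(vals, 1, stats::sd),
               n = length(curves)),
    class = c("tangent_modulus_curve", "data.frame")
  )
}
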