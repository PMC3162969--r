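#' Oscillatory rheometry sweep
#'
#' Container for a parallel-plate frequency or strain-amplitude sweep:
#' rows of (abscissa, storage modulus G', loss modulus G''). Frequency sweeps
#' use Hz; strain sweeps store percent shear-strain amplitude (the instrument
#' convention).
#'
#' @param abscissa strictly increasing frequencies (Hz) or strain amplitudes
#'   (percent).
#' @param G_storage_Pa,G_loss_Pa storage and loss moduli, Pa, > 0.
#' @param mode `"frequency"` or `"strain"`.
#' @param metadata optional list (e.g. crosslinker concentration label,
#'   temperature).
#' @return data.frame of class `oscillatory_sweep` with attributes `mode` and
#'   `metadata`.
#' @export
oscillatory_sweep <- function(abscissa, G_storage_Pa, G_loss_Pa,
                              mode = c("frequency", "strain"),
                              metadata = list()) {
  mode <- match.arg(mode)
  n <- length(abscissa)
  if (n < 1L || length(G_storage_Pa) != n || length(G_loss_Pa) != n) {
    abort_domain("sweep columns must be non-empty and of equal length")
  }
  if (any(!is.finite(abscissa)) || (n > 1L && any(diff(abscissa) <= 0))) {
    abort_domain("sweep abscissa must be finite and strictly increasing")
  }
  if (any(!is.finite(G_storage_Pa)) || any(G_storage_Pa <= 0) ||
      any(!is.finite(G_loss_Pa)) || any(G_loss_Pa <= 0)) {
    abort_domain("moduli must be finite and > 0")
  }
  structure(
    data.frame(abscissa = abscissa, G_storage_Pa = G_storage_Pa,
               G_loss_Pa = G_loss_Pa),
    mode = mode, metadata = metadata,
    class = c("oscillatory_sweep", "data.frame")
  )
}

#' Loss tangent of a sweep
#'
#' Elementwise `tan(delta) = G''/G'`.
#'
#' @param sweep an [oscillatory_sweep()].
#' @return data.frame with columns `abscissa`, `tan_delta`.
#' @export
loss_tangent <- function(sweep) {
  stopifnot(inherits(sweep, "oscillatory_sweep"))
  data.frame(abscissa = sweep$abscissa,
             tan_delta = sweep$G_loss_Pa / sweep$G_storage_Pa)
}

#' Elastic dominance summary
#'
#' Summarizes `G'/G''` over a sweep; a gel with median ratio above 1 is
#' flagged predominantly elastic (collagen gels typically sit near 10).
#'
#' @param sweep an [oscillatory_sweep()].
#' @return list with `median_ratio`, `min_ratio`, `max_ratio`,
#'   `predominantly_elastic`.
#' @export
elastic_dominance <- function(sweep) {
  stopifnot(inherits(sweep, "oscillatory_sweep"))
  r <- sweep$G_storage_Pa / sweep$G_loss_Pa
  list(median_ratio = stats::median(r),
       min_ratio = min(r), max_ratio = max(r),
       predominantly_elastic = stats::median(r) > 1)
}

#' Tensile-to-shear stiffness ratio
#'
#' Ratio of the biaxial tangent modulus `E_t` (interpolated at
#' `strain_for_Et`, converted kPa -> Pa) to the storage modulus `G'`
#' (interpolated at `freq_for_G`; on a log-frequency axis for frequency
#' sweeps, linearly for strain sweeps). For the purely elastic incompressible
#' GOH solid the small-strain ratio is 3 (ideal elastic network); hydrated
#' collagen gels show experimental ratios of 10^2-10^3, attributed to
#' interstitial-fluid (biphasic) effects that the solid model does not
#' represent.
#'
#' @param Et_curve a `tangent_modulus_curve`.
#' @param sweep an [oscillatory_sweep()].
#' @param strain_for_Et strain at which to evaluate `E_t` (within the curve's
#'   span).
#' @param freq_for_G abscissa at which to evaluate `G'` (within the sweep's
#'   span).
#' @return dimensionless ratio `E_t / G'`.
#' @export
tensile_shear_ratio <- function(Et_curve, sweep, strain_for_Et, freq_for_G) {
  stopifnot(inherits(Et_curve, "tangent_modulus_curve"),
            inherits(sweep, "oscillatory_sweep"))
  if (strain_for_Et < min(Et_curve$strain) || strain_for_Et > max(Et_curve$strain)) {
    abort_domain("strain_for_Et = %g outside the tangent-modulus span [%g, %g]",
                 strain_for_Et, min(Et_curve$strain), max(Et_curve$strain))
  }
  if (freq_for_G < min(sweep$abscissa) || freq_for_G > max(sweep$abscissa)) {
    abort_domain("freq_for_G = %g outside the sweep span [%g, %g]",
                 freq_for_G, min(sweep$abscissa), max(sweep$abscissa))
  }
  Et_Pa <- stats::approx(Et_curve$strain, Et_curve$Et_kPa,
                         xout = strain_for_Et)$y * 1000
  if (identical(attr(sweep, "mode"), "frequency")) {
    Gp <- stats::approx(log10(sweep$abscissa), sweep$G_storage_Pa,
                        xout = log10(freq_for_G))$y
  } else {
    Gp <- stats::approx(sweep$abscissa, sweep$G_storage_Pa, xout = freq_for_G)$y
  }
  Et_Pa / Gp
}
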