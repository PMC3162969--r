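# CSV/JSON round-tripping for the pipeline's record types. All numeric CSV
# output is written at full double precision ("%.17g") so write -> read is
# exact.

format_numeric_df <- function(df) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  out
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) abort_format("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_format("cannot parse CSV %s: %s",
                                                  path, conditionMessage(e)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_format("%s: malformed header, missing columns: %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write / read per-axis stress-strain curves as CSV
#'
#' Long format with columns `axis`, `strain`, `stress_kPa`, written at full
#' double precision so the round trip is exact.
#'
#' @param curves a [biaxial_curves()] pair.
#' @param path CSV path.
#' @return `write_curves_csv`: the path, invisibly. `read_curves_csv`: a
#'   [biaxial_curves()] pair.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(inherits(curves, "biaxial_curves"))
  long <- rbind(
    data.frame(axis = "x", strain = curves$x$strain, stress_kPa = curves$x$stress_kPa),
    data.frame(axis = "y", strain = curves$y$strain, stress_kPa = curves$y$stress_kPa)
  )
  utils::write.csv(format_numeric_df(long), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- read_csv_strict(path, c("axis", "strain", "stress_kPa"))
  pick <- function(ax) {
    sub <- df[df$axis == ax, ]
    if (nrow(sub) == 0) abort_format("%s: no rows for axis '%s'", path, ax)
    stress_strain_curve(as.numeric(sub$strain), as.numeric(sub$stress_kPa), ax)
  }
  biaxial_curves(pick("x"), pick("y"))
}

#' Write / read raw biaxial records as CSV
#'
#' One row per frame with columns `time_s`, `m1x`..`m4y` (mm), `load_x_g`,
#' `load_y_g`; header required.
#'
#' @param records a `biaxial_records` data.frame.
#' @param path CSV path.
#' @return `write_records_csv`: the path, invisibly. `read_records_csv`: a
#'   validated `biaxial_records` data.frame.
#' @export
write_records_csv <- function(records, path) {
  records <- as_biaxial_records(records)
  cols <- c("time_s", "m1x", "m1y", "m2x", "m2y", "m3x", "m3y", "m4x", "m4y",
            "load_x_g", "load_y_g")
  utils::write.csv(format_numeric_df(as.data.frame(records)[cols]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- read_csv_strict(path, c("time_s", "m1x", "m1y", "m2x", "m2y", "m3x",
                                "m3y", "m4x", "m4y", "load_x_g", "load_y_g"))
  num <- as.data.frame(lapply(df, as.numeric))
  if (any(!is.finite(as.matrix(num)))) {
    abort_format("%s: non-numeric values in biaxial record columns", path)
  }
  as_biaxial_records(num)
}

#' Write / read an oscillatory sweep as CSV (+ JSON metadata sidecar)
#'
#' Columns `mode`, `abscissa`, `G_storage_Pa`, `G_loss_Pa`. Metadata, if any,
#' goes to `<path>.meta.json`.
#'
#' @param sweep an [oscillatory_sweep()].
#' @param path CSV path.
#' @return `write_sweep_csv`: the path, invisibly. `read_sweep_csv`: an
#'   [oscillatory_sweep()].
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "oscillatory_sweep"))
  df <- data.frame(mode = attr(sweep, "mode"), abscissa = sweep$abscissa,
                   G_storage_Pa = sweep$G_storage_Pa, G_loss_Pa = sweep$G_loss_Pa)
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE, quote = FALSE)
  meta <- attr(sweep, "metadata")
  if (length(meta) > 0) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- read_csv_strict(path, c("mode", "abscissa", "G_storage_Pa", "G_loss_Pa"))
  mode <- unique(df$mode)
  if (length(mode) != 1L || !mode %in% c("frequency", "strain")) {
    abort_format("%s: 'mode' must be a single value, 'frequency' or 'strain'", path)
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  oscillatory_sweep(as.numeric(df$abscissa), as.numeric(df$G_storage_Pa),
                    as.numeric(df$G_loss_Pa), mode = mode, metadata = meta)
}

#' Write a tangent-modulus curve as CSV
#'
#' Columns `axis`, `strain`, `Et_kPa` (plus spread columns when present).
#'
#' @param curve a `tangent_modulus_curve`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_tangent_csv <- function(curve, path) {
  stopifnot(inherits(curve, "tangent_modulus_curve"))
  ax <- attr(curve, "axis")
  df <- cbind(data.frame(axis = if (is.null(ax)) "mean" else ax),
              as.data.frame(curve))
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fit result as JSON
#'
#' Serializes the fitted parameters, pinned values, residual RMS, convergence
#' flag and free-parameter correlation matrix.
#'
#' @param fit a `goh_fit`.
#' @param path JSON path.
#' @return `write_fit_json`: the path, invisibly. `read_fit_json`: a list
#'   with the fitted quantities (parameters reconstructed as
#'   [material_params()]).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "goh_fit"))
  p <- fit$params
  out <- list(
    params = if (is.null(p)) NULL else
      list(C10_kPa = p$C10, k1_kPa = p$k1, k2 = p$k2,
           gamma_deg = p$gamma, kappa = p$kappa),
    free = fit$free, fixed = fit$fixed,
    residual_rms_kPa = fit$residual_rms, loss = fit$loss,
    converged = fit$converged,
    at_kappa_boundary = fit$at_kappa_boundary,
    ordering_matched = fit$ordering_matched,
    param_correlation = fit$param_correlation
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) abort_format("file not found: %s", path)
  out <- jsonlite::fromJSON(path)
  if (!is.null(out$params)) {
    out$material_params <- material_params(
      C10 = out$params$C10_kPa, k1 = out$params$k1_kPa, k2 = out$params$k2,
      gamma = out$params$gamma_deg, kappa = out$params$kappa)
  }
  out
}
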