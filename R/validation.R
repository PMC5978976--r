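#' Percent error between a measured and a predicted dose
#'
#' `100 * (predicted - measured) / measured`: the sign convention puts
#' model under-prediction below zero, with the measurement as the
#' denominator. Values are returned unrounded; report output rounds to
#' one decimal, half away from zero, via [round_report()].
#'
#' @param measured measured dose, mGy (> 0).
#' @param predicted predicted dose, mGy.
#' @return percent error, %.
#' @export
percent_error <- function(measured, predicted) {
  if (any(measured <= 0)) stop("measured dose must be > 0")
  100 * (predicted - measured) / measured
}

#' Round for report output (half away from zero)
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded values.
#' @export
round_report <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summary statistics of a set of percent errors
#'
#' Computed on the unrounded values: the minimum, maximum, mean, and
#' mean absolute percent error.
#'
#' @param percent_errors numeric vector of percent errors (nonempty).
#' @return list with `min`, `max`, `mean`, `mean_abs`, `n`.
#' @export
summarize_percent_errors <- function(percent_errors) {
  if (!length(percent_errors)) stop("no percent errors to summarize")
  list(min = min(percent_errors), max = max(percent_errors),
       mean = mean(percent_errors),
       mean_abs = mean(abs(percent_errors)), n = length(percent_errors))
}

#' Bundled OSLD validation dose dataset
#'
#' Measured and predicted on-phantom OSLD doses for the nine beam
#' qualities in each of three irradiation geometries (on-phantom,
#' behind the table, behind table and pad) plus the 80 kVp / 0.2 mm Cu
#' angular series, with the percent errors as printed in the original
#' validation report. Setups: `phantom`, `phantom_table`,
#' `phantom_table_pad`, `angular`.
#'
#' @param setup optional filter on the `setup` column.
#' @return data.frame with columns `setup`, `kvp`, `cu_mm`, `pad`,
#'   `angle_deg`, `field_cm`, `measured_mGy`, `predicted_mGy`,
#'   `percent_error_printed`.
#' @export
validation_doses <- function(setup = NULL) {
  df <- utils::read.csv(sd_extdata("osld_validation_doses.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(setup)) df <- df[df$setup %in% setup, ]
  df
}

#' Compare a dose map against OSLD grid readings
#'
#' Matches map points and readings by exact grid index `(i, j)` and
#' reports the per-point percent error of the map against the
#' measurement. Points where the map reports zero dose but the OSLD read
#' a nonzero dose are flagged `scatter_only` — the map is scatter-free
#' by construction, so these points carry only scattered radiation from
#' adjacent fields — and are excluded from the error summary rather than
#' producing infinities.
#'
#' @param dosemap_in_osld_domain a `dose_map` already re-expressed in
#'   the OSLD domain (see [to_osld_domain()]).
#' @param readings data.frame with columns `i`, `j`, `dose_mGy`
#'   (duplicate indices are an error).
#' @return list with `rows` (data.frame: `i`, `j`, `measured_mGy`,
#'   `predicted_mGy`, `percent_error`, `percent_error_report`,
#'   `scatter_only`) and `summary` (from [summarize_percent_errors()],
#'   `NULL` when no comparable points exist).
#' @export
compare_map_to_osld <- function(dosemap_in_osld_domain, readings) {
  stopifnot(all(c("i", "j", "dose_mGy") %in% names(readings)),
            all(readings$dose_mGy >= 0))
  key <- paste(readings$i, readings$j)
  if (anyDuplicated(key)) stop("duplicate OSLD grid indices in readings")
  gp <- dosemap_in_osld_domain$grid$points
  map_key <- paste(gp$i, gp$j)
  pos <- match(key, map_key)
  if (anyNA(pos)) {
    stop("OSLD reading at grid index not on the map grid: ",
         key[which(is.na(pos))[1]])
  }
  pred <- dosemap_in_osld_domain$dose[pos]
  meas <- readings$dose_mGy
  scatter_only <- pred == 0 & meas > 0
  comparable <- meas > 0 & !scatter_only
  pe <- rep(NA_real_, length(meas))
  pe[comparable] <- percent_error(meas[comparable], pred[comparable])
  rows <- data.frame(i = readings$i, j = readings$j,
                     measured_mGy = meas, predicted_mGy = pred,
                     percent_error = pe,
                     percent_error_report = round_report(pe),
                     scatter_only = scatter_only)
  list(rows = rows,
       summary = if (any(comparable)) {
         summarize_percent_errors(pe[comparable])
       } else NULL)
}

#' Field-alignment modular check
#'
#' Remainder of the displacement between two field centers modulo the
#' dosimeter grid spacing. A zero remainder means the displaced field
#' centers land exactly on grid points, so center-point doses of the two
#' mapped fields are directly comparable with the dosimeter grid; a
#' nonzero remainder means such center-point agreement is not expected.
#'
#' @param field_displacement_cm displacement between field centers, cm.
#' @param grid_spacing_cm dosimeter grid spacing, cm (> 0).
#' @return remainder in `[0, grid_spacing_cm)`, with floating-point
#'   residue at the period boundary snapped to zero.
#' @export
field_alignment_check <- function(field_displacement_cm, grid_spacing_cm) {
  if (grid_spacing_cm <= 0) stop("grid spacing must be > 0")
  r <- field_displacement_cm -
    grid_spacing_cm * floor(field_displacement_cm / grid_spacing_cm)
  tol <- 1e-9 * max(1, abs(field_displacement_cm))
  r[r > grid_spacing_cm - tol] <- 0
  r[abs(r) < tol] <- 0
  r
}
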