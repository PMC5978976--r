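#' Measured ion-chamber/OSLD cross-calibration factor
#'
#' Ratio of the free-in-air ion-chamber dose to the free-in-air OSLD
#' dose at the same beam quality. Multiplying an OSLD reading by this
#' factor converts it to what the ion chamber — the instrument the
#' dose-mapping algorithm is itself calibrated against — would have
#' read.
#'
#' @param d_ic_air free-in-air ion-chamber dose, mGy (> 0).
#' @param d_osl_air free-in-air OSLD dose, mGy (> 0).
#' @return dimensionless correction factor.
#' @export
cf_measured <- function(d_ic_air, d_osl_air) {
  stopifnot(d_ic_air > 0)
  if (any(d_osl_air <= 0)) stop("free-in-air OSLD dose must be > 0")
  d_ic_air / d_osl_air
}

#' Monte Carlo tally set for one beam quality
#'
#' Energy-deposition tallies (MeV/g per source photon) scored in the
#' OSLD volume for each irradiation geometry, with their relative
#' statistical errors. Tallies with relative error at or above the
#' quality threshold (default 5%) are rejected at use time.
#'
#' @param f6_osl named numeric vector of tallies, e.g. entries `air`,
#'   `phantom`, `phantom_table`, `phantom_table_pad` (all > 0).
#' @param relative_error matching fractional statistical errors.
#' @return object of class `monte_carlo_tally`.
#' @export
monte_carlo_tally <- function(f6_osl, relative_error = 0) {
  stopifnot(is.numeric(f6_osl), all(f6_osl > 0))
  relative_error <- rep_len(relative_error, length(f6_osl))
  stopifnot(all(relative_error >= 0))
  structure(list(f6_osl = f6_osl, relative_error = relative_error),
            class = "monte_carlo_tally")
}

#' Monte Carlo geometry correction factor
#'
#' Ratio of the energy-deposition tally in a complex irradiation
#' geometry (on-phantom, optionally behind table and pad) to the
#' free-in-air tally for the same beam quality. This single factor packs
#' the backscatter, tissue-to-air conversion, and table/pad attenuation
#' of that geometry.
#'
#' @param tally_geometry tally value (MeV/g per source photon) in the
#'   complex geometry.
#' @param tally_air free-in-air tally value.
#' @param relative_error fractional statistical errors of the two
#'   tallies (recycled); either at or above `max_rel_error` is a quality
#'   error.
#' @param max_rel_error acceptance threshold on relative error
#'   (default 0.05).
#' @return dimensionless correction factor.
#' @export
cf_montecarlo <- function(tally_geometry, tally_air,
                          relative_error = 0, max_rel_error = 0.05) {
  stopifnot(tally_geometry > 0, tally_air > 0)
  if (any(relative_error >= max_rel_error)) {
    stop("tally relative error ", max(relative_error),
         " exceeds the quality threshold ", max_rel_error)
  }
  tally_geometry / tally_air
}

#' Predicted on-phantom OSLD response
#'
#' Free-in-air OSLD dose scaled by the Monte Carlo geometry correction
#' factor for the target geometry: the model's prediction of what the
#' dosimeter reads when mounted on the phantom (behind table/pad when
#' those are in the beam).
#'
#' @param d_osl_air free-in-air OSLD dose, mGy (> 0).
#' @param cf_mc Monte Carlo geometry correction factor (> 0).
#' @return predicted on-phantom OSLD dose, mGy.
#' @export
predict_osld <- function(d_osl_air, cf_mc) {
  stopifnot(all(d_osl_air > 0), all(cf_mc > 0))
  d_osl_air * cf_mc
}

#' Re-express an algorithm skin dose in the OSLD measurement domain
#'
#' Divides the ray-traced phantom dose by the measured ion-chamber/OSLD
#' cross-calibration factor, so the dose map and the OSLD grid readings
#' can be compared point by point in the same domain.
#'
#' @param d_map algorithm dose, mGy (a scalar or vector).
#' @param cf measured cross-calibration factor (> 0).
#' @return dose in the OSLD domain, mGy.
#' @export
to_osld_domain <- function(d_map, cf) {
  if (any(cf <= 0)) stop("cross-calibration factor must be > 0")
  d_map / cf
}

#' Correction-factor set for a validation campaign
#'
#' Container for the measured cross-calibration factors and the Monte
#' Carlo geometry correction factors, keyed by beam quality
#' `(kvp, cu_mm)`, geometry (`phantom`, `phantom_table`,
#' `phantom_table_pad`) and incidence angle.
#'
#' @param cf_measured data.frame `kvp, cu_mm, cf` (all cf > 0).
#' @param cf_montecarlo data.frame
#'   `kvp, cu_mm, geometry, angle_deg, cf` (all cf > 0).
#' @return object of class `correction_factor_set`.
#' @export
correction_factor_set <- function(cf_measured, cf_montecarlo) {
  stopifnot(is.data.frame(cf_measured),
            all(c("kvp", "cu_mm", "cf") %in% names(cf_measured)),
            all(cf_measured$cf > 0),
            is.data.frame(cf_montecarlo),
            all(c("kvp", "cu_mm", "geometry", "angle_deg", "cf") %in%
                  names(cf_montecarlo)),
            all(cf_montecarlo$cf > 0))
  structure(list(cf_measured = cf_measured,
                 cf_montecarlo = cf_montecarlo),
            class = "correction_factor_set")
}

#' Look up correction factors from a set
#'
#' `cf_measured` keys must match exactly. Monte Carlo factors were
#' characterized at incidence angles 0, 30 and 60 degrees only; between
#' those anchors the factor is linearly interpolated, and angles outside
#' the characterized span clamp to the nearest anchor.
#'
#' @param cfs a [correction_factor_set()].
#' @param kvp,cu_mm beam-quality key.
#' @param geometry one of the geometry labels in the set (Monte Carlo
#'   lookup only; omit for the measured factor).
#' @param angle_deg incidence angle, degrees.
#' @return the correction factor.
#' @export
cf_lookup <- function(cfs, kvp, cu_mm, geometry = NULL, angle_deg = 0) {
  if (is.null(geometry)) {
    m <- cfs$cf_measured
    hit <- m$kvp == kvp & m$cu_mm == cu_mm
    if (!any(hit)) {
      stop("no measured CF for beam quality (", kvp, " kVp, ", cu_mm,
           " mm Cu)")
    }
    return(m$cf[which(hit)[1]])
  }
  mc <- cfs$cf_montecarlo
  sub <- mc[mc$kvp == kvp & mc$cu_mm == cu_mm & mc$geometry == geometry, ]
  if (!nrow(sub)) {
    stop("no Monte Carlo CF for (", kvp, " kVp, ", cu_mm, " mm Cu, ",
         geometry, ")")
  }
  sub <- sub[order(sub$angle_deg), ]
  if (nrow(sub) == 1) return(sub$cf)
  a <- min(max(angle_deg, min(sub$angle_deg)), max(sub$angle_deg))
  stats::approx(sub$angle_deg, sub$cf, xout = a)$y
}

#' Estimate the KAP-meter calibration factor from calibration exposures
#'
#' Least-squares slope through the origin between doses modeled with
#' beta = 1 and reference doses measured by the calibrated instrument:
#' with a noise-free linear system the configured beta is recovered
#' exactly.
#'
#' @param d_measured reference (measured) doses, mGy.
#' @param d_model_unit doses modeled with beta = 1, mGy.
#' @return the estimated calibration factor.
#' @export
estimate_beta <- function(d_measured, d_model_unit) {
  stopifnot(length(d_measured) == length(d_model_unit),
            any(d_model_unit != 0))
  sum(d_model_unit * d_measured) / sum(d_model_unit^2)
}
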