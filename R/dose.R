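#' Beam-quality correction tables for the dose engine
#'
#' Bundles the backscatter-factor table (keyed by HVL in mm Al and field
#' side at the skin in cm, bilinearly interpolated strictly inside the
#' key hull), the tissue-to-air mass energy-absorption ratio policy, and
#' the attenuation-factor mode. The bundled backscatter defaults are
#' editable configuration: replace them with values matched to the local
#' beam qualities for absolute work.
#'
#' @param bsf data.frame with columns `hvl_mm_al`, `field_side_cm`,
#'   `bsf` on a full rectangular key grid; default: bundled table.
#' @param mu_en_ratio `NULL` to compute the tissue-to-air ratio from the
#'   event spectrum (default), or a fixed number in [0.9, 1.2].
#' @param af_mode `"computed"` (spectral transmission along the traced
#'   slab paths) or `"lookup"` (fixed `af_value`).
#' @param af_value attenuation factor used when `af_mode = "lookup"`.
#' @param attenuation attenuation coefficient tables.
#' @return object of class `beam_quality_tables`.
#' @export
beam_quality_tables <- function(bsf = NULL, mu_en_ratio = NULL,
                                af_mode = c("computed", "lookup"),
                                af_value = 1.0,
                                attenuation = default_attenuation()) {
  af_mode <- match.arg(af_mode)
  if (is.null(bsf)) {
    bsf <- utils::read.csv(sd_extdata("backscatter_factors.csv"),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("hvl_mm_al", "field_side_cm", "bsf") %in% names(bsf)),
            all(bsf$bsf >= 1))
  if (!is.null(mu_en_ratio)) {
    stopifnot(mu_en_ratio >= 0.9, mu_en_ratio <= 1.2)
  }
  stopifnot(af_value > 0, af_value <= 1)
  structure(list(bsf = bsf, mu_en_ratio = mu_en_ratio,
                 af_mode = af_mode, af_value = af_value,
                 attenuation = attenuation),
            class = "beam_quality_tables")
}

#' Backscatter factor lookup with bilinear interpolation
#'
#' Interpolates the backscatter factor at an (HVL, field side) key.
#' Keys outside the tabulated hull raise an error rather than clamping:
#' silent extrapolation of backscatter data is a classic dosimetry bug.
#'
#' @param tables a [beam_quality_tables()].
#' @param hvl_mm_al beam HVL, mm Al.
#' @param field_side_cm equivalent square field side at the skin, cm.
#' @return dimensionless backscatter factor (>= 1).
#' @export
bsf_lookup <- function(tables, hvl_mm_al, field_side_cm) {
  b <- tables$bsf
  hs <- sort(unique(b$hvl_mm_al))
  fs <- sort(unique(b$field_side_cm))
  if (hvl_mm_al < min(hs) || hvl_mm_al > max(hs) ||
      field_side_cm < min(fs) || field_side_cm > max(fs)) {
    stop(sprintf(
      "BSF key (HVL %.3g mm Al, field %.3g cm) outside table hull [%g, %g] x [%g, %g]",
      hvl_mm_al, field_side_cm, min(hs), max(hs), min(fs), max(fs)))
  }
  i <- findInterval(hvl_mm_al, hs, rightmost.closed = TRUE)
  j <- findInterval(field_side_cm, fs, rightmost.closed = TRUE)
  i <- min(i, length(hs) - 1); j <- min(j, length(fs) - 1)
  h0 <- hs[i]; h1 <- hs[i + 1]; f0 <- fs[j]; f1 <- fs[j + 1]
  g <- function(h, f) b$bsf[b$hvl_mm_al == h & b$field_side_cm == f][1]
  th <- (hvl_mm_al - h0) / (h1 - h0)
  tf <- (field_side_cm - f0) / (f1 - f0)
  (1 - th) * (1 - tf) * g(h0, f0) + th * (1 - tf) * g(h1, f0) +
    (1 - th) * tf * g(h0, f1) + th * tf * g(h1, f1)
}

# per-event spectral context reused across grid points: spectrum after
# added Cu filtration, its HVL, and the tissue/air mu_en ratio
event_spectrum_context <- function(event, tables) {
  sp <- generate_spectrum(event$kvp, tables = tables$attenuation)
  if (event$added_filtration_mm_cu > 0) {
    sp <- apply_filtration(sp, "Cu", event$added_filtration_mm_cu,
                           tables$attenuation)
  }
  list(spectrum = sp,
       hvl = compute_hvl(sp, tables = tables$attenuation),
       mu_ratio = if (is.null(tables$mu_en_ratio)) {
         spectrum_weighted_mu_en_ratio(sp, "soft_tissue", "air",
                                       tables$attenuation)
       } else tables$mu_en_ratio)
}

#' Skin dose at one traced point from one irradiation event
#'
#' Evaluates the literal correction-factor product
#' `K_a,r * beta * (d_ref/d_skin)^2 * BSF * (mu_en/rho ratio) * AF`
#' at a traced skin point. Out-of-field points receive exactly 0 mGy:
#' the model carries no scatter from adjacent fields.
#'
#' @param event an [irradiation_event()].
#' @param trace_point one row of a [trace_beam()] result.
#' @param beta KAP-meter calibration factor.
#' @param tables a [beam_quality_tables()].
#' @param spectrum optional precomputed context from the event spectrum;
#'   when `NULL` it is built from the event's beam quality.
#' @return absorbed skin dose, mGy.
#' @export
event_dose <- function(event, trace_point, beta = 1.0,
                       tables = beam_quality_tables(), spectrum = NULL) {
  if (!isTRUE(trace_point$in_field)) return(0)
  ctx <- if (is.null(spectrum)) {
    event_spectrum_context(event, tables)
  } else spectrum
  d_skin <- trace_point$d_skin
  side_skin <- sqrt(event$field_w_iso * event$field_h_iso) *
    d_skin / event$sod
  bsf <- bsf_lookup(tables, ctx$hvl, side_skin)
  af <- if (tables$af_mode == "lookup") {
    tables$af_value
  } else {
    af_from_paths(ctx$spectrum, trace_point$table_path_mm,
                  trace_point$pad_path_mm, tables = tables$attenuation)
  }
  event$k_ar * beta * (event$d_ref / d_skin)^2 * bsf * ctx$mu_ratio * af
}

#' Accumulate a skin dose map over an event log
#'
#' Traces every irradiation event onto the grid and sums the per-event,
#' per-point doses in file order. The per-event contributions are kept
#' as a ledger, so the cumulative map is exactly the ledger row sums and
#' individual events can be audited or re-expressed in the OSLD domain.
#'
#' @param events list of [irradiation_event()]s (an `event_log`).
#' @param grid a [build_grid()] phantom grid.
#' @param config optional list with elements `calibration`
#'   (a [calibration_config()]), `tables` (a [beam_quality_tables()])
#'   and `slabs` (a [slab_config()]); missing elements take defaults.
#' @return An object of class `dose_map`: the grid, the cumulative
#'   `dose` vector (mGy, one entry per grid point), and the
#'   points-by-events `ledger` matrix.
#' @export
accumulate_dose <- function(events, grid, config = list()) {
  calib <- config$calibration
  if (is.null(calib)) calib <- calibration_config()
  tables <- config$tables
  if (is.null(tables)) tables <- beam_quality_tables()
  slabs <- config$slabs
  if (is.null(slabs)) slabs <- slab_config()
  npt <- nrow(grid$points)
  ledger <- matrix(0, nrow = npt, ncol = length(events),
                   dimnames = list(NULL, vapply(events, function(e)
                     e$event_id, character(1))))
  for (k in seq_along(events)) {
    ev <- events[[k]]
    ctx <- event_spectrum_context(ev, tables)
    beta <- beta_for(calib, ev$kvp, ev$added_filtration_mm_cu)
    tr <- trace_beam(beam_from_event(ev), grid, slabs)$points
    idx <- which(tr$in_field)
    if (length(idx)) {
      ledger[idx, k] <- vapply(idx, function(m) {
        event_dose(ev, tr[m, ], beta, tables, ctx)
      }, numeric(1))
    }
  }
  structure(list(grid = grid,
                 dose = if (length(events)) rowSums(ledger) else
                   rep(0, npt),
                 ledger = ledger),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  psd <- peak_skin_dose(x)
  cat(sprintf("<dose_map> %d points, %d events; peak skin dose %.4g mGy at (i=%d, j=%d)\n",
              length(x$dose), ncol(x$ledger), psd$dose_mGy,
              psd$i, psd$j))
  invisible(x)
}

#' Peak skin dose of a dose map
#'
#' The maximum cumulative dose over the grid and where it occurs; ties
#' resolve to the first point in row-major (i, j) order.
#'
#' @param dosemap a [accumulate_dose()] result.
#' @return list with `dose_mGy`, `i`, `j`, and the flat point `index`.
#' @export
peak_skin_dose <- function(dosemap) {
  if (!length(dosemap$dose)) stop("empty dose map")
  k <- which.max(dosemap$dose)   # first max in row-major point order
  list(dose_mGy = dosemap$dose[k],
       i = dosemap$grid$points$i[k], j = dosemap$grid$points$j[k],
       index = k)
}

#' Export a dose map as a flat table
#'
#' @param dosemap a `dose_map`.
#' @param path optional CSV output path (`i,j,x,y,z,dose_mGy`).
#' @return the data.frame, invisibly when written to `path`.
#' @export
dose_map_table <- function(dosemap, path = NULL) {
  df <- cbind(dosemap$grid$points[c("i", "j", "x", "y", "z")],
              dose_mGy = dosemap$dose)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
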