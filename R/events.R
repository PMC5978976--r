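#' Irradiation events and event logs
#'
#' An irradiation event is one fluoroscopic exposure: the reference air
#' kerma it delivered plus the beam quality and C-arm/table geometry
#' needed to trace it onto the skin. Event logs (JSON arrays or CSV with
#' a header row) are the entry point of every dose-mapping run; they
#' stand in for the radiation dose structured report (RDSR) emitted by
#' the fluoroscopic unit, carrying the same per-event scalars.
#'
#' Units are fixed: mGy for kerma, cm for all distances and field sides,
#' kV for tube potential, degrees for gantry angles, mm Cu for added
#' filtration. No unit inference is performed.
#'
#' @param event_id character identifier, unique within a log.
#' @param k_ar reference air kerma for the event, mGy (>= 0).
#' @param kvp peak tube potential, kV, in [40, 150].
#' @param added_filtration_mm_cu added Cu filtration, mm (>= 0).
#' @param field_w_iso,field_h_iso collimated field side lengths at
#'   isocenter, cm (> 0).
#' @param gantry_primary_deg,gantry_secondary_deg gantry rotation angles,
#'   degrees; primary rotates the source in the axial (x-y) plane,
#'   secondary in the sagittal (y-z) plane.
#' @param sod source-to-isocenter distance, cm (> 0).
#' @param d_ref source-to-reference-point distance, cm (> 0).
#' @param table_lateral_cm,table_longitudinal_cm,table_height_cm table
#'   offsets, cm (lateral = patient-left x, longitudinal = cranial z,
#'   height = anterior y).
#' @param n_pulses pulse count.
#' @param pulse_width_ms pulse width, ms.
#' @param tube_current_ma tube current, mA.
#' @return An object of class `irradiation_event` (a named list).
#' @examples
#' ev <- irradiation_event("ev1", k_ar = 100, kvp = 80)
#' ev$k_ar
#' @export
irradiation_event <- function(event_id, k_ar, kvp,
                              added_filtration_mm_cu = 0,
                              field_w_iso = 15, field_h_iso = 15,
                              gantry_primary_deg = 0,
                              gantry_secondary_deg = 0,
                              sod = 75, d_ref = 60,
                              table_lateral_cm = 0,
                              table_longitudinal_cm = 0,
                              table_height_cm = 0,
                              n_pulses = 1, pulse_width_ms = 500,
                              tube_current_ma = 500) {
  ev <- list(event_id = as.character(event_id),
             k_ar = as.numeric(k_ar), kvp = as.numeric(kvp),
             added_filtration_mm_cu = as.numeric(added_filtration_mm_cu),
             field_w_iso = as.numeric(field_w_iso),
             field_h_iso = as.numeric(field_h_iso),
             gantry_primary_deg = as.numeric(gantry_primary_deg),
             gantry_secondary_deg = as.numeric(gantry_secondary_deg),
             sod = as.numeric(sod), d_ref = as.numeric(d_ref),
             table_lateral_cm = as.numeric(table_lateral_cm),
             table_longitudinal_cm = as.numeric(table_longitudinal_cm),
             table_height_cm = as.numeric(table_height_cm),
             n_pulses = as.numeric(n_pulses),
             pulse_width_ms = as.numeric(pulse_width_ms),
             tube_current_ma = as.numeric(tube_current_ma))
  class(ev) <- "irradiation_event"
  validate_event(ev)
  ev
}

.event_fields <- c("event_id", "k_ar", "kvp", "added_filtration_mm_cu",
                   "field_w_iso", "field_h_iso", "gantry_primary_deg",
                   "gantry_secondary_deg", "sod", "d_ref",
                   "table_lateral_cm", "table_longitudinal_cm",
                   "table_height_cm", "n_pulses", "pulse_width_ms",
                   "tube_current_ma")

.event_mandatory <- c("event_id", "k_ar", "kvp", "field_w_iso",
                      "field_h_iso", "sod", "d_ref")

#' Validate an irradiation event against its physical invariants
#'
#' @param ev an `irradiation_event`.
#' @param index optional record index used in error messages.
#' @return `ev`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_event <- function(ev, index = NULL) {
  at <- if (is.null(index)) "" else sprintf(" (record %d)", index)
  chk <- function(ok, msg) if (!isTRUE(ok)) {
    stop("invalid irradiation event", at, ": ", msg, call. = FALSE)
  }
  num <- setdiff(.event_fields, "event_id")
  for (f in num) {
    chk(is.numeric(ev[[f]]) && length(ev[[f]]) == 1 && is.finite(ev[[f]]),
        paste0("field '", f, "' must be a finite number"))
  }
  chk(ev$k_ar >= 0, "k_ar must be >= 0 (mGy)")
  chk(ev$kvp >= 40 && ev$kvp <= 150, "kvp must lie in [40, 150] kV")
  chk(ev$field_w_iso > 0 && ev$field_h_iso > 0, "field sides must be > 0")
  chk(ev$d_ref > 0, "d_ref must be > 0")
  chk(ev$sod > 0, "sod must be > 0")
  chk(ev$added_filtration_mm_cu >= 0,
      "added_filtration_mm_cu must be >= 0")
  invisible(ev)
}

#' @export
print.irradiation_event <- function(x, ...) {
  cat(sprintf(
    "<irradiation_event %s> K_a,r = %.4g mGy @ %g kVp + %g mm Cu, %g x %g cm2, gantry (%g, %g) deg\n",
    x$event_id, x$k_ar, x$kvp, x$added_filtration_mm_cu,
    x$field_w_iso, x$field_h_iso,
    x$gantry_primary_deg, x$gantry_secondary_deg))
  invisible(x)
}

.event_from_record <- function(rec, index) {
  known <- intersect(names(rec), .event_fields)
  unknown <- setdiff(names(rec), .event_fields)
  if (length(unknown)) {
    warning("ignoring unknown event field(s) at record ", index, ": ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.event_mandatory, known)
  if (length(missing)) {
    stop("event log schema error at record ", index,
         ": missing mandatory field(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in setdiff(known, "event_id")) {
    v <- suppressWarnings(as.numeric(rec[[f]]))
    if (is.na(v)) {
      stop("event log parse error at record ", index, ": field '", f,
           "' is not numeric (", rec[[f]], ")", call. = FALSE)
    }
    rec[[f]] <- v
  }
  ev <- do.call(irradiation_event, rec[known])
  tryCatch(validate_event(ev, index), error = function(e) stop(e))
  ev
}

#' Read an irradiation-event log
#'
#' Reads a JSON array of objects or a CSV file with one header row; keys
#' and column names are the snake_case field names of
#' [irradiation_event()]. Events are returned in file order and each is
#' validated; unknown fields are ignored with a warning, missing
#' mandatory fields raise a schema error naming the field and record.
#'
#' @param path path to the log file.
#' @param dialect `"json"` or `"csv"`; default guesses from the
#'   extension.
#' @return A list of `irradiation_event` objects (class `event_log`).
#' @export
read_event_log <- function(path, dialect = c("auto", "json", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stop("event log not found: ", path)
  recs <- if (dialect == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (length(x) && !is.list(x[[1]])) x <- list(x)  # single object
    x
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  events <- lapply(seq_along(recs), function(i) {
    .event_from_record(recs[[i]], i)
  })
  class(events) <- "event_log"
  events
}

#' Write an irradiation-event log
#'
#' Inverse of [read_event_log()]: `read_event_log(write_event_log(x, p))`
#' reproduces `x` field for field, in both dialects.
#'
#' @param events a list of `irradiation_event` objects.
#' @param path output path.
#' @param dialect `"json"` or `"csv"`; default guesses from extension.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, dialect = c("auto", "json", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  lapply(events, validate_event)
  rows <- lapply(events, function(ev) ev[.event_fields])
  if (dialect == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
    if (is.null(df)) {
      df <- as.data.frame(stats::setNames(rep(list(character(0)),
                                       length(.event_fields)),
                                   .event_fields))
    }
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Calibration configuration for the KAP meter
#'
#' The calibration factor beta relates the kerma-area-product meter's
#' reported reference air kerma to the ion-chamber domain. It may be a
#' single scalar (applied to every event) or a table keyed by beam
#' quality `(kvp, cu_mm)`; with a keyed table, events whose beam quality
#' is absent fall back to the scalar default.
#'
#' @param beta scalar calibration factor (> 0), default 1 (the unit on
#'   whose numeric value the vendor record is silent).
#' @param by_quality optional data.frame with columns `kvp`, `cu_mm`,
#'   `beta`.
#' @param description free-text provenance note.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(beta = 1.0, by_quality = NULL,
                               description = "") {
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0)
  if (!is.null(by_quality)) {
    stopifnot(is.data.frame(by_quality),
              all(c("kvp", "cu_mm", "beta") %in% names(by_quality)),
              all(by_quality$beta > 0))
  }
  structure(list(beta = beta, by_quality = by_quality,
                 description = description),
            class = "calibration_config")
}

#' Look up the calibration factor for a beam quality
#'
#' @param config a [calibration_config()].
#' @param kvp,cu_mm the beam quality key.
#' @return the calibration factor beta (scalar broadcast when the keyed
#'   lookup is absent).
#' @export
beta_for <- function(config, kvp, cu_mm = 0) {
  if (!is.null(config$by_quality)) {
    hit <- config$by_quality$kvp == kvp & config$by_quality$cu_mm == cu_mm
    if (any(hit)) return(config$by_quality$beta[which(hit)[1]])
  }
  config$beta
}
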