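#' The nine standard beam qualities
#'
#' Cross product of the three peak tube potentials (50, 80, 100 kVp)
#' with the three added-filtration settings (none, 0.2, 0.6 mm Cu) used
#' throughout the validation scenarios.
#'
#' @return data.frame with columns `kvp`, `cu_mm` (9 rows, no
#'   duplicates).
#' @export
nine_beam_qualities <- function() {
  expand.grid(kvp = c(50, 80, 100), cu_mm = c(0, 0.2, 0.6),
              KEEP.OUT.ATTRS = FALSE)
}

#' Specification of a synthetic validation scenario
#'
#' Names one of the canned phantom-irradiation scenarios and fixes its
#' stochastic ingredients. The noise model is multiplicative lognormal
#' with unit mean (OSL readout uncertainty is proportional to signal);
#' the scatter model inflates in-field readings by `scatter_fraction`
#' and deposits `scatter_fraction` of the mean adjacent in-field dose on
#' the one-point out-of-field border — a geometric stand-in whose only
#' job is to reproduce the sign of the scatter excess real dosimeters
#' record over a scatter-free ray-traced map. With `noise_cv = 0` and
#' `scatter_fraction = 0`, readings equal the ground truth exactly.
#'
#' @param name one of `"table2_grid"`, `"table3_grid"`, `"table4_grid"`
#'   (nine beam qualities on-phantom / behind table / behind table+pad),
#'   `"table5_angles"` (0/30/60 degrees with and without pad at
#'   80 kVp / 0.2 mm Cu, 5 x 5 cm2), `"fig7_two_fields"` (two 5 x 5
#'   fields displaced 6 cm, no table/pad) or `"fig8_two_fields"` (two
#'   5 x 5 fields displaced 4 cm, behind table and pad).
#' @param seed integer RNG seed.
#' @param noise_cv fractional coefficient of variation of the OSLD
#'   readout noise (>= 0, default 0.02).
#' @param scatter_fraction fraction in [0, 0.3) (default 0.05).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("table2_grid", "table3_grid",
                                   "table4_grid", "table5_angles",
                                   "fig7_two_fields", "fig8_two_fields"),
                          seed = 1, noise_cv = 0.02,
                          scatter_fraction = 0.05) {
  name <- match.arg(name)
  stopifnot(noise_cv >= 0, scatter_fraction >= 0, scatter_fraction < 0.3)
  structure(list(name = name, seed = as.integer(seed),
                 noise_cv = noise_cv,
                 scatter_fraction = scatter_fraction),
            class = "scenario_spec")
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic correction-factor fixture for the nine beam qualities:
# measured CFs near unity, Monte Carlo CFs ordered
# phantom >= phantom_table >= phantom_table_pad and mildly decreasing
# with incidence angle
fixture_correction_factors <- function() {
  bq <- nine_beam_qualities()
  cfm <- data.frame(kvp = bq$kvp, cu_mm = bq$cu_mm,
                    cf = 0.94 + 0.0006 * bq$kvp + 0.05 * bq$cu_mm)
  base <- c(phantom = 1.30, phantom_table = 1.21,
            phantom_table_pad = 1.12)
  grid <- expand.grid(kvp = c(50, 80, 100), cu_mm = c(0, 0.2, 0.6),
                      geometry = names(base), angle_deg = c(0, 30, 60),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$cf <- base[grid$geometry] * (1 - 0.0012 * grid$angle_deg) *
    (1 + 0.0002 * (grid$kvp - 80)) * (1 - 0.02 * grid$cu_mm)
  correction_factor_set(cfm, grid)
}

# per-quality reference air kerma magnitudes (mGy) on the scale of the
# on-phantom validation doses, derived from the bundled dataset
fixture_kerma <- function() {
  v <- validation_doses("phantom")
  stats::setNames(v$measured_mGy, paste(v$kvp, v$cu_mm))
}

scenario_event <- function(id, kvp, cu_mm, k_ar, field = 15,
                           angle = 0, ...) {
  irradiation_event(event_id = id, k_ar = k_ar, kvp = kvp,
                    added_filtration_mm_cu = cu_mm,
                    field_w_iso = field, field_h_iso = field,
                    gantry_secondary_deg = angle, ...)
}

#' Re-express a dose map in the OSLD domain, event by event
#'
#' Divides each event's ledger contribution by the measured
#' cross-calibration factor of that event's beam quality and re-sums, so
#' maps accumulated over mixed beam qualities land in the OSLD domain
#' correctly.
#'
#' @param dosemap a `dose_map`.
#' @param events the event log the map was accumulated from (same
#'   order).
#' @param cfs a [correction_factor_set()].
#' @return a `dose_map` in the OSLD domain.
#' @export
dose_map_to_osld <- function(dosemap, events, cfs) {
  stopifnot(length(events) == ncol(dosemap$ledger))
  led <- dosemap$ledger
  for (k in seq_along(events)) {
    cf <- cf_lookup(cfs, events[[k]]$kvp,
                    events[[k]]$added_filtration_mm_cu)
    led[, k] <- to_osld_domain(led[, k], cf)
  }
  structure(list(grid = dosemap$grid,
                 dose = if (ncol(led)) rowSums(led) else
                   rep(0, nrow(dosemap$grid$points)),
                 ledger = led),
            class = "dose_map")
}

# scatter + noise applied to ground-truth OSLD-domain doses on the grid
synthesize_readings <- function(grid, truth, spec) {
  p <- grid$points
  in_field <- truth > 0
  reading <- truth
  if (spec$scatter_fraction > 0 && any(in_field)) {
    reading[in_field] <- truth[in_field] * (1 + spec$scatter_fraction)
    # one-point border: out-of-field points adjacent (Chebyshev 1) to
    # an in-field point pick up a scatter_fraction of the mean
    # neighboring in-field dose
    for (m in which(!in_field)) {
      nb <- which(abs(p$i - p$i[m]) <= 1 & abs(p$j - p$j[m]) <= 1 &
                    in_field)
      if (length(nb)) {
        reading[m] <- spec$scatter_fraction * mean(truth[nb])
      }
    }
  }
  keep <- reading > 0
  out <- data.frame(i = p$i[keep], j = p$j[keep],
                    dose_mGy = reading[keep])
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    out$dose_mGy <- out$dose_mGy *
      with_seed(spec$seed,
                stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2,
                              sdlog = sdlog))
  }
  out
}

#' Build a complete synthetic validation scenario
#'
#' Deterministically generates the event log, correction-factor tables,
#' phantom grid, ground-truth dose map (accumulated through the dose
#' engine), its OSLD-domain counterpart, and synthetic OSLD grid
#' readings for one of the canned scenarios. Identical specs (including
#' seed) give bit-identical outputs.
#'
#' @param spec a [scenario_spec()] (or a scenario name, with spec
#'   defaults).
#' @return list with `spec`, `events`, `conditions` (per-event geometry
#'   flags), `cf` (a [correction_factor_set()]), `grid`, `truth`
#'   (algorithm-domain `dose_map`), `truth_osld` (OSLD-domain
#'   `dose_map`), `readings` (data.frame `i`, `j`, `dose_mGy`) and
#'   `config` (the `accumulate_dose()` config used per condition).
#' @export
make_scenario <- function(spec) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  cf <- fixture_correction_factors()
  grid <- build_grid()
  tables <- beam_quality_tables()
  calib <- calibration_config()
  kar <- fixture_kerma()
  slabs_for <- function(geometry) {
    switch(geometry,
           phantom = slab_config(),
           phantom_table = slab_config(table_present = TRUE),
           phantom_table_pad = slab_config(table_present = TRUE,
                                           pad_present = TRUE))
  }
  if (spec$name %in% c("table2_grid", "table3_grid", "table4_grid")) {
    geometry <- switch(spec$name, table2_grid = "phantom",
                       table3_grid = "phantom_table",
                       table4_grid = "phantom_table_pad")
    bq <- nine_beam_qualities()
    events <- lapply(seq_len(nrow(bq)), function(k) {
      scenario_event(sprintf("bq%02d", k), bq$kvp[k], bq$cu_mm[k],
                     k_ar = kar[[paste(bq$kvp[k], bq$cu_mm[k])]])
    })
    conditions <- data.frame(event_id = vapply(events, `[[`,
                                               character(1), "event_id"),
                             geometry = geometry, angle_deg = 0)
  } else if (spec$name == "table5_angles") {
    cond <- expand.grid(angle = c(0, 30, 60),
                        geometry = c("phantom_table",
                                     "phantom_table_pad"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    events <- lapply(seq_len(nrow(cond)), function(k) {
      scenario_event(sprintf("ang%d_%s", cond$angle[k],
                             sub("phantom_", "", cond$geometry[k])),
                     kvp = 80, cu_mm = 0.2,
                     k_ar = kar[["80 0.2"]], field = 5,
                     angle = cond$angle[k])
    })
    conditions <- data.frame(event_id = vapply(events, `[[`,
                                               character(1), "event_id"),
                             geometry = cond$geometry,
                             angle_deg = cond$angle)
  } else {                               # two-field scenarios
    two <- if (spec$name == "fig7_two_fields") {
      # 6-cm displacement, cranial-caudal and table-height; on-phantom
      list(geometry = "phantom", dz = 6, dx = 0, dy = 6)
    } else {
      # 4-cm displacement, cranial-caudal and left-right; table + pad
      list(geometry = "phantom_table_pad", dz = 4, dx = 4, dy = 0)
    }
    events <- list(
      scenario_event("fieldA", 80, 0.2, k_ar = 100, field = 5),
      scenario_event("fieldB", 80, 0.2, k_ar = 100, field = 5,
                     table_longitudinal_cm = two$dz,
                     table_lateral_cm = two$dx,
                     table_height_cm = two$dy))
    conditions <- data.frame(event_id = c("fieldA", "fieldB"),
                             geometry = two$geometry, angle_deg = 0)
  }
  # accumulate per geometry condition (slab stack differs), then merge
  maps <- lapply(split(seq_along(events), conditions$geometry),
                 function(idx) {
    cfgk <- list(calibration = calib, tables = tables,
                 slabs = slabs_for(conditions$geometry[idx[1]]))
    list(idx = idx,
         map = accumulate_dose(events[idx], grid, cfgk))
  })
  ledger <- matrix(0, nrow = nrow(grid$points), ncol = length(events),
                   dimnames = list(NULL, vapply(events, `[[`,
                                                character(1),
                                                "event_id")))
  for (m in maps) ledger[, m$idx] <- m$map$ledger
  truth <- structure(list(grid = grid, dose = rowSums(ledger),
                          ledger = ledger), class = "dose_map")
  truth_osld <- dose_map_to_osld(truth, events, cf)
  readings <- synthesize_readings(grid, truth_osld$dose, spec)
  class(events) <- "event_log"
  list(spec = spec, events = events, conditions = conditions, cf = cf,
       grid = grid, truth = truth, truth_osld = truth_osld,
       readings = readings,
       config = list(calibration = calib, tables = tables,
                     slabs_for = slabs_for))
}
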