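# Independent oracles and small generators shared across the test files.
# Everything here recomputes quantities by a different route than the
# package code paths under test.

# random valid irradiation event
random_event <- function(id = "ev") {
  irradiation_event(
    event_id = paste0(id, sample.int(1e6, 1)),
    k_ar = runif(1, 1, 500),
    kvp = runif(1, 50, 120),
    added_filtration_mm_cu = sample(c(0, 0.2, 0.6), 1),
    field_w_iso = runif(1, 4, 20), field_h_iso = runif(1, 4, 20),
    gantry_primary_deg = runif(1, -30, 30),
    gantry_secondary_deg = runif(1, -60, 60),
    sod = runif(1, 60, 90), d_ref = runif(1, 40, 75),
    table_lateral_cm = runif(1, -8, 8),
    table_longitudinal_cm = runif(1, -8, 8),
    table_height_cm = runif(1, -5, 5))
}

# brute-force HVL by monotone two-stage thickness scan: 0.01-mm bracket
# sweep, then a full 1e-4-mm sweep inside the bracketing interval
# (air-kerma transmission is strictly decreasing in thickness, so this
# equals a full-range 1e-4 scan). Transmission is recomputed here from
# raw table interpolation, independent of compute_hvl's root finder.
brute_force_hvl <- function(spectrum, step_fine = 1e-4) {
  tab <- load_attenuation_tables()
  al <- tab[tab$material == "Al", ]
  air <- tab[tab$material == "air", ]
  mu <- exp(approx(log(al$energy_keV), log(al$mu_over_rho),
                   xout = log(spectrum$energies))$y) * al$density[1]
  w <- spectrum$fluence * spectrum$energies *
    exp(approx(log(air$energy_keV), log(air$mu_en_over_rho),
               xout = log(spectrum$energies))$y)
  tr <- function(t_mm) colSums(w * exp(-outer(mu, t_mm / 10))) / sum(w)
  coarse <- seq(0, 30, by = 0.01)
  i <- findInterval(-0.5, -tr(coarse))     # last t with transmission > 0.5
  fine <- seq(coarse[i], coarse[min(i + 1, length(coarse))],
              by = step_fine)
  v <- tr(fine)
  fine[which.min(abs(v - 0.5))]
}

# independent in-pyramid classification by explicit half-space planes:
# a point is inside the rectangular collimation pyramid iff it lies on
# the inner side of all four side planes and forward of the apex.
oracle_in_field <- function(beam, pts) {
  v <- sweep(as.matrix(pts[, c("x", "y", "z")]), 2,
             beam$source_position)
  planes <- list(
    cos(beam$half_angle_w) * beam$e_w - sin(beam$half_angle_w) * beam$central_axis,
    -cos(beam$half_angle_w) * beam$e_w - sin(beam$half_angle_w) * beam$central_axis,
    cos(beam$half_angle_h) * beam$e_h - sin(beam$half_angle_h) * beam$central_axis,
    -cos(beam$half_angle_h) * beam$e_h - sin(beam$half_angle_h) * beam$central_axis)
  inside <- v %*% beam$central_axis > 0
  margin <- rep(Inf, nrow(v))
  for (n in planes) {
    s <- v %*% n
    inside <- inside & s <= 0
    margin <- pmin(margin, abs(s))
  }
  facing <- v %*% c(0, -1, 0) < 0           # face normal is (0,-1,0)
  list(in_field = as.vector(inside & facing),
       boundary_margin = as.vector(margin))
}

# percent-error interval attainable from printed doses rounded to their
# last printed digit (half-ulp envelope)
printed_pe_envelope <- function(measured, predicted, ulp = 0.1) {
  h <- ulp / 2
  lo <- 100 * ((predicted - h) - (measured + h)) / (measured + h)
  hi <- 100 * ((predicted + h) - (measured - h)) / (measured - h)
  c(lo, hi)
}
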