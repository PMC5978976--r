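#' Attenuation and energy-absorption coefficient tables
#'
#' Loads the bundled mass attenuation (mu/rho) and mass energy-absorption
#' (mu_en/rho) coefficients, cm^2/g, on the standard 10--150 keV grid for
#' Al, Cu, air, ICRU-44 soft tissue, the Al-equivalent table composite,
#' and low-density pad foam. Coefficients between grid energies are
#' obtained by log-log linear interpolation, the standard treatment for
#' these smooth power-law-like curves.
#'
#' @param path optional CSV path with columns
#'   `material,energy_keV,mu_over_rho,mu_en_over_rho,density`; defaults
#'   to the bundled table.
#' @return data.frame of class `attenuation_table`.
#' @export
load_attenuation_tables <- function(path = NULL) {
  if (is.null(path)) path <- sd_extdata("attenuation_coefficients.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("material", "energy_keV", "mu_over_rho",
                  "mu_en_over_rho", "density") %in% names(tab)),
            all(tab$mu_over_rho > 0), all(tab$mu_en_over_rho > 0))
  tab <- tab[order(tab$material, tab$energy_keV), ]
  class(tab) <- c("attenuation_table", "data.frame")
  tab
}

# cache of the default tables (read-once)
.sd_env <- new.env(parent = emptyenv())

default_attenuation <- function() {
  if (is.null(.sd_env$att)) .sd_env$att <- load_attenuation_tables()
  .sd_env$att
}

# log-log interpolation of a coefficient column onto arbitrary energies.
# Errors if energies fall outside the tabulated range: silently
# extrapolated attenuation coefficients are a classic dosimetry bug.
interp_coeff <- function(tables, material, energies,
                         column = c("mu_over_rho", "mu_en_over_rho")) {
  column <- match.arg(column)
  sub <- tables[tables$material == material, ]
  if (!nrow(sub)) stop("unknown material: ", material)
  rng <- range(sub$energy_keV)
  if (any(energies < rng[1] - 1e-9 | energies > rng[2] + 1e-9)) {
    stop("energies outside tabulated range [", rng[1], ", ", rng[2],
         "] keV for material ", material)
  }
  exp(stats::approx(log(sub$energy_keV), log(sub[[column]]),
                    xout = log(pmin(pmax(energies, rng[1]), rng[2])),
                    rule = 1)$y)
}

material_density <- function(tables, material) {
  sub <- tables[tables$material == material, ]
  if (!nrow(sub)) stop("unknown material: ", material)
  sub$density[1]
}

#' Construct an energy spectrum object
#'
#' @param energies keV bin centers, strictly increasing.
#' @param fluence relative photons per bin, all >= 0.
#' @param kvp peak tube potential, kV; `max(energies) <= kvp`.
#' @return object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies, fluence, kvp) {
  stopifnot(length(energies) >= 2, length(fluence) == length(energies),
            all(diff(energies) > 0), all(fluence >= 0),
            max(energies) <= kvp + 1e-9)
  structure(list(energies = as.numeric(energies),
                 fluence = as.numeric(fluence), kvp = as.numeric(kvp)),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %g kVp, %d bins [%g, %g] keV, mean energy %.2f keV\n",
              x$kvp, length(x$energies), min(x$energies), max(x$energies),
              mean_energy(x)))
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum, keV
#' @param spectrum an `energy_spectrum`.
#' @return mean photon energy, keV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$fluence * spectrum$energies) / sum(spectrum$fluence)
}

#' Generate an equivalent x-ray tube spectrum
#'
#' Semi-empirical bremsstrahlung model: the unfiltered photon fluence
#' follows the Kramers form N(E) proportional to (kVp - E)/E
#' (characteristic lines omitted), then hardened by the tube's inherent
#' filtration as an Al slab. The spectrum endpoint fluence at E = kVp is
#' exactly zero. This is a pluggable stand-in for a full tube model: all
#' downstream quantities (HVL, transmission, mu_en averages) consume only
#' the `energy_spectrum` contract.
#'
#' @param kvp peak tube potential, kV, in [40, 150].
#' @param inherent_filtration_mm_al inherent Al filtration, mm
#'   (default 2.5, typical for interventional tubes).
#' @param bin_keV energy bin width, keV (default 0.5).
#' @param tables attenuation tables (default bundled).
#' @return an `energy_spectrum` with support in [10, kvp] keV.
#' @export
generate_spectrum <- function(kvp, inherent_filtration_mm_al = 2.5,
                              bin_keV = 0.5, tables = default_attenuation()) {
  if (kvp < 40 || kvp > 150) stop("kvp out of range [40, 150]")
  energies <- seq(10, kvp, by = bin_keV)
  if (energies[length(energies)] < kvp) energies <- c(energies, kvp)
  fl <- (kvp - energies) / energies          # Kramers bremsstrahlung
  sp <- energy_spectrum(energies, fl / max(fl), kvp)
  if (inherent_filtration_mm_al > 0) {
    sp <- apply_filtration(sp, "Al", inherent_filtration_mm_al, tables)
  }
  sp
}

#' Filter a spectrum through a material slab
#'
#' Per-bin Beer-Lambert attenuation: fluence is multiplied by
#' exp(-mu(E) t). Zero thickness is the identity; filtering by t1 then t2
#' equals filtering by t1 + t2 bin-exactly.
#'
#' @param spectrum an `energy_spectrum`.
#' @param material material name present in `tables`.
#' @param thickness_mm slab thickness, mm (>= 0).
#' @param tables attenuation tables.
#' @return the hardened `energy_spectrum`.
#' @export
apply_filtration <- function(spectrum, material, thickness_mm,
                             tables = default_attenuation()) {
  stopifnot(thickness_mm >= 0)
  if (thickness_mm == 0) return(spectrum)
  mu <- interp_coeff(tables, material, spectrum$energies, "mu_over_rho") *
    material_density(tables, material)                  # 1/cm
  tr <- exp(-mu * thickness_mm / 10)
  energy_spectrum(spectrum$energies, spectrum$fluence * tr, spectrum$kvp)
}

# air-kerma weights for a spectrum: fluence * E * (mu_en/rho)_air
kerma_weights <- function(spectrum, tables = default_attenuation()) {
  spectrum$fluence * spectrum$energies *
    interp_coeff(tables, "air", spectrum$energies, "mu_en_over_rho")
}

# air-kerma transmission of the spectrum through t mm of a material
kerma_transmission <- function(spectrum, material, thickness_mm,
                               tables = default_attenuation()) {
  w <- kerma_weights(spectrum, tables)
  mu <- interp_coeff(tables, material, spectrum$energies, "mu_over_rho") *
    material_density(tables, material)
  sum(w * exp(-mu * thickness_mm / 10)) / sum(w)
}

#' Half-value layer of a spectrum
#'
#' Thickness of the reference material (mm Al by convention) that halves
#' the air kerma of the beam under narrow-beam, scatter-free conditions:
#' the root of K(t)/K(0) = 1/2 with
#' K(t) = sum fluence * E * (mu_en/rho)_air * exp(-mu(E) t), found by
#' bracketed root search on [0, 30] mm to 1e-6 mm.
#'
#' @param spectrum an `energy_spectrum`.
#' @param reference_material reference material, default `"Al"`.
#' @param tables attenuation tables.
#' @return HVL in mm of the reference material.
#' @export
compute_hvl <- function(spectrum, reference_material = "Al",
                        tables = default_attenuation()) {
  f <- function(t) kerma_transmission(spectrum, reference_material, t,
                                      tables) - 0.5
  if (f(0) < 0 || f(30) > 0) {
    stop("HVL root not bracketed within [0, 30] mm ",
         reference_material)
  }
  stats::uniroot(f, c(0, 30), tol = 1e-6)$root
}

#' Match added filtration to a target half-value layer
#'
#' Finds the Al-equivalent added filtration that brings a tube spectrum
#' at the given kVp to a target HVL, by monotone bisection on the added
#' thickness (HVL increases strictly with added filtration). The matched
#' HVL agrees with the target to within `tol_mm`.
#'
#' @param kvp peak tube potential, kV.
#' @param target_hvl_mm_al target HVL, mm Al.
#' @param inherent_filtration_mm_al inherent filtration of the base
#'   spectrum, mm Al.
#' @param tol_mm matching tolerance on HVL, mm Al (default 0.01).
#' @param tables attenuation tables.
#' @return list with `added_mm_al` (added Al-equivalent filtration, mm)
#'   and `spectrum` (the matched `energy_spectrum`).
#' @export
match_added_filtration <- function(kvp, target_hvl_mm_al,
                                   inherent_filtration_mm_al = 2.5,
                                   tol_mm = 0.01,
                                   tables = default_attenuation()) {
  base <- generate_spectrum(kvp, inherent_filtration_mm_al,
                            tables = tables)
  hvl0 <- compute_hvl(base, tables = tables)
  if (target_hvl_mm_al < hvl0 - tol_mm) {
    stop(sprintf(
      "target HVL %.3f mm Al infeasible: unfiltered spectrum already at %.3f mm Al",
      target_hvl_mm_al, hvl0))
  }
  if (abs(target_hvl_mm_al - hvl0) <= tol_mm) {
    return(list(added_mm_al = 0, spectrum = base))
  }
  hvl_at <- function(t) {
    compute_hvl(apply_filtration(base, "Al", t, tables), tables = tables)
  }
  hi <- 1
  while (hvl_at(hi) < target_hvl_mm_al && hi < 128) hi <- hi * 2
  if (hvl_at(hi) < target_hvl_mm_al) {
    stop("target HVL unreachable with ", hi, " mm added Al")
  }
  lo <- 0
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (hvl_at(mid) < target_hvl_mm_al) lo <- mid else hi <- mid
  }
  t <- (lo + hi) / 2
  list(added_mm_al = t,
       spectrum = apply_filtration(base, "Al", t, tables))
}

#' Spectrum-weighted mass energy-absorption coefficient ratio
#'
#' Energy-fluence-weighted ratio of mass energy-absorption coefficients
#' between two materials,
#' sum(fluence E (mu_en/rho)_num) / sum(fluence E (mu_en/rho)_den),
#' with coefficients log-log interpolated onto the spectrum grid. The
#' tissue-to-air case converts air kerma to tissue dose in the skin-dose
#' model.
#'
#' @param spectrum an `energy_spectrum`.
#' @param numerator_material,denominator_material material names.
#' @param tables attenuation tables.
#' @return dimensionless ratio; exactly 1 when the materials coincide.
#' @export
spectrum_weighted_mu_en_ratio <- function(spectrum, numerator_material,
                                          denominator_material,
                                          tables = default_attenuation()) {
  if (identical(numerator_material, denominator_material)) return(1.0)
  w <- spectrum$fluence * spectrum$energies
  num <- interp_coeff(tables, numerator_material, spectrum$energies,
                      "mu_en_over_rho")
  den <- interp_coeff(tables, denominator_material, spectrum$energies,
                      "mu_en_over_rho")
  sum(w * num) / sum(w * den)
}

#' Table/pad attenuation factor for a slab stack
#'
#' Air-kerma-weighted narrow-beam transmission of the spectrum through a
#' stack of uniform slabs, with oblique incidence lengthening every path
#' by 1/cos(angle). This is the AF term of the skin-dose model: the
#' fraction of energy deposition surviving passage through the patient
#' table and mattress pad.
#'
#' @param spectrum an `energy_spectrum`.
#' @param slabs list of `list(material=, thickness_mm=)` entries; an
#'   empty list returns exactly 1.
#' @param incidence_angle_deg beam angle from the slab normal, degrees,
#'   in [0, 85].
#' @param tables attenuation tables.
#' @return attenuation factor in (0, 1].
#' @export
slab_transmission_factor <- function(spectrum, slabs,
                                     incidence_angle_deg = 0,
                                     tables = default_attenuation()) {
  if (incidence_angle_deg < 0 || incidence_angle_deg >= 90) {
    stop("incidence angle must lie in [0, 90) degrees")
  }
  if (incidence_angle_deg > 85) stop("incidence angle above 85 degrees")
  if (!length(slabs)) return(1.0)
  sec <- 1 / cos(incidence_angle_deg * pi / 180)
  w <- kerma_weights(spectrum, tables)
  atten <- rep(0, length(spectrum$energies))
  for (s in slabs) {
    mu <- interp_coeff(tables, s$material, spectrum$energies,
                       "mu_over_rho") * material_density(tables, s$material)
    atten <- atten + mu * (s$thickness_mm / 10) * sec
  }
  sum(w * exp(-atten)) / sum(w)
}

# AF from already-traced slab path lengths (mm), bypassing the 1/cos
# recomputation; agrees with slab_transmission_factor when paths equal
# thickness/cos(angle).
af_from_paths <- function(spectrum, table_path_mm, pad_path_mm,
                          table_material = "table_composite",
                          pad_material = "pad_foam",
                          tables = default_attenuation()) {
  if (table_path_mm <= 0 && pad_path_mm <= 0) return(1.0)
  w <- kerma_weights(spectrum, tables)
  atten <- rep(0, length(spectrum$energies))
  if (table_path_mm > 0) {
    atten <- atten + interp_coeff(tables, table_material,
                                  spectrum$energies, "mu_over_rho") *
      material_density(tables, table_material) * table_path_mm / 10
  }
  if (pad_path_mm > 0) {
    atten <- atten + interp_coeff(tables, pad_material,
                                  spectrum$energies, "mu_over_rho") *
      material_density(tables, pad_material) * pad_path_mm / 10
  }
  sum(w * exp(-atten)) / sum(w)
}
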