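---
title: "Skin dose mapping from irradiation event logs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin dose mapping from irradiation event logs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skindose)
```

## The dose model

Fluoroscopes report, per irradiation event, the cumulative reference air
kerma $K_{a,r}$ at a standardized point on the beam axis. `skindose`
converts that per-event record into absorbed dose on a lattice of skin
points by the multiplicative correction chain

$$D_{skin} \;=\; K_{a,r}\,\cdot\,\beta\,\cdot\,
\left(\frac{d_{ref}}{d_{skin}}\right)^{2}\,\cdot\,BSF\,\cdot\,
\left(\frac{\mu_{en}}{\rho}\right)_{air}^{tissue}\,\cdot\,AF$$

evaluated only at points the ray tracer classifies as inside the
collimated field. The factors, their units and defaults:

* $\beta$ — KAP-meter cross-calibration factor against a reference ion
  chamber, dimensionless. Scalar or keyed by beam quality
  (`calibration_config()`); default 1.0, because the vendor record is
  silent on its numeric value and it is a per-installation measurement.
* $(d_{ref}/d_{skin})^2$ — inverse square from the reference distance
  $d_{ref}$ (cm, from the event record) to the source-to-skin-point
  distance $d_{skin}$ (cm, from the trace). $d_{skin}$ is measured to
  the grid-point *center*, not to the ray-surface intersection; at the
  1.5-cm default pitch the difference is below the lattice
  discretization error.
* $BSF$ — backscatter factor, $\ge 1$, interpolated bilinearly from a
  bundled table keyed by HVL (mm Al) and equivalent-square field side at
  the skin (cm). The field side at the skin is the isocenter field side
  projected along the diverging beam, $\sqrt{w\,h}\cdot d_{skin}/SOD$,
  since backscatter conventionally depends on the field at the entrance
  surface. The bundled values are plausible handbook-shaped defaults
  covering HVL 1–10 mm Al and field sides 2–25 cm; they are
  configuration, not measurement, and absolute work should replace them
  with values matched to the local beam qualities.
* $(\mu_{en}/\rho)$ ratio — energy-fluence-weighted tissue-to-air ratio
  of mass energy-absorption coefficients, computed from the event's
  spectrum (default) or fixed by the user; across 50–150 kV beams it
  stays near 1.05–1.07.
* $AF$ — air-kerma-weighted narrow-beam transmission through the table
  and pad slabs, evaluated along each traced ray's actual path lengths;
  1 exactly when the beam enters the skin directly.

Out-of-field dose is exactly zero. This is a modeling decision, not an
approximation bug: the algorithm traces primary beam only, so scattered
photons from adjacent fields are invisible to it. Everywhere the package
compares maps against dosimeter readings it therefore flags
zero-map/nonzero-reading points as `scatter_only` instead of treating
them as errors, and the expected signature of real measurements is a
systematic *negative* map-minus-measurement error in-field.

## Spectrum model and beam-quality machinery

Beam-quality-dependent factors need a photon spectrum. The built-in
model is a semi-empirical Kramers bremsstrahlung form,
$N(E)\propto(kVp-E)/E$ hardened by 2.5 mm Al of inherent filtration
(typical for interventional tubes), binned at 0.5 keV on [10, kVp] with
zero fluence at the endpoint and no characteristic lines. This is
deliberately pluggable: every downstream consumer (HVL, transmission,
$\mu_{en}$ averaging, AF) uses only the `energy_spectrum` contract, so a
measured or published spectrum can be substituted bin-for-bin. Under the
built-in model the nine standard beam qualities (50/80/100 kVp ×
{0, 0.2, 0.6} mm Cu) span HVL 1.53–8.83 mm Al; the 80 kVp + 0.2 mm Cu
quality lands at 5.04 mm Al, consistent with the ~5.2–5.6 mm Al range
reported for comparable clinic beams.

Attenuation and energy-absorption coefficients (Al, Cu, air, ICRU-44
soft tissue, the Al-equivalent table composite and low-density pad foam)
are bundled on the standard 10–150 keV reference grid and log-log
interpolated — smooth, standard, and free of network dependence.
Energies outside the tabulated range, and backscatter keys outside the
table hull, raise errors rather than extrapolating: silent extrapolation
of dosimetric coefficients is the classic failure mode in this kind of
code.

HVL is defined on air-kerma transmission (narrow-beam, scatter-free),
found by bracketed root search on [0, 30] mm to $10^{-6}$ mm and
verified in the tests against a $10^{-4}$-mm brute-force transmission
scan. Filtration matching bisects added Al thickness to a 0.01-mm HVL
tolerance; matching is monotone because added filtration strictly
hardens the beam.

## Geometry conventions

Patient supine, head-first: $+z$ cranial, $+x$ patient-left, $+y$
anterior. The phantom is a 32-cm-diameter, 17.5-cm-thick cylinder whose
gridded flat face lies in the $y=0$ plane, centered on the isocenter,
with dosimeter points on a 1.5-cm square lattice clipped to the face
disc (0-based row-major `(i, j)` indices; the beam-axis point at gantry
zero is `(10, 10)`). At gantry (0, 0) the source sits under the table at
the source-to-isocenter distance, pointing $+y$; the primary gantry
angle rotates the source about $z$ (axial plane) and the secondary about
$x$ (sagittal plane), both right-handed — vendors do not share one
convention, so this one is stated explicitly and pinned by tests. Table
offsets move the patient relative to the beam, so the beam is translated
by minus the offset in phantom coordinates.

The collimated field is a rectangular pyramid (four half-space planes),
not a cone, with half-angles $\arctan(s/2\,/\,SOD)$. A point is in-field
iff its ray lies inside the pyramid *and* the point faces the source
(outward normal · ray < 0); grazing incidence classifies out-of-field.
Field centers are never snapped to the lattice: when a field
displacement is an exact multiple of the 1.5-cm pitch (6 cm = 4 × 1.5),
center alignment emerges from the modular arithmetic, and
`field_alignment_check()` computes exactly that remainder. Table and pad
are horizontal slabs below the face (defaults: 1.5 mm Al-equivalent
table, 70 mm foam pad, pad top 7 cm under the face); a traversing ray's
path length is thickness/$\cos\theta$, giving exactly 2× thickness at
60° incidence.

## Correction-factor algebra for OSLD validation

Validating a map against OSLDs requires moving between three dose
domains. The measured factor $CF_{meas} = D_{IC,air}/D_{OSL,air}$
(free-in-air ion chamber over free-in-air OSLD, per beam quality)
carries OSLD readings into the ion-chamber domain the map is calibrated
in. Monte Carlo geometry factors $CF_{MC}$ — ratios of energy-deposition
tallies in the OSLD between a complex geometry (on-phantom, behind
table, behind table+pad) and free-in-air — predict on-phantom response
from free-in-air response, packing $BSF\cdot(\mu_{en}/\rho)\cdot AF$
into a single measured-geometry factor; the tests verify this packing
identity against the dose engine exactly. Both factor families are
*inputs* (the tallies behind them come from transport calculations the
package does not perform); tally sets with relative error ≥ 5% are
rejected. Angle-dependent factors are characterized at 0/30/60° only and
linearly interpolated between anchors, clamping outside. The
map-vs-OSLD comparison divides the map by $CF_{meas}$
(`dose_map_to_osld()`), then compares per grid index with percent error
$100\,(pred-meas)/meas$, rounded half-away-from-zero to one decimal only
at report time.

The bundled validation dataset (`validation_doses()`) carries the
measured and predicted on-phantom doses of a physical OSLD campaign over
the nine beam qualities and three geometries plus an angular series.
Recomputing its percent errors reproduces the printed values exactly for
ten of 27 grid-series rows; the residuals elsewhere (up to ~0.2
percentage points, and larger only for the ~1.5-mGy 50 kVp/0.6 mm Cu
rows) are fully explained by the doses being printed to 0.1 mGy — the
acceptance tests check consistency against the half-ulp rounding
envelope of the printed inputs.

## Synthetic scenarios: what they emulate, and what they do not

`make_scenario()` builds six deterministic campaign-shaped scenarios:
the nine-beam-quality grids in each geometry (`table2_grid`,
`table3_grid`, `table4_grid`), the angular series (`table5_angles`, six
events at 0/30/60° with and without pad, 80 kVp + 0.2 mm Cu, 5 × 5 cm²),
and two two-field patterns: `fig7_two_fields` (6-cm displacement,
on-phantom — the fields are *disjoint* by construction) and
`fig8_two_fields` (4-cm displacement through table and pad — the fields
*overlap*, and the peak lands in the overlap, where the dose is exactly
the superposition of the two single-field doses). Reference air kerma
magnitudes are set to the scale of the bundled on-phantom doses so
synthetic maps land in the tens-to-hundreds of mGy.

Synthetic OSLD readings are ground truth (the engine's own map in the
OSLD domain) times a scatter term times noise. Noise is multiplicative
lognormal with unit mean and CV 0.02 by default — OSL readout
uncertainty is proportional to signal and its dose response is linear in
this range, so no additive term is included; the 2% figure is a
documented assumption about dosimeter repeatability, not a measured
value. Scatter is a geometric border kernel: in-field readings inflate
by `scatter_fraction` (default 0.05) and the one-point out-of-field
border receives `scatter_fraction` times the mean adjacent in-field
dose. This is emphatically not scatter physics; its only job is to
reproduce the *sign* structure of real campaigns (dosimeters read higher
than the scatter-free map everywhere in-field, and out-of-field
dosimeters read nonzero). Consequently, passing closed-loop tests shows
the pipeline's algebra and geometry are self-consistent — it says
nothing about absolute dosimetric accuracy on real patients, which
depends on the measured $\beta$, real backscatter tables and real
table/pad composition. With `noise_cv = 0, scatter_fraction = 0`
readings equal ground truth exactly, and all randomness flows from the
single `seed` in the scenario spec.

## Numerical choices and degenerate inputs

* Root finding: HVL via `uniroot` on [0, 30] mm, tolerance $10^{-6}$ mm;
  unbracketed roots (beams harder than 30 mm Al HVL) error out.
* Bisection: filtration matching to 0.01 mm Al on the added thickness.
* Interpolation: log-log for coefficients, bilinear for BSF, linear in
  angle for Monte Carlo factors; every table refuses out-of-range keys.
* Ties: peak skin dose resolves to the first row-major grid point; an
  all-zero map reports the first point with 0 mGy.
* Tolerances in geometry: $10^{-12}$ slack on the pyramid boundary and
  $10^{-6}$ boundary band exclusion in the sampling-oracle tests;
  grazing rays are out-of-field.
* Degenerate inputs: empty event logs produce a valid all-zero map;
  empty slab lists give AF = 1 exactly; a focal spot inside the phantom
  is a hard geometry error; zero measured dose refuses a percent error.
* Problem sizes: the default grid has 357 points (1.5-cm pitch); tests
  use a 0.5-cm grid (3209 points) for the ray-tracer oracle, 50 random
  beams (~160k classifications), 1000 random dose-product parameter
  sets and 50 random spectra for the HVL scan — sizes chosen so the
  whole suite completes in well under a minute of compute per module.

## Known limitations

* No scatter, by design: in-field doses are systematically conservative
  (low) relative to dosimeters, and out-of-field dose is zero.
* The built-in spectrum model has no characteristic lines and a single
  inherent-filtration parameter; HVLs are realistic but not
  tube-certified. Substitute measured spectra for absolute work.
* Bundled backscatter factors and table/pad compositions are generic
  defaults; $\beta$ defaults to 1.0 and must be measured per
  installation.
* The cylinder phantom's flat face is the only gridded surface; no
  patient-specific surface meshes.
* The event-log dialect is a flat JSON/CSV schema carrying the scalars
  the model needs; it is not a DICOM dose structured report parser.
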