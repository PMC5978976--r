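test_that("generated spectra respect the kVp endpoint and harden as expected", {
  sp <- generate_spectrum(80)
  expect_true(max(sp$energies) <= 80)
  expect_equal(sp$fluence[length(sp$fluence)], 0)   # zero at endpoint
  expect_true(all(sp$fluence >= 0))
  expect_lt(mean_energy(generate_spectrum(50)),
            mean_energy(generate_spectrum(100)))
  # adding Cu hardens the beam: mean energy strictly increases
  expect_gt(mean_energy(apply_filtration(sp, "Cu", 0.2)), mean_energy(sp))
  expect_error(generate_spectrum(30), "kvp")
  expect_error(generate_spectrum(160), "kvp")
})

test_that("filtration is identity at zero, multiplicative, and fluence-decreasing", {
  sp <- generate_spectrum(80)
  expect_identical(apply_filtration(sp, "Cu", 0), sp)
  a <- apply_filtration(apply_filtration(sp, "Cu", 0.13), "Cu", 0.29)
  b <- apply_filtration(sp, "Cu", 0.42)
  expect_equal(a$fluence, b$fluence, tolerance = 1e-12)
  expect_true(all(apply_filtration(sp, "Cu", 0.2)$fluence <= sp$fluence))
  expect_lt(sum(apply_filtration(sp, "Cu", 0.6)$fluence),
            sum(apply_filtration(sp, "Cu", 0.2)$fluence))
  expect_error(apply_filtration(sp, "unobtainium", 1), "unknown material")
})

test_that("a monoenergetic bin halves at mu*t = ln 2 in Cu", {
  tab <- load_attenuation_tables()
  mu <- tab$mu_over_rho[tab$material == "Cu" & tab$energy_keV == 60] *
    tab$density[tab$material == "Cu"][1]           # 1/cm at 60 keV
  t_mm <- 10 * log(2) / mu
  sp <- energy_spectrum(c(60, 61), c(1, 0), kvp = 61)
  out <- apply_filtration(sp, "Cu", t_mm)
  expect_equal(out$fluence[1], 0.5, tolerance = 1e-10)
})

test_that("monoenergetic HVL equals ln2/mu analytically", {
  tab <- load_attenuation_tables()
  mu <- tab$mu_over_rho[tab$material == "Al" & tab$energy_keV == 60] *
    tab$density[tab$material == "Al"][1]
  sp <- energy_spectrum(c(60, 60.5), c(1, 0), kvp = 61)
  expect_equal(compute_hvl(sp), 10 * log(2) / mu, tolerance = 1e-5)
})

test_that("two-line spectrum HVL matches the brute-force transmission scan", {
  # equal air-kerma weights at 30 and 80 keV
  tab <- load_attenuation_tables()
  air <- tab[tab$material == "air", ]
  muen <- function(e) air$mu_en_over_rho[air$energy_keV == e]
  fl <- c(1 / (30 * muen(30)), 1 / (80 * muen(80)))
  sp <- energy_spectrum(c(30, 80), fl, kvp = 81)
  expect_lt(abs(compute_hvl(sp) - brute_force_hvl(sp)), 1e-3)
})

test_that("HVL does not decrease under beam hardening", {
  for (kvp in c(50, 80, 100)) {
    sp <- generate_spectrum(kvp)
    expect_gte(compute_hvl(apply_filtration(sp, "Cu", 0.6)),
               compute_hvl(sp))
  }
})

test_that("filtration matching recovers a known added thickness", {
  base <- generate_spectrum(80)
  target <- compute_hvl(apply_filtration(base, "Al", 1.0))
  fit <- match_added_filtration(80, target)
  expect_lt(abs(fit$added_mm_al - 1.0), 0.01)
  expect_lt(abs(compute_hvl(fit$spectrum) - target), 0.01)
  # target at the unfiltered HVL needs no added filtration
  expect_equal(match_added_filtration(80, compute_hvl(base))$added_mm_al, 0)
  # infeasible below the unfiltered HVL
  expect_error(match_added_filtration(80, compute_hvl(base) - 0.5),
               "infeasible")
  # monotone: a larger target needs at least as much filtration
  t1 <- match_added_filtration(80, target)$added_mm_al
  t2 <- match_added_filtration(80, target + 0.5)$added_mm_al
  expect_gte(t2, t1)
})

test_that("spectrum-weighted mu_en ratios reduce to the expected forms", {
  sp <- apply_filtration(generate_spectrum(80), "Cu", 0.2)
  expect_identical(spectrum_weighted_mu_en_ratio(sp, "air", "air"), 1.0)
  # monoenergetic bin: pointwise coefficient ratio at that energy
  tab <- load_attenuation_tables()
  mono <- energy_spectrum(c(60, 60.5), c(1, 0), kvp = 61)
  num <- tab$mu_en_over_rho[tab$material == "soft_tissue" &
                              tab$energy_keV == 60]
  den <- tab$mu_en_over_rho[tab$material == "air" & tab$energy_keV == 60]
  expect_equal(spectrum_weighted_mu_en_ratio(mono, "soft_tissue", "air"),
               num / den, tolerance = 1e-9)
  # independent summation oracle on the filtered 80-kVp spectrum
  loglog <- function(m, col) {
    s <- tab[tab$material == m, ]
    exp(approx(log(s$energy_keV), log(s[[col]]),
               xout = log(sp$energies))$y)
  }
  w <- sp$fluence * sp$energies
  oracle <- sum(w * loglog("soft_tissue", "mu_en_over_rho")) /
    sum(w * loglog("air", "mu_en_over_rho"))
  expect_equal(spectrum_weighted_mu_en_ratio(sp, "soft_tissue", "air"),
               oracle, tolerance = 1e-12)
})

test_that("slab transmission factors behave like narrow-beam attenuation", {
  sp <- apply_filtration(generate_spectrum(80), "Cu", 0.2)
  table_only <- list(list(material = "table_composite", thickness_mm = 1.5))
  table_pad <- c(table_only,
                 list(list(material = "pad_foam", thickness_mm = 70)))
  expect_identical(slab_transmission_factor(sp, list()), 1.0)
  af_t <- slab_transmission_factor(sp, table_only)
  af_tp <- slab_transmission_factor(sp, table_pad)
  expect_true(af_t > 0 && af_t <= 1)
  expect_lt(af_tp, af_t)                      # more material, more loss
  # oblique incidence lengthens the path: 60-degree AF below normal AF
  expect_lt(slab_transmission_factor(sp, table_pad, 60), af_tp)
  # path-length oracle: AF(60 deg) equals AF(0 deg) with doubled slabs
  doubled <- lapply(table_pad, function(s) {
    s$thickness_mm <- 2 * s$thickness_mm; s
  })
  expect_equal(slab_transmission_factor(sp, table_pad, 60),
               slab_transmission_factor(sp, doubled, 0),
               tolerance = 1e-12)
  expect_error(slab_transmission_factor(sp, table_only, 90), "angle")
})

test_that("transmission factors stay in (0,1] on random spectra and slabs", {
  set.seed(7)
  for (k in 1:20) {
    sp <- apply_filtration(generate_spectrum(runif(1, 45, 120)),
                           "Cu", runif(1, 0, 0.6))
    af <- slab_transmission_factor(
      sp, list(list(material = sample(c("Al", "Cu", "soft_tissue"), 1),
                    thickness_mm = runif(1, 0.1, 5))),
      runif(1, 0, 80))
    expect_true(af > 0 && af <= 1)
  }
})
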