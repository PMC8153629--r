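test_that("baseline correction removes a linear ramp exactly", {
  zero <- simulate_esr_spectrum(0)
  expect_equal(baseline_correct(zero)$intensity, zero$intensity,
               tolerance = 1e-12)

  sp <- simulate_esr_spectrum(1e-8)
  amp <- max(abs(sp$intensity))
  flat <- baseline_correct(sp)
  expect_lt(max(abs(flat$intensity - sp$intensity)), 1e-4 * amp)

  ramp <- sp
  ramp$intensity <- sp$intensity + 3 + 0.02 * sp$field_mT
  fixed <- baseline_correct(ramp)
  # the ramp (many orders of magnitude above the line) is removed entirely
  expect_lt(max(abs(fixed$intensity - flat$intensity)), 1e-8 * amp)
  d_ref <- double_integral(baseline_correct(sp))
  d_fix <- double_integral(fixed)
  expect_lt(abs(d_fix - d_ref) / abs(d_ref), 0.01)
  expect_error(baseline_correct(sp, edge_fraction = 0.5))
})

test_that("double integral of a Gaussian-derivative line recovers the absorption area", {
  # analytic absorption of known area through the generator at 0.7 mT/pt
  sp <- simulate_esr_spectrum(1e-8, mass_g = 0.05, intensity_per_mol = 1e9)
  area_expected <- 1e9 * 1e-8 * 0.05
  di <- double_integral(sp)
  expect_lt(abs(di - area_expected) / area_expected, 1e-3)
  # zero spectrum integrates to zero; scaling is linear
  z <- sp; z$intensity[] <- 0
  expect_equal(double_integral(z), 0)
  s2 <- sp; s2$intensity <- 2 * sp$intensity
  expect_equal(double_integral(s2) / di, 2, tolerance = 1e-10)
  expect_equal(mass_normalize(di, 0.05), di / 0.05)
  expect_error(mass_normalize(di, 0), "> 0")
})

test_that("calibration is linear through the origin over the reference range", {
  concs <- exp(seq(log(5e-10), log(1e-7), length.out = 6))
  cal <- build_calibration(gaussian_reference_spectra(concs), concs)
  expect_gt(cal$r_squared, 0.9999)
  expect_gt(cal$slope, 0)
  expect_error(build_calibration(gaussian_reference_spectra(1e-8), 1e-8),
               "at least 2")
  # 5% intensity noise: slope within 5% of the noiseless slope
  cal5 <- build_calibration(gaussian_reference_spectra(concs, noise_pct = 5,
                                                       seed = 3), concs)
  expect_lt(abs(cal5$slope - cal$slope) / cal$slope, 0.05)
})

test_that("quantification recovers known concentrations and transfers under rescaling", {
  concs <- exp(seq(log(5e-10), log(1e-7), length.out = 6))
  refs <- gaussian_reference_spectra(concs)
  cal <- build_calibration(refs, concs)
  # a reference quantifies to its own concentration
  q_ref <- quantify_concentration(refs[[3]], cal)
  expect_equal(q_ref$concentration_mol_g, concs[3], tolerance = 1e-10)
  # noiseless sample at 1.7e-8 mol/g within 2%
  sample <- simulate_esr_spectrum(1.7e-8)
  q <- quantify_concentration(sample, cal)
  expect_lt(abs(q$concentration_mol_g - 1.7e-8) / 1.7e-8, 0.02)
  # rescaling every spectrum by one constant leaves concentrations unchanged
  scale_sp <- function(sp, k) { sp$intensity <- sp$intensity * k; sp }
  cal_k <- build_calibration(lapply(refs, scale_sp, k = 7.3), concs)
  q_k <- quantify_concentration(scale_sp(sample, 7.3), cal_k)
  expect_equal(q_k$concentration_mol_g, q$concentration_mol_g,
               tolerance = 1e-10)
  expect_error(quantify_concentration(sample, NULL), "calibration")
})

test_that("a blank spectrum quantifies to zero within its uncertainty", {
  concs <- exp(seq(log(5e-10), log(1e-7), length.out = 6))
  refs <- gaussian_reference_spectra(concs, noise_pct = 2, seed = 11)
  cal <- build_calibration(refs, concs)
  amp <- max(abs(simulate_esr_spectrum(1e-8)$intensity))
  blank <- simulate_esr_spectrum(0, noise_sigma = amp * 0.02, seed = 12)
  q <- suppressWarnings(quantify_concentration(blank, cal))
  expect_lt(abs(q$concentration_mol_g), 3 * q$uncertainty_mol_g)
})

test_that("resonance arithmetic matches the X-band maghemite line", {
  expect_equal(g_factor(9.54, 321.5), 2.120, tolerance = 1e-3)
  expect_equal(resonance_field(9.54, 2.0023), 340.4, tolerance = 0.05)
  g <- seq(1.8, 2.3, length.out = 20)
  expect_equal(g_factor(9.54, resonance_field(9.54, g)), g,
               tolerance = 1e-12)
  expect_error(g_factor(-1, 320))
})

test_that("peak-to-peak width: 2 sigma for Gaussian, 2 Gamma/sqrt(3) for Lorentzian", {
  spg <- simulate_esr_spectrum(1e-8, width_pp_mT = 80)
  wg <- peak_to_peak_width(spg)
  expect_lt(abs(wg$width_mT - 80) / 80, 0.005)
  expect_equal(wg$center_mT, 320, tolerance = 0.5)
  # width invariant under intensity scaling
  sps <- spg; sps$intensity <- 0.3 * spg$intensity
  expect_equal(peak_to_peak_width(sps)$width_mT, wg$width_mT)
  # Lorentzian of the same nominal p-p width
  spl <- simulate_esr_spectrum(1e-8, width_pp_mT = 80,
                               lineshape = "lorentzian")
  wl <- peak_to_peak_width(spl)
  expect_lt(abs(wl$width_mT - 80) / 80, 0.01)
  flat <- spg; flat$intensity[] <- 1
  expect_error(peak_to_peak_width(flat), "flat")
})
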