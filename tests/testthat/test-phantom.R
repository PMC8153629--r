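test_that("phantom construction is deterministic and rejects bad geometry", {
  p1 <- build_phantom(seed = 7)
  p2 <- build_phantom(seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_setequal(unique(as.vector(p1$labels)), c(0L, 1L, 2L, 3L))
  expect_gt(sum(p1$labels == organ_codes[["liver"]]), 0)

  expect_error(
    build_phantom(organs = list(liver = list(shape = "ellipse",
                                             center = c(60, 60),
                                             radii = c(20, 20)))),
    "does not fit")
  expect_error(
    build_phantom(organs = list(
      liver = list(shape = "ellipse", center = c(32, 32), radii = c(10, 10)),
      plaque = list(shape = "ellipse", center = c(34, 34), radii = c(8, 8)))),
    "overlaps")
  expect_error(build_phantom(organs = list(gallbladder = list())), "unknown")
})

test_that("tissue, protocol and agent types enforce their invariants", {
  expect_error(tissue_state(-1, 1, 1))
  expect_error(tissue_state(1, 0, 1))
  expect_error(acquisition_protocol(TE_ms = 40, TR_ms = 30))
  expect_error(acquisition_protocol(n_echoes = 5))  # needs dTE
  expect_error(contrast_agent(r2star = 45, r1 = 50))
  tr <- accumulation_truth(Cmax = 2, tau = 0.05)
  expect_equal(tr$t_half_min * tr$tau, log(2))
  expect_error(accumulation_truth(2, 0))
})

test_that("multi-echo protocol arithmetic: 15 echoes at 2.8 + 3.6 ms end at 53.2 ms", {
  tes <- echo_times(multiecho_protocol())
  expect_length(tes, 15)
  expect_equal(tes[1], 2.8)
  expect_equal(tes[15], 53.2)
})

test_that("dynamic series follows the spoiled-GRE forward model at C = 0", {
  s <- make_dynamic(snr = Inf, duration_min = 10)
  st <- small_phantom()$tissue$liver
  expected <- st$M0 * sin(30 * pi / 180) * exp(-0.0034 * st$R2star_baseline)
  liver_vox <- s$data[, , 1][s$labels == organ_codes[["liver"]]]
  expect_lt(max(abs(liver_vox - expected)) / expected, 1e-12)
  # stored truth reproduces the closed-form accumulation: tau t = ln 2
  # halves the gap to Cmax
  tr <- s$truth
  t_star <- log(2) / tr$tau
  expect_equal(tr$Cmax * (1 - exp(-tr$tau * t_star)), tr$Cmax / 2)
})

test_that("closed-form concentration: Cmax 2 mM, tau 0.05/min gives 1 mM at t = ln2/tau", {
  phan <- small_phantom()
  s <- simulate_dynamic_series(phan, acquisition_protocol(frame_duration_s = 6),
                               contrast_agent(),
                               accumulation_truth(2, 0.05),
                               gap_min = log(2) / 0.05, duration_min = 14.2,
                               noise_sigma = 0, seed = 1)
  # first post frame lands at t = ln2/tau = 13.863 min
  i <- which(s$times_min > 0)[1]
  expect_equal(s$times_min[i], 13.8629436, tolerance = 1e-6)
  expect_equal(s$truth$conc_mM[i], 1.0, tolerance = 1e-12)
})

test_that("injection gap leaves no frames between injection and first post frame", {
  s <- make_dynamic(duration_min = 10)
  expect_false(any(s$times_min > 0 & s$times_min < 2))
  expect_equal(min(s$times_min[s$times_min > 0]), 2)
  expect_error(make_dynamic(snr = -1), "sigma")
  expect_error(simulate_dynamic_series(
    small_phantom(), acquisition_protocol(), contrast_agent(),
    structure(list(Cmax = 2, tau = -1), class = "accumulation_truth")),
    "tau")
})

test_that("dynamic series is reproducible and carries the protocol metadata", {
  s1 <- make_dynamic(snr = 30, motion = 1.5, seed = 11, duration_min = 6)
  s2 <- make_dynamic(snr = 30, motion = 1.5, seed = 11, duration_min = 6)
  expect_identical(s1$data, s2$data)
  expect_equal(s1$protocol$flip_deg, 30)
  expect_equal(s1$protocol$TE_ms, 3.4)
})

test_that("Rician noise: constant-region mean matches the analytic Rician mean", {
  set.seed(99)
  s_true <- 420; sigma <- 14  # SNR 30
  draws <- spioquant:::add_rician_noise(rep(s_true, 20000), sigma)
  expected <- spioquant:::rician_mean(s_true, sigma)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
  # the bias term itself is approximately sigma^2 / (2 S) at high SNR
  expect_equal(expected - s_true, sigma^2 / (2 * s_true), tolerance = 0.01)
})

test_that("multi-echo volume: zero gradient gives pure mono-exponential decay", {
  p <- plaque_phantom()
  v <- simulate_multiecho_volume(p, multiecho_protocol(), gz_uT_mm = 0,
                                 noise_sigma = 0)
  sel <- v$labels == organ_codes[["plaque"]]
  s0 <- 800 * sin(60 * pi / 180)
  t2 <- 1000 / 110
  for (k in c(1, 8, 15)) {
    vox <- v$data[, , , k][sel]
    expect_equal(vox, rep(s0 * exp(-v$echo_times_ms[k] / t2), sum(sel)),
                 tolerance = 1e-12)
  }
  expect_error(simulate_multiecho_volume(p, acquisition_protocol()), "echoes")
})

test_that("through-slice gradient attenuates echoes by the sinc factor", {
  p <- plaque_phantom()
  v0 <- simulate_multiecho_volume(p, multiecho_protocol(), gz_uT_mm = 0,
                                  noise_sigma = 0)
  v1 <- simulate_multiecho_volume(p, multiecho_protocol(), gz_uT_mm = 1.5,
                                  noise_sigma = 0)
  gamma <- spio_constants$gyromagnetic_ratio_rad_s_T
  k <- 10
  x <- gamma * 1.5e-3 * 1e-3 * v0$echo_times_ms[k] / 1000 / 2
  sel <- v0$labels == organ_codes[["plaque"]]
  expect_equal(v1$data[, , , k][sel] / v0$data[, , , k][sel],
               rep(abs(sin(x) / x), sum(sel)), tolerance = 1e-12)
})

test_that("ESR spectrum: derivative extrema sit at center +- sigma for a Gaussian", {
  sp <- simulate_esr_spectrum(1e-8, center_mT = 320, width_pp_mT = 80)
  i_max <- which.max(sp$intensity); i_min <- which.min(sp$intensity)
  expect_equal(sp$field_mT[i_max], 280, tolerance = 0.5)
  expect_equal(sp$field_mT[i_min], 360, tolerance = 0.5)
  # zero concentration: flat (zero) spectrum
  sp0 <- simulate_esr_spectrum(0, noise_sigma = 0)
  expect_equal(max(abs(sp0$intensity)), 0)
  # doubling concentration doubles the noiseless double integral
  d1 <- double_integral(baseline_correct(simulate_esr_spectrum(1e-8)))
  d2 <- double_integral(baseline_correct(simulate_esr_spectrum(2e-8)))
  expect_equal(d2 / d1, 2, tolerance = 1e-10)
  expect_error(simulate_esr_spectrum(1e-8, field_mT = seq(300, 340, 0.7)),
               "too narrow")
})

test_that("hemolysis curves are logistic with the stated midpoint", {
  h <- simulate_hemolysis_curve(100, steepness = 0.08, noise_sigma = 0)
  expect_equal(h$hemolysis_pct[h$time_min == 100], 50)
  expect_true(all(diff(h$hemolysis_pct) >= 0))
  # steepness -> infinity approaches a step at T50
  hs <- simulate_hemolysis_curve(100, steepness = 50, noise_sigma = 0)
  expect_lt(hs$hemolysis_pct[hs$time_min == 99], 1e-6)
  expect_gt(hs$hemolysis_pct[hs$time_min == 101], 100 - 1e-6)
  # two curves with T50 100 and 80 cross 50% 20 min apart
  t1 <- t50_hemolysis(simulate_hemolysis_curve(100))$t50_min
  t2 <- t50_hemolysis(simulate_hemolysis_curve(80))$t50_min
  expect_equal(t1 - t2, 20, tolerance = 0.01)
  expect_error(simulate_hemolysis_curve(100, time_min = seq(0, 50, 1)),
               "never reaches")
})

test_that("interface gradient map peaks at the stated edge and decays", {
  g <- interface_gradient_map(c(24, 24), peak_uT_mm = 2, scale_vox = 5)
  expect_equal(max(g), 2)
  expect_equal(g[1, 1], 2)
  expect_lt(g[24, 12], 2 * exp(-4))
})
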