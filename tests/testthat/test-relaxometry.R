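test_that("SNR gate keeps voxels at or above the acceptability limit", {
  img <- matrix(10, 20, 20)
  img[5, 5] <- 100   # SNR 10
  img[6, 6] <- 39    # SNR 3.9
  img[7, 7] <- 40    # SNR 4, boundary: kept
  m <- snr_mask(img, noise_sigma = 10, threshold = 4)
  expect_true(m[5, 5, 1]); expect_false(m[6, 6, 1]); expect_true(m[7, 7, 1])
  expect_false(any(snr_mask(matrix(0, 20, 20), noise_sigma = 1)))
})

test_that("background noise estimate uses the Rayleigh correction", {
  set.seed(3)
  img <- matrix(sqrt(rnorm(64 * 64, 0, 5)^2 + rnorm(64 * 64, 0, 5)^2), 64, 64)
  expect_equal(estimate_background_noise(img), 5, tolerance = 0.15)
  expect_error(estimate_background_noise(matrix(1, 2, 2)), "too small")
})

test_that("sinc correction divides by the attenuation factor and drops dead echoes", {
  p <- plaque_phantom()
  v0 <- simulate_multiecho_volume(p, multiecho_protocol(), gz_uT_mm = 0,
                                  noise_sigma = 0)
  c0 <- b0_sinc_correction(v0)
  expect_equal(c0$data, v0$data, tolerance = 1e-14)
  expect_equal(c0$n_dropped, 0)

  v1 <- simulate_multiecho_volume(p, multiecho_protocol(), gz_uT_mm = 2,
                                  noise_sigma = 0)
  c1 <- b0_sinc_correction(v1)
  sel <- v1$labels == organ_codes[["plaque"]]
  # corrected usable echoes match the gradient-free volume
  for (k in c(1, 3)) {
    expect_true(all(c1$usable[, , , k][sel]))
    expect_equal(c1$data[, , , k][sel], v0$data[, , , k][sel],
                 tolerance = 1e-10)
  }
  expect_gt(c1$n_dropped, 0)
  # a single known factor: measured / 0.9 when sinc factor is 0.9
  expect_equal(spioquant:::sinc(0), 1)
})

test_that("echo alignment detects constructed shifts and rejects single echoes", {
  p <- plaque_phantom(shape = c(32L, 32L))
  v <- simulate_multiecho_volume(p, multiecho_protocol(5), noise_sigma = 0)
  al0 <- suppressWarnings(align_echoes(v))
  expect_lt(max(al0$max_displacement), 0.05)
  # shift echo 5 by one voxel
  v$data[, , 1, 5] <- spioquant:::warp_bilinear(
    v$data[, , 1, 5], matrix(1, 32, 32), matrix(0, 32, 32))
  al1 <- suppressWarnings(align_echoes(v))
  expect_gt(al1$max_displacement[5], 0.5)
  expect_lt(abs(al1$mean_displacement[5] - 1), 0.5)
  expect_error(align_echoes(v$data[, , , 1, drop = FALSE]), "2 echoes")
})

test_that("two-point closed form: 116.7 and 58.35 at 2.8/6.4 ms give T2* = 3.6/ln 2", {
  est <- spioquant:::loglinear_t2star(c(2.8, 6.4), c(116.6958, 58.3479))
  expect_equal(est[2], 3.6 / log(2), tolerance = 1e-4)
  expect_equal(est[2], 5.194, tolerance = 1e-3)
  expect_equal(est[1] * exp(-2.8 / est[2]), 116.6958, tolerance = 1e-3)
})

test_that("noiseless voxel recovery is exact and matches the closed form", {
  p <- plaque_phantom(r2star_baseline = 1000 / 12)  # T2* = 12 ms
  v <- simulate_multiecho_volume(p, multiecho_protocol(), noise_sigma = 0)
  sel <- v$labels == organ_codes[["plaque"]]
  m_lm <- fit_t2star_map(v, mask = sel)
  m_cf <- fit_t2star_map(v, mask = sel, refine = FALSE)
  expect_lt(max(abs(m_lm$t2star_ms[sel] - 12) / 12), 1e-6)
  expect_lt(max(abs(m_lm$t2star_ms[sel] - m_cf$t2star_ms[sel]) / 12), 1e-8)
  expect_true(all(m_lm$r_squared[sel] > 1 - 1e-10))
})

test_that("constant signal across echoes hits the T2* bound and is flagged", {
  dat <- array(100, c(4, 4, 1, 5))
  m <- fit_t2star_map(dat, echo_times_ms = c(2.8, 6.4, 10, 13.6, 17.2),
                      t2star_cap = 500)
  expect_true(all(m$reason == 3L))
  expect_true(all(is.na(m$t2star_ms)))
})

test_that("validity filter: strict 30 ms boundary and hand-counted toy map", {
  vals <- c(5, 10, 15, 20, 25, 29, 31, 35, 50)
  map <- structure(list(
    t2star_ms = array(vals, c(3, 3, 1)),
    s0 = array(1, c(3, 3, 1)),
    r_squared = array(1, c(3, 3, 1)),
    reason = array(0L, c(3, 3, 1)),
    echo_times_ms = c(2.8, 6.4, 10)), class = "t2star_map")
  f <- apply_validity_filters(map, upper_ms = 30)
  cts <- filter_counts(f)
  expect_equal(unname(cts["outlier"]), 3L)
  expect_equal(unname(cts["kept"]), 6L)
  expect_equal(sum(cts), 9L)

  map$t2star_ms[] <- c(40, 30, rep(10, 7))
  f2 <- apply_validity_filters(map, upper_ms = 30)
  expect_equal(f2$reason[1, 1, 1], 2L)  # 40 ms excluded
  expect_equal(f2$reason[2, 1, 1], 0L)  # exactly 30 ms retained
})

test_that("filter accounting: kept + excluded reasons always sum to the total", {
  p <- plaque_phantom()
  s0 <- 800 * sin(pi / 3)
  for (seed in 1:3) {
    v <- simulate_multiecho_volume(p, multiecho_protocol(), gz_uT_mm = 1,
                                   noise_sigma = s0 / 30, seed = seed)
    mask <- snr_mask(v$data[, , , 1], noise_sigma = s0 / 30)
    m <- apply_validity_filters(
      fit_t2star_map(b0_sinc_correction(v), mask = mask,
                     noise_sigma = s0 / 30))
    expect_equal(sum(filter_counts(m)), length(m$t2star_ms))
  }
})

test_that("slice means: arithmetic mean of valid voxels, empty slices stay empty", {
  map <- structure(list(
    t2star_ms = array(c(10, 20, NA, NA), c(2, 1, 2)),
    s0 = array(1, c(2, 1, 2)),
    r_squared = array(1, c(2, 1, 2)),
    reason = array(c(0L, 0L, 2L, 2L), c(2, 1, 2)),
    echo_times_ms = c(2.8, 6.4, 10)), class = "t2star_map")
  st <- slice_mean_t2star(map)
  expect_equal(st$mean_t2star_ms[1], 15)
  expect_true(is.na(st$mean_t2star_ms[2]))
  expect_equal(st$n_valid, c(2L, 0L))
})

test_that("slice mean of a uniform 9 ms plaque at SNR 50 is within 5%", {
  p <- plaque_phantom(r2star_baseline = 1000 / 9)
  s0 <- 800 * sin(pi / 3)
  v <- simulate_multiecho_volume(p, multiecho_protocol(),
                                 noise_sigma = s0 / 50, seed = 2)
  mask <- snr_mask(v$data[, , , 1], noise_sigma = s0 / 50)
  m <- apply_validity_filters(fit_t2star_map(v, mask = mask,
                                             noise_sigma = s0 / 50))
  st <- slice_mean_t2star(m, v$labels == organ_codes[["plaque"]])
  expect_lt(abs(st$mean_t2star_ms[1] - 9) / 9, 0.05)
})

test_that("iron-load ordering: baseline > 24 h > 7 h slice means", {
  p <- plaque_phantom(r2star_baseline = 1000 / 15)  # baseline T2* 15 ms
  s0 <- 800 * sin(pi / 3)
  # iron shortens T2*: heavier 7 h load shortens it most
  v <- simulate_multiecho_volume(p, multiecho_protocol(), n_slices = 3,
                                 t2star_scale = c(1, 0.4, 0.7),
                                 noise_sigma = s0 / 50, seed = 8)
  mask <- snr_mask(v$data[, , , 1], noise_sigma = s0 / 50)
  m <- apply_validity_filters(fit_t2star_map(v, mask = mask,
                                             noise_sigma = s0 / 50))
  st <- slice_mean_t2star(m, v$labels == organ_codes[["plaque"]])
  baseline <- st$mean_t2star_ms[1]
  h7 <- st$mean_t2star_ms[2]
  h24 <- st$mean_t2star_ms[3]
  expect_gt(baseline, h24)
  expect_gt(h24, h7)
})
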