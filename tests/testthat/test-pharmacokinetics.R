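test_that("frame timing: total scan time divided by the frame count", {
  t1 <- estimate_frame_times(500, 10)
  expect_equal(diff(t1)[1], 50 / 60)       # 50 s per dynamic image
  expect_length(t1, 10)
  expect_equal(estimate_frame_times(60, 1, offset_min = 5), 5 + 0.5)
  expect_equal(diff(estimate_frame_times(600, 10))[1], 1)
  expect_error(estimate_frame_times(0, 10))
})

tc <- function(times, values) {
  structure(list(times_min = times, mean = values,
                 sd = rep(0, length(values)),
                 n_voxels = rep(10, length(values)),
                 n_pre = sum(times < 0)),
            class = "signal_timecourse")
}

test_that("session fusion puts the injection at t = 0 and the first post frame at the delay", {
  pre <- tc(estimate_frame_times(480, 8), rep(100, 8))
  post <- tc(estimate_frame_times(3000, 50), seq(100, 80, length.out = 50))
  fused <- fuse_sessions(pre, post, delay_min = 2)
  expect_length(fused$times_min, 58)
  expect_equal(sum(fused$times_min < 0), 8)
  expect_equal(min(fused$times_min[fused$times_min > 0]), 2)
  expect_error(fuse_sessions(pre, tc(numeric(0), numeric(0)), 2), "empty")
  expect_error(fuse_sessions(pre, post, 0), "> 0")
})

test_that("normalization: unity at the reference, baseline modes as stated", {
  course <- tc(c(-1, 1, 2), c(100, 90, 80))
  n1 <- normalize_signal(course, "first-frame")
  expect_equal(n1$s_norm, c(1, 0.9, 0.8))
  course2 <- tc(c(-2, -1, 1), c(98, 102, 90))
  n2 <- normalize_signal(course2, "pre-injection-mean")
  expect_equal(n2$baseline, 100)
  course3 <- tc(c(-1, 1), c(0, 5))
  expect_error(normalize_signal(course3, "first-frame"), "baseline")
})

test_that("concentration conversion follows C = -ln(Snorm)/(TE r2*)", {
  expect_equal(signal_to_concentration(1, TE_ms = 3.4, r2star = 45)$conc_mM, 0)
  c1 <- signal_to_concentration(0.9, TE_ms = 3.4, r2star = 45)$conc_mM
  expect_equal(c1, -log(0.9) / 0.153, tolerance = 1e-12)
  expect_equal(c1, 0.6886, tolerance = 1e-4)
  c2 <- signal_to_concentration(exp(-0.153), TE_ms = 3.4, r2star = 45)$conc_mM
  expect_equal(c2, 1, tolerance = 1e-12)
  expect_error(signal_to_concentration(c(1, -0.1), 3.4, 45), "frame")
  # S_norm > 1 gives a negative concentration, retained by default
  expect_lt(signal_to_concentration(1.05, 3.4, 45)$conc_mM, 0)
  expect_equal(signal_to_concentration(1.05, 3.4, 45,
                                       clamp_negative = TRUE)$conc_mM, 0)
})

test_that("accumulation fit recovers noiseless parameters to 1e-6 relative", {
  t <- seq(2, 48, 1)
  y <- 2 * (1 - exp(-0.05 * t))
  fit <- fit_accumulation(y, times_min = t)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["Cmax"]], 2, tolerance = 1e-6)
  expect_equal(coef(fit)[["tau"]], 0.05, tolerance = 1e-6)
  expect_equal(fit$t_half_min, log(2) / 0.05, tolerance = 1e-6)
  # sub-sampled to 5 points: same recovery
  i <- round(seq(1, length(t), length.out = 5))
  fit5 <- fit_accumulation(y[i], times_min = t[i])
  expect_equal(coef(fit5)[["tau"]], 0.05, tolerance = 1e-6)
})

test_that("degenerate accumulation data is flagged, not thrown", {
  t <- seq(1, 10)
  flat <- fit_accumulation(rep(1.5, 10), times_min = t)
  expect_false(flat$converged)
  expect_true(any(grepl("upper bound", flat$flags)))
  allneg <- fit_accumulation(rep(-0.2, 10), times_min = t)
  expect_false(allneg$converged)
  expect_true(any(grepl("degenerate", allneg$flags)))
  expect_error(fit_accumulation(1:3, times_min = 1:3), "at least 4")
})

test_that("pk_fit methods are coherent", {
  t <- seq(2, 40, 2)
  y <- 1.5 * (1 - exp(-0.1 * t))
  fit <- fit_accumulation(y, times_min = t)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, 0), 0)
  expect_equal(residuals(fit), y - fit$fitted)
  expect_output(print(fit), "t1/2")
  expect_output(print(summary(fit)), "Std. Error")
  sims <- simulate(fit, nsim = 3, seed = 1, sigma = 0.01)
  expect_equal(dim(sims), c(length(t), 3))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("half-life is the exact inverse of the accumulation rate", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.0049972), 138.7, tolerance = 1e-3)
  expect_equal(half_life(0.0067293), 103.0, tolerance = 1e-3)
  expect_error(half_life(0))
  taus <- 10^seq(-4, 1, length.out = 50)
  expect_equal(accumulation_rate(half_life(taus)), taus, tolerance = 1e-14)
})

test_that("dose conversion and antibody:droplet arithmetic", {
  expect_equal(convert_dose(3, 55.845), 53.72, tolerance = 1e-3)
  expect_equal(round(convert_dose(3), 1), 53.7)
  expect_equal(convert_dose(55.845, 55.845), 1000)
  expect_error(convert_dose(0))
  expect_equal(antibodies_per_droplet(1.9, 5.75e13), 19.9, tolerance = 1e-2)
  expect_equal(antibodies_per_droplet(1.9, 2 * 5.75e13),
               antibodies_per_droplet(1.9, 5.75e13) / 2)
  expect_equal(antibodies_per_droplet(0.1, 6.02214076e13), 1, tolerance = 1e-6)
  expect_equal(drug_loading_mg_per_g(5), 50)
})

test_that("noiseless end-to-end round trip recovers C(t) to 1e-10", {
  s <- make_dynamic(t_half = 15, duration_min = 30)
  tcv <- track_organ_timecourse(s, track = FALSE)
  nrm <- normalize_signal(tcv, "first-frame")
  conc <- signal_to_concentration(nrm, TE_ms = 3.4, r2star = 45)
  post <- conc$times_min > 0
  truth <- s$truth$conc_mM[post]
  expect_lt(max(abs(conc$conc_mM[post] - truth)), 1e-10)
})

test_that("fitted half-life is strictly decreasing in the true accumulation rate", {
  t <- seq(2, 60, 1)
  taus <- c(0.005, 0.01, 0.05, 0.1, 0.3)
  est <- vapply(taus, function(tau) {
    fit_accumulation(2 * (1 - exp(-tau * t)), times_min = t)$t_half_min
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})
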