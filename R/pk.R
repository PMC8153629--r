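# Dynamic-signal pharmacokinetics: session fusion, normalization,
# signal-to-concentration conversion, first-order accumulation fit and
# blood half-life.

#' Frame timestamps of a dynamic session
#'
#' The inter-frame time is the total scan duration divided by the number of
#' frames obtained; timestamps are placed at frame centers.
#'
#' @param duration_s total scan duration (s), > 0.
#' @param n_frames number of frames, >= 1.
#' @param offset_min session start offset (min) added to every timestamp.
#' @return Numeric vector of timestamps in minutes.
#' @export
estimate_frame_times <- function(duration_s, n_frames, offset_min = 0) {
  stopifnot(duration_s > 0, n_frames >= 1)
  spacing_min <- duration_s / n_frames / 60
  offset_min + (seq_len(n_frames) - 0.5) * spacing_min
}

#' Fuse pre- and post-injection dynamic sessions
#'
#' Places the injection at t = 0: pre-injection timestamps become negative
#' (counted back from the injection), and the first post-injection frame
#' sits at the measured injection delay.
#'
#' @param pre a `signal_timecourse` for the pre-injection session
#'   (timestamps relative to its own start).
#' @param post a `signal_timecourse` for the post-injection session.
#' @param delay_min measured interval between injection and the first
#'   post-injection frame (min), > 0 (1-3 min in practice).
#' @return A fused `signal_timecourse` with `n_pre` set.
#' @export
fuse_sessions <- function(pre, post, delay_min) {
  stopifnot(inherits(pre, "signal_timecourse"),
            inherits(post, "signal_timecourse"))
  if (delay_min <= 0) stop("injection delay must be > 0")
  if (!length(post$times_min)) stop("post-injection course is empty")
  if (any(diff(pre$times_min) <= 0) || any(diff(post$times_min) <= 0))
    stop("courses must be internally time-ordered")
  t_pre <- pre$times_min - max(pre$times_min) -
    (if (length(pre$times_min) > 1) stats::median(diff(pre$times_min)) / 2 else delay_min / 2)
  t_post <- post$times_min - min(post$times_min) + delay_min
  times <- c(t_pre, t_post)
  if (any(diff(times) <= 0)) stop("overlapping timestamps after fusion")
  structure(list(times_min = times,
                 mean = c(pre$mean, post$mean),
                 sd = c(pre$sd, post$sd),
                 n_voxels = c(pre$n_voxels, post$n_voxels),
                 n_pre = length(pre$times_min)),
            class = "signal_timecourse")
}

#' Normalize a signal time course to its baseline
#'
#' @param course a `signal_timecourse`.
#' @param baseline one of `"first-frame"` (the signal of the first dynamic
#'   acquisition, the conventional choice) or `"pre-injection-mean"` (mean
#'   over all pre-injection frames, more robust to noise).
#' @return An object of class `normalized_timecourse`: `times_min`,
#'   `s_norm` (equal to 1 at the reference by construction), `baseline`,
#'   `n_pre`.
#' @export
normalize_signal <- function(course,
                             baseline = c("first-frame", "pre-injection-mean")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(course, "signal_timecourse"))
  b <- switch(baseline,
    "first-frame" = course$mean[1],
    "pre-injection-mean" = {
      pre <- course$times_min < 0
      if (!any(pre)) pre <- seq_len(max(1, course$n_pre))
      mean(course$mean[pre])
    })
  if (!is.finite(b) || b <= 0) stop("nonpositive baseline signal")
  structure(list(times_min = course$times_min, s_norm = course$mean / b,
                 baseline = b, baseline_mode = baseline,
                 n_pre = course$n_pre),
            class = "normalized_timecourse")
}

#' Convert normalized signal to iron concentration
#'
#' Under the pure-R2* spoiled gradient-echo model the normalized signal is
#' `exp(-TE r2* C(t))`, so `C(t) = -log(S_norm) / (TE r2*)` with TE in
#' seconds. Normalized values above 1 (noise) give negative concentrations,
#' which are retained: clamping them would bias the accumulation fit.
#'
#' @param s_norm a `normalized_timecourse`, or a bare numeric vector of
#'   normalized signals (then `times_min` should be supplied).
#' @param TE_ms echo time (ms), > 0.
#' @param r2star transverse relaxivity (mM^-1 s^-1), > 0.
#' @param times_min timestamps when `s_norm` is a bare vector.
#' @param clamp_negative if `TRUE`, clamp negative concentrations to zero
#'   (display only; keep `FALSE` for fitting).
#' @return An object of class `concentration_curve`: `times_min`, `conc_mM`,
#'   `TE_ms`, `r2star`, `n_pre`.
#' @export
signal_to_concentration <- function(s_norm, TE_ms, r2star, times_min = NULL,
                                    clamp_negative = FALSE) {
  stopifnot(TE_ms > 0, r2star > 0)
  if (inherits(s_norm, "normalized_timecourse")) {
    times_min <- s_norm$times_min
    n_pre <- s_norm$n_pre
    vals <- s_norm$s_norm
  } else {
    vals <- as.numeric(s_norm)
    if (is.null(times_min)) times_min <- seq_along(vals)
    n_pre <- sum(times_min < 0)
  }
  bad <- which(vals <= 0)
  if (length(bad))
    stop("nonpositive normalized signal at frame(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  conc <- -log(vals) / ((TE_ms / 1000) * r2star)
  if (clamp_negative) conc <- pmax(conc, 0)
  structure(list(times_min = times_min, conc_mM = conc,
                 TE_ms = TE_ms, r2star = r2star, n_pre = n_pre),
            class = "concentration_curve")
}

#' Fit the first-order iron accumulation model
#'
#' Levenberg-Marquardt least-squares fit of
#' `C(t) = Cmax (1 - exp(-tau t))` to the post-injection samples of a
#' concentration curve; pre-injection samples define the baseline only and
#' never enter the fit. The blood half-life is `ln(2) / tau`.
#'
#' Initialization: `Cmax0 = max(C)` and `tau0` from the slope of the first
#' two post-injection points divided by `Cmax0`; bounds
#' `Cmax in (0, 10 max C]`, `tau in [1e-6, 10] /min`.
#'
#' @param curve a `concentration_curve`, or a numeric vector of
#'   concentrations with `times_min` supplied.
#' @param times_min timestamps (min) when `curve` is a bare vector.
#' @param start optional named list/vector with `Cmax` and `tau` initial
#'   guesses.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return An object of class `pk_fit` with components `coefficients`
#'   (`Cmax` mM, `tau` /min), `t_half_min`, `se` (parameter standard errors
#'   from the Jacobian), `rss`, `converged`, `flags`, `fitted`,
#'   `residuals`, `times_min`, `conc_mM`. Degenerate data (all C <= 0)
#'   yields a non-converged result with a flag rather than an error.
#' @seealso [half_life()], [predict.pk_fit()], [plot.pk_fit()]
#' @export
fit_accumulation <- function(curve, times_min = NULL, start = NULL,
                             max_iter = 500) {
  if (inherits(curve, "concentration_curve")) {
    times_min <- curve$times_min
    conc <- curve$conc_mM
  } else {
    conc <- as.numeric(curve)
    if (is.null(times_min)) stop("times_min required for a bare vector")
  }
  if (any(diff(times_min) <= 0)) stop("timestamps must be increasing")
  post <- times_min > 0
  t <- times_min[post]; y <- conc[post]
  if (length(t) < 4) stop("at least 4 post-injection points are required")

  failed <- function(flag) {
    structure(list(coefficients = c(Cmax = NA_real_, tau = NA_real_),
                   t_half_min = NA_real_, se = c(Cmax = NA_real_, tau = NA_real_),
                   rss = NA_real_, converged = FALSE, flags = flag,
                   fitted = rep(NA_real_, length(t)),
                   residuals = rep(NA_real_, length(t)),
                   times_min = t, conc_mM = y), class = "pk_fit")
  }
  if (all(y <= 0)) return(failed("degenerate: no positive concentrations"))

  cmax0 <- max(y)
  tau_lo <- 1e-6; tau_hi <- 10
  if (is.null(start)) {
    slope0 <- (y[2] - y[1]) / (t[2] - t[1])
    tau0 <- slope0 / cmax0
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- 0.01
    tau0 <- min(max(tau0, tau_lo * 10), tau_hi / 10)
    start <- c(Cmax = cmax0, tau = tau0)
  } else {
    start <- c(Cmax = unname(start[["Cmax"]]), tau = unname(start[["tau"]]))
  }

  resid_fn <- function(p) y - p[1] * (1 - exp(-p[2] * t))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = c(1e-12, tau_lo), upper = c(10 * cmax0, tau_hi),
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ptol = 1e-12, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("optimizer error"))

  p <- stats::coef(fit)
  names(p) <- c("Cmax", "tau")
  flags <- character(0)
  if (p[["tau"]] >= tau_hi * (1 - 1e-6))
    flags <- c(flags, "tau at upper bound (accumulation faster than sampling)")
  if (p[["tau"]] <= tau_lo * (1 + 1e-6))
    flags <- c(flags, "tau at lower bound")
  converged <- fit$info %in% 1:4 && !length(flags)

  se <- tryCatch({
    s <- summary(fit)
    stats::setNames(s$coefficients[, "Std. Error"], c("Cmax", "tau"))
  }, error = function(e) c(Cmax = NA_real_, tau = NA_real_))

  fitted <- p[["Cmax"]] * (1 - exp(-p[["tau"]] * t))
  structure(list(coefficients = p,
                 t_half_min = log(2) / p[["tau"]],
                 se = se,
                 rss = sum((y - fitted)^2),
                 converged = converged,
                 flags = if (length(flags)) flags else character(0),
                 fitted = fitted, residuals = y - fitted,
                 times_min = t, conc_mM = y),
            class = "pk_fit")
}

#' Blood half-life from the accumulation rate
#'
#' @param tau accumulation rate (1/min), > 0.
#' @return Half-life in minutes, `ln(2) / tau`.
#' @export
half_life <- function(tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  log(2) / tau
}

#' Accumulation rate from the blood half-life (inverse of [half_life()])
#' @param t_half_min half-life (min), > 0.
#' @return tau in 1/min.
#' @export
accumulation_rate <- function(t_half_min) {
  if (any(t_half_min <= 0)) stop("half-life must be > 0")
  log(2) / t_half_min
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("First-order iron accumulation fit: C(t) = Cmax (1 - exp(-tau t))\n")
  if (!x$converged && all(is.na(x$coefficients))) {
    cat("  fit failed:", paste(x$flags, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("  Cmax = %.4g mM,  tau = %.4g /min,  t1/2 = %.4g min\n",
              x$coefficients[["Cmax"]], x$coefficients[["tau"]],
              x$t_half_min))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.pk_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pk_fit")
}

#' @export
print.summary.pk_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!all(is.na(f$coefficients))) {
    tab <- cbind(Estimate = f$coefficients, `Std. Error` = f$se)
    print(tab)
    cat(sprintf("RSS = %.4g over %d post-injection points; converged: %s\n",
                f$rss, length(f$times_min), f$converged))
  }
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) object$coefficients

#' @export
residuals.pk_fit <- function(object, ...) object$residuals

#' Predicted iron concentration from a fitted accumulation model
#' @param object a `pk_fit`.
#' @param newdata optional numeric vector of times (min); defaults to the
#'   fitted times.
#' @param ... ignored.
#' @return Predicted C(t) in mM (0 for t <= 0).
#' @export
predict.pk_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times_min else as.numeric(newdata)
  p <- object$coefficients
  ifelse(t > 0, p[["Cmax"]] * (1 - exp(-p[["tau"]] * t)), 0)
}

#' Simulate concentration curves from a fitted accumulation model
#' @param object a `pk_fit`.
#' @param nsim number of simulated curves.
#' @param seed optional integer seed.
#' @param sigma residual SD used for the Gaussian noise; defaults to the
#'   fit's residual SD.
#' @param ... ignored.
#' @return A matrix with `nsim` columns of noisy C(t) at the fitted times.
#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = NULL, sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma))
    sigma <- sqrt(object$rss / max(1, length(object$times_min) - 2))
  mu <- object$fitted
  matrix(stats::rnorm(length(mu) * nsim, mu, sigma), ncol = nsim)
}

#' Plot a fitted accumulation curve
#' @param x a `pk_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pk_fit <- function(x, ...) {
  graphics::plot(x$times_min, x$conc_mM, xlab = "time since injection (min)",
                 ylab = "iron concentration (mM)", ...)
  tt <- seq(0, max(x$times_min), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  graphics::legend("bottomright", bty = "n", legend = sprintf(
    "Cmax = %.3g mM, t1/2 = %.3g min",
    x$coefficients[["Cmax"]], x$t_half_min))
  invisible(x)
}

#' Convert a mass dose to a molar dose
#'
#' @param dose_mg_kg dose in mg per kg bodyweight, > 0.
#' @param molar_mass_g_mol molar mass (g/mol), > 0; defaults to iron.
#' @return Dose in micromol per kg.
#' @export
convert_dose <- function(dose_mg_kg,
                         molar_mass_g_mol = spio_constants$iron_molar_mass_g_mol) {
  stopifnot(dose_mg_kg > 0, molar_mass_g_mol > 0)
  dose_mg_kg * 1000 / molar_mass_g_mol
}

#' Mean number of antibody molecules per nano-emulsion droplet
#'
#' @param antibody_nmol_mL antibody concentration (nmol/mL), > 0.
#' @param droplets_per_mL droplet number concentration (1/mL), > 0.
#' @return Mean antibodies per droplet (antibody molecules divided by
#'   droplet count).
#' @export
antibodies_per_droplet <- function(antibody_nmol_mL, droplets_per_mL) {
  stopifnot(antibody_nmol_mL > 0, droplets_per_mL > 0)
  antibody_nmol_mL * 1e-9 * spio_constants$avogadro_per_mol / droplets_per_mL
}

#' Drug loading from a w/w composition
#'
#' Converts a percent w/w component of a formulation to mg of component per
#' gram of formulation (e.g. a 5% w/w alpha-tocopherol composition carries
#' 50 mg/g).
#'
#' @param weight_pct component content in percent w/w, in \[0, 100\].
#' @return mg of component per g of formulation.
#' @export
drug_loading_mg_per_g <- function(weight_pct) {
  stopifnot(weight_pct >= 0, weight_pct <= 100)
  weight_pct * 10
}
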