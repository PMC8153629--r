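# Voxelwise T2* mapping from multi-echo magnitude volumes: SNR gating,
# macroscopic-susceptibility (sinc) correction, mono-exponential fitting,
# outlier exclusion and slice summaries.

as_volume_array <- function(volume) {
  if (inherits(volume, "multiecho_volume")) volume$data
  else if (is.array(volume) && length(dim(volume)) == 4) volume
  else stop("expected a multiecho_volume or a 4D array (x, y, slice, echo)")
}

#' Estimate the noise level from magnitude background corners
#'
#' In a magnitude image the signal-free background is Rayleigh distributed
#' with mean `sigma sqrt(pi/2)`; the Gaussian noise level is therefore the
#' corner-patch mean divided by `sqrt(pi/2)`.
#'
#' @param img 2D magnitude image (first echo).
#' @param patch corner patch edge length in voxels.
#' @return Estimated Gaussian noise sigma.
#' @export
estimate_background_noise <- function(img, patch = 6) {
  nx <- nrow(img); ny <- ncol(img)
  p <- min(patch, floor(nx / 4), floor(ny / 4))
  if (p < 1) stop("image too small for a background patch")
  vals <- c(img[1:p, 1:p], img[1:p, (ny - p + 1):ny],
            img[(nx - p + 1):nx, 1:p], img[(nx - p + 1):nx, (ny - p + 1):ny])
  if (!length(vals)) stop("empty background region")
  mean(vals) / sqrt(pi / 2)
}

#' SNR gate for T2* mapping
#'
#' A voxel enters the T2* fit only if its first-echo signal-to-noise ratio
#' reaches the acceptability limit (default 4).
#'
#' @param first_echo 2D or 3D first-echo magnitude image.
#' @param noise_sigma Gaussian noise level; estimated from background
#'   corners (per slice) when `NULL`.
#' @param threshold SNR limit, default 4.
#' @return Logical array: `TRUE` where signal / noise >= threshold.
#' @export
snr_mask <- function(first_echo, noise_sigma = NULL, threshold = 4) {
  stopifnot(threshold > 0)
  if (is.matrix(first_echo)) first_echo <- array(first_echo, c(dim(first_echo), 1))
  out <- array(FALSE, dim(first_echo))
  for (s in seq_len(dim(first_echo)[3])) {
    sl <- first_echo[, , s]
    sg <- if (is.null(noise_sigma)) estimate_background_noise(sl) else noise_sigma
    if (sg <= 0) stop("noise level must be > 0")
    out[, , s] <- sl / sg >= threshold
  }
  out
}

# sinc attenuation factors |sinc(gamma Gz dz TE/2)| per voxel and echo:
# returns an array (x, y, slice, echo).
sinc_factors <- function(gz_uT_mm, dims, echo_times_ms, slice_mm) {
  gz <- gz_uT_mm
  if (length(gz) == 1) gz <- array(gz, dims)
  else if (is.matrix(gz)) gz <- array(rep(gz, dims[3]), dims)
  stopifnot(all(dim(gz) == dims))
  gamma <- spio_constants$gyromagnetic_ratio_rad_s_T
  fac <- array(NA_real_, c(dims, length(echo_times_ms)))
  for (k in seq_along(echo_times_ms)) {
    x <- gamma * gz * 1e-3 * slice_mm * 1e-3 * echo_times_ms[k] / 1000 / 2
    fac[, , , k] <- abs(sinc(x))
  }
  fac
}

#' Correct multi-echo magnitudes for macroscopic through-slice gradients
#'
#' A through-slice field gradient `G_z` attenuates the spoiled gradient-echo
#' magnitude by `|sinc(gamma G_z dz TE/2)|`; dividing each echo by this
#' factor removes the macroscopic-susceptibility bias before T2* fitting.
#' Echoes where the factor falls below `min_factor` carry essentially no
#' signal and would be amplified into noise, so they are dropped from the
#' fit instead.
#'
#' @param volume a `multiecho_volume` or 4D array (x, y, slice, echo).
#' @param gz_uT_mm through-slice gradient map (microtesla/mm): scalar,
#'   matrix or (x, y, slice) array; defaults to the phantom's own map when
#'   `volume` is a `multiecho_volume`.
#' @param echo_times_ms echo times; taken from the volume when available.
#' @param slice_mm slice thickness (mm); taken from the volume's protocol
#'   when available.
#' @param min_factor factor below which an echo is dropped rather than
#'   amplified (default 0.1).
#' @return A list of class `corrected_volume`: `data` (corrected 4D array),
#'   `usable` (logical 4D array: echo retained at voxel),
#'   `echo_times_ms`, `n_dropped` (count of dropped voxel-echoes).
#' @export
b0_sinc_correction <- function(volume, gz_uT_mm = NULL, echo_times_ms = NULL,
                               slice_mm = NULL, min_factor = 0.1) {
  dat <- as_volume_array(volume)
  if (inherits(volume, "multiecho_volume")) {
    if (is.null(gz_uT_mm)) gz_uT_mm <- volume$gz_uT_mm
    if (is.null(echo_times_ms)) echo_times_ms <- volume$echo_times_ms
    if (is.null(slice_mm)) slice_mm <- volume$protocol$slice_thickness_mm
  }
  if (is.null(gz_uT_mm) || is.null(echo_times_ms) || is.null(slice_mm))
    stop("gradient map, echo times and slice thickness are required")
  dims <- dim(dat)[1:3]
  stopifnot(dim(dat)[4] == length(echo_times_ms))
  fac <- sinc_factors(gz_uT_mm, dims, echo_times_ms, slice_mm)
  usable <- fac >= min_factor
  corrected <- ifelse(usable, dat / fac, dat)
  structure(list(data = corrected, usable = usable, factors = fac,
                 echo_times_ms = echo_times_ms,
                 n_dropped = sum(!usable)),
            class = "corrected_volume")
}

#' Align echoes of a multi-echo volume to the first echo
#'
#' Image shifts between echoes would corrupt the voxelwise decay; each echo
#' is registered to echo 1 by optical flow ([estimate_motion()]) and warped
#' back, slice by slice.
#'
#' @param volume a `multiecho_volume` or 4D array.
#' @param lambda optical-flow regularization weight.
#' @return A list: `data` (aligned 4D array), `max_displacement` and
#'   `mean_displacement` (per-echo detected displacement magnitude over the
#'   object, in voxels).
#' @export
align_echoes <- function(volume, lambda = 0.05) {
  dat <- as_volume_array(volume)
  ne <- dim(dat)[4]
  if (ne < 2) stop("at least 2 echoes are required")
  maxdisp <- meandisp <- numeric(ne)
  for (s in seq_len(dim(dat)[3])) {
    ref <- dat[, , s, 1]
    for (k in 2:ne) {
      mov <- dat[, , s, k]
      # echoes decay in brightness; match intensities (least squares) so
      # the flow sees shifts, not T2* decay
      sc <- sum(ref * mov) / max(sum(mov^2), 1e-12)
      fld <- estimate_motion(ref, mov * sc, lambda = lambda)
      d <- sqrt(fld$u^2 + fld$v^2)
      obj <- ref > 0.1 * max(ref)  # report shifts where there is signal
      if (!any(obj)) obj <- !logical(length(d))
      maxdisp[k] <- max(maxdisp[k], max(d[obj]))
      meandisp[k] <- max(meandisp[k], mean(d[obj]))
      dat[, , s, k] <- warp_bilinear(mov, fld$u, fld$v)
    }
  }
  list(data = dat, max_displacement = maxdisp,
       mean_displacement = meandisp)
}

# Weighted log-linear LS: log S = log S0 - TE/T2*, weights S^2 w
# (Gauss-Markov for log-transformed noise; w carries any extra per-echo
# inverse-variance weight). Returns c(S0, T2*).
loglinear_t2star <- function(te_ms, sig, w_extra = 1) {
  w <- sig^2 * w_extra
  ly <- log(sig)
  sw <- sum(w); sx <- sum(w * te_ms); sy <- sum(w * ly)
  sxx <- sum(w * te_ms^2); sxy <- sum(w * te_ms * ly)
  den <- sw * sxx - sx^2
  if (den <= 0) return(c(NA_real_, NA_real_))
  slope <- (sw * sxy - sx * sy) / den
  inter <- (sy - slope * sx) / sw
  c(exp(inter), -1 / slope)
}

#' Voxelwise mono-exponential T2* mapping
#'
#' Fits `S(TE) = S0 exp(-TE / T2*)` at every masked voxel: a weighted
#' log-linear closed form (weights S^2) initializes a Levenberg-Marquardt
#' refinement. Voxels with fewer than 3 usable echoes, or where the fit
#' degenerates, are masked with reason `fit-fail`.
#'
#' @param volume a `multiecho_volume`, a `corrected_volume` from
#'   [b0_sinc_correction()], or a 4D array.
#' @param mask logical array (x, y, slice) of voxels to fit, e.g. from
#'   [snr_mask()]; voxels outside carry reason `low-snr`.
#' @param echo_times_ms echo times; taken from the volume when available.
#' @param noise_sigma Gaussian noise level of the magnitude images; when
#'   supplied, echoes whose measured signal falls below
#'   `snr_limit x noise_sigma` are excluded from that voxel's fit (the SNR
#'   acceptability limit applied inside the T2* calculation, keeping
#'   Rician-floor-dominated late echoes from biasing T2* upward).
#' @param echo_snr_min per-echo measured-SNR floor below which an echo is
#'   excluded from the fit (default 2: below twice the noise level the
#'   second-moment debias becomes unreliable).
#' @param refine run the Levenberg-Marquardt refinement (default `TRUE`);
#'   `FALSE` keeps the closed-form estimate.
#' @param t2star_cap upper parameter bound for the fit (ms).
#' @return An object of class `t2star_map`: arrays `t2star_ms`, `s0`,
#'   `r_squared`, integer `reason` array (0 kept, 1 low-snr, 2 outlier,
#'   3 fit-fail) and `echo_times_ms`.
#' @export
fit_t2star_map <- function(volume, mask = NULL, echo_times_ms = NULL,
                           noise_sigma = NULL, echo_snr_min = 2,
                           refine = TRUE, t2star_cap = 1000) {
  usable <- NULL
  factors <- NULL
  if (inherits(volume, "corrected_volume")) {
    dat <- volume$data
    usable <- volume$usable
    factors <- volume$factors
    if (is.null(echo_times_ms)) echo_times_ms <- volume$echo_times_ms
  } else {
    dat <- as_volume_array(volume)
    if (inherits(volume, "multiecho_volume") && is.null(echo_times_ms))
      echo_times_ms <- volume$echo_times_ms
    if (inherits(volume, "multiecho_volume") && is.null(noise_sigma) &&
        volume$noise_sigma > 0)
      noise_sigma <- volume$noise_sigma
  }
  if (is.null(echo_times_ms)) stop("echo times are required")
  dims <- dim(dat)[1:3]
  ne <- dim(dat)[4]
  stopifnot(ne == length(echo_times_ms), ne >= 3)
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  if (is.null(usable)) usable <- array(TRUE, dim(dat))

  t2 <- array(NA_real_, dims); s0 <- array(NA_real_, dims)
  r2 <- array(NA_real_, dims)
  reason <- array(1L, dims)  # low-snr by default; overwritten inside mask
  reason[!mask] <- 1L

  idx <- which(mask)
  arr_idx <- arrayInd(idx, dims)
  for (i in seq_along(idx)) {
    vx <- arr_idx[i, ]
    sig <- dat[vx[1], vx[2], vx[3], ]
    use <- usable[vx[1], vx[2], vx[3], ] & sig > 0
    fac <- if (is.null(factors)) rep(1, length(sig))
           else factors[vx[1], vx[2], vx[3], ]
    w_echo <- fac  # sinc correction amplifies noise by 1/factor
    if (!is.null(noise_sigma) && noise_sigma > 0) {
      meas <- sig * fac
      # second-moment Rician debias: E[M^2] = S^2 + 2 sigma^2; echoes at or
      # below the noise floor debias to zero and drop out of the fit
      meas2 <- pmax(meas^2 - 2 * noise_sigma^2, 0)
      sig <- sqrt(meas2) / fac
      use <- use & sig > 0 & meas >= echo_snr_min * noise_sigma
      # delta method: Var[sqrt(M^2 - 2 s^2)] = s^2 (M / S)^2, so weight
      # near-floor echoes down by S/M on top of the sinc factor
      w_echo <- ifelse(meas > 0, fac * sqrt(meas2) / meas, 0)
    }
    if (sum(use) < 3) { reason[idx[i]] <- 3L; next }
    te <- echo_times_ms[use]; sg <- sig[use]
    wf <- w_echo[use]
    init <- loglinear_t2star(te, sg, wf^2)
    if (!all(is.finite(init)) || init[2] <= 0 || init[1] <= 0) {
      reason[idx[i]] <- 3L; next
    }
    p <- init
    if (refine) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(S0 = init[1], T2 = min(init[2], t2star_cap)),
          fn = function(p) wf * (sg - p[1] * exp(-te / p[2])),
          lower = c(1e-12, 1e-3), upper = c(Inf, t2star_cap),
          control = minpack.lm::nls.lm.control(maxiter = 200,
                                               ptol = 1e-12, ftol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit)) p <- unname(stats::coef(fit))
    }
    pred <- p[1] * exp(-te / p[2])
    sst <- sum((sg - mean(sg))^2)
    r2[idx[i]] <- if (sst > 0) 1 - sum((sg - pred)^2) / sst else NA_real_
    t2[idx[i]] <- p[2]; s0[idx[i]] <- p[1]
    reason[idx[i]] <- if (p[2] >= t2star_cap * (1 - 1e-9)) 3L else 0L
    if (reason[idx[i]] == 3L) { t2[idx[i]] <- NA_real_; s0[idx[i]] <- NA_real_ }
  }
  structure(list(t2star_ms = t2, s0 = s0, r_squared = r2, reason = reason,
                 echo_times_ms = echo_times_ms),
            class = "t2star_map")
}

reason_labels <- c(`0` = "kept", `1` = "low-snr", `2` = "outlier",
                   `3` = "fit-fail")

#' Exclude non-representative T2* values
#'
#' T2* values above the limit (default 30 ms) are not representative of
#' iron-loaded atheromatous plaque at 4.7 T and are masked as outliers; the
#' exclusion is strict (a voxel exactly at the limit is retained).
#'
#' @param map a `t2star_map`.
#' @param upper_ms exclusion limit (ms), default 30.
#' @return The filtered `t2star_map`; `filter_counts(map)` reports kept /
#'   low-snr / outlier / fit-fail counts.
#' @export
apply_validity_filters <- function(map, upper_ms = 30) {
  stopifnot(inherits(map, "t2star_map"), upper_ms > 0)
  out <- map$reason == 0L & !is.na(map$t2star_ms) & map$t2star_ms > upper_ms
  map$reason[out] <- 2L
  map$t2star_ms[out] <- NA_real_
  map$s0[out] <- NA_real_
  map$upper_ms <- upper_ms
  map
}

#' Voxel accounting of a T2* map
#' @param map a `t2star_map`.
#' @return Named integer vector: kept, low-snr, outlier, fit-fail counts
#'   (summing to the total voxel count).
#' @export
filter_counts <- function(map) {
  stopifnot(inherits(map, "t2star_map"))
  tab <- table(factor(map$reason, levels = 0:3))
  stats::setNames(as.integer(tab), reason_labels)
}

#' Per-slice mean T2* over a segmentation
#'
#' @param map a (filtered) `t2star_map`.
#' @param segmentation logical array matching the map: the manually
#'   segmented plaque/aorta voxels. Default: all voxels.
#' @return A data.frame with one row per slice: `slice`, `mean_t2star_ms`
#'   (`NA` when no valid voxel survives: empty, not zero), `n_valid`.
#' @export
slice_mean_t2star <- function(map, segmentation = NULL) {
  stopifnot(inherits(map, "t2star_map"))
  dims <- dim(map$t2star_ms)
  if (is.null(segmentation)) segmentation <- array(TRUE, dims)
  stopifnot(all(dim(segmentation) == dims))
  res <- lapply(seq_len(dims[3]), function(s) {
    vals <- map$t2star_ms[, , s][segmentation[, , s] & map$reason[, , s] == 0L]
    vals <- vals[!is.na(vals)]
    data.frame(slice = s,
               mean_t2star_ms = if (length(vals)) mean(vals) else NA_real_,
               n_valid = length(vals))
  })
  do.call(rbind, res)
}

#' @export
print.t2star_map <- function(x, ...) {
  cts <- filter_counts(x)
  cat("T2* map:", paste(dim(x$t2star_ms), collapse = " x "), "voxels\n")
  cat("  ", paste(sprintf("%s: %d", names(cts), cts), collapse = ", "), "\n")
  kept <- x$t2star_ms[x$reason == 0L]
  if (length(kept))
    cat(sprintf("  kept T2*: median %.3g ms (range %.3g-%.3g)\n",
                stats::median(kept, na.rm = TRUE),
                min(kept, na.rm = TRUE), max(kept, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.t2star_map <- function(object, ...) {
  list(counts = filter_counts(object),
       slice_stats = slice_mean_t2star(object))
}

#' Display a T2* map slice
#' @param x a `t2star_map`.
#' @param slice slice index.
#' @param ... passed to [graphics::image()].
#' @export
plot.t2star_map <- function(x, slice = 1, ...) {
  graphics::image(x$t2star_ms[, , slice], useRaster = TRUE,
                  main = sprintf("T2* (ms), slice %d", slice), ...)
  invisible(x)
}
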