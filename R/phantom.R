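#' Organ label codes used by the digital phantom
#'
#' Integer codes for the anatomy the phantom can contain: background (0),
#' liver (1), kidney cortex (2), kidney pyramid (3), aorta wall (4) and
#' atheromatous plaque (5).
#'
#' @export
organ_codes <- c(
  background     = 0L,
  liver          = 1L,
  kidney_cortex  = 2L,
  kidney_pyramid = 3L,
  aorta_wall     = 4L,
  plaque         = 5L
)

#' Tissue state for the spoiled gradient-echo signal model
#'
#' @param M0 equilibrium signal (arbitrary units), >= 0.
#' @param R1 longitudinal relaxation rate (1/s), > 0.
#' @param R2star_baseline baseline effective transverse relaxation rate
#'   R2*(0) (1/s), > 0; the rate before any contrast agent arrives.
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(M0, R1, R2star_baseline) {
  stopifnot(is.numeric(M0), M0 >= 0, is.numeric(R1), R1 > 0,
            is.numeric(R2star_baseline), R2star_baseline > 0)
  structure(list(M0 = M0, R1 = R1, R2star_baseline = R2star_baseline),
            class = "tissue_state")
}

#' Acquisition protocol for spoiled gradient-echo imaging
#'
#' @param flip_deg flip angle alpha in degrees, in (0, 180).
#' @param TE_ms echo time (first echo for multi-echo) in ms, > 0.
#' @param TR_ms repetition time in ms, > TE.
#' @param n_echoes number of echoes (1 for dynamic FLASH).
#' @param dTE_ms echo spacing in ms; required when `n_echoes > 1`.
#' @param frame_duration_s duration of one dynamic frame in seconds.
#' @param slice_thickness_mm slice thickness in mm.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(flip_deg = 30, TE_ms = 3.4, TR_ms = 30,
                                 n_echoes = 1L, dTE_ms = NA_real_,
                                 frame_duration_s = 60,
                                 slice_thickness_mm = 1) {
  stopifnot(flip_deg > 0, flip_deg < 180, TE_ms > 0, TR_ms > TE_ms,
            n_echoes >= 1, frame_duration_s > 0, slice_thickness_mm > 0)
  if (n_echoes > 1 && (is.na(dTE_ms) || dTE_ms <= 0))
    stop("dTE_ms must be > 0 when n_echoes > 1")
  structure(list(flip_deg = flip_deg, TE_ms = TE_ms, TR_ms = TR_ms,
                 n_echoes = as.integer(n_echoes), dTE_ms = dTE_ms,
                 frame_duration_s = frame_duration_s,
                 slice_thickness_mm = slice_thickness_mm),
            class = "acquisition_protocol")
}

#' Echo times of a multi-echo protocol (ms)
#' @param protocol an [acquisition_protocol()].
#' @return Numeric vector TE1, TE1 + dTE, ...
#' @export
echo_times <- function(protocol) {
  if (protocol$n_echoes == 1L) return(protocol$TE_ms)
  protocol$TE_ms + (seq_len(protocol$n_echoes) - 1) * protocol$dTE_ms
}

#' Contrast-agent specification
#'
#' @param r2star transverse relaxivity (mM^-1 s^-1), > 0; default 45, the
#'   upper end of the measured 42-45 range for the SPIO nano-emulsions.
#' @param r1 longitudinal relaxivity (mM^-1 s^-1); near zero for SPIO in
#'   oily droplets, which is what justifies the pure-R2* signal model.
#' @param molar_mass_g_mol molar mass of the paramagnetic species (g/mol).
#' @param dose_mg_kg injected dose (mg Fe per kg bodyweight).
#' @return An object of class `contrast_agent`.
#' @export
contrast_agent <- function(r2star = 45, r1 = 0.05,
                           molar_mass_g_mol = spio_constants$iron_molar_mass_g_mol,
                           dose_mg_kg = 3) {
  stopifnot(r2star > 0, r1 >= 0, molar_mass_g_mol > 0, dose_mg_kg > 0)
  if (r1 >= r2star) stop("r1 must be much smaller than r2star for this model")
  structure(list(r2star = r2star, r1 = r1,
                 molar_mass_g_mol = molar_mass_g_mol,
                 dose_mg_kg = dose_mg_kg),
            class = "contrast_agent")
}

#' Ground-truth accumulation parameters
#'
#' First-order accumulation C(t) = Cmax (1 - exp(-tau t)); the implied blood
#' half-life is ln(2)/tau.
#'
#' @param Cmax maximum iron concentration (mM), >= 0.
#' @param tau accumulation rate (1/min), > 0.
#' @return An object of class `accumulation_truth` with fields `Cmax`,
#'   `tau`, `t_half_min`.
#' @export
accumulation_truth <- function(Cmax, tau) {
  stopifnot(Cmax >= 0, tau > 0)
  structure(list(Cmax = Cmax, tau = tau, t_half_min = log(2) / tau),
            class = "accumulation_truth")
}

default_tissue_states <- function() {
  list(
    liver          = tissue_state(M0 = 1000, R1 = 1.25, R2star_baseline = 50),
    kidney_cortex  = tissue_state(M0 = 1100, R1 = 0.80, R2star_baseline = 35),
    kidney_pyramid = tissue_state(M0 = 1200, R1 = 0.60, R2star_baseline = 30),
    aorta_wall     = tissue_state(M0 = 900,  R1 = 1.00, R2star_baseline = 40),
    plaque         = tissue_state(M0 = 800,  R1 = 1.00, R2star_baseline = 110)
  )
}

default_organ_geometry <- function(shape) {
  cx <- shape[1] / 2; cy <- shape[2] / 2
  list(
    liver = list(shape = "ellipse",
                 center = c(cx * 0.62, cy * 0.75),
                 radii  = c(shape[1] * 0.22, shape[2] * 0.18)),
    kidney_cortex = list(shape = "ellipse",
                         center = c(cx * 1.45, cy * 0.55),
                         radii  = c(shape[1] * 0.09, shape[2] * 0.09)),
    kidney_pyramid = list(shape = "ellipse",
                          center = c(cx * 1.45, cy * 1.45),
                          radii  = c(shape[1] * 0.07, shape[2] * 0.07))
  )
}

#' Build a 2D organ label phantom
#'
#' Rasterizes elliptical organ geometries onto an integer label grid. Organs
#' must not overlap; a request that would stack two organs on the same voxel
#' is rejected with the names of the conflicting pair.
#'
#' @param shape integer vector (nx, ny), both positive.
#' @param organs named list of geometries, each
#'   `list(shape = "ellipse", center = c(x, y), radii = c(rx, ry))`; names
#'   must be a subset of `names(organ_codes)` (background excluded).
#'   Defaults to a liver ellipse plus two kidney discs.
#' @param tissue_states named list of [tissue_state()] per organ; defaults
#'   supplied for every organ in `organ_codes`.
#' @param voxel_size_mm voxel edge length (mm), > 0.
#' @param seed integer recorded with the phantom (rasterization itself is
#'   deterministic).
#' @return An object of class `phantom` with fields `labels` (integer
#'   matrix), `voxel_size_mm`, `tissue`, `seed`.
#' @export
build_phantom <- function(shape = c(64L, 64L), organs = NULL,
                          tissue_states = NULL, voxel_size_mm = 0.625,
                          seed = 1L) {
  stopifnot(length(shape) == 2, all(shape > 0), voxel_size_mm > 0)
  if (is.null(organs)) organs <- default_organ_geometry(shape)
  ts <- default_tissue_states()
  if (!is.null(tissue_states)) ts[names(tissue_states)] <- tissue_states
  unknown <- setdiff(names(organs), setdiff(names(organ_codes), "background"))
  if (length(unknown))
    stop("unknown organ label(s): ", paste(unknown, collapse = ", "))

  labels <- matrix(0L, shape[1], shape[2])
  xs <- matrix(seq_len(shape[1]), shape[1], shape[2])
  ys <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (org in names(organs)) {
    g <- organs[[org]]
    if (!identical(g$shape, "ellipse"))
      stop("only elliptical organ geometry is supported")
    if (any(g$center - g$radii < 1) ||
        g$center[1] + g$radii[1] > shape[1] ||
        g$center[2] + g$radii[2] > shape[2])
      stop("organ '", org, "' does not fit inside the grid")
    inside <- ((xs - g$center[1]) / g$radii[1])^2 +
              ((ys - g$center[2]) / g$radii[2])^2 <= 1
    clash <- inside & labels != 0L
    if (any(clash)) {
      other <- names(organ_codes)[match(unique(labels[clash]), organ_codes)]
      stop("organ '", org, "' overlaps '", paste(other, collapse = "', '"),
           "' on ", sum(clash), " voxel(s)")
    }
    if (!any(inside)) stop("organ '", org, "' rasterizes to zero voxels")
    labels[inside] <- organ_codes[[org]]
  }
  if (!any(labels == organ_codes[["liver"]]) && "liver" %in% names(organs))
    stop("liver rasterized to zero voxels")
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 tissue = ts, seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  counts <- table(factor(x$labels, levels = organ_codes,
                         labels = names(organ_codes)))
  cat("Digital organ phantom:", paste(dim(x$labels), collapse = " x "),
      "voxels of", x$voxel_size_mm, "mm\n")
  print(counts[counts > 0])
  invisible(x)
}

# Rician magnitude noise: Gaussian noise on both complex channels.
add_rician_noise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# Expected mean of a Rician variate: sigma sqrt(pi/2) L_{1/2}(-S^2/2sigma^2),
# evaluated with exponentially scaled Bessel functions for stability.
rician_mean <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  x <- -signal^2 / (2 * sigma^2)
  laguerre_half <- (1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
    x * besselI(-x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * laguerre_half
}

# Smooth spatial envelope for the respiratory-like deformation: Gaussian
# bump, unit peak, width ~ grid/3 so displacement gradients stay << 1 and
# the deformation remains invertible.
motion_envelope <- function(shape) {
  sx <- shape[1] / 3; sy <- shape[2] / 3
  cx <- shape[1] / 2; cy <- shape[2] / 2
  xs <- matrix(seq_len(shape[1]), shape[1], shape[2])
  ys <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  exp(-((xs - cx)^2 / (2 * sx^2) + (ys - cy)^2 / (2 * sy^2)))
}

# Bilinear sampling of `img` at (x + u, y + v); out-of-grid positions clamp
# to the border.
warp_bilinear <- function(img, u, v) {
  nx <- nrow(img); ny <- ncol(img)
  xs <- matrix(seq_len(nx), nx, ny) + u
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE) + v
  xs <- pmin(pmax(xs, 1), nx); ys <- pmin(pmax(ys, 1), ny)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(i, j) img[cbind(as.vector(i), as.vector(j))]
  out <- (1 - fx) * (1 - fy) * idx(x0, y0) + fx * (1 - fy) * idx(x1, y0) +
         (1 - fx) * fy       * idx(x0, y1) + fx * fy       * idx(x1, y1)
  matrix(out, nx, ny)
}

#' Simulate a dynamic spoiled gradient-echo series with iron accumulation
#'
#' Forward model: per-voxel signal
#' `M0 sin(alpha) exp(-TE (R2*_baseline + r2* C(t)))` with first-order
#' accumulation `C(t) = Cmax (1 - exp(-tau t))` after injection (t = 0) and
#' C = 0 before. Frames between injection and the first post-injection
#' acquisition are absent, emulating the scan interruption for tail-vein
#' injection. Motion is a smooth, sinusoidal-in-time deformation; noise is
#' Rician.
#'
#' @param phantom a [build_phantom()] result.
#' @param protocol an [acquisition_protocol()].
#' @param agent a [contrast_agent()].
#' @param truth an [accumulation_truth()].
#' @param n_pre number of pre-injection frames, >= 1.
#' @param gap_min delay between injection and the first post-injection
#'   frame (min), > 0.
#' @param duration_min post-injection observation window (min).
#' @param noise_sigma Rician noise parameter, in signal units, >= 0.
#' @param motion_amplitude peak displacement of the respiratory-like
#'   deformation, in voxels.
#' @param motion_period_min period of the deformation (min).
#' @param uptake named per-organ weights on C(t); default: liver 1, all
#'   other organs 0 (liver is the dominant clearance organ).
#' @param seed integer seed; fixed seed + parameters reproduce the series
#'   bit for bit.
#' @return An object of class `dynamic_series`: `data` (nx x ny x nframes),
#'   `times_min` (injection at 0, pre-injection negative), `labels`,
#'   `protocol`, `agent`, `noise_sigma`, and a `truth` record carrying the
#'   accumulation parameters, the noiseless deformation-free per-organ mean
#'   signal at each frame, C(t) at each frame, and the per-frame
#'   displacement fields.
#' @export
simulate_dynamic_series <- function(phantom, protocol, agent, truth,
                                    n_pre = 8L, gap_min = 2,
                                    duration_min = 48,
                                    noise_sigma = 0, motion_amplitude = 0,
                                    motion_period_min = 0.75,
                                    uptake = c(liver = 1), seed = 1L) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(protocol, "acquisition_protocol"),
            inherits(agent, "contrast_agent"),
            inherits(truth, "accumulation_truth"))
  if (n_pre < 1) stop("at least one pre-injection frame is required")
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  if (truth$tau <= 0) stop("tau must be > 0")
  if (gap_min <= 0) stop("injection gap must be > 0")

  dt <- protocol$frame_duration_s / 60
  t_pre <- -rev(seq_len(n_pre) - 0.5) * dt
  n_post <- max(1L, floor((duration_min - gap_min) / dt) + 1L)
  t_post <- gap_min + (seq_len(n_post) - 1) * dt
  times <- c(t_pre, t_post)
  nf <- length(times)

  lab <- phantom$labels
  shape <- dim(lab)
  alpha <- protocol$flip_deg * pi / 180
  TE_s <- protocol$TE_ms / 1000

  organ_names <- setdiff(names(organ_codes), "background")
  up <- stats::setNames(numeric(length(organ_names)), organ_names)
  up[names(uptake)] <- uptake

  conc <- ifelse(times > 0, truth$Cmax * (1 - exp(-truth$tau * times)), 0)

  # per-organ noiseless signal at each frame (deformation-free truth)
  sig_organ <- matrix(NA_real_, nf, length(organ_names),
                      dimnames = list(NULL, organ_names))
  for (org in organ_names) {
    st <- phantom$tissue[[org]]
    sig_organ[, org] <- st$M0 * sin(alpha) *
      exp(-TE_s * (st$R2star_baseline + agent$r2star * conc * up[org]))
  }

  set.seed(seed)
  env <- motion_envelope(shape)
  # anchor the breathing phase so the first frame (the ROI reference) is
  # deformation-free
  phase <- -2 * pi * times[1] / motion_period_min
  data <- array(0, c(shape, nf))
  fields <- vector("list", nf)
  base_img <- matrix(0, shape[1], shape[2])
  for (f in seq_len(nf)) {
    img <- base_img
    for (org in organ_names) {
      sel <- lab == organ_codes[[org]]
      if (any(sel)) img[sel] <- sig_organ[f, org]
    }
    if (motion_amplitude > 0) {
      a <- motion_amplitude * sin(2 * pi * times[f] / motion_period_min + phase)
      d_u <- 0.3 * a * env
      d_v <- a * env
      img <- warp_bilinear(img, d_u, d_v)
      fields[[f]] <- list(u = d_u, v = d_v)
    } else {
      fields[[f]] <- list(u = base_img, v = base_img)
    }
    data[, , f] <- matrix(add_rician_noise(as.vector(img), noise_sigma),
                          shape[1], shape[2])
  }

  structure(list(
    data = data, times_min = times, labels = lab,
    protocol = protocol, agent = agent, noise_sigma = noise_sigma,
    n_pre = as.integer(n_pre), seed = as.integer(seed),
    truth = list(Cmax = truth$Cmax, tau = truth$tau,
                 t_half_min = truth$t_half_min, conc_mM = conc,
                 signal_organ = sig_organ, motion_fields = fields,
                 motion_amplitude = motion_amplitude)
  ), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat("Dynamic series:", paste(dim(x$data)[1:2], collapse = " x "),
      "voxels,", dim(x$data)[3], "frames,",
      sum(x$times_min < 0), "pre-injection\n")
  cat(sprintf("truth: Cmax = %.3g mM, tau = %.4g /min (t1/2 = %.4g min)\n",
              x$truth$Cmax, x$truth$tau, x$truth$t_half_min))
  invisible(x)
}

#' Simulate a multi-echo gradient-echo volume with a through-slice gradient
#'
#' Noiseless voxel signal at echo time TE_k:
#' `S0 exp(-TE_k / T2*) |sinc(gamma G_z dz TE_k / 2)|`, with the
#' unnormalized sinc and gamma the proton gyromagnetic ratio. T2* per voxel
#' comes from the phantom's per-organ baseline R2* (T2* = 1000/R2* in ms).
#' Rician noise is added per echo.
#'
#' @param phantom a [build_phantom()] result; every labeled organ needs a
#'   positive baseline R2*.
#' @param protocol an [acquisition_protocol()] with `n_echoes >= 3`.
#' @param gz_uT_mm through-slice field gradient in microtesla/mm: a scalar,
#'   a matrix matching the phantom grid, or an array (nx, ny, n_slices).
#' @param n_slices number of slice copies of the 2D phantom.
#' @param t2star_scale optional per-slice multiplier on T2* (length
#'   `n_slices`), e.g. to emulate different iron loads per session.
#' @param noise_sigma Rician noise parameter (signal units).
#' @param seed integer seed.
#' @return An object of class `multiecho_volume`: `data` (nx, ny, n_slices,
#'   n_echoes), `echo_times_ms`, `labels`, `gz_uT_mm` (array), `truth`
#'   (per-voxel `t2star_ms` and `s0` arrays), `protocol`, `noise_sigma`.
#' @export
simulate_multiecho_volume <- function(phantom, protocol, gz_uT_mm = 0,
                                      n_slices = 1L, t2star_scale = NULL,
                                      noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(protocol, "acquisition_protocol"))
  if (protocol$n_echoes < 3) stop("at least 3 echoes are required")
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  if (is.null(t2star_scale)) t2star_scale <- rep(1, n_slices)
  stopifnot(length(t2star_scale) == n_slices, all(t2star_scale > 0))

  lab <- phantom$labels
  shape <- dim(lab)
  tes <- echo_times(protocol)
  alpha <- protocol$flip_deg * pi / 180

  t2_map <- matrix(NA_real_, shape[1], shape[2])
  s0_map <- matrix(NA_real_, shape[1], shape[2])
  for (org in setdiff(names(organ_codes), "background")) {
    sel <- lab == organ_codes[[org]]
    if (!any(sel)) next
    st <- phantom$tissue[[org]]
    if (st$R2star_baseline <= 0)
      stop("organ '", org, "' has nonpositive R2*; T2* undefined")
    t2_map[sel] <- 1000 / st$R2star_baseline
    s0_map[sel] <- st$M0 * sin(alpha)
  }

  gz <- gz_uT_mm
  if (length(gz) == 1) gz <- array(gz, c(shape, n_slices))
  else if (is.matrix(gz)) gz <- array(rep(gz, n_slices), c(shape, n_slices))
  stopifnot(all(dim(gz) == c(shape, n_slices)))

  gamma <- spio_constants$gyromagnetic_ratio_rad_s_T
  dz_m <- protocol$slice_thickness_mm * 1e-3

  t2_true <- array(NA_real_, c(shape, n_slices))
  s0_true <- array(NA_real_, c(shape, n_slices))
  labels3 <- array(rep(lab, n_slices), c(shape, n_slices))
  data <- array(0, c(shape, n_slices, length(tes)))
  set.seed(seed)
  for (s in seq_len(n_slices)) {
    t2s <- t2_map * t2star_scale[s]
    t2_true[, , s] <- t2s
    s0_true[, , s] <- s0_map
    for (k in seq_along(tes)) {
      te_s <- tes[k] / 1000
      x <- gamma * gz[, , s] * 1e-3 * dz_m * te_s / 2  # uT/mm -> T/m
      fac <- abs(sinc(x))
      img <- ifelse(is.na(t2s), 0, s0_map * exp(-tes[k] / t2s) * fac)
      data[, , s, k] <- matrix(add_rician_noise(as.vector(img), noise_sigma),
                               shape[1], shape[2])
    }
  }

  structure(list(data = data, echo_times_ms = tes, labels = labels3,
                 gz_uT_mm = gz, protocol = protocol,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 truth = list(t2star_ms = t2_true, s0 = s0_true)),
            class = "multiecho_volume")
}

#' Through-slice gradient map of an air/tissue interface
#'
#' Macroscopic field gradients are strongest at an air/tissue interface and
#' decay with distance from it. This map peaks at `peak_uT_mm` along one
#' grid edge and decays exponentially into the tissue with length
#' `scale_vox`.
#'
#' @param shape grid shape (nx, ny).
#' @param peak_uT_mm peak gradient at the interface (microtesla/mm).
#' @param scale_vox decay length (voxels).
#' @param edge which grid edge carries the interface.
#' @return Matrix of G_z values (microtesla/mm).
#' @export
interface_gradient_map <- function(shape, peak_uT_mm = 2, scale_vox = 5,
                                   edge = c("top", "bottom", "left", "right")) {
  edge <- match.arg(edge)
  stopifnot(peak_uT_mm >= 0, scale_vox > 0)
  d <- switch(edge,
    top    = matrix(seq_len(shape[1]) - 1, shape[1], shape[2]),
    bottom = matrix(rev(seq_len(shape[1])) - 1, shape[1], shape[2]),
    left   = matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE),
    right  = matrix(rev(seq_len(shape[2])) - 1, shape[1], shape[2],
                    byrow = TRUE))
  peak_uT_mm * exp(-d / scale_vox)
}

#' Simulate a first-derivative ESR spectrum
#'
#' The absorption line is Gaussian or Lorentzian, centred at `center_mT`
#' with the stated peak-to-peak derivative width (2 sigma for a Gaussian,
#' 2 Gamma / sqrt(3) for a Lorentzian); the recorded spectrum is its first
#' derivative with additive Gaussian noise. The noiseless double integral
#' is proportional to concentration x sample mass.
#'
#' @param concentration_mol_g spin concentration (mol per g of tissue), >= 0.
#' @param center_mT resonance field (mT).
#' @param width_pp_mT peak-to-peak derivative line width (mT), > 0.
#' @param field_mT strictly increasing field axis (mT); must span
#'   center +- 3 x width. Default: that span at 0.7 mT/pt.
#' @param lineshape "gaussian" (default) or "lorentzian".
#' @param mass_g sample mass (g).
#' @param freq_GHz microwave frequency (GHz).
#' @param intensity_per_mol spectrometer scale factor (arbitrary units of
#'   absorption area per mol of spins).
#' @param noise_sigma additive noise SD on the derivative intensity.
#' @param seed integer seed.
#' @return An object of class `esr_spectrum` with fields `field_mT`,
#'   `intensity`, `freq_GHz`, `mass_g`, and a `truth` record (concentration
#'   and noiseless absorption area).
#' @export
simulate_esr_spectrum <- function(concentration_mol_g, center_mT = 320,
                                  width_pp_mT = 80, field_mT = NULL,
                                  lineshape = c("gaussian", "lorentzian"),
                                  mass_g = 0.05, freq_GHz = 9.54,
                                  intensity_per_mol = 1e9,
                                  noise_sigma = 0, seed = 1L) {
  lineshape <- match.arg(lineshape)
  stopifnot(concentration_mol_g >= 0, width_pp_mT > 0, mass_g > 0)
  if (is.null(field_mT)) {
    n_pts <- ceiling(6 * width_pp_mT / 0.7) + 1
    field_mT <- center_mT - 3 * width_pp_mT + 0.7 * (seq_len(n_pts) - 1)
  }
  if (any(diff(field_mT) <= 0)) stop("field axis must be strictly increasing")
  step <- stats::median(diff(field_mT))
  if (min(field_mT) > center_mT - 3 * width_pp_mT + step / 2 ||
      max(field_mT) < center_mT + 3 * width_pp_mT - step / 2)
    stop("field axis too narrow: must span center +- 3 x width")

  area <- intensity_per_mol * concentration_mol_g * mass_g
  b <- field_mT - center_mT
  if (lineshape == "gaussian") {
    sg <- width_pp_mT / 2
    deriv <- -area * b / (sg^3 * sqrt(2 * pi)) * exp(-b^2 / (2 * sg^2))
  } else {
    gam <- width_pp_mT * sqrt(3) / 2
    deriv <- -area / pi * 2 * gam * b / (b^2 + gam^2)^2
  }
  set.seed(seed)
  if (noise_sigma > 0) deriv <- deriv + stats::rnorm(length(deriv), 0, noise_sigma)

  structure(list(field_mT = field_mT, intensity = deriv,
                 freq_GHz = freq_GHz, mass_g = mass_g,
                 lineshape = lineshape, seed = as.integer(seed),
                 truth = list(concentration_mol_g = concentration_mol_g,
                              area = area, center_mT = center_mT,
                              width_pp_mT = width_pp_mT)),
            class = "esr_spectrum")
}

#' Simulate a hemolysis kinetics curve
#'
#' Logistic hemolysis over time: 50% is reached exactly at `t50_min`; the
#' noiseless curve is nondecreasing.
#'
#' @param t50_min time of 50% hemolysis (min), > 0.
#' @param steepness logistic rate k (1/min), > 0; larger is closer to a
#'   step at `t50_min`.
#' @param time_min sampling grid (min); must extend past the 50% crossing.
#' @param noise_sigma additive noise SD (percentage points).
#' @param label sample label stored with the curve.
#' @param dose_mg_L nano-emulsion dose (mg/L) stored with the curve.
#' @param seed integer seed.
#' @return An object of class `hemolysis_curve` with `time_min`,
#'   `hemolysis_pct` (clipped to \[0, 100\] after noise), metadata, and the
#'   truth record.
#' @export
simulate_hemolysis_curve <- function(t50_min, steepness = 0.08,
                                     time_min = NULL, noise_sigma = 0,
                                     label = "sample", dose_mg_L = 1000,
                                     seed = 1L) {
  stopifnot(t50_min > 0, steepness > 0, noise_sigma >= 0)
  if (is.null(time_min)) time_min <- seq(0, 2.5 * t50_min, by = 1)
  if (any(diff(time_min) <= 0)) stop("time grid must be strictly increasing")
  if (max(time_min) <= t50_min)
    stop("time grid never reaches the 50% crossing at t50 = ", t50_min, " min")
  h <- 100 / (1 + exp(-steepness * (time_min - t50_min)))
  set.seed(seed)
  if (noise_sigma > 0)
    h <- pmin(100, pmax(0, h + stats::rnorm(length(h), 0, noise_sigma)))
  structure(list(time_min = time_min, hemolysis_pct = h, label = label,
                 dose_mg_L = dose_mg_L, seed = as.integer(seed),
                 truth = list(t50_min = t50_min, steepness = steepness)),
            class = "hemolysis_curve")
}
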