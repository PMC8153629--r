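# File interfaces: NIfTI volumes with JSON sidecars for image data, CSV for
# spectra, time courses and hemolysis curves.

#' Write a dynamic series as NIfTI + JSON sidecar
#'
#' The image stack goes to `<path>.nii.gz`; timestamps (min), protocol,
#' agent, seed and the simulation truth go to `<path>.json`.
#'
#' @param series a `dynamic_series`.
#' @param path output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(series$data, nii)
  if (!is.null(series$labels))
    RNifti::writeNifti(series$labels, paste0(path, "_labels.nii.gz"))
  side <- list(times_min = series$times_min, n_pre = series$n_pre,
               protocol = unclass(series$protocol),
               agent = unclass(series$agent),
               noise_sigma = series$noise_sigma, seed = series$seed,
               truth = list(Cmax = series$truth$Cmax, tau = series$truth$tau,
                            t_half_min = series$truth$t_half_min))
  js <- paste0(path, ".json")
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, js))
}

#' Read a dynamic series written by [write_dynamic_series()]
#' @param path path without extension.
#' @return A `dynamic_series` (truth limited to what the sidecar stores).
#' @export
read_dynamic_series <- function(path) {
  dat <- as.array(RNifti::readNifti(paste0(path, ".nii.gz")))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab_file <- paste0(path, "_labels.nii.gz")
  labels <- if (file.exists(lab_file)) {
    l <- as.array(RNifti::readNifti(lab_file))
    matrix(as.integer(round(l)), nrow(l), ncol(l))
  } else NULL
  proto <- do.call(acquisition_protocol, side$protocol[
    c("flip_deg", "TE_ms", "TR_ms", "n_echoes", "dTE_ms",
      "frame_duration_s", "slice_thickness_mm")])
  agent <- do.call(contrast_agent, side$agent[
    c("r2star", "r1", "molar_mass_g_mol", "dose_mg_kg")])
  structure(list(data = dat, times_min = side$times_min, labels = labels,
                 protocol = proto, agent = agent,
                 noise_sigma = side$noise_sigma,
                 n_pre = as.integer(side$n_pre), seed = side$seed,
                 truth = side$truth),
            class = "dynamic_series")
}

#' Write a multi-echo volume as NIfTI + JSON sidecar
#' @param volume a `multiecho_volume`.
#' @param path output path without extension.
#' @return Invisibly, the file paths.
#' @export
write_multiecho_volume <- function(volume, path) {
  stopifnot(inherits(volume, "multiecho_volume"))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(volume$data, nii)
  js <- paste0(path, ".json")
  jsonlite::write_json(
    list(echo_times_ms = volume$echo_times_ms,
         protocol = unclass(volume$protocol),
         noise_sigma = volume$noise_sigma, seed = volume$seed),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, js))
}

#' Write / read a signal time course as CSV
#'
#' Columns: `t_min,mean,sd,n_voxels`.
#' @param course a `signal_timecourse`.
#' @param file CSV path.
#' @return Invisibly, `file`.
#' @export
write_timecourse_csv <- function(course, file) {
  stopifnot(inherits(course, "signal_timecourse"))
  utils::write.csv(data.frame(t_min = course$times_min, mean = course$mean,
                              sd = course$sd, n_voxels = course$n_voxels),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(file) {
  d <- utils::read.csv(file)
  structure(list(times_min = d$t_min, mean = d$mean, sd = d$sd,
                 n_voxels = d$n_voxels, n_pre = sum(d$t_min < 0)),
            class = "signal_timecourse")
}

#' Write / read an ESR spectrum as CSV (+ optional JSON sidecar)
#'
#' Columns: `field_mT,intensity`; the sidecar carries the microwave
#' frequency and sample mass.
#' @param spectrum an `esr_spectrum`.
#' @param file CSV path.
#' @param sidecar write `<file>.json` with frequency and mass.
#' @return Invisibly, `file`.
#' @export
write_spectrum_csv <- function(spectrum, file, sidecar = TRUE) {
  sp <- as_spectrum(spectrum)
  utils::write.csv(data.frame(field_mT = sp$field_mT,
                              intensity = sp$intensity),
                   file, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(list(freq_GHz = sp$freq_GHz, mass_g = sp$mass_g),
                         paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(file) {
  d <- utils::read.csv(file)
  freq <- mass <- NA_real_
  js <- paste0(file, ".json")
  if (file.exists(js)) {
    side <- jsonlite::read_json(js, simplifyVector = TRUE)
    freq <- side$freq_GHz %||% NA_real_
    mass <- side$mass_g %||% NA_real_
  }
  structure(list(field_mT = d$field_mT, intensity = d$intensity,
                 freq_GHz = freq, mass_g = mass),
            class = "esr_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a hemolysis curve as CSV
#'
#' Columns: `time_min,hemolysis_pct`.
#' @param curve a `hemolysis_curve`.
#' @param file CSV path.
#' @return Invisibly, `file`.
#' @export
write_hemolysis_csv <- function(curve, file) {
  h <- as_hemolysis(curve)
  utils::write.csv(data.frame(time_min = h$time_min,
                              hemolysis_pct = h$hemolysis_pct),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_hemolysis_csv
#' @export
read_hemolysis_csv <- function(file) {
  as_hemolysis(utils::read.csv(file))
}
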