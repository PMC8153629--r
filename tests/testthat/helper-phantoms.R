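# Shared fixture builders; everything is generated in code at test time.

small_phantom <- function(shape = c(48L, 48L)) build_phantom(shape = shape)

plaque_phantom <- function(shape = c(24L, 24L), r2star_baseline = 110) {
  build_phantom(
    shape = shape,
    organs = list(plaque = list(shape = "ellipse",
                                center = shape / 2,
                                radii = pmax(3, round(shape * 0.25)))),
    tissue_states = list(plaque = tissue_state(800, 1, r2star_baseline)))
}

multiecho_protocol <- function(n_echoes = 15)
  acquisition_protocol(flip_deg = 60, TE_ms = 2.8, TR_ms = 1300,
                       n_echoes = n_echoes, dTE_ms = 3.6)

# baseline liver signal of the default tissue table under the default
# dynamic protocol (used to convert SNR into a noise sigma)
liver_baseline_signal <- function(phantom = small_phantom(),
                                  protocol = acquisition_protocol()) {
  st <- phantom$tissue$liver
  st$M0 * sin(protocol$flip_deg * pi / 180) *
    exp(-(protocol$TE_ms / 1000) * st$R2star_baseline)
}

make_dynamic <- function(t_half = 15, snr = Inf, motion = 0, seed = 1L,
                         duration_min = 30, shape = c(48L, 48L), ...) {
  phan <- small_phantom(shape)
  proto <- acquisition_protocol()
  sigma <- if (is.finite(snr)) liver_baseline_signal(phan, proto) / snr else 0
  simulate_dynamic_series(phan, proto, contrast_agent(),
                          accumulation_truth(2, log(2) / t_half),
                          duration_min = duration_min, noise_sigma = sigma,
                          motion_amplitude = motion, seed = seed, ...)
}

gaussian_reference_spectra <- function(concs, noise_pct = 0, seed = 1L) {
  lapply(seq_along(concs), function(i) {
    sp0 <- simulate_esr_spectrum(concs[i], noise_sigma = 0)
    amp <- max(abs(sp0$intensity))
    simulate_esr_spectrum(concs[i], noise_sigma = amp * noise_pct / 100,
                          seed = seed + i)
  })
}
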