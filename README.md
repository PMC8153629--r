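# spioquant

Quantitative analysis of superparamagnetic iron oxide (SPIO) loaded
nano-emulsion contrast agents from magnitude MRI, electron spin resonance
(ESR) spectra and free-radical hemolysis (KRL) assays — for researchers
evaluating the stealth, plaque-targeting and antioxidant properties of
nanocarrier formulations in preclinical imaging studies.

## What it computes

**Blood half-life from dynamic liver MRI.** SPIO in oily droplets is a pure
R2* agent (r1 ≈ 0), so the spoiled gradient-echo signal obeys

    S(t)      = M0 sin(α) exp(−TE (R2*(0) + r2* C(t)))
    S_norm(t) = S(t)/S(0) = exp(−TE r2* C(t))
    C(t)      = −ln(S_norm(t)) / (TE · r2*)

Liver iron accumulation after an intravenous injection is first-order,
`C(t) = Cmax (1 − e^(−τt))`, and the apparent blood half-life is
`t1/2 = ln 2 / τ`. The pipeline tracks the liver through respiratory motion
(Horn–Schunck optical flow + elastic ROI propagation), fuses the pre- and
post-injection sessions with the injection at t = 0, converts signal to
concentration, and fits (Cmax, τ) by Levenberg–Marquardt. The fit is a
classed model object with `print`, `summary`, `coef`, `predict`, `plot`,
`residuals` and `simulate` methods.

**T2\* mapping of atheromatous plaque.** Voxelwise mono-exponential fits of
multi-echo magnitude volumes, with macroscopic through-slice gradient
(sinc) correction, an SNR ≥ 4 acceptability gate, strict > 30 ms outlier
exclusion, per-voxel reason codes and per-slice means.

**ESR spin quantification.** Double trapezoidal integration of
first-derivative spectra, mass normalization, calibration through the
origin against references spanning 5×10⁻¹⁰–1×10⁻⁷ mol/g, plus resonance
arithmetic g = hν/(μB·B) and peak-to-peak line-width measurement.

**KRL antioxidant reduction.** T50 (time to 50% hemolysis) by linear
interpolation, percent change versus control, and Trolox equivalents per
gram of nano-emulsion by calibration inversion.

Every input the pipeline consumes can be generated synthetically with known
ground truth (`build_phantom()`, `simulate_dynamic_series()`,
`simulate_multiecho_volume()`, `simulate_esr_spectrum()`,
`simulate_hemolysis_curve()`), so the whole chain is testable end to end.

## Worked example

```r
library(spioquant)

# a dynamic liver series with known truth: t1/2 = 15 min, SNR ~30, breathing
series <- simulate_dynamic_series(
  build_phantom(), acquisition_protocol(), contrast_agent(),
  accumulation_truth(Cmax = 2, tau = log(2) / 15),
  duration_min = 30, noise_sigma = 14, motion_amplitude = 1.5, seed = 1)

fit <- estimate_halflife(series)   # track -> normalize -> concentration -> fit
summary(fit)
#> First-order iron accumulation fit: C(t) = Cmax (1 - exp(-tau t))
#>   Cmax = 1.979 mM,  tau = 0.0468 /min,  t1/2 = 14.81 min
#>        Estimate  Std. Error
#> Cmax 1.97870566 0.027777179
#> tau  0.04680077 0.001096672
#> RSS = 0.005441 over 29 post-injection points; converged: TRUE
```

The true half-life was 15 min; the motion-tracked fit recovers 14.81 min
with a standard error of about 0.35 min on `t1/2` (propagated from τ).
Cmax is the plateau iron concentration in the liver (mM); τ (1/min) is the
accumulation — hence blood clearance — rate.

```r
# ESR: calibrate on six references, quantify an unknown
concs <- exp(seq(log(5e-10), log(1e-7), length.out = 6))
cal <- build_calibration(lapply(concs, simulate_esr_spectrum), concs)
quantify_concentration(simulate_esr_spectrum(1.7e-8), cal)
#> Spin concentration: 1.7e-08 +- 2.7e-22 mol/g  (g = 2.130, p-p width = 80 mT)

# KRL: antioxidant effect of a tocopherol-loaded formulation
ctrl <- simulate_hemolysis_curve(100,    time_min = seq(0, 400), noise_sigma = 0.5, seed = 2)
samp <- simulate_hemolysis_curve(189.24, time_min = seq(0, 400), noise_sigma = 0.5, seed = 3)
cal_tr <- data.frame(trolox_mg = seq(0, 120, 10)); cal_tr$delta_t50_min <- cal_tr$trolox_mg * 2
antioxidant_summary(samp, ctrl, cal_tr, ne_mass_g = 1)
#> T50 = 189.45 min (control 99.81 min): +89.81%
#> Trolox equivalent: 44.82 mg per g of NE
```

`run_synthetic_experiment(seed = 1)` chains all four stages and returns a
report object; `write_report()` serializes it with seed, config and
version. A command-line front end over the same functions lives at
`inst/cli/spioquant.R` (subcommands `simulate`, `fit-halflife`,
`t2star-map`, `esr-quant`, `krl`, `run-all`).

## Package layout

- `R/phantom.R` — label phantoms and seeded generators (+ ground truth)
- `R/motion.R` — optical flow, ROI propagation, time-course extraction
- `R/pk.R` — normalization, concentration, accumulation fit (`pk_fit`),
  dose arithmetic
- `R/relaxometry.R` — SNR gate, sinc correction, T2* maps, filters, slice stats
- `R/esr.R` — baseline, double integration, calibration, resonance arithmetic
- `R/krl.R` — T50, percent change, Trolox equivalents
- `R/io.R` — NIfTI + JSON sidecars, CSV schemas
- `R/pipeline.R` — end-to-end experiment and reporting
- `vignettes/` — the methods vignette (model, assumptions, design choices)
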