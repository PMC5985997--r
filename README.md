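# fcsfit

Quantitative fluorescence correlation spectroscopy (FCS) in R, end to
end: simulate photon-count traces of fluorophores diffusing through a
confocal observation volume, correlate them, fit the one-component 3D
diffusion model with triplet state, calibrate the observation volume
from a reference dye, and convert fits into diffusion coefficients and
molar concentrations. A second arm generates synthetic microscopy images
and quantifies background-corrected per-cell fluorescence to rank
promoter strength — the standard workflow for choosing expression
levels low enough for single-molecule methods.

It is written for microscopists and method developers who need a
testable FCS analysis chain: every stage can be validated against closed
forms and parameter recovery on synthetic data, with no instrument data
required.

## The model

The fluctuation autocorrelation of the photon record,
G(τ) = ⟨δF(t)·δF(t+τ)⟩ / ⟨F⟩², is fitted with

    g(τ) = b + (1/N) · (1 + T/(1−T)·e^(−τ/τ_T))
               · (1 + τ/τ_D)^(−1) · (1 + τ/(S²τ_D))^(−1/2)

where N is the average number of molecules in the effective volume,
τ_D the diffusion time, T and τ_T the triplet (dark-state) fraction and
lifetime, S the axial-to-lateral aspect ratio of the 3D Gaussian
detection profile, and b a baseline. Physical quantities follow from
D = ω²/(4τ_D) and C = N/(V_eff·N_A) with V_eff = π^(3/2)·ω³·S; the
lateral radius ω comes from a reference-dye calibration
(ω = √(4·D_dye·τ_D,dye)).

## Worked example

```r
library(fcsfit)

# 1. Calibrate the observation volume from six simulated 2-s runs of a
#    reference dye (known D = 400 um^2/s) through an omega = 0.25 um,
#    S = 5.747 volume. Replicate curves are pooled, and the computable
#    finite-sample offset of the estimator is fixed in the fit.
dye_cfgs <- lapply(1:6, function(i)
  trace_sim_config(mean_occupancy = 6.02, diff_coeff = 400,
                   duration = 2, bin_width = 2e-6, time_step = 1e-6,
                   seed = 1500 + i))
dye_curves <- lapply(dye_cfgs, function(cfg)
  autocorrelate_multitau(simulate_diffusion_trace(cfg), max_lag = 0.02))
pooled <- average_curves(dye_curves)
cal <- calibrate_volume(pooled, dye_diff_coeff = 400,
                        baseline_offset =
                          finite_sample_offset(pooled,
                                               dye_cfgs[[1]]$n_molecules))
cal
#> Observation-volume calibration:
#>   dye D          : 400 um^2/s (input)
#>   fitted tau_D   : 3.726e-05 s
#>   lateral radius : 0.2442 um
#>   aspect ratio   : 5.747
#>   V_eff          : 0.4658 fl

# 2. Simulate a cellular eGFP-like measurement (occupancy 5,
#    D = 35.4 um^2/s, triplet T = 0.15, tau_T = 5 us), screen, fit, derive.
cfg <- trace_sim_config(mean_occupancy = 5, diff_coeff = 35.4,
                        triplet_fraction = 0.15, triplet_lifetime = 5e-6,
                        duration = 6, bin_width = 2e-6, time_step = 1e-6,
                        seed = 42)
tr  <- simulate_diffusion_trace(cfg)
cv  <- autocorrelate_multitau(tr, max_lag = 0.05)
screen_trace(tr, oscillation_allowance = expected_oscillation_excess(cv))
#> Trace QC: ACCEPTED
#>   drift fraction   : 0.121
#>   oscillation score: 51.7
fit <- fcs_fit(cv, baseline_offset = finite_sample_offset(cv, cfg$n_molecules))
summary(fit, calibration = cal)
#> Triplet 3D-diffusion model fit (converged)
#>                    estimate std_error
#> n_molecules       5.144e+00     0.050
#> diffusion_time    4.185e-04     0.000
#> triplet_fraction  2.207e-01     0.092
#> triplet_lifetime  3.258e-06     0.000
#> aspect_ratio      5.747e+00     fixed
#> baseline         -1.224e-03     fixed
#> chi-square: 45.55
#> derived D: 35.615 um^2/s
#> derived C: 18.338 nM
assess_suitability(coef(fit)[["n_molecules"]],
                   n_se = fit$stderr[["n_molecules"]])
#> N = 5.14 molecules in the observation volume: optimal [5, 20]
```

Reading the output: the dye's known diffusion coefficient converts its
fitted dwell time into the lateral radius (0.244 um here; ground truth
0.25) and the 0.47-fl effective volume (truth 0.5 -- a 12-s calibration
scatters by a few percent in omega, three times that in volume). The
eGFP-like fit recovers the occupancy (5.14 vs 5) and, through the
calibrated radius, the diffusion coefficient (35.6 vs 35.4 um^2/s); the
occupancy converts to 18 nM in the calibrated volume (5 molecules in
0.5 fl is 16.6 nM). The QC screen's oscillation score of 52 is typical
for a genuine diffusion signal at this occupancy, which is why the
expected excess is passed as an allowance. The suitability verdict
confirms the expression level sits in the practical 5-20 molecule FCS
band.

The imaging arm works the same way from `simulate_cell_image()` through
`measure_cells()` to `summarize_promoters()` (reference construct scaled
to 10, >=10 cells per reportable summary); see the methods vignette.

A thin command-line wrapper over these functions is installed at
`inst/scripts/fcs-cli.R` with subcommands `simulate-trace`, `correlate`,
`fit`, `calibrate`, `screen`, `simulate-image`, `quantify`, `report`.

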