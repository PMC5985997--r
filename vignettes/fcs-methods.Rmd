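---
title: "Models and methods behind fcsfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fcsfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement this package models

Fluorescence correlation spectroscopy infers the concentration and
mobility of fluorescent molecules from the *fluctuations* of the
fluorescence collected from a sub-femtolitre confocal observation volume.
As molecules diffuse through the volume the photon count rate flickers;
the normalized autocorrelation of that flicker,

$$G(\tau) = \frac{\langle \delta F(t)\,\delta F(t+\tau)\rangle}
                 {\langle F\rangle^{2}},$$

has amplitude $G(0) \propto 1/N$, the inverse of the average number of
molecules in the volume, and decays on the dwell-time scale of a
molecule. For one freely diffusing species observed through a 3D Gaussian
detection profile with lateral radius $\omega$ and aspect ratio $S$
(axial extent $z_0 = S\omega$), with a fast triplet-state (dark)
correction, the model fitted here is

$$g(\tau) = b + \frac{1}{N}
  \left(1 + \frac{T}{1-T}\,e^{-\tau/\tau_T}\right)
  \left(1 + \frac{\tau}{\tau_D}\right)^{-1}
  \left(1 + \frac{\tau}{S^{2}\tau_D}\right)^{-1/2},$$

with $N$ the occupancy, $\tau_D$ the diffusion time, $T \in [0,1)$ the
stationary triplet fraction, $\tau_T$ the triplet relaxation time and $b$
an additive baseline (0 for ideally normalized curves). Two published
conventions differ by an overall constant (curves decaying to 1 rather
than 0) and by the typography of the triplet prefactor; the package
adopts the decay-to-zero convention with prefactor $1 + T e^{-\tau/\tau_T}/(1-T)$,
which is the standard stationary two-state correction, and exposes $b$
for the alternative convention.

Physical quantities follow from two closed forms: the diffusion
coefficient $D = \omega^2 / (4\tau_D)$ and the molar concentration
$C = N / (V_\mathrm{eff} N_A)$ with
$V_\mathrm{eff} = \pi^{3/2}\omega^3 S$, the standard effective volume
$(\int w)^2 / \int w^2$ of the 3D Gaussian profile
$w = \exp(-2(x^2+y^2)/\omega^2 - 2z^2/z_0^2)$. The geometry itself is
not assumed: it is calibrated by measuring a reference dye of known
diffusion coefficient and inverting $\omega = \sqrt{4 D_\mathrm{dye}\tau_D}$
(`calibrate_volume()`). The dye's literature $D$ is a required input,
not a package constant. The package defaults $\omega = 0.25\,\mu m$ and
$S = 5.747$ describe an instrument whose calibrated effective volume is
$0.5$ fl.

## The synthetic-data generator

`simulate_diffusion_trace()` is a Brownian-dynamics forward model of the
photon record:

* Point emitters diffuse independently in a periodic box with per-axis
  Gaussian steps of variance $2D\Delta t$. The box half-widths are at
  least $5(\omega, \omega, S\omega)$, so re-entry statistics are
  unbiased; the number of molecules is
  `round(occupancy * V_box / V_eff)`, i.e. the concentration implied by
  the requested occupancy.
* Detection weight is the 3D Gaussian profile above; per-bin photon
  counts are Poisson with mean
  $\epsilon\,\Delta t \sum_i w(\mathbf r_i) + \text{background}$.
* Triplet blinking is a discrete-time two-state Markov chain with
  per-step probabilities $(T/\tau_T)\Delta t$ (bright to dark) and
  $((1-T)/\tau_T)\Delta t$ (dark to bright), giving stationary dark
  fraction $T$ and relaxation time $\tau_T$ — the minimal photophysics
  consistent with the fitted model. Blinking coarser than $\tau_T/5$ is
  refused.
* The default time step $\min(\text{bin width}, \tau_D/50, \tau_T/10)$
  resolves both decays. The default acquisition is a 20-s run at 1-µs
  bins; defaults for brightness (30 kHz per molecule at the profile
  maximum) and occupancy (5–20) reflect the low-expression regime the
  method needs.

Two implementation details matter for correctness and speed. First, the
kernel's RNG (xoshiro256++ with a ziggurat normal sampler) is internal,
so a configuration plus seed maps to a bit-identical trace on every
platform. Second, a molecule that is provably outside the detection
region for the next $k$ steps — its distance beyond the region's
bounding slab on some axis exceeds $4\sigma\sqrt{k}$ — is advanced by a
single Gaussian jump of variance $2Dk\Delta t$ instead of $k$ explicit
steps. For free diffusion this is exact: the skipped path emits nothing
(weight below $e^{-10}$ of the peak) and the endpoint distribution is
identical. The optimization was validated against the analytic
correlation function and against the non-skipping kernel; it changes
run time by roughly a factor five, not the statistics.

What the generator deliberately does *not* emulate: detector afterpulse
and dead-time artifacts, photobleaching kinetics, multiple diffusing
species, refractive-index aberrations of the detection profile, and
membrane-confined or anomalous motion. Passing parameter-recovery tests
on these traces therefore demonstrates the correctness of the inference
chain, not robustness to every pathology of live-cell data; the QC
screen (below) is the package's handle on the latter.

## Correlation estimation

`autocorrelate_direct()` evaluates the defining estimator — products of
mean-subtracted counts, normalized by the squared global mean — on a
linear lag grid; it is exact and serves as the oracle for the
production path. `autocorrelate_multitau()` evaluates the same estimator
on a quasi-logarithmic grid: `points_per_octave` native-resolution lags,
then pairwise rebinning with lag spacing doubling per octave. Within the
first octave the two agree to floating precision. Per-lag standard
errors come from recomputing the curve on 8 contiguous blocks; they feed
the weighted fit.

### Finite-sample offset

A curve normalized by the trace's *own* mean sits slightly below the
ideal $G$: estimating the mean on the same finite segment of length
$T_\mathrm{tr}$ removes $\approx (2/T_\mathrm{tr})\int_0^\infty G$, and a
simulation with a *fixed* number $M$ of emitters in a closed box lacks
the open-volume number fluctuations, removing a further $1/M$.
Both terms are computable (`finite_sample_offset()`), and the pipeline
fixes the model baseline $b$ at their sum instead of letting the deficit
bias $\tau_D$ downward by several percent. For real data from an open
volume the $1/M$ term is negligible ($M$ is effectively the number of
molecules in the illuminated sample, not in a 90-µm³ box) and the
truncation term is small for the usual 20-s runs.

## Fitting

`fcs_fit()` minimizes weighted squared residuals to the model with
Levenberg–Marquardt under box bounds ($N \in (0, 10^4]$,
$\tau_D \in [1\,\mu s, 1\,s]$, $T \in [0, 0.5]$,
$\tau_T \in [0.5, 50]\,\mu s$). Default initial guesses come from the
curve itself (inverse amplitude, half-amplitude lag); the aspect ratio
is fixed — it belongs to the dye calibration, not to cell data — and the
baseline is fixed at the supplied offset. Lags below $1.5\,\mu s$
(3 times the lower $\tau_T$ bound, where detector afterpulsing corrupts
real curves) and above a tenth of the acquisition are excluded by
default. Curves whose small-lag amplitude is not positive yield
`converged = FALSE` with a reason, never a silent answer. A noise-free
model curve is recovered to better than $10^{-6}$ relative in all free
parameters, which is the package's round-trip regression test.

## Quality control

Traces from molecules that are confined, aggregated, or colliding with
organelles show slow drifts or oscillations of the count rate and must
be excluded before fitting. `screen_trace()` operationalizes this with
two statistics on 10 equal segments: the range of segment means over the
global mean (`drift_fraction`, threshold 0.2) and the variance of
segment means over its shot-noise expectation (`oscillation_score`,
threshold 3). One subtlety: genuine occupancy fluctuations of a few
bright molecules also produce low-frequency variance, roughly
$2R\int G$ in shot-noise units ($R$ the count rate) — a *correct* FCS
trace at occupancy 5 can score in the hundreds. The pipeline therefore
passes `expected_oscillation_excess()` of the measured curve as an
allowance, so only variance beyond the diffusion signal counts against a
trace. `assess_suitability()` encodes the working band of the method:
five to twenty molecules per volume is optimal; far above it (strong
viral promoters) the relative fluctuations are too small for reliable
correlation. Because 5 and 20 are themselves plausible measurements, the
verdict optionally takes the estimate's standard error: values within
two standard errors of the band are still called optimal, so a cell
measured at 4.9 ± 0.2 molecules is not discarded on a knife edge.

## Intensity quantification

The imaging arm ranks promoter strength by per-cell fluorescence.
`simulate_cell_image()` builds 16-bit frames with uniform background,
Gaussian read noise, non-overlapping elliptical cells at programmed (or
log-normally drawn) plateau intensities, and optional bright foci; the
exact noise-free in-mask mean above background is returned as ground
truth. `subtract_background()` (value supplied or estimated from the
non-cell region) and `measure_cells()` (whole-cell ROI mean, foci
included; saturation flagged when ≥1% of mask pixels sit at the
bit-depth maximum) mirror the usual background-subtract-then-profile
workflow. `summarize_promoters()` reports per-construct mean ± SD over
cells, requires at least 10 cells for a reportable summary, scales the
designated reference construct to 10, and excludes
saturated-out-of-range constructs from the normalized comparison.
`compare_promoters()` uses Welch's two-sample test on per-cell means —
the procedure is deliberately simple and reported next to the raw means
so users can substitute their own.

## Numerical choices and problem sizes

* Fit convergence: `ftol = ptol = 1e-12`, at most 200 iterations;
  standard errors from the scaled inverse Gauss–Newton Hessian.
* The exponential of the detection weight uses a 4096-entry interpolation
  table (relative error < 5 × 10⁻⁵, far below shot noise).
* Test and acceptance ensembles use seconds-long traces and a handful of
  seeds — the estimator is unbiased in trace length, so shorter runs
  only widen the seed scatter, and the chosen sizes keep the whole suite
  in minutes while leaving comfortable margins at the stated tolerances.
  The replicate-averaging helper (`average_curves()`) mirrors the
  measurement protocol of repeated 20-s runs per position.
* The acceptance script reports the recovered eGFP diffusion
  coefficient from 12 runs of 6 s and the dye calibration from 6 pooled
  runs of 2 s.

## Known limitations

Correlations at lags where a molecule can diffuse across the periodic
box (beyond roughly $L^2/8D$, a few milliseconds at the default box for
a fast dye) carry re-entry artifacts of the simulation geometry; the
default fit window and the per-lag weighting keep their influence small,
and enlarging `box_half_widths` pushes them out at linear cost in
molecules. One diffusing component only; no FRET, no two-color cross-correlation,
no photobleaching correction, no anomalous diffusion. Cell masks are
inputs — no segmentation is implemented. The correlator handles binned
counts, not asynchronous photon timestamps. The QC thresholds are
configurable defaults, not universal constants; with real data they
should be tuned on traces judged by eye, exactly as the screen's design
intends.
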