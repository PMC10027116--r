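---
title: "Methods: bispectral coupling analysis of LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bispectral coupling analysis of LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bicoh)
```

## The model

`bicoh` treats an LFP trace as a realization of a stochastic process that is
stationary *within a behavioural condition* — a running-speed bin or a sleep
epoch. Everything downstream follows from three estimators over ensembles of
equal-length, de-meaned windows with DFTs $P, Q, R$:

* cross-spectrum $S(f_n) = \langle P_n Q_n^* \rangle$,
* cross-bispectrum $B(f_m, f_n) = \langle P_m Q_n R^*_{m+n} \rangle$,
* normalized bicoherence
  $b = B / \sqrt{\langle |P_m Q_n|^2\rangle \langle |R_{m+n}|^2 \rangle}$.

The bicoherence modulus is bounded by 1 (Cauchy–Schwarz applied to
$X = P_m Q_n$, $Y = R_{m+n}$) and detects *quadratic phase coupling*: a
fixed relation $\phi(f_m) + \phi(f_n) - \phi(f_m + f_n)$ across windows.
That is exactly the signature of a nonsinusoidal theta wave (harmonics
locked to the fundamental) and of theta-phase-modulated gamma (carrier
side-bands locked to the theta phase), which ordinary power spectra and
power correlations cannot separate from incidental co-variation.

Assumptions worth keeping in mind: windows inside a condition are treated
as exchangeable realizations; with 50% overlap they are not independent,
which the effective-DOF correction (below) absorbs but only approximately;
and the statistics are third-order, so symmetric nonlinearities
(zero-skewness waveforms) are invisible to them.

## Segmentation and key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window length | 1 | s | 1250 samples at 1250 Hz gives exactly 1 Hz resolution, enough to resolve theta harmonics |
| overlap | 0.5 | — | Welch-style variance reduction for LFP; spike-train spectra use non-overlapping 1-s segments |
| speed bins | 1–9, 8–16, >15 | cm/s | the mid bin deliberately overlaps both neighbours; a window may belong to two bins |
| speed smoothing | 0.5 | s | boxcar on the position derivative; tracking jitter at ~39 Hz otherwise aliases into bin assignment |
| theta band | 4–40 | Hz | fundamental plus harmonics up to the 5th |
| gamma band | 42–100 | Hz | unitary gamma range; the 2 Hz gap avoids double-counting the band edge |
| theta phase band | 6–10 | Hz | band-pass + analytic signal; phase 0° at the filtered peak |
| tuning bins | 12 | deg | 30 bins; a 30° variant is available via `bin_width` |

Windows are assigned to a speed bin by their *mean* speed; windows
containing any missing tracking sample are dropped rather than imputed.
No taper is applied inside bispectral windows — a taper would have to be
propagated consistently into both numerator and denominator of $b$, and
rectangular windows keep the normalization exact; a Hann taper is available
for PSD display only.

## Degrees of freedom and significance

Two DOF conventions coexist deliberately. Power spectra carry the
chi-square convention, `dof = 2 × effective segments`. Bispectral
estimates carry `dof = effective segments`, the ensemble size that sets the
null level of $|b|$. With 50% overlap the effective segment count is
`K / (1 + 2·overlap²)` (rectangular-window Welch correction, ≈ `K/1.5`).

`significance_threshold(dof)` calibrates the null by seeded Monte Carlo:
Gaussian white-noise ensembles of `dof` independent segments, $|b|$ at a
fixed interior frequency pair, 2000 replicates, 95th percentile, cached per
`(dof, n_reps, seed)`. The suite verifies the $1/\sqrt{\mathrm{DOF}}$
scaling across DOF ∈ {25, 100, 400}. Numerically the level sits at
$\approx \sqrt{3/\mathrm{DOF}}$ — about 0.17 at DOF 100 and about 0.10
only near 300 independent windows (equivalently ~600 chi-square DOF, the
familiar $\sqrt{6/\mathrm{DOF}}$ rule). Rule-of-thumb levels of
$|b| \gtrsim 0.1$ quoted for "DOF of order 100" in parts of the
electrophysiology literature are therefore optimistic for this estimator;
the package reports what its own null actually does rather than adopting
the quoted pairing, and its acceptance check of that quoted value is
expected to disagree by construction.

## Principal domains and ROI geometry

For real signals, negating both frequencies conjugates $B$, and the first
two slots commute when they hold the same process. The orbit of these
symmetries leaves octants 1 and 8 ($|f_2| \le f_1$) as the nonredundant
plane for two-region `ppq` arrangements; the auto case gains
$B(m,-n) = \overline{B(m-n,n)}$ (note the conjugation, which the algebra
requires) and collapses to octant 1. The suite checks both statements by
brute-force full-plane computation on 64-point grids.

ROI polygons are a design choice, since only the band bounds are canonical:

* `theta_theta`: $\theta_{lo} \le f_2 \le f_1$, $f_1 + f_2 < \theta_{hi}$;
* `theta_gamma_sum` (quadrant 1): $f_1 \in [\gamma_{lo}, \gamma_{hi})$,
  $f_2 \in [\theta_{lo}, \theta_{hi})$ — the $\theta + \gamma = \gamma$ triad;
* `theta_gamma_diff` (octant 8): $f_2 \in (-\theta_{hi}, -\theta_{lo}]$ —
  $\gamma - \theta = \gamma$;
* `theta_gamma_gg` (octant 8): both axes in gamma with
  $f_1 + f_2 \in [\theta_{lo}, \theta_{hi})$ — $\gamma - \gamma = \theta$,
  the "theta-modulated gamma" difference interaction;
* `gamma_gamma`: the octant-1 gamma triangle.

Edges are half-open (lower in, upper out) so adjacent regions never share a
bin; membership is by bin centre; every region is clipped to the principal
domain. For a region pair there are two `ppq` arrangements and hence six
theta–gamma regions, enumerated by `enumerate_triads()`. ROI strength is
the *raw sum* of $|b|$ with the bin count attached, so a mean variant is a
division away.

## Spike and tuning statistics

Spike trains are binarized at the LFP rate by nearest-sample assignment
(a sample is 1 if at least one spike maps to it), cut into 1-s segments,
speed-assigned like the LFP, and spectrally decomposed per cell; each
cell's spectrum is normalized by its mean power over the 4–100 Hz report
band, which starts at 4 Hz because a binary train's positive mean leaks
into the lowest bins.

Tuning curves over head direction or theta phase use 12° bins,
occupancy-normalized; modulation depth is `(max − min)/max` of the bin
rates. The Rayleigh test runs on the spike angles themselves (the
occupancy-weighted bin-rate variant is available by argument); the
concentration $\kappa$ inverts the mean resultant length of the
occupancy-normalized bin rates (Fisher's piecewise inversion, capped at
500 for degenerate profiles). Classification: HD if Rayleigh $p < 0.005$
on direction **and** $\kappa \ge 1$; theta if $p < 0.005$ on phase **and**
depth $\ge 0.1$ (thresholds strict at the boundary); double qualifiers are
labelled HD by default (`precedence` flips it). The 12°-vs-30° bin-width
ambiguity in common practice is resolved in favour of 12° as the default
with the alternative one argument away.

## What the generator emulates — and what it does not

`generator_spec()` fixes the study conditions: 1250 Hz, speed schedule
cycling 5/12/20 cm/s in 10-s blocks (spanning the three bins), theta at
8 Hz with amplitude gain `1 + v/10`, three harmonics decaying by 0.5 with
phase offsets (0° ⇒ pure skewness, 90° ⇒ asymmetry), gamma as narrow-band
filtered noise (so bicoherence, not mere power, carries the coupling) with
envelope `1 + c·cos(theta phase)`, speed-gained amplitude and a
speed-crossfaded carrier for peak-frequency growth, a thalamic channel with
lagged theta and 10× lower gamma power, and HD/theta/untuned Poisson cells
whose modulation scales down with rate (depth–rate anticorrelation).
The theta instantaneous frequency wanders slowly (0.4 Hz scale) so window
phases decorrelate — without that, ensemble averaging would not mix phases
and bicoherence would be degenerate.

Deliberately absent: biophysics (conductances, spiking networks), ripples,
nonstationarity beyond the speed schedule, 60 Hz artifacts, electrode
drift, and volume conduction. Passing tests therefore demonstrate that the
estimators recover known injected structure under the model's assumptions —
not that real recordings satisfy those assumptions.

## Numerical choices

* `df` is computed as `fs/n` so integer-rate grids are exact (a 1250-point
  window at 1250 Hz has `df` identically 1).
* Bins whose normalization denominator is numerically zero (anything
  involving the de-meaned DC bin, or line spectra with empty triads such as
  a square wave's even harmonics) are masked `NA`, never 0/0 noise.
* The bispectral plane can be truncated at `max_freq` (default 110 Hz in
  the speed-binned driver) — DFTs always use the full window, so
  sum-frequency terms stay exact.
* Near-integer sampling rates inferred from time columns are snapped when
  the deviation is float noise, keeping frequency grids exact after I/O
  round trips.
* Monte-Carlo thresholds and all generators restore the caller's RNG state;
  every stochastic routine takes an explicit seed.

## Problem sizes used by the test suite

The suite simulates 120-s sessions (180 s for the 60-cell classification
run) at 1250 Hz, uses 64-point grids for the brute-force symmetry oracle,
and 2000 Monte-Carlo replicates for null calibration; the whole suite runs
in about a minute and a half on one core. These sizes are the package's
validation design: large enough that every monotonicity and recovery check
is stable under its fixed seed, small enough to run everywhere.

## Known limitations

* The overlap DOF correction is the standard rectangular-window
  approximation; exact effective DOF for bispectra under overlap is an open
  problem, so reported `dof` values are honest approximations.
* ROI sums grow with bin count; compare them only across conditions that
  share a grid and ROI (the attached `n_bins` makes the mean available).
* Cross-arrangements other than `ppq` (three distinct series) are computed
  with the octant-1+8 mask but lack the slot-swap symmetry; interpret with
  care.
* `restrict_to_epoch()` concatenates epochs before windowing; windows that
  would straddle an epoch boundary are simply absent, which slightly
  reduces the ensemble relative to a gap-aware segmenter.
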