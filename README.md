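# bicoh

Bispectral cross-frequency coupling analysis of local field potentials (LFP),
with speed-binned spectra, spike-train statistics, and a fully parameterized
synthetic generator for validating every estimator.

## The problem

During locomotion, the rodent hippocampal LFP is dominated by a ~8 Hz theta
rhythm whose amplitude grows with running speed, whose waveform is
nonsinusoidal (harmonics at 16, 24, 32 Hz), and whose phase modulates the
amplitude of the 60–120 Hz gamma band ("theta-modulated gamma"). Regions
connected to the hippocampus — notably the anterior thalamus — share theta
but carry roughly an order of magnitude less gamma power. Quantifying these
within- and cross-regional interactions requires statistics that are
sensitive to *phase* relations among frequency triads, not just power.

`bicoh` implements that analysis chain for anyone working with multi-channel
extracellular recordings: electrophysiologists studying cross-frequency
coupling, and methodologists who need a tested reference implementation of
higher-order spectral estimators.

## The statistic

LFP windows are treated as realizations of a stationary stochastic process.
With `P`, `Q`, `R` the DFTs of de-meaned windows of (up to) three series,
the package estimates the cross-spectrum and cross-bispectrum

    S(f_n)        = ⟨ P_n Q_n* ⟩
    B(f_m, f_n)   = ⟨ P_m Q_n R*_{m+n} ⟩

(⟨·⟩ = average over windows), and the normalized bicoherence

    b(f_m, f_n)   = B(f_m, f_n) / sqrt( ⟨|P_m Q_n|²⟩ ⟨|R_{m+n}|²⟩ )

whose modulus is bounded by 1 (Cauchy–Schwarz) and measures quadratic phase
coupling of the triad `(f_m, f_n, f_m + f_n)`; its argument is the biphase.
For a single channel, `Re b` reflects waveform skewness ("sawtooth"
peakedness) and `Im b` waveform asymmetry. Redundancy under the bispectral
symmetries reduces the plane to octant 1 (auto) or octants 1 + 8 (two-region
`ppq` arrangements), and coupling strength is summarized by summing `|b|`
over regions of interest: the theta–theta harmonic triangle, theta–gamma
trapezoids (sum and difference interactions), and the gamma–gamma triangle,
with bands theta = [4, 40] Hz and gamma = [42, 100] Hz.

Under a Gaussian null the significance level of `|b|` scales as
`1/sqrt(DOF)`; the package calibrates it by seeded Monte Carlo
(`significance_threshold()`).

## Worked example

```r
library(bicoh)
library(dplyr)

# two-region synthetic session: H (hippocampal-like), T (thalamic-like)
ses <- simulate_session(generator_spec(duration = 120), seed = 1)

# speed-binned power spectra: theta grows with running speed
psd_by_speed(ses$lfp, ses$trajectory, max_freq = 120) |>
  filter(region == "H", frequency >= 6, frequency <= 10) |>
  group_by(bin) |> summarise(theta_power = sum(power))
#>   bin   theta_power
#> 1 high       15503.
#> 2 low         4099.
#> 3 mid         8287.

# auto-bicoherence of the high-speed windows
segs <- segment_by_speed(ses$lfp, ses$trajectory)
ss   <- segs$segments[[which(segs$bin == "high" & segs$region == "H")]]
est  <- cross_bispectrum(ss, max_freq = 110)
glance(est)
#>   kind  arrangement n_segments   dof    df max_bicoherence significance_05
#> 1 auto  H-H-H               79  52.7     1           0.968           0.233

roi_coupling_strength(est, coupling_roi("theta_gamma_sum"))
#>   roi             strength n_bins   dof n_segments condition
#> 1 theta_gamma_sum     257.   2088  52.7         79 high

# head-direction / theta-phase cell classification, perfect on this session
phase <- theta_phase(filter(ses$lfp, region == "H"))
classify_cells(ses$spikes, ses$trajectory, phase) |> count(class)
#>   class     n
#> 1 HD       20
#> 2 other    20
#> 3 theta    20
```

Reading the numbers: theta-band power roughly quadruples from the low
(1–9 cm/s) to the high (>15 cm/s) speed bin, matching the generator's
speed gain. The high-speed bicoherence peaks near `|b| = 0.97` (the
theta–harmonic triads), far above the Monte-Carlo null level of 0.23 for
the 53 effective windows. The theta–gamma ROI sum (257 over 2088 bins)
is the scalar coupling statistic that `coupling_by_speed()` tabulates per
region pair, triad arrangement and speed bin. All 60 synthetic cells are
recovered into their ground-truth classes.

`autoplot()` methods exist for spectra, bicoherence planes, power
correlograms and tuning curves; `plot_psd_by_speed()` and
`plot_coupling_summary()` cover the speed-binned tables.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript inst/scripts/bicoh simulate --config sim.yaml --out session/ --seed 7
Rscript inst/scripts/bicoh coupling-summary --in session/ --out results/
```

Subcommands: `simulate`, `psd`, `bicoherence`, `cross-bicoherence`,
`powercorr`, `spike-psd`, `classify`, `coupling-summary`. Every analysis
parameter (bands, bins, window, overlap, seeds) lives in the YAML config;
identical config + seed reproduces outputs byte for byte.

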