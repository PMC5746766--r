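---
title: "From vibrational calculations to SERS classification of dopamine forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vibrational calculations to SERS classification of dopamine forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanforms)
```

## The problem

Dopamine at physiological concentrations (down to ~1e-11 molar) can be
detected label-free by surface-enhanced Raman spectroscopy (SERS) on silver
nanocolloids, but the recorded spectrum is not that of a single species: in
solution and on the metal surface dopamine occurs as the neutral molecule
(DA0), the cation (DA+), the anion (DA-), an internally charge-separated
zwitterion-like configuration (DA+/-), and its two-electron/two-proton
oxidation product dopaminequinone. Each form has its own vibrational
signature, and adsorption onto silver suppresses the strong free-dopamine
ring bands near 750 and 790 cm^-1. Deciding which forms a measured spectrum
supports therefore requires (i) turning quantum-chemical frequency
calculations into spectra that can be overlaid on measurements, (ii)
averaging enough short acquisitions to suppress SERS hot-spot fluctuation,
(iii) pairing calculated with measured band positions, and (iv) reading the
averaged spectrum against per-form marker bands. `ramanforms` implements
this pipeline end to end.

## Activity-to-intensity conversion

Quantum-chemistry codes report a Raman scattering *activity* S_i (A^4/amu)
per normal mode, not an observable intensity. The standard Stokes-branch
conversion is

$$ I_i \;=\; f\, S_i\, \frac{(\nu_0-\nu_i)^4}
   {\nu_i\left[1-\exp\!\left(-\dfrac{h c \nu_i}{k T}\right)\right]} $$

with $\nu_0$ the excitation wavenumber, $\nu_i$ the mode wavenumber, $T$ the
temperature and $f$ a normalization factor. The $(\nu_0-\nu_i)^4$ term is
the scattered-frequency dependence of Raman intensity; the bracket is the
thermal population of the vibrational ground state. `raman_intensity()`
evaluates exactly this expression; $h$, $c$ and $k$ enter only through the
second radiation constant $hc/k$, fixed at its CODATA value 1.4387769 cm K.
All other arithmetic is full double precision.

Defaults (all overridable through `intensity_params()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `excitation_wavenumber` | 1e7/532 = 18,796.99 | cm^-1 | 532 nm frequency-doubled Nd:YAG excitation |
| `temperature` | 293.15 | K | ambient acquisition |
| `norm_factor` | 1e-12 | — | keeps intensities O(1e3-1e5) for typical activities |
| `scale_factor` | 0.98 | — | uniform harmonic-frequency correction (see below) |
| `fwhm` | 7 | cm^-1 | Lorentzian band width typical of these measurements |

The domain is restricted to $0 < \nu_i < \nu_0$: the Boltzmann bracket is
singular at 0 and the anti-Stokes branch is deliberately not modeled.

## Frequency scaling and line-shape synthesis

Harmonic DFT frequencies systematically overestimate observed positions, and
a single multiplicative factor (0.98 here) is the conventional correction.
Because the error is in the *position*, `synthesize_spectrum()` applies the
factor only where positions matter — band placement on the grid — while the
intensity conversion uses the unscaled $\nu_i$. Each line is a **unit-area**
Lorentzian ($\gamma$ = fwhm/2), so a line integrates to $I_i$ and total
scattered intensity is conserved; the alternative unit-height convention
would make tall narrow lines under-weighted in any area-based comparison.
The default grid is 200-1800 cm^-1 at 1 cm^-1 (the fingerprint window
displayed in this kind of study); modes farther than 10 fwhm outside the
grid are skipped as numerically irrelevant, and a table whose modes all fall
outside yields a zero spectrum with a warning rather than an error.
Whether a spectrum was additionally max-normalized is recorded in
`meta$normalized` (`normalize_max = FALSE` by default, since the conversion
already carries the explicit factor $f$).

## Reading mode tables and experimental spectra

`read_mode_table()` parses the classic three-modes-per-block frequency log
layout (`Frequencies --` lines paired with `Raman Activ --` lines); when a
log contains several frequency jobs, the last complete one wins, and a
frequency line with no matching activity line is a parse error that names
its line number. Imaginary frequencies are retained and flagged so that
failed optimizations stay visible. The TSV dialect round-trips tables at
full precision (17 significant digits).

`read_spectrum()` accepts two-column text with any of comma, tab or
whitespace separators, averages exact duplicate wavenumbers, and resamples
non-uniform grids by linear interpolation onto the median spacing — the
minimal-assumption choice — flagging the resampling in the metadata.
`average_series()` takes the plain pointwise mean over every spectrum of
every series, on raw intensities: per-spot normalization before averaging is
possible (`normalize_spectrum()`) but off by default, because the averaging
step exists precisely to let random spot-to-spot intensity fluctuations
cancel. The default baseline treatment is `none`; `rolling_min` and an
iteratively reweighted polynomial fit are available for data that need them.

## Peak detection and matching

`detect_peaks()` keeps local maxima with topographic prominence at least
`min_prominence_frac` (default 0.02) of the spectrum maximum, at least
`min_separation` (default 10 cm^-1) apart, refining each position by a
parabola through the three samples around the maximum — exact for a
symmetric peak sampled near its apex, which is why it was preferred over
centroiding. A flat spectrum returns an empty peak list, not an error.

`match_peaks()` pairs two position lists one-to-one, first maximizing the
number of pairs within the tolerance and then minimizing the total absolute
residual. For sorted lists under an absolute-difference cost an optimal
pairing is non-crossing, so the exact optimum is found by dynamic
programming over the two sorted lists (ties broken towards pairing lower
wavenumbers, making the result deterministic). The default tolerance of
20 cm^-1 sits well above the observed scaled-theory-versus-experiment
discrepancies (largest reference residual: 16 cm^-1) and below the spacing
at which distinct bands could cross-pair. `discrepancy_stats()` reports the
mean and sample standard deviation of |residual| over matched pairs only —
the averaging set is not prescribed anywhere, so this choice is explicit and
the tolerance is configurable. The packaged reference table
(`dopamine_band_table()`) carries positions but no activities (none are
published), so `dopamine_calc_modes()` attaches uniform unit activities:
positions, not intensities, are the reference surface.

## Marker-band profiles and scoring

`builtin_profiles()` encodes the presence/absence logic for the five forms
with +/-10 cm^-1 windows (the same scale as the theory/experiment
discrepancy): quinone requires 950/1360/1510, the anion 1160/1290/1530, the
zwitterion-like form 1280/1640 — each of these *forbidding* the
free-dopamine 750/790 bands, since these forms are observed adsorbed — while
DA0 and DA+ require 750/790 and are explicitly flagged as indistinguishable
by these markers alone. The score

$$ \text{score} = \frac{\text{required found}}{\text{required total}}
   \cdot \max\!\left(0,\, 1-\frac{\text{forbidden found}}{\text{forbidden total}}\right) $$

is a package convention that quantifies an otherwise qualitative reading; it
is isolated in `score_form()` so alternatives can be swapped in, uses
uniform band weights (no basis exists for differential weighting), and is
monotone in the evidence: a peak added inside a required window never lowers
the score, one added inside a forbidden window never raises it.
`classify_spectrum()` ranks forms by score with ties broken in the fixed
prevalence order quinone, DA-, DA+/-, DA0, DA+, so the ranking is
deterministic and independent of the order in which profiles are supplied,
and raises an explicit flag whenever peaks occupy the 750/790 windows
(multilayer neutral or cationic dopamine suspected).

## What the synthetic generator emulates — and what it does not

`generate_mode_table()` returns each form's published band positions
(the 19 calculated bands of neutral dopamine; the eight dominant
free-molecule bands of the anion and cation; the quinone and zwitterion-like
marker sets) with activities drawn log-uniformly in [1, 100]. The activities
are synthetic by construction and never serve as an accuracy target; only
positions carry ground truth. Positions are on the observed scale, so
`generate_sers_series()` synthesizes with scale factor 1.

`generate_sers_series()` models a multi-spot acquisition as
`jitter * clean + baseline + noise`: a per-spectrum lognormal factor of unit
mean (sdlog 0.2 by default — the simplest model of the large spot-to-spot
hot-spot fluctuation that averaging exists to suppress), i.i.d. additive
Gaussian noise (default 5% of the clean maximum, resolved at generation
time), an optional linear background (default slope 0, matching the
no-baseline-correction default of the experimental pipeline), and clipping
at zero to respect the non-negativity invariant of spectra. All draws come
sequentially from one generator seeded by `noise$seed`, so output is
bitwise reproducible; base R offers no splittable generator, and a single
sequential stream gives the same guarantee. The default scheme is 8 series
of 50 spectra of 0.2 s — 400 spectra total.

Ground truth is defined as the peaks of the *clean* spectrum with
prominence at least 5% of its maximum (`truth_prominence_frac`), while
detection defaults to a 2% threshold. The gap is deliberate hysteresis: a
band that barely counts as a clean reference peak is still found comfortably
in the 400-spectrum average (whose noise floor is ~20x below a single
spectrum's), so recovery does not teeter on a knife edge, and with random
log-uniform activities a mode can legitimately be too weak to constitute a
peak at all.

What the generator does **not** emulate: wavenumber calibration drift,
cosmic-ray spikes, detector nonlinearity, the strongly structured
fluorescence background of real SERS substrates, chemical-enhancement
selectivity (which reweights mode intensities on the metal), or correlated
noise between neighbouring pixels. Tests passing on these simulations
therefore validate the pipeline's logic — averaging, detection, matching,
classification — not its robustness to every artifact of real instruments.

A known consequence of faithful inputs: the free-molecule anion table
retains its strong 750/780 cm^-1 ring bands, which the anion's own
*adsorbed-form* profile forbids. A zero-noise spectrum generated from that
full table is therefore not self-classified as the anion — it triggers the
multilayer/cationic flag instead — whereas spectra built from any form's
marker set alone are correctly top-ranked (with the documented DA0/DA+
tie). The tests assert both behaviours.

## Numerical choices and degenerate inputs

* Matching DP is exact, O(n·m); tie-breaking is lexicographic (pairs, cost,
  lower wavenumber), so results are reproducible across platforms.
* Half-maximum widths are measured by linear interpolation between the
  bracketing grid samples.
* Zero-pair match tables make `discrepancy_stats()` an error (undefined
  statistic), an all-zero spectrum refuses `max`/`area` normalization, an
  empty mode table refuses synthesis, and profiles reject overlapping
  required/forbidden windows and non-positive tolerances at construction.
* Duplicate wavenumbers on input are averaged before gridding; plateau
  maxima are reported once, at the leftmost plateau sample, and parabolic
  refinement falls back to the grid point when the three-point stencil is
  not curved downward.

## Problem sizes

The validation suite and the reproduction script use the full reference
acquisition scheme (8 x 50 = 400 spectra on a 1601-point grid), 1,000-draw
oracle comparisons for the intensity conversion, and 100-trial matching
recovery runs; all complete in seconds on one CPU, so nothing is scaled
down from the conditions described above.

## Limitations

Beyond the generator's simplifications listed earlier: the classifier
cannot separate DA0 from DA+ (shared markers) and does not attempt mixture
unmixing or concentration estimates — with overlapping signatures such as
1280/1290 cm^-1 and variable band widths, a reliable numerical estimate of
form contributions is not obtainable from marker logic alone. Anti-Stokes
intensities, resonance-Raman corrections, depolarization ratios and
overtone/combination bands are out of scope, as is any modelling of the
electromagnetic or chemical SERS enhancement itself.
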