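---
title: "Methods: from blinking frames to HER2/CEP17 classification"
author: "fishquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from blinking frames to HER2/CEP17 classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Dual-probe fluorescence in situ hybridization (FISH) scores HER2 gene
amplification in breast-cancer tissue by counting HER2 and CEP17
(chromosome-17 centromere) probe signals per nucleus. At conventional
(diffraction-limited) resolution, amplified loci blur into clusters,
faint CEP17 signals drown in tissue autofluorescence, and observers can
only call such nuclei "more than four signals". Single-molecule
localization microscopy (SMLM) sidesteps the diffraction limit: over
thousands of short exposures individual fluorophores blink on and off,
each blink is fitted with a sub-pixel Gaussian, and the accumulated
localizations render an image with roughly 20-nm structure.

`fishquant` implements the complete processing chain — acquisition
simulation, stack I/O, blind-spot denoising, background subtraction and
regression-based thresholding, localization, rendering, per-nucleus
counting, ASCO/CAP 2018 group classification, and paired
conventional-vs-super-resolution statistics — as a tested toolkit. A
synthetic acquisition generator with full ground truth replaces the
microscope, so every stage is verifiable end to end.

# The acquisition model

`simulate_field()` draws non-overlapping elliptical nuclei in a square
field and places FISH loci inside them. Each locus carries
`emitters_per_signal` fluorophores (default 8) spread so that about 95%
fall within `signal_extent_nm` (default 80 nm, i.e. a Gaussian with
sd = extent/4). Blinking is i.i.d. Bernoulli per frame at `p_on`
(default 0.005) — the simplest model of autonomous photoswitching, with
no dark-state memory — and each on-event emits `Poisson(mean_photons)`
photons (default 1500; the narrow Poisson spread keeps per-event
detectability uniform, which is what matters for counting). A frame is
the sum of an autofluorescence background field (a smooth Gaussian
random field of marginal SD `background_amplitude` over a constant
offset, clipped at zero), the active emitters' PSFs integrated over
pixels (symmetric Gaussian, sigma 130 nm), Poisson shot noise, and
Gaussian read noise, rounded to 16-bit camera units.

Acquisition-protocol defaults mirror the targeted instrument workflow:
5000 frames per signal channel, 1000 DAPI frames, 30 ms exposure. The
camera pitch is not part of that protocol; 100 nm/px is assumed,
consistent with a 100x/1.4 oil objective. Desk-scale choices, stated
once and used throughout: a 64-px (6.4 µm) field with 5 nuclei of
0.7–1.0 µm radius — miniature nuclei, so that a full 5000-frame field
simulates in seconds; background offset 100, amplitude 20, correlation
length 8 px, read noise 3 ADU, gain 1 ADU/photon.

Two extras support the comparison studies. A `cluster_fraction` of
nuclei receives one unresolvable cluster locus: `cluster_signals` (> 4)
signals co-located within `signal_extent_nm`, the fixture for the
"more than four signals" ambiguity rule. And each signal channel also
gets a *conventional-exposure snapshot*: one frame with every
fluorophore emitting at once, which is what a routine fluorescence
microscope records before any photoswitching. A mean projection of the
blinking stack is *not* that image — it is dimmer by roughly the duty
cycle — so the conventional-resolution pipeline uses the snapshot when
present and falls back to the projection otherwise.

What the generator does not emulate: stage drift, chromatic aberration,
3-D defocus and tiling, dark-state kinetics, and the section-thickness
effects of real FFPE tissue. Passing the recovery suites therefore
demonstrates the pipeline's internal consistency at realistic SNR, not
performance on clinical slides.

# Denoising: the blind-spot principle at desk scale

The production workflow trains a deep self-supervised denoiser on
thousands of frames. The principle that makes that possible — predict
each pixel from its neighborhood *excluding the pixel itself*, so that
pixel-independent noise cannot be learned — is implemented here with
two transparent predictors behind the same interface
(`train_blindspot()`): a masked-neighborhood median and a linear
regression on the masked neighborhood fitted by least squares. Both
preserve the self-supervision contract; a convolutional backend could
replace them without touching the rest of the pipeline. Training
defaults (50 frames or fewer, radius 2, 2% masked pixels) are
deliberately small; the denoiser is optional in the localization path
because the simulated SNR does not require it.

# Background, thresholds, and the two calibration regimes

`rolling_ball_background()` estimates background as the grayscale
opening with a flat disk (radius 15 px by default), the standard
approximation of the rolling-ball filter; opening is idempotent and
never exceeds the image. The implementation is deliberately the
textbook definition (erosion then dilation, out-of-bounds neighbors
ignored) and the test suite pins it against an exhaustive brute-force
oracle.

Detection thresholds come from a linear regression of the *optimum*
threshold on an image's mean and standard deviation
(`fit_threshold_model()` / `estimate_threshold()`), emulating a preset
model that thresholds new images from their summary statistics alone.
"Optimum" is operationalized as the threshold maximizing the F1 score
of `pixel > tau` against the simulator's true signal mask — instrument
workflows leave the criterion unstated, and F1 is reproducible,
monotone in SNR, and compatible with the linear mean/SD structure the
regression assumes. Two calibration regimes
matter in practice:

* **Statistics regime** (`calibrate_threshold_model()` defaults): raw
  frames spanning a wide range of background levels, permissive signal
  mask (20% of peak). The fitted-vs-optimum correlation is dominated by
  the autofluorescence level and routinely exceeds 0.95 — this is the
  regime in which a preset regression is a sensible instrument-side
  tool.
* **Detection regime** (`detection_threshold_model()`): frames
  background-subtracted exactly as the localization loop will subtract
  them (rolling ball, radius 4), sparse active emitters, conservative
  core mask (50% of peak). Predicted thresholds then sit above the
  shot-noise maxima. This matters because threshold errors are
  asymmetric: a few ADU too low floods 5000 frames with noise maxima
  that later percolate into spurious localization clusters.

The subtraction radius also deserves a note: the rolling-ball radius
must exceed the PSF spot width (so spots are excluded from the
background estimate) and stay below the autofluorescence correlation
scale (so the background itself is captured). With 100-nm pixels, a
130-nm PSF and an 8-px background correlation length, radius 4
satisfies both; the classic radius 15 suits the brighter, coarser
conventional-exposure images, where it is the default.

# Localization and rendering

Per frame, candidates are 8-connectivity local maxima above the
predicted threshold, with maxima closer than 2 px merged into the
brighter one. Each candidate is fitted with a symmetric 2-D Gaussian
(amplitude, center, sigma, offset) by a damped Levenberg–Marquardt
least-squares iteration (at most 100 iterations, relative tolerance
1e-8) seeded from the window centroid. Fits are rejected when they do
not converge, leave the window, have non-positive amplitude, or return
a sigma outside 0.5–4 times the expected PSF sigma — the last rule is
the main guard against shot-noise spikes, which fit as implausibly
narrow "spots". Photons are `amplitude * 2 * pi * sigma_px^2 / gain` and
the localization uncertainty is the Thompson-style `sigma / sqrt(N)`.

`render_superres()` accumulates localizations on a 20-nm grid, either
as a count histogram (sum exactly equals the localization count) or as
unit-mass Gaussians of width equal to each localization's uncertainty
(sum equal up to edge losses). At the default photon budget the
per-localization precision is a few nanometres, so a 150-nm doublet
that is a single blob in the widefield image splits cleanly in the
rendering.

# From localizations to counts

Nuclei are segmented from the DAPI projection by smoothing (sigma 1 px
— the image is already diffraction-blurred, so heavier smoothing only
distorts boundaries), Otsu thresholding, hole filling and a
distance-transform watershed, with an area filter (40 px minimum).

Localizations are clustered into signals by single-linkage connected
components at `eps_nm = 150` (about the resolvable separation) with at
least `min_pts = 3` members. Two safeguards keep single-linkage honest.
First, the pipeline applies standard SMLM post-fit filtering
(`filter_localizations()`): localizations with fitted sigma outside
0.75–1.3 times the PSF sigma or photons below a quarter of the median
are discarded. These are not single-emitter fits — they arise from
residual background structure or from frames in which emitters of two
*neighbouring* loci are active simultaneously, whose merged fits land
between the loci and would otherwise act as stepping stones that chain
two distinct signals hundreds of nanometres apart into one component.
Second, components weaker than a quarter of the single-signal reference
strength are dropped: a genuine locus blinks throughout the whole
acquisition (about 200 localizations at the defaults), so a component
of a handful of localizations is a noise coincidence, not a locus. A
signal's spatial extent is reported as a robust RMS radius (1.2 times
the median distance to the centroid — the RMS radius of a 2-D Gaussian
cloud, insensitive to the few artifact fits that survive filtering).

Counting follows the field's reading rules. The reference strength of a
single signal is the median over the sample's isolated signals
(operationalized as signals no stronger than 2.5 times the overall
median, which keeps amplification clusters out of the reference). Every
signal is assigned `round(strength / reference)` copies, floored at 1.
A signal implying more than four copies whose spatial extent exceeds
`isolation_extent_nm` cannot be resolved into individual signals: it is
flagged ambiguous and recorded as "more than four" (count 5 with the
flag). The extent threshold is mode-specific by design: 120 nm — just
under the PSF sigma — in the super-resolution path, where genuine
multi-signal clusters span tens of nanometres and are therefore
*countable*; 0 in the conventional path, where any >4-copy spot is by
construction diffraction-blurred. This reproduces the defining
asymmetry of the two readouts: conventional images leave clustered
nuclei ambiguous, super-resolution images leave none.

Signals are assigned to the nucleus whose mask contains their centroid;
signals outside every nucleus are dropped and tallied. Per-nucleus
totals `H` and `C` feed the nine sample-level metrics: nuclei with
(non-ambiguous) HER2 signals, nuclei with ambiguous HER2 signals, total
HER2 signals and HER2 signals per nucleus over the countable nuclei,
the same four for CEP17, and the HER2/CEP17 ratio computed over the
nuclei in which CEP17 is countable (at least one CEP17 signal, none
ambiguous). Ambiguous nuclei are reported in their own tally and enter
neither the totals nor the per-nucleus means — the reading convention
leaves the denominator unstated, and keeping "more than four"
placeholders out of means avoids biasing them low.

# Classification and statistics

`assign_group()` is the 2018 ASCO/CAP dual-probe partition: Group 1
(ratio >= 2, >= 4 HER2/cell), Group 2 (ratio >= 2, < 4; the historical
"monosomy" pattern), Group 3 (ratio < 2, >= 6), Group 4 (ratio < 2,
4 to < 6), Group 5 (ratio < 2, < 4). The guideline's overlapping 3/4
boundary at 6.0 is resolved as Group 4 = [4, 6) so the five regions
tile the plane disjointly — verified exhaustively on a grid. Group 1 is
ISH-positive, Group 5 ISH-negative, Groups 2–4 are adjudicated by the
IHC score (0/1+ negative, 3+ positive, 2+ resolved by the guideline's
concurrent-review outcome and flagged `guideline_default`).

The comparison module provides the three tests the cohort analyses
need, with exact small-sample behavior: a paired Wilcoxon signed-rank
test (zeros dropped, midrank ties; exact p for up to 25 non-zero pairs
via the sign-pattern distribution, tie-corrected normal approximation
beyond), a Mann–Whitney U test (exact by enumeration up to 12
observations), and Pearson's chi-squared *without* continuity
correction — the convention that reproduces the reference cohort
tables' printed p-values, which a Yates-corrected test does not. All
tests are two-sided; p < 0.05 is carried as the significance
convention in reports. `cohort_report()` assembles median (min, max)
summaries per metric, resolution and routine-status stratum, the paired
p-values, and the cross-resolution contingency table of group calls.

# Numerical choices and degenerate inputs

* Coordinates are continuous nanometres; pixel `(i, j)` (0-based) spans
  `[j*p, (j+1)*p) x [i*p, (i+1)*p)`, x rightward, y downward. Rendering,
  clustering and mask assignment all use this convention, so a global
  coordinate rescaling leaves counts invariant (tested).
* The F1-threshold search scans the image's unique intensities and
  breaks ties toward the smaller threshold; thresholding is strict
  (`> tau` survives).
* `apply_threshold`, subtraction and denoising all clip at zero;
  stack writing refuses negatives and the 16-bit range is enforced.
* Degenerate inputs are errors with typed condition classes: all-zero
  paired differences (`fq_degenerate`), zero chi-squared margins,
  collinear threshold calibrations (`fq_rank`), empty truth masks,
  missing IHC for groups 2–4 (`fq_incomplete`). An all-background DAPI
  image yields an empty nucleus map, not an error; an undefined ratio
  (no countable CEP17) is reported as `NA` with a reason string.
* Simulations are deterministic given `seed`; nucleus placement uses
  rejection sampling with restarts and fails loudly if the field
  cannot hold the requested nuclei.

# Problem sizes used by the test suite

The verification suites run at the full acquisition length (5000-frame
channels): 20 default fields for count recovery (at least 90% of nuclei
exactly recovered in both channels), 10 cluster-bearing samples for the
conventional-vs-super-resolution direction (super-resolution HER2 per
nucleus higher in every sample; paired signed-rank p < 0.05; zero
ambiguous super-resolution signals vs at least one conventional),
200-replicate Monte-Carlo localization precision (RMSE < 20 nm at 5000
photons, halving when photons quadruple), 200 random images against the
brute-force opening oracle, and 20-image threshold calibrations
(r > 0.95 in the statistics regime). Known limitations: counts are 2-D
(no 3-D nucleus segmentation), observer variability is out of scope,
and the conventional-path intensity calibration assumes spots of
comparable per-signal brightness within a sample.
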