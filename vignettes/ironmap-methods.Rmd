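---
title: "Models and methods behind ironmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ironmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmap)
```

# The problem

Molecular cardiac MRI with antibody-functionalized iron-oxide microparticles
(MPIO) detects inflammation markers such as P-selectin by the strong local
field distortions the particles induce: bound iron shortens T2\*, i.e.
raises the effective transverse relaxation rate R2\* = 1/T2\*. The analysis
chain that turns image series into biology-facing numbers has several
stages — pixel-wise relaxometry, territory-level difference statistics, a
histogram-tail counting statistic for ex vivo maps, and a set of microscopy
and binding-assay quantifiers. ironmap implements that chain as tested,
seeded, reusable code, together with a digital phantom that generates every
input with known ground truth.

# Signal models and the phantom

## Geometry

`make_phantom()` builds a left-ventricular short-axis ring (inner/outer
radii 0.22/0.42 of the in-plane grid size; configurable) partitioned into
three contiguous 120° angular sectors standing for the LCX, LAD and RCA
coronary territories. No consensus geometry exists for territory borders,
so equal sectors are the default and both the sector rotation and the ring
radii are free parameters. A third grid dimension replicates the ring over
slices for 3D (ex vivo) use. Coordinates are pixel-centred and 0-based.

Tissue parameters default to healthy myocardium at 3 T: S0 = 100 (arbitrary
signal units), T1 = 1200 ms, T2 = 45 ms, R2\* = 33.3 s⁻¹ (T2\* = 30 ms).
Maps are piecewise-constant by default; optional within-tissue variation is
a Gaussian-smoothed random field (zero mean, user-set SD), which keeps the
pixel-value distribution approximately normal — the regime the ex vivo
Gaussian-tail statistic assumes. MPIO deposition adds `mpio_delta_r2star`
(s⁻¹) to R2\* inside the lesion territory; `mpio_fraction < 1` restricts the
increment to a random subset of lesion pixels, modelling the patchy, focal
binding seen ex vivo. A slowly varying macroscopic field-offset map (an R2′
term entering the multi-echo decay only) models susceptibility gradients; it
is identical pre/post contrast, which is exactly why the ΔR2\* statistic
works.

## Acquisition models

`simulate_series()` evaluates, per pixel (times in ms, rates in s⁻¹):

* multi-echo gradient echo: S(TE) = S0 · exp(−TE/1000 · (R2\* + field offset)),
  at the four-echo in vivo schedule TE = 2.4/6.0/9.5/13.0 ms or the
  three-echo ex vivo schedule TE = 3.4/9.8/17.1 ms;
* inversion recovery: S(TI) = |S0 (1 − 2 e^(−TI/T1))|, default eight TIs
  spanning 100–4500 ms;
* T2 preparation: S(τ) = S0 · e^(−τ/T2), τ = 0/30/40 ms.

Noise is Rician, as on vendor magnitude images: independent N(0, σ²) on two
complex channels, then the modulus. σ = 0 returns exact model values, which
the round-trip tests rely on. Background (S0 = 0) pixels therefore show the
Rayleigh floor with mean σ√(π/2).

The phantom deliberately omits cardiac/respiratory motion, coil
sensitivities, bSSFP banding/off-resonance readout effects and partial
volume. Passing tests consequently demonstrate the correctness of the
estimators under the stated signal models, not robustness to those
real-data effects; in particular the vendor's inline motion correction has
no counterpart here and pre/post maps are perfectly co-registered by
construction, which mirrors the method's own assumption.

# Relaxometry

`fit_t2star()` is the study's core fit: per pixel, ordinary least squares
of ln S against TE; R2\* = −slope (converted to s⁻¹), ln S0 = intercept,
quality = R² of the line. Decisions worth spelling out:

* **Unweighted by default.** The reference method is a plain linear fit of
  the log-signal; a signal²-weighted variant (the first-order variance
  stabilization of the log transform) is available via `weighted = TRUE`
  for comparison.
* **Echo exclusion, not clipping.** Echoes with S ≤ `min_signal` are
  dropped per pixel; ln of a clipped value would bias the slope. The
  default floor is 3× the background σ estimated from the four image-corner
  patches via the Rayleigh mean relation — this keeps Rician-floor echoes
  out of the fit.
* **Validity over clamping.** Pixels with fewer than two usable echoes or a
  non-positive fitted R2\* are marked invalid rather than clamped; invalid
  pixels carry NA values and propagate through every downstream statistic.
* **Saturated fits.** With exactly two usable points the line has zero
  residual degrees of freedom and R² = 1 by construction; such pixels
  report quality 0, since the number carries no goodness information. This
  is what guarantees that background pixels which cross the signal floor by
  chance are never silently trusted.

`fit_t2prep()` reuses the same log-linear machinery (T2 = −1/slope).

`fit_t1_ir()` fits the magnitude IR model by nonlinear least squares. The
magnitude operation discards polarity, so for each candidate polarity
restoration point k the first k samples (in TI order) are negated; for
fixed T1 the amplitude has a closed form, which reduces the problem to a
1-D profile over T1. That profile is minimized on a 120-point log-spaced
grid (50–6000 ms) vectorized across pixels, then refined per pixel by
golden-section search, also over the neighbouring polarity candidates —
near the signal null the coarse grid can pick k off by one. The
three-parameter apparent-T1 model |A − B e^(−TI/T1\*)| with
T1 = T1\*(B/A − 1) is available via `model = "ir3"` for readouts that
perturb the recovery; with ideal IR data (B/A = 2) both models coincide.
Non-convergent or degenerate pixels (negative amplitude, all-zero signal)
become invalid pixels, never errors.

All fits sort the series by acquisition time internally, so estimates are
invariant to echo ordering.

# Territory statistics

`delta_r2star()` reports, per territory, the difference of mean R2\* over
the intersection of the pre and post validity masks. Both the macroscopic
field offset and any reperfusion-related R2\* elevation are identical at
the two time points, so the difference isolates the contrast agent. Slice
lists (basal/mid/apical) are pooled per territory before averaging.

`exvivo_count_ratio()` implements the histogram-tail statistic: fit
a · exp(−(x−μ)²/(2σ²)) to the bin counts of the whole-myocardium R2\*
histogram (lesion pixels included), threshold at μ + 2σ, count strictly
greater pixels per territory, normalize by the territory's valid-pixel
count, and take the lesion/reference ratio. Numerical choices:

* **Binning**: Freedman–Diaconis by default, configurable fixed bin count;
  no binning rule is canonical for this statistic.
* **Fit to bin counts, not moments.** The Gaussian is fitted to the
  histogram by Levenberg–Marquardt (`minpack.lm`), initialized at the
  sample moments; the moments are the obvious alternative but the histogram
  fit is the operation this statistic is defined by. A numerically constant
  sample (noiseless piecewise-constant phantom) makes the histogram a
  single spike; that degenerate case short-circuits to μ = the common
  value, σ = the sample SD (≈ 0), so the zero-variation invariant (empty
  tail) holds exactly.
* **Strict threshold** (`>`), and area = valid-pixel count — any physical
  voxel volume cancels in the ratio.
* A failed or singular fit raises an error carrying the histogram for
  inspection rather than returning numbers.

`compare_groups()` delegates to `wilcox.test` (normal approximation with
tie correction; identical groups give p = 1), `t.test`, and
`aov` + pairwise t tests with Bonferroni adjustment (p × number of
comparisons, capped at 1).

# Microscopy quantifiers

**Threshold calibration.** The red-channel (P-selectin) threshold is the
0.95 quantile of the pooled nonzero red intensities of the remote control
sections — one global threshold per experiment. The quantile uses linear
interpolation of the empirical CDF (`type = 4`), the convention under which
pooled values 1…100 give exactly 95 and a strict cut leaves at most
5% + one quantile step of remote signal. Both the convention and the strict
inequality are fixed choices where "approximately 95%" leaves room.

**Coverage.** Tissue = green autofluorescence above an Otsu threshold
(configurable fixed value); coverage = positive-for-both / tissue pixels.
With supra- and sub-threshold intensity distributions separated by ≥ 4σ the
synthetic generator's coverage is recovered to well under 0.02 absolute;
the residual bias is the ~5% of sub-threshold speckle that survives the
cut.

**Spot counting.** Dark particles on a bright background: invert, subtract
a median-filter background (window ≈ 4 radii), threshold the residual at
median + 8 MAD — a robust rule that makes counts invariant to global
intensity scaling — then connected components filtered to an area band
(0.3–3× the expected spot area). `split_touching = TRUE` separates touching
particles by a distance-transform watershed; off by default, and the merged
behaviour is the documented one.

**Incubation proximity rule.** A particle is bound if it lies on top of or
exactly next to a cell; operationally, its centre falls inside the cell
mask dilated by one particle radius (the default adjacency radius — the
phrase has no metric definition, so the radius is explicit and tunable).
Implemented with a Euclidean distance transform; the tests verify it
against a brute-force pairwise-distance oracle.

# Flow-chamber dwell-time rule

A particle counts as bound if it adheres for at least 10 s within the 60 s
observation of a 450 × 350 µm field. Tracking only provides positions, so
"adheres" is operationalized as: the longest interval during which every
sample stays within `stationary_radius` (default 2 µm, about two particle
diameters) of the interval's first position. Anchoring to the first
position (rather than the interval diameter) is simpler and makes the rule
monotone: lowering `min_dwell` can only bind more tracks. Timestamps are
taken relative to the recording start, so a constant time shift changes
nothing; tracks still stationary when the window ends count their observed
dwell.

# Pipeline, determinism and problem sizes

`run_invivo()` simulates pre/post series over three short-axis slices
(default 64×64, 1.4 mm pixels, σ = 2 on S0 = 100, i.e. 2% relative noise,
40 s⁻¹ LCX increment), fits R2\*, and reports pooled per-territory ΔR2\*.
`run_exvivo()` uses a 72×72×12 phantom at 0.58 mm with smooth R2\*
variation (SD 4 s⁻¹) and patchy deposition (+25 s⁻¹ on 30% of LCX pixels) —
a desk-scale stand-in for a whole-heart high-resolution acquisition that
preserves the statistic's regime (thousands of pixels per territory).

Every stochastic step takes an explicit seed; child seeds are derived
deterministically from the master seed, and rerunning any command with the
same configuration reproduces every output file byte-identically (the
manifest lists each artifact with its MD5). The Monte-Carlo checks in the
test suite use 10⁴ pixels for the R2\* and T2 noise characterizations,
2.5×10³ for T1 (whose per-pixel refinement is the slowest step), 20
replicate phantoms for ΔR2\* recovery and 50 for the count-ratio null —
sizes chosen to make sampling error comfortably smaller than the tolerances
they check.

# Known limitations

* The estimators are validated against the stated signal models; motion,
  misregistration between pre and post maps, B0/B1 effects and
  multi-compartment decay are out of scope. With real data, pre/post
  misregistration translates directly into ΔR2\* error.
* The log-linear R2\* fit is biased at low SNR even with echo exclusion
  (the Rician floor lifts late echoes); at the 2% noise level used here the
  bias is well below the reported tolerances, and it largely cancels in the
  pre/post difference.
* The count-ratio statistic assumes the bulk of the myocardium is
  approximately Gaussian in R2\*; widespread (rather than focal) deposition
  makes the histogram bimodal and the fitted σ meaningless — the motivation
  for `mpio_fraction` in the generator.
* The microscopy operators assume reasonably separated intensity
  distributions and thresholdable tissue; stitching, illumination
  correction and true cell segmentation are not provided.
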