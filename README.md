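# ironmap

Quantification toolbox for iron-sensitive molecular cardiac MRI of
ischemia/reperfusion (I/R) injury, built around antibody-functionalized
microparticles of iron oxide (MPIO) targeting P-selectin. The package covers
the full desk-side analysis chain of such a study — from simulated image
data to territory-level statistics — together with the accompanying
microscopy and flow-chamber read-outs.

It is aimed at researchers developing or validating relaxometry-based
molecular imaging pipelines who need a reproducible, fully synthetic test
bed: every input the analysis consumes can be generated by the package
itself, with known ground truth and seeded randomness.

## What it computes

**Pixel-wise relaxometry.** Multi-echo magnitude images follow
S(TE) = S0 · exp(−TE · R2\*); `fit_t2star()` estimates R2\* per pixel by
ordinary least squares on ln S vs TE (R2\* = −slope), with low-SNR echoes
excluded and a per-pixel R² quality map. `fit_t1_ir()` fits the magnitude
inversion-recovery model |A(1 − 2e^(−TI/T1))| (optionally the apparent-T1
form |A − B·e^(−TI/T1\*)| with T1 = T1\*(B/A − 1)), restoring the signal
polarity lost by the magnitude operation. `fit_t2prep()` fits
S(τ) = S0 · e^(−τ/T2) over T2-preparation times. `invert_map()` converts
T2\*[ms] ↔ R2\*[s⁻¹] = 1000/T2\*.

**Territory statistics.** ΔR2\* = mean R2\*(post-injection) − mean
R2\*(pre-injection) per coronary territory (LCX = lesion, LAD = perfused
control, RCA = non-perfused control) isolates the contrast deposition,
since macroscopic field inhomogeneity cancels in the difference. The ex
vivo statistic fits a normal distribution N(μ, σ²) to the histogram of R2\*
over the whole LV myocardium, counts pixels strictly above μ + 2σ in lesion
and reference territories, normalizes by territory area, and reports the
count ratio (≈1 without deposition, >1 with).

**Microscopy and binding assays.** Immunofluorescence coverage = (pixels
positive for both P-selectin and tissue autofluorescence) / (all
autofluorescence-positive pixels), with the red-channel threshold
calibrated on remote sections to eliminate 95% of nonzero signal. Spot
counting per high-power field (dark-particle detection via background
subtraction + connected components), the proximity rule for incubation
assays (a particle is bound if it touches or overlaps a cell), and the
flow-chamber dwell-time rule (bound ⇔ stationary ≥ 10 s within a 60 s
observation of a 450 × 350 µm field).

**Digital phantom.** `make_phantom()` builds a ring-shaped LV with three
120° coronary territories and ground-truth S0/T1/T2/R2\* maps;
`simulate_series()` renders magnitude image series at the study's
acquisition schedules with Rician noise. Generators for synthetic
immunofluorescence pairs, spot fields, and particle tracks complete the
test bed. Everything is bit-reproducible under a fixed seed.

## Worked example

```r
library(ironmap)

# phantom pair: identical tissue, the post map carries a 40 1/s MPIO
# increment in the LCX territory; 2% relative noise (sigma = 2, S0 = 100)
pre  <- make_phantom(c(64, 64), lesion = "none", seed = 42)
post <- make_phantom(c(64, 64), lesion = "LCX", mpio_delta_r2star = 40, seed = 42)
sch  <- schedule_multi_echo_invivo(noise_sigma = 2)   # TE = 2.4, 6.0, 9.5, 13.0 ms

map_pre  <- fit_t2star(simulate_series(pre,  sch, seed = 1))
map_post <- fit_t2star(simulate_series(post, sch, seed = 2))
delta_r2star(map_pre, map_post, pre$territory_labels)
#>   territory mean_pre mean_post       delta n_pixels
#> 1       LCX 33.54455  73.49289 39.94834349      556
#> 2       LAD 33.43948  33.51239  0.07290541      556
#> 3       RCA 33.20151  33.48683  0.28531353      556
```

The lesion territory recovers the injected 40 s⁻¹ increment to 0.1%, while
both control territories stay near zero — the pre/post difference removes
everything that is common to the two time points.

```r
run_exvivo(default_exvivo_config(seed = 42), tempdir())
#> <count_ratio_result> mu = 39.4, sigma = 4.54, threshold = 48.5 1/s
#>   LCX: 2557/8364 px  LAD: 710/8328 px  ratio = 3.586
```

On a 3D ex vivo phantom with patchy deposition in 30% of the LCX, the
Gaussian-tail statistic flags the lesion with a count ratio of 3.6.

```r
tr  <- make_tracks(n_bound = 12, n_transient = 20, seed = 7)
res <- classify_tracks(tr, min_dwell = 10, stationary_radius = 2)
attr(res, "summary")$bound_count
#> [1] 12
```

A command-line front end mirroring these functions ships at
`inst/cli/ironmap.R` (subcommands `simulate`, `fit-t2star`, `delta-r2star`,
`count-ratio`, `if-coverage`, `count-spots`, `incubation`, `flow-binding`,
`run-invivo`, `run-exvivo`).

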