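---
title: "Models and methods behind myopheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myopheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myopheno)
```

`myopheno` re-implements, as a tested and reusable pipeline, the
quantitative layer of a preclinical trial in the GRMD dog model of Duchenne
muscular dystrophy: multi-echo T2 mapping and run-length texture biomarkers
of pelvic-limb muscle MRI, biomechanical endpoint reduction, a
histopathology percent-rescue composite, and the Welch + FDR comparison
layer, all driven by a seeded synthetic-data generator. This vignette is
the package's own account of the models, the parameters that matter, the
numerical choices, and what the green test suite does and does not
establish.

## T2 mapping

Every voxel of the multi-echo spin-echo magnitude series is modelled as
mono-exponential transverse relaxation,

$$S(\mathrm{TE}) = S_0 \, e^{-\mathrm{TE}/T_2},$$

with $T_2$ and TE in milliseconds and $S_0$ in arbitrary signal units. The
default estimator (`method = "log_linear"`) is ordinary least squares of
$\log S$ on TE: $T_2 = -1/\text{slope}$, $S_0 = e^{\text{intercept}}$. The
alternative (`method = "nonlinear"`) refines this start by Gauss–Newton
least squares on the exponential model itself, which matters under noise
because log-transforming reweights the echoes; on noiseless input the two
agree to well below 0.1 ms (tested).

Masking rules are module defaults, not reconstructions of any scanner
software: a voxel is invalid when any echo is at or below
`max(min_signal, 0)` (the log transform requires positive signal;
`min_signal = 0` by default because synthetic data is clean), when its
signal carries any negative value (counted in a warning), or when the
fitted slope is not clearly negative. "Clearly" is a relative test —
$\sum_e y_e \,\widetilde{te}_e < -10^{-12} \sum_e |y_e \widetilde{te}_e|$ —
so that an exactly constant voxel, whose slope is pure rounding error, is
classified invalid rather than mapped to an astronomically large $T_2$.
`r2_of_fit` is the coefficient of determination in the space the model was
fitted in (log-signal or signal); it is reported, never used to exclude,
though values below 0.5 deserve suspicion. `drop_first_echo` is offered
because CPMG first echoes are often biased by imperfect refocusing; the
default keeps all echoes.

## Run-length texture biomarkers

Texture is computed on the fitted T2 map (configurable to a raw echo; the
choice of input image is genuinely open in the source protocol). Within a
muscle ROI, values are quantized to `G` equal-width bins spanning the ROI
min–max; the bin width is the operational "similarity range" that defines
when consecutive voxels count as equal. `G = 16` is the default and every
group comparison must hold `G` fixed — the absolute feature values depend
on it strongly, their ordering much less so. A constant ROI quantizes to a
single level with a warning (degenerate texture); under `fixed_range`
binning, out-of-range values clamp to levels 1 and `G`.

A run is a maximal set of consecutive equal-level voxels along a direction,
confined to the ROI: runs break at mask and volume boundaries and never
bridge background. With $p(i,j)$ the number of runs at level $i$ and length
$j$ and $N_r = \sum_{ij} p(i,j)$:

* Small Lesion Index (short run emphasis),
  $\mathrm{SLI} = \frac{1}{N_r}\sum_{i,j} p(i,j)/j^2 \in (0, 1]$, equal to 1
  exactly when every run has length 1;
* Heterogeneity Index (run-length non-uniformity),
  $\mathrm{HI} = \frac{1}{N_r}\sum_j \big(\sum_i p(i,j)\big)^2 \in [1, N_r]$.

Both are averaged, unweighted, over the 13 unique offsets of the 3D
26-neighborhood (offsets modulo sign, since a run along $d$ and $-d$ is the
same run). This direction set makes the features invariant to axis
permutations of the volume (tested); per-direction matrices remain
available for inspection. The implementation is a vectorized line-sweep;
an independent brute-force walker that starts at every voxel is kept in the
test suite and the two are compared exhaustively on small volumes and on
random masked volumes.

Per-muscle features (volume, mean T2, entropy, SLI, HI) are computed on a
slab of the central 5 slices along the through-plane axis, centered on the
muscle's centroid — a stand-in for an anatomical mid-femur landmark that a
synthetic phantom cannot supply; `n_slices = NA` analyzes the whole muscle.
A muscle whose label has no voxels yields a row flagged `missing`, never a
silently dropped row. Whole-limb composites weight each muscle by its
proportional volume, renormalizing over non-missing muscles; the composite
therefore always lies within the range of the per-muscle values.

## Biomechanical endpoints

Joint torque (N·m) divides by the moment arm to give force (N); the moment
arm is 75% of the hock-to-digit distance (m). Body-mass correction divides
by mass (kg). The eccentric contraction force deficit after $k$ stretches is
$F_d = 100\,(P_{o,0} - P_{o,k})/P_{o,0}$, with the 30-stretch protocol
summarized as ECD(1–10) and ECD(1–30). A negative $F_d$ (post-stretch
potentiation) is reported, not clamped: hiding data pathologies is worse
than printing them. $F_d$ is invariant to rescaling the whole series, so
torque and converted force give identical deficits — which is why the
pipeline accepts either. Left/right limbs are averaged per animal before
any group statistic, preserving one independent observation per animal.
Joint and pelvic angles are carried as measured fields with no computation.

## Histopathology rescue composite

For each muscle and marker (PM2K⁺ macrophage inflammation, necrotic foci,
IgG⁺ myofibers, centrally-located-nuclei regeneration — all "lower is
better"), percent rescue is $R = 100\,(u - t)/u$, undefined at $u = 0$ and
invariant to common rescaling of both groups. Marker averages across the
four muscles are reported to one decimal with ties rounded **half away from
zero** — this is required for an average of 30.25 to print as 30.3 — and
the final composite score is the plain mean of the four marker averages.

The averaging convention is the one place where the published table had to
be reverse-engineered: its necrotic-foci average equals the mean of the
three *significant* muscles (the cranial sartorius cell, a trend at
p = 0.14, is dropped), while its IgG average retains all four muscles even
though the same muscle's IgG cell is also non-significant. Both behaviors
are explicit configuration (`exclusion`, per marker), with the observed
convention as the default; the package takes no position on why the source
analysis differed between the two markers.

## Group statistics

Welch's two-sample *t*-test — $t = (\bar x_1 - \bar x_2)/
\sqrt{s_1^2/n_1 + s_2^2/n_2}$ with Welch–Satterthwaite degrees of freedom —
is the default, appropriate for the unequal group sizes (8/3/10/6) and
variances of this design; the raw-sample route computes summaries first and
agrees with the summary route to machine precision (tested). Histopathology
comparisons use the pooled-variance Student test (`var_equal = TRUE`),
matching that layer's convention. All tests are two-sided. The
Benjamini–Hochberg step-up adjustment is applied within an explicit
endpoint family (muscles within one feature, or endpoints within one
comparison); family membership is configuration because no universal
definition exists. Flags: *significant* below 0.05, *trend* below 0.2.
BH adjustment is *not* idempotent (re-adjusting adjusted values changes
them; the invariants actually tested are agreement with an independent
implementation, order equivariance, monotonicity, and the cap at 1).

## The synthetic world: what it emulates and what it does not

`generate_phantom()` lays muscles out as non-overlapping axis-aligned
ellipsoids (three by default, ~40 ms baseline T2, 1.5×1.5×3 mm voxels),
carves spherical lesion patches (default radius 2 voxels) whose centers are
sampled uniformly inside the muscle and rejected on overlap until the voxel
budget — `lesion_fraction` of the muscle — is met to within one patch, then
synthesizes a 10-echo CPMG-like series (TE 10–100 ms, S0 = 1000). Lesions
shift T2 by +30 ms (hyperintense, emulating necrosis/edema). Noise is
additive Gaussian on the magnitude — a deliberate simplification of Rician
noise, acceptable at the SNR regimes simulated. All randomness flows
through named sub-streams of one seed (`sub_seed()`), so adding a stage
never shifts another stage's draws and identical spec + seed is
bit-identical.

The generator's default is **noiseless** (`noise_sd = 0`). This is a
considered choice, not an omission: the lesion-texture monotonicity
property (more lesions ⇒ higher SLI, HI, and weighted T2) is a statement
about image *structure*, and adaptive min–max quantization destroys it in a
world whose only within-muscle variation is iid voxel noise — there, a
healthy muscle is already maximally fragmented (SLI → 1) and adding lesions
merely widens the bins, lowering SLI. We verified this inversion
experimentally, including with smooth T2 heterogeneity fields layered under
the noise. Real muscle escapes it because its ROI range is dominated by
spatially structured variation; emulating that faithfully is out of scope.
Consequently a green monotonicity test establishes that the texture code
responds to lesion geometry as the biology argument predicts — it does
*not* establish robustness of that ordering to arbitrary noise/quantization
regimes, and absolute SLI/HI magnitudes of real dog MRI are not
reproducible from a phantom (they depend on unstated quantization depth,
ROI sizes, and direction handling). T2 *bias* under noise is tested
separately at 2% Gaussian noise, where the median fitted T2 over 10⁴ voxels
must stay within 1 ms of truth.

`generate_cohort()` draws every endpoint from per-group normal
distributions whose default means and sds are the 6-month values of the
emulated trial (e.g. body-mass-corrected extension force 1.56 ± 0.92 N/kg
untreated vs 2.70 ± 0.65 N/kg treated GRMD, so the programmed treatment
effect is the published ~73% force gain); strictly positive endpoints
redraw negative values and report the redraw count. Endpoints are drawn
independently — the generator makes no claim about their covariance, so
multivariate structure (e.g. force–mass correlation) is absent by design.
`generate_histo_counts()` programs treated means as
$(1 - R/100)\times$ untreated with Gamma noise at coefficient of variation
`dispersion`; at `dispersion = 0` the rescue table reproduces the
programmed world cell-for-cell.

In the full pipeline the per-animal phantoms additionally jitter each
muscle's baseline T2 across animals (`t2_between_animal_sd`, default 3 ms):
the group sds one sees in a real imaging table are between-animal
biological variation, which is a different quantity from within-scan voxel
noise, and only the former is needed for the group-comparison layer to be
exercised meaningfully.

## Numerical and interface choices

* **Rounding**: one decimal, half away from zero, only where the published
  convention demands it (histology averages); everything else is full
  precision, with CSV output passed through `signif(x, 10)` so reruns are
  byte-identical across platforms.
* **Quantization tie-break**: the ROI maximum maps to level `G` (the
  half-open binning is closed on the top bin).
* **Degenerate inputs**: empty masks, all-invalid fits, zero reference
  means, zero untreated levels, and two zero-variance groups all error with
  explicit messages; constant ROIs warn and proceed.
* **NIfTI I/O** is a minimal built-in NIfTI-1 reader/writer (single-file
  `.nii`/`.nii.gz`, little-endian, scalar dtypes, axis-aligned sform),
  cross-validated against nibabel in the test suite; it intentionally
  supports only what the pipeline emits.
* **Config**: YAML or list, deep-merged over defaults; validation collects
  *all* problems and rejects unknown keys, so a typo cannot silently revert
  a parameter to its default.
* **Determinism**: the manifest records the seed and an MD5 of the resolved
  config; no timestamps enter any output.

## Known limitations

Anatomy is schematic (ellipsoids, no fat signal, no T2-weighted TSE
contrast); noise is Gaussian, not Rician; endpoint draws are uncorrelated;
the five-slice slab is centroid-based, not landmark-based; absolute texture
magnitudes are not comparable to scanner data; and the histology exclusion
convention is an inference from a published table, flagged as such above.
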