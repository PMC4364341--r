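# myopheno

Quantitative analysis pipeline for preclinical canine muscular dystrophy
trials, aimed at researchers who quantify therapeutic response in the GRMD
(golden retriever muscular dystrophy) dog model — or comparable large-animal
models — from three kinds of evidence:

* **muscle MRI**: per-voxel T2 mapping from a multi-echo spin-echo (CPMG)
  series, and per-muscle 3D texture biomarkers built on gray-level run-length
  matrices, with proportional-volume-weighted whole-limb composites;
* **biomechanics**: tibiotarsal joint torque → force conversion, body-mass
  correction, eccentric contraction force deficit, group percent change;
* **histopathology**: per-muscle, per-marker percent rescue and a final
  composite score of improvement;

tied together by a Welch *t*-test + Benjamini–Hochberg FDR group-comparison
layer and a seeded synthetic-data generator, so the whole pipeline is
testable with no imaging data on disk.

## The statistics at the core

**T2 mapping.** Each voxel of a multi-echo magnitude volume is modelled as
mono-exponential decay, `S(TE) = S0 · exp(−TE/T2)`. The default fit is
ordinary least squares of `log S` against `TE` (`T2 = −1/slope`); a
Gauss–Newton refinement on the exponential model is available
(`method = "nonlinear"`). Non-decaying or non-positive voxels are masked.

**Run-length texture.** Within a muscle ROI the T2 map is quantized to `G`
equal-width gray levels (default `G = 16` over the ROI min–max; the bin
width realizes the "similarity range" of run-length analysis). A *run* is a
maximal set of consecutive equal-level voxels along a direction, confined to
the ROI. With `p(i,j)` the count of runs of level `i` and length `j` and
`N_r` the total run count:

* Small Lesion Index (short run emphasis):
  `SLI = (1/N_r) Σᵢⱼ p(i,j)/j²` ∈ (0, 1] — near 1 when texture is
  fragmented into short runs, as patchy lesions do to homogeneous muscle;
* Heterogeneity Index (run-length non-uniformity):
  `HI = (1/N_r) Σⱼ (Σᵢ p(i,j))²` ∈ [1, N_r] — large when run counts
  concentrate at few lengths.

Both are averaged over the 13 unique directions of the 3D 26-neighborhood,
plus a first-order histogram entropy `H = −Σ f log₂ f`. Whole-limb scores
are volume-weighted: `Σ w_m x_m`, `w_m = vol_m / Σ vol`.

**Endpoints and group statistics.** Force = torque / (0.75 × hock-to-digit
distance); force deficit `Fd = 100·(Po₀ − Po_k)/Po₀`; percent rescue
`R = 100·(untreated − treated)/untreated`. Groups are compared with Welch's
unequal-variance *t*-test (Satterthwaite df), BH-FDR adjusted within an
endpoint family, flagged *significant* (p < 0.05) or *trend* (p < 0.2).

## Worked example

```r
library(myopheno)

## a dystrophic phantom: 20% of muscle voxels in hyperintense lesion patches
ph   <- generate_phantom(phantom_spec(lesion_fraction = 0.2, seed = 1))
tmap <- fit_t2(ph$volume)
ft   <- muscle_features(tmap, ph$labels, G = 16)
ft[, c("muscle", "mean_t2", "sli", "hi")]
#>             muscle mean_t2    sli    hi
#> 1   biceps_femoris   46.32 0.4042 170.5
#> 2 vastus_lateralis   46.94 0.3891 115.1
#> 3   semitendinosus   46.81 0.4022 106.0
weighted_composite(ft, "mean_t2")   # 46.65 ms (baseline ~40.4 + lesion load)
weighted_composite(ft, "sli")       # 0.399 (0.105 for the same phantom lesion-free)

## group comparison from summary statistics (whole-limb T2, n = 10 vs 6)
welch_t(52.28, 4.52, 10, 47.34, 3.10, 6)
#> Welch t-test: t = 2.588, df = 13.60, p = 0.02189 (diff = 4.94)

## histology percent-rescue composite
counts <- generate_histo_counts()            # programmed treatment effect
rescue_table(counts$untreated, counts$treated, default_histo_significance())
#> marker averages: inflammation=35.5, necrotic_foci=35.3,
#>                  igg_fibers=30.3, regeneration=40.8
#> final composite score of improvement: 35.5%

## treated vs untreated extension force, N/kg
percent_change(1.56, 2.70)                   # 73.08 -> a 73% force gain
```

The mean T2 rises with lesion load because lesions add ~+30 ms voxels; SLI
rises because patches break the long runs of homogeneous muscle; the rescue
composite averages the four marker averages (the necrotic-foci average drops
its one non-significant muscle — see the methods vignette for why).

## Full pipeline and CLI

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

writes `table1_endpoints.csv` (per-group endpoint summaries),
`endpoint_stats.csv`, `muscle_features.csv`, `table2_mri.csv` (per-muscle and
weighted-average T2/SLI/HI by group), `mri_stats.csv`, `table3_rescue.csv`
(+ `.json`), and a `manifest.json` with the seed and config hash. Reruns with
the same seed are byte-identical. The same stages are scriptable:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","myopheno.R",package="myopheno"))')
Rscript $CLI run      --config cfg.yaml --seed 1 --out run1
Rscript $CLI simulate --seed 1 --out sim         # phantom NIfTI + cohort CSVs
Rscript $CLI t2map    sim/phantom.nii.gz --echoes sim/phantom_echoes.json --out maps
Rscript $CLI histo    sim/histo_untreated.csv sim/histo_treated.csv --out rescue.csv
```

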