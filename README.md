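# dermtex

Colored histogram-based local texture descriptors for skin-lesion image
classification.

Automated benign/malignant screening of dermoscopic images classically
converts the color image to grayscale before extracting a texture
descriptor, throwing away the chromatic cues (pigmentation, vascular
color) that carry much of the diagnostic signal. `dermtex` implements the
*colored feature* construction instead: a histogram-based local descriptor
is computed independently on each channel of a decorrelated color space
and the per-channel histograms are concatenated,

    Color LBP_YCbCr = (LBP_Y, LBP_Cb, LBP_Cr)

and analogously for LAB and HSV; a *hybrid feature* concatenates two
descriptors, e.g. `(LBP, MBC)`. Five descriptors are provided, each coding
every interior pixel and histogramming the codes:

| descriptor | per-channel length | code |
|---|---|---|
| LBP  | 256  | 8-bit neighbour ≥ centre comparisons |
| LDN  | 56   | strongest positive + strongest negative Kirsch compass response |
| PHOG | 168  | magnitude-weighted 8-bin orientation histograms over a 3-level spatial pyramid |
| LDiP | 56   | bits of the top-3 absolute Kirsch responses, C(8,3) codes |
| MBC  | 3072 | 8-bit codes of the monogenic amplitude/phase/orientation maps, 2×2 block histograms |

Downstream, the package delegates classification to SVM (`e1071`) or
XGBoost at library defaults, rebalances imbalanced training sets with
SMOTE (training partition only), and evaluates with confusion matrices,
accuracy / precision / recall / F1 and a two-tailed Welch t-test between
two classifiers' predicted labels. A deterministic synthetic
lesion-image generator (skin-toned background, textured irregular
elliptical lesion, class-dependent color and texture) makes the whole
pipeline testable without any external dataset.

## Worked example

```r
library(dermtex)

spec <- lesion_fixture_spec(n_classes = 2, counts = 30, seed = 42)  # 60 images, 224 px
ds   <- make_lesion_dataset(spec)

run <- run_experiment(ds, experiment_config(descriptor = "LDN", space = "YCBCR",
                                            classifier = "XGBOOST", seed = 42))
run
#> <dermtex_run> LDN_YCBCR + XGBOOST | features: 168 | train/test: 48/12
#>   accuracy 1.0000  precision 1.0000  recall 1.0000  F1 1.0000 (binary)
```

The colored LDN feature (3 × 56 = 168 values from the Y, Cb and Cr planes)
separates the two synthetic classes perfectly on the 12 held-out images,
while the grayscale counterpart of the same descriptor reaches only 0.58 —
the class signal in these fixtures lives dominantly in chroma, which the
grayscale pathway cannot see:

```r
gray <- run_experiment(ds, experiment_config(descriptor = "LDN", space = "GRAY",
                                             classifier = "XGBOOST", seed = 42))
gray$metrics$accuracy
#> [1] 0.5833333
```

`glance()` gives one tidy row per run (handy for grids via
`run_experiment_grid()`), `tidy()` per-class metrics, `autoplot()` the
confusion-matrix heatmap. Comparing a run with itself demonstrates the
Welch self-test identity — identical predictions give t = 0, p = 1:

```r
compare_runs(run, run)
#> Welch t = 0.0000, df = 22.0, two-tailed p = 1.0000 (not significant)
```

A thin CLI over the same functions lives at `inst/cli/dermtex.R`
(`fixtures`, `run`, `compare` subcommands) for shell use.

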