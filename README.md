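# erpselect

Tools for linking event-related potentials (ERPs) evoked by visual motion to
continuous trait scores, for researchers studying autistic-trait-related
differences in visual processing. The package reimplements, as a tested and
reusable pipeline, a study design in which participants watched a life-sized
virtual avatar **approaching** (AW), **receding** (RW) or **standing** (ST)
while 6-channel EEG (C3, C4, T5, T6, O1, O2) plus two EOG channels was
recorded at 250 Hz, and each participant's autistic traits were measured with
the SATQ questionnaire (24 Likert items, total score 0–72).

Because no raw EEG from such studies is publicly deposited, the package ships
a first-class **synthetic-data generator** that emulates the statistical
structure the analysis assumes, so every stage is testable offline.

## What it computes

1. **ERP extraction** (`erp` stage). Continuous recordings are band-pass
   filtered (zero-phase, 1–20 Hz), cut into epochs from −200 to 600 ms around
   each stimulus onset, baseline-corrected by the pre-stimulus mean, cleaned
   by a 100 µV peak-to-peak threshold on EOG and scalp channels, and averaged
   per condition. The N170 (negative peak near 170 ms) and P200 (positive
   peak near 200 ms) are located by windowed extremum search at the temporal
   electrodes T5/T6, giving 8 indicators per electrode:
   (latency, amplitude) × (N170, P200) × (AW, RW).

2. **Exhaustive-search regression** (`essearch` stage). With trait score *y*
   and the 8 indicators *x₁…x₈* of one electrode, every nonempty subset
   *S ⊆ {1…8}* (2⁸ − 1 = 255 models) is fit by ordinary least squares,

   &nbsp;&nbsp;&nbsp;&nbsp;*y = β₀ + Σ_{j∈S} βⱼ xⱼ + ε*,

   and scored by leave-one-out cross-validation with the mean absolute error
   as the cross-validation error:

   &nbsp;&nbsp;&nbsp;&nbsp;CVE = (1/n) Σᵢ |ŷ₍ᵢ₎ − yᵢ|,

   where *ŷ₍ᵢ₎* is the prediction for row *i* from the model refit without
   row *i*. Models are ranked by ascending CVE; the top K (default 50) are
   summarized by per-variable **selection frequencies** and a **weight
   diagram** of standardized partial regression coefficients
   (βⱼ·sd(xⱼ)/sd(y); warm colors positive, cool negative, white = variable
   absent).

3. **Synthetic data** (`synth` stage). Trait scores ~ N(27.77, 8.02²)
   truncated to [0, 72] and rounded; 5 stimulus sets × 60 trials at ratio
   AW:RW:ST = 2:2:1 (120/120/60); Gaussian N170 (−5 µV @ 170 ms) and P200
   (+6 µV @ 200 ms) kernels on T5/T6 in AW/RW only; 1/f noise; blink
   artifacts ≥ 100 µV on EOG; and linear trait effects in the AW condition
   (P200 latency at T6 +0.5 ms per score unit, P200 amplitude at T5/T6
   −0.1 µV per score unit) that the downstream analysis is expected to
   recover.

## Worked example

```r
library(erpselect)

cfg <- run_config(
  generative = generative_config(n_participants = 26),
  seed = 7,
  channels = c("T5", "T6", "EOG_upper", "EOG_lower")  # only what is analyzed
)
bundle <- run_full_analysis(cfg)
print(bundle)
#> <run_bundle>
#>   participants: 26 enrolled; retained: T5=26 T6=26
#>   models per electrode: T5=255 T6=255

print(bundle$searches$T5)
#> <es_search> T5: 255 models over 8 indicators, n=26
#>   best model (CVE 4.758): T5_N170_AW_amplitude+T5_P200_AW_amplitude
#>   selection counts in top-50:
#> T5_P200_AW_amplitude T5_N170_AW_amplitude   T5_P200_AW_latency
#>                   50                   22                   20
#> ...
```

The generator put a negative trait effect on the AW P200 amplitude at T5 —
and the search selects exactly that indicator in all 50 of the 50 lowest-CVE
models, with negative standardized coefficients. The best model's report
(here at T6, where the generative effect is a positive latency slope):

```r
print(bundle$searches$T6$best_fit)
#> <ols_fit> k=4, n=26: F(4,21)=69.249, p=0.000, R2=0.930, adjR2=0.916
#>                           B    SE   beta     p
#> T6_N170_AW_latency    0.761 0.237  0.294 0.004
#> T6_N170_AW_amplitude -2.699 0.805 -0.298 0.003
#> T6_P200_AW_latency    1.200 0.203  0.494 0.000
#> T6_P200_RW_latency   -0.451 0.288 -0.094 0.133

single_variable_regression(bundle$features$T6$T6_P200_AW_latency,
                           bundle$features$T6$satq)
#> [1] 0.885887  # positive, as generated (equals the Pearson correlation)
```

Setting `out_dir` in `run_config()` writes the full report bundle (feature
tables, CVE tables, weight diagrams, selection frequencies, best-model
reports, grand averages, exclusion log, MD5 manifest), and
`render_figures(bundle)` adds grand-average and weight-diagram PNGs.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/erpselect synth --out data/ --seed 1
Rscript inst/cli/erpselect run --out results/ --seed 1
```

## Documentation

The methods vignette (`vignettes/erpselect-methods.Rmd`) describes the
generative model, the measurement chain and its numerical choices, what the
synthetic world does and does not establish, and known limitations.
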