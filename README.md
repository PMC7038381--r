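# fsetongue

Classification tools for pulse-voltammetric electronic tongues (e-tongues):
instruments that immerse an array of cross-sensitive metal electrodes in a
liquid, drive the cell with a multi-frequency large-amplitude pulse
voltammetry (MLAPV) excitation, and identify the liquid from the recorded
current transients.

The raw data are long, highly correlated time series: each sample is an
`m × d` matrix (6 electrodes × 9000 points for a 60 s cycle at 150 Hz),
dominated by a *common-mode* component locked to the shared excitation that
carries almost no class information. This package implements:

* **FSE (feature specificity enhancement)** — the pairwise kernel feature
  extractor. Writing each electrode pair as a common-mode part
  `x_c = (x_i + x_j)/2` plus a specificity part `x_s = (x_i − x_j)/2`, FSE
  maps a sample to

  `Z_ij = k(x_i, x_j) = exp(−‖x_i − x_j‖² / (2σ²)),  i ≠ j`,

  one value per ordered electrode pair. The common mode cancels exactly and
  the feature length is `m(m−1)` — 30 numbers instead of 54 000 — with
  every entry in `(0, 1]`.
* **KBM**, the matched contrast method `Z_i = exp(−‖x_i‖²/(2σ²))`, which
  keeps the common mode and isolates its effect in comparisons.
* **ELM / KELM** — extreme learning machine classifiers in closed ridge
  form; the kernel variant solves `(K + I/μ)A = T` by Cholesky and predicts
  `f(x) = k(x, ·) A` with one-hot targets (defaults `μ = 1000`, `θ = 10`).
* An **MLAPV simulator** that generates excitation waveforms and
  class/concentration-dependent electrode responses (neither of the
  original datasets is publicly deposited), so the whole pipeline is
  testable end to end.
* **Evaluation protocols** — leave-one-replicate-per-class-out and
  stratified four-fold cross-validation, accuracy/STD tables in percent,
  and hyperparameter sensitivity sweeps — plus baseline classifier
  adapters (SVM, random forest, LDA, naive Bayes) over their standard
  implementations.

See the methods vignette (`vignettes/fsetongue-methods.Rmd`) for the model,
the simulator's design and its limitations.

## Worked example

```r
library(fsetongue)

# simulate the 63-sample beverage panel: 7 liquids x 3 concentrations x 3
# replicates, each sample 6 electrodes x 9000 time points
panel <- simulate_beverage_dataset(seed = 1)
panel
#> <labeled_dataset> 63 samples, each 6 x 9000; 7 classes

# FSE compresses each sample to the 30 pairwise kernel features
features <- transform_dataset(panel, method = "fse", sigma = 10)
features
#> <feature_table> 63 samples x 30 features (fse, sigma = 10)
round(features$x[1, 1:5], 4)
#>  Z_1_2  Z_1_3  Z_1_4  Z_1_5  Z_1_6
#> 0.9935 0.0000 1.0000 0.0119 1.0000

# nine-round cross-validation: hold out one sample per class per round
plan <- make_loo_replicate_splits(panel)
plan
#> <split_plan> loo_replicate, 9 splits; test sizes: 7/7/7/7/7/7/7/7/7

evaluate_model(panel, plan, feature = "fse", classifier = "kelm")
#> <eval_result> FSE-KELM (loo_replicate): accuracy 100.00% (STD 0.00%)
evaluate_model(panel, plan, feature = "kbm", classifier = "kelm")
#> <eval_result> KBM-KELM (loo_replicate): accuracy 14.29% (STD 0.00%)
```

On this simulated panel the common-mode amplitude is more than ten times
the specificity signal. FSE-KELM classifies every held-out sample; KBM —
the same kernel without common-mode cancellation — collapses to chance
(1/7), which is the point of the comparison.

Kernel-width sensitivity, as a sweep over `σ`:

```r
sensitivity_sweep("sigma", 10^(-3:3), panel, plan)[, 1:4]
#>   parameter value mean_accuracy std_accuracy
#> 1     sigma 1e-03          14.3         0.00
#> 2     sigma 1e-02          66.7        18.90
#> 3     sigma 1e-01         100.0         0.00
#> 4     sigma 1e+00         100.0         0.00
#> 5     sigma 1e+01         100.0         0.00
#> 6     sigma 1e+02         100.0         0.00
#> 7     sigma 1e+03          93.7         7.53
```

Accuracy rises steeply below `σ = 0.1` and is flat across
`σ ∈ [0.1, 1000]` — recognition is insensitive to the kernel width over
four orders of magnitude.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "fsetongue", package = "fsetongue"))') \
    simulate --out panel.rds --seed 1
```

Subcommands: `simulate`, `extract`, `train`, `evaluate`, `sweep`; flags
include `--config` (YAML simulator spec), `--dataset`, `--method
{fse,kbm,raw}`, `--classifier {kelm,elm,svm,rf,lda,nb}`, `--sigma`, `--mu`,
`--theta`, `--protocol {loo,fourfold}`, `--grid` and `--out`. Every run
writes a `run_manifest.json` sufficient to reproduce it.

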