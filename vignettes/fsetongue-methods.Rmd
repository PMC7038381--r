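---
title: "Methods: common-mode cancellation and kernel ELM classification for pulse-voltammetric e-tongues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: common-mode cancellation and kernel ELM classification for pulse-voltammetric e-tongues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and the problem

A voltammetric electronic tongue immerses an array of low-selectivity,
cross-sensitive working electrodes in a liquid and drives the cell with a
shared excitation. With multi-frequency large-amplitude pulse voltammetry
(MLAPV) the excitation is a train of square pulses: several frequency
segments per cycle, each segment stepping through a ladder of pulse
amplitudes, with blank intervals between segments that let the electrodes
relax. Every pulse edge produces a charge/discharge current transient on
every working electrode, so one measurement yields an `m x d` matrix `X`
(`m` electrodes, `d` time points; 6 x 9000 at the default 60 s cycle and
150 Hz sampling).

Two properties of these matrices drive the design of this package:

* The rows are dominated by a *common-mode* component — the part of the
  response locked to the shared excitation, nearly identical on every
  electrode. It is large, highly correlated across electrodes, and carries
  almost no information about the liquid.
* The class-informative signal is the *specificity* — the differences
  between electrodes' responses — which is small relative to the common
  mode and spread over thousands of time points.

Feeding raw rows to a classifier therefore wastes most of the input
dimensions on a component that is the same for every class.

# Feature specificity enhancement (FSE)

For an electrode pair `(i, j)` write

$$x_i = x_c + x_s, \qquad x_j = x_c - x_s,$$

so the common mode is the pair mean `x_c = (x_i + x_j)/2` and the
specificity is the half-difference `x_s = (x_i - x_j)/2`
(`decompose_pair()`). FSE maps the whole sample to the pairwise kernel
values

$$Z_{ij} = k(x_i, x_j) = \exp\!\left(-\frac{\lVert x_i - x_j\rVert_2^2}
  {2\sigma^2}\right), \qquad i \ne j,$$

one number per ordered electrode pair (`fse_transform()`). Because the
kernel depends on `x_i - x_j = 2 x_s` only, any signal common to all rows
cancels *exactly* — the package tests this to a relative tolerance of
1e-12 under additive common-mode offsets. The feature vector has length
`m(m-1)` regardless of `d` (30 for six electrodes), every entry lies in
`(0, 1]`, equals 1 exactly for identical rows, and decreases
monotonically in the pair distance.

Both orderings of each pair are kept by default, so each unordered pair
appears twice. That is deliberate: the reference procedure enumerates all
ordered pairs, and downstream models are unaffected beyond a constant
factor in kernel distances. `unique_pairs = TRUE` emits the `m(m-1)/2`
distinct values instead. The flattening order — `(i, j)` for
`i = 1..m`, `j = 1..m`, `j != i`, row major, named `Z_i_j` — is a package
convention; no ordering is canonical for this transform.

Raw responses enter the kernel unstandardized by default (`sigma` has the
units of the raw signal, here µA, times `sqrt(time points)`); optional
per-electrode z-scoring sits behind `standardize = TRUE`.

The contrast method **KBM** (`kbm_transform()`) applies the same kernel to
each electrode against the origin, `Z_i = exp(-||x_i||^2 / (2\sigma^2))`.
It has length `m` and retains the common mode — a shared offset changes
its output. The pair FSE/KBM isolates exactly one experimental variable:
whether the common-mode component is cancelled before the kernel.

A numerical note: `fse_transform()` computes pair distances by direct row
differencing, never via the Gram-matrix identity
`||a-b||^2 = ||a||^2 + ||b||^2 - 2a'b`. With a common mode thousands of
times larger than the specificity, the Gram route cancels catastrophically
and would destroy the invariance that is the method's point.

# ELM and KELM classifiers

The extreme learning machine is a single-hidden-layer network whose input
weights `W` and biases `b` are random (uniform on `[-1, 1]`, seeded) and
whose output weights are a ridge closed form. With hidden output
`H = g(XW' + b)` (sigmoid by default) and one-hot targets `T`
(`one_hot_encode()`, classes in lexicographic order),

$$\beta = (H'H + I_L/\mu)^{-1} H'T \quad (N \ge L), \qquad
  \beta = H'(HH' + I_N/\mu)^{-1} T \quad (N < L).$$

The two branches are algebraically equivalent up to the ridge and the
package verifies their agreement on square-ish problems at weak
regularization. `mu` is the regularization coefficient: larger `mu`
weights the data misfit more, so training-set predictions interpolate the
targets as `mu` grows (a tested property).

The kernel ELM replaces the random hidden layer with a kernel matrix
`K_ij = k(x_i, x_j)` and predicts

$$f(x) = [k(x, x_1), \ldots, k(x, x_N)] \, (K + I_N/\mu)^{-1}\, T,$$

with the predicted class the argmax of the score row (ties resolved
toward the lowest class index, deterministically). The dual coefficients
are obtained by a Cholesky solve of the symmetric positive-definite system
— never an explicit inverse. Training is fully deterministic. With the
linear kernel, KELM is identical to ridge regression on explicit features
with penalty `1/mu`; the test suite checks this identity to 1e-8 on random
problems, which pins the ridge form independently of the kernel.

**Kernel parameterization.** The KELM RBF is

$$k(u, v) = \exp\!\left(-\frac{\lVert u - v\rVert^2}{\theta}\right),$$

with the width `theta` directly in the denominator — the parameterization
used in the original kernel-ELM literature. This choice matters here and
was made deliberately. FSE features live in `(0, 1]^{m(m-1)}`, so squared
feature distances never exceed `m(m-1)`. Had we reused the
`2\theta^2` convention of the feature kernel, `theta = 10` would give
kernel values confined to `[exp(-30/200), 1] \approx [0.86, 1]`: the
kernel matrix is then nearly constant, the classifier degenerates into a
heavily shrunk linear regression on indicators (with its well-known
multi-class masking pathology), and the reported insensitivity of the
method to `sigma` is unobtainable. With `theta = 10` in the
denominator-`theta` convention the kernel is genuinely local on the
feature cube and the classifier interpolates well-separated clusters. The
two conventions describe the same model family — the choice only relabels
the `theta` axis — but the defaults (`mu = 1000`, `theta = 10`) are
meaningful under this one.

Defaults follow the tuned values reported for this model family:
`mu = 1000` (the regularization coefficient, identical to the "gamma"
swept in sensitivity analyses) and `theta = 10`.

# The MLAPV simulator

Neither of the datasets this methodology was developed on is publicly
deposited, so the package ships a generator that emulates the *structure*
of MLAPV e-tongue data well enough that every claim above is testable
end to end. `excitation_spec()` reproduces the excitation: 60 s cycle,
150 Hz, segments at 0.2/1/2 Hz, five pulses per segment at 1.0 down to
0.2 V effective, 50% duty cycle. Segment active times are 25/5/2.5 s;
the unspecified blank lengths default to an even split of the remaining
27.5 s between the two gaps (13.75 s each) — a convention, configurable.

`electrode_model()` generates electrode currents as

```
x_e(t) = g_cm * s(t)
       + transient( w(t) * [ b_e + conc^alpha * G[class, e, pulse(t)] ];
                    tau_e * tauMod[class, e] )
       + noise
```

* `s(t)`: a shared excitation-locked template — a first-order RC-style
  charge/discharge response to every pulse edge (`tau` 0.5 s), identical
  on all electrodes. Its gain (`common_mode_gain = 2e4`) keeps the common
  mode at least an order of magnitude above the strongest specificity
  signal, the regime the method targets.
* `transient(u; tau)`: the same RC edge response applied to the scaled
  excitation, per electrode, with time constants 0.9 down to 0.07 s across
  the array (double-layer charging differs strongly between electrode
  metals).
* `G[class, e, pulse]`: the analyte fingerprint. Its magnitude structure
  is the load-bearing design decision, described next.
* `noise`: white Gaussian, 1e-4 µA r.m.s. (a good benchtop potentiostat);
  per-replicate electrode drift is lognormal with sdlog 0.01.

**Why magnitudes span decades.** The package's own sensitivity studies
show that recognition that is flat in `sigma` over `[1e-1, 1e3]` requires
class-informative electrode-pair distances in essentially every decade of
`[0.03, 3000]` (in raw signal units): a pair's feature
`exp(-D^2/2\sigma^2)` is informative only where `D` is within roughly one
decade of `sigma`. Liquids genuinely differ that much — conductivities
from distilled-water dilutions to salt solutions span five or more
decades — and a cross-sensitive array pairs each liquid with some
electrodes strongly and others barely. The simulator encodes this as a
per-(class, electrode) log10 magnitude drawn as a *randomly permuted rung
ladder* `(-3.2, -2.0, -1.8, -0.5, 1.2, 3.0)` plus uniform jitter of half a
rung: every liquid spans the array's dynamic range, but *which* electrode
is loud or quiet is liquid-specific. iid draws do not work: with
independent magnitudes a third of the classes have no quiet electrode
pair, all land on the all-zero feature corner at small `sigma`, and the
plateau collapses at its low edge.

Two further structural choices came out of the same studies:

* 70% of the per-(class, electrode, pulse) gain variation (lognormal,
  sdlog 0.8 total) is shared across electrodes — all electrodes see the
  same redox chemistry — so electrodes of near-equal magnitude nearly
  cancel in their difference, producing the fine distance scales that
  break ties between otherwise-colliding classes. Time constants carry an
  additional per-(class, electrode) lognormal modulation (sdlog 0.3):
  liquids alter interface kinetics, not just amplitudes.
* The concentration response is sub-linear, `gain * conc^0.35`. The
  beverage design dilutes concentrated stock solutions to 14/25/100%, a
  regime where electrode response saturates strongly with activity; a
  linear law would scale all pair distances sevenfold within each class
  and make classes multimodal on exactly the axes that separate them.

`simulate_beverage_dataset()` builds the full factorial panel — 7
beverages x 3 concentrations x 3 replicates = 63 samples of 6 x 9000 —
and `simulate_benchmark_dataset()` the benchmark-style set: 13 liquids,
114 samples of 6 x 2050 (the 60 s cycle sampled at 2050 points), using
the most even partition of 114 over 13 classes (ten classes of 9, three
of 8). All randomness flows from one integer seed; equal seeds give
bit-identical datasets.

**What the simulator does not emulate.** There is no electrochemical
kinetics (no Butler–Volmer currents, no diffusion layer), no
session-to-session sensor drift or fouling, no temperature dependence, and
no correlated (pink) instrument noise. Its common mode is *exactly*
identical across electrodes, which is the idealization FSE assumes; real
arrays cancel imperfectly. Passing tests on simulated data therefore show
that the pipeline recovers class structure through a dominant common mode
with realistic dynamic ranges — they do not certify accuracy numbers on
any real instrument, and the package makes no claim to reproduce the
accuracy tables of any particular study.

# Evaluation protocols

`make_loo_replicate_splits()` implements the nine-round protocol for the
balanced panel: samples within each class are ordered by (concentration,
replicate) and round `r` holds out the `r`-th sample of every class —
train 56 / test 7 on the 63-sample design, each sample tested exactly
once. (The protocol is often called "leave-one-out" in this field; the
name here reflects what is actually left out.) `make_fourfold_splits()`
stratifies 114 samples into groups of 28/29/28/29 with every class present
in every group; assignment within a class is seeded-random, since no
canonical assignment exists.

`evaluate_model()` runs one (feature method, classifier) pair under a
split plan: features are extracted per sample (unsupervised — a tested
no-leakage property), the classifier is fit on training indices only, and
mean/STD accuracy are reported in percent (printed to two decimals, the
conventional table format). Baseline classifiers delegate to their
standard implementations — SVM (RBF, cost 1000, kernel coefficient 0.001),
random forest (50 trees), LDA, naive Bayes — behind the same interface;
they are optional and the package's own claims never depend on them.

`sensitivity_sweep()` re-evaluates a model over a grid of one parameter
(`sigma`, `gamma` = `mu`, or `theta`), recording failed grid points (e.g.
classifiers that cannot handle features that have saturated to exact
zeros at extreme widths) as rows with diagnostics rather than dropping
them.

# Numerical choices and degenerate inputs

* SPD solves use Cholesky factorization; a non-PD system (impossible for
  an RBF kernel plus positive ridge, but reachable through user-supplied
  kernels) raises a diagnostic error.
* Argmax ties break to the lowest class index; `max.col`'s random
  tie-breaking is never used.
* `d = 1` samples (single time point) are legal: the kernels operate on
  scalars.
* Empty datasets transform to empty feature tables without error.
* ELM seeds its weight draws through a local RNG scope that restores the
  caller's `.Random.seed`, so model fitting never perturbs a user's
  random stream.
* Text serialization writes 17 significant digits, enough for doubles to
  round-trip exactly; the RDS bundle is the fidelity format.

# Study sizes used by the tests and the acceptance script

The packaged studies run at the full design sizes (63 x 6 x 9000 and
114 x 6 x 2050). The FSE-vs-KBM discrimination study averages over 8
seeded replicate datasets and the sigma sweep uses the seven-point grid
`{1e-3, ..., 1e3}` on one seeded dataset; both sizes are the package's
choice of a study large enough to make the qualitative ordering stable
across seeds while keeping a full run in tens of seconds. Unit tests use
a shortened excitation (8 s at 40 Hz) for speed; nothing in the methods
depends on the cycle length.

# Known limitations

* The flat-kernel failure mode analyzed above means KELM accuracy at
  extreme `sigma` depends on the raw-data dynamic range; on instruments
  with a narrow range the plateau will be narrower than the simulated one.
* The simulator's class model (permuted magnitude ladders) is a
  structural, not a chemical, model of liquid diversity; parameters were
  chosen for realism of scales, not fitted to any measured dataset.
* `kernel_name` values other than `"rbf"` (and `"linear"` for KELM) are
  stubs that raise not-implemented errors, mirroring the scope of the
  underlying methodology.
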