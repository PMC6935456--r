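---
title: "Consolidation-layer networks for multi-study gene selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidation-layer networks for multi-study gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conslayer)
```

## The model

`conslayer` fits a feedforward network whose topology mirrors the
structure of vertically integrated omics data: D studies measure the same
K genes on one cohort of N samples with a binary outcome. Instead of fully
connected layers, every gene k owns a small private branch:

* one **hidden node per study**, `O_km = ReLU(Σ_p v_kmp x_kmp)`, where in
  the common case each node sees a single input feature (that gene's value
  in that study, P = 1);
* one **consolidation node**, `C_k = Σ_m w_km O_km / ‖w_k‖₂`, fusing the
  per-study evidence with norm-normalized weights;
* a logistic **output layer**, `f = plogis(β₀ + Σ_k β_k C_k)`, whose
  coefficients are penalized: the objective is the mean binary
  cross-entropy plus `λ Σ_k |β_k|`, with β₀ unpenalized.

Two consequences of this design carry all the interpretation. First, the
norm normalization makes `C_k` invariant to positive rescaling of `w_k`
(degree-0 homogeneity; its gradient is exactly orthogonal to `w_k`), so
the per-gene scale is identified: only `β_k` says how much gene k matters.
Second, the L1 penalty shrinks the `β_k` of uninformative genes toward
zero, turning the fitted network into a gene-selection device: a gene is
called *selected* when `|β̂_k|` exceeds a threshold ε (default `1e-2`).
The optimizer smooths the penalty, so exact zeros never occur and a
magnitude threshold is the natural call.

Assumptions worth keeping in mind: studies are aligned by gene and by
sample (same cohort, same order), the outcome is binary, and each study
branch has a single hidden layer. Multi-class outcomes and deeper branches
are out of scope.

## Training

**Initialization.** All `v` and `w` weights start at 1, a neutral fusion
of the studies. One feedforward with those unit weights produces the
consolidation matrix C; the output coefficients start at the ridge
solution `(XᵀX + λ_ridge I)⁻¹ Xᵀy` on the design `X = [1 | C]`
(`ridge_lambda`, default 1). The ridge form is essential because K
typically exceeds N; it spreads initial credit across correlated genes.
Note this closed form penalizes the intercept along with the rest, so the
initial β₀ starts well below its optimum — which matters for the learning
rate below.

**Output coefficients (Newton-style).** Each epoch updates every `β_k` by
gradient over curvature, where the data terms are `Σ_i (f_i−y_i) C_ik` and
`Σ_i f_i(1−f_i) C_ik²` and the penalty contributes `Nλ·sign(β_k)` and
`Nλ·z′(β_k)`. Here `z(β) = 2·plogis(β/s) − 1` is a smooth sign
approximation with scale `s` (default `1e-3`): its derivative supplies the
curvature the raw |β| lacks at 0, and because `z′(0) = 1/(2s)` is large, a
coefficient that reaches 0 is effectively pinned there — this is the
mechanism that makes large λ drive every coefficient below ε, which the
test suite checks directly at λ = 10³. `sign(0)` is taken as 0.

Two safeguards wrap this step. Curvatures below `1e-10` (probability
saturation makes `f(1−f)` vanish) fall back to a plain gradient step of
size η. And because the per-gene curvature is only the diagonal of the
true Hessian — it ignores coupling between correlated genes — the
simultaneous full step can overshoot; a backtracking line search halves a
common step factor (starting from the full step, at most 60 halvings)
until the objective, with C held fixed, does not increase. The unmodified
printed step is taken whenever it already descends, which is the usual
case near convergence; without the safeguard the objective can diverge
within a few epochs on perfectly ordinary instances.

**Remaining weights (gradient descent).** β₀, `w` and `v` each take a
full-batch gradient step of size η, in the fixed order β → β₀ → w → v,
each from a freshly recomputed forward state (the implementation
recomputes only the layers downstream of the touched weights, which is
arithmetically identical). The `w` gradient is the exact derivative of the
normalized consolidation,
`(1/N) Σ_i (f_i−y_i) β_k [O_mik/‖w_k‖ − w_mk Σ_s w_sk O_sik / ‖w_k‖³]`;
a squared-norm variant of the correction term can be selected with
`exact_w_grad = FALSE` for comparison, but the cubed norm is what the
chain rule gives and is what matches finite differences (tested to 1e-5
relative error, as are all the other gradients). The ReLU derivative at
exactly 0 is taken as 0, the conventional subgradient choice. If a `w`
step would drive a gene's norm below `1e-8` (the consolidation divides by
it), the updated vector is rescaled to that floor with a warning.

**Learning rate and epochs.** Defaults are `eta = 0.3` and
`epochs = 200`, with an early stop when the objective changes by less
than `tol = 1e-6` between epochs. The learning rate was chosen on
optimization grounds: the intercept's gradient is bounded by 0.5, so a
rate of order 0.01 can move β₀ by at most ~0.005 per epoch while the
ridge initialization leaves it an O(1) distance from its optimum — such a
configuration cannot approach the minimum in any reasonable number of
sweeps, and the slack is absorbed by spurious near-constant ReLU columns
acting as surrogate intercepts. Rates up to 1.0 remained monotone on
simulated data across the noise range (the β step is protected by its own
line search and the `w`/`v` gradients shrink as probabilities saturate);
0.3 keeps a threefold margin. 200 epochs is where both the objective and
the selection pattern plateau on the simulator's problem sizes, and keeps
the 30-repetition benchmark harness affordable. Both are ordinary control
parameters (`idl_control()`) for anyone who wants longer runs.

**Numerical details.** Predicted probabilities are clipped to
`[1e-12, 1 − 1e-12]` before logarithms. Training aborts with a diagnostic
if the objective turns non-finite. Everything is full-batch and
deterministic given the inputs: no minibatching, momentum, or adaptive
rates, and the only randomness in the whole pipeline (generation, splits,
folds) flows from explicit seeds.

## The synthetic-data generator

`sim_design()` / `generate_stack()` emulate a two-class multi-study
design: K = 80 genes per study, of which 16 are *signal* and 64
*nonsignal*, D = 3 studies over one cohort of N = 100 samples (50/50
cases and controls), and a stratified 70/30 train/test split. Nonsignal
genes are `MVN(0, σ²I)` for every sample. Signal genes are
`MVN(m, σ²Σ)`, where m equals μ on every signal gene for cases and 0 for
controls, and Σ is block-exchangeable: the 16 signal genes form two
clusters of 8 with correlation ρ inside a cluster and independence
between clusters and with all nonsignal genes. *Random studies* (0–2 of
the D) replace every gene, signal or not, by `MVN(0, σ²I)` — pure noise
used to probe robustness to uninformative platforms.

Where the design was genuinely open, the defaults are the smallest
structure consistent with the intended picture and were fixed once:
μ = 1 applied to cases only, ρ = 0.5, N = 100 balanced, an 8/8 cluster
split, control-class signal genes sharing the same Σ, and the same mean
shift in both clusters. All are plain fields of `sim_design()`. The
generator's moments are verified against their targets (noise SD scales
with σ; the signal-block covariance recovers σ²Σ to within 5% relative
Frobenius error at large N; random studies carry no class signal).

What the generator does *not* emulate: real TCGA marginal distributions,
methylation beta-value boundedness, CNV discreteness, missingness,
batch effects, or unequal cohorts across studies. Passing benchmarks here
therefore says the method recovers planted multivariate-normal signal
under honest noise — not that it inherits those properties on real
platform data.

One regime deserves an explicit caveat. Because μ is fixed while σ
varies, small σ makes the signal-to-noise ratio extreme (μ/σ = 10 at
σ = 0.1) and the selection problem degenerate in two opposite ways: with
all studies informative, essentially every signal gene is individually a
near-perfect separator and the magnitude threshold selects almost all of
them (sensitivity and specificity both approach 1); with two of three
studies pure noise, a single signal gene suffices for perfect
classification and the penalized optimum concentrates credit on one or
two representatives of the correlated clusters, collapsing sensitivity.
Both behaviors are properties of the lasso-logistic objective under this
generator, not optimizer artifacts, and they bound how literally the
benchmark's low-noise cells should be read.

## Evaluation harness

`call_selection()` scores a selection call against the generator's truth:
sensitivity (signal genes selected), specificity (nonsignal genes left
out), and the Youden J index, enforced as exactly
sensitivity + specificity − 1. Degenerate truths (all signal or all
nonsignal) yield `NA` rates, or an error under `strict = TRUE`.

`lambda_path()` traces coefficients over an increasing penalty grid with
warm starts; the default grid `10^seq(-2.5, -0.5, length 6)` spans
negligible-to-total shrinkage on the standardized scale of the simulator
(total shrinkage at much larger λ is tested separately). `cv_lambda()`
picks λ by stratified 5-fold cross-validation, minimizing held-out
*unpenalized* cross-entropy, with ties broken toward the larger λ.

`run_experiment()` repeats the full pipeline — generate, split 70/30,
tune λ by CV on the training cohort, refit, call selection — `n_reps`
times (default 30) and reports means with standard errors computed as
sample SD / √reps. Within the CV, fold fits are capped at 100 epochs
(`cv_epochs`): they only rank penalties by held-out loss, while the final
fit uses the full budget. The shipped benchmark
(`scripts/acceptance.R` and the end-to-end tests) runs four design cells
(σ ∈ {0.1, 0.9} × {0, 1–2 random studies}) at 30 repetitions each with
these problem sizes; a cell is roughly 30 × (5 folds × 6 grid points + 1)
fits of an 80-gene network on 70 samples.

## Known limitations

* Selection among strongly correlated signal genes inherits the lasso's
  representative-picking behavior; group-style penalties are not
  implemented.
* The Newton-style output step uses diagonal curvature only; the
  backtracking safeguard makes it robust but convergence is linear, not
  quadratic, when genes are strongly coupled.
* Per-gene architecture is rectangular (every gene has the same number of
  hidden nodes and features per node).
* The CLI and file formats support one value per gene per study; richer
  per-node feature sets (P > 1) are available through the programmatic
  interface only.
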