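---
title: "Methods: design, regression ranking, synergy and concordance in qpopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, regression ranking, synergy and concordance in qpopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpopr)
```

`qpopr` implements the analysis layer of a quadratic phenotypic optimization
screen: from a small designed array of drug-dose combinations tested on one
patient sample, estimate a second-order viability model and rank every
candidate combination therapy. This vignette records the model, the
numerical and design choices, and what the synthetic-data generator does and
does not emulate — the reasoning a maintainer or reviewer would otherwise
have to reconstruct.

## The screening model

Each of the 12 panel drugs is tested at three coded dose levels
$x_i \in \{0, 1, 2\}$, corresponding to no drug (IC0), the IC10 dose and the
IC20 dose. Normalized cell viability is modelled as the full second-order
polynomial

$$\mathrm{NCV}(x) = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
  \sum_{i<j} \beta_{ij} x_i x_j,$$

with $1 + 2F + F(F-1)/2 = 91$ terms for $F = 12$. The core assumptions are:

* **Coded-level regression.** The regression operates on the codes, not on
  micromolar doses. Dose spacing differs per drug (each drug's IC10/IC20 are
  its own), and coding absorbs that: the model asks "what happens at this
  drug's calibrated effect levels", not "per µM". A consequence verified by
  a property test is affine-recoding invariance: recoding levels
  $\{0,1,2\} \to \{-1,0,1\}$ changes coefficients but reproduces every
  enumerated prediction to $10^{-10}$, because the model space is the same.
* **Quadratic truncation.** Curvature beyond second order and three-way
  interactions are not estimable from 155 runs and are assumed negligible.
* **Unclipped predictions.** Predicted NCV is not clipped to $[0,1]$;
  strongly synergistic extrapolations can fall below 0 and are annotated
  "≤0 (model extrapolation)" in reports rather than hidden.

## The 155-run composite design

The design concatenates two blocks:

* a $2^{12-5}$ resolution-IV fractional factorial (128 runs) on the extreme
  levels $\{0, 2\}$, which carries most of the main-effect and interaction
  information. The five generator words (factors 8–12 as products of base
  factors 1–7: $x_8 = x_1x_2x_3x_4$, $x_9 = x_1x_2x_3x_5$,
  $x_{10} = x_1x_4x_5x_6$, $x_{11} = x_2x_4x_6x_7$,
  $x_{12} = x_3x_5x_6x_7$) are a fixed constant chosen by exhaustive
  minimum-aberration search over all length-4 generator words; the defining
  contrast subgroup has minimum word length 4 (resolution IV) with a single
  length-4 word, and `oacd_word_lengths()` exposes the full word-length
  pattern so tests verify the resolution rather than assume it;
* the first 12 columns of the canonical L27($3^{13}$) orthogonal array
  (27 runs), generated as all distinct nonzero linear forms over
  $\mathrm{GF}(3)^3$ with leading coefficient 1. Every column carries each
  level exactly 9 times; this block supplies the pure-quadratic information.

`validate_design()` reports the numerical rank of the 155 × 91 expanded
basis; full rank (91) means every coefficient is estimable. The layout is
deterministic: run-to-well randomization, if wanted, belongs to the physical
plate map, not the design object.

## Plates, normalization and quality gating

Raw luminescence is normalized per plate against the mean positive control
(vehicle-treated cells, viability 1) and mean negative control (background,
viability 0): $\mathrm{NCV} = (y - \bar y_{neg})/(\bar y_{pos} - \bar y_{neg})$.
The transform is affine, so it is invariant to any gain/offset applied to
the whole plate, and the mean of replicate NCVs equals the NCV of the mean
raw value — both are property-tested. NCV is never clipped; values outside
$[-0.2, 1.5]$ are flagged for inspection but retained, since the regression
is the proper place to absorb noise.

Assay quality uses the two standard screening statistics with sample SDs
(n − 1): $Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$ and
$\mathrm{SSMD} = (\mu_{pos}-\mu_{neg})/\sqrt{\sigma_{pos}^2+\sigma_{neg}^2}$.
The gate is $Z' \ge 0.5$, the conventional high-throughput threshold; it is
a configurable parameter because the underlying protocol does not fix one.
Gating is per plate, with a sample failing if any of its plates fails
(worst-case pooling). On a noiseless simulated plate $Z' = 1$ exactly while
SSMD is undefined (zero variance in both controls); `ssmd()` errors there,
and the per-plate QC wrapper reports `NA` for SSMD since Z′ — the gating
statistic — is still defined.

## Enumeration, ranking and reports

A therapy of order $k$ is a set of $k$ distinct drugs, each at level 1 or 2,
all others at level 0 (absence of drug; IC0 is operationalized as dose 0).
The "mean NCV of a therapy" averages only these nonzero permutations —
2 values for a single agent, 4 for a pair, 8 for a triplet — because
including level-0 permutations would collapse a therapy into its lower-order
sub-therapies. Unique therapies are ranked ascending by mean NCV with a
deterministic lexicographic tie-break on drug indices; the best
(lowest-NCV) permutation rank is also exported because some users rank on
the best permutation instead, and the two orderings are not identical. The
ranking path is verified against a brute-force enumeration oracle in the
tests.

Response-surface grids evaluate the fitted polynomial over
$[0,2]^2$ for one pair with all other drugs at 0 (41 × 41 nodes by
default); grid corners coincide with point predictions by construction.
Per-sample reports (QC block, top-10 pairs, full single-agent table,
named-therapy comparisons) serialize to JSON deterministically, so
regenerating a report from the same inputs is byte-identical.

## Dose-response fitting

Single-drug curves use the four-parameter logistic on log dose with box
constraints `bottom` ∈ [−0.1, 0.5], `top` ∈ [0.5, 1.2], `hill` ∈ (0.1, 10],
fitted by Levenberg-Marquardt from a multi-start grid (four Hill slopes ×
five IC50 decades spanning the dose range); the best converged start by RSS
wins. Flat data (range < 10⁻³) is rejected up front as unidentifiable
rather than returning an arbitrary boundary IC50. IC values are obtained by
the closed-form inverse $D = \mathrm{IC}_{50}(e/(1-e))^{1/h}$.

The median-effect (Chou) model regresses $\log(f_a/(1-f_a))$ on $\log D$
with $f_a = 1 - \mathrm{NCV}$. Points with $f_a$ exactly 0 or 1 carry no
information on the logit scale and are excluded with a warning (counts
reported); remaining values are clamped to $[10^{-6}, 1-10^{-6}]$. Both the
4PL and the median-effect inversion are provided for IC10/IC20 derivation,
since either is defensible and the choice is left to the user.

## Synergy quantification

The combination index uses the classic constant-ratio, mutually exclusive
Chou-Talalay form: at each affected fraction $f_a$, the combination's own
median-effect fit (on total dose at the fixed panel-derived ratio) gives
the total dose, its components $d_1, d_2$ follow from the ratio, and
$CI = d_1/D_{x,A} + d_2/D_{x,B}$. Two identities anchor the implementation:
a drug combined with itself at 1:1 gives $CI \equiv 1$ (checked to
$10^{-9}$ on a 99-point grid), and jointly rescaling all potencies leaves
CI unchanged.

Bliss scoring clamps inhibition to $[0,1]$ (clamp counts reported), takes
the expectation $i_A + i_B - i_A i_B$ from the zero-dose margins, and
summarizes the excess as the unweighted mean over cells with both doses
nonzero, in percentage points — one score per matrix, classified
synergistic above +10 and antagonistic below −10 with strict inequalities
(a score of exactly 10 is additive). Under an exact product-survival matrix
the score is 0 identically, and a multiplicative potentiation factor
$\gamma$ on combination survival flips the score's sign with
$\mathrm{sign}(1-\gamma)$ — both property-tested.

## Concordance statistics

Responders are PR ∪ SD; the classifier score is the negated mean NCV so
that AUC ≥ 0.5 for a concordant screen. AUC is computed from midranks
(Mann-Whitney with tie correction) and verified against an explicit
pair-counting oracle and against `pROC`; the p-value is the two-sided
Wilcoxon-Mann-Whitney test; the AUC interval is the Hanley-McNeil normal
approximation. The reported NCV cutoff maximizes Youden's J over midpoints
between adjacent distinct values (ties resolved toward the lower
threshold).

The 2×2 responder table reports the sample odds ratio $ad/bc$, a Woolf
logit 95% CI with Haldane 0.5 correction on zero cells (a conditional-MLE
interval via `fisher.test` is available — note the two intervals differ,
and neither is asserted against external values), and the exact two-sided
Fisher p as the sum of hypergeometric point probabilities no larger than
the observed table's (within 10⁻⁷ relative tolerance, guarding against
floating-point near-ties). Total predictive value is $(a+d)/N$; sensitivity
$a/(a+c)$ and specificity $d/(b+d)$ follow the responder-column convention.
Group comparisons default to the equal-variance Student's t (two-sided),
with Welch behind a flag; degenerate zero-variance inputs return the
conventional $t=0, p=1$ for identical groups and are flagged degenerate
otherwise.

## What the synthetic generator emulates — and what it does not

The generator exists so that every pipeline stage has a ground truth. It
emulates:

* quadratic viability surfaces with baseline 1 at zero dose;
* planted synergistic pairs: interaction coefficients at or below
  −`effect_scale` (default 0.2), against a background of small interactions
  (|β| ≤ 0.02) so the planted signal is identifiable;
* heterogeneous single-agent sensitivity: linear coefficients drawn from
  U(−0.13, 0). The anchor is the dose coding — a fully sensitive sample at
  its nominal IC20 has $\beta_i \approx -0.1$ (20% inhibition at level 2,
  with $\beta_{ii} \approx 0$ from solving the IC10/IC20 pair) — while
  resistant samples sit near 0 because nominal IC doses are calibrated on
  reference material, not on the individual sample. Under this prior a
  random two-drug therapy's mean NCV centers near 0.8, the scale on which
  screened therapies discriminate clinical response;
* technical duplicates, 16 positive and 16 negative control wells, and
  additive Gaussian noise on the NCV scale (default SD 0.02 — the true
  screen noise magnitude is unpublished, so this is a documented guess
  exposed as a parameter); control wells get signal-proportional noise
  (CV = `noise_sd`), the way luminescence noise scales;
* outcome-linked cohorts: treatment outcomes labelled responder with
  probability $\mathrm{logit}^{-1}(-k(\overline{\mathrm{NCV}} - c))$
  (defaults $c = 0.8$, $k = 25$, label noise 0.05), split PR/SD in roughly
  the observed 7:9 proportion, PD otherwise.

It deliberately does **not** emulate: tumor biology or subtype structure,
pharmacokinetics, plate-position artifacts (edge effects, drift), dispenser
error, or the zero-count censoring of a real luminometer. The last point is
a conscious trade-off: the simulated signal is the exact affine image of
the surface, so that noiseless plates round-trip through normalization to
the generating surface to machine precision and the 91 coefficients are
recovered exactly — the property the whole recovery test suite rests on. A
real instrument floors at zero counts, which would censor exactly the
strongly-killed wells that carry the synergy signal; robustness to that
censoring is outside what passing tests demonstrate. Likewise, passing
recovery tests show the estimator is correct under the generator's
assumptions, not that real screens meet them.

## Problem sizes and runtime choices

The test suite and acceptance script size their simulations for a desk-scale
run: the planted-pair recovery experiment uses 100 seeded cohorts (one plate
each on the 155-run design, duplicates, noise SD 0.02), and the
outcome-threshold recovery experiment uses 200 seeded cohorts of 3 samples
and 27 outcomes each — enough for a stable median while keeping the full
suite under a minute of simulation. All randomness flows from explicit
seeds; fixed seeds give byte-identical serialized cohorts.

## Known limitations

* Only the 12-factor design is registered; other factor counts need a
  suitable fractional-factorial/orthogonal-array pairing to be added.
* OLS on replicate-level observations, unweighted; no robust or regularized
  variants.
* CI requires a constant-ratio combination series; non-constant-ratio
  designs and Loewe/ZIP/HSA surface models are out of scope.
* The concordance module reproduces the *statistics*, not the study: per-case
  NCVs behind the published ROC are unavailable, so ROC/AUC and cutoff
  behavior are validated by parameter recovery on synthetic cohorts, and the
  published AUC and cutoff values are not asserted anywhere.
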