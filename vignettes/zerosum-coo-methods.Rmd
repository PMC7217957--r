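---
title: "Methods: zero-sum protein signatures for DLBCL cell-of-origin subtyping"
author: "zeroSumCOO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-sum protein signatures for DLBCL cell-of-origin subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeroSumCOO)
```

## The problem

Diffuse large B-cell lymphoma (DLBCL) is routinely subtyped by its putative
cell of origin (COO) into activated B-cell-like (ABC), germinal-center
B-cell-like (GCB) and unclassified cases, because the subtypes differ in
biology, prognosis and treatment response. The reference assays are
transcriptomic and tied to proprietary platforms. This package implements a
protein-level alternative: a sparse linear signature over eight protein
groups, applied to log2-transformed protein intensities from
data-independent-acquisition (SWATH/DIA) mass spectrometry of
formalin-fixed, paraffin-embedded tissue, producing a continuous GCB score
that is thresholded into the three COO classes.

The defining property of the signature is that its weights sum to zero.
For log2 intensities $x_{ij}$ of sample $i$, the score is

$$s_i = \beta_0 + \sum_j \beta_j x_{ij}, \qquad \sum_j \beta_j = 0 .$$

Multiplying all raw intensities of a sample by a constant $2^c$ adds $c$ to
every log2 intensity, and the added term $c\sum_j\beta_j$ vanishes. The
score therefore depends only on intensity *ratios* within a sample and is
insensitive to the reference point of the measurement: sample loading,
ionization efficiency, and — up to a protein-independent offset — the
measurement platform itself. Moving the signature from one instrument to
another requires adjusting only the intercept $\beta_0$.

## Model fitting: zero-sum elastic net

`fitZeroSum()` minimizes

$$\frac{1}{2n}\sum_i\bigl(y_i-\beta_0-x_i^\top\beta\bigr)^2
 + \lambda\Bigl(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Bigr)
 \quad\text{s.t.}\quad \textstyle\sum_j\beta_j = 0,$$

where $y$ are reference GCB scores. The default $\alpha = 1$ (pure lasso
penalty) yields sparse signatures. The constraint is handled by **pairwise
coordinate descent**: ordered coordinate pairs $(j,k)$, $j<k$, are visited
in deterministic cyclic order, and each visit moves
$(\beta_j,\beta_k)\to(\beta_j+\delta,\beta_k-\delta)$ — a direction that
preserves the constraint exactly — with $\delta$ chosen as the exact
minimizer of the one-dimensional piecewise-quadratic restriction (the
stationary points of the four sign regions plus the two kinks at
$\delta=-\beta_j$ and $\delta=\beta_k$). The intercept is unpenalized,
excluded from the constraint, and equals $\bar y - \bar x^\top\beta$ at
every sweep. Deterministic cyclic sweeps were chosen over randomized ones
for bit-reproducibility.

Numerical choices:

* convergence when the objective decreases by less than `tol` $=10^{-8}$
  (absolute) in a full sweep; sweep budget 10,000;
* features are **not standardized** — standardization would destroy both
  the additive-shift invariance and the ratio interpretation;
* the penalty path is geometric from $\lambda_{max}$ (the smallest
  $\lambda$ with an all-zero solution,
  $\max_{j<k}|(x_j-x_k)^\top(y-\bar y)|/(2n\alpha)$) down to
  $10^{-4}\lambda_{max}$ over 100 points, warm-started from larger to
  smaller $\lambda$;
* identical columns make a pair direction degenerate and are skipped; a
  constant response makes $\lambda_{max}=0$ and falls back to a tiny
  default grid with a warning;
* after each path point the (floating-point) constraint drift is removed
  by re-centring the *nonzero* coefficients only, so exact zeros remain
  exact and support counts are meaningful.

The solver is exercised against an exhaustive independent oracle in the
test suite: for $p\le 8$ all $3^p$ sign patterns are enumerated and each
pattern's equality-constrained quadratic subproblem is solved through its
KKT system, which certifies the global optimum of the convex problem.

## Cross-validation and model selection

`cvZeroSum()` assigns samples to ten near-equal folds by a seeded shuffle,
fits the path on each fold complement, and records held-out squared error.
The error curve is the mean of fold means; its standard error is
$sd(\text{fold means})/\sqrt{k}$. The selected penalty is `lambda.1se`,
the largest $\lambda$ within one standard error of the curve minimum —
the parsimony-favouring rule that produced the published eight-protein
model from 780 candidate proteins. Fold means are averaged with equal
weight even when folds differ by one sample.

## Classification, boundaries and platform transfer

`assignLabels()` applies the published decision rule: scores strictly
below the lower boundary are ABC, strictly above the upper boundary GCB,
anything else (including exact boundary hits, which the published strict
inequalities leave unassigned) is unclassified. The packaged boundaries
are $(-3.50,\ 1.28)$.

`trainBoundaries()` re-derives boundaries on a labelled cohort by
exhaustive search over all candidate cut pairs — midpoints between
adjacent distinct sorted scores plus $\pm\infty$ sentinels — minimizing
total misclassifications. Among ties the pair maximizing the minimum
distance from any score to its nearest finite boundary wins, and remaining
ties resolve to the smallest cuts, making the result deterministic. The
search is provably optimal and is compared against an independent
brute-force implementation in the tests.

`tallyDiscrepancies()` follows the field's usage: *minor* discrepancies
are switches involving the unclassified middle class, *major* ones are
direct ABC–GCB swaps.

`transferOffset()` estimates the platform adjustment
$\Delta = \mathrm{mean}(s^{ref} - s^{new})$ over paired samples. Because
the weights sum to zero, any protein-independent platform offset cancels
and $\Delta$ absorbs exactly the protein-*dependent* component; applying
it equalizes platform means exactly and leaves the cross-platform Pearson
correlation untouched.

## Preprocessing rules

`rollupProtein()` sums, per sample and protein group, the six most
abundant proteotypic peptides of at least eight amino acids (ties broken
lexicographically by sequence, for determinism). `filterMissing()` keeps
proteins with fewer than four missing values by default.
`imputeGlobalMin()` replaces missing and zero entries by the smallest
observed intensity of the whole matrix — the global minimum, not a
per-protein one. `totalSumNormalize()` divides each sample by its total
intensity; the zero-sum score is provably identical with or without it
(the tests verify this numerically), so it is kept only for
cross-sample comparability of the intensities themselves.

One wording ambiguity deserves a note: protein quantities are described
both as "summed log2-transformed fragment ion intensities" and as
log2-transformed protein intensities. This package sums raw intensities
within a protein group first and log2-transforms the sum: summing
log-intensities would make the protein value a log of a product rather
than of a total ion current and would destroy the ratio interpretation
the zero-sum construction relies on. The alternative reading is not
asserted to be wrong for the original analysis; it is simply not the one
implemented.

## The targeted panel

`buildSignaturePanel()` emits the 17 proteotypic peptides (eight
proteins) used for targeted verification by SRM/PRM, with precursor and
y/b fragment m/z recomputed from six-decimal monoisotopic residue masses,
water 18.010565 Da and proton 1.007276 Da, plus four modifications:
N-terminal pyro-glutamate (−17.026549), cysteine propionamide
(+71.037114, the acrylamide adduct from gel-assisted digestion),
methionine oxidation (+15.994915) and asparagine deamidation (+0.984016).
Distributed m/z values are library-observed, so agreement is required
within ±0.001 rather than exactly. Charges are assigned per row by best
match to the distributed value: five precursors (including both 22-mer
ribosomal-protein peptides) are only consistent with 3+, and two fragments
of the deamidated peptide with 2+, regardless of the column headers under
which such values are conventionally printed. One distributed fragment
annotated b6 matches b9 theory exactly and is recorded as b9. Neutral
losses, a/c/x/z ions and isotope peaks are out of scope.

## Retention-time recalibration

`fitRtMap()` fits an ordinary least-squares line from observed to
reference retention times on spike-in anchor peptides spanning the
gradient (27 in the standard kit), reporting the residual RMSE;
`matchWithinWindow()` applies the ±5-minute library-matching window,
inclusive at the boundary (a choice this package documents; nothing hangs
on it). No robust loss is used — the anchors are synthetic standards —
and nonlinear (loess/spline) alignment is a non-goal.

## The synthetic cohort generator

`simulateCohort()` generates the statistical structure the analysis
assumes, so every stage is testable without any external download:

$$x_{ij} = b_j + f_i + \ell_j t_i + v_{ij} + \varepsilon_{ij}$$

on the log2 scale, exponentiated to raw intensities, with

* true scores $t_i$ from a bimodal mixture
  ($0.45\,N(-6,1.5^2) + 0.45\,N(4,1.5^2) + 0.10\,U(-3.5,1.28)$), mimicking
  the ABC/GCB poles and sparse unclassified middle of a development cohort
  with an 18/4/20 class split;
* baselines $b_j \sim N(18, 2^2)$ log2 ion-count units, re-centred on the
  signature support so the intercept is honoured;
* per-sample size factors $f_i \sim N(0, 1)$ — the reference-point shifts
  the zero-sum score must cancel;
* loadings $\ell = w/\|w\|_2^2$ for the true signature $w$, so scoring
  noise-free data returns $t_i$ *exactly*;
* per-protein biological variation $v_{ij} \sim N(0, 1)$ whose component
  along $w$ is projected out on the signature support (keeping the score
  identity exact);
* measurement noise $\varepsilon_{ij} \sim N(0, 0.5^2)$;
* missing-not-at-random dropout: only entries in the lowest quartile of
  their protein may drop out, with probability `missingRate/mnarQuantile`
  (defaults 0.05/0.25), reproducing the low-intensity bias of DIA data at
  the few-percent missingness typical of proteins that survive the
  missing-value filter.

The default true signature is the packaged eight-protein weight vector
rescaled to unit L2 norm. At the published scale ($\|w\|\approx 6.9$) the
per-protein signal implied by $\ell = w/\|w\|^2$ would sit far below the
measurement noise and no method could recover anything; unit norm makes
the loadings equal the weights and places per-protein signal and noise in
a realistic ratio.

The biological-variation term deserves its own justification. Without it
the informative part of the data is exactly rank one: every signature
protein carries the *same* latent variable scaled by its loading, so any
two extreme-loading proteins can reproduce the score with smaller
$\ell_1$ norm than the full signature, and an $\ell_1$-penalized fit will
prefer them. Support recovery would then be impossible *by construction*
— not a property of the method but of the simulation. Real protein
abundances vary per protein for biological reasons, and a composite score
is a function of the proteins rather than the other way round; $v_{ij}$
restores exactly this identifiability (cancelling in the true score
because it is orthogonal to $w$) at a magnitude, 1.0 log2 units, typical
of inter-tumour fold changes.

`applyPlatformShift()` re-measures a cohort on a simulated second
platform: a global (or optionally protein-dependent) log2 offset plus
fresh noise. True scores are unchanged; a global offset is cancelled by
any zero-sum signature, while protein-dependent offsets induce exactly
the mean score shift that `transferOffset()` must absorb.

## What the tests do and do not show

The suite verifies, among other things: exact agreement of all 51 panel
transitions with their distributed values within ±0.001; the collapse of
the packaged signature to its intercept on equal intensities; solver
optimality against the sign-enumeration oracle (25 seeded instances,
relative gap $<10^{-5}$) and the $p=2$ closed form ($<10^{-8}$);
reference-point insensitivity of predictions to $10^{-10}$; optimality of
boundary training against brute force up to $n=30$; and score recovery
$r\ge0.9$ on 50 seeded default cohorts (all 50 runs pass).

Two honest caveats. First, on pure-noise responses the `lambda.1se` model
is the null model in about three quarters of seeded runs, not more: with
the standard error defined as $sd(\text{fold means})/\sqrt{k}$, interior
dips of the CV curve exceed one standard error more often than folklore
suggests. Second, at the default study scale the `lambda.1se` model
retains at least six of the eight true proteins with correct signs in
roughly half the runs, not ninety percent: the parsimony rule
systematically drops the two smallest weights (unit-norm magnitudes 0.13
and 0.15 against a 0.65 maximum). This is the same behaviour that makes
the rule select eight proteins out of 780 — parsimony and complete
support recovery pull in opposite directions — and the corresponding
assertion is left failing in the acceptance tests rather than weakened.

Problem sizes throughout (cohorts of $n=100$, $p=50$; 50 seeded
repetitions; oracle instances $n\le20$, $p\le8$) were chosen as the
smallest designs at which the statistical claims are meaningfully
testable.

The generator does not emulate: peptide-level interference, FFPE
degradation chemistry, correlated protein modules beyond the single score
factor, batch structure within a platform, or label noise in the
reference scores. Passing tests therefore show correctness of the
*method* under the stated model, not performance on any particular
clinical cohort; the published cohort-level correlations (0.873, 0.846,
0.815, 0.962, 0.971, 0.981) require the deposited specimen data and are
deliberately not asserted anywhere.

## Known limitations

* Gaussian linear regression only; no binomial or survival families.
* The published signature's weights cannot be re-derived here — that
  requires the original cohort — so the packaged weights are distributed
  as data and verified through their structural consequences (zero sum,
  intercept collapse).
* The boundary trainer is exact but quadratic in the number of distinct
  scores; fine for cohort sizes in the hundreds.
* Scores exactly on a boundary are unclassified; the published rule uses
  strict inequalities and leaves the boundary itself unstated.
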