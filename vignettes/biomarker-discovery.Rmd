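---
title: "Staged biomarker panel discovery when p >> n: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged biomarker panel discovery when p >> n: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sispanel)
```

## The problem and the model

A case–control proteomic discovery study measures p markers (here on the
order of 1433 plasma proteins, as relative-fluorescence-unit intensities)
on n subjects (here 40: 20 cases, 20 matched controls). With p ≫ n, a
single joint model is hopeless: marginal noise accumulates, spurious
correlations between irrelevant markers and the outcome are essentially
guaranteed, and any unregularized logistic fit is wildly overdetermined.
`sispanel` therefore implements a staged reduction:

1. per-marker marginal statistics (volcano view),
2. sure-independence screening (SIS) to a set comparable to n,
3. lasso-penalized logistic selection on the screened set,
4. backward AIC refinement to the final panel,
5. per-marker ROC characterization and leave-one-out cross-validation
   (LOOCV) of that panel.

All modelling happens on **log2-transformed, per-marker standardized**
values: for marker j, \(z_{ij} = (\log_2 x_{ij} - \bar m_j)/s_j\) with
the n−1 sample SD taken over all subjects jointly (cases and controls
pooled). Pooled standardization is a deliberate choice: the transform is
applied once, before any group comparison, so it cannot leak label
information into a single group's scale. Whether to pool is genuinely
open in studies of this kind; since the three group tests used downstream
are invariant to any per-marker affine map, the choice affects only the
scale on which coefficients and thresholds are reported, not the
inference. Fold changes are computed on the log2 values *before*
standardization (the standardized scale would force every marker's
apparent fold change toward the same magnitude), which is why the
standardized table retains its pre-standardization log2 values as an
attribute.

## Per-marker statistics and the volcano rule

Three two-sample tests are computed per marker, in fixed dialects:

* **Welch t** (unequal variances). "Two-sample t-test" is ambiguous;
  Welch is the safer default for intensity data and is what the common
  statistical environments default to. A marker that is constant in both
  groups gets p = 1 when the means agree (no evidence) and p = 0
  otherwise (infinite standardization), both flagged degenerate.
* **Kolmogorov–Smirnov**: exact tail probability when
  \(n_1 n_0 \le 10^4\) and there are no ties, asymptotic otherwise —
  the usual library convention, stated explicitly because exact vs
  asymptotic visibly changes small-sample p-values.
* **Mann–Whitney**: exact enumeration when both groups have ≤ 8
  observations and no ties; otherwise the normal approximation with tie
  and continuity corrections.

The implementations are vectorized across markers from sufficient
statistics (sample moments for Welch; ECDF gaps + `psmirnov` for KS;
midranks + `pwilcox`/normal tail for MW), which makes a full 1433-marker
battery run in well under a second; the test suite verifies each path
against `t.test()`, `ks.test()` and `wilcox.test()` to machine precision
on randomized instances with and without ties.

The volcano rule classifies a marker as differentially expressed iff
\(|\text{log2FC}| \ge 0.2\) (inclusive) and \(p_t < 0.05\) (strict),
with the *t*-test p-value — the volcano is built from separate t-tests.
No multiplicity correction is applied at this stage by design: the
volcano is a descriptive overview, and control of selection noise is
delegated to the screening and penalized-selection stages.

## Consensus sure-independence screening

For each test, markers are ranked by ascending p-value and the top d_n
retained; the **consensus** is the intersection of the per-test top
lists. Requiring a marker to rank highly under three tests with
different sensitivities (location, distribution shape, rank shift) is a
cheap robustness device against any single test's pathologies.

Tunables:

* `d_n` — retention size per test. Default 50 (a deliberately
  conservative choice at n = 40); `recommended_dn(n)` gives the
  screening literature's \(n/\ln n\) preset (11 at n = 40), rounded half
  away from zero.
* Ranking tie-breaks are fully deterministic: ascending p, then
  descending |test statistic|, then lexicographic marker id. The
  consensus is ordered by mean rank across tests — an artifact
  convention for stable output; scientifically the consensus is a set.

An empty consensus is a legal result (warning, not error); the pipeline
wrapper then stops with a stage-level error rather than silently fitting
a null model.

## Lasso selection and the λ question

On the screened markers a logistic lasso is fit (glmnet backend) with
the intercept unpenalized and **no internal re-standardization** — the
columns are already z-scores, and keeping them on that scale is what
makes \(e^\beta\) interpretable as an odds-ratio factor per 1 SD of the
marker.

How λ was chosen in studies of this design is typically unstated, so two
strategies are provided and recorded in the run manifest:

* `"cv"` (default): 10-fold stratified cross-validated deviance, λ at
  the minimum; folds are fixed by the seed, so the fit is reproducible.
* `"support_size:K"`: the largest λ on the path whose support has
  exactly K markers — useful to emulate a reported screened→selected
  step (e.g. 15 → 12) without claiming to recover the original λ. If no
  path point has exactly K nonzero coefficients the largest λ with at
  least K is used and flagged.
* A fixed numeric λ, with λ = 0 meaning the unpenalized maximum
  likelihood fit by Newton/IRLS (verified against `stats::glm` to 1e-4).

Support extraction uses a zero tolerance of 1e-8 on |β|: a marker the
lasso shrank to exactly zero is *excluded*, while a marker retained with
a tiny coefficient (the published panel's TNFSF14 at −0.002 is the
canonical example) is *included*. The support is reported ordered by
per-marker AUC, then |β|.

## Backward AIC and separation

`step_aic_refine()` is a deterministic backward eliminator: from the
lasso support, repeatedly refit the unpenalized logistic model with each
single marker removed, drop the marker whose removal lowers
\(\mathrm{AIC} = -2\log L + 2(k+1)\) the most (k markers + intercept),
stop when no removal lowers AIC; candidate ties break by marker id. The
suite cross-checks the procedure against `MASS::stepAIC` on a clean
fixture.

At n = 40 with strong markers, complete or quasi-separation of the
classes is the norm rather than the exception. Any unpenalized candidate
fit that fails to converge or perfectly separates is refit with a small
ridge (1e-6 added to the Hessian diagonal) and flagged; the AIC of such
a fit uses the unpenalized log-likelihood evaluated at the stabilized
estimate. This keeps the eliminator total and deterministic while
leaving an audit trail (`separation` column in the trace). Under the
null, the removal of a pure-noise marker is accepted whenever its
likelihood-ratio statistic is below the AIC penalty of 2 —
asymptotically with probability `pchisq(2, 1)` ≈ 0.843 — so a single
noise marker survives backward AIC roughly one time in six; this is a
property of AIC itself, not of the implementation, and the test suite
asserts exactly that rate (3σ binomial band) rather than pretending the
step is a perfect filter.

## ROC, Youden cutoffs, LOOCV

Per-marker discrimination is the **empirical AUC** — the normalized
Mann–Whitney U, ties counted half — computed from midranks and verified
exactly against an \(O(n^2)\) pair-counting oracle. Each marker is
oriented so AUC ≥ 0.5, which fixes the decision direction ("case if
value ≥ c" vs "case if ≤ c"). Candidate thresholds are the midpoints
between consecutive sorted unique values plus ±∞, so sensitivity and
specificity are step-consistent regardless of ≥/> conventions; the
returned cutoff maximizes the Youden index J = sensitivity +
specificity − 1, ties resolved toward higher specificity. Thresholds are
reported on the standardized scale, the scale on which the panel
operates.

LOOCV refits the unpenalized logistic model of a **fixed** panel on each
n−1 subset and classifies the held-out subject at probability ≥ 0.5
(the boundary counts as a case). Selection is deliberately *not*
repeated inside the loop — this mirrors the protocol such studies report
and therefore carries the well-known post-selection optimism; the
package documents the bias rather than silently "fixing" it, and the
test suite demonstrates it (in-sample accuracy ≥ LOOCV accuracy in
≥ 95% of simulated replicates). Two exact pathologies make good
canaries and are asserted in the tests: an intercept-only "panel" on
balanced labels misclassifies *every* held-out subject (the held-out
case leaves a case minority behind, and vice versa — accuracy exactly
0), and LOOCV accuracy on label-permuted data stays at the 0.5
no-information level.

## The synthetic cohort generator

`simulate_cohort()` draws marker log2 intensities as Gaussians with
per-marker SD `sigma_log2`; markers in `true_markers` get their case
mean shifted by `delta × sigma_log2` — a *standardized* effect size,
matching the pipeline's analysis scale. Optional block equicorrelation
(`rho`, `block_size`) stresses the screening stage with the correlated
designs the SIS literature warns about. Raw intensities are
\(2^{\text{log2}}\), so the pipeline's log2 transform round-trips
bit-exactly. One integer seed governs everything; cases precede controls
in a fixed subject ordering.

Defaults are the conditions the pipeline targets: 20/20 subjects, 1433
markers, five planted markers at delta = 2, sigma_log2 = 1, independent
markers. Delta = 2 is a strong but not absurd discovery-stage effect —
large enough that a well-behaved screen should recover the planted set
at d_n = 50, which is precisely the sure-screening property the
acceptance tests assert (recovery in ≥ 95 of 100 seeded replicates).

What the generator deliberately does **not** emulate: assay chemistry
and plate effects, hybridization/median normalization, heavy-tailed or
skewed intensity distributions beyond log-normality, missing data, and
label noise. Passing tests therefore certify the *statistical pipeline*
— its tests, rankings, selection and validation logic — not robustness
to real-world assay artifacts. The Gaussian-on-log2 assumption is just
that: an assumption, recorded here because the studies this design
follows describe their data only as "log2-transformed and standardized".

## Problem sizes used by the test suite

The suite favors exact small fixtures (hand-enumerable Mann–Whitney and
Youden examples, two-subject standardization) plus simulation at chosen
scales: moment/correlation convergence at n = 2000; type-I error of the
marker t-test from 3000 null markers; the sure-screening property at the
full design scale (p = 1433, n = 20/20, 100 replicates); AIC and LOOCV
behavior from 100-replicate batches of small cohorts; the
selection-optimism property from 100 cohorts at p = 100. These sizes
keep every stochastic assertion inside comfortable Monte-Carlo bands
while the whole suite runs in a couple of minutes on one core.

## Known limitations

* Marginal (SIS) screening can drop a marker that matters only jointly;
  iterative SIS variants are out of scope.
* The λ actually used by any given published study is generally
  unrecoverable; `support_size:K` emulates the reported support size,
  nothing more.
* LOOCV of a post-selection panel is optimistic (documented above).
* No multiple-testing correction in the volcano stage; no covariate
  adjustment (age/sex matching is assumed to have happened upstream);
  no confidence intervals on AUCs; no elastic-net/SCAD penalties.
* The bundled published panel has no printed intercept; it is stored as
  0 and the worked examples avoid depending on it.
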