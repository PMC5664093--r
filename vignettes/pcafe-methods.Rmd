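---
title: "PCA-based unsupervised feature extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCA-based unsupervised feature extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcafe)
```

## The problem

Given a probe-by-sample expression matrix from a small two-group study
(the motivating design is a muscle-biopsy comparison of 10 healthy controls
against 9 ALS patients), we want a short list of probes whose expression
separates the groups, a validated estimate of how well that list
discriminates, and downstream screens that ask whether the corresponding
genes are linked to cancer survival or concentrated in known gene sets.

The selection step is *unsupervised*: group labels are used only to decide
**which** principal component carries the contrast, never to score
individual probes. This matters in the n-of-19 regime, where any per-probe
supervised statistic overfits badly.

## Gene-embedded PCA

Let $X$ be the $p \times n$ matrix of column-z-normalized expression
($x_{ij}$ = probe $i$, sample $j$; each sample column has mean 0, sd 1 with
the $n-1$ denominator). Instead of the usual sample embedding, probes are
embedded: the PC score vectors $u_k$ are eigenvectors of $XX^\top$,

$$XX^\top u_k = \lambda_k u_k, \qquad \lambda_1 \ge \lambda_2 \ge \dots \ge 0,$$

and the sample-side loadings are $v_k = X^\top u_k$, which are eigenvectors
of $X^\top X$ with the same eigenvalues (multiply the first identity by
$X^\top$). `decompose()` computes both via the thin SVD of $X$ — for
$X = UDV^\top$ we have $u_k = U_{\cdot k}$, $\lambda_k = d_k^2$, and
$v_k = d_k V_{\cdot k}$ — which avoids forming a $p \times p$ Gram matrix at
$p \sim 5\times10^4$ and is numerically stabler. The duality identity
$X^\top X v_k = \lambda_k v_k$ is enforced as a tested invariant (relative
tolerance $10^{-6}$), as are orthonormality of the $u_k$ ($10^{-8}$) and the
eigenvalue ordering.

No probe-side (row) centering is applied beyond the column normalization:
adding it would change the selected set, and the procedure is defined on
the column-normalized matrix as-is.

**Sign convention.** Eigenvector signs are arbitrary; we fix each $u_k$ so
its largest-magnitude component is positive. The selection statistic is
squared, so every downstream p-value is invariant to sign flips — also a
tested invariant — but the convention makes loadings and intermediate files
reproducible run to run.

## Identifying the discriminative PC

For each of the leading PCs, the two groups' loadings are compared with a
two-sample t-test; the PC with the smallest p-value is taken as the
discriminative one (ties break to the smaller index), and an explicit
override is available for users who prefer to fix the PC by inspection, as
the original analysis did with PC2. The default test is the
unequal-variance (Welch) form — the default of R's `t.test`, which the
analysis this reimplements invoked — with the pooled-variance classical
form as an option; the choice is recorded in the run log.

## The chi-squared selection statistic

Let $\sigma$ be the standard deviation of the components of the chosen
score vector $u$ (mean-subtracted, $n-1$ denominator; an uncentered
root-mean-square option exists for sensitivity analysis — the score vector
is near-orthogonal to the constant vector, so the two rarely differ
materially). Each probe receives the statistic $(u_i/\sigma)^2$, referred
to the upper tail of $\chi^2_1$: a single squared standardized quantity has
one degree of freedom under the null that the probe does not load on the
contrast. The df is configurable. P-values are Benjamini–Hochberg adjusted
(step-up, via `stats::p.adjust`) and probes with adjusted $p$ strictly
below the threshold (default 0.01) are selected. Strictness at the
threshold follows the procedure's "less than" phrasing.

The implicit null model is that score components are approximately
Gaussian — reasonable for the bulk of probes after column normalization,
and exactly what the synthetic generator produces. The BH step then
controls the FDR over probes; a 200-replicate pure-noise simulation at the
study's dimensions keeps the realized false-discovery proportion at the
nominal 0.01 in the test suite.

## Discrimination and leave-one-out cross-validation

The selected probes define a reduced matrix, on which the decomposition is
repeated; the chosen PC's loading gives one scalar per sample. Samples are
then classified by a two-class equal-variance Gaussian linear discriminant
on that scalar, evaluated by leave-one-out cross-validation: each sample is
predicted from a model fit on the other $n-1$.

On one dimension the LDA rule is a threshold: with class means $\mu_1,
\mu_2$, pooled within-class variance $s^2$ (denominator $n-2$) and priors
$\pi_1, \pi_2$, the boundary sits where the prior-weighted class densities
are equal,

$$x^* = \frac{\mu_1 + \mu_2}{2} +
  \frac{s^2\,(\log\pi_2 - \log\pi_1)}{\mu_1 - \mu_2}.$$

This closed form is verified against a numerical root of the
density-equality condition to $10^{-8}$, and the per-fold predictions are
cross-checked against an established LDA implementation. Degenerate
corners are defined rather than left to chance: if $s^2 = 0$ but the means
differ, the boundary is their midpoint (the $s^2 \to 0$ limit, where the
prior term vanishes); if the means also coincide, the fold is an error.
Ties exactly at the boundary go to the larger-prior class, then
lexicographically. Predictions are invariant to increasing affine
transforms of the feature, and relabelling the groups transposes the
confusion table — both tested.

**Priors.** Priors default to the whole-cohort class frequencies, held
constant across folds. This is what the standard LDA cross-validation
routine does, and it is the convention under which a pure-noise feature
yields chance-level LOOCV accuracy (mean ≈ 0.49 over 500 replicates in the
test suite). Recomputing priors from each training fold is available as an
option but is *not* the default, because leaving a sample out
under-represents its own class in the fold: the prior then leans toward
the other class for exactly the sample being predicted, and noise-feature
accuracy collapses to ≈ 0.30 — a bias worth knowing about when comparing
implementations. A uniform-prior option exists too.

**Leakage.** The default pipeline selects probes once on all samples and
only refits the LDA per fold, matching the described order of operations of
the original analysis; this leaks the held-out sample into selection, so
the reported accuracy is optimistic. `lda_loocv_strict()` repeats the
entire selection inside every fold (the held-out sample is projected onto
the fold's score vector) and is the honest — and slower — estimate. Both
are exposed; the default records which was used.

## Survival screening

The per-gene screen is a desk-scale stand-in for querying a precomputed
cancer-survival portal: for each gene, the cohort is split at the median
expression (ties at the median fall low — a deterministic rule the source
analysis left unstated), the two halves are compared with the standard
two-group log-rank test referred to $\chi^2_1$, and p-values are
BH-adjusted across the genes screened within one cancer label; genes with
FDR below 0.05 are flagged, together with the direction of the effect
(which half survives longer, judged by observed-versus-expected events). A
per-gene Cox regression on continuous expression is available because the
portal's own rankings are Cox-based; the method used is recorded in every
output row. Kaplan–Meier curves, the log-rank statistic and the Cox fit are
delegated to the survival package behind these interfaces; the test suite
validates them against hand-worked product-limit and observed-minus-
expected tabulations, and checks calibration by simulation (type-I error at
nominal level for hazard ratio 1; power ≥ 0.9 at hazard ratio 3 with 360
patients and 20% censoring).

Exact numeric parity with the original study's 68-gene portal list is not
a goal: the portal's statistic and multiple-testing universe are not
restated in the source and cannot be reproduced from it.

## Enrichment

Over-representation of a query gene list against GMT collections uses the
one-sided hypergeometric upper tail; EASE mode reduces the observed overlap
by one before computing the tail (a conservative variant popularized by
DAVID; overlap ≤ 1 then gives $p = 1$, and EASE $p$ ≥ Fisher $p$ always).
Symbols match case-insensitively and queries are de-duplicated. The
background universe defaults to the union of the collection's genes but
should be set to the array's full gene list when available — the choice
materially shifts p-values, and the original analysis does not state the
background its web tool used. Curated pathway or TF-target content is not
bundled: collections are data, supplied by the user or generated in tests.

## The synthetic generators

`gen_expression()` emulates the study design: Gaussian noise at a chosen
sd for every probe, with the first `n_signal_probes` probes receiving an
additive group-mean shift of `effect` noise-sd units in the case samples;
defaults are 10 controls, 9 cases, 10,000 probes, 100 signal probes and a
2-sd effect. Signal probes are named `sig_0001…` so truth recovery is a
one-liner. `gen_survival()` draws standard-normal expression, exponential
survival with the hazard multiplied by `hazard_ratio` in the upper
expression half, and uniform censoring whose window is solved (via the
closed form $P(\text{censored}) = (1 - e^{-hc})/(hc)$ per patient) so the
expected censored fraction matches the request. Both generators save and
restore the global RNG state, so they are pure functions of their seed —
bit-identical on repeated calls, tested as such.

What the generators deliberately do **not** model: array-specific intensity
distributions, probe-level summarization, batch or sex covariates (the
study's case group was all male), correlated probes, or non-proportional
hazards. Passing tests therefore demonstrate correctness of the machinery
and calibration under the stated model, not robustness to real-array
artifacts; on real data the normalization details upstream of the TSV
export remain the user's responsibility.

## Problem sizes and runtime choices

The simulation-based checks run at the sizes the procedures are designed
for: selection power and null-FDR at 10,000 probes × 19 samples (200
replicates under the null), LDA calibration over 500 noise replicates,
log-rank calibration over 100–200 replicates of 360-patient cohorts, and
exhaustive enrichment enumeration for universes up to 30 genes. These keep
the full suite around two minutes on one core while leaving the Monte
Carlo error of each rate estimate well inside its acceptance band.

## Known limitations

- With very few samples the PC t-test is multiplicity-unadjusted across
  PCs; with ~19 PCs this is mild, but the identified PC should be sanity-
  checked against a plot of its loadings.
- The χ² reference for $(u_i/\sigma)^2$ is approximate: score components
  are neither exactly Gaussian nor independent. The null simulation shows
  the BH step absorbs this at the study's dimensions; far smaller probe
  counts or heavy-tailed data deserve a permutation check.
- The default (non-strict) LOOCV accuracy inherits selection leakage, as
  discussed above.
- CHP/CEL parsing, array QC and summarization are out of scope; ingestion
  starts from a TSV signal matrix.
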