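---
title: "Pathway activation scoring and in-silico drug screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation scoring and in-silico drug screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascloud)
```

## The model

`pascloud` scores signaling pathway disturbance between a case condition
(e.g. a cognitively "enhanced" brain) and a control condition from linear-
scale gene expression. The method is membership-plus-role: a pathway is a
gene set in which each member carries a signed activator/repressor role
weight (ARR), and no pathway topology is modeled. The underlying assumption
is that most signal-transduction proteins operate far from saturation, so
every activator or repressor product is treated as equally important and its
expression level stands in for its activity.

For pathway $p$ and one case sample, the pathway activation strength is

$$\mathrm{PAS}_p = \sum_{n} \mathrm{ARR}_{np} \cdot \mathrm{BTIF}_n \cdot
\log_{10}(\mathrm{ECR}_n)$$

with three ingredients:

* **ECR** (case-to-control expression ratio): the gene's level in the case
  sample divided by the gene's mean level in the normalized control group.
  A small pseudocount is added to numerator and denominator so zero
  expression never divides by zero.
* **BTIF** (beyond-tolerance interval flag): 1 only when *both* criteria
  hold — the ECR exceeds 3/2 or falls below 2/3, *and* the case level
  deviates from the control mean by more than 2 control standard deviations
  (sample SD, $n-1$ denominator). Otherwise the gene contributes nothing.
  The flag suppresses the pervasive small ratios that platform noise
  produces, which is what makes cross-platform use of the score plausible.
* **ARR**: $+1$ for activators, $-1$ for repressors, $0$ for neutral
  members; the file format allows graded magnitudes in $(0, 1]$. The sign
  is always forced by the role.

The multiplicative form, the signaling pathway cloud disturbance
$\mathrm{SPCD} = \prod_i [\mathrm{AGEL}]_i / \prod_j [\mathrm{RGEL}]_j$,
is the exponential counterpart: with unit role weights and all flags
passing, $10^{\mathrm{PAS}} = \mathrm{SPCD}$ exactly. Only ratios and
orderings of SPCD are meaningful; its proportionality constant is fixed
at 1. "lg" is read as $\log_{10}$ throughout — any other base would rescale
every PAS by the same constant and change no ordering.

**Aggregation over case samples.** The score is defined per case sample
against the control mean. Multi-sample designs are aggregated by the
arithmetic mean of per-sample PAS (reported with its SD). The per-sample
form is retained in the output so heterogeneous case groups are visible.
An open alternative — testing the *case-group mean* rather than each sample
against the control SD band — would be more conservative; the per-sample
reading is used because the ratio itself is defined per sample.

**The cloud.** Pathways with $|\mathrm{PAS}|$ strictly above a threshold
(default 0, i.e. any nonzero activation) form the signaling pathway cloud,
each labeled activated or repressed by sign, sorted by descending magnitude
with ties broken by pathway id. A pathway none of whose members are
measured has *undefined* PAS (`NA`), deliberately distinct from 0, and is
excluded from the cloud; per-pathway coverage (`n_measured/n_members`) is
always reported so sparse data is visible rather than silently favorable.

## Enrichment

Gene lists are prioritized against the database with a one-sided (greater)
Fisher's exact test: for each pathway, the $2{\times}2$ table of list ×
pathway membership within a background universe (default: the union of all
database genes, configurable to a measured-gene list). Benjamini–Hochberg
adjustment is applied across pathways and reported alongside the raw p.
Two reporting conventions deserve a note. The overlap percentage uses the
pathway's size within the universe as denominator. The odds ratio is the
sample cross-product $(ad)/(bc)$, reported as infinite when $bc = 0$; a
Haldane-corrected variant (+0.5 per cell) is available behind a flag.
Published tables of this kind sometimes pair odds ratios below 1 with
extreme enrichment p-values, which is inconsistent with the cross-product
convention; `pascloud` makes no attempt to reproduce any particular table
and documents its own convention instead.

## Drug screening

A drug's signature is its own aggregate PAS vector from treated (case) vs
untreated (control) expression, or a precomputed pathway → PAS table.
Scoring is restricted to the target cloud's pathways: with target vector
$t$ and drug vector $v$ (0 where the drug's PAS is undefined, which lowers
the reported coverage),

* **mimic**: $\cos(v, t) \in [-1, 1]$,
* **minimize**: $\cos(v, -t)$ — exactly the dual of mimic,
* **exaggerate**: $(v \cdot t)/\lVert t \rVert^2$, the signed projection
  ratio, so a score above 1 certifies amplitude beyond the target's own.

The match score is a design choice of this package: cosine similarity was
chosen because drug potency (a global scaling of $v$) should not change a
mimicry ranking, while the projection form is deliberately scale-covariant
because "exaggerate" is a claim about amplitude. A weighted variant
(weights $\propto |t|$) is available where strongly disturbed pathways
should dominate the match. "Minimize" is implemented as *reversal* of the
cloud (the drug pushes every pathway the opposite way); the alternative
reading — shrinking $|PAS|$ toward zero — is not a property of a drug
signature alone but of its combination with the condition, so the reversal
reading is the default and only implemented one. Drugs with no signal on
any cloud pathway score 0 and carry a `zero_signal` flag. Ties in the
ranking break lexicographically by drug id, making rankings deterministic.

A caveat follows directly from the cosine form: when the cloud contains a
single pathway, the score degenerates to the sign of the drug's PAS there.
Screens should be run against clouds of several pathways (threshold 0 keeps
every nonzero pathway and is the default for this reason).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fold_upper`, `fold_lower` | 3/2, 2/3 | ratio | the method's printed tolerance bounds; reciprocal pair, so up- and down-regulation are treated symmetrically |
| `sd_multiplier` | 2 | control SDs | the printed deviation criterion |
| `pseudocount` | 1e-8 × matrix median (floor 1e-12) | expression units | guards zeros while perturbing moderate expression by <1e-6 relative |
| `min_control_n` | 3 | samples | a sample SD of fewer than 3 values makes the deviation criterion degenerate |
| normalization | quantile, jointly over all samples | — | the scale-free ratios require comparable columns; joint (not control-only) normalization keeps case and control on one scale |
| cloud `threshold` | 0 | PAS | no principled cutoff exists; 0 admits every nonzero pathway and keeps screening vectors multi-dimensional |

Input expression must be linear-scale and non-negative; log-transformed
data must be de-logged upstream, because the score mixes ratios of levels
with logs of those ratios.

## Numerical choices and degenerate inputs

* `control_sd = 0` (perfectly constant controls): the deviation criterion
  reduces to "the case value differs from the control mean at all";
  a strict inequality against zero would make constant controls permanently
  unflaggable.
* Quantile normalization resolves ties by assigning the mean of the tied
  target quantiles, so normalized columns are identical as multisets and
  within-column ranks are preserved.
* Pathway members absent from the matrix are skipped, never imputed;
  an entirely unmeasured pathway is `NA`, not 0.
* The auto pseudocount is *data-dependent* (it scales with the matrix
  median). Exactness properties — e.g. that noise-free planted data
  reproduce the closed form $(\sum_n |\mathrm{ARR}_n|)\log_{10} f$ to 1e-9
  relative — therefore hold with a fixed negligible pseudocount (the 1e-12
  floor); under the default they hold to about 1e-6 relative.
* All randomness in the simulator flows through named streams derived from
  one global seed (a 31-bit hash of the stream name folded into the seed),
  so adding a simulation stage never changes another stage's draws, and
  identical seeds give byte-identical matrices.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` draws per-gene baselines uniformly in
$\log_{10}$-space (default range 1–3, i.e. levels 10–1000), adds i.i.d.
Gaussian noise of SD `biological_sd` (default 0.1) in $\log_{10}$, and
exponentiates — a log-normal expression model, the simplest generative
model consistent with the ratio-and-log structure of the score. Planted
pathways multiply case-sample activator levels by the fold $f$ and
repressor levels by $1/f$, so the expected aggregate PAS under full flag
passage has the closed form $(\sum_n |\mathrm{ARR}_n|)\log_{10} f$.
Defaults — 5 case and 5 control samples, fold 2, SD 0.1, 10 pathways of
6–12 members — are the study conditions used throughout the tests and the
acceptance script; they correspond to a modest animal-model expression
experiment.

Synthetic pathway databases are *gene-disjoint*, so planted ground truth is
exact (disturbing one pathway cannot leak into another). Real databases
share genes heavily; with a user-supplied overlapping database, planting
accumulates folds multiplicatively and cross-pathway leakage is expected.

The generator deliberately omits: platform-specific noise and probe
effects, library-size or composition artifacts, correlated co-expression
structure, ortholog mapping, and any epigenetic layer. Passing the planted-
recovery tests therefore demonstrates that the chain of estimators is
correct and well-calibrated *under the stated noise model* — not that the
screen will recover drugs on any particular real platform.

Drug libraries contain mimics (same planted pathways and direction as the
target, optionally attenuated), random decoys (same folds planted on
pathways disjoint from the target's) and reversed decoys (reciprocal folds
on the target's pathways, the positive control for minimize mode).

## Known limitations

* **Null calibration at high noise.** Under the null (nothing planted), the
  fraction of gene signals passing the tolerance filter is about 4.55 % in
  the known-variance limit ($P(|z|>2)$, since at $\sigma_{\log_{10}} = 0.1$
  the 2-SD criterion binds more tightly than the fold bounds). With
  realistic control groups the SD is estimated — with 5 controls, on 4
  degrees of freedom — and its underestimation inflates the rate: the
  acceptance script measures ≈ 6.4 % at `biological_sd = 0.1` with 5 + 5
  samples. At `biological_sd = 0.05` the rate collapses to ≈ 0.2 %. Users
  with noisy data and small control groups should expect a few percent of
  spurious flags and rely on the pathway-level aggregation (which this
  package's recovery results show is robust to them) rather than on
  individual gene flags.
* The method sees transcription only: protein-level activation, epigenetic
  state and pathway topology are out of scope by construction.
* PAS values are comparable across pathways only in the loose sense of the
  shared gating rule; a pathway with more members can reach larger |PAS|.
  The cloud and all screening scores are therefore used for *ranking*, not
  as calibrated effect sizes.

## Problem sizes used in the test suite

Statistical checks run at 100–200 seeded replicates of 10–12 pathways ×
6–12 members with 5 + 5 samples; estimator-consistency checks use 1000
random pathways; the Fisher oracle check enumerates 500 random tables with
margins ≤ 30. These sizes give the recovery proportions a standard error
below 2 percentage points while keeping the full suite under half a minute.
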