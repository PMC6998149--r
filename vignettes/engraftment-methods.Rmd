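---
title: "Methods: quantifying donor engraftment after FMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying donor engraftment after FMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtengraft)
```

## The scientific question

A sham-controlled FMT maintenance trial in Crohn's disease asks two coupled
questions: did the donor community *engraft* in the recipient, and is
engraftment linked to staying in clinical remission? This package implements
the quantitative machinery for both, from OTU count tables and visit metadata
down to the endpoint statistics.

## The engraftment model

### Similarity

All similarity statements use the abundance-based Sorensen index
$S = 1 - BC$, where $BC$ is the Bray-Curtis dissimilarity computed on
relative abundances. Working on proportions makes donor/recipient sequencing
depth irrelevant; rarefaction is still applied first so that
presence/absence-sensitive quantities (Chao1, new-OTU detection) are
comparable across samples. Be aware of the naming collision: this is *not*
the presence/absence Sørensen-Dice coefficient, but the trial's definition is
kept because it is the quantity the endpoint is written in.

### The endpoint classifier

`classify_engraftment()` calls success iff (a) the week-6 sample is
*strictly* more similar to the donor than to the subject's own D0 baseline
and (b) the donor similarity is at least 0.6. Both readings are literal: ties
on (a) fail, equality at 0.6 passes (b). A missing week-6 observation is
failure (the trial's intention-to-treat handling of its lost-to-follow-up
subject). The 0.6 threshold is the protocol constant; the separate
`failure_by_low_similarity()` cut (default 0.2) is a *package configuration
default* chosen inside the empirical gap between observed failures (0.12,
0.15) and successes (0.29–0.56), and is flagged as such wherever it appears.

### Source attribution

Bayesian source tracking asks what fraction of a post-FMT community derives
from each candidate source. We answer the same question with a deterministic,
exactly testable estimator: the post sample's counts are modelled as a
multinomial whose category probabilities are the convex mixture
$p = \lambda_d \cdot q_{donor} + \lambda_p \cdot q_{pre} + \lambda_u \cdot u$,
with $u$ uniform over taxa (the "unknown" source absorbing taxa explained by
neither profile). The weights are maximum-likelihood estimates obtained by
EM. Because the log-likelihood is concave in $\lambda$, EM converges to the
global optimum regardless of the uniform initialisation; we iterate until the
relative log-likelihood change falls below $10^{-10}$ (cap 10,000 iterations,
exceeding it is an error carrying the likelihood trace). Source profiles are
smoothed with a per-taxon pseudo-mass of $10^{-6}$ after normalisation so the
likelihood stays finite when the post sample contains taxa unseen in a
source. Trading Gibbs-sampled posteriors for a point estimate loses
uncertainty quantification but gains determinism; the parameter-recovery
suite (below) measures its accuracy directly.

### New-OTU tracking

An OTU is "new" for a subject iff its rarefied count is zero at *both*
pre-intervention visits (W-2 and D0) and positive at the evaluated
post-intervention visit. Zero-after-rarefaction is a detection-limit
semantics, not a biological absence claim, which is why the rarefaction depth
is part of the result's provenance (the pipeline manifest records it).

## Diversity and ordination choices

- **Shannon** uses log base 2 — the QIIME-1 default that the upstream
  toolchain of such trials used. The base is an explicit argument, but the
  package default is what all shipped analyses use.
- **Chao1** follows the classic estimator $S_{obs} + F_1^2/(2F_2)$ when
  doubletons exist and the bias-corrected $S_{obs} + F_1(F_1-1)/(2(F_2+1))$
  when $F_2 = 0$. This is implemented in-package: the vegan estimator applies
  the bias-corrected form unconditionally, which differs on the $F_2 > 0$
  branch.
- **PCoA** is classical metric scaling. Bray-Curtis matrices are generally
  non-Euclidean, so negative eigenvalues arise; they are reported unchanged
  and excluded from the explained-variance normalisation (fractions are taken
  over the positive spectrum only).
- **ANOSIM** uses the rank statistic
  $R = (\bar r_{between} - \bar r_{within}) / (N(N-1)/4)$ with the
  add-one permutation p-value $(1 + \#\{R^* \ge R\})/(1 + n_{perm})$, so p is
  never exactly zero and has resolution $1/(n_{perm}+1)$.
- **Unweighted UniFrac** is presence/absence: unique branch length over union
  branch length. Unrooted or multifurcating input trees are resolved with
  zero-length edges, which leaves the statistic unchanged.

## Clinical endpoint conventions

- **Flare** is CDAI > 220, or CDAI in [150, 220] rising by more than 70
  points over baseline, or new treatment/surgery.
- **Remission rates** are intention-to-treat. The week-24 endpoint imputes
  *flare* for a subject who dropped out in remission before week 24;
  Kaplan-Meier input deliberately does not — there the subject is censored at
  last contact. Both handlings coexist because they answer different
  questions (a binary endpoint vs a hazard over time).
- **Fisher's exact test** is two-sided by the probability-mass rule (sum of
  hypergeometric probabilities of tables no more probable than the observed
  one). A table with an empty success column is a valid input with p = 1;
  only an all-zero table is rejected.
- **Wilcoxon tests** use exact p-values on small tie-free samples (rank-sum:
  combined n ≤ 20; signed-rank: ≤ 15 informative pairs) and the tie-corrected
  normal approximation otherwise; the method used is reported in the result.
  Zero differences are dropped before signed-ranking (Wilcoxon's original
  convention).
- **Sample size** for two proportions uses the normal approximation with
  pooled variance under the null and unpooled under the alternative, no
  continuity correction (the corrected variant is available behind a flag).
  Evaluable n is rounded up, then inflated by $1/(1-\text{attrition})$ and
  rounded up again. Under the trial's design inputs (80% vs 0.5%, two-sided
  α = 0.05, power 0.90, 50% attrition) this yields 12 per group, 24 in total
  — the published calculation.
- **Outcome records** code flares as intervals $(a, b]$ in weeks. The
  packaged trial records carry only interval information because exact flare
  weeks were never published; any operation that needs exact event times
  (`as_survival_records()`) refuses them rather than fabricating times.

## The LEfSe-like screen

Full LEfSe combines Kruskal-Wallis, subclass Wilcoxon consistency checks and
a bootstrapped linear discriminant analysis. The bootstrap makes scores
run-dependent, so this package substitutes a documented closed form: stage 1
is a per-taxon Kruskal-Wallis test at α = 0.05 on relative abundances; stage
2 scores each taxon as
$\mathrm{sign}(\bar p_A - \bar p_B)\,\log_{10}(1 + |\bar p_A - \bar p_B|
\times 10^6)$ — the group-mean difference on the $10^6$-rescaled abundance
axis LEfSe plots on. A taxon passes with p < 0.05 and |score| > 2, the
conventional cut-offs. Consequences: scores are deterministic (the `seed`
argument is accepted for interface stability and ignored), label swaps
negate them exactly, and the screen is invariant to library depth. It is
*not* numerically comparable to LDA-based LEfSe scores, only analogous in
scale and intent.

## What the cohort simulator does and does not emulate

`simulate_cohort()` draws donor and recipient baseline communities from
sparse Dirichlet distributions (concentration 0.3, giving realistically
uneven 16S profiles with partially overlapping dominant taxa), then models
engraftment as *linear compositional mixing*: every post-intervention
expected composition is $\lambda \cdot donor + (1-\lambda) \cdot baseline$,
perturbed by per-visit log-normal drift (sd 0.4, tuned to a within-subject
repeat Bray-Curtis near 0.2 — typical of short-interval stool resampling)
and observed as multinomial counts at a library size of 1–1.3 × the 29,000
rarefaction depth. Sham subjects have $\lambda = 0$. Flares follow
$P(\text{flare by W24}) = \mathrm{logit}^{-1}(0.7 - 2.5\lambda)$: a sham-arm
flare probability near the trial's observed 6/9, falling with engraftment —
a qualitative encoding of the trial's finding that failed engraftment was
associated with flare, not a claim about its effect size.

The linear-mixing choice is deliberate: it is exactly the model the source
attribution estimator inverts, which makes parameter recovery a well-posed
validation (the acceptance suite requires the EM estimate of $\lambda$ to
have mean absolute error below 0.05 over 100 cohorts at depth 29,000). The
simulator does **not** model ecological succession, taxon-taxon interactions,
engraftment that grows or decays over time, inflammation-driven community
shifts, or donor-specific engraftability. Passing tests therefore demonstrate
correctness of the estimators under their own assumptions plus moderate
drift — not that real FMT dynamics are linear.

Problem sizes used by the shipped validation runs — 150 taxa, single-subject
arms for the 100 recovery cohorts, 5–10 replicate cohorts elsewhere — were
chosen as the smallest sizes at which the statistics under test are
well-resolved.

## Pipeline and provenance

`run_pipeline()` wires the stages together and refuses to compute anything
itself: every number in a report comes from one exported function. A JSON
manifest records the configuration hash, seed, rarefaction depth, Shannon
base, the Fisher convention, the similarity basis (relative abundances of
the rarefied table) and the package version, so a re-run from the manifest's
configuration reproduces the reports byte for byte. Whether the trial itself
rarefied before computing Bray-Curtis is unstated in its methods; this
package pins rarefy-first and records the choice in the manifest rather than
leaving it implicit.

## Known limitations

- OTU-level only: no strain-resolved (SNV) engraftment tracking, which can
  distinguish donor strains from shared species.
- The EM attribution gives point estimates without posterior uncertainty.
- The donor sample analysed may be a stool aliquot or the administered
  preparation; the data model records `role = donor` without asserting which.
- The effect-score screen is LEfSe-*like*; thresholds transfer, exact scores
  do not.
- Simulated validation transfers to real data only insofar as the mixing
  model approximates early post-FMT dynamics.
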