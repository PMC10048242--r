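---
title: "Maximum-Entropy gene set analysis: model, null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-Entropy gene set analysis: model, null, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narnea)
```

This vignette is the package's own account of the statistics it
implements: the enrichment model and its assumptions, the parameters that
matter, what the synthetic generators emulate, and the numerical and
design choices made where the design was genuinely open.

## The model

A differential gene expression signature assigns each of $G$ genes a real
value $z_g$, positive when the gene is higher in the test phenotype,
with $|z_g|$ ordering genes by the strength of that evidence and
$z_{AB} = -z_{BA}$ under phenotype exchange. Any statistic with these
properties is admissible; `mwu_signature()` provides the tie-corrected
normal approximation to the two-sample Mann–Whitney U statistic, which
satisfies them by construction and is the default throughout (including
for the totally-null gene-set construction, where its two-sided p-value
defines the "non-differential" pool).

The signature is reduced to ranks of magnitudes and signs,
$r_g = \mathrm{rank}(|z_g|)$, $s_g = \mathrm{sign}(z_g)$. A gene set
(regulon) carries per-target parameters $AW_{rg} > 0$ and
$AM_{rg} \in [-1, 1]$ and is scored by

$$DES = \sum_g AW\,AM\,(r s), \qquad UES = \sum_g AW\,(1-|AM|)\,r .$$

The null hypothesis is that the regulator's activity does not differ
between the phenotypes. The only information then available about a
target is that it sits somewhere in the signature, so the maximum-entropy
joint law places the targets independently and uniformly over the $G$
observed $(r, s)$ entries. Every null moment follows in closed form from
the four signature moments $\overline{rs}$, $\overline{r}$,
$\overline{r^2}$, $\overline{r^2 s}$; the standardized scores are
asymptotically bivariate normal with analytic correlation $\varphi$, and
the rotated pair $NES^\pm = (NDES \pm NUES)/\sqrt{2 \pm 2\varphi}$ is
independent standard normal under the null. Choosing the better of the
two one-sided tails is itself a two-fold multiple test, corrected exactly
by $p = 1 - (1 - \min(p^+, p^-))^2$ because the tails are independent;
the final $NES$ maps $p$ back through the standard normal quantile with
the winning sign.

Asymptotic normality relies on no single target dominating the null
variance of either branch (a Lindeberg-type balance condition). Copula
weights ($\mathrm{rank}/(N+1)$) guarantee this for network-inferred
regulons; `lindeberg_diagnostic()` reports the largest per-target share,
and `narnea()` warns above a configurable threshold (default 0.10, the
point at which one target carries ten times its share of a 100-target
regulon's variance).

## Tunable parameters

* `min_size` (default **30** targets): below this, the central-limit
  approximation underlying the standard-normal null is not guaranteed
  (Berry–Esseen bounds for non-identical summands degrade quickly);
  undersized regulons are skipped with a message.
* `lindeberg_threshold` (default **0.10**, dimensionless share of a
  branch's null variance) — diagnostic only, never changes results.
* Leading-edge adjustment (default **BH**): leading-edge p-values are
  reported per regulon across its targets; BH matches the FDR-centric
  reporting used everywhere else, Bonferroni is available.
* Network module: subsample fraction is fixed at $1 - 1/e \approx
  63.21\%$ of profiles without replacement (the probability a given
  sample enters a bootstrap, giving bootstrap-grade decorrelation without
  the MI bias of replicated points); `fdr` (default **0.05**) controls
  per-subnetwork edge retention by BH on MI null-model p-values;
  `max_nets` (default **30**) and `min_targets` (default **50** unique
  targets per regulator) are the stopping criteria; the MI null model
  uses `n_null` (default $10^6$) shuffled copula pairs.
* APMI internals: quadrant splits proceed while the chi-squared
  uniformity statistic over the four quadrant counts exceeds
  `chi_crit` (default $\chi^2_{3,0.95} = 7.81$) and the cell holds at
  least `min_pts = 8` points. Both knobs are exposed; MI is reported in
  nats.

## Numerical choices and degenerate inputs

* **Ties** in $|z|$ take average ranks, conserving $\sum r = G(G+1)/2$;
  all null moments are computed from the realized $(r, s)$ vectors, never
  from the no-tie closed forms, so ties are handled exactly. `sign(0) = 0`
  is taken literally: a zero gene contributes rank mass to the undirected
  branch and nothing to the signed terms.
* **Extreme scores** are handled in log-tail space
  (`pnorm(..., log.p = TRUE)` end to end), so p-values stay strictly
  positive and the final NES finite at any realistic score.
* **Degenerate branches**: a regulon with all $AM = 0$ (no directed
  information) or all $|AM| = 1$ (no undirected information) has zero null
  variance on one branch; that branch is dropped and the final NES reduces
  to the surviving standardized score with an ordinary two-sided p-value,
  rather than erroring. Both branches degenerate is an error.
* **Exact tail ties** $p^+ = p^-$ take the final sign from the directed
  score, which carries the directional evidence.
* The **null model is with replacement** (i.i.d. uniform placements), the
  literal maximum-entropy law; the enumeration oracle in the tests matches
  this exactly. The **effect-size extremum**, by contrast, places targets
  on *distinct* positions, because a real regulon occupies distinct genes;
  the asymmetry is deliberate.

## The effect size and its extremal placement

$PES = NES / |NES_{\max}|$ (or $|NES_{\min}|$ for negative enrichment),
where the extremum is taken over placements of the regulon's targets on
distinct positions of the observed signature. The null normalization
constants depend only on $(AW, AM)$ and the global signature moments, so
the extremal search only needs to maximize the placement-dependent linear
functional: each target contributes $c_1 (r s) + c_2 r$ with fixed
coefficients. The search sorts targets by coefficient magnitude and lets
each claim its best still-available position; because the per-position
score is monotone in $r$ within a sign class, the best available position
is always one of the six class extremes, making the search $O(N)$ after
one $O(G \log G)$ sort.

This greedy claim order is provably optimal when targets share a
preference ordering but can fall short of the true optimum for strongly
heterogeneous coefficient profiles (it is a two-dimensional assignment
problem). The implementation therefore (i) runs the greedy under three
claim orders — combined magnitude, directed magnitude, undirected weight —
keeping the best, and (ii) bounds the extremum below by the observed
placement, which is itself feasible; together these keep
$PES \in [-1, 1]$ by construction. Exhaustive enumeration at tiny sizes
shows residual shortfalls only in adversarial corners of coefficient
space. The PES confidence interval bootstraps targets with replacement
and builds a normal-theory interval on the Fisher-z scale, the natural
scale for a correlation-like quantity.

## The MI null model and consensus integration

Null MI draws (APMI between independently shuffled copula marginals) form
a piecewise model: the empirical survival function up to the 95th
percentile, and beyond it a linear fit of $\log_{10}$ tail probability
against MI by a Theil–Sen median-of-pairwise-slopes regressor, anchored
at the junction so p-values are continuous and nonincreasing. The robust
regressor matters because the extreme tail is sparse and noisy. One
detail of the estimator: the root cell of the adaptive partition is
always split, and only deeper cells are gated on the chi-squared
uniformity test — under a fully gated rule the vast majority of null
draws are exactly zero and the body/tail decomposition degenerates.

Each subnetwork controls its own edge FDR, but a plain union over $k$
subnetworks accumulates false edges roughly $k$-fold. The consensus
therefore tests each edge's occurrence count against a
$\mathrm{Binomial}(k, \mathrm{fdr})$ null of chance rediscovery, BH-adjusted
across union edges at the same rate (`keep_all = TRUE` disables this); a
single subnetwork is left untouched, being already FDR-controlled.
Regulon parameters come out as the copula transform of the (count, MI)
target ordering ($AW$) and the full-data Spearman correlation ($AM$).
DPI pruning removes the minimum-MI edge of every three-gene clique on the
undirected skeleton in one pass; ties at a clique minimum remove all tied
edges, keeping the operation deterministic and idempotent.

## What the synthetic generators emulate — and what they do not

`synth_signature()` draws i.i.d. values: a signature in which nothing is
enriched. `random_regulons()` draws member sets uniformly (the
"null-model" construction: sets that are biologically meaningless by
design), with copula-uniform weights and uniform modes; its swap mode
replaces a template's members from the complement, keeping parameters.
`tn_regulons()` draws only from genes with Mann–Whitney two-sided
$p > 0.50$ (or $|z|$ below the median in signature-only mode): sets
concentrated in the signature's center, the configuration that defeats
running-sum statistics but must not excite a calibrated test.
`active_signature()` shifts each target's $z$ by
$\mathrm{effect} \times AW \times \mathrm{sign}(AM)$ — the displacement a
positively differentially active regulator induces — acting on the
signature directly rather than re-simulating expression, which keeps
power experiments fast. `synth_expression()` generates the
expression-level analogue for the network module: latent standard-normal
activities, targets at $\mathrm{direction} \times \mathrm{strength}
\times \mathrm{activity} + \mathrm{noise}\,\varepsilon$ with strengths
uniform on $(0.5, 1)$ and noise sd $0.5$ (signal-to-noise in the range a
few hundred profiles can resolve, comparable to what MI-based reverse
engineering faces in practice), then a monotone $\exp$ map to positive
abundances, which rank-based estimators cannot distinguish from the
linear scale.

None of the generators emulate library-size variation, count overdispersion,
normalization artifacts, or correlated co-regulation among decoy genes.
Passing tests therefore certify the statistics — calibration of the
analytical null, recovery of programmed dependencies — not robustness to
every failure mode of real RNA-Seq data.

## Problem sizes used by the tests and the calibration script

The acceptance-style checks run at the scale the published calibrations
use where that is cheap (2 491 gene sets against a 19 350-gene signature;
2 491 central-gene sets over an 80-sample two-phenotype simulation) and at
reduced scale where full scale adds nothing but time ($10^4$ null regulons
on a 2 000-gene signature for the null-normality property; a
20-regulator / 500-decoy / 200-profile network for consensus recovery;
$10^4$ null pairs for test-time MI null models against the $10^6$
default). Monte-Carlo assertions use three-standard-error bands around
their analytical expectations under a fixed seed.

## Known limitations

* The greedy extremal placement behind PES is exact only up to the
  heterogeneity caveat above; PES remains bounded and sign-correct in all
  cases, but may be very slightly conservative-or-liberal in pathological
  coefficient mixtures.
* The tau-b confidence interval uses the standard asymptotic variance
  (consistent under dependence), not a bootstrap.
* The per-cell residual z-scores of the 3×3 agreement analysis use the
  adjusted standardized residual; other residual conventions exist and
  give different (typically smaller) magnitudes.
* Below `min_size` targets the analytical null is simply refused rather
  than replaced by an exact small-sample null; exact enumeration is
  feasible there but out of scope.
* The MWU signature uses the normal approximation with tie correction;
  exact enumeration is unnecessary at signature scale but would matter
  for very small sample sizes.
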