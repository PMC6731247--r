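---
title: "Signature reversal: models, assumptions and design choices"
author: "sigreverse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature reversal: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Transcription-based drug repurposing treats a disease's gene-expression
changes as a high-content quantitative phenotype. If a compound drives
expression changes opposite in sense to those observed in diseased tissue,
it becomes a repositioning candidate — with the standing caveat that some
disease-associated changes are compensatory, so reversal is a hypothesis
generator, not proof of benefit. `sigreverse` implements this pipeline end
to end for bulk expression matrices (microarray-style positive intensity
values), from disease signature construction through drug-profile
conversion, connectivity scoring and consensus analysis, together with a
synthetic-data generator that makes every downstream claim checkable
against planted ground truth.

# Disease signatures

## Scaled-fold contrast profiles

For a case/control contrast, each gene's change is summarised by the
scaled fold

$$f = \frac{\langle d\rangle - \langle c\rangle}
           {\langle d\rangle + \langle c\rangle},$$

the group-mean difference normalised by the group-mean sum. On a positive
intensity scale $f$ is bounded in $[-1, 1]$, symmetric under exchange of a
doubling and a halving, and — unlike a log-ratio — insensitive to the
intensity floor. Significance is an equal-variance two-sample Student
*t*-test: the filter described in the source methodology as dropping folds
"below the 95% confidence interval" is implemented as $p < \alpha$ with
$\alpha = 0.05$, the reading most consistent with the accompanying naming
of Student's *t*; a fold-CI criterion was the other candidate reading and
is noted as an open interpretation. Retention additionally requires
$|f| \ge$ `minFold` (default 0.20).

Genes whose group means are not both positive violate the positivity
premise that bounds $f$; they are dropped with a warning rather than
clamped, so the profile's stated $[-1,1]$ invariant is never patched after
the fact.

## Stage-regression profiles

Ordinal disease-stage series (neuropathological staging, cognitive scores)
are profiled by per-gene ordinary least squares of expression on stage with
categorical covariates (e.g. sex, cell type) as indicator columns. The
stage coefficient's two-sided *t* p-value is mapped to a signed Z via the
standard-normal quantile. The source methodology names a "linear mixed
model" but specifies only fixed terms; with no random-effects structure
stated, a fixed-effects model is what is implemented. Collinear covariates
are dropped with a warning; a constant stage is an error.

Z values are capped at $\pm 8.2$: a perfect fit underflows the p-value near
double precision and would otherwise produce infinities. The cap is far
beyond any plausible biological signal and only marks "as significant as
representable".

Scales that *decrease* with progression (e.g. cognitive scores) are
sign-flipped with `reverseProfile`, an involution that negates values and
senses but keeps p-values.

## Representative profiles

The consensus over $P$ studies is categorical: per gene the regulation
fraction $(n_\uparrow - n_\downarrow)/P$, counting only genes retained by
each study's filters, with absent genes contributing sense 0. The
denominator is the total number of input profiles, not the number of
profiles measuring the gene — this keeps the 20%/33% thresholds comparable
across genes and matches a sum "over the profiles". Retention requires the
absolute fraction to *strictly* exceed `minFraction` (default 0.20; a gene
up in 3 and down in 2 of 5 profiles sits exactly at 0.2 and is dropped)
plus a one-sample *t*-test of the per-profile senses against zero at
$\alpha = 0.05$. A gene with identical nonzero sense in every profile has
zero variance and an undefined *t*; it is retained with $p := 0$, since
perfectly reproduced evidence is maximal, not missing. The same rule is
used when aggregating replicate rank profiles.

# Drug profiles

## Rank profiles

CMAP-style inputs are per-sample rank lists. The linear transform
$1 - 2(R - R_{\min})/(R_{\max} - R_{\min})$ maps ranks onto $[-1, 1]$ with
$+1$ at the most upregulated feature. Tied or non-contiguous ranks are
resolved by average ranking followed by a stable re-rank before scaling.
Replicates are averaged and filtered by a one-sample *t* against zero;
probe-level profiles collapse to genes by the largest-magnitude
*significant* probe (the filter precedes the collapse, following the order
in which the steps are described).

## Treatment profiles and plate normalisation

Plate experiments carry triplicate treated cultures against a triplicate
vehicle control on the same plate. Two profile methods are provided:

* **fold** — the scaled fold of treated vs control means with the
  *t*-filter at `alpha`;
* **zscore** — the control-referenced standardised difference
  $Z = (\bar t - \bar c)\,/\,(s_c \sqrt{1/n_t + 1/n_c})$, retained at
  $|Z| >$ `zThreshold` (default 3). With triplicates the control SD has
  two degrees of freedom, so this filter is deliberately heavy-tailed;
  genes with zero control variance cannot be standardised and are dropped
  with a warning.

Both statistics are exactly invariant to per-plate multiplicative gains
(equivalently, additive offsets on the log scale) because each is a ratio
of quantities scaling identically — this is the precise sense in which
"normalising to the plate control" removes plate effects, and the
synthetic generator plants its plate effects in exactly that form so the
invariance is testable to machine precision in the noise-free limit.
Multiple plate replicates of a drug are kept as separate profiles.

## Cell-identity profiles

The relative rank $(r_0 - r)/r_0$ for $r < r_0$ and $(r_0 - r)/(1 - r_0)$
for $r > r_0$ compares sample mean ranks $r$ (scaled to $[0,1]$, 0 =
highest expression) to a background reference $r_0$. The source prints
both branch conditions identically — an evident typo; the second branch is
taken as $r > r_0$, the only reading that makes the function total. The
degenerate corners $r = r_0 \in \{0, 1\}$ take $\pm 1$ by continuity, with
a warning.

# Connectivity

## Concordance and exact enrichment

A categorical query is compared with a profile by sense agreement over the
gene overlap: score $(n_{\uparrow\uparrow} + n_{\downarrow\downarrow} -
n_{\uparrow\downarrow} - n_{\downarrow\uparrow})/n \in [-1,1]$. The
enrichment probability is the exact Poisson-binomial upper tail of the
concordant count — computed by dynamic programming, exact to double
precision and feasible to $10^4$ trials — with per-gene match
probabilities: 0.5 under the uniform background, or a frequency table from
`backgroundFrequencies`, which down-weights matches on genes regulated by
many database profiles (add-one smoothing keeps probabilities strictly
inside (0, 1)). The "binomial probability sum" of the source is not fully
recoverable; the Poisson-binomial tail is the stated interpretation here.
Enrichment is evaluated in the observed direction (concordant excess for
non-negative scores, discordant otherwise) and the direction is recorded,
as the source does not state sidedness. An empty overlap yields a flagged,
undefined result rather than an error.

## Small-overlap guards

Two guards respond to a structural degeneracy of sparse profiles
discovered during development: a chance overlap of a handful of genes that
happens to be fully discordant scores exactly $-1$ and, at overlap 5,
already reaches a nominal $2^{-5} < 0.05$ tail. Such comparisons carry
almost no information yet would dominate orderings and hit lists.
`rankQuery` therefore flags profiles overlapping the query in fewer than
`minOverlap` (default 5) genes as non-rankable and places them last;
`selectHits` counts a significant anti-correlation only when the overlap
is at least its own `minOverlap` (default 10), below which nominal
significance is achievable only through near-total discordance of a few
genes. Both floors are reported alongside the results, not silently
applied.

## Ranking and KS enrichment

`rankQuery` orders by score (ascending for anti-correlation), breaking
ties by ascending enrichment probability and finally lexicographically by
drug name; the enrichment probability is interposed because score ties are
common at small overlaps and the name alone is arbitrary. Rank enrichment
of a hit set within a ranked universe is the maximal positive deviation of
the cumulative hit fraction above the diagonal,
$D = \max_i (i/m - h_i/N)$, against a Monte-Carlo null of uniformly random
placements with the add-one estimator
$(1 + \#\{D_{perm} \ge D\})/(B + 1)$ — never zero, and uniform under the
null. All permutation streams are explicitly seeded.

## Regression Z

Continuous profile pairs are compared by the least-squares slope of one on
the other over the overlap (at least 4 genes), the slope's *t* p-value
mapped to a signed Z with the same $\pm 8.2$ cap. Whether set summaries
should average signed or absolute Z is not stated in the source; signed is
implemented, so opposing pairs cancel rather than inflate a set's
coherence.

# Consensus analysis

Hits are drugs with at least `minSignatures` (default 2) significant
anti-correlations. Consistently regulated gene cohorts use the sum-sense
ratio $\frac1P\sum_i \mathrm{sign}(g_i)$ with absent genes scored 0 and a
strict threshold (default 1/3; six profiles at $(+,+,+,-,0,0)$ sit exactly
at 1/3 and are dropped). Compounds are clustered by UPGMA on
$1 - \text{concordance score}$ (default; $1 -$ Pearson on the overlap is
the alternative — the source names the algorithm but no metric, and the
sense data being clustered make the concordance distance the natural
default). Node heights are half the average inter-cluster distance, so two
profiles at distance $d$ join at height $d/2$; heights are non-decreasing
and this ultrametric property is asserted by the class validity on every
construction. Pairs with no overlap are imputed at the maximum observed
distance, with a warning. Over-representation of up/down cohorts against
GMT collections uses the hypergeometric upper tail with Benjamini–Hochberg
adjustment — the source names neither test nor correction; these are the
field's defaults.

# The synthetic-data generator

The generator replaces the public disease series and the drug-profile
database downloads with matrices of known structure:

* **Noise model.** Positive intensity-like values with additive Gaussian
  noise of SD 1 around a baseline of 4 units — the Gaussian-on-a-log-like
  scale convention of microarray data. The low baseline is deliberate: a
  planted shift of 3 noise SDs then corresponds to scaled folds of
  $+3/11$ (up) and $-3/5$ (down), comfortably beyond the 20% fold filter,
  i.e. planted genes represent strongly regulated transcripts. At a high
  baseline (say 8 units) a 3-SD shift would yield $f \approx 0.16$ and the
  fold filter, not the *t*-test, would dominate recovery.
* **Disease studies** plant `nUp`/`nDown` genes shifted by
  $\pm\,$`effect` SD in the disease group; a `truth` object can be reused
  across calls to simulate independent replicate studies of one disease.
* **Stage series** plant genes linear in an ordinal stage with categorical
  covariates, plus optional covariate-only genes that a properly adjusted
  regression must *not* recover.
* **Drug plates** place triplicate treated groups and a triplicate vehicle
  control on each plate. Reversers flip a tunable fraction of the planted
  signature; non-reversers perturb random gene sets of the same size, so
  the specificity of downstream queries is testable, not only their
  sensitivity. Plate effects are per-gene multiplicative gains (additive on
  the log scale) shared by all samples on a plate.
* **Probe maps** give each gene 1..`maxDegeneracy` probes for exercising
  the collapse step.

Every generator takes an explicit seed; there is no hidden global random
state beyond R's RNG, which each generator sets.

What the generator does *not* emulate: correlated co-expression modules,
intensity-dependent variance, batch effects beyond the plate gain,
compositional or count noise, dose–response and treatment-duration
structure, and probe-level hybridisation artefacts. Passing the planted
recovery and null-calibration suites therefore demonstrates that the
statistics are implemented correctly and calibrated under their own
assumptions — not that they are robust to everything real arrays do.

# Validation problem sizes

The test suite validates at sizes chosen to make the checks sharp yet
quick: null calibration of both significance filters on 10,000 genes
(99% binomial band around $\alpha = 0.05$); KS null uniformity over 200
repetitions of 25 hits in a universe of 2,000 with 300 permutations each;
single-study recovery at 1,000 genes, 100 planted, effect 3 SD, 5 vs 5;
and an end-to-end screen of 50 drugs (5 reversers at reversal fraction
0.8, triplicates on 10 plates) against five replicate 4,000-gene studies,
with drug profiles built by the fold method at $\alpha = 0.01$. The
stricter profile alpha reflects a power analysis: at $\alpha = 0.05$ every
profile carries $\approx 5\%$ false genes, which alone contributes an
expected ~5-gene chance overlap with a 100-gene signature regardless of
universe size, frequently enough to contaminate hit selection across the
(strongly correlated) replicate signatures; $\alpha = 0.01$ keeps the
expected chance overlap at 1–2 genes, below the floor at which a discrete
tail can reach nominal significance.

# Known limitations

* Disease inputs are gene-level matrices; probe-level disease data and
  annotation translation are out of scope (probe handling exists only on
  the drug-profile side).
* The equal-variance *t* is the canonical filter; Welch-style corrections
  are not currently exposed.
* The zscore treatment filter with triplicate controls is heavy-tailed by
  construction (2 control df); the fold method is the better-calibrated
  default at small replicate counts.
* `setCorrelationSummary` averages signed Z, so an anti-correlated pair
  inside a set lowers, rather than raises, the within-set mean.
* No meta-analytic weighting by study size, no cross-series batch
  correction, no dose–response modelling.
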