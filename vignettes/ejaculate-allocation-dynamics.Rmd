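---
title: "Modelling strategic ejaculate allocation and seminal fluid proteome dynamics"
author: "ejacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling strategic ejaculate allocation and seminal fluid proteome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ejacdyn)
```

## The scientific setting

Males of polygynandrous species are expected to tailor ejaculate expenditure
to the value of each mating opportunity. Two forces pull in opposite
directions over a sequence of matings: depletion of extragonadal sperm and
seminal fluid (SF) reserves drives investment down, while the appearance of
a sexually novel female favours renewed investment (the Coolidge effect).
`ejacdyn` implements the statistical machinery for studying this interplay
in sequential-mating trials of the kind run with fowl: a male mates up to
five consecutive times with a first female and then exactly once with a
second, novel female, with sperm numbers, SF volume and SF protein
concentration recorded at every opportunity, and the SF proteome of
successive ejaculates quantified by spectral counting.

The package has two halves. The behavioral half fits and ranks mixed-effects
models of expenditure and implements a per-male depletion-prediction test.
The proteome half turns spectral counts into compositional abundances and
characterises their temporal structure: dendrogram confidence by multiscale
bootstrap, soft clustering of temporal profiles, set enrichment, and PCA.
A pair of seeded simulators generates behavioral trials and
cluster-structured count matrices with known ground truth, so every stage
has a parameter-recovery test that needs no external data.

## Candidate models and information-criterion selection

For each response — the probability of producing an ejaculate (binomial,
logit link), log sperm number, log SF volume, and SF protein concentration
(gaussian; ejaculated opportunities only) — the candidate set is fixed:

* Null, `F`, `CE`, `CE + F`, `CE + F + CE:F`,

where `CE` is cumulative exposure (the ordinal index of the opportunity
within a male's trial, across both females) and `F` female novelty (first
vs second female). Every model carries a random intercept per male and is
fitted by maximum likelihood — not REML — because likelihoods must be
comparable across fixed-effect structures. The binomial marginal likelihood
integrates the random intercept by adaptive Gauss–Hermite quadrature
(25 nodes by default; the log-likelihood is stable to well below 0.01 under
doubling, which the tests assert).

Models are ranked by the small-sample criterion
$AIC_c = -2\ell + 2k + 2k(k+1)/(n-k-1)$, appropriate because $n/k < 40$ in
trials of this size. The parameter count `k` includes the fixed effects
(with intercept), the random-intercept variance, and — for gaussian
responses — the residual variance. Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ quantify relative support;
the top model set is everything within 2 AICc of the best model, and the
best minimal model is the top-set member with fewest parameters (ties
broken by lower AICc).

Effect sizes are model-averaged over the top set with predictors
standardized to mean 0 and SD 0.5, which puts the continuous `CE` and the
binary `F` on comparable scales. Both averaging variants are reported: the
full average substitutes zero for a term absent from a model (the headline
estimate, shrinking weakly supported effects), and the conditional average
uses only the models containing the term. Because the ranked tables are
invariant to affine predictor coding, selection is run on the natural
scale and standardization applies to the averaging refits.

## The depletion-prediction (Coolidge) test

The single mating with the novel female cannot be analysed like the
familiar-female series — there is only one such opportunity per male. The
bespoke test therefore asks, per male: did he deliver more than his own
depletion trajectory predicts? An ordinary least-squares line of
$\log(1+y)$ on cumulative exposure is fitted over the male's familiar-female
opportunities, *including* opportunities with no ejaculate (entered as
zeros — omitting them would bias the trajectory upward). The line is
evaluated at the exposure of the novel-female mating, back-transformed as
$e^{\hat y}-1$, and clamped at zero. Observed and predicted values are then
compared across males with the paired Wilcoxon signed-rank statistic
$V$ (sum of ranks of positive differences), with the exact null
distribution computed by dynamic programming over doubled midranks for up
to 25 informative pairs, and a tie- and continuity-corrected normal
approximation beyond. Zero differences are dropped by default (their count
is reported); a Pratt-style option retains their ranks. Both one-sided and
two-sided p-values are reported, since the direction of interest (observed
above predicted) is one-sided but V itself is sidedness-free.

Two design points deserve emphasis:

* **Fitting set.** The per-male line is fitted on familiar-female rows only
  and extrapolated to the novel-female exposure; a sensitivity switch
  (`include_female2 = TRUE`) refits with the novel-female row included.
* **Calibration regime.** The signed-rank test assumes differences
  symmetric about zero under the null. When many males fail to ejaculate
  (observed value 0 against a positive prediction, or enormous positive
  differences on the raw scale), that symmetry fails *even with no novelty
  effect*, and simulation shows the test is then anticonservative. The
  package's type-I calibration study therefore runs under a null in which
  every opportunity yields an ejaculate; there the empirical rejection
  rate at the 5% level is 0.05 within Monte-Carlo error (200 seeded
  trials, asserted by the tests). Results of the test on heavily
  zero-inflated data should be read with this asymmetry in mind.

The status contrast compares, between dominant and subdominant males, the
ratio of the novel-female value to the male's last familiar-female value,
using the two-sample rank-sum test with exact dynamic-programming tails
whenever the smaller group has at most 10 males.

## Compositional quantitation and similarity

Spectral counts $n_i$ are converted to compositional abundances
$p_i = C \cdot (n_i/O_i) / \sum_j (n_j/O_j)$, where $O_i$ is a per-protein
detectability probability supplied as an input (uniform by default — the
machine-learning detectability model that produces refined $O_i$ values
operates on MS internals outside this package's scope) and $C$ is the fixed
per-sample total, defaulting to 1 so abundances are proportions. All
downstream analyses are scale-free in $C$. Proteins "identified
consistently" are those with nonzero evidence in every mating; similarity
between samples is the squared Pearson correlation of log abundances over
proteins present in both. Zeros are floored at half the smallest positive
abundance before logs — a conventional pseudo-abundance, configurable.

## Dendrogram confidence by multiscale bootstrap

Samples are clustered with euclidean distance and complete linkage.
Support for each edge (sample bipartition) comes from resampling the
proteins — the features over which samples are compared — at scales
$r \in \{0.5, \dots, 1.4\}$: at each scale, $B$ resamples of
$\lceil rN \rceil$ proteins are drawn with replacement, the tree is rebuilt,
and $bp_r$ is the fraction of replicates containing the bipartition.
The normal quantiles $z_r = \Phi^{-1}(1-bp_r)$ are fitted by weighted least
squares to $z(r) = v\sqrt{r} + c/\sqrt{r}$ (weights from the binomial
variance of $bp_r$ via the delta method), giving the approximately unbiased
p-value $AU = 1-\Phi(v-c)$ and the bias-corrected $BP = 1-\Phi(v+c)$.
Numerical choices: $bp_r$ is clamped to $[1/2B,\ 1-1/2B]$ before the
quantile map; an edge found in essentially every replicate at every scale
carries no information to separate $v$ from $c$ and is reported as
$AU = BP = 1$ directly; with a single usable scale the fit degenerates and
AU falls back to the ordinary bootstrap probability with a flag. Edges are
identified by the bipartition side not containing the lexicographically
smallest sample, so topologically equivalent trees match regardless of
rotation. The default is $B = 1000$ per scale; published analyses of this
kind often use 10000, which simply tightens the Monte-Carlo error.

## Fuzzy temporal clustering

Temporal profiles of the consistently identified proteins (log abundances,
each protein standardized to mean 0, SD 1 across the ordered samples M1,
M2, M3, F2) are soft-clustered by fuzzy c-means: memberships
$u_{ik} = 1/\sum_j (\|x_i-v_k\|/\|x_i-v_j\|)^{2/(m-1)}$, centroids
$v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m$, iterated until the objective
decreases by less than $10^{-6}$, best of 10 seeded restarts. The fuzzifier
defaults to the variance-based estimate
$m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)D^{-0.0406\ln N - 0.1134}$,
about 2.6 for 800 proteins over 4 time points.

The cluster number is chosen from the minimum centroid distance
$D_{\min}(c)$: once $c$ exceeds the number of genuinely distinct profile
groups, surplus centroids crowd into one group and $D_{\min}$ collapses.
We select the $c$ preceding the most abrupt *relative* drop,
$c^* = \arg\min_c D_{\min}(c{+}1)/D_{\min}(c)$, requiring the winning ratio
to fall below 0.5. A simpler threshold rule anchored at $D_{\min}(2)$ was
considered and rejected: with four planted profile groups the 2-to-3 drop
is a geometric consequence of antipodal profile pairs and trips such a
threshold even at high signal, whereas the largest-relative-drop rule
recovers two-, four-group and structureless cases correctly (all three are
asserted in the tests, the last via a warning path that returns 2).

Hard assignment takes each protein's maximal membership. Centroids are
classified by shape over M1..M3, F2: a profile is *novelty-specific* when
its F2 value deviates from the linear extrapolation of the three
familiar-female points by more than their own spread (an F2 value that
merely continues a monotone trend is depletion or enrichment, not novelty);
otherwise monotone non-increasing centroids are *depleted*, non-decreasing
*enriched*, and anything else *other*. Tolerances are relative (5% of the
profile range), so standardized centroids of any scale classify
identically. Membership coherence between clusters is compared pairwise by
the exact rank-sum test on maximal membership values.

## Enrichment and PCA

Cluster composition is tested against user-supplied annotation collections
(GMT format) by the exact hypergeometric test, reporting the fold
enrichment $(k/n)/(K/N)$ and both tails, with Benjamini–Hochberg adjustment
across sets within each cluster. The background defaults to the analyzed
protein universe; a genome-wide background may be supplied where
annotations for unobserved proteins exist.

PCA treats proteins as observations and samples as variables (columns
centred, unscaled — abundances share one compositional scale). Component
significance is assessed against a permutation null that permutes each
sample column independently, preserving marginal abundance distributions
while destroying between-sample correlation; a component is significant
when its variance fraction exceeds the 95th percentile of its permuted
values (999 permutations by default, seeded). With compositional abundance
data the first component tracks overall protein abundance in every sample
— the correlation of PC1 scores with per-sample abundances is reported so
that interpretation can focus on the later, between-sample axes.

## What the simulators emulate — and what they do not

`simulate_behavior()` emulates the trial design: a geometric habituation
phase (mean 2.05 female exposures before the first copulation), up to five
familiar-female opportunities ending at the first failure to ejaculate,
then one novel-female opportunity. Ejaculation is logistic in cumulative
exposure (defaults give roughly 90 opportunity rows across 19 males);
sperm, SF volume and SF protein concentration follow one latent log1p
trajectory `intercept + slope*CE + boost*I(novel)` with normal noise on the
log1p scale and per-response scale factors. The noise law of
absorbance-calibrated sperm counts is not documented for this design; the
lognormal-style choice is an emulation, not a claim. There is deliberately
no male-level random effect in the default truth, which the tests exploit:
mixed-model log-likelihoods must then match fixed-effects fits.

`simulate_proteome()` plants four temporal profile classes (monotone
decrease 43%, monotone increase 19%, novelty-specific increase 21% and
decrease 17% by default — the decomposition such analyses report) on a
log scale over M1, M2, M3, F2, with lognormal protein baselines and
negative-binomial counts around compositional expectations whose column
totals are fixed. One compositional caveat matters for interpretation:
because abundances are constrained to sum to a constant, the log column
total of the planted weights acts as a common shift on every observable
profile. The shift is second-order for amplitudes near 1 but grows
nonlinearly, and by amplitude 2 it makes monotone-decreasing and
novelty-decreasing profiles nearly indistinguishable. The default
amplitude is therefore 1, and the high-signal recovery fixtures use
amplitude 1.2 with deep counts (depth 300, zero dispersion) — conditions
under which the planted partition is recovered with adjusted Rand index
above 0.95 and class fractions within 0.02. Passing these tests shows the
pipeline recovers structure of the planted form at realistic scale; it
does not certify performance on real proteomes, whose amplitude spectrum,
missingness and correlation structure are richer.

## Problem sizes and runtime choices

The test-suite and acceptance-script simulations are sized for a single
CPU: 19-male trials for the behavioral analyses; 100 seeded replicates
for the model-selection recovery study; 200 for the type-I calibration;
400–805 proteins, bootstrap B of a few hundred per scale, and 199–499
permutations for the PCA null. All are package-level choices that keep a
full run in minutes; every quantity concerned is a Monte-Carlo estimate
whose precision, not location, depends on these sizes.

## Known limitations

* The behavioral models cover a single random intercept and the
  binomial/gaussian families only; random slopes and richer hierarchies
  are out of scope.
* The Coolidge test inherits the asymmetry caveat above under heavy
  zero-inflation; the one-sided "greater" p-value is the directional test
  of preferential investment.
* Detectability weights are inputs; no peptide-level inference, FDR
  control or annotation retrieval is performed.
* The enrichment test is the plain hypergeometric; tools built on modified
  Fisher statistics can give slightly different p-values on the same sets.
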