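---
title: "Models and methods in crpopgen"
author: "crpopgen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in crpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

crpopgen analyzes aligned mitochondrial control-region (CR) sequences
sampled from several localities of one species. The CR is the fastest
evolving part of the mitochondrial genome, so a few hundred base pairs
typically resolve dozens of haplotypes even in weakly structured marine
populations. The package covers the standard descriptive layer (haplotype
tables, diversity indices), hypothesis tests for demographic expansion
(Tajima's D, Fu's Fs, the mismatch distribution), distance-based population
structure (AMOVA, pairwise Phi_ST), a minimum spanning haplotype network,
and a reduced isolation-with-migration (IM) coalescent sampler for the
divergence of two populations. A structured coalescent simulator with HKY
sequence evolution generates synthetic data with the statistical structure
all of these analyses assume, and doubles as the engine behind every
permutation, bootstrap and p-value in the package.

## Data model and conventions

An alignment is a set of equal-length sequences over `A,C,G,T,-,N`.
Internally all column coordinates are 0-based half-open intervals; reports
are 1-based. Two sequences carry the same haplotype iff they are identical
strings after uppercasing; an `N` mismatching a base keeps sequences
distinct. This is deliberately conservative: there is no principled way to
merge partially ambiguous sequences without a frequency model, and keeping
them apart never inflates shared-haplotype counts. Indel columns count
toward haplotype identity and toward the number of segregating sites S, but
every *distance* (pairwise differences, p-distance, TN93) uses pairwise
deletion: a site enters a pair's comparison only when both sequences carry
a plain base. Pairwise deletion keeps the maximum information per pair and
is what the standard population-genetics packages do.

## Diversity

Haplotype diversity is Nei's sample-corrected heterozygosity
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with its sampling variance
$V(h) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p^3 - (\sum p^2)^2\right) +
\sum p^2 - (\sum p^2)^2\right]$.
Nucleotide diversity $\pi$ is the mean per-site p-distance over all
sequence pairs; its standard error combines the sampling and coalescent
("stochastic") variance terms
$V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L} +
\frac{2(n^2+n+3)}{9n(n-1)}\pi^2$. The package also provides the closed-form
Tamura–Nei (TN93) distance with optional gamma rate heterogeneity
(default shape $\alpha = 0.61$, matching an HKY+I+G fit to CR data of this
kind); corrected distances feed the structure analyses, while $\pi$ itself
is defined on proportions of differences and therefore stays uncorrected by
default. An invariant-sites fraction can be recorded with the model
parameters but is not used to rescale TN93 distances — there is no standard
closed form for TN93+I, and the reference implementations ignore it too; we
document rather than improvise.

## Neutrality tests

`tajimas_D()` standardizes the difference between the mean number of
pairwise differences and Watterson's $S/a_1$. `fus_Fs()` evaluates the
Ewens sampling formula exactly:
$S' = \Pr(K' \ge K_{obs} \mid \theta = \bar k)$ computed from unsigned
Stirling numbers of the first kind in log space (exact to 1e-10 up to at
least $n = 100$), and $F_s = \ln(S'/(1-S'))$.

p-values come from neutral constant-size coalescent replicates. Following
standard practice, each replicate places exactly the observed number of
segregating sites on the simulated genealogy, multinomially in proportion
to branch length (the conditional test); this removes the scale parameter
from the null entirely. p-values are one-sided toward negative values —
the direction that signals population expansion, which is the alternative
these analyses screen for. The default replicate count is 1000 and the
seed is mandatory.

The conditional placement matters for calibration: with Poisson mutation
under a plug-in $\theta$, the Fs test is anticonservative at the usual
0.05 cutoff (the behaviour behind the classical advice to reject at
$p \le 0.02$), whereas under the conditional null both tests are
exchangeable with their replicates and empirically hold the 5% level —
the test suite verifies this over 1000 neutral data sets.

## Mismatch distribution and sudden expansion

The observed mismatch distribution is the histogram of pairwise difference
counts. Under an instantaneous change from scaled size $\theta_0$ to
$\theta_1$, $\tau$ mutational units ago, the expected distribution is the
classical transient solution
$$F_i = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
\sum_{j=0}^{i}\frac{\tau^j}{j!}\left[\hat F_{i-j}(\theta_0)
- \hat F_{i-j}(\theta_1)\right], \qquad
\hat F_j(\theta) = \frac{\theta^j}{(1+\theta)^{j+1}}.$$
At $\tau = 0$ this reduces to the pre-expansion equilibrium
$\hat F(\theta_0)$; at $\theta_0 = \theta_1$ the bracket vanishes. The
vector is truncated at the largest observed class without renormalization,
and the unallocated tail mass is reported, so the fit is not biased by
hidden renormalization.

Fitting minimizes the unweighted sum of squared deviations over
$\tau \in [0,50]$, $\theta_0 \in [0,50]$, $\theta_1 \in [10^{-6}, 99999]$
with ten deterministic starts (including a method-of-moments start
$\tau \approx$ mean difference count, $\theta_0 \approx 0$, $\theta_1$ at
its bound). The lower bound $10^{-6}$ on $\theta_1$ avoids the undefined
exponent at exactly zero — a measure-zero boundary. When the optimum sits
at the $\theta_1$ bound the conventional sentinel 99999 is reported; for
strongly expanded samples $\theta_1$ is genuinely unidentifiable and the
boundary report is information, not failure. Least squares is unweighted:
the "generalized" in the usual description of this fit refers to the
bootstrap treatment of uncertainty, not to a weighting matrix, and no
published weights exist to copy.

Uncertainty and goodness of fit use a parametric bootstrap (default 200
replicates): data sets are re-simulated under the fitted parameters with
the package's own coalescent (infinite-sites mutation placement, which is
what the mismatch theory assumes), each is refitted, the 2.5/97.5
percentiles of the refitted $\tau$ give the 95% CI (percentile bootstrap —
the reference analyses do not state a fancier method, and percentile is
the transparent default), and `p_SSD` is the fraction of bootstrap SSDs at
or above the observed one. Harpending's raggedness
$r = \sum (x_{i} - x_{i-1})^2$ appends a zero class after the last observed
one; that end convention is documented here because the original
description leaves it open, and it makes $r$ of a single-class distribution
equal 1.

Expansion times convert through $\tau = 2ut$ with $u$ the whole-sequence
per-generation rate; the default scaling ($1.9 \times 10^{-7}$
substitutions/site/year, 993 sites, 1-year generations) uses the unrounded
product, which is what reproduces the published conversions.

## AMOVA and pairwise Phi_ST

AMOVA partitions squared molecular distances. Sums of squares come from
the identity $SS(\text{set}) = \frac{1}{n}\sum_{i<j}\delta^2_{ij}$;
variance components use the standard unequal-size coefficients, and
negative components are reported as estimated, never truncated — small
negative values are the expected behaviour of an unbiased estimator near
zero differentiation. Squared TN93+gamma distances are the default input
(matching the distance model above); a p-distance option exists for
robustness checks. Permutation schemes follow the original convention:
individuals among populations for Phi_ST and Phi_SC (the latter within
groups), whole populations among groups for Phi_CT. p-values carry the
$(\text{hits}+1)/(\text{perms}+1)$ correction, so they are never zero.
Defaults are 1000 permutations for each pairwise comparison and 5000 for
the full AMOVA. Pairwise Phi_ST analyzes each population pair as a
two-population AMOVA; populations of size one are excluded with a warning
because a within-population variance cannot be estimated from them.

## Haplotype network

The minimum spanning network is Kruskal's MST on raw substitution counts
with deterministic tie-breaking (weight, then lexicographic pair), plus a
flag on every non-tree edge whose weight equals the maximum edge weight on
the tree path between its endpoints — the equally minimal alternative
connections. Raw counts, not model-corrected distances, are the right edge
weights here: network tick marks denote individual substitutions. Node
metadata carry total and per-population haplotype frequencies for
plotting.

## The isolation-with-migration sampler

The reduced IM model: an ancestral population of scaled size $\theta_A$
splits at scaled time $t$ into two descendants ($\theta_1$, $\theta_2$)
exchanging migrants at per-lineage rates $m_1, m_2$. Everything is in
per-lineage mutational units (whole-sequence substitution rate 1 per unit
time): the per-pair coalescence rate in deme $i$ is $2/\theta_i$, and a
scaled time converts to years as $t/u$. Priors are uniform on
$[0, \text{bound}]$ per parameter, with user-set bounds (runs on real data
should widen bounds until the posterior mode sits well inside them).

The state is (genealogy with embedded migration events, parameters); the
posterior factorizes as likelihood x structured-coalescent density x
uniform priors. The likelihood is Felsenstein pruning under HKY with
empirical base frequencies and a fixed, moment-estimated
transition/transversion ratio — fixing kappa removes a nuisance dimension
from the state space, and the inference targets are the demographic
parameters, not the substitution model. Rate heterogeneity is deliberately
not part of the IM likelihood. The Metropolis-Hastings move set:

* node-time slides (uniform within the window left free by neighbouring
  nodes and migration events; multiplicative above the last constraint for
  the root);
* subtree detach–reattach respecting deme constraints — the pruned edge
  keeps its migration events, and the attachment point must lie in the
  deme the pruned lineage occupies at its top (no constraint above the
  split). The spliced intermediate state is identical for the forward and
  reverse proposal, which keeps the Hastings ratio exact;
* migration-event pair birth/death on one edge (inserting or deleting an
  adjacent flip-flip pair preserves all endpoint demes) and single-event
  slides;
* a node "retype" move that flips one internal node's deme and
  inserts/deletes one event on each adjacent edge. This is the only move
  that changes the total migration count by an odd number; without it the
  chain is trapped in one parity class of the event space and every
  marginal is biased — the prior-recovery test below fails loudly if this
  move is removed;
* multiplicative scale moves on single parameters;
* a redraw move that resamples one (or all) parameters from their priors
  together with a complete genealogy from the structured-coalescent prior.
  Prior and proposal cancel, so it is accepted on the likelihood ratio
  alone. When the sampler runs with the likelihood switched off the redraw
  move is an exact sampler and is weighted up, which makes the recorded
  prior draws decorrelate quickly.

Posterior summaries use fixed 200-bin histograms over each prior range:
the mode is the midpoint of the maximum bin after a 3-bin moving average
(posterior densities of scaled sizes are ragged without smoothing), the
95% HPD is the shortest run of consecutive bins holding 95% of the mass,
and per-parameter effective sample sizes come from the initial positive
sequence of autocorrelations. TMRCA (the root time) is recorded with the
parameters. Two independent seeded runs that agree within a histogram bin
are the practical convergence check.

Sampler validity is tested two ways rather than trusted: (i) with the
likelihood off, the marginal of every parameter must be its uniform prior
(Kolmogorov–Smirnov on thinned samples) — this catches Hastings-ratio
errors anywhere in the move set; (ii) with parameters fixed, the local
moves alone must reproduce the TMRCA and migration-count distributions of
direct structured-coalescent simulation — this checks the prior density
evaluator against the simulator, the two independent implementations of
the same measure.

## The simulator

Three scenarios share one engine: constant size, sudden expansion
(epoch-switching pair rate), and the two-deme split with migration.
Constant and expansion scenarios run in "tau units" (a *pair* of lineages
accumulates one mutation per unit time), so $\tau, \theta_0, \theta_1$
plug into the mismatch formulas without conversion and $E[S] = \theta a_1$
and $E[\bar k] = \theta$ hold exactly; the split scenario runs in
per-lineage units to match the IM parameterization. Sequences evolve under
HKY via the eigendecomposition of the rate matrix (per-site transition
probabilities, vectorized over sites), with optional gamma rate multipliers
and invariant sites. Defaults mimic an AT-rich CR locus: 993 sites, base
composition A 37.25%, C 9.57%, G 7.93%, T 45.24%. The default study-like
configuration is five demes of 17–21 samples drawn from an expansion
genealogy with high haplotype diversity and moderate nucleotide diversity.
Indels are not simulated: every downstream statistic as implemented treats
them by pairwise deletion, so simulated indels would change nothing but
the bookkeeping.

What passing tests on synthetic data do *not* show: real CR alignments
contain alignment-ambiguous regions, heteroplasmy artifacts, sequencing
ambiguities and mutation-rate heterogeneity along the sequence beyond a
gamma law. The masking step exists precisely because the simulator's clean
columns are not the hard part of real data.

## Problem sizes in the test suite

The test-suite defaults are desk-scale choices made once: neutrality
calibration uses 1000 data sets of n = 30 with 199-replicate conditional
p-values; mismatch recovery uses 200 replicates of n = 17 in the
small-coastal-sample regime; IM prior recovery records 5000 thinned
samples from a 150,000-step likelihood-free chain, and parameter recovery
runs ten 18,000-step chains on n = 10+10, L = 500 splits. The full-size
analyses (5000 AMOVA permutations, million-step IM burn-ins) remain
available through the exported configuration arguments.

## Known limitations

* Single locus, no recombination — appropriate for mtDNA only.
* The IM sampler fixes the substitution model (HKY, fixed kappa) and does
  not sample rate heterogeneity.
* TN93+I is not implemented (documented above); the invariant fraction is
  reporting-only.
* The mismatch CI is a percentile bootstrap; no BCa correction.
* At desk-scale chain lengths the split time t is the slowest-mixing IM
  parameter (its conditional support is pinned between migration events
  and the first cross-deme coalescence); production runs should use far
  longer chains and check t's ESS before interpreting its HPD. With weak
  single-locus data the θ of a deme with no below-split coalescences is
  bounded only by its prior, so prior upper bounds should be set a small
  multiple of the observed mean pairwise difference count rather than left
  arbitrarily wide.
* The median-joining network with inferred median vectors is out of scope;
  the minimum spanning network reproduces the same backbone without latent
  nodes.
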