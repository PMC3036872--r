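# crpopgen

Population-genetic analysis of mitochondrial control-region (CR) sequence
alignments. The CR is the fastest-evolving part of the mitochondrial
genome, which makes a ~1 kb fragment a sensitive marker for the questions
this package is built around: how much haplotype variation does a species
carry, is that variation structured geographically, did the population
expand recently, and when did two populations diverge? Typical users are
population geneticists and fisheries/conservation biologists with an
aligned FASTA of CR sequences from several sampling localities.

## What it computes

* **Haplotype tables and diversity** — collapse sequences into haplotypes,
  per-locality counts, shared vs sample-specific haplotypes, Nei's
  haplotype diversity *h* = *n*(1 − Σp²)/(n−1) and nucleotide diversity π
  with their variances; closed-form Tamura–Nei (TN93, optionally +Γ)
  distances.
* **Neutrality tests** — Tajima's *D* and Fu's *F*s (exact Ewens-formula
  evaluation via log-space Stirling numbers), with p-values from neutral
  coalescent simulation conditional on the observed number of segregating
  sites.
* **Mismatch distributions** — the sudden-expansion model
  *F_i*(τ, θ₀, θ₁) of Rogers–Harpending type, least-squares fitting with
  multi-start bounded optimization, Harpending's raggedness, parametric
  bootstrap CIs and goodness of fit, and conversion of τ to years through
  τ = 2*u*t.
* **Population structure** — AMOVA variance components (one- and
  two-level), Φ-statistics, pairwise Φ_ST, permutation tests.
* **Haplotype network** — minimum spanning tree/network over substitution
  counts with equally-minimal alternative edges flagged.
* **Isolation with migration** — a reduced two-population IM
  Metropolis–Hastings sampler over (genealogy, θ₁, θ₂, θ_A, t, m₁, m₂)
  with an HKY pruning likelihood, giving posterior modes, 95% HPDs and
  TMRCA, and their conversion to calendar years and effective sizes.
* **Simulation** — a structured coalescent simulator (constant size,
  sudden expansion, two-deme split with migration) with HKY sequence
  evolution; it generates the package's synthetic data and drives every
  permutation, bootstrap and coalescent p-value.

## Worked example

Simulate a CR-like data set under a recent expansion and analyze it:

```r
library(crpopgen)
set.seed(7)
cfg <- sim_config("sudden_expansion", n = 25, L = 993,
                  theta0 = 0.05, theta1 = 60, tau = 8)
sim <- simulate_dataset(cfg, seed = 42)
aln <- sim$alignment
pm  <- cr_popmap(setNames(rep(c("north", "south"), c(13, 12)), aln$ids))

collapse_haplotypes(aln, pm)
#> <cr_haplotypes> 20 haplotypes, 25 individuals, 2 populations

neutrality_test(aln, n_reps = 1000, seed = 1)
#> Tajima's D = -1.926 (p = 0.011), Fu's Fs = -7.188 (p = 0.011)

pd  <- pairwise_differences(aln)
fit <- fit_sudden_expansion(observed_mismatch(pd$diff), n = 25,
                            seed = 1, n_boot = 100)
fit
#> sudden-expansion fit: tau = 9.283, theta0 = 0, theta1 = 1e+05
#>   SSD = 0.007187 (p = 0.15), raggedness = 0.01866 (p = 0.18)
#>   tau 95% CI: 5.882 - 11.009 (n_boot = 100)
round(tau_to_years(fit$tau) / 100) * 100
#> [1] 24600
```

Reading the output: 20 haplotypes among 25 sequences give high haplotype
diversity (h = 0.983), the strongly negative and significant *D* and *F*s
flag an excess of rare variants, the mismatch fit recovers an expansion
time τ̂ = 9.3 (true value 8, inside the bootstrap CI 5.9–11.0) with θ₁ at
its boundary sentinel — the usual signature of strong growth — and the
default CR clock converts τ̂ to roughly 24,600 years.

The full pipeline (`run_pipeline()` or
`inst/scripts/crpopgen-cli.R all --fasta ... --popmap ... --out ...`)
writes the haplotype table, diversity/neutrality summary, mismatch curve,
AMOVA and pairwise-Φ_ST tables, the network edge list and a JSON report
into an output directory; `?run_config` lists every knob.

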