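---
title: "Methods: COI population genetics with coipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI population genetics with coipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipop)
```

coipop implements the standard single-marker phylogeography workflow for
mitochondrial COI amplicons. This vignette is the package's own account of
the statistical methods, the conventions chosen where programs in this
field differ, and what the bundled simulators can and cannot tell you
about real data.

## The sequence layer

COI barcoding amplicons from a shared primer pair are co-anchored at the
5' end and, being protein-coding mtDNA, effectively indel-free within a
species. `trim_to_common()` therefore replaces a full multiple alignment
with truncation to the shortest common length, optionally preceded by an
ungapped best-offset anchoring against a reference read
(`anchor_to`) for inputs whose leading bases differ. Any column that
carries a gap character in any record is removed entirely before
statistics (complete deletion), the usable-loci convention of standard
population-genetics software; ambiguity codes other than `N` are recoded
to `N` on import because none of the downstream statistics exploit
partial ambiguity.

Translation QC (`translate_qc()`) screens for nuclear pseudogenes and
frame errors: each record is translated in all three forward frames under
the invertebrate mitochondrial code (NCBI table 5), the frame with the
fewest internal stops is selected (ties to the lowest frame index), and
one or more internal stops in that best frame fails the record. A
terminal stop codon is not counted.

`collapse_haplotypes()` uses exact string matching by default, so two
sequences that differ only at an `N` remain distinct haplotypes. That is
deliberately conservative — treating `N` as a wildcard can chain-merge
distinct haplotypes through a low-quality read — but the wildcard policy
is available (`n_as_wildcard = TRUE`), which greedily merges each record
into the first compatible earlier haplotype. Haplotypes are named
`H1..Hk` by decreasing total count, ties by first appearance, so output
is deterministic under record reordering.

## Diversity and neutrality statistics

Haplotype (gene) diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with its sampling variance (Nei
1987, eq. 8.12). Nucleotide diversity $\pi$ is the mean proportion of
differing sites over all $\binom{n}{2}$ pairs, with pairwise deletion of
`N` positions (whether published tables use pairwise or complete deletion
is rarely stated; pairwise deletion is the default here because it
discards the least data). Its standard deviation uses Nei's total
variance (eq. 10.7), which includes the coalescent (stochastic)
component; reported values can be scaled ×100 (`percent = TRUE`) to match
the "π (%)" convention of published tables.

Tajima's D uses the 1989 constants and requires $n \ge 4$ and at least
one segregating site; monomorphic samples are reported `NA` rather than
zero. Fu's Fs is computed from the Ewens sampling formula:
$S' = \Pr(K \ge k_{obs} \mid \theta = \hat\theta_\pi)$, evaluated through
an unsigned-Stirling-number recursion carried entirely in log space, so
it is exact in floating point up to n in the hundreds; $F_s =
\ln(S'/(1-S'))$, with the complementary tail computed from the lower
probabilities rather than as $1 - S'$ to avoid cancellation.

Both tests get p-values by neutral coalescent simulation conditioned on
the sample size and $\hat\theta_\pi$ (the mean number of pairwise
differences), as Arlequin-style packages do: the reported p is the
lower-tail proportion of simulated statistics at or below the observed
one (10,000 replicates by default, seeded). The conventional Fs
significance threshold of 0.02 is documented here and in the function
help, never silently applied.

## Mismatch distributions and the sudden-expansion model

The expected distribution of pairwise differences after an instantaneous
change of scaled population size $\theta_0 \to \theta_1$ at mutational
time $\tau$ is, with $\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}$,

$$F_i(\tau,\theta_0,\theta_1) = \hat F_i(\theta_1) +
  e^{-\tau(\theta_1+1)/\theta_1}\sum_{j=0}^{i}\frac{\tau^j}{j!}
  \left[\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)\right].$$

Because the observed distribution has finite support $0..d$, the expected
vector is truncated at $d$ and renormalized to sum to one before
computing $SSD = \sum_i (obs_i - exp_i)^2$; observed and expected vectors
are therefore directly comparable and both sum to 1.

Fitting minimizes SSD by Nelder–Mead over log-transformed parameters,
with $\theta_1$ parameterized as $\theta_0 + e^c$ so the constraint
$\theta_1 \ge \theta_0 \ge 0$ holds by construction and capped at
$10^5$ (beyond which the recent epoch is effectively infinite); three
seeded starts spread over moment-based guesses guard against local
minima. Harpending's raggedness index is
$r = \sum_{i=1}^{d}(x_i - x_{i-1})^2$ over the observed classes with no
zero-padding beyond the support — conventions differ between programs, so
the one used is stated prominently.

Goodness-of-fit p-values use a parametric bootstrap: `B` datasets are
simulated under the fitted expansion with the package's own coalescent
generator, each refitted, and p is the fraction of bootstrap SSD
(raggedness) values at or above the observed one. Large p means the
expansion model cannot be rejected. The default is `B = 1000`; the test
suite and examples use smaller B purely as a matter of scale, since each
replicate involves a full refit.

## AMOVA, pairwise ΦST, Holm, Mantel

The AMOVA decomposes the total sum of squared molecular distances —
pairwise difference counts, the standard squared Euclidean distance for
haplotype data — using the classic weighted sums of squares with the
expected-mean-square coefficients for unequal sample sizes; the
implementation reproduces an independent reference implementation (ade4)
to machine precision in the test suite. Negative variance components are
retained in machine-readable output (they are informative about
estimator noise) and clamped to zero only in display, matching the
convention of published pairwise tables.

Permutation schemes follow the standard hierarchy: individuals among
populations for $\Phi_{ST}$; individuals among populations within groups
for $\Phi_{SC}$; whole populations among groups for $\Phi_{CT}$.
P-values are one-tailed with the +1 correction,
$p = (\#\{\Phi^* \ge \Phi\} + 1)/(B + 1)$, so they are never exactly
zero. The default 10,000 permutations is configurable; note that
$\Phi_{CT}$'s whole-population scheme has coarse granularity when few
populations are available (with three populations in two groups the
smallest achievable p is 1/3) — a property of the design, not of the
implementation.

`pairwise_phist()` runs the two-population AMOVA for every site pair and
applies Holm's sequential Bonferroni correction (via `stats::p.adjust`)
to the raw permutation p-values. `scan_grouping_schemes()` evaluates a
list of named candidate groupings — the way barrier hypotheses are
usually compared — and flags the scheme with the largest significant
$\Phi_{CT}$.

The Mantel test reports the classical $Z = \sum_{i<j} g_{ij} d_{ij}$, the
Pearson correlation r of off-diagonal entries, and a one-tailed
permutation p from jointly permuting rows and columns of one matrix. For
small site sets (n! within the permutation budget, or `exact = TRUE`) it
enumerates all n! relabelings and returns the exact p including the
identity permutation.

## Haplotype networks

`build_msn()` computes an ε = 0 minimum spanning network: a canonical
Kruskal MST with deterministic lexicographic tie-breaking, plus every
edge that occurs in at least one MST. An edge (u, v) of weight w is in
some MST iff u and v are disconnected among strictly lighter edges, and
in every MST iff removing it disconnects them among edges of weight ≤ w;
edges in some-but-not-all MSTs are flagged `alternative`, mirroring the
"alternative links" of standard network software, and are never silently
dropped.

Published haplogroup delineations are usually visual. To make them
reproducible, `assign_haplogroups()` removes edges longer than a step
cutoff (default 5) and labels the remaining components by decreasing
total count. The cutoff is an explicit parameter, not a claim about any
published procedure: deeply separated clusters (e.g. 9+ steps) come out
identically for every cutoff below the separation, which the acceptance
test exercises across cutoffs 3–8.

## The simulators, and what passing tests do not show

The generators implement a haploid backwards-in-time coalescent on the
mutational timescale (each lineage mutates at rate 1; a within-deme pair
coalesces at rate 2/θ; in the island model each lineage migrates at rate
M/θ to a uniformly chosen other deme). Mutations follow infinite sites:
each mutation occupies its own uniformly chosen unused column, so
pairwise difference counts equal branch mutation counts exactly, which is
what makes the brute-force oracles in the test suite exact. A sample
whose mutation count exceeds L is rejected with a clear error rather than
silently wrapped. With M = 0 isolated demes can never find a common
ancestor, so each deme's root is joined in a star at a configurable
divergence depth (default 10 expected mutations per root branch) — the
deep-split regime.

Default study conditions mirror a realistic COI phylogeography design: a
563-site amplicon, demes of 10–25 sequences, within-population θ around
2 (a handful of segregating sites per site sample), expansion parameters
(τ = 4, θ₀ = 0.5, θ₁ = 50) in the range typically fitted to star-like
mtDNA samples, and species panels at ~10% between- and ~1%
within-species divergence, the classic barcoding gap.

What the simulators deliberately omit: recombination (appropriate for
mtDNA), selection, finite-sites homoplasy (real COI saturates at deep
divergences, so real step counts can underestimate mutations),
rate variation among sites, sequencing error, and gradual growth
models. Passing simulation tests therefore certifies the estimators and
their bookkeeping under the models' own assumptions — it does not certify
that any particular empirical dataset satisfies those assumptions.

## Numerical and design choices

* Distances default to p-distance for trees/assignment (the simplest and
  most robust choice for closely related barcodes; K2P selectable) and to
  raw difference counts for AMOVA and networks, the Arlequin default for
  DNA haplotypes. K2P values at saturation (non-positive logarithm
  argument) are reported `NaN` with a warning rather than truncated.
* Neighbor joining delegates to ape's Saitou–Nei implementation; negative
  branch lengths are clamped to zero after the fact. Bootstrap support is
  the percentage of column-resampled replicate trees containing each
  internal bipartition of the point tree; an invariant alignment yields
  an arbitrary topology and is flagged degenerate instead of erroring.
* Species assignment is nearest-reference by distance with an ambiguity
  margin (default 0.02): functionally what web barcode identification
  engines do, without requiring tree placement or a web service.
* Per-site analysis seeds are derived deterministically from the master
  seed, so whole-pipeline runs are byte-identical under a fixed seed (the
  run log records every parameter and seed).
* Sites with n below a threshold (default 3) are excluded from structure
  analyses but kept in barcoding, diversity bookkeeping and networks,
  since tiny samples make Φ estimates meaningless but their haplotypes
  still inform the network.
* Test-suite and acceptance-script problem sizes (hundreds of coalescent
  replicates, 10–60 sequences, permutation counts in the hundreds to low
  thousands) are the package's chosen desk-scale defaults for
  verification; production analyses should use the larger defaults baked
  into the functions (10,000 permutations, B = 1000).

## Known limitations

* The anchoring step assumes indel-free amplicons; markers with real
  indels need an external aligner first.
* Fu's Fs p-values rely on $\hat\theta_\pi$ conditioning, which is known
  to be slightly conservative for very negative Fs.
* The sudden-expansion fit can be flat in $\theta_1$ for strongly
  star-like data (any sufficiently large $\theta_1$ fits equally well);
  interpret the fitted $\theta_1$ as a lower-bound-ish quantity and rely
  on τ, which is well identified.
* $\Phi_{CT}$ permutation granularity with few populations, as noted
  above.
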