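# coipop

Population-genetics and DNA-barcoding analysis of mitochondrial COI
amplicons, the single-marker workflow used throughout marine
phylogeography: from a FASTA of co-anchored reads and a sample/site
metadata table to diversity tables, neutrality tests, demographic
inference, AMOVA-based structure analysis, isolation-by-distance tests
and minimum-spanning haplotype networks. It is aimed at researchers who
would otherwise chain FaBox, Arlequin, MEGA and a network drawer by hand,
and who want each of those steps reproducible, scriptable and tested —
including against coalescent simulations bundled with the package.

## What it computes

* **Sequence layer** — FASTA import (`id|site|species` headers or a
  metadata TSV), trimming to the shortest common length over co-anchored
  amplicons, translation QC under the invertebrate mitochondrial code
  (numt/pseudogene screen), and haplotype collapsing with per-site counts.
* **Diversity and neutrality** — Nei's haplotype diversity
  *h* = *n*(1 − Σ*p*²)/(*n* − 1) and nucleotide diversity π (mean pairwise
  proportion of differing sites), both with standard deviations; Tajima's
  *D* = (π̂ − *S*/*a*₁)/√(*e*₁*S* + *e*₂*S*(*S* − 1)); Fu's
  *F*ₛ = ln(*S*′/(1 − *S*′)) with *S*′ = Pr(*K* ≥ *k*obs) from the Ewens
  sampling formula (unsigned Stirling numbers, log space). *D* and *F*ₛ
  p-values come from neutral coalescent simulation conditioned on *n* and
  θ̂π.
* **Demography** — the observed mismatch distribution and the
  sudden-expansion model *F*ᵢ(τ, θ₀, θ₁) fitted by SSD minimization, with
  Harpending's raggedness index and parametric-bootstrap p-values for
  both goodness-of-fit statistics.
* **Structure** — one-level and hierarchical AMOVA on pairwise difference
  counts (Φ\_ST, Φ\_SC, Φ\_CT with the standard unequal-sample-size
  expected-mean-square coefficients), permutation tests at each level,
  pairwise Φ\_ST matrices with Holm's sequential Bonferroni correction,
  and Mantel tests (exact enumeration for small site sets) of genetic
  against geographic distance.
* **Networks and barcoding** — ε = 0 minimum spanning networks over
  haplotype step distances (all ties retained and flagged), haplogroup
  delineation by a step cutoff, per-site haplogroup compositions and
  minimum cross-group separations; neighbor-joining trees (p-distance or
  K2P) with column-bootstrap support and nearest-reference species
  assignment with an ambiguity margin.
* **Simulators** — backwards coalescent generators (finite island model
  with migration; single population with instantaneous expansion;
  multi-species barcoding panels) under infinite sites, so every analysis
  above can be verified against known truth.

## Worked example

```r
library(coipop)

# simulate a 3-deme island-model study and run the whole workflow
aln <- simulate_island_model(island_config(demes = 3, n = 8, theta = 2,
                                           M = 0.5, L = 563, seed = 77))
res <- run_full(as_records(aln), out_dir = "out",
                grouping_schemes = list(near_far = list(G1 = c("d1", "d2"),
                                                        G2 = "d3")),
                nperm = 1000, nsim = 200, B = 50, seed = 5)
res
#> COI population-genetics run
#>   24 sequences, 563 sites, 11 haplotypes
#>   overall PhiST = 0.6964 (p = 0.000999)
#>   haplogroups at cutoff 5: 4
```

The printed block says: the 24 simulated sequences collapse to 11
haplotypes over the 563 usable sites; the one-level AMOVA attributes 70%
of the molecular variance to differences among demes (Φ\_ST = 0.70), and
none of 1000 individual-level permutations reached the observed value
(p ≈ 0.001) — restricted migration (M = 0.5) leaves a strong, significant
signal of structure. The same restriction lets deme-private haplotype
clusters drift more than 5 steps apart, so the network splits into 4
haplogroups at the default cutoff.
`out/` then contains the per-site diversity table, haplotype table, AMOVA
and pairwise-Φ\_ST reports, the network edge/node tables with a DOT
export, and a run log with every seed and parameter.

A thin command-line front end with the same stages
(`simulate`, `barcode`, `diversity`, `structure`, `network`, `run-all`)
ships in `inst/scripts/coipop-cli.R`.

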