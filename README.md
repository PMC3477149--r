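# gametolog

Tools for studying the early differentiation of mammalian sex
chromosomes from codon alignments of X- and Y-linked gametologs —
homologous X/Y gene pairs descended from one ancestral autosomal gene
after recombination arrest.

Once the proto-X and proto-Y stop recombining, each trapped gene pair
diverges like two separate loci, so its synonymous divergence clocks the
arrest event. The package implements the full analysis chain used to ask
whether therian sex chromosomes differentiated in one step or several:

* **Synonymous divergence** — unweighted Nei–Gojobori counting of
  synonymous sites and differences (pathway averaging, stop-aware), with
  the Jukes–Cantor correction `K_S = -(3/4) ln(1 - (4/3) p_S)`,
  binomial/delta-method standard errors, and two-sample Z comparisons.
* **Phylogenies** — deterministic Saitou–Nei neighbor joining on `p_S`
  distances, codon-resampling bootstrap, outgroup-rooted monophyly
  queries, and classification of quartet informative sites into the
  three topologies (X-with-X, species-with-species, crossed).
* **Gene-conversion evidence** — an exact/normal two-sample runs test for
  spatial clustering of informative sites, a permutation global
  fragment test (longest identical pair-fragment over polymorphic
  columns, column-permutation null), and delineation of significantly
  low-divergence regions from 500-bp window profiles (pooled
  two-proportion Z, P < 0.001).
* **Dating** — the male-biased rate chain
  `m_X = (2/3) m_f + (1/3) m_m`, `m_Y = m_m`, `m_XY = m_X + m_Y`
  (`alpha = m_m / m_f`, default 2), autosomal calibration `m_A = K / 2T`,
  and `T = K_S / m_XY` with printed-chain or full-precision rounding.
* **Simulation** — a forward simulator of gametolog evolution
  (recombination arrest, sex-biased rates, conversion tracts, JC69
  substitutions, seed-reproducible) that emits alignments plus a
  ground-truth ledger, so every stage above is testable with no external
  data.

## Worked example

Simulate a gametolog quartet arrested 200 million years ago (the
default scenario), run the composite per-gene analysis, and date the
eutherian X/Y pair with the simulator's own rate model:

```r
library(gametolog)

sim <- simulate_gametologs(sim_config(n_codons = 2000, seed = 7))
rep <- run_gene(list(gene = "demo", alignment = sim$aln, outgroup = "Out",
                     seed = 7, bootstrap_reps = 200, n_perm = 1000))
print(rep)
#> gene report: demo
#>   pair n_codons    S   Sd     pS      se_pS       KS      se_KS
#> 1  Eut     2000 2000 1205 0.6025 0.01094289 1.219684 0.05564182
#> 2  Mar     2000 2000 1245 0.6225 0.01083960 1.328968 0.06376234
#>   X cluster monophyletic: TRUE; Y cluster: TRUE
#> fragment permutation test: 1860 polymorphic columns, max fragment = 9 sites, global p = 0.6803 (1000 permutations)
```

Both species' X/Y divergences are deep (`K_S` ≈ 1.2–1.3), the X copies
and the Y copies each form a clade relative to the outgroup, and the
fragment test finds no conversion signal — the signature of a single
pre-speciation recombination arrest. Dating the eutherian pair:

```r
m <- build_rate_model(3e-9, alpha = 2)
date_divergence(rep$divergence$KS[1], m)
#> dating: KS = 1.22 -> 183-183 MYA (old-young)
```

183 MYA against a true arrest of 200 MYA, within two standard errors
(`se_KS / m_XY` ≈ 8 Myr) for this single 2000-codon draw.

A conversion tract, by contrast, leaves a window-profile footprint.
Simulate a genomic pair whose 3' 4-kb tract was overwritten Y→X
10 million years ago:

```r
gsim <- simulate_gametologs(sim_config(mode = "nucleotide", n_sites = 10000,
  include_outgroup = FALSE, seed = 7,
  conversion_events = list(list(clade = "eutherian", direction = "Y->X",
                                region = c(6000, 10000), t_event = 1e7))))
s <- aln_seqs(gsim$aln)
detect_low_divergence(window_profile(s[["EutX"]], s[["EutY"]]))
#>   start   end n_windows p_inside p_outside        Z p_value
#> 1  6000 10000         8   0.0615    0.6145 55.46024       0
```

The eight flagged windows recover the simulated tract exactly: inside
it the pair differs at 6% of sites versus 61% outside.

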