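---
title: "Methods: divergence, gene conversion and dating of X/Y gametologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, gene conversion and dating of X/Y gametologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametolog)
```

## The problem

Mammalian X and Y chromosomes descend from an ordinary autosome pair.
Once recombination between the proto-X and proto-Y stops, the two copies
of each gene caught in the non-recombining region — a *gametolog* pair —
diverge like separate loci. The amount of synonymous divergence between a
gametolog pair is therefore a molecular clock for the recombination-arrest
event, and comparing arrest times across genes tests whether arrest
happened once (a single "evolutionary stratum") or in several steps.

Two complications make this more than a distance calculation. First, the
Y is male-limited and the X spends two-thirds of its time in females, so
under male-biased mutation the X, Y and autosomes tick at different
per-year rates. Second, ectopic gene conversion between gametologs can
locally overwrite divergence, making a pair look younger than its arrest
time; conversion must be detected and the affected regions excluded
before dating.

This package implements the full chain: synonymous divergence estimation,
trees, conversion detection, rate modelling and dating, plus a simulator
that generates alignments with known truth so each stage can be validated
end to end.

## Synonymous divergence

Divergence between a gametolog pair is measured on synonymous sites only,
with the unweighted Nei–Gojobori method. Per codon, each of the three
positions contributes the fraction of its single-nucleotide changes that
preserve the amino acid; changes that would create a stop codon are
removed from the denominator. Synonymous differences between two codons
are averaged with equal weight over all minimal substitution pathways
that avoid stop-codon intermediates. With $S$ the mean of the two
sequences' synonymous-site totals and $S_d$ the summed differences,

$$p_S = S_d / S, \qquad
  K_S = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3} p_S\right),$$

the Jukes–Cantor correction recovering multiple hits. $K_S$ is undefined
(reported `NA`, never an exception in batch use) at $p_S \ge 0.75$.

Choices worth stating:

* **Unweighted counting.** A transition/transversion-weighted variant of
  the site counts is deliberately not implemented; the unweighted
  estimator is the one all examples and tests pin down, and it is what a
  `R = 1` setting reduces to in practice.
* **Gap and stop policy.** Codon columns with a gap, an `N`, or a stop in
  either sequence are excluded pairwise (complete-codon deletion), and
  the exclusion count is reported. IUPAC ambiguity codes other than `N`
  are collapsed to `N` on input so there is a single degenerate symbol.
* **Standard errors.** `se_pS = sqrt(pS (1 - pS) / S)` (binomial over
  synonymous sites) and the delta-method `se_KS = se_pS / (1 - 4 pS /
  3)`. Published tables computed with other variance estimators can
  differ in the second digit of the SE; the point estimates are not
  affected. `se_pS` is `NA` in the degenerate case `pS > 1`, which only
  tiny alignments can produce.
* **Multi-copy genes.** When a gene has several X or Y copies, the
  reported divergence is the arithmetic mean of `pS` (and of `KS`) over
  all X-by-Y pairs.
* **Two-group comparisons** use the normal-deviate statistic
  $Z = |d_1 - d_2| / \sqrt{se_1^2 + se_2^2}$ with a two-tailed p-value.

The test suite checks the estimator against a literal pathway-enumeration
oracle (written first, kept independent) on every fixture alignment of up
to 5 codons, and checks convergence of `pS` to the Jukes–Cantor
expectation on simulated data.

## Trees

Neighbor joining is run on the matrix of pairwise `pS` values. The
implementation is the standard Saitou–Nei agglomeration with two
determinism rules: ties in the Q criterion are broken toward the
lexicographically smallest cluster-index pair, and a negative branch
length is clamped to zero with the deficit transferred to its sibling so
path lengths are preserved (clamp events are counted). On an additive
matrix the generating tree is recovered exactly — the suite verifies both
topology and path lengths against random trees, and cross-checks against
an independent reference implementation.

Bootstrap support resamples **codons** (not single sites), preserving the
unit on which `pS` is defined; whether the original analyses resampled
codons or sites is not knowable from their description, and codon
resampling is the choice consistent with a codon-based distance.
Replicates in which some pair's `pS` is undefined are redrawn, with a cap
of ten times the replicate count. Trees are built unrooted; monophyly
("do the X copies form a cluster?") is always asked relative to a
user-designated outgroup.

For a eutherian/marsupial quartet (roles EX, EY, MX, MY), second-codon-
position sites — the positions least prone to saturation — are classified
when exactly two states each occur exactly twice: pairing X-with-X
(topology A) indicates differentiation before the species split, pairing
within species (topology B) indicates later differentiation or
conversion, and the cross pairing (topology C) is noise. The partition is
exhaustive by construction (`nA + nB + nC + skipped = sites`).

## Gene-conversion evidence

Three complementary detectors are provided.

**Runs test.** Under no conversion, topology-A and topology-B sites
should interleave randomly along the gene; a conversion tract produces a
block of B sites and thus fewer runs. The one-tailed p-value for
clustering is exact — computed from the closed-form distribution of the
run count, which equals enumeration of all $\binom{n_1+n_2}{n_1}$
arrangements — when $n_1 + n_2 \le 20$, and a continuity-corrected normal
approximation otherwise. Topology-C sites are discarded before testing
(configurable by passing any two-class labelling).

**Permutation fragment test.** A global inner-fragment statistic: condense
the alignment to polymorphic columns; score every sequence pair by its
longest run of consecutive condensed columns at which the pair agrees;
the global statistic is the maximum over pairs. Column order is permuted
(default 10,000 times) to build the null; taking each permutation's
maximum over pairs controls multiplicity, and the add-one estimator
$(1 + \#\{perm \ge obs\})/(1 + n_{perm})$ keeps p strictly positive.
Mismatch-penalised fragments and outer fragments are not scored: the
mismatch-free inner fragment is the fully specified core of this family
of tests, and the suite verifies the p-value is super-uniform under
column-exchangeable nulls.

**Window regions.** Divergence between a genomic pair is profiled in
non-overlapping 500-bp windows (gap/N columns pairwise-deleted; windows
with fewer than half their sites compared, or truncated at the tail, are
flagged unreliable). Runs of at least `min_windows = 2` consecutive
reliable windows below the pooled divergence are kept when a pooled
two-proportion Z test of inside versus outside sites rejects at
$P < 0.001$ (one-tailed, reduction direction). Pooling sites rather than
testing windows individually uses the full count information; the
two-window minimum suppresses single-window artifacts. On null
simulations this procedure fires in well under 7% of replicates; the
P<0.001 threshold and 500-bp window are the conventional settings for
this analysis and are exposed as parameters.

Direction of conversion is reported descriptively (which copy clusters
with the other species' lineage in region trees), never as a test.

## Dating under male-biased mutation

With $\alpha = m_m / m_f$ the male/female germ-line rate ratio and a 1:1
sex ratio (hard-coded; the generalisation is deliberately omitted),

$$m_A = \tfrac{1}{2}(m_m + m_f), \quad
  m_X = \tfrac{2}{3} m_f + \tfrac{1}{3} m_m, \quad
  m_Y = m_m, \quad
  m_{XY} = m_X + m_Y,$$

and a gametolog pair of divergence $K_S$ dates to $T = K_S / m_{XY}$.
The autosomal rate is calibrated from a neutral divergence between two
species with a known split-time interval ($m_A = K / 2T$); the younger
calibration gives the faster rate and hence the younger bound.
$\alpha = 2$ is the default, the conservative end of eutherian estimates
(2–6).

Two rounding modes exist because quoted rate chains are conventionally
rounded to 3 significant figures at each step: `printed-chain` reproduces
that arithmetic exactly (so a published chain can be re-derived digit for
digit), while `full-precision` defers all rounding and is the default for
actual inference. Ages are reported in integer million years, rounded
half-up.

## The simulator

`simulate_gametologs()` evolves a root sequence down the gametolog tree:
the outgroup splits at `T_outgroup`, recombination arrest duplicates the
proto-gene into X and Y at `T_arrest`, speciation at `T_split` yields EX,
EY, MX, MY, and each conversion event instantaneously replaces the
recipient's tract with the donor copy at `t_event` (complete tract
replacement — no patchy tracts, matching the granularity at which
conversion is inferred). Substitution counts per branch are Poisson under
JC69; the end state of a site hit $k$ times is drawn from the exact
$k$-step JC chain, so the process is exact, fast and fully reproducible
from one seed with a fixed branch traversal order.

Defaults are chosen to represent the therian scenario: arrest at 200 MYA,
speciation at 170 MYA (inside the 148–190 MYA calibration interval),
outgroup split at 224 MYA, $m_f = 2 \times 10^{-9}$ per site per year
and $\alpha = 2$ — which makes the implied autosomal rate
$3 \times 10^{-9}$, inside the calibrated 2.68–3.45 range — and 1000
codons, comparable to the larger published gametolog alignments.

Two sequence modes:

* **codon** — a 4-fold-degenerate scaffold: codon positions 1–2 are
  frozen, drawn from the six 4-fold families whose codons carry exactly
  one synonymous site (Leu `CTN` and Arg `CGN` are excluded because
  their synonymous first positions would push `S` above `n_codons`), and
  only third positions evolve. Every change is synonymous and `S` equals
  `n_codons` exactly, decoupling estimator validation from simulator
  detail.
* **nucleotide** — free sites under plain JC69, for window profiling and
  conversion detection on "genomic" sequence.

What the simulator does **not** emulate: codon-usage bias, selection,
indels, among-site rate heterogeneity, and population-level (coalescent)
variance. Passing tests on simulated data therefore validate the
estimators under their own model assumptions — they do not show that real
gametolog alignments satisfy those assumptions. In codon mode second
positions never vary, so quartet informative-site analyses on simulated
data use `quartet_sites()` over nucleotide-mode alignments instead of
`second_position_sites()`.

## Validation problem sizes

The shipped tests run the oracle comparisons on all fixture alignments up
to 5 codons, tree recovery on random additive trees of up to 8 taxa,
runs-test enumeration up to 12 sites with 1000-shuffle type-I
calibration, dating recovery on 100 replicates of 10,000-codon
simulations (coverage of the ±2 SE interval ≥ 90%), and window-region
detection on 500 null replicates of 10,000-site genomic pairs (false-
positive rate ≤ 7%) plus high-signal tract recovery within two windows.
These sizes give stable pass/fail behaviour at interactive runtimes.

## Known limitations

* Standard errors follow the binomial/delta-method formulas above;
  published tables using other variance estimators will not match in the
  SE column, and SEs are accordingly not treated as reproduction targets.
* The fragment test deliberately omits GENECONV's mismatch-penalised and
  outer-fragment machinery.
* The pipeline consumes alignments; it does not build them, fetch
  sequences, or infer exon structure — region splits are supplied as
  coordinates.
* Maximum-likelihood and parsimony trees are out of scope; neighbor
  joining carries the analysis, with clade queries relative to a
  designated outgroup.
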