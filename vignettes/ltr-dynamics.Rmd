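---
title: "Measuring LTR retrotransposon birth and death dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring LTR retrotransposon birth and death dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrdyn)
```

## The problem

Long terminal repeat retrotransposons (LTR-RTs) both grow and shrink plant
genomes. A new insertion adds a full element — two near-identical LTRs
flanking an internal Gag-Pol coding region, the whole cassette bracketed by a
short target-site duplication (TSD). Removal works mostly through
intra-element unequal recombination between the two LTRs, which excises the
internal region and one LTR and leaves behind a *solo LTR*. Incomplete
deletion or assembly breaks leave *truncated* elements with internal sequence
on one side only. The census of intact (I), solo (S) and truncated (T) copies
is therefore a record of the birth/death balance: S:I measures elimination
relative to recent amplification, and genomes dominated by solo LTRs have
been purging elements faster than gaining them.

`ltrdyn` implements that census and the quantitative machinery around it:

* flanking-homology classification of LTR loci into intact / solo /
  truncated, with the ratio statistics S:I, T:I, (S+T):I and S+T+I;
* a scaffold-length stabilization scan for the census;
* the family-level "high elimination" summary (proportion of families with
  S:I > 3);
* insertion dating from LTR-pair divergence, `T = K / (2r)`;
* permutation tests of LTR overlap with structural-variation region classes
  (inversion INV, species-specific SPE, syntenic SYN);
* tandem/proximal gene-duplication calls and pseudogene filtering;
* expression contrasts between genes in SPE vs SYN regions;
* a synthetic-genome simulator that plants all of the above with known truth.

## Classification model

Intact elements are an *input*: structure-aware annotators (LTR harvesting
plus protein-domain classification) define them, and this package consumes
their 5' LTR / internal / 3' LTR coordinates. From those, `classify_genome()`
builds one LTR and one internal (Gag-Pol) reference per family and searches
every scaffold for LTR homology with an internal seed-and-extend local
aligner: exact 11-mers seed ungapped X-drop extensions, trimmed to the
maximal-scoring extent, on both strands; hits need at least 80% identity over
at least 100 bp by default. Hits overlapping an annotated intact element are
excluded so an intact element's own LTRs are never recounted, and overlapping
hits from different families are resolved to the highest-identity extent.

Each remaining LTR locus is then classified by searching a flanking window on
either side for homology to the family's internal reference:

* no internal homology on either side → **solo**;
* internal homology on exactly one side → **truncated**;
* homology on both sides → **intact-overlap**, returned flagged for the
  caller to reconcile rather than silently dropped.

The flank window defaults to 1.5 × the internal reference length, capped at
15 kb: wide enough to span a displaced internal domain, narrow enough not to
reach a well-separated neighboring element. The search parameters
(`word_size = 11`, `min_identity = 0.8`, `min_length = 100`) mirror common
nucleotide-search defaults and are configurable; the aligner is
self-contained so that every call can be checked against an exhaustive
dynamic-programming oracle, which the test suite does on small genomes.

## Census statistics

`run_census()` counts statuses and derives S:I, T:I, (S+T):I and S+T+I, at
full precision internally and printed at two decimals (half-up). Counts are
recomputed after dropping scaffolds shorter than a threshold because short
scaffolds cannot hold a full-length element and therefore inflate the solo
count. `stability_scan()` automates the threshold choice: S:I is recomputed
over a grid (0 plus the deciles of the scaffold-length distribution by
default) and the selected threshold is the first grid point after which the
relative change in S:I stays below 1% for two consecutive steps. The
tolerance, patience and grid are choices of this package — no numeric
stability rule is standard — so selected thresholds are comparable within an
analysis, not across tools. If no grid point satisfies the rule the scan
returns threshold 0 flagged unstable; if a threshold removes every intact
element the scan truncates there with a flag rather than dividing by zero.

`family_census()` computes per-family S:I and the percentage of families
exceeding S:I = 3. A family with solo or truncated copies but no intact copy
is complete elimination — exactly the phenomenon the statistic measures — so
its ratio is treated as +Inf and counted as high-elimination. One formatting
subtlety: published census tables of this kind print the ratio columns
rounded (half-up) but the family percentage truncated to two decimals; the
`proportion_high_2dp` field follows that convention while `proportion_high`
keeps full precision.

## Insertion dating

At insertion the two LTRs are identical; they then diverge independently, so
their pairwise distance K accumulates at twice the per-lineage substitution
rate and the age is `T = K / (2 r)` with `r = 1.3e-8` substitutions per site
per year by default. `align_pair()` is a global affine-gap aligner
(match 2, mismatch −2, gap open 10, gap extend 1, deterministic traceback
preferring substitutions over gaps); transition (P) and transversion (Q)
proportions are taken over ungapped columns, excluding gapped and ambiguous
positions from the denominator. Three distance models are available:

* **K2P** (default, standard for LTR dating):
  `K = -0.5 ln(1 - 2P - Q) - 0.25 ln(1 - 2Q)`
* **JC69**: `K = -0.75 ln(1 - 4p/3)` with `p = P + Q`
* **raw**: `K = P + Q`

Inputs outside a model's logarithmic domain raise a saturation error naming
the model instead of returning NaN. Because published pipelines do not state
which estimator they apply internally, absolute ages from real data should be
compared across tools with caution; within this package the choice is
explicit and configurable.

## Structural-variation enrichment

`permutation_enrichment()` asks whether LTR intervals overlap a region class
(INV / SPE / SYN, as produced by whole-genome comparison tools) more or less
often than random placement predicts. The null re-places the observed
intervals uniformly, preserving the length multiset, choosing scaffolds with
probability proportional to their length — mirroring the behavior of the
standard interval-randomization utilities. Empirical p-values use the +1
correction `p = (1 + #{null >= obs}) / (n_perm + 1)` so p is never 0; the
default `n_perm = 1000` resolves p down to about 0.001. Within a class,
regions are merged on load; across classes overlaps are left intact and each
class is tested independently. `class_coverage()` reports, per class, the
percentage of bases covered by at least one LTR interval (coverage, not
summed lengths); whether published per-class proportions of this kind are
count- or base-based is ambiguous, and the base-pair basis used here is the
deterministic choice.

## Gene duplication, pseudogenes, expression

Tandem duplicates (TD) are homologous genes with zero intervening genes on
the same scaffold; proximal duplicates (PD) are separated by 1–10 genes;
anything else, including cross-scaffold pairs, is neither. Gene order comes
from `rank_genes()` (start, then end, then id — deterministic under input
permutation), homologous pairs are an input, and "adjacent" is purely
positional, irrespective of strand. Pseudogene candidates survive filtering
only with amino-acid identity strictly above 30% and parent coverage
strictly above 50% of the pseudogene.

For expression, genes are assigned to SPE or SYN by majority overlap: the
class holding more than half of the gene's total SPE+SYN overlap wins; exact
ties are "ambiguous" and genes touching neither class are "none", both
excluded downstream. The published workflow resolved dual-overlap genes by
manual browser inspection; the majority rule is the deterministic, logged
replacement. Contrasts are two-sided two-sample t tests on log2(x+1)
expression — Welch by default (robust to unequal variances), with the
pooled-variance variant reachable via `test = "student"` since that is the
test the figure legends name. Significance tiers are reported as
\*\*\* p<0.001, \*\* p<0.01, \* p<0.05, ns.

## The synthetic-data generator

`simulate_genome()` plants truth for every stage. Scaffold lengths are drawn
from a truncated power law (default 24 scaffolds, 30–300 kb, shape 1.8, about
2 Mb total; extra scaffolds are drawn if an unlucky draw cannot hold the
requested elements) so that a meaningful short-scaffold tail exists for the
stability scan. Elements are planted at non-overlapping positions with at
least `min_gap = 5000` bp between them — deliberately larger than the default
4.5 kb flank window so a solo LTR never sees a neighbor's internal domain —
as TSD + LTR5 + internal + LTR3 + TSD (intact), TSD + LTR + TSD (solo), or
LTR + half-internal fragment on one side (truncated), on random strands.

The 3' LTR of each intact element is the 5' LTR passed through
`mutate_sequence()`, which plants **exactly** `round(P·len)` transition and
`round(Q·len)` transversion sites, all at distinct positions. Because no site
is hit twice, the planted (P, Q) are exactly recoverable from the alignment
and the K2P round-trip is an exact test, not a statistical one. Default
divergence draws P ≤ 0.05 and Q ≤ 0.02 — young elements, the regime in which
flanking-homology classification is expected to recover essentially every
planted locus. Region classes (INV 10%, SPE 30%, SYN 40% of each scaffold by
default) are laid out as shuffled blocks whose per-class base totals match
the requested fractions exactly up to rounding, and `ltr_placement_bias`
weights element placement per class for enrichment power studies.

What the generator does **not** emulate: nested insertions, non-uniform base
composition, sequencing or assembly error, indel divergence between LTR
pairs, and gene structure beyond intervals. Passing tests therefore
demonstrate correctness of the statistical machinery on clean planted
signal, not annotation accuracy on real, repeat-nested genomes.

`simulate_gene_set()` plants TD pairs, PD pairs (always including the
boundary case of exactly 10 intervening genes) and distant control pairs
(always including 11), plus pseudogene candidates whose identity/coverage
values straddle the 30/50 thresholds including exact boundary values.
`simulate_expression()` draws log-normal expression (log2 mean 5, sd 1) and
offsets SPE-resident genes by the configured effect (default −1 log2 unit,
with five stages) on the log scale.

## Numerical and design choices

* All internal coordinates are 0-based half-open; GFF3 is emitted 1-based
  closed at the IO boundary, BED stays 0-based. Abutting intervals do not
  overlap.
* TSD length defaults to 5 bp, typical for LTR-RT integration.
* Fixed seeds make every simulated bundle byte-identical; seeded functions
  restore the caller's RNG state.
* Degenerate cases are explicit: I = 0 gives NA ratios, not errors; a
  zero-variance identical-group contrast returns t = 0, p = 1; a degenerate
  permutation null flags z as undefined while p stays valid.
* Problem sizes in the test suite (a ~2 Mb genome with 180 planted elements
  for truth recovery; 200 replicate datasets for the two type-I
  calibrations; 999 or 199 permutations per test) were chosen so the whole
  suite illustrates each claim at desk scale.

## Limitations

Classification trusts the input intact annotation; it does not rediscover
intact elements, resolve nested insertions, or assign families from sequence.
The seed-and-extend search is ungapped within hits, which is appropriate for
the substitution-only divergence regime it targets; strongly indel-diverged
solo LTRs would be found only through their conserved cores. Genome-scale
percentages from real multi-hundred-Mb assemblies depend on upstream
annotation tools and are outside what the synthetic suite validates.
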