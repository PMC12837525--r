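# ltrdyn

Birth and death dynamics of LTR retrotransposons (LTR-RTs) in assembled
genomes, for researchers studying how transposable elements drive genome
size change and structural divergence between related species.

LTR-RTs insert as *intact* elements (two near-identical long terminal
repeats flanking an internal Gag-Pol region) and are purged mainly by
unequal recombination between the two LTRs, which leaves a *solo LTR*;
partial removal leaves *truncated* copies. Counting intact (I), solo (S)
and truncated (T) copies therefore measures the birth/death balance of a
genome's retrotransposon load. `ltrdyn` provides:

* **Census** — flanking-homology classification of LTR loci into
  intact / solo / truncated (internal seed-and-extend homology search, no
  external aligner), the ratio statistics S:I, T:I, (S+T):I, S+T+I, a
  scaffold-length stabilization scan for the census, and the family-level
  proportion of families with S:I > 3.
* **Insertion dating** — per-element LTR-pair divergence from a global
  affine alignment, Kimura 2-parameter distance
  K = −½ln(1−2P−Q) − ¼ln(1−2Q) (JC69 and raw distances available), and
  insertion age T = K/(2r) with r = 1.3×10⁻⁸ substitutions·site⁻¹·yr⁻¹ by
  default, plus per-superfamily age histograms.
* **Structural-variation enrichment** — permutation tests of LTR overlap
  with inversion (INV), species-specific (SPE) and syntenic (SYN) regions,
  with length-preserving interval randomization and +1-corrected empirical
  p-values; per-class base-pair coverage tables.
* **Gene duplication and loss** — tandem (adjacent) and proximal (1–10
  intervening genes) duplication calls from gene order, pseudogene
  filtering at >30% identity and >50% parent coverage (strict), and
  per-gene LTR context reports.
* **Expression contrast** — majority-overlap assignment of genes to SPE vs
  SYN regions and per-stage two-sample t tests on log2(x+1) expression.
* **Synthetic genomes** — a simulator that plants intact/solo/truncated
  elements with exact (P, Q) LTR divergence, labeled SV regions with
  placement bias, TD/PD gene clusters, threshold-straddling pseudogene
  candidates, and stage-wise expression with a planted region effect, so
  every stage above is validated against known truth.

## Worked example

```r
library(ltrdyn)

b    <- simulate_genome(sim_config(seed = 42))   # ~2 Mb, planted truth
loci <- classify_genome(b$scaffolds, b$intact_annotation)
run_census(loci, b$scaffold_lengths, min_scaffold_length = 40000)
#> LTR-RT birth/death census
#>   I=50  S=100  T=30  S+T=130  S+T+I=180
#>   S/I=2.00  T/I=0.60  (S+T)/I=2.60
#>   filtered (scaffolds >= 40,000 bp): I=49 S=96 T=29  S/I=1.96 T/I=0.59 (S+T)/I=2.55

family_census(loci)
#> family census: 6 families, 0 with S/I > 3 (0.00%)

d <- date_elements(b$scaffolds, b$intact_annotation)
max(d$T_years)          # oldest insertion, years
#> [1] 2746348
head(insertion_profile(d, bin_width = 1e6), 4)
#>   superfamily bin_start bin_end count
#> 1       Copia     0e+00   1e+06    10
#> 2       Copia     1e+06   2e+06     7
#> 3       Copia     2e+06   3e+06     8
#> 4       Gypsy     0e+00   1e+06    12
```

All 180 planted elements are recovered with their true status (the census
row equals the planted counts), and the filtered columns show how dropping
scaffolds under 40 kb removes solo-only short scaffolds and lowers S:I.
The dating table recovers each element's planted transition/transversion
proportions exactly, so the histogram reflects the planted age
distribution.

A thin command-line wrapper over the same functions ships at
`inst/cli/ltrdyn.R` with subcommands `simulate`, `census`, `date`,
`enrich`, `dup` and `contrast`.

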