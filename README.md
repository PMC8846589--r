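# regulonscan

Terminal-selector regulon analysis in R: from replicated ChIP-seq peaks,
gene models, a differential-expression table, and a single-cell metacell
footprint matrix to a classified direct-target regulon with per-cell-type
composition statistics.

## The problem

A *terminal selector* is a transcription factor that establishes and
maintains mature cell identity by directly regulating effector genes.
Demonstrating that a factor acts as a terminal selector requires
connecting three independent genome-scale measurements:

1. **Where the factor binds** — ChIP-seq peaks, replicated, reduced to a
   consensus set and checked for the factor's DNA recognition element
   (a degenerate consensus such as `GCAT(A/T)ATT(A/T)AT`, i.e. IUPAC
   `GCATWATTWAT`);
2. **What it regulates** — differential expression between factor-null
   mutants and their siblings: a *directly activated* gene is bound and
   down in the mutant, a *directly repressed* gene is bound and up in the
   mutant;
3. **Where those targets are expressed** — a gene × metacell footprint
   matrix from single-cell transcriptomics, giving per-cell-type regulon
   composition: repression proportion
   `100 · n_repressed / (n_activated + n_repressed)` and markers
   exclusive to one cell type.

The binding-to-gene link uses a *gene territory*: the strand-aware
promoter window (default 350 bp upstream to 100 bp downstream of the
TSS, inclusive of the TSS base) united with the gene body. A gene is a
direct target iff at least one consensus peak overlaps its territory by
at least 1 bp.

Consensus peaks are built from per-replicate narrowPeak files by
transitive overlap grouping; a group is confirmed when every member
passes a weak p-value threshold (default `1e-4`), the Fisher-combined
p-value (`X = -2 Σ ln pᵢ ~ χ²_{2k}`) passes a strong threshold (default
`1e-8`), and enough distinct replicates support it. Motif hits inside
peaks are tested for central positional enrichment against a uniform
null (`n_central ~ Binomial(n_hits, f)`, one-sided exact, default
`f = 0.2`). Gene-set annotation uses the one-sided hypergeometric
overrepresentation test with Benjamini–Hochberg correction.

All coordinates are 1-based inclusive internally (so
`scaffold_353:49524-53227` has length `53227 − 49524 + 1 = 3704` bp);
BED-family formats are converted on read/write.

## Worked example

Every stage is testable without external data through the seeded
synthetic-study generator, which plants a full ground truth (bound
genes, activated/repressed effects, motif instances at peak summits,
skewed metacells):

```r
library(regulonscan)

res <- simulate_study(sim_config(seed = 1), "sim")
rep <- run_regulon_pipeline(res$paths$peaks, res$paths$gff,
                            res$paths$genome, res$paths$de,
                            res$paths$metacells, "out")
print(rep)
```

```
Terminal-selector regulon report
  consensus peaks:           60
  motif hits in peaks:       60  (60 central; enrichment p = 1.15e-42)
  direct target genes:       60
  directly activated:        30
  directly repressed:        15
  bound, not DE (target-only): 15
  per-metacell regulon composition:
 metacell_id n_activated n_repressed n_total repression_pct   exclusive_genes
        mc01          30           2      32           6.25 g0035,g0138,g0154
        mc02           3          15      18          83.33 g0049,g0055,...
        ...
```

The 60 planted bound genes are recovered exactly; the 60 motif hits sit
at peak centers (binomial central-enrichment p = 1.15e-42, far below the
uniform null); `mc01` is the planted activation-skewed cell type (low
repression proportion, three exclusive markers) and `mc02` the planted
repression-skewed one (83.33%).

Individual pieces work standalone, e.g. scanning a 50-bp gel-shift probe
for the core recognition element:

```r
scan_sequence("AAACAAAGATTCTAAGCATCCATTATTAATATACATCCCTAGAAAAAATC",
              "AT(A/T)ATT(A/T)AT")
#>   seqid start strand matched_seq
#> 1   seq    22      +   ATTATTAAT

interval_length(genomic_interval("scaffold_353", 49524, 53227))
#> [1] 3704
repression_proportion(3, 13, 2);  repression_proportion(32, 3, 1)
#> [1] 81.25
#> [1] 8.6
```

## Command line

`inst/cli/regulonscan.R` exposes the stages as subcommands (`simulate`,
`consensus`, `scan`, `targets`, `classify`, `celltype`, `enrich`,
`run-all`), each reading/writing standard formats (FASTA, GFF3,
narrowPeak/BED6, TSV, JSON), so real study data can replace any
synthetic file:

```sh
Rscript inst/cli/regulonscan.R simulate --seed 3 --out-dir sim
Rscript inst/cli/regulonscan.R run-all \
  --peaks sim/rep1.narrowPeak,sim/rep2.narrowPeak,sim/rep3.narrowPeak \
  --gff sim/genes.gff3 --genome sim/genome.fa \
  --de sim/de.tsv --metacells sim/metacells.tsv --out-dir out
```

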