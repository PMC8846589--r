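---
title: "Terminal-selector regulon analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminal-selector regulon analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

# The model

`regulonscan` operationalizes the terminal-selector hypothesis — that a
transcription factor confers mature cell identity by *direct* regulation
of effector genes — as an intersection of three data layers:

* **binding**: replicated ChIP-seq peaks reduced to a consensus set;
* **regulation**: a mutant-vs-sibling differential-expression table;
* **cell-type expression**: a gene × metacell footprint matrix.

A gene is a **direct target** iff at least one consensus peak overlaps
its *territory*. The territory is the strand-aware promoter window —
by default 350 bp upstream through 100 bp downstream of the TSS —
united with the gene body. Since the promoter window contains the TSS,
the union is always one contiguous interval. Direct targets that are
significantly *down* in the factor-null mutant are called **directly
activated** (the factor normally turns them on); targets *up* in the
mutant are **directly repressed**; the remainder are **target-only**
(bound without a detectable expression consequence at the chosen
threshold). The three labels always partition the target set.

## Assumptions

* The TSS is the annotated gene-span boundary. The gene models consumed
  here carry no isoform or UTR structure, so no isoform resolution is
  attempted; with multiple isoforms per locus one representative span
  must be chosen upstream.
* The DE table is taken as-is: fold changes are mutant relative to
  sibling and `padj` is already multiplicity-adjusted. No count
  modeling, shrinkage, or re-adjustment happens in this package. The
  sign convention is load-bearing and is stated on every relevant
  function: *down in mutant = activated by the factor*.
* "Represented in a metacell" means footprint strictly above a
  threshold (default 0, i.e. any nonzero footprint). Published metacell
  gene assignments do not always restate a cutoff, so it is exposed as
  configuration rather than fixed.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `upstream_bp` / `downstream_bp` | 350 / 100 | bp | the promoter-window rule of the emulated target definition |
| `weak_threshold` | 1e-4 | p | per-member peak ceiling, mirroring a two-tier consensus caller run as `-w 1e-4 -s 1e-8` |
| `strong_threshold` | 1e-8 | p | Fisher-combined group ceiling, same source |
| `min_supporting_replicates` | 1 | count | replicate count is a runtime parameter: the emulated design sequenced four biological replicates but quality-checked three, so nothing is hard-coded |
| `alpha` | 0.01 | adjusted p | DE significance, strict inequality |
| `central_fraction` | 0.2 | fraction | width of the "central" band of a peak for positional enrichment |
| `represented_threshold` | 0 | footprint | strict lower bound for metacell representation |
| enrichment `alpha` | 0.05 | adjusted p | reporting threshold for overrepresented terms |

## Coordinate and rounding conventions

Coordinates are 1-based inclusive throughout, matching scaffold-style
citations (`scaffold_353:49524-53227` spans exactly
`53227 − 49524 + 1 = 3704` bp). narrowPeak/BED input is 0-based
half-open and converted on read; all BED-family output converts back.
The promoter window includes the TSS base itself (length
`upstream + downstream + 1`): the source definition does not state
whether the TSS base is counted, and this choice makes "350 upstream"
and "100 downstream" exact counts of flanking bases. Windows are
clipped at scaffold boundaries rather than rejected.

Repression proportions are rounded *half-up* at a caller-chosen number
of decimals, because the quantity is conventionally printed at mixed
precisions (e.g. 81.25% with two decimals beside 8.6% with one); R's
default banker's rounding would disagree with printed values at .5
boundaries. With zero represented targets the proportion is undefined
and reported as missing, never as 0.

# The consensus stage is a documented simplification

The published multi-sample consensus procedure this stage stands in for
has a more elaborate decision rule than its command-line flags reveal.
`build_consensus()` implements a deterministic, order-free reduction
consistent with those flags: candidate groups are maximal sets of
transitively overlapping peaks across replicates (≥ 1 bp, per
scaffold); a group is confirmed iff every member passes the weak
threshold, the Fisher combination of member p-values passes the strong
threshold, and enough distinct replicates are present. The union
interval represents a confirmed group — conservative for downstream
territory-overlap tests (intersection or summit representations would
only shrink overlaps). The stage is bypassable: any pre-made consensus
peak file can be fed directly to `assign_targets()`.

Equally, the central-enrichment statistic is a stand-in. External motif
tools report centrality p-values from unspecified statistics; here a
hit is central when its midpoint lies within the middle
`central_fraction` of its window, and the exact one-sided binomial tail
under uniform placement is returned. It tests the same property but is
*not* numerically comparable to any external tool's p-value.

# Motif matching

Degenerate consensi are matched by per-position IUPAC set membership,
not PWM log-odds: the experimental validation regime being emulated
(gel-shift assays) tests the literal consensus, and de novo PWM
discovery is out of scope. Parenthetical notation (`AT(A/T)ATT(A/T)AT`)
normalizes to IUPAC (`ATWATTWAT`). Matching is delegated to
`Biostrings::matchPattern(fixed = "subject")` with one tightening: an
ambiguity code in the *subject* (e.g. `N`) never matches, which the
raw Biostrings semantics would allow via bitwise intersection. Reverse-
strand hits are found by matching the reverse-complemented pattern
against the forward strand and are reported at forward coordinates with
the forward-strand slice, which keeps sorting and interval overlap
stable. Tests verify equivalence against an independent oracle that
exhaustively enumerates windows against the Cartesian expansion of the
motif.

# The synthetic generator: what a green test establishes

`simulate_study()` writes a complete seeded study — genome FASTA, GFF3
gene models, per-replicate narrowPeak files, DE table, metacell table,
truth JSON — from one pseudo-random stream, so identical configs yield
byte-identical files. Its defaults state the emulated world: 200 genes
on five 200-kb scaffolds, 60 bound genes (half activated, a quarter
repressed), three replicates, `GCATWATTWAT` planted at peak summits
with ±10 bp jitter, 100 weak intergenic decoy peaks, eight metacells
with one activation-skewed and one repression-skewed cell type, planted
|log2FC| ≈ 3 with adjusted p ≤ 1e-5 for regulated genes and ≥ 0.5
otherwise.

Deliberate idealizations, and hence the limits of what recovery tests
show:

* effects are planted far from every threshold, so exact
  precision/recall 1.0 is the *designed* outcome — the tests verify
  correctness of the machinery, not robustness to marginal signal;
* base composition is uniform (25% each), which makes the background
  motif rate analytic (≈ `2·(L−w+1)·m/4^w` for m expansions, checked as
  a Poisson count) but is not a realistic genome composition;
* one binding site per bound gene, non-overlapping genes, no replicate-
  specific noise beyond p-value jitter, no read-level simulation;
* decoy peaks are placed strictly outside (territory ± max peak width),
  so consensus precision is exercised via the weak-threshold rule, not
  via ambiguous borderline overlaps.

# Numerical choices and degenerate inputs

* Fisher combination clamps p = 0 to the smallest positive double with
  a warning; a single p-value is returned unchanged (χ² identity, 2 df).
* Zero-p groups report `combined_neglog10_p` against the same clamp.
* `central_enrichment_test` with no hits returns p = 1.0.
* Ties in all tabular outputs break on ids (genes, peaks, terms), so
  outputs are byte-stable across reorderings of the inputs.
* Empty peak input is a valid study: the pipeline reports zeros and
  succeeds; a missing input file aborts naming the file and stage.

# Design decisions taken where the design was open

* **Ambiguous peaks multi-assign.** A peak overlapping several
  territories supports all of them; the target definition is per-gene
  existence of a peak, so nearest-gene tie-breaking would discard
  defined targets.
* **BH via `stats::p.adjust`.** The step-up procedure is standard
  infrastructure; tests pin it to a hand-computed recursion on fixtures.
* **Interval machinery on GenomicRanges.** Transitive overlap grouping
  is `reduce()` + `findOverlaps()`; the brute-force oracles in the test
  suite re-derive the groupings independently.
* **Accession-backed check.** The cloned transcript length / longest-ORF
  check requires a GenBank record that cannot be fetched in an offline
  build; the ORF machinery (`longest_orf()`, `transcript_stats()`) is
  implemented and tested on constructed synthetic transcripts, and the
  acceptance check remains failing until the real record is placed at
  `inst/extdata/OK338071.fa`. A fabricated stand-in with the published
  lengths would have made the check circular and was rejected.
* **Counts over quoted proportions.** Externally reported repression
  proportions are sometimes internally inconsistent with the
  represented counts they accompany (e.g. a quoted 3/35 beside counts
  summing to 34). `summarize_regulons()` always computes proportions
  from the counts it derives and never attempts to reconcile a printed
  percentage.

# Known limitations

No distal-enhancer or 3D-contact assignment; no transcript isoforms;
no peak calling, alignment, or DE model fitting (their outputs are
inputs here); no GO DAG propagation (term membership is a flat
two-column table); the consensus stage intentionally does not reproduce
any specific external tool's full decision procedure.
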