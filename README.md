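# famtrace

Reconstructing the evolutionary history of a large plant gene superfamily
across related genomes. The motivating system is the family 1
UDP-glycosyltransferases (UGTs) of legumes — hundreds of genes per genome,
recognizable by the 44-residue C-terminal PSPG box — but every stage is
generic: screen candidates, build a neighbor-joining family tree with
bootstrap supports, partition genes into **putative ortholog loci (POLs)**
across species, call intron gain/loss events, classify within-species
duplicates as tandem or segmental from annotated gene order, and date
duplications from synonymous divergence.

The statistics at the core:

* **Poisson-corrected distance** under pairwise deletion,
  `d = -ln(1 - p)`, feeding neighbor-joining with bootstrap supports
  expressed as percentages per internal edge.
* **POL assignment**: within each anchor-defined phylogenetic group
  (A–R), maximal clades whose subtending edge has bootstrap support ≥ 50
  and whose members share ≥ 55% minimum / ≥ 60% mean full-length amino
  acid identity become POLs; everything else stays a singleton locus.
* **Tandem rule**: a same-species POL pair on one chromosome separated by
  ≤ 4 annotated genes (of any kind) is a tandem duplicate; anything else
  is segmental.
* **Nei–Gojobori (1986)** dN/dS with substitution-path averaging and
  Jukes–Cantor correction, and divergence dating
  `T = dS / (2 λ) × 10⁻⁶` million years with species-specific synonymous
  rates λ.
* A **gene-family evolution simulator** (dated species tree, WGD, tandem
  and segmental duplications, losses, intron events, screening decoys)
  provides planted ground truth for every stage.

## Worked example

```r
library(famtrace)

# one seed drives everything: simulation, bootstrap, outputs
res <- run_all(sim_config(), out_dir = "famtrace_out", seed = 42)
res$metrics
#>               metric    value   n
#> 1            pol_ari 1.000000 282
#> 2  dup_mode_accuracy 1.000000 144
#> 3 intron_gain_recall 1.000000   8
#> 4 t_median_rel_error 0.111867 175
```

The default conditions emulate a five-species legume panel (deepest split
48 MY ago, a whole-genome duplication on the Gm branch 13 MY ago, 30
ancestral loci, ~300 emitted genes). The metrics compare the inference
with the simulator's planted history: the POL partition recovered the
true loci exactly (Adjusted Rand Index 1.0 over 282 genes), all 144
single-event duplicate pairs were classified with the correct mode, all 8
detectable planted intron gains were called, and dS-based dates for 175
pairs had a median relative error of 11%.

Individual stages work standalone:

```r
r <- ng86(strrep("TTT", 9), paste0(strrep("TTT", 8), "TTC"))
r
#> NG86: 9 codons  S=3.00 N=24.00 Sd=1.00 Nd=0.00
#>   pS=0.3333 pN=0.0000 dS=0.44084 dN=0

divergence_time(1.2528, 1.08e-8)   # dS, lambda -> 58 million years
#> [1] 58
```

Nine `TTT` codons against eight `TTT` plus one `TTC`: phenylalanine's only
synonymous neighbor is the third-position C↔T swap, so each codon carries
1/3 synonymous site (S = 3 over 9 codons), the single difference is
synonymous (Sd = 1, pS = 1/3) and the Jukes–Cantor correction gives
dS = 0.441. At a synonymous rate of 1.08 × 10⁻⁸ per site per year, a pair
with dS = 1.2528 dates to 58 million years — the age used for the
papilionoid whole-genome duplication.

All pipeline outputs (per-species FASTA/GFF3 inputs, exclusion log,
alignment, tree with supports, `pols.tsv`, `intron_calls.tsv`,
`dup_events.tsv`, summary tables, recovery metrics) land under `out_dir`
and are byte-identical across reruns with the same seed. A thin CLI
wrapper lives at `inst/scripts/famtrace.R`.

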