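---
title: "Tracing gene-family history: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing gene-family history: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`famtrace` reconstructs the evolutionary history of a large plant gene
superfamily — the motivating system is the family 1
UDP-glycosyltransferases (UGTs), whose members carry the 44-residue
C-terminal PSPG box — across several related genomes. This vignette is the
package's own account of the methods: the models and rules each stage
implements, the parameters that matter, what the bundled simulator does
and does not emulate, and the design choices made where the procedure was
genuinely open.

## The pipeline at a glance

```{r}
library(famtrace)
res <- run_all(sim_config(), out_dir = "famtrace_out", seed = 42)
res$metrics
```

Seven stages run in sequence. Each is an exported function and can be used
on its own with real data (protein FASTA, CDS FASTA, GFF3 coordinates, an
anchor FASTA with group labels, and a table of per-species synonymous
substitution rates).

## Screening

Candidate proteins are kept when they are 350–600 residues long
(boundaries inclusive: "shorter than 350" and "longer than 600" are
excluded), start with methionine, and carry the diagnostic C-terminal
motif; afterwards, same-species sequence sets that are 100% identical at
full length are reduced to the lexicographically smallest gene id. Rules
apply in that fixed order and each excluded gene is logged with its first
failing rule, so the exclusion report is deterministic.

The motif check is a reproducible surrogate for what is usually a manual
judgement ("incomplete motif compared to orthologs"): the 44-residue
consensus is slid ungapped over the C-terminal half of the protein, and the
best window must match at least `motif_min_fraction` (default 0.6) of its
aligned columns while covering at least `motif_min_coverage` (default 0.9)
of the 44 columns. Proteins shorter than the consensus fail with coverage
zero. Both thresholds are configurable in `screen_config()`; the defaults
are deliberately permissive because authentic family members diverge
substantially even inside the motif.

Callers are expected to supply primary transcripts only; no transcript
selection happens inside the package, and no HMM domain search is
performed (pre-filter with any domain tool if desired).

## Alignment and distances

Pairwise alignment is global Needleman–Wunsch with affine gaps under
BLOSUM62 (gap open 10, extension 0.5; a gap of length L costs
`open + L * ext`, terminal gaps included). Tie-breaking among co-optimal
alignments is fixed — aligned columns beat gaps, a gap in the first
sequence beats a gap in the second — so results are reproducible to the
byte. Percent identity is identical residues over the full alignment
length: terminal gaps count against identity, and the ambiguity residue X
never matches. This is the "full-length protein identity" used by the POL
gates below; the denominator choice is documented here because published
surveys rarely state theirs.

The multiple alignment is progressive: a UPGMA guide tree over shared
3-mer fractions, then profile–profile merges using the same affine-gap
dynamic program, scoring profile columns by frequency-weighted average
substitution score. With exactly two sequences this reduces to the
pairwise aligner. It makes no claim to match MUSCLE or Clustal Omega
output; it is a deterministic, dependency-free progressive aligner whose
invariants (rows ungap to their inputs, order-stable) are tested.

Distances follow the Poisson model under pairwise deletion: for each pair
of rows, columns gapped in either row are dropped, `p` is the fraction of
differing remaining columns, and `d = -ln(1 - p)`. `p = 1` has no finite
correction and is flagged infinite; the tree builder refuses infinite
full-data distances, while bootstrap replicates cap them (below).

Codon alignments are produced by back-translating the protein alignment:
each residue is replaced by its codon, each gap by `---`; a terminal stop
codon is trimmed; any translation disagreement is an error naming the
residue. Codons aligned to a gap in either sequence are dropped before
dN/dS ("pairwise deletion of gapped codons") — how the original tooling
handled gapped codons is unstated, so the choice is made explicit here.

## Tree, supports and groups

Trees are neighbor-joining (via `ape::nj`) on the Poisson distances, with
negative branch-length estimates clamped to zero. Bootstrap supports
resample alignment columns with replacement, rebuild a replicate tree, and
record for every internal bipartition of the full-data tree the percentage
of replicates containing it; supports are displayed on the full-data
topology (no consensus tree). One RNG stream ordered by replicate index
makes supports reproducible given the seed. A replicate can leave a pair
with no shared or all-different sites; such infinite distances are capped
at twice the largest finite replicate distance rather than discarding the
replicate. The conventional replicate count is 1000; `run_all()` defaults
to 100, which is the desk-scale setting used throughout the package's own
tests and reproduction script (supports are only consumed by a 50%
threshold, which is insensitive to the difference).

Phylogenetic groups (the A–R clades of the plant UGT literature) come from
labelled anchor sequences placed in the same tree. A gene takes the group
of the anchors in the smallest clade — over both sides of every edge of
the unrooted tree — containing the gene and at least one anchor. When that
minimal clade mixes groups (or no split separates gene from anchors, as in
a star), the gene falls back to its highest-identity anchor. The fallback
is a documented choice: how group membership was decided for genes falling
between anchor clades is typically unstated in surveys.

## Putative ortholog loci

A POL (putative ortholog locus) is a cluster of genes, across species,
deemed to descend from one ancestral gene. Within each group the tree is
rooted outside the group and searched top-down for **maximal surviving
clades**: a clade survives when (a) it contains only this group's genes,
(b) its own subtending edge has bootstrap support at least `min_support`
(default 50%), and (c) its gene set passes both identity gates — minimum
pairwise identity at least `theta_min` (default 55%) and mean at least
`theta_mean` (default 60%). Each maximal surviving clade is a POL; genes
under no surviving clade stay singletons, mirroring loci with no
cross-species ortholog in the source data.

Two points deserve emphasis. First, the clade is judged on *its own*
supporting edge: short edges nested deep inside a locus clade legitimately
carry low bootstrap support (there is little signal for the ordering of
near-identical in-locus sequences), and letting them fragment the locus
would be wrong. Second, the identity defaults reflect the within-POL
conservation reported for real legume UGT POLs (roughly 54–99% between
co-members); both are configurable, and raising `theta_min` can only
increase the number of POLs (tested as a monotonicity property).

POLs are named positionally: within each group, clusters are ranked by the
chromosome and start coordinate of the earliest member from the
highest-priority species present (falling back to the next species in
priority order), then labelled `D01`, `D02`, … Copy-number classes per
species are counted as absent / single / double / multi (0 / 1 / 2 / ≥3).

## Intron gain and loss

Intron counts are coding-sequence introns (exon features minus one; UTR
introns are ignored at GFF3 parse time). A POL represented in at least
three species is a *no-intron* (*one-intron*) POL when a strict majority
of represented species have modal intron count 0 (1); modal ties within a
species resolve to the smaller count; everything else — including POLs
seen in fewer than three species, where the rule is undecidable — is
*mixed*. "Most (if not all)" is an informal rule; strict majority is the
deterministic reading adopted here. Species representation is counted over
all members, including eventual outliers.

Calls then flag deviants: any intron in a no-intron POL is a gain, zero
introns in a one-intron POL is a loss, and more than one intron is a gain
in every POL type. Consequences worth knowing: a no-intron POL can never
contain a "lost" call, and a gain that fixed in most of a locus re-types
the locus rather than being called — the method detects minority deviants
by construction, which is also how the recovery metric below defines a
*detectable* planted gain.

## Duplications and dating

All same-species pairs within a POL are paralog pairs. A pair on the same
chromosome separated by four or fewer annotated genes — counting **all**
genes in the annotation, any strand, not only family members, in
start-coordinate order — is a tandem duplicate; five or more intervening
genes, different chromosomes, unplaced scaffolds, or missing coordinates
(flagged with a warning) make it segmental. Gene-level labels use
tandem-over-segmental precedence, so a tandem array member with an
additional cross-chromosome partner still counts as tandem; this is what
makes the tandem + segmental + singleton partition arithmetic of published
tables come out.

dN/dS follows Nei–Gojobori (1986). Site counts: each codon position
contributes the fraction of its three single-nucleotide neighbors that
preserve the amino acid (changes to stop codons count as nonsynonymous),
averaged over the two sequences, so S + N = 3 × codons exactly. Difference
counts: codons differing at several positions are averaged over all
orderings of the single steps, excluding orderings that pass through a
stop codon (if every ordering does, all are counted). Proportions receive
the Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)`, undefined when
the argument is non-positive (`valid = FALSE`, reported and excluded from
dating). The implementation is checked against an independent
site-and-path enumeration oracle on hundreds of random codon pairs.

Dates come from `T = dS / (2 λ) × 10⁻⁶` million years with the species'
synonymous rate λ (per synonymous site per year); the bundled defaults are
the published legume rates of order 10⁻⁸–10⁻⁹. Each pair is dated
separately, so multi-gene POLs naturally yield ranges of event times.
Standard nuclear genetic code only.

## The simulator: what it emulates, and what it does not

`simulate_family()` exists so every stage can be scored against known
truth. Default conditions emulate a five-species papilionoid legume
panel: tree `(((Mt:23,Tp:23):17,Lj:40):8,(Gm:19,Pv:19):29)` (ultrametric,
branch lengths in million years; deepest split 48 MY), a whole-genome
duplication on the Gm terminal branch 13 MY ago, per-species λ of
1.08×10⁻⁸ (Mt), 5.85×10⁻⁹ (Gm), 8.46×10⁻⁹ (Pv), 6.05×10⁻⁹ (Lj) and
8.12×10⁻⁹ (Tp) — the first three are published rates for those species;
for Lj and Tp, which lack published values in the source rate set, two
published rates of neighboring legumes (chickpea and *Arachis*) are reused
as realistic magnitudes. Thirty ancestral loci in six anchor-defined
groups, five chromosomes of forty filler genes each, tandem / segmental /
loss rates of 0.012 / 0.004 / 0.002 events per gene per MY and intron
gain/loss rates of 0.001 / 0.0005 give roughly 300 emitted genes —
comparable, at desk scale, to one species' worth of a real survey.

Sequence evolution is deliberately minimal: single-nucleotide proposals
arrive uniformly at rate λ per site; synonymous proposals are always
accepted, nonsynonymous ones with probability ω (default 0.2), proposals
creating a stop or touching the start codon never. Because the NG86
synonymous site count *is* the synonymous fraction of neighbor changes,
the realized synonymous rate per synonymous site per year equals λ by
construction — which is exactly what makes `T = dS/(2λ)` recoverable and
turns dating into a real end-to-end test (median relative error ≈ 10% at
default scale). There is no rate heterogeneity, no codon-usage bias, no
GTR structure, no indels within the family, no gene conversion and no
recombination; passing recovery tests therefore demonstrates correctness
of the machinery under these idealized conditions, not robustness to real
genomic noise.

Other simulator choices worth knowing:

* **Tandem placement is adjacent** (the unequal-crossover model);
  separation beyond zero intervening genes arises only from later
  insertions, which is what makes the four-gene rule a meaningful
  tolerance. Segmental copies land at a uniform position on a uniformly
  chosen other chromosome; a WGD duplicates every chromosome wholesale.
* **Every fresh duplicate receives one forced nonsynonymous
  substitution.** Without it, a duplication arising close to the present
  produces two byte-identical proteins, and the screening stage's
  100%-identity dedup rule would silently delete a genuine young
  duplicate. One amino-acid change leaves dS untouched and biases dN by
  at most one difference per pair.
* **Lineage rates**: terminal branches use their species' λ; internal
  branches use the mean λ of their descendant species. Dating a pair that
  diverged on an internal branch with the terminal species' λ therefore
  carries a modest systematic error — visible in the recovery metrics as
  part of the ≈10% median relative error.
* **Ancestral loci within a group share the group ancestor's length**;
  groups differ in length, so the family alignment contains gaps between
  groups but within-locus alignments are gap-free. Intron counts evolve
  as a birth–death integer process from the ancestral 0 or 1.
* **Fillers and decoys**: filler genes exist only in the GFF3 (they are
  what "intervening genes" counts); decoys exist only in the FASTA
  records (each violating exactly one screening rule, labelled in the
  truth tables). Duplicate-decoy ids are constructed to sort after their
  source so the dedup rule keeps the authentic gene.
* Events are drawn per branch for the genes present at branch start;
  copies born mid-branch do not themselves duplicate until the next
  branch. At the default rates this second-order effect is negligible.

## Recovery metrics

`recovery_metrics()` scores an analysis against the planted history:
Adjusted Rand Index between the POL partition and true loci; accuracy of
tandem/segmental classification over pairs that *directly witness* one
planted duplication (a pair whose lineages accumulated several
duplications below their split — say, a tandem pair later separated by the
WGD — has no single planted mode and is excluded; true WGD pairs count as
segmental, since a whole-genome duplicate lies on another chromosome);
recall of detectable planted intron gains (gains inside ancestrally
intron-free loci that remain majority intron-free); and the median
relative error of `T` estimates for pairs with valid dS ≤ 0.5. At the
default study conditions all four are comfortably inside their acceptance
bands (ARI ≥ 0.9, accuracy ≥ 0.95, recall ≥ 0.9, median error ≤ 25%).

## Numerical and degenerate-input choices

* Percentages in summary tables are rounded half-up to one decimal
  (`round()`'s half-to-even would print 61.2 where published tables print
  61.3).
* NJ tie-breaks follow `ape::nj`; branch lengths are clamped at zero.
* The p = 1 Poisson distance is infinite: an error in the full-data tree,
  a capped value inside bootstrap replicates.
* An empty POL, an empty sequence, a non-amino-acid character, a CDS that
  does not translate to its protein row — all are errors naming the
  offending gene or position, never silent repairs.
* All randomness (simulation, bootstrap) flows from explicit integer
  seeds; `run_all()` output directories are byte-identical across reruns
  with the same config and seed.

## Problem sizes

The package's own test suite and the reproduction script run the full
pipeline at the default conditions above (≈300 genes, 100 bootstrap
replicates), which completes in about a minute; oracle-equivalence suites
use hundreds of random codon pairs (≤30 codons), exhaustive alignment
enumeration at lengths ≤8, and exhaustive topology search at ≤6 taxa —
sizes at which the independent oracles are exact.

## Limitations

Orthology here is tree-plus-identity clustering: no synteny, no
species-tree reconciliation, no manual curation — published POL tables
built with those extra signals will differ in the hard cases (the source
analyses themselves note that some POLs "can be divided or combined").
Group assignment quality is bounded by anchor choice. The NG86/
Jukes–Cantor pathway saturates near dS ≈ 1 and dates assume a constant λ
per species. The simulator's idealizations are listed above; none of the
recovery numbers should be read as accuracy claims about real genomes.
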