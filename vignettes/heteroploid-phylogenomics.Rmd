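---
title: "Recovering homeolog gene copies and mitochondrial genomes from hybrid fungal endophytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering homeolog gene copies and mitochondrial genomes from hybrid fungal endophytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Asexual *Neotyphodium* endophytes of fescue grasses are heteroploid: their
genomes arose through one or more interspecific hybridisation events between
sexual *Epichloë* species, so a single isolate carries two or three diverged
copies — homeologs — of every nuclear gene, one per progenitor sub-genome.
Whole-genome shotgun assemblers collapse or fragment such multi-copy loci,
and the phylogenetically informative markers (the housekeeping genes *tub2*
and *tefA* and the endophyte-specific peramine synthetase gene *perA*) must
instead be reconstructed copy by copy. The mitochondrial genome, in
contrast, is effectively clonal and present at tens to thousands of copies
per cell, which makes its read depth far higher than the nuclear background
and turns depth itself into a classification signal.

`endophylo` implements this whole analysis as a tested pipeline:

1. **read QC** — sliding-window quality trimming of read pairs;
2. **copy recovery** — reference-guided recruitment of read pairs to a
   marker gene, padding of each read to reference coordinates, variant
   column calling, and variant-linkage phasing of the padded stack into k
   homeologous consensus sequences;
3. **structural and functional characterisation** — deletion detection
   against the reference and functionality prediction by translation;
4. **mitochondrial assembly** — de Bruijn contig assembly with a
   coverage-cut-off classification of organelle contigs, reference-guided
   ordering/merging, read confirmation of gaps, protein-gene annotation and
   complement concatenation;
5. **phylogenetics** — progressive alignment, neighbour-joining and Fitch
   parsimony with majority-rule bootstrap consensus, per gene and for the
   *tub2*–*tefA*–*perA* concatenation and the mitochondrial gene
   complement.

A fully ground-truthed simulator of hybrid genomes and paired-end
sequencing is part of the package, not a test fixture: every downstream
stage is validated against planted truth.

## The synthetic study system

The simulator emulates the biological structure of the study system:

* a common **ancestor genome** with the three marker genes (real open
  reading frames with 100 bp flanks), an intergenic background pool, and a
  circular mitochondrial genome carrying 13 protein-coding genes
  (`cox1 ... nad6`) in a fixed canonical order;
* **progenitor lineages** derived from the ancestor by iid substitutions
  (Jukes–Cantor style, uniform over the three alternative bases) at a
  configurable divergence, plus geometric-length indels. Coding regions
  evolve under purifying selection: substitutions creating in-frame stops
  are rejected and indels are excluded from ORFs, so a copy is
  non-functional only when a lesion is planted deliberately;
* **hybrids** composed of 1–3 donor sub-genomes, one embedded copy of each
  marker per donor (on a random strand, inside ≥ 2 kb of donor background),
  with optional copy losses, multi-hundred-bp deletions, premature-stop
  lesions, and the mitochondrial genome of a designated donor at an
  mt:nuclear copy ratio r;
* **paired-end reads** with FR orientation, fragment lengths
  Normal(400, 80) truncated to [100, 900] bp, 100 bp reads, and a quality
  model of constant Q40 with a 10-cycle 3' tail declining to Q30; per-base
  substitution errors follow the quality. Mitochondrial fragments may span
  the circular origin.

Default study conditions follow the analysed taxa: lineage divergence 5%
from the ancestor (pairwise ≈ 10% between sub-genomes), 50× per-copy
coverage, and the preset hybrid architectures of `default_study()` — a
tri-parental hybrid (three copies of every marker), bi-parental hybrids
(two copies), one taxon with a planted *tub2* copy loss, the two shared
*perA* deletions at reference coordinates 1251–1878 and 4590–4918 on the
FGC1-derived copy, and premature-stop lesions that reproduce the observed
per-taxon functionality patterns (for example 2 functional of 3 copies in
the tri-parental hybrid and 0 of 2 in the UNS-like hybrid).

Genome sizes are scaled down to desk scale — markers of 1.7/1.9/5.6 kb, a
12 kb mitochondrial genome with proportionally shortened genes, ~12 kb of
background per lineage — so a full study simulation and analysis runs in
minutes. The *perA* length (5.6 kb) is chosen so the canonical deletion
coordinates exist on the gene. What the simulator deliberately does *not*
model: repeat landscapes, PCR duplicates, indel sequencing errors, and
within-lineage polymorphism. Passing tests therefore demonstrate the
correctness of the algorithms under the stated error and divergence model,
not performance on arbitrary real libraries.

## Copy recovery: recruit, pad, phase

Recruitment is a similarity search in the BLAST mould, built from exact
13-mer seeding plus ungapped diagonal extension (match +1 / mismatch −2);
significance is assessed with the Karlin–Altschul formula
E = K·m·n·exp(−λS) with fixed nucleotide parameters (λ = 1.28, K = 0.46).
A pair is recruited when **either** mate reaches E ≤ 0.1 (the recruit
threshold), both mates are returned, and antisense hits — and, through the
FR geometry, the partners of hitting mates — are reverse-complemented so
all recruited reads are reference-sense. The seed requirement is what keeps
the false recruitment rate of random reads far below the nominal E-value
(an unseeded random 100-mer never reaches scoring).

Padding places each read at the start coordinate of its best hit; the
placement is the maximal-scoring ungapped segment, so flank overhangs are
clipped automatically. Reads with a large unexplained remainder are either
**split across a reference gap** — producing an internal `-` run that is
direct, read-level evidence for a copy-specific deletion — or re-aligned
with an affine-gap local aligner in a reference window (small indels).
Internal gap runs are left-normalised: when flanking bases coincide with
the deleted sequence the gap placement is ambiguous, and the leftmost
representation is used consistently so junction columns agree across reads.
Mates stay linked by their shared pair id; the pair (fragment) is the
phasing unit, which roughly doubles the linkage range relative to single
reads.

A column is **variant** when at least two alleles each reach depth ≥ 4 and
allele fraction ≥ 0.2; `-` counts as an allele (deletion evidence), leading
and trailing pads are absent from the representation by construction.
Phasing clusters fragments greedily by agreement with cluster allele
profiles (assignment requires ≥ 80% agreement over shared columns;
fragments covering fewer than two variant columns cannot seed new
clusters), merges clusters whose profiles agree ≥ 90% over at least two
shared columns, discards clusters below the support floor
(max(4, 8% of assigned fragments)), caps k at 3, and finally reassigns
every fragment to the surviving clusters. Fragments spanning no variant
column — inevitable for a lost copy or a uniform stack — are counted as
unassigned and only affect consensus depth, and a stack with no variant
columns at all yields k = 1 with the plain majority consensus. Per-cluster
consensus is the column majority with copy-specific deletions preserved as
gap runs; columns a cluster does not cover inherit the overall stack
majority when non-variant and `N` otherwise.

At the default study conditions (5% divergence, 50×) roughly one column in
ten differs between some pair of sub-genome copies, fragments span several
variant columns each, and phasing recovers both the copy number and
consensus sequences ≥ 99.5% identical to the planted copies.

## Functionality calls and deletion coordinates

Deletion detection aligns a copy globally to the reference (match 2 /
mismatch −3, gap opening 40, extension 0.5 — the high opening cost keeps a
long deletion as one gap instead of splitting it around chance
micro-matches) and reports maximal unmatched reference runs ≥ 10 bp, in
1-based inclusive coordinates with length end − start + 1. Gap runs are
again left-normalised. Boundaries are typically exact to ±1–2 bp; when the
bases flanking a deletion coincide with the deleted sequence, the boundary
is genuinely unidentifiable to that resolution and any placement in the
equivalence class may be reported.

Functionality is predicted by projecting the reference exon model through
the alignment and translating with the standard genetic code. A copy is
functional only if every indel run inside the coding region is a multiple
of three **and** frame is preserved across every exon junction, the
translation has no internal stop, and the protein covers ≥ 95% of the
reference protein. The failure reason is reported as frameshift, premature
stop, or truncated; the 329 bp deletion (4590–4918) is a frameshift, so a
copy carrying it is always non-functional, consistent with the invariant
that a detected deletion of length ≢ 0 (mod 3) inside the CDS forces a
non-functional call. The exon model is single-exon for the synthetic
markers; multi-exon projection is implemented and unit-tested.

## Mitochondrial assembly

The assembler builds maximal non-branching paths of the k-mer graph
(strands kept separate, reverse-complement duplicate contigs collapsed by
containment, circular walks detected and trimmed to one rotation) after
pruning k-mers below max(2, depth mode / 20), the mode taken over
multiplicities ≥ 2. Contig depth is the mean combined-strand k-mer
multiplicity, which for fold coverage C and read length L is about
C·(L−k+1)/L.

Classification of organelle contigs combines similarity to the reference mt
genome (exact-match anchor chains scored with the same Karlin–Altschul
formula, threshold E ≤ 0.001) with a **coverage cut-off**: the valley of
the smoothed log-depth density between its two dominant modes (or, for
small contig sets, the midpoint of the largest log-gap; if the distribution
is unimodal the classification falls back to similarity only, with a
warning). Mitochondrial assembly is two-pass: the first pass locates the
cut-off, and the chosen k (maximum mt-contig N50 among assemblies whose
classified total length is within 20% of the reference) is re-assembled
with the cut-off applied as the pruning threshold. The second pass is what
removes both nuclear k-mers and the sequencing-error k-mers that otherwise
fragment a several-hundred-fold-deep organelle graph. Nuclear copies of
mt-like sequence (numts) are handled solely by the depth cut-off; no
sequence-signature filter is applied.

Classified contigs are oriented and ordered by anchor-chain placement on
the reference; exact overlaps ≥ 20 bp merge, non-overlapping neighbours are
joined with the intervening reference interval recorded as a gap
(intervals < 30 bp are ignored as anchor dropouts over diverged sequence),
and conflicting placements resolve towards the higher-depth contig with the
conflict logged. A gap is **confirmed** as a genuine deletion when enough
reads span the junction concordantly (≥ 15 bp each side, few mismatches);
an assembly break has no junction-spanning reads and stays unconfirmed.
Identical gap signatures are grouped across isolates of a taxon.

Protein genes are annotated by best local alignment of each reference gene
(either strand, identity ≥ 70% over the gene), reported in reference gene
order, concatenated strand-resolved in that order, and summarised as total
length, percent protein-gene content (annotated length / total length) and
percent identity of the concatenated complement to the reference
complement. The cut-off is defined in k-mer depth units (the assembler's
native currency); read-depth units differ by the factor (L−k+1)/L stated
above.

## Phylogenetics

Alignment is progressive: a neighbour-joining guide tree on fractional
shared 6-mer distances, then profile–profile merging by global affine-gap
dynamic programming (compiled; match 2 / mismatch −1 / gap 10 + 0.5 per
column). Columns containing `-` or `N` in any row are eliminated before
analysis (complete deletion), and distances are uncorrected p-distances —
adequate at the ≤ 10% divergences involved, and switchable in principle,
but no model correction is applied.

Neighbour-joining uses the standard Q criterion with negative branch
lengths clamped to zero and ties broken towards the smallest label-pair
index; on additive distances it reproduces the generating tree exactly
(this is asserted to 1e-9 in the tests). Fitch parsimony is the linear
two-pass count; search mode is exhaustive over all unrooted topologies up
to 8 taxa (105 topologies at n = 6) and NNI hill-climbing from the NJ tree
with five seed-controlled restarts beyond that. Bootstrap consensus
resamples columns with replacement (1000 replicates by default), roots each
replicate at the first taxon, and returns the majority-rule (> 50%)
consensus with percent supports; the full-data tree with per-edge bootstrap
proportions (which can fall below 50) travels in the `"full_tree"`
attribute. NJ replicates are computed without realigning: the per-column
pairwise mismatch matrix is fixed, so a replicate distance matrix is a
single matrix product with the multinomial column-weight matrix.

Copies are assigned to donor sub-genomes by nearest reference in p-distance
on the per-gene alignment — equivalent, on these clean phylogenies, to
reading the copy's sister taxon off the tree, and deterministic. The three
markers are then concatenated per sub-genome in the order
*tub2*–*tefA*–*perA*, with a missing marker (a lost copy) padded with `N`
of the reference length and flagged.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed; every stage derives child
  seeds deterministically, so identical seeds give byte-identical reports.
* Quality encoding is fixed to Phred+33; decoded scores are validated into
  [0, 60].
* Recruitment ties (equal-score placements) resolve to the smallest start
  coordinate; NJ ties to the smallest pair index; consensus ties prefer a
  base over a gap, alphabetically.
* Empty inputs: QC of zero pairs returns zeroed statistics; an empty
  annotation set is an error for complement concatenation ("no
  complement"); a depth histogram with one mode triggers the
  similarity-only fallback with a warning rather than an error;
  contradictory phasing linkage flags the copy set instead of failing.
* A planted deletion interval is validated against the gene length at
  composition time; the mt copy ratio must be ≥ 1; divergence must lie in
  [0, 0.75).

## Problem sizes

The bundled analyses run at deliberately chosen desk scales: five hybrid
taxa at 50× per-copy nuclear coverage (~10–16 k read pairs each),
twelve-to-twenty replicated two-copy simulations for consensus fidelity, one
mitochondrial recovery at mt:nuclear ratio 100 with the organelle at 500×
(~30 k pairs), and 1000 bootstrap replicates per gene tree. These sizes
exercise every code path at full statistical strength while keeping a
complete run in the tens of minutes on a single core.

## Known limitations

* Phasing reports islands of variation separated by more than the fragment
  span as a single flagged copy set rather than attempting long-range
  linkage; at the study divergences this never occurs.
* Deletion boundaries inherit the intrinsic ±few-bp ambiguity of gap
  placement between repetitive or coincidentally matching flanks.
* The assembler is a minimal de Bruijn implementation: no bubble popping or
  tip clipping beyond multiplicity pruning, which is adequate for the
  clean, high-depth organelle graphs it is pointed at but not for complex
  nuclear assemblies (copy recovery does not depend on contigs at all).
* Maximum-likelihood tree search and phylogenetic networks are out of
  scope; NJ and parsimony are the two cross-checked inference routes.
* Branch lengths of published trees are not reproduction targets: the
  distance model behind them is not specified beyond program defaults.
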