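---
title: "Methods and design notes for famscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for famscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

famscan characterizes an ABC-transporter gene family genome-wide:
identification from domain hits, topology classification, subfamily
assignment, phylogeny, selection and duplication dating, promoter
cis-element scanning, and expression profiling. This vignette records the
models behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Identification and classification

**Inputs.** The pipeline ingests domain hits (HMMER3 `--domtblout`
geometry, or a compact five-column form), proteomes and coding sequences
as FASTA, and gene models as GFF3. It does not run BLAST or HMMER; those
searches happen upstream and famscan consumes their tables. Pfam
accessions map to topology tokens via a packaged, user-overridable table:
PF00005 and PF01061 (the ABC-2 type) to `NBD`, PF00664 (the transporter
transmembrane region) to `TMD`.

**Filtering.** A protein is a family candidate when it carries at least
one NBD hit with E-value at or below the cutoff (default `1e-5`; the rule
excludes hits *strictly above* the cutoff, so the boundary is kept).
Redundant entries — byte-identical sequences, or isoforms sharing a locus
id after stripping a trailing `.N` suffix — collapse to the longest
sequence, ties to the smallest id. These two rules are our own, since
"redundant genes excluded" names no procedure; both are deterministic and
input-order invariant.

**Topology.** Each protein's hits are ordered by alignment start;
same-type hits overlapping by more than half of the shorter hit are
merged (the merge threshold is our choice — domain tables often split one
domain into two partial hits). The resulting NBD/TMD string maps onto
nine classes: `TMD-NBD-TMD-NBD` and `NBD-TMD-NBD-TMD` full-sized
(forward/reverse), `TMD-NBD` and `NBD-TMD` half-sized, single-domain
quarter-sized, `NBD-NBD` (ABC2-type) and `TMD-TMD`, with every other
string — including repeated arrangements like (TMD-NBD)×2 plus a trailing
TMD — classed `UNIQUE`. The classes are mutually exclusive and exhaustive
over non-empty strings. A `soluble` flag (no TMD anywhere) is emitted
separately so that either reading of "soluble ABC protein" — excluding or
including ABC2 structures — is recoverable downstream.

**Physicochemical properties.** Molecular weight is the sum of average
residue masses plus one water (18.0153 Da). The theoretical pI is the pH
where the Henderson–Hasselbalch net charge over the termini and the D, E,
C, Y, H, K, R side chains crosses zero; the charge is strictly decreasing
in pH, so bisection on [0, 14] to 1e-3 pH units finds the unique root.
The pKa set ships as a config file (EMBOSS values) and can be replaced;
published pI values for the same sequence differ across pKa sets by a few
tenths of a unit, which is why the set is explicit rather than baked in.

**Subfamily assignment.** Plant ABC subfamilies are A–G and I. Rather
than re-running an iterative profile search, famscan assigns each
candidate the label of its highest-scoring global alignment against a
labeled reference set (e.g. the Arabidopsis ABC proteins), with ties
broken by the smallest reference id. This is deterministic and desk-scale;
the NJ tree remains available for clade-level inspection, and disagreement
between the two views is something to report, not silently resolve. Gene
symbols are positional within (species, subfamily): index 1..n by
chromosome then start, scaffolds after chromosomes, model-less members
last.

## Alignment

Global alignment uses affine gaps with the gap-open/gap-extension pair
10 / 0.1 — deliberately the same penalties throughout the pipeline — and
BLOSUM62 for proteins or +2/−3 for nucleotides. A gap of length L costs
`open + L·ext`. The dynamic programming itself is delegated to
Biostrings' `pairwiseAlignment()`; the test suite verifies its scores
against an exhaustive enumeration of all alignments for short sequences
and re-scores every emitted traceback.

Codon alignments are protein-guided: translate, align the proteins, then
expand each aligned residue or gap back to its codon triplet, so gaps are
whole codons and the frame is never broken. One trailing stop codon is
trimmed; internal stops are an error rather than a warning because a
frameshifted input would silently corrupt every downstream rate.

Identity is matches over aligned (both-non-gap) columns; coverage is
aligned columns over the *shorter* sequence length. The denominator
convention is documented and configurable in spirit: "coverage of the
alignment length" admits several readings, and the shorter-sequence
convention makes a perfect fragment score 100% coverage, which is the
behavior the ortholog criterion needs. Paralog thresholds are strict
(> 70 / > 70), ortholog thresholds inclusive (identity ≥ 98, coverage
≥ 70), mirroring the symbols in the underlying criteria.

## Phylogeny

Distances are p-distances with pairwise deletion of gapped columns (the
distance function is pluggable; the underlying tree-building tool in the
original workflow does not state its model, and p-distance is the least
committal default). Neighbor joining follows Saitou–Nei with two
determinism guarantees: on equal Q the smallest (row, column) index pair
is joined, and negative branch lengths are clamped to zero with a count
recorded in the `clamped` attribute. The last three lineages are closed
out by the three-point formula, giving the conventional unrooted tree
with a basal trifurcation. On additive matrices the tree reproduces the
input distances to 1e-9 (tested on random 4–8-taxon trees), and the
topology matches `ape::nj` — an independent implementation of the same
published algorithm — on random matrices and under taxa permutation.

Bootstrap supports resample alignment columns with replacement, rebuild
the tree per replicate, and report for each internal bipartition of the
point-estimate tree the percentage of replicates containing it. Trivial
bipartitions are omitted. The default replicate count for production use
is 1000; the tests use 20–200 replicates because what they check —
determinism under a seed, near-total support for a planted clade — does
not sharpen with more.

## Selection and duplication dating

The molecular-evolution core is the Nei–Gojobori (1986) method, written
here rather than bought, with the Jukes–Cantor correction:

- **Sites.** Each codon contributes fractional synonymous sites: at each
  position, the fraction of the possible single-base changes that are
  synonymous, with changes to stop codons excluded from numerator and
  denominator (the position still contributes one full site, so
  S + N = 3 × codons exactly — an invariant asserted on every run).
  Site counts are averaged over the two sequences.
- **Differences.** For a codon pair differing at k positions, all k!
  orderings of the changes are enumerated; pathways through stop codons
  are excluded (if every pathway is blocked, all pathways are used —
  stopping would otherwise discard the codon silently); synonymous and
  non-synonymous step counts are averaged over the surviving pathways.
  Both site and difference lookups are precomputed over the 61 sense
  codons once per session.
- **Rates.** p = D/S (or D/N) per class, d = −(3/4)·ln(1 − (4/3)p).
  p ≥ 3/4 is saturation: the rate is NA and a `saturated` flag is set
  rather than fabricating a number. ω = Ka/Ks is undefined when Ks = 0.
- **Calls.** ω > 1 + ε positive, ω < 1 − ε purifying, within ε neutral
  (ε defaults to 0 so that ω = 1.06 is already a positive call, matching
  how such tables are conventionally read).

Codons containing a gap or stop in either row are excluded from both
sites and differences — standard NG86 practice. The implementation is
verified against a brute-force pathway-enumeration oracle (an
independently written recursion) on a thousand random short alignments,
where the two agree to 1e-12.

Duplication dates use the synonymous clock T = Ks/(2λ) with
λ = 6.96 × 10⁻⁹ synonymous substitutions per site per year (the standard
Solanaceae calibration), reported in million years. Note the model
choice: a tool-based workflow using a model-averaged estimator will not
reproduce NG86 Ka/Ks row for row on real data; per-row agreement with any
particular published table is therefore not claimed — only the
column-level summary statistics of the packaged reference table are,
since those are arithmetic on the printed values. Two quirks of that
table are worth recording: its printed percentages truncate rather than
round (3/14 = 21.43% prints as 21.42), and its printed T values derive
from unrounded Ks, so T ≠ Ks/2λ recomputed from the rounded column.
famscan reports unrounded values and leaves presentation rounding to the
caller. The packaged table shows eight same-prefix (intra-species) pairs,
and famscan counts species membership from the symbol prefixes, taking
the table over any prose that disagrees with it.

Paralog discovery aligns all CDS pairs at codon level and keeps edges
passing the strict 70/70 thresholds. The third published criterion — "a
minimum of two duplication events considered for strongly connected
genes" — is ambiguous as a filter, so famscan operationalizes it as an
annotation: each retained pair carries its connected-component size and a
`strongly_connected` flag (component with ≥ 2 edges), and filtering on it
is opt-in (`require_strong`). Dropping pairs silently on a guessed rule
seemed worse than reporting the flag.

## Promoters and cis-elements

Promoters are the `upstream_length` bases (default 1500 bp) 5' of the
start codon: upstream of `start` for + genes, the reverse complement of
the downstream flank for − genes, truncated (and flagged) at contig
edges; zero upstream bases is an error. Coordinates are 1-based inclusive
throughout the package — the R/Bioconductor convention — with the single
conversion at BED export, which is 0-based half-open.

Motif scanning compiles IUPAC degenerate signals into position-wise set
matchers. One deliberate asymmetry: a pattern `N` matches any sequence
letter, but a sequence `N` (an ambiguous genome base) is matched *only*
by a pattern `N` — an uncalled base should never count as evidence for a
concrete motif letter. Every overlapping occurrence on the requested
strands is reported (both strands by default, the PLACE convention;
minus-strand hits carry forward-orientation coordinates), and
presence/absence summaries collapse the multiplicity.
`common_elements()` intersects presence across a promoter set, counting
promoters with zero hits against every motif. The scanner is verified
against a naive position-by-position oracle on random sequences, and the
packaged catalog ships as a 23-row TSV (name, IUPAC signal, SITE
accession, annotation) that users can replace with a larger catalog in
the same schema.

## Expression

RPKM[g,s] = 10⁹·C[g,s]/(N[s]·L[g]) with lengths in bp; it is linear in
counts and invariant to scaling counts and library sizes together.
Heatmap matrices are log2(RPKM + 1) — the pseudo-count is configurable,
1 keeps zero at zero — with rows (and columns, given ≥ 3 samples) ordered
by average-linkage hierarchical clustering on Euclidean distances; both
choices are configurable because the upstream web tool they emulate
publishes no parameters. "Expressed" for the shared/specific Venn sets
means RPKM ≥ 1 in at least one sample of a group; no threshold is stated
in typical workflows, so 1 RPKM — the conventional detection floor — is
the documented default. Ortholog matching is reciprocal best hit under
the inclusive 98/70 criteria. qPCR fold changes follow Livak's 2^-ΔΔCt
with the reference gene (β-tubulin by convention) and calibrator sample
explicit, replicate means in the ΔCt, and the ΔCt SD propagated in
quadrature from the replicate SDs.

## What the generators emulate — and what they do not

The synthetic module exists to give every stage an input with known
truth, at the scale the real study implies:

- `gen_proteome()` plants domain architectures per topology class
  (E-values log-uniform on [1e-50, 1e-10], the range typical of genuine
  Pfam hits), NBD-free decoys, and non-overlapping gene models on two
  chromosomes and both strands. It does *not* emulate sequence-level
  domain homology: the planted "domains" are random amino acids with
  coordinates in the hit table, which is exactly what the downstream code
  consumes. Recovering planted counts therefore validates the
  filter/merge/classify logic, not domain detection itself (out of scope:
  the pipeline ingests, never runs, the HMM search).
- `gen_diverged_pair()` evolves one ancestor along two branches by
  single-base codon substitutions with relative acceptance 1 for
  synonymous and ω for non-synonymous changes, rejecting stop-creating
  proposals, until each branch reaches Ks_true/2 realized synonymous
  events per ancestral synonymous site. This is a rejection scheme, not a
  full GY94 simulator — adequate because the only claim tested is NG86
  recovery: over 100 replicates at 500 codons, the median estimated ω
  falls within ±25% of truth at ω ∈ {0.2, 2.0} and median Ks within ±10%
  at Ks = 0.2. NG86's known mild downward bias at ω > 1 is visible
  (median ≈ 1.73 at truth 2.0) and tolerated, not corrected.
- `gen_promoters()` builds motif-free backgrounds by local window
  resampling until no catalog signal matches on either strand (bounded
  retries; whole-sequence rejection would never terminate for 4-mers like
  CAAT at 1500 bp), then plants instantiated signals block-wise at
  recorded positions and strands. Planted recall is 100% and background
  false positives 0 by construction — what this shows is scanner
  correctness, not anything about real promoter composition.
- `gen_counts()` inverts the RPKM formula exactly (deterministic mode) or
  adds Poisson noise (noisy mode).

All generators are byte-deterministic under a fixed seed.

## Problem sizes and runtime

The shipped test-suite sizes are chosen to finish in minutes on one CPU
while still exercising the claimed tolerances: 1,000 random short codon
alignments for the NG86 oracle, 100 simulated replicates per ω for
recovery, 100 random additive trees for NJ, 1,000 random 200-bp sequences
for the scanner oracle, 60–70 planted proteins for the identify/classify
chain. Production use scales the same functions to full proteomes
(hundreds of members) and 1000 bootstrap replicates without code changes,
at proportional cost; the all-vs-all paralog search is quadratic in the
number of sequences and is the stage to restrict first on large inputs.

## Known limitations

- Subfamily assignment by nearest labeled reference is only as good as
  the reference set; deep-branching or chimeric proteins can land with a
  best-scoring reference that a full phylogenetic placement would
  contradict. Both outputs are available for comparison.
- NG86+JC ignores transition/transversion bias and codon-frequency
  effects; for publication-grade per-pair estimates on real data a
  model-averaged or ML estimator is the right cross-check.
- The NJ stage accepts a user-supplied MSA; famscan does not perform
  multiple sequence alignment, and p-distance underestimates divergence
  on saturated alignments.
- Synteny is operationalized purely through the homology criteria; no
  genomic-context (collinearity) test is applied, matching the published
  criteria but not the strict sense of "syntenic".
- The promoter definition is fixed-length upstream of the translation
  start, not the transcription start; genes with long 5' UTRs will have
  part of their transcribed region scanned.
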