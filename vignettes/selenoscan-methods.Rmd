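---
title: "Methods: selenoprotein gene discovery and comparative selenoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selenoprotein gene discovery and comparative selenoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Selenocysteine (Sec, `U`) is inserted co-translationally at UGA codons, which
are otherwise stop codons. A selenoprotein gene therefore looks, to a
standard gene model, like a truncated pseudogene. Discovery instead rests on
three signals used jointly: (i) open reading frames that remain homologous to
a known selenoprotein family when internal TGA codons are read through,
(ii) conservation of the residues flanking the family's Sec column, and
(iii) a SECIS element — a specific stem-loop in the 3′-UTR required for UGA
recoding in eukaryotes. `selenoscan` implements that joint procedure, plus
the downstream comparative analyses a multi-species survey needs: Sec→Cys
substitution classes, pseudogene calling, tandem clusters, gene+flank
duplications, and the species × family presence matrix with double
clustering.

# Pipeline model and assumptions

## Read-through ORF enumeration

Within each strand and frame, maximal segments bounded by TAA/TAG (or the
sequence ends) are enumerated. Internal TGA codons are ambiguous: up to
`max_readthrough_tga` of them (default 3 — the largest Sec count per gene
among the reference families, set by the triple-Sec PDI_e pattern) are
provisionally translated as `U`, and for every locus the terminate-at-TGA
prefix variants are emitted as well. The deliberate consequence is that the
ORF stage never decides whether a TGA is Sec or stop; the homology stage
does, by scoring both variants. ORFs need not start with ATG (EST fragments
and partial genes would otherwise be lost); `require_atg = TRUE` restricts
to methionine-initiated ORFs. Codons containing `N` translate to `X` and
never terminate a segment. `min_orf_aa` defaults to 30 residues — shorter
peptides carry too little alignment signal at the default score threshold to
be classifiable anyway.

All coordinates are 0-based half-open on the forward strand regardless of
ORF strand; only the GFF3 writers/readers convert to 1-based closed.

## Sec-aware scoring and alignment

The substitution model extends BLOSUM62: the `U` row and column copy the `C`
row, except `score(U,U) = score(C,C) + sec_bonus` (default +2). Sec and Cys
are the canonical substitution pair, so `U` behaves like cysteine against
every other residue, while the bonus makes Sec–Sec pairings strictly
preferred over Sec–Cys, which in turn outscore any other pairing with Sec.
The base table never stated how to score Sec, so this inherit-C rule is a
design decision of the package; `sec_bonus` must be positive or the ordering
collapses. Gaps are affine: −11 to open, −1 to extend, the familiar BLOSUM62
pairing.

Alignment is exact Smith–Waterman (Rcpp), not a heuristic search engine: at
the scale of a candidate set that has already passed a shared-6-mer
prefilter against the reference database, exactness is affordable and far
easier to test. Traceback is deterministic — diagonal preferred over up over
left, and among equal-scoring end cells the smallest coordinates win — so
reruns are byte-identical. A brute-force dynamic-programming oracle written
independently in plain R checks score equality on random pairs, including
`U`-containing ones, in the test suite.

## Sec-site classification

For every Sec position of the best-hit reference, the aligned query residue
is read off the traceback: `U` → Sec, `C` → Cys, anything else → Other, gap
or outside the aligned span → Unaligned. A site call additionally requires
local conservation: within ±`sec_window` (5) reference columns, at least
`min_window_positive_frac` (40%) of columns must score positively, otherwise
the site is demoted to Unaligned. This encodes the requirement of a
conserved Sec-flank region rather than an incidental U–row match. The
overall class of a call is Sec if any site is Sec, else Cys if any is Cys,
else Other; a pseudogene-flagged locus is never classed Sec.

A Sec call does *not* require a SECIS. The SECIS search runs downstream of
identified genes, and its result sets the confidence tier (`high` for a Sec
call with at least one element, `medium` otherwise). This ordering follows
the discovery procedure the pipeline models, where SECIS searching happens
after homology identification; requiring SECIS would silently convert
detector false negatives into gene false negatives.

## SECIS grammar

Eukaryotic SECIS elements are modelled with an explicit grammar rather than
thermodynamic folding: 5′→3′, a lower helix of at least `helix1_pairs_min`
(4) pairs, the core quartet `AUGA` (DNA `ATGA`), an upper helix of 9–15
pairs with at most 2 non-pairing positions (G·U wobble counts as paired —
standard for RNA stems and material for sensitivity), an apical loop of
3–18 nt containing `AA`, and the 3′ core `GA`. Type-II elements (apical
`CC`) are available by setting `apical_required = "CC"`. Scores are
`pairs − 2·mismatches + 2` (apical bonus). Every candidate coordinate tuple
is enumerated (core occurrences are found allowing self-overlap — `ATGATGA`
hides a core); overlapping parses of one core reduce to the best-scoring
one, while distinct cores are reported separately. The search window
defaults to 3000 nt downstream of the stop codon; the numeric grammar values
follow the canonical eukaryotic SECIS consensus descriptions, as the
original tooling is an online service whose exact patterns are not
re-implementable verbatim. All values are parameters of `secis_grammar()`.

The generator emits elements *from the same grammar object*, so the
round-trip property (every emitted element detected with exact core
coordinates) is a genuine detector test, while the false-positive rate is
measured on dinucleotide-preserving shuffled windows (Altschul–Erikson
shuffle) and asserted under a configured ceiling in the test suite.

## Frameshifts, EST support, pseudogenes

Candidate loci are re-aligned protein-to-DNA with a local DP whose codon
steps may consume 1, 2, 4 or 5 nt instead of 3; every non-3 step is a
frameshift event costing `frameshift_penalty` (−12; tuned so single errors
are detected without fragmenting alignments) with unaligned residues and
extra codons at `fs_gap_penalty` (−8). Genomic TGA translates as `U` here so
Sec genes do not fragment at their own Sec codons. Deletion steps leave a
broken codon of 1–2 nt, scored as the best single-base completion — the
missing base could have been anything, anywhere in the codon. Because
repetitive coding sequence admits co-optimal indel placements, a single
detected event is normalized by full reconstruction: each candidate position
within ±9 nt is repaired (deletions try every fill base), re-translated, and
the position whose repaired protein agrees best with the reference wins
(ties stay at the DP's own placement). This is the protein-level analogue of
indel normalization in variant calling.

A locus is a pseudogene exactly when it carries at least one frameshift
event with no EST support. An EST supports an event when it aligns across
the event at `est_min_identity_frac` (95%) or better *gap-free in the
bridging region* — a gapped bridge means the transcript does not carry the
genomic indel, which is evidence for, not against, pseudogenisation.

Because a frameshift splits a gene into two ORF fragments (the downstream
half reappears in a shifted frame), same-family loci separated by at most
`merge_gap_nt` (1000 nt) are merged before the frameshift scan, and when
events are found the locus is re-delimited by the protein-to-DNA alignment
span. Clean calls are delimited by the genomic span of the aligned query
region rather than the whole open segment, since read-through ORFs extend
into flanking sequence up to the previous in-frame stop.

## Locus collapsing, fusions, motifs

Overlapping ORF variants of one locus (same contig and strand) collapse to
the highest-scoring hit, ties broken by longest ORF then leftmost — the
full read-through variant of a true Sec gene always outscores its
terminate-at-TGA prefix because the alignment is longer. Fusion calls
require two non-overlapping hits from different families on a single ORF,
each at or above `min_hit_score`. The reported Sec-flank motif is the query
substring aligned to the family's canonical motif (with `x` matching any
residue) when one is declared, else the ±2-residue window around the first
Sec column; `U` is retained, so a Cys-homolog of a `UxxC` family shows its
`CxxC` form directly.

`min_hit_score` (60, raw score) has no externally anchored value; it was
chosen once as roughly the score of ~25 well-matching residues under
BLOSUM62, high enough that random 30–50-aa peptides essentially never reach
it and low enough that half of a frameshift-split gene still hits. The
pipeline exposes it, like every threshold here, as a parameter.

## Comparative analytics

*Clusters* are maximal chains of calls (any class) on one contig with
consecutive gaps ≤ `cluster_max_gap_nt` (10 kb), at least two members.

*Duplications* follow the two-stage published rule: same-species,
same-family call pairs whose optimal protein alignment has a positive rate
above 50% proceed to nucleotide comparison of their gene ± 10 kb flank
segments; identity blocks ≥ 80% must cover ≥ 20% of the compared segment.
Positive rate is defined as positively scoring columns over all aligned
columns including gaps — the source procedure never defined its
denominator. The 20% coverage is applied to the *actual* segment length:
the stated absolute threshold (40 kb as 20% of 200 kb) is arithmetically
inconsistent with 10-kb flanks, so the fraction, not the absolute number,
is treated as the rule, and both flank length and fraction are parameters.
Block finding uses exact 20-mer anchors on shared diagonals, merged while
the merged block stays at or above the identity threshold — a deterministic
stand-in for a pairwise BLAST. When two genes sit close enough that their
flank windows overlap on the contig, the shared genomic interval is masked
out of the coverage count: self-identity is not duplication evidence.

*The presence matrix* records per (species, family) the set-union of call
classes — `absent`, `Sec`, `Cys`, `Other` or a combination. Pseudogene
calls never fill a cell. *Double clustering* encodes each cell as three
binary indicators (Sec, Cys, Other) per family, computes binary Jaccard
distances (vegan), with the convention that two all-absent profiles are at
distance 0 and absent-versus-present at 1 (undefined under Jaccard), and
applies average-linkage `hclust`. Rows are sorted by name before
clustering, which together with deterministic distances makes leaf orders
invariant to the order calls were supplied in.

# The synthetic-data generator

`simulate_cohort()` is first-class, tested code, and its defaults *are* the
package's reference study conditions: 5 species × four 500-kb contigs; per
species 30 Sec genes, 20 Cys-homologs, 5 Other-homologs and 5 frameshifted
pseudogenes drawn from 10 families (round-robin over families for the Sec
budget, so every family including the triple-Sec PDI_e is planted); 2
tandem clusters and 2 gene+flank duplications per species; every Sec gene
followed by a canonical SECIS at 50–400 nt; 120 ESTs of 300 nt at 0.5%
error. Planted CDS are noise-free (`mutation_rate = 0`) — the reference
conditions ask for unambiguous classes — while duplication copies diverge
by 0.5% in their flanks, emulating >98%-positive copy pairs; a mutation
that would create an in-frame stop is reverted so a planted class can never
silently change. Genes are intronless by design: the discovery logic under
test is codon-, alignment- and SECIS-level, and exon structure would add
simulation complexity without exercising any of it. Back-translation uses a
fixed one-codon-per-residue table, which keeps truth classes unambiguous
but also means planted genes are *easier* than real genes: there is no
codon usage variation, no paralog interference beyond what is planted, and
no sequencing error in the genome. Passing the end-to-end tests therefore
demonstrates the correctness of the decision logic, not field performance
on real assemblies.

Every truth record is sliced back out of the emitted genome and
re-translated on emission; generation aborts if any planted class fails to
re-derive. Cohort and truth are jointly reproducible from (spec, seed);
genes are planted on the forward strand by default, with
`plant_reverse = TRUE` exercising strand handling.

# Numerical choices and degenerate inputs

- Ties everywhere resolve lexicographically or leftmost (best-hit ties by
  family name then reference id; collapsing ties by length then
  coordinate; clustering by sorted names) so that all outputs are
  reproducible byte-for-byte.
- A region shorter than the minimal SECIS span, an ORF at the contig edge
  with no downstream sequence, an empty genome, or an empty call set all
  return empty, correctly typed tibbles rather than errors.
- A reference database without any `U` triggers a warning and yields only
  homolog classes.
- Packing of planted features is validated up front (features plus
  separation must fit in ~80% of the contigs), and placement failures after
  bounded retries abort rather than emit a malformed cohort.
- Evaluation matches calls to truth by ≥50% reciprocal coordinate overlap
  on the same contig and strand; precision over an empty call class is
  reported as `NA`, not 0.

# Problem sizes in the test suite

The unit suite runs oracle comparisons at small sizes (alignments ≤ 40
residues, contigs ≤ 10 kb, frameshift instances ≤ 15 codons, 100 random
cluster layouts) and the end-to-end checks on a one-species 400-kb cohort.
The acceptance suite and `scripts/acceptance.R` use the full five-species
reference cohort (~2 Mb per species) plus 200 aligner-oracle pairs, 100
SECIS round-trips, 100 shuffled null windows, and 50 single-indel CDSs —
sizes chosen so the complete run finishes in a few minutes on a single CPU
while every component still faces a non-trivial instance.

# Known limitations

- No spliced-gene modelling: real algal genes have introns; EST-to-genome
  support is a simplified identity check, not spliced alignment.
- No E-value statistics: hits are thresholded on raw score, which is
  appropriate for a curated family database but not for open-ended
  homolog discovery against large databases.
- The SECIS model is grammatical, not thermodynamic; elements with
  non-canonical cores or unusual helix geometry will be missed, and the
  grammar is parameterized precisely because the reference tooling's exact
  patterns are not public.
- The duplication stage compares call pairs within a species only, and its
  anchor-based block finder assumes largely collinear segments (no
  inversions within a duplicated block).
- The generator does not attempt to mimic real base composition, codon
  usage, or genome size; measured sensitivities on it are upper bounds for
  real data.
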