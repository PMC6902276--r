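---
title: "Feature-weighted alignment for annotation lift-over: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-weighted alignment for annotation lift-over: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebralift)
```

## The model

`zebralift` aligns a query sequence against a reference gene window whose
bases are labelled with feature classes — start/stop codon, splice site,
CDS, intron, other — and scores every column with class-specific
parameters. The intent is that the cost of placing an edit depends on *what
the reference base does*: a 13-bp deletion costs a handful of points inside
an intron but hundreds across a splice site, so whenever an INDEL has
several sequence-equivalent placements, the optimum is the one that leaves
the coding structure untouched.

The alignment is semi-global: the reference window (start codon to stop
codon) must be covered end to end, while the query — the candidate locus
extended by one gene length on each side — has free overhangs at both ends.
Concretely, the first DP row and column are zero, the traceback starts at
the maximum cell of the last reference column (smallest query row on
ties), and reference columns left of the path start are emitted as free
deletions so the reported alignment always covers the whole window.

### Recurrences and the gap model

Three channels are maintained per cell (query rows $i$, reference columns
$j$, class $c(j)$ of column $j$):

$$E_{i,j} = \max(E_{i,j-1} - G^{ext}_{c(j)},\; H_{i,j-1} - G^{open}_{c(j)})$$
$$F_{i,j} = \max(F_{i-1,j} - G^{ext}_{c(j)},\; H_{i-1,j} - G^{open}_{c(j)})$$
$$M_{i,j} = H_{i-1,j-1} + W_{c(j)}(q_i, d_j), \qquad
  H_{i,j} = \max(E_{i,j}, F_{i,j}, M_{i,j})$$

$E$ is a gap in the query (a deletion: it consumes reference columns and is
charged per consumed column's class), $F$ a gap in the reference (an
insertion: it stays at column $j$ and is charged with the class of the most
recently consumed reference column). Both channels take the better of
extending the current gap run or opening a new one, which makes the DP
exactly the optimum of a path score in which each gap run costs
$G^{open}$ for its first base and $G^{ext}$ for each further base. This
equivalence is what the exhaustive-enumeration tests assert.

An earlier formulation conditions gap extension on the *traceback label* of
the neighbouring cell rather than on the gap channel itself. That greedy
form can miss the run-cost optimum whenever extending a non-argmax gap
state beats re-opening ($H - E < G^{open} - G^{ext}$), so the package
implements the two-channel (Gotoh) form; with a uniform profile it
provably reduces to a textbook semi-global affine aligner, and the test
suite verifies that reduction against an independent full-matrix
implementation.

### Traceback

The traceback matrix stores one byte per cell: the subset of
$\{M, E, F\}$ that attained $H$ — a composite label when several tie — plus
two bits recording whether each gap channel used extension. Traceback is a
deterministic state machine: inside a gap run the extension bit decides
whether the run continues; at an $H$ cell the current move type is kept
when it is among the cell's options, otherwise the precedence is
match > deletion > insertion. The reconstructed path always achieves the
reported score (asserted in tests). Labels follow VCF orientation
(deletion = missing query bases); the composite labels mark genuine ties
and are resolved only during traceback.

### The striped solver

`zsdp_align()` is an equivalence-contracted faster formulation: for each
feature class and reference residue a query profile vector
$W_c(r, q_i)$ over $i$ is precomputed once, columns are evaluated in
batched passes ($M$ and $E$ first, then a sequential lazy-$F$ correction
pass down the column), and scores are stored in 8-bit integers, escalating
to 16 and then 32 bits the moment any value cannot be represented. Each
cell is computed in 32-bit arithmetic before narrowing, so escalation is
deterministic and the results — scores, aligned strings, traceback bytes —
are bitwise identical to the scalar solver at every width. Hardware vector
intrinsics are deliberately not used; the batched-array realization keeps
the code portable and the contract testable.

### Sliding windows

For long sequences `sliding_window_align()` tiles the DP space with
`window_size` × `window_size` blocks. The first block uses the free
semi-global boundaries; the maximum cell on a block's last row or last
column (scanning the last column first, rows ascending) anchors the next
block, whose first row and column are paid gap runs from the anchor.
Runtime is linear in sequence length at fixed window. The heuristic can
miss the global optimum when the true path wanders more than a window away
from the anchored diagonal; a window at least as large as the sequences
reproduces the exact solver (in that case the exact code path is invoked
directly), and gap re-opening at block boundaries slightly over-penalizes
gaps that straddle a block seam. All uses inside the package treat the
window as an accuracy/speed dial with default 1000 bp.

## ORF checking

`check_orf_state()` evaluates seven rules and reports *all* failures:
splice motifs at CDS-internal intron ends, minimum intron length, minimum
CDS length, frame, premature stops, a terminal stop codon, and an ATG
start. Rule order is irrelevant since nothing short-circuits; UTR introns
are ignored because they cannot affect the reading frame. IUPAC ambiguity
is resolved by base-set intersection with deliberately asymmetric
semantics: motif, start and terminal-stop comparisons are permissive (some
resolution matches), while a premature stop requires *every* resolution to
be a stop. The asymmetry errs against false loss-of-function calls — an
`NNN` codon neither proves nor disproves a stop, so it must not kill the
transcript. With a broken frame, codon-level rules are evaluated on the
complete in-frame codons (the trailing partial codon is ignored).

Defaults: `min_intron_length = 5` bp and `min_cds_length = 9` bp (both
strict lower bounds). They admit the smallest biologically sensible
models — a 6-bp intron and a start-codon/residue/stop-codon CDS — and are
overridable everywhere, including the CLI. The default splice-motif set is
GT–AG, GC–AG, AT–AC (shipped as `inst/extdata/splice_sites.txt`).

## Scoring profile defaults

The per-class defaults are, as `(match, mismatch, gap_open, gap_ext)`:
CDS `(6, −6, 26, 2)`; splice sites and start/stop codons
`(30, −30, 110, 110)`; intron and other `(2, −2, 4, 1)`. The specific
numbers are a design choice — what matters, and what the package enforces
(as a warning, since exotic profiles are legitimate for experiments), is
the ordering: coding features are penalized far above intronic sequence,
and splice/codon columns are effectively gap-proof. With these values a
13-bp intronic deletion costs 16 points while the same deletion crossing
an acceptor costs hundreds, which is the margin the ambiguity tests rely
on. `uniform_profile()` collapses all classes for comparison work.

## Coordinate lift-over

Pseudo-genomes are built by left-anchored allele substitution; the shift
index records, per variant, the replaced reference span and where its ALT
allele lands. Base positions lift by the cumulative offset of strictly
upstream variants; a position inside deleted sequence reports the *gap
locus* — the destination coordinate of the first surviving base to the
right, which equals one past the last surviving base on the left — as both
flanks. Feature boundaries use the same monotone prefix-length map, so
start boundaries snap right and exclusive ends snap left ("toward the
feature interior"), lifted features never grow across deleted sequence,
and adjacent features keep tiling — the property the variant-calling and
uniformization round trips depend on. Overlapping variant records are a
hard validation error; multi-allelic VCF sites are split on read and
collapsed to their first ALT before haploid application.

## Pipelines

Resequencing mode lifts by shift counting, ORF-checks every transcript
against the pseudo-genome, and realigns only the broken ones (the ORF
check is the trigger; intact transcripts never pay for a realignment).
Realignment that fails to rescue leaves the standard model in place and
the transcript reported lost — a conservative choice, since an
unrescuable ORF is as likely an assembly or variant-calling artifact as a
real loss. Variant rewriting (`rewrite_variants()`) replaces a rescued
transcript's window records with the re-called ones only after verifying
byte-identity of the implied pseudo-genome; otherwise the old records are
kept. Minus-strand transcripts are aligned in forward genomic orientation
— the feature track is positional, so this is equivalent to aligning the
reverse-complemented strand up to tie-breaking — and ORF checks remain
strand-aware.

Assembly mode consumes coarse range pairs (the seven-column interchange
format; produced upstream by any whole-genome aligner), aligns each pair
with the sliding-window aligner, projects contained transcripts through
the alignment columns, and falls back to zebraic realignment exactly as in
resequencing mode. Transcripts contained in no range pair are `UNPLACED`.
The cascade below realignment (orthologue search, ab initio annotation,
transcript assembly) is an interface only: `integrate_external_models()`
merges externally produced candidate models by priority, replacing a
lifted model only when it is broken and the candidate is intact. No
external annotation tool is bundled or invoked.

Variant calling anchors the genome-wide alignment on gene order: the two
per-chromosome gene-ID sequences are globally aligned
(Needleman–Wunsch, +1 match on identical IDs, −1 mismatch, −1 gap — the
values are this package's choice; only the match criterion is inherent),
matched genes' span boundaries split both genomes into paired fragments,
and each fragment is aligned and walked for records. Non-colinear matches
are dropped rather than modelled, so relocations surface as paired
DEL+INS records — the calls stay complete and the query genome is
reconstructible byte-exactly, which is the module's central contract.
Within one chromosome all fragment alignments are concatenated and walked
once, so records can never overlap; the one residual collision (a
right-anchored run at the chromosome start followed by a run left-anchored
on the same base) is fused into a single record.

## Variant uniformization

The reference is partitioned at feature boundaries into CDS, intron and
intergenic elements; each element is multiple-aligned across accessions
and every accession's records are re-derived from its row. The MSA core is
reference-centred star alignment: each accession is aligned pairwise
against the reference element (directly when it fits in one window,
through the anchored sliding-window aligner otherwise) and the pairwise
alignments are merged on reference slots. The choice keeps reference
coordinates primary, is deterministic, and makes the convergence property
structural — identical element sequences produce identical pairwise
alignments, hence identical records. A seam-resolving overlapping-window
MSA was considered for long elements and rejected: with a star core every
row reduces to a pairwise problem the anchored window driver already
solves seam-free.

One subtlety is where an accession's element interval comes from. Lifting
element boundaries through the accession's shift index would make the
spans depend on the very record representations uniformization exists to
erase — two encodings of one haplotype would partition differently and
diverge. Spans are therefore projected through a deterministic
chromosome-scale zebraic alignment of each pseudo-genome against the
reference, which depends only on sequence content. Applying each
accession's uniformized records reproduces its pseudo-genome byte-exactly
because elements tile both sequences.

## The synthetic-data generator

All tests run on generated data. `generate_genome_with_annotation()` lays
out genes with GC≈0.5 intergenic spacers; CDS codons are drawn from the 61
non-stop codons between a forced ATG and stop, introns are GT…AG with
lengths above the ORF minimum, strands are mixed, and every generated
transcript is verified ORF-intact before the fixture is returned.
`plant_variants()` adds non-overlapping, non-adjacent SNPs and short
INDELs with a ground-truth record set. `plant_ambiguous_indel_locus()`
rewrites the 39 bp across a splice acceptor junction into three copies of
a 13-mer chosen so that no reading frame across the junction can form a
stop codon; a 13-bp deletion in that region then has several equal-cost
placements under uniform scoring, exactly one class of which preserves the
motif — the canonical tandem-repeat cause of INDEL placement ambiguity.

The generator emulates gene structure, not population genetics: there is
no coalescent, no recombination, no sequencing error, no repeat content
beyond the engineered loci, and intergenic sequence is i.i.d. Passing
tests therefore demonstrate algorithmic correctness (score optimality,
equivalences, round-trip exactness, representation convergence) — not
calibrated performance on real genomes, where repeat structure and
assembly artifacts add failure modes the fixtures do not model.

Determinism: every fixture operation seeds the RNG locally
(`withr::with_seed`), so regeneration is byte-identical and the global RNG
state is untouched.

## Numerical and degenerate-input choices

* All scores are integers; there are no floating-point tolerances anywhere
  in the aligner.
* Tie-breaks are fixed: smallest query row at the traceback start,
  prefer-continue then match > deletion > insertion during traceback,
  extension preferred on gap-cost ties, last column before last row when
  anchoring sliding blocks.
* Empty reference or query is a contract error for the aligners; an empty
  variant set, an empty annotation, and zero-length fragments are all
  legal and handled as identities.
* A query region the alignment cannot cover yields an `UNPLACED` outcome,
  never an exception, inside the pipelines.
* Width escalation bounds: a stored score outside the representable range
  of the current integer width triggers a clean rerun one width up;
  results are identical across widths by construction.

## Problem sizes used by the test and acceptance suites

The suites are sized for a single CPU: path-enumeration oracles run on
sequences up to 8 bp (about 200 cases), solver equivalences on hundreds of
pairs of 50–300 bp, window exactness on 10-kb sequences at window 1000,
splice-preservation on ~100 engineered loci, reconstruction round trips on
genomes of 10–100 kb with 5–50 genes, and uniformization on small
multi-accession populations. These sizes exercise every code path,
including width escalation and multi-block windows, while keeping a full
run in minutes.

## Known limitations

* The sliding-window heuristic can misplace edits when the optimal path
  drifts more than a window off-diagonal; all callers expose the window
  size.
* Gene models are assumed single-ORF and standard-code; selenocysteine
  recoding and polycistronic models are out of scope.
* Pseudo-genomes are haploid (first ALT at multi-allelic sites); phasing
  and genotype-aware allele selection are out of scope.
* Assembly-mode projection trusts the coarse range pairs; genes absent
  from them are reported unplaced, and inversions inside a same-strand
  range pair are not modelled.
* Variant calling decomposes structural variation into SNP/INDEL records;
  it never classifies rearrangements.
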