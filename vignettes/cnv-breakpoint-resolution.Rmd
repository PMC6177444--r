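---
title: "Resolving intragenic CNV breakpoints to the base pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving intragenic CNV breakpoints to the base pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamacnv)
```

## The problem

Exon-level dosage assays (MLPA, array CGH, read-depth callers) tell you
*which exons* a deletion or duplication covers, but not where it begins and
ends. For a recessive disease gene such as *LAMA2* — 65 exons spread over a
~650-kb region, where intragenic deletions account for roughly a fifth of
pathogenic alleles — base-pair breakpoints carry real information: the exact
event length and reading-frame consequence, the junction sequence that
betrays the repair mechanism, and coordinate-level identity that exposes
founder alleles recurring across unrelated families (dosage assays cannot
distinguish two different deletions of the same exon).

`lamacnv` implements the composite strategy used in targeted-capture studies
of such genes: a read-depth screen against a control sample for approximate
events, split-read (soft-clip) analysis for exact junctions, sequence-level
junction characterization, and rule-based mechanism classification, topped
by cohort-level spectrum statistics. Because no patient sequencing data can
be shipped, a synthetic-data module generates the statistical structure the
pipeline assumes, and the cohort statistics run on curated plain-text tables
transcribed from a published Chinese *LAMA2* muscular dystrophy cohort
(96 genetically diagnosed subjects; 29 CNV probands; the transcription
keeps the published per-row values, including two rows whose printed
lengths disagree with their printed coordinates by a few base pairs — the
curator notes flag them, and coordinate-derived lengths are used wherever
arithmetic is needed).

## Coordinates

Everything internal is 0-based half-open, so `length = end - start` with no
off-by-one cases. Published breakpoint tables in this field print 1-based
position pairs whose difference equals the printed length; that dialect maps
onto the internal convention with the printed numbers unchanged (verified on
the fixture rows where length and coordinates are mutually consistent), and
`region_from_published()` makes the conversion explicit.

## The depth screen and its windows

Counts are reads whose first aligned base falls in a window; windows are
exons padded by 50 bp plus 500-bp intronic tiles, so a breakpoint landing in
a long intron still bounds a search window. Ratios use **median-of-ratios
normalization**: per-window test/control ratios divided by their median
across windows. The more obvious total-count normalization is biased in this
single-region setting — deleting x % of the target removes x % of the test
library, inflating every copy-neutral window's ratio by 1/(1−x), enough to
push neutral windows over the 1.25 duplication threshold once events reach a
few percent of the region. The median is taken over all windows and is
robust as long as under half the region is copy-altered. Total-count
normalization remains available (`normalization = "total"`).

Thresholds are the field-standard 0.75 (deletion) and 1.25 (duplication).
Zygosity bands on the mean event ratio — hom-del below 0.1, het-del within
[0.3, 0.7] — are operational estimates, never assertions; everything else is
`unknown`. With ~200–500-bp windows at 100×, individual windows have
counting noise of 5–15 %, so isolated windows occasionally cross a
threshold; such one-window approximate calls are expected screening noise,
and only events corroborated by split reads become base-precise.

## Split-read resolution

Soft clips of ≥20 bp are clustered by side and boundary (±5 bp jitter,
≥3 supporting reads — conservative split-read-caller defaults, all
configurable). The consensus contig is a per-column majority vote (ties:
highest count, then lexicographic) over reads sharing the modal boundary;
reads whose boundary was dragged a few bases by a sequencing error near the
junction still count as support but are excluded from the vote, keeping the
consensus clean at per-base error rates around 10⁻³.

The clipped consensus is remapped by exact 20-mer seeds grouped into
diagonals; each diagonal's match vector is cut at runs of ≥3 consecutive
mismatches and the block containing the seed must reach ≥95 % identity over
≥20 bp. A unique best block (score margin ≥5 over any other diagonal)
defines the partner breakpoint; ties leave the cluster unresolved — the
deliberate behaviour at repeat-mediated junctions, where unique placement is
genuinely impossible and wet-lab follow-up is the honest answer. Bases
between the junction and the matched block are carried forward as putative
inserted sequence.

Deletion-type candidates have their partner downstream of a right-side clip
(or upstream of a left-side clip); the reverse orientation is a head-to-tail
tandem-duplication junction. The two per-event candidates (one per junction
side, placements differing by up to the microhomology length) collapse to
one, and a cluster at the partner position whose clip maps back confirms the
event reciprocally.

Reconciliation with the depth screen: a candidate whose breakpoints fall in
a depth call's search windows upgrades that call to `base_precise`;
candidates without depth support become calls flagged `depth_unsupported`
(how a 56-bp intra-exonic deletion — invisible to exon-level dosage — is
still recovered exactly); depth calls without candidates stay approximate,
as happens when a breakpoint falls in unsequenced territory. Two
base-precise deletions separated by a retained segment of ≤5 kb are flagged
as one complex DEL-NML-DEL event (the retained segment in the motivating
complex case is ~300 bp; 5 kb keeps clearly independent events apart).

## Junction characterization

With the contig anchored to the reference at both ends, the maximal prefix
matching the left flank (ending at P) and maximal suffix matching the right
flank (starting at S) decide the signature: overlap (P ≥ S) is
**microhomology** `contig[S..P]`; exact abutment is **blunt**; a gap is an
**insertion**. Flank boundaries are the ends of perfect-match runs of
≥10 bp, chosen outermost-first subject to ≥95 % cumulative flank identity —
this tolerates isolated flank errors without letting a chance match beyond
the junction drag the boundary outward. The signature itself remains a
maximal *exact* match, the standard definition; a substitution landing
inside the few bases of true microhomology would truncate it, a known
limitation shared with any exact-match definition.

Microhomology makes the breakpoint placement ambiguous within its length;
reported coordinates are **left-aligned** (the leftmost equivalent
placement), with the shared sequence recorded. A single shared base counts
as microhomology, not blunt — following how published junction tables
treat 1-bp shares.

Insertions shorter than 5 bp are classified random without a search (the
published convention for "random nucleotides"); longer ones are searched at
≥90 % identity within ±2 kb of either breakpoint and then across the whole
region — a hit makes them templated, the serial-replication-stalling
signature. Near-breakpoint substitutions are read directly off the
contig/reference comparison within 150 bp of the junction (substitutions
only; the simulator plants no indel errors) and can be filtered against a
user-supplied polymorphism list, standing in for a population-database
absence check. Repeat annotation intersects breakpoints with a
RepeatMasker-style track; when both ends sit in same-class repeats, the two
copies are locally aligned (`Biostrings::pairwiseAlignment`) and an identity
block of ≥100 bp at ≥95 % sets the homologous-pair (NAHR-like) flag — the
published analysis reports one such pair with a 471-bp identity block but
states no threshold, so 100 bp/95 % is a configurable package choice.

Mechanism rules, in priority order: homologous repeat pair →
`repeat_mediated_rearrangement`; complex DEL-NML-DEL → `FoSTeS_MMBIR`;
templated insertion → `serial_replication_stalling`; random insertion or
blunt → `NHEJ`; microhomology → `NHEJ_or_MMBIR`. The function is pure and
deterministic, so identical records always classify identically. The
distinction between serial replication stalling (simple event, templated
insertion) and FoSTeS/MMBIR (multi-segment event) reflects the two
attributions the source analysis makes; both are stated there as inferences,
which is why the rules live in one small function a user can replace.

## The cohort tables and their statistics

Three tables drive the spectrum statistics: per-junction breakpoints and
signatures, per-proband exon spans/frame/zygosity, and per-subject allele
pairs. Deduplication collapses records by canonical coordinates and type; a
1-kb size floor excludes the 56-bp event from the CNV tally (it is retained
as a small variant — the source cohort itself treats that carrier as
"without CNVs" while still counting the allele, a tension the fixture notes
rather than hides). The unresolved event with only one mapped breakpoint
counts as distinct via its resolved end. Founder candidates require
identical coordinates *and* identical junction signature across at least
two families — the computational proxy for haplotype sharing, since
identity-by-descent predicts both. All percentages recompute from integer
counts at call time.

Two published summary numbers are deliberately *not* reproduced: the
cohort's mean/median CNV size, which cannot be regenerated from the printed
per-row lengths under any inclusion rule tried (per-allele, per-proband,
per-distinct), and the repeat-overlap rate, which depends on a real
RepeatMasker annotation not shippable here. The report computes mean/median
descriptively and counts repeat overlap only against the shipped *synthetic*
track, constructed so that 11 of the 27 resolved events have a repeat at a
junction end. The five affected relatives' family memberships are likewise
unpublished; the fixture places them in five non-founder families and flags
the placement as synthetic in its curator notes.

The domain map ships as N-terminal = exons 1–30 and G domain = exons 46–63,
the two explicitly stated ranges; exons 31–45 and 64–65 are unassigned
(the source quotes a 3′ hotspot at "exons 56 to 65" elsewhere, but the
explicit G-domain statement wins; the map is user-overridable). The
N-terminal cohort tally uses strict containment within exons 1–30, which is
the counting rule under which the published 20/28 reproduces; per-domain
intersection counts are also reported.

## What the simulator emulates — and what it does not

`make_reference()` draws i.i.d. bases at a target GC (default 0.42,
human-like). `apply_cnv()` first *edits* the reference so each junction
carries exactly the requested signature — for microhomology `m` of length
k, both breakpoint-proximal k-mers are set to `m` and the bases just outside
are made unequal, so `m` is the maximal share; analogous caps make blunt and
insertion junctions exact — then builds the mutant haplotype(s) and records
ground truth (junctions, haplotype block map). `simulate_reads()` draws
fragments uniformly (normal length 400±60, reads 150 bp, substitution errors
at 10⁻³, Poisson pair counts at the requested depth, het haplotypes sampled
50/50). `align_reads()` places reads from known provenance and then extends
the mapped segment maximally against the reference — reproducing the
aligner behaviour that shifts clip boundaries across junction microhomology
— with a 20-bp minimum anchor; a real aligner remains usable through SAM
input (`read_alignments()`).

Not modelled: capture/GC bias, PCR duplicates, indel sequencing errors,
quality-score variation, alignment artefacts in low-complexity sequence.
Passing recovery tests therefore demonstrates the *logic* of the pipeline —
exact breakpoint arithmetic, signature detection, mechanism rules, the
depth/split-read division of labour — not robustness to every artefact of
real capture data. Default simulated depth is 100× (a typical capture
working depth; the source study does not state its achieved depth), and
recovery properties are exercised down to 60×.

## Problem sizes and numerical choices

The test and acceptance runs use 15–50-kb references at 60–100×
(thousands to tens of thousands of read pairs), sizes at which the full
suite completes in about a minute while every detection statistic retains
comfortable margins (a 3-kb deletion at 100× yields ~40 clipped reads per
junction against a min-support of 3). Determinism: every stochastic step
takes an explicit seed; consensus ties break by count then lexicographic
order; candidate collapsing keeps the leftmost placement; degenerate inputs
(empty clip sets, zero-control windows, unmappable tails) return typed empty
results or flagged records rather than errors, while genuinely invalid
inputs (inverted thresholds, overlapping exons, out-of-range segments) fail
loudly with the offending value named.

## Known limitations

Inversions and inter-chromosomal events are out of scope (orientation
handling covers deletion-type and tandem-duplication junctions only).
Events extending beyond the sequenced target can only be reported
one-sided. Near-breakpoint error scanning reports substitutions, not
micro-indels. The homologous-repeat-pair check aligns the first
same-class repeat pair only. Founder grouping is a coordinate/signature
proxy — definitive founder status needs haplotype data.
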