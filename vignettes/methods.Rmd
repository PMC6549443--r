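---
title: "How quantnet evaluates assemblies and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How quantnet evaluates assemblies and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(quantnet)
```

## The problem

A *de novo* transcriptome assembly is an imperfect stand-in for the true
transcript set, and quantifiers estimate abundance on whatever sequences
they are given. Two failure modes dominate. *Completeness* errors —
contigs that recover only part of a transcript or carry extraneous
sequence — change the effective length that TPM normalizes by.
*Ambiguity* errors — one contig standing in for a gene family, or several
near-identical contigs for one transcript — confuse the read-assignment
step of every quantifier. quantnet measures both, given the assembly, the
reference transcripts, their BLASTn alignments, and quantifier output.

## From local alignments to global ones

BLASTn reports local alignments (HSPs). We keep HSPs with identity
strictly above 70% and E-value strictly below 1e-5, then merge all HSPs
of a contig–transcript pair by projecting them onto the coordinates of
each sequence and taking the union of the covered intervals. Recovery is
the covered fraction of the transcript, accuracy the covered fraction of
the contig, and the alignment score their geometric mean. Coverage counts
each base once: no gap penalties, no colinearity requirement, and HSPs
from both strands enter one union (a mixed-strand pair raises a warning).
The union is computed by sorted interval merging and is checked in the
test suite against a per-base boolean-array oracle on random instances.

Measuring "matched nucleotides" as plain coverage rather than
identity-weighted coverage is a deliberate choice: the retained HSPs have
already passed the 70% identity gate, and the 12-column BLAST dialect
carries no per-base identity map. `merge_global(identity_weighted =
TRUE)` provides the weighted alternative (per-HSP coverage scaled by
identity, overlaps resolved by the higher identity) for users who want
it.

A transcript is assigned to a contig when recovery **or** accuracy
reaches 0.9. The boundary is inclusive (≥ 0.9): the category definitions
are phrased as "recovery ≥ 90" throughout, and an inclusive gate keeps
the assignment rule and the category gates consistent. Both the
threshold and the strictness are arguments.

## Ambiguity networks

Sequence ambiguity is represented as connected components over the contig
set and over the transcript set. Two sequences join one component when
the number of identical nucleotides between them exceeds 90% of either
sequence's length — strictly greater, reading "over 90%" literally. The
identical-nucleotide count is estimated from the self-alignment HSPs as
identity-weighted coverage (per-HSP span × identity, overlaps resolved by
the higher identity), because the tabular dialect gives identity only per
HSP. A `join_metric = "alignment-length"` option uses plain aligned
length instead, matching the looser phrasing sometimes used for this
rule. Self-hits are ignored and symmetric duplicate rows are collapsed
before the union-find closure, which is order-invariant by construction
(union by minimum root). Components partition the sequence set; members
of singleton components are *unique sequences*.

## Contig categories

Each contig gets exactly one label, decided in this order:

1. **unassigned** — no transcript passes the assignment rule.
2. **family-collapse** — at least two assigned transcripts and every
   assigned alignment has accuracy ≥ 0.9. The accuracy gate (rather than
   recovery) is intentional: a collapsed contig is *accurate* — each
   family member covers essentially the whole contig — but cannot be
   fully recovered by any single member once the family diverges.
3. **duplication** — the contig's ambiguity component has ≥ 2 members,
   the contig has exactly one assigned transcript with recovery ≥ 0.9,
   and at least one other member of the same component is assigned that
   same transcript. Duplication is gated on recovery because each
   duplicate recovers the transcript. Contigs assigned the same
   transcript but sitting in different components are *not* duplication;
   they fall through to `ambiguous-other`.
4. **full-length / incompleteness / over-extension** — unique contigs
   with exactly one assigned transcript, split on the 0.9 gate:
   both ≥ 0.9 / accuracy only / recovery only.
5. **ambiguous-other** — everything else.

Collapse is tested before duplication: a contig satisfying both is
primarily a collapse, since multiple assigned transcripts dominate its
interpretation. The detailed published definitions of these categories
live in supplementary material that is not machine-readable; the
procedure above is a reconstruction from the category descriptions and
the network depictions, and both the order and the gates are exposed as
arguments rather than hard-coded.

Completeness is profiled by binning the percentage difference in length,
`(l_c − l_t)/(l_c + l_t) × 100`, into 10-point lower-inclusive bins
labeled by their lower bound (so −10 means [−10, 0)).

## Quantification metrics

Ground-truth TPM is computed from simulated read counts `f_i` and
effective lengths `l_i = max(length − mean_fragment + 1, 1)` as
`(f_i/l_i)/Σ_k(f_k/l_k) × 10^6`; the default mean fragment length is
200 nt, a typical paired-end insert size, and is configurable. Without
simulation truth, the per-transcript mean TPM across the supplied
quantifier tables serves as ground truth (`experimental-average-truth`
mode).

The relative error `(est − gt)/(est + gt) × 100` is symmetric, bounded in
[−100, 100], and defined as 0 when both terms are 0: an unexpressed,
unestimated sequence is a correct call, not a degenerate one. RPEA — a
contig's share of the reads allocated within its component — is set to
`1/n` uniformly in a component with zero allocated reads, preserving the
sum-to-one property without a special case downstream. Max-RPEA values
are binned at width 0.05, lower-inclusive, with exact 1.0 kept in the top
bin.

Family-collapse contigs are scored against three candidate references
(best-aligned transcript, highest-expressed transcript, transcript-
component total); duplicated contigs likewise (best-aligned contig,
most-read contig, contig-component total). For component-level
quantification we build *super-components*: connected components of the
union graph with contig–contig, transcript–transcript and assignment
edges. The published analysis does not state how the two networks are
linked for this comparison; the union graph is the most conservative
choice — any chain of ambiguity or assignment merges the sequences — and
only super-components containing at least one assignment are scored.

## What the synthetic generator emulates

`make_fixture_world()` builds a transcriptome of gene families (founder
sequences point-mutated at 2% per base), corrupts it into a contig set
with every category planted, writes analytically exact BLAST tables, and
emulates a quantifier. Defaults: 115 genes (87 singletons, 28 families of
2–3), lengths uniform in 1000–2500 nt, log-normal read counts
(meanlog = log 300, sdlog = 1). These sizes keep the full test suite and
the acceptance script to a few seconds per world while leaving ≥ 20
contigs in every planted category.

Choices worth knowing:

* **Substitutions only.** Family members and duplicated copies keep the
  founder's length. This is what makes the allocation model *exactly*
  TPM-lossless on length-preserving corruption plans: pooled read
  density is conserved term by term, so a collapse contig's TPM equals
  its family's summed TPM to floating-point precision. Truncation and
  extension deliberately break this, which is the point of the
  completeness analyses.
* **Planted fractions avoid the gates.** Truncations keep 55–85% of the
  transcript and extensions append 15–60%: a 10% extension would leave
  accuracy at 1/1.1 ≈ 0.909, *above* the 0.9 gate, and the planted
  "over-extension" would be a correct full-length call. The generator's
  job is to plant unambiguous instances, so its ranges stay clear of the
  boundaries.
* **Analytic HSPs.** Alignment coordinates follow from the known edit
  provenance and identity is measured from the actual sequences, so the
  BLAST tables are exact by construction and no aligner is needed.
  Uniform base composition is used throughout; composition is immaterial
  to coordinate arithmetic.
* **Read allocation.** Each transcript's reads are pooled into the
  ambiguity component of its best-aligned contig (ties broken by id), so
  reads are conserved; the component pool is then split winner-take-all
  (the empirically common behavior), evenly, or by random Dirichlet
  shares. Contig TPM is recomputed from the allocated counts over contig
  effective lengths.

What the generator does **not** emulate: sequencing errors and read-level
noise, fragment and positional bias, chimeric contigs, strand errors,
isoform structure (alternative splicing), indel divergence within
families, and expression-dependent assembly failure. Passing tests on
these worlds therefore validate the *metrics and their bookkeeping* — not
robustness of BLASTn, assemblers or quantifiers on real reads. On real
data, alignment noise makes boundary cases (contigs near the 0.9 gates,
pairs near the 90% join rule) sensitive to aligner parameters in a way
the fixtures cannot show.

## Numerical and degenerate-input conventions

* "over 500 nucleotides" is read strictly (> 500) for the contig length
  filter, with an `inclusive` flag; the same literal reading gives the
  strict joins (> 90%) and the strict HSP filter (> 70%, < 1e-5).
* Merging an empty HSP set is an error, not a zero-coverage alignment.
* Minus-strand subject coordinates are normalized to forward orientation
  at parse time and the strand is kept as a flag; normalization is
  idempotent and round-trips through the writer.
* `n_identical` is derived as `round(pident/100 × length)` since the
  12-column dialect lacks an identical-bases column.
* TPM normalization refuses an all-zero input rather than returning NaN.
* Report rows are sorted by id and numbers written with fixed formats, so
  identical configurations reproduce the report bundle byte for byte.

## Limitations

The category reconstruction, the accuracy-vs-recovery gating of collapse
and duplication, and the union-graph super-components are documented
design choices where the published description is incomplete; all are
parameterized. Identity weighting of coverage is available but off by
default. The evaluation assumes one reference transcript set; it does not
model genome polyploidy, and it evaluates quantifiers only through their
output tables, never by re-running them.
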