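---
title: "Benchmarking long-read structural variant callsets with lrsvbench"
author: "lrsvbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking long-read structural variant callsets with lrsvbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrsvbench)
```

## The problem

Structural variants (SVs) — deletions, insertions, inversions, duplications
and translocations of at least 50 bp — are called from long-read data by
many tools, and two callers rarely report the same event with identical
breakpoints, size or allele sequence. Comparing a callset against a truth
set therefore cannot demand exact identity; instead two records are deemed
the same SV when their differences fall inside a tolerance envelope.
`lrsvbench` implements that envelope, the bookkeeping around it (one-to-one
assignment, genotype-aware metrics, grid searches, multi-caller
concordance), the evaluation rules specific to translocations, inversions,
duplications and somatic SVs, an orthogonal validation route that re-aligns
candidate SVs against an alternative assembly, and a seeded synthetic-data
generator so every stage can be exercised without sequencing data or
external callers.

## The matching model

A truth record and a call match under the tolerance quadruple
$(p, P, O, r)$ iff all applicable conditions hold:

* equal SV type (cross-type matches are never allowed);
* **size similarity** $\min(\ell_1,\ell_2)/\max(\ell_1,\ell_2) \ge P$;
* **reference distance** $\le r$, where the distance is
  $|\Delta\text{start}|$ for insertions and
  $\max(|\Delta\text{start}|, |\Delta\text{end}|)$ for deletion-class
  records — the same quantity reported as the *breakpoint shift* of a true
  positive;
* **reciprocal overlap** $\ge O$, defined as overlap length over the longer
  interval and applied to deletions only (an insertion occupies a point on
  the reference, so overlap is meaningless for it);
* **sequence similarity** $\ge p$ when $p > 0$, where similarity is
  $1 - d_\mathrm{Lev}/\max(|s_1|,|s_2|)$ on the comparison sequences.
  Setting $p = 0$ disables the sequence comparison entirely, which matters
  in practice because several callers emit no insertion allele sequence.

All comparisons are inclusive ($\ge$ for similarities, $\le$ for
distances). Two presets are provided: *moderate*
$(p=0, P=0.5, O=0, r=500)$ — the fixed setting used for headline
comparisons — and *strict* $(p=1, P=1, O=1, r=0)$, the exact-match limit.

**Comparison sequences.** The natural allele sequence is the inserted ALT
for insertions. Deletion calls usually carry a symbolic ALT, so the package
uses the deleted reference segment as the deletion's comparison sequence.
Inversions and duplications have no comparison sequence; under $p > 0$ such
pairs fail with reason `no_sequence`, which is why sequence-aware
evaluation is a deletion/insertion affair.

**Assignment.** Candidate pairs passing the predicate are assigned
one-to-one greedily: best sequence similarity first (where applicable),
then best size similarity, then smallest reference distance, with record
ids as the final tie-break. This is deterministic and, whenever truth
records are spaced more than $2r$ apart (so no call has two candidate
truth records), provably attains the maximum matching; the test suite
verifies this against an exhaustive matching oracle on random small
instances. The genotype-concordant subset TP\_GT keeps the same
denominators as TP in the gt metrics, so a genotype-discordant TP degrades
genotyping accuracy without being demoted to a false positive — which is
why gt-F1 can never exceed overall F1.

**Grid search.** `gridSearch()` sweeps any combination of the four axes
(default: $p \times O$ from 0 to 1 in steps of 0.1 at $P=0.5$, $r=500$,
121 points; an insertion-oriented $p \times r$ sweep uses $r$ from 0 to
1000 bp in 100 bp steps). Per-pair measurements are computed once and
cached; only thresholding and assignment are redone per grid point, which
makes the full sweep linear in the candidate count.

## Multi-caller concordance

`iterativeMerge()` reproduces the iterative merge-with-provenance scheme:
the first callset seeds the merge; every subsequent callset is assigned
against the current merge under the moderate preset; matched merge records
keep their coordinates (first-seen representative) and append the new
caller to their source-caller (SC) field; unmatched records from either
side stay in the pool. The procedure is order-dependent, and no canonical
order exists; determinism is achieved by using and recording the
user-supplied order. `supportCounts()` then classifies each merged record
against the truth set and tabulates support (|SC|) per caller and per
TP/FP category, with unmatched truth records counted as FN.

## Complex SVs

Translocations are evaluated at the breakend level. A reciprocal
translocation between $(A, p_A)$ and $(B, p_B)$ contributes four breakend
signatures — the two derivative-chromosome junctions, each recorded from
both partners' perspectives. The strand assignment of the four signatures
is an internal convention: the count (4 per event) is what matters, and
truth and calls agree by construction because both pass through the same
expansion or the same bracket-ALT parser (`t[p[` → (+,+), `t]p]` → (+,−),
`[p[t` → (−,+), `]p]t` → (−,−); any fixed bijection works). A call
breakend is TP iff both chromosomes, both strands, and both positions
(within 1 kb, inclusive) agree with an unconsumed truth breakend.

Inversions and duplications are matched on
$(\text{chrom}, \text{start}, \text{end}, \text{size}, \text{GT})$:
both endpoints within 500 bp and size similarity at least 0.5; a TP with
matching het/hom genotype is additionally TP\_GT.

## Somatic SVs

Tumor and normal callsets are first split into a TRA partition and five
size windows by svlen — 50–100, 101–500, 501–1000, 1001–30000 and
\>30000 bp, inclusive bounds. Each window pair is merged by single-linkage
clustering with the window's lower bound as breakpoint-distance threshold
(50 bp in the smallest window), mirroring the external merge tool the
procedure replaces; the clustering semantics (type agreement, distance
threshold, no genotype requirement) are implemented in-package rather than
shelled out. The TRA threshold is not pinned down by the published
procedure; the package defaults to 1000 bp and makes it a parameter.
Breakend clustering additionally requires strand agreement: the two
strand-paired signatures of one reciprocal junction share coordinates, and
ignoring strands would collapse them within a single callset. Records
supported by the tumor but not the normal set are the somatic callset.
Evaluation against a somatic truth set is per type — TRA: breakend shift
$\le$ 1 kb; others: shift $\le$ 500 bp and size similarity $\ge 0.5$ —
with recall and precision reported separately because somatic truth sets
are typically incomplete.

## Orthogonal validation

For a candidate deletion or insertion, a *pseudo-read* is built from the
source reference: 10 kb of flank on each side, with the inserted sequence
in between (insertions, length $20\,\mathrm{kb} + \ell$) or with the
deleted segment excised (deletions, exactly 20 kb). The pseudo-read is
aligned to an orthogonal assembly, and the alignment is scored on the
*segment of interest* — read positions 9900 to $10100 + \ell$ for
insertions and 9900 to 10100 for deletions (the SV plus 100 bp of context):

* $M = N_\text{matching}/N_\text{seg} \times 100$, counting `=` CIGAR
  operations (bare `M` counts as match, with a flagged caveat, since
  without per-base annotation match/mismatch cannot be split);
* $D = \sum_i \mathrm{CDL}_i / \ell \times 100$, summing deletion-CIGAR
  lengths whose read-side anchor (the read base immediately before the
  deletion) lies in the segment;
* $B$, the base shift: the absolute difference between the target
  coordinate reached after consuming the 10 kb left flank and the
  candidate's source position, set to $\infty$ for unmapped reads or
  cross-chromosome alignments. The left-flank projection is the package's
  choice of breakpoint projection; any monotone CIGAR-walk projection
  gives the same support decisions at the 10 Mb scale of the threshold.

A candidate is *supported* iff $M > 95$, $D < 5$ and $B < 10\,\mathrm{Mb}$
(strict inequalities). The assembly-graph mode (for targets that are not
chromosome-level assemblies) skips the chromosome and $B$ checks, so its
supported set is always a superset of the chromosome-level mode's.
Alignment production is decoupled from scoring: the scorer consumes
SAM-semantics records from any mapper, or analytically constructed ones
from the generator, so the module is testable without an aligner binary.
Only primary alignments are scored; records without a primary alignment
are excluded from the supported-fraction denominator and counted.

## The synthetic-data generator

The generator emulates a full evaluation scenario end to end: an i.i.d. random
reference (default 2 chromosomes of 1 Mb; at least ~24 kb of end margin is
reserved so every placed SV admits 10 kb pseudo-read flanks), a truth set
with per-type counts, log-uniform sizes on [50, 1000] bp, a minimum
inter-SV spacing of 2 kb, per-chromosome genotypes (a chromosome is
homozygous with probability 0.5, making all its SVs 1/1, otherwise 0/1),
and reciprocal translocation events expanded to four breakends each. The
default complex-SV counts are scaled down (20 TRA, 40 DUP, 20 INV per run)
from the 380 translocations, 3712 duplications and 44 inversions of the
public dbVar-derived truth sets this emulates, and the full counts remain
reachable through the configuration; test and acceptance runs restore the
full 380 where the count itself is the quantity under test.

A caller-like callset is derived from the truth by dropping records with
probability `fn_rate`, jittering breakpoints, corrupting comparison
sequences, flipping genotypes with probability `gt_error_rate`, and
fabricating false positives at `fp_rate` on unoccupied loci (defaults
0.05 each, a mid-range error profile for long-read callers). Two modeling
choices are deliberate:

* **Jitter** draws one magnitude per record uniformly from
  $\{0,\dots,\texttt{max\_shift}\}$ (default 50 bp), a random sign, and
  applies it to both endpoints, preserving SV size. The measured
  breakpoint shift of a TP then equals the drawn magnitude exactly, so the
  jitter distribution is recoverable from the shift histogram (mean 25 for
  `max_shift = 50`) — a calibration property the suite tests at three
  standard errors over 600 TPs.
* **Corruption** is substitution-only (each base flips to a different base
  with probability `corruption_rate`), so the expected sequence similarity
  of a corrupted allele is $1 - \text{rate}$ up to the small downward bias
  of edit distance under chance realignments; at rate 0.25 on length-100
  alleles the suite verifies a mean of 0.75 within three standard errors
  over 500 pairs.

The spacing constraint (`min_spacing` > 2 × `max_shift`) guarantees that a
jittered call can only be attributed to its generating truth record, which
is what makes the greedy-equals-optimal property hold by construction on
generated data. Diploid genomes follow the two-haplotype scheme: haplotype
1 carries every SV (edits applied in descending coordinate order so truth
coordinates stay in reference space); haplotype 2 is per chromosome either
a copy of haplotype 1 (homozygous) or of the reference (heterozygous).
Translocation arm exchanges are only applied to chromosomes without other
edits — mixing both would shift coordinates — so each complex SV type gets
its own simulated genome. Constructed alignments realize the four
validation scenarios (supported, unsupported, cross-chromosome, unmapped)
with analytically built CIGARs, optionally diverged at a per-base rate.

What the generator does **not** emulate: sequencing reads and their error
profiles, coverage and its fluctuations, alignment ambiguity in repeats,
and caller-specific biases. Green tests therefore certify the evaluation
machinery — matching semantics, conservation laws, calibration of the
error model, scoring arithmetic — not the behavior of any real caller on
real data.

## Numerical and design notes

* Internal coordinates are 0-based half-open; the 1-based VCF boundary
  conversion happens only in `readSVVcf()`/`writeSVVcf()`, and a
  write-then-read round trip preserves every record field.
* Symbolic records missing both END and SVLEN are skipped and counted;
  malformed genotypes become `missing`; genotypes are normalized to
  het / hom\_alt / missing (1/1 → hom\_alt; 0/1, 1/0 → het).
* Whether the reference-distance of the matching envelope compares starts
  only or both endpoints is not uniquely determined by published
  descriptions; the package uses the max-of-endpoint-differences form so
  that the quantity gating `r` and the reported breakpoint shift are one
  and the same.
* Ties in greedy assignment are broken by record id, making every result
  reproducible to the byte under a fixed seed.
* Metrics with zero denominators are reported as 0; empty callsets are
  legal everywhere.
* Deterministic problem sizes used by the shipped checks (a few hundred
  SVs, 1–2 Mb references, 121-point grids) were chosen as the smallest
  scales at which the statistical calibration properties are sharp; all
  are configurable upward.

## Known limitations

* Multi-sample VCFs, phasing, CNV and SNV records are out of scope; only
  the first ALT allele of a record is considered.
* Sequence similarity compares allele sequences directly rather than
  reconstructing full alternate haplotypes; for heavily shifted but
  sequence-identical calls the two definitions can differ.
* The iterative merge keeps first-seen coordinates, so merge order affects
  representative coordinates (not membership) — the order is recorded.
* The orthogonal-validation scorer trusts its input alignments; it does
  not attempt re-alignment or split-read reconciliation.
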