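---
title: "Methods: barcode-free plasmid-pool validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-free plasmid-pool validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidpool)
```

`plasmidpool` validates plasmid sequences from pooled nanopore runs without
per-sample barcodes. This vignette explains the models and procedures, the
tunable parameters and their defaults, the numerical choices that were
genuinely open, what the bundled simulator does and does not emulate, and
the package's known limitations.

## The alignment engine

Every stage rests on affine-gap pairwise alignment (the Gotoh three-state
recurrence) in three modes: global (Needleman–Wunsch), local
(Smith–Waterman), and semiglobal *overlap* alignment for read-to-reference
mapping, in which leading/trailing gaps on either sequence are free at the
ends of the other — a read lands anywhere inside the reference, and is
soft-clipped only where the alignment runs off a reference end.

Conventions that matter to users:

* A gap of length $L$ costs $\text{open} + (L-1)\,\text{extend}$ (both
  negative). With the binning scheme (3, −6, −10, −5) a 1-bp gap costs 10;
  with the needle-style report scheme (5, −4, −10, −0.5) it costs 10 and
  each further base 0.5. Scores are doubled internally so half-point
  penalties stay exact integers.
* `N` never matches anything, including another `N`; it always scores as a
  mismatch. This is the simplest defensible rule and only matters for the
  rare reads carrying ambiguous base calls.
* Among co-optimal alignments the traceback is deterministic: diagonal
  (match/mismatch) steps are preferred over gaps, and deletions over
  insertions. Every result is therefore reproducible bit-for-bit.
* Long alignments are banded around a diagonal seeded by shared 13-mers;
  the default half-width is $100 + 0.05 \times \text{read length}$, wide
  enough that a 100-bp indel plus 10 % scattered error stays inside the
  band. A banded score is exact whenever the optimal path fits the band
  (asserted in the tests against the unbanded aligner); if the band admits
  no path at all, the caller retries unbanded or drops the read with a
  counted reason.

Two stock scoring schemes exist because they serve different goals. The
binning scheme's expensive gap extension (−5) is right for deciding *whether
a short marker is present*. It is wrong for mapping reads that may carry
long insertions: under it, a 100-bp foreign insertion aligns as fragments
interleaved with chance matches rather than one gap run. Read mapping for
consensus therefore defaults to the needle-style scheme, whose mild
extension (−0.5) keeps long indels contiguous.

## Read filtering

Mean read quality is computed as the Phred transform of the arithmetic mean
per-base error probability, $-10\log_{10}\overline{p}$, not the mean of the
Q values — the convention of the standard nanopore filtering tools, and the
conservative choice (a read with qualities {20, 2} has mean error
probability 0.32, mean quality ≈ 4.9, and fails the default Q ≥ 7 gate that
a naive mean of Q values, 11, would pass).

## Unique-region binning

The scanner looks for *markers*: subsequences of at least `min_len` (default
4 bp, i.e. longer than 3 bp) that occur — on either strand — in exactly one
reference of the pool. Repeats within the owning reference do not disqualify
a marker; uniqueness across references is what read attribution needs.
Circular references are scanned on their doubled sequence so markers
spanning the origin are found, with coordinates reported modulo the length.

The implementation computes, for each start position, the shortest window
absent from all other references, checked on a geometric length grid
(exact at the grid points), keeps positions that are locally minimal from
the right, merges overlapping windows, and then restricts each merged
cluster to its minimal-length plateau — the windows within one grid step of
the cluster minimum. The plateau restriction pins regions to the actual
difference zone; without it, long *just*-unique windows drag the region
into sequence shared with other references, and the fine-score stage would
then accept wrong references whose markers differ in only a few bases.
Merged regions are capped at 64 bp (keeping the leading window, which
always still contains a complete unique substring) and at 8 regions per
reference, longest first; both caps bound binning cost on pools of up to
~100 plasmids and are engineering choices, not biology.

Binning is two-staged, with both scores normalized to percent of the
perfect-match score of their target
($100 \cdot \text{score}/(\text{match} \times \text{target length})$):

1. **Context score** — the read (both orientations) is locally aligned
   against the marker extended by 20-bp flanks. The flanks anchor the
   alignment in sequence shared with the read even when the marker itself
   carries read errors. The default gate of 55 % was chosen so that a
   full-length context hit tolerates roughly 10 % read error; the gate is
   deliberately permissive because stage 2 does the discriminating.
2. **Fine score** — the context-stage hit is re-aligned against the bare
   marker, gated at > 80 %. For a 24-bp marker one substitution scores
   87.5 (passes) and a 4-bp deletion ≈ 48.6 (fails), so only reads whose
   marker region is nearly intact are assigned.

A read is assigned iff exactly one reference passes both gates; reads
passing for two or more references (e.g. chimeras) are *ambiguous*, and the
rest are below-threshold. The percent-of-maximum normalization and the
context default are this package's interpretation — the gates are exposed
as parameters precisely because they are tunable operating points, and the
fine gate is strict enough that assignment rates at 10 % error are modest
(roughly a quarter to a third of reads). That is intended behaviour: with
hundreds of reads per plasmid, binning precision matters far more than
recall, and the misassignment rate among assigned reads is what the
acceptance tests bound.

## Rotated-reference demultiplexing

For clonal pools the unique-region scanner finds nothing, so attribution
uses library preparation instead: each clone is cut at a different
restriction site, and the reference is supplied once per clone, rewritten
linearly from that clone's cut position. Reads are never rotated — only
references are — so read handling stays uniform. A full-length read matches
its own rotation end-to-end; against a rotation cut $d$ bases away, a
stretch of about $d$ bases has nowhere to go and is clipped or gapped,
costing about $d \times \text{match}$ score. The assignment rule requires
the top rotation to beat the second by at least `margin_pct` (default 5 %)
of the read's maximum possible score, so rotations separated by more than
about 5 % of the plasmid length are cleanly separable, short fragments that
span no cut junction stay unassigned, and identical non-rotated duplicates
tie and assign nothing. The margin rule (rather than "unique best score")
is this package's choice, made for robustness with near-full-length reads;
consensus for each clone is then built in its own rotated coordinate frame.

## Reference-guided consensus

Reads are mapped by seeding shared 13-mers, clustering seed diagonals
(modulo the length for circular references, so a read spanning the origin
maps once with wrapped coordinates), and banded overlap alignment in the
better-seeded orientation. An alignment is kept iff its identity is at
least `min_identity` (default 70 %) over aligned columns and its seed locus
is unambiguous (the second-best diagonal cluster has less than half the
best cluster's seed support). These two gates replace the mapping-quality
filter that an external mapper would provide.

The pileup counts {A, C, G, T, deletion} per reference column; each column
is called by plurality. Ties resolve toward the reference base if it is
among the tied symbols, else lexicographically — deterministic and
conservative. Coverage below `min_depth` (default 5) inside the covered
interval yields `N`; zero-coverage runs at the extremities are trimmed.
The consensus never contains a base at a position no read covered — there
is no back-fill from the reference, so a missing consensus base is evidence
of missing data, never silent reference bleed-through.

Insertions need more care than substitutions or deletions, for two reasons
established while building the package. First, at 10 % read error
essentially no single read carries a 100-bp insertion verbatim, so no
plurality over raw inserted strings can work. Second, an aligner may split
one long foreign insertion around chance matches to the reference, so
per-read insertion records are fragmentary and their junctions jitter.
The package therefore calls insertions by *local reassembly*: insertion
observations are first re-joined per read (gap runs whose junctions lie
within 25 columns) and pooled across ±5 columns; where more than `ins_frac`
(default 0.5) of spanning reads carry an insertion, the query segments of
*all* spanning reads over a ±25-column window are collected, their
consensus is built (draft = the most common median-length segment, then
per-column votes including majority insertions, iterated to a fixed point),
and that segment consensus is globally re-anchored to the reference window
using a stiff gap-open (−40) so the foreign block stays one gap run. The
insertion that alignment implies is emitted at its canonical junction. One
call is allowed per neighbourhood scaled to the called insertion's length.

## The consensus-versus-reference report

The final comparison is a global alignment under needle-default scoring.
The `GapReport` tallies substitutions per column and each maximal gap run
as one event with its length in bases, and summarizes them as

$$\text{quality} = 100\left(1 - \frac{\text{subs} + \text{ins bases} + \text{del bases}}{\text{alignment columns}}\right),$$

floored at 0. The formula is this package's definition (stated here because
the score concept it implements is otherwise underspecified); it equals 100
iff consensus and reference agree exactly. Both substitution and indel
tallies are exposed separately so either a "per-base differences" or an
"indel bases only" reading can be recovered. A plasmid is *flagged* — never
dropped — when quality < 99.5 or any single indel ≥ 10 bp exists.

One caveat the package turns into an explicit helper: a global aligner may
render a long insertion of random sequence as several gap runs broken by
chance matches (deletions cannot split this way — the consensus has no
bases inside them). `indel_at()` therefore reports the *net*
inserted-minus-deleted bases within ±50 bp of a locus, which is how one
reads a needle report, and is the measure the acceptance tests use for
"an indel of size N recovered at this locus".

## The simulator

`make_pool()` builds either dissimilar pools (independent random circular
sequences, ±10 % length jitter, GC 0.5) or marker pools (one backbone,
a distinct random marker substituted at a fixed locus) — the latter being
the hard case for barcode-free binning. `simulate_pool()` draws reads with:

* independent per-base substitution/insertion/deletion errors at
  4 %/3 %/3 % (≈ 10 % aggregate, the usual figure for nanopore base calls),
  with the deletion rate doubled inside homopolymer runs of ≥ 4 — the
  dominant nanopore error mode;
* lognormal read lengths (meanlog = log 6000, sdlog = 0.55, targeting an
  N50 near 6 kb) truncated at the template length, so most reads span a
  whole plasmid, as they do in real pooled plasmid runs;
* uniform read starts on the circle (transposase preparation) or fixed
  cut-site starts with exponentially distributed end trims
  (mean 20 bp; restriction preparation);
* random orientation; constant per-base qualities consistent with the
  configured error rate (Q10 at 10 %); injectable insertion/deletion/
  substitution variants, optionally subclonal.

Fixed seeds give byte-identical output, and every sub-draw derives from the
one seed, so fixtures regenerate exactly.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: basecaller-specific error correlations and quality
profiles (errors here are independent given the homopolymer state), adapter
or chimera artifacts, coverage bias, and signal-level effects. Results on
real flow-cell data will differ in degree (in particular, homopolymer gaps
in real consensuses are more frequent than this error model produces); the
pipeline's logic, thresholds and bookkeeping are what the simulation
validates.

## Problem sizes in the test-suite and acceptance runs

The shipped tests and the acceptance script run desk-scale versions of the
experiments the design targets: pools of 8–16 plasmids of 1.5–4.5 kb with
200 reads per plasmid for binning (3 200 reads), 100 reads per plasmid for
indel recovery on a ~3-kb plasmid, and three rotations of a 6.5-kb plasmid
with a dozen reads per clone for demultiplexing. These sizes were chosen so
the full suite completes in minutes on one CPU while every rate being
measured still has enough events to be meaningful; the statistical
behaviour of the method does not change with more reads, only the error
bars shrink.

## Known limitations

* Homopolymer errors are not specially corrected; a consensus can carry a
  gap at a long homopolymer when a majority of reads dropped a base there.
  This is an accepted error mode of nanopore consensus polishing generally.
* Subclonal variation is surfaced in the emitted SAM (both read populations
  are visible by CIGAR), never in the consensus, which carries the majority
  allele only.
* The binning fine gate trades recall for precision by design; pools with
  < 12 bp of unique sequence per plasmid assign few reads and should use
  the cut-site protocol and rotated mode instead.
* `map-all` mode assigns each read to its best-scoring reference with no
  uniqueness requirement; it is the right tool only for dissimilar pools.
* The aligner is a plain banded CPU implementation — adequate for pools of
  up to ~100 plasmids of a few kb, not for genome-scale work.
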