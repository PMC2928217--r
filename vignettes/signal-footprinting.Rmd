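---
title: "Dense binary signal tracks and strand-aware footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense binary signal tracks and strand-aware footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfoot)
```

## The problem and the representation

Massively parallel sequencing assays (ChIP-seq, MNase-seq, RNA-seq) reduce,
after alignment, to sets of stranded genomic intervals. Most biological
questions about them are asked through *footprints*: the average signal over
thousands to hundreds of thousands of anchor positions — transcription start
sites, exon boundaries, motif matches — oriented along each anchor's
transcription direction. Computing such meta-profiles from interval lists is
slow when every query rescans the fragments.

seqfoot instead pays the aggregation cost once. `build_tracks()` turns the
fragments into a *dense* per-base count array per chromosome and stratum,
and the on-disk format stores a single coordinate offset in its header, so
any position is read by moving a file pointer to
`payload_start + (coordinate - offset) * element_width`. Lookup cost is then
essentially independent of how many fragments were sequenced or how large
the track is — trading disk space (bases with no fragments still occupy an
element) for constant-time random access.

Three strata are kept per chromosome:

* **forward** and **reverse** — per-base counts of fragments aligned to each
  strand;
* **combined** — both strands with every fragment replaced by an interval of
  a user-chosen *prolongation length* L anchored at its 5' end (forward:
  `[start, start + L - 1]`; reverse: `[end - L + 1, end]`, clipped at
  coordinate 1). This approximates the original sonicated fragment from the
  sequenced tag. We take L as the exact final length: fragments longer than
  L are truncated to it, which keeps the combined track equal to the track
  one would build from pre-prolonged fragments (a property the tests check).

With `starts_only = TRUE` only each fragment's 5' base is counted. This is
the right representation for cut-preference questions (e.g. micrococcal
nuclease sequence bias at intron–exon junctions), where coverage would smear
the signal over the whole fragment.

## Input normalization

All four readers normalize to one record type: chromosome, 1-based closed
`start`/`end`, strand, positive multiplicity.

* **BED** is 0-based half-open, so `start = chromStart + 1`,
  `end = chromEnd`. Strandless 3-column records default to forward — the
  combined stratum is the only strand-sensitive consumer and no convention
  exists for strandless input. The BED score is *not* a multiplicity; only
  the GFF-like reader has a count column.
* **GFF-like** text is fully configurable via `column_spec()`: delimiter,
  column indices and the strand-symbol mapping. Coordinates are taken as
  already 1-based closed; a configured count column becomes the
  multiplicity.
* **SAM**: unmapped reads (FLAG 0x4) are skipped; strand is reverse iff
  FLAG 0x10; the reference span is the sum of reference-consuming CIGAR
  operations (M, D, N, `=`, X). Basing the span on the CIGAR rather than the
  read length is a design choice: it is the only interpretation consistent
  with spliced or gapped alignments. Secondary alignments and duplicates are
  kept — the counting model is "all aligned fragments".
* **WIG** (fixedStep and variableStep, spans expanded) yields single-base
  records with the value as multiplicity. Zero values are dropped (they add
  no signal); negative values are rejected, since a pileup multiplicity has
  no meaning below zero — use a floating-point element and a GFF-like file
  if signed signal is ever needed.

Parsing is strict by default (first malformed line aborts, with its line
number); lenient mode skips and tallies. Input order never matters.

## The element type and saturation

Counts are stored per an `element_spec()`: unsigned integers of 1–8 bytes or
floats of 4/8 bytes. The default 2-byte unsigned element represents
2^16 = 65536 distinct states, so the largest storable count is 65535; a
position whose true count exceeds that is stored saturated and tallied as a
*truncated position* in the build statistics, never silently wrapped.
Fractional input destined for an integer element is rounded half-to-even —
deterministic and unbiased. Floating-point elements never saturate and suit
mappability or microarray-style tracks.

The storage arithmetic is transparent: a 250 Mb chromosome at 2 bytes/base
needs `payload_size(250e6) = 5e8` bytes (~0.5 GB) per stratum, ~1.5 GB for
all three.

## Footprint semantics

`extract_window(store, q, U, D)` returns `U + D + 1` values oriented 5'→3'
in the query's transcription direction: the genomic slice
`[anchor - U, anchor + D]` for forward anchors, the reversed slice
`[anchor - D, anchor + U]` for reverse ones. `make_footprint()` averages
windows over queries; `extract_signal_matrix()` keeps them as rows (its
column means equal the footprint — the matrix is the input for clustering
individual signals or drawing heat maps, which are deliberately left to
standard tools like `kmeans()` and image plotting).

Two boundary decisions:

* Reads outside a track's stored extent return **zero**, not an error —
  zero coverage is the semantically correct pileup value there — while an
  unknown chromosome or absent stratum *is* an error, so typos never
  masquerade as empty signal.
* Anchors whose window overhangs coordinate 1 contribute zero-filled
  positions instead of being excluded. This keeps the per-offset query
  count `n` constant across offsets and matches the zero-fill semantics;
  the alternative (excluding edge anchors) would make `n` offset-dependent.

`shift_queries()` moves anchors along their *transcription direction*
(forward `+d`, reverse `-d`), not genomically. A shifted query set is a
negative control, and a control should keep its window geometry relative to
gene orientation; a genomic shift would fold strand asymmetries into the
control. Anchors shifted below coordinate 1 are dropped and tallied.
`filter_threshold()` keeps positions *strictly above* the threshold —
"above t" is read literally, so `t = 0` means "any signal".

## Analysis utilities

* `mnase_rescale()` replaces one biased offset of an aggregate profile
  (e.g. the cut-preference spike 2 bases upstream of exon starts) by the
  mean of the profile over a window excluding that offset. It operates on
  the aggregate footprint vector, not on stored reads: regenerating the
  profile from rescaled counts and rescaling the aggregate are equivalent
  for this statistic, and the aggregate form never mutates stored data.
  The operation is idempotent and leaves flat profiles unchanged.
* `equal_count_bins()` sorts features by score and cuts them into k
  contiguous bins with sizes differing by at most one; any remainder goes
  to the lowest bins, and ties keep input order (stable sort). Typical use:
  expression deciles over exons.
* `above_below_split()` counts per-feature averages against a reference
  mean, ties counting as "above" — a feature exactly at the genome average
  is not evidence of depletion.
* `binomial_enrichment(k, n, p0)` is the exact upper tail
  `P(X >= k)`, `X ~ Binomial(n, p0)`. It is one-sided by design — the
  scientific claim is an *excess* of low-scoring features — with `p0` taken
  as the genome-wide below-average fraction; callers conventionally compare
  against 0.001.

## What the synthetic generator emulates — and what it does not

`gen_fragments()` places stranded fragments uniformly on toy chromosomes
with normally distributed lengths (default mean 150 bp, sd 20 — a typical
short-read library after size selection), and `gen_queries()` scatters
anchors uniformly within chromosomes with chromosomes drawn uniformly,
which maximizes switches between signal sources during querying. Both are
seeded and leave the caller's RNG stream untouched.

This emulates the *geometry* of real data — placement, strandedness,
overlap depth, chromosome switching — which is exactly what the storage and
aggregation layer is sensitive to. It does not emulate biological structure:
no nucleosome phasing, no GC or mappability bias, no duplicate towers, no
chromatin-driven coverage autocorrelation. Passing tests therefore
demonstrate that counting, orientation, saturation and persistence are
exact, not that any biological signal will look a particular way.

## Numerical and implementation choices

* Accumulation is a difference array plus cumulative sum per chromosome —
  O(fragments + span) and exact for integer counts. Tracks are compared in
  tests against a naive per-base loop at every position.
* On-disk format: little-endian; 8-byte magic, version byte, element kind
  and width bytes, stratum byte, unsigned 64-bit offset and length, then
  the chromosome name and the raw payload. The header is self-describing;
  reading with a mismatched element expectation errors rather than
  reinterpreting bytes. One file per (chromosome, stratum), named
  `<base>.<chrom>.<fwd|rev|comb>`, plus a labeled `key=value` statistics
  text file.
* `open_store()` reads only headers; region queries seek. `read_store()`
  loads payloads for repeated in-memory querying.
* Problem sizes in the test suite and the reproduction script are the
  package's own choices: oracle comparisons use 1,000 fragments on a 100 kb
  chromosome (every position checked, all prolongation and starts-only
  settings), and the scalability exercise builds 1,000,000 fragments on a
  4.5 Mb toy genome and answers a 10,000-anchor, ±1 kb footprint — large
  enough to exercise every code path at full density while completing in
  seconds.

## Known limitations

* Dense storage wastes space where nothing aligned; that is the accepted
  price of constant-time access. No compression or sparse encoding.
* No BAM/CRAM decoding (convert to SAM first), no paired-end fragment
  inference, no interactive browsing or plotting beyond a basic
  `plot()` method for footprints.
* The 8-byte unsigned element is exact only up to 2^53 because values pass
  through R doubles — far beyond any realistic pileup.
* One-sided binomial testing and no multiple-testing correction: the
  enrichment helper answers a directional question per bin; correction
  policy is left to the caller.
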