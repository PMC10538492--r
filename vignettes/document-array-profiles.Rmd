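---
title: "Document array profiles: model, construction and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Document array profiles: model, construction and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docarray)
```

## The model

A collection of `d` documents over the DNA alphabet is concatenated, one
separator appended to each document, and indexed with the classical
suffix structures: suffix array `SA`, inverse `ISA`, LCP array,
Burrows-Wheeler transform `BWT`, LF-mapping and document array `DA`.
The object of interest is the *document array profile*: for each BWT
position `i`, the `d`-vector whose entry `j` is the best
longest-common-prefix between the suffix at `SA[i]` and any suffix of
document `j`. Thresholding a profile at a match length `l` answers
document listing — *which* documents contain the match — with `d`
comparisons, however many occurrences the match has. That is the point
of the structure: locate-based listing does work proportional to the
occurrence count `occ`, which against a repetitive pangenome grows with
database size, while the profile path does not (the package exposes both
and the tests assert the operation-count contrast, not wall-clock).

Keeping all `n` profiles is `O(nd)` space. Instead, profiles are stored
only at BWT run boundaries: for each maximal equal-letter run
`BWT[s..e]`, the profiles at `LF(s)` and `LF(e)` (2r samples, `O(rd)`
space). Two facts make the sampled set sufficient during backward
search. First, an LF step from a position whose document does not change
can raise any profile entry by at most one. Second, with
`l = max(LCP[s], LCP[e+1]) + 1` (the minimal length of a substring whose
occurrences are confined to the run; `LCP[n+1] = 0` by convention),
every entry at least `l` grows by *exactly* one. Hence, processing the
pattern right to left: if the current interval contains a boundary of a
run of the next character, the sample stored there is adopted; if the
interval is strictly inside a run, all `d` entries are incremented. The
maintained vector `P` then satisfies the search invariant — after
matching a suffix of length `m - q + 1` of the pattern, `P[j]` reaches
that length exactly for the documents containing it.

## Separator semantics

The definition of the profile depends on how suffixes interact across
document boundaries, which the sampled-profile machinery itself does not
pin down. The package uses *distinct-sentinel* semantics, implemented by
an integer-mapped text in which the k-th separator receives code `k`
(all smaller than every alphabet symbol):

* all suffixes are distinct, so `SA` is well defined;
* an LCP value never extends across a separator;
* a suffix's lcp with itself is its full length *including* its
  separator, which is what makes the own-document profile entry equal
  the suffix length;
* the only positions where `DA[i] != DA[LF(i)]` are separator positions
  of the BWT (asserted by the tests).

For run-length purposes all separators count as the same character `#`,
so consecutive separators form one run, as they would with a single `$`
symbol.

## The three constructions and their roles

* `profilesNaive()` — entry-by-entry evaluation of the defining maximum
  by direct pairwise lcp computation. Quadratic; exists purely as ground
  truth.
* `profilesTwoPass()` — the best lcp against a document is achieved by
  the nearest preceding or nearest following suffix of that document in
  SA order, so a forward and a backward scan chaining running minima of
  the LCP array reproduce the full matrix in `O(nd)`. Used as the large-
  input cross-check.
* `profilesStreaming()` — the construction actually used by
  `buildDocProfileIndex()`: a single left-to-right scan over
  `(BWT, SA, LCP, DA)` that emits only the 2r boundary samples. The
  predecessor halves come from a `Pred[doc][char]` table of running
  minima; the successor halves are filled in by a queue of pending
  positions, each update bounded by a running minimum `ell` of LCP
  values, with per-(document, character) counters deciding when a
  pending profile can no longer improve and may be emitted.

Correctness of the streaming scan is *defined* by equivalence to
sampling the naive matrix, and the test suite enforces it entry-for-
entry on hundreds of random collections.

Bookkeeping choices in the streaming scan that the mathematics leaves
open, decided here once:

* Pending profiles are kept in "un-prepended" units; the `+1` for the
  character prepended by the LF step is applied at emission. The value
  `-1` marks "no supporting suffix of this document seen", emitting 0.
* Separator positions are special: since distinct sentinels give their
  suffixes lcp 0 against everything else, their profiles are fixed at
  insertion (own document = suffix length, 0 elsewhere). They are
  treated as complete immediately — they stay in the queue only to keep
  the LCP chain contiguous and are excluded from the counters. Without
  this, an early separator tuple could never complete until all `d`
  separators had been seen and would block the queue behind it for most
  of the scan; with it, the observed peak queue length on 80-240 kb
  inputs drops from ~0.8 n to a few hundred.
* End-of-scan flush: tuples still pending when the scan ends are emitted
  with the information available; (document, character) contexts that
  never appeared contribute 0. Required for termination; covered by the
  same oracle equivalence.

## Query-side conventions

* The first character of the backward scan is treated as the
  boundary-adoption case over the full range `[1, n]`, which always
  contains a boundary of a run of that character when it occurs at all.
* When several run boundaries of the next character fall inside the
  interval, the lowest-position one is used; when a run of length one
  puts a start and an end at the same position, the start sample is
  used. Any valid boundary preserves the invariant, so this is purely a
  determinism convention.
* The empty pattern is rejected (it occurs everywhere; a listing is not
  defined); characters outside the alphabet make a pattern absent rather
  than raising an error.
* The one-document baseline (`sampledDaLookup()`) mimics a sampled
  document array that knows `DA` only at run boundaries: first run start
  inside the interval, else the interval's end if it closes a run, else
  the document of the interval's first position (the toehold a
  run-length index carries through backward search). The fallback order
  guarantees the reported document always contains the match, which the
  tests assert; a rule that consulted a boundary *outside* the interval
  could not.

## Truncation

`truncateIndex()` caps every stored value at `cap` (default 255, one
byte per entry). Adopted samples may subsequently be incremented past
the cap during within-run extension steps; that is harmless. The
guarantee is: listings are exact for match lengths up to the cap,
because thresholding at `l <= cap` cannot distinguish a value capped
from above. Queries longer than the cap may over-report; the intended
regime is short reads or bounded MEM lengths, where matches beyond 255
are rare.

## MEMs and classification

Matching statistics (longest match starting at each read position) are
computed by per-position binary search in the suffix array; maximal
exact matches are the right-maximal matches (by definition of the
statistics) that are also left-maximal (the previous position's match
does not cover them), filtered to a minimum length of 15 by default —
shorter exact matches carry little taxonomic signal. Each MEM is
re-queried backward to attach its SA interval and final profile.

Classification weights every (MEM, document) pair by the MEM length and
assigns the read to the document with the largest total. In `full` mode
the documents are the MEM's complete listing; in `one_doc` mode the
single baseline document. Ties are reported as `unclassified`: the
underlying structure genuinely cannot distinguish the tied documents, so
refusing is the honest choice and keeps accuracy comparisons meaningful;
reads shorter than the MEM filter are unclassified outright. Accuracy
counts unclassified reads as errors. One consequence worth knowing: the
one-doc baseline never ties between documents (every MEM contributes to
exactly one), so it can "commit" to a wrong strain where the full
listing abstains.

## The synthetic generator

`generateCollection()` draws a uniform random ancestor, derives one
class ancestor per class at the between-class divergence and the
genomes of a class at the within-class divergence; a class's genomes are
concatenated into one document (one document = one class). Divergence
and read error are i.i.d. per-site processes: a site is substituted, or
starts an insertion or deletion of geometric length (mean 1.5); rates
are specified per affected base, so initiation probabilities are scaled
by the mean indel length. Divergence events are split 90%
substitutions / 10% indels; read errors 50:25:25
substitution:insertion:deletion at per-base rate `1 - accuracy`
(default accuracy 0.95). `simulateReads()` draws uniform start
positions and records the true class. Everything is deterministic given
the seed.

Tier presets mirror increasingly hard classification regimes: `genus`
(20% between-class divergence, 3 genomes/class at 1% within), `species`
(5% between), `strain` (0.5% between — at least 99.5% identity — one
genome per class). Defaults are ancestor 20 kb, 4 classes, 500 reads of
1 kb per class.

What the generator does *not* emulate: real genome length and gene
content, rearrangements and horizontal transfer, homopolymer-biased
nanopore error profiles, chimeric reads, and coverage bias.
Consequently, passing tests demonstrate the correctness of the data
structure and the *direction* of the classification comparison under
controlled divergence, not field accuracy on real mock communities.
Within-class concatenation also introduces `docsPerClass - 1` spurious
junction contexts per document; at the divergences and read lengths
used their effect on MEM statistics is negligible.

## Problem sizes and numerical conventions

The property suites run on random collections with `n <= 200`,
`d` in 1..6 and 2- or 4-letter alphabets (hundreds of instances), where
the quadratic oracles are exact and fast; the classification suite runs
the strain and genus presets at their default sizes (~80 kb and ~240 kb
of indexed sequence, 2000 reads each), chosen so a full
simulate-build-classify cycle completes in about a minute per tier on
one core. All public coordinates are 1-based; the integer-mapped text
is an implementation detail that never leaves the object. Suffix
sorting uses prefix doubling — any correct algorithm is acceptable
since correctness is defined by the brute-force oracle. Index
serialization is a versioned JSON container; a load reconstructs the
suffix structures deterministically from the stored text and verifies a
content hash.

## Known limitations

* Plain integer arrays, not succinct structures: memory is `O(n)` words,
  suitable for desk-scale pangenomes (megabases), not RefSeq-scale
  databases.
* Space for the profile samples grows linearly in `d`; sparse or top-k
  profile variants that would relax this are out of scope.
* Document frequencies (how often a pattern occurs per document) are not
  reported, only membership.
* The streaming scan's queue updates are worst-case quadratic for
  adversarial texts; on genomic collections the completion counters keep
  the queue short (observed peak a few hundred on 240 kb).
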