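---
title: "All-mapping with q-gram filtration and packed banded bit-vector verification"
author: "qgmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{All-mapping with q-gram filtration and packed banded bit-vector verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgmapper)
```

## The problem

Given a reference genome $S$, a set of short reads $R$, and an edit-distance
threshold $k$, an *all-mapper* reports **every** location in $S$ where a read
aligns within $k$ edits — not just a best hit. All-mapping is what
copy-number, structural-variant and ChIP-style analyses need, and it is
expensive because the verification step (scoring a read against a candidate
region under edit distance) dominates the running time. `qgmapper`
implements the two-stage filtration + verification architecture in which
verification is done by a banded Myers bit-vector algorithm whose state for
*several* candidate regions is packed into one wide machine word, so that
one read is scored against many candidate windows simultaneously.

## Filtration: the pigeonhole principle

Each read of length $m$ is cut into $k+1$ non-overlapping $q$-gram seeds,
leftmost-packed at read offsets $0, q, 2q, \dots, kq$ (any tail beyond
$(k+1)q$ symbols carries no seed; the principle only requires
non-overlapping seeds). Since each of the $\le k$ edits can corrupt at most
one seed, any true match within $k$ edits leaves at least one seed matching
the reference *exactly*. Every exact occurrence $d_q$ of the seed at offset
$c$ (found in a hash index of the genome's $q$-grams) therefore implies a
candidate anchor $d = d_q - c$.

For an anchor $d$ the only genome interval that can contain a $\le k$-edit
alignment of the read is the **verification window** $[d-k,\ d+m+k)$, of
length $m + 2k$: at most $k$ deletions push the end right by $k$, at most
$k$ insertions pull the start left by $k$. Anchors are deduplicated before
verification (the same $d$ reached from different seeds is verified once);
distinct anchors with overlapping windows are each verified, and final
mappings are deduplicated by alignment start instead. A merge of
*near*-identical anchors before verification was considered and rejected:
verification is cheap once packed, and exact-$d$ dedup keeps the
full-sensitivity argument trivially intact.

The classical count-filtering threshold $T = |s| - (k+1)q + 1$ is exposed as
a utility (`countFilterThreshold()`), but the mapper's own path is purely
pigeonhole-based: with verification this fast, the cheaper filter wins.

### Choice of q

The seed length is not dictated by the method, only constrained by
$(k+1)\,q \le m$. The default rule `defaultQ(m, k)` is
$q = \max(10, \min(16, \lfloor m/(k+1)\rfloor))$: 16 caps the 2-bit-packed
key to one machine word, the floor of 10 keeps random hits rare
($4^{10} \approx 10^6$), and the $\lfloor m/(k+1)\rfloor$ term is the
largest seed that still lets $k+1$ seeds fit. For 100 bp reads at $k=5$
this gives $q=16$. Reads shorter than $(k+1)q$ are reported unmapped with a
warning — never an error — since no seeding scheme with this $q$ can
guarantee sensitivity for them.

## Verification

### The banded computing area

Scoring a read against a window is semi-global alignment: the read must be
consumed in full, the window substring is free at both ends. The classic
dynamic-programming matrix $C$ solves it in $O(mn)$ with the recurrence

$$C[i,j] = \min\big(C[i,j-1]+1,\; C[i-1,j]+1,\; C[i-1,j-1]+E[i,j]\big),
\qquad C[0,j]=0,\; C[i,0]=i,$$

with $E[i,j]=0$ iff read symbol $i$ equals window symbol $j$ (`N` mismatches
everything, including itself — a deliberate, conservative choice that also
gives the sentinel symbol below its semantics). `dpEditMatrix()` implements
exactly this and serves as the package's reference oracle.

With the threshold fixed in advance, only a band of $2k+1$ diagonals around
the **base diagonal** (shifted $k$ right of the main diagonal) can carry an
alignment that stays within $k$ edits of the anchor: the anchored match
passes through the seed's diagonal, and each edit moves the path at most one
diagonal. The banded verifier therefore computes only those $2k+1$ cells
per column, one column per read symbol.

### Myers' delta encoding, banded

Adjacent cells of $C$ differ by at most 1, so a column is encoded by two
bit-vectors (VP/VN: vertical delta $+1$/$-1$) and updated wholesale with a
handful of word operations from the per-symbol match masks (Peq), producing
the horizontal and diagonal deltas (HP/HN/D0) on the way. In the banded
variant the vectors are $2k+1$ bits long; each column the band slides one
row down the window, so Peq is shifted right by one and the next window
symbol's bit enters at the top. The running score E tracks the band's
bottom cell via the diagonal identity $E \mathrel{+}= 1 - D0[2k]$, and the
semi-global answer is recovered at the last column by walking the final
VP/VN deltas up the band: the minimum over the band's end cells, with the
smallest end offset winning ties (a determinism choice; the method itself
is silent on ties).

Windows clamped at record boundaries are padded — conceptually to the full
$m+2k$ — with a sentinel whose Peq bits are all zero, so edge effects can
only increase distances, never fabricate matches. The same trick pads a
left-clamped window at a record start, which keeps the band geometry
anchored at $d-k$; the traceback then re-expresses any sentinel-consuming
head operations as insertions so reported positions never precede the
record.

### What the band does and does not promise

The banded verifier computes the DP recurrence above restricted to the banded
computing area. For **anchored** candidates — the only ones filtration ever
produces — this equals the unrestricted semi-global minimum whenever that
minimum is $\le k$, which is the full-sensitivity guarantee. For arbitrary
(read, window) pairs with no anchoring seed, alignments that start more
than $2k$ rows into the window (or end before row $m$) fall outside any
$2k+1$-band, and *no* banded algorithm can see them; the verifier then
reports the band-restricted optimum, which is still a real alignment and
never better than the true one. The test suite pins both facts: exhaustive
equivalence with a plain cell-by-cell banded DP on a micro-grid (every
read/window over {A,C} up to length 6, $k \le 2$), consistency bounds
against the full DP on the same grid, and exact full-DP agreement on
thousands of anchored instances.

### Packing several patterns into one word

The column update uses only $\oplus, |, \&, \sim, \gg, +$. The bitwise
group acts independently per bit, so several patterns' vectors can share
one wide word untouched; `+` and `\gg` leak across patterns. Each pattern
therefore owns a slot of $2k+2$ bits — the band plus one **buffer bit**
kept at zero so addition carries die at the slot boundary — and the
right-shift's cross-slot leak is removed with one extra AND against a
precomputed mask. E is packed the same way, one running distance per slot,
incremented per column by the slot's $1 - D0[2k]$ bit (with a saturation
guard once a slot is provably hopeless, so no carry can ever cross slots).
A 128-bit word at $k=4$ holds $\lfloor 128/10\rfloor = 12$ patterns.

Word widths of 64 and 128 bits are supported, emulated with fixed-width
integer arithmetic rather than SIMD intrinsics: the hardware register is an
implementation vehicle, not part of the method, and the emulation is
bit-for-bit the same computation (the 128-bit case uses the compiler's
native 128-bit integers).

### How many slots to use

Verification of a packed word ends only when every slot is finished or cut,
so very wide packings wait on their slowest member. The default used slot
count is $\min(\lfloor W/(2k+2)\rfloor, 8)$ — 8 where it fits, the full
(smaller) capacity at high $k$, e.g. 4 at $k=15$ with $W=128$ — and it is
exposed as a parameter (`slots` in `mapConfig()`, `defaultSlots()`)
rather than guessed further.

### Branch-cut

A slot is cut as soon as the minimum value across its band column exceeds
$k$: band minima never decrease (every dependency of a later cell traces
back through the current column), so the cut is sound. The exact minimum is
recovered from E and the VP/VN suffix sums only when the cheap necessary
condition $E > k$ holds, keeping the common case branch-free. Disabling the
cut never changes results, only runtime — a property the suite checks on
thousands of random packings.

### Verification scheme

One read is the shared text; its candidate windows are the packed patterns
(the genome's repeat structure makes candidate sets per read large, and
this orientation needs no index of the reads). The alternative — packing
multiple reads against one location — would require a read index and is out
of scope.

### Traceback

Matched candidates get a CIGAR by recomputing the plain DP over the
(padded) window and backtracking from the verified end, preferring
diagonal over up over left on ties. The full $(m+1)\times(n+1)$ matrix is
used rather than only the band: windows are at most $m+2k$ symbols so the
cost is negligible, and it is robust at band edges. `NM` equals the
verified distance; M+I lengths sum to $m$.

## The mapper

`mapReads()` runs both strands (the index stores only the forward genome;
the read is reverse-complemented instead, halving the index), verifies
candidates in packed chunks, deduplicates alignments by (record, position,
strand) keeping the minimum distance, and emits SAM: `@HD`/`@SQ`/`@PG`
headers, FLAG 16 for reverse-strand lines (with reverse-complemented SEQ
and reversed QUAL), FLAG 256 on every line after a read's first, FLAG 4
once per unmapped read, MAPQ 255, and `NM:i` tags. The per-read threshold
is an explicit $k$ or $\lfloor 0.05\,m\rfloor$ by default — 5, 7 and 15 for
100, 151 and 300 bp reads — matching standard all-mapping practice. Reads
are independent work units; any execution order yields byte-identical
output after the final sort.

## Synthetic data and evaluation

`randomGenome()` draws i.i.d. symbols at a configurable GC fraction
(default 0.41, a mammalian-like value) and can copy a segment to extra loci
to create known multi-mapping structure. `sampleReads()` plants reads at
uniform positions with 0–`maxEdits` edits per read (uniform count, types
drawn 4:1:1 substitution:insertion:deletion to mimic Illumina's
substitution-dominant profile), records a truth table with the edit script,
and places each read on either strand. What the generator does *not*
emulate: position-dependent error rates, quality-correlated errors,
real repeat families, or polymorphism between sample and reference — so
passing the synthetic experiments demonstrates algorithmic sensitivity on
clean planted data, not robustness to every artefact of real libraries.

`goldStandard()` is the independent referee: a brute-force start-anchored
DP scan (plain recurrence cells, with the classic cut-off that skips cells
provably above $k$ — cell-exact for all values $\le k$) over both strands.
Qualifying starts are merged into intervals — runs bridged across gaps of
up to $k$ failing starts, so the shifted shadows of one match count once —
and each interval is represented by its best start. A reported position
hits an interval when it lies within $\pm k$ of that best start; this point
containment is a deliberate simplification of Rabema's trace-equivalence
machinery, sufficient for synthetic data. `evaluateSensitivity()` reports
the *all*, *all-best* and *any-best* fractions.

## Problem sizes used by the checks

The package's experiment of record is deliberately desk-scale: a 1 Mb
seeded random genome, 10,000 planted 100 bp reads with at most 5 edits,
mapped at $k=5$, scored against the oracle restricted to $\pm k$ around the
planted loci plus one exhaustively scanned 10 kb negative-control region.
At these sizes the mapper recovers 100% of best intervals, mirroring
full-sensitivity behaviour, and the whole experiment runs in a few minutes
on one core. Property suites use an exhaustive micro-grid (all reads and
windows over {A,C} up to length 6, $k\le2$) plus $\ge 10^4$ seeded random
instances with $k \le 7$, $m \le 160$.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based appears
  only in SAM.
* Positions are stored as 32-bit integers (sufficient to 2 Gb genomes; a
  larger genome is rejected with a clear error rather than silently
  wrapped).
* A gram containing `N` is never indexed and never matches; a read whose
  every seed contains `N` simply yields no candidates and is unmapped.
* `k = 0` is supported (the band degenerates to the base diagonal);
  $2k+2$ must fit the configured word width, otherwise a parameter error
  directs the caller to a wider word.
* Empty candidate lists, empty mapping tables and all-unmapped SAM files
  are valid, exercised outputs.

## Limitations

* Single-end mapping only; no paired-end rescue, no base-quality-aware
  scoring, no mapping-quality model (MAPQ is 255 by design).
* The index is rebuilt per session or serialized whole; no FM-index-style
  compressed alternative.
* Hardware SIMD (SSE/AVX) is intentionally not used; the packed words are
  emulated in portable integer arithmetic.
* Multi-threading is out of scope; determinism is guaranteed instead.
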