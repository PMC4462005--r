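# qgmapper

Short-read **all-mapping** in R: find *every* location in a reference
genome where a read aligns within an edit-distance threshold *k*, not just
a best hit. Full sensitivity at the threshold is the design goal — the kind
of guarantee that copy-number calling, structural-variant detection and
ChIP-style analyses rely on.

The mapper has the classic two-stage architecture:

* **Filtration (pigeonhole principle).** Each read of length *m* is cut
  into *k*+1 non-overlapping *q*-gram seeds. At most *k* edits can corrupt
  at most *k* seeds, so any true match leaves one seed matching the genome
  exactly. Exact seed hits, found in a hash index of the genome's
  *q*-grams, yield candidate anchors *d* = *dq* − *c*, each with a
  verification window [*d*−*k*, *d*+*m*+*k*) of length *m*+2*k* — the only
  interval that can contain a ≤ *k*-edit alignment for that anchor.
* **Verification (packed banded Myers bit-vector).** Semi-global edit
  distance over the window is computed on a band of 2*k*+1 diagonals
  around the base diagonal using Myers' delta encoding (VP/VN/HP/HN/D0
  bit-vectors, Peq match masks). The states of several candidate windows
  are packed into one wide word — each pattern in a slot of 2*k*+2 bits,
  one buffer bit stopping addition carries at the slot boundary — so one
  read is scored against up to ⌊*W*/(2*k*+2)⌋ windows simultaneously
  (12 at *k* = 4 with a 128-bit word). A sound branch-cut retires hopeless
  candidates early without ever changing results.

Matches get CIGARs by banded traceback, and everything is emitted as SAM
(secondary alignments flagged, `NM` tags, both strands via
reverse-complementing the read). A synthetic-data module generates seeded
genomes and truth-tracked reads with planted edits, and scores any SAM
against a brute-force dynamic-programming gold standard
(Rabema-style *all* / *all-best* / *any-best*).

## Worked example

```r
library(qgmapper)

g   <- randomGenome(50000, gc = 0.41, seed = 4)      # 50 kb toy genome
sim <- sampleReads(g, m = 100, count = 5, maxEdits = 3, seed = 5)
idx <- buildIndex(g, defaultQ(100, 5))               # q = 16 seeds
mp  <- mapReads(sim$reads, idx, g, mapConfig(k = 5))
mp
```

```
     readId refName   pos strand distance    cigar nm
1 sim000001    chr1 34604      +        0     100M  0
2 sim000002    chr1 17914      +        2     100M  2
3 sim000003    chr1 13854      -        0     100M  0
4 sim000004    chr1 28670      -        1 84M1I15M  1
5 sim000005    chr1  2045      -        1     100M  1
```

Each row is one reported location: 1-based leftmost position, strand,
edit distance (= `NM`), and CIGAR. `writeSam(mp, sim$reads, g, "out.sam")`
writes the SAM file; `evaluateSensitivity()` scores it against the
brute-force oracle:

```r
sam <- tempfile(fileext = ".sam")
writeSam(mp, sim$reads, g, sam)
evaluateSensitivity(sam, genome = g, k = 5, reads = sim$reads,
                    gold = goldStandard(sim$reads, g, k = 5))
```

```
Sensitivity (interval hit = reported pos within +/-k of the gold start):
  all:      100.00 %  (5 intervals)
  all-best: 100.00 %  (5 best intervals)
  any-best: 100.00 %  (5 reads)
```

A thin command-line front end ships in `inst/exec/qgmapper`:

```sh
Rscript inst/exec/qgmapper index --ref ref.fa --q 16 --out ref.idx
Rscript inst/exec/qgmapper map --ref ref.fa --index ref.idx \
    --reads reads.fq.gz --error-rate 0.05 --out out.sam
```

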