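#include "qgm.h"
using namespace Rcpp;

struct Cand {
  double d;    // anchor (global, may precede the record start)
  double ws;   // clamped window start (global)
  double we;   // clamped window end (global, half-open)
  int rec;
};

// Pigeonhole candidates for one oriented read: k+1 leftmost-packed seeds at
// offsets 0, q, ..., k*q; every exact seed hit dq at offset c yields anchor
// d = dq - c; anchors are deduplicated and given [d-k, d+m+k) windows clamped to
// their record.
static void candidatesCore(const std::vector<uint8_t>& seq, int k, int q,
                           const double* keys, int nk,
                           const int* starts, const int* positions,
                           const double* recStart, const double* recEnd, int nrec,
                           int occCap, std::vector<Cand>& out) {
  const int m = (int)seq.size();
  std::vector<std::pair<double, int> > anchors;
  for (int si = 0; si <= k; ++si) {
    const int c = si * q;
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < q; ++i) {
      if (seq[c + i] > 3) { ok = false; break; }
      key = (key << 2) | seq[c + i];
    }
    if (!ok) continue;
    const double dkey = (double)key;
    const double* lo = std::lower_bound(keys, keys + nk, dkey);
    if (lo == keys + nk || *lo != dkey) continue;
    const int ki = (int)(lo - keys);
    // optional cap on seed occurrences; forfeits the full-sensitivity
    // guarantee and is off (0) by default
    if (occCap > 0 && starts[ki + 1] - starts[ki] > occCap) continue;
    for (int p = starts[ki]; p < starts[ki + 1]; ++p) {
      const double dq = (double)positions[p];
      const int rec = (int)(std::upper_bound(recStart, recStart + nrec, dq) - recStart) - 1;
      anchors.push_back(std::make_pair(dq - c, rec));
    }
  }
  std::sort(anchors.begin(), anchors.end());
  anchors.erase(std::unique(anchors.begin(), anchors.end()), anchors.end());
  out.clear();
  out.reserve(anchors.size());
  for (size_t i = 0; i < anchors.size(); ++i) {
    Cand cd;
    cd.d = anchors[i].first;
    cd.rec = anchors[i].second;
    cd.ws = std::max(recStart[cd.rec], cd.d - k);
    cd.we = std::min(recEnd[cd.rec], cd.d + m + k);
    out.push_back(cd);
  }
}

// [[Rcpp::export]]
List cpp_candidates(std::string seq, int k, int q,
                    NumericVector keys, IntegerVector starts, IntegerVector positions,
                    NumericVector recStarts, NumericVector recEnds, int occCap) {
  std::vector<uint8_t> enc = encodeSeq(seq);
  if ((int)enc.size() < (k + 1) * q)
    stop("read of length %d is too short for %d seeds of length %d",
         (int)enc.size(), k + 1, q);
  std::vector<Cand> cands;
  candidatesCore(enc, k, q, keys.begin(), (int)keys.size(), starts.begin(),
                 positions.begin(), recStarts.begin(), recEnds.begin(),
                 (int)recStarts.size(), occCap, cands);
  const int nc = (int)cands.size();
  NumericVector d(nc), ws(nc), we(nc);
  IntegerVector rec(nc);
  for (int i = 0; i < nc; ++i) {
    d[i] = cands[i].d;
    ws[i] = cands[i].ws;
    we[i] = cands[i].we;
    rec[i] = cands[i].rec + 1;
  }
  return List::create(_["anchor"] = d, _["windowStart"] = ws,
                      _["windowEnd"] = we, _["record"] = rec);
}

struct Hit {
  int rec;
  double pos;   // 1-based leftmost position within the record
  char strand;
  int nm;
  std::string cigar;
};

// Verify one oriented read against its candidate set in packed chunks and
// collect alignments. stats: {candidates, verified, cut}.
template <typename word>
static void verifyStrand(const std::vector<uint8_t>& seq, char strand,
                         int k, int q, int nUse,
                         const double* keys, int nk,
                         const int* starts, const int* positions,
                         const double* recStart, const double* recEnd, int nrec,
                         const std::vector<std::vector<uint8_t> >& encRecs,
                         int occCap, bool branchCut,
                         std::vector<Hit>& hits, long* stats) {
  std::vector<Cand> cands;
  candidatesCore(seq, k, q, keys, nk, starts, positions, recStart, recEnd, nrec,
                 occCap, cands);
  stats[0] += (long)cands.size();
  const int m = (int)seq.size();
  for (size_t c0 = 0; c0 < cands.size(); c0 += nUse) {
    const size_t c1 = std::min(cands.size(), c0 + nUse);
    std::vector<std::vector<uint8_t> > pats;
    std::vector<int> padLefts;
    for (size_t ci = c0; ci < c1; ++ci) {
      const Cand& cd = cands[ci];
      const int padLeft = (int)(cd.ws - (cd.d - k));
      const int off = (int)(cd.ws - recStart[cd.rec]);
      const int len = (int)(cd.we - cd.ws);
      std::vector<uint8_t> p((size_t)(padLeft > 0 ? padLeft : 0), (uint8_t)4);
      const std::vector<uint8_t>& rs = encRecs[cd.rec];
      p.insert(p.end(), rs.begin() + off, rs.begin() + off + len);
      pats.push_back(p);
      padLefts.push_back(padLeft > 0 ? padLeft : 0);
    }
    std::vector<VerifyRes> res =
        packedRun<word>(seq.data(), m, pats, k, branchCut, false);
    stats[1] += (long)res.size();
    for (size_t i = 0; i < res.size(); ++i) {
      if (res[i].cut) ++stats[2];
      if (res[i].dist > k) continue;
      const Cand& cd = cands[c0 + i];
      TBRes tb = tracebackCore(seq, pats[i], k, res[i].end, padLefts[i]);
      const double globalStart = (cd.d - k) + tb.alnStart;
      Hit h;
      h.rec = cd.rec;
      h.pos = globalStart - recStart[cd.rec] + 1;
      h.strand = strand;
      h.nm = tb.nm;
      h.cigar = tb.cigar;
      hits.push_back(h);
    }
  }
}

// End-to-end single-end batch mapper: seeds -> candidates -> packed
// verification -> CIGAR, both strands, all locations within k, deduplicated
// by (record, pos, strand) keeping the minimum distance.
// [[Rcpp::export]]
List cpp_map_batch(CharacterVector readSeqs, IntegerVector ks,
                   NumericVector keys, IntegerVector starts, IntegerVector positions,
                   int q, CharacterVector recSeqs,
                   NumericVector recStarts, NumericVector recEnds,
                   int wordWidth, int nslots, int occCap, bool branchCut) {
  const int nr = (int)readSeqs.size();
  std::vector<std::vector<uint8_t> > encRecs(recSeqs.size());
  for (int i = 0; i < recSeqs.size(); ++i)
    encRecs[i] = encodeSeq(as<std::string>(recSeqs[i]));
  std::vector<int> outRead, outRec, outNm;
  std::vector<double> outPos;
  std::vector<char> outStrand;
  std::vector<std::string> outCigar;
  LogicalVector tooShort(nr);
  long stats[3] = {0, 0, 0};
  for (int r = 0; r < nr; ++r) {
    const int k = ks[r];
    if (k < 0) stop("k must be non-negative");
    if (2 * k + 2 > wordWidth)
      stop("slot width 2k+2 = %d exceeds the word width %d", 2 * k + 2, wordWidth);
    const int h = wordWidth / (2 * k + 2);
    const int nUse = nslots > 0 ? std::min(nslots, h) : std::min(h, 8);
    const std::vector<uint8_t> fwd = encodeSeq(as<std::string>(readSeqs[r]));
    const int m = (int)fwd.size();
    if (m < (k + 1) * q) {
      tooShort[r] = true;
      continue;
    }
    std::vector<Hit> hits;
    for (int s = 0; s < 2; ++s) {
      const std::vector<uint8_t> seq = (s == 0) ? fwd : revCompCodes(fwd);
      if (wordWidth == 64)
        verifyStrand<uint64_t>(seq, s == 0 ? '+' : '-', k, q, nUse,
                               keys.begin(), (int)keys.size(), starts.begin(),
                               positions.begin(), recStarts.begin(), recEnds.begin(),
                               (int)recStarts.size(), encRecs, occCap, branchCut,
                               hits, stats);
      else if (wordWidth == 128)
        verifyStrand<unsigned __int128>(seq, s == 0 ? '+' : '-', k, q, nUse,
                               keys.begin(), (int)keys.size(), starts.begin(),
                               positions.begin(), recStarts.begin(), recEnds.begin(),
                               (int)recStarts.size(), encRecs, occCap, branchCut,
                               hits, stats);
      else
        stop("word width must be 64 or 128");
    }
    // dedup by (rec, pos, strand), keep minimum distance (ties: first seen),
    // then sort by (rec, pos)
    std::stable_sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      if (a.rec != b.rec) return a.rec < b.rec;
      if (a.pos != b.pos) return a.pos < b.pos;
      if (a.strand != b.strand) return a.strand < b.strand;
      return false;
    });
    for (size_t i = 0; i < hits.size(); ++i) {
      if (i > 0 && hits[i].rec == hits[i - 1].rec && hits[i].pos == hits[i - 1].pos &&
          hits[i].strand == hits[i - 1].strand)
        continue;
      // scan the tie group for the minimum nm
      size_t bestIdx = i;
      for (size_t j2 = i + 1; j2 < hits.size(); ++j2) {
        if (hits[j2].rec != hits[i].rec || hits[j2].pos != hits[i].pos ||
            hits[j2].strand != hits[i].strand)
          break;
        if (hits[j2].nm < hits[bestIdx].nm) bestIdx = j2;
      }
      outRead.push_back(r + 1);
      outRec.push_back(hits[bestIdx].rec + 1);
      outPos.push_back(hits[bestIdx].pos);
      outStrand.push_back(hits[bestIdx].strand);
      outNm.push_back(hits[bestIdx].nm);
      outCigar.push_back(hits[bestIdx].cigar);
    }
  }
  const int no = (int)outRead.size();
  CharacterVector strandOut(no), cigarOut(no);
  for (int i = 0; i < no; ++i) {
    strandOut[i] = std::string(1, outStrand[i]);
    cigarOut[i] = outCigar[i];
  }
  return List::create(
      _["readIdx"] = IntegerVector(outRead.begin(), outRead.end()),
      _["record"] = IntegerVector(outRec.begin(), outRec.end()),
      _["pos"] = NumericVector(outPos.begin(), outPos.end()),
      _["strand"] = strandOut,
      _["nm"] = IntegerVector(outNm.begin(), outNm.end()),
      _["cigar"] = cigarOut,
      _["tooShort"] = tooShort,
      _["stats"] = NumericVector::create(_["candidates"] = (double)stats[0],
                                         _["verified"] = (double)stats[1],
                                         _["cutEarly"] = (double)stats[2]));
}
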