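#include "qgm.h"
using namespace Rcpp;

static void checkK(int k, int wordWidth) {
  if (k < 0) stop("k must be non-negative");
  if (2 * k + 2 > wordWidth)
    stop("slot width 2k+2 = %d exceeds the word width %d", 2 * k + 2, wordWidth);
}

// [[Rcpp::export]]
IntegerMatrix cpp_dp_edit_matrix(std::string read, std::string text) {
  if (read.empty() || text.empty()) stop("read and text must be non-empty");
  std::vector<uint8_t> r = encodeSeq(read), s = encodeSeq(text);
  const int m = (int)r.size(), n = (int)s.size();
  std::vector<int> C = dpMatrixCore(r.data(), m, s.data(), n);
  IntegerMatrix M(m + 1, n + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j)
      M(i, j) = C[(size_t)i * (n + 1) + j];
  return M;
}

// [[Rcpp::export]]
List cpp_banded_myers(std::string read, std::string window, int k, bool branchCut) {
  checkK(k, 64);
  if (read.empty()) stop("read must be non-empty");
  std::vector<uint8_t> t = encodeSeq(read), p = encodeSeq(window);
  const int m = (int)t.size();
  if ((int)p.size() > m + 2 * k)
    stop("window of length %d exceeds the verification-window bound m + 2k = %d",
         (int)p.size(), m + 2 * k);
  VerifyRes v = bandedMyersCore(t.data(), m, p.data(), (int)p.size(), k, branchCut);
  return List::create(_["matched"] = v.dist <= k,
                      _["distance"] = v.dist <= k ? v.dist : NA_INTEGER,
                      _["bestEnd"] = v.dist <= k ? v.end : NA_INTEGER,
                      _["cut"] = v.cut);
}

template <typename word>
static RawVector wordToRaw(word x) {
  RawVector r((int)sizeof(word));
  for (int i = 0; i < (int)sizeof(word); ++i)
    r[i] = (uint8_t)(x >> (8 * i));
  return r;
}

static std::vector<std::vector<uint8_t> > encodeAll(CharacterVector windows) {
  std::vector<std::vector<uint8_t> > pats(windows.size());
  for (int i = 0; i < windows.size(); ++i)
    pats[i] = encodeSeq(as<std::string>(windows[i]));
  return pats;
}

template <typename word>
static List packToList(const std::vector<std::vector<uint8_t> >& pats, int k) {
  PackedInit<word> P = packInit<word>(pats, k);
  return List::create(
      _["VP"] = wordToRaw<word>(P.VP), _["VN"] = wordToRaw<word>(P.VN),
      _["E"] = wordToRaw<word>(P.E),
      _["Peq"] = List::create(wordToRaw<word>(P.Peq[0]), wordToRaw<word>(P.Peq[1]),
                              wordToRaw<word>(P.Peq[2]), wordToRaw<word>(P.Peq[3])),
      _["bandMask"] = wordToRaw<word>(P.bandAll),
      _["bufferMask"] = wordToRaw<word>(P.bufferAll),
      _["baseMask"] = wordToRaw<word>(P.baseAll),
      _["slotWidth"] = P.s, _["slotCapacity"] = P.h);
}

// [[Rcpp::export]]
List cpp_pack_patterns(CharacterVector windows, int k, int wordWidth) {
  checkK(k, wordWidth);
  std::vector<std::vector<uint8_t> > pats = encodeAll(windows);
  if (wordWidth == 64) return packToList<uint64_t>(pats, k);
  if (wordWidth == 128) return packToList<unsigned __int128>(pats, k);
  stop("word width must be 64 or 128");
}

// [[Rcpp::export]]
List cpp_vectorized_banded(std::string read, CharacterVector windows, int k,
                           int wordWidth, bool branchCut, bool validate) {
  checkK(k, wordWidth);
  if (read.empty()) stop("read must be non-empty");
  std::vector<uint8_t> t = encodeSeq(read);
  std::vector<std::vector<uint8_t> > pats = encodeAll(windows);
  for (size_t i = 0; i < pats.size(); ++i)
    if ((int)pats[i].size() > (int)t.size() + 2 * k)
      stop("window %d exceeds the verification-window bound m + 2k", (int)i + 1);
  std::vector<VerifyRes> res;
  if (wordWidth == 64)
    res = packedRun<uint64_t>(t.data(), (int)t.size(), pats, k, branchCut, validate);
  else if (wordWidth == 128)
    res = packedRun<unsigned __int128>(t.data(), (int)t.size(), pats, k, branchCut, validate);
  else
    stop("word width must be 64 or 128");
  const int np = (int)res.size();
  LogicalVector matched(np), cut(np);
  IntegerVector dist(np), bestEnd(np);
  for (int i = 0; i < np; ++i) {
    matched[i] = res[i].dist <= k;
    dist[i] = matched[i] ? res[i].dist : NA_INTEGER;
    bestEnd[i] = matched[i] ? res[i].end : NA_INTEGER;
    cut[i] = res[i].cut;
  }
  return List::create(_["matched"] = matched, _["distance"] = dist,
                      _["bestEnd"] = bestEnd, _["cut"] = cut);
}

// [[Rcpp::export]]
List cpp_traceback(std::string read, std::string window, int k, int bestEnd,
                   int padLeft) {
  if (read.empty()) stop("read must be non-empty");
  std::vector<uint8_t> r = encodeSeq(read), w = encodeSeq(window);
  std::vector<uint8_t> padded;
  if (padLeft > 0) {
    padded.assign((size_t)padLeft, (uint8_t)4);
    padded.insert(padded.end(), w.begin(), w.end());
  } else {
    padded = w;
  }
  TBRes t = tracebackCore(r, padded, k, bestEnd, padLeft);
  return List::create(_["cigar"] = t.cigar, _["nm"] = t.nm,
                      _["alnStart"] = t.alnStart, _["distance"] = t.dist);
}

// Minimum edit distance of `read` against a substring of `text` starting at
// each position (free end): the brute-force start-anchored oracle, computed
// by a reversed DP pass. With maxDist >= 0 the classic Ukkonen cut-off
// skips cells provably above the threshold (cell-exact for all values
// <= maxDist; larger distances are reported as maxDist + 1).
// [[Rcpp::export]]
IntegerVector cpp_start_distances(std::string read, std::string text,
                                  int maxDist = -1) {
  if (read.empty() || text.empty()) stop("read and text must be non-empty");
  std::vector<uint8_t> r0 = encodeSeq(read), t0 = encodeSeq(text);
  std::vector<uint8_t> r(r0.rbegin(), r0.rend()), t(t0.rbegin(), t0.rend());
  const int m = (int)r.size(), n = (int)t.size();
  IntegerVector D(n);
  if (maxDist < 0) {
    std::vector<int> row(n + 1, 0), nrow(n + 1);
    for (int i = 1; i <= m; ++i) {
      nrow[0] = i;
      const uint8_t ri = r[i - 1];
      for (int j = 1; j <= n; ++j) {
        const int e = (ri == t[j - 1] && ri < 4) ? 0 : 1;
        int v = row[j - 1] + e;
        const int a = nrow[j - 1] + 1;
        const int b = row[j] + 1;
        if (a < v) v = a;
        if (b < v) v = b;
        nrow[j] = v;
      }
      std::swap(row, nrow);
    }
    for (int s = 0; s < n; ++s) D[s] = row[n - s];
    return D;
  }
  // column-wise with cut-off: col holds column j-1, rows above the last
  // active cell saturate at cap
  const int cap = maxDist + 1;
  std::vector<int> col(m + 2), ncol(m + 2);
  for (int i = 0; i <= m; ++i) col[i] = std::min(i, cap);
  int lac = std::min(m, maxDist);  // last active (<= maxDist) row of col 0
  if (lac + 1 <= m) col[lac + 1] = cap;
  for (int j = 1; j <= n; ++j) {
    ncol[0] = 0;
    const uint8_t tj = t[j - 1];
    const int hi = std::min(m, lac + 1);
    int newLac = 0;
    for (int i = 1; i <= hi; ++i) {
      const int e = (r[i - 1] == tj && r[i - 1] < 4) ? 0 : 1;
      int v = col[i - 1] + e;
      const int a = ncol[i - 1] + 1;
      const int b = col[i] + 1;
      if (a < v) v = a;
      if (b < v) v = b;
      if (v > cap) v = cap;
      ncol[i] = v;
      if (v <= maxDist) newLac = i;
    }
    if (hi + 1 <= m) ncol[hi + 1] = cap;
    lac = newLac;
    std::swap(col, ncol);
    // forward start s = n - j; C[m][j] is exact when row m was computed
    D[n - j] = (hi == m && col[m] <= maxDist) ? col[m] : cap;
  }
  return D;
}
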