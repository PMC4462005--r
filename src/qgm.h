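#ifndef QGM_H
#define QGM_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

// Symbol codes: A=0, C=1, G=2, T=3, N=4. Code 4 matches nothing (also used
// as the universal-mismatch sentinel that pads clamped verification windows).

inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
  }
}

inline std::vector<uint8_t> encodeSeq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = baseCode(s[i]);
    if (c < 0)
      Rcpp::stop("invalid symbol '%s' at position %d; alphabet is A,C,G,T,N",
                 std::string(1, s[i]).c_str(), (int)i + 1);
    v[i] = (uint8_t)c;
  }
  return v;
}

inline std::vector<uint8_t> revCompCodes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

struct VerifyRes {
  int dist;   // k+1 encodes "> k"
  int end;    // 0-based end offset in the window, -1 when no match
  bool cut;   // band minimum exceeded k before the last column
};

// ---------------------------------------------------------------------------
// Full semi-global dynamic programming matrix, read rows x text columns,
// semi-global boundary C[0,j] = 0, C[i,0] = i. N mismatches every symbol.
inline std::vector<int> dpMatrixCore(const uint8_t* r, int m,
                                     const uint8_t* s, int n) {
  std::vector<int> C((size_t)(m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) C[j] = 0;
  for (int i = 1; i <= m; ++i) {
    int* cur = &C[(size_t)i * (n + 1)];
    const int* up = &C[(size_t)(i - 1) * (n + 1)];
    cur[0] = i;
    const uint8_t ri = r[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int e = (ri == s[j - 1] && ri < 4) ? 0 : 1;
      int v = up[j - 1] + e;
      const int a = cur[j - 1] + 1;
      const int b = up[j] + 1;
      if (a < v) v = a;
      if (b < v) v = b;
      cur[j] = v;
    }
  }
  return C;
}

// ---------------------------------------------------------------------------
// Scalar banded Myers bit-vector verifier.
//
// The read is the text (one column step per read symbol); the window is the
// pattern. Band of width 2k+1 centred on the base diagonal (shifted k right
// of the main diagonal); the tracked score E is the band's bottom cell,
// advanced diagonally by 1 - D0[2k] each column. Pattern rows beyond the
// window length behave as the sentinel (Peq bits 0).
inline VerifyRes bandedMyersCore(const uint8_t* text, int m,
                                 const uint8_t* pat, int n,
                                 int k, bool branchCut) {
  const int w = 2 * k + 1;
  const uint64_t bandMask = (w >= 64) ? ~0ULL : ((1ULL << w) - 1);
  uint64_t VP = 0, VN = 0;
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < w && i < n; ++i)
    if (pat[i] < 4) Peq[pat[i]] |= (1ULL << i);
  long E = 0;
  for (int j = 0; j < m; ++j) {
    // re-centre the band one row down; the row entering at the bottom gets a
    // conservative +1 vertical delta (cells below the band are unknown)
    VP = ((VP >> 1) | (1ULL << (2 * k))) & bandMask;
    VN = (VN >> 1) & bandMask;
    const uint64_t Pt = (text[j] < 4) ? Peq[text[j]] : 0ULL;
    const uint64_t X = Pt | VN;
    uint64_t D0 = (((X & VP) + VP) ^ VP) | X;
    D0 &= bandMask;
    const uint64_t HP = (VN | ~(D0 | VP)) & bandMask;
    const uint64_t HN = D0 & VP;
    E += 1 - (int)((D0 >> (2 * k)) & 1ULL);
    const uint64_t X2 = (HP << 1) & bandMask;
    VN = X2 & D0;
    VP = ((HN << 1) | (~(X2 | D0) & bandMask)) & bandMask;
    for (int a = 0; a < 4; ++a) Peq[a] >>= 1;
    const int nxt = j + w;  // pattern row entering the band next column
    if (nxt < n && pat[nxt] < 4) Peq[pat[nxt]] |= (1ULL << (2 * k));
    if (branchCut && E > k && j < m - 1) {
      long v = E, mn = E;
      for (int i = 2 * k; i >= 1; --i) {
        v -= (long)((VP >> i) & 1ULL) - (long)((VN >> i) & 1ULL);
        if (v < mn) mn = v;
      }
      if (mn > k) return VerifyRes{k + 1, -1, true};
    }
  }
  // final column cells C[m+i, m], i = 0..2k, recovered from E and VP/VN
  std::vector<long> cells(w);
  cells[2 * k] = E;
  long v = E;
  for (int i = 2 * k; i >= 1; --i) {
    v -= (long)((VP >> i) & 1ULL) - (long)((VN >> i) & 1ULL);
    cells[i - 1] = v;
  }
  long best = cells[0];
  int bi = 0;
  for (int i = 1; i < w; ++i)
    if (cells[i] < best) { best = cells[i]; bi = i; }
  if (best > k) return VerifyRes{k + 1, -1, false};
  int endRow = m + bi;
  if (endRow > n) endRow = n;  // sentinel tail rows map to the clamped end
  return VerifyRes{(int)best, endRow - 1, false};
}

// ---------------------------------------------------------------------------
// Packed multi-pattern state: h slots of width s = 2k+2 (band bits 0..2k
// plus one buffer bit) in one wide word.
template <typename word>
struct PackedInit {
  word VP, VN, E;
  word Peq[4];
  word bandAll, bufferAll, baseAll, bottomAll;
  int s, h;
};

template <typename word>
PackedInit<word> packInit(const std::vector<std::vector<uint8_t> >& pats, int k) {
  const int W = (int)(sizeof(word) * 8);
  const int s = 2 * k + 2;
  PackedInit<word> P;
  P.s = s;
  P.h = W / s;
  if ((int)pats.size() > P.h)
    Rcpp::stop("too many patterns for one word: %d slots of %d bits fit in %d bits; chunk the candidate set",
               P.h, s, W);
  P.VP = P.VN = P.E = 0;
  P.bandAll = P.bufferAll = P.baseAll = P.bottomAll = 0;
  for (int a = 0; a < 4; ++a) P.Peq[a] = 0;
  const word one = 1;
  const word slotBand = (one << (2 * k + 1)) - 1;
  for (size_t l = 0; l < pats.size(); ++l) {
    const int base = s * (int)l;
    P.bandAll |= slotBand << base;
    P.bufferAll |= one << (base + s - 1);
    P.baseAll |= one << base;
    P.bottomAll |= one << (base + 2 * k);
    const std::vector<uint8_t>& p = pats[l];
    for (int i = 0; i <= 2 * k && i < (int)p.size(); ++i)
      if (p[i] < 4) P.Peq[p[i]] |= one << (base + i);
  }
  return P;
}

// One read (text) against up to h windows (patterns) simultaneously.
// Per-slot semantics identical to bandedMyersCore.
template <typename word>
std::vector<VerifyRes> packedRun(const uint8_t* text, int m,
                                 const std::vector<std::vector<uint8_t> >& pats,
                                 int k, bool branchCut, bool validate) {
  PackedInit<word> P = packInit<word>(pats, k);
  const int s = P.s;
  const int np = (int)pats.size();
  const word one = 1;
  word VP = P.VP, VN = P.VN, E = P.E;
  word Peq[4] = {P.Peq[0], P.Peq[1], P.Peq[2], P.Peq[3]};
  std::vector<char> active(np, 1);
  std::vector<VerifyRes> res(np, VerifyRes{k + 1, -1, false});
  int nActive = np;
  int j = 0;
  for (; j < m && nActive > 0; ++j) {
    VP = ((VP >> 1) & P.bandAll) | P.bottomAll;
    VN = (VN >> 1) & P.bandAll;
    const word Pt = (text[j] < 4) ? Peq[text[j]] : (word)0;
    const word X = Pt | VN;
    word D0 = (((X & VP) + VP) ^ VP) | X;
    D0 &= P.bandAll;
    const word HP = (VN | ~(D0 | VP)) & P.bandAll;
    const word HN = D0 & VP;
    // E slots: += 1 - D0[bottom], saturating once the buffer bit is reached
    // (a saturated slot is already provably > k)
    word inc = ((~D0) >> (2 * k)) & P.baseAll;
    inc &= ~((E >> (s - 1)) & P.baseAll);
    E += inc;
    const word X2 = (HP << 1) & P.bandAll;
    VN = X2 & D0;
    VP = ((HN << 1) | (~(X2 | D0) & P.bandAll)) & P.bandAll;
    // shift Peq right one row; the cross-slot leak is removed by the band
    // mask, then each pattern's next symbol enters at the slot top
    for (int a = 0; a < 4; ++a) Peq[a] = (Peq[a] >> 1) & P.bandAll;
    const int nxt = j + 2 * k + 1;
    for (int l = 0; l < np; ++l) {
      if (nxt < (int)pats[l].size()) {
        const uint8_t c = pats[l][nxt];
        if (c < 4) Peq[c] |= one << (s * l + 2 * k);
      }
    }
    if (validate) {
      if ((VP & VN) != 0)
        Rcpp::stop("packed state violation: VP & VN != 0 at column %d", j + 1);
      if (((VP | VN | Peq[0] | Peq[1] | Peq[2] | Peq[3]) & P.bufferAll) != 0)
        Rcpp::stop("packed state violation: buffer bit set at column %d", j + 1);
    }
    if (branchCut && j < m - 1) {
      for (int l = 0; l < np; ++l) {
        if (!active[l]) continue;
        const long El = (long)((E >> (s * l)) & ((one << s) - 1));
        if (El <= k) continue;
        long v = El, mn = El;
        for (int i = 2 * k; i >= 1; --i) {
          v -= (long)((VP >> (s * l + i)) & 1) - (long)((VN >> (s * l + i)) & 1);
          if (v < mn) mn = v;
        }
        if (mn > k) {
          active[l] = 0;
          res[l] = VerifyRes{k + 1, -1, true};
          --nActive;
        }
      }
    }
  }
  if (j == m) {
    for (int l = 0; l < np; ++l) {
      if (!active[l]) continue;
      const long El = (long)((E >> (s * l)) & ((one << s) - 1));
      std::vector<long> cells(2 * k + 1);
      cells[2 * k] = El;
      long v = El;
      for (int i = 2 * k; i >= 1; --i) {
        v -= (long)((VP >> (s * l + i)) & 1) - (long)((VN >> (s * l + i)) & 1);
        cells[i - 1] = v;
      }
      long best = cells[0];
      int bi = 0;
      for (int i = 1; i <= 2 * k; ++i)
        if (cells[i] < best) { best = cells[i]; bi = i; }
      if (best > k) {
        res[l] = VerifyRes{k + 1, -1, false};
      } else {
        int endRow = m + bi;
        const int n = (int)pats[l].size();
        if (endRow > n) endRow = n;
        res[l] = VerifyRes{(int)best, endRow - 1, false};
      }
    }
  }
  return res;
}

// ---------------------------------------------------------------------------
// CIGAR traceback over the full DP matrix of (read, window).
// Tie preference diagonal > up > left. Head operations that consume leading
// sentinel columns (padLeft of them) are re-expressed as insertions so the
// reported alignment start never precedes the record.
struct TBRes {
  std::string cigar;
  int nm;
  int alnStart;
  int dist;
};

inline TBRes tracebackCore(const std::vector<uint8_t>& r,
                           const std::vector<uint8_t>& w,
                           int k, int bestEnd, int padLeft) {
  const int m = (int)r.size(), n = (int)w.size();
  if (bestEnd < 0 || bestEnd >= n)
    Rcpp::stop("best_end %d out of range for window of length %d", bestEnd, n);
  std::vector<int> C = dpMatrixCore(r.data(), m, w.data(), n);
  const int stride = n + 1;
  const int jEnd = bestEnd + 1;
  const int dist = C[(size_t)m * stride + jEnd];
  if (dist > k)
    Rcpp::stop("traceback called on a non-match: distance %d at best_end exceeds k = %d", dist, k);
  std::string ops;
  int i = m, j = jEnd;
  while (i > 0) {
    const int e = (j > 0 && r[i - 1] == w[j - 1] && r[i - 1] < 4) ? 0 : 1;
    if (j > 0 && C[(size_t)i * stride + j] == C[(size_t)(i - 1) * stride + j - 1] + e) {
      ops.push_back('M'); --i; --j;
    } else if (C[(size_t)i * stride + j] == C[(size_t)(i - 1) * stride + j] + 1) {
      ops.push_back('I'); --i;
    } else {
      ops.push_back('D'); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int alnStart = j;
  if (alnStart < padLeft) {
    int col = alnStart;
    for (size_t p = 0; p < ops.size() && col < padLeft; ++p) {
      if (ops[p] == 'M') { ops[p] = 'I'; ++col; }
      else if (ops[p] == 'D') { ++col; }  // unreachable on an optimal path
    }
    alnStart = col;
  }
  // collapse runs; nm = substitutions + insertions + deletions = path cost
  std::string cig;
  int nm = 0;
  {
    int runLen = 0;
    char runOp = 0;
    int ci = alnStart;  // window column under the diagonal pointer
    int ri = 0;
    for (size_t p = 0; p < ops.size(); ++p) {
      const char op = ops[p];
      if (op == 'M') {
        if (!(r[ri] == w[ci] && r[ri] < 4)) ++nm;
        ++ri; ++ci;
      } else if (op == 'I') {
        ++nm; ++ri;
      } else {
        ++nm; ++ci;
      }
      if (op == runOp) ++runLen;
      else {
        if (runLen > 0) { cig += std::to_string(runLen); cig.push_back(runOp); }
        runOp = op; runLen = 1;
      }
    }
    if (runLen > 0) { cig += std::to_string(runLen); cig.push_back(runOp); }
  }
  TBRes out;
  out.cigar = cig;
  out.nm = nm;
  out.alnStart = alnStart;
  out.dist = dist;
  return out;
}

#endif
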