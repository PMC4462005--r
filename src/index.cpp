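#include "qgm.h"
using namespace Rcpp;

// 2-bit packed key of a q-gram; q <= 16 so the key fits 32 bits (returned as
// a double, which is exact far beyond that). ok = false when the gram
// contains N.
static inline uint64_t gramKey(const uint8_t* s, int q, bool& ok) {
  uint64_t key = 0;
  ok = true;
  for (int i = 0; i < q; ++i) {
    if (s[i] > 3) { ok = false; return 0; }
    key = (key << 2) | s[i];
  }
  return key;
}

// [[Rcpp::export]]
double cpp_gram_key(std::string gram) {
  std::vector<uint8_t> g = encodeSeq(gram);
  bool ok;
  uint64_t key = gramKey(g.data(), (int)g.size(), ok);
  return ok ? (double)key : -1.0;
}

// Build the q-gram index over every position whose gram is N-free and lies
// within a single record. Returns a CSR layout: sorted unique keys, per-key
// offsets into the ascending global position vector.
// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, int q) {
  std::vector<std::pair<uint64_t, int> > pairs;
  double offset = 0;
  for (int r = 0; r < seqs.size(); ++r) {
    const std::string s = as<std::string>(seqs[r]);
    const std::vector<uint8_t> enc = encodeSeq(s);
    const int len = (int)enc.size();
    if (offset + len > 2147483647.0)
      stop("genome longer than 2^31-1 is not supported by the 32-bit position index");
    uint64_t key = 0;
    int valid = 0;  // symbols since the last N
    const uint64_t mask = (q == 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
    for (int i = 0; i < len; ++i) {
      if (enc[i] > 3) {
        valid = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | enc[i]) & mask;
      if (++valid >= q)
        pairs.push_back(std::make_pair(key, (int)offset + i - q + 1));
    }
    offset += len;
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<double> keys;
  std::vector<int> starts;
  IntegerVector positions((int)pairs.size());
  for (size_t i = 0; i < pairs.size(); ++i) {
    if (i == 0 || pairs[i].first != pairs[i - 1].first) {
      keys.push_back((double)pairs[i].first);
      starts.push_back((int)i);
    }
    positions[(int)i] = pairs[i].second;
  }
  starts.push_back((int)pairs.size());
  return List::create(_["keys"] = NumericVector(keys.begin(), keys.end()),
                      _["starts"] = IntegerVector(starts.begin(), starts.end()),
                      _["positions"] = positions);
}

// [[Rcpp::export]]
IntegerVector cpp_lookup(NumericVector keys, IntegerVector starts,
                         IntegerVector positions, double key) {
  if (key < 0) return IntegerVector(0);
  const double* lo = std::lower_bound(keys.begin(), keys.end(), key);
  if (lo == keys.end() || *lo != key) return IntegerVector(0);
  const int ki = (int)(lo - keys.begin());
  const int a = starts[ki], b = starts[ki + 1];
  IntegerVector out(b - a);
  for (int i = a; i < b; ++i) out[i - a] = positions[i];
  return out;
}

// FNV-1a over the record sequences (with separators), used to tie an index
// file to the genome it was built from.
// [[Rcpp::export]]
std::string cpp_digest(CharacterVector seqs) {
  uint64_t h = 14695981039346656037ULL;
  for (int r = 0; r < seqs.size(); ++r) {
    const std::string s = as<std::string>(seqs[r]);
    for (size_t i = 0; i < s.size(); ++i) {
      h ^= (uint8_t)s[i];
      h *= 1099511628211ULL;
    }
    h ^= 0xff;
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
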