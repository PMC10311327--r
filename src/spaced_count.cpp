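#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cctype>
using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Canonical form: lexicographic min of the spaced k-mer and its reverse
// complement (A < C < G < T, i.e. plain ASCII order).
static inline void canonical_inplace(std::string &kmer, std::string &rc) {
  const int w = (int) kmer.size();
  for (int j = 0; j < w; ++j) rc[j] = complement_base(kmer[w - 1 - j]);
  if (rc < kmer) kmer = rc;
}

// Scan every length-l window of `seq` (upper-cased) and emit the spaced
// k-mer at the seed's care positions.  A window is skipped iff a non-ACGT
// symbol sits on a care position; don't-care columns tolerate anything.
template <typename Sink>
static void scan_sequence(const std::string &seq_in, const std::vector<int> &care,
                          int l, bool canonical, long long &windows_total,
                          long long &windows_skipped, Sink &&sink) {
  std::string seq = seq_in;
  for (auto &c : seq) c = (char) std::toupper((unsigned char) c);
  const int w = (int) care.size();
  const int n = (int) seq.size();
  std::string kmer(w, 'N'), rc(w, 'N');
  for (int pos = 0; pos + l <= n; ++pos) {
    ++windows_total;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      char c = seq[pos + care[j]];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
      kmer[j] = c;
    }
    if (!ok) { ++windows_skipped; continue; }
    if (canonical) canonical_inplace(kmer, rc);
    sink(kmer);
  }
}

static std::vector<int> care_positions(const std::string &pattern) {
  std::vector<int> care;
  for (int i = 0; i < (int) pattern.size(); ++i)
    if (pattern[i] == '1') care.push_back(i);
  return care;
}

// [[Rcpp::export]]
List cpp_spaced_count(CharacterVector seqs, std::string pattern, bool canonical) {
  const std::vector<int> care = care_positions(pattern);
  const int l = (int) pattern.size();
  std::unordered_map<std::string, double> tab;
  long long wt = 0, ws = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const std::string seq = as<std::string>(seqs[s]);
    scan_sequence(seq, care, l, canonical, wt, ws,
                  [&](const std::string &k) { tab[k] += 1.0; });
  }
  const R_xlen_t m = (R_xlen_t) tab.size();
  CharacterVector kmers(m);
  NumericVector counts(m);
  R_xlen_t i = 0;
  for (const auto &kv : tab) { kmers[i] = kv.first; counts[i] = kv.second; ++i; }
  return List::create(_["kmer"] = kmers, _["count"] = counts,
                      _["windows_total"] = (double) wt,
                      _["windows_skipped"] = (double) ws);
}

// [[Rcpp::export]]
CharacterVector cpp_spaced_kmers(std::string seq, std::string pattern, bool canonical) {
  const std::vector<int> care = care_positions(pattern);
  const int l = (int) pattern.size();
  long long wt = 0, ws = 0;
  std::vector<std::string> out;
  scan_sequence(seq, care, l, canonical, wt, ws,
                [&](const std::string &k) { out.push_back(k); });
  return wrap(out);
}
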