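// Exact affine-gap Smith-Waterman primitives used by the BBH / AAI / ANI layers.
// A gap of length L costs open + L * ext (BLAST convention: the first gapped
// residue pays both the opening and one extension).
#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

namespace {

struct AlnResult {
  int score = 0;
  int aln_len = 0;      // aligned columns incl. gaps
  int n_ident = 0;      // identical residue columns
  int q_start = 0, q_end = -1;  // 0-based inclusive; empty if score == 0
  int s_start = 0, s_end = -1;
};

// char -> row index of the scoring matrix; -1 for unknown
void build_lookup(const std::string &alphabet, int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i) {
    lut[(unsigned char)std::toupper(alphabet[i])] = (int)i;
    lut[(unsigned char)std::tolower(alphabet[i])] = (int)i;
  }
}

std::vector<int> encode(const char *s, const int *lut, bool &ok) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  ok = true;
  for (size_t i = 0; i < n; ++i) {
    v[i] = lut[(unsigned char)s[i]];
    if (v[i] < 0) ok = false;
  }
  return v;
}

// Score-only SW, O(min(n,m)) memory rows over the subject.
int sw_score(const std::vector<int> &q, const std::vector<int> &s,
             const std::vector<int> &mat, int nal, int open, int ext) {
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> H(m + 1, 0), E(m + 1, INT_MIN / 4);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0, F = INT_MIN / 4, Hprev = 0;
    const int *row = &mat[q[i - 1] * nal];
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - open - ext, E[j] - ext);
      F = std::max(Hprev - open - ext, F - ext);
      int h = Hdiag + row[s[j - 1]];
      h = std::max(h, std::max(E[j], F));
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full SW with traceback for identity / coverage statistics.
AlnResult sw_traceback(const std::vector<int> &q, const std::vector<int> &s,
                       const std::vector<int> &mat, int nal, int open, int ext) {
  AlnResult res;
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) return res;
  const size_t W = (size_t)m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0), E(H.size(), INT_MIN / 4),
      F(H.size(), INT_MIN / 4);
  // pointers: tbH 0=stop 1=diag 2=fromE 3=fromF; tbE/tbF: 1=opened 0=extended
  std::vector<unsigned char> tbH(H.size(), 0), tbE(H.size(), 0), tbF(H.size(), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int *row = &mat[q[i - 1] * nal];
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * W + j, up = c - W, left = c - 1;
      int eo = H[left] - open - ext, ee = E[left] - ext;
      if (eo >= ee) { E[c] = eo; tbE[c] = 1; } else { E[c] = ee; tbE[c] = 0; }
      int fo = H[up] - open - ext, fe = F[up] - ext;
      if (fo >= fe) { F[c] = fo; tbF[c] = 1; } else { F[c] = fe; tbF[c] = 0; }
      int diag = H[up - 1] + row[s[j - 1]];
      int h = diag; unsigned char p = 1;
      if (E[c] > h) { h = E[c]; p = 2; }
      if (F[c] > h) { h = F[c]; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      H[c] = h; tbH[c] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best == 0) return res;
  // trace back from the best cell
  int i = bi, j = bj, state = 0;  // 0 = in H
  res.q_end = bi - 1; res.s_end = bj - 1;
  while (true) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      unsigned char p = tbH[c];
      if (p == 0) break;
      if (p == 1) {
        ++res.aln_len;
        if (q[i - 1] == s[j - 1]) ++res.n_ident;
        res.q_start = i - 1; res.s_start = j - 1;
        --i; --j;
      } else if (p == 2) state = 2;
      else state = 3;
    } else if (state == 2) {  // gap in query (consume subject)
      ++res.aln_len;
      res.s_start = j - 1;
      if (tbE[c] == 1) state = 0;
      --j;
    } else {  // gap in subject (consume query)
      ++res.aln_len;
      res.q_start = i - 1;
      if (tbF[c] == 1) state = 0;
      --i;
    }
  }
  return res;
}

// --- k-mer helpers -----------------------------------------------------------

// protein k-mers: 5 bits per residue, k <= 12
inline bool kmer_aa(const std::vector<int> &v, int pos, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int c = v[pos + i];
    if (c < 0 || c > 31) return false;
    code = (code << 5) | (uint64_t)c;
  }
  return true;
}

// nucleotide 2-bit codes (A0 C1 G2 T3, else -1)
inline int nt2(char c) {
  switch (std::toupper(c)) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

}  // namespace

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string query, std::string subject, IntegerMatrix submat,
                 std::string alphabet, int gap_open, int gap_ext) {
  int lut[256];
  build_lookup(alphabet, lut);
  bool okq, oks;
  std::vector<int> q = encode(query.c_str(), lut, okq);
  std::vector<int> s = encode(subject.c_str(), lut, oks);
  if (!okq) stop("query contains a residue outside the scoring alphabet");
  if (!oks) stop("subject contains a residue outside the scoring alphabet");
  int nal = submat.nrow();
  std::vector<int> mat(submat.begin(), submat.end());
  // submat comes in column-major; transpose into row-major for cache locality
  std::vector<int> rm((size_t)nal * nal);
  for (int i = 0; i < nal; ++i)
    for (int j = 0; j < nal; ++j) rm[(size_t)i * nal + j] = submat(i, j);
  AlnResult r = sw_traceback(q, s, rm, nal, gap_open, gap_ext);
  return List::create(
      _["score"] = r.score, _["aln_len"] = r.aln_len, _["n_ident"] = r.n_ident,
      _["q_start"] = r.q_start + 1, _["q_end"] = r.q_end + 1,
      _["s_start"] = r.s_start + 1, _["s_end"] = r.s_end + 1);
}

// Best subject hit per query: optional exact k-mer prescreen, score-only DP on
// candidates, traceback once on the winner. Ties broken toward the
// lexicographically smallest subject id.
// [[Rcpp::export(name = ".best_hits_cpp")]]
DataFrame best_hits_cpp(CharacterVector queries, CharacterVector subjects,
                        IntegerMatrix submat, std::string alphabet,
                        int gap_open, int gap_ext, int min_raw,
                        int kmer, bool prescreen) {
  int lut[256];
  build_lookup(alphabet, lut);
  int nal = submat.nrow();
  std::vector<int> rm((size_t)nal * nal);
  for (int i = 0; i < nal; ++i)
    for (int j = 0; j < nal; ++j) rm[(size_t)i * nal + j] = submat(i, j);

  int nq = queries.size(), ns = subjects.size();
  CharacterVector qnames = queries.names(), snames = subjects.names();
  std::vector<std::vector<int>> senc(ns), qenc(nq);
  for (int j = 0; j < ns; ++j) {
    bool ok; senc[j] = encode(CHAR(STRING_ELT(subjects, j)), lut, ok);
    if (!ok) stop("subject protein %s contains a residue outside the scoring alphabet",
                  std::string(snames[j]));
  }
  for (int i = 0; i < nq; ++i) {
    bool ok; qenc[i] = encode(CHAR(STRING_ELT(queries, i)), lut, ok);
    if (!ok) stop("query protein %s contains a residue outside the scoring alphabet",
                  std::string(qnames[i]));
  }

  std::unordered_map<uint64_t, std::vector<int>> index;
  if (prescreen) {
    for (int j = 0; j < ns; ++j) {
      const std::vector<int> &v = senc[j];
      uint64_t code;
      int last = (int)v.size() - kmer;
      for (int p = 0; p <= last; ++p) {
        if (!kmer_aa(v, p, kmer, code)) continue;
        std::vector<int> &lst = index[code];
        if (lst.empty() || lst.back() != j) lst.push_back(j);
      }
    }
  }

  std::vector<std::string> out_q, out_s;
  std::vector<int> out_raw, out_len, out_ident, out_qs, out_qe;
  std::vector<bool> out_tie;
  std::vector<char> seen(ns, 0);
  std::vector<int> cand;
  cand.reserve(ns);

  for (int i = 0; i < nq; ++i) {
    cand.clear();
    if (prescreen) {
      std::fill(seen.begin(), seen.end(), 0);
      const std::vector<int> &v = qenc[i];
      uint64_t code;
      int last = (int)v.size() - kmer;
      for (int p = 0; p <= last; ++p) {
        if (!kmer_aa(v, p, kmer, code)) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (int j : it->second)
          if (!seen[j]) { seen[j] = 1; cand.push_back(j); }
      }
    } else {
      for (int j = 0; j < ns; ++j) cand.push_back(j);
    }
    int best = -1, best_j = -1;
    bool tie = false;
    for (int j : cand) {
      int sc = sw_score(qenc[i], senc[j], rm, nal, gap_open, gap_ext);
      if (sc < min_raw) continue;
      if (sc > best) { best = sc; best_j = j; tie = false; }
      else if (sc == best && best >= 0) {
        tie = true;
        if (std::string(snames[j]) < std::string(snames[best_j])) best_j = j;
      }
    }
    if (best_j < 0) continue;
    AlnResult r = sw_traceback(qenc[i], senc[best_j], rm, nal, gap_open, gap_ext);
    out_q.push_back(std::string(qnames[i]));
    out_s.push_back(std::string(snames[best_j]));
    out_raw.push_back(r.score);
    out_len.push_back(r.aln_len);
    out_ident.push_back(r.n_ident);
    out_qs.push_back(r.q_start + 1);
    out_qe.push_back(r.q_end + 1);
    out_tie.push_back(tie);
  }
  return DataFrame::create(
      _["query_id"] = out_q, _["subject_id"] = out_s, _["raw_score"] = out_raw,
      _["aln_len"] = out_len, _["n_ident"] = out_ident,
      _["q_start"] = out_qs, _["q_end"] = out_qe, _["tie"] = out_tie,
      _["stringsAsFactors"] = false);
}

// One-way fragment ANI: cut query contigs into consecutive frag_len windows,
// place each by its best-supported k-mer diagonal in the subject, then run the
// exact affine-gap DP against a window around that diagonal.
// [[Rcpp::export(name = ".ani_fragments_cpp")]]
DataFrame ani_fragments_cpp(CharacterVector query_contigs,
                            CharacterVector subject_contigs,
                            int frag_len, int kmer,
                            int match, int mismatch, int gap_open, int gap_ext) {
  // 4-letter scoring matrix for nucleotides
  const int nal = 4;
  std::vector<int> rm(16);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) rm[i * 4 + j] = (i == j) ? match : mismatch;

  int nsc = subject_contigs.size();
  std::vector<std::vector<int>> senc(nsc);
  for (int c = 0; c < nsc; ++c) {
    const char *s = CHAR(STRING_ELT(subject_contigs, c));
    size_t L = std::strlen(s);
    senc[c].resize(L);
    for (size_t p = 0; p < L; ++p) senc[c][p] = nt2(s[p]);
  }
  // k-mer index: code -> packed (contig, pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  for (int c = 0; c < nsc; ++c) {
    const std::vector<int> &v = senc[c];
    if ((int)v.size() < kmer) continue;
    uint64_t code = 0, mask = (kmer < 32) ? ((1ULL << (2 * kmer)) - 1) : ~0ULL;
    int run = 0;
    for (size_t p = 0; p < v.size(); ++p) {
      if (v[p] < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)v[p]) & mask;
      if (++run >= kmer)
        index[code].push_back(((uint64_t)c << 40) | (uint64_t)(p - kmer + 1));
    }
  }

  std::vector<int> frag_id, frag_contig;
  std::vector<int> frag_start;
  std::vector<double> pid, cov;
  int id = 0;
  for (int qc = 0; qc < query_contigs.size(); ++qc) {
    const char *qs = CHAR(STRING_ELT(query_contigs, qc));
    int L = (int)std::strlen(qs);
    for (int fs = 0; fs + frag_len <= L; fs += frag_len) {
      ++id;
      std::vector<int> frag(frag_len);
      bool any = false;
      for (int p = 0; p < frag_len; ++p) frag[p] = nt2(qs[fs + p]);
      // vote for (contig, diagonal)
      std::unordered_map<uint64_t, int> votes;
      uint64_t code = 0, mask = (kmer < 32) ? ((1ULL << (2 * kmer)) - 1) : ~0ULL;
      int run = 0;
      for (int p = 0; p < frag_len; ++p) {
        if (frag[p] < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)frag[p]) & mask;
        if (++run < kmer) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        int fpos = p - kmer + 1;
        for (uint64_t packed : it->second) {
          int c = (int)(packed >> 40);
          long long spos = (long long)(packed & ((1ULL << 40) - 1));
          long long diag = spos - fpos;  // subject start of the fragment
          uint64_t key = ((uint64_t)c << 42) | (uint64_t)(diag + (1LL << 41));
          ++votes[key];
          any = true;
        }
      }
      frag_id.push_back(id);
      frag_contig.push_back(qc + 1);
      frag_start.push_back(fs + 1);
      if (!any) { pid.push_back(NA_REAL); cov.push_back(0.0); continue; }
      uint64_t best_key = 0; int best_votes = -1;
      for (auto &kv : votes) {
        if (kv.second > best_votes ||
            (kv.second == best_votes && kv.first < best_key)) {
          best_votes = kv.second; best_key = kv.first;
        }
      }
      int c = (int)(best_key >> 42);
      long long diag = (long long)(best_key & ((1ULL << 42) - 1)) - (1LL << 41);
      long long w0 = diag - frag_len / 2;
      long long w1 = diag + frag_len + frag_len / 2;
      if (w0 < 0) w0 = 0;
      if (w1 > (long long)senc[c].size()) w1 = (long long)senc[c].size();
      if (w1 <= w0) { pid.push_back(NA_REAL); cov.push_back(0.0); continue; }
      std::vector<int> win(senc[c].begin() + w0, senc[c].begin() + w1);
      // replace ambiguous bases by a mismatch-to-everything dummy: map -1 -> 0
      // after remembering positions would bias identity; instead drop frags/wins
      // with N by scoring N as mismatch via a 5th letter
      bool frag_has_n = false;
      for (int &x : frag) if (x < 0) { frag_has_n = true; break; }
      bool win_has_n = false;
      for (int &x : win) if (x < 0) { win_has_n = true; break; }
      std::vector<int> rm5;
      const std::vector<int> *usemat = &rm;
      int use_nal = nal;
      if (frag_has_n || win_has_n) {
        rm5.assign(25, mismatch);
        for (int i = 0; i < 4; ++i) rm5[i * 5 + i] = match;
        for (int i = 0; i < 5; ++i) { rm5[i * 5 + 4] = mismatch; rm5[4 * 5 + i] = mismatch; }
        for (int &x : frag) if (x < 0) x = 4;
        for (int &x : win) if (x < 0) x = 4;
        usemat = &rm5;
        use_nal = 5;
      }
      AlnResult r = sw_traceback(frag, win, *usemat, use_nal, gap_open, gap_ext);
      if (r.score <= 0 || r.aln_len == 0) {
        pid.push_back(NA_REAL); cov.push_back(0.0); continue;
      }
      pid.push_back(100.0 * r.n_ident / r.aln_len);
      cov.push_back((double)(r.q_end - r.q_start + 1) / frag_len);
    }
  }
  return DataFrame::create(
      _["fragment"] = frag_id, _["contig"] = frag_contig,
      _["start"] = frag_start, _["pident"] = pid, _["coverage"] = cov,
      _["stringsAsFactors"] = false);
}
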