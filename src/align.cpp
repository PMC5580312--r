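#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length L costs open + L * ext
// (both positive penalties), i.e. the first gapped residue costs open + ext.

struct SWResult {
  double score;
  int aln_len, n_ident;
  int a_start, a_end, b_start, b_end; // 1-based inclusive, 0 when empty
};

// Smith-Waterman, affine gaps, full traceback statistics.
// a, b: 0-based indices into the substitution matrix alphabet.
// Best cell: highest score, ties broken by smallest (i, j).
// Traceback move preference: diagonal > up (gap in b) > left (gap in a).
static SWResult sw_core(const std::vector<int>& a, const std::vector<int>& b,
                        const NumericMatrix& mat, double open, double ext,
                        bool traceback) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  SWResult res = {0.0, 0, 0, 0, 0, 0, 0};
  if (n == 0 || m == 0) return res;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG); // ending with gap in a (left)
  std::vector<double> F((n + 1) * (m + 1), NEG); // ending with gap in b (up)
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[idx(i, j - 1)] - open - ext, E[idx(i, j - 1)] - ext);
      double f = std::max(H[idx(i - 1, j)] - open - ext, F[idx(i - 1, j)] - ext);
      double d = H[idx(i - 1, j - 1)] + mat(a[i - 1], b[j - 1]);
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0.0 || !traceback) return res;
  // traceback from (bi, bj) in state H
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (left), 2 = F (up)
  int aln = 0, ident = 0, ai_end = bi, bj_end = bj, ai_start = bi, bj_start = bj;
  const double tol = 1e-9;
  while (i > 0 && j > 0) {
    if (state == 0) {
      double h = H[idx(i, j)];
      if (h <= tol) break;
      double d = H[idx(i - 1, j - 1)] + mat(a[i - 1], b[j - 1]);
      if (std::abs(h - d) < tol) {
        ++aln; if (a[i - 1] == b[j - 1]) ++ident;
        ai_start = i; bj_start = j; --i; --j;
      } else if (std::abs(h - F[idx(i, j)]) < tol) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) { // gap in b, consume a[i]
      ++aln; ai_start = i;
      double f = F[idx(i, j)];
      if (std::abs(f - (H[idx(i - 1, j)] - open - ext)) < tol) state = 0;
      --i;
    } else { // state == 1: gap in a, consume b[j]
      ++aln; bj_start = j;
      double e = E[idx(i, j)];
      if (std::abs(e - (H[idx(i, j - 1)] - open - ext)) < tol) state = 0;
      --j;
    }
  }
  res.aln_len = aln; res.n_ident = ident;
  res.a_start = ai_start; res.a_end = ai_end;
  res.b_start = bj_start; res.b_end = bj_end;
  return res;
}

static std::vector<int> as_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_ext) {
  SWResult r = sw_core(as_vec(a), as_vec(b), mat, gap_open, gap_ext, true);
  return List::create(_["score"] = r.score, _["aln_len"] = r.aln_len,
                      _["n_ident"] = r.n_ident,
                      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
                      _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

// k-mer fingerprints: sorted vectors of k-mer codes (base = alphabet size)
static std::vector<int> kmer_codes(const std::vector<int>& s, int k, int base) {
  std::vector<int> out;
  if ((int)s.size() < k) return out;
  for (size_t i = 0; i + k <= s.size(); ++i) {
    int code = 0;
    for (int j = 0; j < k; ++j) code = code * base + s[i + j];
    out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static int n_shared(const std::vector<int>& x, const std::vector<int>& y) {
  int n = 0; size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (x[i] > y[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// Batched all-vs-all: for each requested pair run the BLOSUM62 prefilter
// alignment (score only); if its raw score reaches raw62_min, run the
// BLOSUM50 alignment with traceback statistics. Pairs sharing fewer than
// min_shared k-mers are skipped outright (kept = 0 rows are dropped in R).
// Returns a matrix with one row per pair:
// kept, raw62, raw50, aln_len, n_ident, a_start, a_end, b_start, b_end
// [[Rcpp::export(name = ".cpp_sw_batch")]]
NumericMatrix cpp_sw_batch(List seqs, IntegerVector ia, IntegerVector ib,
                           NumericMatrix mat50, NumericMatrix mat62,
                           double gap_open, double gap_ext,
                           double raw62_min, int kmer_k, int min_shared) {
  const int ns = seqs.size(), np = ia.size();
  std::vector<std::vector<int> > sq(ns);
  for (int i = 0; i < ns; ++i) sq[i] = as_vec(seqs[i]);
  const int base = mat50.nrow();
  std::vector<std::vector<int> > fp(ns);
  if (min_shared > 0)
    for (int i = 0; i < ns; ++i) fp[i] = kmer_codes(sq[i], kmer_k, base);
  NumericMatrix out(np, 9);
  for (int p = 0; p < np; ++p) {
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
    int u = ia[p] - 1, v = ib[p] - 1;
    if (min_shared > 0 && n_shared(fp[u], fp[v]) < min_shared) continue;
    SWResult pre = sw_core(sq[u], sq[v], mat62, gap_open, gap_ext, false);
    out(p, 1) = pre.score;
    if (pre.score < raw62_min) continue;
    SWResult r = sw_core(sq[u], sq[v], mat50, gap_open, gap_ext, true);
    out(p, 0) = 1;
    out(p, 2) = r.score; out(p, 3) = r.aln_len; out(p, 4) = r.n_ident;
    out(p, 5) = r.a_start; out(p, 6) = r.a_end;
    out(p, 7) = r.b_start; out(p, 8) = r.b_end;
  }
  return out;
}

// Profile-profile global alignment (Needleman-Wunsch, affine gaps, terminal
// gaps penalised). Profiles are integer matrices: rows = sequences, columns =
// alignment columns, entries = matrix alphabet indices or -1 for a gap.
// Column score = mean of mat over all residue pairs (gapped pairs score 0).
// Returns two integer vectors mapping merged columns to source columns
// (1-based) or 0 for a newly introduced gap.
// [[Rcpp::export(name = ".cpp_profile_align")]]
List cpp_profile_align(IntegerMatrix pa, IntegerMatrix pb, NumericMatrix mat,
                       double gap_open, double gap_ext) {
  const int n = pa.ncol(), m = pb.ncol();
  const int ra = pa.nrow(), rb = pb.nrow();
  const double NEG = -1e30;
  // precompute column pair scores
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int x = 0; x < ra; ++x) {
        int cx = pa(x, i);
        if (cx < 0) continue;
        for (int y = 0; y < rb; ++y) {
          int cy = pb(y, j);
          if (cy < 0) continue;
          s += mat(cx, cy);
        }
      }
      S(i, j) = s / (double)(ra * rb);
    }
  std::vector<double> H((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  H[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) E[idx(0, j)] = -gap_open - gap_ext * j;
  for (int i = 1; i <= n; ++i) F[idx(i, 0)] = -gap_open - gap_ext * i;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double hl = std::max(H[idx(i, j - 1)], F[idx(i, j - 1)]);
      E[idx(i, j)] = std::max(hl - gap_open - gap_ext, E[idx(i, j - 1)] - gap_ext);
      double hu = std::max(H[idx(i - 1, j)], E[idx(i - 1, j)]);
      F[idx(i, j)] = std::max(hu - gap_open - gap_ext, F[idx(i - 1, j)] - gap_ext);
      double prev = std::max(H[idx(i - 1, j - 1)],
                             std::max(E[idx(i - 1, j - 1)], F[idx(i - 1, j - 1)]));
      H[idx(i, j)] = prev + S(i - 1, j - 1);
    }
  // traceback from the best of the three states at (n, m)
  std::vector<int> ca, cb;
  int i = n, j = m;
  int state; // 0 H, 1 E (left, gap in a), 2 F (up, gap in b)
  {
    double h = H[idx(n, m)], e = E[idx(n, m)], f = F[idx(n, m)];
    state = (h >= e && h >= f) ? 0 : (f >= e ? 2 : 1);
  }
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { ca.push_back(0); cb.push_back(j); --j; continue; }
    if (j == 0) { ca.push_back(i); cb.push_back(0); --i; continue; }
    if (state == 0) {
      ca.push_back(i); cb.push_back(j);
      double prev = H[idx(i, j)] - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(prev - H[idx(i, j)]) < tol) state = 0;
      else if (std::abs(prev - F[idx(i, j)]) < tol) state = 2;
      else state = 1;
    } else if (state == 2) { // gap in b
      ca.push_back(i); cb.push_back(0);
      double f = F[idx(i, j)];
      double hu = std::max(H[idx(i - 1, j)], E[idx(i - 1, j)]);
      if (std::abs(f - (hu - gap_open - gap_ext)) < tol) {
        --i;
        if (std::abs(hu - H[idx(i, j)]) < tol) state = 0; else state = 1;
      } else { --i; state = 2; }
    } else { // gap in a
      ca.push_back(0); cb.push_back(j);
      double e = E[idx(i, j)];
      double hl = std::max(H[idx(i, j - 1)], F[idx(i, j - 1)]);
      if (std::abs(e - (hl - gap_open - gap_ext)) < tol) {
        --j;
        if (std::abs(hl - H[idx(i, j)]) < tol) state = 0; else state = 2;
      } else { --j; state = 1; }
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  return List::create(_["a"] = wrap(ca), _["b"] = wrap(cb));
}
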