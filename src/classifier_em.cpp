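// EM fitting of extended-haplotype (SNP pattern + HLA allele) frequency
// tables from unphased genotypes with known unordered HLA pairs, and
// diplotype posterior prediction from such tables.
//
// SNP patterns over a classifier subset of k <= 25 sites are bit-encoded
// in a uint32 (bit i = alternate allele at subset site i). All sums over
// phase configurations use ordered haplotype pairs, so heterozygous
// diplotypes are automatically counted twice.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

typedef std::pair<uint32_t, uint32_t> upair;

// Enumerate ordered completions (p1, p2) of one genotype row.
// g: length-k vector with values 0/1/2 or NA (missing site: both alleles
// free on both haplotypes, i.e. the site is marginalised).
// Returns false if the enumeration would exceed max_pairs.
static bool enumerate_pairs(const int *g, int k, std::vector<upair> &out,
                            size_t max_pairs) {
  out.clear();
  out.push_back(upair(0u, 0u));
  static const int opt_na[4][2] = {{0, 0}, {0, 1}, {1, 0}, {1, 1}};
  static const int opt_het[2][2] = {{0, 1}, {1, 0}};
  for (int i = 0; i < k; ++i) {
    const int (*opts)[2];
    int n_opt;
    int gi = g[i];
    if (gi == NA_INTEGER) { opts = opt_na; n_opt = 4; }
    else if (gi == 0) { static const int o[1][2] = {{0, 0}}; opts = o; n_opt = 1; }
    else if (gi == 2) { static const int o[1][2] = {{1, 1}}; opts = o; n_opt = 1; }
    else { opts = opt_het; n_opt = 2; }
    if (n_opt == 1 && opts[0][0] == opts[0][1]) {
      if (opts[0][0] == 1) {
        uint32_t bit = 1u << i;
        for (size_t j = 0; j < out.size(); ++j) {
          out[j].first |= bit;
          out[j].second |= bit;
        }
      }
      continue;
    }
    size_t cur = out.size();
    if (cur * n_opt > max_pairs) { out.clear(); return false; }
    std::vector<upair> nxt;
    nxt.reserve(cur * n_opt);
    for (size_t j = 0; j < cur; ++j)
      for (int o = 0; o < n_opt; ++o)
        nxt.push_back(upair(out[j].first | ((uint32_t)opts[o][0] << i),
                            out[j].second | ((uint32_t)opts[o][1] << i)));
    out.swap(nxt);
  }
  return true;
}

// Fit extended-haplotype frequencies by EM.
// geno: N x k dosage matrix (0/1/2/NA); hla: N x 2 zero-based allele codes
// (unordered; homozygotes repeat the code). Returns the pruned, renormalised
// frequency table plus per-sample drop indicators (samples whose phase
// enumeration exceeds max_pairs contribute nothing and are flagged).
// [[Rcpp::export(name = ".cpp_em_fit")]]
List cpp_em_fit(IntegerMatrix geno, IntegerMatrix hla, double tol,
                int max_iter, double prune, double max_pairs) {
  int N = geno.nrow(), k = geno.ncol();
  size_t cap = (size_t)max_pairs;
  std::unordered_map<uint64_t, int> hap_index; // (pattern<<16)|allele -> id
  std::vector<uint32_t> hap_pat;
  std::vector<int> hap_hla;
  std::vector<int> pair_i1, pair_i2, samp_start;
  LogicalVector dropped(N);
  std::vector<upair> pairs;
  std::vector<int> grow(k);

  int n_used = 0;
  for (int s = 0; s < N; ++s) {
    samp_start.push_back((int)pair_i1.size());
    for (int j = 0; j < k; ++j) grow[j] = geno(s, j);
    bool ok = enumerate_pairs(grow.data(), k, pairs, cap);
    if (!ok) { dropped[s] = true; continue; }
    int a = hla(s, 0), b = hla(s, 1);
    int n_ord = (a == b) ? 1 : 2;
    for (size_t p = 0; p < pairs.size(); ++p) {
      for (int o = 0; o < n_ord; ++o) {
        int ha = (o == 0) ? a : b, hb = (o == 0) ? b : a;
        uint64_t k1 = ((uint64_t)pairs[p].first << 16) | (uint64_t)ha;
        uint64_t k2 = ((uint64_t)pairs[p].second << 16) | (uint64_t)hb;
        int i1, i2;
        std::unordered_map<uint64_t, int>::iterator it = hap_index.find(k1);
        if (it == hap_index.end()) {
          i1 = (int)hap_pat.size();
          hap_index[k1] = i1;
          hap_pat.push_back(pairs[p].first);
          hap_hla.push_back(ha);
        } else i1 = it->second;
        it = hap_index.find(k2);
        if (it == hap_index.end()) {
          i2 = (int)hap_pat.size();
          hap_index[k2] = i2;
          hap_pat.push_back(pairs[p].second);
          hap_hla.push_back(hb);
        } else i2 = it->second;
        pair_i1.push_back(i1);
        pair_i2.push_back(i2);
      }
    }
    ++n_used;
  }
  samp_start.push_back((int)pair_i1.size());

  int H = (int)hap_pat.size();
  if (H == 0 || n_used == 0)
    return List::create(_["pattern"] = IntegerVector(0),
                        _["hla"] = IntegerVector(0),
                        _["freq"] = NumericVector(0),
                        _["dropped"] = dropped,
                        _["n_iter"] = 0, _["loglik"] = R_NegInf);

  std::vector<double> f(H, 1.0 / H), cnt(H);
  int iter = 0;
  double denom = 2.0 * n_used;
  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int s = 0; s < N; ++s) {
      int lo = samp_start[s], hi = samp_start[s + 1];
      if (lo == hi) continue;
      double tot = 0.0;
      for (int p = lo; p < hi; ++p) tot += f[pair_i1[p]] * f[pair_i2[p]];
      if (tot <= 0.0) continue;
      for (int p = lo; p < hi; ++p) {
        double w = f[pair_i1[p]] * f[pair_i2[p]] / tot;
        cnt[pair_i1[p]] += w;
        cnt[pair_i2[p]] += w;
      }
    }
    double maxdiff = 0.0;
    for (int h = 0; h < H; ++h) {
      double fn = cnt[h] / denom;
      double d = fn > f[h] ? fn - f[h] : f[h] - fn;
      if (d > maxdiff) maxdiff = d;
      f[h] = fn;
    }
    if (maxdiff < tol) break;
  }

  // prune tiny frequencies, renormalise
  double tot = 0.0;
  std::vector<int> keep;
  for (int h = 0; h < H; ++h)
    if (f[h] >= prune) { keep.push_back(h); tot += f[h]; }
  int Hk = (int)keep.size();
  IntegerVector out_pat(Hk), out_hla(Hk);
  NumericVector out_f(Hk);
  for (int j = 0; j < Hk; ++j) {
    out_pat[j] = (int)hap_pat[keep[j]];
    out_hla[j] = hap_hla[keep[j]];
    out_f[j] = f[keep[j]] / tot;
  }

  // observed-data log-likelihood at the pruned solution
  std::vector<double> fp(H, 0.0);
  for (int j = 0; j < Hk; ++j) fp[keep[j]] = out_f[j];
  double ll = 0.0;
  for (int s = 0; s < N; ++s) {
    int lo = samp_start[s], hi = samp_start[s + 1];
    if (lo == hi) continue;
    double ptot = 0.0;
    for (int p = lo; p < hi; ++p) ptot += fp[pair_i1[p]] * fp[pair_i2[p]];
    ll += (ptot > 0.0) ? std::log(ptot) : R_NegInf;
  }

  return List::create(_["pattern"] = out_pat, _["hla"] = out_hla,
                      _["freq"] = out_f, _["dropped"] = dropped,
                      _["n_iter"] = iter > max_iter ? max_iter : iter,
                      _["loglik"] = ll);
}

// Per-sample posteriors over unordered HLA allele pairs for one classifier.
// pattern/hlaidx/freq: the classifier table (hlaidx zero-based over the
// model allele set of size n_alleles). geno: N x k over the classifier's
// subset, columns in table bit order. Returns an N x (n_alleles*(n_alleles+1)/2)
// matrix of UNnormalised posterior mass; a zero row means the classifier has
// no support for that sample (caller skips it). Pair (a <= b) is stored at
// column a*n_alleles - a*(a-1)/2 + (b - a) (zero-based).
// [[Rcpp::export(name = ".cpp_predict")]]
NumericMatrix cpp_predict(IntegerVector pattern, IntegerVector hlaidx,
                          NumericVector freq, int n_alleles,
                          IntegerMatrix geno, double max_pairs) {
  int N = geno.nrow(), k = geno.ncol(), H = pattern.size();
  size_t cap = (size_t)max_pairs;
  int P = n_alleles * (n_alleles + 1) / 2;
  NumericMatrix post(N, P);
  // pattern -> list of (allele, freq)
  std::unordered_map<uint32_t, std::vector<std::pair<int, double> > > tab;
  for (int h = 0; h < H; ++h)
    tab[(uint32_t)pattern[h]].push_back(std::make_pair(hlaidx[h], freq[h]));

  std::vector<upair> pairs;
  std::vector<int> g(k);
  for (int s = 0; s < N; ++s) {
    bool all_na = true;
    for (int j = 0; j < k; ++j) {
      g[j] = geno(s, j);
      if (g[j] != NA_INTEGER) all_na = false;
    }
    if (all_na) continue; // classifier unusable for this sample
    if (!enumerate_pairs(g.data(), k, pairs, cap)) continue;
    for (size_t p = 0; p < pairs.size(); ++p) {
      std::unordered_map<uint32_t, std::vector<std::pair<int, double> > >::iterator
          it1 = tab.find(pairs[p].first);
      if (it1 == tab.end()) continue;
      std::unordered_map<uint32_t, std::vector<std::pair<int, double> > >::iterator
          it2 = tab.find(pairs[p].second);
      if (it2 == tab.end()) continue;
      const std::vector<std::pair<int, double> > &L1 = it1->second;
      const std::vector<std::pair<int, double> > &L2 = it2->second;
      for (size_t u = 0; u < L1.size(); ++u)
        for (size_t v = 0; v < L2.size(); ++v) {
          int a = L1[u].first, b = L2[v].first;
          if (a > b) { int t = a; a = b; b = t; }
          int col = a * n_alleles - a * (a - 1) / 2 + (b - a);
          post(s, col) += L1[u].second * L2[v].second;
        }
    }
  }
  return post;
}
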