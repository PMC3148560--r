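#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Identity-class walk from a core SNP in one direction.
//
// Carriers of the core allele are partitioned into identity classes over
// the interval covered so far; at each query SNP the weighted EHH is
//   (sum_h W_h^2 - sum_I U_I^2) / ((sum U)^2 - sum U^2),
// W_h the total weight of class h. Missing alleles (NA) mismatch
// everything, including other missings. Stops after the first value below
// `trunc` or at the chromosome end (reached_end = true).
static void walk(const IntegerMatrix& alleles,
                 const std::vector<int>& carriers,
                 const std::vector<double>& U,
                 int core, int step, double trunc,
                 std::vector<double>& out, bool& reached_end) {
  const int m = (int)carriers.size();
  const int S = alleles.ncol();
  double sumU2 = 0.0, sumU = 0.0;
  for (int i = 0; i < m; ++i) { sumU2 += U[i] * U[i]; sumU += U[i]; }
  const double denom = sumU * sumU - sumU2;
  if (denom <= 0) stop("degenerate weights: denominator <= 0");

  std::vector<int> group(m, 0);
  int ngroups = 1;
  out.clear();
  out.push_back(1.0);
  reached_end = true;

  std::unordered_map<long long, int> relabel;
  std::vector<double> W;
  for (int y = core + step; y >= 0 && y < S; y += step) {
    relabel.clear();
    int next = 0;
    for (int i = 0; i < m; ++i) {
      int a = alleles(carriers[i], y);
      if (a == NA_INTEGER) { group[i] = next++; continue; }
      long long key = (long long)group[i] * 2LL + a;
      auto it = relabel.find(key);
      if (it == relabel.end()) { relabel.emplace(key, next); group[i] = next++; }
      else group[i] = it->second;
    }
    ngroups = next;
    W.assign(ngroups, 0.0);
    for (int i = 0; i < m; ++i) W[group[i]] += U[i];
    double sumW2 = 0.0;
    for (int g = 0; g < ngroups; ++g) sumW2 += W[g] * W[g];
    double ehh = (sumW2 - sumU2) / denom;
    if (ehh < 0) ehh = 0.0;
    out.push_back(ehh);
    if (ehh < trunc) { reached_end = false; return; }
  }
}

// [[Rcpp::export]]
NumericVector ehh_walk_cpp(const IntegerMatrix& alleles,
                           const IntegerVector& carriers,
                           const NumericVector& U,
                           int core, int step, double trunc) {
  if (carriers.size() < 2) stop("need at least 2 carriers");
  std::vector<int> cv(carriers.begin(), carriers.end());
  std::vector<double> uv(U.begin(), U.end());
  std::vector<double> out;
  bool reached_end;
  walk(alleles, cv, uv, core, step, trunc, out, reached_end);
  NumericVector res(out.begin(), out.end());
  res.attr("reached_end") = reached_end;
  return res;
}

// trapezoid of the decay against |genetic distance to the core|,
// through the first point below trunc
static double trapezoid(const std::vector<double>& ehh,
                        const NumericVector& gpos, int core, int step,
                        double trunc) {
  double total = 0.0;
  for (size_t k = 1; k < ehh.size(); ++k) {
    int i0 = core + step * (int)(k - 1);
    int i1 = core + step * (int)k;
    double dg = std::fabs(gpos[i1] - gpos[i0]);
    total += dg * (ehh[k - 1] + ehh[k]) / 2.0;
    if (ehh[k] < trunc) break;
  }
  return total;
}

// uniqueness weights U(I) = m * Dbar(I) / sum_J Dbar(J) from the
// genome-wide distance matrix; unit fallback when all distances vanish
static bool uniqueness_weights(const NumericMatrix& dm,
                               const std::vector<int>& carriers,
                               std::vector<double>& U) {
  const int m = (int)carriers.size();
  U.assign(m, 1.0);
  double tot = 0.0;
  std::vector<double> dbar(m, 0.0);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j)
      if (j != i) s += dm(carriers[i], carriers[j]);
    dbar[i] = s / (m - 1);
    tot += dbar[i];
  }
  if (tot <= 0.0) return false;  // unit fallback
  double mn = dbar[0], mx = dbar[0];
  for (int i = 1; i < m; ++i) {
    if (dbar[i] < mn) mn = dbar[i];
    if (dbar[i] > mx) mx = dbar[i];
  }
  if (mn == mx) return true;     // equidistant carriers: exactly unit
  for (int i = 0; i < m; ++i) U[i] = m * dbar[i] / tot;
  return true;
}

// Integrated-EHH genome scan (shared by the iHS and WiHS drivers).
//
// For every SNP with no missing allele and minor allele frequency >=
// maf_min, walks the EHH decay of the derived (1) and ancestral (0)
// allele in both directions and integrates each on the genetic map. When
// `dm` is a matrix, carriers are weighted by their uniqueness; when NULL,
// unit weights.
//
// status: 0 = ok, 1 = too few carriers of one allele, 2 = a decay hit the
// chromosome end before dropping below trunc (boundary).
// op_count accumulates carriers x steps over all walks.
// [[Rcpp::export]]
List scan_integrated_cpp(const IntegerMatrix& alleles,
                         const NumericVector& gpos,
                         double maf_min, double trunc,
                         Nullable<NumericMatrix> dm) {
  const int n = alleles.nrow();
  const int S = alleles.ncol();
  const bool weighted = dm.isNotNull();
  NumericMatrix dmv;
  if (weighted) dmv = dm.get();

  std::vector<int> pass;
  pass.reserve(S);
  std::vector<double> freq(S, 0.0);
  for (int j = 0; j < S; ++j) {
    int c1 = 0;
    bool na = false;
    for (int i = 0; i < n; ++i) {
      int a = alleles(i, j);
      if (a == NA_INTEGER) { na = true; break; }
      c1 += a;
    }
    if (na) continue;
    double f = (double)c1 / n;
    freq[j] = f;
    if (std::min(f, 1.0 - f) >= maf_min && c1 > 0 && c1 < n)
      pass.push_back(j);
  }

  const int P = (int)pass.size();
  NumericVector iwA(P, NA_REAL), iwD(P, NA_REAL), fr(P);
  IntegerVector status(P), idx(P);
  double op_count = 0.0;

  std::vector<int> carriers;
  std::vector<double> U, decay;
  bool reached;

  for (int k = 0; k < P; ++k) {
    int j = pass[k];
    idx[k] = j + 1;       // 1-based for R
    fr[k] = freq[j];
    double iw[2];
    int st = 0;
    for (int allele = 0; allele <= 1 && st != 1; ++allele) {
      carriers.clear();
      for (int i = 0; i < n; ++i)
        if (alleles(i, j) == allele) carriers.push_back(i);
      if (carriers.size() < 2) { st = 1; break; }
      if (weighted) uniqueness_weights(dmv, carriers, U);
      else U.assign(carriers.size(), 1.0);

      double total = 0.0;
      for (int step = -1; step <= 1; step += 2) {
        walk(alleles, carriers, U, j, step, trunc, decay, reached);
        op_count += (double)carriers.size() * (double)(decay.size() - 1);
        if (reached && st == 0) st = 2;
        total += trapezoid(decay, gpos, j, step, trunc);
      }
      iw[allele] = total;
    }
    status[k] = st;
    if (st != 1) { iwA[k] = iw[0]; iwD[k] = iw[1]; }
  }

  return List::create(_["snp_index"] = idx, _["derived_freq"] = fr,
                      _["iwEHH_A"] = iwA, _["iwEHH_D"] = iwD,
                      _["status"] = status, _["op_count"] = op_count);
}

// PHS accumulation over all haplotype pairs.
//
// For each unordered pair (i,j) computes, at every SNP x, the genetic
// length d of the maximal interval containing x over which i and j are
// identical (0 when they differ at x; missing counts as a mismatch),
// z-standardizes d within the pair across all SNPs (sample SD), and
// accumulates the z scores into a per-SNP sum over all pairs and a per-SNP
// sum over pairs in which both members carry the derived allele at x.
//
// Returns: all_sum (S), der_sum (S), der_pairs (S), n_pairs, n_zero_sd.
// [[Rcpp::export]]
List phs_accumulate_cpp(const IntegerMatrix& alleles,
                        const NumericVector& gpos) {
  const int n = alleles.nrow();
  const int S = alleles.ncol();
  if (n < 2) stop("need at least 2 haplotypes");

  NumericVector all_sum(S), der_sum(S);
  NumericVector der_pairs(S);
  std::vector<double> d(S);
  long long n_pairs = 0, n_zero_sd = 0;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      ++n_pairs;
      int prev_mis = -1;
      int x = 0;
      while (x < S) {
        int ai = alleles(i, x), aj = alleles(j, x);
        bool mis = (ai == NA_INTEGER) || (aj == NA_INTEGER) || (ai != aj);
        if (mis) {
          d[x] = 0.0;
          prev_mis = x;
          ++x;
        } else {
          int y = x;
          while (y < S) {
            int bi = alleles(i, y), bj = alleles(j, y);
            if (bi == NA_INTEGER || bj == NA_INTEGER || bi != bj) break;
            ++y;
          }
          int lo = prev_mis + 1;
          int hi = (y < S) ? y - 1 : S - 1;
          double len = gpos[hi] - gpos[lo];
          for (int k = x; k < y; ++k) d[k] = len;
          x = y;
        }
      }
      double mean = 0.0;
      for (int k = 0; k < S; ++k) mean += d[k];
      mean /= S;
      double ss = 0.0;
      for (int k = 0; k < S; ++k) { double e = d[k] - mean; ss += e * e; }
      double sd = (S > 1) ? std::sqrt(ss / (S - 1)) : 0.0;
      bool zero_sd = (sd <= 0.0);
      if (zero_sd) ++n_zero_sd;  // pair's z set to 0; still counted below
      for (int k = 0; k < S; ++k) {
        double z = zero_sd ? 0.0 : (d[k] - mean) / sd;
        all_sum[k] += z;
        int ai = alleles(i, k), aj = alleles(j, k);
        if (ai == 1 && aj == 1) {
          der_sum[k] += z;
          der_pairs[k] += 1.0;
        }
      }
    }
  }
  return List::create(_["all_sum"] = all_sum,
                      _["der_sum"] = der_sum,
                      _["der_pairs"] = der_pairs,
                      _["n_pairs"] = (double)n_pairs,
                      _["n_zero_sd"] = (double)n_zero_sd);
}
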