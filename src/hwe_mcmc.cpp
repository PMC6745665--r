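#include <Rcpp.h>
using namespace Rcpp;

// Markov chain over diploid genotype tables with fixed allele counts.
// The state is the assignment of the observed allele copies to the 2n
// genotype slots of the labelled individuals; swapping one allele between
// two individuals is a symmetric proposal and every distinct assignment
// is equally likely under the Hardy-Weinberg conditional null, so each
// swap is accepted.  The induced distribution over genotype tables
// {n_ij} is the exact conditional one, proportional to
// 2^h / prod(n_ij!) with h the number of heterozygotes.  The two-sided
// exact p-value is the chain frequency of tables no more probable than the
// observed one; the deficit-side p uses the heterozygote count as score.

static inline int cell(int i, int j, int k) {
  if (i > j) { int t = i; i = j; j = t; }
  return i * k + j;
}

// [[Rcpp::export]]
List hwe_chain_cpp(IntegerVector ai, IntegerVector bi, int k,
                   int dememorization, int batches, int iters_per_batch) {
  int n = ai.size();
  std::vector<int> a(ai.begin(), ai.end()), b(bi.begin(), bi.end());
  std::vector<int> cnt(k * k, 0);
  int het = 0;
  for (int u = 0; u < n; ++u) {
    cnt[cell(a[u], b[u], k)]++;
    if (a[u] != b[u]) het++;
  }
  const double LOG2 = std::log(2.0);
  double logw = het * LOG2;
  for (int c = 0; c < k * k; ++c)
    if (cnt[c] > 0) logw -= std::lgamma(cnt[c] + 1.0);
  const double logw0 = logw;
  const int het0 = het;
  const double eps = 1e-9 * (1.0 + std::fabs(logw0));

  long steps = 0;
  std::vector<double> bm_two(batches), bm_def(batches);

  auto step = [&]() {
    int u = (int)(unif_rand() * n);
    int v = (int)(unif_rand() * (n - 1));
    if (v >= u) v++;
    bool xu = unif_rand() < 0.5, xv = unif_rand() < 0.5;
    int au = xu ? a[u] : b[u], ou = xu ? b[u] : a[u];
    int av = xv ? a[v] : b[v], ov = xv ? b[v] : a[v];
    if (au == av) return;  // proposal identical to current state
    int A = cell(au, ou, k), B = cell(av, ov, k);
    int C = cell(av, ou, k), D = cell(au, ov, k);
    if (A == C && B == D) return;
    double delta = 0.0;
    int dhet = (int)(av != ou) + (int)(au != ov)
             - (int)(au != ou) - (int)(av != ov);
    delta += dhet * LOG2;
    // track log table-probability through the four affected cells
    delta += std::log((double)cnt[A]); cnt[A]--;
    delta += std::log((double)cnt[B]); cnt[B]--;
    delta -= std::log((double)cnt[C] + 1.0); cnt[C]++;
    delta -= std::log((double)cnt[D] + 1.0); cnt[D]++;
    if (xu) a[u] = av; else b[u] = av;
    if (xv) a[v] = au; else b[v] = au;
    het += dhet;
    logw += delta;
  };

  for (int i = 0; i < dememorization; ++i) step();
  for (int bt = 0; bt < batches; ++bt) {
    long c_two = 0, c_def = 0;
    for (int i = 0; i < iters_per_batch; ++i) {
      step(); steps++;
      if (logw <= logw0 + eps) c_two++;
      if (het <= het0) c_def++;
    }
    bm_two[bt] = (double)c_two / iters_per_batch;
    bm_def[bt] = (double)c_def / iters_per_batch;
  }
  double p_two = 0, p_def = 0;
  for (int bt = 0; bt < batches; ++bt) { p_two += bm_two[bt]; p_def += bm_def[bt]; }
  p_two /= batches; p_def /= batches;
  double se_two = 0, se_def = 0;
  if (batches > 1) {
    for (int bt = 0; bt < batches; ++bt) {
      se_two += (bm_two[bt] - p_two) * (bm_two[bt] - p_two);
      se_def += (bm_def[bt] - p_def) * (bm_def[bt] - p_def);
    }
    se_two = std::sqrt(se_two / (batches - 1.0) / batches);
    se_def = std::sqrt(se_def / (batches - 1.0) / batches);
  }
  return List::create(_["p_two"] = p_two, _["p_deficit"] = p_def,
                      _["se_two"] = se_two, _["se_deficit"] = se_def,
                      _["steps"] = (double)steps);
}
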