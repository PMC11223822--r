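// Reference scorer by exhaustive path enumeration.  Recursively walks every
// legal state path of the local multihit FA codon model (match 1-5 nt,
// insert 3 nt, delete 0 nt, N/C/J flanks 1 nt per loop), accumulating exact
// log path weights; Forward = log-sum over paths, Viterbi = max.  Entirely
// separate from the DP engines: no dynamic programming and its own emission
// lookup code.  Exponential cost; usable only on tiny instances.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace refenum {

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Model {
  int M, S, n;
  NumericMatrix ltr, lsense_m, lstop_m, lq1, lq2, lq4, lq5, lsense_i, lstop_i;
  NumericVector lentry, lbg;
  IntegerVector aa_of_codon, stop_index;
  std::vector<int> win;
};

// emission of a match (ins=false) or insert (ins=true) chunk ending at
// window offset j0 (0-based start) with length l
static double emission(const Model& m, int k, int j0, int l, bool ins) {
  double bgl = 0.0;
  int v[5];
  for (int t = 0; t < l; ++t) {
    v[t] = m.win[j0 + t];
    if (v[t] < 0) return 0.0;  // chunk containing N is neutral
    bgl += m.lbg[v[t]];
  }
  if (l == 3) {
    int ci = v[0] * 16 + v[1] * 4 + v[2];
    int aa = m.aa_of_codon[ci];
    if (aa == 0) {
      const NumericMatrix& t = ins ? m.lstop_i : m.lstop_m;
      return t(k - 1, m.stop_index[ci] - 1) - bgl;
    }
    const NumericMatrix& t = ins ? m.lsense_i : m.lsense_m;
    return t(k - 1, aa - 1) - bgl;
  }
  if (ins) return NEG_INF;
  int q = 0;
  for (int t = 0; t < l; ++t) q = q * 4 + v[t];
  const NumericMatrix& t = (l == 1) ? m.lq1 : (l == 2) ? m.lq2
                         : (l == 4) ? m.lq4 : m.lq5;
  return t(k - 1, q) - bgl;
}

struct Acc {
  double max_w;
  double sum;      // sum of exp(w - shift)
  double shift;    // running shift for stability
  long long count;
  long long limit;
  bool overflow;
  void add(double w) {
    if (++count > limit) { overflow = true; return; }
    if (w == NEG_INF) return;
    if (w > max_w) max_w = w;
    if (w > shift) {  // rescale
      sum = sum * exp(shift - w) + 1.0;
      shift = w;
    } else {
      sum += exp(w - shift);
    }
  }
  double logsum() const { return count == 0 || sum == 0 ? NEG_INF : shift + log(sum); }
};

struct Walker {
  const Model& m;
  double nloop, nmove, jloop, jmove, cloop, cmove, ej, ec, nullsc;
  Acc acc;
  Walker(const Model& mm, long long limit) : m(mm) {
    double nn = (double)m.n;
    nloop = log(nn / (nn + 3.0)); nmove = log(3.0 / (nn + 3.0));
    jloop = nloop; jmove = nmove; cloop = nloop; cmove = nmove;
    ej = log(0.5); ec = log(0.5);
    nullsc = nn * log(nn / (nn + 1.0)) + log(1.0 / (nn + 1.0));
    acc.max_w = NEG_INF; acc.sum = 0.0; acc.shift = NEG_INF;
    acc.count = 0; acc.limit = limit; acc.overflow = false;
  }

  // after E at position j with weight w: J loops or C finish
  void after_exit(int j, double w) {
    acc.add(w + ec + (m.n - j) * cloop + cmove);
    for (int g = 0; j + g <= m.n && !acc.overflow; ++g) {
      start_pass(j + g, w + ej + g * jloop + jmove);
    }
  }

  // core walk in state kind (0 M, 1 I, 2 D) at node k, consumed to j
  void core(int kind, int k, int j, double w) {
    if (acc.overflow) return;
    if (kind == 0 || kind == 2) after_exit(j, w);  // free exit from M and D
    if (k >= m.M && kind != 1) return;
    if (kind == 0) {
      for (int l = 1; l <= 5; ++l) {
        if (j + l > m.n) break;
        double e = emission(m, k + 1, j, l, false);
        if (e != NEG_INF) core(0, k + 1, j + l, w + m.ltr(k - 1, 0) + e);
      }
      if (j + 3 <= m.n) {
        double e = emission(m, k, j, 3, true);
        if (e != NEG_INF) core(1, k, j + 3, w + m.ltr(k - 1, 1) + e);
      }
      core(2, k + 1, j, w + m.ltr(k - 1, 2));
    } else if (kind == 1) {
      for (int l = 1; l <= 5; ++l) {
        if (j + l > m.n) break;
        double e = emission(m, k + 1, j, l, false);
        if (e != NEG_INF) core(0, k + 1, j + l, w + m.ltr(k - 1, 3) + e);
      }
      if (j + 3 <= m.n) {
        double e = emission(m, k, j, 3, true);
        if (e != NEG_INF) core(1, k, j + 3, w + m.ltr(k - 1, 4) + e);
      }
    } else {
      for (int l = 1; l <= 5; ++l) {
        if (j + l > m.n) break;
        double e = emission(m, k + 1, j, l, false);
        if (e != NEG_INF) core(0, k + 1, j + l, w + m.ltr(k - 1, 5) + e);
      }
      core(2, k + 1, j, w + m.ltr(k - 1, 6));
    }
  }

  void start_pass(int jB, double w) {
    for (int k = 1; k <= m.M && !acc.overflow; ++k) {
      for (int l = 1; l <= 5; ++l) {
        if (jB + l > m.n) break;
        double e = emission(m, k, jB, l, false);
        if (e != NEG_INF) core(0, k, jB + l, w + m.lentry[k - 1] + e);
      }
    }
  }

  void run() {
    for (int a = 0; a <= m.n && !acc.overflow; ++a) {
      start_pass(a, a * nloop + nmove);
    }
  }
};

}  // namespace refenum

// [[Rcpp::export]]
List cpp_fa_reference(List pack, IntegerVector win, double path_limit) {
  using namespace refenum;
  Model m;
  m.M = as<int>(pack["M"]); m.S = as<int>(pack["S"]);
  m.ltr = as<NumericMatrix>(pack["ltr"]);
  m.lentry = as<NumericVector>(pack["lentry"]);
  m.lbg = as<NumericVector>(pack["lbg"]);
  m.lsense_m = as<NumericMatrix>(pack["lsense_m"]);
  m.lstop_m = as<NumericMatrix>(pack["lstop_m"]);
  m.lq1 = as<NumericMatrix>(pack["lq1_m"]);
  m.lq2 = as<NumericMatrix>(pack["lq2_m"]);
  m.lq4 = as<NumericMatrix>(pack["lq4_m"]);
  m.lq5 = as<NumericMatrix>(pack["lq5_m"]);
  m.lsense_i = as<NumericMatrix>(pack["lsense_i"]);
  m.lstop_i = as<NumericMatrix>(pack["lstop_i"]);
  m.aa_of_codon = as<IntegerVector>(pack["aa_of_codon"]);
  m.stop_index = as<IntegerVector>(pack["stop_index"]);
  m.n = win.size();
  m.win.assign(win.begin(), win.end());
  Walker wk(m, (long long)path_limit);
  wk.run();
  double nullsc = wk.nullsc;
  return List::create(
    _["forward_bits"] = wk.acc.count == 0 ? R_NegInf : (wk.acc.logsum() - nullsc) / M_LN2,
    _["viterbi_bits"] = wk.acc.count == 0 ? R_NegInf : (wk.acc.max_w - nullsc) / M_LN2,
    _["n_paths"] = (double)wk.acc.count,
    _["overflow"] = wk.acc.overflow);
}
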