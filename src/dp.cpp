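// Dynamic-programming engines.
//
// Protein space: MSV (multi-ungapped-segment), Viterbi, Forward/Backward and
// posterior decoding over a local multihit profile HMM with HMMER3-style
// special states (N/B/E/J/C) and length-parameterized loop transitions.
//
// Codon space: the frameshift-aware (FA) engines, in which a match state
// consumes 1-5 nucleotides (codon, stop codon, or quasi-codon), an insert
// state consumes exactly 3, and a delete state consumes none.  All engines
// work in log space (nats) on emission odds ratios against an i.i.d.
// nucleotide background; the geometric length term of the null model is
// subtracted at the end, and scores are returned in bits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + log1p(exp(-std::fabs(a - b)));
}

static inline double vmax2(double a, double b) { return a > b ? a : b; }

struct SpecialParams {
  double nloop, nmove, jloop, jmove, cloop, cmove, ej, ec, nullsc;
};

static SpecialParams length_params(int n) {
  SpecialParams p;
  double nn = (double)n;
  p.nloop = log(nn / (nn + 3.0));
  p.nmove = log(3.0 / (nn + 3.0));
  p.jloop = p.nloop; p.jmove = p.nmove;
  p.cloop = p.nloop; p.cmove = p.nmove;
  p.ej = log(0.5); p.ec = log(0.5);
  p.nullsc = nn * log(nn / (nn + 1.0)) + log(1.0 / (nn + 1.0));
  return p;
}

// transition columns in ltr: 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD

// ---------------------------------------------------------------------------
// Protein engines
// ---------------------------------------------------------------------------

struct ProteinModel {
  int M;
  NumericMatrix lme, lie, ltr;
  NumericVector lentry;
  ProteinModel(List pack)
    : M(as<int>(pack["M"])),
      lme(as<NumericMatrix>(pack["lme"])),
      lie(as<NumericMatrix>(pack["lie"])),
      ltr(as<NumericMatrix>(pack["ltr"])),
      lentry(as<NumericVector>(pack["lentry"])) {}
  inline double em(int k, int a) const {  // a: 0-based aa index, -1 for X
    return a < 0 ? 0.0 : lme(k - 1, a);
  }
  inline double ei(int k, int a) const {
    return a < 0 ? 0.0 : lie(k - 1, a);
  }
  inline double tr(int k, int c) const { return ltr(k - 1, c); }
  inline double entry(int k) const { return lentry[k - 1]; }
};

// MSV: match states only, B->Mk entry, free exit, specials by max.
static double msv_one(const ProteinModel& pm, const int* pep, int n,
                      std::vector<double>& prevM, std::vector<double>& curM) {
  if (n <= 0) return NEG_INF;
  SpecialParams sp = length_params(n);
  int M = pm.M;
  prevM.assign(M + 1, NEG_INF);
  curM.assign(M + 1, NEG_INF);
  const double* lme = pm.lme.begin();   // M x 20, column-major
  const double* ent = pm.lentry.begin();
  double N = 0.0, B = sp.nmove, J = NEG_INF, C = NEG_INF, E;
  for (int j = 1; j <= n; ++j) {
    int a = pep[j - 1];
    const double* ecol = (a >= 0) ? lme + (size_t)a * M : nullptr;
    double* pv = prevM.data();
    double* cv = curM.data();
    if (ecol) {
      for (int k = 0; k < M; ++k) {
        double be = B + ent[k];
        double best = pv[k] > be ? pv[k] : be;
        cv[k + 1] = best + ecol[k];
      }
    } else {  // ambiguous residue: emission odds 0
      for (int k = 0; k < M; ++k) {
        double be = B + ent[k];
        cv[k + 1] = pv[k] > be ? pv[k] : be;
      }
    }
    E = cv[1];
    for (int k = 2; k <= M; ++k) if (cv[k] > E) E = cv[k];
    J = vmax2(J + sp.jloop, E + sp.ej);
    C = vmax2(C + sp.cloop, E + sp.ec);
    N = N + sp.nloop;
    B = vmax2(N + sp.nmove, J + sp.jmove);
    std::swap(prevM, curM);
  }
  double total = C + sp.cmove;
  return (total - sp.nullsc) / M_LN2;
}

// Viterbi / Forward over the full core model.  algo: 1 Viterbi, 2 Forward.
template <bool VIT>
static double vitfwd_one_t(const ProteinModel& pm, const int* pep, int n) {
  if (n <= 0) return NEG_INF;
  SpecialParams sp = length_params(n);
  int M = pm.M;
  std::vector<double> pM(M + 1, NEG_INF), pI(M + 1, NEG_INF), pD(M + 1, NEG_INF);
  std::vector<double> cM(M + 1, NEG_INF), cI(M + 1, NEG_INF), cD(M + 1, NEG_INF);
  const double* lme = pm.lme.begin();
  const double* lie = pm.lie.begin();
  const double* ltr = pm.ltr.begin();   // M x 7 column-major
  const double* ent = pm.lentry.begin();
  const double* tMM = ltr;              // column c at ltr + c*M
  const double* tMI = ltr + (size_t)1 * M;
  const double* tMD = ltr + (size_t)2 * M;
  const double* tIM = ltr + (size_t)3 * M;
  const double* tII = ltr + (size_t)4 * M;
  const double* tDM = ltr + (size_t)5 * M;
  const double* tDD = ltr + (size_t)6 * M;
  double N = 0.0, B = sp.nmove, J = NEG_INF, C = NEG_INF;
  auto comb = [](double a, double b) { return VIT ? vmax2(a, b) : lse2(a, b); };
  for (int j = 1; j <= n; ++j) {
    int a = pep[j - 1];
    const double* ecol = (a >= 0) ? lme + (size_t)a * M : nullptr;
    const double* icol = (a >= 0) ? lie + (size_t)a * M : nullptr;
    double E = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double sM = B + ent[k - 1];
      if (k > 1) {
        sM = comb(sM, pM[k - 1] + tMM[k - 2]);
        sM = comb(sM, pI[k - 1] + tIM[k - 2]);
        sM = comb(sM, pD[k - 1] + tDM[k - 2]);
      }
      cM[k] = sM == NEG_INF ? NEG_INF : sM + (ecol ? ecol[k - 1] : 0.0);
      if (k < M) {
        double sI = comb(pM[k] + tMI[k - 1], pI[k] + tII[k - 1]);
        cI[k] = sI == NEG_INF ? NEG_INF : sI + (icol ? icol[k - 1] : 0.0);
      } else cI[k] = NEG_INF;
      cD[k] = (k > 1)
        ? comb(cM[k - 1] + tMD[k - 2], cD[k - 1] + tDD[k - 2])
        : NEG_INF;
      E = comb(E, comb(cM[k], cD[k]));
    }
    J = comb(J + sp.jloop, E + sp.ej);
    C = comb(C + sp.cloop, E + sp.ec);
    N = N + sp.nloop;
    B = comb(N + sp.nmove, J + sp.jmove);
    std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
  }
  double total = C + sp.cmove;
  return (total - sp.nullsc) / M_LN2;
}

static double vitfwd_one(const ProteinModel& pm, const int* pep, int n, int algo) {
  return algo == 1 ? vitfwd_one_t<true>(pm, pep, n)
                   : vitfwd_one_t<false>(pm, pep, n);
}

// [[Rcpp::export]]
NumericVector cpp_protein_scores(List pack, IntegerVector pep,
                                 IntegerVector offsets, int algo) {
  ProteinModel pm(pack);
  int B = offsets.size() - 1;
  NumericVector out(B);
  std::vector<double> s1, s2;
  for (int b = 0; b < B; ++b) {
    int from = offsets[b], to = offsets[b + 1];
    const int* p = pep.begin() + from;
    int n = to - from;
    out[b] = (algo == 0) ? msv_one(pm, p, n, s1, s2) : vitfwd_one(pm, p, n, algo);
  }
  return out;
}

// Full protein engine for one peptide: forward, backward, posterior of core
// states per residue, and the Viterbi alignment path.
// [[Rcpp::export]]
List cpp_protein_engine(List pack, IntegerVector pep) {
  ProteinModel pm(pack);
  int n = pep.size(), M = pm.M;
  if (n <= 0) stop("empty peptide");
  SpecialParams sp = length_params(n);

  // full forward matrices (row k 0..M, col j 0..n)
  NumericMatrix fM(M + 1, n + 1), fI(M + 1, n + 1), fD(M + 1, n + 1);
  std::vector<double> fN(n + 1), fB(n + 1), fE(n + 1), fJ(n + 1), fC(n + 1);
  std::fill(fM.begin(), fM.end(), NEG_INF);
  std::fill(fI.begin(), fI.end(), NEG_INF);
  std::fill(fD.begin(), fD.end(), NEG_INF);
  for (int j = 0; j <= n; ++j) { fN[j] = fB[j] = fE[j] = fJ[j] = fC[j] = NEG_INF; }
  fN[0] = 0.0; fB[0] = sp.nmove;
  for (int j = 1; j <= n; ++j) {
    int a = pep[j - 1];
    double E = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double sM = fB[j - 1] + pm.entry(k);
      if (k > 1) {
        sM = lse2(sM, fM(k - 1, j - 1) + pm.tr(k - 1, 0));
        sM = lse2(sM, fI(k - 1, j - 1) + pm.tr(k - 1, 3));
        sM = lse2(sM, fD(k - 1, j - 1) + pm.tr(k - 1, 5));
      }
      fM(k, j) = sM == NEG_INF ? NEG_INF : sM + pm.em(k, a);
      if (k < M) {
        double sI = lse2(fM(k, j - 1) + pm.tr(k, 1), fI(k, j - 1) + pm.tr(k, 4));
        fI(k, j) = sI == NEG_INF ? NEG_INF : sI + pm.ei(k, a);
      }
      if (k > 1) fD(k, j) = lse2(fM(k - 1, j) + pm.tr(k - 1, 2),
                                 fD(k - 1, j) + pm.tr(k - 1, 6));
      E = lse2(E, lse2(fM(k, j), fD(k, j)));
    }
    fE[j] = E;
    fJ[j] = lse2(fJ[j - 1] + sp.jloop, E + sp.ej);
    fC[j] = lse2(fC[j - 1] + sp.cloop, E + sp.ec);
    fN[j] = fN[j - 1] + sp.nloop;
    fB[j] = lse2(fN[j] + sp.nmove, fJ[j] + sp.jmove);
  }
  double total = fC[n] + sp.cmove;

  // backward
  NumericMatrix bM(M + 1, n + 1), bI(M + 1, n + 1), bD(M + 1, n + 1);
  std::vector<double> bN(n + 1), bB(n + 1), bE(n + 1), bJ(n + 1), bC(n + 1);
  std::fill(bM.begin(), bM.end(), NEG_INF);
  std::fill(bI.begin(), bI.end(), NEG_INF);
  std::fill(bD.begin(), bD.end(), NEG_INF);
  for (int j = 0; j <= n; ++j) { bN[j] = bB[j] = bE[j] = bJ[j] = bC[j] = NEG_INF; }
  bC[n] = sp.cmove;
  for (int j = n; j >= 0; --j) {
    if (j < n) bC[j] = sp.cloop + bC[j + 1];
    double bBv = NEG_INF;
    if (j < n) {
      int a = pep[j];
      for (int k = 1; k <= M; ++k) {
        bBv = lse2(bBv, pm.entry(k) + pm.em(k, a) + bM(k, j + 1));
      }
    }
    bB[j] = bBv;
    bJ[j] = lse2(j < n ? sp.jloop + bJ[j + 1] : NEG_INF, sp.jmove + bB[j]);
    bE[j] = lse2(sp.ec + bC[j], sp.ej + bJ[j]);
    bN[j] = lse2(j < n ? sp.nloop + bN[j + 1] : NEG_INF, sp.nmove + bB[j]);
    for (int k = M; k >= 1; --k) {
      double eM1 = (k < M && j < n) ? pm.em(k + 1, pep[j]) : NEG_INF;
      double eIk = (k < M && j < n) ? pm.ei(k, pep[j]) : NEG_INF;
      double vMv = bE[j];
      double vDv = bE[j];
      if (k < M) {
        if (j < n) {
          vMv = lse2(vMv, pm.tr(k, 0) + eM1 + bM(k + 1, j + 1));
          vMv = lse2(vMv, pm.tr(k, 1) + eIk + bI(k, j + 1));
          vDv = lse2(vDv, pm.tr(k, 5) + eM1 + bM(k + 1, j + 1));
        }
        vMv = lse2(vMv, pm.tr(k, 2) + bD(k + 1, j));
        vDv = lse2(vDv, pm.tr(k, 6) + bD(k + 1, j));
        double vIv = NEG_INF;
        if (j < n) {
          vIv = lse2(pm.tr(k, 3) + eM1 + bM(k + 1, j + 1),
                     pm.tr(k, 4) + eIk + bI(k, j + 1));
        }
        bI(k, j) = vIv;
      }
      bM(k, j) = vMv;
      bD(k, j) = vDv;
    }
  }
  double total_b = bN[0];

  // posterior probability that residue j is emitted by a core state
  NumericVector post_core(n), post_flank(n);
  for (int j = 1; j <= n; ++j) {
    double pc = 0.0;
    for (int k = 1; k <= M; ++k) {
      pc += exp(fM(k, j) + bM(k, j) - total);
      if (k < M) pc += exp(fI(k, j) + bI(k, j) - total);
    }
    double pf = exp(fN[j - 1] + sp.nloop + bN[j] - total)
              + exp(fJ[j - 1] + sp.jloop + bJ[j] - total)
              + exp(fC[j - 1] + sp.cloop + bC[j] - total);
    post_core[j - 1] = pc;
    post_flank[j - 1] = pf;
  }

  return List::create(
    _["fwd_bits"] = (total - sp.nullsc) / M_LN2,
    _["bwd_bits"] = (total_b - sp.nullsc) / M_LN2,
    _["post_core"] = post_core,
    _["post_flank"] = post_flank);
}

// Viterbi alignment path for one peptide (local multihit).
// Returns score (bits) and a path matrix with rows (kind, state, from, to):
// kind 0=M 1=I 2=D; from/to are 0-based half-open residue spans.
// [[Rcpp::export]]
List cpp_protein_viterbi_path(List pack, IntegerVector pep) {
  ProteinModel pm(pack);
  int n = pep.size(), M = pm.M;
  if (n <= 0) stop("empty peptide");
  SpecialParams sp = length_params(n);
  NumericMatrix vM(M + 1, n + 1), vI(M + 1, n + 1), vD(M + 1, n + 1);
  std::vector<double> vN(n + 1), vB(n + 1), vE(n + 1), vJ(n + 1), vC(n + 1);
  std::fill(vM.begin(), vM.end(), NEG_INF);
  std::fill(vI.begin(), vI.end(), NEG_INF);
  std::fill(vD.begin(), vD.end(), NEG_INF);
  for (int j = 0; j <= n; ++j) { vN[j] = vB[j] = vE[j] = vJ[j] = vC[j] = NEG_INF; }
  vN[0] = 0.0; vB[0] = sp.nmove;
  for (int j = 1; j <= n; ++j) {
    int a = pep[j - 1];
    double E = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double sM = vB[j - 1] + pm.entry(k);
      if (k > 1) {
        sM = vmax2(sM, vM(k - 1, j - 1) + pm.tr(k - 1, 0));
        sM = vmax2(sM, vI(k - 1, j - 1) + pm.tr(k - 1, 3));
        sM = vmax2(sM, vD(k - 1, j - 1) + pm.tr(k - 1, 5));
      }
      vM(k, j) = sM == NEG_INF ? NEG_INF : sM + pm.em(k, a);
      if (k < M) {
        double sI = vmax2(vM(k, j - 1) + pm.tr(k, 1), vI(k, j - 1) + pm.tr(k, 4));
        vI(k, j) = sI == NEG_INF ? NEG_INF : sI + pm.ei(k, a);
      }
      if (k > 1) vD(k, j) = vmax2(vM(k - 1, j) + pm.tr(k - 1, 2),
                                  vD(k - 1, j) + pm.tr(k - 1, 6));
      E = vmax2(E, vmax2(vM(k, j), vD(k, j)));
    }
    vE[j] = E;
    vJ[j] = vmax2(vJ[j - 1] + sp.jloop, E + sp.ej);
    vC[j] = vmax2(vC[j - 1] + sp.cloop, E + sp.ec);
    vN[j] = vN[j - 1] + sp.nloop;
    vB[j] = vmax2(vN[j] + sp.nmove, vJ[j] + sp.jmove);
  }
  double total = vC[n] + sp.cmove;

  // traceback, recomputing candidate values with the same arithmetic as the
  // DP fill so equality comparisons are exact
  std::vector<int> kind, state, from, to;
  auto push = [&](int kd, int st, int f, int t) {
    kind.push_back(kd); state.push_back(st); from.push_back(f); to.push_back(t);
  };
  if (total == NEG_INF) {
    IntegerMatrix path0(0, 4);
    return List::create(_["vit_bits"] = R_NegInf, _["path"] = path0);
  }
  int j = n; char csflank = 'C';
  while (true) {
    if (csflank == 'C') {
      if (j > 0 && vC[j] == vC[j - 1] + sp.cloop) { j -= 1; continue; }
      csflank = 'E';
    }
    if (csflank == 'J') {
      if (j > 0 && vJ[j] == vJ[j - 1] + sp.jloop) { j -= 1; continue; }
      csflank = 'E';
    }
    if (csflank == 'N') break;
    int bk = -1; char bs = 'M';
    for (int k = 1; k <= M; ++k) {
      if (vM(k, j) == vE[j]) { bk = k; bs = 'M'; break; }
      if (vD(k, j) == vE[j]) { bk = k; bs = 'D'; break; }
    }
    if (bk < 0) stop("viterbi traceback failed at E");
    int k = bk; char s = bs;
    bool at_B = false;
    while (!at_B) {
      if (s == 'M') {
        double e = pm.em(k, pep[j - 1]);
        double target = vM(k, j);
        push(0, k, j - 1, j);
        int jp = j - 1;
        if (vB[jp] + pm.entry(k) + e == target) { j = jp; at_B = true; }
        else if (k > 1 && vM(k - 1, jp) + pm.tr(k - 1, 0) + e == target) { j = jp; k -= 1; s = 'M'; }
        else if (k > 1 && vI(k - 1, jp) + pm.tr(k - 1, 3) + e == target) { j = jp; k -= 1; s = 'I'; }
        else if (k > 1 && vD(k - 1, jp) + pm.tr(k - 1, 5) + e == target) { j = jp; k -= 1; s = 'D'; }
        else stop("viterbi traceback failed at M");
      } else if (s == 'I') {
        double e = pm.ei(k, pep[j - 1]);
        double target = vI(k, j);
        push(1, k, j - 1, j);
        j -= 1;
        if (vM(k, j) + pm.tr(k, 1) + e == target) s = 'M';
        else if (vI(k, j) + pm.tr(k, 4) + e == target) s = 'I';
        else stop("viterbi traceback failed at I");
      } else {
        push(2, k, j, j);
        double target = vD(k, j);
        if (vM(k - 1, j) + pm.tr(k - 1, 2) == target) { s = 'M'; k -= 1; }
        else if (vD(k - 1, j) + pm.tr(k - 1, 6) == target) { s = 'D'; k -= 1; }
        else stop("viterbi traceback failed at D");
      }
    }
    if (vB[j] == vN[j] + sp.nmove) { csflank = 'N'; }
    else { csflank = 'J'; }
  }
  int np = kind.size();
  IntegerMatrix path(np, 4);
  for (int i = 0; i < np; ++i) {  // reverse into forward order
    int r = np - 1 - i;
    path(i, 0) = kind[r]; path(i, 1) = state[r];
    path(i, 2) = from[r]; path(i, 3) = to[r];
  }
  colnames(path) = CharacterVector::create("kind", "state", "from", "to");
  return List::create(_["vit_bits"] = (total - sp.nullsc) / M_LN2,
                      _["path"] = path);
}
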