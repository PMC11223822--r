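// Frameshift-aware codon-space engines: Forward, Backward, posterior
// decoding, and Viterbi with traceback over the FA codon profile.  Match
// states consume 1-5 nt (sense codon, stop codon, or quasi-codon), insert
// states consume exactly 3 nt, delete states none; N/C/J flank states
// consume 1 nt per loop at null frequency.  Scores are log odds (nats)
// against i.i.d. nucleotide background, converted to bits after removing
// the geometric length term, exactly as in the protein engines.

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

struct SpecialParamsFa {
  double nloop, nmove, jloop, jmove, cloop, cmove, ej, ec, nullsc;
};
static SpecialParamsFa length_params_fa(int n) {
  SpecialParamsFa p;
  double nn = (double)n;
  p.nloop = log(nn / (nn + 3.0));
  p.nmove = log(3.0 / (nn + 3.0));
  p.jloop = p.nloop; p.jmove = p.nmove;
  p.cloop = p.nloop; p.cmove = p.nmove;
  p.ej = log(0.5); p.ec = log(0.5);
  p.nullsc = nn * log(nn / (nn + 1.0)) + log(1.0 / (nn + 1.0));
  return p;
}

// chunk classes
enum ChunkClass { CH_SENSE = 0, CH_STOP = 1, CH_QUASI = 2, CH_NEUTRAL = 3 };

struct FaModel {
  int M, S;
  NumericMatrix ltr;
  NumericVector lentry, lbg;
  NumericMatrix lsense_m, lstop_m, lq1_m, lq2_m, lq4_m, lq5_m;
  NumericMatrix lsense_i, lstop_i;
  IntegerVector aa_of_codon, stop_index;
  // naive-mode data
  NumericMatrix me, ie, lZq_m, lZq_i;
  NumericVector lnsyn;
  double lnorm, lpstop;
  NumericVector lpen;  // by length 1,2,4,5 -> index 0..3
  List qcand, qcand_off;  // per length: concat aa (1-based), offsets
  IntegerVector stop_cand, stop_cand_off;

  FaModel(List p)
    : M(as<int>(p["M"])), S(as<int>(p["S"])),
      ltr(as<NumericMatrix>(p["ltr"])),
      lentry(as<NumericVector>(p["lentry"])),
      lbg(as<NumericVector>(p["lbg"])),
      lsense_m(as<NumericMatrix>(p["lsense_m"])),
      lstop_m(as<NumericMatrix>(p["lstop_m"])),
      lq1_m(as<NumericMatrix>(p["lq1_m"])),
      lq2_m(as<NumericMatrix>(p["lq2_m"])),
      lq4_m(as<NumericMatrix>(p["lq4_m"])),
      lq5_m(as<NumericMatrix>(p["lq5_m"])),
      lsense_i(as<NumericMatrix>(p["lsense_i"])),
      lstop_i(as<NumericMatrix>(p["lstop_i"])),
      aa_of_codon(as<IntegerVector>(p["aa_of_codon"])),
      stop_index(as<IntegerVector>(p["stop_index"])),
      me(as<NumericMatrix>(p["me"])),
      ie(as<NumericMatrix>(p["ie"])),
      lZq_m(as<NumericMatrix>(p["lZq_m"])),
      lZq_i(as<NumericMatrix>(p["lZq_i"])),
      lnsyn(as<NumericVector>(p["lnsyn"])),
      lnorm(as<double>(p["lnorm"])),
      lpstop(as<double>(p["lpstop"])),
      lpen(as<NumericVector>(p["lpen"])),
      qcand(as<List>(p["qcand"])),
      qcand_off(as<List>(p["qcand_off"])),
      stop_cand(as<IntegerVector>(p["stop_cand"])),
      stop_cand_off(as<IntegerVector>(p["stop_cand_off"])) {}

  inline double tr(int k, int c) const { return ltr(k - 1, c); }
  inline double entry(int k) const { return lentry[k - 1]; }
};

static inline int len_slot(int l) { return l == 1 ? 0 : (l == 2 ? 1 : (l == 4 ? 2 : 3)); }

struct Chunk { int cls; int idx; double bgl; };

// decode the window chunk ending at 1-based position j with length l
static Chunk decode_chunk(const FaModel& fm, const int* win, int j, int l,
                          long long* counter) {
  (*counter)++;
  Chunk ch;
  bool hasN = false;
  double bgl = 0.0;
  int v[5];
  for (int t = 0; t < l; ++t) {
    int nt = win[j - l + t];
    v[t] = nt;
    if (nt < 0) hasN = true; else bgl += fm.lbg[nt];
  }
  if (hasN) { ch.cls = CH_NEUTRAL; ch.idx = 0; ch.bgl = 0.0; return ch; }
  ch.bgl = bgl;
  if (l == 3) {
    int ci = v[0] * 16 + v[1] * 4 + v[2];
    int aa = fm.aa_of_codon[ci];
    if (aa == 0) { ch.cls = CH_STOP; ch.idx = fm.stop_index[ci]; }
    else { ch.cls = CH_SENSE; ch.idx = aa; }
  } else {
    int q = 0;
    for (int t = 0; t < l; ++t) q = q * 4 + v[t];
    ch.cls = CH_QUASI; ch.idx = q;
  }
  return ch;
}

// emission log-odds from the precomputed per-state tables
static inline double em_from_tables(const FaModel& fm, int k, int l,
                                    const Chunk& ch, bool insert_state) {
  if (ch.cls == CH_NEUTRAL) return 0.0;
  if (insert_state) {
    if (ch.cls == CH_SENSE) return fm.lsense_i(k - 1, ch.idx - 1) - ch.bgl;
    return fm.lstop_i(k - 1, ch.idx - 1) - ch.bgl;  // CH_STOP
  }
  switch (ch.cls) {
  case CH_SENSE: return fm.lsense_m(k - 1, ch.idx - 1) - ch.bgl;
  case CH_STOP:  return fm.lstop_m(k - 1, ch.idx - 1) - ch.bgl;
  default: {
    const NumericMatrix& tab = (l == 1) ? fm.lq1_m : (l == 2) ? fm.lq2_m
                             : (l == 4) ? fm.lq4_m : fm.lq5_m;
    return tab(k - 1, ch.idx) - ch.bgl;
  }
  }
}

// emission log-odds recomputed from scratch (no precomputed max tables);
// arithmetic mirrors the table construction so results are bit-identical
static double em_naive(const FaModel& fm, int k, int l, const Chunk& ch,
                       bool insert_state) {
  if (ch.cls == CH_NEUTRAL) return 0.0;
  const NumericMatrix& em = insert_state ? fm.ie : fm.me;
  if (ch.cls == CH_SENSE) {
    return fm.lnorm + log(em(k - 1, ch.idx - 1)) - fm.lnsyn[ch.idx - 1] - ch.bgl;
  }
  if (ch.cls == CH_STOP) {
    int si = ch.idx;
    int from = fm.stop_cand_off[si - 1], to = fm.stop_cand_off[si];
    if (from == to) return NEG_INF;
    double mx = 0.0;
    for (int t = from; t < to; ++t) {
      double v = em(k - 1, fm.stop_cand[t] - 1);
      if (t == from || v > mx) mx = v;
    }
    return fm.lpstop + log(mx) - ch.bgl;
  }
  int slot = len_slot(l);
  IntegerVector cand = fm.qcand[slot];
  IntegerVector off = fm.qcand_off[slot];
  int from = off[ch.idx], to = off[ch.idx + 1];
  if (from == to) return NEG_INF;
  double mx = 0.0;
  for (int t = from; t < to; ++t) {
    double v = em(k - 1, cand[t] - 1);
    if (t == from || v > mx) mx = v;
  }
  const NumericMatrix& lZ = insert_state ? fm.lZq_i : fm.lZq_m;
  return fm.lpen[slot] + log(mx) - lZ(k - 1, slot) - ch.bgl;
}

struct EmissionCacheCpp {
  int n, M;
  std::vector<double> emM;  // [(j-1)*5 + (l-1)] * M + (k-1)
  std::vector<double> emI;  // [(j-1)] * M + (k-1)
  std::vector<int> cls, idx;      // per (j,l): 5*(j-1)+(l-1)
  std::vector<double> bgl;
  long long n_decodes;
  inline double M_(int k, int j, int l) const {
    return emM[((size_t)(j - 1) * 5 + (l - 1)) * M + (k - 1)];
  }
  inline double I_(int k, int j) const {
    return emI[(size_t)(j - 1) * M + (k - 1)];
  }
};

static void build_emissions(const FaModel& fm, const int* win, int n,
                            bool use_cache, EmissionCacheCpp& ec) {
  ec.n = n; ec.M = fm.M; ec.n_decodes = 0;
  ec.emM.assign((size_t)n * 5 * fm.M, NEG_INF);
  ec.emI.assign((size_t)n * fm.M, NEG_INF);
  ec.cls.assign((size_t)n * 5, -1);
  ec.idx.assign((size_t)n * 5, 0);
  ec.bgl.assign((size_t)n * 5, 0.0);
  static const int lens[5] = {1, 2, 3, 4, 5};
  if (use_cache) {
    for (int j = 1; j <= n; ++j) {
      for (int li = 0; li < 5; ++li) {
        int l = lens[li];
        if (l > j) continue;
        Chunk ch = decode_chunk(fm, win, j, l, &ec.n_decodes);
        ec.cls[(j - 1) * 5 + li] = ch.cls;
        ec.idx[(j - 1) * 5 + li] = ch.idx;
        ec.bgl[(j - 1) * 5 + li] = ch.bgl;
        for (int k = 1; k <= fm.M; ++k) {
          ec.emM[((size_t)(j - 1) * 5 + li) * fm.M + (k - 1)] =
            em_from_tables(fm, k, l, ch, false);
          if (l == 3 && k < fm.M && ch.cls != CH_QUASI) {
            ec.emI[(size_t)(j - 1) * fm.M + (k - 1)] =
              em_from_tables(fm, k, l, ch, true);
          }
        }
      }
    }
  } else {
    for (int j = 1; j <= n; ++j) {
      for (int li = 0; li < 5; ++li) {
        int l = lens[li];
        if (l > j) continue;
        for (int k = 1; k <= fm.M; ++k) {
          Chunk ch = decode_chunk(fm, win, j, l, &ec.n_decodes);
          if (k == 1) {
            ec.cls[(j - 1) * 5 + li] = ch.cls;
            ec.idx[(j - 1) * 5 + li] = ch.idx;
            ec.bgl[(j - 1) * 5 + li] = ch.bgl;
          }
          ec.emM[((size_t)(j - 1) * 5 + li) * fm.M + (k - 1)] =
            em_naive(fm, k, l, ch, false);
          if (l == 3 && k < fm.M) {
            ec.emI[(size_t)(j - 1) * fm.M + (k - 1)] =
              em_naive(fm, k, l, ch, true);
          }
        }
      }
    }
  }
}

// Full FA engine.  Returns forward/backward bits, posteriors, Viterbi path.
// [[Rcpp::export]]
List cpp_fa_engine(List pack, IntegerVector win, bool use_cache,
                   bool do_bwd, bool do_post, bool do_vit) {
  FaModel fm(pack);
  int n = win.size(), M = fm.M;
  if (n < 1) {
    return List::create(_["fwd_bits"] = R_NegInf, _["bwd_bits"] = R_NegInf,
                        _["n_decodes"] = 0.0);
  }
  SpecialParamsFa sp = length_params_fa(n);
  EmissionCacheCpp ec;
  build_emissions(fm, win.begin(), n, use_cache, ec);

  // ---------------- forward ----------------
  NumericMatrix fM(M + 1, n + 1), fI(M + 1, n + 1), fD(M + 1, n + 1);
  std::vector<double> fN(n + 1, NEG_INF), fB(n + 1, NEG_INF), fE(n + 1, NEG_INF),
    fJ(n + 1, NEG_INF), fC(n + 1, NEG_INF);
  std::fill(fM.begin(), fM.end(), NEG_INF);
  std::fill(fI.begin(), fI.end(), NEG_INF);
  std::fill(fD.begin(), fD.end(), NEG_INF);
  fN[0] = 0.0; fB[0] = sp.nmove;
  static const int lens[5] = {1, 2, 3, 4, 5};
  // raw pointers and hoisted transition rows for the hot loop
  double* pfM = fM.begin();
  double* pfI = fI.begin();
  double* pfD = fD.begin();
  const int R = M + 1;
  std::vector<double> tMM(M + 1), tMI(M + 1), tMD(M + 1), tIM(M + 1),
    tII(M + 1), tDM(M + 1), tDD(M + 1), ent(M + 1);
  for (int k = 1; k <= M; ++k) {
    tMM[k] = fm.tr(k, 0); tMI[k] = fm.tr(k, 1); tMD[k] = fm.tr(k, 2);
    tIM[k] = fm.tr(k, 3); tII[k] = fm.tr(k, 4); tDM[k] = fm.tr(k, 5);
    tDD[k] = fm.tr(k, 6); ent[k] = fm.entry(k);
  }
  double buf[24];
  for (int j = 1; j <= n; ++j) {
    double E = NEG_INF;
    int lmax = j < 5 ? j : 5;
    for (int k = 1; k <= M; ++k) {
      int nb = 0;
      double bmax = NEG_INF;
      const double* emrow = &ec.emM[(size_t)(j - 1) * 5 * M + (k - 1)];
      for (int li = 0; li < lmax; ++li) {
        double e = emrow[(size_t)li * M];
        if (e == NEG_INF) continue;
        int jp = j - (li + 1);
        double t = fB[jp] + ent[k] + e;
        if (t != NEG_INF) { buf[nb++] = t; if (t > bmax) bmax = t; }
        if (k > 1) {
          size_t off = (size_t)jp * R + (k - 1);
          t = pfM[off] + tMM[k - 1] + e;
          if (t != NEG_INF) { buf[nb++] = t; if (t > bmax) bmax = t; }
          t = pfI[off] + tIM[k - 1] + e;
          if (t != NEG_INF) { buf[nb++] = t; if (t > bmax) bmax = t; }
          t = pfD[off] + tDM[k - 1] + e;
          if (t != NEG_INF) { buf[nb++] = t; if (t > bmax) bmax = t; }
        }
      }
      double sM = NEG_INF;
      if (nb > 0 && bmax != NEG_INF) {
        double acc = 0.0;
        for (int b = 0; b < nb; ++b) acc += exp(buf[b] - bmax);
        sM = bmax + log(acc);
      }
      size_t cur = (size_t)j * R + k;
      pfM[cur] = sM;
      if (k < M && j >= 3) {
        double e = ec.I_(k, j);
        if (e != NEG_INF) {
          size_t o3 = (size_t)(j - 3) * R + k;
          double in = lse2(pfM[o3] + tMI[k], pfI[o3] + tII[k]);
          pfI[cur] = in == NEG_INF ? NEG_INF : in + e;
        }
      }
      if (k > 1) pfD[cur] = lse2(pfM[cur - 1] + tMD[k - 1],
                                 pfD[cur - 1] + tDD[k - 1]);
      E = lse2(E, lse2(pfM[cur], pfD[cur]));
    }
    fE[j] = E;
    fJ[j] = lse2(fJ[j - 1] + sp.jloop, E + sp.ej);
    fC[j] = lse2(fC[j - 1] + sp.cloop, E + sp.ec);
    fN[j] = fN[j - 1] + sp.nloop;
    fB[j] = lse2(fN[j] + sp.nmove, fJ[j] + sp.jmove);
  }
  double total = fC[n] + sp.cmove;
  double fwd_bits = (total - sp.nullsc) / M_LN2;

  List out = List::create(_["fwd_bits"] = fwd_bits,
                          _["n_decodes"] = (double)ec.n_decodes);

  // ---------------- backward (+ posterior) ----------------
  if (do_bwd || do_post) {
    NumericMatrix bM(M + 1, n + 1), bI(M + 1, n + 1), bD(M + 1, n + 1);
    std::vector<double> bN(n + 1, NEG_INF), bB(n + 1, NEG_INF), bE(n + 1, NEG_INF),
      bJ(n + 1, NEG_INF), bC(n + 1, NEG_INF);
    std::fill(bM.begin(), bM.end(), NEG_INF);
    std::fill(bI.begin(), bI.end(), NEG_INF);
    std::fill(bD.begin(), bD.end(), NEG_INF);
    bC[n] = sp.cmove;
    double bufM[16], bufD[8], bufI[8];
    for (int j = n; j >= 0; --j) {
      if (j < n) bC[j] = sp.cloop + bC[j + 1];
      double bBv = NEG_INF;
      {
        double bmax = NEG_INF, acc = 0.0;
        for (int li = 0; li < 5; ++li) {
          int l = lens[li];
          if (j + l > n) break;
          for (int k = 1; k <= M; ++k) {
            double e = ec.M_(k, j + l, l);
            if (e == NEG_INF) continue;
            double t = fm.entry(k) + e + bM(k, j + l);
            if (t == NEG_INF) continue;
            if (t > bmax) {
              acc = acc * exp(bmax - t) + 1.0;
              bmax = t;
            } else {
              acc += exp(t - bmax);
            }
          }
        }
        if (bmax != NEG_INF) bBv = bmax + log(acc);
      }
      bB[j] = bBv;
      bJ[j] = lse2(j < n ? sp.jloop + bJ[j + 1] : NEG_INF, sp.jmove + bB[j]);
      bE[j] = lse2(sp.ec + bC[j], sp.ej + bJ[j]);
      bN[j] = lse2(j < n ? sp.nloop + bN[j + 1] : NEG_INF, sp.nmove + bB[j]);
      for (int k = M; k >= 1; --k) {
        if (k < M) {
          int nm = 0, nd = 0, ni = 0;
          bufM[nm++] = bE[j];
          bufD[nd++] = bE[j];
          for (int li = 0; li < 5; ++li) {
            int l = lens[li];
            if (j + l > n) break;
            double e = ec.M_(k + 1, j + l, l);
            if (e == NEG_INF) continue;
            double bm = bM(k + 1, j + l);
            if (bm == NEG_INF) continue;
            bufM[nm++] = fm.tr(k, 0) + e + bm;
            bufD[nd++] = fm.tr(k, 5) + e + bm;
            bufI[ni++] = fm.tr(k, 3) + e + bm;
          }
          if (j + 3 <= n) {
            double eI = ec.I_(k, j + 3);
            if (eI != NEG_INF && bI(k, j + 3) != NEG_INF) {
              bufM[nm++] = fm.tr(k, 1) + eI + bI(k, j + 3);
              bufI[ni++] = fm.tr(k, 4) + eI + bI(k, j + 3);
            }
          }
          if (bD(k + 1, j) != NEG_INF) {
            bufM[nm++] = fm.tr(k, 2) + bD(k + 1, j);
            bufD[nd++] = fm.tr(k, 6) + bD(k + 1, j);
          }
          auto gsum = [](double* buf, int nb) {
            double bmax = NEG_INF;
            for (int b = 0; b < nb; ++b) if (buf[b] > bmax) bmax = buf[b];
            if (bmax == NEG_INF) return NEG_INF;
            double acc = 0.0;
            for (int b = 0; b < nb; ++b) acc += exp(buf[b] - bmax);
            return bmax + log(acc);
          };
          bM(k, j) = gsum(bufM, nm);
          bD(k, j) = gsum(bufD, nd);
          bI(k, j) = gsum(bufI, ni);
        } else {
          bM(k, j) = bE[j];
          bD(k, j) = bE[j];
        }
      }
    }
    out["bwd_bits"] = (bN[0] - sp.nullsc) / M_LN2;

    if (do_post) {
      NumericVector post_core(n), post_flank(n);
      for (int j = 1; j <= n; ++j) {
        // flank loops consuming nt j
        double pf = exp(fN[j - 1] + sp.nloop + bN[j] - total)
                  + exp(fJ[j - 1] + sp.jloop + bJ[j] - total)
                  + exp(fC[j - 1] + sp.cloop + bC[j] - total);
        post_flank[j - 1] = pf;
      }
      // core chunks: distribute cell posterior over consumed nts; the cell
      // probability is the plain sum of exp over incoming transitions
      for (int j = 1; j <= n; ++j) {
        for (int k = 1; k <= M; ++k) {
          double bMkj = bM(k, j);
          if (bMkj != NEG_INF) {
            for (int li = 0; li < 5; ++li) {
              int l = lens[li];
              if (l > j) break;
              double e = ec.M_(k, j, l);
              if (e == NEG_INF) continue;
              int jp = j - l;
              double base = e + bMkj - total;
              double p = exp(fB[jp] + fm.entry(k) + base);
              if (k > 1) {
                p += exp(fM(k - 1, jp) + fm.tr(k - 1, 0) + base);
                p += exp(fI(k - 1, jp) + fm.tr(k - 1, 3) + base);
                p += exp(fD(k - 1, jp) + fm.tr(k - 1, 5) + base);
              }
              if (p > 0) for (int t = jp; t < j; ++t) post_core[t] += p;
            }
          }
          if (k < M && j >= 3 && fI(k, j) != NEG_INF) {
            double p = exp(fI(k, j) + bI(k, j) - total);
            if (p > 0) for (int t = j - 3; t < j; ++t) post_core[t] += p;
          }
        }
      }
      out["post_core"] = post_core;
      out["post_flank"] = post_flank;
    }
  }

  // ---------------- Viterbi (+ traceback) ----------------
  if (do_vit) {
    NumericMatrix vM(M + 1, n + 1), vI(M + 1, n + 1), vD(M + 1, n + 1);
    std::vector<double> vN(n + 1, NEG_INF), vB(n + 1, NEG_INF), vE(n + 1, NEG_INF),
      vJ(n + 1, NEG_INF), vC(n + 1, NEG_INF);
    std::fill(vM.begin(), vM.end(), NEG_INF);
    std::fill(vI.begin(), vI.end(), NEG_INF);
    std::fill(vD.begin(), vD.end(), NEG_INF);
    vN[0] = 0.0; vB[0] = sp.nmove;
    for (int j = 1; j <= n; ++j) {
      double E = NEG_INF;
      for (int k = 1; k <= M; ++k) {
        double sM = NEG_INF;
        for (int li = 0; li < 5; ++li) {
          int l = lens[li];
          if (l > j) break;
          double e = ec.M_(k, j, l);
          if (e == NEG_INF) continue;
          int jp = j - l;
          double in = vB[jp] + fm.entry(k);
          if (k > 1) {
            in = vmax2(in, vM(k - 1, jp) + fm.tr(k - 1, 0));
            in = vmax2(in, vI(k - 1, jp) + fm.tr(k - 1, 3));
            in = vmax2(in, vD(k - 1, jp) + fm.tr(k - 1, 5));
          }
          if (in != NEG_INF) sM = vmax2(sM, in + e);
        }
        vM(k, j) = sM;
        if (k < M && j >= 3) {
          double e = ec.I_(k, j);
          if (e != NEG_INF) {
            double in = vmax2(vM(k, j - 3) + fm.tr(k, 1), vI(k, j - 3) + fm.tr(k, 4));
            vI(k, j) = in == NEG_INF ? NEG_INF : in + e;
          }
        }
        if (k > 1) vD(k, j) = vmax2(vM(k - 1, j) + fm.tr(k - 1, 2),
                                    vD(k - 1, j) + fm.tr(k - 1, 6));
        E = vmax2(E, vmax2(vM(k, j), vD(k, j)));
      }
      vE[j] = E;
      vJ[j] = vmax2(vJ[j - 1] + sp.jloop, E + sp.ej);
      vC[j] = vmax2(vC[j - 1] + sp.cloop, E + sp.ec);
      vN[j] = vN[j - 1] + sp.nloop;
      vB[j] = vmax2(vN[j] + sp.nmove, vJ[j] + sp.jmove);
    }
    double vtotal = vC[n] + sp.cmove;
    out["vit_bits"] = (vtotal - sp.nullsc) / M_LN2;

    // traceback; kind 0=M 1=I 2=D 3=N 4=C 5=J
    // cls 0=sense 1=stop 2..5=quasi(1,2,4,5) 6=gap 7=flank 8=neutral
    std::vector<int> kind, state, from, to, cls;
    auto push = [&](int kd, int st, int f, int t, int cl) {
      kind.push_back(kd); state.push_back(st);
      from.push_back(f); to.push_back(t); cls.push_back(cl);
    };
    auto chunk_cls = [&](int j, int l) {
      int c = ec.cls[(j - 1) * 5 + (l - 1)];
      if (c == CH_NEUTRAL) return 8;
      if (c == CH_STOP) return 1;
      if (c == CH_SENSE) return 0;
      return l == 1 ? 2 : (l == 2 ? 3 : (l == 4 ? 4 : 5));
    };
    int j = n; char csflank = 'C';
    int flank_end = n;
    if (vtotal == NEG_INF) {
      out["path"] = IntegerMatrix(0, 5);
      return out;
    }
    while (true) {
      if (csflank == 'C') {
        if (j > 0 && vC[j] == vC[j - 1] + sp.cloop) { j -= 1; continue; }
        if (flank_end > j) push(4, 0, j, flank_end, 7);
        csflank = 'E';
      }
      if (csflank == 'J') {
        if (j > 0 && vJ[j] == vJ[j - 1] + sp.jloop) { j -= 1; continue; }
        if (flank_end > j) push(5, 0, j, flank_end, 7);
        csflank = 'E';
      }
      if (csflank == 'N') {
        if (j > 0) push(3, 0, 0, j, 7);
        break;
      }
      // at E[j]: find the core path ending here
      int bk = -1; char bs = 'M';
      for (int k = 1; k <= M; ++k) {
        if (vM(k, j) == vE[j]) { bk = k; bs = 'M'; break; }
        if (vD(k, j) == vE[j]) { bk = k; bs = 'D'; break; }
      }
      if (bk < 0) stop("FA viterbi traceback failed at E");
      int k = bk; char s = bs;
      bool at_B = false;
      while (!at_B) {
        if (s == 'M') {
          // recompute candidate values with the same arithmetic as the DP
          // fill so equality comparisons are exact
          bool found = false;
          for (int li = 0; li < 5 && !found; ++li) {
            int l = lens[li];
            if (l > j) break;
            double e = ec.M_(k, j, l);
            if (e == NEG_INF) continue;
            int jp = j - l;
            double target = vM(k, j);
            if (vB[jp] + fm.entry(k) + e == target) {
              push(0, k, jp, j, chunk_cls(j, l));
              j = jp; at_B = true; found = true;
            } else if (k > 1 && vM(k - 1, jp) + fm.tr(k - 1, 0) + e == target) {
              push(0, k, jp, j, chunk_cls(j, l));
              j = jp; k -= 1; s = 'M'; found = true;
            } else if (k > 1 && vI(k - 1, jp) + fm.tr(k - 1, 3) + e == target) {
              push(0, k, jp, j, chunk_cls(j, l));
              j = jp; k -= 1; s = 'I'; found = true;
            } else if (k > 1 && vD(k - 1, jp) + fm.tr(k - 1, 5) + e == target) {
              push(0, k, jp, j, chunk_cls(j, l));
              j = jp; k -= 1; s = 'D'; found = true;
            }
          }
          if (!found) stop("FA viterbi traceback failed at M");
        } else if (s == 'I') {
          double e = ec.I_(k, j);
          double target = vI(k, j);
          push(1, k, j - 3, j, chunk_cls(j, 3));
          j -= 3;
          if (vM(k, j) + fm.tr(k, 1) + e == target) s = 'M';
          else if (vI(k, j) + fm.tr(k, 4) + e == target) s = 'I';
          else stop("FA viterbi traceback failed at I");
        } else {  // D
          push(2, k, j, j, 6);
          double need = vD(k, j);
          if (vM(k - 1, j) + fm.tr(k - 1, 2) == need) { s = 'M'; k -= 1; }
          else if (vD(k - 1, j) + fm.tr(k - 1, 6) == need) { s = 'D'; k -= 1; }
          else stop("FA viterbi traceback failed at D");
        }
      }
      // at B[j]: came from N (done after flank) or J (another hit)
      if (vB[j] == vN[j] + sp.nmove) { csflank = 'N'; }
      else { csflank = 'J'; flank_end = j; }
    }
    int np = kind.size();
    IntegerMatrix path(np, 5);
    for (int i = 0; i < np; ++i) {
      int r = np - 1 - i;
      path(i, 0) = kind[r]; path(i, 1) = state[r];
      path(i, 2) = from[r]; path(i, 3) = to[r]; path(i, 4) = cls[r];
    }
    colnames(path) = CharacterVector::create("kind", "state", "from", "to", "cls");
    out["path"] = path;
  }
  return out;
}
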