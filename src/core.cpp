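// Core scenario-enumeration engine.
//
// Reads are integer-encoded (A=0, C=1, G=2, T=3, N=-1) and assumed to be
// 3'-anchored windows of the recombined sequence: the last read base
// coincides with the 3' end of the J segment core, while the 5' end may
// truncate into the retained V segment.  Scenario coordinates are 0-based,
// half-open on the read: V covers [0, x), the V-D insertion [x, a), the
// retained D [a, b), the D-J insertion [b, y) and J [y, L).  For VJ chains
// the insertion is [x, y) and there is no D.
//
// Candidate (gene, diagonal, deletion) placements are generated per read,
// filtered by alignment-score thresholds, and combined in a descending
// branch-and-bound join: branches whose optimistic completion bound falls
// below prune_ratio * best-scenario-so-far are discarded and their bound
// accumulated into a truncated-mass estimate.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_QUARTER = -1.3862943611198906;

struct Acc {
  double m;
  double S;
  long n;
  Acc() : m(R_NegInf), S(0.0), n(0) {}
  void add(double lp) {
    if (!R_finite(lp)) return;
    n++;
    if (lp > m) {
      S = (m == R_NegInf) ? 1.0 : S * std::exp(m - lp) + 1.0;
      m = lp;
    } else {
      S += std::exp(lp - m);
    }
  }
  double logsum() const { return (n == 0 || S <= 0.0) ? R_NegInf : m + std::log(S); }
};

struct VRow {
  int v, off, d, x, mm, zmm, zlo;
  double lp, lpclean;
  int vbase;
};
struct JRow {
  int j, d, y, mm, zmm, zhi;
  double lp, lpclean;
  int jbase;
};
struct DRow {
  int g, dl, dr, a, b, mm;
  double lp, lpclean, sortkey;
};

struct ErrModel {
  int kind;  // 0 uniform, 1 pwm
  bool exact;
  double lerr3, l1e;    // uniform
  int m;                 // pwm half-width
  double mu;
  std::vector<double> e; // (2m+1) x 4, idx pos*4 + base
  double lp_fb_mut, lp_fb_nomut; // fallback when context undefined
  double lp_mm_max;      // optimistic per-mismatch factor (upper bound)

  // exact pwm factor given summed motif score s and mismatch flag
  inline double pwm_factor(double s, bool mism) const {
    double lx = std::log(mu) + s;        // log odds
    double l1px = (lx > 30) ? lx : std::log1p(std::exp(lx));
    if (mism) return lx - l1px - 1.0986122886681098; // log(Pmut/3)
    return -l1px;                                     // log(1 - Pmut)
  }
};

struct Scen {
  double lp, lpclean;
  int v, g, j, delv, dl, dr, delj, x, a, b, y, mm;
};

static inline bool scen_key_less(const Scen &p, const Scen &q) {
  if (p.v != q.v) return p.v < q.v;
  if (p.g != q.g) return p.g < q.g;
  if (p.j != q.j) return p.j < q.j;
  if (p.delv != q.delv) return p.delv < q.delv;
  if (p.dl != q.dl) return p.dl < q.dl;
  if (p.dr != q.dr) return p.dr < q.dr;
  if (p.delj != q.delj) return p.delj < q.delj;
  return p.a < q.a;
}
// ranking order: higher lp first, then lexicographic key
static inline bool scen_before(const Scen &p, const Scen &q) {
  if (p.lp != q.lp) return p.lp > q.lp;
  return scen_key_less(p, q);
}

// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, double s_match,
                    double s_mism, double s_gap) {
  // Smith-Waterman local alignment score, linear gap penalty.
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; i++) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; j++) {
      double sub = (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ? s_match : s_mism;
      double v = prev[j - 1] + sub;
      v = std::max(v, prev[j] + s_gap);
      v = std::max(v, cur[j - 1] + s_gap);
      v = std::max(v, 0.0);
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// ---------------------------------------------------------------------------

class Annotator {
public:
  const int *r;
  int L;
  int chain; // 0 VJ, 1 VDJ
  int maxp;
  int nV, nD, nJ;
  std::vector<const int *> Vext, Dext, Jext;
  std::vector<int> Vextlen, Dextlen, Jextlen;
  std::vector<int> Vcore, Dcore, Jcore;
  int dv0, dv1, dj0, dj1, dl0, dl1, dr0, dr1, insmax;
  const double *lpV, *lpVJ, *lpDJ, *lpdelV, *lpdelJ, *lpdelD;
  const double *lpinsVD, *lpinsDJ, *lpinsVJ;
  const double *lTvd, *lTdj, *lTvj;
  ErrModel em;
  double thr_v, thr_j, s_match, s_mism;
  double prune_ratio, floor_lp, mm_budget;
  int k_top;
  bool want_stats;

  std::vector<int> nNpre;         // read N prefix counts
  std::vector<double> cumTvd, revTdj, cumTvj; // content transition cumsums
  std::vector<VRow> vrows;
  std::vector<JRow> jrows;
  std::vector<DRow> drows;

  // results
  Acc acc;
  double best;
  double cut;
  double lpr;
  double pruned; // linear-scale bound on pruned mass (relative to exp)
  std::vector<Scen> heap;
  long n_scen;
  // truth
  bool have_truth;
  Scen truth;
  double truth_lp, truth_lpclean;
  long n_above, n_tie_before;
  // stats
  double ref;
  std::vector<double> cV, cVJ, cDJ, cdelV, cdelJ, cdelD, cinsVD, cinsDJ,
      cinsVJ, cTvdc, cTdjc, cTvjc;
  double s_err_ev, s_err_opp, s_wlogp, s_w;

  Annotator() : best(R_NegInf), cut(R_NegInf), pruned(0.0), n_scen(0),
                have_truth(false), truth_lp(NA_REAL), truth_lpclean(NA_REAL),
                n_above(0), n_tie_before(0), ref(0.0), s_err_ev(0), s_err_opp(0),
                s_wlogp(0), s_w(0) {}

  inline double lTrans(const double *T, int prev, int next) const {
    if (prev < 0 || next < 0) return LOG_QUARTER;
    return T[prev * 4 + next];
  }

  void precompute_read() {
    nNpre.assign(L + 1, 0);
    for (int p = 0; p < L; p++) nNpre[p + 1] = nNpre[p] + (r[p] < 0 ? 1 : 0);
    cumTvd.assign(L, 0.0);
    cumTvj.assign(L, 0.0);
    for (int p = 1; p < L; p++) {
      cumTvd[p] = cumTvd[p - 1] + (chain == 1 ? lTrans(lTvd, r[p - 1], r[p]) : 0.0);
      cumTvj[p] = cumTvj[p - 1] + (chain == 0 ? lTrans(lTvj, r[p - 1], r[p]) : 0.0);
    }
    revTdj.assign(L + 1, 0.0);
    if (chain == 1) {
      for (int p = L - 2; p >= 0; p--)
        revTdj[p] = revTdj[p + 1] + lTrans(lTdj, r[p + 1], r[p]);
    }
  }

  inline double contentVD(int x, int a, int vbase) const {
    if (a <= x) return 0.0;
    return lTrans(lTvd, vbase, r[x]) + (cumTvd[a - 1] - cumTvd[x]);
  }
  inline double contentVJ(int x, int y, int vbase) const {
    if (y <= x) return 0.0;
    return lTrans(lTvj, vbase, r[x]) + (cumTvj[y - 1] - cumTvj[x]);
  }
  inline double contentDJ(int b, int y, int jbase) const {
    if (y <= b) return 0.0;
    return lTrans(lTdj, jbase, r[y - 1]) + (revTdj[b] - revTdj[y - 1]);
  }

  // uniform-error factor for a covered block given mismatches and non-N len
  inline double ublock(int mm, int cov) const {
    if (em.exact) return (mm > 0) ? R_NegInf : 0.0;
    return mm * em.lerr3 + (cov - mm) * em.l1e;
  }

  // ---- candidate construction -------------------------------------------

  void build_vrows() {
    int mzone = (em.kind == 1) ? em.m : 0;
    for (int v = 0; v < nV; v++) {
      int Lc = Vcore[v], elen = Vextlen[v];
      const int *E = Vext[v];
      int offmax = Lc - dv0 - 1;
      for (int off = 0; off <= offmax; off++) {
        int xmax = std::min(L - 1, Lc - dv0 - off); // largest usable boundary
        if (xmax < 1) continue;
        // quick pass: mismatches and score
        std::vector<int> cmm(xmax + 1, 0);
        double sc = 0.0, smax = 0.0;
        bool any_exact = true;
        for (int p = 0; p < xmax; p++) {
          int q = p + off;
          int g = (q < elen) ? E[q] : -2;
          bool mism = (r[p] < 0) || (g < 0) || (r[p] != g);
          cmm[p + 1] = cmm[p] + ((r[p] >= 0 && g >= 0 && r[p] != g) ? 1 : 0);
          sc += mism ? s_mism : s_match;
          if (sc < 0) sc = 0; // prefix-local
          if (sc > smax) smax = sc;
        }
        if (!em.exact && smax < thr_v) continue;
        if (em.exact) {
          // need at least one zero-mismatch boundary
          bool ok = false;
          for (int d = dv0; d <= dv1; d++) {
            int x = Lc - d - off;
            if (x >= 1 && x <= xmax && cmm[x] == 0 && nNpre[x] == 0) { ok = true; break; }
          }
          if (!ok) continue;
          (void)any_exact;
        }
        // factor cumsum
        std::vector<double> cF(xmax + 1, 0.0);
        if (!em.exact) {
          for (int p = 0; p < xmax; p++) {
            double f = 0.0;
            if (r[p] >= 0) {
              int q = p + off;
              int g = (q < elen) ? E[q] : -2;
              bool mism = (g < 0) || (r[p] != g);
              if (em.kind == 0) {
                f = mism ? em.lerr3 : em.l1e;
              } else {
                // full-germline context along this diagonal
                double s = 0.0; bool undef = false;
                for (int i = -em.m; i <= em.m; i++) {
                  int qq = q + i;
                  if (qq < 0 || qq >= elen) { undef = true; break; }
                  s += em.e[(i + em.m) * 4 + E[qq]];
                }
                if (undef || g < 0) f = mism ? em.lp_fb_mut : em.lp_fb_nomut;
                else f = em.pwm_factor(s, mism);
              }
            }
            cF[p + 1] = cF[p] + f;
          }
        }
        for (int d = dv0; d <= dv1; d++) {
          int x = Lc - d - off;
          if (x < 1 || x > xmax) continue;
          double lpd = lpdelV[v + (size_t)nV * (d - dv0)];
          if (!R_finite(lpd)) continue;
          if (em.exact && (cmm[x] > 0 || nNpre[x] > 0)) continue;
          VRow row;
          row.v = v; row.off = off; row.d = d; row.x = x;
          row.mm = cmm[x];
          row.zlo = std::max(0, x - mzone);
          row.zmm = cmm[x] - cmm[row.zlo];
          row.vbase = E[Lc - d - 1];
          double gene = (chain == 1) ? lpV[v] : 0.0;
          double errpart;
          if (em.exact) errpart = 0.0;
          else if (em.kind == 0) errpart = cF[x];
          else errpart = cF[row.zlo] + row.zmm * em.lp_mm_max;
          row.lpclean = gene + lpd;
          row.lp = row.lpclean + errpart;
          if (R_finite(row.lp)) vrows.push_back(row);
        }
      }
    }
  }

  void build_jrows() {
    int mzone = (em.kind == 1) ? em.m : 0;
    for (int j = 0; j < nJ; j++) {
      int Lc = Jcore[j], elen = Jextlen[j];
      const int *E = Jext[j];
      int off = maxp + Lc - L; // forced: read 3' end == J core 3' end
      int ymin = std::max(1, -off);
      // suffix mismatch / score / factor
      std::vector<int> smm(L + 1, 0);
      std::vector<double> sF(L + 1, 0.0);
      double sc = 0.0, smax = 0.0;
      for (int p = L - 1; p >= ymin; p--) {
        int q = p + off;
        int g = (q >= 0 && q < elen) ? E[q] : -2;
        bool mism = (r[p] < 0) || (g < 0) || (r[p] != g);
        smm[p] = smm[p + 1] + ((r[p] >= 0 && g >= 0 && r[p] != g) ? 1 : 0);
        sc += mism ? s_mism : s_match;
        if (sc < 0) sc = 0;
        if (sc > smax) smax = sc;
        double f = 0.0;
        if (!em.exact && r[p] >= 0) {
          if (em.kind == 0) f = mism ? em.lerr3 : em.l1e;
          else {
            double s = 0.0; bool undef = false;
            for (int i = -em.m; i <= em.m; i++) {
              int qq = q + i;
              if (qq < 0 || qq >= elen) { undef = true; break; }
              s += em.e[(i + em.m) * 4 + E[qq]];
            }
            // context past the read 3' end does not exist in the ancestor
            if (p + em.m >= L) undef = true;
            if (undef || g < 0) f = mism ? em.lp_fb_mut : em.lp_fb_nomut;
            else f = em.pwm_factor(s, mism);
          }
        }
        sF[p] = sF[p + 1] + f;
      }
      if (!em.exact && smax < thr_j) continue;
      for (int d = dj0; d <= dj1; d++) {
        int y = maxp + d - off;
        if (y < ymin || y > L - 1) continue;
        double lpd = lpdelJ[j + (size_t)nJ * (d - dj0)];
        if (!R_finite(lpd)) continue;
        int mm = smm[y];
        if (em.exact && (mm > 0 || nNpre[L] - nNpre[y] > 0)) continue;
        JRow row;
        row.j = j; row.d = d; row.y = y; row.mm = mm;
        row.zhi = std::min(L, y + mzone);
        row.zmm = mm - smm[row.zhi];
        row.jbase = E[maxp + d];
        double errpart;
        if (em.exact) errpart = 0.0;
        else if (em.kind == 0) errpart = sF[y];
        else errpart = sF[row.zhi] + row.zmm * em.lp_mm_max;
        row.lpclean = lpd;
        row.lp = row.lpclean + errpart;
        if (R_finite(row.lp)) jrows.push_back(row);
      }
    }
  }

  void build_drows() {
    if (chain != 1) return;
    double lp_mm_unit = (em.kind == 0) ? (em.lerr3 - em.l1e) : em.lp_mm_max;
    int mm_cap = em.exact ? 0
        : (int)std::ceil(mm_budget / std::max(1e-9, -lp_mm_unit));
    // under a permissive PWM the optimistic per-mismatch bound is mild; cap
    // the D mismatch count so candidate placements stay tractable (reads
    // carry only a handful of mutations, a single D stub carrying more than
    // 8 contributes negligibly)
    if (mm_cap > 8 && !em.exact && em.kind == 1) mm_cap = 8;
    int ndl = dl1 - dl0 + 1, ndr = dr1 - dr0 + 1;
    for (int g = 0; g < nD; g++) {
      int Lc = Dcore[g];
      const int *E = Dext[g];
      double maxdj = R_NegInf;
      for (int j = 0; j < nJ; j++) maxdj = std::max(maxdj, lpDJ[g + (size_t)nD * j]);
      if (!R_finite(maxdj)) continue;
      for (int dl = dl0; dl <= dl1; dl++) {
        for (int dr = dr0; dr <= dr1; dr++) {
          int len = Lc - dl - dr;
          if (len < 0) continue;
          double lpd = lpdelD[(g * (size_t)ndl + (dl - dl0)) * ndr + (dr - dr0)];
          if (!R_finite(lpd)) continue;
          int q0 = maxp + dl;
          for (int a = 1; a + len <= L - 1; a++) {
            int mm = 0;
            bool skip = false;
            for (int k = 0; k < len; k++) {
              int rb = r[a + k];
              if (rb >= 0 && rb != E[q0 + k]) {
                if (++mm > mm_cap) { skip = true; break; }
              }
            }
            if (skip) continue;
            if (em.exact && mm > 0) continue;
            DRow row;
            row.g = g; row.dl = dl; row.dr = dr; row.a = a; row.b = a + len;
            row.mm = mm;
            row.lpclean = lpd;
            double errpart;
            if (em.exact) errpart = 0.0;
            else if (em.kind == 0)
              errpart = ublock(mm, len - (nNpre[row.b] - nNpre[a]));
            else errpart = mm * em.lp_mm_max; // optimistic; exact at join
            row.lp = lpd + errpart;
            row.sortkey = row.lp + maxdj;
            if (R_finite(row.lp)) drows.push_back(row);
          }
        }
      }
    }
  }

  // ---- pwm join-time exact correction ------------------------------------

  // ancestral base at read position p under scenario pieces
  inline int anc_base(int p, const VRow &V, const DRow *D, const JRow &J) const {
    if (p < V.x) {
      int q = p + V.off;
      return (q >= 0 && q < Vextlen[V.v]) ? Vext[V.v][q] : -2;
    }
    int a = D ? D->a : J.y, b = D ? D->b : J.y;
    if (p < a) return r[p];
    if (p < b) return Dext[D->g][maxp + D->dl + (p - a)];
    if (p < J.y) return r[p];
    int q = p + (maxp + Jcore[J.j] - L);
    return (q >= 0 && q < Jextlen[J.j]) ? Jext[J.j][q] : -2;
  }

  inline double pwm_pos_factor(int p, const VRow &V, const DRow *D,
                               const JRow &J) const {
    if (r[p] < 0) return 0.0;
    int g = anc_base(p, V, D, J);
    double s = 0.0;
    bool undef = (g < 0);
    if (!undef) {
      for (int i = -em.m; i <= em.m; i++) {
        int c = anc_base(p + i, V, D, J);
        if (c < 0) { undef = true; break; }
        s += em.e[(i + em.m) * 4 + c];
      }
    }
    bool mism = (g < 0) || (r[p] != g);
    if (undef) return mism ? em.lp_fb_mut : em.lp_fb_nomut;
    return em.pwm_factor(s, mism);
  }

  // exact error factor for the boundary zones + D block, minus the
  // optimistic bounds already contained in the row lp's
  inline double pwm_corr(const VRow &V, const DRow *D, const JRow &J) const {
    double corr = 0.0;
    for (int p = V.zlo; p < V.x; p++) corr += pwm_pos_factor(p, V, D, J);
    corr -= V.zmm * em.lp_mm_max;
    if (D) {
      for (int p = D->a; p < D->b; p++) corr += pwm_pos_factor(p, V, D, J);
      corr -= D->mm * em.lp_mm_max;
    }
    for (int p = J.y; p < J.zhi; p++) corr += pwm_pos_factor(p, V, D, J);
    corr -= J.zmm * em.lp_mm_max;
    return corr;
  }

  // ---- scenario evaluation ------------------------------------------------

  inline double eval(const VRow &V, const DRow *D, const JRow &J,
                     double &lpclean) const {
    double lp, clean;
    if (chain == 1) {
      int ivd = D->a - V.x, idj = J.y - D->b;
      clean = V.lpclean + D->lpclean + J.lpclean +
              lpDJ[D->g + (size_t)nD * J.j] + lpinsVD[ivd] + lpinsDJ[idj] +
              contentVD(V.x, D->a, V.vbase) + contentDJ(D->b, J.y, J.jbase);
      lp = clean + (V.lp - V.lpclean) + (D->lp - D->lpclean) +
           (J.lp - J.lpclean);
    } else {
      int ins = J.y - V.x;
      clean = V.lpclean + J.lpclean + lpVJ[V.v + (size_t)nV * J.j] +
              lpinsVJ[ins] + contentVJ(V.x, J.y, V.vbase);
      lp = clean + (V.lp - V.lpclean) + (J.lp - J.lpclean);
    }
    if (em.kind == 1 && !em.exact && R_finite(lp)) {
      // row factors bound the boundary-zone/D error terms optimistically, so
      // lp here is an upper bound: skip the exact correction when the bound
      // is already below the pruning cut (the caller then discards it)
      if (lp >= cut) lp += pwm_corr(V, D, J);
    }
    lpclean = clean;
    return lp;
  }

  void record(const VRow &V, const DRow *D, const JRow &J, double lp,
              double lpclean) {
    acc.add(lp);
    n_scen++;
    Scen s;
    s.lp = lp; s.lpclean = lpclean;
    s.v = V.v; s.g = D ? D->g : -1; s.j = J.j;
    s.delv = V.d; s.dl = D ? D->dl : 0; s.dr = D ? D->dr : 0; s.delj = J.d;
    s.x = V.x; s.a = D ? D->a : J.y; s.b = D ? D->b : J.y; s.y = J.y;
    s.mm = V.mm + (D ? D->mm : 0) + J.mm;
    if (lp > best) {
      best = lp;
      cut = (lpr == R_NegInf) ? R_NegInf : best + lpr;
    }
    if (k_top > 0) {
      if ((int)heap.size() < k_top) {
        heap.push_back(s);
        std::push_heap(heap.begin(), heap.end(), scen_before);
      } else if (scen_before(s, heap.front())) {
        std::pop_heap(heap.begin(), heap.end(), scen_before);
        heap.back() = s;
        std::push_heap(heap.begin(), heap.end(), scen_before);
      }
    }
    if (have_truth && R_finite(truth_lp)) {
      if (lp > truth_lp + 1e-9) n_above++;
      else if (std::fabs(lp - truth_lp) <= 1e-9) {
        if (scen_key_less(s, truth)) n_tie_before++;
      }
    }
    if (want_stats) {
      double w = std::exp(lp - ref);
      if (w > 0) {
        s_w += w;
        s_wlogp += w * lp;
        int cov, mmt = s.mm;
        if (chain == 1) {
          cV[s.v] += w;
          cDJ[s.g + (size_t)nD * s.j] += w;
          cdelV[s.v + (size_t)nV * (s.delv - dv0)] += w;
          cdelJ[s.j + (size_t)nJ * (s.delj - dj0)] += w;
          int ndl = dl1 - dl0 + 1, ndr = dr1 - dr0 + 1;
          cdelD[(s.g * (size_t)ndl + (s.dl - dl0)) * ndr + (s.dr - dr0)] += w;
          int ivd = s.a - s.x, idj = s.y - s.b;
          cinsVD[ivd] += w;
          cinsDJ[idj] += w;
          if (ivd >= 1) {
            if (V.vbase >= 0 && r[s.x] >= 0) cTvdc[V.vbase * 4 + r[s.x]] += w;
            for (int q = s.x + 1; q < s.a; q++)
              if (r[q - 1] >= 0 && r[q] >= 0) cTvdc[r[q - 1] * 4 + r[q]] += w;
          }
          if (idj >= 1) {
            if (J.jbase >= 0 && r[s.y - 1] >= 0) cTdjc[J.jbase * 4 + r[s.y - 1]] += w;
            for (int q = s.b; q < s.y - 1; q++)
              if (r[q + 1] >= 0 && r[q] >= 0) cTdjc[r[q + 1] * 4 + r[q]] += w;
          }
          cov = (s.x - nNpre[s.x]) + (s.b - s.a - (nNpre[s.b] - nNpre[s.a])) +
                (L - s.y - (nNpre[L] - nNpre[s.y]));
        } else {
          cVJ[s.v + (size_t)nV * s.j] += w;
          cdelV[s.v + (size_t)nV * (s.delv - dv0)] += w;
          cdelJ[s.j + (size_t)nJ * (s.delj - dj0)] += w;
          int ins = s.y - s.x;
          cinsVJ[ins] += w;
          if (ins >= 1) {
            if (V.vbase >= 0 && r[s.x] >= 0) cTvjc[V.vbase * 4 + r[s.x]] += w;
            for (int q = s.x + 1; q < s.y; q++)
              if (r[q - 1] >= 0 && r[q] >= 0) cTvjc[r[q - 1] * 4 + r[q]] += w;
          }
          cov = (s.x - nNpre[s.x]) + (L - s.y - (nNpre[L] - nNpre[s.y]));
        }
        s_err_ev += w * mmt;
        s_err_opp += w * cov;
      }
    }
  }

  // ---- truth -------------------------------------------------------------

  void locate_truth(const NumericVector &tr) {
    // tr: v, g, j, delv, dl, dr, delj, x, a, y   (indices 0-based; g = -1 for VJ)
    have_truth = true;
    truth.v = (int)tr[0]; truth.g = (int)tr[1]; truth.j = (int)tr[2];
    truth.delv = (int)tr[3]; truth.dl = (int)tr[4]; truth.dr = (int)tr[5];
    truth.delj = (int)tr[6]; truth.x = (int)tr[7]; truth.a = (int)tr[8];
    truth.y = (int)tr[9];
    const VRow *V = NULL; const JRow *J = NULL; const DRow *D = NULL;
    for (auto &row : vrows)
      if (row.v == truth.v && row.d == truth.delv && row.x == truth.x) { V = &row; break; }
    for (auto &row : jrows)
      if (row.j == truth.j && row.d == truth.delj) { J = &row; break; }
    if (chain == 1) {
      for (auto &row : drows)
        if (row.g == truth.g && row.dl == truth.dl && row.dr == truth.dr &&
            row.a == truth.a) { D = &row; break; }
    }
    if (V == NULL || J == NULL || (chain == 1 && D == NULL)) return;
    if (truth.y != J->y) return;
    int a = chain == 1 ? D->a : J->y;
    if (V->x > a || a - V->x > insmax) return;
    if (chain == 1 && (D->b > J->y || J->y - D->b > insmax)) return;
    double saved_cut = cut;
    cut = R_NegInf;  // truth likelihood must be exact, never bound-skipped
    double clean;
    double lp = eval(*V, D, *J, clean);
    cut = saved_cut;
    if (R_finite(lp)) { truth_lp = lp; truth_lpclean = clean; }
    truth.b = chain == 1 ? D->b : J->y;
  }

  // ---- join ---------------------------------------------------------------

  void phaseA() {
    // quick pass over the top rows of each table to seed the bound
    size_t kv = std::min<size_t>(vrows.size(), 25);
    size_t kj = std::min<size_t>(jrows.size(), 25);
    size_t kd = chain == 1 ? std::min<size_t>(drows.size(), 60) : 1;
    for (size_t ij = 0; ij < kj; ij++) {
      const JRow &J = jrows[ij];
      for (size_t id = 0; id < kd; id++) {
        const DRow *D = chain == 1 ? &drows[id] : NULL;
        if (D && (D->b > J.y || J.y - D->b > insmax)) continue;
        if (D && !R_finite(lpDJ[D->g + (size_t)nD * J.j])) continue;
        for (size_t iv = 0; iv < kv; iv++) {
          const VRow &V = vrows[iv];
          int a = D ? D->a : J.y;
          if (V.x > a || a - V.x > insmax) continue;
          double clean;
          double lp = eval(V, D, J, clean);
          if (R_finite(lp) && lp > best) best = lp;
        }
      }
    }
    if (R_finite(best) && lpr != R_NegInf) cut = best + lpr;
    ref = R_finite(best) ? best : 0.0;
  }

  void join() {
    double ubV = R_NegInf;
    for (auto &v : vrows) ubV = std::max(ubV, v.lp);
    // insertion bounds include the content chain: len inserted bases cost at
    // least len * (max log transition), still an optimistic upper bound
    double mTvd = R_NegInf, mTdj = R_NegInf, mTvj = R_NegInf;
    for (int i = 0; i < 16; i++) {
      mTvd = std::max(mTvd, lTvd[i]);
      mTdj = std::max(mTdj, lTdj[i]);
      mTvj = std::max(mTvj, lTvj[i]);
    }
    mTvd = std::min(mTvd, 0.0); mTdj = std::min(mTdj, 0.0);
    mTvj = std::min(mTvj, 0.0);
    double ubIvd = R_NegInf, ubIdj = R_NegInf, ubIvj = R_NegInf;
    for (int i = 0; i <= insmax; i++) {
      if (chain == 1) {
        ubIvd = std::max(ubIvd, lpinsVD[i] + i * mTvd);
        ubIdj = std::max(ubIdj, lpinsDJ[i] + i * mTdj);
      } else ubIvj = std::max(ubIvj, lpinsVJ[i] + i * mTvj);
    }
    size_t nv = vrows.size(), nd = drows.size(), nj = jrows.size();
    if (chain == 1) {
      double ubDsk = R_NegInf;
      for (auto &d : drows) ubDsk = std::max(ubDsk, d.sortkey);
      for (size_t ij = 0; ij < nj; ij++) {
        const JRow &J = jrows[ij];
        double bJ = J.lp + ubDsk + ubIdj + ubV + ubIvd;
        if (bJ < cut) { pruned += std::exp(bJ) * (double)(nd * nv); continue; }
        for (size_t id = 0; id < nd; id++) {
          const DRow &D = drows[id];
          double b2 = J.lp + D.sortkey + ubIdj + ubV + ubIvd;
          if (b2 < cut) { // sorted desc by sortkey
            pruned += std::exp(b2) * (double)((nd - id) * nv);
            break;
          }
          if (D.b > J.y) continue;
          int idj = J.y - D.b;
          if (idj > insmax) continue;
          double lpdj = lpDJ[D.g + (size_t)nD * J.j];
          if (!R_finite(lpdj)) continue;
          double partial = J.lp + D.lp + lpdj + lpinsDJ[idj] +
                           contentDJ(D.b, J.y, J.jbase);
          if (!R_finite(partial)) continue;
          if (partial + ubV + ubIvd < cut) {
            pruned += std::exp(partial + ubV + ubIvd) * (double)nv;
            continue;
          }
          for (size_t iv = 0; iv < nv; iv++) {
            const VRow &V = vrows[iv];
            double b3 = partial + V.lp + ubIvd;
            if (b3 < cut) { // sorted desc by lp
              pruned += std::exp(b3) * (double)(nv - iv);
              break;
            }
            if (V.x > D.a) continue;
            int ivd = D.a - V.x;
            if (ivd > insmax) continue;
            if (partial + V.lp + lpinsVD[ivd] + ivd * mTvd < cut) continue;
            double clean;
            double lp = eval(V, &D, J, clean);
            if (!R_finite(lp)) continue;
            if (lp < cut) { pruned += std::exp(lp); continue; }
            record(V, &D, J, lp, clean);
          }
        }
      }
    } else {
      for (size_t ij = 0; ij < nj; ij++) {
        const JRow &J = jrows[ij];
        if (J.lp + ubV + ubIvj < cut) {
          pruned += std::exp(J.lp + ubV + ubIvj) * (double)nv;
          continue;
        }
        for (size_t iv = 0; iv < nv; iv++) {
          const VRow &V = vrows[iv];
          double b2 = J.lp + V.lp + ubIvj;
          if (b2 < cut) { pruned += std::exp(b2) * (double)(nv - iv); break; }
          if (V.x > J.y) continue;
          int ins = J.y - V.x;
          if (ins > insmax) continue;
          if (J.lp + V.lp + lpinsVJ[ins] + ins * mTvj < cut) continue;
          double clean;
          double lp = eval(V, NULL, J, clean);
          if (!R_finite(lp)) continue;
          if (lp < cut) { pruned += std::exp(lp); continue; }
          record(V, NULL, J, lp, clean);
        }
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_annotate(IntegerVector read, List cm, List opts) {
  Annotator A;
  std::vector<int> rd(read.begin(), read.end());
  A.r = rd.data();
  A.L = rd.size();
  A.chain = as<int>(cm["chain"]);
  A.maxp = as<int>(cm["maxp"]);
  List Ve = cm["Vext"], Je = cm["Jext"];
  IntegerVector Vc = cm["Vcore"], Jc = cm["Jcore"];
  A.nV = Ve.size(); A.nJ = Je.size();
  std::vector<IntegerVector> keepiv; // keep SEXPs alive
  for (int i = 0; i < A.nV; i++) {
    IntegerVector s = Ve[i];
    keepiv.push_back(s);
    A.Vext.push_back(INTEGER(s));
    A.Vextlen.push_back(s.size());
    A.Vcore.push_back(Vc[i]);
  }
  for (int i = 0; i < A.nJ; i++) {
    IntegerVector s = Je[i];
    keepiv.push_back(s);
    A.Jext.push_back(INTEGER(s));
    A.Jextlen.push_back(s.size());
    A.Jcore.push_back(Jc[i]);
  }
  A.nD = 0;
  if (A.chain == 1) {
    List De = cm["Dext"];
    IntegerVector Dc = cm["Dcore"];
    A.nD = De.size();
    for (int i = 0; i < A.nD; i++) {
      IntegerVector s = De[i];
      keepiv.push_back(s);
      A.Dext.push_back(INTEGER(s));
      A.Dextlen.push_back(s.size());
      A.Dcore.push_back(Dc[i]);
    }
  }
  A.dv0 = as<int>(cm["dv0"]); A.dv1 = as<int>(cm["dv1"]);
  A.dj0 = as<int>(cm["dj0"]); A.dj1 = as<int>(cm["dj1"]);
  A.dl0 = as<int>(cm["dl0"]); A.dl1 = as<int>(cm["dl1"]);
  A.dr0 = as<int>(cm["dr0"]); A.dr1 = as<int>(cm["dr1"]);
  A.insmax = as<int>(cm["insmax"]);
  NumericVector lpV = cm["lpV"], lpVJ = cm["lpVJ"], lpDJ = cm["lpDJ"];
  NumericVector lpdelV = cm["lpdelV"], lpdelJ = cm["lpdelJ"], lpdelD = cm["lpdelD"];
  NumericVector lpinsVD = cm["lpinsVD"], lpinsDJ = cm["lpinsDJ"], lpinsVJ = cm["lpinsVJ"];
  NumericVector lTvd = cm["lTvd"], lTdj = cm["lTdj"], lTvj = cm["lTvj"];
  A.lpV = REAL(lpV); A.lpVJ = REAL(lpVJ); A.lpDJ = REAL(lpDJ);
  A.lpdelV = REAL(lpdelV); A.lpdelJ = REAL(lpdelJ); A.lpdelD = REAL(lpdelD);
  A.lpinsVD = REAL(lpinsVD); A.lpinsDJ = REAL(lpinsDJ); A.lpinsVJ = REAL(lpinsVJ);
  A.lTvd = REAL(lTvd); A.lTdj = REAL(lTdj); A.lTvj = REAL(lTvj);

  A.em.kind = as<int>(cm["err_kind"]);
  A.em.exact = as<bool>(opts["exact"]);
  NumericVector pwm_e;
  if (A.em.kind == 0) {
    double rate = as<double>(cm["err_rate"]);
    rate = std::min(std::max(rate, 1e-12), 0.75);
    A.em.lerr3 = std::log(rate / 3.0);
    A.em.l1e = std::log1p(-rate);
    A.em.lp_mm_max = A.em.lerr3;
  } else {
    A.em.m = as<int>(cm["pwm_m"]);
    A.em.mu = as<double>(cm["pwm_mu"]);
    pwm_e = cm["pwm_e"];
    A.em.e.assign(pwm_e.begin(), pwm_e.end());
    double pfb = A.em.mu / (1.0 + A.em.mu);
    A.em.lp_fb_mut = std::log(pfb / 3.0);
    A.em.lp_fb_nomut = std::log1p(-pfb);
    double smax = 0.0;
    for (int i = 0; i <= 2 * A.em.m; i++) {
      double mx = R_NegInf;
      for (int b = 0; b < 4; b++) mx = std::max(mx, A.em.e[i * 4 + b]);
      smax += mx;
    }
    double xmax = A.em.mu * std::exp(smax);
    A.em.lp_mm_max = std::log(xmax / (1.0 + xmax) / 3.0);
  }

  A.thr_v = as<double>(opts["thr_v"]);
  A.thr_j = as<double>(opts["thr_j"]);
  A.s_match = as<double>(opts["s_match"]);
  A.s_mism = as<double>(opts["s_mism"]);
  A.prune_ratio = as<double>(opts["prune_ratio"]);
  A.lpr = (A.prune_ratio > 0) ? std::log(A.prune_ratio) : R_NegInf;
  A.floor_lp = as<double>(opts["floor_lp"]);
  A.mm_budget = as<double>(opts["mm_budget"]);
  A.k_top = as<int>(opts["k_top"]);
  A.want_stats = as<bool>(opts["want_stats"]);

  A.precompute_read();
  A.build_vrows();
  A.build_jrows();
  A.build_drows();

  std::sort(A.vrows.begin(), A.vrows.end(),
            [](const VRow &a, const VRow &b) { return a.lp > b.lp; });
  std::sort(A.jrows.begin(), A.jrows.end(),
            [](const JRow &a, const JRow &b) { return a.lp > b.lp; });
  std::sort(A.drows.begin(), A.drows.end(),
            [](const DRow &a, const DRow &b) { return a.sortkey > b.sortkey; });

  if (A.want_stats) {
    A.cV.assign(A.nV, 0.0);
    A.cVJ.assign((size_t)A.nV * A.nJ, 0.0);
    A.cDJ.assign(std::max<size_t>(1, (size_t)A.nD * A.nJ), 0.0);
    A.cdelV.assign((size_t)A.nV * (A.dv1 - A.dv0 + 1), 0.0);
    A.cdelJ.assign((size_t)A.nJ * (A.dj1 - A.dj0 + 1), 0.0);
    A.cdelD.assign(std::max<size_t>(1, (size_t)A.nD * (A.dl1 - A.dl0 + 1) *
                                           (A.dr1 - A.dr0 + 1)), 0.0);
    A.cinsVD.assign(A.insmax + 1, 0.0);
    A.cinsDJ.assign(A.insmax + 1, 0.0);
    A.cinsVJ.assign(A.insmax + 1, 0.0);
    A.cTvdc.assign(16, 0.0); A.cTdjc.assign(16, 0.0); A.cTvjc.assign(16, 0.0);
  }

  A.phaseA();
  if (!opts.containsElementNamed("truth") || Rf_isNull(opts["truth"])) {
    A.have_truth = false;
  } else {
    A.locate_truth(as<NumericVector>(opts["truth"]));
  }
  A.join();

  double log_pread = A.acc.logsum();
  bool failed = (A.n_scen == 0) || (log_pread < A.floor_lp);

  List out = List::create(
      _["log_pread"] = log_pread, _["log_best"] = A.best,
      _["n_scenarios"] = (double)A.n_scen, _["failed"] = failed,
      _["pruned_bound"] = A.pruned,
      _["truth_logp"] = A.truth_lp, _["truth_logprecomb"] = A.truth_lpclean,
      _["rank_above"] = (double)A.n_above + (double)A.n_tie_before);

  if (A.k_top > 0) {
    std::sort(A.heap.begin(), A.heap.end(), scen_before);
    int n = A.heap.size();
    NumericMatrix sc(n, 15);
    colnames(sc) = CharacterVector::create(
        "v", "d", "j", "del_v", "del_d_l", "del_d_r", "del_j", "x", "a", "b",
        "y", "mm", "logp", "logprecomb", "rank");
    for (int i = 0; i < n; i++) {
      const Scen &s = A.heap[i];
      sc(i, 0) = s.v + 1;
      sc(i, 1) = s.g >= 0 ? s.g + 1 : NA_REAL;
      sc(i, 2) = s.j + 1;
      sc(i, 3) = s.delv; sc(i, 4) = A.chain == 1 ? s.dl : NA_REAL;
      sc(i, 5) = A.chain == 1 ? s.dr : NA_REAL; sc(i, 6) = s.delj;
      sc(i, 7) = s.x; sc(i, 8) = s.a; sc(i, 9) = s.b; sc(i, 10) = s.y;
      sc(i, 11) = s.mm; sc(i, 12) = s.lp; sc(i, 13) = s.lpclean;
      sc(i, 14) = i + 1;
    }
    out["scenarios"] = sc;
  }
  if (A.want_stats) {
    double W = std::exp(log_pread - A.ref);
    auto norm = [&](std::vector<double> &v) {
      NumericVector o(v.size());
      for (size_t i = 0; i < v.size(); i++) o[i] = failed || W <= 0 ? 0.0 : v[i] / W;
      return o;
    };
    out["stats"] = List::create(
        _["cV"] = norm(A.cV), _["cVJ"] = norm(A.cVJ), _["cDJ"] = norm(A.cDJ),
        _["cdelV"] = norm(A.cdelV), _["cdelJ"] = norm(A.cdelJ),
        _["cdelD"] = norm(A.cdelD), _["cinsVD"] = norm(A.cinsVD),
        _["cinsDJ"] = norm(A.cinsDJ), _["cinsVJ"] = norm(A.cinsVJ),
        _["cTvd"] = norm(A.cTvdc), _["cTdj"] = norm(A.cTdjc),
        _["cTvj"] = norm(A.cTvjc),
        _["err_events"] = (failed || W <= 0) ? 0.0 : A.s_err_ev / W,
        _["err_opps"] = (failed || W <= 0) ? 0.0 : A.s_err_opp / W,
        _["wlogp"] = (failed || W <= 0) ? 0.0 : A.s_wlogp / W,
        _["wsum"] = (failed || W <= 0) ? 0.0 : A.s_w / W);
  }
  return out;
}
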