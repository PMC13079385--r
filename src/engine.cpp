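// Partition-function engine for nested RNA secondary structures on one or
// more strands (nicked concatenation), under a nearest-neighbor model with
// stacks, hairpin/bulge/interior size penalties, terminal AU/GU penalties,
// and zero-cost multiloops and nick-containing (exterior) loops.
//
// Conventions (shared with the R-level enumeration oracle):
//  - pairs are Watson-Crick or G.U wobble; no pseudoknots;
//  - hairpin loops contain >= min_hairpin unpaired bases and no nick;
//  - interior/bulge loops are nick-free and capped at max_interior_loop
//    unpaired bases in total; larger nick-free one-branch loops are excluded;
//  - any loop may contain at most one nick (polymer-graph connectedness);
//    the exterior loop of the linearized complex contains none, its budget
//    being the implicit wrap-around nick;
//  - terminal AU/GU penalties are charged once per helix end: a pair pays on
//    each side on which it faces a non-stack loop.
//
// Weights carry a per-base scaling factor exp(lns) to avoid overflow on
// long complexes; all returned quantities are corrected back to log scale.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 6; // (branches 0/1/2+) x (loop-level nicks 0/1)

struct Engine {
  int n;
  std::vector<int> s;         // 1=A 2=C 3=G 4=U
  std::vector<char> nickb;    // nickb[p]: nick between p and p+1 (size n-1)
  std::vector<char> masked;   // forced-unpaired bases
  int fi, fj;                 // forbidden pair (or -1,-1)
  double kT, lxc, tau, lns;
  double stk[6][6];
  std::vector<double> hp, bu, itl; // indexed by loop size
  int minh, maxloop;
  std::vector<int> cum;       // cum[i] = number of nick boundaries p < i
  std::vector<double> QB;
  std::vector<double> QX[NSTATE];
  bool overflow;

  static int ptype(int x, int y) {
    if (x == 2 && y == 3) return 0; // CG
    if (x == 3 && y == 2) return 1; // GC
    if (x == 3 && y == 4) return 2; // GU
    if (x == 4 && y == 3) return 3; // UG
    if (x == 1 && y == 4) return 4; // AU
    if (x == 4 && y == 1) return 5; // UA
    return -1;
  }
  double auP(int t) const { return t >= 2 ? tau : 0.0; }
  int pt(int i, int j) const {
    if (masked[i] || masked[j]) return -1;
    if (i == fi && j == fj) return -1;
    return ptype(s[i], s[j]);
  }
  int nicksIn(int a, int b) const { // boundaries p with a <= p <= b
    if (a > b) return 0;
    return cum[b + 1] - cum[a];
  }
  double hairpinE(int u) const {
    if (u <= 30) return hp[u];
    return hp[30] + lxc * std::log(u / 30.0);
  }
  double qb(int i, int j) const { return QB[(size_t)i * n + j]; }
  double qx(int st, int i, int j) const {
    if (i > j) return st == 0 ? 1.0 : 0.0;
    return QX[st][(size_t)i * n + j];
  }

  // ---- forward fill ----------------------------------------------------
  void fillQB(int i, int j) {
    double q = 0.0;
    int t = pt(i, j);
    if (t >= 0) {
      if (nicksIn(i, j - 1) == 0) { // hairpin
        int u = j - i - 1;
        if (u >= minh)
          q += std::exp(-(hairpinE(u) + auP(t)) / kT + (j - i + 1) * lns);
      }
      if (j - i >= 3 && !nickb[i] && !nickb[j - 1]) { // stack
        int t2 = pt(i + 1, j - 1);
        if (t2 >= 0) {
          double w = qb(i + 1, j - 1);
          if (w > 0) q += std::exp(-stk[t][t2] / kT + 2 * lns) * w;
        }
      }
      for (int k = i + 1; k <= i + 1 + maxloop && k < j; ++k) { // interior/bulge
        int u1 = k - i - 1;
        if (nicksIn(i, k - 1) > 0) break;
        for (int l = j - 1; l > k; --l) {
          int u2 = j - l - 1;
          if (u1 + u2 > maxloop) break;
          if (u1 == 0 && u2 == 0) continue; // that is the stack
          if (nicksIn(l, j - 1) > 0) break;
          int t2 = pt(k, l);
          if (t2 < 0) continue;
          double w = qb(k, l);
          if (w <= 0) continue;
          int u = u1 + u2;
          double le = (u1 == 0 || u2 == 0) ? bu[u] : itl[u];
          q += std::exp(-(le + auP(t) + auP(t2)) / kT + (u + 2) * lns) * w;
        }
      }
      // multiloops and nick-containing loops
      int nke = (j == i + 1) ? (int)nickb[i] : (int)nickb[i] + (int)nickb[j - 1];
      if (nke <= 1) {
        double g = 0.0;
        for (int nb = 0; nb < 3; ++nb)
          for (int nk = 0; nk < 2; ++nk) {
            int tot = nke + nk;
            if (tot > 1) continue;
            if (!(nb == 2 || tot == 1)) continue;
            g += qx(nb * 2 + nk, i + 1, j - 1);
          }
        if (g > 0) q += std::exp(-auP(t) / kT + 2 * lns) * g;
      }
    }
    if (!std::isfinite(q)) overflow = true;
    QB[(size_t)i * n + j] = q;
  }

  void fillQX(int i, int j) {
    double acc[NSTATE] = {0, 0, 0, 0, 0, 0};
    int dn = (i < j && nickb[i]) ? 1 : 0; // base i unpaired
    for (int nb = 0; nb < 3; ++nb)
      for (int nk = 0; nk < 2; ++nk) {
        int nkc = nk - dn;
        if (nkc < 0) continue;
        acc[nb * 2 + nk] += std::exp(lns) * qx(nb * 2 + nkc, i + 1, j);
      }
    for (int l = i + 1; l <= j; ++l) { // branch (i,l)
      int t = pt(i, l);
      if (t < 0) continue;
      double w = qb(i, l);
      if (w <= 0) continue;
      double bw = w * std::exp(-auP(t) / kT);
      int dn2 = (l < j && nickb[l]) ? 1 : 0;
      for (int nbc = 0; nbc < 3; ++nbc)
        for (int nkc = 0; nkc < 2; ++nkc) {
          int nb = nbc + 1 > 2 ? 2 : nbc + 1;
          int nk = nkc + dn2;
          if (nk > 1) continue;
          acc[nb * 2 + nk] += bw * qx(nbc * 2 + nkc, l + 1, j);
        }
    }
    for (int st = 0; st < NSTATE; ++st) {
      if (!std::isfinite(acc[st])) overflow = true;
      QX[st][(size_t)i * n + j] = acc[st];
    }
  }

  // returns log of the exterior-loop sum (scaled); -Inf if zero
  double run() {
    overflow = false;
    QB.assign((size_t)n * n, 0.0);
    for (int st = 0; st < NSTATE; ++st) QX[st].assign((size_t)n * n, 0.0);
    for (int d = 0; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        if (d >= 1) fillQB(i, j);
        fillQX(i, j);
        if (overflow) return NA_REAL;
      }
    }
    double QE = 0.0;
    for (int nb = 0; nb < 3; ++nb) QE += qx(nb * 2 + 0, 0, n - 1);
    if (!std::isfinite(QE)) { overflow = true; return NA_REAL; }
    if (QE <= 0.0) return R_NegInf;
    return std::log(QE);
  }

  // Fill with automatic rescaling; returns true log partition function.
  double computeLogQ() {
    lns = n <= 60 ? 0.0 : -1.0;
    for (int iter = 0; iter < 25; ++iter) {
      double lq = run();
      if (overflow) { lns -= 600.0 / n; continue; }
      if (lq == R_NegInf && lns < -1e-9) { lns += 600.0 / n; if (lns > 0) lns = 0; continue; }
      return lq == R_NegInf ? R_NegInf : lq - n * lns;
    }
    stop("partition function scaling failed to converge");
  }

  // ---- stochastic traceback -------------------------------------------
  void sampleX(int i, int j, int nb, int nk, std::vector<int>& pr) {
    if (i > j) return;
    double target = qx(nb * 2 + nk, i, j) * unif_rand();
    double run0 = 0.0;
    int dn = (i < j && nickb[i]) ? 1 : 0;
    if (nk - dn >= 0) {
      run0 += std::exp(lns) * qx(nb * 2 + (nk - dn), i + 1, j);
      if (run0 >= target) { sampleX(i + 1, j, nb, nk - dn, pr); return; }
    }
    for (int l = i + 1; l <= j; ++l) {
      int t = pt(i, l);
      if (t < 0) continue;
      double w = qb(i, l);
      if (w <= 0) continue;
      double bw = w * std::exp(-auP(t) / kT);
      int dn2 = (l < j && nickb[l]) ? 1 : 0;
      int nkc = nk - dn2;
      if (nkc < 0) continue;
      // child branch classes mapping to parent class nb
      for (int nbc = 0; nbc < 3; ++nbc) {
        int nbp = nbc + 1 > 2 ? 2 : nbc + 1;
        if (nbp != nb) continue;
        double wcase = bw * qx(nbc * 2 + nkc, l + 1, j);
        run0 += wcase;
        if (run0 >= target) {
          pr[i] = l; pr[l] = i;
          sampleB(i, l, pr);
          sampleX(l + 1, j, nbc, nkc, pr);
          return;
        }
      }
    }
    // numerical slack: fall back on the last feasible case
    sampleX(i + 1, j, nb, nk - dn >= 0 ? nk - dn : nk, pr);
  }

  void sampleB(int i, int j, std::vector<int>& pr) {
    int t = pt(i, j);
    double target = qb(i, j) * unif_rand();
    double run0 = 0.0;
    if (nicksIn(i, j - 1) == 0) {
      int u = j - i - 1;
      if (u >= minh) {
        run0 += std::exp(-(hairpinE(u) + auP(t)) / kT + (j - i + 1) * lns);
        if (run0 >= target) return; // hairpin
      }
    }
    if (j - i >= 3 && !nickb[i] && !nickb[j - 1]) {
      int t2 = pt(i + 1, j - 1);
      if (t2 >= 0) {
        double w = qb(i + 1, j - 1);
        if (w > 0) {
          run0 += std::exp(-stk[t][t2] / kT + 2 * lns) * w;
          if (run0 >= target) {
            pr[i + 1] = j - 1; pr[j - 1] = i + 1;
            sampleB(i + 1, j - 1, pr);
            return;
          }
        }
      }
    }
    for (int k = i + 1; k <= i + 1 + maxloop && k < j; ++k) {
      int u1 = k - i - 1;
      if (nicksIn(i, k - 1) > 0) break;
      for (int l = j - 1; l > k; --l) {
        int u2 = j - l - 1;
        if (u1 + u2 > maxloop) break;
        if (u1 == 0 && u2 == 0) continue;
        if (nicksIn(l, j - 1) > 0) break;
        int t2 = pt(k, l);
        if (t2 < 0) continue;
        double w = qb(k, l);
        if (w <= 0) continue;
        int u = u1 + u2;
        double le = (u1 == 0 || u2 == 0) ? bu[u] : itl[u];
        run0 += std::exp(-(le + auP(t) + auP(t2)) / kT + (u + 2) * lns) * w;
        if (run0 >= target) {
          pr[k] = l; pr[l] = k;
          sampleB(k, l, pr);
          return;
        }
      }
    }
    int nke = (j == i + 1) ? (int)nickb[i] : (int)nickb[i] + (int)nickb[j - 1];
    if (nke <= 1) {
      double pref = std::exp(-auP(t) / kT + 2 * lns);
      for (int nb = 0; nb < 3; ++nb)
        for (int nk = 0; nk < 2; ++nk) {
          int tot = nke + nk;
          if (tot > 1) continue;
          if (!(nb == 2 || tot == 1)) continue;
          double wcase = pref * qx(nb * 2 + nk, i + 1, j - 1);
          run0 += wcase;
          if (run0 >= target) {
            sampleX(i + 1, j - 1, nb, nk, pr);
            return;
          }
        }
    }
    // numerical slack: open hairpin if legal, else leave unpaired interior
  }

  void sampleTop(std::vector<int>& pr) {
    double tot = 0.0;
    for (int nb = 0; nb < 3; ++nb) tot += qx(nb * 2, 0, n - 1);
    double target = tot * unif_rand(), run0 = 0.0;
    for (int nb = 0; nb < 3; ++nb) {
      run0 += qx(nb * 2, 0, n - 1);
      if (run0 >= target || nb == 2) { sampleX(0, n - 1, nb, 0, pr); return; }
    }
  }
};

static Engine makeEngine(const IntegerVector& seq, const IntegerVector& nicks,
                         const List& par, const IntegerVector& mask,
                         int forbid_i, int forbid_j) {
  Engine e;
  e.n = seq.size();
  e.s.assign(seq.begin(), seq.end());
  e.nickb.assign(std::max(e.n - 1, 0), 0);
  for (int p : nicks) {
    if (p < 0 || p >= e.n - 1) stop("nick position out of range");
    e.nickb[p] = 1;
  }
  e.masked.assign(e.n, 0);
  for (int m : mask) {
    if (m < 0 || m >= e.n) stop("mask position out of range");
    e.masked[m] = 1;
  }
  e.fi = forbid_i; e.fj = forbid_j;
  e.kT = as<double>(par["kT"]);
  e.lxc = as<double>(par["lxc"]);
  e.tau = as<double>(par["terminal_au"]);
  e.minh = as<int>(par["min_hairpin"]);
  e.maxloop = as<int>(par["max_interior_loop"]);
  NumericMatrix st = par["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) e.stk[a][b] = st(a, b);
  NumericVector h = par["hairpin"], b = par["bulge"], it = par["internal"];
  e.hp.assign(h.begin(), h.end());
  e.bu.assign(b.begin(), b.end());
  e.itl.assign(it.begin(), it.end());
  e.cum.assign(e.n + 1, 0);
  for (int i = 0; i < e.n - 1; ++i) e.cum[i + 1] = e.cum[i] + e.nickb[i];
  if (e.n >= 1) e.cum[e.n] = e.cum[e.n - 1];
  return e;
}

// [[Rcpp::export]]
double pf_logq_cpp(IntegerVector seq, IntegerVector nicks, List par,
                   IntegerVector mask, int forbid_i, int forbid_j) {
  Engine e = makeEngine(seq, nicks, par, mask, forbid_i, forbid_j);
  return e.computeLogQ();
}

// [[Rcpp::export]]
IntegerMatrix pf_sample_cpp(IntegerVector seq, IntegerVector nicks, List par,
                            int nsamp) {
  Engine e = makeEngine(seq, nicks, par, IntegerVector(0), -1, -1);
  double lq = e.computeLogQ(); // leaves tables filled at final scaling
  if (lq == R_NegInf) stop("no legal structure to sample from");
  IntegerMatrix out(nsamp, e.n);
  std::vector<int> pr(e.n);
  for (int k = 0; k < nsamp; ++k) {
    std::fill(pr.begin(), pr.end(), -1);
    e.sampleTop(pr);
    for (int i = 0; i < e.n; ++i) out(k, i) = pr[i];
  }
  return out;
}

// [[Rcpp::export]]
List pair_probs_cpp(IntegerVector seq, IntegerVector nicks, List par) {
  int n = seq.size();
  Engine e0 = makeEngine(seq, nicks, par, IntegerVector(0), -1, -1);
  double lq = e0.computeLogQ();
  NumericMatrix pp(n, n);
  NumericVector pu(n);
  if (lq == R_NegInf) stop("empty structure ensemble");
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (Engine::ptype(seq[i], seq[j]) < 0) continue;
      Engine e = makeEngine(seq, nicks, par, IntegerVector(0), i, j);
      double lqf = e.computeLogQ();
      double p = lqf == R_NegInf ? 1.0 : -std::expm1(lqf - lq);
      if (p < 0) p = 0;
      pp(i, j) = pp(j, i) = p;
    }
  for (int i = 0; i < n; ++i) {
    IntegerVector m(1); m[0] = i;
    Engine e = makeEngine(seq, nicks, par, m, -1, -1);
    double lqc = e.computeLogQ();
    pu[i] = lqc == R_NegInf ? 0.0 : std::exp(lqc - lq);
  }
  return List::create(_["p_pair"] = pp, _["p_unpaired"] = pu);
}

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, double match,
                    double mismatch, double gap) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double v = d;
      if (u > v) v = u;
      if (l > v) v = l;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}
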