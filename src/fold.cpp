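// Thermodynamic-ensemble folding engine.
//
// Inside-outside dynamic programming over an unambiguous nested-structure
// grammar, in O(n^3) time (interior loops capped at max_interior unpaired
// nucleotides, so the interior sums are O(cap^2) per cell). All partition
// arrays are per-position scaled to avoid overflow: every unpaired position
// contributes a factor u = 1/s and every paired position likewise, with
// s chosen from the MFE so that the scaled partition sum stays in double
// range. Pair probabilities are exact (up to floating point), verified
// against exhaustive enumeration in the test suite.
//
// Grammars (1 character per position, 0-based, i < j):
//  pairsum:  S(a,b) -> S(a,b-1) u | S(a,h-1) P(h,b)
//            P(i,j) -> wpair(i,j) u^2 S(i+1,j-1)
//  stacking: S as above;
//            P(i,j) -> hairpin | interior/stack x P(k,l) | u^2 M(i+1,h-1) P1(h,j-1)
//            M(a,b) -> M(a,b-1) u | (M(a,h-1) | u^{h-a}) P(h,b)
//            P1(h,e) -> P1(h,e-1) u | P(h,e)
// Multibranch and exterior loops carry no energy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Model {
  int kind;          // 0 = pairsum, 1 = stacking
  double RT;
  int mh;            // min hairpin
  int cap;           // max interior unpaired total
  double pairE[6];
  double stackE[6][6];
  double hpA, hpB, inA, inB, inAsym;
};

// pair type: AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 = not pairable.
// codes: A=0 C=1 G=2 U=3
static inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static inline double hairpinE(const Model& m, int L) {
  return m.hpA + m.hpB * std::log((double)L / 3.0);
}
static inline double interiorE(const Model& m, int a, int b) {
  if (a + b == 0) return INF;          // that is a stack, not a loop
  if (a + b > m.cap) return INF;
  return m.inA + m.inB * std::log((double)(a + b)) + m.inAsym * std::abs(a - b);
}

class Mat {
public:
  Mat(int n, double fill = 0.0) : n_(n), v_((size_t)n * n, fill) {}
  inline double& at(int i, int j) { return v_[(size_t)i * n_ + j]; }
  inline double get(int i, int j) const { return v_[(size_t)i * n_ + j]; }
private:
  int n_;
  std::vector<double> v_;
};

// ---------------------------------------------------------------- MFE ----

// pairsum MFE: Vb(i,j) = E(i,j) + Wseg(i+1,j-1); Wseg left-based.
// stacking MFE: Vb = min(hairpin, interior + Vb, multiloop via Vm/Vm1).
struct MfeResult {
  double energy;
  std::vector<std::pair<int,int> > pairs;
};

struct MfeDP {
  int n;
  const std::vector<int>& s;
  const Model& m;
  Mat Vb, Wseg, Vm, Vm1;
  MfeDP(int n_, const std::vector<int>& s_, const Model& m_)
    : n(n_), s(s_), m(m_), Vb(n_, INF), Wseg(n_, 0.0), Vm(n_, INF), Vm1(n_, INF) {}

  inline double wseg(int a, int b) { return (a > b) ? 0.0 : Wseg.get(a, b); }
  inline double vm(int a, int b)   { return (a > b) ? INF : Vm.get(a, b); }
  inline double vm1(int a, int b)  { return (a > b) ? INF : Vm1.get(a, b); }

  void run() {
    for (int span = 1; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        int pt = ptype(s[i], s[j]);
        if (pt >= 0 && span >= m.mh + 2) {
          double best = INF;
          if (m.kind == 0) {
            best = m.pairE[pt] + wseg(i + 1, j - 1);
          } else {
            best = hairpinE(m, j - i - 1);
            // stack / interior
            for (int k = i + 1; k <= j - 2 && k - i - 1 <= m.cap; ++k) {
              for (int l = j - 1; l > k; --l) {
                int a = k - i - 1, b = j - l - 1;
                if (a + b > m.cap) break;
                if (l - k - 1 < m.mh) continue;
                double vkl = Vb.get(k, l);
                if (vkl >= INF) continue;
                double e = (a == 0 && b == 0)
                  ? m.stackE[pt][ptype(s[k], s[l])]
                  : interiorE(m, a, b);
                if (e + vkl < best) best = e + vkl;
              }
            }
            // multiloop: >= 2 branches, no closing energy
            for (int h = i + 2; h <= j - 1; ++h) {
              double a1 = vm(i + 1, h - 1), a2 = vm1(h, j - 1);
              if (a1 < INF && a2 < INF && a1 + a2 < best) best = a1 + a2;
            }
          }
          Vb.at(i, j) = best;
        }
      }
      // auxiliary arrays for segments of this span (needed by larger spans)
      for (int a = 0; a + span - 1 < n; ++a) {
        int b = a + span - 1;
        // Vm1(a,b): one branch starting at a, tail unpaired
        double v1 = vm1(a, b - 1);
        if (Vb.get(a, b) < v1) v1 = Vb.get(a, b);
        Vm1.at(a, b) = v1;
        // Vm(a,b): >= 1 branch; left-based
        double v = vm(a + 1, b); // a unpaired
        for (int k = a + m.mh + 1; k <= b; ++k) {
          double vb = Vb.get(a, k);
          if (vb >= INF) continue;
          double rest = std::min(0.0, vm(k + 1, b));
          if (vb + rest < v) v = vb + rest;
        }
        Vm.at(a, b) = v;
        // Wseg(a,b): unconstrained; left-based
        double w = wseg(a + 1, b); // a unpaired
        for (int k = a + m.mh + 1; k <= b; ++k) {
          double vb = Vb.get(a, k);
          if (vb >= INF) continue;
          double cand = vb + wseg(k + 1, b);
          if (cand < w) w = cand;
        }
        Wseg.at(a, b) = w;
      }
    }
  }

  // Deterministic traceback, preferring "left position unpaired" first and
  // then candidate pairs in ascending order.
  static constexpr double EPS = 1e-9;
  void tb_seg(int a, int b, std::vector<std::pair<int,int> >& out) {
    if (a > b) return;
    double w = Wseg.get(a, b);
    if (std::abs(wseg(a + 1, b) - w) <= EPS * (1 + std::abs(w))) { tb_seg(a + 1, b, out); return; }
    for (int k = a + m.mh + 1; k <= b; ++k) {
      double vb = Vb.get(a, k);
      if (vb >= INF) continue;
      if (std::abs(vb + wseg(k + 1, b) - w) <= EPS * (1 + std::abs(w))) {
        tb_pair(a, k, out); tb_seg(k + 1, b, out); return;
      }
    }
    tb_seg(a + 1, b, out); // numerical fallback
  }
  void tb_pair(int i, int j, std::vector<std::pair<int,int> >& out) {
    out.push_back(std::make_pair(i, j));
    double v = Vb.get(i, j);
    int pt = ptype(s[i], s[j]);
    if (m.kind == 0) { tb_seg(i + 1, j - 1, out); return; }
    if (std::abs(hairpinE(m, j - i - 1) - v) <= EPS * (1 + std::abs(v))) return;
    for (int k = i + 1; k <= j - 2 && k - i - 1 <= m.cap; ++k) {
      for (int l = j - 1; l > k; --l) {
        int a = k - i - 1, b = j - l - 1;
        if (a + b > m.cap) break;
        if (l - k - 1 < m.mh) continue;
        double vkl = Vb.get(k, l);
        if (vkl >= INF) continue;
        double e = (a == 0 && b == 0) ? m.stackE[pt][ptype(s[k], s[l])] : interiorE(m, a, b);
        if (std::abs(e + vkl - v) <= EPS * (1 + std::abs(v))) { tb_pair(k, l, out); return; }
      }
    }
    for (int h = i + 2; h <= j - 1; ++h) {
      double a1 = vm(i + 1, h - 1), a2 = vm1(h, j - 1);
      if (a1 < INF && a2 < INF &&
          std::abs(a1 + a2 - v) <= EPS * (1 + std::abs(v))) {
        tb_vm(i + 1, h - 1, out); tb_vm1(h, j - 1, out); return;
      }
    }
  }
  void tb_vm(int a, int b, std::vector<std::pair<int,int> >& out) {
    if (a > b) return;
    double v = Vm.get(a, b);
    if (std::abs(vm(a + 1, b) - v) <= EPS * (1 + std::abs(v))) { tb_vm(a + 1, b, out); return; }
    for (int k = a + m.mh + 1; k <= b; ++k) {
      double vb = Vb.get(a, k);
      if (vb >= INF) continue;
      double rest = std::min(0.0, vm(k + 1, b));
      if (std::abs(vb + rest - v) <= EPS * (1 + std::abs(v))) {
        tb_pair(a, k, out);
        if (vm(k + 1, b) < 0 && std::abs(vm(k + 1, b) - rest) <= EPS) tb_vm(k + 1, b, out);
        return;
      }
    }
  }
  void tb_vm1(int h, int e, std::vector<std::pair<int,int> >& out) {
    double v = Vm1.get(h, e);
    for (int l = h + m.mh + 1; l <= e; ++l) {
      if (std::abs(Vb.get(h, l) - v) <= EPS * (1 + std::abs(v))) { tb_pair(h, l, out); return; }
    }
  }
};

// ------------------------------------------------- partition / outside ----

// [[Rcpp::export]]
List fold_engine_cpp(IntegerVector codes, int kind, double RT, int mh, int cap,
                     NumericVector pairE, NumericMatrix stackE,
                     double hpA, double hpB, double inA, double inB, double inAsym,
                     bool want_bppm = true) {
  int n = codes.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = codes[i];
  Model m;
  m.kind = kind; m.RT = RT; m.mh = mh; m.cap = cap;
  for (int i = 0; i < 6; ++i) m.pairE[i] = pairE[i];
  for (int i = 0; i < 6; ++i) for (int j = 0; j < 6; ++j) m.stackE[i][j] = stackE(i, j);
  m.hpA = hpA; m.hpB = hpB; m.inA = inA; m.inB = inB; m.inAsym = inAsym;

  // ---- MFE (also fixes the scale factor) ----
  MfeDP mfe(n, s, m);
  mfe.run();
  double mfeE = mfe.wseg(0, n - 1);
  std::vector<std::pair<int,int> > mpairs;
  if (mfeE < 0) mfe.tb_seg(0, n - 1, mpairs);

  double u = (mfeE < 0) ? std::exp(1.07 * mfeE / (RT * n)) : 1.0;
  double ln_u = std::log(u);

  NumericMatrix bppm(n, n);
  double logZ = 0.0;

  if (m.kind == 0) {
    // ---------------- pairsum ----------------
    Mat QS(n, 0.0), QP(n, 0.0);
    auto qs = [&](int a, int b) -> double { return (a > b) ? 1.0 : QS.get(a, b); };
    for (int span = 1; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        int pt = ptype(s[i], s[j]);
        if (pt >= 0 && span >= m.mh + 2) {
          QP.at(i, j) = std::exp(-m.pairE[pt] / RT) * u * u * qs(i + 1, j - 1);
        }
        double q = qs(i, j - 1) * u;  // j unpaired
        for (int h = i; h <= j - m.mh - 1; ++h) {
          double qp = QP.get(h, j);
          if (qp > 0) q += qs(i, h - 1) * qp;
        }
        QS.at(i, j) = q;
      }
    }
    double Zs = qs(0, n - 1);
    logZ = std::log(Zs) - n * ln_u;

    if (want_bppm) {
      Mat OS(n, 0.0), OP(n, 0.0);
      for (int span = n; span >= 1; --span) {
        for (int i = 0; i + span - 1 < n; ++i) {
          int j = i + span - 1;
          // OS(i,j)
          double os = (i == 0 && j == n - 1) ? 1.0 : 0.0;
          if (j + 1 < n) {
            os += OS.get(i, j + 1) * u;
            for (int b2 = j + m.mh + 2; b2 < n; ++b2) {
              double qp = QP.get(j + 1, b2);
              if (qp > 0) os += OS.get(i, b2) * qp;
            }
          }
          if (i > 0 && j + 1 < n) {
            int pt = ptype(s[i - 1], s[j + 1]);
            if (pt >= 0) os += OP.get(i - 1, j + 1) * std::exp(-m.pairE[pt] / RT) * u * u;
          }
          OS.at(i, j) = os;
          // OP(i,j)
          if (QP.get(i, j) > 0) {
            double op = 0.0;
            for (int a = 0; a <= i; ++a) op += OS.get(a, j) * qs(a, i - 1);
            OP.at(i, j) = op;
          }
        }
      }
      for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
        double qp = QP.get(i, j);
        if (qp > 0) {
          double p = qp * OP.get(i, j) / Zs;
          if (p < 0) p = 0; if (p > 1) p = 1;
          bppm(i, j) = p; bppm(j, i) = p;
        }
      }
    }
  } else {
    // ---------------- stacking ----------------
    Mat QP(n, 0.0), QM(n, 0.0), QP1(n, 0.0);
    auto qm = [&](int a, int b) -> double { return (a > b) ? 0.0 : QM.get(a, b); };
    auto qp1 = [&](int a, int b) -> double { return (a > b) ? 0.0 : QP1.get(a, b); };
    // powers of u
    std::vector<double> upow(n + 2);
    upow[0] = 1.0;
    for (int i = 1; i <= n + 1; ++i) upow[i] = upow[i - 1] * u;

    for (int span = 1; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        int pt = ptype(s[i], s[j]);
        if (pt >= 0 && span >= m.mh + 2) {
          double q = std::exp(-hairpinE(m, j - i - 1) / RT) * upow[j - i - 1] * u * u;
          for (int k = i + 1; k <= j - 2 && k - i - 1 <= m.cap; ++k) {
            for (int l = j - 1; l > k; --l) {
              int a = k - i - 1, b = j - l - 1;
              if (a + b > m.cap) break;
              if (l - k - 1 < m.mh) continue;
              double qkl = QP.get(k, l);
              if (qkl <= 0) continue;
              double e = (a == 0 && b == 0) ? m.stackE[pt][ptype(s[k], s[l])]
                                            : interiorE(m, a, b);
              q += std::exp(-e / RT) * upow[a + b] * u * u * qkl;
            }
          }
          for (int h = i + 2; h <= j - 1; ++h) {
            double a1 = qm(i + 1, h - 1), a2 = qp1(h, j - 1);
            if (a1 > 0 && a2 > 0) q += u * u * a1 * a2;
          }
          QP.at(i, j) = q;
        }
        // QP1(i,j): one branch starting at i, tail unpaired
        QP1.at(i, j) = qp1(i, j - 1) * u + QP.get(i, j);
        // QM(i,j): >= 1 branch
        double qmv = qm(i, j - 1) * u;
        for (int h = i; h <= j - m.mh - 1; ++h) {
          double qp = QP.get(h, j);
          if (qp > 0) qmv += (qm(i, h - 1) + upow[h - i]) * qp;
        }
        QM.at(i, j) = qmv;
      }
    }
    // exterior prefix F and suffix R
    std::vector<double> F(n + 1), Rr(n + 2);
    F[0] = 1.0;                               // F[b+1] = partition of [0..b]
    for (int b = 0; b < n; ++b) {
      double f = F[b] * u;
      for (int h = 0; h <= b - m.mh - 1; ++h) {
        double qp = QP.get(h, b);
        if (qp > 0) f += F[h] * qp;
      }
      F[b + 1] = f;
    }
    Rr[n] = 1.0;                              // Rr[a] = partition of [a..n-1]
    for (int a = n - 1; a >= 0; --a) {
      double r = Rr[a + 1] * u;
      for (int b = a + m.mh + 1; b < n; ++b) {
        double qp = QP.get(a, b);
        if (qp > 0) r += QP.get(a, b) * Rr[b + 1];
      }
      Rr[a] = r;
    }
    double Zs = F[n];
    logZ = std::log(Zs) - n * ln_u;

    if (want_bppm) {
      Mat OP(n, 0.0), OM(n, 0.0), OP1(n, 0.0);
      for (int span = n; span >= 1; --span) {
        for (int i = 0; i + span - 1 < n; ++i) {
          int j = i + span - 1;
          // --- OP1(i,j): P1(i,j) appears in P(k, j+1) multiloop and in P1(i, j+1)
          double op1 = 0.0;
          if (j + 1 < n) {
            op1 += OP1.get(i, j + 1) * u;
            for (int k = 0; k <= i - 2; ++k) {
              double op = OP.get(k, j + 1);
              if (op > 0) op1 += op * u * u * qm(k + 1, i - 1);
            }
          }
          OP1.at(i, j) = op1;
          // --- OM(i,j): from P(i-1, j2) multiloop, from M(i, b2) with extra
          //     branch, and from M(i, j+1) with j+1 unpaired
          double om = 0.0;
          if (j + 1 < n) om += OM.get(i, j + 1) * u;
          for (int b2 = j + m.mh + 2; b2 < n; ++b2) {
            double qp = QP.get(j + 1, b2);
            if (qp > 0) om += OM.get(i, b2) * qp;
          }
          if (i > 0) {
            for (int j2 = j + 2; j2 < n; ++j2) {
              double op = OP.get(i - 1, j2);
              if (op > 0) {
                double q1 = qp1(j + 1, j2 - 1);
                if (q1 > 0) om += op * u * u * q1;
              }
            }
          }
          OM.at(i, j) = om;
          // --- OP(i,j)
          if (QP.get(i, j) > 0) {
            double op = 0.0;
            // exterior: S(0,*) -> ... P(i,j), remaining = prefix x suffix
            op += F[i] * Rr[j + 1];
            // enclosed by interior/stack of (k,l)
            for (int k = i - 1; k >= 0 && i - k - 1 <= m.cap; --k) {
              int pt2 = ptype(s[k], s[j + 1]); // quick reject below per l
              (void)pt2;
              for (int l = j + 1; l < n; ++l) {
                int a = i - k - 1, b = l - j - 1;
                if (a + b > m.cap) break;
                int pt = ptype(s[k], s[l]);
                if (pt < 0) continue;
                double okl = OP.get(k, l);
                if (okl <= 0) continue;
                int pin = ptype(s[i], s[j]);
                double e = (a == 0 && b == 0) ? m.stackE[pt][pin] : interiorE(m, a, b);
                if (!std::isfinite(e)) continue;
                op += okl * std::exp(-e / RT) * upow[a + b] * u * u;
              }
            }
            // as a branch inside a multiloop segment M(a, j); a == i is the
            // first branch with an empty unpaired prefix
            for (int a = 0; a <= i; ++a) {
              double omv = OM.get(a, j);
              if (omv > 0) op += omv * (qm(a, i - 1) + upow[i - a]);
            }
            // as the last branch: P1(i, e) -> P(i, j) handled via OP1
            op += OP1.get(i, j);
            OP.at(i, j) = op;
          }
        }
      }
      for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
        double qp = QP.get(i, j);
        if (qp > 0) {
          double p = qp * OP.get(i, j) / Zs;
          if (p < 0) p = 0; if (p > 1) p = 1;
          bppm(i, j) = p; bppm(j, i) = p;
        }
      }
    }
  }

  IntegerVector mi(mpairs.size()), mj(mpairs.size());
  for (size_t k = 0; k < mpairs.size(); ++k) { mi[k] = mpairs[k].first; mj[k] = mpairs[k].second; }
  return List::create(_["log_Z"] = logZ,
                      _["bppm"] = bppm,
                      _["mfe_energy"] = (mfeE < 0 ? mfeE : 0.0),
                      _["mfe_i"] = mi, _["mfe_j"] = mj);
}
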