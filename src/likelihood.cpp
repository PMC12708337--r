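// Pruning engine for reversible 4-state substitution models with discrete
// gamma rate categories and a proportion of invariant sites, plus a
// branch-length coordinate optimizer and a Fitch parsimony scorer.
//
// Trees arrive as ape-style edge matrices (1-based node ids, tips 1..ntip).
// Tip states are IUPAC bitmasks (A=1, C=2, G=4, T=8; gap/N = 15) indexing a
// 15 x 4 contrast matrix of partial likelihoods.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double SCALE_THRESH = 1e-200;
static const double SCALE_FACTOR = 1e200;
static const double LOG_SCALE_FACTOR = std::log(1e200);

// P(t*r) = evec diag(exp(eval*t*r)) ievec, row-major P[x*4+y].
// evec/ievec are column-major 4x4 as they come from R.
static void pmat(const double* evec, const double* ievec, const double* eval,
                 double tr, double* P) {
  double ex[4];
  for (int k = 0; k < 4; ++k) ex[k] = std::exp(eval[k] * tr);
  for (int x = 0; x < 4; ++x) {
    for (int y = 0; y < 4; ++y) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += evec[k * 4 + x] * ex[k] * ievec[y * 4 + k];
      P[x * 4 + y] = s < 0.0 ? 0.0 : s;
    }
  }
}

struct Engine {
  int ntip, nnode, nedge, npat, ncat, root;
  std::vector<int> eparent, echild;     // 0-based node ids
  std::vector<double> el;
  const int* tip;                       // npat x ntip column-major (code 1..15)
  const double* contrast;               // 15 x 4 column-major
  double pi[4];
  std::vector<double> rates, wts;
  double pinv;
  const double* evec; const double* ievec; const double* eval;
  const double* patw;

  std::vector<std::vector<int> > kids;  // node -> edge indices of child edges
  std::vector<int> porder;              // edge indices, children before parents

  std::vector<double> down;             // [cat][node][x][pat]
  std::vector<double> dscale;           // [cat][node][pat]
  std::vector<double> eprod;            // [cat][edge][x][pat] = P_e %*% down[child]
  std::vector<double> escale;           // [cat][edge][pat]
  std::vector<double> P;                // [cat][edge][16]
  std::vector<double> inv;              // [pat]

  inline double* Dn(int c, int v) { return &down[((size_t)c * nnode + v) * 4 * npat]; }
  inline double* Ds(int c, int v) { return &dscale[((size_t)c * nnode + v) * npat]; }
  inline double* Ep(int c, int e) { return &eprod[((size_t)c * nedge + e) * 4 * npat]; }
  inline double* Es(int c, int e) { return &escale[((size_t)c * nedge + e) * npat]; }
  inline double* Pm(int c, int e) { return &P[((size_t)c * nedge + e) * 16]; }

  void init(IntegerMatrix edge, NumericVector el_, int ntip_,
            IntegerMatrix tip_, NumericMatrix contrast_, NumericVector pi_,
            NumericVector rates_, NumericVector wts_, double pinv_,
            NumericMatrix evec_, NumericMatrix ievec_, NumericVector eval_,
            NumericVector patw_) {
    nedge = edge.nrow();
    ntip = ntip_;
    npat = tip_.nrow();
    ncat = rates_.size();
    eparent.resize(nedge); echild.resize(nedge);
    int maxn = 0;
    for (int e = 0; e < nedge; ++e) {
      eparent[e] = edge(e, 0) - 1;
      echild[e] = edge(e, 1) - 1;
      if (eparent[e] > maxn) maxn = eparent[e];
      if (echild[e] > maxn) maxn = echild[e];
    }
    nnode = maxn + 1;
    el.assign(el_.begin(), el_.end());
    tip = INTEGER(tip_);
    contrast = REAL(contrast_);
    for (int i = 0; i < 4; ++i) pi[i] = pi_[i];
    rates.assign(rates_.begin(), rates_.end());
    wts.assign(wts_.begin(), wts_.end());
    pinv = pinv_;
    evec = REAL(evec_); ievec = REAL(ievec_); eval = REAL(eval_);
    patw = REAL(patw_);

    // children lists and root
    kids.assign(nnode, std::vector<int>());
    std::vector<int> haspar(nnode, 0);
    for (int e = 0; e < nedge; ++e) {
      kids[eparent[e]].push_back(e);
      haspar[echild[e]] = 1;
    }
    root = -1;
    for (int e = 0; e < nedge; ++e)
      if (!haspar[eparent[e]]) { root = eparent[e]; break; }
    if (root < 0) stop("tree has no root node");

    // postorder over edges: iterative DFS
    porder.clear(); porder.reserve(nedge);
    std::vector<int> stack; stack.reserve(nedge);
    for (size_t i = 0; i < kids[root].size(); ++i) stack.push_back(kids[root][i]);
    std::vector<int> out; out.reserve(nedge);
    while (!stack.empty()) {
      int e = stack.back(); stack.pop_back();
      out.push_back(e);
      int v = echild[e];
      if (v >= ntip)
        for (size_t i = 0; i < kids[v].size(); ++i) stack.push_back(kids[v][i]);
    }
    for (int i = (int)out.size() - 1; i >= 0; --i) porder.push_back(out[i]);
    if ((int)porder.size() != nedge) stop("disconnected edge matrix");

    down.assign((size_t)ncat * nnode * 4 * npat, 0.0);
    dscale.assign((size_t)ncat * nnode * npat, 0.0);
    eprod.assign((size_t)ncat * nedge * 4 * npat, 0.0);
    escale.assign((size_t)ncat * nedge * npat, 0.0);
    P.assign((size_t)ncat * nedge * 16, 0.0);

    // tip partials (same for every category)
    for (int c = 0; c < ncat; ++c) {
      for (int v = 0; v < ntip; ++v) {
        double* d = Dn(c, v);
        for (int s = 0; s < npat; ++s) {
          int code = tip[(size_t)v * npat + s];
          if (code < 1 || code > 15) code = 15;
          for (int x = 0; x < 4; ++x)
            d[x * npat + s] = contrast[(size_t)x * 15 + (code - 1)];
        }
      }
    }

    // invariant-class site likelihoods
    inv.assign(npat, 0.0);
    for (int s = 0; s < npat; ++s) {
      int m = 15;
      for (int v = 0; v < ntip; ++v) {
        int code = tip[(size_t)v * npat + s];
        if (code < 1 || code > 15) code = 15;
        m &= code;
      }
      double s0 = 0.0;
      for (int b = 0; b < 4; ++b) if (m & (1 << b)) s0 += pi[b];
      inv[s] = s0;
    }
  }

  void compute_all_P() {
    for (int c = 0; c < ncat; ++c)
      for (int e = 0; e < nedge; ++e)
        pmat(evec, ievec, eval, el[e] * rates[c], Pm(c, e));
  }

  void compute_P_edge(int e) {
    for (int c = 0; c < ncat; ++c)
      pmat(evec, ievec, eval, el[e] * rates[c], Pm(c, e));
  }

  // eprod[e] = P_e %*% down[child(e)], escale[e] = dscale[child]
  void compute_eprod(int e) {
    int v = echild[e];
    for (int c = 0; c < ncat; ++c) {
      const double* p = Pm(c, e);
      const double* d = Dn(c, v);
      double* out = Ep(c, e);
      for (int x = 0; x < 4; ++x) {
        double* o = out + (size_t)x * npat;
        const double p0 = p[x * 4 + 0], p1 = p[x * 4 + 1],
                     p2 = p[x * 4 + 2], p3 = p[x * 4 + 3];
        const double* d0 = d; const double* d1 = d + npat;
        const double* d2 = d + 2 * (size_t)npat; const double* d3 = d + 3 * (size_t)npat;
        for (int s = 0; s < npat; ++s)
          o[s] = p0 * d0[s] + p1 * d1[s] + p2 * d2[s] + p3 * d3[s];
      }
      double* es = Es(c, e);
      if (v >= ntip) {
        const double* ds = Ds(c, v);
        std::memcpy(es, ds, sizeof(double) * npat);
      } else {
        std::memset(es, 0, sizeof(double) * npat);
      }
    }
  }

  void postorder_pass() {
    // reset internal node partials
    for (int c = 0; c < ncat; ++c)
      for (int v = ntip; v < nnode; ++v) {
        double* d = Dn(c, v);
        for (size_t i = 0; i < (size_t)4 * npat; ++i) d[i] = 1.0;
        std::memset(Ds(c, v), 0, sizeof(double) * npat);
      }
    for (size_t i = 0; i < porder.size(); ++i) {
      int e = porder[i];
      compute_eprod(e);
      int p = eparent[e];
      for (int c = 0; c < ncat; ++c) {
        double* d = Dn(c, p);
        double* ds = Ds(c, p);
        const double* ep = Ep(c, e);
        const double* es = Es(c, e);
        for (int x = 0; x < 4; ++x) {
          double* dx = d + (size_t)x * npat;
          const double* ex = ep + (size_t)x * npat;
          for (int s = 0; s < npat; ++s) dx[s] *= ex[s];
        }
        for (int s = 0; s < npat; ++s) ds[s] += es[s];
        // rescale small columns
        for (int s = 0; s < npat; ++s) {
          double mx = d[s];
          for (int x = 1; x < 4; ++x) {
            double v2 = d[(size_t)x * npat + s];
            if (v2 > mx) mx = v2;
          }
          if (mx < SCALE_THRESH && mx > 0.0) {
            for (int x = 0; x < 4; ++x) d[(size_t)x * npat + s] *= SCALE_FACTOR;
            ds[s] -= LOG_SCALE_FACTOR;
          }
        }
      }
    }
  }

  // per-pattern log-likelihood from root partials
  void root_loglik(double* out) {
    std::vector<double> lcat((size_t)ncat * npat);
    for (int c = 0; c < ncat; ++c) {
      const double* d = Dn(c, root);
      double* l = &lcat[(size_t)c * npat];
      for (int s = 0; s < npat; ++s)
        l[s] = pi[0] * d[s] + pi[1] * d[npat + s] +
               pi[2] * d[2 * (size_t)npat + s] + pi[3] * d[3 * (size_t)npat + s];
    }
    for (int s = 0; s < npat; ++s) {
      double msc = -HUGE_VAL;
      for (int c = 0; c < ncat; ++c) {
        double sc = Ds(c, root)[s];
        if (sc > msc) msc = sc;
      }
      double mix = 0.0;
      for (int c = 0; c < ncat; ++c)
        mix += wts[c] * std::exp(Ds(c, root)[s] - msc) * lcat[(size_t)c * npat + s];
      double a = pinv * inv[s];
      double b = (1.0 - pinv) * mix;
      if (a > 0.0) out[s] = std::log(a + std::exp(msc) * b);
      else out[s] = msc + std::log(b);
    }
  }

  double total_loglik() {
    std::vector<double> sl(npat);
    root_loglik(&sl[0]);
    double tot = 0.0;
    for (int s = 0; s < npat; ++s) tot += patw[s] * sl[s];
    return tot;
  }
};

// ---- exported: per-pattern log-likelihoods -------------------------------

// [[Rcpp::export]]
List c_site_loglik(IntegerMatrix edge, NumericVector el, int ntip,
                   IntegerMatrix tip, NumericMatrix contrast, NumericVector pi,
                   NumericVector rates, NumericVector wts, double pinv,
                   NumericMatrix evec, NumericMatrix ievec, NumericVector eval,
                   NumericVector patw) {
  Engine en;
  en.init(edge, el, ntip, tip, contrast, pi, rates, wts, pinv, evec, ievec,
          eval, patw);
  en.compute_all_P();
  en.postorder_pass();
  NumericVector sl(en.npat);
  en.root_loglik(REAL(sl));
  double tot = 0.0;
  for (int s = 0; s < en.npat; ++s) tot += patw[s] * sl[s];
  return List::create(_["sitell"] = sl, _["total"] = tot);
}

// ---- branch-length optimization ------------------------------------------

struct EdgeObjective {
  Engine* en;
  int e;
  std::vector<double> O;       // [cat][x][pat] pi-weighted "up" side
  std::vector<double> Osc;     // [cat][pat]
  std::vector<double> work;    // 16 per cat

  double eval_t(double t) {
    Engine& E = *en;
    int npat = E.npat, ncat = E.ncat;
    int v = E.echild[e];
    std::vector<double> m((size_t)ncat * npat);
    std::vector<double> sc((size_t)ncat * npat);
    double Pt[16];
    for (int c = 0; c < ncat; ++c) {
      pmat(E.evec, E.ievec, E.eval, t * E.rates[c], Pt);
      const double* d = E.Dn(c, v);
      const double* o = &O[(size_t)c * 4 * npat];
      double* mm = &m[(size_t)c * npat];
      for (int s = 0; s < npat; ++s) mm[s] = 0.0;
      for (int x = 0; x < 4; ++x) {
        const double p0 = Pt[x * 4 + 0], p1 = Pt[x * 4 + 1],
                     p2 = Pt[x * 4 + 2], p3 = Pt[x * 4 + 3];
        const double* ox = o + (size_t)x * npat;
        for (int s = 0; s < npat; ++s) {
          double t4 = p0 * d[s] + p1 * d[npat + s] +
                      p2 * d[2 * (size_t)npat + s] + p3 * d[3 * (size_t)npat + s];
          mm[s] += ox[s] * t4;
        }
      }
      double* scc = &sc[(size_t)c * npat];
      const double* osc = &Osc[(size_t)c * npat];
      if (v >= E.ntip) {
        const double* ds = E.Ds(c, v);
        for (int s = 0; s < npat; ++s) scc[s] = osc[s] + ds[s];
      } else {
        std::memcpy(scc, osc, sizeof(double) * npat);
      }
    }
    double tot = 0.0;
    for (int s = 0; s < npat; ++s) {
      double msc = -HUGE_VAL;
      for (int c = 0; c < ncat; ++c)
        if (sc[(size_t)c * npat + s] > msc) msc = sc[(size_t)c * npat + s];
      double mix = 0.0;
      for (int c = 0; c < ncat; ++c)
        mix += E.wts[c] * std::exp(sc[(size_t)c * npat + s] - msc) *
               m[(size_t)c * npat + s];
      double a = E.pinv * E.inv[s];
      double b = (1.0 - E.pinv) * mix;
      double ls;
      if (a > 0.0) ls = std::log(a + std::exp(msc) * b);
      else ls = msc + std::log(b <= 0.0 ? 1e-320 : b);
      tot += E.patw[s] * ls;
    }
    return tot;
  }
};

// Brent maximization on [a, b]
static double brent_max(EdgeObjective& f, double a, double b, double tol,
                        double* fmax) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv;
  x = w = v = a + gold * (b - a);
  fx = fw = fv = f.eval_t(x);
  double d = 0.0, ee = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(ee) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = ee; ee = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      ee = (x >= xm ? a - x : b - x);
      d = gold * ee;
    }
    double u = (std::fabs(d) >= tol1 ? x + d : x + (d >= 0 ? tol1 : -tol1));
    double fu = f.eval_t(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmax = fx;
  return x;
}

// [[Rcpp::export]]
List c_optim_bl(IntegerMatrix edge, NumericVector el, int ntip,
                IntegerMatrix tip, NumericMatrix contrast, NumericVector pi,
                NumericVector rates, NumericVector wts, double pinv,
                NumericMatrix evec, NumericMatrix ievec, NumericVector eval,
                NumericVector patw, int nsweep, double tol, double elmin,
                double elmax, IntegerVector opt_edges) {
  Engine en;
  en.init(edge, el, ntip, tip, contrast, pi, rates, wts, pinv, evec, ievec,
          eval, patw);
  int npat = en.npat, ncat = en.ncat;
  en.compute_all_P();

  std::vector<double> A((size_t)ncat * en.nnode * 4 * npat);
  std::vector<double> Asc((size_t)ncat * en.nnode * npat);
  EdgeObjective obj;
  obj.en = &en;
  obj.O.resize((size_t)ncat * 4 * npat);
  obj.Osc.resize((size_t)ncat * npat);
  std::vector<char> do_opt(en.nedge, 1);
  if (opt_edges.size() > 0) {
    std::fill(do_opt.begin(), do_opt.end(), 0);
    for (int i = 0; i < opt_edges.size(); ++i) {
      int e = opt_edges[i] - 1;
      if (e >= 0 && e < en.nedge) do_opt[e] = 1;
    }
  }

  double prev = -HUGE_VAL;
  for (int sweep = 0; sweep < nsweep; ++sweep) {
    en.postorder_pass();
    // A[root] = pi
    for (int c = 0; c < ncat; ++c) {
      double* a = &A[((size_t)c * en.nnode + en.root) * 4 * npat];
      for (int x = 0; x < 4; ++x)
        for (int s = 0; s < npat; ++s) a[(size_t)x * npat + s] = en.pi[x];
      std::memset(&Asc[((size_t)c * en.nnode + en.root) * npat], 0,
                  sizeof(double) * npat);
    }
    // preorder = reverse postorder
    for (int i = (int)en.porder.size() - 1; i >= 0; --i) {
      int e = en.porder[i];
      int p = en.eparent[e], v = en.echild[e];
      // O = A[p] * prod of sibling eprods
      for (int c = 0; c < ncat; ++c) {
        const double* ap = &A[((size_t)c * en.nnode + p) * 4 * npat];
        double* o = &obj.O[(size_t)c * 4 * npat];
        std::memcpy(o, ap, sizeof(double) * 4 * npat);
        double* osc = &obj.Osc[(size_t)c * npat];
        std::memcpy(osc, &Asc[((size_t)c * en.nnode + p) * npat],
                    sizeof(double) * npat);
        for (size_t k = 0; k < en.kids[p].size(); ++k) {
          int e2 = en.kids[p][k];
          if (e2 == e) continue;
          const double* ep2 = en.Ep(c, e2);
          const double* es2 = en.Es(c, e2);
          for (size_t ii = 0; ii < (size_t)4 * npat; ++ii) o[ii] *= ep2[ii];
          for (int s = 0; s < npat; ++s) osc[s] += es2[s];
        }
        // rescale
        for (int s = 0; s < npat; ++s) {
          double mx = o[s];
          for (int x = 1; x < 4; ++x)
            if (o[(size_t)x * npat + s] > mx) mx = o[(size_t)x * npat + s];
          if (mx < SCALE_THRESH && mx > 0.0) {
            for (int x = 0; x < 4; ++x) o[(size_t)x * npat + s] *= SCALE_FACTOR;
            osc[s] -= LOG_SCALE_FACTOR;
          }
        }
      }
      if (do_opt[e]) {
        obj.e = e;
        double fmax;
        double t = brent_max(obj, elmin, elmax, 1e-8, &fmax);
        en.el[e] = t;
        en.compute_P_edge(e);
        en.compute_eprod(e);
      }
      // A[v](y) = sum_x O(x) P_xy
      if (v >= en.ntip) {
        for (int c = 0; c < ncat; ++c) {
          const double* o = &obj.O[(size_t)c * 4 * npat];
          const double* Pt = en.Pm(c, e);
          double* av = &A[((size_t)c * en.nnode + v) * 4 * npat];
          for (int y = 0; y < 4; ++y) {
            double* ay = av + (size_t)y * npat;
            const double p0 = Pt[0 * 4 + y], p1 = Pt[1 * 4 + y],
                         p2 = Pt[2 * 4 + y], p3 = Pt[3 * 4 + y];
            for (int s = 0; s < npat; ++s)
              ay[s] = p0 * o[s] + p1 * o[npat + s] +
                      p2 * o[2 * (size_t)npat + s] + p3 * o[3 * (size_t)npat + s];
          }
          std::memcpy(&Asc[((size_t)c * en.nnode + v) * npat],
                      &obj.Osc[(size_t)c * npat], sizeof(double) * npat);
        }
      }
    }
    en.postorder_pass();
    double cur = en.total_loglik();
    if (cur - prev < tol && sweep > 0) { prev = cur; break; }
    prev = cur;
  }
  en.postorder_pass();
  NumericVector sl(npat);
  en.root_loglik(REAL(sl));
  double tot = 0.0;
  for (int s = 0; s < npat; ++s) tot += patw[s] * sl[s];
  return List::create(_["el"] = NumericVector(en.el.begin(), en.el.end()),
                      _["total"] = tot, _["sitell"] = sl);
}

// ---- Fitch parsimony -------------------------------------------------------

// edge: any parent/child matrix of a binary tree (root may trifurcate);
// tip: npat x ntip bitmask codes; patw: pattern weights.
// [[Rcpp::export]]
double c_fitch(IntegerMatrix edge, int ntip, IntegerMatrix tip,
               NumericVector patw) {
  int nedge = edge.nrow();
  int npat = tip.nrow();
  std::vector<int> eparent(nedge), echild(nedge);
  int maxn = 0;
  for (int e = 0; e < nedge; ++e) {
    eparent[e] = edge(e, 0) - 1;
    echild[e] = edge(e, 1) - 1;
    if (eparent[e] > maxn) maxn = eparent[e];
    if (echild[e] > maxn) maxn = echild[e];
  }
  int nnode = maxn + 1;
  std::vector<std::vector<int> > kids(nnode);
  std::vector<int> haspar(nnode, 0);
  for (int e = 0; e < nedge; ++e) {
    kids[eparent[e]].push_back(e);
    haspar[echild[e]] = 1;
  }
  int root = -1;
  for (int e = 0; e < nedge; ++e)
    if (!haspar[eparent[e]]) { root = eparent[e]; break; }
  if (root < 0) stop("tree has no root node");
  // postorder edges
  std::vector<int> stack, out;
  for (size_t i = 0; i < kids[root].size(); ++i) stack.push_back(kids[root][i]);
  while (!stack.empty()) {
    int e = stack.back(); stack.pop_back();
    out.push_back(e);
    int v = echild[e];
    if (v >= ntip)
      for (size_t i = 0; i < kids[v].size(); ++i) stack.push_back(kids[v][i]);
  }
  const int* tp = INTEGER(tip);
  std::vector<int> S((size_t)nnode * npat, 0);
  std::vector<char> init(nnode, 0);
  std::vector<double> len(npat, 0.0);
  for (int v = 0; v < ntip; ++v) {
    for (int s = 0; s < npat; ++s) {
      int code = tp[(size_t)v * npat + s];
      if (code < 1 || code > 15) code = 15;
      S[(size_t)v * npat + s] = code;
    }
    init[v] = 1;
  }
  for (int i = (int)out.size() - 1; i >= 0; --i) {
    int e = out[i];
    int p = eparent[e], v = echild[e];
    int* sp = &S[(size_t)p * npat];
    const int* sv = &S[(size_t)v * npat];
    if (!init[p]) {
      std::memcpy(sp, sv, sizeof(int) * npat);
      init[p] = 1;
    } else {
      for (int s = 0; s < npat; ++s) {
        int is = sp[s] & sv[s];
        if (is == 0) { sp[s] = sp[s] | sv[s]; len[s] += 1.0; }
        else sp[s] = is;
      }
    }
  }
  double tot = 0.0;
  for (int s = 0; s < npat; ++s) tot += patw[s] * len[s];
  return tot;
}

// ---- RELL resampling -------------------------------------------------------

// B replicate totals of per-site log-likelihoods: each replicate draws
// `size` site indices with replacement (same indices for all trees).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix c_rell(NumericMatrix m, int B, int size) {
  int n = m.nrow(), M = m.ncol();
  NumericMatrix out(B, M);
  const double* mm = REAL(m);
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < size; ++s) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      for (int k = 0; k < M; ++k) out(b, k) += mm[(size_t)k * n + i];
    }
  }
  return out;
}
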