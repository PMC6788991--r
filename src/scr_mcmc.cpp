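// Metropolis-within-Gibbs sampler for the bilateral-flank spatial
// capture-recapture model: detection/flank parameters, latent left-right
// identity matching, activity centres on the habitat-mask lattice, and
// abundance N under the semi-complete-data likelihood.
//
// The cloglog half-normal model factorizes as hazard
//   h(s, t, j, b) = H(t, j, b) * G(s, j),
//   H = exp(distance-free linear predictor), G = exp(-d^2 / (2 sigma^2)),
// so non-detection cells contribute -sum(h) and both the per-history
// likelihood over all mask cells and p0 reduce to matrix-vector products.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double log1mexpNeg(double h) {
  // log(1 - exp(-h)), h >= 0
  if (h <= 0.6931471805599453)
    return std::log(-std::expm1(-h));
  return std::log1p(-std::exp(-h));
}

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Det { int t, j, code; };

struct Ind {
  std::vector<int> hists;      // owned observed-history indices
  std::vector<int> codeGrid;   // T*J combined codes
  std::vector<char> prevGrid;  // T*J previous-capture state
  std::vector<double> A;       // per-trap hazard sum over zero cells
  std::vector<Det> dets;
  int n12, n3, n4;             // detection counts by code class
  int cell;
  double ll;
};

struct ScrCore {
  // data
  int M, T, J, S;
  std::vector<int> codes;   // m + M*t + M*T*j
  std::vector<int> kind;    // 0 left, 1 right, 2 known
  std::vector<char> op;     // t + T*j
  std::vector<double> trapx, trapy;
  std::vector<int> water;
  std::vector<double> cellx, celly;
  double mesh, originx, originy;
  int nx, ny;
  std::vector<int> grid;    // ix + nx*iy -> included-cell index or -1
  std::vector<double> d2;   // s + S*j

  // spec: 0 const, 1 per-occasion, 2 trend
  int timeMode; bool behav, placement, interact;

  // priors
  double betaSd, effSd, logSigmaMean, logSigmaSd;
  int priorN;               // 0: p(N) ~ 1/N, 1: uniform
  int Nmax;

  // parameter layout
  int nBeta, idxTrend, idxC, idxW, idxCW, idxLS, idxD, idxA, np;

  // state
  std::vector<double> th;
  std::vector<double> H0, H1;   // t + T*j
  std::vector<double> G;        // s + S*j
  std::vector<int> partner;     // per history: right partner of a left hist
  std::vector<Ind> inds;
  std::vector<double> A0;
  std::vector<double> E0;       // per-cell total hazard sum_j A0_j G_sj
  double logp0;
  int N;

  void refreshE0() {
    E0.assign(S, 0.0);
    for (int j = 0; j < J; ++j) {
      double a = A0[j];
      if (a == 0.0) continue;
      const double* gc = &G[(size_t)S * j];
      for (int s = 0; s < S; ++s) E0[s] += a * gc[s];
    }
  }
  double logp0FromE0(double f) const {
    double acc = 0.0;
    for (int s = 0; s < S; ++s) acc += std::exp(-f * E0[s]);
    return std::log(acc / S);
  }

  // scratch (proposals)
  std::vector<double> pH0, pH1, pG, pA0;
  std::vector<std::vector<double> > pA;
  std::vector<double> pll;
  double plogp0;

  // lgamma tables
  std::vector<double> lgt;   // lgamma(x + 1), x = 0..Nmax
  std::vector<double> logNt; // log(x), x = 1..Nmax

  void layout() {
    nBeta = (timeMode == 1) ? T : 1;
    int k = nBeta;
    idxTrend = (timeMode == 2) ? k++ : -1;
    idxC = behav ? k++ : -1;
    idxW = placement ? k++ : -1;
    idxCW = interact ? k++ : -1;
    idxLS = k++; idxD = k++; idxA = k++;
    np = k;
  }

  double tTilde(int t) const { return T > 1 ? (double)t / (T - 1) - 0.5 : 0.0; }

  void computeH(const std::vector<double>& v, std::vector<double>& h0,
                std::vector<double>& h1) const {
    for (int j = 0; j < J; ++j) {
      for (int t = 0; t < T; ++t) {
        double base = (timeMode == 1) ? v[t] : v[0];
        if (timeMode == 2) base += v[idxTrend] * tTilde(t);
        if (placement) base += v[idxW] * water[j];
        double e0 = base;
        double e1 = base + (behav ? v[idxC] : 0.0) +
                    (interact ? v[idxCW] * water[j] : 0.0);
        h0[t + T * j] = std::exp(e0);
        h1[t + T * j] = behav ? std::exp(e1) : h0[t + T * j];
      }
    }
  }

  void computeG(const std::vector<double>& v, std::vector<double>& g) const {
    double sig = std::exp(v[idxLS]);
    double inv = 1.0 / (2.0 * sig * sig);
    for (size_t k = 0; k < d2.size(); ++k) g[k] = std::exp(-d2[k] * inv);
  }

  void rebuildInd(Ind& ind) const {
    ind.codeGrid.assign(T * J, 0);
    ind.prevGrid.assign(T * J, 0);
    ind.dets.clear();
    for (size_t h = 0; h < ind.hists.size(); ++h) {
      int m = ind.hists[h];
      for (int j = 0; j < J; ++j)
        for (int t = 0; t < T; ++t) {
          int c = codes[m + M * t + M * T * j];
          if (c) {
            int& cur = ind.codeGrid[t + T * j];
            cur = cur == 0 ? c : (cur == 4 || c == 4) ? 4
                  : (cur == 3 || c == 3) ? 3 : (cur != c ? 3 : cur);
          }
        }
    }
    for (int j = 0; j < J; ++j) {
      bool seen = false;
      for (int t = 0; t < T; ++t) {
        ind.prevGrid[t + T * j] = seen ? 1 : 0;
        if (ind.codeGrid[t + T * j]) seen = true;
      }
    }
    ind.n12 = ind.n3 = ind.n4 = 0;
    for (int j = 0; j < J; ++j)
      for (int t = 0; t < T; ++t) {
        int c = ind.codeGrid[t + T * j];
        if (c) {
          Det d; d.t = t; d.j = j; d.code = c; ind.dets.push_back(d);
          if (c <= 2) ++ind.n12; else if (c == 3) ++ind.n3; else ++ind.n4;
        }
      }
  }

  void computeAInd(const Ind& ind, const std::vector<double>& h0,
                   const std::vector<double>& h1, std::vector<double>& A) const {
    A.assign(J, 0.0);
    for (int j = 0; j < J; ++j) {
      double a = 0.0;
      for (int t = 0; t < T; ++t) {
        int k = t + T * j;
        if (op[k] && ind.codeGrid[k] == 0)
          a += ind.prevGrid[k] ? h1[k] : h0[k];
      }
      A[j] = a;
    }
  }

  double logCodeFactor(int code, double delta, double alpha) const {
    switch (code) {
      case 1: case 2: return std::log(delta);
      case 3: return std::log1p(-alpha) + std::log(1.0 - 2.0 * delta);
      default: return std::log(alpha) + std::log(1.0 - 2.0 * delta);
    }
  }

  double llIndAt(const Ind& ind, const std::vector<double>& A, int cell,
                 const std::vector<double>& h0, const std::vector<double>& h1,
                 const std::vector<double>& g, double delta,
                 double alpha) const {
    double ll = 0.0;
    for (int j = 0; j < J; ++j) ll -= A[j] * g[cell + S * j];
    for (size_t k = 0; k < ind.dets.size(); ++k) {
      const Det& d = ind.dets[k];
      int kk = d.t + T * d.j;
      double h = (ind.prevGrid[kk] ? h1[kk] : h0[kk]) * g[cell + S * d.j];
      ll += logCodeFactor(d.code, delta, alpha) + log1mexpNeg(h);
    }
    return ll;
  }

  void llIndAll(const Ind& ind, const std::vector<double>& A,
                const std::vector<double>& h0, const std::vector<double>& h1,
                const std::vector<double>& g, double delta, double alpha,
                std::vector<double>& out) const {
    out.assign(S, 0.0);
    for (int j = 0; j < J; ++j) {
      double a = A[j];
      if (a == 0.0) continue;
      const double* gc = &g[S * j];
      for (int s = 0; s < S; ++s) out[s] -= a * gc[s];
    }
    for (size_t k = 0; k < ind.dets.size(); ++k) {
      const Det& d = ind.dets[k];
      int kk = d.t + T * d.j;
      double hb = ind.prevGrid[kk] ? h1[kk] : h0[kk];
      double lf = logCodeFactor(d.code, delta, alpha);
      const double* gc = &g[S * d.j];
      for (int s = 0; s < S; ++s)
        out[s] += lf + log1mexpNeg(hb * gc[s]);
    }
  }

  double logSumExpVec(const std::vector<double>& v) const {
    double m = -std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < v.size(); ++i) if (v[i] > m) m = v[i];
    if (!R_FINITE(m)) return m;
    double s = 0.0;
    for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
    return m + std::log(s);
  }

  void computeA0(const std::vector<double>& h0, std::vector<double>& A) const {
    A.assign(J, 0.0);
    for (int j = 0; j < J; ++j) {
      double a = 0.0;
      for (int t = 0; t < T; ++t)
        if (op[t + T * j]) a += h0[t + T * j];
      A[j] = a;
    }
  }

  double computeLogp0(const std::vector<double>& A,
                      const std::vector<double>& g) const {
    // mean over cells of exp(-sum_j A_j G_sj)
    std::vector<double> e(S, 0.0);
    for (int j = 0; j < J; ++j) {
      double a = A[j];
      if (a == 0.0) continue;
      const double* gc = &g[S * j];
      for (int s = 0; s < S; ++s) e[s] -= a * gc[s];
    }
    double acc = 0.0;
    for (int s = 0; s < S; ++s) acc += std::exp(e[s]);
    return std::log(acc / S);
  }

  double delta_() const { return 0.5 * plogis_(th[idxD]); }
  double alpha_() const { return plogis_(th[idxA]); }

  double logPriorParams(const std::vector<double>& v) const {
    double lp = 0.0;
    for (int k = 0; k < nBeta; ++k) lp += R::dnorm(v[k], 0.0, betaSd, 1);
    if (idxTrend >= 0) lp += R::dnorm(v[idxTrend], 0.0, effSd, 1);
    if (idxC >= 0) lp += R::dnorm(v[idxC], 0.0, effSd, 1);
    if (idxW >= 0) lp += R::dnorm(v[idxW], 0.0, effSd, 1);
    if (idxCW >= 0) lp += R::dnorm(v[idxCW], 0.0, effSd, 1);
    lp += R::dnorm(v[idxLS], logSigmaMean, logSigmaSd, 1);
    // uniform priors on delta in (0, 0.5) and alpha in (0, 1): logit Jacobians
    double sd_ = plogis_(v[idxD]), sa = plogis_(v[idxA]);
    lp += std::log(sd_) + std::log1p(-sd_);
    lp += std::log(sa) + std::log1p(-sa);
    return lp;
  }

  double logPriorN(int nn) const { return priorN == 0 ? -logNt[nn - 1] : 0.0; }

  int n_() const { return (int)inds.size(); }

  double dataLogpost() const {
    // likelihood + latent-centre prior part (excludes parameter priors)
    int n = n_();
    double lp = lgt[N] - lgt[N - n] + (N - n) * logp0 - n * std::log((double)S);
    for (int i = 0; i < n; ++i) lp += inds[i].ll;
    return lp;
  }

  double fullLogpost() const {
    return dataLogpost() + logPriorParams(th) + logPriorN(N);
  }

  // rebuild the individuals list from the partner vector
  void buildIndividuals(const std::vector<int>& cellOfHist) {
    inds.clear();
    // partnered right histories are consumed by their left partner,
    // regardless of index order
    std::vector<char> isPartnerR(M, 0);
    for (int m = 0; m < M; ++m)
      if (kind[m] == 0 && partner[m] >= 0) isPartnerR[partner[m]] = 1;
    for (int m = 0; m < M; ++m) {
      if (isPartnerR[m]) continue;
      Ind ind;
      ind.hists.push_back(m);
      if (kind[m] == 0 && partner[m] >= 0)
        ind.hists.push_back(partner[m]);
      ind.cell = cellOfHist[m];
      inds.push_back(ind);
    }
    double del = delta_(), alp = alpha_();
    for (size_t i = 0; i < inds.size(); ++i) {
      rebuildInd(inds[i]);
      computeAInd(inds[i], H0, H1, inds[i].A);
      inds[i].ll = llIndAt(inds[i], inds[i].A, inds[i].cell, H0, H1, G,
                           del, alp);
    }
  }

  void refreshAll() {
    computeH(th, H0, H1);
    computeG(th, G);
    computeA0(H0, A0);
    refreshE0();
    logp0 = logp0FromE0(1.0);
    double del = delta_(), alp = alpha_();
    for (size_t i = 0; i < inds.size(); ++i) {
      computeAInd(inds[i], H0, H1, inds[i].A);
      inds[i].ll = llIndAt(inds[i], inds[i].A, inds[i].cell, H0, H1, G,
                           del, alp);
    }
  }

  int snapCell(double x, double y) const {
    int ix = (int)std::lround((x - originx) / mesh);
    int iy = (int)std::lround((y - originy) / mesh);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return -1;
    return grid[ix + nx * iy];
  }

  int sampleFromLog(const std::vector<double>& lw) const {
    double m = -std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < lw.size(); ++i) if (lw[i] > m) m = lw[i];
    double tot = 0.0;
    std::vector<double> w(lw.size());
    for (size_t i = 0; i < lw.size(); ++i) { w[i] = std::exp(lw[i] - m); tot += w[i]; }
    double u = R::runif(0.0, tot), c = 0.0;
    for (size_t i = 0; i < lw.size(); ++i) { c += w[i]; if (u <= c) return (int)i; }
    return (int)lw.size() - 1;
  }
};

static ScrCore buildCore(List data, List maskL, List specL, List priorsL) {
  ScrCore c;
  IntegerVector codes = data["codes"];
  IntegerVector dims = codes.attr("dim");
  c.M = dims[0]; c.T = dims[1]; c.J = dims[2];
  c.codes.assign(codes.begin(), codes.end());
  IntegerVector kind = data["kind"];
  c.kind.assign(kind.begin(), kind.end());
  LogicalMatrix op = data["op"]; // T x J
  c.op.assign(c.T * c.J, 0);
  for (int j = 0; j < c.J; ++j)
    for (int t = 0; t < c.T; ++t)
      c.op[t + c.T * j] = op(t, j) ? 1 : 0;
  NumericVector tx = data["trapx"], ty = data["trapy"];
  c.trapx.assign(tx.begin(), tx.end());
  c.trapy.assign(ty.begin(), ty.end());
  IntegerVector wt = data["water"];
  c.water.assign(wt.begin(), wt.end());

  NumericVector cx = maskL["cellx"], cy = maskL["celly"];
  c.S = cx.size();
  c.cellx.assign(cx.begin(), cx.end());
  c.celly.assign(cy.begin(), cy.end());
  c.mesh = as<double>(maskL["mesh"]);
  c.originx = as<double>(maskL["originx"]);
  c.originy = as<double>(maskL["originy"]);
  c.nx = as<int>(maskL["nx"]); c.ny = as<int>(maskL["ny"]);
  IntegerVector gr = maskL["grid"];
  c.grid.assign(gr.begin(), gr.end());
  c.d2.assign((size_t)c.S * c.J, 0.0);
  for (int j = 0; j < c.J; ++j)
    for (int s = 0; s < c.S; ++s) {
      double dx = c.cellx[s] - c.trapx[j], dy = c.celly[s] - c.trapy[j];
      c.d2[s + (size_t)c.S * j] = dx * dx + dy * dy;
    }

  c.timeMode = as<int>(specL["timeMode"]);
  c.behav = as<bool>(specL["behav"]);
  c.placement = as<bool>(specL["placement"]);
  c.interact = as<bool>(specL["interact"]);
  c.layout();

  c.betaSd = as<double>(priorsL["betaSd"]);
  c.effSd = as<double>(priorsL["effSd"]);
  c.logSigmaMean = as<double>(priorsL["logSigmaMean"]);
  c.logSigmaSd = as<double>(priorsL["logSigmaSd"]);
  c.priorN = as<int>(priorsL["priorN"]);
  c.Nmax = as<int>(priorsL["Nmax"]);
  c.lgt.resize(c.Nmax + 1);
  c.logNt.resize(c.Nmax);
  for (int x = 0; x <= c.Nmax; ++x) c.lgt[x] = std::lgamma(x + 1.0);
  for (int x = 1; x <= c.Nmax; ++x) c.logNt[x - 1] = std::log((double)x);

  c.H0.assign(c.T * c.J, 0.0); c.H1.assign(c.T * c.J, 0.0);
  c.G.assign((size_t)c.S * c.J, 0.0);
  return c;
}

static void initState(ScrCore& c, List initL) {
  NumericVector th = initL["params"];
  if ((int)th.size() != c.np)
    stop("init parameter vector has wrong length");
  c.th.assign(th.begin(), th.end());
  IntegerVector pt = initL["partner"];
  c.partner.assign(pt.begin(), pt.end());
  IntegerVector ch = initL["cellOfHist"];
  std::vector<int> cells(ch.begin(), ch.end());
  c.N = as<int>(initL["N"]);
  c.computeH(c.th, c.H0, c.H1);
  c.computeG(c.th, c.G);
  c.computeA0(c.H0, c.A0);
  c.refreshE0();
  c.logp0 = c.logp0FromE0(1.0);
  c.buildIndividuals(cells);
  if (c.N < c.n_()) c.N = c.n_();
}

// [[Rcpp::export(name = ".scr_logpost")]]
List scr_logpost(List data, List maskL, List specL, List priorsL, List initL) {
  ScrCore c = buildCore(data, maskL, specL, priorsL);
  initState(c, initL);
  NumericVector ll(c.n_());
  for (int i = 0; i < c.n_(); ++i) ll[i] = c.inds[i].ll;
  return List::create(_["dataLogpost"] = c.dataLogpost(),
                      _["fullLogpost"] = c.fullLogpost(),
                      _["logp0"] = c.logp0,
                      _["llInd"] = ll,
                      _["n"] = c.n_());
}

// marginal semi-complete log likelihood (activity centres integrated over the
// mask) for a given parameter vector, matching encoding and abundance
// [[Rcpp::export(name = ".scr_semicomplete")]]
double scr_semicomplete(List data, List maskL, List specL, List priorsL,
                        NumericVector params, IntegerVector partner, int N) {
  ScrCore c = buildCore(data, maskL, specL, priorsL);
  c.th.assign(params.begin(), params.end());
  if ((int)c.th.size() != c.np) stop("parameter vector has wrong length");
  c.partner.assign(partner.begin(), partner.end());
  c.computeH(c.th, c.H0, c.H1);
  c.computeG(c.th, c.G);
  c.computeA0(c.H0, c.A0);
  c.refreshE0();
  c.logp0 = c.logp0FromE0(1.0);
  std::vector<int> cells(c.M, 0);
  c.buildIndividuals(cells);
  int n = c.n_();
  if (N < n) return R_NegInf;
  double del = c.delta_(), alp = c.alpha_();
  double ll = std::lgamma(N + 1.0) - std::lgamma(N - n + 1.0) +
              (N == n ? 0.0 : (N - n) * c.logp0);
  std::vector<double> lv;
  for (int i = 0; i < n; ++i) {
    c.llIndAll(c.inds[i], c.inds[i].A, c.H0, c.H1, c.G, del, alp, lv);
    ll += c.logSumExpVec(lv) - std::log((double)c.S);
  }
  return ll;
}

// exact Gibbs draw of N from its full conditional (standalone, for tests)
// [[Rcpp::export(name = ".scr_sample_N")]]
IntegerVector scr_sample_N(int n, double logp0, int Nmax, int priorN,
                           int nDraws) {
  int lo = std::max(n, 1);  // the 1/N prior is supported on [1, Nmax]
  std::vector<double> lw(Nmax - lo + 1);
  for (int N = lo; N <= Nmax; ++N) {
    double v = std::lgamma(N + 1.0) - std::lgamma(N - n + 1.0) +
               (N == n ? 0.0 : (N - n) * logp0);
    if (priorN == 0) v -= std::log((double)N);
    lw[N - lo] = v;
  }
  double m = *std::max_element(lw.begin(), lw.end());
  std::vector<double> w(lw.size());
  double tot = 0.0;
  for (size_t i = 0; i < lw.size(); ++i) { w[i] = std::exp(lw[i] - m); tot += w[i]; }
  IntegerVector out(nDraws);
  for (int d = 0; d < nDraws; ++d) {
    double u = R::runif(0.0, tot), cum = 0.0;
    int pick = (int)lw.size() - 1;
    for (size_t i = 0; i < lw.size(); ++i) {
      cum += w[i];
      if (u <= cum) { pick = (int)i; break; }
    }
    out[d] = lo + pick;
  }
  return out;
}

// [[Rcpp::export(name = ".scr_chain")]]
List scr_chain(List data, List maskL, List specL, List priorsL, List configL,
               List initL) {
  ScrCore c = buildCore(data, maskL, specL, priorsL);
  initState(c, initL);

  int nAdapt = as<int>(configL["nAdapt"]);
  int nSample = as<int>(configL["nSample"]);
  int nBurn = as<int>(configL["nBurn"]);
  int thin = as<int>(configL["thin"]);
  bool updParams = as<bool>(configL["updParams"]);
  bool updCentres = as<bool>(configL["updCentres"]);
  bool updMatching = as<bool>(configL["updMatching"]);
  bool updN = as<bool>(configL["updN"]);
  int matchMoves = as<int>(configL["matchMoves"]);
  bool storeLatent = as<bool>(configL["storeLatent"]);
  int storeCentresEvery = as<int>(configL["storeCentresEvery"]);
  double target = as<double>(configL["targetAccept"]);
  LogicalVector fixedPar = configL["fixedParams"];

  std::vector<double> sc(c.np, 0.2);
  sc[c.idxLS] = 0.1;
  double scCentre = as<double>(configL["centreScale"]);
  std::vector<int> accP(c.np, 0), tryP(c.np, 0);
  int accC = 0, tryC = 0, accMat = 0, tryMat = 0;
  long accPTot = 0, tryPTot = 0, accCTot = 0, tryCTot = 0;
  int win = 50, winCount = 0;

  int nRet = (nSample - nBurn) / thin;
  int extra = 5; // sigma, delta, alpha, N, n  (+psi, logpost below)
  NumericMatrix draws(nRet, c.np + extra + 2);
  IntegerMatrix latent(storeLatent ? nRet : 0, storeLatent ? c.M : 0);
  int nCentRows = (storeCentresEvery > 0 && nRet > 0)
                    ? (nRet - 1) / storeCentresEvery + 1 : 0;
  IntegerMatrix centres(nCentRows, c.M > 0 ? c.M : 1);

  double del, alp;
  c.pA.resize(64);

  int totalIter = nAdapt + nSample;
  int retIdx = 0, centRow = 0;

  for (int iter = 0; iter < totalIter; ++iter) {
    bool adapting = iter < nAdapt;

    if (updParams) {
      for (int k = 0; k < c.np; ++k) {
        if (fixedPar[k]) continue;
        ++tryP[k];
        if (!adapting) ++tryPTot;
        bool accepted = false;
        int n = c.n_();
        double step = R::rnorm(0.0, sc[k]);

        if (k == c.idxD || k == c.idxA) {
          // flank parameters touch only the multinomial code factors
          std::vector<double> thNew = c.th;
          thNew[k] += step;
          double dOld = c.delta_(), aOld = c.alpha_();
          double dNew = 0.5 * plogis_(thNew[c.idxD]);
          double aNew = plogis_(thNew[c.idxA]);
          double lr = c.logPriorParams(thNew) - c.logPriorParams(c.th);
          c.pll.assign(n, 0.0);
          for (int i = 0; i < n; ++i) {
            const Ind& ind = c.inds[i];
            double di = ind.n12 * (std::log(dNew) - std::log(dOld)) +
              ind.n3 * (std::log1p(-aNew) + std::log(1 - 2 * dNew) -
                        std::log1p(-aOld) - std::log(1 - 2 * dOld)) +
              ind.n4 * (std::log(aNew) + std::log(1 - 2 * dNew) -
                        std::log(aOld) - std::log(1 - 2 * dOld));
            c.pll[i] = di;
            lr += di;
          }
          if (R_FINITE(lr) && std::log(R::unif_rand()) < lr) {
            c.th = thNew;
            for (int i = 0; i < n; ++i) c.inds[i].ll += c.pll[i];
            accepted = true;
          }
        } else if (k < c.nBeta && c.nBeta == 1) {
          // single cloglog intercept: every hazard scales by exp(step)
          double f = std::exp(step);
          std::vector<double> thNew = c.th;
          thNew[k] += step;
          double del = c.delta_(), alp = c.alpha_();
          double lp0New = c.logp0FromE0(f);
          double lr = (c.N - n) * (lp0New - c.logp0) +
            c.logPriorParams(thNew) - c.logPriorParams(c.th);
          c.pll.assign(n, 0.0);
          for (int i = 0; i < n; ++i) {
            const Ind& ind = c.inds[i];
            double z = 0.0;
            for (int j = 0; j < c.J; ++j)
              z += ind.A[j] * c.G[ind.cell + (size_t)c.S * j];
            double ll = -f * z;
            for (size_t q = 0; q < ind.dets.size(); ++q) {
              const Det& d = ind.dets[q];
              int kk = d.t + c.T * d.j;
              double h = (ind.prevGrid[kk] ? c.H1[kk] : c.H0[kk]) *
                c.G[ind.cell + (size_t)c.S * d.j];
              ll += c.logCodeFactor(d.code, del, alp) + log1mexpNeg(f * h);
            }
            c.pll[i] = ll;
            lr += ll - ind.ll;
          }
          if (R_FINITE(lr) && std::log(R::unif_rand()) < lr) {
            c.th = thNew;
            for (size_t q = 0; q < c.H0.size(); ++q) {
              c.H0[q] *= f; c.H1[q] *= f;
            }
            for (int j = 0; j < c.J; ++j) c.A0[j] *= f;
            for (int s = 0; s < c.S; ++s) c.E0[s] *= f;
            c.logp0 = lp0New;
            for (int i = 0; i < n; ++i) {
              for (int j = 0; j < c.J; ++j) c.inds[i].A[j] *= f;
              c.inds[i].ll = c.pll[i];
            }
            accepted = true;
          }
        } else {
          // structured detection terms (and sigma): full recompute
          std::vector<double> thNew = c.th;
          thNew[k] += step;
          c.pH0 = c.H0; c.pH1 = c.H1;
          c.computeH(thNew, c.pH0, c.pH1);
          bool sigChanged = (k == c.idxLS);
          if (sigChanged) { c.pG = c.G; c.computeG(thNew, c.pG); }
          const std::vector<double>& g = sigChanged ? c.pG : c.G;
          c.computeA0(c.pH0, c.pA0);
          c.plogp0 = c.computeLogp0(c.pA0, g);
          double delN = 0.5 * plogis_(thNew[c.idxD]);
          double alpN = plogis_(thNew[c.idxA]);
          double lpNew = (c.N - n) * c.plogp0 + c.logPriorParams(thNew);
          double lpOld = (c.N - n) * c.logp0 + c.logPriorParams(c.th);
          if ((int)c.pA.size() < n) c.pA.resize(n);
          c.pll.assign(n, 0.0);
          for (int i = 0; i < n; ++i) {
            c.computeAInd(c.inds[i], c.pH0, c.pH1, c.pA[i]);
            c.pll[i] = c.llIndAt(c.inds[i], c.pA[i], c.inds[i].cell, c.pH0,
                                 c.pH1, g, delN, alpN);
            lpNew += c.pll[i];
            lpOld += c.inds[i].ll;
          }
          if (R_FINITE(lpNew) &&
              std::log(R::unif_rand()) < lpNew - lpOld) {
            c.th = thNew;
            c.H0.swap(c.pH0); c.H1.swap(c.pH1);
            if (sigChanged) c.G.swap(c.pG);
            c.A0.swap(c.pA0);
            c.refreshE0();
            c.logp0 = c.plogp0;
            for (int i = 0; i < n; ++i) {
              c.inds[i].A.swap(c.pA[i]);
              c.inds[i].ll = c.pll[i];
            }
            accepted = true;
          }
        }
        if (accepted) {
          ++accP[k];
          if (!adapting) ++accPTot;
        }
      }
    }

    del = c.delta_(); alp = c.alpha_();

    if (updCentres) {
      for (int i = 0; i < c.n_(); ++i) {
        double x = c.cellx[c.inds[i].cell] + R::rnorm(0.0, scCentre);
        double y = c.celly[c.inds[i].cell] + R::rnorm(0.0, scCentre);
        ++tryC;
        if (!adapting) ++tryCTot;
        int cNew = c.snapCell(x, y);
        if (cNew < 0) continue;
        double llNew = c.llIndAt(c.inds[i], c.inds[i].A, cNew, c.H0, c.H1,
                                 c.G, del, alp);
        if (std::log(R::runif(0.0, 1.0)) < llNew - c.inds[i].ll) {
          c.inds[i].cell = cNew;
          c.inds[i].ll = llNew;
          ++accC;
          if (!adapting) ++accCTot;
        }
      }
    }

    if (updMatching && c.M > 1) {
      for (int mv = 0; mv < matchMoves; ++mv) {
        // unmatched lefts/rights and merged pairs
        std::vector<int> UL, UR, PIdx;
        for (int m = 0; m < c.M; ++m) {
          if (c.kind[m] == 0 && c.partner[m] < 0) UL.push_back(m);
          if (c.kind[m] == 0 && c.partner[m] >= 0) PIdx.push_back(m);
        }
        std::vector<char> matchedR(c.M, 0);
        for (size_t q = 0; q < PIdx.size(); ++q) matchedR[c.partner[PIdx[q]]] = 1;
        for (int m = 0; m < c.M; ++m)
          if (c.kind[m] == 1 && !matchedR[m]) UR.push_back(m);
        bool canMerge = !UL.empty() && !UR.empty();
        bool canSplit = !PIdx.empty();
        if (!canMerge && !canSplit) break;
        bool doMerge = canMerge && (!canSplit || R::unif_rand() < 0.5);
        double pFwd = (canMerge && canSplit) ? 0.5 : 1.0;
        ++tryMat;
        int n = c.n_();
        if (doMerge) {
          int l = UL[(int)std::floor(R::unif_rand() * UL.size())];
          int r = UR[(int)std::floor(R::unif_rand() * UR.size())];
          Ind merged; merged.hists.push_back(l); merged.hists.push_back(r);
          c.rebuildInd(merged);
          c.computeAInd(merged, c.H0, c.H1, merged.A);
          std::vector<double> lvM;
          c.llIndAll(merged, merged.A, c.H0, c.H1, c.G, del, alp, lvM);
          double margM = c.logSumExpVec(lvM) - std::log((double)c.S);
          // marginals of the two current singletons
          int il = -1, ir = -1;
          for (int i = 0; i < n; ++i) {
            if (c.inds[i].hists.size() == 1 && c.inds[i].hists[0] == l) il = i;
            if (c.inds[i].hists.size() == 1 && c.inds[i].hists[0] == r) ir = i;
          }
          std::vector<double> lvL, lvR;
          c.llIndAll(c.inds[il], c.inds[il].A, c.H0, c.H1, c.G, del, alp, lvL);
          c.llIndAll(c.inds[ir], c.inds[ir].A, c.H0, c.H1, c.G, del, alp, lvR);
          double margL = c.logSumExpVec(lvL) - std::log((double)c.S);
          double margR = c.logSumExpVec(lvR) - std::log((double)c.S);
          bool canMergeAfter = (UL.size() > 1 && UR.size() > 1);
          double pRev = canMergeAfter ? 0.5 : 1.0; // split prob at new state
          double lr = -std::log((double)(c.N - n + 1)) + c.logp0 +
                      margM - margL - margR +
                      std::log(pRev) - std::log((double)(PIdx.size() + 1)) -
                      (std::log(pFwd) - std::log((double)(UL.size() * UR.size())));
          if (std::log(R::unif_rand()) < lr) {
            merged.cell = c.sampleFromLog(lvM);
            merged.ll = lvM[merged.cell];
            int hi = std::max(il, ir), lo = std::min(il, ir);
            c.inds.erase(c.inds.begin() + hi);
            c.inds.erase(c.inds.begin() + lo);
            c.inds.push_back(merged);
            c.partner[l] = r;
            ++accMat;
          }
        } else {
          if (c.N <= n) continue; // split needs an extra latent slot
          int l = PIdx[(int)std::floor(R::unif_rand() * PIdx.size())];
          int r = c.partner[l];
          int im = -1;
          for (int i = 0; i < n; ++i)
            if (c.inds[i].hists.size() == 2 && c.inds[i].hists[0] == l) im = i;
          Ind L, Rr;
          L.hists.push_back(l); Rr.hists.push_back(r);
          c.rebuildInd(L); c.rebuildInd(Rr);
          c.computeAInd(L, c.H0, c.H1, L.A);
          c.computeAInd(Rr, c.H0, c.H1, Rr.A);
          std::vector<double> lvL, lvR, lvM;
          c.llIndAll(L, L.A, c.H0, c.H1, c.G, del, alp, lvL);
          c.llIndAll(Rr, Rr.A, c.H0, c.H1, c.G, del, alp, lvR);
          c.llIndAll(c.inds[im], c.inds[im].A, c.H0, c.H1, c.G, del, alp, lvM);
          double margL = c.logSumExpVec(lvL) - std::log((double)c.S);
          double margR = c.logSumExpVec(lvR) - std::log((double)c.S);
          double margM = c.logSumExpVec(lvM) - std::log((double)c.S);
          bool canSplitAfter = PIdx.size() > 1;
          double pRev = canSplitAfter ? 0.5 : 1.0; // merge prob at new state
          double nULnew = (double)(UL.size() + 1), nURnew = (double)(UR.size() + 1);
          double lr = std::log((double)(c.N - n)) - c.logp0 +
                      margL + margR - margM +
                      std::log(pRev) - std::log(nULnew * nURnew) -
                      (std::log(pFwd) - std::log((double)PIdx.size()));
          if (std::log(R::unif_rand()) < lr) {
            L.cell = c.sampleFromLog(lvL); L.ll = lvL[L.cell];
            Rr.cell = c.sampleFromLog(lvR); Rr.ll = lvR[Rr.cell];
            c.inds.erase(c.inds.begin() + im);
            c.inds.push_back(L);
            c.inds.push_back(Rr);
            c.partner[l] = -1;
            ++accMat;
          }
        }
      }
    }

    if (updN) {
      int n = c.n_();
      int lo = std::max(n, 1);  // the 1/N prior is supported on [1, Nmax]
      std::vector<double> lw(c.Nmax - lo + 1);
      for (int NN = lo; NN <= c.Nmax; ++NN) {
        double v = c.lgt[NN] - c.lgt[NN - n] +
                   (NN == n ? 0.0 : (NN - n) * c.logp0);
        if (c.priorN == 0) v -= c.logNt[NN - 1];
        lw[NN - lo] = v;
      }
      c.N = lo + c.sampleFromLog(lw);
    }

    // adaptation of proposal scales (frozen after the adaptive phase)
    if (adapting) {
      ++winCount;
      if (winCount == win) {
        double step = 0.5;
        for (int k = 0; k < c.np; ++k) {
          if (tryP[k] > 0)
            sc[k] *= std::exp(step * ((double)accP[k] / tryP[k] - target));
          accP[k] = 0; tryP[k] = 0;
        }
        if (tryC > 0) {
          scCentre *= std::exp(step * ((double)accC / tryC - target));
          accC = 0; tryC = 0;
        }
        winCount = 0;
      }
    }

    // storage
    int sIter = iter - nAdapt;
    if (sIter >= nBurn && (sIter - nBurn) % thin == 0 && retIdx < nRet) {
      int n = c.n_();
      int col = 0;
      for (int k = 0; k < c.np; ++k) draws(retIdx, col++) = c.th[k];
      draws(retIdx, col++) = std::exp(c.th[c.idxLS]);
      draws(retIdx, col++) = 0.5 * plogis_(c.th[c.idxD]);
      draws(retIdx, col++) = plogis_(c.th[c.idxA]);
      draws(retIdx, col++) = c.N;
      draws(retIdx, col++) = n;
      draws(retIdx, col++) = c.M > 0 ? (double)n / c.M : 1.0;
      draws(retIdx, col++) = c.fullLogpost();
      if (storeLatent)
        for (int m = 0; m < c.M; ++m) latent(retIdx, m) = c.partner[m];
      if (storeCentresEvery > 0 && retIdx % storeCentresEvery == 0 &&
          centRow < nCentRows) {
        for (int i = 0; i < n; ++i)
          for (size_t q = 0; q < c.inds[i].hists.size(); ++q)
            centres(centRow, c.inds[i].hists[q]) = c.inds[i].cell;
        ++centRow;
      }
      ++retIdx;
    }
  }

  List accL = List::create(
    _["params"] = tryPTot > 0 ? (double)accPTot / tryPTot : NA_REAL,
    _["centres"] = tryCTot > 0 ? (double)accCTot / tryCTot : NA_REAL,
    _["matching"] = tryMat > 0 ? (double)accMat / tryMat : NA_REAL);

  NumericVector finalTh(c.th.begin(), c.th.end());
  IntegerVector finalPartner(c.partner.begin(), c.partner.end());
  IntegerVector finalCells(c.M);
  for (int i = 0; i < c.n_(); ++i)
    for (size_t q = 0; q < c.inds[i].hists.size(); ++q)
      finalCells[c.inds[i].hists[q]] = c.inds[i].cell;

  return List::create(_["draws"] = draws,
                      _["latent"] = latent,
                      _["centres"] = centres,
                      _["accept"] = accL,
                      _["scales"] = NumericVector(sc.begin(), sc.end()),
                      _["centreScale"] = scCentre,
                      _["finalParams"] = finalTh,
                      _["finalPartner"] = finalPartner,
                      _["finalCells"] = finalCells,
                      _["finalN"] = c.N);
}
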