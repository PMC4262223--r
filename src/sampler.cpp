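// Collapsed Gibbs samplers: hierarchical random-effects mixture (main model)
// and pooled Dirichlet-process Gaussian mixture (baseline).
//
// State is kept as sufficient statistics per local cluster plus per-class
// aggregates of the transformed cluster contributions, so every predictive
// evaluation is O(d^2) against a cached Cholesky factor of the class's
// posterior scale matrix.  All statistics are rebuilt from the assignment
// vectors at the start of every sweep, which bounds floating-point drift.
// The inner loops run on preallocated buffers; the dimensionality of
// cytometry panels is small (d <= ~10), so Cholesky factorisations are
// hand-rolled rather than delegated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Hyper {
  double alpha, gamma, kappa0, kappa1, m;
  vec mu0;
  mat Sigma0;
  int d;
  double logdetSigma0;
};

Hyper make_hyper(const Rcpp::List &hp) {
  Hyper h;
  h.alpha = hp["alpha"];
  h.gamma = hp["gamma"];
  h.kappa0 = hp["kappa0"];
  h.kappa1 = hp["kappa1"];
  h.m = hp["m"];
  h.mu0 = Rcpp::as<vec>(hp["mu0"]);
  h.Sigma0 = Rcpp::as<mat>(hp["Sigma0"]);
  h.d = h.mu0.n_elem;
  double sign;
  log_det(h.logdetSigma0, sign, h.Sigma0);
  return h;
}

double lmvgamma(double a, int d) {
  double v = d * (d - 1) / 4.0 * std::log(M_PI);
  for (int j = 1; j <= d; ++j) v += std::lgamma(a + (1.0 - j) / 2.0);
  return v;
}

// in-place upper Cholesky of column-major d x d matrix A (A = R'R)
// returns false if not positive definite; also returns log det(A)
bool chol_small(const double *A, double *R, int d, double &logdet) {
  logdet = 0.0;
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < d; ++i) R[j * d + i] = 0.0;
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= R[j * d + k] * R[j * d + k];
    if (s <= 0.0) return false;
    double rjj = std::sqrt(s);
    R[j * d + j] = rjj;
    logdet += 2.0 * std::log(rjj);
    for (int i = j + 1; i < d; ++i) {
      double t = A[i * d + j];
      for (int k = 0; k < j; ++k) t -= R[j * d + k] * R[i * d + k];
      R[i * d + j] = t / rjj;
    }
  }
  return true;
}

// q = (x - cen)' A^{-1} (x - cen) given upper Cholesky R of A, buffer z
double quadform_chol(const double *x, const double *cen, const double *R,
                     int d, double *z) {
  // forward substitution with R' (lower): note column-major R
  double q = 0.0;
  for (int i = 0; i < d; ++i) {
    double s = x[i] - cen[i];
    for (int k = 0; k < i; ++k) s -= R[i * d + k] * z[k];
    z[i] = s / R[i * d + i];
    q += z[i] * z[i];
  }
  return q;
}

// Student-t log density with scale (cc/dof) * Lambda; R = chol(Lambda)
double mvt_logdens_raw(const double *x, const double *cen, const double *R,
                       double logdetL, double cc, double dof, int d,
                       double *z) {
  double q = quadform_chol(x, cen, R, d, z);
  return std::lgamma((dof + d) / 2.0) - std::lgamma(dof / 2.0) -
         (d / 2.0) * std::log(dof * M_PI) -
         0.5 * (d * std::log(cc / dof) + logdetL) -
         ((dof + d) / 2.0) * std::log1p(q / cc);
}

int sample_log_weights(const std::vector<double> &lw, std::vector<double> &w) {
  double mx = -datum::inf;
  for (double v : lw) mx = std::max(mx, v);
  if (!std::isfinite(mx)) Rcpp::stop("all assignment weights are zero");
  w.resize(lw.size());
  double tot = 0;
  for (size_t i = 0; i < lw.size(); ++i) {
    w[i] = std::exp(lw[i] - mx);
    tot += w[i];
  }
  double u = unif_rand() * tot, acc = 0;
  for (size_t i = 0; i < lw.size(); ++i) {
    acc += w[i];
    if (u <= acc) return static_cast<int>(i);
  }
  return static_cast<int>(lw.size()) - 1;
}

std::string canonical_code(const std::vector<int> &labels) {
  std::map<int, int> seen;
  std::string out;
  int next = 1;
  for (int l : labels) {
    auto it = seen.find(l);
    int c;
    if (it == seen.end()) {
      c = next++;
      seen[l] = c;
    } else
      c = it->second;
    if (!out.empty()) out += '.';
    out += std::to_string(c);
  }
  return out;
}

std::vector<int> densify(const std::vector<int> &raw) {
  std::vector<int> lab(raw.size());
  std::map<int, int> dense;
  int next = 1;
  for (size_t i = 0; i < raw.size(); ++i) {
    auto it = dense.find(raw[i]);
    if (it == dense.end()) {
      dense[raw[i]] = next;
      lab[i] = next++;
    } else
      lab[i] = it->second;
  }
  return lab;
}

struct Cluster {
  int j = -1;  // sample index
  int k = -1;  // class index
  int n = 0;
  std::vector<double> sum;      // d
  std::vector<double> scatter;  // d*d column-major
  bool alive = false;
};

struct ClassK {
  int nclust = 0;  // local clusters across all samples (m_.k)
  int N = 0;       // events across all samples
  double W = 0;    // sum of effective weights ntil
  std::vector<double> V;  // d
  std::vector<double> M;  // d*d
  double logw = 0;
  bool alive = false;
  // lazily refreshed posterior cache
  bool dirty = true;
  double kappa_n = 0, m_n = 0, logdetL = 0, marg = 0;
  std::vector<double> mu_n;  // d
  std::vector<double> R;     // d*d upper Cholesky of Lambda
};

class DpgmmSampler {
public:
  DpgmmSampler(const mat &Xin, const Hyper &hyp) : h(hyp) {
    Xt = Xin.t();
    Ntot = Xt.n_cols;
    d = h.d;
    assign.assign(Ntot, -1);
    zbuf.assign(d, 0.0);
    Lbuf.assign(d * d, 0.0);
    prior.sum.assign(d, 0.0);
    prior.scatter.assign(d * d, 0.0);
    prior.alive = true;
    refresh(prior);
    lg_m = lmvgamma(h.m / 2.0, d);
  }

  Hyper h;
  mat Xt;
  int Ntot, d;
  std::vector<int> assign;
  struct Cl {
    int n = 0;
    std::vector<double> sum, scatter;
    bool alive = false;
    bool dirty = true;
    double kappa_n = 0, m_n = 0, logdetL = 0;
    std::vector<double> mu_n, R;
  };
  std::vector<Cl> cls;
  Cl prior;
  double lg_m;
  std::vector<double> zbuf, Lbuf, lw_, wbuf_;
  std::vector<int> cand_;

  const double *event(int i) const { return Xt.colptr(i); }

  // plain NIW posterior for one cluster: kappa_n = kappa0 + n,
  // Lambda = Sigma0 + scatter + kappa0 mu0 mu0' - kappa_n mu_n mu_n'
  void refresh(Cl &c) {
    if (!c.dirty && c.alive) return;
    c.kappa_n = h.kappa0 + c.n;
    c.mu_n.resize(d);
    c.R.resize(d * d);
    for (int i = 0; i < d; ++i)
      c.mu_n[i] = (h.kappa0 * h.mu0[i] + c.sum[i]) / c.kappa_n;
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        Lbuf[cix * d + rix] = h.Sigma0(rix, cix) + c.scatter[cix * d + rix] +
                              h.kappa0 * h.mu0[rix] * h.mu0[cix] -
                              c.kappa_n * c.mu_n[rix] * c.mu_n[cix];
    if (!chol_small(Lbuf.data(), c.R.data(), d, c.logdetL))
      Rcpp::stop("numerical breakdown: posterior scale not positive definite");
    c.m_n = h.m + c.n;
    c.dirty = false;
  }

  double logpred(const double *x, Cl &c) {
    refresh(c);
    double cc = 1.0 + 1.0 / c.kappa_n;
    return mvt_logdens_raw(x, c.mu_n.data(), c.R.data(), c.logdetL, cc,
                           c.m_n - d + 1, d, zbuf.data());
  }

  void add_point(int i, int cid) {
    Cl &c = cls[cid];
    const double *x = event(i);
    c.n += 1;
    for (int a = 0; a < d; ++a) c.sum[a] += x[a];
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        c.scatter[cix * d + rix] += x[rix] * x[cix];
    c.dirty = true;
    assign[i] = cid;
  }

  void remove_point(int i) {
    Cl &c = cls[assign[i]];
    const double *x = event(i);
    c.n -= 1;
    for (int a = 0; a < d; ++a) c.sum[a] -= x[a];
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        c.scatter[cix * d + rix] -= x[rix] * x[cix];
    c.dirty = true;
    if (c.n == 0) c.alive = false;
    assign[i] = -1;
  }

  void assign_event(int i) {
    const double *x = event(i);
    lw_.clear();
    cand_.clear();
    for (size_t c = 0; c < cls.size(); ++c) {
      if (!cls[c].alive) continue;
      cand_.push_back(static_cast<int>(c));
      lw_.push_back(std::log(static_cast<double>(cls[c].n)) +
                    logpred(x, cls[c]));
    }
    cand_.push_back(-1);
    if (cand_.size() == 1)
      lw_.push_back(0.0);
    else
      lw_.push_back((h.alpha > 0 ? std::log(h.alpha) : -datum::inf) +
                    logpred(x, prior));
    int pick = sample_log_weights(lw_, wbuf_);
    int cid = cand_[pick];
    if (cid < 0) {
      Cl c;
      c.sum.assign(d, 0.0);
      c.scatter.assign(d * d, 0.0);
      c.alive = true;
      cls.push_back(c);
      cid = static_cast<int>(cls.size()) - 1;
    }
    add_point(i, cid);
  }

  void rebuild() {
    std::vector<int> cmap(cls.size(), -1);
    std::vector<Cl> nc;
    for (size_t c = 0; c < cls.size(); ++c) {
      if (!cls[c].alive) continue;
      cmap[c] = static_cast<int>(nc.size());
      Cl x;
      x.sum.assign(d, 0.0);
      x.scatter.assign(d * d, 0.0);
      x.alive = true;
      nc.push_back(x);
    }
    cls.swap(nc);
    for (int i = 0; i < Ntot; ++i) {
      assign[i] = cmap[assign[i]];
      Cl &c = cls[assign[i]];
      const double *x = event(i);
      c.n += 1;
      for (int a = 0; a < d; ++a) c.sum[a] += x[a];
      for (int cix = 0; cix < d; ++cix)
        for (int rix = 0; rix < d; ++rix)
          c.scatter[cix * d + rix] += x[rix] * x[cix];
    }
  }

  void sweep() {
    rebuild();
    for (int i = 0; i < Ntot; ++i) {
      remove_point(i);
      assign_event(i);
    }
  }

  // plain NIW marginal likelihood of one cluster's data
  double cluster_marg(Cl &c) {
    if (c.n == 0) return 0.0;
    refresh(c);
    double m_n = h.m + c.n;
    return -(c.n * d / 2.0) * std::log(M_PI) +
           (d / 2.0) * std::log(h.kappa0 / c.kappa_n) +
           lmvgamma(m_n / 2.0, d) - lg_m + (h.m / 2.0) * h.logdetSigma0 -
           (m_n / 2.0) * c.logdetL;
  }

  double total_marg() {
    double s = 0;
    for (auto &c : cls)
      if (c.alive) s += cluster_marg(c);
    return s;
  }

  std::vector<int> labels() { return densify(assign); }

  int K() {
    int k = 0;
    for (auto &c : cls)
      if (c.alive) ++k;
    return k;
  }
};

// ------------------------------------------------------------------------
// Hierarchical sampler
// ------------------------------------------------------------------------

class AspireSampler {
public:
  AspireSampler(const Rcpp::List &batch, const Rcpp::List &hp, bool strict)
      : h(make_hyper(hp)), strict_(strict) {
    J = batch.size();
    mat X;
    for (int j = 0; j < J; ++j) {
      mat Xj = Rcpp::as<mat>(batch[j]);
      offset.push_back(static_cast<int>(X.n_rows));
      nj.push_back(static_cast<int>(Xj.n_rows));
      X = join_cols(X, Xj);
    }
    Ntot = X.n_rows;
    Xt = X.t();  // d x N, events contiguous
    d = h.d;
    tassign.assign(Ntot, -1);
    by_sample.assign(J, {});
    zbuf.assign(d, 0.0);
    cenbuf.assign(d, 0.0);
    xbarbuf.assign(d, 0.0);
    Lbuf.assign(d * d, 0.0);
    // prior cache (empty class)
    prior.V.assign(d, 0.0);
    prior.M.assign(d * d, 0.0);
    prior.alive = true;
    refresh(prior);
    lg_m = lmvgamma(h.m / 2.0, d);
  }

  Hyper h;
  int J = 0, Ntot = 0, d = 0;
  mat Xt;
  std::vector<int> offset, nj;
  std::vector<int> tassign;
  std::vector<Cluster> clusters;
  std::vector<ClassK> classes;
  std::vector<std::vector<int>> by_sample;
  int total_clusters = 0;  // m_..
  ClassK prior;
  double lg_m = 0;
  bool strict_;
  int cur_strict_k = -1;
  // scratch
  std::vector<double> zbuf, cenbuf, xbarbuf, Lbuf;
  std::vector<double> lw_, wbuf_;
  std::vector<int> cand_, kid_;
  std::vector<double> klw_;

  const double *event(int i) const { return Xt.colptr(i); }

  void refresh(ClassK &C) {
    if (!C.dirty && C.alive) return;
    C.kappa_n = h.kappa0 + C.W;
    C.mu_n.resize(d);
    C.R.resize(d * d);
    for (int i = 0; i < d; ++i)
      C.mu_n[i] = (h.kappa0 * h.mu0[i] + C.V[i]) / C.kappa_n;
    // Lambda = Sigma0 + M + kappa0 mu0 mu0' - kappa_n mu_n mu_n'
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        Lbuf[cix * d + rix] = h.Sigma0(rix, cix) + C.M[cix * d + rix] +
                              h.kappa0 * h.mu0[rix] * h.mu0[cix] -
                              C.kappa_n * C.mu_n[rix] * C.mu_n[cix];
    if (!chol_small(Lbuf.data(), C.R.data(), d, C.logdetL))
      Rcpp::stop("numerical breakdown: posterior scale not positive definite");
    C.m_n = h.m + C.N;
    C.marg = (C.N == 0) ? 0.0
             : -(C.N * d / 2.0) * std::log(M_PI) + C.logw +
               (d / 2.0) * std::log(h.kappa0 / C.kappa_n) +
               lmvgamma(C.m_n / 2.0, d) - lg_m +
               (h.m / 2.0) * h.logdetSigma0 - (C.m_n / 2.0) * C.logdetL;
    C.dirty = false;
  }

  void class_add_contrib(ClassK &C, const Cluster &cl, double sgn) {
    double n = cl.n;
    double ntil = n * h.kappa1 / (n + h.kappa1);
    C.N += static_cast<int>(sgn) * cl.n;
    C.W += sgn * ntil;
    for (int i = 0; i < d; ++i) xbarbuf[i] = cl.sum[i] / n;
    for (int i = 0; i < d; ++i) C.V[i] += sgn * ntil * xbarbuf[i];
    double nshr = n - ntil;
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        C.M[cix * d + rix] +=
            sgn * (cl.scatter[cix * d + rix] - nshr * xbarbuf[rix] * xbarbuf[cix]);
    C.logw += sgn * (d / 2.0) * std::log(h.kappa1 / (h.kappa1 + n));
    C.dirty = true;
  }

  int new_class() {
    ClassK C;
    C.V.assign(d, 0.0);
    C.M.assign(d * d, 0.0);
    C.alive = true;
    classes.push_back(C);
    return static_cast<int>(classes.size()) - 1;
  }

  int new_cluster(int j, int k) {
    Cluster cl;
    cl.j = j;
    cl.k = k;
    cl.sum.assign(d, 0.0);
    cl.scatter.assign(d * d, 0.0);
    cl.alive = true;
    clusters.push_back(cl);
    int id = static_cast<int>(clusters.size()) - 1;
    by_sample[j].push_back(id);
    classes[k].nclust += 1;
    total_clusters += 1;
    return id;
  }

  void drop_cluster(int cid) {
    Cluster &cl = clusters[cid];
    cl.alive = false;
    auto &v = by_sample[cl.j];
    v.erase(std::remove(v.begin(), v.end(), cid), v.end());
    ClassK &C = classes[cl.k];
    C.nclust -= 1;
    total_clusters -= 1;
    if (C.N == 0 && C.nclust == 0) C.alive = false;
  }

  void add_point(int i, int cid) {
    Cluster &cl = clusters[cid];
    ClassK &C = classes[cl.k];
    if (cl.n > 0) class_add_contrib(C, cl, -1.0);
    const double *x = event(i);
    cl.n += 1;
    for (int a = 0; a < d; ++a) cl.sum[a] += x[a];
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        cl.scatter[cix * d + rix] += x[rix] * x[cix];
    class_add_contrib(C, cl, +1.0);
    tassign[i] = cid;
  }

  void remove_point(int i) {
    int cid = tassign[i];
    Cluster &cl = clusters[cid];
    ClassK &C = classes[cl.k];
    class_add_contrib(C, cl, -1.0);
    const double *x = event(i);
    cl.n -= 1;
    for (int a = 0; a < d; ++a) cl.sum[a] -= x[a];
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        cl.scatter[cix * d + rix] -= x[rix] * x[cix];
    if (cl.n > 0)
      class_add_contrib(C, cl, +1.0);
    else
      drop_cluster(cid);
    tassign[i] = -1;
  }

  double logpred_join(const double *x, const Cluster &cl, ClassK &C) {
    refresh(C);
    double n = cl.n;
    double w = h.kappa1 / (h.kappa1 + n);
    for (int i = 0; i < d; ++i)
      cenbuf[i] = w * C.mu_n[i] + (1.0 - w) * cl.sum[i] / n;
    double cc = 1.0 + 1.0 / (h.kappa1 + n) + w * w / C.kappa_n;
    return mvt_logdens_raw(x, cenbuf.data(), C.R.data(), C.logdetL, cc,
                           C.m_n - d + 1, d, zbuf.data());
  }

  double logpred_new_in_class(const double *x, ClassK &C) {
    refresh(C);
    double cc = 1.0 + 1.0 / h.kappa1 + 1.0 / C.kappa_n;
    return mvt_logdens_raw(x, C.mu_n.data(), C.R.data(), C.logdetL, cc,
                           C.m_n - d + 1, d, zbuf.data());
  }

  // class weights for a single point opening a new local cluster:
  // log(m_.k) + classpred_k, and log(gamma) + prior predictive
  void point_class_weights(const double *x) {
    kid_.clear();
    klw_.clear();
    for (size_t k = 0; k < classes.size(); ++k) {
      if (!classes[k].alive || classes[k].N == 0) continue;
      kid_.push_back(static_cast<int>(k));
      klw_.push_back(std::log(static_cast<double>(classes[k].nclust)) +
                     logpred_new_in_class(x, classes[k]));
    }
    kid_.push_back(-1);
    klw_.push_back((h.gamma > 0 ? std::log(h.gamma) : -datum::inf) +
                   logpred_new_in_class(x, prior));
  }

  // assign a currently unassigned event (used by both init and the t-loop)
  void assign_event(int i, int j) {
    const double *x = event(i);
    lw_.clear();
    cand_.clear();
    for (int cid : by_sample[j]) {
      Cluster &cl = clusters[cid];
      if (strict_ && cur_strict_k >= 0 && cl.k != cur_strict_k) continue;
      cand_.push_back(cid);
      lw_.push_back(std::log(static_cast<double>(cl.n)) +
                    logpred_join(x, cl, classes[cl.k]));
    }
    if (strict_ && cur_strict_k >= 0 && classes[cur_strict_k].alive) {
      kid_.assign(1, cur_strict_k);
      klw_.assign(1, logpred_new_in_class(x, classes[cur_strict_k]));
    } else {
      point_class_weights(x);
    }
    // mixture over the class of the would-be new cluster; the class weights
    // m_.k and gamma must be normalised by (m_.. + gamma) so the new-cluster
    // likelihood is a proper density
    double mix = -datum::inf;
    for (double v : klw_) mix = std::max(mix, v);
    if (std::isfinite(mix)) {
      double s = 0;
      for (double v : klw_) s += std::exp(v - mix);
      mix += std::log(s);
    }
    if (!(strict_ && cur_strict_k >= 0))
      mix -= std::log(static_cast<double>(total_clusters) + h.gamma);
    double la = (h.alpha > 0) ? std::log(h.alpha) : -datum::inf;
    cand_.push_back(-1);
    if (cand_.size() == 1)
      lw_.push_back(0.0);  // no existing cluster: a new one is forced
    else
      lw_.push_back(la + mix);
    int pick = sample_log_weights(lw_, wbuf_);
    int cid;
    if (cand_[pick] >= 0) {
      cid = cand_[pick];
    } else {
      int k = (kid_.size() == 1) ? kid_[0] : kid_[sample_log_weights(klw_, wbuf_)];
      if (k < 0) k = new_class();
      cid = new_cluster(j, k);
    }
    add_point(i, cid);
  }

  void t_step(int i, int j) {
    if (strict_) cur_strict_k = clusters[tassign[i]].k;
    remove_point(i);
    if (strict_ && cur_strict_k >= 0 && !classes[cur_strict_k].alive)
      cur_strict_k = -1;
    assign_event(i, j);
    cur_strict_k = -1;
  }

  // marginal of aggregates (N, W, V, M, logw) without touching any cache
  double marg_raw(int N, double W, const std::vector<double> &V,
                  const std::vector<double> &M, double logw) {
    if (N == 0) return 0.0;
    double kappa_n = h.kappa0 + W;
    for (int i = 0; i < d; ++i)
      cenbuf[i] = (h.kappa0 * h.mu0[i] + V[i]) / kappa_n;
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        Lbuf[cix * d + rix] = h.Sigma0(rix, cix) + M[cix * d + rix] +
                              h.kappa0 * h.mu0[rix] * h.mu0[cix] -
                              kappa_n * cenbuf[rix] * cenbuf[cix];
    double logdetL;
    std::vector<double> R(d * d);
    if (!chol_small(Lbuf.data(), R.data(), d, logdetL))
      Rcpp::stop("numerical breakdown: posterior scale not positive definite");
    double m_n = h.m + N;
    return -(N * d / 2.0) * std::log(M_PI) + logw +
           (d / 2.0) * std::log(h.kappa0 / kappa_n) +
           lmvgamma(m_n / 2.0, d) - lg_m + (h.m / 2.0) * h.logdetSigma0 -
           (m_n / 2.0) * logdetL;
  }

  void c_step(int cid) {
    Cluster &cl = clusters[cid];
    if (!cl.alive || cl.n == 0) return;
    int k0 = cl.k;
    {
      ClassK &C0 = classes[k0];
      class_add_contrib(C0, cl, -1.0);
      C0.nclust -= 1;
      total_clusters -= 1;
      if (C0.N == 0 && C0.nclust == 0) C0.alive = false;
    }
    kid_.clear();
    lw_.clear();
    std::vector<double> Vtmp(d), Mtmp(d * d);
    for (size_t k = 0; k < classes.size(); ++k) {
      ClassK &C = classes[k];
      if (!C.alive) continue;
      refresh(C);
      // aggregates with this cluster attached
      int N = C.N;
      double W = C.W, logw = C.logw;
      Vtmp = C.V;
      Mtmp = C.M;
      attach_tmp(N, W, Vtmp, Mtmp, logw, cl);
      double aug = marg_raw(N, W, Vtmp, Mtmp, logw);
      kid_.push_back(static_cast<int>(k));
      lw_.push_back(std::log(static_cast<double>(C.nclust)) + (aug - C.marg));
    }
    {
      int N = 0;
      double W = 0, logw = 0;
      std::fill(Vtmp.begin(), Vtmp.end(), 0.0);
      std::fill(Mtmp.begin(), Mtmp.end(), 0.0);
      attach_tmp(N, W, Vtmp, Mtmp, logw, cl);
      kid_.push_back(-1);
      double lnew = (h.gamma > 0 ? std::log(h.gamma) : -datum::inf) +
                    marg_raw(N, W, Vtmp, Mtmp, logw);
      lw_.push_back(kid_.size() == 1 ? 0.0 : lnew);
    }
    int k = kid_[sample_log_weights(lw_, wbuf_)];
    if (k < 0) k = new_class();
    cl.k = k;
    classes[k].alive = true;
    classes[k].nclust += 1;
    total_clusters += 1;
    class_add_contrib(classes[k], cl, +1.0);
  }

  void attach_tmp(int &N, double &W, std::vector<double> &V,
                  std::vector<double> &M, double &logw, const Cluster &cl) {
    double n = cl.n;
    double ntil = n * h.kappa1 / (n + h.kappa1);
    N += cl.n;
    W += ntil;
    for (int i = 0; i < d; ++i) xbarbuf[i] = cl.sum[i] / n;
    for (int i = 0; i < d; ++i) V[i] += ntil * xbarbuf[i];
    double nshr = n - ntil;
    for (int cix = 0; cix < d; ++cix)
      for (int rix = 0; rix < d; ++rix)
        M[cix * d + rix] += cl.scatter[cix * d + rix] -
                            nshr * xbarbuf[rix] * xbarbuf[cix];
    logw += (d / 2.0) * std::log(h.kappa1 / (h.kappa1 + n));
  }

  // rebuild all statistics from the assignment vector; compacts dead slots
  void rebuild() {
    std::vector<int> cmap(clusters.size(), -1), kmap(classes.size(), -1);
    std::vector<Cluster> ncl;
    std::vector<ClassK> nk;
    for (size_t c = 0; c < clusters.size(); ++c) {
      if (!clusters[c].alive) continue;
      int k = clusters[c].k;
      if (kmap[k] < 0) {
        kmap[k] = static_cast<int>(nk.size());
        ClassK C;
        C.V.assign(d, 0.0);
        C.M.assign(d * d, 0.0);
        C.alive = true;
        nk.push_back(C);
      }
      cmap[c] = static_cast<int>(ncl.size());
      Cluster x;
      x.j = clusters[c].j;
      x.k = kmap[k];
      x.sum.assign(d, 0.0);
      x.scatter.assign(d * d, 0.0);
      x.alive = true;
      ncl.push_back(x);
    }
    clusters.swap(ncl);
    classes.swap(nk);
    for (int i = 0; i < Ntot; ++i) {
      tassign[i] = cmap[tassign[i]];
      Cluster &cl = clusters[tassign[i]];
      const double *x = event(i);
      cl.n += 1;
      for (int a = 0; a < d; ++a) cl.sum[a] += x[a];
      for (int cix = 0; cix < d; ++cix)
        for (int rix = 0; rix < d; ++rix)
          cl.scatter[cix * d + rix] += x[rix] * x[cix];
    }
    total_clusters = 0;
    for (auto &v : by_sample) v.clear();
    for (size_t c = 0; c < clusters.size(); ++c) {
      by_sample[clusters[c].j].push_back(static_cast<int>(c));
      classes[clusters[c].k].nclust += 1;
      class_add_contrib(classes[clusters[c].k], clusters[c], +1.0);
      total_clusters += 1;
    }
  }

  void sweep() {
    rebuild();
    for (int j = 0; j < J; ++j)
      for (int i = offset[j]; i < offset[j] + nj[j]; ++i) t_step(i, j);
    size_t ncl = clusters.size();  // clusters created mid-loop keep their class
    for (size_t c = 0; c < ncl; ++c) c_step(static_cast<int>(c));
  }

  void init(const std::string &mode) {
    if (mode == "single") {
      new_class();
      for (int j = 0; j < J; ++j) {
        int cid = new_cluster(j, 0);
        for (int i = offset[j]; i < offset[j] + nj[j]; ++i) add_point(i, cid);
      }
    } else if (mode == "dpgmm") {
      init_dpgmm();
    } else {
      for (int j = 0; j < J; ++j)
        for (int i = offset[j]; i < offset[j] + nj[j]; ++i) assign_event(i, j);
    }
  }

  // Warm start: fit a plain DP Gaussian mixture within each sample to seed
  // coherent local clusters (each starting in its own class), then let the
  // class-assignment step coalesce classes across samples before the first
  // full sweep.  Incremental Gibbs started from scattered assignments can
  // lodge in a metastable mode where within-cluster variance is re-explained
  // as random-effects displacement of many small clusters; seeding whole
  // local clusters avoids that basin.
  void init_dpgmm(int init_sweeps = 25, int c_passes = 3) {
    for (int j = 0; j < J; ++j) {
      mat Xj = Xt.cols(offset[j], offset[j] + nj[j] - 1).t();
      DpgmmSampler S(Xj, h);
      for (int i = 0; i < S.Ntot; ++i) S.assign_event(i);
      for (int s = 0; s < init_sweeps; ++s) S.sweep();
      std::vector<int> lab = S.labels();
      int nlab = *std::max_element(lab.begin(), lab.end());
      std::vector<int> cids(nlab);
      for (int t = 0; t < nlab; ++t) cids[t] = new_cluster(j, new_class());
      for (int i = 0; i < nj[j]; ++i)
        add_point(offset[j] + i, cids[lab[i] - 1]);
    }
    for (int p = 0; p < c_passes; ++p) {
      size_t ncl = clusters.size();
      for (size_t c = 0; c < ncl; ++c) c_step(static_cast<int>(c));
    }
  }

  int n_alive_classes() {
    int K = 0;
    for (auto &C : classes)
      if (C.alive && C.N > 0) ++K;
    return K;
  }

  double total_marg() {
    double s = 0;
    for (auto &C : classes)
      if (C.alive && C.N > 0) {
        refresh(C);
        s += C.marg;
      }
    return s;
  }

  std::vector<int> class_labels() {
    std::vector<int> raw(Ntot);
    for (int i = 0; i < Ntot; ++i) raw[i] = clusters[tassign[i]].k;
    return densify(raw);
  }

  std::vector<int> cluster_labels() { return densify(tassign); }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_aspire_gibbs")]]
Rcpp::List cpp_aspire_gibbs(Rcpp::List batch, Rcpp::List hp, int n_sweeps,
                            int burn_in, int thin, int n_saved,
                            std::string init, bool strict,
                            bool trace_partitions) {
  AspireSampler S(batch, hp, strict);
  S.init(init);

  Rcpp::IntegerVector trace_K(n_sweeps);
  Rcpp::NumericVector trace_ll(n_sweeps);
  Rcpp::IntegerVector trace_nclust(n_sweeps);
  std::vector<std::string> part_t, part_c;
  Rcpp::List saved_c, saved_t;
  std::vector<double> saved_ll;

  for (int s = 1; s <= n_sweeps; ++s) {
    S.sweep();
    trace_K[s - 1] = S.n_alive_classes();
    trace_ll[s - 1] = S.total_marg();
    trace_nclust[s - 1] = S.total_clusters;
    if (trace_partitions) {
      part_t.push_back(canonical_code(S.cluster_labels()));
      part_c.push_back(canonical_code(S.class_labels()));
    }
    if (s > burn_in && (s - burn_in) % thin == 0 &&
        static_cast<int>(saved_c.size()) < n_saved) {
      saved_c.push_back(Rcpp::wrap(S.class_labels()));
      saved_t.push_back(Rcpp::wrap(S.cluster_labels()));
      saved_ll.push_back(S.total_marg());
    }
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("saved_class_labels") = saved_c,
      Rcpp::Named("saved_cluster_labels") = saved_t,
      Rcpp::Named("saved_loglik") = Rcpp::wrap(saved_ll),
      Rcpp::Named("final_class_labels") = Rcpp::wrap(S.class_labels()),
      Rcpp::Named("final_cluster_labels") = Rcpp::wrap(S.cluster_labels()),
      Rcpp::Named("trace_K") = trace_K,
      Rcpp::Named("trace_loglik") = trace_ll,
      Rcpp::Named("trace_nclusters") = trace_nclust);
  if (trace_partitions) {
    out["partition_t"] = Rcpp::wrap(part_t);
    out["partition_c"] = Rcpp::wrap(part_c);
  }
  return out;
}

// ------------------------------------------------------------------------
// Pooled DPGMM baseline: one CRP over pooled events, plain NIW predictives
// ------------------------------------------------------------------------



// [[Rcpp::export(name = ".cpp_dpgmm_gibbs")]]
Rcpp::List cpp_dpgmm_gibbs(arma::mat X, Rcpp::List hp, int n_sweeps,
                           int burn_in, int thin, int n_saved,
                           bool trace_partitions) {
  DpgmmSampler S(X, make_hyper(hp));
  for (int i = 0; i < S.Ntot; ++i) S.assign_event(i);

  Rcpp::IntegerVector trace_K(n_sweeps);
  Rcpp::NumericVector trace_ll(n_sweeps);
  std::vector<std::string> part;
  Rcpp::List saved;
  std::vector<double> saved_ll;
  for (int s = 1; s <= n_sweeps; ++s) {
    S.sweep();
    trace_K[s - 1] = S.K();
    trace_ll[s - 1] = S.total_marg();
    if (trace_partitions) part.push_back(canonical_code(S.labels()));
    if (s > burn_in && (s - burn_in) % thin == 0 &&
        static_cast<int>(saved.size()) < n_saved) {
      saved.push_back(Rcpp::wrap(S.labels()));
      saved_ll.push_back(S.total_marg());
    }
    if (s % 200 == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("saved_class_labels") = saved,
      Rcpp::Named("saved_loglik") = Rcpp::wrap(saved_ll),
      Rcpp::Named("final_class_labels") = Rcpp::wrap(S.labels()),
      Rcpp::Named("trace_K") = trace_K,
      Rcpp::Named("trace_loglik") = trace_ll);
  if (trace_partitions) out["partition_t"] = Rcpp::wrap(part);
  return out;
}
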