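// Felsenstein pruning engine for the Goldman-Yang branch-site mixture.
//
// The rate matrix Q over the 61 sense codons has q_ij = pi_j * kappa^[ts] *
// omega^[nonsyn] for single-nucleotide neighbours, 0 otherwise. Q is
// time-reversible, so P(t) = exp(Qt) is computed through the symmetrized
// eigendecomposition D^{1/2} Q D^{-1/2} (D = diag(pi)). Branch lengths are
// expected substitutions per codon: each branch type (background /
// foreground) carries one scaling constant, the class-proportion-weighted
// mean substitution rate of that type's omega set.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const int NC = 61;

struct PairTable {
  ivec i, j;        // 0-based sense-codon indices
  ivec ts, ns;      // transition / non-synonymous flags
};

static PairTable as_pairs(const Rcpp::List& pr) {
  PairTable p;
  p.i  = Rcpp::as<ivec>(pr["i"]);
  p.j  = Rcpp::as<ivec>(pr["j"]);
  p.ts = Rcpp::as<ivec>(pr["ts"]);
  p.ns = Rcpp::as<ivec>(pr["ns"]);
  return p;
}

// expected substitution rate of the *unscaled* Q at stationarity
static double rate_away(double kappa, double omega, const vec& pi,
                        const PairTable& pr) {
  double r = 0.0;
  for (uword k = 0; k < pr.i.n_elem; ++k) {
    double mult = (pr.ts[k] ? kappa : 1.0) * (pr.ns[k] ? omega : 1.0);
    r += 2.0 * pi[pr.i[k]] * pi[pr.j[k]] * mult;
  }
  return r;
}

struct Eig {
  mat V1, V2;  // P(t) = V1 diag(exp(lambda t)) V2
  vec lambda;
};

static Eig eig_gy(double kappa, double omega, const vec& pi,
                  const PairTable& pr) {
  mat Q(NC, NC, fill::zeros);
  for (uword k = 0; k < pr.i.n_elem; ++k) {
    int a = pr.i[k], b = pr.j[k];
    double mult = (pr.ts[k] ? kappa : 1.0) * (pr.ns[k] ? omega : 1.0);
    Q(a, b) = pi[b] * mult;
    Q(b, a) = pi[a] * mult;
  }
  Q.diag() = -sum(Q, 1);
  vec sq = sqrt(pi);
  mat B = Q;
  B.each_col() %= sq;        // row i * sqrt(pi_i)
  B.each_row() /= sq.t();    // col j / sqrt(pi_j)
  B = 0.5 * (B + B.t());
  Eig e;
  mat U;
  eig_sym(e.lambda, U, B);
  e.V1 = U;  e.V1.each_col() /= sq;
  e.V2 = U.t();  e.V2.each_row() %= sq.t();
  return e;
}

static mat pmat(const Eig& e, double t) {
  if (t <= 0.0) return eye(NC, NC);
  mat P = e.V1;
  P.each_row() %= exp(e.lambda.t() * t);
  P = P * e.V2;
  P.clamp(0.0, datum::inf);   // kill eigen-roundoff negatives
  return P;
}

// log site likelihood per pattern for one set of per-edge P matrices
static rowvec prune_log_sitelik(const std::vector<const mat*>& P,
                                const imat& tipstate,
                                const ivec& parent, const ivec& child,
                                int ntip, int nnode, int root,
                                const vec& pi) {
  const int npat = tipstate.n_cols;
  std::vector<mat> partial(nnode + 1);
  std::vector<rowvec> logoff(nnode + 1);
  std::vector<bool> started(nnode + 1, false);

  for (uword e = 0; e < parent.n_elem; ++e) {
    int pa = parent[e], ch = child[e];
    mat M(NC, npat);
    rowvec off;
    if (ch <= ntip) {
      for (int s = 0; s < npat; ++s) {
        int st = tipstate(ch - 1, s);
        if (st < 0) M.col(s).ones();
        else        M.col(s) = P[e]->col(st);
      }
      off = rowvec(npat, fill::zeros);
    } else {
      M = (*P[e]) * partial[ch];
      off = logoff[ch];
    }
    if (!started[pa]) {
      partial[pa] = std::move(M);
      logoff[pa] = std::move(off);
      started[pa] = true;
    } else {
      partial[pa] %= M;
      logoff[pa] += off;
    }
    rowvec mx = max(partial[pa], 0);
    for (int s = 0; s < npat; ++s) {
      if (mx[s] > 0 && mx[s] != 1.0) {
        partial[pa].col(s) /= mx[s];
        logoff[pa][s] += std::log(mx[s]);
      }
    }
  }
  rowvec out(npat);
  for (int s = 0; s < npat; ++s) {
    double lik = dot(pi, partial[root].col(s));
    out[s] = lik > 0 ? std::log(lik) + logoff[root][s] : -datum::inf;
  }
  return out;
}

// Assemble per-edge P pointers for one (background omega, foreground omega)
// class combo from a cache of decompositions.
static void fill_P(std::vector<mat>& store, std::vector<const mat*>& ptrs,
                   const Eig& ebg, const Eig& efg,
                   const vec& tlen, const ivec& is_fg,
                   double sbg, double sfg) {
  const uword ne = tlen.n_elem;
  store.clear(); store.reserve(ne);
  ptrs.assign(ne, nullptr);
  for (uword e = 0; e < ne; ++e) {
    if (is_fg[e]) store.push_back(pmat(efg, tlen[e] / sfg));
    else          store.push_back(pmat(ebg, tlen[e] / sbg));
  }
  for (uword e = 0; e < ne; ++e) ptrs[e] = &store[e];
}

// [[Rcpp::export]]
Rcpp::List cpp_branch_site_loglik(double kappa, double w0, double w2,
                                  double p0, double p1,
                                  const arma::vec& pi,
                                  const Rcpp::List& pairs,
                                  const arma::ivec& parent,
                                  const arma::ivec& child,
                                  const arma::vec& tlen,
                                  const arma::ivec& is_fg,
                                  int ntip, int nnode, int root,
                                  const arma::imat& tipstate,
                                  const arma::vec& patwt,
                                  bool site_values = false) {
  PairTable pr = as_pairs(pairs);
  double psum = p0 + p1;
  double p2a = (1.0 - psum) * p0 / psum;
  double p2b = (1.0 - psum) * p1 / psum;
  vec props = {p0, p1, p2a, p2b};
  // class omegas: background (w0, 1, w0, 1); foreground (w0, 1, w2, w2)
  vec wbg = {w0, 1.0, w0, 1.0}, wfg = {w0, 1.0, w2, w2};
  double sbg = 0.0, sfg = 0.0;
  double r_w0 = rate_away(kappa, w0, pi, pr);
  double r_1  = rate_away(kappa, 1.0, pi, pr);
  double r_w2 = rate_away(kappa, w2, pi, pr);
  vec rates = {r_w0, r_1, r_w2};
  auto ridx = [&](double w) { return w == w0 ? 0 : (w == 1.0 ? 1 : 2); };
  for (int c = 0; c < 4; ++c) {
    sbg += props[c] * rates[ridx(wbg[c])];
    sfg += props[c] * rates[ridx(wfg[c])];
  }
  Eig e_w0 = eig_gy(kappa, w0, pi, pr);
  Eig e_1  = eig_gy(kappa, 1.0, pi, pr);
  Eig e_w2 = eig_gy(kappa, w2, pi, pr);
  const Eig* eigs[3] = {&e_w0, &e_1, &e_w2};

  const int npat = tipstate.n_cols;
  mat class_ls(4, npat);
  std::vector<mat> store;
  std::vector<const mat*> ptrs;
  for (int c = 0; c < 4; ++c) {
    fill_P(store, ptrs, *eigs[ridx(wbg[c])], *eigs[ridx(wfg[c])],
           tlen, is_fg, sbg, sfg);
    class_ls.row(c) = prune_log_sitelik(ptrs, tipstate, parent, child,
                                        ntip, nnode, root, pi);
  }
  vec lp = log(props);
  rowvec site_log(npat);
  for (int s = 0; s < npat; ++s) {
    vec v = class_ls.col(s) + lp;
    double m = v.max();
    site_log[s] = std::isfinite(m) ? m + std::log(sum(exp(v - m))) : m;
  }
  double lnL = dot(patwt, site_log);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("lnL") = lnL,
                                      Rcpp::Named("scale_bg") = sbg,
                                      Rcpp::Named("scale_fg") = sfg);
  if (site_values) {
    out["site_log"] = site_log;
    out["class_site_log"] = class_ls;
  }
  return out;
}

// Per-pattern log site likelihood for a single (bg, fg) omega pair with
// given branch-type scaling constants. Used by the M0 fit (wbg == wfg) and
// by the BEB grid, where scalings stay frozen at their MLE values.
// [[Rcpp::export]]
arma::rowvec cpp_class_site_loglik(double kappa, double wbg, double wfg,
                                   double sbg, double sfg,
                                   const arma::vec& pi,
                                   const Rcpp::List& pairs,
                                   const arma::ivec& parent,
                                   const arma::ivec& child,
                                   const arma::vec& tlen,
                                   const arma::ivec& is_fg,
                                   int ntip, int nnode, int root,
                                   const arma::imat& tipstate) {
  PairTable pr = as_pairs(pairs);
  Eig ebg = eig_gy(kappa, wbg, pi, pr);
  Eig efg = (wfg == wbg) ? ebg : eig_gy(kappa, wfg, pi, pr);
  std::vector<mat> store;
  std::vector<const mat*> ptrs;
  fill_P(store, ptrs, ebg, efg, tlen, is_fg, sbg, sfg);
  return prune_log_sitelik(ptrs, tipstate, parent, child,
                           ntip, nnode, root, pi);
}

// [[Rcpp::export]]
double cpp_rate_away(double kappa, double omega, const arma::vec& pi,
                     const Rcpp::List& pairs) {
  PairTable pr = as_pairs(pairs);
  return rate_away(kappa, omega, pi, pr);
}
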