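// Pruning-algorithm core for site-wise log-likelihoods under a reversible
// amino-acid model with discrete rate categories, plus directional
// ("outside-subtree") partials used for fast per-edge and per-placement
// likelihood evaluation.
//
// Conventions (shared with the R layer):
//  - nodes use ape numbering: tips 1..ntip, internal ntip+1..ntip+nnode,
//    root = ntip+1; `edge` is the 2-column matrix in postorder.
//  - tip states are integer codes 1..20, 0 = missing (gap or X).
//  - the transition matrix is P(t) = B diag(exp(lambda t)) Binv from the
//    symmetric eigendecomposition of the generator; entries clamped to [0,1].
//  - likelihood underflow is controlled by per-node column rescaling with
//    accumulated log-scalers, one scaler vector per (pattern, category).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat pmat(const mat& B, const mat& Binv, const vec& lam, double t) {
  mat P = B * diagmat(exp(lam * t)) * Binv;
  P.clamp(0.0, 1.0);
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const arma::mat& B, const arma::mat& Binv,
                   const arma::vec& lam, double t) {
  return pmat(B, Binv, lam, t);
}

static void tip_partial(mat& out, const IntegerMatrix& tipcodes, int tip, int npat) {
  // indicator columns; all-ones for missing data
  out.set_size(20, npat);
  for (int j = 0; j < npat; ++j) {
    int code = tipcodes(tip, j);
    if (code == 0) {
      out.col(j).ones();
    } else {
      out.col(j).zeros();
      out(code - 1, j) = 1.0;
    }
  }
}

// Core traversal shared by the exported functions. Computes, for one category:
//  - down partials D(v) for every node (20 x npat slices of `part`),
//  - log-scalers per node (`lsc`, npat x M),
//  - optionally per-edge messages  M_e = P_e D(child)  (rescaled, with
//    their own scalers) when msg/mscal are non-null.
static void down_partials(const IntegerMatrix& edge, const NumericVector& elen,
                          int ntip, int M, const IntegerMatrix& tipcodes,
                          const mat& B, const mat& Binv, const vec& lam,
                          double rate, int npat,
                          cube& part, mat& lsc, cube* msg, mat* mscal) {
  int E = edge.nrow();
  std::vector<bool> init(M, false);
  mat tp;
  for (int e = 0; e < E; ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    mat P = pmat(B, Binv, lam, elen[e] * rate);
    mat contrib;
    rowvec chsc(npat, fill::zeros);
    if (ch < ntip) {
      tip_partial(tp, tipcodes, ch, npat);
      contrib = P * tp;
    } else {
      contrib = P * part.slice(ch);
      chsc = lsc.row(ch);
    }
    // rescale the message
    rowvec mx = max(contrib, 0);
    mx.transform([](double x) { return x > 0.0 ? x : 1.0; });
    contrib.each_row() /= mx;
    rowvec msc = chsc + log(mx);
    if (msg) {
      msg->slice(e) = contrib;
      mscal->row(e) = msc;
    }
    if (!init[par]) {
      part.slice(par) = contrib;
      lsc.row(par) = msc;
      init[par] = true;
    } else {
      part.slice(par) %= contrib;
      lsc.row(par) += msc;
    }
  }
}

// Site log-likelihoods per rate category (gamma categories only; the
// rate-zero invariant class is mixed in by the R layer, where it reduces to
// a branch-length-free term). Returns an npat x ncat matrix.
// [[Rcpp::export]]
arma::mat cpp_cat_loglik(const IntegerMatrix& edge, const NumericVector& elen,
                         int ntip, int nnode, const IntegerMatrix& tipcodes,
                         const arma::mat& B, const arma::mat& Binv,
                         const arma::vec& lam, const arma::vec& rates,
                         const arma::vec& pi) {
  int npat = tipcodes.ncol();
  int M = ntip + nnode;
  int K = rates.n_elem;
  int root = ntip; // 0-based index of ape root node ntip+1
  mat out(npat, K);
  for (int k = 0; k < K; ++k) {
    cube p2(20, npat, M, fill::none);
    mat l2(M, npat, fill::zeros);
    down_partials(edge, elen, ntip, M, tipcodes, B, Binv, lam, rates[k], npat,
                  p2, l2, nullptr, nullptr);
    rowvec L = pi.t() * p2.slice(root);
    out.col(k) = (log(L) + l2.row(root)).t();
  }
  return out;
}

// Down partial at the root of a (sub)tree per category: 20 x npat x K cube
// plus log-scalers (npat x K). Used for the query-clade subtree in the
// placement scan.
// [[Rcpp::export]]
List cpp_root_partial(const IntegerMatrix& edge, const NumericVector& elen,
                      int ntip, int nnode, const IntegerMatrix& tipcodes,
                      const arma::mat& B, const arma::mat& Binv,
                      const arma::vec& lam, const arma::vec& rates) {
  int npat = tipcodes.ncol();
  int M = ntip + nnode;
  int K = rates.n_elem;
  int root = ntip;
  cube out(20, npat, K);
  mat scal(npat, K);
  for (int k = 0; k < K; ++k) {
    cube part(20, npat, M, fill::none);
    mat lsc(M, npat, fill::zeros);
    down_partials(edge, elen, ntip, M, tipcodes, B, Binv, lam, rates[k],
                  npat, part, lsc, nullptr, nullptr);
    out.slice(k) = part.slice(root);
    scal.col(k) = lsc.row(root).t();
  }
  return List::create(_["part"] = out, _["scal"] = scal);
}

// Directional context for every edge (or a single edge if `only_edge` >= 1,
// 1-based in postorder edge numbering). For edge e = (u, v):
//   V_e = everything outside the subtree below v, seen at u (includes pi),
//   D_e = down partial of v (the subtree below v), both per category.
// Returns cubes with E*K slices (slice index e + E*k) and scaler matrices
// (npat x E*K); in single-edge mode only K slices (index k) are returned.
// [[Rcpp::export]]
List cpp_edge_contexts(const IntegerMatrix& edge, const NumericVector& elen,
                       int ntip, int nnode, const IntegerMatrix& tipcodes,
                       const arma::mat& B, const arma::mat& Binv,
                       const arma::vec& lam, const arma::vec& rates,
                       const arma::vec& pi, int only_edge = 0) {
  int npat = tipcodes.ncol();
  int M = ntip + nnode;
  int E = edge.nrow();
  int K = rates.n_elem;
  int root = ntip;
  uword nsl = only_edge > 0 ? (uword)K : (uword)E * K;
  cube Vout(20, npat, nsl, fill::zeros);
  cube Dout(20, npat, nsl, fill::zeros);
  mat vscal(npat, nsl, fill::zeros);
  mat dscal(npat, nsl, fill::zeros);

  // children edge lists per node
  std::vector<std::vector<int>> child_edges(M);
  for (int e = 0; e < E; ++e) child_edges[edge(e, 0) - 1].push_back(e);

  mat tp;
  for (int k = 0; k < K; ++k) {
    cube part(20, npat, M, fill::none);
    mat lsc(M, npat, fill::zeros);
    cube msg(20, npat, E, fill::none);
    mat mscal(E, npat, fill::zeros);
    down_partials(edge, elen, ntip, M, tipcodes, B, Binv, lam, rates[k], npat,
                  part, lsc, &msg, &mscal);

    // preorder: U at nodes, V at edges
    cube U(20, npat, M, fill::none);
    mat usc(M, npat, fill::zeros);
    U.slice(root) = repmat(pi, 1, npat);
    usc.row(root).zeros();
    for (int e = E - 1; e >= 0; --e) { // reverse postorder = valid preorder
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      mat V = U.slice(par);
      rowvec vs = usc.row(par);
      for (int e2 : child_edges[par]) {
        if (e2 == e) continue;
        V %= msg.slice(e2);
        vs += mscal.row(e2);
      }
      rowvec mx = max(V, 0);
      mx.transform([](double x) { return x > 0.0 ? x : 1.0; });
      V.each_row() /= mx;
      vs += log(mx);
      if (only_edge == 0 || only_edge == e + 1) {
        uword sl = only_edge > 0 ? (uword)k : (uword)e + (uword)E * k;
        Vout.slice(sl) = V;
        vscal.col(sl) = vs.t();
        if (ch < ntip) {
          tip_partial(tp, tipcodes, ch, npat);
          Dout.slice(sl) = tp;
        } else {
          Dout.slice(sl) = part.slice(ch);
          dscal.col(sl) = lsc.row(ch).t();
        }
      }
      if (ch >= ntip) { // tips never become parents
        mat P = pmat(B, Binv, lam, elen[e] * rates[k]);
        mat Uc = P.t() * V;
        rowvec mx2 = max(Uc, 0);
        mx2.transform([](double x) { return x > 0.0 ? x : 1.0; });
        Uc.each_row() /= mx2;
        U.slice(ch) = Uc;
        usc.row(ch) = vs + log(mx2);
      }
    }
  }
  return List::create(_["V"] = Vout, _["vscal"] = vscal,
                      _["D"] = Dout, _["dscal"] = dscal);
}

// Per-category site log-likelihoods of an edge as a function of its length t:
// ll_k = log( sum_s V_k(s) [P(t r_k) D_k](s) ) + vscal_k + dscal_k.
// V, D are 20 x npat x K cubes for ONE edge; scalers npat x K.
// [[Rcpp::export]]
arma::mat cpp_edge_loglik(const arma::cube& V, const arma::mat& vscal,
                          const arma::cube& D, const arma::mat& dscal,
                          const arma::mat& B, const arma::mat& Binv,
                          const arma::vec& lam, const arma::vec& rates,
                          double t) {
  int K = rates.n_elem;
  int npat = V.n_cols;
  mat out(npat, K);
  for (int k = 0; k < K; ++k) {
    mat P = pmat(B, Binv, lam, t * rates[k]);
    rowvec s = sum(V.slice(k) % (P * D.slice(k)), 0);
    out.col(k) = (log(s) + vscal.col(k).t() + dscal.col(k).t()).t();
  }
  return out;
}

// Mix per-category log-likelihoods with the rate-zero invariant class:
// site logL = log( invc + wg * sum_k exp(ll_k) ), with invc = p_inv * pi_a
// for columns constant ignoring missing data (0 otherwise) and
// wg = (1 - p_inv)/K. Computed with a max shift for stability.
// [[Rcpp::export]]
arma::vec cpp_mix_loglik(const arma::mat& catll, const arma::vec& invc,
                         double wg) {
  int npat = catll.n_rows;
  vec out(npat);
  for (int i = 0; i < npat; ++i) {
    double m = catll.row(i).max();
    double a = invc[i] > 0 ? std::log(invc[i]) : -datum::inf;
    double Mx = std::max(m, a);
    double s = 0.0;
    for (uword k = 0; k < catll.n_cols; ++k)
      s += std::exp(catll(i, k) - Mx);
    double iv = std::isfinite(a) ? std::exp(a - Mx) : 0.0;
    out[i] = Mx + std::log(iv + wg * s);
  }
  return out;
}

// Graft-point likelihood profile. G = (P(t1)^T V) o (P(t2) D) precomputed per
// category for one backbone edge (20 x npat x K, scaler gscal npat x K);
// C = clade root partial (20 x npat x K, scaler cscal). For a given graft
// branch length tg the per-category site log-likelihood is
//   ll_k = log( sum_s G_k(s) [P(tg r_k) C_k](s) ) + gscal_k + cscal_k.
// Optimizes total mixed lnL over tg by golden-section on [lo, hi] and
// returns the optimum, its total lnL, and the site log-likelihood vector.
// [[Rcpp::export]]
List cpp_graft_opt(const arma::cube& G, const arma::mat& gscal,
                   const arma::cube& C, const arma::mat& cscal,
                   const arma::mat& B, const arma::mat& Binv,
                   const arma::vec& lam, const arma::vec& rates,
                   const arma::vec& invc, double wg, const arma::vec& wts,
                   double lo, double hi, double tol, int do_opt) {
  int K = rates.n_elem;
  int npat = G.n_cols;
  mat catll(npat, K);
  auto eval = [&](double tg) -> double {
    for (int k = 0; k < K; ++k) {
      mat P = pmat(B, Binv, lam, tg * rates[k]);
      rowvec s = sum(G.slice(k) % (P * C.slice(k)), 0);
      catll.col(k) = (log(s) + gscal.col(k).t() + cscal.col(k).t()).t();
    }
    vec site = cpp_mix_loglik(catll, invc, wg);
    return dot(site, wts);
  };
  double best_t = lo, best_f;
  if (do_opt) {
    // golden-section search on log scale
    const double gr = 0.6180339887498949;
    double a = std::log(lo), b = std::log(hi);
    double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
    double f1 = eval(std::exp(c1)), f2 = eval(std::exp(c2));
    while (b - a > tol) {
      if (f1 < f2) { a = c1; c1 = c2; f1 = f2; c2 = a + gr * (b - a); f2 = eval(std::exp(c2)); }
      else { b = c2; c2 = c1; f2 = f1; c1 = b - gr * (b - a); f1 = eval(std::exp(c1)); }
    }
    best_t = std::exp((a + b) / 2);
  }
  best_f = eval(best_t);
  vec site = cpp_mix_loglik(catll, invc, wg);
  return List::create(_["t"] = best_t, _["loglik"] = best_f,
                      _["catll"] = catll, _["site"] = site);
}
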