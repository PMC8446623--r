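// GY94 omega-mixture pruning likelihood for codon alignments.
//
// States are the 61 sense codons. For each mixture category the rate matrix
// is built from the codon pair-type classification, symmetrized via the
// stationary frequencies, eigendecomposed, and branch transition matrices
// are formed by spectral reconstruction. Felsenstein pruning runs over
// unique site patterns with per-node column rescaling to avoid underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List gy94_loglik_cpp(IntegerMatrix tips, NumericVector patWeight,
                     IntegerMatrix edge, NumericVector edgeLen,
                     int nTip, NumericVector pi, IntegerMatrix pairType,
                     double kappa, NumericVector omegas, NumericVector catW,
                     double scale, bool wantSite) {
  const int nS = 61;
  const int nPat = tips.ncol();
  const int nCat = omegas.size();
  const int nEdge = edge.nrow();

  arma::vec piv(pi.begin(), nS);
  arma::vec sq = arma::sqrt(piv);

  // per-category unnormalized Q, eigen pieces, and stationary rate
  std::vector<arma::mat> Uv(nCat), Lv(nCat), Rv(nCat);
  std::vector<arma::vec> lamv(nCat);
  arma::vec rate(nCat);
  for (int k = 0; k < nCat; ++k) {
    double w = omegas[k];
    arma::mat Q(nS, nS, arma::fill::zeros);
    for (int i = 0; i < nS; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < nS; ++j) {
        if (i == j) continue;
        double c;
        switch (pairType(i, j)) {
          case 1: c = 1.0; break;
          case 2: c = kappa; break;
          case 3: c = w; break;
          case 4: c = w * kappa; break;
          default: c = 0.0;
        }
        double q = c * piv[j];
        Q(i, j) = q;
        rowsum += q;
      }
      Q(i, i) = -rowsum;
    }
    rate[k] = -arma::dot(piv, Q.diag());
    arma::mat A = Q;
    for (int i = 0; i < nS; ++i)
      for (int j = 0; j < nS; ++j)
        A(i, j) *= sq[i] / sq[j];
    A = 0.5 * (A + A.t());
    arma::vec lam;
    arma::mat U;
    arma::eig_sym(lam, U, A);
    lamv[k] = lam;
    Uv[k] = U;
    arma::mat left = U;
    left.each_col() /= sq;                 // D^{-1/2} U
    arma::mat right = U.t();
    right.each_row() %= sq.t();            // U' D^{1/2}
    Lv[k] = left;
    Rv[k] = right;
  }
  double meanRate = 0.0;
  for (int k = 0; k < nCat; ++k) meanRate += catW[k] * rate[k];
  if (meanRate <= 0) meanRate = 1.0;

  const int nNodeTot = nTip + nTip;        // upper bound on ape node ids
  arma::mat S(nPat, nCat);                 // per-pattern per-cat log-lik

  for (int k = 0; k < nCat; ++k) {
    // transition matrices per edge
    std::vector<arma::mat> P(nEdge);
    for (int e = 0; e < nEdge; ++e) {
      double t = edgeLen[e] * scale / meanRate;
      if (t < 0) t = 0;
      arma::mat expd = Rv[k];
      expd.each_col() %= arma::exp(lamv[k] * t);
      arma::mat Pe = Lv[k] * expd;
      Pe.transform([](double v) { return v < 0 ? 0.0 : v; });
      P[e] = Pe;
    }
    std::vector<arma::mat> part(nNodeTot + 1);
    std::vector<bool> started(nNodeTot + 1, false);
    arma::rowvec logScale(nPat, arma::fill::zeros);
    int root = edge(nEdge - 1, 0);
    for (int e = 0; e < nEdge; ++e) {
      int par = edge(e, 0), ch = edge(e, 1);
      arma::mat M(nS, nPat);
      if (ch <= nTip) {
        for (int p = 0; p < nPat; ++p) {
          int s = tips(ch - 1, p);
          if (s == 0) M.col(p).ones();
          else M.col(p) = P[e].col(s - 1);
        }
      } else {
        arma::mat &Lc = part[ch];
        arma::rowvec mx = arma::max(Lc, 0);
        for (int p = 0; p < nPat; ++p) {
          double m = mx[p];
          if (m <= 0) m = 1e-300;
          Lc.col(p) /= m;
          logScale[p] += std::log(m);
        }
        M = P[e] * Lc;
      }
      if (!started[par]) { part[par] = M; started[par] = true; }
      else part[par] %= M;
    }
    arma::rowvec lik = piv.t() * part[root];
    for (int p = 0; p < nPat; ++p) {
      double v = lik[p];
      S(p, k) = (v > 0 ? std::log(v) : -1e300) + logScale[p];
    }
  }

  // combine categories and weight patterns
  double total = 0.0;
  for (int p = 0; p < nPat; ++p) {
    double mx = -1e300;
    for (int k = 0; k < nCat; ++k)
      if (catW[k] > 0 && S(p, k) + std::log(catW[k]) > mx)
        mx = S(p, k) + std::log(catW[k]);
    double s = 0.0;
    for (int k = 0; k < nCat; ++k)
      if (catW[k] > 0) s += std::exp(S(p, k) + std::log(catW[k]) - mx);
    total += patWeight[p] * (mx + std::log(s));
  }

  if (wantSite) return List::create(_["loglik"] = total, _["site"] = S);
  return List::create(_["loglik"] = total);
}
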