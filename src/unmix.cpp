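#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-voxel linear unmixing against a shared endmember matrix E (channels x
// endmembers), for all voxel spectra Y (voxels x channels) at once.
//
// OLS is the normal-equations solution. NNLS is solved exactly: a fast
// path restricts the solution to the positive support of the OLS solution
// and accepts it when it satisfies the KKT conditions (primal feasibility
// and non-positive gradient on the zeroed coordinates); the few remaining
// voxels fall back to enumerating all active supports — any
// support-restricted LS solution that is non-negative is a feasible point,
// so the feasible one with the smallest residual is the optimum. p is
// small (<= 8), so enumeration is exact and cheap.
// [[Rcpp::export]]
List cpp_unmix(const arma::mat& E, const arma::mat& Y, bool nonneg,
               double tol) {
  const arma::uword p = E.n_cols, N = Y.n_rows;
  if (p > 8) stop("cpp_unmix: more than 8 endmembers not supported");
  arma::mat G = E.t() * E;
  arma::mat B = (Y * E).t();          // p x N
  arma::vec y2 = arma::sum(arma::square(Y), 1);
  arma::mat A = arma::solve(G, B, arma::solve_opts::likely_sympd);
  arma::vec rss(N);
  for (arma::uword j = 0; j < N; ++j) {
    double s = 0;
    for (arma::uword i = 0; i < p; ++i) s += A(i, j) * B(i, j);
    rss(j) = y2(j) - s;
  }
  if (nonneg) {
    const unsigned M = 1u << p;
    std::vector<arma::mat> Ginv(M);
    std::vector<std::vector<arma::uword> > sup(M);
    for (unsigned m = 1; m < M; ++m) {
      std::vector<arma::uword> S;
      for (arma::uword i = 0; i < p; ++i)
        if (m & (1u << i)) S.push_back(i);
      arma::uvec Su(S);
      Ginv[m] = arma::inv_sympd(G.submat(Su, Su));
      sup[m] = S;
    }
    arma::vec best(p);
    double asv[8], aj[8];
    for (arma::uword j = 0; j < N; ++j) {
      bool ok = true;
      for (arma::uword i = 0; i < p; ++i)
        if (A(i, j) < -tol) { ok = false; break; }
      if (ok) {
        for (arma::uword i = 0; i < p; ++i)
          if (A(i, j) < 0) A(i, j) = 0;
        continue;
      }
      // fast path: the positive support of the OLS solution
      unsigned mpos = 0;
      for (arma::uword i = 0; i < p; ++i)
        if (A(i, j) > tol) mpos |= (1u << i);
      bool solved = false;
      if (mpos) {
        const std::vector<arma::uword>& S = sup[mpos];
        const arma::mat& Gi = Ginv[mpos];
        bool feas = true;
        for (size_t r = 0; r < S.size() && feas; ++r) {
          double v = 0;
          for (size_t c = 0; c < S.size(); ++c) v += Gi(r, c) * B(S[c], j);
          if (v < -tol) feas = false; else asv[r] = v;
        }
        if (feas) {
          for (arma::uword i = 0; i < p; ++i) aj[i] = 0;
          for (size_t r = 0; r < S.size(); ++r) aj[S[r]] = asv[r];
          // dual feasibility: gradient on the zeroed coordinates <= 0
          bool dual = true;
          for (arma::uword i = 0; i < p && dual; ++i) {
            if (mpos & (1u << i)) continue;
            double w = B(i, j);
            for (arma::uword k = 0; k < p; ++k) w -= G(i, k) * aj[k];
            if (w > tol) dual = false;
          }
          if (dual) {
            double rs = y2(j);
            for (size_t r = 0; r < S.size(); ++r) rs -= asv[r] * B(S[r], j);
            for (arma::uword i = 0; i < p; ++i)
              A(i, j) = aj[i] < 0 ? 0 : aj[i];
            rss(j) = rs;
            solved = true;
          }
        }
      }
      if (solved) continue;
      double best_rss = y2(j);          // empty support: a = 0
      best.zeros();
      for (unsigned m = 1; m < M; ++m) {
        const std::vector<arma::uword>& S = sup[m];
        const arma::mat& Gi = Ginv[m];
        bool feas = true;
        double rs = y2(j);
        for (size_t r = 0; r < S.size(); ++r) {
          double v = 0;
          for (size_t c = 0; c < S.size(); ++c) v += Gi(r, c) * B(S[c], j);
          if (v < -tol) { feas = false; break; }
          asv[r] = v;
          rs -= v * B(S[r], j);
        }
        if (!feas) continue;
        if (rs < best_rss - 1e-15) {
          best_rss = rs;
          best.zeros();
          for (size_t r = 0; r < S.size(); ++r)
            best(S[r]) = asv[r] < 0 ? 0 : asv[r];
        }
      }
      for (arma::uword i = 0; i < p; ++i) A(i, j) = best(i);
      rss(j) = best_rss;
    }
  }
  return List::create(_["A"] = A, _["rss"] = rss);
}

// Poisson shot noise plus Gaussian read noise on the detected-count scale,
// returned on the abundance scale. Single pass; uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_detection_noise(NumericVector x, double counts_scale,
                                  double gaussian_sd, bool poisson) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double lam = x[i] * counts_scale;
    if (lam < 0) lam = 0;
    double v = poisson ? R::rpois(lam) : lam;
    if (gaussian_sd > 0) v += R::norm_rand() * gaussian_sd;
    out[i] = v / counts_scale;
  }
  return out;
}

// Spectral mixing and detection noise fused in one pass: the endmember
// abundances (M, voxels x endmembers) are projected through the endmember
// matrix (E, channels x endmembers), optionally clipped at a full-well
// value, and carried through Poisson + Gaussian detection noise on the
// count scale. Returns voxels x channels, walking input and output
// contiguously one channel plane at a time.
// [[Rcpp::export]]
arma::mat cpp_mix_noise(const arma::mat& M, const arma::mat& E,
                        double counts_scale, double gaussian_sd,
                        bool poisson, bool noise, double clip) {
  const arma::uword N = M.n_rows, p = M.n_cols, C = E.n_rows;
  arma::mat out(N, C);
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword j = 0; j < N; ++j) {
      double v = 0;
      for (arma::uword k = 0; k < p; ++k) v += E(c, k) * M(j, k);
      if (clip >= 0 && v > clip) v = clip;
      if (noise) {
        double lam = v * counts_scale;
        if (lam < 0) lam = 0;
        double w = poisson ? R::rpois(lam) : lam;
        if (gaussian_sd > 0) w += R::norm_rand() * gaussian_sd;
        v = w / counts_scale;
      }
      out(j, c) = v;
    }
  }
  return out;
}
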