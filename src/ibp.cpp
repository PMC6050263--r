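// Collapsed Gibbs sampler for the linear-Gaussian latent-feature model with
// an Indian Buffet Process prior. Loadings A are integrated out; the sampler
// maintains G = Z'Z and Z'X incrementally so each conditional costs
// O(K^3 + K^2 D). All randomness comes from R's RNG (deterministic under
// set.seed on the R side).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log p(X | Z, sx, sa) with A integrated out:
//   -(N D / 2) log(2 pi) - (N - K) D log sx - K D log sa
//   - (D/2) log|G + (sx^2/sa^2) I|
//   - (tr X'X - tr((Z'X)' M (Z'X))) / (2 sx^2),  M = (G + (sx^2/sa^2) I)^-1
static double collapsed_ll_stats(const arma::mat& G, const arma::mat& ZtX,
                                 double trXX, int N, int D,
                                 double sx, double sa) {
  int K = G.n_rows;
  double c = (sx * sx) / (sa * sa);
  double quad = 0.0, logdet = 0.0;
  if (K > 0) {
    arma::mat Mi = G + c * arma::eye(K, K);
    arma::mat L = arma::chol(Mi, "lower");
    logdet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat S = arma::solve(arma::trimatl(L), ZtX);
    quad = arma::accu(S % S);
  }
  return -0.5 * N * D * std::log(2.0 * M_PI)
         - (double)(N - K) * D * std::log(sx) - (double)K * D * std::log(sa)
         - 0.5 * D * logdet - (trXX - quad) / (2.0 * sx * sx);
}

// [[Rcpp::export]]
double cpp_collapsed_loglik(const arma::mat& Z, const arma::mat& X,
                            double sigma_x, double sigma_a) {
  if (Z.n_rows != X.n_rows) stop("Z and X must have the same number of rows");
  arma::mat G = Z.t() * Z;
  arma::mat ZtX = Z.t() * X;
  double trXX = arma::accu(X % X);
  return collapsed_ll_stats(G, ZtX, trXX, X.n_rows, X.n_cols,
                            sigma_x, sigma_a);
}

// Exchangeable IBP pmf (lof-equivalence classes):
// log P(Z | alpha) = K log(alpha) - sum_h log(K_h!) - alpha H_N
//                    + sum_k [ lgamma(N - m_k + 1) + lgamma(m_k) - lgamma(N + 1) ]
// [[Rcpp::export]]
double cpp_log_ibp_prior(const arma::mat& Z, double alpha) {
  int N = Z.n_rows, K = Z.n_cols;
  double HN = 0.0;
  for (int i = 1; i <= N; ++i) HN += 1.0 / i;
  double lp = K * std::log(alpha) - alpha * HN;
  std::map<std::string, int> hist;
  for (int k = 0; k < K; ++k) {
    double m = arma::accu(Z.col(k));
    lp += std::lgamma(N - m + 1.0) + std::lgamma(m) - std::lgamma(N + 1.0);
    std::string key;
    key.reserve(N);
    for (int i = 0; i < N; ++i) key.push_back(Z(i, k) > 0.5 ? '1' : '0');
    hist[key] += 1;
  }
  for (std::map<std::string, int>::iterator it = hist.begin();
       it != hist.end(); ++it) {
    lp -= std::lgamma(it->second + 1.0);
  }
  return lp;
}

static int sample_trunc_pois(double lambda, int cap) {
  // inverse-cdf draw from Poisson(lambda) truncated to 0..cap
  std::vector<double> w(cap + 1);
  double tot = 0.0;
  for (int j = 0; j <= cap; ++j) {
    w[j] = R::dpois(j, lambda, 0);
    tot += w[j];
  }
  double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
  for (int j = 0; j <= cap; ++j) {
    acc += w[j];
    if (u <= acc) return j;
  }
  return cap;
}

static int sample_grid(const arma::vec& logw) {
  arma::vec w = arma::exp(logw - logw.max());
  double u = R::runif(0.0, 1.0) * arma::accu(w), acc = 0.0;
  for (arma::uword j = 0; j < w.n_elem; ++j) {
    acc += w(j);
    if (u <= acc) return (int)j;
  }
  return (int)w.n_elem - 1;
}

// Full sampler. Returns traces, thinned post-burn-in Z samples, and the
// sample maximizing the joint log posterior log p(X|Z) + log P(Z|alpha).
// [[Rcpp::export]]
List cpp_ibp_gibbs(const arma::mat& X, double a_alpha, double b_alpha,
                   const arma::vec& sx_grid, const arma::vec& sa_grid,
                   int n_sweeps, int burn_in, int max_new,
                   const arma::mat& Z_init, double alpha_init,
                   int sx_init, int sa_init, int thin) {
  const int N = X.n_rows, D = X.n_cols;
  double trXX = arma::accu(X % X);
  double HN = 0.0;
  for (int i = 1; i <= N; ++i) HN += 1.0 / i;

  arma::mat Z = Z_init;
  arma::mat G = Z.t() * Z;
  arma::mat ZtX = Z.t() * X;
  double alpha = alpha_init;
  double sx = sx_grid(sx_init), sa = sa_grid(sa_init);

  // flip Z(i,k) to val, updating G and ZtX
  auto set_z = [&](int i, int k, double val) {
    double d = val - Z(i, k);
    if (d == 0.0) return;
    for (arma::uword j = 0; j < Z.n_cols; ++j) {
      if ((int)j == k) continue;
      double upd = d * Z(i, j);
      G(k, j) += upd;
      G(j, k) += upd;
    }
    G(k, k) += d;  // z_ik^2 term (binary entries)
    ZtX.row(k) += d * X.row(i);
    Z(i, k) = val;
  };

  IntegerVector K_trace(n_sweeps);
  NumericVector alpha_trace(n_sweeps), joint_trace(n_sweeps),
      loglik_trace(n_sweeps), sx_trace(n_sweeps), sa_trace(n_sweeps);
  List z_samples;
  std::vector<double> sample_joint, sample_sx, sample_sa;

  arma::vec xnorm2(N);
  for (int i = 0; i < N; ++i) xnorm2(i) = arma::dot(X.row(i), X.row(i));

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < N; ++i) {
      // existing (shared) features: incremental Sherman-Morrison updates of
      // M = (G + cI)^-1, its log-determinant, and the quadratic form
      // tr(ZtX' M ZtX); refreshed from scratch once per subject to bound
      // floating-point drift. Per-flip cost O(K D) instead of O(K^2 D).
      int K = Z.n_cols;
      if (K > 0) {
        double c = (sx * sx) / (sa * sa);
        arma::mat Mi = G + c * arma::eye(K, K);
        arma::mat M = arma::inv_sympd(Mi);
        double logdet, sgn;
        arma::log_det(logdet, sgn, Mi);
        arma::mat MP = M * ZtX;
        double quad = arma::accu(ZtX % MP);
        const double constK = -0.5 * N * D * std::log(2.0 * M_PI) -
            (double)(N - K) * D * std::log(sx) - (double)K * D * std::log(sa);
        for (int k = 0; k < K; ++k) {
          double m_minus = G(k, k) - Z(i, k);
          if (m_minus <= 0.5) continue;  // i's singleton: MH step below
          double d = 1.0 - 2.0 * Z(i, k);  // flip direction
          arma::vec w = d * Z.row(i).t();
          w(k) += 0.5;
          arma::vec g1 = M.col(k);
          double denom1 = 1.0 + arma::dot(w, g1);
          bool ok = std::abs(denom1) > 1e-10;
          double llc = 0, logdetc = 0, quadc = 0;
          arma::vec g2, h1, h2;
          arma::rowvec pg1, pg2, ph1, ph2;
          if (ok) {
            g2 = M * w;
            h1 = g2 - g1 * (arma::dot(g2, w) / denom1);   // M1 w
            h2 = g1 - g2 * (g1(k) / denom1);              // (u' M1)'
            double denom2 = 1.0 + h1(k);
            double dprod = denom1 * denom2;
            ok = dprod > 1e-12 && std::abs(denom2) > 1e-10;
            if (ok) {
              logdetc = logdet + std::log(dprod);
              pg1 = g1.t() * ZtX;
              pg2 = g2.t() * ZtX;
              ph1 = h1.t() * ZtX;
              ph2 = h2.t() * ZtX;
              double trPM2P = quad - arma::dot(pg1, pg2) / denom1 -
                              arma::dot(ph1, ph2) / denom2;
              arma::rowvec rk = MP.row(k) - (g1(k) / denom1) * pg2 -
                                (h1(k) / denom2) * ph2;
              double M2kk = M(k, k) - g1(k) * g2(k) / denom1 -
                            h1(k) * h2(k) / denom2;
              quadc = trPM2P + 2.0 * d * arma::dot(rk, X.row(i)) +
                      xnorm2(i) * M2kk;
              llc = constK - 0.5 * D * logdetc -
                    (trXX - quadc) / (2.0 * sx * sx);
              // commit bookkeeping deferred until the draw below
              h2 /= denom2;  // fold denominators into the rank-1 factors
              g2 /= denom1;
              ph2 /= denom2;
              pg2 /= denom1;
            }
          }
          if (!ok) {
            // rare near-singular update: evaluate the candidate from scratch
            set_z(i, k, 1.0 - Z(i, k));
            llc = collapsed_ll_stats(G, ZtX, trXX, N, D, sx, sa);
            set_z(i, k, 1.0 - Z(i, k));
          }
          double llcur = constK - 0.5 * D * logdet -
                         (trXX - quad) / (2.0 * sx * sx);
          double lp1, lp0;
          if (Z(i, k) < 0.5) {  // current 0, candidate 1
            lp1 = std::log(m_minus / N) + llc;
            lp0 = std::log(1.0 - m_minus / N) + llcur;
          } else {
            lp1 = std::log(m_minus / N) + llcur;
            lp0 = std::log(1.0 - m_minus / N) + llc;
          }
          double p1 = 1.0 / (1.0 + std::exp(lp0 - lp1));
          bool want_one = R::runif(0.0, 1.0) < p1;
          bool flip = (want_one != (Z(i, k) > 0.5));
          if (flip) {
            if (ok) {
              M -= g1 * g2.t();
              M -= h1 * h2.t();
              MP -= g1 * pg2;
              MP -= h1 * ph2;
              set_z(i, k, want_one ? 1.0 : 0.0);   // updates G, ZtX, Z
              MP += d * M.col(k) * X.row(i);
              logdet = logdetc;
              quad = quadc;
            } else {
              set_z(i, k, want_one ? 1.0 : 0.0);
              arma::mat Mi2 = G + c * arma::eye(K, K);
              M = arma::inv_sympd(Mi2);
              arma::log_det(logdet, sgn, Mi2);
              MP = M * ZtX;
              quad = arma::accu(ZtX % MP);
            }
          }
        }
      }
      // birth/death of i's singleton features (MH, truncated-Poisson proposal)
      std::vector<int> singles;
      for (int k = 0; k < (int)Z.n_cols; ++k) {
        if (Z(i, k) > 0.5 && G(k, k) < 1.5) singles.push_back(k);
      }
      int k_old = (int)singles.size();
      int k_new = sample_trunc_pois(alpha / N, max_new);
      if (k_new != k_old) {
        int K0 = Z.n_cols;
        int Kkeep = K0 - k_old;
        int Kc = Kkeep + k_new;
        arma::uvec keep(Kkeep);
        int pos = 0;
        for (int k = 0; k < K0; ++k) {
          if (std::find(singles.begin(), singles.end(), k) == singles.end()) {
            keep(pos++) = k;
          }
        }
        arma::mat Gc(Kc, Kc, arma::fill::zeros);
        arma::mat ZtXc(Kc, D, arma::fill::zeros);
        if (Kkeep > 0) {
          Gc.submat(0, 0, Kkeep - 1, Kkeep - 1) = G.submat(keep, keep);
          ZtXc.rows(0, Kkeep - 1) = ZtX.rows(keep);
        }
        for (int j = 0; j < k_new; ++j) {
          int idx = Kkeep + j;
          Gc(idx, idx) = 1.0;
          for (int l = 0; l < Kkeep; ++l) {
            double v = Z(i, keep(l));
            Gc(idx, l) = v;
            Gc(l, idx) = v;
          }
          for (int l = 0; l < k_new; ++l) {
            if (l != j) Gc(idx, Kkeep + l) = 1.0;
          }
          ZtXc.row(idx) = X.row(i);
        }
        double ll_cur = collapsed_ll_stats(G, ZtX, trXX, N, D, sx, sa);
        double ll_new = collapsed_ll_stats(Gc, ZtXc, trXX, N, D, sx, sa);
        if (std::log(R::runif(0.0, 1.0)) < ll_new - ll_cur) {
          arma::mat Zc(N, Kc, arma::fill::zeros);
          if (Kkeep > 0) Zc.cols(0, Kkeep - 1) = Z.cols(keep);
          for (int j = 0; j < k_new; ++j) Zc(i, Kkeep + j) = 1.0;
          Z = Zc;
          G = Gc;
          ZtX = ZtXc;
        }
      }
    }
    // prune empty columns (defensive; deaths happen via the MH step)
    {
      arma::uvec keep = arma::find(arma::sum(Z, 0).t() > 0.5);
      if (keep.n_elem < Z.n_cols) {
        Z = Z.cols(keep);
        G = Z.t() * Z;
        ZtX = Z.t() * X;
      }
    }
    // burn-in only: greedy column merges (a := a OR b, drop b) accepted when
    // they raise the joint posterior. Collapsed Gibbs alone mixes very
    // slowly out of "split-feature" local optima (two columns sharing one
    // true feature's loading); merging during warm-up escapes them while
    // leaving the post-burn-in kernel exact.
    if (sweep < burn_in && Z.n_cols >= 2) {
      bool improved = true;
      while (improved && Z.n_cols >= 2) {
        improved = false;
        double cur = collapsed_ll_stats(G, ZtX, trXX, N, D, sx, sa) +
                     cpp_log_ibp_prior(Z, alpha);
        int K0 = Z.n_cols;
        for (int a = 0; a < K0 && !improved; ++a) {
          for (int b = 0; b < K0 && !improved; ++b) {
            if (a == b) continue;
            // union move a := a | b (b dropped), and difference move
            // a := a & !b (b kept) — together they dissolve the
            // "union column + correction columns" optima
            for (int mv = 0; mv < 2 && !improved; ++mv) {
              arma::mat Zc = Z;
              if (mv == 0) {
                Zc.col(a) = arma::max(Zc.col(a), Zc.col(b));
                Zc.shed_col(b);
              } else {
                Zc.col(a) = Zc.col(a) % (1.0 - Zc.col(b));
                if (arma::accu(Zc.col(a)) < 0.5) Zc.shed_col(a);
              }
              arma::mat Gc = Zc.t() * Zc;
              arma::mat ZtXc = Zc.t() * X;
              double cand = collapsed_ll_stats(Gc, ZtXc, trXX, N, D, sx, sa) +
                            cpp_log_ibp_prior(Zc, alpha);
              if (cand > cur) {
                Z = Zc;
                G = Gc;
                ZtX = ZtXc;
                improved = true;
              }
            }
          }
        }
      }
    }
    // noise / loading scales: conditional posterior over fixed grids
    {
      arma::vec lw(sx_grid.n_elem);
      for (arma::uword j = 0; j < sx_grid.n_elem; ++j) {
        lw(j) = collapsed_ll_stats(G, ZtX, trXX, N, D, sx_grid(j), sa);
      }
      sx = sx_grid(sample_grid(lw));
      arma::vec lw2(sa_grid.n_elem);
      for (arma::uword j = 0; j < sa_grid.n_elem; ++j) {
        lw2(j) = collapsed_ll_stats(G, ZtX, trXX, N, D, sx, sa_grid(j));
      }
      sa = sa_grid(sample_grid(lw2));
    }
    // concentration: conjugate Gamma update
    alpha = R::rgamma(a_alpha + Z.n_cols, 1.0 / (b_alpha + HN));

    double ll = collapsed_ll_stats(G, ZtX, trXX, N, D, sx, sa);
    double joint = ll + (Z.n_cols > 0 ? cpp_log_ibp_prior(Z, alpha)
                                      : -alpha * HN);
    K_trace[sweep] = Z.n_cols;
    alpha_trace[sweep] = alpha;
    loglik_trace[sweep] = ll;
    joint_trace[sweep] = joint;
    sx_trace[sweep] = sx;
    sa_trace[sweep] = sa;
    if (sweep >= burn_in && (sweep - burn_in) % thin == 0) {
      z_samples.push_back(wrap(arma::conv_to<arma::imat>::from(Z)));
      sample_joint.push_back(joint);
      sample_sx.push_back(sx);
      sample_sa.push_back(sa);
    }
  }
  return List::create(
      _["z_samples"] = z_samples, _["K_trace"] = K_trace,
      _["alpha_trace"] = alpha_trace, _["loglik_trace"] = loglik_trace,
      _["joint_logpost_trace"] = joint_trace, _["sx_trace"] = sx_trace,
      _["sa_trace"] = sa_trace, _["sample_joint"] = wrap(sample_joint),
      _["sample_sx"] = wrap(sample_sx), _["sample_sa"] = wrap(sample_sa));
}
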