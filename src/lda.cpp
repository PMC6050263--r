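// Collapsed Gibbs sampler for latent Dirichlet allocation over binary
// property assignments (subjects = documents, active properties = tokens of
// count 1), plus fold-in inference for new documents with phi frozen.
// Randomness comes from R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int sample_cat(const arma::vec& w) {
  double u = R::runif(0.0, 1.0) * arma::accu(w), acc = 0.0;
  for (arma::uword f = 0; f < w.n_elem; ++f) {
    acc += w(f);
    if (u <= acc) return (int)f;
  }
  return (int)w.n_elem - 1;
}

// doc / word ids are 0-based, one entry per token.
// Returns posterior-mean theta (n_docs x k) and phi (k x n_words) averaged
// over post-burn-in sweeps.
// [[Rcpp::export]]
List cpp_lda_gibbs(const arma::ivec& doc_ids, const arma::ivec& word_ids,
                   int n_docs, int n_words, int k, double alpha, double beta,
                   int n_sweeps, int burn_in) {
  const int T = doc_ids.n_elem;
  arma::mat n_df(n_docs, k, arma::fill::zeros);
  arma::mat n_fw(k, n_words, arma::fill::zeros);
  arma::vec n_f(k, arma::fill::zeros);
  arma::vec n_d(n_docs, arma::fill::zeros);
  arma::ivec z(T);
  for (int t = 0; t < T; ++t) {
    int f = (int)std::floor(R::runif(0.0, 1.0) * k);
    if (f == k) f = k - 1;
    z(t) = f;
    n_df(doc_ids(t), f) += 1.0;
    n_fw(f, word_ids(t)) += 1.0;
    n_f(f) += 1.0;
    n_d(doc_ids(t)) += 1.0;
  }
  arma::mat theta_acc(n_docs, k, arma::fill::zeros);
  arma::mat phi_acc(k, n_words, arma::fill::zeros);
  arma::mat phi_ref;   // first post-burn-in sample: within-chain alignment
  int n_acc = 0;
  arma::vec w(k);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int t = 0; t < T; ++t) {
      int d = doc_ids(t), v = word_ids(t), f = z(t);
      n_df(d, f) -= 1.0;
      n_fw(f, v) -= 1.0;
      n_f(f) -= 1.0;
      for (int g = 0; g < k; ++g) {
        w(g) = (n_df(d, g) + alpha) * (n_fw(g, v) + beta) /
               (n_f(g) + n_words * beta);
      }
      f = sample_cat(w);
      z(t) = f;
      n_df(d, f) += 1.0;
      n_fw(f, v) += 1.0;
      n_f(f) += 1.0;
    }
    if (sweep >= burn_in) {
      arma::mat theta_s(n_docs, k), phi_s(k, n_words);
      for (int d = 0; d < n_docs; ++d) {
        for (int g = 0; g < k; ++g) {
          theta_s(d, g) = (n_df(d, g) + alpha) / (n_d(d) + k * alpha);
        }
      }
      for (int g = 0; g < k; ++g) {
        for (int v = 0; v < n_words; ++v) {
          phi_s(g, v) = (n_fw(g, v) + beta) / (n_f(g) + n_words * beta);
        }
      }
      // label switching within the chain would turn the running averages
      // into mode mixtures; align each sample to the first by exact
      // assignment (k! enumeration, k is small) on squared phi distance
      if (phi_ref.n_rows == 0) {
        phi_ref = phi_s;
      } else if (k > 1 && k <= 8) {
        std::vector<int> perm(k), best(k);
        for (int g = 0; g < k; ++g) perm[g] = g;
        arma::mat cost(k, k);
        for (int i = 0; i < k; ++i) {
          for (int j = 0; j < k; ++j) {
            cost(i, j) = arma::accu(arma::square(phi_ref.row(i) -
                                                 phi_s.row(j)));
          }
        }
        double bestc = std::numeric_limits<double>::infinity();
        do {
          double cc = 0;
          for (int i = 0; i < k; ++i) cc += cost(i, perm[i]);
          if (cc < bestc) {
            bestc = cc;
            best = perm;
          }
        } while (std::next_permutation(perm.begin(), perm.end()));
        arma::uvec idx(k);
        for (int i = 0; i < k; ++i) idx(i) = best[i];
        theta_s = theta_s.cols(idx);
        phi_s = phi_s.rows(idx);
      }
      theta_acc += theta_s;
      phi_acc += phi_s;
      ++n_acc;
    }
  }
  if (n_acc == 0) stop("no post-burn-in sweeps");
  arma::mat theta = theta_acc / n_acc;
  arma::mat phi = phi_acc / n_acc;
  // renormalize away averaging round-off
  theta.each_col() /= arma::sum(theta, 1);
  phi.each_col() /= arma::sum(phi, 1);
  return List::create(_["theta"] = theta, _["phi"] = phi);
}

// Fold-in: sample token-factor indicators for new documents with phi frozen;
// theta is averaged over the last n_avg sweeps.
// [[Rcpp::export]]
arma::mat cpp_lda_foldin(const arma::ivec& doc_ids, const arma::ivec& word_ids,
                         int n_docs, const arma::mat& phi, double alpha,
                         int n_sweeps, int n_avg) {
  const int T = doc_ids.n_elem;
  const int k = phi.n_rows;
  arma::mat n_df(n_docs, k, arma::fill::zeros);
  arma::vec n_d(n_docs, arma::fill::zeros);
  arma::ivec z(T);
  for (int t = 0; t < T; ++t) {
    int f = (int)std::floor(R::runif(0.0, 1.0) * k);
    if (f == k) f = k - 1;
    z(t) = f;
    n_df(doc_ids(t), f) += 1.0;
    n_d(doc_ids(t)) += 1.0;
  }
  arma::mat theta_acc(n_docs, k, arma::fill::zeros);
  int n_acc = 0;
  arma::vec w(k);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int t = 0; t < T; ++t) {
      int d = doc_ids(t), v = word_ids(t), f = z(t);
      n_df(d, f) -= 1.0;
      for (int g = 0; g < k; ++g) {
        w(g) = (n_df(d, g) + alpha) * phi(g, v);
      }
      f = sample_cat(w);
      z(t) = f;
      n_df(d, f) += 1.0;
    }
    if (sweep >= n_sweeps - n_avg) {
      for (int d = 0; d < n_docs; ++d) {
        for (int g = 0; g < k; ++g) {
          theta_acc(d, g) += (n_df(d, g) + alpha) / (n_d(d) + k * alpha);
        }
      }
      ++n_acc;
    }
  }
  arma::mat theta = theta_acc / std::max(n_acc, 1);
  theta.each_col() /= arma::sum(theta, 1);
  return theta;
}
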