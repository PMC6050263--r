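#' Configuration for the IBP latent-feature sampler
#'
#' @param alpha_prior length-2 vector `(shape, rate)` of the Gamma
#'   hyperprior on the IBP concentration `alpha` (default `c(1, 1)`).
#' @param sigma_x noise scale: either a single value or a grid of candidate
#'   values resampled by conditional posterior weight each sweep. `NULL`
#'   (default) uses a data-adaptive log-spaced grid.
#' @param sigma_a loading scale, same conventions as `sigma_x`.
#' @param n_sweeps total Gibbs sweeps (default 1000).
#' @param burn_in sweeps discarded before sampling (default 500; must be
#'   `< n_sweeps`).
#' @param max_new_features_per_step cap on new features proposed per
#'   subject per sweep (default 4).
#' @param thin keep every `thin`-th post-burn-in sample (default 1).
#' @param n_restarts independent chains run from different initializations;
#'   the chain containing the maximum-joint-posterior sample is kept
#'   (default 3). Latent-feature Gibbs samplers are prone to
#'   "split-feature" local optima; restarts plus posterior-based selection
#'   are the standard remedy.
#' @param seed integer seed.
#' @return An `ibp_config` list.
#' @export
ibp_config <- function(alpha_prior = c(1, 1), sigma_x = NULL, sigma_a = NULL,
                       n_sweeps = 1000L, burn_in = 500L,
                       max_new_features_per_step = 4L, thin = 1L,
                       n_restarts = 3L, seed = 1L) {
  if (burn_in >= n_sweeps) stop("burn_in must be < n_sweeps")
  if (length(alpha_prior) != 2L || any(alpha_prior <= 0)) {
    stop("alpha_prior must be two positive numbers (shape, rate)")
  }
  if (!is.null(sigma_x) && any(sigma_x <= 0)) stop("sigma_x values must be > 0")
  if (!is.null(sigma_a) && any(sigma_a <= 0)) stop("sigma_a values must be > 0")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  structure(list(alpha_prior = alpha_prior, sigma_x = sigma_x,
                 sigma_a = sigma_a, n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in),
                 max_new_features_per_step = as.integer(max_new_features_per_step),
                 thin = as.integer(thin), n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "ibp_config")
}

#' Collapsed log marginal likelihood of the linear-Gaussian feature model
#'
#' `log p(X | Z, sigma_x, sigma_a)` with the Gaussian loadings integrated
#' out analytically:
#' \deqn{-\frac{ND}{2}\log 2\pi - (N-K)D\log\sigma_x - KD\log\sigma_a
#'   - \frac{D}{2}\log|Z^\top Z + \frac{\sigma_x^2}{\sigma_a^2} I|
#'   - \frac{1}{2\sigma_x^2}\mathrm{tr}\,X^\top(I - Z M Z^\top)X}
#' with \eqn{M = (Z^\top Z + \frac{\sigma_x^2}{\sigma_a^2} I)^{-1}}.
#' At `K = 0` this reduces to the product of `N(0, sigma_x^2)` densities of
#' the entries of `X`.
#'
#' @param Z binary matrix, subjects x features (may have 0 columns).
#' @param X numeric matrix (or [cohort_matrix()]), subjects x edges.
#' @param sigma_x,sigma_a noise and loading scales.
#' @return Log marginal likelihood (scalar).
#' @export
collapsed_loglik <- function(Z, X, sigma_x, sigma_a) {
  if (inherits(X, "cohort_matrix")) X <- X$X
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(X)) stop("Z and X row dimensions disagree")
  storage.mode(Z) <- "double"
  cpp_collapsed_loglik(Z, X, sigma_x, sigma_a)
}

# conditional probability the collapsed Gibbs sampler assigns to z_ik = 1
# given the rest of Z (shared features only, prior mass m_{-i,k} / N)
ibp_conditional_z <- function(Z, X, i, k, sigma_x, sigma_a) {
  if (inherits(X, "cohort_matrix")) X <- X$X
  n <- nrow(Z)
  m_minus <- sum(Z[-i, k])
  if (m_minus == 0) return(0)
  Z1 <- Z; Z1[i, k] <- 1
  Z0 <- Z; Z0[i, k] <- 0
  lp1 <- log(m_minus / n) + collapsed_loglik(Z1, X, sigma_x, sigma_a)
  lp0 <- log(1 - m_minus / n) + collapsed_loglik(Z0, X, sigma_x, sigma_a)
  1 / (1 + exp(lp0 - lp1))
}

#' Log pmf of the Indian Buffet Process prior
#'
#' Exchangeable (left-ordered-class) form of `P(Z | alpha)`.
#'
#' @param Z binary matrix with no all-zero columns.
#' @param alpha concentration parameter.
#' @return Log prior probability.
#' @export
log_ibp_prior <- function(Z, alpha) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- nrow(Z)
  if (ncol(Z) == 0L) return(-alpha * sum(1 / seq_len(n)))
  cpp_log_ibp_prior(Z, alpha)
}

#' Simulate binary feature matrices from the IBP prior
#'
#' Sequential "buffet" construction: subject `i` takes existing dish `k`
#' with probability `m_k / i` and tries `Poisson(alpha / i)` new dishes.
#' The expected number of non-empty dishes after `n` subjects is
#' `alpha * H_n` (harmonic number).
#'
#' @param n_subjects number of subjects.
#' @param alpha concentration.
#' @return Binary matrix (may have 0 columns).
#' @export
simulate_ibp_prior <- function(n_subjects, alpha) {
  Z <- matrix(0L, n_subjects, 0)
  for (i in seq_len(n_subjects)) {
    if (ncol(Z) > 0) {
      m <- colSums(Z[seq_len(i - 1), , drop = FALSE])
      Z[i, ] <- as.integer(stats::runif(ncol(Z)) < m / i)
    }
    k_new <- stats::rpois(1, alpha / i)
    if (k_new > 0) {
      newcols <- matrix(0L, n_subjects, k_new)
      newcols[i, ] <- 1L
      Z <- cbind(Z, newcols)
    }
  }
  Z
}

#' Resample the IBP concentration parameter
#'
#' Conjugate update: `alpha | K+, n ~ Gamma(a + K+, b + H_n)` where `H_n`
#' is the n-th harmonic number.
#'
#' @param K_plus current number of non-empty features.
#' @param n_subjects number of subjects.
#' @param prior length-2 `(shape a, rate b)` of the Gamma hyperprior.
#' @param seed optional integer seed (set for a reproducible single draw;
#'   leave `NULL` inside a sampler).
#' @return One draw of `alpha`.
#' @export
sample_alpha <- function(K_plus, n_subjects, prior = c(1, 1), seed = NULL) {
  if (length(prior) != 2L || any(prior <= 0)) stop("invalid Gamma prior")
  if (K_plus < 0) stop("K_plus must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  H_n <- sum(1 / seq_len(n_subjects))
  stats::rgamma(1, shape = prior[1] + K_plus, rate = prior[2] + H_n)
}

#' Posterior mean loadings given a feature assignment
#'
#' Ridge-regularized normal equations
#' `A = (Z'Z + (sigma_x^2 / sigma_a^2) I)^-1 Z'X` — the posterior mean of
#' the Gaussian loadings conditional on `Z`; always well-posed.
#'
#' @param Z binary matrix with no all-zero columns.
#' @param X numeric matrix or [cohort_matrix()].
#' @param sigma_x,sigma_a noise and loading scales.
#' @return `K x n_edges` loading matrix.
#' @export
posterior_mean_loadings <- function(Z, X, sigma_x, sigma_a) {
  if (inherits(X, "cohort_matrix")) X <- X$X
  Z <- as.matrix(Z)
  if (ncol(Z) == 0L) return(matrix(0, 0, ncol(X)))
  if (any(colSums(Z) == 0)) stop("Z contains an all-zero column; prune first")
  storage.mode(Z) <- "double"
  ridge <- (sigma_x^2) / (sigma_a^2)
  solve(crossprod(Z) + diag(ridge, ncol(Z)), crossprod(Z, X))
}

default_sigma_grid <- function(X, what = c("x", "a")) {
  what <- match.arg(what)
  s <- stats::sd(as.vector(X))
  if (!is.finite(s) || s == 0) s <- 1
  if (what == "x") s * 10^seq(-1.5, 0.3, length.out = 8)
  else s * 10^seq(-0.7, 0.7, length.out = 6)
}

#' Fit the IBP linear-Gaussian latent-feature model
#'
#' Collapsed Gibbs sampling: per sweep, each subject's assignment to every
#' shared feature is resampled from its collapsed conditional; new features
#' are born (and singletons die) through a Metropolis–Hastings step with
#' truncated-Poisson(`alpha/n`) proposals; `sigma_x` and `sigma_a` are
#' resampled over fixed grids by conditional posterior weight; `alpha` gets
#' its conjugate Gamma update. The number of features is thus inferred from
#' the data rather than fixed in advance.
#'
#' @param X numeric matrix or [cohort_matrix()], subjects x edges; must be
#'   finite with >= 2 subjects.
#' @param config an [ibp_config()].
#' @return An `ibp_posterior` list: `z_samples`, `K_trace`, `alpha_trace`,
#'   `joint_logpost_trace`, `loglik_trace`, `sigma_x_trace`,
#'   `sigma_a_trace`, `selected_Z` (maximum-joint-posterior sample,
#'   left-ordered, no empty columns), `A_mean` (posterior mean loadings for
#'   `selected_Z`), `sigma_x`, `sigma_a` (scales at the selected sample),
#'   and `n_subjects`.
#' @export
fit_ibp <- function(X, config = ibp_config()) {
  if (inherits(X, "cohort_matrix")) X <- X$X
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite")
  if (nrow(X) < 2L) stop("X must have at least 2 subjects")
  stopifnot(inherits(config, "ibp_config"))

  sx_grid <- if (is.null(config$sigma_x)) default_sigma_grid(X, "x") else config$sigma_x
  sa_grid <- if (is.null(config$sigma_a)) default_sigma_grid(X, "a") else config$sigma_a

  n <- nrow(X)
  # initialize at the approximate signal rank (components covering 90% of
  # variance, capped): growing features one singleton birth at a time from a
  # near-empty start mixes far too slowly when many features are present
  sv <- svd(X, nu = 0, nv = 0)$d^2
  K_init <- if (sum(sv) <= 0) 1L else
    max(1L, min(unname(which(cumsum(sv) / sum(sv) >= 0.9)[1]),
                floor(n / 4), 30L))
  chains <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(derive_seed(config$seed, paste0("ibp-gibbs-", r)))
    Z_init <- matrix(as.numeric(stats::runif(n * K_init) < 0.3), n, K_init)
    Z_init <- Z_init[, colSums(Z_init) > 0, drop = FALSE]
    chains[[r]] <- cpp_ibp_gibbs(
      X, config$alpha_prior[1], config$alpha_prior[2],
      sx_grid, sa_grid, config$n_sweeps, config$burn_in,
      config$max_new_features_per_step, Z_init,
      alpha_init = 1,
      sx_init = which.min(abs(sx_grid - stats::sd(X))) - 1L,
      sa_init = length(sa_grid) %/% 2L,
      thin = config$thin)
  }
  res <- chains[[which.max(vapply(chains, function(ch) max(ch$sample_joint),
                                  0))]]

  best <- which.max(res$sample_joint)
  selected <- res$z_samples[[best]]
  if (is.null(dim(selected))) selected <- matrix(selected, n, 0)
  selected <- selected[, colSums(selected) > 0, drop = FALSE]
  selected <- left_order(selected)
  storage.mode(selected) <- "integer"
  best_sx <- res$sample_sx[best]
  best_sa <- res$sample_sa[best]
  A_mean <- posterior_mean_loadings(selected, X, best_sx, best_sa)

  structure(list(z_samples = res$z_samples, K_trace = res$K_trace,
                 alpha_trace = res$alpha_trace,
                 loglik_trace = res$loglik_trace,
                 joint_logpost_trace = res$joint_logpost_trace,
                 sigma_x_trace = res$sx_trace, sigma_a_trace = res$sa_trace,
                 sample_joint = res$sample_joint,
                 selected_Z = selected, A_mean = A_mean,
                 sigma_x = best_sx, sigma_a = best_sa,
                 n_subjects = n, config = config),
            class = "ibp_posterior")
}

#' Select the property-assignment matrix from an IBP posterior
#'
#' Returns the stored post-burn-in sample with the highest joint log
#' posterior, all-zero columns removed and columns in left-ordered canonical
#' form, as the discrete positive-valued representation handed to the LDA
#' stage.
#'
#' @param posterior an `ibp_posterior` from [fit_ibp()].
#' @return A `property_assignments` list with binary matrix `Z` and
#'   `property_ids`.
#' @export
select_assignment <- function(posterior) {
  stopifnot(inherits(posterior, "ibp_posterior"))
  if (length(posterior$z_samples) == 0L) {
    stop("posterior holds no post-burn-in samples")
  }
  best <- which.max(posterior$sample_joint)
  Z <- as.matrix(posterior$z_samples[[best]])
  Z <- Z[, colSums(Z) > 0, drop = FALSE]
  property_assignments(left_order(Z))
}

#' Construct a property-assignments object
#'
#' @param Z binary matrix, subjects x properties.
#' @param property_ids optional property identifiers.
#' @return A `property_assignments` list.
#' @export
property_assignments <- function(Z, property_ids = NULL) {
  Z <- as.matrix(Z)
  if (length(Z) && !all(Z %in% c(0, 1))) stop("Z entries must be 0/1")
  storage.mode(Z) <- "integer"
  if (is.null(property_ids)) property_ids <- sprintf("prop%02d", seq_len(ncol(Z)))
  structure(list(Z = Z, property_ids = property_ids),
            class = "property_assignments")
}
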