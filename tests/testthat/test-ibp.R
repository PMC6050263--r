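test_that("collapsed likelihood closed form is exact at K = 0 and symmetric", {
  set.seed(31)
  X <- matrix(rnorm(12), 4, 3)
  Z0 <- matrix(0, 4, 0)
  expect_equal(collapsed_loglik(Z0, X, 0.7, 1.3),
               sum(dnorm(X, sd = 0.7, log = TRUE)))
  Z <- matrix(rbinom(8, 1, 0.5), 4, 2)
  Z[1, ] <- c(1, 0)  # ensure the two columns differ
  expect_equal(collapsed_loglik(Z, X, 0.5, 1.1),
               collapsed_loglik(Z[, 2:1], X, 0.5, 1.1), tolerance = 1e-12)
})

test_that("collapsed likelihood matches an independent determinant oracle", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(3:6, 1); D <- sample(2:4, 1); K <- sample(1:3, 1)
    Z <- matrix(rbinom(n * K, 1, 0.5), n, K)
    X <- matrix(rnorm(n * D), n, D)
    sx <- runif(1, 0.3, 1); sa <- runif(1, 0.5, 2)
    expect_equal(collapsed_loglik(Z, X, sx, sa),
                 collapsed_loglik_oracle(Z, X, sx, sa), tolerance = 1e-10)
  }
})

test_that("collapsed likelihood agrees with Monte-Carlo integration over loadings", {
  set.seed(33)
  n <- 3; D <- 2; K <- 2
  Z <- matrix(c(1, 0, 1, 0, 1, 1), n, K)
  X <- matrix(rnorm(n * D, sd = 1.2), n, D)
  sx <- 0.8; sa <- 1.1
  n_mc <- 1e6
  # vectorized: draws stacked column-wise, one (K x D) loading matrix per draw
  A_stack <- matrix(rnorm(K * D * n_mc, sd = sa), nrow = K)
  ZA <- Z %*% A_stack                      # n x (D * n_mc)
  resid <- matrix(as.vector(X), n, D * n_mc) - ZA
  dim(resid) <- c(n * D, n_mc)
  ll_draws <- colSums(dnorm(resid, sd = sx, log = TRUE))
  m <- max(ll_draws)
  w <- exp(ll_draws - m)
  mc_ll <- m + log(mean(w))
  # delta-method standard error of log-mean-exp
  mc_se <- sd(w) / (mean(w) * sqrt(n_mc))
  expect_lt(abs(collapsed_loglik(Z, X, sx, sa) - mc_ll), 3 * mc_se)
})

test_that("Gibbs conditionals match exhaustive joint-posterior enumeration", {
  set.seed(34)
  n <- 3; K <- 2; D <- 2
  X <- matrix(rnorm(n * D), n, D)
  sx <- 0.6; sa <- 1.0; alpha <- 1.5
  # joint-based conditional using only the independent oracle pieces:
  # P(z_ik = 1 | Z_-ik, X) = joint(Z: z_ik=1) / (joint(0) + joint(1))
  count_prior <- function(Z) {
    # exchangeable column-count factor of the IBP pmf (shared columns only;
    # the fixtures below never create duplicate or empty columns)
    sum(vapply(seq_len(ncol(Z)), function(k) {
      m <- sum(Z[, k])
      lgamma(nrow(Z) - m + 1) + lgamma(m) - lgamma(nrow(Z) + 1)
    }, 0))
  }
  fixtures <- list(
    list(Z = matrix(c(1, 1, 0, 0, 1, 1), n, K), i = 1, k = 2),
    list(Z = matrix(c(1, 1, 1, 1, 0, 1), n, K), i = 3, k = 2),
    list(Z = matrix(c(0, 1, 1, 1, 1, 0), n, K), i = 1, k = 1))
  for (fx in fixtures) {
    Z1 <- fx$Z; Z1[fx$i, fx$k] <- 1
    Z0 <- fx$Z; Z0[fx$i, fx$k] <- 0
    stopifnot(all(colSums(Z0) > 0),
              !any(duplicated(t(Z0))), !any(duplicated(t(Z1))))
    lj1 <- collapsed_loglik_oracle(Z1, X, sx, sa) + count_prior(Z1)
    lj0 <- collapsed_loglik_oracle(Z0, X, sx, sa) + count_prior(Z0)
    p_enum <- 1 / (1 + exp(lj0 - lj1))
    p_gibbs <- endofactor:::ibp_conditional_z(fx$Z, X, fx$i, fx$k, sx, sa)
    expect_equal(p_gibbs, p_enum, tolerance = 1e-6)
  }
})

test_that("the IBP prior predictive mean feature count is alpha * H_n", {
  set.seed(35)
  alpha <- 2; n <- 10
  H_n <- sum(1 / seq_len(n))
  draws <- replicate(2000, ncol(simulate_ibp_prior(n, alpha)))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - alpha * H_n), 3 * se)  # alpha * H_10 = 5.859
})

test_that("alpha resampling follows its conjugate Gamma update", {
  expect_equal(sum(1 / seq_len(10)), 2.928968, tolerance = 1e-6)
  set.seed(36)
  # (a=1,b=1,K=0,n=1): Gamma(1, 2), mean 0.5
  d1 <- replicate(1e5, sample_alpha(0, 1, prior = c(1, 1)))
  expect_equal(mean(d1), 0.5, tolerance = 0.01 / 0.5)
  # general case vs analytic mean (a + K) / (b + H_n)
  a <- 2; b <- 3; K <- 7; n <- 50
  d2 <- replicate(1e5, sample_alpha(K, n, prior = c(a, b)))
  mu <- (a + K) / (b + sum(1 / seq_len(n)))
  se <- sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - mu), 3 * se)
})

test_that("posterior mean loadings solve the ridge normal equations", {
  set.seed(37)
  # identity Z, vanishing ridge: loadings approach the data rows
  X <- matrix(rnorm(5 * 4), 5, 4)
  A <- posterior_mean_loadings(diag(5), X, sigma_x = 1e-4, sigma_a = 10)
  expect_equal(unname(A), X, tolerance = 1e-6)
  # generic ridge oracle
  Z <- matrix(rbinom(6 * 3, 1, 0.6), 6, 3)
  Z[, colSums(Z) == 0] <- 1
  ridge <- (0.5^2) / (1.2^2)
  oracle <- qr.solve(rbind(Z, sqrt(ridge) * diag(3)),
                     rbind(X2 <- matrix(rnorm(6 * 4), 6, 4), matrix(0, 3, 4)))
  expect_equal(posterior_mean_loadings(Z, X2, 0.5, 1.2), oracle,
               tolerance = 1e-8)
  # K = 1 all-ones column: scalar closed form
  Z1 <- matrix(1, 6, 1)
  A1 <- posterior_mean_loadings(Z1, X2, 0.5, 1.2)
  expect_equal(as.vector(A1), colSums(X2) / (6 + ridge), tolerance = 1e-12)
  expect_error(posterior_mean_loadings(cbind(Z1, 0), X2, 0.5, 1.2),
               "all-zero")
})

test_that("assignment selection picks the MAP sample in left-ordered form", {
  expect_identical(left_order(matrix(c(0, 1, 1, 0), 2, 2)),
                   matrix(c(1, 0, 0, 1), 2, 2))
  post <- structure(list(
    z_samples = list(matrix(c(1, 0, 0, 1), 2, 2),
                     matrix(c(0, 1, 1, 0), 2, 2),
                     matrix(c(1, 1, 1, 1), 2, 2)),
    sample_joint = c(-5, -3, -9)), class = "ibp_posterior")
  sel <- select_assignment(post)
  expect_identical(unname(sel$Z),
                   matrix(c(1L, 0L, 0L, 1L), 2, 2))  # second, left-ordered
  # fuzzed posteriors never yield an all-zero column
  set.seed(38)
  for (rep in 1:20) {
    zs <- lapply(1:4, function(i) {
      matrix(rbinom(12, 1, 0.3), 4, 3)
    })
    p2 <- structure(list(z_samples = zs, sample_joint = rnorm(4)),
                    class = "ibp_posterior")
    Zsel <- select_assignment(p2)$Z
    if (ncol(Zsel) > 0) expect_true(all(colSums(Zsel) > 0))
  }
})

test_that("the sampler recovers a noise-free planted structure", {
  dat <- make_planted_lgm(n = 100, D = 20, K = 3, noise_sd = 0.05, seed = 39)
  fit <- fit_ibp(dat$X, ibp_config(n_sweeps = 300, burn_in = 150,
                                   n_restarts = 2, seed = 5))
  expect_gte(ncol(fit$selected_Z), 3)
  expect_lte(ncol(fit$selected_Z), 5)
  m <- endofactor:::match_binary_columns(fit$selected_Z, dat$Z)
  expect_lte(m$mismatches / m$cells, 0.02)
})

test_that("an all-zero data matrix yields no latent features", {
  X <- matrix(0, 30, 8)
  fit <- fit_ibp(X, ibp_config(n_sweeps = 100, burn_in = 50,
                               n_restarts = 1, seed = 2))
  expect_identical(ncol(fit$selected_Z), 0L)
})

test_that("the sampler is deterministic given seed and config", {
  dat <- make_planted_lgm(n = 30, D = 8, K = 2, noise_sd = 0.3, seed = 40)
  cfg <- ibp_config(n_sweeps = 80, burn_in = 40, n_restarts = 2, seed = 77)
  f1 <- fit_ibp(dat$X, cfg)
  f2 <- fit_ibp(dat$X, cfg)
  expect_identical(f1$K_trace, f2$K_trace)
  expect_identical(f1$joint_logpost_trace, f2$joint_logpost_trace)
  expect_identical(f1$selected_Z, f2$selected_Z)
  expect_error(fit_ibp(matrix(c(1, NA, 2, 3), 2, 2), cfg), "finite")
})

test_that("subject exchangeability: permuted rows recover the same structure", {
  # row order carries no information: fitting the original and a permuted
  # cohort (different RNG paths) must both land on the planted structure
  dat <- make_planted_lgm(n = 60, D = 15, K = 2, noise_sd = 0.1, seed = 41)
  cfg <- ibp_config(n_sweeps = 400, burn_in = 200, n_restarts = 3, seed = 9)
  f1 <- fit_ibp(dat$X, cfg)
  set.seed(42)
  perm <- sample(nrow(dat$X))
  f2 <- fit_ibp(dat$X[perm, ], cfg)
  m1 <- endofactor:::match_binary_columns(f1$selected_Z, dat$Z)
  m2 <- endofactor:::match_binary_columns(f2$selected_Z[order(perm), ,
                                                        drop = FALSE],
                                          dat$Z)
  expect_lte(m1$mismatches / m1$cells, 0.02)
  expect_lte(m2$mismatches / m2$cells, 0.02)
})
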