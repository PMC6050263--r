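test_that("theta and phi live on their simplices for any fit", {
  set.seed(51)
  Z <- matrix(rbinom(40 * 10, 1, 0.3), 40, 10)
  Z[1, ] <- 0  # an empty subject
  fit <- fit_lda(Z, lda_config(k = 3, n_sweeps = 200, burn_in = 100,
                               seed = 4))
  expect_true(all(abs(rowSums(fit$theta) - 1) < 1e-8))
  expect_true(all(abs(rowSums(fit$phi) - 1) < 1e-8))
  expect_true(all(fit$theta >= 0) && all(fit$phi >= 0))
  expect_true(fit$empty_subjects[1])
  expect_equal(fit$theta[1, ], rep(1 / 3, 3))
})

test_that("k = 1 collapses to the smoothed empirical property frequencies", {
  set.seed(52)
  Z <- matrix(rbinom(30 * 6, 1, 0.4), 30, 6)
  Z[rowSums(Z) == 0, 1] <- 1
  beta <- 0.1
  fit <- fit_lda(Z, lda_config(k = 1, alpha_lda = 1, beta_lda = beta,
                               n_sweeps = 50, burn_in = 10, seed = 1))
  counts <- colSums(Z)
  expect_equal(as.vector(fit$phi),
               (counts + beta) / (sum(counts) + 6 * beta), tolerance = 1e-10)
  expect_equal(as.vector(fit$theta), rep(1, 30))
})

test_that("planted disjoint-support factors are recovered", {
  set.seed(53)
  n <- 300; K <- 45; k <- 3
  theta <- matrix(rgamma(n * k, 0.5), n, k); theta <- theta / rowSums(theta)
  phi <- matrix(0, k, K)
  for (f in seq_len(k)) phi[f, ((f - 1) * 15 + 1):(f * 15)] <- 1 / 15
  Z <- matrix(rbinom(n * K, 1, pmin(1, 8 * theta %*% phi)), n, K)
  fit <- fit_lda(Z, lda_config(k = 3, seed = 3))
  perm <- match_factors(fit$phi, phi)
  expect_lte(mean(abs(fit$theta[, perm] - theta)), 0.15)
  for (f in seq_len(k)) {
    expect_gte(cor(fit$phi[perm[f], ], phi[f, ]), 0.8)
  }
})

test_that("fold-in inference respects supports, emptiness, and seeds", {
  set.seed(54)
  K <- 60  # 20 properties per factor so a pure subject carries many tokens
  phi <- matrix(0, 3, K)
  phi[1, 1:20] <- 1 / 20; phi[2, 21:40] <- 1 / 20; phi[3, 41:60] <- 1 / 20
  model <- structure(list(phi = phi, config = lda_config(k = 3)),
                     class = "factor_model")
  pure2 <- rep(0, K); pure2[21:40] <- 1   # active across factor 2's support
  Znew <- rbind(pure2, rep(0, K))
  th <- infer_theta_new(property_assignments(Znew), model, seed = 8)
  expect_gte(th[1, 2], 0.9)
  expect_equal(th[2, ], rep(1 / 3, 3))
  expect_identical(th, infer_theta_new(property_assignments(Znew), model,
                                       seed = 8))
  bad <- property_assignments(matrix(1, 2, K + 1))
  expect_error(infer_theta_new(bad, model), "match")
})

test_that("factor edge weights are the phi-projection of the loadings", {
  set.seed(55)
  A <- matrix(rnorm(5 * 210), 5, 210)
  phi <- matrix(0, 3, 5)
  phi[1, 2] <- 1                          # one-hot
  phi[2, ] <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  phi[3, ] <- c(0.5, 0.5, 0, 0, 0)
  model <- structure(list(phi = phi, config = lda_config(k = 3)),
                     class = "factor_model")
  few <- factor_edge_weights(model, A)
  expect_identical(dim(few$W), c(3L, 210L))
  expect_equal(few$W[1, ], A[2, ])
  # linearity: the weight map of an averaged phi is the average of maps
  mavg <- model; mavg$phi <- (phi + phi[c(2, 3, 1), ]) / 2
  expect_equal(factor_edge_weights(mavg, A)$W,
               (few$W + few$W[c(2, 3, 1), ]) / 2)
  expect_error(factor_edge_weights(model, A[1:4, ]), "align")
})

test_that("biological labels are the argmax factor with low-index ties", {
  expect_identical(assign_biological_label(c(0.6, 0.3, 0.1)), 0L)
  expect_identical(assign_biological_label(c(0.5, 0.5, 0.0)), 0L)
  expect_identical(assign_biological_label(c(0.2, 0.3, 0.5)), 2L)
  expect_identical(assign_biological_label(rbind(c(1, 0), c(0, 1))),
                   c(0L, 1L))
  expect_error(assign_biological_label(c(0.9, 0.3)), "sum to 1")
})

test_that("held-out likelihood of a fitted model is close to the truth's", {
  set.seed(56)
  n <- 200; K <- 20; k <- 3
  gaps <- replicate(10, {
    theta <- matrix(rgamma((n + 60) * k, 0.7), n + 60, k)
    theta <- theta / rowSums(theta)
    phi <- matrix(rgamma(k * K, 0.3), k, K); phi <- phi / rowSums(phi)
    Z <- matrix(rbinom((n + 60) * K, 1, pmin(1, 6 * theta %*% phi)),
                n + 60, K)
    keep <- rowSums(Z) > 0
    Z <- Z[keep, ]; theta <- theta[keep, ]
    tr <- seq_len(min(n, nrow(Z) - 40)); ho <- setdiff(seq_len(nrow(Z)), tr)
    fit <- fit_lda(Z[tr, ], lda_config(k = k, n_sweeps = 400,
                                       burn_in = 200, seed = 1))
    ll_fit <- lda_heldout_loglik(fit, property_assignments(Z[ho, ]), seed = 2)
    truth <- structure(list(phi = phi, config = lda_config(k = k)),
                       class = "factor_model")
    ll_true <- lda_heldout_loglik(truth, property_assignments(Z[ho, ]),
                                  seed = 3)
    (ll_true - ll_fit) / abs(ll_true)
  })
  expect_lte(median(gaps), 0.05)
})

test_that("k = 2 factors are perfectly anti-correlated on 3-factor data", {
  set.seed(57)
  co <- generate_cohort(synthetic_config(n_subjects = 120, n_edges = 40,
                                         seed = 5))
  fit <- fit_lda(co$ground_truth$Z_true, lda_config(k = 2, seed = 2))
  expect_lte(cor(fit$theta[, 1], fit$theta[, 2]), -0.95)
})
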