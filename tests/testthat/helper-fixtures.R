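# Small fixtures shared across test files; everything is generated in code.

# a small, strong-signal latent-feature dataset for sampler tests
make_planted_lgm <- function(n = 100, D = 20, K = 3, p_active = 0.4,
                             noise_sd = 0, seed = 101) {
  set.seed(seed)
  Z <- matrix(rbinom(n * K, 1, p_active), n, K)
  # guard against empty columns in tiny draws
  for (k in seq_len(K)) if (sum(Z[, k]) == 0) Z[sample(n, 3), k] <- 1L
  A <- matrix(rnorm(K * D, sd = 1), K, D)
  X <- Z %*% A
  if (noise_sd > 0) X <- X + matrix(rnorm(n * D, sd = noise_sd), n, D)
  list(Z = Z, A = A, X = X)
}

# independent textbook Pearson correlation (no cor())
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# independent collapsed marginal likelihood via determinant/solve in R --
# a separate code path from the compiled implementation
collapsed_loglik_oracle <- function(Z, X, sx, sa) {
  N <- nrow(X); D <- ncol(X); K <- ncol(Z)
  if (K == 0) return(sum(dnorm(X, sd = sx, log = TRUE)))
  M <- solve(crossprod(Z) + diag((sx^2) / (sa^2), K))
  quad <- sum(diag(t(X) %*% (diag(N) - Z %*% M %*% t(Z)) %*% X))
  -N * D / 2 * log(2 * pi) - (N - K) * D * log(sx) - K * D * log(sa) -
    D / 2 * determinant(crossprod(Z) + diag((sx^2) / (sa^2), K))$modulus[1] -
    quad / (2 * sx^2)
}

# exact assignment-aligned label agreement for k-class labelings
aligned_label_agreement <- function(labels, truth, k) {
  perms <- endofactor:::all_permutations(k)
  max(apply(perms, 1, function(p) mean((p[labels + 1] - 1) == truth)))
}
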