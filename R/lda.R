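#' Configuration for the mixed-membership factor model
#'
#' Latent Dirichlet allocation over property assignments: subjects are
#' documents, active properties are tokens of count 1, factors are topics.
#'
#' Default `alpha_lda = 1`: subjects carry only a handful of active
#' properties (tens of tokens at most), so the heavy smoothing conventional
#' for large text corpora would pull every factor-weight vector to the
#' uniform point; a unit concentration keeps theta informative while still
#' proper.
#'
#' @param k number of factors (>= 1; 3 in the reference analysis).
#' @param alpha_lda symmetric document–factor concentration (> 0).
#' @param beta_lda symmetric factor–property concentration (> 0,
#'   default 0.1).
#' @param n_sweeps total Gibbs sweeps (default 1000).
#' @param burn_in sweeps discarded (default 500).
#' @param seed integer seed.
#' @return An `lda_config` list.
#' @export
lda_config <- function(k = 3L, alpha_lda = 1, beta_lda = 0.1,
                       n_sweeps = 1000L, burn_in = 500L, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (alpha_lda <= 0 || beta_lda <= 0) stop("concentrations must be > 0")
  if (burn_in >= n_sweeps) stop("burn_in must be < n_sweeps")
  structure(list(k = as.integer(k), alpha_lda = alpha_lda,
                 beta_lda = beta_lda, n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "lda_config")
}

assignments_to_tokens <- function(Z) {
  idx <- which(Z == 1, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  list(doc = as.integer(idx[ord, 1] - 1L), word = as.integer(idx[ord, 2] - 1L))
}

#' Fit the k-factor mixed-membership model over property assignments
#'
#' Collapsed Gibbs sampling of token–factor indicators; `theta` (subject
#' factor weights on the k-simplex) and `phi` (per-factor property
#' distributions) are posterior means over post-burn-in sweeps. Subjects
#' with zero active properties receive the uniform `theta = 1/k` and are
#' flagged.
#'
#' @param assignments a [property_assignments()] (or binary matrix).
#' @param config an [lda_config()].
#' @return A `factor_model` list: `phi` (k x K), `theta` (n x k),
#'   `empty_subjects` (logical flag vector), `property_ids`, `config`.
#' @export
fit_lda <- function(assignments, config = lda_config()) {
  if (!inherits(assignments, "property_assignments")) {
    assignments <- property_assignments(assignments)
  }
  stopifnot(inherits(config, "lda_config"))
  Z <- assignments$Z
  if (sum(Z) == 0L) stop("empty corpus: no subject has an active property")
  if (config$k > ncol(Z)) {
    warning("k exceeds the number of properties; factors will be redundant")
  }
  tok <- assignments_to_tokens(Z)
  set.seed(derive_seed(config$seed, "lda-gibbs"))
  res <- cpp_lda_gibbs(tok$doc, tok$word, nrow(Z), ncol(Z), config$k,
                       config$alpha_lda, config$beta_lda,
                       config$n_sweeps, config$burn_in)
  empty <- rowSums(Z) == 0
  theta <- res$theta
  theta[empty, ] <- 1 / config$k
  structure(list(phi = res$phi, theta = theta, empty_subjects = empty,
                 property_ids = assignments$property_ids, config = config),
            class = "factor_model")
}

#' Infer factor weights for new subjects with a trained model
#'
#' Fold-in Gibbs sampling with `phi` frozen: 200 sweeps, `theta` averaged
#' over the last 100. Subjects with zero active properties receive the
#' uniform `theta`.
#'
#' @param assignments_new a [property_assignments()] over the same property
#'   set as the trained model.
#' @param model a `factor_model` from [fit_lda()].
#' @param seed integer seed.
#' @param n_sweeps,n_avg fold-in sweep counts.
#' @return Row-stochastic matrix, new subjects x k.
#' @export
infer_theta_new <- function(assignments_new, model, seed = 1L,
                            n_sweeps = 200L, n_avg = 100L) {
  if (!inherits(assignments_new, "property_assignments")) {
    assignments_new <- property_assignments(assignments_new)
  }
  stopifnot(inherits(model, "factor_model"))
  Z <- assignments_new$Z
  if (ncol(Z) != ncol(model$phi)) {
    stop("property set of the new assignments does not match the model")
  }
  k <- nrow(model$phi)
  if (sum(Z) == 0L) return(matrix(1 / k, nrow(Z), k))
  tok <- assignments_to_tokens(Z)
  set.seed(derive_seed(seed, "lda-foldin"))
  theta <- cpp_lda_foldin(tok$doc, tok$word, nrow(Z), model$phi,
                          model$config$alpha_lda, n_sweeps, n_avg)
  theta[rowSums(Z) == 0, ] <- 1 / k
  theta
}

#' Project factors onto edge-coupling weight maps
#'
#' Each factor's property distribution is pushed through the posterior mean
#' loadings: `W = phi %*% A_mean`, giving a `k x n_edges` map of how each
#' factor expresses itself in connectivity space (row f is the
#' phi-weighted convex combination of the property loading rows).
#'
#' @param model a `factor_model`.
#' @param A_mean `K x n_edges` loading matrix (e.g. from [fit_ibp()]).
#' @param edge_names_ optional edge names.
#' @return A `factor_edge_weights` list with matrix `W` and `edge_names`.
#' @export
factor_edge_weights <- function(model, A_mean, edge_names_ = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (ncol(model$phi) != nrow(A_mean)) {
    stop("phi columns do not align with loading rows")
  }
  W <- model$phi %*% A_mean
  if (is.null(edge_names_)) edge_names_ <- colnames(A_mean)
  structure(list(W = W, edge_names = edge_names_),
            class = "factor_edge_weights")
}

#' Assign a biological group label from factor weights
#'
#' The label is the index (0-based) of the most important factor — the
#' argmax of the subject's theta row, ties broken toward the lowest index.
#'
#' @param theta_row numeric vector on the k-simplex (sums to 1 within 1e-6),
#'   or a row-stochastic matrix (one label per row).
#' @return Integer label(s) in `0:(k-1)`.
#' @export
assign_biological_label <- function(theta_row) {
  if (is.matrix(theta_row)) {
    return(vapply(seq_len(nrow(theta_row)),
                  function(i) assign_biological_label(theta_row[i, ]),
                  integer(1)))
  }
  if (any(!is.finite(theta_row)) || any(theta_row < -1e-9) ||
      abs(sum(theta_row) - 1) > 1e-6) {
    stop("theta row must be non-negative and sum to 1")
  }
  as.integer(which.max(theta_row) - 1L)
}

#' Held-out per-token log-likelihood of a factor model
#'
#' Average `log sum_f theta_df phi_fv` over the active properties of the
#' held-out subjects, with `theta` inferred by fold-in. Used to compare
#' models across `k`.
#'
#' @param model a `factor_model`.
#' @param assignments_holdout held-out [property_assignments()].
#' @param seed integer seed for the fold-in step.
#' @return Mean per-token log-likelihood.
#' @export
lda_heldout_loglik <- function(model, assignments_holdout, seed = 1L) {
  if (!inherits(assignments_holdout, "property_assignments")) {
    assignments_holdout <- property_assignments(assignments_holdout)
  }
  Z <- assignments_holdout$Z
  theta <- infer_theta_new(assignments_holdout, model, seed = seed)
  tok <- assignments_to_tokens(Z)
  p <- rowSums(theta[tok$doc + 1L, , drop = FALSE] *
                 t(model$phi)[tok$word + 1L, , drop = FALSE])
  mean(log(p))
}
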