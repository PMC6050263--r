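#' Configuration for pre-validation
#'
#' @param m number of pseudo-randomized splits (default 10, the reference
#'   protocol value; must be >= 2 and no larger than the smallest class).
#' @param seed integer seed.
#' @param ibp_config an [ibp_config()] for the internal model.
#' @param lda_config an [lda_config()].
#' @param refit_ibp_per_fold refit the IBP inside every training fold
#'   (default `TRUE`, the statistically cleaner reading); `FALSE` fits the
#'   IBP once on all fingerprints and refits only the LDA per fold.
#' @return A `prevalidation_config` list.
#' @export
prevalidation_config <- function(m = 10L, seed = 1L,
                                 ibp_config = endofactor::ibp_config(),
                                 lda_config = endofactor::lda_config(),
                                 refit_ibp_per_fold = TRUE) {
  if (m < 2) stop("m must be >= 2")
  structure(list(m = as.integer(m), seed = as.integer(seed),
                 ibp_config = ibp_config, lda_config = lda_config,
                 refit_ibp_per_fold = isTRUE(refit_ibp_per_fold)),
            class = "prevalidation_config")
}

#' Stratified pseudo-randomized splits
#'
#' Partitions subjects into `m` folds such that per-class counts across
#' folds differ by at most 1 ("balanced groups in both training and test
#' set"). Deterministic given the seed.
#'
#' @param labels integer (or factor) class labels.
#' @param m number of folds.
#' @param seed integer seed.
#' @return Integer fold assignment in `1:m`, one per subject.
#' @export
make_stratified_splits <- function(labels, m, seed = 1L) {
  labels <- as.integer(as.factor(labels))
  counts <- table(labels)
  if (any(counts < m)) {
    stop(sprintf("class %s has fewer than m = %d members",
                 names(counts)[which(counts < m)[1]], m))
  }
  set.seed(derive_seed(seed, "stratified-splits"))
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    # deal round-robin, rotating the starting fold across classes so the
    # remainder subjects do not pile up in fold 1
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% m) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# Condition held-out rows on trained loadings: per-row collapsed Gibbs over
# z_i with A and sigma_x frozen, feature prior = training prevalence.
# Returns the final sweep's state — an actual draw from the conditional.
# (Thresholding the posterior mean at 0.5 systematically starves subjects of
# active properties when near-duplicate features split the posterior mass.)
infer_assignments_new <- function(X_new, A_mean, sigma_x, prevalence,
                                  n_sweeps = 50L, seed = 1L) {
  X_new <- as.matrix(X_new)
  K <- nrow(A_mean)
  n <- nrow(X_new)
  if (K == 0L) return(matrix(0L, n, 0))
  prevalence <- pmin(pmax(prevalence, 1e-6), 1 - 1e-6)
  lp_prior <- log(prevalence) - log1p(-prevalence)
  set.seed(derive_seed(seed, "ibp-holdout"))
  Zout <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    z <- as.numeric(stats::runif(K) < prevalence)
    resid <- X_new[i, ] - as.vector(z %*% A_mean)
    for (s in seq_len(n_sweeps)) {
      for (k in seq_len(K)) {
        r0 <- if (z[k] == 1) resid + A_mean[k, ] else resid  # z_k = 0 residual
        d1 <- r0 - A_mean[k, ]
        # log-likelihood difference (z_k = 1) - (z_k = 0)
        dll <- (sum(r0^2) - sum(d1^2)) / (2 * sigma_x^2)
        p1 <- 1 / (1 + exp(-(lp_prior[k] + dll)))
        znew <- as.numeric(stats::runif(1) < p1)
        resid <- if (znew == 1) r0 - A_mean[k, ] else r0
        z[k] <- znew
      }
    }
    Zout[i, ] <- as.integer(z)
  }
  Zout
}

#' Pre-validate: derive unbiased brain-derived labels
#'
#' For each of `m` stratified splits, the internal model (IBP feature
#' inference plus LDA factorization) is trained on the other `m - 1` splits
#' only; the held-out subjects' property assignments are then obtained by
#' conditioning on the trained loadings (never re-estimating them), factor
#' weights follow by fold-in, and the biological label is the dominant
#' factor. Every subject's label and theta therefore come from a model that
#' never saw that subject's data — they can be used downstream as if
#' measured on an independent cohort. Clinical labels are used **only** to
#' stratify the splits, never inside the internal model.
#'
#' Fold-specific factor identities are aligned to the first fold by exact
#' assignment on the correlation of training factor weights over the
#' subjects the two training sets share (any two training sets overlap in
#' `m - 2` of the `m` splits), preventing label switching across folds.
#' Edge-weight maps (`phi %*% A_mean`) are used as a fallback when the
#' overlap carries no signal.
#'
#' @param cohort a [cohort_matrix()] (or numeric matrix) of fingerprints.
#' @param clinical_labels integer labels used for stratification only.
#' @param config a [prevalidation_config()].
#' @param fold_assignment optional pre-computed fold vector in `1:m`,
#'   bypassing stratification (the labels are then ignored entirely).
#' @return A `prevalidation_result` list: `labels_prevalidated` (0-based),
#'   `theta_prevalidated` (n x k), `fold_assignment`, `per_fold_models`
#'   (list of fold models with aligned `theta`/`phi`/`W`), `k`.
#' @export
prevalidate <- function(cohort, clinical_labels, config = prevalidation_config(),
                        fold_assignment = NULL) {
  if (inherits(cohort, "cohort_matrix")) X <- cohort$X else X <- as.matrix(cohort)
  n <- nrow(X)
  stopifnot(length(clinical_labels) == n)
  stopifnot(inherits(config, "prevalidation_config"))
  k <- config$lda_config$k

  fold <- if (is.null(fold_assignment)) {
    make_stratified_splits(clinical_labels, config$m,
                           seed = derive_seed(config$seed, "prevalidation"))
  } else {
    stopifnot(length(fold_assignment) == n)
    as.integer(fold_assignment)
  }

  shared_posterior <- NULL
  if (!config$refit_ibp_per_fold) {
    cfg <- config$ibp_config
    cfg$seed <- derive_seed(config$seed, "ibp-shared")
    shared_posterior <- fit_ibp(X, cfg)
  }

  theta_out <- matrix(NA_real_, n, k)
  labels_out <- integer(n)
  models <- vector("list", config$m)
  W_ref <- NULL
  theta_ref <- NULL   # reference fold's training theta, full-cohort indexed

  for (f in seq_len(config$m)) {
    train <- which(fold != f)
    test <- which(fold == f)
    if (length(unique(clinical_labels[train])) < 2L) {
      stop(sprintf("fold %d has fewer than 2 classes in training data", f))
    }
    if (config$refit_ibp_per_fold) {
      cfg <- config$ibp_config
      cfg$seed <- derive_seed(config$seed, paste0("ibp-fold", f))
      post <- fit_ibp(X[train, , drop = FALSE], cfg)
      Z_train <- post$selected_Z
    } else {
      post <- shared_posterior
      Z_train <- post$selected_Z[train, , drop = FALSE]
      keep <- colSums(Z_train) > 0
      Z_train <- Z_train[, keep, drop = FALSE]
    }
    K_f <- ncol(Z_train)

    if (K_f == 0L || sum(Z_train) == 0L) {
      # no structure found in this training set: uniform factor weights
      theta_test <- matrix(1 / k, length(test), k)
      W_f <- matrix(0, k, ncol(X))
      model_f <- NULL
      perm <- seq_len(k)
    } else {
      A_f <- if (config$refit_ibp_per_fold) post$A_mean else
        posterior_mean_loadings(Z_train, X[train, , drop = FALSE],
                                post$sigma_x, post$sigma_a)
      lcfg <- config$lda_config
      lcfg$seed <- derive_seed(config$seed, paste0("lda-fold", f))
      model_f <- fit_lda(property_assignments(Z_train), lcfg)

      Z_test <- infer_assignments_new(
        X[test, , drop = FALSE], A_f, post$sigma_x,
        prevalence = colMeans(Z_train),
        seed = derive_seed(config$seed, paste0("holdout-fold", f)))
      theta_test <- infer_theta_new(
        property_assignments(Z_test, model_f$property_ids), model_f,
        seed = derive_seed(config$seed, paste0("foldin-fold", f)))

      W_f <- model_f$phi %*% A_f
      theta_full <- matrix(NA_real_, n, k)
      theta_full[train, ] <- model_f$theta
      if (is.null(W_ref)) {
        W_ref <- W_f
        theta_ref <- theta_full
        perm <- seq_len(k)
      } else {
        # align on the training subjects the two folds share; fall back to
        # edge-weight maps if the overlap is degenerate
        shared <- which(!is.na(theta_ref[, 1]) & !is.na(theta_full[, 1]))
        ok <- length(shared) >= 3 &&
          all(apply(theta_full[shared, , drop = FALSE], 2, stats::sd) > 0) &&
          all(apply(theta_ref[shared, , drop = FALSE], 2, stats::sd) > 0)
        perm <- if (ok) {
          match_factors(t(theta_full[shared, , drop = FALSE]),
                        t(theta_ref[shared, , drop = FALSE]))
        } else {
          match_factors(W_f, W_ref)
        }
      }
      theta_test <- theta_test[, perm, drop = FALSE]
      W_f <- W_f[perm, , drop = FALSE]
      model_f$phi <- model_f$phi[perm, , drop = FALSE]
      model_f$theta <- model_f$theta[, perm, drop = FALSE]
    }

    theta_out[test, ] <- theta_test
    labels_out[test] <- assign_biological_label(theta_test)
    models[[f]] <- list(model = model_f, W = W_f, fold = f,
                        n_properties = K_f)
  }

  structure(list(labels_prevalidated = labels_out,
                 theta_prevalidated = theta_out,
                 fold_assignment = fold, per_fold_models = models,
                 k = k, config = config),
            class = "prevalidation_result")
}

#' Write pre-validated labels to TSV
#'
#' @param result a `prevalidation_result`.
#' @param path output file.
#' @param subject_ids optional identifiers.
#' @return `path`, invisibly.
#' @export
write_prevalidated <- function(result, path, subject_ids = NULL) {
  stopifnot(inherits(result, "prevalidation_result"))
  n <- length(result$labels_prevalidated)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%04d", seq_len(n))
  df <- data.frame(subject_id = subject_ids, fold = result$fold_assignment,
                   label = result$labels_prevalidated,
                   result$theta_prevalidated)
  names(df)[-(1:3)] <- paste0("theta_", seq_len(result$k))
  write_tsv(df, path)
}
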