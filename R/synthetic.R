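#' Configuration for a synthetic cohort
#'
#' Defines the generative conditions for a cohort with planted latent
#' structure mirroring the model the pipeline fits: binary latent properties
#' `Z_true` with Gaussian edge loadings `A_true`, a mixed-membership factor
#' layer (`theta_true`, `phi_true`) governing which properties activate,
#' additive per-site edge offsets, Gaussian observation noise, and clinical
#' labels that are noisy corruptions of each subject's dominant factor.
#'
#' The defaults define the package's standard synthetic cohort: 600
#' subjects on the 210-edge (21-ROI) network, 15 planted properties grouped
#' under 3 factors with around 6 active properties per subject, unit
#' loading scale with noise scale 0.5, two sites with offset scale 0.1, and
#' a 40% label-corruption rate — a desk-scale analogue of a multi-site,
#' three-group clinical cohort in which many connectivity properties are
#' broadly shared across subjects and categorical diagnoses only partially
#' reflect the underlying biology. The property space is kept rich enough
#' that a subject's dominant factor is identifiable from its assignments;
#' with very few, rarely active properties the dominant factor is
#' statistically under-determined even given the true assignments.
#'
#' @param n_subjects number of subjects.
#' @param n_edges number of connectivity edges (default 210 = choose(21, 2)).
#' @param n_properties_true number of planted binary properties (K_true).
#' @param n_factors_true number of planted factors (must be >= 2 when
#'   labels are generated).
#' @param dirichlet_concentration symmetric Dirichlet concentration for the
#'   per-subject factor weights `theta_true`; values < 1 concentrate mass on
#'   a dominant factor.
#' @param expected_active target mean number of active properties per
#'   subject; activation probabilities `sum_f theta_if phi_fp` are scaled to
#'   this expectation (capped at 1).
#' @param loading_scale standard deviation of the Gaussian edge loadings.
#' @param noise_scale standard deviation of the additive observation noise.
#' @param site_count number of acquisition sites.
#' @param site_effect_scale standard deviation of the per-site per-edge
#'   constant offsets.
#' @param label_flip_rate probability that a subject's clinical label is
#'   replaced by a uniformly drawn different class.
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   bit for bit.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 600L, n_edges = 210L,
                             n_properties_true = 15L, n_factors_true = 3L,
                             dirichlet_concentration = 0.5,
                             expected_active = 6,
                             loading_scale = 1, noise_scale = 0.5,
                             site_count = 2L, site_effect_scale = 0.1,
                             label_flip_rate = 0.4, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_edges = as.integer(n_edges),
              n_properties_true = as.integer(n_properties_true),
              n_factors_true = as.integer(n_factors_true),
              dirichlet_concentration = dirichlet_concentration,
              expected_active = expected_active,
              loading_scale = loading_scale, noise_scale = noise_scale,
              site_count = as.integer(site_count),
              site_effect_scale = site_effect_scale,
              label_flip_rate = label_flip_rate, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  pos <- c("n_subjects", "n_edges", "n_properties_true", "n_factors_true",
           "site_count")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1) {
      stop(sprintf("invalid config: '%s' must be a positive count", f))
    }
  }
  if (cfg$n_factors_true < 2) {
    stop("invalid config: 'n_factors_true' must be >= 2 when labels are generated")
  }
  nonneg <- c("dirichlet_concentration", "expected_active", "loading_scale",
              "noise_scale", "site_effect_scale")
  for (f in nonneg) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("invalid config: '%s' must be non-negative", f))
    }
  }
  if (cfg$dirichlet_concentration <= 0 || cfg$loading_scale <= 0) {
    stop("invalid config: concentration and loading scale must be positive")
  }
  if (cfg$label_flip_rate < 0 || cfg$label_flip_rate > 1) {
    stop("invalid config: 'label_flip_rate' must lie in [0, 1]")
  }
  invisible(cfg)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Generative chain: per-subject factor weights `theta_i ~ Dirichlet`;
#' per-factor property distributions `phi_f` concentrate 80% of their mass
#' on a factor-specific block of properties; property `p` of subject `i`
#' activates with probability `min(1, s * sum_f theta_if phi_fp)` where `s`
#' scales the expected active count to `expected_active`; fingerprints
#' `X = Z_true A_true + site offset + Gaussian noise`; clinical labels are
#' [corrupt_labels()] applied to the dominant factor (`argmax theta_i`).
#' Synthetic symptom scores (one per factor, `theta` plus noise) are
#' attached for association analyses.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_cohort` list with elements `X` (subjects x edges),
#'   `clinical_labels` (0-based integers), `site_labels`, `scores`
#'   (subjects x factors data frame), `subject_ids`, `ground_truth`
#'   (`Z_true`, `A_true`, `theta_true`, `phi_true`,
#'   `biological_labels_true`, `site_labels`), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(derive_seed(cfg$seed, "synthetic-cohort"))
  n <- cfg$n_subjects; K <- cfg$n_properties_true; k <- cfg$n_factors_true
  D <- cfg$n_edges

  theta <- rdirichlet(n, rep(cfg$dirichlet_concentration, k))

  # factor -> property distributions: 80% of mass on a contiguous block of
  # properties owned by the factor, 20% spread over the rest
  blocks <- split(seq_len(K), cut(seq_len(K), k, labels = FALSE))
  phi <- matrix(0.2 / K, k, K)
  for (f in seq_len(k)) {
    phi[f, blocks[[f]]] <- phi[f, blocks[[f]]] + 0.8 / length(blocks[[f]])
  }
  phi <- phi / rowSums(phi)

  act_prob <- pmin(1, cfg$expected_active * (theta %*% phi))
  Z <- matrix(as.integer(stats::runif(n * K) < act_prob), n, K)
  A <- matrix(stats::rnorm(K * D, sd = cfg$loading_scale), K, D)

  site <- rep(seq_len(cfg$site_count), length.out = n) - 1L
  site_offsets <- matrix(stats::rnorm(cfg$site_count * D,
                                      sd = cfg$site_effect_scale),
                         cfg$site_count, D)

  X <- Z %*% A + site_offsets[site + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * D, sd = cfg$noise_scale), n, D)

  bio_labels <- max.col(theta, ties.method = "first") - 1L
  clinical <- corrupt_labels(bio_labels, cfg$label_flip_rate, k,
                             seed = derive_seed(cfg$seed, "label-corruption"))

  scores <- as.data.frame(theta * 10 +
                            matrix(stats::rnorm(n * k, sd = 1), n, k))
  names(scores) <- paste0("score_", seq_len(k))

  structure(list(
    X = X,
    clinical_labels = clinical,
    site_labels = site,
    scores = scores,
    subject_ids = sprintf("sub-%04d", seq_len(n)),
    ground_truth = list(Z_true = Z, A_true = A, theta_true = theta,
                        phi_true = phi, biological_labels_true = bio_labels,
                        site_labels = site),
    config = cfg
  ), class = "synthetic_cohort")
}

#' Corrupt integer labels at a fixed flip rate
#'
#' Each label is independently replaced, with probability `flip_rate`, by a
#' uniformly drawn *different* class — a model of categorical diagnoses that
#' imperfectly reflect the underlying biology.
#'
#' @param labels integer vector with values in `0:(n_classes - 1)`.
#' @param flip_rate flip probability in `[0, 1]`.
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @return Integer vector of corrupted labels.
#' @export
corrupt_labels <- function(labels, flip_rate, n_classes, seed = 1L) {
  if (!is.finite(flip_rate) || flip_rate < 0 || flip_rate > 1) {
    stop("'flip_rate' must lie in [0, 1]")
  }
  if (any(labels < 0 | labels >= n_classes)) {
    stop("labels must lie in 0:(n_classes - 1)")
  }
  set.seed(seed)
  n <- length(labels)
  flip <- stats::runif(n) < flip_rate
  out <- as.integer(labels)
  if (any(flip)) {
    # uniform over the n_classes - 1 other classes
    shift <- sample.int(n_classes - 1L, sum(flip), replace = TRUE)
    out[flip] <- (out[flip] + shift) %% n_classes
  }
  out
}

#' Project a symmetric matrix to the nearest PSD correlation matrix
#'
#' Eigenvalues are clipped at `1e-8` and the diagonal re-normalized to 1.
#'
#' @param m symmetric matrix.
#' @return List with `matrix` (the projected correlation matrix) and
#'   `projected` (logical; whether any clipping occurred).
#' @keywords internal
nearest_psd_corr <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  projected <- any(e$values < 1e-8)
  if (projected) {
    vals <- pmax(e$values, 1e-8)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
  }
  list(matrix = (m + t(m)) / 2, projected = projected)
}

#' Simulate ROI time-series realizing a target connectivity fingerprint
#'
#' Samples a multivariate Gaussian time-series whose population correlation
#' matrix is the devectorized fingerprint, projecting to the nearest
#' positive-semidefinite correlation matrix first if necessary. Lets the
#' fingerprint construction be tested end to end against a known target.
#'
#' @param fingerprint numeric vector of pairwise correlations in `[-1, 1]`,
#'   length `n_rois (n_rois - 1) / 2`.
#' @param n_timepoints number of timepoints (>= 2 x number of ROIs).
#' @param seed integer seed.
#' @param roi_names optional ROI names; defaults to `R1..Rn`.
#' @return A `roi_timeseries` object (see [roi_timeseries()]) with attribute
#'   `psd_projected` flagging whether the target needed PSD projection.
#' @export
timeseries_from_fingerprint <- function(fingerprint, n_timepoints,
                                        seed = 1L, roi_names = NULL) {
  if (any(!is.finite(fingerprint)) || any(abs(fingerprint) > 1)) {
    stop("fingerprint entries must be finite and lie in [-1, 1]")
  }
  p <- (1 + sqrt(1 + 8 * length(fingerprint))) / 2
  if (p != round(p)) stop("fingerprint length is not a triangular number")
  p <- as.integer(p)
  if (n_timepoints < 2L * p) stop("n_timepoints must be >= 2 x number of ROIs")
  if (is.null(roi_names)) roi_names <- paste0("R", seq_len(p))

  target <- devectorize(fingerprint, p)
  proj <- nearest_psd_corr(target)

  set.seed(seed)
  e <- eigen(proj$matrix, symmetric = TRUE)
  half <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  z <- matrix(stats::rnorm(n_timepoints * p), n_timepoints, p)
  ts <- z %*% t(half)

  out <- roi_timeseries(ts, roi_names = roi_names, subject_id = "synthetic")
  attr(out, "psd_projected") <- proj$projected
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `fingerprints.tsv` (subjects x named edge columns; values clipped
#' to `[-1, 1]` when `correlation_mode = TRUE`), `metadata.tsv`
#' (subject_id, clinical_label, site, score columns) and a serialized
#' ground-truth bundle `ground_truth.rds`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @param correlation_mode clip fingerprints to `[-1, 1]` on export.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, correlation_mode = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- cohort$X
  if (correlation_mode) X <- pmin(1, pmax(-1, X))
  fp <- data.frame(subject_id = cohort$subject_ids, X, check.names = FALSE)
  nr <- (1 + sqrt(1 + 8 * ncol(cohort$X))) / 2
  colnames(fp)[-1] <- if (nr == round(nr)) {
    edge_names(paste0("R", seq_len(nr)))
  } else {
    paste0("edge_", seq_len(ncol(cohort$X)))
  }
  write_tsv(fp, file.path(dir, "fingerprints.tsv"))
  meta <- data.frame(subject_id = cohort$subject_ids,
                     clinical_label = cohort$clinical_labels,
                     site = cohort$site_labels, cohort$scores)
  write_tsv(meta, file.path(dir, "metadata.tsv"))
  saveRDS(cohort$ground_truth, file.path(dir, "ground_truth.rds"))
  invisible(dir)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
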