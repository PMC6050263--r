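#' Cross-validated one-vs-rest linear SVM accuracy
#'
#' The external model of the validation experiments: for each fold, a
#' linear SVM (cost fixed at `regularization`, one-vs-rest for multiclass)
#' is trained on the other `m - 1` folds and tested on the held-out fold.
#' Features are standardized with training-fold means and scales only.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels integer (or factor) class labels.
#' @param fold_assignment integer fold labels in `1:m`.
#' @param regularization SVM cost parameter (default 1).
#' @param experiment_id identifier recorded in the report.
#' @return A `classification_report` list: `per_fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, `chance_level`, `n_folds`,
#'   `experiment_id`.
#' @export
svm_cv_accuracy <- function(features, labels, fold_assignment,
                            regularization = 1,
                            experiment_id = "experiment") {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n, length(fold_assignment) == n)
  labels <- as.integer(as.factor(labels)) - 1L
  classes <- sort(unique(labels))
  folds <- sort(unique(fold_assignment))
  acc <- numeric(length(folds))
  for (j in seq_along(folds)) {
    tr <- fold_assignment != folds[j]
    te <- !tr
    y_tr <- labels[tr]
    if (length(unique(y_tr)) < 2L) {
      stop(sprintf("fold %s: training data has a single class", folds[j]))
    }
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    x_tr <- scale(features[tr, , drop = FALSE], center = mu, scale = sdv)
    x_te <- scale(features[te, , drop = FALSE], center = mu, scale = sdv)
    pred <- ovr_svm_predict(x_tr, y_tr, x_te, classes, regularization)
    acc[j] <- mean(pred == labels[te])
  }
  report <- list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 chance_level = 1 / length(classes),
                 n_folds = length(folds), experiment_id = experiment_id)
  class(report) <- "classification_report"
  report
}

# one-vs-rest: one binary linear SVM per class, predict by maximal decision
# value (class side oriented positive)
ovr_svm_predict <- function(x_tr, y_tr, x_te, classes, cost) {
  present <- classes[classes %in% y_tr]
  dec <- matrix(-Inf, nrow(x_te), length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    if (!(cl %in% present)) next
    y_bin <- factor(ifelse(y_tr == cl, "pos", "rest"),
                    levels = c("pos", "rest"))
    fit <- e1071::svm(x_tr, y_bin, kernel = "linear", cost = cost,
                      scale = FALSE)
    dvm <- attr(stats::predict(fit, x_te, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1]
    if (colnames(dvm)[1] == "rest/pos") dv <- -dv  # orient positive = "pos"
    dec[, ci] <- dv
  }
  classes[max.col(dec, ties.method = "first")]
}

#' Compare two experiments' fold accuracies by Welch t-test
#'
#' Two-sided unequal-variance t-test on the per-fold accuracy vectors.
#'
#' @param report_a,report_b `classification_report`s with >= 2 folds each.
#' @return List with `t_statistic`, `p_value`, `df`, and the two means.
#' @export
compare_experiments <- function(report_a, report_b) {
  a <- report_a$per_fold_accuracy
  b <- report_b$per_fold_accuracy
  if (length(a) < 2L || length(b) < 2L) {
    stop("both reports need at least 2 folds")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t_statistic = 0, p_value = 1, df = NA_real_,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Factor–symptom association table
#'
#' Pearson correlation (two-sided test) between each factor-weight column
#' and each symptom-score column, pairwise-complete over missing values.
#' Zero-variance scores are flagged `undefined` rather than dropped.
#'
#' @param theta subjects x k factor-weight matrix.
#' @param scores_table data frame of numeric symptom scores (may contain
#'   `NA`).
#' @param adjust apply Benjamini–Hochberg correction to the p-values
#'   (default `FALSE`: raw r and p are reported).
#' @return Data frame with columns `factor_id`, `score_name`, `r`, `p`,
#'   `n`, `undefined`.
#' @export
factor_associations <- function(theta, scores_table, adjust = FALSE) {
  theta <- as.matrix(theta)
  out <- list()
  for (f in seq_len(ncol(theta))) {
    for (s in seq_along(scores_table)) {
      x <- theta[, f]
      y <- scores_table[[s]]
      ok <- stats::complete.cases(x, y)
      undef <- sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0
      if (undef) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        factor_id = f, score_name = names(scores_table)[s],
        r = r, p = p, n = sum(ok), undefined = undef)
    }
  }
  res <- do.call(rbind, out)
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Property occurrence by clinical group
#'
#' Per property x group counts of subjects with the property active, with a
#' flag for properties whose carriers are exclusive to one group.
#'
#' @param assignments a [property_assignments()] (or binary matrix).
#' @param labels group labels aligned with assignment rows.
#' @return List with `counts` (properties x groups matrix) and
#'   `exclusive` (logical per property).
#' @export
property_occurrence_by_group <- function(assignments, labels) {
  if (inherits(assignments, "property_assignments")) {
    Z <- assignments$Z
  } else {
    Z <- as.matrix(assignments)
  }
  stopifnot(length(labels) == nrow(Z))
  groups <- sort(unique(labels))
  counts <- sapply(groups, function(g) colSums(Z[labels == g, , drop = FALSE]))
  counts <- matrix(counts, nrow = ncol(Z),
                   dimnames = list(sprintf("prop%02d", seq_len(ncol(Z))),
                                   paste0("group_", groups)))
  present <- rowSums(counts > 0)
  exclusive <- present == 1 & rowSums(counts) > 0
  list(counts = counts, exclusive = exclusive)
}
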