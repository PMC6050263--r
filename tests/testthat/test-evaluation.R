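test_that("separable classes are classified almost perfectly", {
  set.seed(71)
  n <- 150
  labs <- rep(0:2, each = 50)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  X <- centers[labs + 1, ] + matrix(rnorm(n * 2, sd = 0.3), n, 2)
  fold <- make_stratified_splits(labs, 5, seed = 1)
  rep_ <- svm_cv_accuracy(X, labs, fold)
  expect_gte(rep_$mean_accuracy, 0.99)
  expect_length(rep_$per_fold_accuracy, 5)
  expect_equal(rep_$chance_level, 1 / 3)
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(72)
  n <- 300
  X <- matrix(rnorm(n * 20), n, 20)
  labs <- sample(rep(0:2, each = 100))
  fold <- make_stratified_splits(labs, 10, seed = 2)
  rep_ <- svm_cv_accuracy(X, labs, fold)
  ci <- binom.test(round(n / 3), n)$conf.int
  expect_gte(rep_$mean_accuracy, ci[1])
  expect_lte(rep_$mean_accuracy, ci[2])
})

test_that("single-class training folds are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(svm_cv_accuracy(X, rep(0, 10), rep(1:2, 5)), "single class")
})

test_that("fold standardization is computed from training data only", {
  set.seed(73)
  n <- 60
  labs <- rep(0:2, 20)
  X <- matrix(rnorm(n * 4), n, 4) + 2 * labs
  fold <- rep(1:2, 30)
  base <- svm_cv_accuracy(X, labs, fold)
  # a gross outlier in ONE test row of fold 2 can change at most its own
  # prediction: the scaler and model for fold 2 come from fold 1 alone, and
  # with a leaky (all-data) scaler the distorted standardization would sink
  # every fold-2 prediction
  X_out <- X
  out_row <- which(fold == 2)[1]
  X_out[out_row, ] <- 1e6
  pert <- svm_cv_accuracy(X_out, labs, fold)
  n2 <- sum(fold == 2)
  expect_lte(abs(base$per_fold_accuracy[2] - pert$per_fold_accuracy[2]),
             1 / n2 + 1e-12)
})

test_that("Welch comparison matches the textbook formula", {
  r <- function(acc) list(per_fold_accuracy = acc)
  same <- compare_experiments(r(c(0.5, 0.6, 0.7)), r(c(0.5, 0.6, 0.7)))
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)

  a <- c(0.6, 0.7); b <- c(0.1, 0.2)
  out <- compare_experiments(r(a), r(b))
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-10)
  expect_error(compare_experiments(r(0.5), r(c(0.1, 0.2))), "2 folds")
})

test_that("fold vectors with the published summary statistics separate sharply", {
  set.seed(74)
  make_folds <- function(mean_pct, sd_pct, m = 10) {
    x <- rnorm(m)
    (mean_pct + sd_pct * (x - mean(x)) / sd(x)) / 100
  }
  a <- make_folds(67.33, 3.07)
  b <- make_folds(46.73, 3.97)
  expect_equal(mean(a) * 100, 67.33, tolerance = 1e-10)
  expect_equal(sd(b) * 100, 3.97, tolerance = 1e-10)
  out <- compare_experiments(list(per_fold_accuracy = a),
                             list(per_fold_accuracy = b))
  # Welch t from these summaries is ~13; far beyond the p < 1e-4 threshold
  expect_equal(out$t_statistic, 12.98, tolerance = 0.01 / 12.98)
  expect_lt(out$p_value, 1e-4)
})

test_that("factor-score associations report r, p, n and undefined flags", {
  set.seed(75)
  n <- 1000
  theta <- matrix(rgamma(n * 3, 1), n, 3); theta <- theta / rowSums(theta)
  scores <- data.frame(self = theta[, 2],
                       noise = rnorm(n),
                       const = rep(1, n))
  res <- factor_associations(theta, scores)
  expect_identical(nrow(res), 9L)
  self2 <- res[res$factor_id == 2 & res$score_name == "self", ]
  expect_equal(self2$r, 1, tolerance = 1e-10)
  expect_lt(self2$p, 1e-10)
  noise1 <- res[res$factor_id == 1 & res$score_name == "noise", ]
  expect_lt(abs(noise1$r), 0.1)
  expect_true(all(res$undefined[res$score_name == "const"]))
  expect_true(all(is.na(res$r[res$undefined])))
  # missing values: n reflects pairwise-complete cases
  scores$noise[1:100] <- NA
  res2 <- factor_associations(theta, scores)
  expect_identical(res2$n[res2$score_name == "noise"][1], 900L)
  # optional BH adjustment adds a column
  expect_true("p_adj" %in% names(factor_associations(theta, scores,
                                                     adjust = TRUE)))
})

test_that("property occurrence counts respect group sizes and exclusivity", {
  Z <- cbind(rep(1, 9),            # active in everyone
             c(1, 1, 1, 0, 0, 0, 0, 0, 0),  # group-0 exclusive
             rep(0, 9))            # empty
  labs <- rep(0:2, each = 3)
  occ <- property_occurrence_by_group(Z, labs)
  expect_equal(unname(occ$counts[1, ]), c(3, 3, 3))
  expect_equal(unname(occ$counts[3, ]), c(0, 0, 0))
  expect_identical(unname(occ$exclusive), c(FALSE, TRUE, FALSE))
})

test_that("shared factor structure leaves no group-exclusive properties", {
  co <- generate_cohort(synthetic_config(n_subjects = 200, n_edges = 20,
                                         n_properties_true = 10,
                                         expected_active = 4, seed = 77))
  occ <- property_occurrence_by_group(co$ground_truth$Z_true,
                                      co$clinical_labels)
  expect_lte(sum(occ$exclusive), 1)
})
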