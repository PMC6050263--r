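test_that("zero-noise cohorts are exactly the planted low-rank structure", {
  cfg <- synthetic_config(n_subjects = 60, n_edges = 45,
                          n_properties_true = 5, noise_scale = 0,
                          site_effect_scale = 0, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(co$X, co$ground_truth$Z_true %*% co$ground_truth$A_true)
  expect_lte(qr(co$X)$rank, 5)
})

test_that("cohort generation is bit-identical under the same config and seed", {
  cfg <- synthetic_config(n_subjects = 40, n_edges = 30, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("ground-truth simplex and binary invariants hold", {
  co <- generate_cohort(synthetic_config(n_subjects = 50, n_edges = 28,
                                         seed = 2))
  gt <- co$ground_truth
  expect_true(all(abs(rowSums(gt$theta_true) - 1) < 1e-10))
  expect_true(all(abs(rowSums(gt$phi_true) - 1) < 1e-10))
  expect_true(all(gt$Z_true %in% c(0L, 1L)))
  expect_true(all(co$clinical_labels %in% 0:(co$config$n_factors_true - 1)))
  expect_false(anyNA(co$X))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 0), "positive count")
  expect_error(synthetic_config(n_edges = -5), "positive count")
  expect_error(synthetic_config(label_flip_rate = 1.2), "0, 1")
  expect_error(synthetic_config(noise_scale = -1), "non-negative")
})

test_that("label corruption hits its nominal rate and edge cases", {
  labs <- rep(0:2, length.out = 10000)
  expect_identical(corrupt_labels(labs, 0, 3, seed = 1), as.integer(labs))
  out1 <- corrupt_labels(labs, 1, 3, seed = 2)
  expect_true(all(out1 != labs))
  expect_true(all(out1 %in% 0:2))
  out <- corrupt_labels(labs, 0.4, 3, seed = 3)
  frac <- mean(out != labs)
  expect_gt(frac, 0.38)
  expect_lt(frac, 0.42)
  # exact binomial interval around the realized flip count covers 0.4
  ci <- binom.test(sum(out != labs), length(labs))$conf.int
  expect_true(ci[1] <= 0.4 && 0.4 <= ci[2])
  expect_error(corrupt_labels(labs, 1.5, 3), "0, 1")
})

test_that("generated cohorts flip the configured fraction of labels", {
  cfg <- synthetic_config(n_subjects = 10000, n_edges = 6,
                          n_properties_true = 4, label_flip_rate = 0.4,
                          seed = 6)
  co <- generate_cohort(cfg)
  frac <- mean(co$clinical_labels != co$ground_truth$biological_labels_true)
  expect_gt(frac, 0.38)
  expect_lt(frac, 0.42)
})

test_that("mean active-property count tracks its configured expectation", {
  cfg <- synthetic_config(n_subjects = 1000, n_edges = 10,
                          n_properties_true = 12, expected_active = 5,
                          seed = 8)
  co <- generate_cohort(cfg)
  m <- mean(rowSums(co$ground_truth$Z_true))
  # probabilities are capped at 1, so the realized mean can only fall short
  # of the target by the capping amount; allow Monte-Carlo error both ways
  se <- sd(rowSums(co$ground_truth$Z_true)) / sqrt(1000)
  expect_lt(abs(m - 5), 0.25 + 3 * se)
})

test_that("time-series realize a target fingerprint", {
  # identity target: all off-diagonal correlations near zero
  p <- 6
  fp0 <- rep(0, p * (p - 1) / 2)
  ts <- timeseries_from_fingerprint(fp0, 10000, seed = 4)
  r <- cor(ts$data)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  expect_false(attr(ts, "psd_projected"))

  # 2-ROI target r = 0.8 recovered within Fisher-z sampling error
  ts2 <- timeseries_from_fingerprint(0.8, 10000, seed = 5)
  expect_equal(cor(ts2$data)[1, 2], 0.8, tolerance = 0.02 / 0.8)

  # non-PSD target gets projected and flagged
  bad <- c(0.9, 0.9, -0.9)   # 3-ROI impossible correlation pattern
  ts3 <- timeseries_from_fingerprint(bad, 500, seed = 6)
  expect_true(attr(ts3, "psd_projected"))
  ev <- eigen(cor(ts3$data), symmetric = TRUE)$values
  expect_true(all(ev > -1e-10))

  expect_error(timeseries_from_fingerprint(c(0.5, 1.2, 0), 100), "\\[-1, 1\\]")
  expect_error(timeseries_from_fingerprint(rep(0, 3), 4), "n_timepoints")
})

test_that("fingerprint -> time-series -> fingerprint round-trips", {
  set.seed(11)
  p <- 8
  m <- nearest_psd <- endofactor:::nearest_psd_corr(
    devectorize(runif(p * (p - 1) / 2, -0.4, 0.6), p))$matrix
  target <- vectorize_upper(m)
  T_len <- 40000
  ts <- timeseries_from_fingerprint(target, T_len, seed = 12)
  got <- compute_fingerprint(ts)$values
  expect_lt(max(abs(got - target)), 3 / sqrt(T_len))
})

test_that("cohorts round-trip through their TSV representation", {
  co <- generate_cohort(synthetic_config(n_subjects = 15, n_edges = 10,
                                         seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  cm <- read_fingerprints(file.path(dir, "fingerprints.tsv"), metadata = meta)
  expect_equal(unname(cm$X), unname(co$X), tolerance = 1e-9)
  expect_identical(meta$clinical_label, co$clinical_labels)
  expect_identical(cm$site_labels, co$site_labels)
})
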