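test_that("neighbour features are read off directly from flanking CpGs", {
  betas <- cbind(c(0.9, NA, 0.1), c(0.5, 0.4, 0.5))
  beta <- beta_from_matrix(c(100L, 200L, 300L), betas)
  f <- impute_features(beta, "S1",
                       loci = tibble::tibble(chrom = "chr1", pos = 200L))
  expect_equal(f$dist_up, 100)
  expect_equal(f$beta_up, 0.9)
  expect_equal(f$dist_down, 100)
  expect_equal(f$beta_down, 0.1)
  expect_equal(f$beta_other_mean, 0.4)
})

test_that("a CpG with no upstream neighbour gets the sentinel and fallback", {
  betas <- cbind(c(NA, 0.8), c(0.3, 0.4))
  beta <- beta_from_matrix(c(100L, 300L), betas)
  f <- impute_features(beta, "S1",
                       loci = tibble::tibble(chrom = "chr1", pos = 100L))
  expect_equal(f$dist_up, 1e6)
  expect_equal(f$beta_up, f$beta_other_mean)  # boundary rule
  expect_equal(f$dist_down, 200)
  expect_equal(f$beta_down, 0.8)
})

test_that("cross-sample mean averages the non-missing other samples", {
  betas <- cbind(c(NA, 0.5), c(0.2, 0.5), c(0.4, 0.5), c(NA, 0.5))
  beta <- beta_from_matrix(c(10L, 20L), betas)
  f <- impute_features(beta, "S1",
                       loci = tibble::tibble(chrom = "chr1", pos = 10L))
  expect_equal(f$beta_other_mean, 0.3)  # mean(0.2, 0.4), hand-computed
  expect_false(f$low_confidence)
})

test_that("a locus missing in all other samples is flagged low-confidence", {
  betas <- cbind(c(NA, 0.8, 0.6), c(NA, 0.1, 0.3))
  beta <- beta_from_matrix(c(10L, 20L, 30L), betas)
  f <- impute_features(beta, "S1",
                       loci = tibble::tibble(chrom = "chr1", pos = 10L))
  expect_true(f$low_confidence)
  expect_equal(f$beta_other_mean, mean(c(0.8, 0.6)))  # own chrom-wide mean
})

test_that("observed neighbours never include the target CpG itself", {
  betas <- cbind(c(0.1, 0.9, 0.2))
  beta <- beta_from_matrix(c(10L, 20L, 30L), betas, samples = "S1")
  beta2 <- dplyr::bind_rows(beta, dplyr::mutate(beta, sample = "S2"))
  f <- impute_features(beta2, "S1")
  expect_true(all(f$dist_up > 0))
  expect_true(all(f$dist_down > 0))
  expect_equal(f$beta_up[2], 0.1)
  expect_equal(f$beta_down[2], 0.2)
})

test_that("rmse matches hand calculations and rejects length mismatches", {
  expect_equal(rmse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(rmse(c(0.3, 0.5) + 0.1, c(0.3, 0.5)), 0.1)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("rmse is invariant under permutation of the held-out set", {
  withr::with_seed(9, {
    pred <- runif(50); truth <- runif(50)
    perm <- sample.int(50)
    expect_equal(rmse(pred, truth), rmse(pred[perm], truth[perm]))
  })
})

test_that("training is deterministic under a fixed seed and caps n_train", {
  cohort <- small_cohort(n_samples = 3, n_cpgs = 6000, seed = 5)
  expect_warning(
    m1 <- train_imputer(cohort$beta, "S01", n_train = 1e6, min_depth = 5,
                        seed = 11),
    "exceeds")
  suppressWarnings(
    m2 <- train_imputer(cohort$beta, "S01", n_train = 1e6, min_depth = 5,
                        seed = 11))
  expect_equal(m1$rmse, m2$rmse)
  expect_equal(m1$config$n_train, m1$config$n_eligible)
  g <- glance(m1)
  expect_equal(g$rmse, m1$rmse)
})

test_that("training refuses a sample with too few eligible CpGs", {
  cohort <- small_cohort(n_samples = 2, n_cpgs = 1500, seed = 5)
  expect_error(train_imputer(cohort$beta, "S01", min_depth = 60, seed = 1),
               "at least 1000")
})

test_that("a noiseless locally-constant methylome imputes almost exactly", {
  # missing betas equal the mean of their flanking neighbours by design,
  # so the features encode the target perfectly
  withr::with_seed(3, {
    n <- 6000
    pos <- sort(sample.int(6e5, n))
    level <- rep(rbeta(ceiling(n / 20), 0.5, 0.5), each = 20)[1:n]
    betas <- cbind(level, level, level)
  })
  beta <- beta_from_matrix(pos, betas)
  suppressWarnings(
    m <- train_imputer(beta, "S1", n_train = n, min_depth = 1, seed = 2))
  expect_lt(m$rmse, 0.05)
})

test_that("cohort imputation fills masked cells, in [0,1], observed untouched", {
  cohort <- small_cohort(n_samples = 4, n_cpgs = 12000, seed = 8)
  masked <- mask_beta(cohort$beta, fraction = 0.17, seed = 21)
  suppressWarnings(
    res <- impute_cohort(masked$beta, min_depth = 5, seed = 3))
  out <- res$beta
  key <- paste(out$chrom, out$pos, out$sample)
  # observed cells are bit-identical
  obs <- !is.na(masked$beta$beta)
  m_key <- paste(masked$beta$chrom, masked$beta$pos, masked$beta$sample)
  expect_equal(out$beta[match(m_key[obs], key)], masked$beta$beta[obs])
  expect_false(any(out$imputed[match(m_key[obs], key)]))
  # all masked cells were imputable here and are flagged + bounded
  mk <- match(paste(masked$masked$chrom, masked$masked$pos,
                    masked$masked$sample), key)
  expect_true(all(out$imputed[mk]))
  expect_true(all(out$beta[mk] >= 0 & out$beta[mk] <= 1))
  expect_equal(res$report$n_imputed, res$report$n_missing)
  expect_true(all(res$report$fraction_imputed > 0.1 &
                    res$report$fraction_imputed < 0.25))
})

test_that("masking at random and imputing recovers betas within the error bound", {
  cohort <- small_cohort(n_samples = 5, n_cpgs = 20000, seed = 13)
  for (frac in c(0.1, 0.2)) {
    masked <- mask_beta(cohort$beta, fraction = frac, seed = 100 + frac * 10)
    suppressWarnings(
      res <- impute_cohort(masked$beta, min_depth = 10, seed = 7))
    expect_true(all(res$report$rmse <= 0.22))
    # recovery error against the withheld observed betas, per sample
    key <- paste(res$beta$chrom, res$beta$pos, res$beta$sample)
    mk <- match(paste(masked$masked$chrom, masked$masked$pos,
                      masked$masked$sample), key)
    rec <- tibble::tibble(sample = masked$masked$sample,
                          pred = res$beta$beta[mk],
                          truth = masked$masked$beta_true)
    per_sample <- dplyr::summarise(
      dplyr::group_by(rec, sample),
      rmse = rmse(pred, truth), .groups = "drop")
    expect_true(all(per_sample$rmse <= 0.22))
  }
})

test_that("imputed values preserve the bimodal beta distribution", {
  cohort <- small_cohort(n_samples = 4, n_cpgs = 15000, seed = 19)
  masked <- mask_beta(cohort$beta, fraction = 0.17, seed = 4)
  suppressWarnings(res <- impute_cohort(masked$beta, min_depth = 5, seed = 5))
  imp <- res$beta$beta[res$beta$imputed]
  expect_gt(mean(imp <= 0.2 | imp >= 0.8), 0.6)
  expect_gt(mean(imp <= 0.2), 0.15)  # both modes populated
  expect_gt(mean(imp >= 0.8), 0.15)
})

test_that("a cohort with no missing cells passes through unchanged", {
  betas <- matrix(rep(seq(0.05, 0.95, length.out = 60), 3), ncol = 3)
  withr::with_seed(2, betas <- betas[, ] + 0)
  pos <- seq(100L, by = 50L, length.out = 60)
  beta <- beta_from_matrix(pos, betas)
  big <- dplyr::bind_rows(lapply(1:40, function(i) {
    dplyr::mutate(beta, pos = pos + i * 4000L)
  }))
  suppressWarnings(res <- impute_cohort(big, min_depth = 1, seed = 1))
  expect_equal(sum(res$report$n_imputed), 0L)
  expect_equal(dplyr::arrange(res$beta, chrom, pos, sample)$beta,
               dplyr::arrange(big, chrom, pos, sample)$beta)
})

test_that("single-sample cohorts are rejected with a clear message", {
  beta <- beta_from_matrix(c(1L, 2L), cbind(c(0.1, 0.2)), samples = "only")
  expect_error(impute_cohort(beta), "cross-sample")
})
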