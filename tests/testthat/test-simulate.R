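test_that("config validation lists every offending field", {
  expect_error(sim_config(n_samples = 5), "seed is mandatory")
  err <- tryCatch(sim_config(diff_fraction = 1.5, array_density = -0.1,
                             lambda = 0, seed = 1),
                  error = conditionMessage)
  expect_match(err, "diff_fraction")
  expect_match(err, "array_density")
  expect_match(err, "lambda")
})

test_that("the same seed reproduces methylomes bit-identically", {
  cfg <- sim_config(n_samples = 3, n_cpgs = 4000, seed = 12)
  s1 <- simulate_methylomes(cfg)
  s2 <- simulate_methylomes(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$truth$groups, s2$truth$groups)
  r1 <- simulate_reads(s1$beta, cfg)
  r2 <- simulate_reads(s2$beta, cfg)
  expect_identical(r1, r2)
})

test_that("background betas are bimodal with heavy mass near 0 and 1", {
  cfg <- sim_config(n_samples = 4, n_cpgs = 20000, diff_fraction = 0,
                    seed = 3)
  sim <- simulate_methylomes(cfg)
  b <- sim$beta$beta
  expect_gt(mean(b <= 0.1 | b >= 0.9), 0.6)
})

test_that("zero differential fraction leaves no group signal", {
  cfg <- sim_config(n_samples = 8, n_groups = 2, n_cpgs = 5000,
                    diff_fraction = 0, seed = 9)
  sim <- simulate_methylomes(cfg)
  ws <- dplyr::left_join(sim$beta, sim$truth$groups, by = "sample")
  per_locus <- ws |>
    dplyr::group_by(chrom, pos, group) |>
    dplyr::summarise(m = mean(beta), .groups = "drop_last") |>
    dplyr::summarise(between = diff(range(m)), .groups = "drop")
  # between-group locus differences stay at noise scale
  expect_lt(mean(per_locus$between), 0.05)
})

test_that("read totals follow the Poisson depth and CNV copy scaling", {
  ev <- tibble::tibble(sample = "S01", chrom = "chr1", start = 0,
                       end = 5e5, copy = 1)
  cfg <- sim_config(n_samples = 2, n_cpgs = 20000, lambda = 10,
                    cnv_events = ev, seed = 14)
  sim <- simulate_methylomes(cfg)
  counts <- simulate_reads(sim$beta, cfg)
  diploid <- counts$total[counts$sample == "S02"]
  expect_lt(abs(mean(diploid) - 10), 0.2)
  mono <- counts$total[counts$sample == "S01" & counts$chrom == "chr1" &
                         counts$pos < 5e5]
  expect_lt(abs(mean(mono) - 5), 0.3)
})

test_that("empirical betas converge to truth at high depth", {
  cfg <- sim_config(n_samples = 2, n_cpgs = 3000, lambda = 600, seed = 6)
  sim <- simulate_methylomes(cfg)
  counts <- simulate_reads(sim$beta, cfg)
  deep <- counts$total >= 500
  emp <- counts$meth[deep] / counts$total[deep]
  expect_lt(mean(abs(emp - sim$beta$beta[deep])), 0.02)
})

test_that("fragment density scales with copy number", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2", "chr3"), size = 2e6)
  ev <- tibble::tibble(sample = c("S01", "S01"),
                       chrom = c("chr2", "chr3"),
                       start = c(0, 1e6), end = c(2e6, 1.15e6),
                       copy = c(1, 8))
  cfg <- sim_config(n_samples = 1, n_cpgs = 1000, chrom_sizes = sizes,
                    lambda = 10, cnv_events = ev, seed = 20)
  fr <- simulate_fragments(cfg, "S01")
  dens <- function(ch, lo, hi) {
    sum(fr$chrom == ch & (fr$start + fr$end) / 2 >= lo &
          (fr$start + fr$end) / 2 < hi) / (hi - lo)
  }
  base <- dens("chr1", 0, 2e6)
  expect_lt(abs(dens("chr2", 0, 2e6) / base - 0.5), 0.05)
  expect_lt(abs(dens("chr3", 1e6, 1.15e6) / base - 4), 0.3)
})

test_that("a diploid genome segments as neutral end to end", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), size = 2e6)
  cfg <- sim_config(n_samples = 1, n_cpgs = 1000, chrom_sizes = sizes,
                    lambda = 10, seed = 25)
  fr <- simulate_fragments(cfg, "S01")
  track <- count_fragments(fr, make_bins(sizes, 50000)) |>
    filter_bins() |> normalize_log2() |> drop_outliers()
  segs <- classify_segments(segment_cbs(track))
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$state == "neutral"))
})

test_that("the array counterpart reproduces betas and squeezes extremes", {
  cfg <- sim_config(n_samples = 2, n_cpgs = 5000, array_noise_sd = 0,
                    seed = 16)
  sim <- simulate_methylomes(cfg)
  exact <- simulate_array(sim$beta, cfg, squeeze = FALSE)
  joined <- dplyr::inner_join(
    exact, sim$beta, by = c("chrom", "pos", "sample"),
    suffix = c("_arr", "_true"))
  expect_equal(joined$beta_arr, joined$beta_true)
  squeezed <- simulate_array(sim$beta, cfg, squeeze = TRUE)
  expect_true(all(squeezed$beta > 0 & squeezed$beta < 1))
})

test_that("array and deep read-based betas correlate strongly", {
  cfg <- sim_config(n_samples = 3, n_cpgs = 10000, lambda = 30, seed = 18)
  sim <- simulate_methylomes(cfg)
  counts <- simulate_reads(sim$beta, cfg)
  wgbs <- compute_beta(counts, min_depth = 1)
  arr <- simulate_array(sim$beta, cfg)
  probes <- dplyr::distinct(arr, probe_id, chrom, pos) |>
    dplyr::arrange(chrom, pos)
  loci <- dplyr::distinct(wgbs, chrom, pos) |> dplyr::arrange(chrom, pos)
  pairing <- match_array_loci(loci, probes)
  cors <- pearson_per_sample(wgbs, arr, pairing)
  expect_true(all(cors$r > 0.9))
})

test_that("mask accounting balances: every masked cell is missing", {
  cohort <- small_cohort(n_samples = 3, n_cpgs = 4000, seed = 29)
  masked <- mask_beta(cohort$beta, fraction = 0.17, seed = 2)
  n_before <- sum(is.na(cohort$beta$beta))
  n_after <- sum(is.na(masked$beta$beta))
  expect_equal(n_after - n_before, nrow(masked$masked))
  expect_equal(nrow(masked$masked),
               floor(0.17 * sum(!is.na(cohort$beta$beta))))
  key <- paste(masked$beta$chrom, masked$beta$pos, masked$beta$sample)
  mk <- match(paste(masked$masked$chrom, masked$masked$pos,
                    masked$masked$sample), key)
  expect_true(all(is.na(masked$beta$beta[mk])))
})
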