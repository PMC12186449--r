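test_that("loci are ranked by cross-sample standard deviation", {
  betas <- rbind(c(0, 1), c(0.5, 0.5), c(0.4, 0.6))
  beta <- beta_from_matrix(c(10L, 20L, 30L), betas)
  top1 <- top_variable(beta, k = 1)
  expect_equal(top1$pos, 10L)
  expect_equal(top1$sd, sd(c(0, 1)))
  all3 <- top_variable(beta, k = 3)
  expect_equal(all3$pos, c(10L, 30L, 20L))
  expect_equal(top_variable(beta, k = 0)$pos, integer(0) + numeric(0))
  expect_warning(big <- top_variable(beta, k = 10), "exceeds")
  expect_equal(nrow(big), 3L)
})

test_that("constant matrices have zero sd and loci with NAs are excluded", {
  betas <- rbind(c(0.5, 0.5), c(NA, 0.1))
  beta <- beta_from_matrix(c(10L, 20L), betas)
  out <- top_variable(beta, k = 5) |> suppressWarnings()
  expect_equal(out$pos, 10L)
  expect_equal(out$sd, 0)
})

test_that("selection is invariant under duplicating every sample column", {
  cohort <- small_cohort(n_samples = 3, n_cpgs = 3000, seed = 33)
  beta <- cohort$beta
  dup <- dplyr::mutate(beta, sample = paste0(sample, "_copy"))
  both <- dplyr::bind_rows(beta, dup)
  k <- 200
  a <- top_variable(beta, k = k)
  b <- top_variable(both, k = k)
  expect_setequal(paste(a$chrom, a$pos), paste(b$chrom, b$pos))
})

test_that("island-relative categories use the 2 kb shore / 2 kb shelf rule", {
  islands <- tibble::tibble(chrom = "chr1", start = 10000, end = 11000)
  loci <- tibble::tibble(chrom = "chr1",
                         pos = c(10500, 11000 + 1500, 11000 + 2500,
                                 11000 + 10000, 10000 - 2001))
  out <- assign_categories(loci, islands)
  expect_equal(out$category,
               c("island", "shore", "shelf", "open_sea", "shelf"))
  expect_match(out$region_id[1], "^island:chr1:")
})

test_that("nearby islands merge their shores into a single region", {
  islands <- tibble::tibble(chrom = "chr1", start = c(10000, 13000),
                            end = c(11000, 14000))
  loci <- tibble::tibble(chrom = "chr1", pos = c(11500, 12500))
  out <- assign_categories(loci, islands)
  expect_equal(out$category, c("shore", "shore"))
  expect_equal(out$region_id[1], out$region_id[2])
})

test_that("open-sea loci share the gap interval between shelf boundaries", {
  islands <- tibble::tibble(chrom = "chr1", start = c(10000, 60000),
                            end = c(11000, 61000))
  loci <- tibble::tibble(chrom = "chr1", pos = c(30000, 40000, 5, 100000))
  out <- assign_categories(loci, islands)
  expect_true(all(out$category == "open_sea"))
  expect_equal(out$region_id[1], out$region_id[2])
  expect_false(out$region_id[3] == out$region_id[1])
  expect_false(out$region_id[4] == out$region_id[1])
})

test_that("region collapse keeps the highest-sd member as representative", {
  islands <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  ann <- assign_categories(
    tibble::tibble(chrom = "chr1",
                   pos = c(1100, 1200, 1300, 1400, 50000)), islands)
  ann$sd <- c(0.2, 0.5, 0.5, 0.1, 0.3)
  out <- collapse_to_regions(ann)
  expect_equal(attr(out, "n_unique_regions"), 2L)  # island + open sea
  reps <- out[out$is_representative, ]
  expect_equal(sort(reps$pos), c(1200, 50000))  # sd tie broken to lower pos
  expect_true(all(tapply(out$sd, out$region_id, max) ==
                    reps$sd[order(reps$region_id)]))
})

test_that("collapse is idempotent and singleton regions all survive", {
  loci <- tibble::tibble(chrom = "chr1", pos = c(1e4, 5e4, 9e4))
  ann <- assign_categories(loci, tibble::tibble(chrom = "chr1",
                                                start = 0, end = 100)[0, ])
  ann$sd <- c(0.1, 0.2, 0.3)
  ann$region_id <- paste0("r", 1:3)  # force distinct regions
  once <- collapse_to_regions(ann)
  expect_equal(attr(once, "n_unique_regions"), 3L)
  expect_true(all(once$is_representative))
  twice <- collapse_to_regions(once)
  expect_equal(twice$is_representative, once$is_representative)
})

test_that("clustered variable CpGs collapse to far fewer unique regions", {
  # differential CpGs planted in blocks: top-variable loci co-locate
  cfg <- sim_config(n_samples = 8, n_cpgs = 20000, diff_fraction = 0.03,
                    seed = 55)
  sim <- simulate_methylomes(cfg)
  top <- top_variable(sim$beta, k = 500)
  islands <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric())
  # use the simulator's own 1 kb block structure as the annotation scale
  ann <- dplyr::mutate(top,
    category = "open_sea",
    region_id = paste0(chrom, "_", pos %/% 1000))
  out <- collapse_to_regions(ann)
  expect_lt(attr(out, "n_unique_regions"), 0.5 * nrow(top))
})

test_that("manifest overlap counting partitions the loci", {
  manifest <- tibble::tibble(probe_id = paste0("p", 1:3), chrom = "chr1",
                             pos = c(100, 500, 900))
  loci <- tibble::tibble(chrom = "chr1",
                         pos = c(110, 480, 700, 300, 1100))
  out <- manifest_overlap_count(dplyr::arrange(loci, pos), manifest,
                                max_dist = 25)
  expect_equal(out$n_overlapping, 2L)      # 110 and 480
  expect_equal(out$n_non_overlapping, 3L)
  far <- tibble::tibble(chrom = "chr1", pos = c(200, 600))
  out2 <- manifest_overlap_count(far, manifest, max_dist = 25)
  expect_equal(out2$n_overlapping, 0L)
  out3 <- manifest_overlap_count(
    tibble::tibble(chrom = "chr1", pos = c(100, 500)), manifest)
  expect_equal(out3$n_non_overlapping, 0L)
})
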