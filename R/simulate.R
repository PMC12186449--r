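# Synthetic cohorts with known truth.
#
# The simulator emulates the salient structure of a molecularly grouped
# tumour WGBS cohort: bimodal CpG methylation with short-range spatial
# autocorrelation, group-differential CpGs clustered in contiguous blocks,
# binomial read sampling at a target mean depth, CNV events that scale
# coverage by copy ratio, and a noisy array-like counterpart of the same
# betas. Every draw is governed by the config seed.

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the toolkit targets: a cohort of
#' 20 samples in 4 molecular groups, ~1 CpG per 100 bp across 4
#' chromosomes, mean sequencing depth 10x (low-pass), 5% of CpG blocks
#' carrying group-differential methylation in 1 kb clusters.
#'
#' @param n_samples Number of samples (default 20).
#' @param n_groups Number of molecular groups (default 4).
#' @param n_cpgs Total CpGs across the genome (default 200,000).
#' @param chrom_sizes Optional tibble (`chrom`, `size`); default 4 equal
#'   chromosomes sized for ~1 CpG / 100 bp.
#' @param lambda Mean read depth per CpG on diploid background (default 10;
#'   use 30 for the high-coverage regime).
#' @param diff_fraction Fraction of blocks that are group-differential
#'   (default 0.05).
#' @param block_bp Methylation block length in bp (default 1,000): CpGs in
#'   a block share a regional methylation level, giving the spatial
#'   autocorrelation the imputer exploits.
#' @param locus_sd,sample_sd Gaussian jitter of locus-level and per-cell
#'   betas around the block level (defaults 0.02 and 0.03).
#' @param cnv_events Optional tibble (`sample`, `chrom`, `start`, `end`,
#'   `copy`) of copy-number events (copy 2 = neutral).
#' @param array_noise_sd Array counterpart noise sd (default 0.03).
#' @param array_density Fraction of CpGs carrying an array probe (default
#'   0.25).
#' @param fragment_len Fragment length for coverage simulation (150 bp).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 20, n_groups = 4, n_cpgs = 200000,
                       chrom_sizes = NULL, lambda = 10,
                       diff_fraction = 0.05, block_bp = 1000,
                       locus_sd = 0.02, sample_sd = 0.03,
                       cnv_events = NULL, array_noise_sd = 0.03,
                       array_density = 0.25, fragment_len = 150,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("sim_config(): seed is mandatory")
  problems <- character(0)
  frac_fields <- c(diff_fraction = diff_fraction,
                   array_density = array_density)
  for (f in names(frac_fields)) {
    if (frac_fields[[f]] < 0 || frac_fields[[f]] > 1) {
      problems <- c(problems, sprintf("%s must be in [0, 1]", f))
    }
  }
  if (n_samples < 1) problems <- c(problems, "n_samples must be >= 1")
  if (n_groups < 1) problems <- c(problems, "n_groups must be >= 1")
  if (lambda <= 0) problems <- c(problems, "lambda must be > 0")
  if (!is.null(cnv_events) && any(cnv_events$copy < 0)) {
    problems <- c(problems, "cnv_events copy numbers must be >= 0")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid simulation config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  if (is.null(chrom_sizes)) {
    n_chroms <- 4
    size <- ceiling(n_cpgs * 100 / n_chroms)
    chrom_sizes <- tibble::tibble(chrom = paste0("chr", seq_len(n_chroms)),
                                  size = size)
  }
  structure(list(n_samples = n_samples, n_groups = n_groups,
                 n_cpgs = n_cpgs, chrom_sizes = chrom_sizes,
                 lambda = lambda, diff_fraction = diff_fraction,
                 block_bp = block_bp, locus_sd = locus_sd,
                 sample_sd = sample_sd, cnv_events = cnv_events,
                 array_noise_sd = array_noise_sd,
                 array_density = array_density,
                 fragment_len = fragment_len, seed = as.integer(seed)),
            class = "sim_config")
}

sample_ids <- function(config) sprintf("S%02d", seq_len(config$n_samples))

# Regional methylation level: 50/50 mixture of Beta(0.5, 8) (unmethylated
# mode) and Beta(8, 0.5) (methylated mode).
draw_block_levels <- function(n) {
  hi <- runif(n) < 0.5
  ifelse(hi, rbeta(n, 8, 0.5), rbeta(n, 0.5, 8))
}

#' Simulate ground-truth methylomes
#'
#' CpG positions are placed uniformly per chromosome (density proportional
#' to size) and grouped into blocks of `block_bp`. Each block draws a
#' regional level from the bimodal mixture; differential blocks draw one
#' level per molecular group instead. Locus- and cell-level Gaussian jitter
#' is added and values are clamped to [0, 1].
#'
#' @param config A [sim_config()].
#' @return List with `beta` (long true-beta tibble: `chrom`, `pos`,
#'   `sample`, `beta`) and `truth` (list: `groups` tibble, `loci` tibble
#'   with block and differential flags, `config`).
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    cs <- config$chrom_sizes
    n_per <- round(config$n_cpgs * cs$size / sum(cs$size))
    loci <- purrr::map_dfr(seq_len(nrow(cs)), function(i) {
      pos <- sort(sample.int(cs$size[i] - 2, n_per[i]))
      tibble::tibble(chrom = cs$chrom[i], pos = pos)
    })
    loci$block <- paste0(loci$chrom, "_b", loci$pos %/% config$block_bp)
    blocks <- unique(loci$block)
    n_blocks <- length(blocks)

    groups <- tibble::tibble(
      sample = sample_ids(config),
      group = paste0("G", rep_len(seq_len(config$n_groups), config$n_samples)))

    diff_block <- setNames(runif(n_blocks) < config$diff_fraction, blocks)
    base_level <- setNames(draw_block_levels(n_blocks), blocks)
    # group-specific levels for differential blocks
    grp_levels <- matrix(rep(base_level, config$n_groups), ncol = config$n_groups)
    rownames(grp_levels) <- blocks
    if (any(diff_block)) {
      nd <- sum(diff_block)
      grp_levels[diff_block, ] <- matrix(
        draw_block_levels(nd * config$n_groups), ncol = config$n_groups)
    }

    locus_jitter <- rnorm(nrow(loci), 0, config$locus_sd)
    bi <- match(loci$block, blocks)
    gi <- match(groups$group, paste0("G", seq_len(config$n_groups)))
    beta_mat <- vapply(seq_len(config$n_samples), function(s) {
      mu <- grp_levels[cbind(bi, gi[s])] + locus_jitter
      clamp01(mu + rnorm(nrow(loci), 0, config$sample_sd))
    }, numeric(nrow(loci)))
    colnames(beta_mat) <- groups$sample

    beta <- tibble::tibble(
      chrom = rep(loci$chrom, times = config$n_samples),
      pos = rep(loci$pos, times = config$n_samples),
      sample = rep(groups$sample, each = nrow(loci)),
      beta = as.vector(beta_mat))
    loci$differential <- diff_block[loci$block]
    list(beta = beta,
         truth = list(groups = groups, loci = tibble::as_tibble(loci),
                      config = config))
  })
}

# Copy number of each (locus, sample) cell given the event table.
copy_at <- function(chrom, pos, sample, cnv_events) {
  copy <- rep(2, length(pos))
  if (is.null(cnv_events) || nrow(cnv_events) == 0) return(copy)
  for (i in seq_len(nrow(cnv_events))) {
    e <- cnv_events[i, ]
    hit <- sample == e$sample & chrom == e$chrom & pos >= e$start & pos < e$end
    copy[hit] <- e$copy
  }
  copy
}

#' Simulate read counts from true betas
#'
#' Per cell, total reads are Poisson with mean `lambda * copy / 2` (the
#' sample's copy number at the locus scales coverage) and methylated reads
#' are binomial in the true beta. Cells with zero total are the natural
#' missingness of low-pass data.
#'
#' @param true_beta Long true-beta tibble from [simulate_methylomes()].
#' @param config The [sim_config()].
#' @param seed Seed for the read sampling; defaults to `config$seed + 1`.
#' @return Count tibble (`chrom`, `pos`, `sample`, `meth`, `total`).
#' @export
simulate_reads <- function(true_beta, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    copy <- copy_at(true_beta$chrom, true_beta$pos, true_beta$sample,
                    config$cnv_events)
    total <- rpois(nrow(true_beta), config$lambda * copy / 2)
    meth <- rbinom(nrow(true_beta), total, true_beta$beta)
    tibble::tibble(chrom = true_beta$chrom, pos = true_beta$pos,
                   sample = true_beta$sample, meth = meth, total = total)
  })
}

#' Simulate a fragment coverage track for one sample
#'
#' Fragment midpoints fall uniformly within each copy-state region at a
#' rate proportional to `copy / 2`, at a genome-wide density equivalent to
#' the configured mean depth; fragments have fixed length (default 150 bp).
#'
#' @param config The [sim_config()] (its `cnv_events` define the sample's
#'   copy landscape).
#' @param sample Sample id.
#' @param seed Seed; defaults to a sample-specific offset of the config
#'   seed.
#' @return Fragment tibble (`chrom`, `start`, `end`), sorted.
#' @export
simulate_fragments <- function(config, sample,
                               seed = config$seed + 100L +
                                 match(sample, sample_ids(config))) {
  stopifnot(inherits(config, "sim_config"))
  flen <- config$fragment_len
  rate <- config$lambda / flen  # fragments per bp at copy 2
  ev <- config$cnv_events
  ev <- if (is.null(ev)) NULL else ev[ev$sample == sample, ]
  withr::with_seed(seed, {
    frags <- purrr::map_dfr(seq_len(nrow(config$chrom_sizes)), function(i) {
      ch <- config$chrom_sizes$chrom[i]
      size <- config$chrom_sizes$size[i]
      # piecewise-constant copy profile over the chromosome
      bounds <- sort(unique(c(0, size,
                              ev$start[ev$chrom == ch], ev$end[ev$chrom == ch])))
      bounds <- bounds[bounds >= 0 & bounds <= size]
      purrr::map_dfr(seq_len(length(bounds) - 1), function(b) {
        lo <- bounds[b]; hi <- bounds[b + 1]
        cp <- copy_at(ch, lo, sample, ev)
        n <- rpois(1, (hi - lo) * rate * cp / 2)
        if (n == 0) return(NULL)
        mid <- floor(runif(n, lo, hi))
        tibble::tibble(chrom = ch,
                       start = pmax(0, mid - flen %/% 2),
                       end = pmin(size, mid + flen %/% 2))
      })
    })
    frags[order(chrom_order(frags$chrom), frags$start), ] |>
      tibble::as_tibble()
  })
}

#' Simulate an array-like counterpart of a methylome
#'
#' Subsamples loci at the manifest density, adds truncated Gaussian noise,
#' and (by default) applies a fixed logistic squeeze mapping [0, 1] into
#' roughly (0.1, 0.9) to mimic the compressed intensity scale of array
#' betas.
#'
#' @param true_beta Long true-beta tibble.
#' @param config The [sim_config()].
#' @param squeeze Apply the logistic compression (default `TRUE`).
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return Long array tibble (`probe_id`, `chrom`, `pos`, `sample`,
#'   `beta`).
#' @export
simulate_array <- function(true_beta, config, squeeze = TRUE,
                           seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    loci <- dplyr::distinct(true_beta, .data$chrom, .data$pos)
    loci <- arrange_loci(loci)
    keep <- runif(nrow(loci)) < config$array_density
    probes <- loci[keep, ]
    probes$probe_id <- sprintf("cg%07d", seq_len(nrow(probes)))
    out <- dplyr::inner_join(true_beta, probes, by = c("chrom", "pos"))
    x <- out$beta
    if (config$array_noise_sd > 0) {
      x <- clamp01(x + rnorm(length(x), 0, config$array_noise_sd))
    }
    if (squeeze) x <- stats::plogis(4 * (x - 0.5))
    tibble::tibble(probe_id = out$probe_id, chrom = out$chrom,
                   pos = out$pos, sample = out$sample, beta = x)
  })
}

#' Mask beta cells completely at random
#'
#' Utility for imputation-recovery experiments: sets a random fraction of
#' the non-missing cells to NA and records which, so recovery error can be
#' measured against the withheld values.
#'
#' @param beta Long beta tibble.
#' @param fraction Fraction of non-missing cells to mask.
#' @param seed Integer seed.
#' @return List with `beta` (masked table) and `masked` (tibble of the
#'   withheld cells: `chrom`, `pos`, `sample`, `beta_true`).
#' @export
mask_beta <- function(beta, fraction, seed) {
  check_columns(beta, c("chrom", "pos", "sample", "beta"), "beta table")
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  withr::with_seed(seed, {
    obs <- which(!is.na(beta$beta))
    n_mask <- floor(fraction * length(obs))
    hit <- sample(obs, n_mask)
    masked <- tibble::tibble(chrom = beta$chrom[hit], pos = beta$pos[hit],
                             sample = beta$sample[hit],
                             beta_true = beta$beta[hit])
    beta$beta[hit] <- NA_real_
    list(beta = beta, masked = masked)
  })
}
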