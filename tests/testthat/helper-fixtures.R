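# Shared fixtures and independent oracles, all built in code.

write_report_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small hand-specified cohort count table.
toy_counts <- function() {
  tibble::tibble(
    chrom = rep(c("chr1", "chr1", "chr2"), each = 2),
    pos = rep(c(100L, 250L, 40L), each = 2),
    sample = rep(c("A", "B"), times = 3),
    meth = c(5L, 0L, 3L, 8L, 2L, 2L),
    total = c(10L, 4L, 3L, 10L, 2L, 8L))
}

# Long beta table from explicit wide spec: betas is a loci x samples matrix.
beta_from_matrix <- function(pos, betas, chrom = "chr1",
                             samples = paste0("S", seq_len(ncol(betas))),
                             depth = 30L) {
  pos_col <- rep(pos, times = ncol(betas))
  sample_col <- rep(samples, each = length(pos))
  tibble::tibble(
    chrom = chrom,
    pos = pos_col,
    sample = sample_col,
    beta = as.vector(betas),
    depth = depth,
    imputed = FALSE)
}

# Brute-force nearest-CpG matcher (the oracle for match_array_loci):
# all-pairs search, ties to the lower coordinate.
brute_force_match <- function(wgbs_loci, probe_coords, max_dist) {
  purrr::map_dfr(seq_len(nrow(probe_coords)), function(i) {
    p <- probe_coords[i, ]
    cand <- wgbs_loci[wgbs_loci$chrom == p$chrom, ]
    if (nrow(cand) == 0) {
      return(tibble::tibble(probe_id = p$probe_id, pos = NA_real_))
    }
    d <- abs(cand$pos - p$pos)
    best <- which(d == min(d))
    best <- best[which.min(cand$pos[best])]
    if (d[best] > max_dist) {
      tibble::tibble(probe_id = p$probe_id, pos = NA_real_)
    } else {
      tibble::tibble(probe_id = p$probe_id, pos = cand$pos[best])
    }
  })
}

# Piecewise-constant log2 track over one chromosome, as emitted by the
# normalisation step (no dropped bins).
flat_track <- function(log2, chrom = "chr1", width = 50000) {
  n <- length(log2)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * width,
                 end = seq_len(n) * width, count = 100L,
                 dropped = NA_character_, log2 = log2)
}

# Small simulated cohort shared by several imputation tests.
small_cohort <- function(n_samples = 5, n_cpgs = 20000, lambda = 10,
                         seed = 42) {
  cfg <- sim_config(n_samples = n_samples, n_cpgs = n_cpgs,
                    lambda = lambda, seed = seed)
  sim <- simulate_methylomes(cfg)
  counts <- simulate_reads(sim$beta, cfg)
  list(cfg = cfg, true_beta = sim$beta, truth = sim$truth,
       beta = compute_beta(counts, min_depth = 1))
}
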