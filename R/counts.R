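#' Merge per-sample count tables into a cohort table
#'
#' Takes per-sample count tables (as returned by [read_cytosine_report()])
#' and produces one table over the sorted union of loci: every (locus,
#' sample) cell is present, with `total = 0` encoding "not covered in this
#' sample". Merging is order-independent.
#'
#' @param per_sample A list of tidy count tables, each with columns `chrom`,
#'   `pos`, `sample`, `meth`, `total` and a single distinct sample id.
#' @return A tibble with one row per (locus, sample) cell over the union of
#'   loci, sorted by (chrom, pos, sample).
#' @export
merge_cohort <- function(per_sample) {
  if (length(per_sample) < 1) abort("merge_cohort() needs at least one sample")
  ids <- vapply(per_sample, function(x) {
    check_columns(x, c("chrom", "pos", "sample", "meth", "total"), "count table")
    u <- unique(x$sample)
    if (length(u) > 1) abort("each input table must hold a single sample")
    if (length(u) == 0) NA_character_ else u
  }, character(1))
  ids <- ids[!is.na(ids)]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  all <- dplyr::bind_rows(per_sample)
  full <- tidyr::complete(all, tidyr::nesting(chrom, pos), sample,
                          fill = list(meth = 0L, total = 0L))
  full <- full[!is.na(full$sample), , drop = FALSE]
  full[order(chrom_order(full$chrom), full$pos, full$sample), ] |>
    tibble::as_tibble()
}

#' Compute beta values from methylation counts
#'
#' The beta value of a CpG is the methylated fraction `meth / total`. Cells
#' with coverage below `min_depth` are set to missing rather than discarded;
#' the depth is carried through so later stages (imputation training) can
#' apply stricter depth cuts.
#'
#' @param counts Cohort count table (`chrom`, `pos`, `sample`, `meth`,
#'   `total`).
#' @param min_depth Minimum total reads for a beta call (default 1: any
#'   covered CpG yields a beta).
#' @return Tibble with columns `chrom`, `pos`, `sample`, `beta` (NA when
#'   below depth), `depth`, `imputed` (all `FALSE`).
#' @export
compute_beta <- function(counts, min_depth = 1) {
  check_columns(counts, c("chrom", "pos", "sample", "meth", "total"), "counts")
  if (min_depth < 1) abort("min_depth must be >= 1")
  if (any(counts$meth > counts$total)) abort("meth exceeds total")
  beta <- ifelse(counts$total >= min_depth, counts$meth / counts$total,
                 NA_real_)
  tibble::tibble(chrom = counts$chrom, pos = counts$pos,
                 sample = counts$sample, beta = beta,
                 depth = as.integer(counts$total), imputed = FALSE)
}
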