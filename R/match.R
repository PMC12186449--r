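#' Match array probes to WGBS CpG loci
#'
#' Array probes interrogate a ~50 bp region around a target CpG, so a probe
#' and a sequencing-derived CpG are treated as the same locus when their
#' coordinates lie within `max_dist` bp of each other. Each probe is paired
#' to its nearest CpG within the tolerance; at equal distance the lower
#' genomic coordinate wins. Probes with no CpG inside the tolerance are
#' retained with `pos = NA` so unpaired entries stay visible.
#'
#' @param wgbs_loci Tibble of CpG loci (`chrom`, `pos`), sorted by
#'   (chrom, pos).
#' @param probe_coords Tibble of probe coordinates (`probe_id`, `chrom`,
#'   `pos`), sorted by (chrom, pos).
#' @param max_dist Matching tolerance in bp (default 25).
#' @return Tibble with one row per probe: `probe_id`, `chrom`, `probe_pos`,
#'   `pos` (matched CpG position or NA), `distance` (bp or NA).
#' @export
match_array_loci <- function(wgbs_loci, probe_coords,
                             max_dist = lowmeth_defaults()$probe_match_dist) {
  check_columns(wgbs_loci, c("chrom", "pos"), "wgbs_loci")
  check_columns(probe_coords, c("probe_id", "chrom", "pos"), "probe_coords")
  if (max_dist < 0) abort("max_dist must be >= 0")
  if (!is_sorted_loci(wgbs_loci)) abort("wgbs_loci must be sorted by (chrom, pos)")
  if (!is_sorted_loci(probe_coords)) abort("probe_coords must be sorted by (chrom, pos)")

  out <- probe_coords |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(p, key) {
      cpg <- wgbs_loci$pos[wgbs_loci$chrom == key$chrom]
      match_nearest(p, cpg, max_dist)
    }) |>
    dplyr::ungroup()
  out[order(chrom_order(out$chrom), out$probe_pos), ] |>
    dplyr::select("probe_id", "chrom", "probe_pos", "pos", "distance") |>
    tibble::as_tibble()
}

# Nearest sorted CpG for each probe row; ties break to the lower coordinate.
match_nearest <- function(probes, cpg_pos, max_dist) {
  n <- length(cpg_pos)
  pp <- probes$pos
  if (n == 0) {
    return(tibble::tibble(probe_id = probes$probe_id, probe_pos = pp,
                          pos = NA_real_, distance = NA_real_))
  }
  k <- findInterval(pp, cpg_pos)
  lo <- ifelse(k >= 1, cpg_pos[pmax(k, 1)], NA_real_)
  hi <- ifelse(k < n, cpg_pos[pmin(k + 1, n)], NA_real_)
  d_lo <- abs(pp - lo)
  d_hi <- abs(hi - pp)
  # lower coordinate wins ties, so <= on the lower candidate
  use_lo <- !is.na(d_lo) & (is.na(d_hi) | d_lo <= d_hi)
  pos <- ifelse(use_lo, lo, hi)
  dist <- ifelse(use_lo, d_lo, d_hi)
  within <- !is.na(dist) & dist <= max_dist
  tibble::tibble(probe_id = probes$probe_id, probe_pos = pp,
                 pos = ifelse(within, pos, NA_real_),
                 distance = ifelse(within, dist, NA_real_))
}

#' Per-sample Pearson correlation across platforms
#'
#' Correlates WGBS-derived betas with array betas at paired loci, one
#' Pearson r per sample, using only cells non-missing on both platforms.
#' Samples with fewer than 3 usable pairs or zero variance on either side
#' are flagged `undefined` rather than silently dropped.
#'
#' @param wgbs Long WGBS beta table (`chrom`, `pos`, `sample`, `beta`).
#' @param array Long array beta table (`probe_id`, `sample`, `beta`).
#' @param pairing Probe-to-CpG pairing from [match_array_loci()].
#' @return Tibble with columns `sample`, `n_used`, `r`, `status`
#'   (`"ok"`/`"undefined"`). The cohort mean and sd of the defined r values
#'   are attached as attributes `cohort_mean` and `cohort_sd`.
#' @export
pearson_per_sample <- function(wgbs, array, pairing) {
  check_columns(wgbs, c("chrom", "pos", "sample", "beta"), "wgbs")
  check_columns(array, c("probe_id", "sample", "beta"), "array")
  check_columns(pairing, c("probe_id", "chrom", "pos"), "pairing")
  samples <- sort(intersect(unique(wgbs$sample), unique(array$sample)))
  if (length(samples) == 0) abort("no shared sample ids between platforms")

  paired <- pairing[!is.na(pairing$pos), c("probe_id", "chrom", "pos")]
  arr <- array[array$sample %in% samples,
               c("probe_id", "sample", "beta"), drop = FALSE]
  joined <- paired |>
    dplyr::inner_join(arr, by = "probe_id", relationship = "many-to-many") |>
    dplyr::inner_join(wgbs, by = c("chrom", "pos", "sample"),
                      suffix = c("_array", "_wgbs"))

  out <- purrr::map_dfr(samples, function(s) {
    d <- joined[joined$sample == s, ]
    ok <- !is.na(d$beta_array) & !is.na(d$beta_wgbs)
    x <- d$beta_wgbs[ok]; y <- d$beta_array[ok]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || sd(y) == 0) {
      tibble::tibble(sample = s, n_used = n, r = NA_real_,
                     status = "undefined")
    } else {
      tibble::tibble(sample = s, n_used = n, r = cor(x, y),
                     status = "ok")
    }
  })
  rdef <- out$r[out$status == "ok"]
  attr(out, "cohort_mean") <- if (length(rdef)) mean(rdef) else NA_real_
  attr(out, "cohort_sd") <- if (length(rdef) > 1) sd(rdef) else NA_real_
  out
}
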