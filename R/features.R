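# Variance-based CpG selection, island-relative annotation, and collapsing
# of correlated proximal CpGs to unique genomic regions.

#' Select the most variably methylated CpGs
#'
#' Ranks loci by the standard deviation (n - 1 denominator) of their beta
#' values across samples and returns the top `k`. Loci with any missing
#' value are excluded (a fully imputed matrix has none). Ties rank in
#' genomic order.
#'
#' @param beta Long beta table (`chrom`, `pos`, `sample`, `beta`).
#' @param k Number of loci to keep (default 10,000).
#' @return Tibble (`chrom`, `pos`, `sd`) ranked by decreasing sd.
#' @export
top_variable <- function(beta, k = lowmeth_defaults()$top_k) {
  check_columns(beta, c("chrom", "pos", "sample", "beta"), "beta table")
  if (k < 0) abort("k must be >= 0")
  ws <- cells_to_matrix(beta, "beta")
  if (ncol(ws$values) < 2) abort("need at least 2 samples to rank variability")
  complete <- rowSums(is.na(ws$values)) == 0
  m <- ws$values[complete, , drop = FALSE]
  n <- ncol(m)
  mu <- rowMeans(m)
  sds <- sqrt(pmax(0, (rowSums(m^2) - n * mu^2) / (n - 1)))
  out <- ws$loci[complete, ]
  out$sd <- sds
  out <- out[order(-out$sd, chrom_order(out$chrom), out$pos), ]
  if (k > nrow(out)) {
    warn(sprintf("k (%d) exceeds the %d complete loci; returning all", k, nrow(out)))
    k <- nrow(out)
  }
  tibble::as_tibble(head(out, k))
}

#' Annotate loci relative to CpG islands
#'
#' Classifies each locus as island, shore (within 2 kb of an island), shelf
#' (2-4 kb) or open sea, and assigns a `region_id` naming the containing
#' interval: the island/shore/shelf interval, or the gap between shelf
#' boundaries for open-sea loci. Shores and shelves of nearby islands that
#' touch or overlap merge into single regions.
#'
#' @param loci Tibble (`chrom`, `pos`) — 0-based positions; a `sd` column,
#'   when present, is carried through.
#' @param islands CpG island intervals (`chrom`, `start`, `end`), 0-based
#'   half-open, sorted and non-overlapping.
#' @param shore_bp,shelf_bp Category widths in bp (defaults 2,000 each).
#' @return `loci` with `category` (island/shore/shelf/open_sea) and
#'   `region_id` columns.
#' @export
assign_categories <- function(loci, islands, shore_bp = 2000, shelf_bp = 2000) {
  check_columns(loci, c("chrom", "pos"), "loci")
  check_columns(islands, c("chrom", "start", "end"), "islands")
  out <- loci
  out$category <- "open_sea"
  out$region_id <- NA_character_
  for (ch in unique(out$chrom)) {
    li <- which(out$chrom == ch)
    p1 <- out$pos[li] + 1  # 1-based closed for IRanges
    isl_ch <- islands[islands$chrom == ch, ]
    if (nrow(isl_ch) > 0) {
      isl <- IRanges::reduce(IRanges::IRanges(start = isl_ch$start + 1,
                                              end = isl_ch$end))
      shore_zone <- IRanges::restrict(IRanges::reduce(isl + shore_bp), start = 1L)
      shelf_zone <- IRanges::restrict(IRanges::reduce(isl + shore_bp + shelf_bp),
                                      start = 1L)
      shores <- IRanges::setdiff(shore_zone, isl)
      shelves <- IRanges::setdiff(shelf_zone, shore_zone)
      sea_end <- max(max(p1), max(IRanges::end(shelf_zone))) + 1L
      sea <- IRanges::gaps(shelf_zone, start = 1L, end = sea_end)
      sets <- list(island = isl, shore = shores, shelf = shelves,
                   open_sea = sea)
    } else {
      sea_end <- max(p1)
      sets <- list(open_sea = IRanges::IRanges(start = 1L, end = sea_end))
    }
    q <- IRanges::IRanges(start = p1, width = 1L)
    for (cat in names(sets)) {
      hits <- IRanges::findOverlaps(q, sets[[cat]])
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      if (length(qh) == 0) next
      iv <- sets[[cat]][sh]
      out$category[li[qh]] <- cat
      out$region_id[li[qh]] <- sprintf("%s:%s:%d-%d", cat, ch,
                                       IRanges::start(iv) - 1L,
                                       IRanges::end(iv))
    }
  }
  tibble::as_tibble(out)
}

#' Collapse annotated CpGs to unique genomic regions
#'
#' CpGs sharing a `region_id` (e.g. the same CpG island) are treated as
#' non-unique; each region keeps a single representative, the member with
#' the highest sd (ties to the lower genomic coordinate). The operation is
#' idempotent.
#'
#' @param annotated Tibble from [assign_categories()] with an `sd` column.
#' @return `annotated` with an `is_representative` column; the number of
#'   unique regions is attached as attribute `n_unique_regions`.
#' @export
collapse_to_regions <- function(annotated) {
  check_columns(annotated, c("chrom", "pos", "sd", "region_id"), "annotated")
  # which.max takes the first maximum, so sorting by genomic order first
  # makes the lower coordinate win sd ties
  out <- annotated |>
    dplyr::arrange(chrom_order(.data$chrom), .data$pos) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::mutate(is_representative = dplyr::row_number() ==
                    which.max(.data$sd)) |>
    dplyr::ungroup()
  attr(out, "n_unique_regions") <- dplyr::n_distinct(out$region_id)
  out
}

#' Count loci overlapping an array probe manifest
#'
#' Partitions the input loci into those lying within `max_dist` bp of any
#' manifest probe coordinate and those that do not — the accounting used to
#' ask how much of a variable-CpG set an array design can see at all.
#'
#' @param loci Tibble (`chrom`, `pos`), sorted.
#' @param manifest_coords Probe manifest (`probe_id`, `chrom`, `pos`),
#'   sorted.
#' @param max_dist Matching tolerance in bp (default 25).
#' @return One-row tibble: `n_overlapping`, `n_non_overlapping`.
#' @export
manifest_overlap_count <- function(loci, manifest_coords,
                                   max_dist = lowmeth_defaults()$probe_match_dist) {
  check_columns(loci, c("chrom", "pos"), "loci")
  check_columns(manifest_coords, c("probe_id", "chrom", "pos"), "manifest")
  # reuse the probe matcher with roles swapped: pair each locus against the
  # manifest coordinates
  as_probes <- tibble::tibble(probe_id = paste0("locus_", seq_len(nrow(loci))),
                              chrom = loci$chrom, pos = loci$pos)
  as_probes <- as_probes[order(chrom_order(as_probes$chrom), as_probes$pos), ]
  targets <- manifest_coords[order(chrom_order(manifest_coords$chrom),
                                   manifest_coords$pos), c("chrom", "pos")]
  pairing <- match_array_loci(targets, as_probes, max_dist = max_dist)
  n_hit <- sum(!is.na(pairing$pos))
  tibble::tibble(n_overlapping = n_hit,
                 n_non_overlapping = nrow(loci) - n_hit)
}
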