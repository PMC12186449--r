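# Reference-free copy-number estimation from low-pass coverage.
#
# Coverage is summarised in fixed-width bins (default 50 kb, chosen for
# low-pass depth), filtered against a blacklist of poorly mappable regions,
# normalised to log2 ratios against the sample's own autosomal median (no
# panel of normals), screened for outlier bins, and segmented.

#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_sizes Tibble (`chrom`, `size`).
#' @param width Bin width in bp (default 50,000). The terminal bin of each
#'   chromosome may be shorter.
#' @return Tibble (`chrom`, `start`, `end`) of half-open bins, with
#'   `count = 0` and `dropped = NA`.
#' @export
make_bins <- function(chrom_sizes, width = lowmeth_defaults()$bin_width) {
  check_columns(chrom_sizes, c("chrom", "size"), "chrom_sizes")
  if (width <= 0) abort("width must be > 0")
  purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    size <- chrom_sizes$size[i]
    starts <- seq(0, size - 1, by = width)
    tibble::tibble(chrom = chrom_sizes$chrom[i], start = starts,
                   end = pmin(starts + width, size))
  }) |>
    dplyr::mutate(count = 0L, dropped = NA_character_)
}

#' Count fragments into bins
#'
#' Each fragment is assigned to exactly one bin by its midpoint. Fragments
#' on chromosomes absent from the bin set (or with midpoints beyond the last
#' bin) are skipped and reported.
#'
#' @param fragments Tibble of intervals (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param bins Bin tibble from [make_bins()].
#' @return `bins` with the `count` column filled; the number of skipped
#'   fragments is attached as attribute `n_skipped` (with a warning when
#'   non-zero).
#' @export
count_fragments <- function(fragments, bins) {
  check_columns(fragments, c("chrom", "start", "end"), "fragments")
  check_columns(bins, c("chrom", "start", "end"), "bins")
  mid <- floor((fragments$start + fragments$end) / 2)
  counts <- integer(nrow(bins))
  skipped <- 0L
  for (ch in unique(fragments$chrom)) {
    bidx <- which(bins$chrom == ch)
    m <- mid[fragments$chrom == ch]
    if (length(bidx) == 0) {
      skipped <- skipped + length(m)
      next
    }
    k <- findInterval(m, bins$start[bidx])
    inside <- k >= 1 & m < bins$end[bidx][pmax(k, 1)]
    skipped <- skipped + sum(!inside)
    tab <- tabulate(k[inside], nbins = length(bidx))
    counts[bidx] <- counts[bidx] + tab
  }
  out <- bins
  out$count <- counts
  if (skipped > 0) {
    warn(sprintf("%d fragment(s) fell outside the bin set and were skipped",
                 skipped))
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Flag blacklisted and low-coverage bins
#'
#' A bin is dropped as `blacklist` when more than half of its length
#' overlaps the blacklist (centromeres, telomeres, poor-mappability
#' regions), and as `low_coverage` when its count is below `min_count`
#' (default 1, i.e. zero-count bins).
#'
#' @param track Bin tibble with counts.
#' @param blacklist Optional interval tibble (`chrom`, `start`, `end`).
#' @param min_count Minimum count to retain a bin (default 1).
#' @return `track` with the `dropped` column set to `"blacklist"`,
#'   `"low_coverage"` or `NA`.
#' @export
filter_bins <- function(track, blacklist = NULL, min_count = 1) {
  check_columns(track, c("chrom", "start", "end", "count"), "track")
  dropped <- rep(NA_character_, nrow(track))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    ov <- overlap_length(track, blacklist)
    dropped[ov > 0.5 * (track$end - track$start)] <- "blacklist"
  }
  low <- is.na(dropped) & track$count < min_count
  dropped[low] <- "low_coverage"
  track$dropped <- dropped
  track
}

# Total length of each query interval covered by the (merged) subject set.
overlap_length <- function(query, subject) {
  out <- numeric(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0) next
    q <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    s <- IRanges::reduce(IRanges::IRanges(start = subject$start[si] + 1,
                                          end = subject$end[si]))
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    inter <- IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                 s[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(inter), S4Vectors::queryHits(hits), sum)
    out[qi[as.integer(names(w))]] <- as.numeric(w)
  }
  out
}

#' Normalise bin counts to log2 copy ratios
#'
#' Reference-free normalisation: each retained bin's count is divided by the
#' sample's own median autosomal non-dropped count and log2-transformed;
#' when a `gc` column is present a loess correction of log2 on GC fraction
#' is applied first, and the autosomal median log2 is re-centred to 0. A
#' diploid genome therefore sits at log2 = 0 without any external
#' reference.
#'
#' @param track Filtered bin tibble.
#' @param sex_chroms Chromosome names excluded from the median (default X/Y
#'   with or without "chr" prefix).
#' @return `track` with a `log2` column (NA for dropped bins).
#' @export
normalize_log2 <- function(track, sex_chroms = c("chrX", "chrY", "X", "Y")) {
  check_columns(track, c("chrom", "start", "end", "count", "dropped"), "track")
  keep <- is.na(track$dropped)
  auto <- keep & !track$chrom %in% sex_chroms
  m <- median(track$count[auto])
  if (!is.finite(m) || m == 0) abort("degenerate track: median autosomal count is 0")
  log2r <- rep(NA_real_, nrow(track))
  log2r[keep] <- log2(track$count[keep] / m)
  if ("gc" %in% names(track) && any(!is.na(track$gc[keep]))) {
    fitdat <- data.frame(y = log2r[keep], gc = track$gc[keep])
    fit <- loess(y ~ gc, data = fitdat, degree = 2, span = 0.75)
    log2r[keep] <- log2r[keep] - predict(fit, fitdat)
  }
  log2r[keep] <- log2r[keep] - median(log2r[auto])
  track$log2 <- log2r
  track
}

#' Screen bins for outlying log2 values
#'
#' Flags bins whose log2 deviates from a rolling median (window 51 bins,
#' per chromosome) by more than `factor` times the rolling MAD of the
#' residuals. At the default factor of 100 the screen is deliberately
#' permissive, removing only technical spikes while leaving genuine copy
#' number structure untouched.
#'
#' @param track Normalised bin tibble.
#' @param factor MAD multiplier (default 100); `Inf` disables the screen.
#' @param window Rolling window in bins (odd, default 51).
#' @return `track` with outlying bins marked `dropped = "outlier"` and
#'   their `log2` set to NA.
#' @export
drop_outliers <- function(track, factor = lowmeth_defaults()$outlier_factor,
                          window = 51) {
  check_columns(track, c("chrom", "log2", "dropped"), "track")
  if (is.infinite(factor)) return(track)
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch & is.na(track$dropped))
    n <- length(idx)
    if (n < 3) next
    x <- track$log2[idx]
    k <- min(window, if (n %% 2 == 1) n else n - 1)
    rm_ <- runmed(x, k = k, endrule = "median")
    resid <- x - rm_
    rmad <- roll_mad(resid, window)
    out <- abs(resid) > factor * rmad
    track$dropped[idx[out]] <- "outlier"
    track$log2[idx[out]] <- NA_real_
  }
  track
}
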