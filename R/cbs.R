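# Circular binary segmentation with analytic t-distribution p-values.
#
# Within each chromosome the bin-level log2 values are treated as a circle;
# the arc (i, j] maximising the two-sample t statistic between arc and
# complement is found exhaustively, and the segment is split there when the
# analytic p-value falls below alpha. The analytic test (rather than a
# permutation null) makes extreme thresholds such as 1e-15 attainable and
# the procedure fully deterministic.

# Best arc of x: returns list(i, j, t) where the arc is x[(i+1):j].
cbs_best_arc <- function(x) {
  n <- length(x)
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x^2))
  total <- S[n + 1]
  qtot <- Q[n + 1]
  best <- list(t = -Inf, i = NA_integer_, j = NA_integer_)
  for (i in 0:(n - 1)) {
    j <- (i + 1):n
    n1 <- j - i
    n2 <- n - n1
    ok <- n2 >= 1
    if (!any(ok)) next
    j <- j[ok]; n1 <- n1[ok]; n2 <- n2[ok]
    sum1 <- S[j + 1] - S[i + 1]
    q1 <- Q[j + 1] - Q[i + 1]
    mean1 <- sum1 / n1
    mean2 <- (total - sum1) / n2
    ss <- pmax(0, (q1 - n1 * mean1^2) + (qtot - q1 - n2 * mean2^2))
    s2 <- ss / max(n - 2, 1)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    delta <- abs(mean1 - mean2)
    tt <- delta / se
    # zero pooled variance: a genuine mean difference is an infinite t, but
    # differences at floating-point rounding scale are no difference at all
    eps <- 1e-9 * (1 + abs(total) / n)
    tt[se == 0 & delta > eps] <- Inf
    tt[se == 0 & delta <= eps] <- 0
    k <- which.max(tt)
    if (tt[k] > best$t) best <- list(t = tt[k], i = i, j = j[k])
  }
  best
}

# p-value for the best arc under the analytic two-sample t reference.
cbs_pvalue <- function(tstat, n) {
  if (!is.finite(tstat)) return(if (tstat > 0) 0 else 1)
  2 * pt(-abs(tstat), df = max(n - 2, 1))
}

# Recursive splitting; returns sorted interior breakpoints (split after
# position b) of x.
cbs_recurse <- function(x, offset, alpha) {
  n <- length(x)
  if (n < 2) return(integer(0))
  arc <- cbs_best_arc(x)
  if (is.na(arc$i)) return(integer(0))
  if (cbs_pvalue(arc$t, n) >= alpha) return(integer(0))
  cuts <- sort(unique(c(arc$i, arc$j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (length(cuts) == 0) return(integer(0))
  bounds <- c(0, cuts, n)
  res <- integer(0)
  for (b in seq_len(length(bounds) - 1)) {
    lo <- bounds[b] + 1
    hi <- bounds[b + 1]
    res <- c(res, cbs_recurse(x[lo:hi], offset + lo - 1, alpha))
  }
  sort(unique(c(offset + cuts, res)))
}

#' Segment a normalised bin track by circular binary segmentation
#'
#' Recursively partitions each chromosome's non-dropped bins into
#' constant-mean segments. A split is accepted when the two-sample t
#' statistic between the best arc and its complement has an analytic
#' p-value below `alpha`; the default 1e-15 is intentionally stringent so
#' that only unambiguous copy-number transitions create breakpoints at
#' 50 kb bin resolution. The procedure is deterministic for fixed input.
#'
#' @param track Normalised bin tibble (from [normalize_log2()] /
#'   [drop_outliers()]); a `sample` column, when present, is carried
#'   through.
#' @param alpha Split significance threshold (default 1e-15).
#' @return Segment tibble: `chrom`, `start`, `end`, `n_bins`, `mean_log2`
#'   (plus `sample` when present), sorted and non-overlapping within each
#'   chromosome, covering all non-dropped bins.
#' @export
segment_cbs <- function(track, alpha = lowmeth_defaults()$cbs_alpha) {
  check_columns(track, c("chrom", "start", "end", "log2", "dropped"), "track")
  sample_id <- if ("sample" %in% names(track)) unique(track$sample) else NULL
  if (length(sample_id) > 1) {
    return(purrr::map_dfr(sample_id, function(s) {
      segment_cbs(track[track$sample == s, ], alpha)
    }))
  }
  chroms <- unique(track$chrom)
  segs <- purrr::map_dfr(chroms, function(ch) {
    idx <- which(track$chrom == ch & is.na(track$dropped) &
                   !is.na(track$log2))
    if (length(idx) == 0) return(NULL)
    x <- track$log2[idx]
    breaks <- if (length(x) < 2) integer(0) else cbs_recurse(x, 0L, alpha)
    bounds <- c(0, breaks, length(x))
    purrr::map_dfr(seq_len(length(bounds) - 1), function(b) {
      sel <- idx[(bounds[b] + 1):bounds[b + 1]]
      tibble::tibble(chrom = ch,
                     start = track$start[sel[1]],
                     end = track$end[sel[length(sel)]],
                     n_bins = length(sel),
                     mean_log2 = mean(track$log2[sel]))
    })
  })
  if (!is.null(sample_id) && nrow(segs) > 0) {
    segs <- dplyr::mutate(segs, sample = sample_id, .before = 1)
  }
  segs
}
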