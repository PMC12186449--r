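# Absolute copy-state classification, arm-level aggregation and
# cross-platform segment concordance.

#' Copy-state classification thresholds
#'
#' Log2-ratio cut-offs mapping segment means to absolute copy states. The
#' `"wgbs"` preset was calibrated on tumours with unambiguous monosomies
#' (log2 near -1) and single-copy whole-chromosome gains (log2 near
#' +0.585): gain at 0.3, amplification at 0.7, loss at -0.4, deletion at
#' -1.1. The `"wes"` preset is the symmetric +/-0.2 gain/loss rule used by
#' exome copy-number tools (no amplification/deletion tiers).
#'
#' @param preset `"wgbs"` (default) or `"wes"`.
#' @return Named list with elements `gain`, `amplification`, `loss`,
#'   `deletion` satisfying deletion < loss < 0 < gain < amplification.
#' @export
copy_state_thresholds <- function(preset = c("wgbs", "wes")) {
  preset <- match.arg(preset)
  th <- switch(preset,
    wgbs = list(gain = 0.3, amplification = 0.7, loss = -0.4, deletion = -1.1),
    wes = list(gain = 0.2, amplification = Inf, loss = -0.2, deletion = -Inf))
  stopifnot(th$deletion < th$loss, th$loss < 0, 0 < th$gain,
            th$gain < th$amplification)
  th
}

copy_states <- c("deletion", "loss", "neutral", "gain", "amplification")

#' Assign absolute copy states to segments
#'
#' Boundaries are inclusive toward the non-neutral call: a segment mean
#' exactly at a threshold receives the corresponding state.
#'
#' @param segments Segment tibble with `mean_log2`.
#' @param thresholds Thresholds from [copy_state_thresholds()].
#' @return `segments` with a `state` column (factor over deletion, loss,
#'   neutral, gain, amplification).
#' @export
classify_segments <- function(segments, thresholds = copy_state_thresholds()) {
  check_columns(segments, "mean_log2", "segments")
  m <- segments$mean_log2
  state <- dplyr::case_when(
    m >= thresholds$amplification ~ "amplification",
    m >= thresholds$gain ~ "gain",
    m <= thresholds$deletion ~ "deletion",
    m <= thresholds$loss ~ "loss",
    TRUE ~ "neutral"
  )
  segments$state <- factor(state, levels = copy_states)
  segments
}

#' Aggregate segment states into arm-level calls
#'
#' For each chromosome arm, the classified length (total overlap with
#' state-bearing segments) is tallied per state; the arm is called with the
#' non-neutral state of greatest covering length provided it covers more
#' than half of the arm's classified length, otherwise neutral. Arms with
#' no classified bins are reported `no-data`.
#'
#' @param segments Classified segment tibble (optionally per `sample`).
#' @param arms Arm definition tibble (`arm`, `chrom`, `start`, `end`).
#' @return Tibble: (`sample`,) `arm`, `chrom`, `state`, `fraction` (of
#'   classified length supporting the call).
#' @export
call_arms <- function(segments, arms) {
  check_columns(segments, c("chrom", "start", "end", "state"), "segments")
  check_columns(arms, c("arm", "chrom", "start", "end"), "arms")
  if ("sample" %in% names(segments)) {
    return(purrr::map_dfr(unique(segments$sample), function(s) {
      out <- call_arms(dplyr::select(segments[segments$sample == s, ], -"sample"), arms)
      dplyr::mutate(out, sample = s, .before = 1)
    }))
  }
  purrr::map_dfr(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    seg <- segments[segments$chrom == a$chrom, ]
    ov <- pmax(0, pmin(seg$end, a$end) - pmax(seg$start, a$start))
    seg <- seg[ov > 0, ]; ov <- ov[ov > 0]
    if (nrow(seg) == 0) {
      return(tibble::tibble(arm = a$arm, chrom = a$chrom, state = "no-data",
                            fraction = NA_real_))
    }
    len_by_state <- tapply(ov, factor(seg$state, levels = copy_states), sum,
                           default = 0)
    classified <- sum(len_by_state)
    nn <- len_by_state[setdiff(copy_states, "neutral")]
    top <- names(nn)[which.max(nn)]
    if (nn[top] > 0.5 * classified) {
      tibble::tibble(arm = a$arm, chrom = a$chrom, state = top,
                     fraction = unname(nn[top]) / classified)
    } else {
      tibble::tibble(arm = a$arm, chrom = a$chrom, state = "neutral",
                     fraction = unname(len_by_state["neutral"]) / classified)
    }
  })
}

#' Cross-platform segment concordance
#'
#' A query segment is concordant when some single same-state segment in the
#' reference set overlaps more than `min_overlap` of the query segment's
#' length (one-directional by default; set `reciprocal = TRUE` to also
#' require the overlap to exceed the same fraction of the reference
#' segment). Sensitivity is the fraction of non-neutral query segments that
#' are concordant. When both sets carry a `sample` column, comparison is
#' within sample.
#'
#' @param a Query segment tibble (classified).
#' @param b Reference segment tibble (classified).
#' @param min_overlap Minimum overlap fraction (default 0.5).
#' @param reciprocal Require the overlap on both segment lengths.
#' @return `a` with a `concordant` column; sensitivity (and the counts
#'   behind it) attached as attributes `sensitivity`, `n_concordant`,
#'   `n_non_neutral`.
#' @export
segment_concordance <- function(a, b,
                                min_overlap = lowmeth_defaults()$concordance_min_overlap,
                                reciprocal = FALSE) {
  check_columns(a, c("chrom", "start", "end", "state"), "a")
  check_columns(b, c("chrom", "start", "end", "state"), "b")
  if (nrow(b) == 0) warn("reference segment set is empty; sensitivity is 0")
  by_sample <- "sample" %in% names(a) && "sample" %in% names(b)
  conc <- vapply(seq_len(nrow(a)), function(i) {
    q <- a[i, ]
    cand <- b[b$chrom == q$chrom & as.character(b$state) == as.character(q$state), ]
    if (by_sample) cand <- cand[cand$sample == q$sample, ]
    if (nrow(cand) == 0) return(FALSE)
    ov <- pmax(0, pmin(cand$end, q$end) - pmax(cand$start, q$start))
    hit <- ov > min_overlap * (q$end - q$start)
    if (reciprocal) hit <- hit & ov > min_overlap * (cand$end - cand$start)
    any(hit)
  }, logical(1))
  a$concordant <- conc
  nn <- as.character(a$state) != "neutral"
  attr(a, "n_non_neutral") <- sum(nn)
  attr(a, "n_concordant") <- sum(conc & nn)
  attr(a, "sensitivity") <- if (sum(nn) == 0) NA_real_ else sum(conc & nn) / sum(nn)
  a
}
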