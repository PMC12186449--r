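# Internal helpers shared across modules.

clamp01 <- function(x) pmin(1, pmax(0, x))

# Canonical chromosome ordering: natural sort so "chr2" < "chr10".
chrom_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  ord <- order(is.na(num), num, u)
  factor(as.character(chrom), levels = u[ord])
}

arrange_loci <- function(df) {
  df[order(chrom_order(df$chrom), df$pos), , drop = FALSE]
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s must have columns: %s (missing: %s)",
                  what, paste(cols, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_sorted_loci <- function(df) {
  o <- order(chrom_order(df$chrom), df$pos)
  identical(o, seq_len(nrow(df)))
}

# Wide locus x sample matrix from a long cell table; loci are the sorted
# unique (chrom, pos) pairs, column order is sort(unique(sample)).
cells_to_matrix <- function(df, value_col, fill = NA_real_) {
  loci <- dplyr::distinct(df, .data$chrom, .data$pos)
  loci <- arrange_loci(loci)
  key <- paste(loci$chrom, loci$pos)
  samples <- sort(unique(df$sample))
  m <- matrix(fill, nrow = nrow(loci), ncol = length(samples),
              dimnames = list(NULL, samples))
  i <- match(paste(df$chrom, df$pos), key)
  j <- match(df$sample, samples)
  m[cbind(i, j)] <- df[[value_col]]
  list(loci = tibble::as_tibble(loci), samples = samples, values = m)
}

# Rolling median absolute deviation with partial windows at the ends.
roll_mad <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mad(x[lo:hi])
  }, numeric(1))
}
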