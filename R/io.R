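#' Read per-CpG methylation counts for one sample
#'
#' Parses a Bismark-style cytosine report or a bedGraph/coverage-style file
#' into a tidy count table. Coordinates are converted to 0-based half-open
#' convention at this boundary, and CpGs reported separately on the two
#' strands are collapsed onto the forward-strand cytosine position by summing
#' their read counts, so that downstream code sees one record per CpG site.
#'
#' File dialects:
#' \describe{
#'   \item{`cytosine_report`}{Six tab-separated columns, 1-based positions:
#'     chrom, pos, strand (+/-), count methylated, count unmethylated,
#'     context. A reverse-strand cytosine at 1-based position p belongs to
#'     the CpG whose forward cytosine sits at p - 1.}
#'   \item{`bedgraph_coverage`}{Bismark coverage dialect: chrom, start
#'     (1-based), end, percent methylation, count methylated, count
#'     unmethylated. Already one row per cytosine position; no strand
#'     collapsing is applied.}
#' }
#'
#' @param path Path to the input file. May be empty (zero loci returned).
#' @param dialect One of `"cytosine_report"`, `"bedgraph_coverage"`.
#' @param sample Sample identifier; defaults to the file name without
#'   extension.
#' @return A tibble with columns `chrom`, `pos` (0-based forward-strand
#'   cytosine), `sample`, `meth`, `total`, sorted by (chrom, pos).
#' @seealso [write_cytosine_report()], [merge_cohort()], [compute_beta()]
#' @export
read_cytosine_report <- function(path,
                                 dialect = c("cytosine_report", "bedgraph_coverage"),
                                 sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))

  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          sample = character(), meth = integer(),
                          total = integer())
  if (file.size(path) == 0) return(empty)

  if (dialect == "cytosine_report") {
    raw <- suppressWarnings(
      readr::read_tsv(path, col_names = c("chrom", "pos", "strand",
                                          "meth", "unmeth", "context"),
                      col_types = "ciciic", progress = FALSE))
    stop_on_parse_problems(raw, path)
    bad <- which(!raw$strand %in% c("+", "-"))
    if (length(bad) > 0) {
      abort(sprintf("parse error in %s, line %d: strand must be + or -",
                    path, bad[1]))
    }
    # 1-based -> 0-based; reverse-strand C maps to the forward C one base up.
    pos0 <- ifelse(raw$strand == "+", raw$pos - 1L, raw$pos - 2L)
    if (any(pos0 < 0)) {
      abort(sprintf("parse error in %s, line %d: position out of range",
                    path, which(pos0 < 0)[1]))
    }
    out <- tibble::tibble(chrom = raw$chrom, pos = pos0,
                          meth = raw$meth, total = raw$meth + raw$unmeth)
  } else {
    raw <- suppressWarnings(
      readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                          "pct", "meth", "unmeth"),
                      col_types = "ciidii", progress = FALSE))
    stop_on_parse_problems(raw, path)
    out <- tibble::tibble(chrom = raw$chrom, pos = raw$start - 1L,
                          meth = raw$meth, total = raw$meth + raw$unmeth)
  }

  out <- collapse_strands(out)
  out$sample <- sample
  if (any(out$meth > out$total)) {
    abort(sprintf("data error in %s: methylated count exceeds total", path))
  }
  arrange_loci(out)[, c("chrom", "pos", "sample", "meth", "total")] |>
    tibble::as_tibble()
}

stop_on_parse_problems <- function(raw, path) {
  pr <- readr::problems(raw)
  if (nrow(pr) > 0) {
    abort(sprintf("parse error in %s, line %d: %s",
                  path, pr$row[1], pr$expected[1]))
  }
  invisible(raw)
}

# Sum counts of records sharing a (chrom, pos) key. Idempotent.
collapse_strands <- function(df) {
  df |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(meth = sum(.data$meth), total = sum(.data$total),
                     .groups = "drop")
}

#' Write a count table back to cytosine-report format
#'
#' Emits one forward-strand, 1-based row per CpG so that
#' [read_cytosine_report()] reproduces the table exactly (round-trip safe).
#'
#' @param counts Tidy count table (`chrom`, `pos`, `meth`, `total`), one
#'   sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(counts, path) {
  check_columns(counts, c("chrom", "pos", "meth", "total"), "counts")
  if ("sample" %in% names(counts) && dplyr::n_distinct(counts$sample) > 1) {
    abort("write_cytosine_report() writes a single sample; split the cohort first")
  }
  out <- tibble::tibble(chrom = counts$chrom, pos = counts$pos + 1L,
                        strand = "+", meth = counts$meth,
                        unmeth = counts$total - counts$meth, context = "CG")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chrom, size (no header).
#' @return Tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"), col_types = "cd",
                  progress = FALSE)
}

#' Read a BED file of intervals
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used; a fourth column, when present, is kept as `name`.
#'
#' @param path BED path.
#' @return Tibble with columns `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  ncol <- if (length(first) == 0) 3L else length(strsplit(first, "\t")[[1]])
  if (ncol >= 4) {
    readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                    col_types = "cddc", col_select = 1:4, progress = FALSE)
  } else {
    readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                    col_types = "cdd", progress = FALSE)
  }
}

#' Read an array beta table
#'
#' Expects a header row: `probe_id`, `chrom`, `pos`, then one column per
#' sample holding beta values (empty cells = missing).
#'
#' @param path TSV path.
#' @return Long tibble with columns `probe_id`, `chrom`, `pos`, `sample`,
#'   `beta`.
#' @export
read_array_betas <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = "c", chrom = "c", pos = "i", .default = "d"), progress = FALSE)
  check_columns(wide, c("probe_id", "chrom", "pos"), "array beta table")
  tidyr::pivot_longer(wide, cols = -c("probe_id", "chrom", "pos"),
                      names_to = "sample", values_to = "beta")
}

#' Write a beta table in wide, classifier-ready layout
#'
#' Rows are loci keyed `chrom:pos` (or the probe id when present), columns
#' are samples; missing betas are written as empty cells. This is the layout
#' external array-trained classifiers consume.
#'
#' @param beta Long beta table (`chrom`, `pos`, `sample`, `beta`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  check_columns(beta, c("chrom", "pos", "sample", "beta"), "beta table")
  wide <- beta |>
    dplyr::mutate(locus = paste0(.data$chrom, ":", .data$pos)) |>
    dplyr::select("locus", "sample", "beta") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "beta")
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a wide beta matrix written by [write_beta_matrix()]
#'
#' @param path TSV path with a `locus` column (`chrom:pos`) and one column
#'   per sample.
#' @return Long tibble (`chrom`, `pos`, `sample`, `beta`).
#' @export
read_beta_matrix <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    locus = "c", .default = "d"), progress = FALSE)
  check_columns(wide, "locus", "beta matrix")
  long <- tidyr::pivot_longer(wide, cols = -"locus",
                              names_to = "sample", values_to = "beta")
  parts <- strsplit(long$locus, ":", fixed = TRUE)
  long$chrom <- vapply(parts, `[`, character(1), 1)
  long$pos <- as.integer(vapply(parts, `[`, character(1), 2))
  dplyr::select(long, "chrom", "pos", "sample", "beta")
}
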