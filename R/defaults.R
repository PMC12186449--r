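#' Default pipeline constants
#'
#' The tuned constants of the low-pass WGBS workflow, collected in one place
#' so that every entry point (R functions, [run_pipeline()], the command-line
#' wrapper) shares a single source of truth. Individual functions expose the
#' same values as argument defaults.
#'
#' @return A named list:
#' \describe{
#'   \item{bin_width}{CNV bin width in bp (50,000).}
#'   \item{n_train}{Per-sample imputation training-set size (1,000,000 CpGs).}
#'   \item{train_min_depth}{Minimum read depth for a CpG to be eligible as an
#'     imputation training example (10).}
#'   \item{probe_match_dist}{Maximum distance in bp for matching a CpG to an
#'     array probe coordinate (25).}
#'   \item{concordance_min_overlap}{Minimum fraction of a segment's length
#'     that a same-state segment must overlap to count as concordant (0.5).}
#'   \item{cbs_alpha}{Significance threshold for accepting a segmentation
#'     split (1e-15).}
#'   \item{outlier_factor}{Rolling-MAD multiplier for the bin outlier screen
#'     (100).}
#'   \item{top_k}{Number of most-variable CpGs selected (10,000).}
#'   \item{beta_min_depth}{Minimum depth for calling a beta value (1).}
#' }
#' @examples
#' lowmeth_defaults()$bin_width
#' @export
lowmeth_defaults <- function() {
  list(
    bin_width = 50000L,
    n_train = 1000000L,
    train_min_depth = 10L,
    probe_match_dist = 25L,
    concordance_min_overlap = 0.5,
    cbs_alpha = 1e-15,
    outlier_factor = 100,
    top_k = 10000L,
    beta_min_depth = 1L
  )
}
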