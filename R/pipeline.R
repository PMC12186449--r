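# End-to-end orchestration: simulate -> impute -> correlate -> select ->
# cnv, with provenance and an output manifest.

pipeline_stages <- c("simulate", "impute", "correlate", "select", "cnv")

require_fields <- function(config, fields, where = "config") {
  for (f in fields) {
    if (is.null(config[[f]])) {
      abort(sprintf("pipeline config validation failed: missing required field '%s' in %s",
                    f, where))
    }
  }
  invisible(config)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in canonical order (simulate, impute,
#' correlate, select, cnv), writing every artefact under `out_dir` along
#' with a provenance file (the effective configuration) and a manifest
#' listing each output with its MD5 checksum. Identical config and seed
#' reproduce identical checksums.
#'
#' @param config A named list (or path to a YAML file) with at least
#'   `out_dir` and `seed`; optional `stages` (default all) and per-stage
#'   parameter blocks `simulate`, `impute`, `select`, `cnv`.
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  require_fields(config, c("out_dir", "seed"))
  stages <- config$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) {
    abort(sprintf("unknown pipeline stage(s): %s", paste(bad, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(obj, path, na = "", progress = FALSE)
    written <<- c(written, path)
    path
  }

  sim_args <- config$simulate %||% list()
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)

  state <- list()
  for (stage in stages) {
    switch(stage,
      simulate = {
        sim <- simulate_methylomes(cfg)
        counts <- simulate_reads(sim$beta, cfg)
        arr <- simulate_array(sim$beta, cfg)
        state$truth <- sim$truth
        state$beta <- compute_beta(counts, min_depth = 1)
        state$array <- arr
        emit(counts, "counts.tsv")
        emit(arr, "array_betas.tsv")
        emit(sim$truth$groups, "truth_groups.tsv")
      },
      impute = {
        if (is.null(state$beta)) {
          require_fields(config$inputs %||% list(), "beta", "config$inputs")
          state$beta <- read_beta_matrix(config$inputs$beta)
        }
        ia <- config$impute %||% list()
        res <- impute_cohort(state$beta,
                             n_train = ia$n_train %||% lowmeth_defaults()$n_train,
                             min_depth = ia$min_depth %||% lowmeth_defaults()$train_min_depth,
                             seed = config$seed)
        state$beta <- res$beta
        emit(res$report, "imputation_report.tsv")
        write_beta_matrix(res$beta, file.path(out_dir, "imputed_betas.tsv"))
        written <- c(written, file.path(out_dir, "imputed_betas.tsv"))
      },
      correlate = {
        if (is.null(state$array) || is.null(state$beta)) {
          abort("correlate stage needs the simulate stage (or array/beta inputs)")
        }
        probes <- dplyr::distinct(state$array, .data$probe_id, .data$chrom,
                                  .data$pos)
        probes <- probes[order(chrom_order(probes$chrom), probes$pos), ]
        wloci <- arrange_loci(dplyr::distinct(state$beta, .data$chrom, .data$pos))
        pairing <- match_array_loci(wloci, probes)
        cors <- pearson_per_sample(state$beta, state$array, pairing)
        emit(cors, "cross_platform_correlation.tsv")
      },
      select = {
        if (is.null(state$beta)) {
          require_fields(config$inputs %||% list(), "beta", "config$inputs")
          state$beta <- read_beta_matrix(config$inputs$beta)
        }
        sa <- config$select %||% list()
        top <- top_variable(state$beta, k = sa$k %||% lowmeth_defaults()$top_k)
        islands <- if (!is.null(sa$islands)) read_bed(sa$islands) else NULL
        if (!is.null(islands)) {
          ann <- assign_categories(top, islands)
          coll <- collapse_to_regions(ann)
          emit(coll, "variable_cpgs.tsv")
        } else {
          emit(top, "variable_cpgs.tsv")
        }
      },
      cnv = {
        ca <- config$cnv %||% list()
        width <- ca$bin_width %||% lowmeth_defaults()$bin_width
        alpha <- ca$alpha %||% lowmeth_defaults()$cbs_alpha
        segs <- purrr::map_dfr(sample_ids(cfg), function(s) {
          frags <- simulate_fragments(cfg, s)
          track <- count_fragments(frags, make_bins(cfg$chrom_sizes, width)) |>
            filter_bins() |>
            normalize_log2() |>
            drop_outliers()
          track$sample <- s
          segment_cbs(track, alpha) |>
            classify_segments()
        })
        emit(segs, "cnv_segments.tsv")
      })
  }

  prov <- file.path(out_dir, "provenance.yaml")
  yaml::write_yaml(list(config = config, stages = stages), prov)
  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written)))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}
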