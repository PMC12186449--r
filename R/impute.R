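# Per-sample gradient-boosted imputation of missing beta values.
#
# The feature design exploits the strong spatial autocorrelation of CpG
# methylation plus its cross-sample stability: for a target CpG in a target
# sample we use the distance to and beta of the nearest non-missing CpG on
# either side (same chromosome, same sample) and the mean beta of all other
# samples at the same locus.

SENTINEL_DIST <- 1e6

# Internal workspace: wide matrices keyed by sorted loci, plus cross-sample
# running sums so the leave-one-out mean is O(1) per sample.
beta_workspace <- function(beta) {
  check_columns(beta, c("chrom", "pos", "sample", "beta"), "beta table")
  b <- cells_to_matrix(beta, "beta")
  d <- if ("depth" %in% names(beta)) {
    cells_to_matrix(beta, "depth", fill = 0)$values
  } else {
    matrix(Inf, nrow(b$values), ncol(b$values))
  }
  list(
    loci = b$loci,
    chrom_id = as.integer(chrom_order(b$loci$chrom)),
    samples = b$samples,
    beta = b$values,
    depth = d,
    row_sum = rowSums(b$values, na.rm = TRUE),
    row_nobs = rowSums(!is.na(b$values))
  )
}

# Features for one sample at the given locus rows (indices into ws$loci).
features_for <- function(ws, sample, rows) {
  s <- match(sample, ws$samples)
  if (is.na(s)) abort(sprintf("unknown sample: %s", sample))
  bs <- ws$beta[, s]
  obs_s <- !is.na(bs)

  nobs_other <- ws$row_nobs - obs_s
  sum_other <- ws$row_sum - ifelse(obs_s, bs, 0)
  bom <- ifelse(nobs_other > 0, sum_other / nobs_other, NA_real_)
  low_conf <- is.na(bom)

  # fallback: target sample's chromosome-wide mean beta
  if (any(low_conf)) {
    chrom_mean <- tapply(bs, ws$chrom_id, mean, na.rm = TRUE)
    fb <- chrom_mean[as.character(ws$chrom_id)]
    fb[!is.finite(fb)] <- mean(bs, na.rm = TRUE)
    fb[!is.finite(fb)] <- 0.5
    bom[low_conf] <- fb[low_conf]
  }

  pos <- ws$loci$pos
  n <- length(pos)
  dist_up <- rep(SENTINEL_DIST, n)
  beta_up <- rep(NA_real_, n)
  dist_down <- rep(SENTINEL_DIST, n)
  beta_down <- rep(NA_real_, n)

  for (cid in unique(ws$chrom_id)) {
    idx <- which(ws$chrom_id == cid)
    p <- pos[idx]
    obs <- which(obs_s[idx])
    if (length(obs) == 0) next
    po <- p[obs]
    bo <- bs[idx][obs]
    k <- findInterval(p, po)
    self <- k >= 1 & po[pmax(k, 1)] == p
    up <- k - as.integer(self)
    down <- k + 1L
    has_up <- up >= 1
    has_down <- down <= length(po)
    dist_up[idx[has_up]] <- p[has_up] - po[up[has_up]]
    beta_up[idx[has_up]] <- bo[up[has_up]]
    dist_down[idx[has_down]] <- po[down[has_down]] - p[has_down]
    beta_down[idx[has_down]] <- bo[down[has_down]]
  }

  beta_up <- ifelse(is.na(beta_up), bom, beta_up)
  beta_down <- ifelse(is.na(beta_down), bom, beta_down)

  out <- tibble::tibble(
    chrom = ws$loci$chrom, pos = pos,
    dist_up = dist_up, beta_up = beta_up,
    dist_down = dist_down, beta_down = beta_down,
    beta_other_mean = bom, low_confidence = low_conf
  )
  out[rows, , drop = FALSE]
}

#' Imputation features for one sample
#'
#' Computes, for each requested locus, the four-feature design used by the
#' boosted-tree imputer: distance to and beta value of the nearest
#' non-missing CpG upstream and downstream (same chromosome, same sample;
#' the target CpG itself never counts as its own neighbour), and the mean
#' beta of all other samples at the locus. When a neighbour does not exist
#' in a direction the distance is set to the sentinel 1e6 bp and the
#' neighbour beta falls back to the cross-sample mean; when no other sample
#' covers the locus the cross-sample mean falls back to the target sample's
#' chromosome-wide mean and the row is flagged `low_confidence`.
#'
#' @param beta Long beta table (`chrom`, `pos`, `sample`, `beta`, optionally
#'   `depth`).
#' @param sample Target sample id.
#' @param loci Optional tibble (`chrom`, `pos`) restricting the output;
#'   default all loci.
#' @return Tibble with columns `chrom`, `pos`, `dist_up`, `beta_up`,
#'   `dist_down`, `beta_down`, `beta_other_mean`, `low_confidence`.
#' @export
impute_features <- function(beta, sample, loci = NULL) {
  ws <- beta_workspace(beta)
  rows <- if (is.null(loci)) {
    seq_len(nrow(ws$loci))
  } else {
    m <- match(paste(loci$chrom, loci$pos),
               paste(ws$loci$chrom, ws$loci$pos))
    if (anyNA(m)) abort("some requested loci are absent from the beta table")
    m
  }
  features_for(ws, sample, rows)
}

#' Root mean squared error
#'
#' @param pred,truth Numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("pred and truth differ in length")
  if (length(pred) < 1) abort("need at least one value")
  sqrt(mean((pred - truth)^2))
}

feature_cols <- c("dist_up", "beta_up", "dist_down", "beta_down",
                  "beta_other_mean")

default_booster_params <- function() {
  list(max_depth = 6, eta = 0.1, nrounds = 500, early_stopping = 20)
}

#' Train the per-sample beta imputer
#'
#' Fits a gradient-boosted regression-tree model (squared-error objective)
#' predicting a CpG's beta from its neighbour and cross-sample features.
#' Training examples are non-missing CpGs of the target sample with depth at
#' least `min_depth`; up to `n_train` of them are sampled without
#' replacement and partitioned 80/10/10 into train/validation/test. Boosting
#' early-stops on the validation partition and the reported RMSE is computed
#' on the held-out test partition, so it is an out-of-sample error.
#'
#' @param beta Long beta table with `depth` (`chrom`, `pos`, `sample`,
#'   `beta`, `depth`).
#' @param sample Target sample id.
#' @param n_train Maximum training-set size (default 1,000,000); capped at
#'   the number of eligible CpGs with a warning.
#' @param min_depth Minimum depth for a training example (default 10).
#' @param seed Integer seed; the sampling, partitioning and boosting are
#'   fully deterministic given the seed.
#' @param params Booster hyper-parameters (`max_depth`, `eta`, `nrounds`,
#'   `early_stopping`).
#' @return A `methyl_imputer` object with elements `sample`, `booster`,
#'   `rmse` (test-partition RMSE), `config`.
#' @export
train_imputer <- function(beta, sample,
                          n_train = lowmeth_defaults()$n_train,
                          min_depth = lowmeth_defaults()$train_min_depth,
                          seed = 1L,
                          params = default_booster_params()) {
  ws <- beta_workspace(beta)
  train_imputer_ws(ws, sample, n_train, min_depth, seed, params)
}

train_imputer_ws <- function(ws, sample, n_train, min_depth, seed, params) {
  s <- match(sample, ws$samples)
  if (is.na(s)) abort(sprintf("unknown sample: %s", sample))
  eligible <- which(!is.na(ws$beta[, s]) & ws$depth[, s] >= min_depth)
  if (length(eligible) < 1000) {
    abort(sprintf(paste0(
      "sample %s has only %d CpGs that are non-missing at depth >= %d; ",
      "at least 1000 are required to train. Lower min_depth or sequence ",
      "deeper."), sample, length(eligible), min_depth))
  }
  if (n_train > length(eligible)) {
    warn(sprintf("n_train (%d) exceeds the %d eligible CpGs of sample %s; using all",
                 n_train, length(eligible), sample))
  }
  n <- min(n_train, length(eligible))

  fit <- withr::with_seed(seed, {
    picked <- sample(eligible, n)
    n_tr <- floor(0.8 * n)
    n_va <- floor(0.1 * n)
    part <- c(rep("train", n_tr), rep("valid", n_va),
              rep("test", n - n_tr - n_va))
    feats <- features_for(ws, sample, picked)
    x <- as.matrix(feats[, feature_cols])
    y <- ws$beta[picked, s]
    dtr <- xgboost::xgb.DMatrix(x[part == "train", , drop = FALSE],
                                label = y[part == "train"], nthread = 1)
    dva <- xgboost::xgb.DMatrix(x[part == "valid", , drop = FALSE],
                                label = y[part == "valid"], nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1, seed = seed),
      data = dtr, nrounds = params$nrounds,
      evals = list(valid = dva),
      early_stopping_rounds = params$early_stopping, verbose = 0)
    test_x <- x[part == "test", , drop = FALSE]
    pred <- clamp01(predict(booster, xgboost::xgb.DMatrix(test_x, nthread = 1)))
    list(booster = booster, rmse = rmse(pred, y[part == "test"]),
         n_test = sum(part == "test"))
  })

  structure(list(
    sample = sample, booster = fit$booster, rmse = fit$rmse,
    config = list(n_train = n, n_eligible = length(eligible),
                  n_test = fit$n_test, min_depth = min_depth, seed = seed,
                  params = params)
  ), class = "methyl_imputer")
}

#' @method print methyl_imputer
#' @export
print.methyl_imputer <- function(x, ...) {
  cat(sprintf("<methyl_imputer> sample %s: %d training CpGs, holdout RMSE %.4f\n",
              x$sample, x$config$n_train, x$rmse))
  invisible(x)
}

#' @method glance methyl_imputer
#' @export
glance.methyl_imputer <- function(x, ...) {
  tibble::tibble(sample = x$sample, n_train = x$config$n_train,
                 n_eligible = x$config$n_eligible, rmse = x$rmse)
}

#' @method tidy methyl_imputer
#' @export
tidy.methyl_imputer <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(feature = imp$Feature, gain = imp$Gain,
                 cover = imp$Cover, frequency = imp$Frequency)
}

#' Impute missing beta values across a cohort
#'
#' Trains one boosted-tree imputer per sample (see [train_imputer()]) and
#' fills every originally-missing cell that has at least one non-missing
#' CpG on its chromosome in that sample. Predictions are clipped to [0, 1]
#' and flagged `imputed`; observed cells are never modified.
#'
#' @inheritParams train_imputer
#' @param keep_models Keep the fitted boosters in the result (default
#'   `FALSE`; they are large).
#' @return A `methyl_imputation` object: `beta` (the completed long beta
#'   table), `report` (per-sample tibble: `sample`, `n_missing`,
#'   `n_imputed`, `fraction_imputed`, `rmse`), and `models` when requested.
#'   `tidy()` returns the report, `glance()` a one-row cohort summary.
#' @export
impute_cohort <- function(beta,
                          n_train = lowmeth_defaults()$n_train,
                          min_depth = lowmeth_defaults()$train_min_depth,
                          seed = 1L,
                          params = default_booster_params(),
                          keep_models = FALSE) {
  ws <- beta_workspace(beta)
  if (length(ws$samples) < 2) {
    abort(paste("impute_cohort() needs at least 2 samples: the",
                "cross-sample mean feature is undefined for a single-sample cohort"))
  }
  n_loci <- nrow(ws$loci)
  out_beta <- ws$beta
  imputed <- matrix(FALSE, n_loci, length(ws$samples))
  models <- list()
  report <- purrr::map_dfr(seq_along(ws$samples), function(s) {
    sample_id <- ws$samples[s]
    model <- train_imputer_ws(ws, sample_id, n_train, min_depth,
                              seed + s, params)
    missing_rows <- which(is.na(ws$beta[, s]))
    # only chromosomes where the sample has at least one observed CpG
    obs_chroms <- unique(ws$chrom_id[!is.na(ws$beta[, s])])
    fillable <- missing_rows[ws$chrom_id[missing_rows] %in% obs_chroms]
    if (length(fillable) > 0) {
      feats <- features_for(ws, sample_id, fillable)
      x <- as.matrix(feats[, feature_cols])
      pred <- clamp01(predict(model$booster,
                              xgboost::xgb.DMatrix(x, nthread = 1)))
      out_beta[fillable, s] <<- pred
      imputed[fillable, s] <<- TRUE
    }
    if (keep_models) models[[sample_id]] <<- model
    tibble::tibble(sample = sample_id,
                   n_missing = length(missing_rows),
                   n_imputed = length(fillable),
                   fraction_imputed = length(fillable) / n_loci,
                   rmse = model$rmse)
  })

  long <- tibble::tibble(
    chrom = rep(ws$loci$chrom, times = length(ws$samples)),
    pos = rep(ws$loci$pos, times = length(ws$samples)),
    sample = rep(ws$samples, each = n_loci),
    beta = as.vector(out_beta),
    depth = as.integer(as.vector(ws$depth)),
    imputed = as.vector(imputed)
  )
  structure(list(beta = long, report = report,
                 models = if (keep_models) models else NULL),
            class = "methyl_imputation")
}

#' @method print methyl_imputation
#' @export
print.methyl_imputation <- function(x, ...) {
  cat(sprintf("<methyl_imputation> %d samples, mean holdout RMSE %.4f, %d cells imputed\n",
              nrow(x$report), mean(x$report$rmse), sum(x$report$n_imputed)))
  invisible(x)
}

#' @method tidy methyl_imputation
#' @export
tidy.methyl_imputation <- function(x, ...) x$report

#' @method glance methyl_imputation
#' @export
glance.methyl_imputation <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$report),
                 mean_rmse = mean(x$report$rmse),
                 max_rmse = max(x$report$rmse),
                 total_imputed = sum(x$report$n_imputed),
                 mean_fraction_imputed = mean(x$report$fraction_imputed))
}
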