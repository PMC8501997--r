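#' Configuration of a full per-gene run
#'
#' @param upstream_ext,downstream_ext Window extension in bp around the
#'   gene (defaults 25000).
#' @param bin_size Signal bin width in bp.
#' @param encoding A [seg_config()].
#' @param regression A [reg_config()].
#' @param correlation Correlation used at candidate selection
#'   (\code{"spearman"} default).
#' @param p_threshold Candidate-selection significance threshold.
#' @param mode One of \code{"default"}, \code{"nested"},
#'   \code{"downsample"}.
#' @param nested_reps Monte Carlo repetitions of the nested mode.
#' @param downsample_fractions Training fractions for the down-sampling
#'   mode.
#' @param seed Master seed; per-gene seeds are derived from it together
#'   with a hash of the gene identifier, so partial runs reproduce the full
#'   run's per-gene results.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(upstream_ext = 25000, downstream_ext = 25000,
                       bin_size = 1, encoding = seg_config(),
                       regression = reg_config(),
                       correlation = c("spearman", "pearson"),
                       p_threshold = 0.05,
                       mode = c("default", "nested", "downsample"),
                       nested_reps = 10,
                       downsample_fractions = c(0.4, 0.5, 0.6, 0.7, 0.8,
                                                0.9, 1.0),
                       seed = 1L) {
  structure(list(upstream_ext = upstream_ext,
                 downstream_ext = downstream_ext, bin_size = bin_size,
                 encoding = encoding, regression = regression,
                 correlation = match.arg(correlation),
                 p_threshold = p_threshold, mode = match.arg(mode),
                 nested_reps = nested_reps,
                 downsample_fractions = downsample_fractions,
                 seed = as.integer(seed)),
            class = "run_config")
}

gene_seed <- function(master, gene_id) {
  if (is.na(gene_id)) return(as.integer(master))
  h <- sum(utf8ToInt(gene_id) * seq_along(utf8ToInt(gene_id))) %% 100000L
  as.integer((master + h) %% .Machine$integer.max)
}

skip_model <- function(gene_id, mode, reason) {
  structure(list(gene_id = gene_id, mode = mode, records = empty_records(),
                 performance = NULL, model_p = NA_real_, q = NA_real_,
                 n_candidates = 0L, reason = reason),
            class = "rem_model")
}

empty_records <- function() {
  as.data.frame(setNames(
    list(character(0), numeric(0), numeric(0), character(0), numeric(0),
         character(0), character(0), numeric(0), numeric(0), numeric(0),
         numeric(0)), rem_columns))
}

#' @exportS3Method base::print
print.rem_model <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("rem_model %s [%s]: skipped (%s)\n", x$gene_id, x$mode,
                x$reason))
  } else {
    cat(sprintf(
      "rem_model %s [%s]: %d candidate(s), %d REM(s); mean held-out r=%.3f rho=%.3f (p=%.3g)\n",
      x$gene_id, x$mode, x$n_candidates, nrow(x$records),
      x$mean_test_r, x$mean_test_rho, x$model_p))
  }
  invisible(x)
}

records_from_ols <- function(sm, candidates, ols, method) {
  k <- nrow(candidates)
  has_coords <- "genomic_start" %in% names(candidates)
  chrom <- if (!is.null(sm$chrom) && !is.na(sm$chrom)) sm$chrom else "chrU"
  start <- if (has_coords) candidates$genomic_start else candidates$start_col - 1
  end <- if (has_coords) candidates$genomic_end else candidates$end_col
  corr <- if (method == "spearman") candidates$spearman_rho else candidates$pearson_r
  corr_p <- if (method == "spearman") candidates$spearman_p else candidates$pearson_p
  gid <- if (is.na(sm$gene_id)) "gene" else sm$gene_id
  data.frame(
    chrom = chrom, start = start, end = end,
    rem_id = paste0(gid, "_REM", seq_len(k)),
    score = round(pmin(1000, -10 * log10(pmax(ols$pvalues, 1e-100)))),
    strand = ".", gene_id = gid,
    ols_coefficient = unname(ols$coefficients),
    ols_pvalue = unname(ols$pvalues),
    correlation = corr, correlation_pvalue = corr_p,
    stringsAsFactors = FALSE)
}

#' Run the full element-discovery pipeline for one gene
#'
#' Discretises the gene's expression, segments the signal matrix by the MDL
#' criterion, filters segments by correlation with continuous expression,
#' refines the candidates by elastic-net Monte Carlo cross-validation and
#' attaches OLS coefficients and p-values to the retained elements.
#'
#' Modes: \code{"default"} segments and selects on all samples and
#' estimates performance by the outer Monte Carlo splits of the regression.
#' \code{"nested"} repeats the whole feature-generation process inside each
#' Monte Carlo repetition: segmentation, candidate selection and the
#' elastic-net fit all see only the 80% training samples, and performance
#' is measured on the untouched 20%, avoiding the circularity of selecting
#' features on data later used for testing. \code{"downsample"} is the
#' nested mode with the training side thinned to each configured fraction.
#' Nested and down-sampling modes are performance-estimation protocols:
#' they return the per-repetition performance table, while the element
#' catalogue itself is produced by the default mode.
#'
#' The model q-value is NA here: the gate is applied across a cohort (see
#' [run_cohort()]), since the correction depends on the full set of models.
#'
#' @param sm A \code{signal_matrix} for the gene.
#' @param y Continuous expression values aligned with the matrix rows.
#' @param cfg A [run_config()].
#' @param mode Overrides \code{cfg$mode} when given.
#' @return An object of class \code{rem_model}.
#' @export
run_gene <- function(sm, y, cfg = run_config(), mode = NULL) {
  mode <- if (is.null(mode)) cfg$mode else
    match.arg(mode, c("default", "nested", "downsample"))
  values <- if (inherits(sm, "signal_matrix")) sm$values else as.matrix(sm)
  if (!inherits(sm, "signal_matrix")) {
    sm <- structure(list(gene_id = NA_character_, sample_ids = rownames(values),
                         values = values,
                         positions = seq_len(ncol(values)) - 1, bin_size = 1,
                         chrom = NA_character_), class = "signal_matrix")
  }
  if (length(y) != nrow(values)) stop("unpaired samples: length(y) != nrow(signal)")
  gid <- sm$gene_id
  gseed <- gene_seed(cfg$seed, gid)

  if (mode == "default") {
    return(run_gene_default(sm, y, cfg, gseed))
  }
  fractions <- if (mode == "nested") 1 else cfg$downsample_fractions
  run_gene_nested(sm, y, cfg, gseed, fractions, mode)
}

run_gene_default <- function(sm, y, cfg, gseed) {
  gid <- sm$gene_id
  assignment <- discretize_expression(y, seed = gseed, gene_id = gid)
  if (!assignment$informative)
    return(skip_model(gid, "default", "non-informative expression (single class)"))
  seg <- chunked_segmentation(sm$values, assignment, cfg$encoding)
  scored <- score_segments(seg, sm, y, method = cfg$correlation,
                           p_threshold = cfg$p_threshold)
  cand <- select_candidates(scored, sm)
  if (ncol(cand$X) == 0)
    return(skip_model(gid, "default", "no candidate segments passed the correlation filter"))
  rcfg <- cfg$regression
  rcfg$seed <- gseed
  en <- fit_elastic_net_mc_cv(cand$X, y, rcfg)
  nz <- median_nonzero(en)
  out <- list(gene_id = gid, mode = "default", assignment = assignment,
              segmentation = seg, candidates = cand$candidates,
              n_candidates = ncol(cand$X), en = en,
              performance = en$folds,
              mean_test_r = en$mean_test_r, mean_test_rho = en$mean_test_rho,
              mean_test_mse = en$mean_test_mse,
              model_p = en$model_p, q = NA_real_, reason = NULL)
  if (length(nz) == 0) {
    out$records <- empty_records()
    out$reason <- "no feature with non-zero median coefficient"
  } else {
    ols <- fit_ols(cand$X[, nz, drop = FALSE], y, rcfg$pseudo_count)
    out$selected <- nz
    out$ols <- ols
    out$records <- records_from_ols(sm, cand$candidates[nz, , drop = FALSE],
                                    ols, cfg$correlation)
  }
  structure(out, class = "rem_model")
}

run_gene_nested <- function(sm, y, cfg, gseed, fractions, mode) {
  values <- sm$values
  m <- nrow(values)
  n_test <- max(1, round(cfg$regression$test_fraction * m))
  perf <- expand.grid(rep = seq_len(cfg$nested_reps), fraction = fractions)
  perf$n_candidates <- NA_integer_
  perf$alpha <- perf$lambda <- perf$test_r <- perf$test_rho <-
    perf$test_mse <- NA_real_
  pooled <- list(pred = numeric(0), obs = numeric(0))

  for (rep_i in seq_len(cfg$nested_reps)) {
    set.seed(gseed + rep_i)
    test_idx <- sample(m, n_test)
    train_all <- setdiff(seq_len(m), test_idx)
    for (fr in fractions) {
      row <- which(perf$rep == rep_i & perf$fraction == fr)
      train_idx <- if (fr >= 1) train_all else
        sort(sample(train_all, max(cfg$regression$inner_folds + 2,
                                   round(fr * length(train_all)))))
      a_tr <- tryCatch(
        discretize_expression(y[train_idx], seed = gseed + rep_i,
                              gene_id = sm$gene_id),
        error = function(e) NULL)
      if (is.null(a_tr) || !a_tr$informative) next
      seg <- chunked_segmentation(values[train_idx, , drop = FALSE], a_tr,
                                  cfg$encoding)
      scored <- score_segments(seg, values[train_idx, , drop = FALSE],
                               y[train_idx], method = cfg$correlation,
                               p_threshold = cfg$p_threshold)
      cand <- select_candidates(scored, values[train_idx, , drop = FALSE])
      perf$n_candidates[row] <- ncol(cand$X)
      if (ncol(cand$X) == 0) next
      tx <- transform_features(cand$X, cfg$regression$pseudo_count)
      ty <- transform_features(y[train_idx], cfg$regression$pseudo_count)
      if (length(tx$kept) == 0 || stats::sd(as.numeric(ty$X)) == 0) next
      foldid <- sample(rep(seq_len(cfg$regression$inner_folds),
                           length.out = length(train_idx)))
      pick <- cv_pick_alpha(as.matrix(tx$X), as.numeric(ty$X),
                            cfg$regression, foldid)
      # held-out features: same segments, signal summed over test rows
      Xte_raw <- vapply(seq_len(nrow(cand$candidates)), function(i)
        segment_signal(values[test_idx, , drop = FALSE],
                       c(cand$candidates$start_col[i],
                         cand$candidates$end_col[i])),
        numeric(length(test_idx)))
      if (is.null(dim(Xte_raw))) Xte_raw <- matrix(Xte_raw, nrow = length(test_idx))
      Xte <- transform_features(Xte_raw, cfg$regression$pseudo_count,
                                center = tx$center, scale = tx$scale)$X
      yte <- transform_features(y[test_idx], cfg$regression$pseudo_count,
                                center = ty$center, scale = ty$scale)$X
      Xte_fit <- if (pick$pad) cbind(as.matrix(Xte), 0) else as.matrix(Xte)
      pred <- as.numeric(stats::predict(pick$fit, newx = Xte_fit,
                                        s = "lambda.min"))
      perf$alpha[row] <- pick$alpha
      perf$lambda[row] <- pick$fit$lambda.min
      perf$test_r[row] <- if (stats::sd(pred) > 0) stats::cor(pred, yte) else NA
      perf$test_rho[row] <- if (stats::sd(pred) > 0)
        suppressWarnings(stats::cor(pred, yte, method = "spearman")) else NA
      perf$test_mse[row] <- mean((pred - as.numeric(yte))^2)
      if (fr >= 1) {
        pooled$pred <- c(pooled$pred, pred)
        pooled$obs <- c(pooled$obs, as.numeric(yte))
      }
    }
  }
  model_p <- if (length(pooled$pred) > 3 && stats::sd(pooled$pred) > 0)
    stats::cor.test(pooled$pred, pooled$obs)$p.value else NA_real_
  structure(list(
    gene_id = sm$gene_id, mode = mode, performance = perf,
    n_candidates = as.integer(stats::median(perf$n_candidates, na.rm = TRUE)),
    mean_test_r = mean(perf$test_r[perf$fraction == max(fractions)], na.rm = TRUE),
    mean_test_rho = mean(perf$test_rho[perf$fraction == max(fractions)], na.rm = TRUE),
    mean_test_mse = mean(perf$test_mse[perf$fraction == max(fractions)], na.rm = TRUE),
    model_p = model_p, q = NA_real_, records = empty_records(),
    reason = NULL), class = "rem_model")
}
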