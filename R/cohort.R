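#' Run the pipeline over a cohort of genes
#'
#' Executes [run_gene()] independently for every gene (genes share no
#' mutable state, so per-gene execution is safely parallelisable by the
#' caller), then applies the Benjamini-Yekutieli correction across the
#' cohort's model p-values and gates models at
#' \code{cfg$regression$q_threshold}. Per-gene failures are logged and
#' skipped; they never abort the cohort. Because the correction depends on
#' the gene set, q-values must be recomputed whenever the gene set changes;
#' single-gene results from [run_gene()] therefore carry raw p-values only.
#'
#' @param cohort Named list of per-gene inputs, each a list with \code{sm}
#'   (a \code{signal_matrix}) and \code{y} (expression vector), e.g. from
#'   [simulate_cohort()].
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   \code{rems.tsv} (records of gate-passing models, via
#'   [write_rem_records()]), \code{summary.tsv} (one row per gene) and
#'   \code{config.txt} (the configuration, echoed verbatim).
#' @return List with \code{models} (per-gene \code{rem_model}s, q-values
#'   filled in) and \code{summary} (data frame: gene, candidate and element
#'   counts, mean held-out performance, p, q, pass/skip status and reason).
#' @export
run_cohort <- function(cohort, cfg = run_config(), out_dir = NULL) {
  stopifnot(length(cohort) >= 1)
  if (is.null(names(cohort)) || anyNA(names(cohort)))
    stop("cohort must be a named list (gene ids)")
  models <- lapply(names(cohort), function(g) {
    tryCatch(run_gene(cohort[[g]]$sm, cohort[[g]]$y, cfg),
             error = function(e) skip_model(g, cfg$mode,
                                            paste("error:", conditionMessage(e))))
  })
  names(models) <- names(cohort)

  p <- vapply(models, function(mo) mo$model_p, numeric(1))
  fitted <- which(!is.na(p))
  q <- rep(NA_real_, length(models))
  q[fitted] <- by_correction(p[fitted])
  for (i in seq_along(models)) models[[i]]$q <- q[i]

  summary <- data.frame(
    gene_id = names(models),
    n_candidates = vapply(models, function(mo) as.integer(mo$n_candidates), 1L),
    n_rems = vapply(models, function(mo) nrow(mo$records), 1L),
    mean_test_r = vapply(models, function(mo)
      if (is.null(mo$mean_test_r)) NA_real_ else mo$mean_test_r, 1),
    mean_test_rho = vapply(models, function(mo)
      if (is.null(mo$mean_test_rho)) NA_real_ else mo$mean_test_rho, 1),
    mean_test_mse = vapply(models, function(mo)
      if (is.null(mo$mean_test_mse)) NA_real_ else mo$mean_test_mse, 1),
    model_p = p, q = q,
    passed = !is.na(q) & q <= cfg$regression$q_threshold,
    reason = vapply(models, function(mo)
      if (is.null(mo$reason)) "" else mo$reason, ""),
    row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- summary$passed & summary$n_rems > 0
    recs <- do.call(rbind, lapply(models[keep], `[[`, "records"))
    write_rem_records(recs, file.path(out_dir, "rems.tsv"))
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(utils::capture.output(utils::str(cfg)),
               file.path(out_dir, "config.txt"))
  }
  list(models = models, summary = summary)
}
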