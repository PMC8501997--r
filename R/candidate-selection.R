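#' Per-sample aggregate signal of a segment
#'
#' Sum of the signal matrix values over the segment's columns, one value per
#' sample. Sums (rather than means) are used; within one gene all
#' correlations are unaffected by the choice because segment length is fixed
#' across samples.
#'
#' @param values Signal matrix (or \code{signal_matrix}).
#' @param segment \code{c(start_col, end_col)}, 1-based inclusive.
#' @return Numeric vector of length m.
#' @export
segment_signal <- function(values, segment) {
  if (inherits(values, "signal_matrix")) values <- values$values
  stopifnot(segment[1] >= 1, segment[2] <= ncol(values))
  rowSums(values[, segment[1]:segment[2], drop = FALSE])
}

#' Correlate segments with continuous expression
#'
#' For every segment of a segmentation, computes Pearson and Spearman
#' correlation (with two-sided p-values) between the per-sample segment
#' signal and the gene's continuous expression. A segment passes when the
#' p-value of the chosen method is at most \code{p_threshold}. Two-sided
#' tests are used throughout because negatively associated elements
#' (repressors) are explicitly of interest. Segments with constant signal
#' across samples have undefined correlation and never pass; dropping them
#' silently is deliberate, as zero-accessibility segments are common.
#'
#' No multiple-testing correction is applied at this stage; correction
#' happens once, at the model level, across genes.
#'
#' @param segmentation A \code{segmentation} (or a two-column segment
#'   table).
#' @param sm A \code{signal_matrix} (or bare matrix).
#' @param y Continuous expression values aligned with the matrix rows.
#' @param method Correlation used for the pass/fail decision:
#'   \code{"spearman"} (default) or \code{"pearson"}.
#' @param p_threshold Significance threshold (default 0.05).
#' @return Data frame of scored segments: columns \code{start_col},
#'   \code{end_col}, \code{pearson_r}, \code{pearson_p},
#'   \code{spearman_rho}, \code{spearman_p}, \code{passes}, plus genomic
#'   coordinates when \code{sm} is a \code{signal_matrix}.
#' @export
score_segments <- function(segmentation, sm, y,
                           method = c("spearman", "pearson"),
                           p_threshold = 0.05) {
  method <- match.arg(method)
  segs <- if (inherits(segmentation, "segmentation")) segmentation$segments
          else as.data.frame(segmentation)[, 1:2]
  names(segs)[1:2] <- c("start_col", "end_col")
  values <- if (inherits(sm, "signal_matrix")) sm$values else as.matrix(sm)
  if (length(y) != nrow(values))
    stop("expression vector length does not match the number of samples")
  if (length(y) < 4) stop("need at least 4 samples to score segments")

  one <- function(i) {
    v <- segment_signal(values, c(segs$start_col[i], segs$end_col[i]))
    if (stats::sd(v) == 0 || stats::sd(y) == 0) {
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    }
    pe <- stats::cor.test(v, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(v, y, method = "spearman"))
    c(pe$estimate, pe$p.value, sp$estimate, sp$p.value)
  }
  sc <- t(vapply(seq_len(nrow(segs)), one, numeric(4)))
  out <- data.frame(segs,
                    pearson_r = sc[, 1], pearson_p = sc[, 2],
                    spearman_rho = sc[, 3], spearman_p = sc[, 4])
  pcol <- if (method == "spearman") out$spearman_p else out$pearson_p
  out$passes <- !is.na(pcol) & pcol <= p_threshold
  if (inherits(sm, "signal_matrix")) {
    out$chrom <- sm$chrom
    out$genomic_start <- sm$positions[out$start_col]
    out$genomic_end <- sm$positions[out$end_col] + sm$bin_size
  }
  out
}

#' Retain passing segments and build the candidate feature matrix
#'
#' @param scored Output of [score_segments()].
#' @param sm The \code{signal_matrix} (or matrix) the segments refer to.
#' @return List with \code{candidates} (the passing rows of \code{scored},
#'   genomic order preserved) and \code{X}, the m x k matrix whose column j
#'   is the per-sample signal of candidate j. Zero candidates yield a
#'   zero-column \code{X}; such genes are skipped downstream and counted in
#'   the learned-models tally.
#' @export
select_candidates <- function(scored, sm) {
  values <- if (inherits(sm, "signal_matrix")) sm$values else as.matrix(sm)
  keep <- scored[scored$passes, , drop = FALSE]
  keep <- keep[order(keep$start_col), , drop = FALSE]
  X <- if (nrow(keep) == 0) {
    matrix(numeric(0), nrow = nrow(values), ncol = 0)
  } else {
    vapply(seq_len(nrow(keep)),
           function(i) segment_signal(values, c(keep$start_col[i], keep$end_col[i])),
           numeric(nrow(values)))
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = nrow(values))
  colnames(X) <- if (nrow(keep)) paste0("seg_", keep$start_col, "_", keep$end_col)
                 else character(0)
  list(candidates = keep, X = X)
}
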