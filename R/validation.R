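df_to_granges <- function(d) {
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1, end = d$end))
}

#' Matched background element sets
#'
#' For each gene, generates \code{n_sets} random interval sets matching the
#' real elements in count and length, placed around the gene's TSS by an
#' exponential distance model: each background interval sits at distance
#' \eqn{d \cdot W} from the TSS, \eqn{d \sim Exp(rate)}, where \eqn{W} is
#' the gene's search-window span. This concentrates background elements
#' near the TSS, reflecting the established expectation that regulatory
#' elements cluster there. Each interval keeps the side (upstream or
#' downstream of the TSS) of the real element it matches, so per-side
#' counts are preserved. Intervals are shifted (not truncated) at the
#' chromosome start so the length multiset is preserved exactly. No
#' exclusion of the real elements is applied.
#'
#' The rate is a dimensionless decay on the window-span scale (mean
#' placement around \eqn{W / rate}); it is exposed as a knob.
#'
#' @param rems Data frame of elements: \code{chrom}, \code{start},
#'   \code{end}, \code{gene_id} (0-based half-open).
#' @param genes Gene annotation (as from [read_gene_annotation()]) covering
#'   every \code{gene_id} in \code{rems}.
#' @param rate Exponential rate parameter (default 7).
#' @param n_sets Number of background sets (default 10).
#' @param seed Master seed; set \code{i} uses \code{seed + i}, so all sets
#'   differ yet the whole collection is reproducible.
#' @param upstream_ext,downstream_ext Window extensions used for the span
#'   \eqn{W}.
#' @return List of \code{n_sets} data frames, each with the schema of
#'   \code{rems} plus \code{set_index}.
#' @export
generate_background <- function(rems, genes, rate = 7, n_sets = 10,
                                seed = 1L, upstream_ext = 25000,
                                downstream_ext = 25000) {
  stopifnot(rate > 0, n_sets >= 1)
  gidx <- match(rems$gene_id, genes$gene_id)
  if (anyNA(gidx)) stop("element gene_id absent from annotation: ",
                        rems$gene_id[which(is.na(gidx))[1]])
  span <- (genes$end - genes$start + upstream_ext + downstream_ext)[gidx]
  tss <- genes$tss[gidx]
  len <- rems$end - rems$start
  mid <- (rems$start + rems$end) / 2
  upstream <- ifelse(genes$strand[gidx] == "+", mid < tss, mid > tss)
  dir_sign <- ifelse(xor(upstream, genes$strand[gidx] == "-"), -1, 1)

  lapply(seq_len(n_sets), function(i) {
    set.seed(seed + i)
    d <- stats::rexp(nrow(rems), rate = rate)
    offset <- dir_sign * d * span
    start_bg <- round(tss + offset - ifelse(dir_sign < 0, len, 0))
    start_bg <- pmax(0, start_bg)
    data.frame(chrom = rems$chrom, start = start_bg, end = start_bg + len,
               gene_id = rems$gene_id, set_index = i,
               stringsAsFactors = FALSE)
  })
}

#' Count elements supported by same-gene annotations
#'
#' Number of unique elements overlapping (>= 1 bp, half-open arithmetic) at
#' least one annotation interval assigned to the same gene. An element
#' overlapping several same-gene annotations counts once.
#'
#' @param rems Elements with \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}.
#' @param annotations Intervals with the same schema (e.g. eQTLs with their
#'   gene assignment).
#' @return Integer count O.
#' @export
count_gene_matched_overlaps <- function(rems, annotations) {
  if (nrow(rems) == 0 || nrow(annotations) == 0) return(0L)
  hits <- GenomicRanges::findOverlaps(df_to_granges(rems),
                                      df_to_granges(annotations))
  same <- rems$gene_id[S4Vectors::queryHits(hits)] ==
    annotations$gene_id[S4Vectors::subjectHits(hits)]
  length(unique(S4Vectors::queryHits(hits)[same]))
}

#' Count elements supported by chromatin interactions
#'
#' An element-gene link is supported by a paired-anchor interaction when
#' one anchor overlaps the element and the other anchor overlaps the linked
#' gene's body (in either orientation). The whole gene body stands in for
#' the gene side, covering alternative transcription start sites and
#' intragenic regulatory contacts. Unique elements are counted, so
#' duplicated interaction records do not inflate the result.
#'
#' @param rems Elements with \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}.
#' @param interactions Data frame with anchors \code{chrom1},
#'   \code{start1}, \code{end1}, \code{chrom2}, \code{start2}, \code{end2}
#'   (BEDPE-like, 0-based half-open).
#' @param gene_bodies Gene annotation with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @return Integer count O.
#' @export
count_interaction_support <- function(rems, interactions, gene_bodies) {
  if (nrow(rems) == 0 || nrow(interactions) == 0) return(0L)
  gidx <- match(rems$gene_id, gene_bodies$gene_id)
  if (anyNA(gidx)) stop("element gene_id absent from gene bodies")
  gr_rem <- df_to_granges(rems)
  gr_gene <- df_to_granges(data.frame(chrom = gene_bodies$chrom[gidx],
                                      start = gene_bodies$start[gidx],
                                      end = gene_bodies$end[gidx]))
  a1 <- df_to_granges(data.frame(chrom = interactions$chrom1,
                                 start = interactions$start1,
                                 end = interactions$end1))
  a2 <- df_to_granges(data.frame(chrom = interactions$chrom2,
                                 start = interactions$start2,
                                 end = interactions$end2))
  pair_hits <- function(q, s) {
    h <- GenomicRanges::findOverlaps(q, s)
    paste(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
  }
  rem_a1 <- pair_hits(gr_rem, a1); gene_a2 <- pair_hits(gr_gene, a2)
  rem_a2 <- pair_hits(gr_rem, a2); gene_a1 <- pair_hits(gr_gene, a1)
  supported <- union(intersect(rem_a1, gene_a2), intersect(rem_a2, gene_a1))
  length(unique(as.integer(sub(" .*", "", supported))))
}

#' Observed/expected enrichment ratio
#'
#' Observed count of correctly supported elements divided by the arithmetic
#' mean of the background counts.
#'
#' @param observed Observed count O.
#' @param background_counts Vector of counts, one per background set.
#' @return The OE ratio, or \code{NA} (with a warning) when the expected
#'   mean is zero.
#' @export
oe_ratio <- function(observed, background_counts) {
  e <- mean(background_counts)
  if (e <= 0) {
    warning("mean background count is zero: OE ratio not computable")
    return(NA_real_)
  }
  observed / e
}

#' Activity-weighted element ranking for experiment design
#'
#' Multiplies each element's OLS regression coefficient by its signal
#' abundance (sum over the element's interval) in a condition-specific
#' track, ranking elements jointly by predicted relevance and activity in
#' the cell type of interest. Doubling the track doubles every score, so
#' the ranking is invariant to track scale.
#'
#' @param rems Element records with \code{start}, \code{end},
#'   \code{ols_coefficient} (e.g. from [run_gene()] or
#'   [read_rem_records()]).
#' @param track Signal track data frame (\code{position}, \code{value}) or
#'   path.
#' @return \code{rems} with added \code{abundance} and \code{score}
#'   columns, sorted by decreasing \code{|score|}.
#' @export
rem_activity_score <- function(rems, track) {
  if (is.character(track)) track <- read_signal_track(track)
  ab <- vapply(seq_len(nrow(rems)), function(i) {
    sel <- track$position >= rems$start[i] & track$position < rems$end[i]
    sum(track$value[sel])
  }, numeric(1))
  rems$abundance <- ab
  rems$score <- rems$ols_coefficient * ab
  rems[order(abs(rems$score), decreasing = TRUE), , drop = FALSE]
}
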