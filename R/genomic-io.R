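#' Read gene-level annotation from a GTF file
#'
#' Imports gene features and converts the 1-based closed GTF coordinates to
#' the package's 0-based half-open convention. The transcription start site
#' (TSS) is the 5' end of the gene (the interval start on \code{+}, the
#' interval end on \code{-}) and the transcription termination site (TTS)
#' the 3' end. Multiple transcripts are not resolved: the method operates on
#' gene-level outermost coordinates.
#'
#' @param path Path to a GTF file containing \code{gene} features with a
#'   \code{gene_id} attribute and defined strand.
#' @return A data frame with one row per gene: \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{tss}, \code{tts}.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr))) gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop("no gene features found in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("gene feature without gene_id attribute in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("missing strand for gene ", gr$gene_id[which(strand == "*")[1]])
  ann <- data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) stop("duplicate gene_id in annotation: ", dup[1])
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann$tts <- ifelse(ann$strand == "+", ann$end, ann$start)
  ann
}

#' Extended search window around a gene
#'
#' The gene body extended by \code{upstream_ext} bp 5' of the TSS and
#' \code{downstream_ext} bp 3' of the TTS (strand-aware), clipped at zero
#' and, when known, at the chromosome length. With the 25-kb defaults this
#' is the genomic search space in which regulatory elements are sought.
#'
#' @param gene One-row gene annotation (as from [read_gene_annotation()]).
#' @param upstream_ext,downstream_ext Extensions in bp (default 25000 each).
#' @param chrom_length Optional chromosome length for right clipping.
#' @return List with \code{chrom}, \code{window_start}, \code{window_end}
#'   (0-based half-open).
#' @export
gene_window <- function(gene, upstream_ext = 25000, downstream_ext = 25000,
                        chrom_length = NA) {
  stopifnot(upstream_ext >= 0, downstream_ext >= 0)
  if (gene$strand == "+") {
    ws <- gene$start - upstream_ext
    we <- gene$end + downstream_ext
  } else {
    ws <- gene$start - downstream_ext
    we <- gene$end + upstream_ext
  }
  ws <- max(0, ws)
  if (!is.na(chrom_length)) we <- min(we, chrom_length)
  list(chrom = gene$chrom, window_start = ws, window_end = we,
       upstream_ext = upstream_ext, downstream_ext = downstream_ext)
}

#' Read a per-sample signal track
#'
#' Accepts either the plain-text two-column dialect
#' \code{position<TAB>value} (0-based positions; positions absent from the
#' file carry signal 0) or, when the file extension is \code{.bw}/
#' \code{.bigwig} and \pkg{rtracklayer} is available, a bigWig track.
#'
#' @param path Track file.
#' @return Data frame with columns \code{position} (0-based) and
#'   \code{value}.
#' @export
read_signal_track <- function(path) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read bigWig tracks")
    gr <- rtracklayer::import(path, format = "BigWig")
    pos <- unlist(lapply(seq_along(gr), function(i) {
      seq(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)
    }))
    val <- rep(gr$score, GenomicRanges::width(gr))
    return(data.frame(position = pos, value = val))
  }
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("position", "value"))
  d
}

#' Build a per-gene signal matrix over a window
#'
#' Assembles the m-samples-by-n-positions matrix of epigenetic signal the
#' segmentation operates on. Column \eqn{j} holds, for each sample, the sum
#' of per-base signal falling in bin \eqn{j}; positions without coverage
#' contribute 0 (accessibility tracks are sparse by nature). With the
#' default \code{bin_size = 1} the matrix is the raw per-base signal.
#'
#' @param tracks Named list (one element per sample) of track data frames
#'   (as from [read_signal_track()]) or file paths.
#' @param window A [gene_window()].
#' @param bin_size Bin width in bp (default 1).
#' @param samples Optional character vector of required sample names; an
#'   absent sample is an error naming it.
#' @param gene_id Optional gene identifier carried on the result.
#' @return An object of class \code{signal_matrix}: list with \code{values}
#'   (m x n), \code{sample_ids}, \code{positions} (genomic start of each
#'   bin), \code{bin_size}, \code{chrom}, \code{gene_id}.
#' @export
build_signal_matrix <- function(tracks, window, bin_size = 1,
                                samples = NULL, gene_id = NA_character_) {
  stopifnot(bin_size >= 1)
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(tracks))
    if (length(missing))
      stop("sample missing from signal tracks: ", missing[1])
    tracks <- tracks[samples]
  }
  ws <- window$window_start; we <- window$window_end
  wlen <- we - ws
  n <- ceiling(wlen / bin_size)
  vals <- t(vapply(tracks, function(tr) {
    if (is.character(tr)) tr <- read_signal_track(tr)
    sel <- tr$position >= ws & tr$position < we
    out <- numeric(n)
    if (any(sel)) {
      bin <- (tr$position[sel] - ws) %/% bin_size + 1
      agg <- tapply(tr$value[sel], bin, sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }, numeric(n)))
  if (n == 1) vals <- matrix(vals, ncol = 1)
  structure(list(gene_id = gene_id, sample_ids = names(tracks),
                 values = vals, positions = ws + (seq_len(n) - 1) * bin_size,
                 bin_size = bin_size, chrom = window$chrom),
            class = "signal_matrix")
}

#' @exportS3Method base::print
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d samples x %d bins (bin %d bp) %s:%d-%d gene %s\n",
              nrow(x$values), ncol(x$values), as.integer(x$bin_size),
              x$chrom, min(x$positions),
              max(x$positions) + x$bin_size, x$gene_id))
  invisible(x)
}

rem_columns <- c("chrom", "start", "end", "rem_id", "score", "strand",
                 "gene_id", "ols_coefficient", "ols_pvalue",
                 "correlation", "correlation_pvalue")

#' Write REM records to a BED6+ TSV
#'
#' One row per regulatory element with its target gene, OLS coefficient and
#' p-value, and the correlation used at candidate selection. Rows are
#' ordered deterministically by (chrom, start, gene_id). Overlapping REMs
#' linked to different genes are all emitted: no merging is performed, since
#' one element may regulate several genes.
#'
#' @param rems Data frame of REM records (see \code{rem_columns} in the
#'   package source for the schema).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_rem_records <- function(rems, path) {
  if (is.null(rems) || nrow(rems) == 0) {
    rems <- as.data.frame(setNames(rep(list(logical(0)), length(rem_columns)),
                                   rem_columns))
  } else {
    missing <- setdiff(rem_columns, names(rems))
    if (length(missing)) stop("REM record missing column: ", missing[1])
    rems <- rems[order(rems$chrom, rems$start, rems$gene_id), rem_columns]
  }
  utils::write.table(rems, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read REM records written by [write_rem_records()]
#' @param path Input path.
#' @return Data frame of REM records.
#' @export
read_rem_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", strand = "character",
                                   rem_id = "character",
                                   gene_id = "character"))
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated, first column \code{gene_id}, remaining columns samples
#' (TPM-like continuous values).
#'
#' @param path Input path.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a signal track in the plain TSV dialect
#' @param track Data frame with \code{position}, \code{value}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_signal_track <- function(track, path) {
  utils::write.table(track[, c("position", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
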