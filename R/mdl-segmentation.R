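#' Encoding configuration for MDL segmentation
#'
#' Bundles the parameters of the two-part minimum description length score
#' used to segment a per-gene signal matrix.
#'
#' @param tau Data resolution \eqn{\tau \le 1}: the precision (in signal
#'   units) at which continuous values are encoded. Both the model and the
#'   data code lengths depend on it. Default 1, appropriate for count-like
#'   signal.
#' @param beta Minimum segment length in columns. Default 10.
#' @param chunk_size Number of columns processed per independent chunk of the
#'   dynamic program; segments never span chunk boundaries. Default 5000.
#' @param variance_floor Lower bound on the maximum-likelihood variance used
#'   in the Gaussian code length, preventing infinite code lengths for
#'   constant blocks. Default \code{tau^2 / 12}, the quantisation-noise
#'   variance at resolution \code{tau}.
#' @param range_floor Lower bound on the signal range \eqn{|max - min|} used
#'   in the parameter-cost term, so its logarithm is non-negative. Default
#'   \code{tau}.
#' @return An object of class \code{seg_config}.
#' @export
seg_config <- function(tau = 1, beta = 10, chunk_size = 5000,
                       variance_floor = tau^2 / 12, range_floor = tau) {
  stopifnot(tau > 0, tau <= 1, beta >= 1, chunk_size >= beta,
            variance_floor > 0, range_floor > 0)
  structure(list(tau = tau, beta = as.integer(beta),
                 chunk_size = as.integer(chunk_size),
                 variance_floor = variance_floor, range_floor = range_floor),
            class = "seg_config")
}

#' Rissanen universal code length for positive integers
#'
#' Code length in bits of the universal prior for integers:
#' \eqn{\log_2 c_0 + \log_2 k + \log_2\log_2 k + \dots} keeping only the
#' positive iterated-logarithm terms, with \eqn{c_0 = 2.865064}.
#'
#' @param k Vector of positive integers.
#' @return Code lengths in bits.
#' @export
universal_integer_code <- function(k) {
  if (any(k < 1)) stop("universal integer code is defined for k >= 1")
  vapply(as.numeric(k), function(x) {
    bits <- log2(2.865064)
    t <- log2(x)
    while (isTRUE(t > 0)) {
      bits <- bits + t
      t <- log2(t)
    }
    bits
  }, numeric(1))
}

#' Model cost of a segmentation
#'
#' Code length in bits of the segmentation itself: the number of segments
#' under the universal integer prior, one mean per segment and class encoded
#' to resolution \code{tau} within the observed data range, and the choice of
#' segment boundaries among the \eqn{n - 1} possible positions (binomial
#' coefficient, evaluated in log space).
#'
#' @param n_segments Number of segments \eqn{|S|}.
#' @param n Number of columns of the signal matrix.
#' @param n_classes Number of expression classes \eqn{|C|}.
#' @param data_max,data_min Extremes of the whole signal matrix.
#' @param cfg A [seg_config()].
#' @return Model cost in bits.
#' @export
model_cost <- function(n_segments, n, n_classes, data_max, data_min,
                       cfg = seg_config()) {
  stopifnot(n_segments >= 1, n_segments <= n, n_classes >= 1)
  rng <- abs(data_max - data_min)
  if (rng < cfg$range_floor) rng <- cfg$range_floor
  universal_integer_code(n_segments) +
    n_segments * n_classes * log2(rng / cfg$tau) +
    lchoose(n - 1, n_segments - 1) / log(2)
}

#' Gaussian code length of one segment for one expression class
#'
#' Encodes the values of the block (segment columns, rows of one class)
#' assuming a Gaussian with the block's maximum-likelihood mean and variance,
#' to resolution \code{tau}:
#' \eqn{\frac{|s||C_k|}{2}(1/\ln 2 + \log_2 2\pi\hat\sigma^2) +
#' |s||C_k|\log_2\tau}. The variance is floored at
#' \code{cfg$variance_floor}.
#'
#' @param values Signal matrix (samples in rows).
#' @param segment Integer vector \code{c(start_col, end_col)} (1-based,
#'   inclusive).
#' @param rows Row indices belonging to the class.
#' @param cfg A [seg_config()].
#' @return Code length in bits.
#' @export
segment_class_cost <- function(values, segment, rows, cfg = seg_config()) {
  stopifnot(length(rows) >= 1)
  v <- as.numeric(values[rows, segment[1]:segment[2], drop = FALSE])
  cnt <- length(v)
  s1 <- sum(v)
  s2 <- sum(v * v)
  mu <- s1 / cnt
  sig2 <- s2 / cnt - mu * mu
  if (!(sig2 > cfg$variance_floor)) sig2 <- cfg$variance_floor
  (cnt / 2) * (1 / log(2) + log2(2 * pi * sig2)) + cnt * log2(cfg$tau)
}

# Per-segment data cost: class costs weighted by 1/|C_k|, accumulated in
# class order. Shared by data_cost() and (with identical operation order)
# the C++ dynamic program.
segment_data_cost <- function(values, segment, partition, cfg) {
  acc <- 0
  for (k in seq_along(partition)) {
    rows <- partition[[k]]
    acc <- acc + segment_class_cost(values, segment, rows, cfg) / length(rows)
  }
  acc
}

#' Data cost of a segmentation
#'
#' Sum over segments and classes of the class-conditional Gaussian code
#' length, each class weighted by \eqn{1/|C_k|}.
#'
#' @param values Signal matrix.
#' @param segments Two-column matrix or data frame of segment start/end
#'   columns (1-based, inclusive), in genomic order, covering \code{1..n}.
#' @param assignment A [class_assignment()] (or anything accepted by
#'   [class_partition()]).
#' @param cfg A [seg_config()].
#' @return Data cost in bits.
#' @export
data_cost <- function(values, segments, assignment, cfg = seg_config()) {
  segments <- as.matrix(segments)[, 1:2, drop = FALSE]
  partition <- class_partition(assignment)
  if (any(vapply(partition, length, 1L) == 0))
    stop("empty expression class: data cost undefined (1/|C_k| weight)")
  acc <- 0
  for (i in seq_len(nrow(segments))) {
    acc <- acc + segment_data_cost(values, segments[i, ], partition, cfg)
  }
  acc
}

new_segmentation <- function(segments, model_bits, data_bits, total_bits, n) {
  structure(list(segments = segments, model_cost_bits = model_bits,
                 data_cost_bits = data_bits, total_bits = total_bits, n = n),
            class = "segmentation")
}

#' @exportS3Method base::print
print.segmentation <- function(x, ...) {
  cat(sprintf("MDL segmentation: %d segments over %d columns (%.2f bits: %.2f model + %.2f data)\n",
              nrow(x$segments), x$n, x$total_bits, x$model_cost_bits,
              x$data_cost_bits))
  invisible(x)
}

#' Optimal MDL segmentation by dynamic programming
#'
#' Finds, among all segmentations of the \code{n} columns into contiguous
#' segments of length at least \code{beta}, the one minimising model cost
#' plus data cost. The dynamic program builds the best data cost for exactly
#' \eqn{i} segments ending at each column from the \eqn{i - 1} layer, then
#' adds the segment-count-dependent model cost and picks the best count.
#' Ties are broken toward fewer segments, then toward the earlier last
#' boundary, so results are deterministic.
#'
#' @param values Signal matrix (or a \code{signal_matrix}; its \code{values}
#'   are used).
#' @param assignment A [class_assignment()] giving one expression class per
#'   row.
#' @param cfg A [seg_config()].
#' @return A \code{segmentation}: the segment table (columns
#'   \code{start_col}, \code{end_col}) plus model, data and total code
#'   lengths in bits.
#' @export
optimal_segmentation <- function(values, assignment, cfg = seg_config()) {
  if (inherits(values, "signal_matrix")) values <- values$values
  values <- as.matrix(values)
  n <- ncol(values)
  partition <- class_partition(assignment)
  if (any(vapply(partition, length, 1L) == 0))
    stop("empty expression class")
  if (nrow(values) != sum(lengths(partition)))
    stop("assignment does not match the number of rows")

  dmax <- max(values); dmin <- min(values)
  if (n < cfg$beta) {
    warning(sprintf("n = %d < beta = %d: returning a single segment", n, cfg$beta))
    seg <- data.frame(start_col = 1L, end_col = n)
    db <- data_cost(values, cbind(1L, n), assignment, cfg)
    mb <- model_cost(1L, n, length(partition), dmax, dmin, cfg)
    return(new_segmentation(seg, mb, db, db + mb, n))
  }

  kmax <- n %/% cfg$beta
  mcost <- vapply(seq_len(kmax), model_cost, numeric(1), n = n,
                  n_classes = length(partition), data_max = dmax,
                  data_min = dmin, cfg = cfg)
  res <- cpp_mdl_dp(values, partition, cfg$beta, cfg$tau,
                    cfg$variance_floor, mcost)
  starts <- res$starts
  ends <- c(starts[-1] - 1L, n)
  seg <- data.frame(start_col = as.integer(starts), end_col = as.integer(ends))
  new_segmentation(seg, mcost[res$n_segments], res$data_bits,
                   res$total_bits, n)
}

#' Chunked MDL segmentation
#'
#' Splits the columns into \eqn{l = \lceil n / \mathrm{chunk\_size} \rceil}
#' consecutive chunks, segments each independently with
#' [optimal_segmentation()] (chunks share no mutable state, so they are
#' safely parallelisable), and concatenates the results in genomic order.
#' Segments never span chunk boundaries; a terminal remainder chunk shorter
#' than \code{beta} becomes a single short segment.
#'
#' @inheritParams optimal_segmentation
#' @return A \code{segmentation} covering all columns; its cost fields are
#'   the sums over chunks.
#' @export
chunked_segmentation <- function(values, assignment, cfg = seg_config()) {
  if (inherits(values, "signal_matrix")) values <- values$values
  values <- as.matrix(values)
  n <- ncol(values)
  l <- ceiling(n / cfg$chunk_size)
  if (l <= 1) return(optimal_segmentation(values, assignment, cfg))
  bounds <- c(seq(1L, n, by = cfg$chunk_size), n + 1L)
  segs <- vector("list", l)
  mb <- db <- 0
  for (i in seq_len(l)) {
    lo <- bounds[i]; hi <- bounds[i + 1] - 1L
    sub <- suppressWarnings(
      optimal_segmentation(values[, lo:hi, drop = FALSE], assignment, cfg))
    s <- sub$segments
    s$start_col <- s$start_col + lo - 1L
    s$end_col <- s$end_col + lo - 1L
    segs[[i]] <- s
    mb <- mb + sub$model_cost_bits
    db <- db + sub$data_cost_bits
  }
  new_segmentation(do.call(rbind, segs), mb, db, mb + db, n)
}
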