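#' Specification of a synthetic locus
#'
#' Describes an m-samples-by-n-positions signal matrix with class-dependent
#' Gaussian blocks: outside the true segments every entry is background
#' noise around \code{baseline}; inside true segment \eqn{j}, rows of class
#' \eqn{k} are drawn around that segment's class-\eqn{k} mean. This is
#' exactly the block structure the class-conditional Gaussian code length
#' assumes, so implanted boundaries are the ground truth a segmentation
#' should recover.
#'
#' @param m Number of samples.
#' @param n Number of positions.
#' @param class_fractions Per-class sample fractions (sum to 1).
#' @param true_segments Data frame with \code{start_col}, \code{end_col}
#'   (1-based, inclusive, non-overlapping).
#' @param class_means Matrix (classes x segments) of within-segment means.
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline Background mean.
#' @param seed Seed; generation is a pure function of spec + seed.
#' @return An object of class \code{locus_spec}.
#' @export
locus_spec <- function(m, n, class_fractions = c(0.5, 0.5),
                       true_segments = data.frame(start_col = integer(0),
                                                  end_col = integer(0)),
                       class_means = NULL, noise_sd = 0.5, baseline = 0,
                       seed = 1L) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8, m >= 2, n >= 1)
  if (nrow(true_segments) > 0) {
    o <- order(true_segments$start_col)
    true_segments <- true_segments[o, , drop = FALSE]
    if (any(true_segments$start_col[-1] <= true_segments$end_col[-nrow(true_segments)]))
      stop("true segments overlap")
    if (max(true_segments$end_col) > n || min(true_segments$start_col) < 1)
      stop("true segments outside 1..n")
    if (is.null(class_means) ||
        ncol(class_means) != nrow(true_segments) ||
        nrow(class_means) != length(class_fractions))
      stop("class_means must be a classes x segments matrix")
  }
  structure(list(m = m, n = n, class_fractions = class_fractions,
                 true_segments = true_segments, class_means = class_means,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "locus_spec")
}

#' Simulate a locus with implanted class-dependent segments
#'
#' @param spec A [locus_spec()].
#' @return List with \code{sm} (a \code{signal_matrix}), \code{assignment}
#'   (the generating [class_assignment()]) and \code{truth} (the implanted
#'   segment table). Values are clipped at zero to honour signal
#'   non-negativity; the clipping bias is checked empirically in the test
#'   suite.
#' @export
simulate_locus <- function(spec) {
  set.seed(spec$seed)
  counts <- diff(round(cumsum(c(0, spec$class_fractions)) * spec$m))
  labels <- rep(seq_along(counts) - 1L, counts)
  mu <- matrix(spec$baseline, spec$m, spec$n)
  if (nrow(spec$true_segments) > 0) {
    for (j in seq_len(nrow(spec$true_segments))) {
      cols <- spec$true_segments$start_col[j]:spec$true_segments$end_col[j]
      for (k in seq_along(counts)) {
        mu[labels == k - 1L, cols] <- spec$class_means[k, j]
      }
    }
  }
  vals <- matrix(stats::rnorm(spec$m * spec$n, mean = mu, sd = spec$noise_sd),
                 spec$m, spec$n)
  vals[vals < 0] <- 0
  sm <- structure(list(gene_id = "synthetic_locus",
                       sample_ids = paste0("s", seq_len(spec$m)),
                       values = vals, positions = seq_len(spec$n) - 1,
                       bin_size = 1, chrom = "chrS"),
                  class = "signal_matrix")
  list(sm = sm, assignment = class_assignment(labels, "synthetic_locus"),
       truth = spec$true_segments)
}

#' Specification of a synthetic regulatory gene
#'
#' Emulates the generative assumption of the regression refinement: a gene
#' whose (log-scale) expression is a linear combination of the signal in a
#' handful of true regulatory segments, plus noise, surrounded by decoy
#' segments whose activity is only weakly correlated with expression.
#'
#' Layout: \code{n_true + n_decoys} non-overlapping segments of
#' \code{seg_len} columns, separated by \code{gap} background columns, in
#' seeded random order. True segment \eqn{j} carries a per-sample activity
#' \eqn{a_{sj} \sim N(act\_mean, act\_sd^2)}; expression derives from
#' \eqn{\eta = \sum_j b_j S_j + \varepsilon}, where \eqn{S_j} is the
#' realised (noisy, clipped) segment signal and \eqn{\varepsilon} is scaled
#' to the requested signal-to-noise ratio. Negative \eqn{b_j} model
#' repressors. Decoy activities follow a single shared "accessibility
#' program" latent \eqn{u} whose correlation with the noiseless predictor
#' is \code{confounder_cor}; each decoy loads on \eqn{u} with weight
#' \code{decoy_cor}. At the default \code{confounder_cor = 0} the decoys
#' form structure-rich noise: they segment like real elements and share a
#' sample-level accessibility program, yet are independent of expression,
#' so only a chance fraction passes the candidate filter. Raising
#' \code{confounder_cor} creates confounded decoys that correlate with
#' expression marginally but carry no information conditional on the true
#' segments.
#' Expression is emitted on the raw
#' scale as \eqn{\exp(\cdot) - 1} of an affine map of \eqn{\eta} (log-scale
#' mean 3, sd 1, floored at 0), so the pipeline's log(x+1) transform
#' recovers the linear structure.
#'
#' @param m Samples (default 60).
#' @param b True-segment coefficients, signed (default
#'   \code{c(1, 0.8, 0.6, -0.8, -1)}: three activators, two repressors).
#' @param n_decoys Number of decoy segments (default 20: together with the
#'   background gaps the segmentation then scores on the order of fifty
#'   candidate segments per locus).
#' @param decoy_cor Loading of each decoy's activity on the shared
#'   confounder latent (default 0.5).
#' @param confounder_cor Correlation of the shared confounder with the
#'   noiseless expression predictor (default 0).
#' @param seg_len Segment length in columns (default 20; both segments
#'   and gaps must exceed the minimum segment size of the segmentation for
#'   boundaries to be recoverable).
#' @param gap Background columns between segments (default 15).
#' @param act_mean,act_sd Activity distribution of segments (defaults 10 and
#'   2: active elements stand roughly an order of magnitude above background,
#'   as accessibility peaks do).
#' @param noise_sd Positionwise signal noise (default 1).
#' @param baseline Background signal mean (default 0.5).
#' @param snr Ratio of predictor SD to expression-noise SD (default 3).
#' @param seed Seed.
#' @return An object of class \code{cohort_gene_spec}.
#' @export
cohort_gene_spec <- function(m = 60, b = c(1, 0.8, 0.6, -0.8, -1),
                             n_decoys = 20, decoy_cor = 0.5,
                             confounder_cor = 0, seg_len = 20,
                             gap = 15, act_mean = 10, act_sd = 2,
                             noise_sd = 1, baseline = 0.5, snr = 3,
                             seed = 1L) {
  stopifnot(length(b) >= 1, any(b != 0), m >= 8)
  structure(list(m = m, b = b, n_decoys = n_decoys, decoy_cor = decoy_cor,
                 confounder_cor = confounder_cor,
                 seg_len = seg_len, gap = gap, act_mean = act_mean,
                 act_sd = act_sd, noise_sd = noise_sd, baseline = baseline,
                 snr = snr, seed = as.integer(seed)),
            class = "cohort_gene_spec")
}

#' Simulate one regulatory gene (signal matrix + expression + truth)
#'
#' @param spec A [cohort_gene_spec()].
#' @param gene_id Identifier for the simulated gene.
#' @param null_gene If \code{TRUE}, expression is generated independently
#'   of the signal (all \code{b} effectively zero): a negative-control
#'   gene.
#' @return List with \code{sm}, \code{y} (raw-scale expression) and
#'   \code{truth} (data frame of true segments with their coefficients).
#' @export
simulate_regulatory_gene <- function(spec = cohort_gene_spec(),
                                     gene_id = "geneS",
                                     null_gene = FALSE) {
  set.seed(spec$seed)
  J <- length(spec$b)
  n_seg <- J + spec$n_decoys
  starts <- cumsum(c(spec$gap + 1,
                     rep(spec$seg_len + spec$gap, n_seg - 1)))
  n <- starts[n_seg] + spec$seg_len - 1 + spec$gap
  which_true <- sort(sample(n_seg, J))

  m <- spec$m
  vals <- matrix(pmax(0, stats::rnorm(m * n, spec$baseline, spec$noise_sd)),
                 m, n)
  true_cols <- lapply(seq_len(J), function(j) {
    s <- starts[which_true[j]]
    s:(s + spec$seg_len - 1)
  })
  for (j in seq_len(J)) {
    a <- stats::rnorm(m, spec$act_mean, spec$act_sd)
    block <- outer(a, rep(1, spec$seg_len)) +
      stats::rnorm(m * spec$seg_len, 0, spec$noise_sd)
    vals[, true_cols[[j]]] <- pmax(0, block)
  }
  S <- vapply(true_cols, function(cols) rowSums(vals[, cols, drop = FALSE]),
              numeric(m))
  eta_raw <- as.numeric(S %*% spec$b)
  sigma_y <- stats::sd(eta_raw) / spec$snr
  eta <- if (null_gene) stats::rnorm(m, 0, 1) else
    eta_raw + stats::rnorm(m, 0, sigma_y)

  z <- as.numeric(scale(eta_raw))
  u <- spec$confounder_cor * z +
    sqrt(1 - spec$confounder_cor^2) * stats::rnorm(m)
  decoy_idx <- setdiff(seq_len(n_seg), which_true)
  for (d in decoy_idx) {
    e <- stats::rnorm(m)
    a <- spec$act_mean + spec$act_sd *
      (spec$decoy_cor * u + sqrt(1 - spec$decoy_cor^2) * e)
    cols <- starts[d]:(starts[d] + spec$seg_len - 1)
    block <- outer(a, rep(1, spec$seg_len)) +
      stats::rnorm(m * spec$seg_len, 0, spec$noise_sd)
    vals[, cols] <- pmax(0, block)
  }

  lp <- 3 + as.numeric(scale(eta))
  lp[lp < 0] <- 0
  y <- exp(lp) - 1

  sm <- structure(list(gene_id = gene_id,
                       sample_ids = paste0("s", seq_len(m)),
                       values = vals, positions = seq_len(n) - 1,
                       bin_size = 1, chrom = "chrS"),
                  class = "signal_matrix")
  truth <- data.frame(
    start_col = starts[which_true],
    end_col = starts[which_true] + spec$seg_len - 1,
    b = if (null_gene) rep(0, J) else spec$b)
  list(sm = sm, y = y, truth = truth)
}

#' Simulate a cohort of genes with and without regulatory structure
#'
#' Generates \code{n_signal} genes whose expression is driven by implanted
#' segments and \code{n_null} negative-control genes whose expression is
#' independent of the signal, all sharing the sample set.
#'
#' @param n_signal,n_null Gene counts.
#' @param base_spec A [cohort_gene_spec()] serving as the template; each
#'   gene uses \code{seed + gene index}.
#' @param seed Cohort seed.
#' @return Named list of per-gene lists (\code{sm}, \code{y},
#'   \code{truth}).
#' @export
simulate_cohort <- function(n_signal = 10, n_null = 10,
                            base_spec = cohort_gene_spec(), seed = 1L) {
  out <- list()
  for (i in seq_len(n_signal + n_null)) {
    sp <- base_spec
    sp$seed <- as.integer(seed + i)
    gid <- sprintf("gene%02d%s", i, if (i > n_signal) "_null" else "")
    out[[gid]] <- simulate_regulatory_gene(sp, gene_id = gid,
                                           null_gene = i > n_signal)
  }
  out
}
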