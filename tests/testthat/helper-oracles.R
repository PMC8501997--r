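# Independent oracles used across the suite. These reimplement the scored
# quantities from their definitions, separately from the package's code
# paths, so agreement is evidence rather than tautology.

# All ordered segmentations of 1..n with minimum segment length beta.
enumerate_segmentations <- function(n, beta = 1) {
  res <- list()
  rec <- function(start, acc) {
    if (start > n) {
      res[[length(res) + 1]] <<- acc
      return(invisible())
    }
    for (len in beta:(n - start + 1)) {
      remaining <- n - start + 1 - len
      if (remaining != 0 && remaining < beta) next
      rec(start + len, rbind(acc, c(start, start + len - 1)))
    }
  }
  rec(1, NULL)
  res
}

# Direct (definition-level) evaluation of the Gaussian block code length.
oracle_block_cost <- function(vals, i, j, rows, tau = 1, var_floor = tau^2 / 12) {
  v <- as.numeric(vals[rows, i:j, drop = FALSE])
  sig2 <- max(mean(v^2) - mean(v)^2, var_floor)
  cnt <- length(v)
  cnt / 2 * (1 / log(2) + log2(2 * pi * sig2)) + cnt * log2(tau)
}

oracle_data_cost <- function(vals, segs, labels, tau = 1,
                             var_floor = tau^2 / 12) {
  parts <- split(seq_along(labels), labels)
  total <- 0
  for (r in seq_len(nrow(segs))) {
    for (p in parts) {
      total <- total +
        oracle_block_cost(vals, segs[r, 1], segs[r, 2], p, tau, var_floor) /
        length(p)
    }
  }
  total
}

oracle_model_cost <- function(k, n, n_classes, rng, tau = 1) {
  c0 <- 2.865064
  ln <- log2(c0)
  t <- log2(k)
  while (t > 0) { ln <- ln + t; t <- log2(t) }
  ln + k * n_classes * log2(max(rng, tau) / tau) + log(choose(n - 1, k - 1), 2)
}

# Exhaustive minimum-description-length optimum. Per-segment costs come from
# the package's exported cost functions (independent of the C++ dynamic
# program) and are accumulated left-to-right exactly as the DP accumulates,
# so agreement is expected bit for bit.
brute_force_best <- function(vals, labels, cfg) {
  n <- ncol(vals)
  partition <- class_partition(labels)
  nclass <- length(partition)
  segcost <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < cfg$beta) next
      acc <- 0
      for (p in partition) {
        acc <- acc + segment_class_cost(vals, c(i, j), p, cfg) / length(p)
      }
      segcost[i, j] <- acc
    }
  }
  best <- Inf
  for (s in enumerate_segmentations(n, cfg$beta)) {
    dsum <- 0
    for (r in seq_len(nrow(s))) dsum <- dsum + segcost[s[r, 1], s[r, 2]]
    tot <- dsum + model_cost(nrow(s), n, nclass, max(vals), min(vals), cfg)
    if (tot < best) best <- tot
  }
  best
}

# Step-up Benjamini-Yekutieli from its formula.
oracle_by <- function(p) {
  M <- length(p)
  cM <- sum(1 / seq_len(M))
  o <- order(p)
  q <- pmin(1, p[o] * M * cM / seq_len(M))
  q <- rev(cummin(rev(q)))
  out <- numeric(M)
  out[o] <- q
  out
}

# Shared synthetic two-regime locus used by the boundary-recovery checks:
# class-0 rows flat, class-1 rows at mean_gap over the first half of the
# columns, both flat afterwards.
two_regime_locus <- function(seed, m = 40, n = 100, mean_gap = 5,
                             noise_sd = 0.5, boundary = 50) {
  sp <- locus_spec(
    m = m, n = n, class_fractions = c(0.5, 0.5),
    true_segments = data.frame(start_col = 1, end_col = boundary),
    class_means = matrix(c(0, mean_gap), 2, 1),
    noise_sd = noise_sd, baseline = 0, seed = seed)
  simulate_locus(sp)
}
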