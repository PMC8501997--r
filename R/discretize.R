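#' Class assignment constructor
#'
#' Holds the discrete expression state of one gene across samples: integer
#' labels in \code{0..K-1}, ordered so that class 0 has the lowest mean
#' expression.
#'
#' @param labels Integer vector of per-sample class labels (0-based).
#' @param gene_id Optional gene identifier.
#' @param model_loglik_2,model_loglik_3 Log-likelihoods of the 2- and
#'   3-component mixture fits (NA when not fitted).
#' @return An object of class \code{class_assignment}.
#' @export
class_assignment <- function(labels, gene_id = NA_character_,
                             model_loglik_2 = NA_real_,
                             model_loglik_3 = NA_real_) {
  labels <- as.integer(labels)
  k <- length(unique(labels))
  stopifnot(all(labels >= 0), all(labels < k))
  structure(list(gene_id = gene_id, labels = labels, K = k,
                 class_sizes = as.integer(table(factor(labels, levels = 0:(k - 1)))),
                 model_loglik_2 = model_loglik_2,
                 model_loglik_3 = model_loglik_3,
                 informative = k > 1),
            class = "class_assignment")
}

#' Discretize a gene's expression into 2 or 3 classes
#'
#' Fits univariate Gaussian mixtures with 2 and 3 components (unequal
#' variances) to \code{log(y + 1)} by EM and keeps the fit with the better
#' BIC; samples are labelled with their maximum a posteriori component,
#' components ordered by mean (0 = lowest expression). A raw likelihood
#' comparison cannot choose between nested mixtures, so BIC is used as the
#' penalised selection rule. If a component receives no samples under MAP
#' labelling the model is downgraded to fewer classes, keeping every class
#' non-empty as the downstream \eqn{1/|C_k|} weighting requires.
#'
#' Degenerate input (essentially constant expression) yields a single-class
#' assignment flagged non-informative; such genes are skipped downstream.
#'
#' @param y Non-negative per-sample expression values (length >= 4).
#' @param seed Integer seed for the (deterministic) fit; retained for
#'   interface stability.
#' @param gene_id Optional gene identifier carried through.
#' @return A [class_assignment()].
#' @export
discretize_expression <- function(y, seed = 1L, gene_id = NA_character_) {
  if (length(y) < 4) stop("need at least 4 samples to discretize expression")
  if (any(!is.finite(y)) || any(y < 0)) stop("expression must be finite and >= 0")
  ly <- log(y + 1)
  if (stats::sd(ly) < 1e-10) {
    return(class_assignment(rep(0L, length(y)), gene_id))
  }
  set.seed(seed)
  fit_g <- function(g) {
    tryCatch(
      suppressWarnings(Mclust(ly, G = g, modelNames = "V",
                              verbose = FALSE)),
      error = function(e) NULL)
  }
  f2 <- fit_g(2)
  f3 <- if (length(y) >= 6) fit_g(3) else NULL
  ll2 <- if (!is.null(f2)) f2$loglik else NA_real_
  ll3 <- if (!is.null(f3)) f3$loglik else NA_real_
  pick <- NULL
  if (!is.null(f2) && !is.null(f3)) {
    pick <- if (f3$bic > f2$bic) f3 else f2
  } else if (!is.null(f2)) pick <- f2
  else if (!is.null(f3)) pick <- f3
  if (is.null(pick)) {
    return(class_assignment(rep(0L, length(y)), gene_id, ll2, ll3))
  }

  labels_from <- function(fit) {
    ord <- order(fit$parameters$mean)
    match(fit$classification, ord) - 1L
  }
  lab <- labels_from(pick)
  # downgrade while some MAP class is empty
  while (length(unique(lab)) < max(lab) + 1L || max(lab) + 1L < pick$G) {
    g <- max(2L, pick$G - 1L)
    if (pick$G <= 2L) {
      lab <- rep(0L, length(y))
      break
    }
    pick <- fit_g(g)
    if (is.null(pick)) { lab <- rep(0L, length(y)); break }
    lab <- labels_from(pick)
  }
  # relabel to a dense 0..K-1 range in mean order
  lab <- as.integer(factor(lab)) - 1L
  class_assignment(lab, gene_id, ll2, ll3)
}

#' Partition sample indices by expression class
#'
#' @param assignment A [class_assignment()], or a bare vector of 0-based
#'   integer labels.
#' @return List of integer index vectors \eqn{C_k}, one per class in label
#'   order; disjoint, jointly covering all samples.
#' @export
class_partition <- function(assignment) {
  labels <- if (inherits(assignment, "class_assignment")) assignment$labels
            else as.integer(assignment)
  k <- max(labels) + 1L
  lapply(0:(k - 1L), function(cl) which(labels == cl))
}
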