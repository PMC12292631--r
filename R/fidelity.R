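# Fidelity audit suite for synthetic tabular data: maximum mean
# discrepancy (global distributional similarity), pairwise correlation
# difference (inter-variable structure), per-feature Shannon entropy and
# information gain, and an ordinal star-ranking summary across backends.

#' Squared maximum mean discrepancy between two samples
#'
#' Biased V-statistic estimator with an RBF kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`. The default bandwidth is
#' the median heuristic: `sigma` = median pairwise Euclidean distance over
#' the pooled sample (a floor of `1e-12` is applied, with a warning, when
#' all pooled points coincide). Identical inputs give exactly 0.
#'
#' @param X,Y Numeric sample matrices with equal column counts.
#' @param bandwidth `"median"` (default) or a positive number used as
#'   `sigma` directly.
#' @return A non-negative scalar.
#' @export
mmd <- function(X, Y, bandwidth = "median") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty sample", call. = FALSE)
  if (ncol(X) != ncol(Y)) {
    stop("feature counts differ: ", ncol(X), " vs ", ncol(Y), call. = FALSE)
  }
  pool <- rbind(X, Y)
  d2 <- pairwise_sqdist(pool, pool)
  if (identical(bandwidth, "median")) {
    dvec <- sqrt(pmax(d2[upper.tri(d2)], 0))
    sigma <- stats::median(dvec)
    if (!is.finite(sigma) || sigma <= 0) {
      warning("median pairwise distance is zero; applying bandwidth floor")
      sigma <- 1e-12
    }
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    sigma <- bandwidth
  }
  K <- exp(-d2 / (2 * sigma^2))
  n <- nrow(X); m <- nrow(Y)
  ix <- seq_len(n); iy <- n + seq_len(m)
  val <- mean(K[ix, ix]) + mean(K[iy, iy]) - 2 * mean(K[ix, iy, drop = FALSE])
  max(val, 0)
}

pairwise_sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  pmax(d2, 0)
}

#' Pairwise correlation difference between two samples
#'
#' Frobenius norm (default) or mean absolute difference of the two Pearson
#' correlation matrices. Constant columns get correlation 0 by convention,
#' with a warning.
#'
#' @param X,Y Numeric matrices with the same `>= 2` columns and `>= 3` rows.
#' @param method `"frobenius"` (default) or `"mean_abs"`.
#' @return A non-negative scalar; 0 for identical inputs.
#' @export
pcd <- function(X, Y, method = c("frobenius", "mean_abs")) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) < 2 || ncol(Y) < 2) {
    stop("pcd needs at least 2 features", call. = FALSE)
  }
  stopifnot(ncol(X) == ncol(Y), nrow(X) >= 3, nrow(Y) >= 3)
  safe_cor <- function(M) {
    cc <- suppressWarnings(stats::cor(M))
    if (anyNA(cc)) {
      warning("constant column(s); correlation set to 0 by convention")
      cc[is.na(cc)] <- 0
      diag(cc) <- 1
    }
    cc
  }
  d <- safe_cor(X) - safe_cor(Y)
  if (method == "frobenius") sqrt(sum(d^2)) else mean(abs(d))
}

#' Shannon entropy of a binned empirical distribution
#'
#' Continuous values are discretized into `bins` equal-width bins over the
#' observed range (values at the top edge fall in the last bin);
#' categorical vectors use their native categories. Entropy is reported in
#' bits.
#'
#' @param values Non-empty numeric vector.
#' @param bins Number of bins (default 64).
#' @param categorical Treat values as native categories instead of binning.
#' @param binning `"width"` (default, equal-width over the observed range)
#'   or `"quantile"` (rank-based equal-frequency bins, invariant to
#'   strictly monotone transforms).
#' @return Entropy in bits (`>= 0`; 0 for a constant vector).
#' @export
shannon_entropy <- function(values, bins = 64, categorical = FALSE,
                            binning = c("width", "quantile")) {
  stopifnot(length(values) >= 1)
  b <- bin_values(values, bins, categorical, match.arg(binning))
  p <- tabulate(b, nbins = max(b)) / length(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# map values onto 1-based bin ids: equal-width over the observed range
# (top edge clamped into the last bin) or rank-based equal-frequency;
# categoricals keep native levels
bin_values <- function(values, bins, categorical, binning = "width") {
  if (categorical || length(unique(values)) <= 1) {
    return(as.integer(factor(values)))
  }
  if (binning == "quantile") {
    r <- rank(values, ties.method = "min")
    return(pmin(as.integer(floor((r - 1) / length(values) * bins)) + 1L,
                as.integer(bins)))
  }
  lo <- min(values); hi <- max(values)
  b <- floor((values - lo) / (hi - lo) * bins) + 1L
  pmin(as.integer(b), as.integer(bins))
}

#' Information gain of a feature about a binary label
#'
#' `IG = H(labels) - sum_b p(b) H(labels | bin b)` under the same binning
#' rule as [shannon_entropy()]. Bounded by `[0, H(labels)]`.
#'
#' @param values Numeric feature vector.
#' @param labels Binary label vector of the same length, both classes
#'   present.
#' @param bins Number of bins (default 64).
#' @param categorical Treat `values` as native categories.
#' @param binning Binning rule, as in [shannon_entropy()].
#' @return Information gain in bits.
#' @export
information_gain <- function(values, labels, bins = 64, categorical = FALSE,
                             binning = c("width", "quantile")) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_label <- h(table(labels) / length(labels))
  b <- bin_values(values, bins, categorical, match.arg(binning))
  cond <- 0
  for (bb in unique(b)) {
    sel <- b == bb
    w <- mean(sel)
    cond <- cond + w * h(table(labels[sel]) / sum(sel))
  }
  max(0, min(h_label, h_label - cond))
}

#' Fidelity report comparing a real cohort to its augmented counterpart
#'
#' Computes MMD and PCD between the two feature matrices and, per feature,
#' entropy and information gain before vs after augmentation (the standard
#' "before and after" audit of an augmentation stage). Deterministic given
#' its inputs.
#'
#' @param real The original `cohort_table`.
#' @param augmented The augmented `cohort_table` (same schema).
#' @param backend Name recorded in the report.
#' @param bins Binning for entropy/IG (default 64).
#' @return A list of class `fidelity_report` with fields `backend`, `mmd`,
#'   `pcd` and `per_feature` (a data.frame).
#' @export
fidelity_report <- function(real, augmented, backend = "unknown", bins = 64) {
  stopifnot(inherits(real, "cohort_table"), inherits(augmented, "cohort_table"))
  if (!identical(real$schema$features$name, augmented$schema$features$name)) {
    stop("schemas do not match", call. = FALSE)
  }
  feats <- real$schema$features
  per <- do.call(rbind, lapply(seq_len(nrow(feats)), function(j) {
    iscat <- feats$dtype[j] == "categorical"
    data.frame(
      name = feats$name[j],
      entropy_real = shannon_entropy(real$values[, j], bins, iscat),
      entropy_aug = shannon_entropy(augmented$values[, j], bins, iscat),
      ig_real = information_gain(real$values[, j], real$labels, bins, iscat),
      ig_aug = information_gain(augmented$values[, j], augmented$labels,
                                bins, iscat))
  }))
  structure(list(backend = backend,
                 mmd = mmd(real$values, augmented$values),
                 pcd = pcd(real$values, augmented$values),
                 per_feature = per),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> backend ", x$backend,
      sprintf(": MMD %.4g, PCD %.4g\n", x$mmd, x$pcd), sep = "")
  invisible(x)
}

#' Map per-backend metric scores onto a 1-5 star scale
#'
#' Backends are ranked on the metric and ranks are mapped linearly onto
#' `{1..5}` (best rank maps to 5 when higher is better, to 1 otherwise —
#' pass `higher_is_better = FALSE` for losses such as MMD or PCD, whose
#' smallest value then earns 5 stars). Ties share the higher rating; with
#' three backends the ratings are `{5, 3, 1}`; a single backend gets 5.
#'
#' @param scores Named numeric vector of per-backend scores.
#' @param higher_is_better Direction of merit (default `TRUE`).
#' @return Named integer vector of ratings in 1..5.
#' @export
rank_to_stars <- function(scores, higher_is_better = TRUE) {
  stopifnot(length(scores) >= 1)
  m <- length(scores)
  if (m == 1) return(setNames(5L, names(scores)))
  r <- rank(if (higher_is_better) -scores else scores, ties.method = "min")
  stars <- 5 - (r - 1) * 4 / (m - 1)
  setNames(as.integer(round_half_up(stars, 0)), names(scores))
}
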