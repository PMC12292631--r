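# Clustering-based undersampling (CBU): k-means++ partitioning of the
# training cohort followed by rule-based discard of low-information
# clusters (pure-negative clusters and clusters with a worse-than-1:200
# positive:negative ratio).

#' Clustering configuration for CBU
#'
#' @param k Number of clusters (default 10).
#' @param metric Assignment distance: `"euclidean"`, `"manhattan"` or
#'   `"cosine"`. Non-Euclidean metrics use metric-swapped Lloyd iterations:
#'   assignment under the chosen metric, coordinate-wise-mean centroid
#'   updates (an approximation to true k-medians / spherical k-means).
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Convergence tolerance on the largest centroid movement
#'   (Euclidean norm).
#' @param seed Integer seed for the D-squared seeding draw.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(k = 10, metric = c("euclidean", "manhattan", "cosine"),
                              max_iter = 100, tol = 1e-6, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(k >= 1, max_iter >= 1, tol >= 0)
  structure(list(k = as.integer(k), metric = metric,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

# n x k matrix of distances from rows of X to rows of C under `metric`
dist_to_centroids <- function(X, C, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
      outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
    sqrt(pmax(d2, 0))
  } else if (metric == "manhattan") {
    vapply(seq_len(nrow(C)), function(i) {
      rowSums(abs(sweep(X, 2, C[i, ])))
    }, numeric(nrow(X)))
  } else {
    xn <- sqrt(rowSums(X^2))
    cn <- sqrt(rowSums(C^2))
    cs <- (X %*% t(C)) / outer(xn, pmax(cn, .Machine$double.eps))
    d <- 1 - cs
    d[, cn == 0] <- 1  # degenerate centroid: treat as orthogonal
    pmax(d, 0)
  }
}

#' Cluster a cohort with k-means++
#'
#' Seeding follows the k-means++ rule (each new centre sampled with
#' probability proportional to the squared distance, under the configured
#' metric, to the nearest centre already chosen), then Lloyd iterations:
#' assignment by the configured metric with ties broken towards the lowest
#' cluster index, centroid update by the coordinate-wise mean. Clusters
#' that empty out are re-seeded from the point farthest from its assigned
#' centroid. Deterministic given the config seed.
#'
#' @param table A `cohort_table` with at least `k` rows.
#' @param config A `clustering_config`.
#' @return An object of class `cluster_assignment` with fields `config`,
#'   `labels_by_row` (1-based cluster indices), `centroids` and
#'   `n_iter_run`.
#' @export
assign_clusters <- function(table, config) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "clustering_config"))
  X <- table$values
  n <- nrow(X); k <- config$k
  if (n < k) stop("need at least k = ", k, " rows, got ", n, call. = FALSE)
  if (config$metric == "cosine") {
    zero <- which(rowSums(X^2) == 0)
    if (length(zero)) {
      stop("row ", zero[1], " is a zero vector; cosine distance undefined",
           call. = FALSE)
    }
  }
  res <- with_seed(config$seed, {
    # k-means++ seeding (D^2 sampling under the configured metric)
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    if (k > 1) {
      dmin <- dist_to_centroids(X, X[centers[1], , drop = FALSE],
                                config$metric)[, 1]
      for (i in 2:k) {
        w <- dmin^2
        centers[i] <- if (sum(w) <= 0) sample.int(n, 1) else {
          sample.int(n, 1, prob = w / sum(w))
        }
        dnew <- dist_to_centroids(X, X[centers[i], , drop = FALSE],
                                  config$metric)[, 1]
        dmin <- pmin(dmin, dnew)
      }
    }
    C <- X[centers, , drop = FALSE]
    assign <- integer(n)
    iter <- 0L
    for (it in seq_len(config$max_iter)) {
      iter <- it
      D <- dist_to_centroids(X, C, config$metric)
      assign <- max.col(-D, ties.method = "first")
      # re-seed empty clusters from the farthest point
      own <- D[cbind(seq_len(n), assign)]
      for (j in seq_len(k)) {
        if (!any(assign == j)) {
          far <- which.max(own)
          C[j, ] <- X[far, ]
          assign[far] <- j
          own[far] <- 0
        }
      }
      Cnew <- C
      for (j in seq_len(k)) {
        rows <- assign == j
        if (any(rows)) Cnew[j, ] <- colMeans(X[rows, , drop = FALSE])
      }
      move <- sqrt(max(rowSums((Cnew - C)^2)))
      C <- Cnew
      if (move < config$tol) break
    }
    # final assignment against converged centroids
    D <- dist_to_centroids(X, C, config$metric)
    assign <- max.col(-D, ties.method = "first")
    list(assign = assign, C = C, iter = iter)
  })
  structure(list(config = config, labels_by_row = res$assign,
                 centroids = res$C, n_iter_run = res$iter),
            class = "cluster_assignment")
}

#' Per-cluster class counts and imbalance ratios
#'
#' @param assignment A `cluster_assignment`.
#' @param labels Binary label vector of the clustered rows.
#' @return A data.frame with one row per non-empty cluster: `cluster_id`,
#'   `n_pos`, `n_neg`, `neg_per_pos` (`Inf` for pure-negative clusters) and
#'   `pure_negative`.
#' @export
summarize_clusters <- function(assignment, labels) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  labels <- as.integer(labels)
  if (length(labels) != length(assignment$labels_by_row)) {
    stop("labels length (", length(labels), ") does not match assignment (",
         length(assignment$labels_by_row), ")", call. = FALSE)
  }
  ids <- sort(unique(assignment$labels_by_row))
  out <- do.call(rbind, lapply(ids, function(j) {
    sel <- assignment$labels_by_row == j
    np <- sum(labels[sel] == 1L); nn <- sum(labels[sel] == 0L)
    data.frame(cluster_id = j, n_pos = np, n_neg = nn,
               neg_per_pos = if (np > 0) nn / np else Inf,
               pure_negative = np == 0)
  }))
  rownames(out) <- NULL
  out
}

#' Discard policy for low-information clusters
#'
#' @param max_neg_per_pos Ratio threshold: clusters whose
#'   negatives-per-positive ratio strictly exceeds it are discarded
#'   (default 200, i.e. the 1:200 rule; the boundary itself is retained).
#' @param drop_pure_negative Drop clusters containing no positives
#'   (default `TRUE`).
#' @param retain_positives_from_dropped Keep the positives of
#'   over-threshold clusters, dropping only their negatives (default
#'   `TRUE`; set `FALSE` for the literal whole-cluster discard).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(max_neg_per_pos = 200, drop_pure_negative = TRUE,
                          retain_positives_from_dropped = TRUE) {
  stopifnot(max_neg_per_pos > 0)
  structure(list(max_neg_per_pos = max_neg_per_pos,
                 drop_pure_negative = drop_pure_negative,
                 retain_positives_from_dropped = retain_positives_from_dropped),
            class = "filter_policy")
}

#' Apply the cluster discard rules
#'
#' Removes all rows of pure-negative clusters (when the policy says so) and
#' the negatives of clusters whose imbalance exceeds the threshold
#' (positives of such clusters are retained under the default policy, so
#' the positive count never decreases). Row order is stable.
#'
#' @param table The clustered `cohort_table`.
#' @param assignment Its `cluster_assignment`.
#' @param policy A `filter_policy`.
#' @return The filtered `cohort_table`.
#' @export
filter_clusters <- function(table, assignment, policy = filter_policy()) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(assignment, "cluster_assignment"),
            inherits(policy, "filter_policy"))
  if (length(assignment$labels_by_row) != n_rows(table)) {
    stop("assignment does not match table", call. = FALSE)
  }
  summ <- summarize_clusters(assignment, table$labels)
  keep <- rep(TRUE, n_rows(table))
  for (i in seq_len(nrow(summ))) {
    sel <- assignment$labels_by_row == summ$cluster_id[i]
    if (summ$pure_negative[i]) {
      if (policy$drop_pure_negative) keep[sel] <- FALSE
    } else if (summ$neg_per_pos[i] > policy$max_neg_per_pos) {
      if (policy$retain_positives_from_dropped) {
        keep[sel & table$labels == 0L] <- FALSE
      } else {
        keep[sel] <- FALSE
      }
    }
  }
  cohort_subset(table, keep)
}

#' Random undersampling baseline (RUS)
#'
#' Uniformly subsamples negatives to at most `r_target` negatives per
#' positive; positives and row order are untouched. The baseline
#' comparator for CBU in ablations.
#'
#' @param table A `cohort_table` with at least one positive.
#' @param r_target Target negatives-per-positive ratio.
#' @param seed Integer seed.
#' @return The undersampled `cohort_table`.
#' @export
random_undersample <- function(table, r_target, seed) {
  stopifnot(inherits(table, "cohort_table"), r_target > 0)
  cr <- class_ratio(table)
  if (cr$n_pos == 0) stop("no positives to balance towards", call. = FALSE)
  n_keep <- min(cr$n_neg, ceiling(cr$n_pos * r_target))
  neg_rows <- which(table$labels == 0L)
  keep_neg <- with_seed(seed, sample(neg_rows, n_keep))
  keep <- sort(c(which(table$labels == 1L), keep_neg))
  cohort_subset(table, keep)
}
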