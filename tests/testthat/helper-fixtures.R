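# Shared fixture builders. Everything is generated in code; no data files.

# compact 4-feature schema for fast unit tests
toy_schema <- function() {
  feature_schema(data.frame(
    name = c("age", "crp", "wbc", "pyuria"),
    category = c("demographic", "blood", "blood", "urine"),
    dtype = c("continuous", "continuous", "count", "categorical")),
    label_name = "label")
}

# small labelled cohort with a class shift on `crp`
toy_cohort <- function(n = 40, pos_frac = 0.25, seed = 1, shift = 2) {
  set.seed(seed)
  y <- as.integer(seq_len(n) <= round(pos_frac * n))
  vals <- cbind(age = rnorm(n, 3, 1),
                crp = rnorm(n) + shift * y,
                wbc = rpois(n, 9),
                pyuria = rbinom(n, 1, 0.2 + 0.3 * y))
  cohort_table(toy_schema(), vals, y)
}

# hand-built cluster assignment (bypasses k-means) for filter tests
manual_assignment <- function(labels_by_row, k = max(labels_by_row)) {
  structure(list(config = clustering_config(k = k),
                 labels_by_row = as.integer(labels_by_row),
                 centroids = matrix(0, k, 1), n_iter_run = 0L),
            class = "cluster_assignment")
}

# independent re-implementation of the discard rules, used as the oracle
# against filter_clusters: literal per-cluster application
oracle_filter <- function(labels, cluster, max_ratio = 200,
                          drop_pure = TRUE, retain_pos = TRUE) {
  keep <- rep(TRUE, length(labels))
  for (cl in unique(cluster)) {
    rows <- which(cluster == cl)
    np <- sum(labels[rows] == 1); nn <- sum(labels[rows] == 0)
    if (np == 0) {
      if (drop_pure) keep[rows] <- FALSE
    } else if (nn / np > max_ratio) {
      if (retain_pos) keep[rows[labels[rows] == 0]] <- FALSE
      else keep[rows] <- FALSE
    }
  }
  which(keep)
}

# brute-force AUC by pair counting (ties count one half)
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# lighter stacking config for unit tests (not the study conditions)
fast_stacking <- function(seed = 1, n_folds = 5) {
  stacking_config(n_folds = n_folds,
                  xgb_params = list(eta = 0.1, max_depth = 6, nrounds = 30),
                  ada_params = list(n_estimators = 15, max_leaves = 31,
                                    colsample = 0.8),
                  lgb_params = list(nrounds = 20, max_leaves = 31, eta = 0.1),
                  seed = seed)
}

# small end-to-end pipeline config on a reduced cohort (fast path checks)
small_pipeline_config <- function(seed = 3, n = 2600, ...) {
  sim <- cohort_sim_config(n_rows = n, pos_rate = 1 / 40,
                           seed = derive_seed(seed, "sim"))
  coh <- simulate_cohort(sim)
  sp <- split_cohort(coh, 0.25, seed = derive_seed(seed, "split"))
  pipeline_config(train = sp$train, test = sp$test,
                  stacking = fast_stacking(), seed = seed, ...)
}
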