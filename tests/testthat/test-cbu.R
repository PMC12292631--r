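test_that("k = 1 assigns everything to one cluster with the column-mean centroid", {
  tab <- toy_cohort(n = 25, seed = 2)
  a <- assign_clusters(tab, clustering_config(k = 1, seed = 1))
  expect_true(all(a$labels_by_row == 1L))
  expect_equal(as.numeric(a$centroids[1, ]), as.numeric(colMeans(tab$values)))
})

test_that("well-separated blobs are recovered exactly under every metric", {
  set.seed(11)
  n <- 100
  blob <- rep(1:2, each = n)
  X <- rbind(matrix(rnorm(n * 2, mean = 10), ncol = 2),
             matrix(rnorm(n * 2, mean = -10), ncol = 2))
  sch <- feature_schema(data.frame(name = c("x1", "x2"), category = "blood",
                                   dtype = "continuous"))
  tab <- cohort_table(sch, X, rep(0:1, n))
  for (metric in c("euclidean", "manhattan", "cosine")) {
    a <- assign_clusters(tab, clustering_config(k = 2, metric = metric,
                                                seed = 5))
    purity <- max(table(a$labels_by_row, blob)) / n
    expect_equal(purity, 1, info = metric)
    # every row sits with its nearest centroid (brute-force oracle)
    D <- kdscreen:::dist_to_centroids(X, a$centroids, metric)
    expect_identical(a$labels_by_row, max.col(-D, ties.method = "first"))
  }
})

test_that("clustering is deterministic and validates its preconditions", {
  tab <- toy_cohort(n = 30, seed = 3)
  cfg <- clustering_config(k = 3, seed = 9)
  a <- assign_clusters(tab, cfg)
  b <- assign_clusters(tab, cfg)
  expect_identical(a$labels_by_row, b$labels_by_row)
  expect_identical(a$centroids, b$centroids)
  expect_error(assign_clusters(tab, clustering_config(k = 31)), "at least k")

  zr <- tab
  zr$values[4, ] <- 0
  expect_error(assign_clusters(zr, clustering_config(k = 2, metric = "cosine")),
               "row 4")
})

test_that("cluster summaries count classes and conserve totals", {
  a <- manual_assignment(rep(1L, 10))
  s <- summarize_clusters(a, c(rep(1, 3), rep(0, 7)))
  expect_identical(s$n_pos, 3L)
  expect_identical(s$n_neg, 7L)
  expect_equal(s$neg_per_pos, 7 / 3)
  expect_false(s$pure_negative)

  s2 <- summarize_clusters(manual_assignment(rep(1L, 12)), rep(0, 12))
  expect_true(s2$pure_negative)
  expect_identical(s2$neg_per_pos, Inf)

  expect_error(summarize_clusters(a, c(0, 1)), "match")

  # conservation on random fixtures
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:60, 1)
    cl <- sample(1:4, n, replace = TRUE)
    y <- rbinom(n, 1, 0.3)
    summ <- summarize_clusters(manual_assignment(cl, 4), y)
    expect_identical(sum(summ$n_pos), sum(y == 1))
    expect_identical(sum(summ$n_neg), sum(y == 0))
  }
})

test_that("filter rules drop pure-negative clusters and over-ratio negatives", {
  # clusters: A (0 pos / 50 neg), B (1 pos / 300 neg), C (2 pos / 100 neg)
  labels <- c(rep(0, 50), 1, rep(0, 300), 1, 1, rep(0, 100))
  cl <- c(rep(1, 50), rep(2, 301), rep(3, 102))
  sch <- feature_schema(data.frame(name = "x", category = "blood",
                                   dtype = "continuous"))
  tab <- cohort_table(sch, matrix(seq_along(labels), ncol = 1), labels)
  out <- filter_clusters(tab, manual_assignment(cl, 3), filter_policy())
  expect_identical(sum(out$labels == 1), 3L)   # all positives survive
  expect_identical(sum(out$labels == 0), 100L) # only C's negatives survive
  # literal whole-cluster discard removes B's positive too
  out2 <- filter_clusters(tab, manual_assignment(cl, 3),
                          filter_policy(retain_positives_from_dropped = FALSE))
  expect_identical(sum(out2$labels == 1), 2L)
})

test_that("a permissive policy is the identity", {
  tab <- toy_cohort(n = 40, seed = 4)
  cl <- sample(1:3, 40, replace = TRUE)
  out <- filter_clusters(tab, manual_assignment(cl, 3),
                         filter_policy(max_neg_per_pos = Inf,
                                       drop_pure_negative = FALSE))
  expect_identical(out$values, tab$values)
  expect_identical(out$labels, tab$labels)
})

test_that("the exact 1:200 boundary is retained", {
  labels <- c(1, rep(0, 200))
  sch <- feature_schema(data.frame(name = "x", category = "blood",
                                   dtype = "continuous"))
  tab <- cohort_table(sch, matrix(seq_along(labels), ncol = 1), labels)
  out <- filter_clusters(tab, manual_assignment(rep(1, 201), 1),
                         filter_policy(max_neg_per_pos = 200))
  expect_identical(n_rows(out), 201L)
})

test_that("filtering matches the exhaustive rule oracle on small instances", {
  for (case in 1:200) {
    set.seed(case)
    n <- sample(2:20, 1)
    k <- sample(1:4, 1)
    cl <- sample(seq_len(k), n, replace = TRUE)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    max_ratio <- sample(c(0.5, 1, 2, 200), 1)
    retain <- sample(c(TRUE, FALSE), 1)
    drop_pure <- sample(c(TRUE, FALSE), 1)
    sch <- feature_schema(data.frame(name = "x", category = "blood",
                                     dtype = "continuous"))
    tab <- cohort_table(sch, matrix(seq_len(n), ncol = 1), y)
    got <- filter_clusters(tab, manual_assignment(cl, k),
                           filter_policy(max_neg_per_pos = max_ratio,
                                         drop_pure_negative = drop_pure,
                                         retain_positives_from_dropped = retain))
    want <- oracle_filter(y, cl, max_ratio, drop_pure, retain)
    expect_identical(as.integer(got$values[, 1]), want)
    # default-policy invariants
    if (retain) {
      expect_identical(sum(got$labels == 1), sum(y == 1))
    }
    expect_lte(sum(got$labels == 0), sum(y == 0))
  }
})

test_that("filtering never worsens the class ratio when clusters are dropped", {
  for (s in 1:20) {
    set.seed(s)
    n <- 150
    cl <- sample(1:4, n, replace = TRUE)
    y <- rbinom(n, 1, 0.05)
    if (sum(y) == 0) next
    sch <- feature_schema(data.frame(name = "x", category = "blood",
                                     dtype = "continuous"))
    tab <- cohort_table(sch, matrix(seq_len(n), ncol = 1), y)
    out <- filter_clusters(tab, manual_assignment(cl, 4),
                           filter_policy(max_neg_per_pos = 20))
    if (n_rows(out) < n) {
      expect_lte(class_ratio(out)$neg_per_pos, class_ratio(tab)$neg_per_pos)
    }
  }
})

test_that("random undersampling hits the target ratio and keeps positives", {
  tab <- toy_cohort(n = 200, pos_frac = 0.05, seed = 6)
  out <- random_undersample(tab, r_target = 5, seed = 8)
  cr <- class_ratio(out)
  expect_identical(cr$n_pos, sum(tab$labels))
  expect_identical(cr$n_neg, as.integer(ceiling(cr$n_pos * 5)))
  out2 <- random_undersample(tab, r_target = 5, seed = 8)
  expect_identical(out$values, out2$values)
  # target above the current ratio: nothing removed
  expect_identical(n_rows(random_undersample(tab, 1e6, seed = 1)), 200L)
})
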