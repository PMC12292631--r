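test_that("bundled KD schema has the expected shape", {
  sch <- kd_schema()
  counts <- table(sch$features$category)
  expect_identical(as.integer(counts[c("demographic", "blood", "urine")]),
                   c(3L, 17L, 2L))
  expect_identical(sch$label_name, "KD")
  expect_false(sch$label_name %in% sch$features$name)
})

test_that("schema construction rejects malformed input", {
  feats <- data.frame(name = c("a", "a"), category = "blood",
                      dtype = "continuous")
  expect_error(feature_schema(feats), "unique")
  feats2 <- data.frame(name = c("a", "label"), category = "blood",
                       dtype = "continuous")
  expect_error(feature_schema(feats2, label_name = "label"), "label")
  expect_error(feature_schema(data.frame(name = "a", category = "bone",
                                         dtype = "continuous")), "category")
})

test_that("schema sidecar round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(kd_schema(), path)
  back <- read_schema(path)
  expect_identical(back$features, kd_schema()$features)
  expect_identical(back$label_name, "KD")
})

test_that("cohort read/write round-trips values, labels and provenance", {
  tab <- toy_cohort(n = 30, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  # purely real cohorts omit the provenance column
  expect_false(grepl("provenance", readLines(path, n = 1)))
  expect_identical(length(readLines(path)), 31L)
  back <- read_cohort(path, toy_schema())
  expect_equal(back$values, tab$values)
  expect_identical(back$labels, tab$labels)
  expect_identical(back$provenance, tab$provenance)

  tab$provenance[5] <- "synthetic"
  write_cohort(tab, path)
  expect_true(grepl("provenance", readLines(path, n = 1)))
  back <- read_cohort(path, toy_schema())
  expect_identical(back$provenance, tab$provenance)
})

test_that("read_cohort reports missing columns and bad labels by name/row", {
  tab <- toy_cohort(n = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(tab$values)
  df$label <- tab$labels
  df$crp <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path, toy_schema()), "crp")

  df <- as.data.frame(tab$values)
  df$label <- c(0, 1, 2, 0, 1)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path, toy_schema()), "row 3")
})

test_that("missing values are rejected unless imputation is requested", {
  tab <- toy_cohort(n = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(tab$values)
  df$label <- tab$labels
  df$crp[4] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path, toy_schema()), "missing")
  imp <- read_cohort(path, toy_schema(), impute_median = TRUE)
  expect_equal(unname(imp$values[4, "crp"]), median(df$crp[-4]))
})

test_that("stratified split preserves class composition and partitions rows", {
  tab <- toy_cohort(n = 20, pos_frac = 0.5)
  sp <- split_cohort(tab, 0.5, seed = 9)
  expect_identical(sum(sp$test$labels), 5L)
  expect_identical(sum(sp$test$labels == 0), 5L)
  expect_identical(n_rows(sp$train) + n_rows(sp$test), 20L)
  # partition: every original row appears exactly once across the two parts
  all_rows <- rbind(sp$train$values, sp$test$values)
  expect_equal(all_rows[order(all_rows[, "age"]), ],
               tab$values[order(tab$values[, "age"]), ])
  sp2 <- split_cohort(tab, 0.5, seed = 9)
  expect_identical(sp2$test$values, sp$test$values)
})

test_that("an 8:2 split of a 1:64 cohort lands on the expected test counts", {
  # 1,142 positives / 73,499 negatives: per-class ceiling gives 229 / 14,700
  sch <- feature_schema(data.frame(name = "x", category = "blood",
                                   dtype = "continuous"))
  n <- 1142 + 73499
  tab <- cohort_table(sch, matrix(seq_len(n), ncol = 1),
                      c(rep(1L, 1142), rep(0L, 73499)))
  sp <- split_cohort(tab, 0.2, seed = 1)
  expect_identical(sum(sp$test$labels == 1), 229L)
  expect_identical(sum(sp$test$labels == 0), 14700L)
  expect_identical(sum(sp$train$labels == 1), 913L)
  expect_identical(sum(sp$train$labels == 0), 58799L)
})

test_that("split refuses classes too small to stratify", {
  sch <- toy_schema()
  tab <- cohort_table(sch, matrix(rnorm(4 * 3), ncol = 4), c(1, 0, 0))
  expect_error(split_cohort(tab, 0.5, seed = 1), "stratify")
})

test_that("class_ratio matches the published training-set arithmetic", {
  sch <- feature_schema(data.frame(name = "x", category = "blood",
                                   dtype = "continuous"))
  tab <- cohort_table(sch, matrix(0, 913 + 58799, 1),
                      c(rep(1L, 913), rep(0L, 58799)))
  cr <- class_ratio(tab)
  expect_identical(cr$n_pos, 913L)
  expect_identical(cr$n_neg, 58799L)
  expect_equal(cr$neg_per_pos, 58799 / 913)
  expect_equal(round(cr$neg_per_pos), 64)

  even <- cohort_table(sch, matrix(0, 20, 1), rep(c(0L, 1L), 10))
  expect_equal(class_ratio(even)$neg_per_pos, 1)

  nopos <- cohort_table(sch, matrix(0, 5, 1), rep(0L, 5))
  cr0 <- class_ratio(nopos)
  expect_true(cr0$undefined)
  expect_true(is.na(cr0$neg_per_pos))
})

test_that("cohort construction validates labels and dimensions", {
  sch <- toy_schema()
  expect_error(cohort_table(sch, matrix(0, 2, 4), c(0, 2)), "row 2")
  expect_error(cohort_table(sch, matrix(0, 2, 3), c(0, 1)), "columns")
  expect_error(cohort_table(sch, matrix(0, 2, 4), c(0, 1),
                            provenance = c("real", "fake")), "provenance")
})
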