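test_that("augmentation sizing reproduces the published balancing arithmetic", {
  plan <- augmentation_count(52454, 913, 24, "ceil")
  expect_identical(plan$n_aug, 1273L)
  expect_identical(plan$n_final_minor, 2186L)
  expect_identical(plan$n_final_minor, as.integer(ceiling(52454 / 24)))

  # already at or beyond target: nothing to generate
  expect_identical(augmentation_count(2400, 100, 24)$n_aug, 0L)
  expect_identical(augmentation_count(0, 10, 24)$n_aug, 0L)

  # rounding rules differ only in the fractional step
  expect_identical(augmentation_count(100, 0, 24, "floor")$n_final_minor, 4L)
  expect_identical(augmentation_count(100, 0, 24, "ceil")$n_final_minor, 5L)
  expect_identical(augmentation_count(100, 0, 24, "nearest")$n_final_minor, 4L)
})

test_that("post-augmentation ratio stays within one unit of the target", {
  for (s in 1:50) {
    set.seed(s)
    n_major <- sample(100:60000, 1)
    n_minor <- sample(1:1000, 1)
    rule <- sample(c("ceil", "nearest", "floor"), 1)
    plan <- augmentation_count(n_major, n_minor, 24, rule)
    if (plan$n_aug > 0) {
      ratio <- n_major / plan$n_final_minor
      expect_gte(ratio, 23)
      expect_lte(ratio, 25)
    }
  }
})

test_that("unavailable adapter backends fail loudly, never silently", {
  minority <- cohort_subset(toy_cohort(40, pos_frac = 0.5), 1:20)
  expect_error(fit_backend(minority, backend_config("ctgan")), "adapter")
  expect_error(fit_backend(minority, backend_config("ganblr")), "adapter")
})

test_that("backend fitting validates the minority table", {
  tab <- toy_cohort(40, pos_frac = 0.5)
  expect_error(fit_backend(tab, backend_config("kde")), "labels 1")
  empty <- cohort_subset(tab, integer(0))
  expect_error(fit_backend(empty, backend_config("kde")), "empty")
})

test_that("KDE samples concentrate on training points as bandwidth vanishes", {
  minority <- cohort_subset(toy_cohort(20, pos_frac = 1), 1:5)
  gen <- fit_backend(minority, backend_config("kde", bandwidth_factor = 1e-9))
  batch <- sample_synthetic(gen, 50, seed = 3)
  # categoricals are resampled independently by design; concentration is a
  # property of the kernel-perturbed numeric coordinates
  num <- gen$numeric_cols
  dist_to_train <- apply(batch$rows[, num, drop = FALSE], 1, function(r) {
    min(sqrt(rowSums(sweep(minority$values[, num, drop = FALSE], 2, r)^2)))
  })
  expect_lt(max(dist_to_train), 1e-6)
})

test_that("KDE samples stay within a few bandwidths of the minority support", {
  minority <- cohort_subset(toy_cohort(120, pos_frac = 1, seed = 31), 1:120)
  gen <- fit_backend(minority, backend_config("kde"))
  batch <- sample_synthetic(gen, 200, seed = 4)
  bw <- gen$fit$bandwidth
  bw[bw == 0] <- 1e-12
  num <- gen$numeric_cols
  # per-feature standardized distance to the nearest training row
  ok <- apply(batch$rows, 1, function(r) {
    std <- sweep(abs(sweep(minority$values[, num, drop = FALSE], 2, r[num])),
                 2, bw[num], "/")
    min(apply(std, 1, max)) < 6
  })
  expect_true(all(ok))
})

test_that("synthetic sampling respects types, counts and determinism", {
  minority <- cohort_subset(toy_cohort(60, pos_frac = 1, seed = 5), 1:60)
  for (be in c("kde", "gaussian_copula")) {
    gen <- fit_backend(minority, backend_config(be))
    expect_identical(nrow(sample_synthetic(gen, 0, seed = 1)$rows), 0L)
    expect_error(sample_synthetic(gen, -1), "non-negative")
    b1 <- sample_synthetic(gen, 37, seed = 2)
    b2 <- sample_synthetic(gen, 37, seed = 2)
    expect_identical(b1$rows, b2$rows)
    expect_identical(nrow(b1$rows), 37L)
    # count features: non-negative integers
    wbc <- b1$rows[, "wbc"]
    expect_true(all(wbc >= 0 & wbc == round(wbc)))
    # categorical features snap to observed categories
    expect_true(all(b1$rows[, "pyuria"] %in% unique(minority$values[, "pyuria"])))
    expect_identical(b1$source_fingerprint, gen$source_fingerprint)
  }
})

test_that("KDE synthetic means track the fitting means (4 SE, seed-averaged)", {
  minority <- cohort_subset(toy_cohort(60, pos_frac = 1, seed = 6), 1:60)
  gen <- fit_backend(minority, backend_config("kde"))
  num <- gen$numeric_cols
  devs <- sapply(1:5, function(s) {
    batch <- sample_synthetic(gen, 600, seed = s)
    colMeans(batch$rows[, num, drop = FALSE]) -
      colMeans(minority$values[, num, drop = FALSE])
  })
  mean_dev <- rowMeans(devs)
  # synthetic draws have variance sd^2 + bandwidth^2; SE over 5 x 600 draws
  sd_synth <- sqrt(apply(minority$values[, num, drop = FALSE], 2, var) +
                     gen$fit$bandwidth[num]^2)
  se <- pmax(sd_synth / sqrt(5 * 600), 1e-9)
  expect_true(all(abs(mean_dev) < 4 * se))
})

test_that("balance_cohort reaches the target and never touches real rows", {
  tab <- toy_cohort(260, pos_frac = 0.04, seed = 7)  # ~10 pos / 250 neg
  res <- balance_cohort(tab, r_target = 5, backend = backend_config("kde", seed = 8))
  out <- res$table
  cr_in <- class_ratio(tab)
  cr_out <- class_ratio(out)
  expect_identical(cr_out$n_neg, cr_in$n_neg)
  expect_identical(cr_out$n_pos, res$plan$n_final_minor)
  expect_identical(cr_out$n_pos, as.integer(ceiling(cr_in$n_neg / 5)))
  # original rows pass through bit-identically, synthetic rows are flagged
  expect_identical(out$values[seq_len(n_rows(tab)), ], tab$values)
  expect_identical(out$provenance[seq_len(n_rows(tab))], tab$provenance)
  expect_true(all(out$provenance[-seq_len(n_rows(tab))] == "synthetic"))
  expect_true(all(out$labels[-seq_len(n_rows(tab))] == 1L))

  # already balanced: untouched
  res2 <- balance_cohort(out, r_target = 24)
  expect_identical(res2$table$values, out$values)
  expect_identical(res2$plan$n_aug, 0L)
})

test_that("copula backend preserves a strong pairwise correlation", {
  set.seed(9)
  n <- 300
  x1 <- rnorm(n)
  sch <- feature_schema(data.frame(name = c("a", "b"), category = "blood",
                                   dtype = "continuous"))
  minority <- cohort_table(sch, cbind(x1, 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)),
                           rep(1L, n))
  gen <- fit_backend(minority, backend_config("gaussian_copula"))
  batch <- sample_synthetic(gen, 1000, seed = 10)
  expect_gt(cor(batch$rows[, 1], batch$rows[, 2]), 0.7)
})
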