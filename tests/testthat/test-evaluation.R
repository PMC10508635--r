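test_that("sparse split is compound-disjoint, label-covering and near 30% per kinase", {
  mat <- fx_matrix()
  sp <- sparse_split(mat, split_spec("sparse", seed = 5))
  expect_length(intersect(unique(sp$train$inchikey),
                          unique(sp$test$inchikey)), 0)
  expect_setequal(unique(sp$train$protein_label), mat$proteins)
  expect_setequal(unique(sp$test$protein_label), mat$proteins)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(mat$data))
  expect_true(all(sp$achieved$test_fraction >= 0.25 &
                  sp$achieved$test_fraction <= 0.35))
  # determinism per seed
  sp2 <- sparse_split(mat, split_spec("sparse", seed = 5))
  expect_identical(sp$assignment, sp2$assignment)
  # a protein fed by a single compound cannot be split
  bad <- merge_and_aggregate(data.frame(
    inchikey = c("A", "A", "B", "C"),
    protein_label = c("K01", "K01", "K02", "K02"),
    pactivity = c(5, 6, 7, 8), stringsAsFactors = FALSE))
  expect_error(sparse_split(bad, split_spec("sparse")), "K01")
})

test_that("split invariants hold across 20 seeds", {
  mat <- fx_matrix()
  for (seed in 1:20) {
    sp <- sparse_split(mat, split_spec("sparse", seed = seed))
    expect_length(intersect(unique(sp$train$inchikey),
                            unique(sp$test$inchikey)), 0)
    expect_setequal(unique(sp$train$protein_label), mat$proteins)
    expect_setequal(unique(sp$test$protein_label), mat$proteins)
  }
})

test_that("dense split thresholds on the per-compound kinase count", {
  mk <- function(profile) {
    rows <- do.call(rbind, lapply(names(profile), function(ck)
      data.frame(inchikey = ck, protein_label = profile[[ck]],
                 pactivity = 6, stringsAsFactors = FALSE)))
    merge_and_aggregate(rows)
  }
  mat <- mk(list(deep1 = c("K01", "K02", "K03", "K04"),
                 deep2 = c("K01", "K02", "K03", "K04"),
                 edge3 = c("K02", "K03", "K04"),
                 a = c("K01", "K02"),
                 b = c("K01", "K03", "K04")))
  sp <- dense_split(mat, split_spec("dense", min_kinases_dense = 4))
  # compounds at the threshold go to test, just below it to train
  expect_setequal(unique(sp$test$inchikey), c("deep1", "deep2"))
  expect_setequal(unique(sp$train$inchikey), c("edge3", "a", "b"))
  expect_error(dense_split(mat, split_spec("dense", min_kinases_dense = 60)),
               "no compound")
  # a deep compound monopolizing a protein violates the both-sides invariant
  bad <- mk(list(deep = c("K01", "K02", "K03"), a = c("K01", "K02"),
                 b = c("K01", "K02")))
  expect_error(dense_split(bad, split_spec("dense", min_kinases_dense = 3)),
               "K03")
})

test_that("design matrices concatenate Morgan and protein feature blocks", {
  fps <- fx_fps()
  mat <- fx_matrix()
  pf <- fx_protein_features()
  pairs <- mat$data[1:50, ]
  expect_equal(ncol(assemble_design(pairs, fps)$X), 1024)
  expect_equal(ncol(assemble_design(pairs, fps, pf$onehot)$X), 1024 + 8)
  expect_equal(ncol(assemble_design(pairs, fps, pf$zscales_whole)$X), 1029)
  expect_equal(ncol(assemble_design(pairs, fps, pf$zscales_residue)$X), 1449)
  expect_equal(ncol(assemble_design(pairs, fps, pf$protvec)$X), 1124)
  expect_equal(assemble_design(pairs, fps)$y, pairs$pactivity)
  bad <- pairs; bad$inchikey[1] <- "MISSING"
  expect_error(assemble_design(bad, fps), "MISSING")
})

test_that("the forest is seeded-deterministic and handles a constant response", {
  set.seed(2)
  X <- matrix(rbinom(200 * 30, 1, 0.3), 200)
  colnames(X) <- sprintf("f%02d", 1:30)
  y <- 5 + 2 * X[, 1] + X[, 2] + rnorm(200, sd = 0.3)
  f1 <- train_rf(X, y, model_spec(1, seed = 9))
  f2 <- train_rf(X, y, model_spec(1, seed = 9))
  Xt <- matrix(rbinom(50 * 30, 1, 0.3), 50, dimnames = list(NULL, colnames(X)))
  expect_identical(predict_rf(f1, Xt), predict_rf(f2, Xt))
  # in-sample error is smaller than out-of-sample error
  yt <- 5 + 2 * Xt[, 1] + Xt[, 2] + rnorm(50, sd = 0.3)
  expect_lt(sqrt(mean((predict_rf(f1, X) - y)^2)),
            sqrt(mean((predict_rf(f1, Xt) - yt)^2)))
  expect_warning(fc <- train_rf(X, rep(5, 200), model_spec(1)), "constant")
  expect_true(all(predict_rf(fc, Xt) == 5))
  expect_error(train_rf(X[1:5, ], y[1:5]), "at least 10")
})

test_that("regression metrics match a brute-force oracle", {
  expect_equal(regression_metrics(1:5, 1:5)$rmse, 0)
  expect_equal(regression_metrics(1:5, 1:5)$r2, 1)
  expect_equal(unname(regression_metrics(1:5, 1:5)$band_fractions[1]), 1)
  shifted <- regression_metrics(1:5 + 0.7, 1:5)
  expect_equal(shifted$rmse, 0.7)
  expect_equal(unname(shifted$band_fractions[2]), 1)
  # |error| of exactly 0.5 falls in the 0-0.5 band
  half <- regression_metrics(c(5.5, 6.5), c(5, 6))
  expect_equal(unname(half$band_fractions[1]), 1)
  # r2 undefined for a constant observation vector
  expect_true(is.na(regression_metrics(c(1, 2), c(3, 3))$r2))
  expect_error(regression_metrics(1:3, 1:4), "differ")
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    pred <- rnorm(n, 6); obs <- rnorm(n, 6)
    bins <- factor(sample(levels(tanimoto_bin(0)), n, TRUE),
                   levels = levels(tanimoto_bin(0)))
    m <- regression_metrics(pred, obs, bins)
    expect_equal(m$rmse, sqrt(sum((pred - obs)^2) / n), tolerance = 1e-12)
    expect_equal(m$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
    expect_equal(sum(m$band_fractions), 1, tolerance = 1e-9)
    for (b in levels(bins)) {
      ix <- bins == b
      if (any(ix))
        expect_equal(unname(m$rmse_per_bin[b]),
                     sqrt(mean((pred[ix] - obs[ix])^2)), tolerance = 1e-12)
    }
  }
})

test_that("classification metrics at threshold 7 match exhaustive enumeration", {
  # all positive: TPR 1, FPR undefined (no negatives)
  allpos <- classification_metrics(c(7, 8), c(7.5, 9))
  expect_equal(allpos$tpr, 1)
  expect_true(is.na(allpos$fpr))
  # nothing predicted positive: TPR 0, FN = n/2
  none <- classification_metrics(rep(5, 10), rep(c(6, 8), 5))
  expect_equal(none$tpr, 0)
  expect_equal(none$fn, 5)
  set.seed(12)
  for (rep in 1:100) {
    n <- 40
    pred <- runif(n, 4, 10); obs <- runif(n, 4, 10)
    m <- classification_metrics(pred, obs, threshold = 7)
    tp <- sum(pred >= 7 & obs >= 7); fp <- sum(pred >= 7 & obs < 7)
    fn <- sum(pred < 7 & obs >= 7); tn <- sum(pred < 7 & obs < 7)
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
    expect_equal(m$tpr, tp / (tp + fn), tolerance = 1e-12)
    expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
    expect_equal(m$balanced_accuracy,
                 (tp / (tp + fn) + tn / (tn + fp)) / 2, tolerance = 1e-12)
  }
  # per-group confusion sums to the overall counts
  g <- rep(c("K01", "K02"), each = 20)
  pred <- runif(40, 4, 10); obs <- runif(40, 4, 10)
  per <- classification_metrics(pred, obs, 7, group = g)
  tot <- classification_metrics(pred, obs, 7)
  expect_equal(sum(per$tp), tot$tp)
  expect_equal(sum(per$tp + per$fp + per$tn + per$fn), 40)
})

test_that("the median baseline is a per-kinase constant floor", {
  train <- data.frame(inchikey = rep(c("a", "b", "c"), 2),
                      protein_label = rep(c("K01", "K02"), each = 3),
                      pactivity = c(5, 5, 5, 7, 7, 7), stringsAsFactors = FALSE)
  mb <- median_baseline(train, train)
  expect_true(all(mb$per_kinase$rmse == 0))
  # constant predictor on a non-constant kinase has r2 <= 0
  test <- data.frame(inchikey = c("x", "y"), protein_label = "K01",
                     pactivity = c(4, 9), stringsAsFactors = FALSE)
  mb2 <- median_baseline(train, test)
  expect_lte(mb2$per_kinase$r2, 0)
  # brute-force oracle on the fixture split
  mat <- fx_matrix()
  sp <- sparse_split(mat, split_spec("sparse", seed = 3))
  mb3 <- median_baseline(sp$train, sp$test)
  meds <- tapply(sp$train$pactivity, sp$train$protein_label, median)
  for (k in sample(mat$proteins, 3)) {
    ix <- sp$test$protein_label == k
    expect_equal(mb3$per_kinase$rmse[mb3$per_kinase$protein_label == k],
                 sqrt(mean((meds[k] - sp$test$pactivity[ix])^2)),
                 tolerance = 1e-12)
  }
  expect_error(median_baseline(train[train$protein_label == "K01", ], test =
    data.frame(inchikey = "x", protein_label = "K02", pactivity = 5)),
    "K02")
})

test_that("skewness and kurtosis match the bias-corrected textbook estimators", {
  expect_equal(distribution_stats(c(1, 2, 3))$skewness, 0)
  expect_true(is.na(distribution_stats(c(1, 2))$skewness))
  expect_true(is.na(distribution_stats(rep(4, 10))$skewness))
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(sample(10:200, 1), sd = runif(1, 0.5, 3))
    ds <- distribution_stats(x)
    expect_equal(ds$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
    expect_equal(ds$excess_kurtosis, e1071::kurtosis(x, type = 2),
                 tolerance = 1e-12)
  }
  # large normal sample: excess kurtosis near 0
  x <- rnorm(10000)
  expect_lt(abs(distribution_stats(x)$excess_kurtosis), 0.15)
})
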