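#' Split specification
#'
#' @param kind "sparse" (compound-disjoint, ~30\% of each protein's
#'   measurements in test) or "dense" (compounds measured on at least
#'   `min_kinases_dense` proteins form the test panel)
#' @param test_fraction sparse test fraction (default 0.3)
#' @param min_kinases_dense dense panel threshold (default 60)
#' @param seed RNG seed for the sparse assignment
#' @return object of class `split_spec`
#' @export
split_spec <- function(kind = c("sparse", "dense"), test_fraction = 0.3,
                       min_kinases_dense = 60L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(test_fraction > 0, test_fraction < 1, min_kinases_dense >= 1)
  structure(list(kind = kind, test_fraction = test_fraction,
                 min_kinases_dense = as.integer(min_kinases_dense),
                 seed = as.integer(seed)),
            class = "split_spec")
}

.split_obj <- function(train, test, assignment, achieved = NULL) {
  structure(list(train = train, test = test, assignment = assignment,
                 achieved = achieved), class = "activity_split")
}

.check_split <- function(split, proteins) {
  both <- intersect(split$train$inchikey, split$test$inchikey)
  if (length(both) > 0)
    stopf("split is not compound-disjoint (%d shared compounds)", length(both))
  missing <- union(setdiff(proteins, unique(split$train$protein_label)),
                   setdiff(proteins, unique(split$test$protein_label)))
  if (length(missing) > 0)
    stopf("proteins missing from one side of the split: %s",
          paste(missing, collapse = ", "))
  invisible(split)
}

#' Sparse compound-disjoint split
#'
#' Assigns whole compounds (never individual measurements) to train or test
#' with a seeded greedy pass that targets `test_fraction` of every protein's
#' measurements in the test side: compounds are visited in random order and
#' go to test while their proteins still have unmet test quota. A repair
#' pass then guarantees every protein appears on both sides; a protein whose
#' measurements all come from a single compound cannot satisfy that
#' invariant and raises an error naming it.
#'
#' @param matrix an `activity_matrix`
#' @param spec a [split_spec()] of kind "sparse"
#' @return an `activity_split` with `train`/`test` pair tables, the
#'   per-compound `assignment` and the `achieved` per-protein test fractions
#' @export
sparse_split <- function(matrix, spec = split_spec("sparse")) {
  d <- matrix$data
  proteins <- matrix$proteins
  single <- vapply(split(d$inchikey, d$protein_label),
                   function(x) length(unique(x)) == 1L, logical(1))
  if (any(single))
    stopf("cannot split: all measurements of protein(s) %s come from one compound",
          paste(names(single)[single], collapse = ", "))
  with_seed(spec$seed, {
    target <- vapply(split(d$pactivity, d$protein_label), length, numeric(1)) *
      spec$test_fraction
    deficit <- target  # remaining test quota per protein
    comp <- split(seq_len(nrow(d)), d$inchikey)
    side <- setNames(rep("train", length(comp)), names(comp))
    for (cid in sample(names(comp))) {
      prots <- d$protein_label[comp[[cid]]]
      if (sum(deficit[prots] - 0.5) > 0) {
        side[cid] <- "test"
        deficit[prots] <- deficit[prots] - 1
      }
    }
    # repair: every protein must occur on both sides
    for (p in proteins) {
      rows <- d$protein_label == p
      comps <- unique(d$inchikey[rows])
      on_test <- side[comps] == "test"
      if (!any(on_test) || !all(on_test)) {
        if (!any(on_test)) {
          cand <- comps[order(vapply(comp[comps], length, integer(1)))]
          side[cand[1]] <- "test"
        }
        next
      }
      # all on test: move the smallest compound back to train
      cand <- comps[order(vapply(comp[comps], length, integer(1)))]
      side[cand[1]] <- "train"
    }
    test_rows <- d$inchikey %in% names(side)[side == "test"]
    ach <- vapply(split(seq_len(nrow(d)), d$protein_label),
                  function(ix) mean(test_rows[ix]), numeric(1))
    sp <- .split_obj(d[!test_rows, , drop = FALSE],
                     d[test_rows, , drop = FALSE], side,
                     achieved = data.frame(protein_label = names(ach),
                                           test_fraction = as.numeric(ach),
                                           stringsAsFactors = FALSE))
    .check_split(sp, proteins)
  })
}

#' Dense chemogenomic split
#'
#' Compounds measured on at least `min_kinases_dense` proteins form the
#' dense test panel; all remaining compounds train. Deterministic.
#'
#' @param matrix an `activity_matrix`
#' @param spec a [split_spec()] of kind "dense"
#' @return an `activity_split`
#' @export
dense_split <- function(matrix, spec = split_spec("dense")) {
  d <- matrix$data
  nprot <- vapply(split(d$protein_label, d$inchikey),
                  function(x) length(unique(x)), integer(1))
  panel <- names(nprot)[nprot >= spec$min_kinases_dense]
  if (length(panel) == 0)
    stopf("no compound is measured on >= %d proteins", spec$min_kinases_dense)
  test_rows <- d$inchikey %in% panel
  side <- setNames(ifelse(names(nprot) %in% panel, "test", "train"),
                   names(nprot))
  sp <- .split_obj(d[!test_rows, , drop = FALSE],
                   d[test_rows, , drop = FALSE], side)
  .check_split(sp, matrix$proteins)
}

#' Model specification for the potency regressors
#'
#' The six benchmark models share 1024-bit Morgan compound fingerprints and
#' differ in the protein feature block: model 1 none, 2 one-hot, 3 whole-
#' sequence z-scales, 4 per-residue z-scales, 5 ProtVec, 6 the structural
#' CNN fingerprint.
#'
#' @param model_id integer 1..6
#' @param n_trees random-forest size (default 100)
#' @param seed RNG seed for the forest
#' @return object of class `model_spec`
#' @export
model_spec <- function(model_id, n_trees = 100L, seed = 1L) {
  stopifnot(model_id %in% 1:6, n_trees >= 1)
  sets <- c("none", "onehot", "zscales_whole", "zscales_residue", "protvec", "3dfp")
  structure(list(model_id = as.integer(model_id),
                 protein_set = sets[model_id],
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "model_spec")
}

#' Assemble the design matrix for one split side
#'
#' Each row is the concatenation of the compound's Morgan fingerprint and
#' the protein feature vector of the pair's protein (absent for model 1),
#' and `y` is the pair's pActivity.
#'
#' @param pairs data frame with inchikey, protein_label, pactivity
#' @param fps 0/1 matrix of Morgan fingerprints keyed by InChIKey rowname
#' @param prot_feats protein feature matrix keyed by label rowname, or NULL
#'   for the compound-only model
#' @return list with `X` and `y`
#' @export
assemble_design <- function(pairs, fps, prot_feats = NULL) {
  mi <- match(pairs$inchikey, rownames(fps))
  if (anyNA(mi))
    stopf("missing fingerprints for: %s",
          paste(unique(pairs$inchikey[is.na(mi)])[1:5], collapse = ", "))
  X <- fps[mi, , drop = FALSE]
  if (!is.null(prot_feats)) {
    pi <- match(pairs$protein_label, rownames(prot_feats))
    if (anyNA(pi))
      stopf("missing protein features for: %s",
            paste(unique(pairs$protein_label[is.na(pi)]), collapse = ", "))
    X <- cbind(X, prot_feats[pi, , drop = FALSE])
  }
  colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  rownames(X) <- NULL
  list(X = X, y = pairs$pactivity)
}

#' Train the random-forest potency regressor
#'
#' 100 trees by default with the forest library's remaining settings left at
#' their defaults, seeded for reproducibility.
#'
#' @param X design matrix
#' @param y pActivity vector
#' @param spec a [model_spec()]
#' @return a fitted `ranger` regressor
#' @export
train_rf <- function(X, y, spec = model_spec(1)) {
  if (nrow(X) < 10) stopf("need at least 10 training rows (got %d)", nrow(X))
  if (length(unique(y)) == 1L)
    warning("constant response: the forest will predict a constant",
            call. = FALSE)
  ranger::ranger(x = X, y = y, num.trees = spec$n_trees, seed = spec$seed,
                 num.threads = 1)
}

#' Predict potencies from a fitted forest
#'
#' @param fit a `ranger` fit from [train_rf()]
#' @param X design matrix
#' @return numeric predictions
#' @export
predict_rf <- function(fit, X) {
  predict(fit, data = X, num.threads = 1)$predictions
}

.rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

.r2 <- function(pred, obs) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

.band_labels <- c("0-0.5", "0.5-1", "1-1.5", ">1.5")

#' Regression metric battery
#'
#' RMSE, R-squared, the fraction of predictions within 0-0.5, 0.5-1, 1-1.5
#' and >1.5 log units of the observation (boundaries closed on the left
#' band: an absolute error of exactly 0.5 falls in "0-0.5"), and RMSE per
#' Tanimoto-similarity bin when a bin assignment is supplied.
#'
#' @param pred,obs equal-length prediction and observation vectors
#' @param bins optional factor (levels = the five Tanimoto bins) giving each
#'   test pair's compound similarity bin
#' @return list with `rmse`, `r2`, `band_fractions`, `rmse_per_bin`, `n`
#' @export
regression_metrics <- function(pred, obs, bins = NULL) {
  if (length(pred) != length(obs))
    stopf("pred and obs lengths differ (%d vs %d)", length(pred), length(obs))
  if (length(pred) == 0) stopf("empty input")
  err <- abs(pred - obs)
  band <- cut(err, breaks = c(0, 0.5, 1, 1.5, Inf), labels = .band_labels,
              include.lowest = TRUE, right = TRUE)
  bf <- as.numeric(table(band)) / length(err)
  names(bf) <- .band_labels
  rpb <- NULL
  if (!is.null(bins)) {
    stopifnot(length(bins) == length(pred))
    rpb <- vapply(levels(bins), function(b) {
      ix <- which(bins == b)
      if (length(ix) == 0) NA_real_ else .rmse(pred[ix], obs[ix])
    }, numeric(1))
  }
  list(rmse = .rmse(pred, obs), r2 = .r2(pred, obs), band_fractions = bf,
       rmse_per_bin = rpb, n = length(pred))
}

.confusion <- function(pred, obs, threshold) {
  pp <- pred >= threshold
  op <- obs >= threshold
  tp <- sum(pp & op); fp <- sum(pp & !op)
  fn <- sum(!pp & op); tn <- sum(!pp & !op)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  ba <- if (!is.na(tpr) && !is.na(tnr)) (tpr + tnr) / 2 else NA_real_
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn, tpr = tpr, fpr = fpr,
             tnr = tnr, balanced_accuracy = ba, f1 = f1)
}

#' Classification metrics at the potency threshold
#'
#' Binarizes observed and predicted pActivity at the threshold (positive
#' means potency greater than or equal to 7.0 by default) and reports the
#' confusion counts, TPR, FPR, balanced accuracy and F1 — overall or per
#' group (per kinase, per compound). Groups lacking positives or negatives
#' report the affected rate as NA.
#'
#' @param pred,obs equal-length vectors
#' @param threshold potency threshold (default 7)
#' @param group optional grouping vector (e.g. kinase or compound of each
#'   pair) for per-group tables
#' @return a one-row data frame, or one row per group when `group` is given
#' @export
classification_metrics <- function(pred, obs, threshold = 7, group = NULL) {
  if (length(pred) != length(obs))
    stopf("pred and obs lengths differ")
  if (is.null(group)) return(.confusion(pred, obs, threshold))
  stopifnot(length(group) == length(pred))
  res <- do.call(rbind, lapply(split(seq_along(pred), group), function(ix)
    .confusion(pred[ix], obs[ix], threshold)))
  cbind(data.frame(group = rownames(res), stringsAsFactors = FALSE,
                   row.names = NULL), res)
}

#' Per-kinase median-baseline control
#'
#' Predicts every test pair of a kinase with the training-set median potency
#' of that kinase (a constant per kinase) and reports per-kinase RMSE and
#' R-squared plus their medians across kinases — the floor any informative
#' model must beat.
#'
#' @param train_pairs,test_pairs pair tables (inchikey, protein_label,
#'   pactivity)
#' @return list with `per_kinase` (data frame), `median_rmse`, `median_r2`,
#'   and the test-set `predictions`
#' @export
median_baseline <- function(train_pairs, test_pairs) {
  med <- vapply(split(train_pairs$pactivity, train_pairs$protein_label),
                median, numeric(1))
  missing <- setdiff(unique(test_pairs$protein_label), names(med))
  if (length(missing) > 0)
    stopf("kinases absent from the training side: %s",
          paste(missing, collapse = ", "))
  pred <- med[test_pairs$protein_label]
  per <- do.call(rbind, lapply(split(seq_len(nrow(test_pairs)),
                                     test_pairs$protein_label), function(ix) {
    data.frame(rmse = .rmse(pred[ix], test_pairs$pactivity[ix]),
               r2 = .r2(pred[ix], test_pairs$pactivity[ix]),
               n = length(ix))
  }))
  per <- cbind(data.frame(protein_label = rownames(per), row.names = NULL,
                          stringsAsFactors = FALSE), per)
  list(per_kinase = per,
       median_rmse = median(per$rmse),
       median_r2 = median(per$r2, na.rm = TRUE),
       predictions = as.numeric(pred))
}

#' Skewness and excess kurtosis of a potency distribution
#'
#' Reports the bias-corrected sample skewness G1 (the "unbiased" skew) and
#' the bias-corrected Fisher excess kurtosis G2, alongside the plain
#' population-moment skewness. Undefined cases (n below 3 for skewness, n
#' below 4 for kurtosis, or zero variance) are returned as NA.
#'
#' @param values numeric sample (e.g. all pActivities of one kinase)
#' @return list with `skewness` (G1), `skewness_population`,
#'   `excess_kurtosis` (G2) and `n`
#' @export
distribution_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  out <- list(skewness = NA_real_, skewness_population = NA_real_,
              excess_kurtosis = NA_real_, n = n)
  if (n < 3 || m2 == 0) return(out)
  g1 <- mean((values - m)^3) / m2^1.5
  out$skewness_population <- g1
  out$skewness <- g1 * sqrt(n * (n - 1)) / (n - 2)
  if (n >= 4) {
    g2 <- mean((values - m)^4) / m2^2 - 3
    out$excess_kurtosis <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  out
}

.protein_sets <- c("1" = "none", "2" = "onehot", "3" = "zscales_whole",
                   "4" = "zscales_residue", "5" = "protvec", "6" = "3dfp")

#' Run the full model benchmark
#'
#' Trains and evaluates the requested models on the requested splits and
#' assembles one metric report per (model, split): RMSE, R-squared, RMSE per
#' Tanimoto-similarity bin, error-band fractions, the confusion battery at
#' the potency threshold and the median-baseline control. Optionally writes
#' the metric table, per-kinase tables and the dense observed-vs-predicted
#' heatmap (TSV + PNG) to `out_dir`.
#'
#' @param matrix an `activity_matrix`
#' @param fps Morgan fingerprint matrix (rownames = InChIKeys)
#' @param protein_features named list of protein feature matrices (elements
#'   "onehot", "zscales_whole", "zscales_residue", "protvec", "3dfp"; only
#'   those needed by `model_ids` are required)
#' @param splits named list of `activity_split` objects (e.g. sparse, dense)
#' @param model_ids models to run (subset of 1..6)
#' @param n_trees forest size (default 100)
#' @param seed seed passed to every forest
#' @param threshold potency threshold for the confusion battery (default 7)
#' @param out_dir optional output directory for TSV/PNG reports
#' @return list with `metrics` (one row per model x split) and `reports`
#'   (the full per-run metric objects)
#' @export
run_benchmark <- function(matrix, fps, protein_features, splits,
                          model_ids = 1:6, n_trees = 100L, seed = 1L,
                          threshold = 7, out_dir = NULL) {
  rows <- list(); reports <- list()
  for (sname in names(splits)) {
    sp <- splits[[sname]]
    # per-test-compound Tanimoto bin against the training compounds
    train_fps <- fps[rownames(fps) %in% unique(sp$train$inchikey), , drop = FALSE]
    test_cmp <- unique(sp$test$inchikey)
    sim <- vapply(test_cmp, function(ck)
      max_train_similarity(fps[ck, ], train_fps)$max_similarity, numeric(1))
    bins <- tanimoto_bin(sim)[match(sp$test$inchikey, test_cmp)]
    base <- median_baseline(sp$train, sp$test)
    for (mid in model_ids) {
      ms <- model_spec(mid, n_trees = n_trees, seed = seed)
      pf <- if (ms$protein_set == "none") NULL else {
        if (is.null(protein_features[[ms$protein_set]]))
          stopf("protein feature set '%s' not supplied", ms$protein_set)
        protein_features[[ms$protein_set]]
      }
      tr <- assemble_design(sp$train, fps, pf)
      te <- assemble_design(sp$test, fps, pf)
      fit <- train_rf(tr$X, tr$y, ms)
      pred <- predict_rf(fit, te$X)
      reg <- regression_metrics(pred, te$y, bins)
      cls <- classification_metrics(pred, te$y, threshold)
      cls_k <- classification_metrics(pred, te$y, threshold,
                                      group = sp$test$protein_label)
      cls_c <- classification_metrics(pred, te$y, threshold,
                                      group = sp$test$inchikey)
      per_k <- do.call(rbind, lapply(split(seq_along(pred),
                                           sp$test$protein_label), function(ix)
        data.frame(rmse = .rmse(pred[ix], te$y[ix]),
                   r2 = .r2(pred[ix], te$y[ix]), n = length(ix))))
      per_k <- cbind(data.frame(protein_label = rownames(per_k),
                                row.names = NULL, stringsAsFactors = FALSE),
                     per_k)
      reports[[paste(sname, mid, sep = ".")]] <- list(
        split = sname, model_id = mid, regression = reg, confusion = cls,
        confusion_per_kinase = cls_k, confusion_per_compound = cls_c,
        per_kinase = per_k, median_baseline = base, predictions = pred,
        observed = te$y, design_width = ncol(tr$X))
      rows[[length(rows) + 1L]] <- data.frame(
        split = sname, model_id = mid, protein_set = ms$protein_set,
        n_test = reg$n, design_width = ncol(tr$X),
        rmse = reg$rmse, r2 = reg$r2,
        rmse_bin_0_0.2 = reg$rmse_per_bin[1],
        rmse_bin_0.2_0.4 = reg$rmse_per_bin[2],
        rmse_bin_0.4_0.6 = reg$rmse_per_bin[3],
        rmse_bin_0.6_0.8 = reg$rmse_per_bin[4],
        rmse_bin_0.8_1.0 = reg$rmse_per_bin[5],
        frac_0_0.5 = reg$band_fractions[1],
        frac_0.5_1 = reg$band_fractions[2],
        frac_1_1.5 = reg$band_fractions[3],
        frac_gt_1.5 = reg$band_fractions[4],
        tpr = cls$tpr, fpr = cls$fpr,
        balanced_accuracy = cls$balanced_accuracy, f1 = cls$f1,
        baseline_median_rmse = base$median_rmse,
        baseline_median_r2 = base$median_r2,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(reports)) {
      write.table(reports[[nm]]$per_kinase,
                  file.path(out_dir, paste0("per_kinase_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("dense" %in% names(splits))
      export_dense_heatmap(splits$dense, reports, threshold, out_dir)
  }
  list(metrics = metrics, reports = reports)
}

#' Export the dense observed-vs-predicted heatmap
#'
#' Writes aligned observed and predicted compound x kinase panels as TSV, a
#' computed overlay mask marking matching true positives/negatives at the
#' threshold, and a PNG rendering.
#'
#' @param dense_split an `activity_split` of the dense panel
#' @param reports report list from [run_benchmark()]
#' @param threshold potency threshold
#' @param out_dir output directory
#' @export
export_dense_heatmap <- function(dense_split, reports, threshold, out_dir) {
  dense_ids <- grep("^dense\\.", names(reports), value = TRUE)
  if (length(dense_ids) == 0) return(invisible(NULL))
  te <- dense_split$test
  cmp <- sort(unique(te$inchikey)); prt <- sort(unique(te$protein_label))
  wide <- function(v) {
    m <- matrix(NA_real_, length(cmp), length(prt), dimnames = list(cmp, prt))
    m[cbind(match(te$inchikey, cmp), match(te$protein_label, prt))] <- v
    m
  }
  obs <- wide(te$pactivity)
  write.table(obs, file.path(out_dir, "dense_observed.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  for (nm in dense_ids) {
    rep <- reports[[nm]]
    pred <- wide(rep$predictions)
    write.table(pred, file.path(out_dir, paste0("dense_predicted_m",
                                                rep$model_id, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
    mask <- matrix("", nrow(obs), ncol(obs), dimnames = dimnames(obs))
    mask[!is.na(obs) & obs >= threshold & pred >= threshold] <- "TP"
    mask[!is.na(obs) & obs < threshold & pred < threshold] <- "TN"
    write.table(mask, file.path(out_dir, paste0("dense_overlay_m",
                                                rep$model_id, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
    grDevices::png(file.path(out_dir, paste0("dense_heatmap_m",
                                             rep$model_id, ".png")),
                   width = 900, height = 450)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    zl <- range(c(obs, pred), na.rm = TRUE)
    graphics::image(t(obs), main = "observed", zlim = zl, axes = FALSE,
                    xlab = "kinase", ylab = "compound")
    graphics::image(t(pred), main = sprintf("predicted (model %d)",
                                            rep$model_id),
                    zlim = zl, axes = FALSE, xlab = "kinase", ylab = "compound")
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(NULL)
}
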