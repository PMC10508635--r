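test_that("shape propagation follows the flatten law 8 * (edge/16)^3", {
  b48 <- build_network(network_config(14, 48, 69))
  expect_equal(b48$flatten_length, 216)
  expect_equal(b48$layers$n_out[b48$layers$layer == "output"], 69)
  expect_equal(build_network(network_config(14, 16, 4))$flatten_length, 8)
  for (edge in c(16, 32, 48, 64))
    expect_equal(build_network(network_config(14, edge, 5))$flatten_length,
                 8 * (edge / 16)^3)
  expect_error(build_network(network_config(14, 48, 69, linear_in = 100)),
               "output")
  expect_error(network_config(14, 40, 69), "multiple of 16")
})

test_that("training reduces test cross-entropy and is deterministic without augmentation", {
  m <- toy_cnn_cached()
  h <- m$loss_history
  expect_equal(nrow(h), 50)
  expect_lt(h$test_loss[nrow(h)], h$test_loss[1])
  # determinism contract: same data, same seed, augmentation off
  m1 <- toy_cnn(epochs = 4, seed = 3, augment = FALSE)
  m2 <- toy_cnn(epochs = 4, seed = 3, augment = FALSE)
  expect_identical(m1$loss_history, m2$loss_history)
  # a label only in the test split is a split error
  man <- toy_manifest()
  bad <- list(train = man$structure_id[man$protein_label != "K03"],
              test = man$structure_id[man$protein_label == "K03"][1])
  expect_error(
    train_classifier(toy_structures(), bad, spec = toy_grid_spec(),
                     config = train_config(max_epochs = 1)),
    "K03")
})

test_that("rotation-augmented training runs and still reduces the test loss", {
  m <- toy_cnn(epochs = 10, seed = 5, augment = TRUE)
  h <- m$loss_history
  expect_equal(nrow(h), 10)
  expect_true(all(is.finite(h$train_loss)))
  expect_lt(h$test_loss[10], h$test_loss[1])
})

test_that("classification returns a softmax over labels for any valid grid", {
  m <- toy_cnn_cached()
  s <- toy_structures()[[1]]
  g <- voxelize_structure(s, spec = toy_grid_spec())
  p <- classify(m, g)
  expect_length(p, 4)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # an all-zero grid is still a valid input
  z <- array(0, c(14, 16, 16, 16))
  pz <- classify(m, z)
  expect_equal(sum(pz), 1, tolerance = 1e-6)
  expect_error(classify(m, array(0, c(14, 32, 32, 32))), "shape")
})

test_that("a trained model recognizes held-out conformers and separates classes", {
  m <- toy_cnn_cached()
  split <- stratified_structure_split(toy_manifest(), 0.25, seed = 7)
  st <- toy_structures()
  names(st) <- vapply(st, function(s) s$structure_id, "")
  hits <- vapply(split$test, function(id) {
    p <- classify(m, voxelize_structure(st[[id]], spec = toy_grid_spec()))
    names(which.max(p)) == st[[id]]$protein_label
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # learning sanity across seeds: high final training accuracy
  accs <- vapply(c(7, 8, 9), function(sd)
    max(tail(toy_cnn(seed = sd)$loss_history$train_acc, 5)),
    numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("fingerprint extraction is deterministic and class-discriminative", {
  m <- toy_cnn_cached()
  st <- toy_structures()
  f1 <- extract_fingerprint(m, st[[1]])
  f2 <- extract_fingerprint(m, st[[1]])
  expect_length(f1$values, build_network(m$config)$flatten_length)
  expect_identical(f1$values, f2$values)
  expect_equal(f1$source_structure_id, st[[1]]$structure_id)
  # within-class fingerprints are more alike than between-class
  fps <- lapply(st, function(s) extract_fingerprint(m, s))
  labs <- vapply(st, function(s) s$protein_label, "")
  sims <- outer(seq_along(fps), seq_along(fps), Vectorize(function(i, j)
    cosine_sim(fps[[i]]$values, fps[[j]]$values)))
  same <- outer(labs, labs, "==")
  diag(same) <- NA
  expect_gt(mean(sims[which(same)], na.rm = TRUE),
            mean(sims[which(!same)], na.rm = TRUE))
})

test_that("fingerprint_table picks one deterministic representative per label", {
  m <- toy_cnn_cached()
  split <- stratified_structure_split(toy_manifest(), 0.25, seed = 7)
  tab <- fingerprint_table(m, toy_structures(), split$test)
  expect_equal(dim(tab), c(4, 8))
  expect_equal(rownames(tab), c("K01", "K02", "K03", "K04"))
  # representative = lexicographically smallest test id of the label
  labs <- toy_manifest()
  for (lab in rownames(tab)) {
    cand <- sort(intersect(split$test,
                           labs$structure_id[labs$protein_label == lab]))
    expect_equal(unname(attr(tab, "source_ids")[rownames(tab) == lab]), cand[1])
  }
  # rerun gives an identical TSV
  t1 <- tempfile(); t2 <- tempfile()
  write_fingerprint_tsv(tab, t1)
  write_fingerprint_tsv(fingerprint_table(m, toy_structures(), split$test), t2)
  expect_identical(readLines(t1), readLines(t2))
  # a label with no test structure is an error naming it
  expect_error(
    fingerprint_table(m, toy_structures(),
                      setdiff(split$test,
                              labs$structure_id[labs$protein_label == "K02"])),
    "K02")
})

test_that("pretrained initialization loads all layers but the output head", {
  m <- toy_cnn_cached()
  ck <- tempfile(fileext = ".rds")
  saveRDS(m$weights, ck)
  split <- stratified_structure_split(toy_manifest(), 0.25, seed = 7)
  warm <- train_classifier(
    toy_structures(), split, spec = toy_grid_spec(),
    config = train_config(max_epochs = 1, seed = 99,
                          rotation_augmentation = FALSE,
                          pretrained_weights_path = ck))
  expect_s3_class(warm, "trained_cnn")
  # an incompatible checkpoint is a load error
  bad <- m$weights
  bad[[1]] <- bad[[1]][, -1]
  saveRDS(bad, ck)
  expect_error(
    train_classifier(toy_structures(), split, spec = toy_grid_spec(),
                     config = train_config(max_epochs = 1,
                                           pretrained_weights_path = ck)),
    "incompatible")
})
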