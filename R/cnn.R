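#' Configuration of the 3D convolutional classifier
#'
#' The fixed architecture is: AvgPool(k2 s2) - Conv(C, 32, k3, pad 1) - ReLU -
#' Conv(32, 32, k1) - ReLU - AvgPool - Conv(32, 64, k3, pad 1) - ReLU -
#' Conv(64, 64, k1) - ReLU - AvgPool - Conv(64, 128, k3, pad 1) - ReLU -
#' AvgPool - Conv(128, 8, k3, pad 1) - Flatten - Linear(flatten, n_classes).
#' No activation sits between the last convolution and the flatten layer.
#' For a cubic input of edge E (divisible by 16) the flatten length is
#' `8 * (E/16)^3`; the 48-voxel default gives 216, the length of the
#' structural fingerprint.
#'
#' @param n_channels input channels (default 14)
#' @param edge voxels per axis of the cubic input (default 48; must be a
#'   multiple of 16)
#' @param n_classes number of output units (one per protein label)
#' @param linear_in input size of the final linear layer; default `NULL`
#'   computes it from the shape propagation. Supplying a wrong value is a
#'   configuration error, caught by [build_network()].
#' @return object of class `network_config`
#' @export
network_config <- function(n_channels = 14L, edge = 48L, n_classes,
                           linear_in = NULL) {
  if (edge %% 16 != 0 || edge <= 0)
    stopf("input edge must be a positive multiple of 16 (got %d)", edge)
  structure(list(n_channels = as.integer(n_channels), edge = as.integer(edge),
                 n_classes = as.integer(n_classes),
                 linear_in = if (is.null(linear_in)) NULL else as.integer(linear_in)),
            class = "network_config")
}

#' Propagate shapes through the network
#'
#' Returns the layer graph with the output shape of every layer and the
#' flatten length, validating that the flatten length matches the input size
#' of the final linear layer.
#'
#' @param config a [network_config()]
#' @return list with `layers` (data frame: layer, out_channels, edge, n_out)
#'   and `flatten_length`
#' @export
build_network <- function(config) {
  C <- config$n_channels; E <- config$edge
  shp <- function(ch, e) c(ch, e)
  rows <- list(c("input", C, E))
  add <- function(name, ch, e) rows[[length(rows) + 1L]] <<- c(name, ch, e)
  E2 <- E / 2; add("unit1_pool", C, E2)
  add("unit1_conv", 32, E2); add("unit1_relu", 32, E2)
  add("unit2_conv", 32, E2); add("unit2_relu", 32, E2)
  E4 <- E2 / 2; add("unit3_pool", 32, E4)
  add("unit3_conv", 64, E4); add("unit3_relu", 64, E4)
  add("unit4_conv", 64, E4); add("unit4_relu", 64, E4)
  E8 <- E4 / 2; add("unit5_pool", 64, E8)
  add("unit5_conv", 128, E8); add("unit5_relu", 128, E8)
  E16 <- E8 / 2; add("unit6_pool", 128, E16)
  add("unit6_conv", 8, E16)
  flat <- 8L * as.integer(E16)^3
  layers <- data.frame(
    layer = vapply(rows, `[`, character(1), 1),
    out_channels = as.integer(vapply(rows, `[`, character(1), 2)),
    edge = as.integer(vapply(rows, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  layers$n_out <- layers$out_channels * layers$edge^3
  layers <- rbind(layers,
                  data.frame(layer = "flatten", out_channels = NA_integer_,
                             edge = NA_integer_, n_out = flat),
                  data.frame(layer = "output", out_channels = NA_integer_,
                             edge = NA_integer_, n_out = config$n_classes))
  lin_in <- config$linear_in %||% flat
  if (lin_in != flat)
    stopf("layer 'output': linear input size %d does not match flatten length %d",
          lin_in, flat)
  list(layers = layers, flatten_length = flat, n_classes = config$n_classes)
}

#' Training configuration
#'
#' SGD with learning rate 0.01 and momentum 0.9 on the cross-entropy loss,
#' mirroring the published optimizer settings.
#'
#' @param learning_rate SGD learning rate (default 0.01)
#' @param momentum SGD momentum (default 0.9)
#' @param batch_size minibatch size (default 32)
#' @param max_epochs training epochs (default 50)
#' @param seed RNG seed for initialization, shuffling and augmentation
#' @param rotation_augmentation voxelize each presentation under a fresh
#'   uniformly random rotation (default TRUE)
#' @param pretrained_weights_path optional checkpoint whose layers (all but
#'   the final linear) initialize the network
#' @return object of class `train_config`
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 32L, max_epochs = 50L, seed = 1L,
                         rotation_augmentation = TRUE,
                         pretrained_weights_path = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 rotation_augmentation = isTRUE(rotation_augmentation),
                 pretrained_weights_path = pretrained_weights_path),
            class = "train_config")
}

# He-normal initialization of all layer parameters
.init_weights <- function(config) {
  C <- config$n_channels
  E16 <- config$edge / 16L
  flat <- 8L * E16^3
  he <- function(nout, nin) matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  list(he(32, C * 27), numeric(32),
       he(32, 32), numeric(32),
       he(64, 32 * 27), numeric(64),
       he(64, 64), numeric(64),
       he(128, 64 * 27), numeric(128),
       he(8, 128 * 27), numeric(8),
       he(config$n_classes, flat), numeric(config$n_classes))
}

.zero_like <- function(w) lapply(w, function(m) {
  if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m))
})

# layer-sequential variance calibration: rescale each layer's weights so its
# activation has unit spread on a calibration batch. Voxel grids are sparse
# and far from unit variance, so a plain He initialization leaves the deep
# stack with vanishing activations and SGD cannot move in the few steps a
# desk-scale corpus affords; calibrating restores healthy gradient flow
# without touching the architecture or the optimizer.
.calibrate_weights <- function(weights, calib_grids, C, N) {
  xb <- unlist(calib_grids, use.names = FALSE)
  B <- length(calib_grids)
  for (i in 1:7) {
    st <- cpp_net_layer_stats(weights, xb, C, N, B)
    if (is.finite(st[i]) && st[i] > 0)
      weights[[2 * i - 1]] <- weights[[2 * i - 1]] / st[i]
  }
  weights
}

.load_pretrained <- function(weights, path) {
  pre <- readRDS(path)
  if (!is.list(pre) || length(pre) < 12)
    stopf("weights file %s is not a recognizable checkpoint", path)
  if (is.list(pre$weights)) pre <- pre$weights  # accept a saved model too
  shape_of <- function(m) {
    # biases travel as either plain vectors or n x 1 matrices
    if (is.matrix(m) && ncol(m) > 1) dim(m) else length(m)
  }
  for (i in 1:12) {  # everything except the final linear layer
    cur <- weights[[i]]; new <- pre[[i]]
    if (!identical(shape_of(cur), shape_of(new)))
      stopf("pretrained layer %d has incompatible shape", i)
    weights[[i]] <- new
  }
  weights
}

.softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# forward a list of grid arrays through the network, in small chunks
.forward_grids <- function(weights, grids, C, N, want_flatten = FALSE,
                           chunk = 8L) {
  n <- length(grids)
  K <- length(weights[[14]])
  scores <- matrix(0, K, n)
  flats <- NULL
  for (i0 in seq(1, n, by = chunk)) {
    ix <- i0:min(i0 + chunk - 1L, n)
    xb <- unlist(grids[ix], use.names = FALSE)
    out <- cpp_net_forward(weights, xb, C, N, length(ix), want_flatten)
    scores[, ix] <- out$scores
    if (want_flatten) {
      if (is.null(flats)) flats <- matrix(0, nrow(out$flatten), n)
      flats[, ix] <- out$flatten
    }
  }
  list(scores = scores, flatten = flats)
}

.ce_loss <- function(scores, labels_idx) {
  # mean cross-entropy of raw score columns against 1-based label indices
  n <- ncol(scores)
  ls <- apply(scores, 2, function(s) {
    m <- max(s); s - m - log(sum(exp(s - m)))
  })
  -mean(ls[cbind(labels_idx, seq_len(n))])
}

#' Train the 3D convolutional classifier
#'
#' Trains the network of [build_network()] to recognize the protein label of
#' each voxelized structure with SGD (cross-entropy loss). When rotation
#' augmentation is on, every presentation of a structure is voxelized under a
#' fresh uniformly random rotation; test grids always use the identity pose.
#' Per-epoch train and test cross-entropy are recorded and the weights with
#' the best test loss are kept.
#'
#' @param structures list of `structure_complex`
#' @param split list with character vectors `train` and `test` of structure
#'   ids; every label must appear in the training side and the test side must
#'   be non-empty
#' @param net a [network_config()]; `n_classes` may be omitted (`NA`) to
#'   derive it from the labels present
#' @param config a [train_config()]
#' @param scheme atom typing scheme
#' @param spec grid specification (its edge must equal `net$edge`)
#' @param verbose print per-epoch losses
#' @return object of class `trained_cnn` with fields `weights`, `config`,
#'   `label_order`, `loss_history`, `scheme`, `spec`
#' @export
train_classifier <- function(structures, split, net = NULL,
                             config = train_config(),
                             scheme = default_atom_typing(),
                             spec = grid_spec(), verbose = FALSE) {
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  labels <- vapply(structures, function(s) s$protein_label, character(1))
  names(structures) <- ids
  if (!all(split$train %in% ids) || !all(split$test %in% ids))
    stopf("split refers to unknown structure ids")
  if (length(split$test) == 0) stopf("test split must be non-empty")
  label_order <- sort(unique(labels[ids %in% c(split$train, split$test)]))
  missing_train <- setdiff(unique(labels[ids %in% split$test]),
                           unique(labels[ids %in% split$train]))
  if (length(missing_train) > 0)
    stopf("labels present only in the test split: %s",
          paste(missing_train, collapse = ", "))
  if (is.null(net))
    net <- network_config(n_channels = scheme$n_channels,
                          edge = spec$n_voxels, n_classes = length(label_order))
  if (net$n_channels != scheme$n_channels || net$edge != spec$n_voxels)
    stopf("network input shape (%d, %d^3) does not match scheme/grid (%d, %d^3)",
          net$n_channels, net$edge, scheme$n_channels, spec$n_voxels)
  build_network(net)  # validates shapes

  typed <- lapply(structures, function(s) assign_atom_types(s, scheme)$typed)
  centers <- lapply(structures, function(s) s$center)
  lab_idx <- match(labels, label_order)
  names(lab_idx) <- ids

  vox <- function(id, transform) {
    as.numeric(cpp_voxelize(
      as.integer(typed[[id]]$channel),
      as.matrix(typed[[id]][, c("x", "y", "z")]),
      as.numeric(typed[[id]]$radius),
      spec$n_channels, spec$n_voxels, spec$spacing,
      centers[[id]], transform$rotation, transform$translation))
  }

  with_seed(config$seed, {
    weights <- .init_weights(net)
    if (!is.null(config$pretrained_weights_path)) {
      weights <- .load_pretrained(weights, config$pretrained_weights_path)
    } else {
      calib_ids <- sort(split$train)[seq_len(min(8, length(split$train)))]
      weights <- .calibrate_weights(
        weights, lapply(calib_ids, vox, transform = identity_transform()),
        net$n_channels, net$edge)
    }
    velocity <- .zero_like(weights)

    idg <- identity_transform()
    test_grids <- lapply(split$test, vox, transform = idg)
    train_idgrids <- if (config$rotation_augmentation) NULL
                     else lapply(split$train, vox, transform = idg)

    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_acc = numeric(0), test_loss = numeric(0),
                       test_acc = numeric(0))
    best <- list(loss = Inf, weights = weights)
    n_train <- length(split$train)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_train)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n_train, by = config$batch_size)) {
        bix <- ord[b0:min(b0 + config$batch_size - 1L, n_train)]
        bids <- split$train[bix]
        grids <- if (config$rotation_augmentation)
          lapply(bids, function(id) vox(id, .random_rotation()))
        else train_idgrids[bix]
        res <- cpp_net_train_batch(
          weights, velocity, unlist(grids, use.names = FALSE),
          lab_idx[bids] - 1L, net$n_channels, net$edge,
          config$learning_rate, config$momentum)
        weights <- res$weights; velocity <- res$velocity
        ep_loss <- ep_loss + res$loss * length(bids)
        ep_correct <- ep_correct + res$correct
      }
      tst <- .forward_grids(weights, test_grids, net$n_channels, net$edge)
      tl <- .ce_loss(tst$scores, lab_idx[split$test])
      ta <- mean(apply(tst$scores, 2, which.max) == lab_idx[split$test])
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = ep_loss / n_train,
        train_acc = ep_correct / n_train, test_loss = tl, test_acc = ta))
      if (tl < best$loss) best <- list(loss = tl, weights = weights)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f (acc %.2f)  test %.4f (acc %.2f)",
                        epoch, ep_loss / n_train, ep_correct / n_train, tl, ta))
    }
    structure(list(weights = best$weights, final_weights = weights,
                   config = net, train_config = config,
                   label_order = label_order, loss_history = hist,
                   scheme = scheme, spec = spec),
              class = "trained_cnn")
  })
}

#' Stratified structure-level train/test split
#'
#' Splits structure ids per protein label at roughly `1 - test_fraction` /
#' `test_fraction` (default 90/10), guaranteeing at least one test structure
#' per label, seeded.
#'
#' @param manifest data frame with structure_id and protein_label
#' @param test_fraction fraction of each label's structures held out
#' @param seed RNG seed
#' @return list with `train` and `test` id vectors
#' @export
stratified_structure_split <- function(manifest, test_fraction = 0.1,
                                       seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    test <- unlist(lapply(split(manifest$structure_id,
                                manifest$protein_label), function(ids) {
      k <- max(1L, round(test_fraction * length(ids)))
      sample(ids, k)
    }), use.names = FALSE)
    list(train = setdiff(manifest$structure_id, test), test = test)
  })
}

#' Classify a voxel grid
#'
#' @param model a `trained_cnn`
#' @param grid a `voxel_grid` (or a raw array of matching shape)
#' @return named probability vector over the model's labels (softmax of the
#'   final-layer scores; sums to 1)
#' @export
classify <- function(model, grid) {
  vals <- if (inherits(grid, "voxel_grid")) grid$values else grid
  expect <- c(model$config$n_channels, rep(model$config$edge, 3))
  if (!identical(as.integer(dim(vals)), as.integer(expect)))
    stopf("grid shape (%s) does not match model input (%s)",
          paste(dim(vals), collapse = ","), paste(expect, collapse = ","))
  out <- cpp_net_forward(model$weights, as.numeric(vals),
                         model$config$n_channels, model$config$edge, 1L, FALSE)
  p <- .softmax(out$scores[, 1])
  names(p) <- model$label_order
  p
}

#' Extract the structural fingerprint of a structure
#'
#' Voxelizes the structure in the identity pose (no rotation, so extraction
#' is deterministic) and returns the activation of the flatten layer: the
#' structural fingerprint (216 values for the default 48-voxel grid).
#'
#' @param model a `trained_cnn`
#' @param structure a `structure_complex`
#' @return object of class `fingerprint3d`: list(protein_label, values,
#'   source_structure_id)
#' @export
extract_fingerprint <- function(model, structure) {
  g <- voxelize_structure(structure, model$scheme, model$spec,
                          identity_transform())
  out <- cpp_net_forward(model$weights, as.numeric(g$values),
                         model$config$n_channels, model$config$edge, 1L, TRUE)
  structure(list(protein_label = structure$protein_label,
                 values = as.numeric(out$flatten[, 1]),
                 source_structure_id = structure$structure_id),
            class = "fingerprint3d")
}

#' Fingerprint table: one structural fingerprint per protein label
#'
#' For every label of the model, the lexicographically smallest test-split
#' structure id provides the representative structure whose flatten-layer
#' activation becomes the label's fingerprint.
#'
#' @param model a `trained_cnn`
#' @param structures list of `structure_complex`
#' @param test_ids character vector of structure ids in the test split
#' @return matrix (labels x flatten length) with attribute `source_ids`
#' @export
fingerprint_table <- function(model, structures, test_ids) {
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  labels <- vapply(structures, function(s) s$protein_label, character(1))
  names(structures) <- ids
  rows <- lapply(model$label_order, function(lab) {
    cand <- sort(ids[labels == lab & ids %in% test_ids])
    if (length(cand) == 0) return(NULL)
    cand[1]
  })
  missing <- model$label_order[vapply(rows, is.null, logical(1))]
  if (length(missing) > 0)
    stopf("labels with no test-split structure: %s",
          paste(missing, collapse = ", "))
  src <- unlist(rows)
  fp <- t(vapply(src, function(id)
    extract_fingerprint(model, structures[[id]])$values,
    numeric(build_network(model$config)$flatten_length)))
  rownames(fp) <- model$label_order
  attr(fp, "source_ids") <- src
  fp
}

#' Write a fingerprint table as TSV
#'
#' Columns: protein_label, source_structure_id, fp_001..fp_NNN.
#'
#' @param fp matrix from [fingerprint_table()]
#' @param path output file
#' @export
write_fingerprint_tsv <- function(fp, path) {
  df <- data.frame(protein_label = rownames(fp),
                   source_structure_id = attr(fp, "source_ids"),
                   fp, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("fp_%03d", seq_len(ncol(fp)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is self-describing: layer shapes, label order and weights.
#'
#' @param model a `trained_cnn`
#' @param path checkpoint file
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_cnn")) stopf("%s is not a trained_cnn checkpoint", path)
  m
}
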