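# Shared fixtures, computed lazily and cached for the whole test run.
# The default fixture (8 classes x 12 structures, 1000 compounds) is the
# study condition every benchmark test runs under; the CNN helpers train on
# it once and are reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

fx_dir <- function() cached("dir", {
  d <- file.path(tempdir(), "pocketfp-fixture")
  dir.create(d, showWarnings = FALSE)
  d
})

fx <- function() cached("fx", generate_fixture(fixture_config(seed = 20), fx_dir()))

fx_std <- function() cached("std", standardize_compounds(fx()$compounds))

fx_fps <- function() cached("fps", morgan_fps(fx_std()))

fx_matrix <- function() cached("matrix", {
  cur <- curate_bioactivities(fx()$records,
                              label_set = rownames(fx()$class_latents))
  res <- resolve_inchikeys(cur$curated, fx_std())
  merge_and_aggregate(res$curated)
})

fx_structures <- function() cached("structures", {
  man <- fx()$manifest
  lapply(seq_len(nrow(man)), function(i)
    parse_structure(man$path[i], man$protein_label[i]))
})

# compound_id -> inchikey map for pair bookkeeping
fx_key_map <- function() cached("key_map", {
  std <- fx_std()
  setNames(std$inchikey, std$compound_id)
})

# protein feature tables on the fixture sequences
fx_protein_features <- function() cached("pfeat", {
  sq <- fx()$sequences
  list(onehot = protein_feature_table(sq, "onehot"),
       zscales_whole = protein_feature_table(sq, "zscales_whole"),
       zscales_residue = protein_feature_table(sq, "zscales_residue"),
       protvec = protein_feature_table(sq, "protvec", embedding = fx()$protvec))
})

# full-size (14 x 48^3) CNN trained on the default fixture structures in the
# identity pose (desk-scale training condition); 15 epochs at batch 4 reach
# ~100% held-out accuracy on the strongly separable synthetic classes while
# keeping the suite fast
fx_cnn <- function() cached("cnn", {
  split <- stratified_structure_split(fx()$manifest, 0.1, seed = 20)
  train_classifier(fx_structures(), split,
                   config = train_config(max_epochs = 15, batch_size = 4,
                                         seed = 20,
                                         rotation_augmentation = FALSE))
})

fx_cnn_split <- function() cached("cnn_split",
  stratified_structure_split(fx()$manifest, 0.1, seed = 20))

fx_fp_table <- function() cached("fp_table",
  fingerprint_table(fx_cnn(), fx_structures(), fx_cnn_split()$test))

# small 16-voxel setup for cheap CNN behaviour tests: 4 classes x 8
# structures, 1 A spacing so the whole cloud fits a 15 A box
toy_grid_spec <- function() grid_spec(16, 1.0, 14)

toy_structures <- function() cached("toy_structures", {
  man <- fx()$manifest
  keep <- man$protein_label %in% c("K01", "K02", "K03", "K04") &
    as.integer(sub(".*_s", "", man$structure_id)) <= 8
  man <- man[keep, , drop = FALSE]
  lapply(seq_len(nrow(man)), function(i)
    parse_structure(man$path[i], man$protein_label[i]))
})

toy_manifest <- function() {
  st <- toy_structures()
  data.frame(structure_id = vapply(st, function(s) s$structure_id, ""),
             protein_label = vapply(st, function(s) s$protein_label, ""),
             stringsAsFactors = FALSE)
}

toy_cnn <- function(epochs = 50, seed = 7, augment = FALSE) {
  split <- stratified_structure_split(toy_manifest(), 0.25, seed = seed)
  train_classifier(toy_structures(), split, spec = toy_grid_spec(),
                   config = train_config(max_epochs = epochs, batch_size = 4,
                                         seed = seed,
                                         rotation_augmentation = augment))
}

toy_cnn_cached <- function() cached("toy_cnn", toy_cnn())

# minimal in-memory structure stub for unit tests
stub_structure <- function(id, label, atoms) {
  structure(list(structure_id = id, protein_label = label, atoms = atoms,
                 center = c(mean(atoms$x), mean(atoms$y), mean(atoms$z))),
            class = "structure_complex")
}

stub_atoms <- function(elements, coords, residue = "GLY", hetero = FALSE) {
  data.frame(element = elements, x = coords[, 1], y = coords[, 2],
             z = coords[, 3], residue_name = residue,
             residue_index = seq_along(elements), chain_id = "A",
             atom_name = paste0(elements, seq_along(elements)),
             is_hetero = hetero, stringsAsFactors = FALSE)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
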