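test_that("parse_structure reads a toy PDB, drops waters, centers on protein atoms", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.100   1.300   0.000  1.00  0.00           C",
    "END"), p)
  s <- parse_structure(p, "K01")
  expect_s3_class(s, "structure_complex")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$center, c(mean(c(0, 1.5, 2.1)), mean(c(0, 0, 1.3)), 0))
  expect_equal(s$structure_id, tools::file_path_sans_ext(basename(p)))

  # waters only -> empty-structure error
  w <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), w)
  expect_error(parse_structure(w, "K01"), "no usable atoms")
  expect_error(parse_structure(p, ""), "non-empty")
})

test_that("fixture PDBs round-trip with the expected atom and chain counts", {
  s <- fx_structures()[[1]]
  expect_gte(nrow(s$atoms), 100)
  expect_setequal(unique(s$atoms$chain_id), c("A", "B"))
})

test_that("deduplication keeps one representative per (label, ligand, conformation)", {
  mk <- function(id, lab) stub_structure(id, lab,
    stub_atoms("C", matrix(0, 1, 3)))
  key <- data.frame(structure_id = c("s2", "s1", "s3", "s4"),
                    ligand_id = c("L1", "L1", "L1", "L2"),
                    conformation_tag = c("in", "in", "out", "in"),
                    stringsAsFactors = FALSE)
  # same label/ligand/"in": one survivor, lexicographically smallest id
  out <- deduplicate_structures(list(mk("s2", "K01"), mk("s1", "K01")), key)
  expect_length(out, 1)
  expect_equal(out[[1]]$structure_id, "s1")
  # "in" vs "out": both kept
  out2 <- deduplicate_structures(list(mk("s1", "K01"), mk("s3", "K01")), key)
  expect_length(out2, 2)
  # different labels, same ligand/tag: both kept
  out3 <- deduplicate_structures(list(mk("s1", "K01"), mk("s2", "K02")), key)
  expect_length(out3, 2)
  # missing from the key = unique
  out4 <- deduplicate_structures(list(mk("s1", "K01"), mk("zz", "K01")), key)
  expect_length(out4, 2)
  expect_identical(deduplicate_structures(list(), key), list())
})

test_that("atom typing maps elements to channels and skips unknown elements", {
  sch <- default_atom_typing()
  expect_equal(sch$n_channels, 14)
  s <- stub_structure("t", "K01", stub_atoms("C", matrix(0, 1, 3)))
  ty <- assign_atom_types(s, sch)
  expect_equal(nrow(ty$typed), 1)
  expect_equal(ty$typed$channel, 0)  # plain aliphatic carbon
  # selenium is not in the default table: skipped, counted, not fatal
  s2 <- stub_structure("t2", "K01",
                       stub_atoms(c("C", "SE"), matrix(0, 2, 3)))
  ty2 <- assign_atom_types(s2, sch)
  expect_equal(nrow(ty2$typed), 1)
  expect_equal(ty2$n_skipped, 1)
  # element histogram matches construction
  elems <- c(rep("C", 5), rep("N", 3), rep("O", 2))
  s3 <- stub_structure("t3", "K01",
                       stub_atoms(elems, matrix(rnorm(30), 10, 3)))
  ty3 <- assign_atom_types(s3, sch)
  ch <- ty3$typed$channel
  expect_equal(sum(ch %in% 0:3), 5)   # carbons
  expect_equal(sum(ch %in% 4:7), 3)   # nitrogens
  expect_equal(sum(ch %in% 8:9), 2)   # oxygens
})

test_that("sampled rotations are orthonormal, deterministic and uniform", {
  r1 <- sample_rotation(11)
  r2 <- sample_rotation(11)
  expect_identical(r1$rotation, r2$rotation)
  R <- r1$rotation
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-8)
  expect_equal(det(R), 1, tolerance = 1e-8)
  # Monte-Carlo uniformity: mean image of a fixed unit vector is ~0
  v <- c(1, 0, 0)
  set.seed(99)
  imgs <- t(vapply(1:10000, function(i)
    as.numeric(pocketfp:::.random_rotation()$rotation %*% v), numeric(3)))
  expect_lt(sqrt(sum(colMeans(imgs)^2)), 0.05)
})

test_that("voxelization deposits the truncated Gaussian kernel correctly", {
  spec <- grid_spec(48, 0.5, 14)
  # empty atom list -> all-zero grid
  empty <- data.frame(channel = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius = numeric(0))
  expect_equal(sum(voxelize(empty, spec, c(0, 0, 0))$values), 0)
  # one atom at the grid center: central voxel has density exp(0) = 1
  one <- data.frame(channel = 0L, x = 0, y = 0, z = 0, radius = 1.9)
  g <- voxelize(one, spec, c(0, 0, 0))
  ix <- which(g$values == max(g$values), arr.ind = TRUE)
  expect_equal(max(g$values), 1)
  expect_equal(unname(ix[1, ]), c(1, 25, 25, 25))  # channel 1, voxel 24 each axis
  expect_true(all(g$values >= 0))
  # kernel value at d = r is exp(-2), at 1.5 r it vanishes
  k <- function(d, r = 1) {
    a <- voxelize(data.frame(channel = 0L, x = d, y = 0, z = 0, radius = r),
                  grid_spec(16, 1, 1), c(0, 0, 0))
    a$values[1, 9, 9, 9]
  }
  expect_equal(k(1), exp(-2), tolerance = 1e-12)
  expect_equal(k(1.5), 0)
  expect_gt(k(1.2), 0)
})

test_that("voxel grids are rotation-near-conserving, local and deterministic", {
  spec <- grid_spec(48, 0.5, 14)
  set.seed(5)
  cloud <- data.frame(channel = sample(0:13, 60, TRUE),
                      x = rnorm(60, sd = 2.5), y = rnorm(60, sd = 2.5),
                      z = rnorm(60, sd = 2.5), radius = 1.8)
  g0 <- voxelize(cloud, spec, c(0, 0, 0))
  sums0 <- apply(g0$values, 1, sum)
  for (seed in 1:3) {
    gr <- voxelize(cloud, spec, c(0, 0, 0), sample_rotation(seed))
    sums <- apply(gr$values, 1, sum)
    rel <- abs(sums - sums0)[sums0 > 0] / sums0[sums0 > 0]
    expect_lt(max(rel), 0.02)
  }
  # locality: atoms beyond box half-edge + 1.5 * max radius change nothing
  far <- rbind(cloud, data.frame(channel = 0L, x = 12 + 1.5 * 1.8 + 0.6,
                                 y = 0, z = 0, radius = 1.8))
  gf <- voxelize(far, spec, c(0, 0, 0))
  expect_identical(gf$values, g0$values)
  # determinism
  expect_identical(voxelize(cloud, spec, c(0, 0, 0))$values, g0$values)
})
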