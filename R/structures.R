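#' Grid specification for voxelization
#'
#' Geometry of the density grid the convolutional network consumes: `n_voxels`
#' points per axis at `spacing` Angstrom, giving a physical edge of
#' `(n_voxels - 1) * spacing` (23.5 A for the 48 x 0.5 default), with one
#' density channel per atom type.
#'
#' @param n_voxels voxels per axis (default 48)
#' @param spacing voxel spacing in Angstrom (default 0.5)
#' @param n_channels number of atom-type channels (default 14)
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(n_voxels = 48L, spacing = 0.5, n_channels = 14L) {
  stopifnot(n_voxels > 0, spacing > 0, n_channels > 0)
  structure(list(n_voxels = as.integer(n_voxels), spacing = spacing,
                 n_channels = as.integer(n_channels)),
            class = "grid_spec")
}

#' Read an atom-typing scheme from TSV
#'
#' The scheme maps (element, context flag) pairs to a channel index and an
#' atomic radius. Context flags are derived from residue and atom names by
#' [assign_atom_types()]; elements with flag `any` match regardless of
#' context.
#'
#' @param path TSV with columns element, context_flag, channel_index,
#'   radius_angstrom
#' @return an object of class `atom_typing`
#' @export
read_atom_typing <- function(path) {
  rules <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "context_flag", "channel_index", "radius_angstrom")
  if (!all(need %in% names(rules)))
    stopf("atom typing table must have columns: %s", paste(need, collapse = ", "))
  rules$element <- toupper(rules$element)
  n_channels <- max(rules$channel_index) + 1L
  if (any(rules$channel_index < 0) || any(rules$radius_angstrom <= 0))
    stopf("invalid atom typing table: negative channel or non-positive radius")
  structure(list(rules = rules, n_channels = n_channels), class = "atom_typing")
}

#' Default 14-channel receptor typing scheme
#'
#' Four carbon types (aliphatic/aromatic x hydrophobic/polar), four nitrogen
#' types (donor, acceptor, donor+acceptor, plain), two oxygen types (acceptor,
#' donor+acceptor), sulfur, phosphorus, halogens and metals.
#'
#' @return an `atom_typing` object with 14 channels
#' @export
default_atom_typing <- function() {
  read_atom_typing(system.file("extdata", "atom_types_default.tsv",
                               package = "pocketfp", mustWork = TRUE))
}

#' Parse a prepared protein structure from a PDB file
#'
#' Reads one pocket-aligned structure, drops hydrogens and waters, and
#' records the centroid of the non-hetero atoms as the default grid center.
#'
#' @param path PDB file
#' @param protein_label class label (protein identity) of the structure
#' @return an object of class `structure_complex` with fields `structure_id`
#'   (file name without extension), `protein_label`, `atoms` (data frame with
#'   element, x, y, z, residue_name, residue_index, chain_id, atom_name,
#'   is_hetero) and `center`
#' @export
parse_structure <- function(path, protein_label) {
  if (!nzchar(protein_label)) stopf("protein_label must be non-empty")
  if (!file.exists(path)) stopf("cannot read structure file: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stopf("failed to parse PDB %s: %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  # fall back to the first letter of the atom name when the element column
  # is blank (common in minimal PDB writers)
  blank <- !nzchar(elem) | is.na(elem)
  elem[blank] <- toupper(substr(trimws(at$elety[blank]), 1, 1))
  keep <- !(elem %in% c("H", "D")) & !(toupper(at$resid) %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0)
    stopf("structure %s contains no usable atoms after removing hydrogens and waters", path)
  atoms <- data.frame(
    element = elem,
    x = at$x, y = at$y, z = at$z,
    residue_name = toupper(at$resid),
    residue_index = at$resno,
    chain_id = as.character(at$chain),
    atom_name = trimws(at$elety),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("structure %s has non-finite coordinates", path)
  prot <- atoms[!atoms$is_hetero, , drop = FALSE]
  if (nrow(prot) == 0)
    stopf("structure %s has no non-hetero protein atoms", path)
  structure(list(
    structure_id = tools::file_path_sans_ext(basename(path)),
    protein_label = protein_label,
    atoms = atoms,
    center = c(mean(prot$x), mean(prot$y), mean(prot$z))),
    class = "structure_complex")
}

#' Remove redundant structures sharing a ligand and conformation
#'
#' Structures of the same protein that carry the identical orthosteric ligand
#' in the same DFG conformation are collapsed to a single representative (the
#' lexicographically smallest `structure_id`). Structures with the same ligand
#' but different conformation tags (e.g. DFG-in vs DFG-out) are all kept, as
#' are structures missing from the ligand key.
#'
#' @param structures list of `structure_complex`
#' @param ligand_key data frame with columns structure_id, ligand_id,
#'   conformation_tag
#' @return the surviving subset of `structures`
#' @export
deduplicate_structures <- function(structures, ligand_key) {
  if (length(structures) == 0) return(structures)
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  labels <- vapply(structures, function(s) s$protein_label, character(1))
  m <- match(ids, ligand_key$structure_id)
  key <- ifelse(is.na(m), paste0("unique::", ids),
                paste(labels, ligand_key$ligand_id[m],
                      ligand_key$conformation_tag[m], sep = "::"))
  keep <- unlist(lapply(split(seq_along(ids), key), function(ix) {
    ix[order(ids[ix])][1]
  }), use.names = FALSE)
  structures[sort(keep)]
}

# context flag heuristics for standard amino-acid residues -------------------

.aromatic_c <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1"))

.polar_side_c <- list(
  SER = "CB", THR = "CB", CYS = "CB", ASP = "CG", GLU = "CD", ASN = "CG",
  GLN = "CD", ARG = "CZ", LYS = "CE", MET = c("CG", "CE"), TYR = "CZ",
  TRP = c("CD1", "CE2"), HIS = c("CG", "CD2", "CE1"))

.atom_context <- function(element, residue_name, atom_name) {
  if (element == "C") {
    arom <- atom_name %in% (.aromatic_c[[residue_name]] %||% character(0))
    polar <- atom_name %in% c("C", "CA") ||
      atom_name %in% (.polar_side_c[[residue_name]] %||% character(0))
    if (arom) {
      if (polar) "aromatic_polar" else "aromatic_hydrophobic"
    } else {
      if (polar) "aliphatic_polar" else "aliphatic_hydrophobic"
    }
  } else if (element == "N") {
    if (residue_name == "HIS" && atom_name %in% c("ND1", "NE2")) "donor_acceptor"
    else if (residue_name == "PRO" && atom_name == "N") "plain"
    else if (atom_name == "N") "donor"
    else if (residue_name %in% c("LYS", "ARG", "TRP", "ASN", "GLN") &&
             atom_name %in% c("NZ", "NE", "NH1", "NH2", "NE1", "ND2", "NE2")) "donor"
    else "acceptor"
  } else if (element == "O") {
    if ((residue_name == "SER" && atom_name == "OG") ||
        (residue_name == "THR" && atom_name == "OG1") ||
        (residue_name == "TYR" && atom_name == "OH")) "donor_acceptor"
    else "acceptor"
  } else {
    "any"
  }
}

#' Assign density channels to the atoms of a structure
#'
#' Maps every non-hetero heavy atom to a (channel, radius) pair under the
#' typing scheme. Context flags (aromaticity, donor/acceptor character) are
#' derived from residue and atom names of the standard amino acids; atoms of
#' elements absent from the scheme are skipped and counted, never fatal.
#' Hetero (ligand/ion) atoms are excluded: the grid is receptor-only.
#'
#' @param structure a `structure_complex`
#' @param scheme an `atom_typing` scheme
#' @return list with `typed` (data frame: channel, x, y, z, radius),
#'   `n_skipped`, and `skipped_elements` (table)
#' @export
assign_atom_types <- function(structure, scheme = default_atom_typing()) {
  atoms <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  rules <- scheme$rules
  n <- nrow(atoms)
  channel <- integer(n)
  radius <- numeric(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    ctx <- .atom_context(atoms$element[i], atoms$residue_name[i], atoms$atom_name[i])
    hit <- which(rules$element == atoms$element[i] &
                 (rules$context_flag == ctx | rules$context_flag == "any"))
    if (length(hit) > 0) {
      channel[i] <- rules$channel_index[hit[1]]
      radius[i] <- rules$radius_angstrom[hit[1]]
      ok[i] <- TRUE
    }
  }
  list(
    typed = data.frame(channel = channel[ok], x = atoms$x[ok], y = atoms$y[ok],
                       z = atoms$z[ok], radius = radius[ok]),
    n_skipped = sum(!ok),
    skipped_elements = table(atoms$element[!ok]))
}

#' Identity rigid transform
#' @return a `rigid_transform` with identity rotation and zero translation
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0)),
            class = "rigid_transform")
}

# draw one rotation uniform on SO(3) from the current RNG stream
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  structure(list(rotation = R, translation = c(0, 0, 0)),
            class = "rigid_transform")
}

#' Sample a uniformly random rotation
#'
#' Unit-quaternion sampling gives a rotation uniform on SO(3); translation is
#' zero. Deterministic for a fixed seed and independent of the caller's RNG
#' state.
#'
#' @param seed integer seed
#' @return a `rigid_transform`
#' @export
sample_rotation <- function(seed) {
  with_seed(seed, .random_rotation())
}

#' Voxelize typed atoms onto a Gaussian density grid
#'
#' Each atom deposits a truncated Gaussian on its channel:
#' `exp(-2 d^2 / r^2)` for `d <= r`, a quartic continuation on
#' `r < d <= 1.5 r` (continuous in value and slope at `r`, zero at `1.5 r`),
#' and zero beyond. Contributions of atoms sum; atoms wholly outside the box
#' contribute nothing. The rigid transform rotates atoms about the grid
#' center before depositing, emulating rotational augmentation.
#'
#' @param typed_atoms data frame with channel, x, y, z, radius (as returned
#'   in `$typed` by [assign_atom_types()])
#' @param spec a [grid_spec()]
#' @param center 3-vector, grid center in Angstrom
#' @param transform a `rigid_transform` (default identity)
#' @return an object of class `voxel_grid` holding the
#'   `n_channels x N x N x N` array plus spec/center/transform metadata
#' @export
voxelize <- function(typed_atoms, spec = grid_spec(), center,
                     transform = identity_transform()) {
  stopifnot(inherits(spec, "grid_spec"), inherits(transform, "rigid_transform"))
  if (abs(det(transform$rotation) - 1) > 1e-8)
    stopf("rotation matrix must have determinant +1")
  vals <- cpp_voxelize(
    as.integer(typed_atoms$channel),
    as.matrix(typed_atoms[, c("x", "y", "z")]),
    as.numeric(typed_atoms$radius),
    spec$n_channels, spec$n_voxels, spec$spacing,
    as.numeric(center), transform$rotation, transform$translation)
  structure(list(values = vals, spec = spec, center = as.numeric(center),
                 transform_applied = transform),
            class = "voxel_grid")
}

#' Voxelize a structure in one call
#'
#' @inheritParams voxelize
#' @param structure a `structure_complex`
#' @param scheme an `atom_typing` scheme
#' @return a `voxel_grid`
#' @export
voxelize_structure <- function(structure, scheme = default_atom_typing(),
                               spec = grid_spec(),
                               transform = identity_transform()) {
  typed <- assign_atom_types(structure, scheme)$typed
  voxelize(typed, spec, structure$center, transform)
}

#' Read a structure manifest
#'
#' @param path CSV with columns structure_id, path, protein_label, ligand_id,
#'   conformation_tag
#' @return data frame
#' @export
read_structure_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "path", "protein_label")
  if (!all(need %in% names(man)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  man
}
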