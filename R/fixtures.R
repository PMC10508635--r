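#' Configuration of the synthetic fixture generator
#'
#' The generator emulates the statistical shape of a curated kinase-inhibitor
#' corpus at desk scale: multi-conformer structures per protein class with
#' class-distinctive atom motifs, 85-residue binding-site sequences sharing a
#' consensus, valid drug-like SMILES, and a bioactivity matrix with a sparse
#' block (most compounds measured on one class, mirroring the ~80\%
#' single-kinase skew of public data) and a dense panel block of compounds
#' measured on essentially every class.
#'
#' @param n_classes protein classes (default 8)
#' @param structures_per_class conformers per class (default 12)
#' @param n_compounds compounds (default 1000)
#' @param panel_size compounds measured on the full class panel (default 30)
#' @param single_target_fraction fraction of non-panel compounds measured on
#'   exactly one class (default 0.8)
#' @param noise_sd measurement noise, pActivity log units (default 0.3)
#' @param inactive_level baseline pActivity of a non-binder (default 5)
#' @param seed RNG seed; everything downstream is deterministic given it
#' @return object of class `fixture_config`
#' @export
fixture_config <- function(n_classes = 8L, structures_per_class = 12L,
                           n_compounds = 1000L, panel_size = 30L,
                           single_target_fraction = 0.8, noise_sd = 0.3,
                           inactive_level = 5.0, seed = 1L) {
  stopifnot(n_classes >= 1, structures_per_class >= 1, n_compounds >= 1,
            panel_size >= 1, panel_size <= n_compounds,
            single_target_fraction >= 0, single_target_fraction <= 1,
            noise_sd >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 structures_per_class = as.integer(structures_per_class),
                 n_compounds = as.integer(n_compounds),
                 panel_size = as.integer(panel_size),
                 single_target_fraction = single_target_fraction,
                 noise_sd = noise_sd, inactive_level = inactive_level,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

.latent_dim <- 8L

.unit <- function(v) v / sqrt(sum(v^2))

.class_labels <- function(n) sprintf("K%02d", seq_len(n))

# one fixed-width PDB ATOM line
.pdb_line <- function(serial, name, resn, chain, resi, x, y, z, element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resi, x, y, z, 1, 0, element)
}

# class-specific motif driven by the class latent vector: atoms of polar /
# heavy elements placed along 8 fixed directions, count and distance set by
# the latent loadings
.motif_atoms <- function(latent) {
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                c(0,0,1), c(0,0,-1), .unit(c(1,1,1)), .unit(c(-1,-1,1)))
  elems <- c("N", "O", "S", "P", "F", "N", "O", "S")
  out <- NULL
  for (d in seq_len(.latent_dim)) {
    k <- 1L + (abs(latent[d]) > 0.5) + (abs(latent[d]) > 1.2)
    r <- 2.5 + 1.5 * sign(latent[d]) * min(abs(latent[d]), 1.5) / 1.5
    for (j in seq_len(k)) {
      out <- rbind(out, data.frame(
        element = elems[d],
        x = dirs[d, 1] * (r + 0.8 * (j - 1)),
        y = dirs[d, 2] * (r + 0.8 * (j - 1)),
        z = dirs[d, 3] * (r + 0.8 * (j - 1)),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Generate synthetic pocket structures, manifest and sequences
#'
#' Every class shares a common scaffold atom cloud (~100 atoms within ~7 A
#' of the origin, so rotated copies stay fully inside the default grid) plus
#' a class-specific motif of 8-24 polar atoms whose elements and placement
#' are driven by the class latent vector. Individual structures add 0.3 A
#' coordinate jitter and occasional element swaps, emulating conformers.
#' The 85-residue sequences share a consensus with class-specific positions
#' (two per latent dimension) so sequence features carry the same class
#' signal, and include a couple of alignment gaps.
#'
#' @param config a [fixture_config()]
#' @param dir output directory (`pdb/` subdir, `manifest.csv`,
#'   `sequences.tsv`)
#' @return list with `manifest`, `sequences`, `class_latents`
#' @export
generate_structures <- function(config, dir) {
  dir.create(file.path(dir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  labels <- .class_labels(config$n_classes)
  with_seed(config$seed + 101L, {
    class_latents <- matrix(rnorm(config$n_classes * .latent_dim),
                            config$n_classes, .latent_dim,
                            dimnames = list(labels, NULL))
    # shared scaffold cloud
    n_scaff <- 100L
    scaff <- data.frame(
      element = sample(c("C", "N", "O"), n_scaff, TRUE, prob = c(0.7, 0.15, 0.15)),
      x = rnorm(n_scaff, sd = 3.5), y = rnorm(n_scaff, sd = 3.5),
      z = rnorm(n_scaff, sd = 3.5), stringsAsFactors = FALSE)
    # clamp inside a 7 A ball so any rotation keeps atoms inside the grid
    rad <- sqrt(scaff$x^2 + scaff$y^2 + scaff$z^2)
    shrink <- pmin(1, 7 / pmax(rad, 1e-6))
    scaff$x <- scaff$x * shrink; scaff$y <- scaff$y * shrink
    scaff$z <- scaff$z * shrink

    # consensus sequence with two gap columns
    alphabet <- c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V")
    consensus <- sample(alphabet, 85, TRUE)
    gap_pos <- sample(85, 2)
    consensus[gap_pos] <- "-"
    var_pos <- sample(setdiff(1:85, gap_pos), 2 * .latent_dim)
    pos_letters <- matrix(c("K","E","F","S","W","G","R","D",
                            "I","T","Y","N","L","Q","V","H"),
                          nrow = 2)

    manifest <- NULL
    seqs <- character(config$n_classes)
    for (ci in seq_len(config$n_classes)) {
      lat <- class_latents[ci, ]
      motif <- .motif_atoms(lat)
      sq <- consensus
      for (d in seq_len(.latent_dim)) {
        pick <- if (lat[d] > 0) 1L else 2L
        sq[var_pos[2 * d - 1]] <- pos_letters[pick, ((d - 1) %% 8) + 1]
        sq[var_pos[2 * d]] <- pos_letters[3L - pick, ((d - 1) %% 8) + 1]
      }
      seqs[ci] <- paste(sq, collapse = "")
      for (si in seq_len(config$structures_per_class)) {
        sid <- sprintf("%s_s%02d", labels[ci], si)
        atoms <- rbind(
          cbind(scaff, chain = "A", stringsAsFactors = FALSE),
          cbind(motif, chain = "B", stringsAsFactors = FALSE))
        # conformer jitter and sporadic isosteric element swaps
        atoms$x <- atoms$x + rnorm(nrow(atoms), sd = 0.3)
        atoms$y <- atoms$y + rnorm(nrow(atoms), sd = 0.3)
        atoms$z <- atoms$z + rnorm(nrow(atoms), sd = 0.3)
        swap <- runif(nrow(atoms)) < 0.03 & atoms$element %in% c("C", "N")
        atoms$element[swap] <- ifelse(atoms$element[swap] == "C", "N", "C")
        lines <- vapply(seq_len(nrow(atoms)), function(i) {
          .pdb_line(i, paste0(atoms$element[i], i %% 100),
                    ifelse(atoms$chain[i] == "A", "GLY", "UNK"),
                    atoms$chain[i], (i - 1) %/% 4 + 1,
                    atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i])
        }, character(1))
        path <- file.path(dir, "pdb", paste0(sid, ".pdb"))
        writeLines(c(lines, "END"), path)
        manifest <- rbind(manifest, data.frame(
          structure_id = sid, path = path, protein_label = labels[ci],
          ligand_id = paste0("LIG_", sid),
          conformation_tag = sample(c("in", "out"), 1),
          stringsAsFactors = FALSE))
      }
    }
    sequences <- data.frame(protein_label = labels, sequence85 = seqs,
                            stringsAsFactors = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.table(sequences, file.path(dir, "sequences.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(manifest = manifest, sequences = sequences,
         class_latents = class_latents)
  })
}

# concatenation-safe SMILES fragment vocabulary (each fragment starts with
# an atom and carries balanced ring closures, so fragments chain by plain
# string concatenation into valid molecules)
.frag_cores <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "c1ccsc1", "C1CCCCC1",
                 "c1ccc2ccccc2c1", "c1ccoc1", "c1ccc2ncccc2c1")
.frag_linkers <- c("C", "CC", "CCC", "C(=O)N", "S(=O)(=O)N", "NC(=O)",
                   "COC", "OCC", "CNC")
.frag_tails <- c("C", "CO", "C(F)(F)F", "C#N", "CN1CCOCC1", "c1ccc(Cl)cc1",
                 "c1ccc(O)cc1", "c1ccc(OC)cc1", "CCN(C)C", "c1ccncc1")

#' Generate synthetic drug-like compounds
#'
#' Assembles SMILES from a fragment vocabulary (ring systems, linkers and
#' decorations) whose molecular weights fall inside the 180-700 g/mol
#' filter window by construction. Each fragment carries a fixed latent
#' contribution; a compound's latent vector is the normalized sum over its
#' fragments, so compounds sharing scaffolds form chemical series that are
#' close both in fingerprint space and in latent pharmacology.
#'
#' @param config a [fixture_config()]
#' @return list with `compounds` (compound_id, smiles, scaffold) and
#'   `compound_latents` (matrix n_compounds x 8)
#' @export
generate_compounds <- function(config) {
  with_seed(config$seed + 202L, {
    vocab <- c(.frag_cores, .frag_linkers, .frag_tails)
    frag_lat <- matrix(rnorm(length(vocab) * .latent_dim), length(vocab),
                       .latent_dim, dimnames = list(vocab, NULL))
    n <- config$n_compounds
    smiles <- character(n); scaffold <- character(n)
    lat <- matrix(0, n, .latent_dim)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      repeat {  # resample assemblies until the SMILES string is unique
        core <- sample(.frag_cores, 1)
        n_ring <- sample(c(1L, 1L, 2L), 1)
        frs <- core
        for (r in seq_len(n_ring))
          frs <- c(frs, sample(.frag_linkers, 1), sample(.frag_cores, 1))
        frs <- c(frs, sample(.frag_linkers, 1), sample(.frag_tails, 1))
        smi <- paste(frs, collapse = "")
        if (is.null(seen[[smi]])) { seen[[smi]] <- TRUE; break }
      }
      smiles[i] <- smi
      scaffold[i] <- core
      lat[i, ] <- .unit(colSums(frag_lat[frs, , drop = FALSE]))
    }
    ids <- sprintf("CPD%05d", seq_len(n))
    rownames(lat) <- ids
    list(compounds = data.frame(compound_id = ids, smiles = smiles,
                                scaffold = scaffold, stringsAsFactors = FALSE),
         compound_latents = lat)
  })
}

#' Generate raw bioactivity records with known ground truth
#'
#' The latent pharmacology links classes and compounds: the true pActivity
#' of a pair is `inactive_level + softplus(6 * <class latent, compound
#' latent> - 1.5)` (both latents unit length; the shift puts the modal
#' potency at the inactive level with a right tail, the shape of a curated
#' kinase corpus), each measurement adds Gaussian
#' noise of `noise_sd` log units and is clipped to `[4, 10]`. Panel
#' compounds are measured on every class (with dropout capped so coverage
#' stays at or above 95\%); the remaining compounds follow the sparse
#' profile (80\% one class, 12\% two, 8\% three to five by default). About
#' 5\% of records are emitted as censored or mid-range percentage types to
#' exercise the curation rejections, plus a few valid threshold records
#' (relation `>=` at 10,000 nM, \%inhibition below 10, \%activity above 90)
#' that curate to pActivity 5. Roughly 2\% carry a low confidence score.
#'
#' @param config a [fixture_config()]
#' @param class_latents matrix from [generate_structures()]
#' @param compound_latents matrix from [generate_compounds()]
#' @return list with `records` (raw bioactivity table with record_id),
#'   `expect` (record_id, expected disposition, reason) and `pair_truth`
#'   (compound_id, protein_label, true pactivity)
#' @export
generate_bioactivities <- function(config, class_latents, compound_latents) {
  labels <- rownames(class_latents)
  n_cls <- nrow(class_latents)
  ids <- rownames(compound_latents)
  with_seed(config$seed + 303L, {
    ulat <- t(apply(class_latents, 1, .unit))
    panel <- ids[seq_len(config$panel_size)]
    rest <- setdiff(ids, panel)
    max_drop <- floor(0.05 * n_cls)

    pairs <- list()
    for (cid in panel) {
      drop_k <- sample(0:max_drop, 1)
      keep <- if (drop_k > 0) sample(labels, n_cls - drop_k) else labels
      pairs[[cid]] <- keep
    }
    n_rest <- length(rest)
    n1 <- round(config$single_target_fraction * n_rest)
    n2 <- round(0.12 * n_rest)
    n_multi <- n_rest - n1 - n2
    counts <- c(rep(1L, n1), rep(2L, n2),
                sample(3:min(5, n_cls), n_multi, TRUE))
    counts <- sample(counts)
    for (j in seq_along(rest)) {
      # sparse-block measurements skew toward the kinases a compound actually
      # hits (compounds are assayed against their intended targets), which is
      # what leaves the dense panel inactive-dominated relative to the
      # sparse corpus
      aff <- softplus(6 * as.numeric(ulat %*% compound_latents[rest[j], ]) - 1.5)
      pairs[[rest[j]]] <- sample(labels, counts[j], prob = exp(1.5 * aff))
    }

    rec <- list()
    truth <- list()
    rid <- 0L
    emit <- function(cid, lab, type, relation, value, units, confidence,
                     source, expect, reason = "") {
      rid <<- rid + 1L
      rec[[rid]] <<- data.frame(
        record_id = sprintf("R%06d", rid), compound_key = cid,
        protein_label = lab, data_type = type, relation = relation,
        value = value, units = units, confidence = confidence,
        source = source, stringsAsFactors = FALSE)
      truth[[rid]] <<- data.frame(record_id = sprintf("R%06d", rid),
                                  expect = expect, reason = reason,
                                  stringsAsFactors = FALSE)
    }

    pt <- list()
    for (cid in names(pairs)) {
      for (lab in pairs[[cid]]) {
        p_true <- config$inactive_level +
          softplus(6 * sum(ulat[lab, ] * compound_latents[cid, ]) - 1.5)
        pt[[length(pt) + 1L]] <- data.frame(
          compound_id = cid, protein_label = lab, pactivity_true = p_true,
          stringsAsFactors = FALSE)
        n_meas <- sample(1:3, 1, prob = c(0.90, 0.07, 0.03))
        for (m in seq_len(n_meas)) {
          p_meas <- min(max(p_true + rnorm(1, sd = config$noise_sd), 4), 10)
          from_chembl <- runif(1) < 0.7
          emit(cid, lab, sample(c("IC50", "Ki", "Kd"), 1), "=",
               10^(9 - p_meas), "nM",
               if (from_chembl) sample(7:9, 1) else NA,
               if (from_chembl) "chembl" else "panel_src",
               "curated", "")
        }
        # rejection-exercise records are extras on top of the valid
        # measurements, so curation never erases a generated pair
        u <- runif(1)
        if (u < 0.02) {
          p_extra <- min(max(p_true + rnorm(1, sd = config$noise_sd), 4), 10)
          emit(cid, lab, "IC50", "=", 10^(9 - p_extra), "nM", 5, "chembl",
               "rejected", "low_confidence")
        } else if (u < 0.045) {
          emit(cid, lab, "Ki", "<", 10000, "nM", 8, "chembl",
               "rejected", "censored_below")
        } else if (u < 0.055) {
          emit(cid, lab, "%inhibition", "=", runif(1, 15, 85), "%", 8,
               "chembl", "rejected", "percent_uninformative")
        } else if (u < 0.06) {
          emit(cid, lab, "IC50", ">=", 10000, "nM", 8, "chembl",
               "curated", "")
        } else if (u < 0.07) {
          emit(cid, lab, "%inhibition", "=", runif(1, 0, 9.9), "%", 8,
               "chembl", "curated", "")
        } else if (u < 0.08) {
          emit(cid, lab, "%activity", "=", runif(1, 90.1, 100), "%", 8,
               "chembl", "curated", "")
        }
      }
    }
    records <- do.call(rbind, rec)
    expect <- do.call(rbind, truth)
    pair_truth <- do.call(rbind, pt)
    list(records = records, expect = expect, pair_truth = pair_truth)
  })
}

#' Generate a deterministic pseudo-random 3-mer embedding table
#'
#' One unit-length 100-vector per 3-mer over the 20-letter amino-acid
#' alphabet (8000 rows), reproducible per seed. Stands in for a learned
#' k-mer embedding in tests and demonstrations.
#'
#' @param seed RNG seed
#' @param dim embedding width (default 100)
#' @return matrix (8000 x dim) with 3-mers as row names
#' @export
generate_protvec_table <- function(seed, dim = 100L) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  kmers <- as.vector(outer(outer(aa, aa, paste0), aa, paste0))
  kmers <- sort(kmers)
  with_seed(seed, {
    m <- matrix(rnorm(length(kmers) * dim), length(kmers), dim)
    m <- m / sqrt(rowSums(m^2))
    rownames(m) <- kmers
    m
  })
}

#' Write a ProtVec embedding matrix as TSV
#' @param m matrix from [generate_protvec_table()]
#' @param path output TSV
#' @export
write_protvec_tsv <- function(m, path) {
  df <- data.frame(kmer = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- sprintf("e%d", seq_len(ncol(m)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate the complete synthetic fixture set
#'
#' Structures + manifest + sequences, compounds, raw bioactivities and the
#' 3-mer embedding table, all deterministic per seed, written to `dir`
#' together with `truth.json` (latents and per-record bookkeeping).
#'
#' @param config a [fixture_config()]
#' @param dir output directory
#' @param protvec_dim embedding width (default 100)
#' @return list with all generated tables and latent matrices
#' @export
generate_fixture <- function(config = fixture_config(), dir,
                             protvec_dim = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  str_out <- generate_structures(config, dir)
  cmp_out <- generate_compounds(config)
  act_out <- generate_bioactivities(config, str_out$class_latents,
                                    cmp_out$compound_latents)
  pv <- generate_protvec_table(config$seed + 404L, protvec_dim)
  write.csv(cmp_out$compounds, file.path(dir, "compounds.csv"),
            row.names = FALSE)
  write.csv(act_out$records, file.path(dir, "raw_bioactivities.csv"),
            row.names = FALSE)
  write_protvec_tsv(pv, file.path(dir, "protvec.tsv"))
  jsonlite::write_json(
    list(config = unclass(config),
         class_latents = str_out$class_latents,
         compound_latents = cmp_out$compound_latents,
         expect = act_out$expect,
         pair_truth = act_out$pair_truth),
    file.path(dir, "truth.json"), digits = NA)
  list(manifest = str_out$manifest, sequences = str_out$sequences,
       class_latents = str_out$class_latents,
       compounds = cmp_out$compounds,
       compound_latents = cmp_out$compound_latents,
       records = act_out$records, expect = act_out$expect,
       pair_truth = act_out$pair_truth, protvec = pv)
}
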