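#' Validate an 85-residue binding-site sequence
#'
#' Binding-site sequences are fixed-length 85-character strings over the 20
#' amino-acid letters plus `-` for an alignment gap.
#'
#' @param seq character scalar
#' @return the sequence, invisibly, after validation
#' @export
check_binding_site_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) != 85)
    stopf("binding-site sequence must have exactly 85 characters (got %d)",
          nchar(seq))
  bad <- setdiff(strsplit(seq, "")[[1]], c(.aa_letters, "-"))
  if (length(bad) > 0)
    stopf("invalid residue characters: %s", paste(unique(bad), collapse = ", "))
  invisible(seq)
}

.aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a z-scale table
#'
#' Five physicochemical descriptors per amino acid from principal-property
#' analysis (the canonical 1998 five-descriptor parameterization ships with
#' the package).
#'
#' @param path TSV with columns letter, z1..z5
#' @return matrix (20 x 5) with amino-acid letters as row names
#' @export
read_zscales <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("letter", paste0("z", 1:5)) %in% names(tab)))
  m <- as.matrix(tab[, paste0("z", 1:5)])
  rownames(m) <- tab$letter
  if (!setequal(rownames(m), .aa_letters))
    stopf("z-scale table must cover exactly the 20 amino acids")
  if (any(!is.finite(m))) stopf("z-scale table has non-finite values")
  m
}

#' @rdname read_zscales
#' @export
default_zscales <- function() {
  read_zscales(system.file("extdata", "zscales.tsv", package = "pocketfp",
                           mustWork = TRUE))
}

#' One-hot protein encoding
#'
#' @param protein_label label to encode
#' @param label_universe ordered vector of all labels; sorted alphabetically
#'   before encoding
#' @return indicator vector of length `length(label_universe)`
#' @export
one_hot <- function(protein_label, label_universe) {
  universe <- sort(label_universe)
  i <- match(protein_label, universe)
  if (is.na(i)) stopf("label '%s' is not in the universe", protein_label)
  v <- numeric(length(universe))
  v[i] <- 1
  names(v) <- universe
  v
}

#' Whole-sequence z-scale features (length 5)
#'
#' Arithmetic mean of the per-residue z1..z5 over the non-gap positions of
#' the 85-residue binding-site sequence.
#'
#' @param seq 85-character binding-site sequence
#' @param table z-scale matrix from [read_zscales()]
#' @return numeric vector of length 5
#' @export
zscales_whole <- function(seq, table = default_zscales()) {
  check_binding_site_sequence(seq)
  chars <- strsplit(seq, "")[[1]]
  res <- chars[chars != "-"]
  if (length(res) == 0) stopf("all-gap sequence has no z-scale features")
  colMeans(table[res, , drop = FALSE])
}

#' Per-residue z-scale features (length 425)
#'
#' Concatenates the five z-scales position by position (5 x 85 = 425). Gap
#' positions contribute five zeros, keeping the dimension fixed.
#'
#' @inheritParams zscales_whole
#' @return numeric vector of length 425
#' @export
zscales_per_residue <- function(seq, table = default_zscales()) {
  check_binding_site_sequence(seq)
  chars <- strsplit(seq, "")[[1]]
  out <- matrix(0, nrow = 5, ncol = 85)
  hit <- chars != "-"
  out[, hit] <- t(table[chars[hit], , drop = FALSE])
  as.numeric(out)
}

#' Read a ProtVec 3-mer embedding table
#'
#' @param path TSV with columns kmer, e1..e100 (or any fixed embedding width)
#' @return matrix with 3-mers as row names
#' @export
read_protvec_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("kmer" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "kmer"), drop = FALSE])
  rownames(m) <- tab$kmer
  if (any(nchar(rownames(m)) != 3)) stopf("embedding keys must be 3-mers")
  m
}

#' ProtVec sequence embedding (length 100)
#'
#' Gaps are removed; the ungapped sequence is decomposed into its three
#' reading frames of non-overlapping 3-mers, and the returned vector is the
#' sum of the embeddings of all those 3-mers (the original ProtVec
#' construction). 3-mers absent from the table contribute a zero vector; the
#' count of unknown 3-mers is attached as an attribute.
#'
#' @param seq 85-character binding-site sequence
#' @param embedding matrix from [read_protvec_table()]
#' @return numeric vector of the embedding width with attribute `n_unknown`
#' @export
protvec <- function(seq, embedding) {
  check_binding_site_sequence(seq)
  res <- gsub("-", "", seq, fixed = TRUE)
  n <- nchar(res)
  if (n < 3) stopf("fewer than 3 non-gap residues: no 3-mers to embed")
  kmers <- unlist(lapply(0:2, function(frame) {
    if (1 + frame > n - 2) return(character(0))
    starts <- seq(1 + frame, n - 2, by = 3)
    substring(res, starts, starts + 2)
  }))
  hit <- kmers %in% rownames(embedding)
  v <- if (any(hit)) colSums(embedding[kmers[hit], , drop = FALSE])
       else numeric(ncol(embedding))
  attr(v, "n_unknown") <- sum(!hit)
  v
}

#' Build a protein feature table for a set of labels
#'
#' One row per protein label, using the chosen feature set. The `3dfp` set
#' is produced by [fingerprint_table()] instead.
#'
#' @param sequences data frame with columns protein_label, sequence85
#' @param set one of "onehot", "zscales_whole", "zscales_residue", "protvec"
#' @param embedding ProtVec embedding matrix (required for `set = "protvec"`)
#' @param zscale_table z-scale matrix (default the shipped table)
#' @return matrix (labels x feature dimension)
#' @export
protein_feature_table <- function(sequences, set,
                                  embedding = NULL,
                                  zscale_table = default_zscales()) {
  labs <- sort(sequences$protein_label)
  sequences <- sequences[match(labs, sequences$protein_label), , drop = FALSE]
  rows <- switch(set,
    onehot = lapply(labs, one_hot, label_universe = labs),
    zscales_whole = lapply(sequences$sequence85, zscales_whole, table = zscale_table),
    zscales_residue = lapply(sequences$sequence85, zscales_per_residue, table = zscale_table),
    protvec = {
      if (is.null(embedding)) stopf("protvec requires an embedding table")
      lapply(sequences$sequence85, protvec, embedding = embedding)
    },
    stopf("unknown feature set '%s'", set))
  m <- do.call(rbind, lapply(rows, as.numeric))
  rownames(m) <- labs
  m
}
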