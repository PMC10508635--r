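# locate the python interpreter used for the RDKit helper
.find_python <- function() {
  py <- Sys.getenv("POCKETFP_PYTHON", "")
  if (nzchar(py)) return(py)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stopf("no python interpreter found; set POCKETFP_PYTHON")
}

.run_compound_tool <- function(mode, df, extra = character(0)) {
  script <- system.file("python", "compound_tools.py", package = "pocketfp",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  write.csv(df, fin, row.names = FALSE)
  status <- system2(.find_python(), c(shQuote(script), mode, shQuote(fin),
                                      shQuote(fout), extra),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout))
    stopf("compound helper '%s' failed (exit %d)", mode, status)
  read.csv(fout, stringsAsFactors = FALSE, colClasses = "character")
}

#' Standardize compounds from SMILES
#'
#' Per compound: parse, keep the largest organic fragment (salt stripping),
#' canonicalize the tautomer, compute the InChIKey and apply the molecular
#' weight filter (180 to 700 g/mol inclusive). Records that fail any step
#' are retained with a machine-readable `rejection_reason`
#' (`parse_error`, `mw_below_180`, `mw_above_700`, `inchikey_error`);
#' unparseable SMILES never abort the batch.
#'
#' @param compounds data frame with columns `compound_id` and `smiles`
#' @return data frame with columns compound_id, input_smiles,
#'   canonical_smiles, inchikey, mw, passed_filters, rejection_reason
#' @export
standardize_compounds <- function(compounds) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  out <- .run_compound_tool("standardize",
                            compounds[, c("compound_id", "smiles")])
  out$mw <- suppressWarnings(as.numeric(out$mw))
  out$passed_filters <- out$passed_filters == "true"
  out
}

#' Hashed Morgan fingerprints (radius 2, 1024 bits)
#'
#' Computes the circular fingerprint of every compound that passed the
#' standardization filters. Compounds sharing an InChIKey collapse to a
#' single row (duplicate records merge on the key).
#'
#' @param std data frame from [standardize_compounds()]
#' @param bits fingerprint length (default 1024)
#' @param radius Morgan radius (default 2)
#' @return integer 0/1 matrix with one row per unique InChIKey
#' @export
morgan_fps <- function(std, bits = 1024L, radius = 2L) {
  ok <- std[std$passed_filters, , drop = FALSE]
  if (nrow(ok) == 0) stopf("no compounds passed the filters")
  ok <- ok[!duplicated(ok$inchikey), c("inchikey", "canonical_smiles")]
  out <- .run_compound_tool("fps", ok,
                            c("--bits", bits, "--radius", radius))
  m <- t(vapply(out$bits,
                function(s) as.integer(charToRaw(s) == charToRaw("1")),
                integer(bits)))
  rownames(m) <- out$inchikey
  m
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits; two empty fingerprints have
#' similarity 0 by convention.
#'
#' @param a,b 0/1 vectors of equal length
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("fingerprint lengths differ (%d vs %d)",
                                    length(a), length(b))
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

.tanimoto_bin_labels <- c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1.0")

#' Bin a Tanimoto similarity
#'
#' Five equal-width bins, right-open except the last: `[0,0.2)`, `[0.2,0.4)`,
#' `[0.4,0.6)`, `[0.6,0.8)`, `[0.8,1.0]`.
#'
#' @param s similarity values in `[0, 1]`
#' @return factor with the five bin labels
#' @export
tanimoto_bin <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  idx <- pmin(findInterval(s, c(0, 0.2, 0.4, 0.6, 0.8)), 5L)
  factor(.tanimoto_bin_labels[idx], levels = .tanimoto_bin_labels)
}

#' Maximum similarity of a test compound to a training set
#'
#' The largest Tanimoto similarity of the test fingerprint to any training
#' fingerprint, plus its similarity bin. This drives the per-bin RMSE rows
#' of the evaluation battery.
#'
#' @param test_fp 0/1 vector
#' @param train_fps 0/1 matrix, one training fingerprint per row
#' @return list with `max_similarity` and `bin`
#' @export
max_train_similarity <- function(test_fp, train_fps) {
  if (is.null(dim(train_fps)) || nrow(train_fps) == 0)
    stopf("training fingerprint set is empty")
  tf <- test_fp != 0
  tm <- train_fps != 0
  inter <- as.numeric(tm %*% tf)
  uni <- sum(tf) + rowSums(tm) - inter
  s <- ifelse(uni == 0, 0, inter / uni)
  mx <- max(s)
  list(max_similarity = mx, bin = tanimoto_bin(mx))
}
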