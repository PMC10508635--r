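#' Convert a nanomolar activity to pActivity
#'
#' pActivity is the negative decadic log of the molar activity:
#' `9 - log10(value_nM)`. 10,000 nM maps to 5.0 and 1 nM to 9.0.
#'
#' @param value_nM concentration in nM (strictly positive)
#' @return pActivity
#' @export
to_pactivity <- function(value_nM) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0))
    stopf("activity values must be positive and finite")
  9 - log10(value_nM)
}

.allowed_types <- c("IC50", "Ki", "Kd", "Potency", "%inhibition", "%activity")
.percent_types <- c("%inhibition", "%activity")

#' Curate raw bioactivity records
#'
#' Applies the curation rule table, in order, to every record:
#' \enumerate{
#'   \item protein must belong to the configured label set;
#'   \item records carrying a confidence score below `confidence_min` are
#'     removed (records whose source provides no confidence pass);
#'   \item data type must be one of IC50, Ki, Kd, Potency, \%inhibition,
#'     \%activity;
#'   \item records without a value are removed;
#'   \item concentration types in nM: relation `=` converts via
#'     [to_pactivity()]; relation `>=` at exactly 10,000 nM becomes 5.0;
#'     relation `<` is removed (censored); any other relation is removed;
#'   \item percentage types (measured at 10,000 nM): \%inhibition below 10
#'     or \%activity above 90 become 5.0; the rest are removed.
#' }
#' Every record is either curated or rejected with a machine-readable
#' reason; the two counts always reconcile with the input.
#'
#' @param raw data frame with columns compound_key, protein_label, data_type,
#'   relation, value, units, confidence, source
#' @param label_set character vector of accepted protein labels
#' @param confidence_min minimum confidence score (default 7)
#' @return list with `curated` (compound_key, protein_label, pactivity,
#'   source), `rejected` (the failing rows plus `reason`) and `summary`
#'   (reason histogram)
#' @export
curate_bioactivities <- function(raw, label_set, confidence_min = 7) {
  need <- c("compound_key", "protein_label", "data_type", "relation", "value")
  if (!all(need %in% names(raw)))
    stopf("raw bioactivities must have columns: %s", paste(need, collapse = ", "))
  if (is.null(raw$units)) raw$units <- "nM"
  if (is.null(raw$confidence)) raw$confidence <- NA_real_
  if (is.null(raw$source)) raw$source <- "unknown"
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  pact <- rep(NA_real_, n)
  val <- suppressWarnings(as.numeric(raw$value))
  conf <- suppressWarnings(as.numeric(raw$confidence))
  rel <- trimws(raw$relation)

  for (i in seq_len(n)) {
    if (!(raw$protein_label[i] %in% label_set)) { reason[i] <- "unknown_protein"; next }
    if (!is.na(conf[i]) && conf[i] < confidence_min) { reason[i] <- "low_confidence"; next }
    if (!(raw$data_type[i] %in% .allowed_types)) { reason[i] <- "unsupported_type"; next }
    if (is.na(val[i])) { reason[i] <- "missing_value"; next }
    if (raw$data_type[i] %in% .percent_types) {
      if (raw$data_type[i] == "%inhibition" && val[i] < 10) pact[i] <- 5.0
      else if (raw$data_type[i] == "%activity" && val[i] > 90) pact[i] <- 5.0
      else reason[i] <- "percent_uninformative"
      next
    }
    # concentration types
    if (!(toupper(raw$units[i]) %in% c("NM"))) { reason[i] <- "non_nM_units"; next }
    if (rel[i] == "=") {
      if (val[i] > 0) pact[i] <- to_pactivity(val[i])
      else reason[i] <- "nonpositive_value"
    } else if (rel[i] %in% c(">=", "> =")) {
      if (val[i] == 10000) pact[i] <- 5.0
      else reason[i] <- "ge_not_10000"
    } else if (rel[i] == "<") {
      reason[i] <- "censored_below"
    } else {
      reason[i] <- "unsupported_relation"
    }
  }
  ok <- is.na(reason)
  list(
    curated = data.frame(compound_key = raw$compound_key[ok],
                         protein_label = raw$protein_label[ok],
                         pactivity = pact[ok],
                         source = raw$source[ok],
                         stringsAsFactors = FALSE),
    rejected = cbind(raw[!ok, , drop = FALSE],
                     data.frame(reason = reason[!ok], stringsAsFactors = FALSE)),
    summary = as.data.frame(table(reason = reason[!ok]),
                            stringsAsFactors = FALSE))
}

#' Resolve compound keys to InChIKeys
#'
#' Joins curated records to standardized compounds; records whose compound
#' failed the standardization filters are dropped with reason
#' `compound_filtered`.
#'
#' @param curated `curated` data frame from [curate_bioactivities()] whose
#'   `compound_key` matches `std$compound_id`
#' @param std data frame from [standardize_compounds()]
#' @return list with `curated` (inchikey, protein_label, pactivity, source)
#'   and `n_dropped`
#' @export
resolve_inchikeys <- function(curated, std) {
  m <- match(curated$compound_key, std$compound_id)
  okc <- !is.na(m) & std$passed_filters[m]
  list(curated = data.frame(inchikey = std$inchikey[m[okc]],
                            protein_label = curated$protein_label[okc],
                            pactivity = curated$pactivity[okc],
                            source = curated$source[okc],
                            stringsAsFactors = FALSE),
       n_dropped = sum(!okc))
}

#' Merge curated measurements into an activity matrix
#'
#' Exact duplicates (same compound, protein and value, e.g. the same
#' measurement reported by two sources) count once; the remaining repeated
#' measurements of a (compound, protein) pair collapse to their median (the
#' even-count median being the mean of the two middle values).
#'
#' @param curated data frame with columns inchikey, protein_label, pactivity
#' @return object of class `activity_matrix`: list with `data` (one row per
#'   filled cell: inchikey, protein_label, pactivity, n_measurements),
#'   `compounds`, `proteins`
#' @export
merge_and_aggregate <- function(curated) {
  stopifnot(all(c("inchikey", "protein_label", "pactivity") %in% names(curated)))
  dup <- duplicated(curated[, c("inchikey", "protein_label", "pactivity")])
  curated <- curated[!dup, , drop = FALSE]
  key <- paste(curated$inchikey, curated$protein_label, sep = "\r")
  agg <- tapply(curated$pactivity, key, median)
  cnt <- tapply(curated$pactivity, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  data <- data.frame(inchikey = parts[, 1], protein_label = parts[, 2],
                     pactivity = as.numeric(agg),
                     n_measurements = as.integer(cnt),
                     stringsAsFactors = FALSE)
  rownames(data) <- NULL
  data <- data[order(data$inchikey, data$protein_label), , drop = FALSE]
  structure(list(data = data,
                 compounds = sort(unique(data$inchikey)),
                 proteins = sort(unique(data$protein_label))),
            class = "activity_matrix")
}

#' Coverage of an activity matrix
#'
#' Percentage of filled cells out of compounds x proteins, reported with one
#' decimal.
#'
#' @param matrix an `activity_matrix`
#' @param n_compounds,n_proteins optional full matrix dimensions (default:
#'   those observed in the data)
#' @return percent filled, rounded to one decimal
#' @export
matrix_coverage <- function(matrix, n_compounds = NULL, n_proteins = NULL) {
  nr <- n_compounds %||% length(matrix$compounds)
  nc <- n_proteins %||% length(matrix$proteins)
  if (nr == 0 || nc == 0) stopf("degenerate matrix: zero rows or columns")
  round(100 * nrow(matrix$data) / (nr * nc), 1)
}

#' Widen an activity matrix
#'
#' @param matrix an `activity_matrix`
#' @return numeric matrix (compounds x proteins) with NA for missing cells
#' @export
as_wide_matrix <- function(matrix) {
  m <- matrix(NA_real_, length(matrix$compounds), length(matrix$proteins),
              dimnames = list(matrix$compounds, matrix$proteins))
  m[cbind(match(matrix$data$inchikey, matrix$compounds),
          match(matrix$data$protein_label, matrix$proteins))] <-
    matrix$data$pactivity
  m
}
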