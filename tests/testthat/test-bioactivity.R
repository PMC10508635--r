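test_that("pActivity conversion inverts nanomolar concentrations", {
  expect_equal(to_pactivity(10000), 5.0)
  expect_equal(to_pactivity(1), 9.0)
  expect_equal(to_pactivity(100), 7.0)
  expect_error(to_pactivity(0), "positive")
  expect_error(to_pactivity(-5), "positive")
  # strictly decreasing and self-inverse: to_pactivity(10^(9-p)) = p
  p <- seq(3, 11, by = 0.25)
  expect_equal(to_pactivity(10^(9 - p)), p)
  expect_true(all(diff(to_pactivity(c(1, 10, 100, 1000))) < 0))
})

test_that("the curation rule table disposes of a 20-record worked input exactly", {
  rec <- function(type, rel, val, conf = 8, prot = "K01", units = "nM") {
    data.frame(compound_key = "c1", protein_label = prot, data_type = type,
               relation = rel, value = val, units = units, confidence = conf,
               source = "chembl", stringsAsFactors = FALSE)
  }
  raw <- rbind(
    rec("IC50", "=", 50),                    #  1 curated: 9 - log10(50)
    rec("Ki",   "=", 10000),                 #  2 curated: 5.0
    rec("Kd",   "=", 1),                     #  3 curated: 9.0
    rec("Potency", "=", 1000),               #  4 curated: 6.0
    rec("IC50", "=", 200, conf = NA),        #  5 curated: no confidence carried
    rec("IC50", ">=", 10000),                #  6 curated: 5.0
    rec("%inhibition", "=", 5),              #  7 curated: 5.0
    rec("%activity", "=", 95),               #  8 curated: 5.0
    rec("Ki", "<", 100),                     #  9 rejected censored_below
    rec("IC50", "=", 50, prot = "XXX"),      # 10 rejected unknown_protein
    rec("IC50", "=", 50, conf = 6),          # 11 rejected low_confidence
    rec("EC50", "=", 50),                    # 12 rejected unsupported_type
    rec("IC50", "=", NA),                    # 13 rejected missing_value
    rec("IC50", ">", 10000),                 # 14 rejected unsupported_relation
    rec("IC50", "~", 50),                    # 15 rejected unsupported_relation
    rec("IC50", ">=", 5000),                 # 16 rejected ge_not_10000
    rec("%inhibition", "=", 50),             # 17 rejected percent_uninformative
    rec("%activity", "=", 50),               # 18 rejected percent_uninformative
    rec("IC50", "=", -3),                    # 19 rejected nonpositive_value
    rec("IC50", "=", 50, units = "uM"))      # 20 rejected non_nM_units
  out <- curate_bioactivities(raw, label_set = c("K01", "K02"))
  expect_equal(nrow(out$curated), 8)
  expect_equal(out$curated$pactivity,
               c(9 - log10(50), 5, 9, 6, 9 - log10(200), 5, 5, 5))
  expect_equal(nrow(out$rejected), 12)
  expect_equal(out$rejected$reason,
               c("censored_below", "unknown_protein", "low_confidence",
                 "unsupported_type", "missing_value", "unsupported_relation",
                 "unsupported_relation", "ge_not_10000",
                 "percent_uninformative", "percent_uninformative",
                 "nonpositive_value", "non_nM_units"))
  # every record is exactly one of curated / rejected-with-reason
  expect_equal(nrow(out$curated) + nrow(out$rejected), nrow(raw))
  expect_equal(sum(out$summary$Freq), nrow(out$rejected))
})

test_that("boundary percentages are strict: 10% inhibition and 90% activity are removed", {
  raw <- data.frame(compound_key = "c", protein_label = "K01",
                    data_type = c("%inhibition", "%inhibition",
                                  "%activity", "%activity"),
                    relation = "=", value = c(10, 9.99, 90, 90.01),
                    units = "%", confidence = 8, source = "s",
                    stringsAsFactors = FALSE)
  out <- curate_bioactivities(raw, "K01")
  expect_equal(nrow(out$curated), 2)
  expect_true(all(out$curated$pactivity == 5))
  expect_true(all(out$rejected$reason == "percent_uninformative"))
})

test_that("aggregation takes medians after removing exact cross-source duplicates", {
  cur <- function(ik, prot, p, src = "a")
    data.frame(inchikey = ik, protein_label = prot, pactivity = p,
               source = src, stringsAsFactors = FALSE)
  # odd count -> middle value; even count -> mean of middle two
  m1 <- merge_and_aggregate(rbind(cur("A", "K01", 6), cur("A", "K01", 7),
                                  cur("A", "K01", 9)))
  expect_equal(m1$data$pactivity, 7.0)
  expect_equal(m1$data$n_measurements, 3L)
  m2 <- merge_and_aggregate(rbind(cur("A", "K01", 6), cur("A", "K01", 8)))
  expect_equal(m2$data$pactivity, 7.0)
  # identical (pair, value) from two sources counts once
  m3 <- merge_and_aggregate(rbind(cur("A", "K01", 6, "a"),
                                  cur("A", "K01", 6, "b"),
                                  cur("A", "K01", 8, "a")))
  expect_equal(m3$data$pactivity, 7.0)
  expect_equal(m3$data$n_measurements, 2L)
  # idempotent and order-invariant
  set.seed(4)
  many <- rbind(cur(sample(LETTERS[1:5], 40, TRUE),
                    sample(c("K01", "K02"), 40, TRUE),
                    sample(seq(5, 9, 0.5), 40, TRUE)))
  a <- merge_and_aggregate(many)
  b <- merge_and_aggregate(many[sample(nrow(many)), ])
  expect_equal(a$data, b$data)
  redo <- merge_and_aggregate(a$data[, c("inchikey", "protein_label", "pactivity")])
  expect_equal(redo$data$pactivity, a$data$pactivity)
})

test_that("coverage reports the filled-cell percentage with one decimal", {
  stub <- function(n_filled, compounds, proteins) {
    structure(list(data = data.frame(inchikey = rep("x", n_filled),
                                     protein_label = rep("K01", n_filled),
                                     pactivity = rep(5, n_filled)),
                   compounds = compounds, proteins = proteins),
              class = "activity_matrix")
  }
  # the curated corpus scale: 169,723 cells of 82,960 x 69 is 3.0%
  expect_equal(matrix_coverage(stub(169723, "x", "K01"),
                               n_compounds = 82960, n_proteins = 69), 3.0)
  expect_equal(matrix_coverage(stub(4, c("a", "b"), c("K01", "K02"))), 100.0)
  expect_equal(matrix_coverage(stub(1, c("a", "b"), c("K01", "K02"))), 25.0)
  expect_error(matrix_coverage(stub(0, character(0), character(0))), "degenerate")
})

test_that("resolution to InChIKeys drops compounds that failed the filters", {
  std <- data.frame(compound_id = c("c1", "c2"),
                    inchikey = c("IK1", "IK2"),
                    passed_filters = c(TRUE, FALSE),
                    stringsAsFactors = FALSE)
  cur <- data.frame(compound_key = c("c1", "c2", "c3"),
                    protein_label = "K01", pactivity = 6, source = "s",
                    stringsAsFactors = FALSE)
  out <- resolve_inchikeys(cur, std)
  expect_equal(out$curated$inchikey, "IK1")
  expect_equal(out$n_dropped, 2)
})
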