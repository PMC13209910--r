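write_fixture <- function(dir, drug, reaction, demographic) {
  paths <- c(drug = file.path(dir, "drug.csv"),
             reaction = file.path(dir, "reaction.csv"),
             demographic = file.path(dir, "demographic.csv"))
  write.csv(drug, paths["drug"], row.names = FALSE)
  write.csv(reaction, paths["reaction"], row.names = FALSE)
  write.csv(demographic, paths["demographic"], row.names = FALSE)
  paths
}

test_that("read_tables reads fields verbatim and enforces the contract", {
  dir <- withr::local_tempdir()
  drug <- drug_rows(c("A1", "A2", "A3"), "suspected",
                    c("x", "y", "z"), c("20200101", "202001", "2020"))
  reaction <- reaction_rows("A1", "Guillain-Barre syndrome", "20200110")
  demo <- demo_rows("A1", "male", "50s", "61")
  paths <- write_fixture(dir, drug, reaction, demo)

  tb <- sm(read_tables(paths["drug"], paths["reaction"],
                       paths["demographic"]))
  expect_identical(as.data.frame(tb$drug), drug)
  expect_identical(tb$demographic$weight, "61")

  # a missing required column is fatal and names the column
  bad <- drug[, setdiff(names(drug), "involvement")]
  write.csv(bad, paths["drug"], row.names = FALSE)
  expect_error(
    sm(read_tables(paths["drug"], paths["reaction"], paths["demographic"])),
    "involvement")

  # a missing file is fatal and names the table
  expect_error(
    sm(read_tables(file.path(dir, "nope.csv"), paths["reaction"],
                   paths["demographic"])),
    "Drug table")
})

test_that("rows with empty report_id are dropped with a counted warning", {
  dir <- withr::local_tempdir()
  drug <- drug_rows(c("A1", "", "  "), "suspected", "x", "20200101")
  paths <- write_fixture(dir, drug,
                         reaction_rows("A1", "Nausea", "20200110"),
                         demo_rows("A1", "male", "50s"))
  expect_warning(
    tb <- sm(read_tables(paths["drug"], paths["reaction"],
                         paths["demographic"])),
    "2 row")
  expect_equal(nrow(tb$drug), 1)
})

test_that("deduplication removes exact copies only and is idempotent", {
  drug <- drug_rows(rep("A1", 4), "suspected", "x",
                    c("20200101", "20200101", "20200101", "20200202"))
  tb <- make_tables(drug, reaction_rows("A1", "Nausea", "20200110"))
  out <- sm(deduplicate_tables(tb))
  # triplicate collapses to one; the row differing in start_date survives
  expect_equal(nrow(out$drug), 2)
  expect_equal(out$drug$start_date, c("20200101", "20200202"))
  expect_identical(sm(deduplicate_tables(out)), out)
})

test_that("dedup removes exactly the generator-injected duplicates", {
  cfg <- tiny_config(duplicate_row_rate = 0.1)
  tb <- sm(generate_tables(cfg))
  injected <- attr(tb, "bookkeeping")$n_duplicates_injected
  out <- sm(deduplicate_tables(tb))
  removed <- vapply(names(injected), function(nm)
    nrow(tb[[nm]]) - nrow(out[[nm]]), integer(1))
  expect_equal(removed, injected)
})

test_that("suspected-drug filtering keeps only the suspected category", {
  drug <- drug_rows("A1", c("suspected", "concomitant", "interacting"),
                    c("x", "x", "x"), "20200101")
  tb <- make_tables(drug, reaction_rows("A1", "Nausea", "20200110"))
  out <- sm(filter_suspected(tb))
  expect_equal(nrow(out$drug), 1)
  expect_equal(out$drug$involvement, "suspected")
  expect_identical(sm(filter_suspected(out)), out)   # idempotent

  # unrecognized labels are dropped with a warning
  drug2 <- drug_rows("A1", c("suspected", "mystery"), "x", "20200101")
  tb2 <- make_tables(drug2, reaction_rows("A1", "Nausea", "20200110"))
  expect_warning(out2 <- sm(filter_suspected(tb2)), "unrecognized")
  expect_equal(nrow(out2$drug), 1)
})

test_that("suspected fraction matches the configured involvement mix", {
  cfg <- synthetic_config(
    profiles = list(drug_profile("mixed", 6000,
                                 involvement_mix = c(suspected = 0.6,
                                                     concomitant = 0.3,
                                                     interacting = 0.1))),
    n_background_reports = 200, seed = 2, extra_drug_lambda = 0
  )
  tb <- sm(generate_tables(cfg))
  rows <- tb$drug[tb$drug$drug_name == "mixed", ]
  frac <- mean(rows$involvement == "suspected")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(rows)))
  out <- sm(filter_suspected(tb))
  expect_equal(sum(out$drug$drug_name == "mixed"), 6000)
})

test_that("decade codes map to midpoints, totally, onto {5,...,105, NA}", {
  expect_equal(convert_age("100s"), 105)
  expect_equal(convert_age("under 10"), 5)
  expect_true(is.na(convert_age("")))
  expect_equal(
    convert_age(c("10s", "20s", "30s", "40s", "50s", "60s", "70s",
                  "80s", "90s", "100s", "0s")),
    c(15, 25, 35, 45, 55, 65, 75, 85, 95, 105, 5))
  expect_equal(convert_age(" 70S "), 75)   # case/whitespace insensitive
  # total on arbitrary garbage; image is the midpoint set plus NA
  junk <- c("adult", "12", NA, "teens", "10s")
  out <- convert_age(junk)
  expect_length(out, length(junk))
  expect_true(all(is.na(out) | out %in% seq(5, 105, by = 10)))
  # alias table extends the mapping
  expect_equal(convert_age("10歳代",
                           aliases = c("10歳代" = 15)), 15)
})

test_that("merging expands drug x reaction pairs and keeps demographic-less reports", {
  drug <- drug_rows("A1", "suspected", c("x", "y"), "20200101")
  reaction <- reaction_rows("A1", c("Nausea", "Rash", "Pyrexia"), "20200110")
  tb <- make_tables(drug, reaction)
  rec <- sm(merge_tables(tb))
  expect_equal(nrow(rec), 6)           # 2 drugs x 3 reactions
  expect_true(all(rec$gender == "unknown"))
  expect_true(all(is.na(rec$age_years)))
})

test_that("merged record count equals the sum of per-report drug x reaction products", {
  cfg <- tiny_config(duplicate_row_rate = 0)
  tb <- sm(filter_suspected(deduplicate_tables(generate_tables(cfg))))
  rec <- sm(merge_tables(tb))
  nd <- table(tb$drug$report_id)
  nr <- table(tb$reaction$report_id)
  shared <- intersect(names(nd), names(nr))
  expect_equal(nrow(rec),
               sum(as.numeric(nd[shared]) * as.numeric(nr[shared])))
})
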