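test_that("contingency cells partition the report set", {
  rec <- records_df(report_id = c("r1", "r2", "r3", "r4"),
                    drug_name = c("x", "x", "y", "y"),
                    gbs_case = c(TRUE, FALSE, TRUE, FALSE))
  ct <- build_contingency(rec, "x")
  expect_equal(unlist(ct[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 1L, 1L, 1L))

  # a drug absent from the data has a zero drug margin
  ct0 <- build_contingency(rec, "not_there")
  expect_equal(ct0$a + ct0$b, 0L)
  expect_equal(ct0$c + ct0$d, 4L)

  expect_error(build_contingency(rec[0, ], "x"), "empty")
})

test_that("report-unit cells agree with an independent per-report scan", {
  cfg <- tiny_config(duplicate_row_rate = 0)
  rec <- sm(flag_events(merge_tables(filter_suspected(
    deduplicate_tables(generate_tables(cfg))))))
  ct <- build_contingency(rec, "alpha_drug")
  # brute force: loop over reports, re-derive each cell
  a <- b <- c <- d <- 0L
  for (rows in split(rec, rec$report_id)) {
    has_drug <- any(rows$drug_name == "alpha_drug")
    has_event <- any(rows$gbs_case)
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) c <- c + 1L
    else d <- d + 1L
  }
  expect_equal(unlist(ct[c("a", "b", "c", "d")], use.names = FALSE),
               c(a, b, c, d))
  # pair-unit counts rows instead of reports
  ctp <- build_contingency(rec, "alpha_drug", unit = "pair")
  expect_equal(ctp$a + ctp$b + ctp$c + ctp$d, nrow(rec))
})

test_that("Haldane-corrected ROR equals direct arithmetic and handles zeros", {
  r <- ror_corrected(list(a = 10, b = 90, c = 1000, d = 9000))
  expect_equal(r$ror, (10.5 * 9000.5) / (90.5 * 1000.5))
  expect_equal(r$ln_ror, log(r$ror))

  for (k in c(0, 1, 7, 123)) {   # symmetric tables give exactly 1
    expect_identical(ror_corrected(list(a = k, b = k, c = k, d = k))$ror, 1)
  }

  z <- ror_corrected(list(a = 0, b = 100, c = 50, d = 10000))
  expect_true(is.finite(z$ror) && z$ror > 0)
  expect_true(all(is.finite(c(z$ci_low, z$ci_high))))

  set.seed(4)
  for (i in 1:50) {   # random tables including zero cells
    cells <- rpois(4, 5)
    r <- ror_corrected(as.list(setNames(cells, c("a", "b", "c", "d"))))
    expect_equal(r$ror, ((cells[1] + .5) * (cells[4] + .5)) /
                   ((cells[2] + .5) * (cells[3] + .5)))
    expect_true(r$ci_low < r$ror && r$ror < r$ci_high)
  }
})

test_that("the correction vanishes as cells grow", {
  set.seed(9)
  for (i in 1:20) {
    cells <- sample(500:5000, 4)
    corr <- ror_corrected(as.list(setNames(cells, c("a", "b", "c", "d"))))$ror
    raw <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_lt(abs(corr - raw) / raw, 0.01)
  }
})

test_that("Fisher p matches its stated conventions and the reference test", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact_2x2(0, 0, 3, 5), 1)   # zero margin convention
  expect_error(fisher_exact_2x2(1.5, 1, 1, 1), "integer")

  set.seed(2)
  for (i in 1:200) {   # independent oracle: stats::fisher.test
    cells <- c(sample(0:30, 2), sample(0:30, 2))
    mine <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, min(ref, 1), tolerance = 1e-9)
  }
})

test_that("ROR is strictly increasing in a with the other cells fixed", {
  rors <- vapply(0:40, function(a)
    ror_corrected(list(a = a, b = 30, c = 12, d = 200))$ror, numeric(1))
  expect_true(all(diff(rors) > 0))
})

test_that("the signal rule is a strict conjunction with stated boundaries", {
  expect_true(classify_signal(2.0, 0.01, 150))
  expect_false(classify_signal(0.8, 0.001, 5000))
  expect_false(classify_signal(3.0, 0.2, 150))
  expect_false(classify_signal(1.0, 0.01, 150))    # ror exactly 1 fails
  expect_false(classify_signal(2.0, 0.05, 150))    # p exactly 0.05 fails
  expect_true(classify_signal(2.0, 0.01, 100))     # n exactly 100 passes
  expect_false(classify_signal(2.0, 0.01, 99))
})

test_that("screening returns one deterministic row per drug", {
  cfg <- tiny_config(duplicate_row_rate = 0)
  rec <- sm(flag_events(merge_tables(filter_suspected(
    deduplicate_tables(generate_tables(cfg))))))
  s1 <- sm(screen_signals(rec, min_reports = 100))
  s2 <- sm(screen_signals(rec, min_reports = 100))
  expect_identical(s1, s2)
  expect_equal(sort(unique(rec$drug_name)), sort(s1$drug))
  # cell conservation: every drug partitions the same report set
  expect_equal(unique(s1$a + s1$b + s1$c + s1$d),
               length(unique(rec$report_id)))
  # sorted by descending -log10 p, ties by drug name
  ord <- order(-s1$neg_log10_p, s1$drug)
  expect_equal(ord, seq_len(nrow(s1)))
  # the planted signal drug tops the ranking
  expect_true(s1$is_signal[s1$drug == "alpha_drug"])
  expect_false(s1$is_signal[s1$drug == "beta_drug"])

  empty <- sm(screen_signals(rec[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("volcano coordinates are the log identities with the 0.05 reference", {
  res <- data.frame(drug = c("p05", "unit", "e"),
                    ln_ror = log(c(2, 1, exp(1))),
                    neg_log10_p = -log10(c(0.05, 0.5, 0.001)),
                    is_signal = c(TRUE, FALSE, TRUE))
  vc <- volcano_coordinates(res)
  expect_equal(vc$x[vc$drug == "e"], 1)
  expect_equal(vc$x[vc$drug == "unit"], 0)
  expect_equal(vc$y[vc$drug == "p05"], 1.30103, tolerance = 1e-6)
  expect_equal(attr(vc, "reference_line"), -log10(0.05))
  expect_equal(vc$class_label, c("signal", "no signal", "signal"))
})
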