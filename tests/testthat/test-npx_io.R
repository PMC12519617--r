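test_that("read_npx_long parses one record per row and validates input", {
  vals <- rand_mat(2, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_npx_long(make_records(vals, "Inflammation_I"), path)

  rec <- read_npx_long(path, panel_names = "Inflammation_I")
  expect_equal(nrow(rec), 6L)
  expect_type(rec$npx, "double")

  expect_error(read_npx_long(path, panel_names = c("Neurology_I")),
               "Inflammation_I.*allowed panels.*Neurology_I")

  # missing required column is named in the error
  broken <- read.csv(path)
  broken$NPX <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, path2, row.names = FALSE)
  expect_error(read_npx_long(path2, "Inflammation_I"), "NPX")

  # non-numeric NPX reported with a line number
  broken2 <- read.csv(path)
  broken2$NPX[3] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken2, path3, row.names = FALSE)
  expect_error(read_npx_long(path3, "Inflammation_I"), "line.*3")
})

test_that("long-format write/read round-trips the synthetic cohort", {
  cohort <- small_cohort(seed = 3, n = 12, n_proteins = 18)
  rec <- npx_to_long(cohort$npx)
  path <- withr::local_tempfile(fileext = ".csv")
  write_npx_long(rec, path)
  back <- read_npx_long(path, panel_names = unique(rec$panel))
  expect_equal(back$sample_id, rec$sample_id)
  expect_equal(back$protein_symbol, rec$protein_symbol)
  expect_equal(back$qc_pass, rec$qc_pass)
  expect_equal(back$npx, rec$npx, tolerance = 1e-9)

  merged <- merge_panels(back)
  expect_equal(merged$values[rownames(cohort$npx$values), colnames(cohort$npx$values)],
               cohort$npx$values, tolerance = 1e-9)
})

test_that("merge_panels keeps the duplicate with the higher geometric mean", {
  a <- rand_mat(4, 2, seed = 5); colnames(a) <- c("X", "UNIQ_A")
  b <- a[, 1, drop = FALSE] + 1; colnames(b) <- "X"  # higher mean NPX in panel B
  rec <- rbind(make_records(a, "A"), make_records(b, "B"))
  m <- merge_panels(rec)
  expect_equal(sum(colnames(m$values) == "X"), 1L)
  expect_equal(m$assay_meta$panel[m$assay_meta$protein_symbol == "X"], "B")
  expect_equal(m$values[, "X"], b[, "X"])
})

test_that("symbols duplicated across two panels each yield exactly one column", {
  set.seed(8)
  inf <- rand_mat(5, 3, seed = 8); colnames(inf) <- c("TNF", "IL6", "CXCL8")
  neu <- inf + matrix(rnorm(15, sd = 0.5), 5, 3)
  colnames(neu) <- colnames(inf)
  rec <- rbind(make_records(inf, "Inflammation_I"), make_records(neu, "Neurology_I"))
  m <- merge_panels(rec)
  expect_equal(sort(colnames(m$values)), sort(c("TNF", "IL6", "CXCL8")))
  # retained column's mean NPX is at least every discarded duplicate's
  for (sym in colnames(inf)) {
    kept <- mean(m$values[, sym])
    expect_gte(kept + 1e-12, max(mean(inf[, sym]), mean(neu[, sym])) - 1e-12)
  }
})

test_that("exact mean-NPX ties break to the lexicographically first panel", {
  a <- rand_mat(3, 1, seed = 2); colnames(a) <- "X"
  rec <- rbind(make_records(a, "PanelB"), make_records(a, "PanelA"))
  expect_warning(m <- merge_panels(rec), "tie")
  expect_equal(m$assay_meta$panel, "PanelA")
})

test_that("merge_panels is idempotent and validates sample alignment", {
  cohort <- small_cohort(seed = 4, n = 10, n_proteins = 17)
  rec <- npx_to_long(cohort$npx)
  m1 <- merge_panels(rec)
  m2 <- merge_panels(npx_to_long(m1))
  expect_equal(m1$values, m2$values)
  expect_equal(m1$assay_meta, m2$assay_meta)

  expect_error(merge_panels(rec[0, ]), "nonempty")
  rec_bad <- rec[!(rec$sample_id == rec$sample_id[1] & rec$panel == "Inflammation_I"), ]
  expect_error(merge_panels(rec_bad), "mismatch|missing sample")
})

test_that("qc_filter removes flagged proteins and preserves column order", {
  vals <- rand_mat(4, 10)
  qc <- rep(TRUE, 10); qc[c(2, 5, 9)] <- FALSE
  m <- make_npx(vals, qc_pass = qc)
  expect_message(f <- qc_filter(m), "removed 3")
  expect_equal(ncol(f$values), 7L)
  expect_equal(colnames(f$values), colnames(vals)[qc])
  expect_equal(ncol(f$values) + 3L, ncol(m$values))

  # identity when everything passes
  m_ok <- make_npx(vals)
  expect_identical(qc_filter(m_ok)$values, m_ok$values)

  expect_error(qc_filter(make_npx(vals, qc_pass = rep(FALSE, 10))), "All proteins")
})

test_that("a 1466-protein fixture with 19 QC failures retains 1447", {
  p <- 1466
  vals <- matrix(rnorm(3 * p), 3, p,
                 dimnames = list(c("S1", "S2", "S3"), sprintf("P%04d", 1:p)))
  qc <- rep(TRUE, p); qc[sample.int(p, 19)] <- FALSE
  f <- suppressMessages(qc_filter(make_npx(vals, qc_pass = qc)))
  expect_equal(ncol(f$values), 1447L)
})
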