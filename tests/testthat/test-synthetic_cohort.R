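test_that("same seed reproduces clinical and NPX outputs bit-identically", {
  p <- synthetic_params(n_patients = 30, n_proteins = 20, seed = 42)
  c1 <- generate_cohort(p); c2 <- generate_cohort(p)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$npx$values, c2$npx$values)
  # different seed gives a different draw
  c3 <- generate_cohort(synthetic_params(n_patients = 30, n_proteins = 20, seed = 43))
  expect_false(identical(c1$npx$values, c3$npx$values))
})

test_that("clinical tables respect the study's covariate structure", {
  clin <- generate_clinical(synthetic_params(seed = 5))
  expect_equal(nrow(clin), 176L)
  expect_true(all(clin$age >= 18 & clin$age <= 50))
  expect_true(all(clin$n_asm >= 0))
  expect_true(all(clin$seizure_count_2mo >= 0 & clin$seizure_count_2mo <= 98))

  big <- generate_clinical(synthetic_params(n_patients = 10000, seed = 6))
  status <- derive_seizure_status(big$days_since_last_seizure)
  expect_equal(mean(status == "seizure_free"), 0.50, tolerance = 0.02 / 0.50)
  expect_equal(mean(big$gender == "female"), 0.585, tolerance = 0.04)
})

test_that("rho_block = 0 leaves the 12 block proteins uncorrelated", {
  p <- synthetic_params(n_patients = 5000, n_proteins = 20, rho_block = 0,
                        rho_nefl = 0, seed = 9)
  npx <- generate_npx(generate_clinical(p), p)
  r <- cor(npx$values[, pi_proteins()], method = "spearman")
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
})

test_that("planted NEFL-composite coupling and block correlation are recovered at n = 5000", {
  p <- synthetic_params(n_patients = 5000, n_proteins = 20, seed = 10)
  npx <- generate_npx(generate_clinical(p), p)
  z <- zscore(npx, pi_proteins())
  pi <- pi_score(z)
  r <- spearman_test(npx$values[, "NEFL"], pi$pi_score)$r
  expect_equal(r, 0.1, tolerance = 0.05 / 0.1)
  # pairwise block Spearman near the 0.4 target for full-loading proteins
  full <- setdiff(pi_proteins(), c("CASP1", "IL2"))
  rb <- cor(npx$values[, full], method = "spearman")
  expect_equal(mean(rb[upper.tri(rb)]), 0.4, tolerance = 0.05 / 0.4)
})

test_that("the blood-brain barrier shift is planted at its stated size", {
  p <- synthetic_params(n_patients = 5000, n_proteins = 20, seed = 12)
  npx <- generate_npx(generate_clinical(p), p)
  hi <- attr(npx, "latent_high_high"); lo <- attr(npx, "latent_normal_low")
  f <- attr(npx, "latent_factor"); lam <- attr(npx, "loadings")
  expect_gt(sum(hi), 50); expect_gt(sum(lo), 50)
  df_factor <- mean(f[hi]) - mean(f[lo])
  for (sym in c("MMP1", "VEGFA", "HGF")) {
    raw_diff <- mean(npx$values[hi, sym]) - mean(npx$values[lo, sym])
    # raw contrast carries the factor loading on top of the planted shift
    expect_gt(raw_diff, 1.0)
    shift_hat <- raw_diff - lam[[sym]] * df_factor
    expect_equal(shift_hat, 1.0, tolerance = 0.1 / 1.0)
  }
})

test_that("outcome enrichment is detectable at study size and null seeds are calibrated", {
  quadrant_chisq_p <- function(seed, odds) {
    cohort <- generate_cohort(synthetic_params(n_patients = 176, n_proteins = 16,
                                               outcome_odds = odds, seed = seed))
    quad <- cohort_quadrants(cohort)
    clin <- derive_clinical(cohort$clinical)
    tab <- contingency_table(quad$quadrant, clin$epilepsy_status)
    tryCatch(suppressWarnings(chi_square(tab))$p, error = function(e) NA_real_)
  }
  p_alt <- vapply(1:60, quadrant_chisq_p, numeric(1), odds = 4)
  expect_gt(mean(p_alt < 0.05, na.rm = TRUE), 0.5)
  p_null <- vapply(61:160, quadrant_chisq_p, numeric(1), odds = 1)
  rate <- mean(p_null < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.0); expect_lt(rate, 0.12)
})

test_that("fixture tables match their transcription", {
  tabs <- fixture_tables()
  expect_named(tabs, c("seizure_status", "epilepsy_type", "gender",
                       "epilepsy_status", "n_asm"))
  expect_true(all(vapply(tabs, sum, numeric(1)) == 139))
  expect_true(all(vapply(tabs, function(t) all(rowSums(t) == c(14, 19, 50, 56)),
                         logical(1))))
  expect_equal(unname(tabs$epilepsy_status["High-High", ]), c(11L, 5L, 3L))
  expect_equal(unname(colSums(tabs$gender)), c(60L, 79L))
  expect_equal(unname(tabs$seizure_status["Normal-Low", ]), c(18L, 4L, 34L))
  # transcription checksum over all cells, in a fixed serialization order
  all_cells <- unlist(lapply(tabs, function(t) as.vector(t(t))))
  expect_equal(sum(all_cells * seq_along(all_cells)), 21822)
})

test_that("cohort files round-trip through the I/O layer", {
  cohort <- small_cohort(seed = 21, n = 10, n_proteins = 17)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  clin <- read_clinical(paths["clinical"])
  expect_equal(clin$patient_id, cohort$clinical$patient_id)
  expect_equal(clin$n_asm, cohort$clinical$n_asm)
})
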