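#' The 12 pro-inflammatory proteins of the composite score
#'
#' Gene symbols of the twelve plasma proteins whose Z-scores are summed into
#' the composite pro-inflammatory score. All twelve are cytokines/chemokines
#' repeatedly reported as elevated in serum or plasma of people with epilepsy.
#'
#' @return Character vector of length 12.
#' @export
pi_proteins <- function() {
  c("CASP1", "CCL11", "CCL2", "CCL3", "CXCL8", "IFNG",
    "IL17A", "IL18", "IL1B", "IL2", "IL6", "TNF")
}

#' Parameters of the synthetic cohort generator
#'
#' Bundles and validates the knobs of the synthetic-cohort model. Defaults
#' describe the study conditions the pipeline is designed for: 176 adult
#' epilepsy patients, 1447 QC-passing proteins, a positively inter-correlated
#' 12-protein pro-inflammatory block, NEFL weakly coupled to the composite
#' score, and outcome enrichment in the high-NEFL/high-inflammation stratum.
#'
#' @param n_patients Number of patients (default 176).
#' @param n_proteins Number of proteins (default 1447).
#' @param pi_block_symbols The 12 pro-inflammatory block symbols.
#' @param rho_block Target pairwise Spearman correlation within the block
#'   (default 0.4).
#' @param rho_nefl Target Spearman correlation between NEFL and the composite
#'   score (default 0.1).
#' @param bbb_shift NPX shift planted on MMP1/VEGFA/HGF in latent high-high
#'   patients (default +1.0), emulating blood-brain barrier involvement.
#' @param outcome_odds Odds multiplier for recent seizures and multi-ASM use
#'   in the latent high-high stratum (default 4.0).
#' @param qc_fail_symbols Protein symbols to flag as QC failures (default none).
#' @param seed Integer seed; sub-generators derive their own streams from it.
#' @return A validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_patients = 176L,
                             n_proteins = 1447L,
                             pi_block_symbols = pi_proteins(),
                             rho_block = 0.4,
                             rho_nefl = 0.1,
                             bbb_shift = 1.0,
                             outcome_odds = 4.0,
                             qc_fail_symbols = character(0),
                             seed = 1L) {
  stopifnot(n_patients >= 8, n_proteins >= length(pi_block_symbols) + 4,
            length(pi_block_symbols) == 12L,
            rho_block >= 0, rho_block < 1, abs(rho_nefl) < 1,
            outcome_odds > 0, is.numeric(seed), length(seed) == 1L)
  structure(list(
    n_patients = as.integer(n_patients), n_proteins = as.integer(n_proteins),
    pi_block_symbols = pi_block_symbols, rho_block = rho_block,
    rho_nefl = rho_nefl, bbb_shift = bbb_shift, outcome_odds = outcome_odds,
    qc_fail_symbols = qc_fail_symbols, seed = as.integer(seed),
    # study-condition marginals used by the clinical generator
    p_female = 0.585,
    p_epilepsy_type = c(focal = 0.477, generalized = 0.278, unknown = 0.244),
    p_seizure_status = c(recent = 0.40, intermediate = 0.10, seizure_free = 0.50),
    p_asm = c(`0` = 0.090, `1` = 0.557, `2` = 0.233, `3+` = 0.119)
  ), class = "synthetic_params")
}

# derived integer seeds for the independent sub-generators (kept < 2^31)
.sub_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

.sample_days <- function(status, n) {
  # days since last seizure consistent with a seizure-status label;
  # NA encodes "no seizure ever recorded" (treated as seizure-free)
  vapply(seq_len(n), function(i) {
    switch(status[i],
      recent = sample(0:61, 1L),
      intermediate = sample(62:365, 1L),
      seizure_free = if (stats::runif(1) < 0.15) NA_integer_
                     else sample(366:3650, 1L))
  }, integer(1))
}

.sample_asm <- function(n, p_asm) {
  grp <- sample(names(p_asm), n, replace = TRUE, prob = p_asm)
  out <- integer(n)
  out[grp == "0"] <- 0L
  out[grp == "1"] <- 1L
  out[grp == "2"] <- 2L
  plus <- grp == "3+"
  out[plus] <- sample(3:5, sum(plus), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  out
}

#' Generate a synthetic clinical table
#'
#' Draws per-patient covariates matching the study's marginal distributions:
#' ages uniform on 18-50 years, 58.5% female, epilepsy types
#' focal/generalized/unknown at (0.477, 0.278, 0.244), seizure-status
#' marginals (0.40 recent, 0.10 intermediate, 0.50 seizure-free) realised
#' through days-since-last-seizure, a heavy-tailed 2-month seizure count for
#' patients with recent seizures (range capped at 98), and an anti-seizure
#' medication count at (0.090, 0.557, 0.233, 0.119) for 0/1/2/3+.
#'
#' @param params A [synthetic_params()] object.
#' @return Clinical data frame (see [read_clinical()] for columns).
#' @export
generate_clinical <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  n <- params$n_patients
  set.seed(.sub_seed(params$seed, 0L))
  status <- sample(names(params$p_seizure_status), n, replace = TRUE,
                   prob = params$p_seizure_status)
  counts <- integer(n)
  recent <- status == "recent"
  counts[recent] <- pmin(1L + stats::rnbinom(sum(recent), size = 0.6, mu = 5), 98L)
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = sample(18:50, n, replace = TRUE),
    gender = ifelse(stats::runif(n) < params$p_female, "female", "male"),
    epilepsy_type = sample(names(params$p_epilepsy_type), n, replace = TRUE,
                           prob = params$p_epilepsy_type),
    days_since_last_seizure = .sample_days(status, n),
    seizure_count_2mo = counts,
    n_asm = .sample_asm(n, params$p_asm),
    stringsAsFactors = FALSE
  )
}

# Factor loadings for the pro-inflammatory block. A single Gaussian latent
# factor induces the positive inter-correlation; the target pairwise Spearman
# rho_s maps to a latent Pearson rho_p = 2*sin(pi*rho_s/6), so equal loadings
# lambda = sqrt(rho_p) give the block that Spearman at large n. CASP1 and IL2
# get reduced loadings, mirroring their weaker coupling to the rest.
.block_loadings <- function(params) {
  rho_p <- 2 * sin(pi * params$rho_block / 6)
  lam <- rep(sqrt(rho_p), 12L)
  names(lam) <- params$pi_block_symbols
  lam[names(lam) %in% c("CASP1", "IL2")] <- lam[names(lam) %in% c("CASP1", "IL2")] * 0.6
  lam
}

# NEFL loading on the shared factor tuned so that corr(NEFL, PI score) hits
# the Pearson equivalent of the target Spearman rho_nefl. The composite score
# of standardized block columns has variance 12 + (sum lam)^2 - sum lam^2 and
# covariance a * sum(lam) with NEFL = a*f + sqrt(1-a^2)*noise.
.nefl_loading <- function(params) {
  lam <- .block_loadings(params)
  s <- sum(lam)
  if (s == 0) {
    if (abs(params$rho_nefl) > 1e-8) {
      warning("rho_block = 0 leaves no shared factor; NEFL coupling set to 0")
    }
    return(0)
  }
  target_p <- 2 * sin(pi * params$rho_nefl / 6)
  sd_pi <- sqrt(12 + s^2 - sum(lam^2))
  a <- target_p * sd_pi / s
  if (abs(a) >= 1) stop("rho_nefl unattainable with the given rho_block")
  a
}

#' Generate a synthetic NPX matrix
#'
#' Generates a samples x proteins log2-scale NPX matrix with the structure
#' the downstream analysis assumes: the 12 pro-inflammatory block proteins
#' load on a shared Gaussian latent inflammation factor (CASP1 and IL2 with
#' reduced loadings), NEFL is weakly coupled to the factor so that its
#' Spearman correlation with the composite score approximates `rho_nefl`,
#' MMP1/VEGFA/HGF carry a modest factor loading plus a planted `bbb_shift`
#' in latent high-high patients, and 10% of the remaining proteins load
#' weakly on the factor while the rest are independent noise.
#'
#' The latent high-high stratum (NEFL above the 0.5 NPX cutoff and composite
#' score above its 60th percentile) is recorded in the
#' `latent_high_high` attribute; the complementary normal-low stratum in
#' `latent_normal_low`. The shared latent factor and per-protein loadings are
#' recorded in `latent_factor` and `loadings` as generator ground truth for
#' parameter-recovery checks (the planted shift on a protein with a nonzero
#' loading is identified by subtracting the loading-times-factor contrast).
#'
#' @param clinical Clinical table from [generate_clinical()] (row count sets
#'   the sample size).
#' @param params A [synthetic_params()] object.
#' @return An [npx_matrix()] with stratum attributes.
#' @export
generate_npx <- function(clinical, params) {
  stopifnot(inherits(params, "synthetic_params"), nrow(clinical) > 0L)
  n <- nrow(clinical)
  p <- params$n_proteins
  block <- params$pi_block_symbols
  special <- c("NEFL", "MMP1", "VEGFA", "HGF")
  if (any(special %in% block)) stop("pi_block_symbols must not contain ", paste(special, collapse = "/"))
  n_filler <- p - length(block) - length(special)
  symbols <- c(block, special,
               if (n_filler > 0) sprintf("PROT%04d", seq_len(n_filler)))
  if (anyDuplicated(symbols)) stop("protein symbol clash in synthetic set")

  set.seed(.sub_seed(params$seed, 1L))
  f <- stats::rnorm(n)

  lam <- numeric(p); names(lam) <- symbols
  lam[block] <- .block_loadings(params)
  a_nefl <- .nefl_loading(params)
  lam["NEFL"] <- a_nefl
  lam[c("MMP1", "VEGFA", "HGF")] <- 0.3
  if (n_filler > 0) {
    weak <- sample(sprintf("PROT%04d", seq_len(n_filler)),
                   size = max(1L, round(0.10 * n_filler)))
    lam[weak] <- 0.2
  }

  mu <- stats::rnorm(p, mean = 5, sd = 2); names(mu) <- symbols
  mu["NEFL"] <- -0.38   # puts ~19% of patients above the 0.5 NPX cutoff

  eps <- matrix(stats::rnorm(n * p), nrow = n)
  vals <- sweep(outer(f, lam) + sweep(eps, 2L, sqrt(1 - lam^2), `*`),
                2L, mu, `+`)
  dimnames(vals) <- list(clinical$patient_id, symbols)

  # latent strata from the pre-shift data: NEFL cutoff x composite-score band
  z_block <- scale(vals[, block, drop = FALSE])
  pi_raw <- rowSums(z_block)
  hi <- vals[, "NEFL"] > 0.5 & pi_raw > stats::quantile(pi_raw, 0.60)
  lo <- vals[, "NEFL"] <= 0.5 & pi_raw < stats::quantile(pi_raw, 0.40)
  vals[hi, c("MMP1", "VEGFA", "HGF")] <-
    vals[hi, c("MMP1", "VEGFA", "HGF")] + params$bbb_shift

  panel <- rep("Explore_Synthetic", p)
  panel[symbols %in% block] <- "Inflammation_I"
  panel[symbols == "NEFL"] <- "Neurology_I"
  meta <- data.frame(protein_symbol = symbols, assay_id = symbols,
                     panel = panel,
                     qc_pass = !(symbols %in% params$qc_fail_symbols),
                     stringsAsFactors = FALSE)
  out <- npx_matrix(vals, meta)
  attr(out, "latent_high_high") <- unname(hi)
  attr(out, "latent_normal_low") <- unname(lo)
  attr(out, "latent_factor") <- f
  attr(out, "loadings") <- lam
  out
}

#' Generate a coherent synthetic cohort (clinical + NPX)
#'
#' Composes [generate_clinical()] and [generate_npx()], then enriches the
#' clinical outcomes of the latent high-high stratum: the odds of recent
#' seizures and of being on two or more anti-seizure medications are both
#' multiplied by `outcome_odds`, which jointly raises the drug-resistant
#' epilepsy rate in that stratum. With `outcome_odds = 1` the clinical table
#' is left untouched (null cohort).
#'
#' @param params A [synthetic_params()] object.
#' @return List with elements `clinical` (data frame) and `npx`
#'   ([npx_matrix()] with latent stratum attributes).
#' @export
generate_cohort <- function(params = synthetic_params()) {
  clinical <- generate_clinical(params)
  npx <- generate_npx(clinical, params)
  hi <- attr(npx, "latent_high_high")
  if (params$outcome_odds != 1 && any(hi)) {
    set.seed(.sub_seed(params$seed, 2L))
    idx <- which(hi)
    ps <- params$p_seizure_status
    odds <- ps[["recent"]] / (1 - ps[["recent"]]) * params$outcome_odds
    p_recent <- odds / (1 + odds)
    rest <- ps[c("intermediate", "seizure_free")]
    p_status <- c(recent = p_recent, (1 - p_recent) * rest / sum(rest))
    status <- sample(names(p_status), length(idx), replace = TRUE, prob = p_status)
    clinical$days_since_last_seizure[idx] <- .sample_days(status, length(idx))
    recent <- status == "recent"
    clinical$seizure_count_2mo[idx] <- 0L
    clinical$seizure_count_2mo[idx[recent]] <-
      pmin(1L + stats::rnbinom(sum(recent), size = 0.6, mu = 5), 98L)

    p_multi <- sum(params$p_asm[c("2", "3+")])
    odds_m <- p_multi / (1 - p_multi) * params$outcome_odds
    p_multi_hi <- odds_m / (1 + odds_m)
    multi <- stats::runif(length(idx)) < p_multi_hi
    lowp <- params$p_asm[c("0", "1")]
    highp <- params$p_asm[c("2", "3+")]
    clinical$n_asm[idx[!multi]] <- sample(0:1, sum(!multi), replace = TRUE, prob = lowp)
    asm_hi <- sample(c("2", "3+"), sum(multi), replace = TRUE, prob = highp)
    clinical$n_asm[idx[multi]] <- ifelse(
      asm_hi == "2", 2L, sample(3:5, sum(multi), replace = TRUE, prob = c(0.7, 0.2, 0.1)))
  }
  list(clinical = clinical, npx = npx)
}

#' Convert an NPX matrix to long-format assay records
#'
#' @param matrix An [npx_matrix()].
#' @return Assay-record data frame (see [read_npx_long()]).
#' @export
npx_to_long <- function(matrix) {
  stopifnot(inherits(matrix, "npx_matrix"))
  samples <- rownames(matrix$values)
  meta <- matrix$assay_meta
  data.frame(
    sample_id = rep(samples, times = nrow(meta)),
    protein_symbol = rep(meta$protein_symbol, each = length(samples)),
    assay_id = rep(meta$assay_id, each = length(samples)),
    panel = rep(meta$panel, each = length(samples)),
    npx = as.vector(matrix$values),
    qc_pass = rep(meta$qc_pass, each = length(samples)),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort to disk in the formats the readers consume
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`npx`, `clinical`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  npx_path <- file.path(dir, "npx_long.csv")
  clin_path <- file.path(dir, "clinical.csv")
  write_npx_long(npx_to_long(cohort$npx), npx_path)
  write_clinical(cohort$clinical, clin_path)
  invisible(c(npx = npx_path, clinical = clin_path))
}

#' Contingency tables of the published quadrant-by-category counts
#'
#' Returns the five quadrant-by-category contingency tables transcribed from
#' the study's statistical summary: seizure status (4x3), epilepsy type
#' (4x3), gender (4x2), epilepsy status (4x3), and number of anti-seizure
#' medications (4x6). Rows are the four quadrants (High-Low, High-High,
#' Normal-High, Normal-Low, in NEFL-inflammation order); each table covers
#' the 139 quadrant-classified patients.
#'
#' @return Named list of integer matrices with dimnames.
#' @export
fixture_tables <- function() {
  dir <- system.file("extdata", package = "quadstrat")
  files <- c(seizure_status = "quadrant_counts_seizure_status.csv",
             epilepsy_type = "quadrant_counts_epilepsy_type.csv",
             gender = "quadrant_counts_gender.csv",
             epilepsy_status = "quadrant_counts_epilepsy_status.csv",
             n_asm = "quadrant_counts_n_asm.csv")
  out <- lapply(files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("Packaged fixture missing: ", f)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    m
  })
  if (!all(vapply(out, sum, numeric(1)) == 139L)) {
    stop("Fixture tables corrupted: grand totals must all be 139")
  }
  out
}
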