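# shared fixture builders; everything is generated in code at test time

make_npx <- function(values, panels = NULL, qc_pass = NULL) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("PR%02d", seq_len(ncol(values)))
  if (is.null(panels)) panels <- rep("Inflammation_I", ncol(values))
  if (is.null(qc_pass)) qc_pass <- rep(TRUE, ncol(values))
  npx_matrix(values, data.frame(
    protein_symbol = colnames(values), assay_id = colnames(values),
    panel = panels, qc_pass = qc_pass, stringsAsFactors = FALSE))
}

# long records for a panel from a samples x proteins matrix
make_records <- function(values, panel, qc_pass = TRUE) {
  samples <- rownames(values); proteins <- colnames(values)
  data.frame(
    sample_id = rep(samples, times = length(proteins)),
    protein_symbol = rep(proteins, each = length(samples)),
    assay_id = rep(proteins, each = length(samples)),
    panel = panel,
    npx = as.vector(values),
    qc_pass = qc_pass,
    stringsAsFactors = FALSE)
}

rand_mat <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, mean = 5), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("PR%02d", 1:p)))
  m
}

# small fast synthetic cohort used by several files
small_cohort <- function(seed = 11, n = 176, n_proteins = 20, ...) {
  generate_cohort(synthetic_params(n_patients = n, n_proteins = n_proteins,
                                   seed = seed, ...))
}

# quadrants from a cohort via the scoring/stratification surface
cohort_quadrants <- function(cohort) {
  z <- zscore(cohort$npx, pi_proteins())
  pi <- pi_score(z)
  nefl <- classify_nefl(stats::setNames(cohort$npx$values[, "NEFL"],
                                        rownames(cohort$npx$values)))
  assign_quadrants(nefl, inflammation_class(pi))
}
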