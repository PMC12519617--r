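#' Column-wise Z-score standardization of NPX values
#'
#' Standardizes each requested protein column to mean 0 and unit standard
#' deviation over the full cohort: Z = (NPX - mean NPX) / SD, with the
#' sample standard deviation (n-1 denominator). Standardization over the
#' whole cohort, before any quadrant exclusion, is what makes the later
#' percentile banding act on all patients.
#'
#' @param matrix An [npx_matrix()].
#' @param proteins Symbols to standardize; default all columns.
#' @return A list of class `z_matrix` with `sample_ids`, `protein_symbols`
#'   and the `z_values` matrix.
#' @export
zscore <- function(matrix, proteins = NULL) {
  stopifnot(inherits(matrix, "npx_matrix"))
  if (is.null(proteins)) proteins <- colnames(matrix$values)
  unknown <- setdiff(proteins, colnames(matrix$values))
  if (length(unknown) > 0L) {
    stop("Unknown protein symbol(s): ", paste(unknown, collapse = ", "))
  }
  vals <- matrix$values[, proteins, drop = FALSE]
  sds <- apply(vals, 2L, stats::sd)
  degenerate <- proteins[sds == 0 | !is.finite(sds)]
  if (length(degenerate) > 0L) {
    stop("Zero-variance protein column(s), cannot standardize: ",
         paste(degenerate, collapse = ", "))
  }
  z <- scale(vals, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(sample_ids = rownames(vals),
                 protein_symbols = proteins,
                 z_values = z),
            class = "z_matrix")
}

#' Composite pro-inflammatory score
#'
#' Sums the per-sample Z-scores of the 12 pro-inflammatory block proteins
#' into a single dimensionless composite score. Any other columns present in
#' the Z-matrix are ignored.
#'
#' @param z A `z_matrix` from [zscore()].
#' @param block The 12 block symbols (default [pi_proteins()]).
#' @return Data frame with `sample_id` and `pi_score`.
#' @export
pi_score <- function(z, block = pi_proteins()) {
  stopifnot(inherits(z, "z_matrix"))
  missing <- setdiff(block, z$protein_symbols)
  if (length(missing) > 0L) {
    stop("Z-matrix is missing composite-score protein(s): ",
         paste(missing, collapse = ", "))
  }
  score <- rowSums(z$z_values[, block, drop = FALSE])
  data.frame(sample_id = z$sample_ids, pi_score = unname(score),
             stringsAsFactors = FALSE)
}

#' Classify NEFL against the fixed NPX cutoff
#'
#' Plasma neurofilament light chain above 0.5 NPX is classified as high; the
#' cutoff corresponds to the 10 pg/mL threshold above which NEFL is abnormal
#' for ages 18-50 (calibrated externally against Simoa). The boundary value
#' itself is "normal": only strictly greater values are abnormal.
#'
#' @param nefl_npx Named (or unnamed) numeric vector of NEFL NPX values.
#' @param cutoff NPX cutoff, default 0.5.
#' @return Data frame with `sample_id` (names, or index if unnamed),
#'   `nefl_npx` and factor `nefl_class` in `{normal, high}`; the cutoff is
#'   carried in attributes `cutoff_npx` and `cutoff_pg_ml`.
#' @export
classify_nefl <- function(nefl_npx, cutoff = 0.5) {
  if (!is.numeric(nefl_npx) || any(!is.finite(nefl_npx))) {
    stop("NEFL NPX values must be finite numerics")
  }
  ids <- names(nefl_npx)
  if (is.null(ids)) ids <- as.character(seq_along(nefl_npx))
  out <- data.frame(
    sample_id = ids,
    nefl_npx = unname(nefl_npx),
    nefl_class = factor(ifelse(nefl_npx > cutoff, "high", "normal"),
                        levels = c("normal", "high")),
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff_npx") <- cutoff
  attr(out, "cutoff_pg_ml") <- 10
  out
}
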