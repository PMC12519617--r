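#' Differential protein expression between two patient groups
#'
#' Per protein, the log2 fold change is the difference in mean NPX between
#' the two groups (NPX is already log2-scaled, so a mean difference *is* a
#' log2 fold change - the Olink convention). Two-sided p-values come from
#' the unequal-variance two-sample t test by default, or the Wilcoxon
#' rank-sum test; BH adjustment runs across all proteins. A protein is
#' `significant` when FDR < 0.05, raw p < 0.05 and |log2 FC| >= 1;
#' `significant_relaxed` uses |log2 FC| > 0.5 with the same p/FDR gates.
#'
#' @param matrix An [npx_matrix()].
#' @param group_a,group_b Disjoint sample-id vectors, each of size >= 2.
#'   Fold changes are mean(group_a) - mean(group_b).
#' @param test `"t"` (Welch, default) or `"wilcox"`.
#' @param alpha Significance level for the p/FDR gates (default 0.05).
#' @param lfc,lfc_relaxed Fold-change cutoffs (defaults 1.0 and 0.5).
#' @return Data frame with one row per protein: `protein_symbol`,
#'   `log2_fc`, `p`, `fdr`, `significant`, `significant_relaxed`.
#' @export
diff_expression <- function(matrix, group_a, group_b,
                            test = c("t", "wilcox"),
                            alpha = 0.05, lfc = 1.0, lfc_relaxed = 0.5) {
  stopifnot(inherits(matrix, "npx_matrix"))
  test <- match.arg(test)
  samples <- rownames(matrix$values)
  missing <- setdiff(c(group_a, group_b), samples)
  if (length(missing) > 0L) {
    stop("Unknown sample id(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (length(intersect(group_a, group_b)) > 0L) stop("Groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("Each group needs at least 2 samples")
  }
  A <- matrix$values[group_a, , drop = FALSE]
  B <- matrix$values[group_b, , drop = FALSE]
  log2_fc <- colMeans(A) - colMeans(B)
  p <- vapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]; b <- B[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(1)
    }
    if (test == "t") stats::t.test(a, b, var.equal = FALSE)$p.value
    else suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  fdr <- bh_adjust(p)
  data.frame(
    protein_symbol = colnames(matrix$values),
    log2_fc = unname(log2_fc),
    p = p,
    fdr = fdr,
    significant = fdr < alpha & p < alpha & abs(log2_fc) >= lfc,
    significant_relaxed = fdr < alpha & p < alpha & abs(log2_fc) > lfc_relaxed,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Top differentially expressed proteins
#'
#' Orders by ascending p-value, breaking ties by descending |log2 FC| and
#' then by symbol, and returns the first `n` (the labelling rule of the
#' volcano plot, default top 20).
#'
#' @param results Data frame from [diff_expression()].
#' @param n Number of proteins to return (default 20).
#' @return The ordered subset of `results`.
#' @export
de_top_n <- function(results, n = 20L) {
  stopifnot(is.data.frame(results), n >= 1L)
  ord <- order(results$p, -abs(results$log2_fc), results$protein_symbol)
  utils::head(results[ord, , drop = FALSE], n)
}

#' Volcano-plot coordinates
#'
#' Maps each protein to (log2 fold change, -log10 p) with a display
#' category: the 12 composite-score proteins and NEFL are flagged
#' `pi_score_protein` regardless of significance, significant proteins are
#' `significant`, and the rest `other`. Zero p-values are mapped to the
#' smallest representable positive double, with a message.
#'
#' @param results Data frame from [diff_expression()].
#' @param pi_block Symbols flagged as score constituents
#'   (default [pi_proteins()] plus `"NEFL"`).
#' @return Data frame with `protein_symbol`, `log2_fc`, `neg_log10_p`,
#'   `category`.
#' @export
volcano_coordinates <- function(results, pi_block = c(pi_proteins(), "NEFL")) {
  stopifnot(is.data.frame(results))
  p <- results$p
  if (any(p == 0)) {
    message("Mapping ", sum(p == 0), " zero p-value(s) to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  category <- ifelse(results$protein_symbol %in% pi_block, "pi_score_protein",
                     ifelse(results$significant, "significant", "other"))
  data.frame(
    protein_symbol = results$protein_symbol,
    log2_fc = results$log2_fc,
    neg_log10_p = -log10(p),
    category = factor(category, levels = c("significant", "pi_score_protein", "other")),
    stringsAsFactors = FALSE
  )
}
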