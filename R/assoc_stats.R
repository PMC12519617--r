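#' Spearman correlation with t-approximation p-value
#'
#' Ranks both vectors with mid-rank ties, takes the Pearson correlation of
#' the ranks, and computes a two-sided p-value from the t approximation with
#' n-2 degrees of freedom. A result is "highlighted" when |r| > 0.1 and
#' p < 0.05, the rule used for the correlation plots.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List of class `correlation_result` with `r`, `p`, `n`,
#'   `highlight`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  n <- length(x)
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n,
                 highlight = abs(r) > 0.1 && p < 0.05),
            class = "correlation_result")
}

#' All pairwise Spearman correlations among a set of variables
#'
#' @param values Numeric matrix (samples x variables) or an [npx_matrix()].
#' @param targets Optional subset of column names.
#' @return List with matrices `r`, `p`, `highlight`.
#' @export
correlation_matrix <- function(values, targets = NULL) {
  if (inherits(values, "npx_matrix")) values <- values$values
  stopifnot(is.matrix(values), nrow(values) >= 3L)
  if (!is.null(targets)) {
    bad <- setdiff(targets, colnames(values))
    if (length(bad) > 0L) stop("Unknown column(s): ", paste(bad, collapse = ", "))
    values <- values[, targets, drop = FALSE]
  }
  k <- ncol(values)
  nm <- colnames(values)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      res <- spearman_test(values[, i], values[, j])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
    }
  }
  list(r = r, p = p, highlight = abs(r) > 0.1 & p < 0.05)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on k-1 degrees of freedom. When every pooled value is identical the
#' statistic is 0 and p is 1 (returned, not an error).
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return List of class `kw_result` with `H`, `p`, `df`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L), sum(lengths(groups)) >= 3L)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    res <- list(H = 0, p = 1, df = length(groups) - 1L)
  } else {
    kt <- stats::kruskal.test(pooled, factor(rep(seq_along(groups), lengths(groups))))
    res <- list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
  }
  structure(c(res, list(group_sizes = lengths(groups))), class = "kw_result")
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z statistics on mean ranks of the pooled sample, with the
#' tie-corrected pooled variance, two-sided normal p-values, and Bonferroni
#' adjustment over all pairs (capped at 1). If the pooled rank variance is
#' zero (everything tied), every adjusted p is 1.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @param labels Optional group labels (defaults to names or indices).
#' @return Data frame of class `posthoc_result` with columns `group1`,
#'   `group2`, `z`, `raw_p`, `adjusted_p`; attribute `method` is
#'   `"bonferroni"`.
#' @export
dunn_posthoc <- function(groups, labels = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) >= 1L))
  if (is.null(labels)) labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(pooled)
  rk <- rank(pooled)
  mean_ranks <- tapply(rk, g, mean)
  n_i <- lengths(groups)
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_corr

  pairs <- utils::combn(seq_along(groups), 2L)
  z <- raw_p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(base_var * (1 / n_i[i] + 1 / n_i[j]))
    z[k] <- if (se == 0) 0 else (mean_ranks[i] - mean_ranks[j]) / se
    raw_p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  out <- data.frame(
    group1 = labels[pairs[1L, ]], group2 = labels[pairs[2L, ]],
    z = z, raw_p = raw_p,
    adjusted_p = bonferroni_adjust(raw_p),
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- "bonferroni"
  class(out) <- c("posthoc_result", class(out))
  out
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic on a labeled contingency table with expected counts
#' from the row/column margins, no continuity correction, and a chi-square
#' p-value on (r-1)(c-1) degrees of freedom. A warning is issued when any
#' expected count is below 5 (the test is still run; no minimum-count guard
#' is applied).
#'
#' @param table Non-negative integer matrix.
#' @return List of class `chisq_result` with `statistic`, `df`, `p`,
#'   `expected`, `observed`.
#' @export
chi_square <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0), sum(table) >= 1)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("Contingency table has a zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("Expected count(s) below 5; chi-square approximation may be coarse")
  }
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 expected = ct$expected,
                 observed = table),
            class = "chisq_result")
}

#' Pairwise post hoc chi-square tests with Benjamini-Hochberg correction
#'
#' For every unordered pair of rows, runs [chi_square()] on the 2 x c
#' sub-table (columns whose margin is zero within the pair are dropped
#' first, with a message) and adjusts the raw p-values across all pairs by
#' the BH step-up procedure.
#'
#' @param table Contingency matrix with >= 3 rows.
#' @return Data frame of class `posthoc_result` with columns `group1`,
#'   `group2`, `statistic`, `raw_p`, `adjusted_p`; attribute `method` is
#'   `"benjamini_hochberg"`.
#' @export
pairwise_chi_square <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 3L)
  rows <- rownames(table)
  if (is.null(rows)) rows <- as.character(seq_len(nrow(table)))
  pairs <- utils::combn(nrow(table), 2L)
  stat <- raw_p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    sub <- table[pairs[, k], , drop = FALSE]
    zero <- colSums(sub) == 0
    if (any(zero)) {
      message("Dropping zero-margin column(s) ",
              paste(colnames(sub)[zero], collapse = ", "),
              " for pair ", rows[pairs[1L, k]], " vs ", rows[pairs[2L, k]])
      sub <- sub[, !zero, drop = FALSE]
    }
    res <- suppressWarnings(chi_square(sub))
    stat[k] <- res$statistic
    raw_p[k] <- res$p
  }
  out <- data.frame(
    group1 = rows[pairs[1L, ]], group2 = rows[pairs[2L, ]],
    statistic = stat, raw_p = raw_p,
    adjusted_p = bh_adjust(raw_p),
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- "benjamini_hochberg"
  class(out) <- c("posthoc_result", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return `p * length(p)`, capped at 1, in the input order.
#' @export
bonferroni_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Build a quadrant-by-category contingency table
#'
#' Cross-tabulates quadrant assignments against a clinical category,
#' excluding unclassified patients, with rows in the standard quadrant
#' order.
#'
#' @param quadrant Factor of quadrant labels (may include `unclassified`).
#' @param category Factor or character vector of the same length.
#' @param drop_unclassified Drop unclassified patients (default TRUE).
#' @return Integer contingency matrix with dimnames.
#' @export
contingency_table <- function(quadrant, category, drop_unclassified = TRUE) {
  stopifnot(length(quadrant) == length(category))
  keep <- if (drop_unclassified) quadrant != "unclassified" else rep(TRUE, length(quadrant))
  q <- factor(as.character(quadrant[keep]), levels = quadrant_levels())
  tab <- table(q, factor(category[keep]))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
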