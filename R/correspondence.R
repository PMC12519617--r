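#' Correspondence analysis of a contingency table
#'
#' Classical correspondence analysis from the singular value decomposition
#' of the standardized residual matrix. With correspondence matrix
#' P = counts / N, row masses r and column masses c, the residuals are
#' S = (P - r c') / sqrt(r c'); a thin SVD S = U D V' yields row principal
#' coordinates F = diag(r)^(-1/2) U D and column principal coordinates
#' G = diag(c)^(-1/2) V D. The total inertia (sum of squared singular
#' values over all nontrivial dimensions) times N equals the table's
#' Pearson chi-square.
#'
#' @param table Non-negative contingency matrix without zero row/column
#'   margins.
#' @param k Number of dimensions to retain (default 2, the most a 4 x 3
#'   table supports).
#' @return List of class `ca_result`: `row_masses`, `col_masses`,
#'   `singular_values` (all nontrivial dimensions), `row_coords` (rows x k),
#'   `col_coords` (cols x k), `total_inertia`, `N`.
#' @export
ca_fit <- function(table, k = 2L) {
  stopifnot(is.matrix(table), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("Correspondence analysis requires nonzero row and column margins")
  }
  kmax <- min(dim(table)) - 1L
  if (k > kmax) stop("k = ", k, " exceeds the ", kmax, " nontrivial dimension(s)")
  N <- sum(table)
  P <- table / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  dec <- svd(S)
  sigma <- dec$d[seq_len(kmax)]
  F <- sweep(dec$u, 1L, sqrt(r), `/`) %*% diag(dec$d, nrow = length(dec$d))
  G <- sweep(dec$v, 1L, sqrt(cc), `/`) %*% diag(dec$d, nrow = length(dec$d))
  rownames(F) <- rownames(table)
  rownames(G) <- colnames(table)
  structure(list(
    row_masses = r, col_masses = cc,
    singular_values = sigma,
    row_coords = F[, seq_len(k), drop = FALSE],
    col_coords = G[, seq_len(k), drop = FALSE],
    total_inertia = sum(sigma^2),
    N = N
  ), class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d row / %d column points, %d dim(s) retained\n",
              nrow(x$row_coords), nrow(x$col_coords), ncol(x$row_coords)))
  cat("singular values:", paste(signif(x$singular_values, 4), collapse = ", "),
      sprintf(" total inertia %.5f (chi-square %.3f at N = %d)\n",
              x$total_inertia, x$total_inertia * x$N, x$N))
  invisible(x)
}

#' Euclidean distances between quadrant and category points
#'
#' Distances between every row (quadrant) point and every column (category)
#' point of the symmetric map, i.e. with both sets in principal coordinates,
#' in the retained dimensions. These row-to-column distances are descriptive
#' proximities: unlike row-to-row distances they are not chi-square
#' distances, but shorter distances still indicate stronger association.
#' They are invariant to the SVD's arbitrary sign choices.
#'
#' @param result A [ca_fit()] result.
#' @return Numeric matrix, rows x columns, of Euclidean distances.
#' @export
ca_distances <- function(result) {
  stopifnot(inherits(result, "ca_result"), ncol(result$row_coords) >= 1L)
  F <- result$row_coords
  G <- result$col_coords
  d <- matrix(0, nrow(F), nrow(G), dimnames = list(rownames(F), rownames(G)))
  for (i in seq_len(nrow(F))) {
    d[i, ] <- sqrt(colSums((t(G) - F[i, ])^2))
  }
  d
}
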