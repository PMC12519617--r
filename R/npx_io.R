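# Default column names of the Olink-style long export this package reads.
.default_npx_cols <- c(
  sample = "SampleID", assay = "Assay", panel = "Panel",
  npx = "NPX", qc = "QC_Warning"
)

#' Read an Olink-style long-format NPX file
#'
#' Reads a comma-delimited long-format table of NPX measurements (one row per
#' sample x assay x panel) into a validated assay-record data frame. NPX values
#' are relative protein abundances on a log2 scale.
#'
#' @param path Path to a CSV file with a header row.
#' @param panel_names Character vector of allowed panel names; rows carrying
#'   any other panel name are a validation error.
#' @param col_names Named character vector mapping the roles
#'   `sample`, `assay`, `panel`, `npx`, `qc` to column names in the file.
#'   Defaults to the Olink convention (`SampleID`, `Assay`, `Panel`, `NPX`,
#'   `QC_Warning` with values `"PASS"`/`"WARN"`).
#'
#' @return A data frame of assay records with columns `sample_id`,
#'   `protein_symbol`, `assay_id`, `panel`, `npx` (numeric, log2 scale) and
#'   `qc_pass` (logical).
#' @export
read_npx_long <- function(path, panel_names, col_names = .default_npx_cols) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("NPX file not found: ", path)
  cols <- .default_npx_cols
  cols[names(col_names)] <- col_names

  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing) > 0L) {
    stop("NPX file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }

  npx_chr <- raw[[cols[["npx"]]]]
  npx <- suppressWarnings(as.numeric(npx_chr))
  bad <- which(is.na(npx) | !is.finite(npx))
  if (length(bad) > 0L) {
    stop("Non-numeric or non-finite NPX value(s) in ", path,
         " at data line(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }

  panel <- raw[[cols[["panel"]]]]
  unknown <- setdiff(unique(panel), panel_names)
  if (length(unknown) > 0L) {
    stop("Unknown panel name(s): ", paste(unknown, collapse = ", "),
         "; allowed panels: ", paste(panel_names, collapse = ", "))
  }

  qc_raw <- raw[[cols[["qc"]]]]
  qc_pass <- toupper(trimws(qc_raw)) %in% c("PASS", "TRUE", "1")

  rec <- data.frame(
    sample_id = raw[[cols[["sample"]]]],
    protein_symbol = raw[[cols[["assay"]]]],
    assay_id = if ("AssayID" %in% names(raw)) raw[["AssayID"]]
               else raw[[cols[["assay"]]]],
    panel = panel,
    npx = npx,
    qc_pass = qc_pass,
    stringsAsFactors = FALSE
  )
  key <- paste(rec$panel, rec$sample_id, rec$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("Duplicated (sample, assay) row(s) within a panel in ", path)
  }
  rec
}

#' Construct an NPX matrix object
#'
#' Low-level constructor for the samples x proteins NPX container used
#' throughout the package.
#'
#' @param values Numeric matrix, samples in rows and proteins in columns,
#'   with complete dimnames.
#' @param assay_meta Data frame with one row per protein column, columns
#'   `protein_symbol`, `assay_id`, `panel`, `qc_pass`.
#' @return An object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, assay_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("NPX value matrix must carry sample and protein dimnames")
  }
  if (!all(is.finite(values))) stop("NPX values must be finite; missing cells are not supported")
  req <- c("protein_symbol", "assay_id", "panel", "qc_pass")
  stopifnot(is.data.frame(assay_meta), all(req %in% names(assay_meta)))
  if (nrow(assay_meta) != ncol(values) ||
      !identical(assay_meta$protein_symbol, colnames(values))) {
    stop("assay_meta must align one-to-one with the protein columns")
  }
  if (anyDuplicated(colnames(values))) stop("duplicated protein symbols in NPX matrix")
  structure(list(values = values, assay_meta = assay_meta), class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> %d samples x %d proteins, %d panel(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$assay_meta$panel))))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Merge panels, resolving duplicated assays by geometric-mean expression
#'
#' Combines long-format assay records from one or more panels into a single
#' samples x proteins matrix. When the same protein symbol is measured on
#' more than one panel, the panel whose geometric mean expression on the
#' linear scale is highest is retained. Because NPX is log2-scaled, the
#' geometric mean of 2^NPX orders identically to the arithmetic mean of NPX,
#' so the comparison is done on mean NPX directly (numerically safer).
#' Exact ties are broken toward the lexicographically first panel name,
#' with a warning.
#'
#' @param records Assay-record data frame as returned by [read_npx_long()].
#' @return An [npx_matrix()] with one column per distinct protein symbol.
#' @export
merge_panels <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("merge_panels() needs a nonempty assay-record data frame")
  }
  panels <- unique(records$panel)
  samples <- unique(records$sample_id)
  # every sample must appear in every panel
  for (p in panels) {
    have <- unique(records$sample_id[records$panel == p])
    if (!setequal(have, samples)) {
      stop("Sample set mismatch: panel ", p, " is missing sample(s) ",
           paste(setdiff(samples, have), collapse = ", "))
    }
  }

  key <- paste(records$panel, records$assay_id, sep = "\r")
  first_idx <- !duplicated(key)
  meta <- records[first_idx, c("protein_symbol", "assay_id", "panel", "qc_pass"),
                  drop = FALSE]
  # candidate column per (panel, assay): mean NPX decides duplicates
  mean_npx <- vapply(split(records$npx, key), mean, numeric(1))
  meta$mean_npx <- mean_npx[paste(meta$panel, meta$assay_id, sep = "\r")]

  keep <- logical(nrow(meta))
  for (sym in unique(meta$protein_symbol)) {
    idx <- which(meta$protein_symbol == sym)
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    m <- meta$mean_npx[idx]
    best <- idx[m == max(m)]
    if (length(best) > 1L) {
      best <- best[order(meta$panel[best])]
      warning("Exact mean-NPX tie for duplicated symbol ", sym,
              "; retaining panel ", meta$panel[best[1L]],
              " (lexicographic tie-break)")
    }
    keep[best[1L]] <- TRUE
  }
  meta <- meta[keep, , drop = FALSE]

  vals <- matrix(NA_real_, nrow = length(samples), ncol = nrow(meta),
                 dimnames = list(samples, meta$protein_symbol))
  for (i in seq_len(nrow(meta))) {
    sel <- records$panel == meta$panel[i] & records$assay_id == meta$assay_id[i]
    sub <- records[sel, , drop = FALSE]
    vals[sub$sample_id, i] <- sub$npx
  }
  if (anyNA(vals)) stop("Missing NPX cell(s) after merging; dense input required")
  meta$mean_npx <- NULL
  rownames(meta) <- NULL
  npx_matrix(vals, meta)
}

#' Drop proteins that failed batch-release quality control
#'
#' Restricts an NPX matrix to assays with `qc_pass = TRUE`, preserving the
#' original column order among survivors. The sample set is unchanged.
#'
#' @param matrix An [npx_matrix()].
#' @return The filtered `npx_matrix`.
#' @export
qc_filter <- function(matrix) {
  stopifnot(inherits(matrix, "npx_matrix"))
  keep <- matrix$assay_meta$qc_pass
  if (!any(keep)) stop("All proteins failed QC; refusing to return an empty matrix")
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(sprintf("qc_filter: removed %d protein(s) failing QC, %d retained",
                    n_removed, sum(keep)))
  }
  meta <- matrix$assay_meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  npx_matrix(matrix$values[, keep, drop = FALSE], meta)
}

#' Write an NPX matrix as a wide TSV with a JSON metadata sidecar
#'
#' @param matrix An [npx_matrix()].
#' @param path Output TSV path (samples as rows, proteins as columns; first
#'   column `sample_id`).
#' @param meta_path Optional path for a JSON sidecar holding the assay
#'   metadata; defaults to `path` with a `.json` extension appended.
#' @return Invisibly, `path`.
#' @export
write_npx_wide <- function(matrix, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(matrix, "npx_matrix"))
  df <- data.frame(sample_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(matrix$assay_meta, meta_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write assay records as a long-format NPX CSV
#'
#' Inverse of [read_npx_long()] in the default column dialect; used by the
#' synthetic-cohort generator and round-trip tests.
#'
#' @param records Assay-record data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_npx_long <- function(records, path) {
  out <- data.frame(
    SampleID = records$sample_id,
    Assay = records$protein_symbol,
    AssayID = records$assay_id,
    Panel = records$panel,
    NPX = records$npx,
    QC_Warning = ifelse(records$qc_pass, "PASS", "WARN"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.clinical_cols <- c("patient_id", "age", "gender", "epilepsy_type",
                    "days_since_last_seizure", "seizure_count_2mo", "n_asm")

#' Read a clinical covariate table
#'
#' @param path CSV with columns `patient_id`, `age`, `gender`,
#'   `epilepsy_type`, `days_since_last_seizure` (integer days; empty/NA means
#'   no seizure ever recorded), `seizure_count_2mo`, `n_asm`.
#' @return A clinical data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("Clinical file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.clinical_cols, names(df))
  if (length(missing) > 0L) {
    stop("Clinical table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a clinical covariate table
#' @param clinical Clinical data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical[, intersect(c(.clinical_cols,
                                          setdiff(names(clinical), .clinical_cols)),
                                        names(clinical))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
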