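#' Quadrant labels in NEFL-inflammation order
#' @return Character vector of the four quadrant labels.
#' @export
quadrant_levels <- function() c("High-Low", "High-High", "Normal-High", "Normal-Low")

#' Stratification parameters
#'
#' @param lower_percentile Composite-score percentile below which patients
#'   are "low inflammation" (default 40).
#' @param upper_percentile Percentile above which patients are "high
#'   inflammation" (default 60); the band in between is excluded as
#'   ambiguous.
#' @param nefl_cutoff_npx NEFL cutoff in NPX units (default 0.5).
#' @return A validated list of class `stratification_params`.
#' @export
stratification_params <- function(lower_percentile = 40,
                                  upper_percentile = 60,
                                  nefl_cutoff_npx = 0.5) {
  stopifnot(lower_percentile > 0, upper_percentile < 100,
            lower_percentile < upper_percentile)
  structure(list(lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 nefl_cutoff_npx = nefl_cutoff_npx),
            class = "stratification_params")
}

#' Band patients into low/high inflammation by composite-score percentiles
#'
#' Computes the lower and upper percentiles of the composite pro-inflammatory
#' score by linear interpolation (rank = 1 + p*(n-1), the standard type-7
#' quantile) and classifies scores strictly below the lower percentile as
#' low, strictly above the upper percentile as high, and everything in
#' between - the ambiguous central band - as unclassified. With the default
#' 40th/60th percentiles the central ~20% of patients are excluded, reducing
#' classification noise near the median.
#'
#' @param pi Data frame from [pi_score()], or a numeric vector of scores.
#' @param params A [stratification_params()] object.
#' @return Factor in `{low, high, unclassified}`, one element per patient,
#'   with the two percentile thresholds in attribute `thresholds`.
#' @export
inflammation_class <- function(pi, params = stratification_params()) {
  scores <- if (is.data.frame(pi)) pi$pi_score else pi
  if (length(scores) < 5L) stop("Need at least 5 patients to band by percentiles")
  if (any(!is.finite(scores))) stop("Composite scores must be finite")
  qs <- stats::quantile(scores,
                        probs = c(params$lower_percentile, params$upper_percentile) / 100,
                        type = 7, names = FALSE)
  cls <- factor(ifelse(scores < qs[1], "low",
                ifelse(scores > qs[2], "high", "unclassified")),
                levels = c("low", "high", "unclassified"))
  attr(cls, "thresholds") <- c(lower = qs[1], upper = qs[2])
  cls
}

#' Cross NEFL class with inflammation band into quadrants
#'
#' Patients whose inflammation band is unclassified remain unclassified;
#' otherwise the quadrant is the cross of NEFL class (normal/high) and
#' inflammation band (low/high), labelled in NEFL-inflammation order
#' (e.g. "High-Low" is high NEFL, low inflammation).
#'
#' @param nefl Data frame from [classify_nefl()].
#' @param infl Factor from [inflammation_class()] over the same patients, in
#'   the same order.
#' @return Data frame with `patient_id`, `nefl_class`, `inflammation_class`
#'   and factor `quadrant` with levels [quadrant_levels()] plus
#'   `unclassified`.
#' @export
assign_quadrants <- function(nefl, infl) {
  if (nrow(nefl) != length(infl)) {
    stop("NEFL classification and inflammation band cover different patient sets")
  }
  quadrant <- ifelse(infl == "unclassified", "unclassified",
                     paste(ifelse(nefl$nefl_class == "high", "High", "Normal"),
                           ifelse(infl == "high", "High", "Low"), sep = "-"))
  data.frame(
    patient_id = nefl$sample_id,
    nefl_class = nefl$nefl_class,
    inflammation_class = infl,
    quadrant = factor(quadrant, levels = c(quadrant_levels(), "unclassified")),
    stringsAsFactors = FALSE
  )
}

#' Seizure status from days since last seizure
#'
#' At most 2 months (61 days) since the last seizure is "recent"; more than
#' 1 year (365 days), or no seizure ever recorded (NA), is "seizure_free";
#' the band in between is "intermediate". The calendar phrases are
#' operationalized as 61 and 365 days.
#'
#' @param days_since_last_seizure Integer days; NA means never.
#' @param recent_days,year_days Boundary constants (defaults 61 and 365).
#' @return Factor in `{recent, intermediate, seizure_free}`.
#' @export
derive_seizure_status <- function(days_since_last_seizure,
                                  recent_days = 61L, year_days = 365L) {
  d <- days_since_last_seizure
  if (any(d < 0, na.rm = TRUE)) stop("days_since_last_seizure must be non-negative")
  factor(ifelse(is.na(d) | d > year_days, "seizure_free",
         ifelse(d <= recent_days, "recent", "intermediate")),
         levels = c("recent", "intermediate", "seizure_free"))
}

#' Epilepsy status from medication count and recent seizure history
#'
#' Drug-resistant epilepsy (DRE): two or more anti-seizure medications and
#' seizures within the last year. Well-controlled epilepsy (WCE): exactly
#' one medication and seizure-free for over a year. Everyone else, including
#' unmedicated patients, is undetermined.
#'
#' @param n_asm Non-negative integer count of anti-seizure medications.
#' @param seizure_within_1yr Logical.
#' @return Factor in `{DRE, undetermined, WCE}`.
#' @export
derive_epilepsy_status <- function(n_asm, seizure_within_1yr) {
  stopifnot(all(n_asm >= 0), length(n_asm) == length(seizure_within_1yr))
  factor(ifelse(n_asm >= 2 & seizure_within_1yr, "DRE",
         ifelse(n_asm == 1 & !seizure_within_1yr, "WCE", "undetermined")),
         levels = c("DRE", "undetermined", "WCE"))
}

#' Bin the 2-month seizure count into frequency groups
#'
#' @param count Integer seizure counts in 0..100 (the study observed 0-98).
#' @return Factor in `{0, 1, 2-100}`.
#' @export
bin_seizure_frequency <- function(count) {
  stopifnot(all(count >= 0))
  if (any(count > 100)) stop("Seizure counts above 100 are outside the study convention")
  factor(ifelse(count == 0, "0", ifelse(count == 1, "1", "2-100")),
         levels = c("0", "1", "2-100"))
}

# round half away from zero, matching how the published percentages are printed
.round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a quadrant's patients falling in selected categories
#'
#' @param table Contingency matrix with quadrant rows and category columns.
#' @param row Row (quadrant) label.
#' @param cols Column label(s) to sum.
#' @return List with `percent` (integer, rounded half away from zero),
#'   `exact` (the unrounded percentage), `numerator`, `denominator`.
#' @export
quadrant_percentage <- function(table, row, cols) {
  stopifnot(is.matrix(table), length(cols) >= 1L)
  if (!row %in% rownames(table)) stop("Unknown quadrant row: ", row)
  bad <- setdiff(cols, colnames(table))
  if (length(bad) > 0L) stop("Unknown column(s): ", paste(bad, collapse = ", "))
  num <- sum(table[row, cols])
  den <- sum(table[row, ])
  if (den == 0) stop("Quadrant row ", row, " has zero total")
  exact <- 100 * num / den
  list(percent = .round_half_away(exact), exact = exact,
       numerator = num, denominator = den)
}

#' Add derived clinical categories to a clinical table
#'
#' Adds `seizure_status`, `epilepsy_status` and `freq_bin` columns derived
#' from the raw covariates. Seizure-within-one-year for the epilepsy status
#' is taken as `seizure_status != "seizure_free"` (both definitions reference
#' the same 1-year window).
#'
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @return The clinical data frame with the three derived columns appended.
#' @export
derive_clinical <- function(clinical) {
  clinical$seizure_status <- derive_seizure_status(clinical$days_since_last_seizure)
  clinical$epilepsy_status <- derive_epilepsy_status(
    clinical$n_asm, clinical$seizure_status != "seizure_free")
  clinical$freq_bin <- bin_seizure_frequency(clinical$seizure_count_2mo)
  clinical
}
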