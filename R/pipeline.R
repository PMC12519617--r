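# polynomial rolling hash over the serialized config; cheap provenance fingerprint
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble and validate a pipeline configuration
#'
#' Either a `simulate` block ([synthetic_params()]) or a pair of input paths
#' must be supplied, not neither.
#'
#' @param simulate Optional [synthetic_params()] for a synthetic cohort.
#' @param npx_path,clinical_path Optional paths to a long-format NPX CSV and
#'   a clinical CSV (used when `simulate` is absent).
#' @param panel_names Allowed panel names when reading from files.
#' @param strat A [stratification_params()] object.
#' @param alpha Significance level (default 0.05).
#' @param de_test Differential-expression test, `"t"` or `"wilcox"`.
#' @param lfc,lfc_relaxed Fold-change cutoffs (defaults 1.0, 0.5).
#' @param out_dir Optional output directory for the report and stage TSVs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, npx_path = NULL, clinical_path = NULL,
                            panel_names = c("Neurology_I", "Neurology_II",
                                            "Inflammation_I", "Inflammation_II",
                                            "Explore_Synthetic"),
                            strat = stratification_params(),
                            alpha = 0.05, de_test = "t",
                            lfc = 1.0, lfc_relaxed = 0.5,
                            out_dir = NULL) {
  if (is.null(simulate) && (is.null(npx_path) || is.null(clinical_path))) {
    stop("Provide either a simulate block or both npx_path and clinical_path")
  }
  stopifnot(alpha > 0, lfc > 0, lfc_relaxed > 0)
  structure(list(simulate = simulate, npx_path = npx_path,
                 clinical_path = clinical_path, panel_names = panel_names,
                 strat = strat, alpha = alpha, de_test = de_test,
                 lfc = lfc, lfc_relaxed = lfc_relaxed, out_dir = out_dir),
            class = "pipeline_config")
}

# association battery on a per-patient table; quadrants are taken as given
.analyze_cohort <- function(per_patient, npx, config) {
  classified <- per_patient[per_patient$quadrant != "unclassified", , drop = FALSE]
  categorical <- list(
    seizure_status = classified$seizure_status,
    epilepsy_type = classified$epilepsy_type,
    gender = classified$gender,
    epilepsy_status = classified$epilepsy_status,
    n_asm = classified$n_asm,
    freq_bin = classified$freq_bin
  )
  tables <- lapply(categorical, function(v) {
    tryCatch(contingency_table(classified$quadrant, v),
             error = function(e) NULL)
  })
  chisq <- lapply(tables, function(tab) {
    if (is.null(tab)) return(NULL)
    tryCatch({
      res <- suppressWarnings(chi_square(tab))
      posthoc <- if (res$p < config$alpha) {
        suppressWarnings(suppressMessages(pairwise_chi_square(tab)))
      } else NULL
      list(statistic = res$statistic, df = res$df, p = res$p, posthoc = posthoc)
    }, error = function(e) NULL)
  })

  q <- droplevels(factor(classified$quadrant, levels = quadrant_levels()))
  kw <- lapply(list(age = classified$age,
                    seizure_count_2mo = classified$seizure_count_2mo),
               function(v) {
    groups <- split(v, q)
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) return(NULL)
    res <- kruskal_wallis(groups)
    posthoc <- if (res$p < config$alpha) dunn_posthoc(groups, names(groups)) else NULL
    list(H = res$H, df = res$df, p = res$p,
         group_sizes = as.list(res$group_sizes), posthoc = posthoc)
  })

  ca <- lapply(tables[c("seizure_status", "epilepsy_status")], function(tab) {
    if (is.null(tab)) return(NULL)
    tryCatch({
      fit <- ca_fit(tab, k = min(2L, min(dim(tab)) - 1L))
      list(singular_values = fit$singular_values,
           total_inertia = fit$total_inertia,
           distances = ca_distances(fit))
    }, error = function(e) NULL)
  })

  de <- NULL
  hh <- classified$patient_id[classified$quadrant == "High-High"]
  nl <- classified$patient_id[classified$quadrant == "Normal-Low"]
  if (length(hh) >= 2L && length(nl) >= 2L) {
    res <- diff_expression(npx, hh, nl, test = config$de_test,
                           alpha = config$alpha, lfc = config$lfc,
                           lfc_relaxed = config$lfc_relaxed)
    de <- list(n_significant = sum(res$significant),
               n_significant_relaxed = sum(res$significant_relaxed),
               top20 = de_top_n(res, 20L),
               results = res)
  }

  counts <- table(factor(per_patient$quadrant,
                         levels = c(quadrant_levels(), "unclassified")))
  list(quadrant_counts = as.list(as.integer(counts)) |>
         stats::setNames(names(counts)),
       contingency_tables = tables,
       chi_square = chisq,
       kruskal_wallis = kw,
       correspondence = ca,
       diffexp = de)
}

#' Run the full stratification pipeline
#'
#' Executes ingest (simulate or read) -> QC filter -> composite scoring and
#' NEFL classification -> percentile banding and quadrant assignment ->
#' association statistics (chi-square with BH post hoc, Kruskal-Wallis with
#' Dunn post hoc) -> correspondence-analysis distances -> differential
#' expression between the High-High and Normal-Low quadrants. When
#' `config$out_dir` is set, stage outputs (wide NPX TSV, per-patient TSV,
#' contingency TSVs) and a machine-readable `report.json` are written there.
#'
#' @param config A [pipeline_config()].
#' @return List of class `analysis_report`: `per_patient` (data frame with
#'   scores, classes and quadrant per patient), the association results (see
#'   details), and `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    clinical <- cohort$clinical
    npx <- cohort$npx
  } else {
    records <- read_npx_long(config$npx_path, config$panel_names)
    npx <- merge_panels(records)
    clinical <- read_clinical(config$clinical_path)
  }
  npx <- suppressMessages(qc_filter(npx))

  block <- if (!is.null(config$simulate)) config$simulate$pi_block_symbols else pi_proteins()
  z <- zscore(npx, block)
  pi <- pi_score(z, block)
  nefl <- classify_nefl(stats::setNames(npx$values[, "NEFL"], rownames(npx$values)),
                        cutoff = config$strat$nefl_cutoff_npx)
  infl <- inflammation_class(pi, config$strat)
  quad <- assign_quadrants(nefl, infl)

  clinical <- derive_clinical(clinical)
  per_patient <- merge(quad, clinical, by = "patient_id", sort = FALSE)
  per_patient$pi_score <- pi$pi_score[match(per_patient$patient_id, pi$sample_id)]
  per_patient$nefl_npx <- nefl$nefl_npx[match(per_patient$patient_id, nefl$sample_id)]
  if (nrow(per_patient) != nrow(quad)) {
    stop("Clinical table and NPX matrix cover different patient sets")
  }

  analysis <- .analyze_cohort(per_patient, npx, config)
  report <- structure(c(
    list(per_patient = per_patient, npx = npx, config = config),
    analysis,
    list(provenance = list(
      config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
      seed = if (!is.null(config$simulate)) config$simulate$seed else NA_integer_,
      package_version = as.character(utils::packageVersion("quadstrat"))
    ))
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_npx_wide(report$npx, file.path(out_dir, "npx_wide.tsv"))
  utils::write.table(report$per_patient, file.path(out_dir, "per_patient.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$contingency_tables)) {
    tab <- report$contingency_tables[[nm]]
    if (is.null(tab)) next
    utils::write.table(data.frame(quadrant = rownames(tab), tab, check.names = FALSE),
                       file.path(out_dir, paste0("contingency_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  slim <- report
  slim$npx <- NULL
  slim$per_patient <- NULL
  slim$config <- NULL
  if (!is.null(slim$diffexp)) slim$diffexp$results <- NULL
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Re-tabulate the pipeline within one epilepsy type
#'
#' Re-runs the association battery on the subset of patients with the given
#' epilepsy type. Quadrant membership is *not* re-derived: the percentile
#' banding and quadrants computed on the full cohort are reused, so a
#' patient's quadrant is identical in the full and subgroup reports.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param filter One of `"focal"`, `"generalized"`, `"unknown"`.
#' @return An `analysis_report` for the subgroup.
#' @export
subgroup_run <- function(report, filter = c("focal", "generalized", "unknown")) {
  stopifnot(inherits(report, "analysis_report"))
  filter <- match.arg(filter)
  sub <- report$per_patient[report$per_patient$epilepsy_type == filter, , drop = FALSE]
  if (nrow(sub) == 0L) stop("Empty subgroup: no ", filter, " patients")
  analysis <- .analyze_cohort(sub, report$npx, report$config)
  structure(c(list(per_patient = sub, npx = report$npx, config = report$config,
                   subgroup = filter),
              analysis,
              list(provenance = report$provenance)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n  quadrant counts: ",
      paste(names(x$quadrant_counts), unlist(x$quadrant_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  for (nm in names(x$chi_square)) {
    r <- x$chi_square[[nm]]
    if (is.null(r)) next
    cat(sprintf("  chi-square %-15s X2 = %6.2f, df = %d, p = %.3f\n",
                nm, r$statistic, r$df, r$p))
  }
  if (!is.null(x$diffexp)) {
    cat(sprintf("  diffexp High-High vs Normal-Low: %d significant (%d relaxed)\n",
                x$diffexp$n_significant, x$diffexp$n_significant_relaxed))
  }
  invisible(x)
}

#' Validate the pipeline against the published summary tables
#'
#' Runs the chi-square, pairwise post hoc, and correspondence-analysis
#' machinery on the packaged quadrant-by-category contingency tables
#' ([fixture_tables()]) and returns the recomputed statistics next to the
#' published values.
#'
#' @return List with per-table chi-square results, the epilepsy-status
#'   pairwise BH-adjusted p-values, and the two CA distance matrices.
#' @export
run_fixture_validation <- function() {
  tabs <- fixture_tables()
  chisq <- lapply(tabs, function(t) {
    r <- suppressWarnings(chi_square(t))
    list(statistic = r$statistic, df = r$df, p = r$p)
  })
  posthoc <- suppressWarnings(pairwise_chi_square(tabs$epilepsy_status))
  dist <- lapply(tabs[c("seizure_status", "epilepsy_status")],
                 function(t) ca_distances(ca_fit(t, k = 2L)))
  list(chi_square = chisq, epilepsy_status_posthoc = posthoc,
       ca_distances = dist)
}
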