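#' Run the full biomarker validation and combination pipeline
#'
#' Chains every stage of the analysis on a set of cohort bundles
#' (simulated or read from disk): marker scoring, responder labelling,
#' per-cohort ROC/Youden evaluation, cross-cohort AUC summaries, cohort
#' merging, Pearson correlation filtering, the exhaustive majority-voting
#' combination search, the marker-frequency report, and the binomial GLM
#' with repeated holdout validation. All tabular results are written as
#' TSV files in `out_dir` together with a JSON manifest recording the
#' thresholds and decisions in force, so a run is reproducible from the
#' manifest alone.
#'
#' @param cohorts A named list of cohort bundles ([simulate_cohorts()] or
#'   [read_cohort()]).
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @param panel Marker panel; defaults to [builtin_panel()].
#' @param r_cut,alpha Pearson filter thresholds (see [pearson_filter()]).
#' @param auc_floor Acceptable-combination AUC floor (see
#'   [frequency_report()]).
#' @param os_cutoff_years Responder rule survival cutoff.
#' @param test_fraction,glm_iterations Repeated-holdout settings.
#' @param seed Seed for the holdout split schedule.
#' @return Invisibly, a list with `scores`, `labels`, `evaluations`,
#'   `summary`, `correlation`, `merged`, `combinations`, `frequencies`,
#'   `glm_fit`, `glm_coefficients`, `cv`.
#' @export
run_pipeline <- function(cohorts, out_dir = NULL, panel = builtin_panel(),
                         r_cut = 0.5, alpha = 0.01, auc_floor = 0.65,
                         os_cutoff_years = 2, test_fraction = 0.2,
                         glm_iterations = 10000, seed = 1L) {
  written <- character(0)
  emit <- function(x, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, name)
    readr::write_tsv(x, f, na = "NA", progress = FALSE)
    written <<- c(written, f)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in written) file.rename(f, paste0(f, ".partial"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  scores <- stage("score", {
    dplyr::bind_rows(purrr::map(cohorts, assemble_scores, panel = panel))
  })
  emit(scores, "marker_scores.tsv")

  labels <- stage("label", {
    dplyr::bind_rows(purrr::map(cohorts, function(b) {
      assign_labels(b$clinical, os_cutoff_years = os_cutoff_years)
    }))
  })
  emit(labels, "labels.tsv")

  evaluations <- stage("evaluate", evaluate_markers(scores, labels))
  emit(dplyr::select(evaluations, -"calls"), "marker_evaluations.tsv")

  summary_tbl <- stage("summarize", summarize_markers(evaluations))
  emit(summary_tbl, "marker_summary.tsv")

  # combination analyses run on the cohorts carrying RNA data, restricted
  # to the markers evaluable in every one of them (mutational load and the
  # plug-ins enter only when present throughout)
  rna_cohorts <- names(cohorts)[vapply(cohorts, function(b) {
    isTRUE(b$rna_available)
  }, logical(1))]

  merged <- stage("merge", {
    if (length(rna_cohorts) == 0) {
      stop("no cohort carries RNA data", call. = FALSE)
    }
    merge_cohorts(evaluations, labels, cohorts = rna_cohorts,
                  intersect_markers = TRUE)
  })

  correlation <- stage("correlate", {
    cont <- scores[scores$cohort %in% rna_cohorts, ]
    shared <- setdiff(names(merged), c("patient_id", "cohort", "label"))
    priority <- stats::setNames(summary_tbl$auc_mean, summary_tbl$marker)
    pearson_filter(cont[c("patient_id", "cohort", shared)],
                   r_cut = r_cut, alpha = alpha, priority = priority)
  })
  emit(dplyr::mutate(correlation$edges,
                     excluded = .data$marker_a %in% correlation$excluded |
                       .data$marker_b %in% correlation$excluded),
       "correlation_report.tsv")

  combinations <- stage("combine", {
    combination_search(merged, markers = sort(correlation$retained))
  })
  emit(combinations, "combination_records.tsv")

  frequencies <- stage("frequencies", {
    frequency_report(combinations, auc_floor = auc_floor)
  })
  emit(frequencies$frequency, "marker_frequencies.tsv")

  glm_fit <- stage("glm", fit_glm(merged, markers = correlation$retained))
  glm_coefs <- coefficient_table(glm_fit)
  emit(glm_coefs, "glm_coefficients.tsv")

  cv <- stage("holdout", {
    repeated_holdout(merged, markers = correlation$retained,
                     test_fraction = test_fraction,
                     iterations = glm_iterations, seed = seed)
  })
  emit(glance(cv), "glm_summary.tsv")

  if (!is.null(out_dir)) {
    manifest <- list(
      package = "icibench",
      version = as.character(utils::packageVersion("icibench")),
      seed = seed,
      cohorts = names(cohorts),
      rna_cohorts = rna_cohorts,
      thresholds = list(
        r_cut = r_cut, alpha = alpha, auc_floor = auc_floor,
        os_cutoff_years = os_cutoff_years,
        test_fraction = test_fraction, glm_iterations = glm_iterations
      ),
      decisions = list(
        gene_set_aggregation = "mean of log2(TPM+1) over genes found",
        roc_orientation = "automatic, AUC >= 0.5 reported with direction",
        youden_ties = "smallest oriented threshold (most sensitive)",
        call_rule = "oriented score >= threshold predicts responder",
        vote_ties = "at least half of markers => responder",
        combination_auc = "(sensitivity + specificity) / 2",
        correlation_exclusion = "exact minimum vertex cover, priority = mean AUC",
        holdout_splits = "simple random, unstratified",
        glm_inputs = "dichotomous per-cohort Youden calls"
      ),
      excluded_markers = correlation$excluded,
      retained_markers = correlation$retained
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(
    scores = scores, labels = labels, evaluations = evaluations,
    summary = summary_tbl, correlation = correlation, merged = merged,
    combinations = combinations, frequencies = frequencies,
    glm_fit = glm_fit, glm_coefficients = glm_coefs, cv = cv
  ))
}
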