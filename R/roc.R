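#' Empirical ROC curve with automatic orientation
#'
#' Builds the empirical receiver operating characteristic curve of a
#' continuous marker against the dichotomous response label. Candidate
#' cutpoints are the midpoints between consecutive distinct sorted scores
#' plus the two infinite endpoints, and a patient is called positive when
#' the oriented score is greater than or equal to the cutpoint.
#'
#' Orientation is automatic: when the raw marker discriminates in the
#' "lower score = responder" direction (raw AUC below 0.5, as for resistance
#' signatures), the score is negated internally so the reported AUC is
#' always at least 0.5, and the direction is recorded.
#'
#' @param scores Numeric marker scores, one per patient.
#' @param labels Response labels: a character vector of
#'   `"responder"`/`"non-responder"`, or a logical vector (`TRUE` =
#'   responder).
#' @return An object of class `ici_roc`: a list with `thresholds`
#'   (ascending, on the oriented scale), `tpr`, `fpr`, `orientation`
#'   (`"higher-is-responder"` or `"lower-is-responder"`), `n_pos`, `n_neg`,
#'   and the oriented `scores`/`labels` used.
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' auc(roc)
#' @export
roc_curve <- function(scores, labels) {
  y <- as_response_logical(labels)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]
  y <- y[keep]
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  if (length(unique(scores)) < 2) {
    warning("all scores identical: flat ROC curve, AUC 0.5", call. = FALSE)
  }
  raw_auc <- rank_auc(scores, y)
  orientation <- if (raw_auc >= 0.5) "higher-is-responder" else "lower-is-responder"
  x <- if (orientation == "higher-is-responder") scores else -scores

  su <- sort(unique(x))
  thr <- if (length(su) >= 2) {
    c(-Inf, (su[-length(su)] + su[-1]) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
  tpr <- vapply(thr, function(t) sum(x >= t & y) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(x >= t & !y) / n_neg, numeric(1))

  structure(
    list(
      thresholds = thr, tpr = tpr, fpr = fpr,
      orientation = orientation,
      n_pos = n_pos, n_neg = n_neg,
      scores = x, labels = y
    ),
    class = "ici_roc"
  )
}

as_response_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  lab <- as.character(labels)
  ok <- lab %in% c("responder", "non-responder") | is.na(lab)
  if (!all(ok)) {
    stop("labels must be responder/non-responder (or logical)", call. = FALSE)
  }
  lab == "responder"
}

# Mann-Whitney AUC: ties contribute 1/2.
rank_auc <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y)
  n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under a ROC curve
#'
#' Trapezoidal area under an [roc_curve()]. With midpoint cutpoints this is
#' identical to the Mann-Whitney rank formulation in which tied
#' responder/non-responder score pairs contribute one half.
#'
#' @param curve An `ici_roc` object.
#' @return AUC in `[0.5, 1]` (orientation guarantees the lower bound).
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "ici_roc"))
  o <- order(curve$fpr, curve$tpr)
  fpr <- curve$fpr[o]
  tpr <- curve$tpr[o]
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Picks the cutpoint maximizing sensitivity + specificity (Youden's J + 1)
#' over all candidate cutpoints of the curve. Ties are broken by the
#' smallest oriented threshold, i.e. the most sensitive of the tied
#' cutpoints.
#'
#' @param curve An `ici_roc` object.
#' @return A tibble with one row: `threshold` (oriented scale),
#'   `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_threshold <- function(curve) {
  stopifnot(inherits(curve, "ici_roc"))
  j <- curve$tpr + (1 - curve$fpr) - 1
  best <- max(j)
  idx <- which(j >= best - 1e-12)
  pick <- idx[which.min(curve$thresholds[idx])]
  tibble::tibble(
    threshold = curve$thresholds[pick],
    sensitivity = curve$tpr[pick],
    specificity = 1 - curve$fpr[pick],
    youden_j = j[pick]
  )
}

#' Evaluate one marker on one cohort
#'
#' Builds the ROC curve, computes the AUC, picks the Youden-optimal
#' threshold and dichotomizes every patient (oriented score >= threshold =>
#' predicted responder). Patients with missing scores are excluded from the
#' evaluation (complete-case per marker).
#'
#' @param scores Numeric marker scores, one per patient.
#' @param labels Response labels (see [roc_curve()]).
#' @param marker,cohort Names recorded in the output.
#' @param patient_ids Optional patient identifiers for the per-patient
#'   calls; defaults to the score vector's names or positional IDs.
#' @return A one-row tibble of class `ici_marker_eval` with columns
#'   `marker`, `cohort`, `n`, `auc`, `orientation`, `threshold`,
#'   `sensitivity`, `specificity`, `youden_j` and a list-column `calls`
#'   holding a tibble (`patient_id`, `call`) of binary responder calls.
#' @export
evaluate_marker <- function(scores, labels, marker = "marker",
                            cohort = "cohort", patient_ids = NULL) {
  if (is.null(patient_ids)) {
    patient_ids <- names(scores) %||% as.character(seq_along(scores))
  }
  y <- as_response_logical(labels)
  keep <- !is.na(scores) & !is.na(y)
  curve <- roc_curve(scores[keep], y[keep])
  yj <- youden_threshold(curve)
  calls <- tibble::tibble(
    patient_id = patient_ids[keep],
    call = as.integer(curve$scores >= yj$threshold)
  )
  out <- tibble::tibble(
    marker = marker, cohort = cohort,
    n = sum(keep),
    auc = auc(curve),
    orientation = curve$orientation,
    threshold = yj$threshold,
    sensitivity = yj$sensitivity,
    specificity = yj$specificity,
    youden_j = yj$youden_j,
    calls = list(calls)
  )
  class(out) <- c("ici_marker_eval", class(out))
  out
}

#' Evaluate every marker on every cohort
#'
#' Applies [evaluate_marker()] to each marker column of a stacked score
#' table, per cohort. Marker/cohort pairs whose score column is entirely
#' missing (data type unavailable) or whose labelled patients cover only one
#' class are skipped.
#'
#' @param scores Score table as returned by [assemble_scores()] (possibly
#'   row-bound over cohorts): `patient_id`, `cohort`, one column per marker.
#' @param labels Label table from [assign_labels()] (`patient_id`, `label`).
#' @return A tibble of class `ici_marker_eval` with one row per evaluable
#'   (marker, cohort) pair; columns as in [evaluate_marker()].
#' @export
evaluate_markers <- function(scores, labels) {
  stopifnot(all(c("patient_id", "cohort") %in% names(scores)))
  marker_cols <- setdiff(names(scores), c("patient_id", "cohort"))
  lab <- labels$label[match(scores$patient_id, labels$patient_id)]
  rows <- purrr::map(split(seq_len(nrow(scores)), scores$cohort), function(i) {
    purrr::map(marker_cols, function(m) {
      s <- scores[[m]][i]
      l <- lab[i]
      keep <- !is.na(s) & !is.na(l)
      if (sum(keep) == 0) return(NULL)
      if (length(unique(l[keep])) < 2) return(NULL)
      evaluate_marker(s, l, marker = m, cohort = scores$cohort[i][1],
                      patient_ids = scores$patient_id[i])
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("ici_marker_eval", class(out))
  out
}

#' Summarize a marker's AUCs across cohorts
#'
#' Joins the per-cohort AUCs of each marker into minimum, mean, maximum and
#' the max-min performance delta.
#'
#' @param evaluations Tibble from [evaluate_markers()].
#' @return A tibble with columns `marker`, `n_datasets`, `auc_min`,
#'   `auc_mean`, `auc_max`, `auc_delta`, sorted by decreasing mean AUC.
#' @export
summarize_markers <- function(evaluations) {
  stopifnot(nrow(evaluations) >= 1)
  evaluations |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      auc_min = min(.data$auc),
      auc_mean = mean(.data$auc),
      auc_max = max(.data$auc),
      auc_delta = max(.data$auc) - min(.data$auc),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$auc_mean))
}

#' Count the evaluable (marker, cohort) tests
#'
#' A marker is testable on a cohort when the cohort carries the marker's
#' data type: RNA markers need expression data, the mutational load needs a
#' WES mutation list.
#'
#' @param rna_available,dna_available Logical vectors, one element per
#'   cohort.
#' @param panel Marker panel tibble; defaults to [builtin_panel()].
#' @return Integer number of evaluable (marker, cohort) pairs.
#' @examples
#' # the study design emulated by the synthetic generator: RNA for 3 of 5
#' # cohorts, WES for all 5, a panel of 17 RNA markers + 1 DNA marker
#' count_tests(c(TRUE, TRUE, FALSE, FALSE, TRUE), rep(TRUE, 5))
#' @export
count_tests <- function(rna_available, dna_available, panel = builtin_panel()) {
  stopifnot(length(rna_available) == length(dna_available))
  n_rna_markers <- sum(panel$origin == "RNA")
  n_dna_markers <- sum(panel$origin == "DNA")
  n_rna_markers * sum(rna_available) + n_dna_markers * sum(dna_available)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
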