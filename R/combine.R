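#' Merge per-cohort dichotomous marker calls into one table
#'
#' Stacks the per-patient binary responder calls of several cohorts into a
#' single patients-by-markers 0/1 table for the combination analyses.
#' Thresholds stay cohort-specific: each cohort's calls come from its own
#' Youden cutpoint, only the resulting dichotomous predictions are pooled.
#'
#' @param evaluations Tibble from [evaluate_markers()] (carries the per
#'   patient `calls` list-column).
#' @param labels Label table (`patient_id`, `label`).
#' @param cohorts Cohorts to merge; default all cohorts present.
#' @param intersect_markers When cohorts were evaluated on different marker
#'   sets, restrict to the shared markers (`TRUE`) or fail (`FALSE`,
#'   default).
#' @return A tibble with `patient_id`, `cohort`, `label` and one integer
#'   0/1 column per marker (1 = marker votes responder).
#' @export
merge_cohorts <- function(evaluations, labels, cohorts = NULL,
                          intersect_markers = FALSE) {
  if (is.null(cohorts)) cohorts <- unique(evaluations$cohort)
  ev <- dplyr::filter(evaluations, .data$cohort %in% cohorts)
  marker_sets <- lapply(split(ev$marker, ev$cohort), unique)
  shared <- Reduce(intersect, marker_sets)
  if (!all(vapply(marker_sets, function(s) setequal(s, shared), logical(1)))) {
    if (!intersect_markers) {
      stop("cohorts were evaluated on different marker sets; ",
           "set intersect_markers = TRUE to restrict to the ",
           length(shared), " shared markers", call. = FALSE)
    }
    if (length(shared) == 0) {
      stop("no marker is shared by all selected cohorts", call. = FALSE)
    }
    ev <- dplyr::filter(ev, .data$marker %in% shared)
  }

  per_cohort <- purrr::map(split(ev, ev$cohort), function(e) {
    wide <- purrr::reduce(
      purrr::map2(e$marker, e$calls, function(m, cl) {
        stats::setNames(cl, c("patient_id", m))
      }),
      function(a, b) dplyr::inner_join(a, b, by = "patient_id")
    )
    dplyr::bind_cols(tibble::tibble(cohort = e$cohort[1]),
                     wide)[, c("patient_id", "cohort", sort(shared))]
  })
  merged <- dplyr::bind_rows(per_cohort)
  dup <- unique(merged$patient_id[duplicated(merged$patient_id)])
  if (length(dup) > 0) {
    stop("duplicate patient IDs across merged cohorts: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  merged$label <- labels$label[match(merged$patient_id, labels$patient_id)]
  dplyr::relocate(merged, "label", .after = "cohort")
}

#' Filter correlated markers by Pearson correlation
#'
#' Computes pairwise Pearson correlations (with two-sided p-values) among
#' all marker columns of a continuous score table, links every pair with
#' `|r| > r_cut` and `p < alpha`, and excludes the minimum number of markers
#' whose removal breaks every such link — an exact minimum vertex cover,
#' feasible for panels of up to ~20 markers. Ties between equal-size covers
#' are broken by excluding the markers with the lowest `priority` (by
#' convention each marker's mean individual AUC), then by name for full
#' determinism.
#'
#' @param scores Tibble with marker columns (any `patient_id`, `cohort`,
#'   `label` columns are ignored); rows are patients, pooled over cohorts.
#' @param r_cut Correlation threshold; pairs above it (in absolute value)
#'   are considered linked.
#' @param alpha Significance level for the correlation test.
#' @param priority Optional named numeric vector, higher = keep in ties.
#' @return An object of class `ici_corr_filter`: list with `markers`, `r`
#'   and `p` (symmetric matrices), `edges` (tibble of linked pairs),
#'   `excluded`, `retained`.
#' @export
pearson_filter <- function(scores, r_cut = 0.5, alpha = 0.01,
                           priority = NULL) {
  marker_cols <- setdiff(names(scores), c("patient_id", "cohort", "label"))
  if (length(marker_cols) < 2) stop("need at least 2 markers", call. = FALSE)
  x <- as.matrix(scores[marker_cols])
  storage.mode(x) <- "double"

  const <- vapply(marker_cols, function(m) {
    v <- x[, m]
    stats::var(v[!is.na(v)]) == 0 || sum(!is.na(v)) < 3
  }, logical(1))
  if (any(const)) {
    stop("correlation undefined for constant or near-empty marker column(s): ",
         paste(marker_cols[const], collapse = ", "), call. = FALSE)
  }

  k <- length(marker_cols)
  r <- diag(1, k)
  p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(marker_cols, marker_cols)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(x[, c(i, j)])
      if (sum(ok) < 3) {
        stop("fewer than 3 complete observations for pair ",
             marker_cols[i], " / ", marker_cols[j], call. = FALSE)
      }
      ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }

  linked <- which(abs(r) > r_cut & p < alpha & upper.tri(r), arr.ind = TRUE)
  edges <- tibble::tibble(
    marker_a = marker_cols[linked[, 1]],
    marker_b = marker_cols[linked[, 2]],
    r = r[linked],
    p = p[linked]
  )

  if (is.null(priority)) priority <- stats::setNames(rep(0, k), marker_cols)
  excluded <- min_vertex_cover(edges$marker_a, edges$marker_b,
                               priority = priority)
  structure(
    list(
      markers = marker_cols, r = r, p = p, edges = edges,
      excluded = excluded, retained = setdiff(marker_cols, excluded),
      r_cut = r_cut, alpha = alpha
    ),
    class = "ici_corr_filter"
  )
}

# Exact minimum vertex cover over the correlation graph. Only vertices
# incident to an edge can be needed, so the search space is the subsets of
# those; subsets are scanned in increasing size, which guarantees minimal
# cardinality. Among minimum covers the one sacrificing the least total
# priority wins; remaining ties go to the lexicographically first cover.
min_vertex_cover <- function(from, to, priority) {
  if (length(from) == 0) return(character(0))
  verts <- sort(unique(c(from, to)))
  if (length(verts) > 20) {
    stop("exact vertex-cover search supports at most 20 linked markers",
         call. = FALSE)
  }
  ia <- match(from, verts)
  ib <- match(to, verts)
  prio <- priority[verts]
  prio[is.na(prio)] <- 0
  for (size in seq_along(verts)) {
    combs <- utils::combn(length(verts), size)
    covers <- which(apply(combs, 2, function(s) {
      all(ia %in% s | ib %in% s)
    }))
    if (length(covers) > 0) {
      cost <- vapply(covers, function(ci) sum(prio[combs[, ci]]), numeric(1))
      best <- covers[order(cost, covers)][1]
      return(verts[combs[, best]])
    }
  }
  verts
}

#' @export
print.ici_corr_filter <- function(x, ...) {
  cat("Pearson correlation filter (|r| >", x$r_cut, ", p <", x$alpha, ")\n")
  cat("  markers:", length(x$markers), " linked pairs:", nrow(x$edges), "\n")
  cat("  excluded:", if (length(x$excluded)) paste(x$excluded, collapse = ", ")
      else "(none)", "\n")
  cat("  retained:", length(x$retained), "markers\n")
  invisible(x)
}

#' Count the marker subsets of size two and above
#'
#' The exhaustive majority-voting search spans every subset of at least two
#' of the `n` retained markers; there are
#' `sum(choose(n, 2:n)) = 2^n - n - 1` such subsets.
#'
#' @param n Number of retained markers (>= 2).
#' @return A tibble with columns `n` and `n_combinations`.
#' @examples
#' enumerate_combinations(17) # 131054 subsets
#' @export
enumerate_combinations <- function(n) {
  if (n < 2) stop("need at least 2 markers to combine", call. = FALSE)
  tibble::tibble(n = n, n_combinations = 2^n - n - 1)
}

#' Majority vote over a set of binary marker calls
#'
#' Predicts a patient as responder when at least half of the subset's
#' markers vote responder; an exact tie therefore goes to the responder
#' class by default (`ties = "non-responder"` flips that reading).
#'
#' @param calls Patients-by-markers 0/1 matrix (or data frame) of
#'   responder votes for the subset; at least two columns, no missing
#'   votes.
#' @param ties Class awarded when exactly half the markers vote responder.
#' @return Integer vector of per-patient predictions (1 = responder).
#' @export
majority_vote <- function(calls, ties = c("responder", "non-responder")) {
  ties <- match.arg(ties)
  m <- as.matrix(calls)
  if (ncol(m) < 2) stop("a combination needs at least 2 markers", call. = FALSE)
  if (anyNA(m)) stop("missing votes in the call matrix", call. = FALSE)
  votes <- rowSums(m)
  half <- ncol(m) / 2
  if (ties == "responder") as.integer(votes >= half) else as.integer(votes > half)
}

#' Evaluate one marker combination by majority voting
#'
#' @param subset Character vector of marker names (>= 2), all columns of
#'   `merged`.
#' @param merged Merged call table from [merge_cohorts()].
#' @param ties Tie-vote rule, see [majority_vote()].
#' @return One-row tibble: `combination`, `size`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `auc`. For a dichotomous predictor the
#'   AUC is the one-point ROC trapezoid, `(sensitivity + specificity) / 2`.
#' @export
evaluate_combination <- function(subset, merged,
                                 ties = c("responder", "non-responder")) {
  ties <- match.arg(ties)
  stopifnot(all(subset %in% names(merged)))
  y <- as_response_logical(merged$label)
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("both classes must be present in the merged table", call. = FALSE)
  }
  pred <- majority_vote(merged[subset], ties = ties) == 1
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    combination = paste(subset, collapse = " + "),
    size = length(subset),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    auc = (sens + spec) / 2
  )
}

#' Exhaustive majority-voting search over all marker subsets
#'
#' Evaluates every subset of at least `min_size` of the marker columns of
#' the merged call table — `2^n - n - 1` subsets for `min_size = 2` — by
#' majority voting. Subsets are enumerated in lexicographic order by marker
#' index; the result is sorted by AUC (descending) then size (ascending)
#' for output stability. The whole search is vectorized by subset size, so
#' the full 17-marker space (131,054 subsets) runs in seconds.
#'
#' @param merged Merged call table from [merge_cohorts()].
#' @param markers Marker columns to search over; default every call column.
#' @param min_size Smallest subset size (default 2).
#' @param ties Tie-vote rule, see [majority_vote()].
#' @return A tibble of class `ici_combination_search` with the columns of
#'   [evaluate_combination()].
#' @export
combination_search <- function(merged, markers = NULL, min_size = 2,
                               ties = c("responder", "non-responder")) {
  ties <- match.arg(ties)
  if (is.null(markers)) {
    markers <- setdiff(names(merged), c("patient_id", "cohort", "label"))
  }
  n <- length(markers)
  if (n < min_size) stop("fewer markers than min_size", call. = FALSE)
  m <- as.matrix(merged[markers])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing votes in the merged call table", call. = FALSE)
  y <- as_response_logical(merged$label)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present in the merged table", call. = FALSE)
  }

  per_size <- purrr::map(min_size:n, function(j) {
    combs <- utils::combn(n, j)
    ncomb <- ncol(combs)
    ind <- matrix(0, n, ncomb)
    ind[cbind(as.vector(combs), rep(seq_len(ncomb), each = j))] <- 1
    votes <- m %*% ind
    pred <- if (ties == "responder") votes >= j / 2 else votes > j / 2
    tp <- as.vector(crossprod(pred, y))
    fp <- as.vector(crossprod(pred, !y))
    sens <- tp / n_pos
    spec <- (n_neg - fp) / n_neg
    tibble::tibble(
      combination = apply(combs, 2, function(s) {
        paste(markers[s], collapse = " + ")
      }),
      size = j,
      tp = tp, fp = fp, tn = n_neg - fp, fn = n_pos - tp,
      sensitivity = sens, specificity = spec,
      auc = (sens + spec) / 2
    )
  })
  out <- dplyr::bind_rows(per_size) |>
    dplyr::arrange(dplyr::desc(.data$auc), .data$size, .data$combination)
  class(out) <- c("ici_combination_search", class(out))
  out
}

#' Marker frequencies among the acceptable combinations
#'
#' Keeps the combinations whose majority-vote AUC reaches `auc_floor` and
#' reports, for each marker, the fraction of those acceptable combinations
#' that contain it, plus the overall acceptable fraction.
#'
#' @param records Combination records from [combination_search()].
#' @param auc_floor Minimum acceptable AUC (default 0.65).
#' @return An object of class `ici_freq_report`: list with `auc_floor`,
#'   `n_records`, `n_acceptable`, `acceptable_fraction` and `frequency`
#'   (tibble `marker`, `frequency`, sorted decreasing).
#' @export
frequency_report <- function(records, auc_floor = 0.65) {
  stopifnot(nrow(records) >= 1)
  acc <- records[records$auc >= auc_floor, ]
  markers <- sort(unique(unlist(strsplit(records$combination, " + ",
                                         fixed = TRUE))))
  if (nrow(acc) == 0) {
    warning("no combination reaches AUC >= ", auc_floor, call. = FALSE)
    freq <- tibble::tibble(marker = markers, frequency = NA_real_)
  } else {
    members <- strsplit(acc$combination, " + ", fixed = TRUE)
    counts <- table(factor(unlist(members), levels = markers))
    freq <- tibble::tibble(
      marker = markers,
      frequency = as.numeric(counts) / nrow(acc)
    ) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$marker)
  }
  structure(
    list(
      auc_floor = auc_floor,
      n_records = nrow(records),
      n_acceptable = nrow(acc),
      acceptable_fraction = nrow(acc) / nrow(records),
      frequency = freq
    ),
    class = "ici_freq_report"
  )
}

#' @export
print.ici_freq_report <- function(x, ...) {
  cat("Majority-voting frequency report (AUC floor ", x$auc_floor, ")\n",
      sep = "")
  cat(sprintf("  acceptable combinations: %d of %d (%.1f%%)\n",
              x$n_acceptable, x$n_records, 100 * x$acceptable_fraction))
  print(utils::head(x$frequency, 10))
  invisible(x)
}

#' @rdname frequency_report
#' @param x An `ici_freq_report` object.
#' @param ... Unused.
#' @export
tidy.ici_freq_report <- function(x, ...) x$frequency
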