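#' Fit a binomial GLM on the merged marker calls
#'
#' Fits a plain logistic regression (binomial family, logit link, maximum
#' likelihood, no penalization) of the responder label on the dichotomous
#' marker calls. Constant feature columns are dropped with a warning.
#' Complete separation is detected (fitted probabilities pinned at 0/1 or a
#' diverging coefficient) and flagged honestly rather than regularized
#' away.
#'
#' @param merged Merged call table from [merge_cohorts()] (columns
#'   `patient_id`, `cohort`, `label`, one column per marker), or any tibble
#'   with a `label` column plus numeric features.
#' @param markers Feature columns to use; default every non-metadata
#'   column.
#' @return An object of class `ici_glm`: list with `model` (the underlying
#'   [stats::glm] fit), `coefficients` (tibble `term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`), `converged`, `separation`,
#'   `n_train`, `markers`. The `t_value` column is the Wald statistic
#'   (estimate / std. error); p-values use its normal approximation.
#' @export
fit_glm <- function(merged, markers = NULL) {
  if (is.null(markers)) {
    markers <- setdiff(names(merged), c("patient_id", "cohort", "label"))
  }
  y <- as_response_logical(merged$label)
  if (anyNA(y)) stop("missing labels", call. = FALSE)
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("both classes must be present to fit the GLM", call. = FALSE)
  }
  x <- as.matrix(merged[markers])
  storage.mode(x) <- "double"
  const <- vapply(seq_len(ncol(x)), function(j) stats::var(x[, j]) == 0,
                  logical(1))
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(markers[const], collapse = ", "), call. = FALSE)
    markers <- markers[!const]
    x <- x[, !const, drop = FALSE]
  }

  dat <- data.frame(.response = as.integer(y), x, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(
      .response ~ ., data = dat, family = stats::binomial(link = "logit")
    ),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
      # non-convergence is reported through the converged flag instead
      if (grepl("did not converge", msg)) invokeRestart("muffleWarning")
    }
  )
  separation <- sep_warn || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = gsub("^`|`$", "", rownames(sm)),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]),
    t_value = unname(sm[, 3]),
    p_value = unname(2 * stats::pnorm(-abs(sm[, 3])))
  )
  structure(
    list(
      model = fit,
      coefficients = coefs,
      converged = fit$converged && !separation,
      separation = separation,
      n_train = nrow(x),
      markers = markers
    ),
    class = "ici_glm"
  )
}

#' Predict response probabilities from a fitted GLM
#'
#' @param fit An `ici_glm` object.
#' @param features Tibble/matrix carrying every feature column of the fit.
#' @return Numeric vector of responder probabilities in (0, 1).
#' @export
predict_glm <- function(fit, features) {
  stopifnot(inherits(fit, "ici_glm"))
  missing_cols <- setdiff(fit$markers, colnames(features))
  if (length(missing_cols) > 0) {
    stop("feature column(s) missing from prediction data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  newdata <- as.data.frame(features[, fit$markers, drop = FALSE])
  names(newdata) <- fit$markers
  unname(stats::predict(fit$model, newdata = newdata, type = "response"))
}

#' @export
print.ici_glm <- function(x, ...) {
  cat("Binomial GLM (logit link) on", length(x$markers), "marker calls,",
      x$n_train, "patients\n")
  if (!x$converged) {
    cat("  WARNING:",
        if (x$separation) "separation detected —" else "did not converge —",
        "coefficients unreliable\n")
  }
  print(x$coefficients)
  invisible(x)
}

#' Tidy a fitted marker GLM
#'
#' @param x An `ici_glm` object.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_error`,
#'   `t_value`, `p_value`).
#' @export
tidy.ici_glm <- function(x, ...) x$coefficients

#' One-row summary of a fitted marker GLM
#'
#' @param x An `ici_glm` object.
#' @param ... Unused.
#' @export
glance.ici_glm <- function(x, ...) {
  tibble::tibble(
    n = x$n_train,
    n_terms = nrow(x$coefficients),
    null_deviance = x$model$null.deviance,
    deviance = x$model$deviance,
    aic = x$model$aic,
    converged = x$converged,
    separation = x$separation
  )
}

#' Coefficient significance table
#'
#' Sorts the GLM terms by p-value and flags significance at the 1% and 5%
#' levels. A non-converged or separated fit is flagged with a warning and
#' in the `reliable` column; its p-values should not be trusted.
#'
#' @param fit An `ici_glm` object.
#' @return Tibble `term`, `estimate`, `std_error`, `t_value`, `p_value`,
#'   `signif_0.01`, `signif_0.05`, `reliable`, sorted by p-value.
#' @export
coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "ici_glm"))
  if (!fit$converged) {
    warning("fit did not converge cleanly (separation or iteration limit); ",
            "p-values are unreliable", call. = FALSE)
  }
  fit$coefficients |>
    dplyr::mutate(
      signif_0.01 = .data$p_value < 0.01,
      signif_0.05 = .data$p_value < 0.05,
      reliable = fit$converged
    ) |>
    dplyr::arrange(.data$p_value)
}

# Fast logistic fit + test metrics for one holdout split; avoids the
# formula machinery of stats::glm inside the 10,000-iteration loop.
holdout_once <- function(x, y, test_idx) {
  ytr <- y[-test_idx]
  yte <- y[test_idx]
  if (sum(yte) == 0 || sum(!yte) == 0) return(NULL)
  if (sum(ytr) == 0 || sum(!ytr) == 0) return(NULL)
  xtr <- x[-test_idx, , drop = FALSE]
  keep <- c(TRUE, apply(xtr, 2, function(v) stats::var(v) > 0))
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, xtr)[, keep, drop = FALSE], as.integer(ytr),
    family = stats::binomial(link = "logit")
  ))
  eta <- cbind(1, x[test_idx, , drop = FALSE])[, keep, drop = FALSE] %*%
    fit$coefficients
  probs <- stats::plogis(as.vector(eta))
  c(auc = rank_auc(probs, yte), youden_scan(probs, yte))
}

# Best (Youden) sensitivity/specificity over midpoint cutpoints, >= rule,
# no orientation flip (probabilities are already directional).
youden_scan <- function(scores, y) {
  su <- sort(unique(scores))
  thr <- if (length(su) >= 2) {
    c(-Inf, (su[-length(su)] + su[-1]) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
  n_pos <- sum(y)
  n_neg <- sum(!y)
  sens <- vapply(thr, function(t) sum(scores >= t & y) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !y) / n_neg, numeric(1))
  i <- which.max(sens + spec)
  c(sensitivity = sens[i], specificity = spec[i])
}

#' Repeated 80/20 holdout validation of the marker GLM
#'
#' Repeatedly splits the merged call table into a random training set
#' (80% by default, simple random — unstratified) and a test set, fits the
#' binomial GLM on the training patients, predicts the held-out patients,
#' and records the test AUC together with the best (Youden-optimal)
#' sensitivity and specificity on the test ROC. Iterations whose training
#' or test set lacks one of the classes are skipped and counted, not
#' imputed.
#'
#' @param merged Merged call table from [merge_cohorts()].
#' @param markers Feature columns; default every call column.
#' @param test_fraction Fraction of patients held out per iteration.
#' @param iterations Number of random splits.
#' @param seed Integer seed making the whole schedule reproducible.
#' @param stratified Draw the test set separately within each class,
#'   preserving the class balance (off by default).
#' @return An object of class `ici_cv`: list with `iterations`,
#'   `valid_iterations`, `degenerate_iterations`, `mean_auc`,
#'   `mean_best_sensitivity`, `mean_best_specificity`, `results`
#'   (per-iteration tibble), `test_fraction`, `seed`.
#' @export
repeated_holdout <- function(merged, markers = NULL, test_fraction = 0.2,
                             iterations = 10000, seed = NULL,
                             stratified = FALSE) {
  if (is.null(markers)) {
    markers <- setdiff(names(merged), c("patient_id", "cohort", "label"))
  }
  x <- as.matrix(merged[markers])
  storage.mode(x) <- "double"
  y <- as_response_logical(merged$label)
  n <- length(y)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("test fraction leaves no training data", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  idx_pos <- which(y)
  idx_neg <- which(!y)
  draws <- purrr::map(seq_len(iterations), function(i) {
    test_idx <- if (stratified) {
      c(sample(idx_pos, max(1L, round(length(idx_pos) * test_fraction))),
        sample(idx_neg, max(1L, round(length(idx_neg) * test_fraction))))
    } else {
      sample.int(n, n_test)
    }
    holdout_once(x, y, test_idx)
  })
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > 0.5) {
    stop("more than half of the holdout iterations had a single-class ",
         "training or test set; the data are too small or too unbalanced ",
         "for this test fraction", call. = FALSE)
  }
  res <- tibble::as_tibble(do.call(rbind, draws[ok]))
  names(res) <- c("auc", "best_sensitivity", "best_specificity")
  res$iteration <- which(ok)
  structure(
    list(
      iterations = iterations,
      valid_iterations = sum(ok),
      degenerate_iterations = sum(!ok),
      mean_auc = mean(res$auc),
      mean_best_sensitivity = mean(res$best_sensitivity),
      mean_best_specificity = mean(res$best_specificity),
      results = res[, c("iteration", "auc", "best_sensitivity",
                        "best_specificity")],
      test_fraction = test_fraction,
      seed = seed
    ),
    class = "ici_cv"
  )
}

#' @export
print.ici_cv <- function(x, ...) {
  cat("Repeated holdout validation:", x$valid_iterations, "valid of",
      x$iterations, "iterations (test fraction", x$test_fraction, ")\n")
  cat(sprintf("  mean AUC %.3f, mean best sensitivity %.3f, mean best specificity %.3f\n",
              x$mean_auc, x$mean_best_sensitivity, x$mean_best_specificity))
  invisible(x)
}

#' Per-iteration holdout results
#'
#' @param x An `ici_cv` object.
#' @param ... Unused.
#' @export
tidy.ici_cv <- function(x, ...) x$results

#' One-row summary of a repeated-holdout run
#'
#' @param x An `ici_cv` object.
#' @param ... Unused.
#' @export
glance.ici_cv <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    valid_iterations = x$valid_iterations,
    degenerate_iterations = x$degenerate_iterations,
    mean_auc = x$mean_auc,
    mean_best_sensitivity = x$mean_best_sensitivity,
    mean_best_specificity = x$mean_best_specificity
  )
}
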