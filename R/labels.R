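#' Assign responder / non-responder labels
#'
#' Dichotomizes heterogeneous clinical annotations with the rule used
#' throughout the package: patients annotated CR, PR, SD or LB (long-term
#' benefit) are responders regardless of survival; PD patients are
#' responders only when their overall survival is known and strictly greater
#' than the cutoff (default 2 years); PD patients with unknown or shorter
#' survival, and NB (no benefit) patients, are non-responders.
#'
#' Overall survival is converted to days internally (1 year = 365.25 days),
#' so cohorts reporting OS in days, months or years mix freely.
#'
#' @param clinical Tibble with columns `patient_id`,
#'   `response_category` (one of CR, PR, SD, PD, LB, NB), `os_value`
#'   (numeric, may be `NA`), `os_unit` (`"days"`, `"months"` or `"years"`)
#'   and `os_known` (logical).
#' @param os_cutoff_years Survival cutoff for PD patients, in years.
#' @return A tibble with columns `patient_id`, `label`
#'   (`"responder"`/`"non-responder"`) and `basis` (`"category-only"` or
#'   `"category+OS"`).
#' @examples
#' clin <- tibble::tibble(
#'   patient_id = c("A", "B", "C"),
#'   response_category = c("PD", "PD", "CR"),
#'   os_value = c(3, NA, 0.5), os_unit = "years",
#'   os_known = c(TRUE, FALSE, TRUE)
#' )
#' assign_labels(clin)
#' @export
assign_labels <- function(clinical, os_cutoff_years = 2) {
  req <- c("patient_id", "response_category", "os_value", "os_unit", "os_known")
  stopifnot(is.data.frame(clinical), all(req %in% names(clinical)))
  valid <- c("CR", "PR", "SD", "PD", "LB", "NB")
  bad <- !clinical$response_category %in% valid
  if (any(bad)) {
    stop("unknown response categories in rows ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(clinical$response_category[bad]), collapse = ", "),
         call. = FALSE)
  }
  os_days <- os_to_days(clinical$os_value, clinical$os_unit)
  cutoff_days <- os_cutoff_years * 365.25
  known <- clinical$os_known & !is.na(os_days)

  is_pd <- clinical$response_category == "PD"
  responder <- clinical$response_category %in% c("CR", "PR", "SD", "LB") |
    (is_pd & known & os_days > cutoff_days)
  tibble::tibble(
    patient_id = clinical$patient_id,
    label = ifelse(responder, "responder", "non-responder"),
    basis = ifelse(is_pd, "category+OS", "category-only")
  )
}

os_to_days <- function(value, unit) {
  factor <- c(days = 1, months = 365.25 / 12, years = 365.25)[unit]
  if (anyNA(factor[!is.na(unit)])) {
    stop("os_unit must be one of days/months/years", call. = FALSE)
  }
  value * unname(factor)
}

#' Responder fraction of a label set
#'
#' @param labels Tibble as returned by [assign_labels()], or any tibble with
#'   a `label` column.
#' @return Fraction of responders among all labelled patients, in `[0, 1]`.
#' @export
label_balance <- function(labels) {
  stopifnot(is.data.frame(labels), "label" %in% names(labels))
  if (nrow(labels) == 0) stop("no labels supplied", call. = FALSE)
  mean(labels$label == "responder")
}
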