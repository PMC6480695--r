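#' Read a TPM expression table
#'
#' Expects a tab-separated file whose first column `gene` holds gene
#' symbols and whose remaining columns are patients. Duplicate gene rows
#' are collapsed by the per-patient maximum (with a warning); duplicate
#' patient columns or non-numeric cells are errors reported with their
#' location.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene` character column and one numeric column
#'   per patient.
#' @export
read_expression <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  if (header[1] != "gene") {
    stop("expression file must have 'gene' as its first column, found '",
         header[1], "'", call. = FALSE)
  }
  dups <- unique(header[duplicated(header)])
  if (length(dups) > 0) {
    stop("duplicate patient column(s) in ", path, ": ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(gene = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop("malformed cell(s) in ", path, ": line ", probs$row[1] , ", column ",
         probs$col[1], " (expected ", probs$expected[1], ")", call. = FALSE)
  }
  if (anyDuplicated(x$gene)) {
    dupg <- unique(x$gene[duplicated(x$gene)])
    warning("collapsing ", length(dupg),
            " duplicated gene symbol(s) by max: ",
            paste(utils::head(dupg, 5), collapse = ", "), call. = FALSE)
    x <- x |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), max),
                       .groups = "drop")
  }
  x
}

#' Read a MAF-like mutation table
#'
#' Minimal MAF dialect: columns `patient_id`, `hugo_symbol`, `chromosome`,
#' `position` (1-based), `ref`, `alt`, `variant_class`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of variant records.
#' @export
read_mutations <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      hugo_symbol = readr::col_character(),
      chromosome = readr::col_character(),
      position = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      variant_class = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop("malformed cell(s) in ", path, ": row ", probs$row[1], ", column ",
         probs$col[1], call. = FALSE)
  }
  x
}

#' Read a clinical annotation table
#'
#' Columns: `patient_id`, `response_category` (CR/PR/SD/PD/LB/NB after any
#' study-specific mapping), `os_value`, `os_unit` (days/months/years),
#' `os_known` (logical).
#'
#' @param path Path to the TSV file.
#' @param response_map Optional named character vector mapping
#'   study-specific response strings to the six canonical codes; applied
#'   before validation.
#' @return A tibble.
#' @export
read_clinical <- function(path, response_map = NULL) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      response_category = readr::col_character(),
      os_value = readr::col_double(),
      os_unit = readr::col_character(),
      os_known = readr::col_logical()
    ),
    progress = FALSE
  )
  if (!is.null(response_map)) {
    mapped <- x$response_category %in% names(response_map)
    x$response_category[mapped] <- response_map[x$response_category[mapped]]
  }
  x
}

#' Read a plug-in marker score table
#'
#' @param path Path to a TSV with a `patient_id` column and one numeric
#'   column per plug-in marker (e.g. TIDE, IPS).
#' @return A tibble.
#' @export
read_plugin_scores <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(patient_id = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
}

cohort_file <- function(directory, cohort_id, what) {
  file.path(directory, paste0(cohort_id, "_", what, ".tsv"))
}

#' Write a cohort bundle to disk
#'
#' Emits up to four TSV files in `directory`, named
#' `<cohort_id>_{expression,mutations,clinical,plugin_scores}.tsv`; the
#' expression and mutation files are only written when the cohort carries
#' that data type. The files round-trip through [read_cohort()].
#'
#' @param bundle A cohort bundle (see [simulate_cohorts()]).
#' @param directory Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_cohort <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  id <- bundle$cohort_id
  written <- character(0)
  if (!is.null(bundle$expression)) {
    f <- cohort_file(directory, id, "expression")
    readr::write_tsv(bundle$expression, f, progress = FALSE)
    written <- c(written, f)
  }
  if (!is.null(bundle$mutations)) {
    f <- cohort_file(directory, id, "mutations")
    readr::write_tsv(bundle$mutations, f, progress = FALSE)
    written <- c(written, f)
  }
  f <- cohort_file(directory, id, "clinical")
  readr::write_tsv(bundle$clinical, f, progress = FALSE)
  written <- c(written, f)
  if (!is.null(bundle$plugin_scores)) {
    f <- cohort_file(directory, id, "plugin_scores")
    readr::write_tsv(bundle$plugin_scores, f, progress = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read a cohort bundle from disk
#'
#' Inverse of [write_cohort()]: availability flags are inferred from file
#' presence.
#'
#' @param directory Directory holding the cohort's TSV files.
#' @param cohort_id Cohort identifier (file-name prefix).
#' @param response_map Optional response-code mapping, see
#'   [read_clinical()].
#' @return A cohort bundle list.
#' @export
read_cohort <- function(directory, cohort_id, response_map = NULL) {
  expr_f <- cohort_file(directory, cohort_id, "expression")
  mut_f <- cohort_file(directory, cohort_id, "mutations")
  clin_f <- cohort_file(directory, cohort_id, "clinical")
  plug_f <- cohort_file(directory, cohort_id, "plugin_scores")
  if (!file.exists(clin_f)) {
    stop("no clinical table for cohort '", cohort_id, "' in ", directory,
         call. = FALSE)
  }
  list(
    cohort_id = cohort_id,
    expression = if (file.exists(expr_f)) read_expression(expr_f) else NULL,
    mutations = if (file.exists(mut_f)) read_mutations(mut_f) else NULL,
    clinical = read_clinical(clin_f, response_map = response_map),
    plugin_scores = if (file.exists(plug_f)) read_plugin_scores(plug_f)
                    else NULL,
    rna_available = file.exists(expr_f),
    dna_available = file.exists(mut_f)
  )
}
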