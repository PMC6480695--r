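#' Configure a synthetic multi-cohort ICI study
#'
#' Builds the configuration for [simulate_cohorts()]. The defaults emulate
#' the shape of the published ICI trial compendium the package benchmarks
#' against: five cohorts of 28/49/33/63/41 patients, expression data for
#' three of them, WES mutation lists for all five, responder fractions
#' between 38% and 70%, marker effects spanning per-marker AUCs from the
#' mid-0.4s to just under 0.9, and one marker pair correlated above 0.5.
#'
#' Marker effects are binormal class-mean shifts on the latent score scale:
#' a marker with effect `delta` is standard normal among non-responders and
#' `N(delta, 1)` among responders, so its population AUC is
#' `pnorm(delta / sqrt(2))` (after orientation, for negative effects).
#' Correlations between latent scores are induced by a Gaussian copula whose
#' off-diagonal entries are adjusted for the label-induced covariance, so
#' the configured Pearson r is recovered on the observed scores.
#'
#' @param cohort_ids Character vector of cohort identifiers.
#' @param n_patients Integer vector, patients per cohort.
#' @param rna_available,dna_available Logical vectors per cohort.
#' @param responder_fraction Numeric vector per cohort, in (0, 1).
#' @param marker_effects Named numeric vector of latent mean shifts; names
#'   must be panel markers. Negative values model resistance markers whose
#'   low scores mark responders.
#' @param marker_correlations Tibble/data frame with columns `marker_a`,
#'   `marker_b`, `r`: target Pearson correlations between observed latent
#'   scores.
#' @param os_unit Unit used in the clinical table: days, months or years.
#' @param baseline_log_expr Baseline log2 expression added to latent scores
#'   when back-filling TPM values.
#' @param signature_noise_sd SD of the independent per-gene noise added
#'   around a signature's latent score.
#' @param mutation_mu,mutation_size Negative-binomial mean and dispersion
#'   of the per-patient mutation count (before the mutational-load effect).
#' @param pd_responder_fraction Fraction of responders annotated PD (their
#'   OS is drawn above the 2-year cutoff).
#' @param nb_fraction Fraction of non-responders annotated NB (the rest are
#'   PD with short or unknown OS).
#' @param os_unknown_fraction Fraction of non-responder PD patients with
#'   unknown OS.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `ici_sim_config`.
#' @export
simulation_config <- function(
    cohort_ids = paste0("SIM", 1:5),
    n_patients = c(28L, 49L, 33L, 63L, 41L),
    rna_available = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    dna_available = rep(TRUE, 5),
    responder_fraction = c(0.57, 0.38, 0.45, 0.52, 0.70),
    marker_effects = default_marker_effects(),
    marker_correlations = tibble::tibble(
      marker_a = "PDCD1", marker_b = "IFN-y (reduced set)", r = 0.6
    ),
    os_unit = c("years", "days", "months"),
    baseline_log_expr = 5,
    signature_noise_sd = 1,
    mutation_mu = 100,
    mutation_size = 1.5,
    pd_responder_fraction = 0.15,
    nb_fraction = 0.3,
    os_unknown_fraction = 0.2,
    seed = 1L) {
  os_unit <- match.arg(os_unit)
  n_cohorts <- length(cohort_ids)
  stopifnot(
    length(n_patients) == n_cohorts,
    length(rna_available) == n_cohorts,
    length(dna_available) == n_cohorts,
    length(responder_fraction) == n_cohorts,
    all(responder_fraction > 0 & responder_fraction < 1),
    all(n_patients >= 1)
  )
  panel <- builtin_panel()
  unknown <- setdiff(names(marker_effects), panel$marker)
  if (length(unknown) > 0) {
    stop("marker_effects names not in the built-in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rna_markers <- panel$marker[panel$origin == "RNA"]
  nonzero_rna <- intersect(names(marker_effects)[marker_effects != 0],
                           rna_markers)
  if (length(nonzero_rna) > 0 && !any(rna_available)) {
    stop("configured effect on RNA marker '", nonzero_rna[1],
         "' but no cohort (", paste(cohort_ids, collapse = ", "),
         ") carries RNA data", call. = FALSE)
  }
  if (!is.null(marker_correlations) && nrow(marker_correlations) > 0) {
    cm <- unique(c(marker_correlations$marker_a, marker_correlations$marker_b))
    bad <- setdiff(cm, panel$marker)
    if (length(bad) > 0) {
      stop("marker_correlations names not in the panel: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      cohort_ids = cohort_ids, n_patients = as.integer(n_patients),
      rna_available = rna_available, dna_available = dna_available,
      responder_fraction = responder_fraction,
      marker_effects = marker_effects,
      marker_correlations = marker_correlations,
      os_unit = os_unit,
      baseline_log_expr = baseline_log_expr,
      signature_noise_sd = signature_noise_sd,
      mutation_mu = mutation_mu, mutation_size = mutation_size,
      pd_responder_fraction = pd_responder_fraction,
      nb_fraction = nb_fraction,
      os_unknown_fraction = os_unknown_fraction,
      seed = as.integer(seed)
    ),
    class = "ici_sim_config"
  )
}

#' Default latent marker effects of the synthetic study
#'
#' Class-mean shifts chosen so the panel's per-marker AUCs span the
#' mid-0.4s to just under 0.9, with a handful of informative markers (TIDE,
#' an ICB resistance signature, CTLA4, POLE4, the mutational load) and the
#' rest near-null. Resistance markers carry negative shifts: their low
#' scores mark responders.
#'
#' @return Named numeric vector over the 18 panel markers.
#' @export
default_marker_effects <- function() {
  # shifts back-solved from the population AUCs the study design assumes
  # via delta = sqrt(2) * qnorm(AUC): TIDE 0.71, ICB resistance signature 1
  # 0.67 (anti-correlated), CTLA4 0.66 for the top three mean AUCs; the
  # remaining markers weakly informative to near-null
  c(
    "CD274" = 0.30,
    "Mutational load" = 0.45,
    "IFN-y (reduced set)" = 0.40,
    "IFN-y (expanded set)" = 0.40,
    "IPS" = 0.43,
    "PDCD1" = 0.35,
    "POLE" = 0.10,
    "POLE2" = 0,
    "POLE3" = -0.10,
    "POLE4" = 0.50,
    "CTLA4" = 0.58,
    "PDCD1LG2" = 0.20,
    "ICB resist. signature 1" = -0.62,
    "ICB resist. signature 2" = -0.15,
    "ICB resist. signature 3" = -0.05,
    "AXL pathway" = -0.25,
    "AXL" = -0.45,
    "TIDE" = 0.78
  )
}

#' Simulate synthetic ICI cohorts
#'
#' Draws, for each configured cohort: latent responder status; latent
#' marker scores from the binormal mean-shift model (correlated pairs via a
#' Gaussian copula); a TPM expression matrix back-filled so that the
#' package's own scoring recovers each RNA marker's latent score (single
#' genes exactly, signatures up to the per-gene noise); a MAF-like mutation
#' list whose per-patient count is a monotone negative-binomial transform
#' of the mutational-load latent score; a clinical table whose response
#' categories and overall survival reproduce the latent labels under the
#' package's responder rule; and plug-in TIDE/IPS score columns for RNA
#' cohorts.
#'
#' @param config An `ici_sim_config` from [simulation_config()].
#' @return A named list of cohort bundles. Each bundle is a list with
#'   `cohort_id`, `expression` (tibble or `NULL`), `mutations` (tibble or
#'   `NULL`), `clinical`, `plugin_scores` (tibble or `NULL`),
#'   `rna_available`, `dna_available`, and `latent` (ground-truth tibble
#'   with the responder status and every latent marker score — for
#'   validation, never an input to the pipeline).
#' @examples
#' cohorts <- simulate_cohorts(simulation_config(seed = 42))
#' names(cohorts)
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "ici_sim_config"))
  set.seed(config$seed)
  panel <- builtin_panel()
  out <- purrr::map(seq_along(config$cohort_ids), function(ci) {
    simulate_one_cohort(config, ci, panel)
  })
  names(out) <- config$cohort_ids
  out
}

simulate_one_cohort <- function(config, ci, panel) {
  n <- config$n_patients[ci]
  id <- config$cohort_ids[ci]
  p <- config$responder_fraction[ci]
  ids <- sprintf("%s_P%03d", id, seq_len(n))

  y <- stats::rbinom(n, 1, p) == 1
  z <- draw_latent_scores(n, y, p, panel$marker, config, panel)

  expression <- NULL
  plugin <- NULL
  if (config$rna_available[ci]) {
    expression <- backfill_expression(z, ids, panel, config)
    plugin <- tibble::tibble(
      patient_id = ids,
      TIDE = z[, "TIDE"],
      IPS = z[, "IPS"]
    )
  }
  mutations <- NULL
  if (config$dna_available[ci]) {
    mutations <- draw_mutations(z[, "Mutational load"], ids, config)
  }
  clinical <- draw_clinical(y, ids, config)

  latent <- dplyr::bind_cols(
    tibble::tibble(patient_id = ids, responder = y),
    tibble::as_tibble(z, .name_repair = "minimal")
  )
  list(
    cohort_id = id,
    expression = expression,
    mutations = mutations,
    clinical = clinical,
    plugin_scores = plugin,
    rna_available = config$rna_available[ci],
    dna_available = config$dna_available[ci],
    latent = latent
  )
}

# Latent scores: Gaussian copula noise + class mean shift. The copula
# entry for a configured pair is adjusted for the label-induced covariance
# delta_a * delta_b * p(1-p) and for the attenuation caused by the per-gene
# noise of gene-set signatures (variance sd^2 / n_genes on the recovered
# score), so the configured Pearson r is what the observed, downstream
# marker scores achieve.
draw_latent_scores <- function(n, y, p, markers, config, panel) {
  k <- length(markers)
  delta <- stats::setNames(rep(0, k), markers)
  delta[names(config$marker_effects)] <- config$marker_effects
  # score-level noise variance added on top of the latent score when the
  # marker is recovered from back-filled expression
  noise_var <- stats::setNames(rep(0, k), markers)
  is_set <- panel$kind == "gene-set"
  noise_var[panel$marker[is_set]] <- config$signature_noise_sd^2 /
    vapply(panel$genes[is_set], length, numeric(1))
  sigma <- diag(1, k)
  dimnames(sigma) <- list(markers, markers)
  mc <- config$marker_correlations
  if (!is.null(mc) && nrow(mc) > 0) {
    v <- p * (1 - p)
    for (i in seq_len(nrow(mc))) {
      a <- mc$marker_a[i]; b <- mc$marker_b[i]
      target <- mc$r[i]
      adj <- target * sqrt((1 + delta[a]^2 * v + noise_var[a]) *
                             (1 + delta[b]^2 * v + noise_var[b])) -
        delta[a] * delta[b] * v
      if (abs(adj) >= 1) {
        stop("target correlation ", target, " between '", a, "' and '", b,
             "' is unattainable given their effect sizes", call. = FALSE)
      }
      sigma[a, b] <- sigma[b, a] <- adj
    }
  }
  noise <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma)
  if (n == 1) noise <- matrix(noise, nrow = 1)
  z <- noise + outer(as.numeric(y), delta)
  colnames(z) <- markers
  z
}

# Back-fill a TPM matrix so that scoring recovers the latent scores.
# Single-gene markers own their gene (log2(TPM+1) = baseline + z exactly);
# signature member genes not owned by a single-gene marker scatter around
# their signature's latent score with independent noise. Genes shared by
# several signatures keep the first assignment (panel order), which leaves
# a mild, realistic correlation between overlapping signatures.
backfill_expression <- function(z, ids, panel, config) {
  base <- config$baseline_log_expr
  logexpr <- list()
  single <- panel[panel$kind == "single-gene", ]
  for (i in seq_len(nrow(single))) {
    logexpr[[single$genes[[i]]]] <- base + z[, single$marker[i]]
  }
  sets <- panel[panel$kind == "gene-set", ]
  for (i in seq_len(nrow(sets))) {
    for (g in sets$genes[[i]]) {
      if (is.null(logexpr[[g]])) {
        logexpr[[g]] <- base + z[, sets$marker[i]] +
          stats::rnorm(length(ids), sd = config$signature_noise_sd)
      }
    }
  }
  genes <- names(logexpr)
  mat <- do.call(rbind, logexpr)
  tpm <- pmax(2^mat - 1, 0)
  dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(stats::setNames(as.data.frame(tpm), ids))
  )
}

# Per-patient counts: monotone negative-binomial transform of the
# mutational-load latent score, so the marker's ROC is preserved while the
# marginal count distribution stays overdispersed-realistic.
draw_mutations <- function(z_ml, ids, config) {
  u <- if (length(z_ml) > 1 && stats::sd(z_ml) > 0) {
    stats::pnorm(z_ml, mean = mean(z_ml), sd = stats::sd(z_ml))
  } else {
    stats::pnorm(z_ml)
  }
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  counts <- stats::qnbinom(u, size = config$mutation_size,
                           mu = config$mutation_mu)
  total <- sum(counts)
  if (total == 0) {
    return(tibble::tibble(
      patient_id = character(0), hugo_symbol = character(0),
      chromosome = character(0), position = integer(0),
      ref = character(0), alt = character(0), variant_class = character(0)
    ))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble::tibble(
    patient_id = rep(ids, counts),
    hugo_symbol = sprintf("GENE%04d", sample.int(5000, total, replace = TRUE)),
    chromosome = as.character(sample(1:22, total, replace = TRUE)),
    position = sample.int(2e8, total, replace = TRUE),
    ref = ref,
    alt = unname(alt),
    variant_class = sample(
      c("Missense_Mutation", "Nonsense_Mutation", "Silent", "Splice_Site"),
      total, replace = TRUE, prob = c(0.6, 0.1, 0.25, 0.05)
    )
  )
}

# Clinical annotations consistent with the latent labels under the 2-year
# responder rule: responders are CR/PR/SD/LB or PD with OS > 2 years;
# non-responders are NB or PD with OS <= 2 years or unknown.
draw_clinical <- function(y, ids, config) {
  n <- length(y)
  category <- character(n)
  os_years <- numeric(n)
  os_known <- logical(n)

  resp <- which(y)
  pd_resp <- resp[stats::runif(length(resp)) < config$pd_responder_fraction]
  cat_resp <- setdiff(resp, pd_resp)
  category[cat_resp] <- sample(c("CR", "PR", "SD", "LB"), length(cat_resp),
                               replace = TRUE, prob = c(0.15, 0.35, 0.35, 0.15))
  os_years[cat_resp] <- stats::rexp(length(cat_resp), rate = 1 / 3)
  os_known[cat_resp] <- TRUE
  category[pd_resp] <- "PD"
  os_years[pd_resp] <- 2 + stats::rexp(length(pd_resp), rate = 1 / 2)
  os_known[pd_resp] <- TRUE

  nonresp <- which(!y)
  nb <- nonresp[stats::runif(length(nonresp)) < config$nb_fraction]
  pd_non <- setdiff(nonresp, nb)
  category[nb] <- "NB"
  os_years[nb] <- stats::rexp(length(nb), rate = 1)
  os_known[nb] <- TRUE
  category[pd_non] <- "PD"
  unknown <- stats::runif(length(pd_non)) < config$os_unknown_fraction
  # OS truncated below the cutoff via inverse-CDF so the label stays exact
  os_years[pd_non] <- stats::qexp(
    stats::runif(length(pd_non)) * stats::pexp(2, rate = 1), rate = 1
  )
  os_known[pd_non] <- !unknown
  os_years[pd_non][unknown] <- NA_real_

  factor_to_unit <- c(years = 1, months = 12, days = 365.25)[config$os_unit]
  tibble::tibble(
    patient_id = ids,
    response_category = category,
    os_value = os_years * unname(factor_to_unit),
    os_unit = config$os_unit,
    os_known = os_known
  )
}
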