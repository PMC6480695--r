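#' The built-in ICI biomarker panel
#'
#' Returns the 18 response biomarkers benchmarked by the package: eight
#' single genes, six gene-set signatures, the absolute tumour mutational
#' load, and two algorithmic plug-in scores (TIDE and IPS) that the package
#' accepts as precomputed columns rather than recomputing.
#'
#' @return A tibble with one row per marker and columns
#'   \describe{
#'     \item{marker}{marker name, used verbatim as a column name downstream}
#'     \item{origin}{`"RNA"` or `"DNA"` — which data type the marker needs}
#'     \item{kind}{`"single-gene"`, `"gene-set"`, `"count"` or `"plug-in"`}
#'     \item{genes}{list-column of HGNC symbols; empty for count and plug-in
#'       markers}
#'     \item{description}{free-text description}
#'   }
#' @examples
#' builtin_panel()
#' @export
builtin_panel <- function() {
  tibble::tibble(
    marker = c(
      "CD274", "Mutational load", "IFN-y (reduced set)", "IFN-y (expanded set)",
      "IPS", "PDCD1", "POLE", "POLE2", "POLE3", "POLE4", "CTLA4", "PDCD1LG2",
      "ICB resist. signature 1", "ICB resist. signature 2",
      "ICB resist. signature 3", "AXL pathway", "AXL", "TIDE"
    ),
    origin = c(
      "RNA", "DNA", "RNA", "RNA", "RNA", "RNA", "RNA", "RNA", "RNA", "RNA",
      "RNA", "RNA", "RNA", "RNA", "RNA", "RNA", "RNA", "RNA"
    ),
    kind = c(
      "single-gene", "count", "gene-set", "gene-set", "plug-in", "single-gene",
      "single-gene", "single-gene", "single-gene", "single-gene", "single-gene",
      "single-gene", "gene-set", "gene-set", "gene-set", "gene-set",
      "single-gene", "plug-in"
    ),
    genes = list(
      "CD274",
      character(0),
      c("CXCL10", "CXCL9", "HLA-DRA", "IDO1", "IFNG", "STAT1"),
      c("CCL5", "CD2", "CD3D", "CD3E", "CIITA", "CXCL10", "CXCL13", "CXCR6",
        "GZMB", "GZMK", "HLA-DRA", "HLA-E", "IDO1", "IL2RG", "LAG3", "NKG7",
        "STAT1", "TAGAP"),
      character(0),
      "PDCD1",
      "POLE",
      "POLE2",
      "POLE3",
      "POLE4",
      "CTLA4",
      "PDCD1LG2",
      c("ADAMTS7", "AXL", "COL12A1", "COL8A1", "FAP", "FBLN1", "INHBA",
        "LOXL2", "MMP1", "MMP13", "ROR2", "TAGLN", "TWIST2", "WNT5A"),
      c("CNN1", "COL3A1", "MXRA7", "SERPINF2"),
      c("CST2", "LAMA3"),
      c("AXL", "FLT1", "FLT4", "GAS6", "KDR", "MERTK", "MET", "RET", "TEK",
        "TYRO3"),
      "AXL",
      character(0)
    ),
    description = c(
      "Programmed death 1 ligand 1 (PD-L1) expression",
      "Absolute number of somatic mutations in WES",
      "Interferon gamma signature, reduced set",
      "Interferon gamma signature, expanded set",
      "ImmunoPhenoScore (external algorithm, plug-in column)",
      "Programmed death 1 (PD-1) expression",
      "DNA polymerase epsilon, catalytic subunit",
      "DNA polymerase epsilon 2, accessory subunit",
      "DNA polymerase epsilon 3, accessory subunit",
      "DNA polymerase epsilon 4, accessory subunit",
      "Cytotoxic T-lymphocyte associated protein 4",
      "Programmed cell death 1 ligand 2",
      "Epithelial-mesenchymal transition / ICB resistance signature 1",
      "Epithelial-mesenchymal transition / ICB resistance signature 2",
      "Epithelial-mesenchymal transition / ICB resistance signature 3",
      "AXL receptor tyrosine kinase pathway",
      "AXL receptor tyrosine kinase",
      "Tumor immune dysfunction and exclusion (external algorithm, plug-in column)"
    )
  )
}

#' Reference gene list of the ImmunoPhenoScore
#'
#' The IPS is an external published algorithm whose score enters this
#' package only as a plug-in column; its gene list is stored here for
#' reference and is never used for scoring. The list is deduplicated and
#' symbol spellings are normalised (no embedded whitespace).
#'
#' @return Character vector of HGNC symbols.
#' @export
ips_reference_genes <- function() {
  genes <- c(
    "ACAP1", "ADRM1", "AHSA1", "AIM2", "APOL3", "ARHGAP10", "ATM", "ATP10D",
    "B2M", "BIRC3", "BRIP1", "C1GALT1C1", "C3AR1", "CASP3", "CASQ1", "CCL20",
    "CCL3L1", "CCL4", "CCL5", "CCNB1", "CCR2", "CCR5", "CCR7", "CCT6B",
    "CD14", "CD160", "CD2", "CD27", "CD274", "CD300E", "CD37", "CD3D",
    "CD3E", "CD3G", "CD55", "CD69", "CD72", "CD86", "CD8A", "CETN3",
    "CFLAR", "CLEC5A", "CMKLR1", "CSE1L", "CTLA4", "CXCR4", "DAPP1", "DARS",
    "DOCK9", "DUSP2", "ESCO2", "ETS1", "EXO1", "EXOC6", "EXOSC9", "EZH2",
    "FCGR2A", "FCGR2B", "FCGR3A", "FCRL6", "FERMT3", "FLT3LG", "FOXP3",
    "GDE1", "GEMIN6", "GNLY", "GPSM3", "GPT2", "GZMA", "GZMH", "GZMK",
    "GZMM", "HAPLN3", "HAVCR2", "HLA-A", "HLA-B", "HLA-C", "HLA-DMB",
    "HLA-DPA1", "HLA-DPB1", "HLA-E", "HLA-F", "IARS", "ICOS", "IDO1",
    "IFI16", "IL18BP", "IL2RB", "IL34", "IL4R", "ITGA4", "ITGAL", "ITGAM",
    "KIF11", "KNTC1", "L1CAM", "LAG3", "LCK", "LIME1", "LIPA", "LRP1",
    "LRRC42", "LTK", "MARCO", "MMP12", "MNDA", "MPZL1", "MRC1", "MS4A6A",
    "NCOA4", "NEFL", "NFKBIA", "NKG7", "NUF2", "PARVG", "PDCD1", "PDCD1LG2",
    "PDGFRL", "PELO", "PIK3IP1", "PLEK", "PRC1", "PRSS23", "PSAP", "PSAT1",
    "PTGER2", "PTGES2", "PTGIR", "PTGS1", "PTRH2", "REPS1", "RGS1", "RTKN2",
    "S100A8", "S100A9", "SAMSN1", "SCG2", "SDPR", "SELL", "SETD7",
    "SIGLEC14", "SIGLEC6", "SIK1", "ST8SIA4", "STAB1", "TAL1", "TAP1",
    "TAP2", "TFEC", "TIGIT", "TIMM13", "TIPIN", "TPK1", "TRAT1", "TRIB2",
    "UQCRB", "USP9Y", "WIPF1", "ZAP70", "ZCRB1"
  )
  unique(genes)
}

# Coerce an expression table (tibble with a `gene` column, one column per
# patient) or an already-built matrix into a genes x patients numeric matrix.
# Duplicate gene symbols are collapsed by max, matching the reader contract.
as_expression_matrix <- function(expression) {
  if (is.matrix(expression)) {
    stopifnot(!is.null(rownames(expression)))
    return(expression)
  }
  stopifnot(is.data.frame(expression), "gene" %in% names(expression))
  genes <- trimws(as.character(expression$gene))
  mat <- as.matrix(expression[setdiff(names(expression), "gene")])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    mat <- do.call(rbind, lapply(split(seq_len(nrow(mat)), genes), function(i) {
      apply(mat[i, , drop = FALSE], 2, max)
    }))
  }
  mat
}

#' Score a single-gene marker
#'
#' The per-patient score of a single-gene marker is `log2(TPM + 1)` of that
#' gene. Gene-symbol matching is exact and case-sensitive after trimming
#' whitespace; no alias resolution is attempted.
#'
#' @param expression Expression table as returned by [read_expression()]
#'   (tibble with a `gene` column and one numeric column per patient), or a
#'   genes-by-patients numeric matrix with gene rownames.
#' @param gene HGNC symbol to score.
#' @return A tibble with columns `patient_id` and `score`.
#' @examples
#' expr <- tibble::tibble(gene = "CD274", P1 = 7, P2 = 0)
#' score_single_gene(expr, "CD274")
#' @export
score_single_gene <- function(expression, gene) {
  mat <- as_expression_matrix(expression)
  gene <- trimws(gene)
  if (!gene %in% rownames(mat)) {
    stop("gene '", gene, "' not found in the expression matrix", call. = FALSE)
  }
  tibble::tibble(
    patient_id = colnames(mat),
    score = unname(log2(mat[gene, ] + 1))
  )
}

#' Score a gene-set signature marker
#'
#' The signature score is the arithmetic mean of `log2(TPM + 1)` over the
#' member genes found in the matrix. Member genes absent from the matrix are
#' skipped (the mean is taken over the genes found) and reported in the
#' `missing_genes` attribute; scoring fails only when no member gene is
#' present at all.
#'
#' @inheritParams score_single_gene
#' @param genes Character vector of member HGNC symbols.
#' @return A tibble with columns `patient_id` and `score`; attribute
#'   `missing_genes` lists member genes absent from the matrix.
#' @export
score_gene_set <- function(expression, genes) {
  mat <- as_expression_matrix(expression)
  genes <- trimws(genes)
  found <- intersect(genes, rownames(mat))
  if (length(found) == 0) {
    stop("none of the ", length(genes),
         " signature genes are present in the expression matrix",
         call. = FALSE)
  }
  logx <- log2(mat[found, , drop = FALSE] + 1)
  out <- tibble::tibble(
    patient_id = colnames(mat),
    score = unname(colMeans(logx))
  )
  attr(out, "missing_genes") <- setdiff(genes, found)
  out
}

#' Score the mutational-load marker
#'
#' Tumour mutational load is the absolute number of somatic variant records
#' per patient. By default records are counted as listed, duplicates
#' included; `dedup = TRUE` counts each distinct
#' (gene, chromosome, position, ref, alt) variant once per patient.
#'
#' @param mutations Tibble of variant records with at least a `patient_id`
#'   column (the MAF-like dialect of [read_mutations()]).
#' @param patient_ids Character vector of patients to report; patients with
#'   no records score 0.
#' @param dedup Count each distinct variant once per patient?
#' @return A tibble with columns `patient_id` and `score` (integer counts).
#' @export
score_mutational_load <- function(mutations, patient_ids, dedup = FALSE) {
  stopifnot(is.data.frame(mutations), "patient_id" %in% names(mutations))
  extra <- setdiff(unique(mutations$patient_id), patient_ids)
  if (length(extra) > 0) {
    stop("mutation records for unknown patients: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (dedup) {
    keys <- intersect(
      c("patient_id", "hugo_symbol", "chromosome", "position", "ref", "alt"),
      names(mutations)
    )
    mutations <- dplyr::distinct(mutations, dplyr::across(dplyr::all_of(keys)))
  }
  counts <- table(factor(mutations$patient_id, levels = patient_ids))
  tibble::tibble(
    patient_id = patient_ids,
    score = as.integer(counts)
  )
}

#' Assemble the per-cohort marker score table
#'
#' Computes one continuous score column per panel marker for a cohort.
#' RNA markers are `NA` when the cohort has no expression data, the
#' mutational load is `NA` without mutation data, and plug-in markers (TIDE,
#' IPS) are taken from `plugin_scores` or left `NA`.
#'
#' @param bundle A cohort bundle as produced by [simulate_cohorts()] or
#'   [read_cohort()]: a list with `cohort_id`, `expression` (tibble or
#'   `NULL`), `mutations` (tibble or `NULL`), `clinical` (tibble) and
#'   optionally `plugin_scores` (tibble with `patient_id` plus plug-in
#'   columns).
#' @param panel Marker panel tibble; defaults to [builtin_panel()].
#' @param plugin_scores Optional override for `bundle$plugin_scores`.
#' @return A tibble with `patient_id`, `cohort` and one numeric column per
#'   panel marker (`NA` where the marker's data type is unavailable).
#' @export
assemble_scores <- function(bundle, panel = builtin_panel(),
                            plugin_scores = bundle$plugin_scores) {
  clinical <- bundle$clinical
  stopifnot(is.data.frame(clinical), "patient_id" %in% names(clinical))
  ids <- clinical$patient_id
  has_rna <- !is.null(bundle$expression)
  has_dna <- !is.null(bundle$mutations)

  if (!is.null(plugin_scores)) {
    stopifnot("patient_id" %in% names(plugin_scores))
    bad <- setdiff(plugin_scores$patient_id, ids)
    if (length(bad) > 0) {
      stop("plug-in scores carry patient IDs not in cohort '",
           bundle$cohort_id, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  score_one <- function(marker, kind, genes) {
    if (kind %in% c("single-gene", "gene-set")) {
      if (!has_rna) return(rep(NA_real_, length(ids)))
      sc <- if (kind == "single-gene") {
        score_single_gene(bundle$expression, genes[[1]])
      } else {
        score_gene_set(bundle$expression, genes)
      }
      sc$score[match(ids, sc$patient_id)]
    } else if (kind == "count") {
      if (!has_dna) return(rep(NA_real_, length(ids)))
      sc <- score_mutational_load(bundle$mutations, ids)
      as.numeric(sc$score[match(ids, sc$patient_id)])
    } else { # plug-in
      if (is.null(plugin_scores) || !marker %in% names(plugin_scores)) {
        return(rep(NA_real_, length(ids)))
      }
      plugin_scores[[marker]][match(ids, plugin_scores$patient_id)]
    }
  }

  cols <- purrr::pmap(
    list(panel$marker, panel$kind, panel$genes),
    function(m, k, g) score_one(m, k, g)
  )
  names(cols) <- panel$marker
  dplyr::bind_cols(
    tibble::tibble(patient_id = ids, cohort = bundle$cohort_id),
    tibble::as_tibble(cols, .name_repair = "minimal")
  )
}
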