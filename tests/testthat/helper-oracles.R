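# Independent oracles: brute-force implementations used only to verify the
# package's fast paths. They share no code with the implementation.

# AUC as the Mann-Whitney pair statistic: over all (responder,
# non-responder) pairs, count wins, half-count ties.
oracle_auc_paircount <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Best sensitivity + specificity by exhaustive scan over every midpoint
# between consecutive distinct sorted scores plus the infinite endpoints
# (>= rule, higher = positive).
oracle_youden_scan <- function(scores, y) {
  su <- sort(unique(scores))
  cand <- c(-Inf, if (length(su) >= 2) (su[-length(su)] + su[-1]) / 2, Inf)
  best <- -Inf
  best_thr <- NA
  for (t in cand) {
    sens <- sum(scores >= t & y) / sum(y)
    spec <- sum(scores < t & !y) / sum(!y)
    if (sens + spec > best + 1e-12) {
      best <- sens + spec
      best_thr <- t
    }
  }
  list(j = best - 1, threshold = best_thr)
}

# Minimum vertex cover size by exhaustive subset search over the vertices
# incident to at least one edge.
oracle_min_cover_size <- function(from, to) {
  if (length(from) == 0) return(0L)
  verts <- unique(c(from, to))
  for (size in seq_along(verts)) {
    combs <- utils::combn(verts, size, simplify = FALSE)
    for (s in combs) {
      if (all(from %in% s | to %in% s)) return(size)
    }
  }
  length(verts)
}

# A small fully-populated synthetic cohort bundle for scoring tests.
toy_bundle <- function(seed = 1, n = 30) {
  cfg <- simulation_config(
    cohort_ids = "TOY", n_patients = n, rna_available = TRUE,
    dna_available = TRUE, responder_fraction = 0.5, seed = seed
  )
  simulate_cohorts(cfg)[[1]]
}
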