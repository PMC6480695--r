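# A small deterministic merged call table: 20 patients, 3 markers.
toy_merged <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:20),
    cohort = rep(c("c1", "c2"), each = 10),
    label = rep(c("responder", "non-responder"), each = 10),
    A = as.integer(1:20 %in% c(1:8, 11:13)),
    B = as.integer(1:20 %in% c(1:6, 11, 12, 14)),
    C = as.integer(1:20 %in% c(5:10, 15))
  )
}

test_that("combination enumeration obeys 2^n - n - 1", {
  expect_equal(enumerate_combinations(17)$n_combinations, 131054)
  expect_equal(enumerate_combinations(2)$n_combinations, 1)
  expect_equal(enumerate_combinations(3)$n_combinations, 4)
  for (n in 2:20) {
    expect_equal(enumerate_combinations(n)$n_combinations,
                 sum(choose(n, 2:n)))
  }
  expect_error(enumerate_combinations(1), "at least 2")
})

test_that("majority voting reads 'at least half' literally", {
  expect_equal(majority_vote(cbind(1, 1, 0)), 1L)
  expect_equal(majority_vote(cbind(1, 0)), 1L)               # tie -> responder
  expect_equal(majority_vote(cbind(1, 0), ties = "non-responder"), 0L)
  expect_equal(majority_vote(cbind(0, 0, 0, 1)), 0L)
  expect_error(majority_vote(cbind(1)), "at least 2")
  expect_error(majority_vote(cbind(c(1, NA), c(0, 1))), "issing")
})

test_that("a subset of identical call copies votes like the single marker", {
  set.seed(7)
  calls <- rbinom(50, 1, 0.5)
  for (k in 2:5) {
    m <- matrix(rep(calls, k), ncol = k)
    expect_equal(majority_vote(m), calls)
  }
})

test_that("evaluate_combination matches a hand-tallied confusion matrix", {
  merged <- toy_merged()
  # subset {A, B}, tie -> responder: predicted = A OR B
  # responders P1..P10: pred 1 for P1..P8       -> TP 8, FN 2
  # non-responders P11..P20: pred 1 for P11..P14 -> FP 4, TN 6
  rec <- evaluate_combination(c("A", "B"), merged)
  expect_equal(rec$tp, 8); expect_equal(rec$fn, 2)
  expect_equal(rec$fp, 4); expect_equal(rec$tn, 6)
  expect_equal(rec$sensitivity, 0.8)
  expect_equal(rec$specificity, 0.6)
  expect_equal(rec$auc, 0.7)
  expect_equal(rec$tp + rec$fp + rec$tn + rec$fn, nrow(merged))

  # predictions identical to labels
  perfect <- merged
  perfect$A <- perfect$B <- as.integer(perfect$label == "responder")
  recp <- evaluate_combination(c("A", "B"), perfect)
  expect_equal(recp$sensitivity, 1)
  expect_equal(recp$specificity, 1)
  expect_equal(recp$auc, 1)

  # all-responder predictor: sens 1, spec 0, AUC 0.5
  allr <- merged
  allr$A <- allr$B <- 1L
  reca <- evaluate_combination(c("A", "B"), allr)
  expect_equal(reca$sensitivity, 1)
  expect_equal(reca$specificity, 0)
  expect_equal(reca$auc, 0.5)
})

test_that("combination_search enumerates every subset and agrees with
           per-subset evaluation", {
  merged <- toy_merged()
  rec <- combination_search(merged)
  expect_equal(nrow(rec), 2^3 - 3 - 1)
  for (i in seq_len(nrow(rec))) {
    subset <- strsplit(rec$combination[i], " + ", fixed = TRUE)[[1]]
    single <- evaluate_combination(subset, merged)
    expect_equal(rec$auc[i], single$auc)
    expect_equal(rec$tp[i], single$tp)
    expect_equal(rec$size[i], length(subset))
  }
  # sorted by AUC descending, then size
  expect_true(all(diff(rec$auc) <= 1e-12))
})

test_that("adding an always-responder marker to an odd subset cannot lower
           sensitivity", {
  set.seed(11)
  merged <- tibble::tibble(
    patient_id = paste0("P", 1:40),
    cohort = "c",
    label = rep(c("responder", "non-responder"), 20),
    A = rbinom(40, 1, 0.6), B = rbinom(40, 1, 0.5), C = rbinom(40, 1, 0.4),
    YES = 1L
  )
  base <- evaluate_combination(c("A", "B", "C"), merged)
  plus <- evaluate_combination(c("A", "B", "C", "YES"), merged)
  expect_gte(plus$sensitivity, base$sensitivity)
})

test_that("pearson_filter links only strong significant pairs and excludes a
           minimal set", {
  set.seed(21)
  n <- 200
  z <- rnorm(n)
  scores <- tibble::tibble(
    patient_id = paste0("P", 1:n),
    M1 = z + rnorm(n, sd = 0.5),          # M1, M2 strongly correlated
    M2 = z + rnorm(n, sd = 0.5),
    M3 = rnorm(n),                        # independent
    M4 = rnorm(n)
  )
  flt <- pearson_filter(scores, priority = c(M1 = 0.7, M2 = 0.6))
  expect_equal(nrow(flt$edges), 1)
  expect_setequal(unique(c(flt$edges$marker_a, flt$edges$marker_b)),
                  c("M1", "M2"))
  expect_equal(flt$excluded, "M2")        # lower priority goes
  expect_setequal(flt$retained, c("M1", "M3", "M4"))
  # matrices are symmetric with unit diagonal
  expect_equal(flt$r, t(flt$r))
  expect_equal(unname(diag(flt$r)), rep(1, 4))
  # among retained markers no pair is linked
  sub <- abs(flt$r[flt$retained, flt$retained])
  expect_true(all(sub[upper.tri(sub)] <= 0.5 |
                    flt$p[flt$retained, flt$retained][upper.tri(sub)] >= 0.01))
})

test_that("a triangle of correlated markers loses exactly two members", {
  set.seed(31)
  n <- 300
  z <- rnorm(n)
  scores <- tibble::tibble(
    patient_id = paste0("P", 1:n),
    T1 = z + rnorm(n, sd = 0.4),
    T2 = z + rnorm(n, sd = 0.4),
    T3 = z + rnorm(n, sd = 0.4),
    U = rnorm(n)
  )
  flt <- pearson_filter(scores)
  expect_equal(nrow(flt$edges), 3)
  expect_equal(length(flt$excluded), 2)
  expect_true("U" %in% flt$retained)
})

test_that("pearson_filter rejects constant columns", {
  scores <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                           M1 = c(1, 2, 3, 4), M2 = 5)
  expect_error(pearson_filter(scores), "M2")
})

test_that("excluded set size matches the exhaustive vertex-cover oracle on
           random correlation structures", {
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(4:9, 1)
    n <- 120
    # random block structure: markers share latent factors at random
    n_fact <- sample(2:4, 1)
    fac <- matrix(rnorm(n * n_fact), n, n_fact)
    assign <- sample(n_fact, k, replace = TRUE)
    x <- sapply(seq_len(k), function(j) {
      fac[, assign[j]] + rnorm(n, sd = runif(1, 0.3, 2))
    })
    scores <- tibble::as_tibble(as.data.frame(x))
    names(scores) <- paste0("M", seq_len(k))
    flt <- pearson_filter(scores, r_cut = 0.4, alpha = 0.05)
    expect_equal(length(flt$excluded),
                 oracle_min_cover_size(flt$edges$marker_a,
                                       flt$edges$marker_b))
  }
})

test_that("merge_cohorts stacks cohorts, keeps labels, rejects collisions", {
  b1 <- toy_bundle(seed = 41, n = 15)
  cfg2 <- simulation_config(cohort_ids = "TOY2", n_patients = 12,
                            rna_available = TRUE, dna_available = TRUE,
                            responder_fraction = 0.5, seed = 42)
  b2 <- simulate_cohorts(cfg2)[[1]]
  scores <- dplyr::bind_rows(assemble_scores(b1), assemble_scores(b2))
  labels <- dplyr::bind_rows(assign_labels(b1$clinical),
                             assign_labels(b2$clinical))
  ev <- evaluate_markers(scores, labels)
  merged <- merge_cohorts(ev, labels)
  expect_equal(nrow(merged), 27)  # 15 + 12
  expect_true(all(merged$label %in% c("responder", "non-responder")))
  call_cols <- setdiff(names(merged), c("patient_id", "cohort", "label"))
  expect_true(all(as.matrix(merged[call_cols]) %in% 0:1))

  # single cohort is the identity on rows
  m1 <- merge_cohorts(ev, labels, cohorts = "TOY")
  expect_equal(nrow(m1), 15)

  # patient-ID collision across cohorts
  collide <- ev
  collide$calls[collide$cohort == "TOY2"] <- lapply(
    collide$calls[collide$cohort == "TOY2"],
    function(d) { d$patient_id <- sub("TOY2", "TOY", d$patient_id); d }
  )
  expect_error(merge_cohorts(collide, labels), "duplicate")
})

test_that("disjoint marker sets across cohorts need the intersection flag", {
  ev <- tibble::tibble(
    marker = c("A", "B", "A", "C"),
    cohort = c("c1", "c1", "c2", "c2"),
    calls = list(
      tibble::tibble(patient_id = c("p1", "p2"), call = c(1L, 0L)),
      tibble::tibble(patient_id = c("p1", "p2"), call = c(0L, 1L)),
      tibble::tibble(patient_id = c("q1", "q2"), call = c(1L, 1L)),
      tibble::tibble(patient_id = c("q1", "q2"), call = c(0L, 0L))
    )
  )
  labels <- tibble::tibble(patient_id = c("p1", "p2", "q1", "q2"),
                           label = c("responder", "non-responder",
                                     "responder", "non-responder"))
  expect_error(merge_cohorts(ev, labels), "intersect_markers")
  merged <- merge_cohorts(ev, labels, intersect_markers = TRUE)
  expect_equal(setdiff(names(merged), c("patient_id", "cohort", "label")),
               "A")
  expect_equal(nrow(merged), 4)
})

test_that("frequency_report computes acceptable fraction and containment", {
  merged <- toy_merged()
  rec <- combination_search(merged)
  fr <- frequency_report(rec, auc_floor = 0)
  expect_equal(fr$acceptable_fraction, 1)
  # with everything acceptable each marker's frequency is its containment
  # rate among all subsets: a marker is in (2^(n-1) - 1) of 2^n - n - 1
  expect_true(all(abs(fr$frequency$frequency - 3 / 4) < 1e-12))

  fr0 <- suppressWarnings(frequency_report(rec, auc_floor = 1.01))
  expect_equal(fr0$acceptable_fraction, 0)
  expect_warning(frequency_report(rec, auc_floor = 1.01), "no combination")

  fr65 <- frequency_report(rec, auc_floor = 0.65)
  expect_equal(fr65$n_acceptable, sum(rec$auc >= 0.65))
  expect_true(all(fr65$frequency$frequency >= 0 &
                    fr65$frequency$frequency <= 1))
})

test_that("informative markers dominate the acceptable combinations", {
  set.seed(91)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  mk_call <- function(acc) ifelse(runif(n) < acc, as.integer(y),
                                  as.integer(runif(n) < 0.5))
  merged <- tibble::tibble(
    patient_id = paste0("P", 1:n), cohort = "c",
    label = ifelse(y, "responder", "non-responder"),
    S1 = mk_call(0.85), S2 = mk_call(0.85), S3 = mk_call(0.85),
    N1 = mk_call(0), N2 = mk_call(0), N3 = mk_call(0), N4 = mk_call(0),
    N5 = mk_call(0), N6 = mk_call(0)
  )
  fr <- frequency_report(combination_search(merged), auc_floor = 0.65)
  top3 <- fr$frequency$marker[1:3]
  expect_setequal(top3, c("S1", "S2", "S3"))
})
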