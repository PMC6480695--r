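sim_glm_data <- function(n, beta, intercept = 0, prefix = "F") {
  k <- length(beta)
  x <- matrix(rbinom(n * k, 1, 0.5), n, k)
  colnames(x) <- paste0(prefix, seq_len(k))
  eta <- intercept + x %*% beta
  y <- runif(n) < plogis(eta)
  dplyr::bind_cols(
    tibble::tibble(patient_id = paste0("P", seq_len(n)), cohort = "c",
                   label = ifelse(y, "responder", "non-responder")),
    tibble::as_tibble(as.data.frame(x))
  )
}

test_that("intercept-only fit on balanced labels estimates logit(0.5) = 0", {
  d <- tibble::tibble(
    patient_id = paste0("P", 1:40), cohort = "c",
    label = rep(c("responder", "non-responder"), 20)
  )
  fit <- fit_glm(d, markers = character(0))
  expect_true(fit$converged)
  expect_equal(nrow(fit$coefficients), 1)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-8)
})

test_that("constant features are dropped with a warning", {
  set.seed(5)
  d <- sim_glm_data(80, beta = c(1, 0.5))
  d$CONST <- 1
  expect_warning(fit <- fit_glm(d), "CONST")
  expect_false("CONST" %in% fit$coefficients$term)
})

test_that("complete separation is detected and flagged, not hidden", {
  d <- tibble::tibble(
    patient_id = paste0("P", 1:30), cohort = "c",
    label = rep(c("responder", "non-responder"), c(15, 15)),
    PERFECT = rep(c(1, 0), c(15, 15)),
    NOISE = rbinom(30, 1, 0.5)
  )
  fit <- fit_glm(d)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_warning(ct <- coefficient_table(fit), "unreliable")
  expect_false(any(ct$reliable))
})

test_that("predict_glm is the inverse-logit of the linear predictor", {
  set.seed(6)
  d <- sim_glm_data(200, beta = c(1, -0.5))
  fit <- fit_glm(d)
  probs <- predict_glm(fit, d)
  expect_true(all(probs > 0 & probs < 1))
  b <- fit$coefficients$estimate
  eta <- b[1] + as.matrix(d[fit$markers]) %*% b[-1]
  expect_equal(probs, as.vector(plogis(eta)), tolerance = 1e-8)
  # an all-zero feature row predicts inverse-logit(intercept)
  zero_row <- d[1, ]
  zero_row[fit$markers] <- 0
  expect_equal(predict_glm(fit, zero_row), unname(plogis(b[1])),
               tolerance = 1e-8)
  expect_error(predict_glm(fit, d[, 1:3]), "missing")
})

test_that("toy logit algebra: beta = (0, log 9) and feature 1 gives 0.9", {
  # build a fit whose coefficients are known by direct construction
  set.seed(8)
  d <- sim_glm_data(400, beta = 2)
  fit <- fit_glm(d)
  fit$model$coefficients[] <- c(0, log(9))
  fit$coefficients$estimate <- c(0, log(9))
  one <- tibble::tibble(F1 = 1)
  expect_equal(predict_glm(fit, one), 0.9, tolerance = 1e-12)
})

test_that("training probabilities average to the responder fraction", {
  set.seed(9)
  d <- sim_glm_data(150, beta = c(0.8, -0.6, 0.3))
  fit <- fit_glm(d)
  expect_equal(mean(predict_glm(fit, d)), mean(d$label == "responder"),
               tolerance = 1e-6)
  # gradient of the log-likelihood is ~0 at the optimum (score equations)
  x <- cbind(1, as.matrix(d[fit$markers]))
  resid <- (d$label == "responder") - predict_glm(fit, d)
  expect_lt(max(abs(crossprod(x, resid))), 1e-6)
})

test_that("coefficients recover the truth within 3 SE on simulated data", {
  set.seed(10)
  beta <- c(1.2, -0.8, 0.5, 0)
  hits <- 0
  total <- 0
  for (r in 1:30) {
    d <- sim_glm_data(1500, beta = beta, intercept = -0.2)
    fit <- fit_glm(d)
    est <- fit$coefficients$estimate[-1]
    se <- fit$coefficients$std_error[-1]
    hits <- hits + sum(abs(est - beta) <= 3 * se)
    total <- total + length(beta)
  }
  expect_gte(hits / total, 0.95)
})

test_that("repeated holdout is deterministic, honest about degeneracy, and
           near 0.5 on shuffled labels", {
  set.seed(12)
  d <- sim_glm_data(150, beta = c(1, 1, -1))
  cv1 <- repeated_holdout(d, iterations = 50, seed = 99)
  cv2 <- repeated_holdout(d, iterations = 50, seed = 99)
  expect_identical(glance(cv1), glance(cv2))
  expect_identical(cv1$results, cv2$results)
  expect_equal(cv1$valid_iterations + cv1$degenerate_iterations, 50)
  expect_true(all(tidy(cv1)$auc >= 0 & tidy(cv1)$auc <= 1))

  # label shuffle: no signal left
  null_d <- d
  set.seed(13)
  null_d$label <- sample(null_d$label)
  cv0 <- repeated_holdout(null_d, iterations = 300, seed = 7)
  expect_lt(abs(cv0$mean_auc - 0.5), 0.05)

  # pathologically unbalanced data trips the reliability error
  tiny <- d[c(which(d$label == "responder")[1], which(d$label != "responder")[1:19]), ]
  expect_error(repeated_holdout(tiny, iterations = 40, seed = 1),
               "single-class")
})

test_that("holdout mean AUC approaches the model's analytic discrimination", {
  # one strong binary feature: P(y|x=1)=plogis(b/2), P(y|x=0)=plogis(-b/2);
  # the analytic ROC of a binary score has
  # AUC = sens*spec + (sens+spec)/2 - ... computed directly below
  set.seed(14)
  b <- 2.5
  d <- sim_glm_data(600, beta = b, intercept = -b / 2)
  # analytic: among x=1 (half the patients) P(resp)=plogis(b/2); x=0:
  # plogis(-b/2). For score=x, AUC = P(x1>x0) + 0.5 P(tie) over class pairs
  p1 <- plogis(b / 2); p0 <- plogis(-b / 2)
  pr_x1_given_resp <- p1 / (p1 + p0)
  pr_x1_given_non <- (1 - p1) / ((1 - p1) + (1 - p0))
  a_analytic <- pr_x1_given_resp * (1 - pr_x1_given_non) +
    0.5 * (pr_x1_given_resp * pr_x1_given_non +
             (1 - pr_x1_given_resp) * (1 - pr_x1_given_non))
  cv <- repeated_holdout(d, iterations = 400, seed = 21)
  expect_lt(abs(cv$mean_auc - a_analytic), 0.03)
})

test_that("coefficient_table sorts by p-value and flags significance", {
  set.seed(15)
  d <- sim_glm_data(400, beta = c(2, 0, 0))
  fit <- fit_glm(d)
  ct <- coefficient_table(fit)
  expect_true(all(diff(ct$p_value) >= 0))
  expect_true(ct$signif_0.01[ct$term == "F1"])
  expect_true(all(ct$signif_0.05 | !ct$signif_0.01))

  # a strong simulated marker is flagged at 1% in most replicates
  flagged <- 0
  for (r in 1:20) {
    dd <- sim_glm_data(300, beta = 2)
    ctt <- coefficient_table(fit_glm(dd))
    flagged <- flagged + ctt$signif_0.01[ctt$term == "F1"]
  }
  expect_gte(flagged / 20, 0.9)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(16)
  d <- sim_glm_data(100, beta = c(0.5, -0.5))
  fit <- fit_glm(d)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "t_value", "p_value"))
  expect_equal(nrow(td), 3)  # intercept + 2 features
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  expect_true(is.logical(gl$converged))
})
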