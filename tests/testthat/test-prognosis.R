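test_that("Cox fitting recovers a planted coefficient and guards input", {
  set.seed(60)
  n <- 500
  v <- rnorm(n)
  sv <- sim_surv(v, censor_rate = 0)
  fit <- cox_fit(v, sv$time, sv$event)
  expect_equal(fit$coefficients[1], 1, tolerance = 0.15)
  expect_true(fit$converged)
  expect_error(cox_fit(rep(1, n), sv$time, sv$event), "constant")
  expect_error(cox_fit(v, sv$time, rep(0, n)), "no events")
})

test_that("the fast univariate path matches the full Cox fit", {
  set.seed(61)
  n <- 80
  v <- rnorm(n)
  sv <- sim_surv(0.5 * v)
  full <- cox_fit(v, sv$time, sv$event)
  fast <- myelomics:::cox_p_uni(v, survival::Surv(sv$time, sv$event))
  expect_equal(fast[1], unname(full$coefficients[1]), tolerance = 1e-9)
  expect_equal(fast[2], unname(full$p_values[1]), tolerance = 1e-9)
})

test_that("the screen keeps only fully quantified features", {
  set.seed(62)
  n <- 60
  X <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("P", 1:5), sprintf("S%02d", 1:n)))
  X[2, 4] <- NA
  sv <- sim_surv(0.8 * X[1, ])
  cl <- make_clinical(colnames(X), sv$time, sv$event)
  res <- cox_screen(make_qm(X, features = rownames(X),
                            samples = colnames(X)), cl)
  expect_false("P2" %in% res$feature_id)  # not fully quantified
  expect_equal(nrow(res), 4)
  expect_lt(res$p_value[res$feature_id == "P1"], 0.05)
  expect_true(all(res$fdr >= res$p_value - 1e-12, na.rm = TRUE))
})

test_that("bootstrap p-value CIs are seeded and separate signal from null", {
  set.seed(63)
  n <- 100
  X <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("P", 1:6), sprintf("S%03d", 1:n)))
  sv <- sim_surv(1.2 * X[1, ])
  cl <- make_clinical(colnames(X), sv$time, sv$event)
  qm <- make_qm(X, features = rownames(X), samples = colnames(X))
  b1 <- bootstrap_p_ci(qm, cl, B = 100, seed = 5)
  b2 <- bootstrap_p_ci(qm, cl, B = 100, seed = 5)
  expect_identical(b1, b2)
  expect_lt(b1$boot_p_upper[b1$feature_id == "P1"], 0.1)
  expect_gt(median(b1$boot_p_upper[-1]), 0.5)  # null features stay high
  expect_true(all(b1$boot_p_upper >= b1$boot_p_lower))
  expect_error(bootstrap_p_ci(qm, cl, B = 1), "at least 2")
})

test_that("candidate gating is the AND of FDR and bootstrap rules", {
  screen <- data.frame(
    feature_id = paste0("P", 1:5),
    coefficient = 1, hazard_ratio = exp(1),
    p_value = c(0.001, 0.002, 0.003, 0.5, 0.004),
    fdr = c(0.05, 0.05, 0.2, 0.5, 0.08),
    stringsAsFactors = FALSE)
  boot <- data.frame(
    feature_id = paste0("P", 1:5),
    boot_p_lower = 0,
    boot_p_upper = c(0.05, 0.2, 0.05, 0.9, 0.09),
    stringsAsFactors = FALSE)
  out <- select_candidates(screen, boot)
  # P1: both pass; P2: fdr ok, upper fails; P3: fdr fails; P5: both pass
  expect_identical(out, c("P1", "P5"))
})

test_that("forward AIC selection drops redundant duplicate covariates", {
  set.seed(64)
  n <- 150
  X <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("A", "B"), sprintf("S%03d", 1:n)))
  X["B", ] <- X["A", ]  # exact duplicate
  sv <- sim_surv(1 * X["A", ])
  cl <- make_clinical(colnames(X), sv$time, sv$event)
  mod <- stepwise_aic(c("A", "B"), X, cl,
                      screen_p = c(A = 1e-5, B = 1e-4))
  expect_identical(mod$proteins, "A")
  expect_length(mod$aic_trace, 1)
  # a single strong candidate yields a 1-protein model beating the null
  mod1 <- stepwise_aic("A", X, cl)
  expect_identical(mod1$proteins, "A")
  expect_error(stepwise_aic(character(0), X, cl), "no candidates")
})

test_that("risk scores are the coefficient-weighted sum with omissions", {
  mod <- structure(list(proteins = c("A", "B"),
                        coefficients = c(A = 0.5, B = -1),
                        aic_trace = numeric(0), endpoint = "pfs"),
                   class = "risk_model")
  x <- make_qm(matrix(c(2, 1), 2, 1), features = c("A", "B"),
               samples = "s1")
  expect_equal(unname(risk_scores(mod, x)), 0)  # 0.5*2 - 1*1
  # linearity in the abundances
  x3 <- make_qm(matrix(c(2, 1) * 3, 2, 1), features = c("A", "B"),
                samples = "s1")
  expect_equal(unname(risk_scores(mod, x3)),
               3 * unname(risk_scores(mod, x)))
  # protein absent from the matrix is omitted with a message
  xa <- make_qm(matrix(c(2, 4), 1, 2), features = "A",
                samples = c("s1", "s2"))
  expect_message(sc <- risk_scores(mod, xa), "B")
  expect_equal(unname(sc), c(1, 2))
  # per-sample missing values are omitted from the sum
  xm <- make_qm(matrix(c(2, NA), 2, 1), features = c("A", "B"),
                samples = "s1")
  expect_equal(unname(risk_scores(mod, xm)), 1)
  xz <- make_qm(matrix(c(0, 0), 2, 1), features = c("A", "B"),
                samples = "s1")
  expect_equal(unname(risk_scores(mod, xz)), 0)
  none <- make_qm(matrix(1, 1, 1), features = "Z", samples = "s1")
  expect_error(risk_scores(mod, none), "no model protein")
  # predict method is the same computation
  expect_equal(predict(mod, x), risk_scores(mod, x))
})

test_that("quartile stratification follows the round(n/4) rule", {
  set.seed(65)
  g100 <- stratify_quartiles(setNames(rnorm(100), sprintf("s%03d", 1:100)))
  expect_equal(unname(table(g100)), c(25L, 50L, 25L), ignore_attr = TRUE)
  g4 <- stratify_quartiles(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(as.character(g4), c("low", "medium", "medium", "high"))
  # all-tied scores: assignment by stable input order
  g8 <- stratify_quartiles(setNames(rep(0, 8), letters[1:8]))
  expect_identical(as.character(g8),
                   c("low", "low", "medium", "medium", "medium",
                     "medium", "high", "high"))
  expect_error(stratify_quartiles(1:3), "at least 4")
  # the low group always holds the smallest scores
  sc <- rnorm(37)
  g <- stratify_quartiles(setNames(sc, paste0("x", 1:37)))
  expect_true(max(sc[g == "low"]) <= min(sc[g == "high"]))
})

test_that("KM medians order with planted hazard and log-rank reacts", {
  set.seed(66)
  n <- 300
  score <- rnorm(n)
  sv <- sim_surv(score, censor_rate = 0.2)
  g <- stratify_quartiles(setNames(score, sprintf("s%03d", 1:n)))
  km <- km_logrank(g, sv$time, sv$event)
  expect_true(km$medians[["low"]] > km$medians[["medium"]])
  expect_true(km$medians[["medium"]] > km$medians[["high"]])
  expect_lt(km$p_value, 0.001)
  expect_equal(km$df, 2)
  expect_error(km_logrank(factor(rep("a", n)), sv$time, sv$event),
               "2 nonempty groups")
})

test_that("multivariable model reports HR per term and drops missing R-ISS", {
  set.seed(67)
  n <- 300
  score <- rnorm(n)
  r_iss <- sample(c("I", "II", "III"), n, replace = TRUE)
  r_iss[1:15] <- NA
  sv <- sim_surv(score, censor_rate = 0.2)
  expect_message(
    res <- multivariable_cox(score, r_iss, sv$time, sv$event),
    "15 sample")
  expect_equal(nrow(res), 3)  # score + R-ISS II + R-ISS III
  hr_score <- res$hr[res$term == "score"]
  expect_equal(hr_score, exp(1), tolerance = 0.2)
  expect_true(res$ci_lower[1] < hr_score & hr_score < res$ci_upper[1])
})

test_that("external transfer omits absent terms and splits at the median", {
  set.seed(68)
  mod <- structure(list(proteins = paste0("P", 1:8),
                        coefficients = setNames(rnorm(8), paste0("P", 1:8)),
                        aic_trace = numeric(0), endpoint = "pfs"),
                   class = "risk_model")
  ext <- random_qm(7, 40, seed = 68)
  rownames(ext) <- paste0("P", 1:7)  # P8 not quantified externally
  ext <- quant_matrix(unclass(ext), "protein")
  expect_message(tr <- transfer_external(mod, ext), "P8")
  expect_identical(tr$omitted, "P8")
  expect_lte(abs(sum(tr$groups == "high") - sum(tr$groups == "low")), 1)
  # single shared protein: scores proportional to that protein
  ext1 <- ext[1, , drop = FALSE]
  suppressMessages(tr1 <- transfer_external(mod, ext1))
  expect_equal(unname(tr1$scores),
               unname(mod$coefficients["P1"] * ext[1, ]))
  # training-cohort consistency: the high quartile lies above the median
  sc <- rnorm(100)
  names(sc) <- paste0("s", 1:100)
  q <- stratify_quartiles(sc)
  expect_true(all(sc[q == "high"] > median(sc)))
})
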