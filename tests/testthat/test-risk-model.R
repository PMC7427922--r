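test_that("logistic fit matches the 2 x 2 closed form and the null", {
  # one binary covariate: coefficient is the log odds ratio of the 2 x 2
  x <- rep(c(0, 1), c(60, 40))
  y <- c(rep(c(0, 1), c(45, 15)), rep(c(0, 1), c(10, 30)))
  m <- fit_logistic(data.frame(exposed = x), y)
  or_closed <- (30 * 45) / (10 * 15)
  expect_equal(unname(m$coefficients["exposed"]), log(or_closed),
               tolerance = 1e-6)
  expect_equal(unname(m$coefficients["(Intercept)"]), log(15 / 45),
               tolerance = 1e-6)
  expect_equal(m$cutoff, m$prevalence)
  expect_true(m$diagnostics$converged)
  # independence: coefficients within 3 SEs of zero, intercept near logit(prev)
  set.seed(101)
  X <- data.frame(a = rnorm(800), b = rbinom(800, 1, 0.4))
  y0 <- rbinom(800, 1, 0.45)
  m0 <- fit_logistic(X, y0)
  se <- sqrt(diag(m0$vcov))
  expect_lt(abs(m0$coefficients[["a"]]), 3 * se[["a"]])
  expect_lt(abs(m0$coefficients[["b"]]), 3 * se[["b"]])
  expect_lt(abs(m0$coefficients[["(Intercept)"]] - qlogis(mean(y0))),
            3 * se[["(Intercept)"]])
})

test_that("degenerate designs are rejected and separation is flagged", {
  X <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))  # aliased
  expect_error(fit_logistic(X, c(0, 1, 0, 1)), "aliased.*b")
  expect_error(fit_logistic(data.frame(a = 1:4), c(1, 1, 1, 1)),
               "single class")
  sep <- data.frame(a = c(rep(0, 20), rep(1, 20)))
  expect_warning(fit_logistic(sep, rep(c(0, 1), each = 20)), "separation")
})

test_that("planted coefficients are recovered by refitting", {
  # averaged over a few replicates so the check reflects estimator bias
  # rather than one draw of sampling noise
  set.seed(102)
  n <- 5000
  truth <- c(diabetes = 1.14, ckd = 1.37, afib = 1.08, diuretic = 1.39)
  est <- rowMeans(vapply(1:5, function(i) {
    X <- data.frame(diabetes = rbinom(n, 1, 0.42), ckd = rbinom(n, 1, 0.44),
                    afib = rbinom(n, 1, 0.29), diuretic = rbinom(n, 1, 0.53))
    y <- rbinom(n, 1, plogis(-1.94 + as.matrix(X) %*% truth))
    m <- fit_logistic(X, y)
    c(m$coefficients[names(truth)], m$coefficients[["(Intercept)"]])
  }, numeric(5)))
  for (i in 1:4) expect_lt(abs(est[i] - truth[[i]]), 0.15)
  expect_lt(abs(est[5] + 1.94), 0.15)
})

test_that("recovery bias shrinks as the cohort grows", {
  bias_at <- function(n, seed) {
    set.seed(seed)
    X <- data.frame(f = rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X$f))
    mean(vapply(1:20, function(i) {
      set.seed(seed + i)
      X <- data.frame(f = rbinom(n, 1, 0.5))
      y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X$f))
      fit_logistic(X, y)$coefficients[["f"]] - 1.2
    }, numeric(1)))
  }
  biases <- abs(c(bias_at(500, 1), bias_at(2000, 2), bias_at(8000, 3)))
  expect_lt(biases[3], 0.05)
  expect_lt(biases[3], biases[1] + 0.02)
})

test_that("the shipped equations evaluate exactly as printed", {
  eq <- whole_cohort_equation()
  all4 <- c(diabetes = 1, ckd = 1, afib = 1, diuretic = 1)
  none <- c(diabetes = 0, ckd = 0, afib = 0, diuretic = 0)
  expect_equal(predict_probability(eq, all4),
               1 / (1 + exp(1.94 - 1.14 - 1.37 - 1.08 - 1.39)),
               tolerance = 1e-12)
  expect_equal(round(predict_probability(eq, all4), 4), 0.9543)
  expect_equal(round(predict_probability(eq, none), 4), 0.1256)
  expect_error(predict_probability(eq, none[-1]), "diabetes")
  # the exponent-subtraction display form and plogis agree on random inputs
  eqB <- cluster_b_equation()
  set.seed(103)
  for (i in 1:20) {
    cov <- c(diabetes = rbinom(1, 1, 0.5), ckd = rbinom(1, 1, 0.5),
             diuretic = rbinom(1, 1, 0.5),
             av_max_gradient = runif(1, 0, 60),
             diastolic_wall_strain = runif(1, 0.1, 0.5))
    expo <- 4.44 - 2.30 * cov["diabetes"] - 2.30 * cov["ckd"] -
      2.28 * cov["diuretic"] + 0.11 * cov["av_max_gradient"] -
      13.29 * cov["diastolic_wall_strain"]
    expect_equal(predict_probability(eqB, cov), unname(1 / (1 + exp(expo))),
                 tolerance = 1e-12)
  }
  eqC <- cluster_c_equation()
  zero <- c(ckd = 0, diuretic = 0, age_dd = 0, esvi = 0)
  expect_equal(round(predict_probability(eqC, zero), 4), 0.0423)
})

test_that("two or more of the four factors always crosses the 53% cutoff", {
  eq <- whole_cohort_equation()
  vars <- model_variables(eq)
  patterns <- expand.grid(rep(list(0:1), 4))
  names(patterns) <- vars
  p <- predict_probability(eq, patterns)
  nfac <- rowSums(patterns)
  expect_identical(p > eq$cutoff, nfac >= 2)
})

test_that("classification counts sensitivity and specificity correctly", {
  eq <- whole_cohort_equation()
  set.seed(104)
  n <- 400
  cov <- data.frame(diabetes = rbinom(n, 1, 0.4), ckd = rbinom(n, 1, 0.45),
                    afib = rbinom(n, 1, 0.3), diuretic = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, predict_probability(eq, cov))
  res <- classify(eq, cov, y)
  expect_equal(res$sensitivity, res$tp / (res$tp + res$fn))
  expect_equal(res$specificity, res$tn / (res$tn + res$fp))
  expect_equal(res$tp + res$fp + res$tn + res$fn, n)
  # cutoff zero predicts everything positive
  res0 <- classify(eq, cov, y, cutoff = 0)
  expect_equal(res0$sensitivity, 1)
  expect_equal(res0$specificity, 0)
  expect_error(classify(eq, cov, integer(0)), "no labelled")
})

test_that("odds ratios exponentiate the printed coefficients", {
  ors <- odds_ratios(whole_cohort_equation())
  expect_equal(round(unname(ors), 2), c(3.13, 3.94, 2.94, 4.01))
  expect_equal(unname(ors["diuretic"]), exp(1.39), tolerance = 1e-12)
  # a zero coefficient is a unit odds ratio
  m <- new_model <- hfpefmap:::new_logistic_model(
    c("(Intercept)" = 0, x = 0), binary_vars = "x", cutoff = 0.5,
    prevalence = 0.5, complete_case_n = 10L)
  expect_equal(unname(odds_ratios(m)["x"]), 1)
})

test_that("predictor selection keeps true signals and prunes duplicates", {
  spec <- small_spec(seed = 105, sizes = c(A = 120L, B = 160L, C = 120L))
  cohort <- simulate_cohort(spec)
  # a literal duplicate of a true predictor: exactly one survives
  schema <- attr(cohort, "schema")
  schema2 <- variable_schema(c(schema$name, "ckd_copy"),
                            c(schema$kind, "categorical"),
                            c(schema$levels, list(c("yes", "no"))),
                            c(schema$units, ""))
  cohort2 <- cohort
  cohort2$ckd_copy <- cohort2$ckd
  cohort2 <- hfpefmap:::as_cohort_table(cohort2, schema2)
  m <- suppressWarnings(
    select_predictors(cohort2, candidates = c("ckd", "ckd_copy")))
  expect_equal(length(model_variables(m)), 1L)
  expect_true(model_variables(m) %in% c("ckd", "ckd_copy"))
})

test_that("selection recovers planted predictors among noise variables", {
  truth <- c(diabetes = 1.14, ckd = 1.37, afib = 1.08, diuretic = 1.39)
  hits <- 0L; noise_kept <- integer(0)
  n <- 1000
  for (seed in 1:10) {
    set.seed(200 + seed)
    df <- data.frame(patient_id = sprintf("P%04d", 1:n))
    for (v in names(truth)) df[[v]] <- ifelse(rbinom(n, 1, 0.45) == 1,
                                              "yes", "no")
    for (j in 1:10) df[[paste0("noise", j)]] <- rnorm(n)
    eta <- -1.94 + rowSums(sapply(names(truth), function(v)
      truth[[v]] * (df[[v]] == "yes")))
    df$outcome <- rbinom(n, 1, plogis(eta))
    sch <- variable_schema(
      c(names(truth), paste0("noise", 1:10)),
      c(rep("categorical", 4), rep("numeric", 10)),
      c(rep(list(c("yes", "no")), 4), vector("list", 10)))
    tab <- hfpefmap:::as_cohort_table(df, sch)
    m <- suppressWarnings(select_predictors(tab, candidates = sch$name))
    kept <- model_variables(m)
    if (all(names(truth) %in% kept)) hits <- hits + 1L
    noise_kept <- c(noise_kept, sum(grepl("noise", kept)))
  }
  expect_gte(hits, 8L)
  expect_lte(mean(noise_kept), 1)
})

test_that("all-noise candidates give an empty model with a warning", {
  set.seed(106)
  n <- 300
  df <- data.frame(patient_id = sprintf("P%03d", 1:n))
  for (j in 1:6) df[[paste0("noise", j)]] <- rnorm(n)
  df$outcome <- rbinom(n, 1, 0.5)
  sch <- variable_schema(paste0("noise", 1:6), rep("numeric", 6),
                         vector("list", 6))
  # under the null each variable survives at roughly the screening level, so
  # most seeds keep nothing and the average kept count stays well below 1
  kept <- vapply(1:10, function(seed) {
    set.seed(400 + seed)
    for (j in 1:6) df[[paste0("noise", j)]] <- rnorm(n)
    df$outcome <- rbinom(n, 1, 0.5)
    tab <- hfpefmap:::as_cohort_table(df, sch)
    m <- suppressWarnings(select_predictors(tab, candidates = sch$name))
    length(model_variables(m))
  }, integer(1))
  expect_gte(sum(kept == 0L), 5L)
  expect_lte(mean(kept), 1)
})

test_that("two-fold folds alternate within outcome strata", {
  spec <- small_spec(seed = 107, sizes = c(A = 54L, B = 54L, C = 54L))
  spec$missing_rates <- numeric(0)
  cohort <- attach_outcomes(generate_cohort(spec), spec)
  cv <- twofold_cv(cohort, fixed_variables = c("ckd", "diuretic"))
  fold <- cv$fold
  y <- cohort$outcome[match(names(fold), cohort$patient_id)]
  for (s in unique(y)) {
    sizes <- table(fold[y == s])
    expect_lte(abs(diff(as.integer(sizes))), 1L)
  }
  expect_equal(length(cv$directions), 2L)
  expect_equal(sort(unique(fold)), c(1L, 2L))
})

test_that("cross-validated predictions beat chance on a planted-signal cohort", {
  set.seed(108)
  n <- 600
  df <- data.frame(patient_id = sprintf("P%04d", 1:n))
  truth <- c(diabetes = 1.14, ckd = 1.37, afib = 1.08, diuretic = 1.39)
  for (v in names(truth)) df[[v]] <- ifelse(rbinom(n, 1, 0.45) == 1,
                                            "yes", "no")
  eta <- -1.94 + rowSums(sapply(names(truth), function(v)
    truth[[v]] * (df[[v]] == "yes")))
  df$outcome <- rbinom(n, 1, plogis(eta))
  sch <- variable_schema(names(truth), rep("categorical", 4),
                         rep(list(c("yes", "no")), 4))
  tab <- hfpefmap:::as_cohort_table(df, sch)
  cv <- twofold_cv(tab, fixed_variables = names(truth))
  for (d in cv$directions) {
    expect_gt(d$discovery$accuracy, 0.5)
    expect_gt(d$validation$accuracy, 0.5)
  }
})

test_that("validation accuracy shows optimism relative to discovery on average", {
  set.seed(109)
  gaps <- vapply(1:60, function(i) {
    n <- 160
    df <- data.frame(patient_id = sprintf("P%03d", 1:n),
                     f1 = ifelse(rbinom(n, 1, 0.5) == 1, "yes", "no"),
                     f2 = rnorm(n))
    eta <- -0.3 + 0.8 * (df$f1 == "yes") + 0.4 * df$f2
    df$outcome <- rbinom(n, 1, plogis(eta))
    sch <- variable_schema(c("f1", "f2"), c("categorical", "numeric"),
                           list(c("yes", "no"), NULL))
    tab <- hfpefmap:::as_cohort_table(df, sch)
    cv <- twofold_cv(tab, fixed_variables = c("f1", "f2"))
    mean(vapply(cv$directions, function(d)
      d$discovery$accuracy - d$validation$accuracy, numeric(1)))
  }, numeric(1))
  expect_gte(mean(gaps), 0)
})

test_that("diastolic wall strain derives from the posterior-wall thicknesses", {
  expect_equal(diastolic_wall_strain(2.0, 1.4), 0.3)
  expect_equal(diastolic_wall_strain(c(2, 1.6), c(1.5, 1.2)),
               c(0.25, 0.25))
})
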