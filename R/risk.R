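#' Build a numeric covariate frame from cohort variables
#'
#' Categorical variables contribute the indicator of their first declared
#' level (for the default yes/no comorbidity and medication variables this is
#' the positive-history indicator); numeric variables enter as-is.
#'
#' @param table a cohort table.
#' @param variables variable names.
#' @param schema a [variable_schema()].
#' @return data.frame of numeric covariates (may contain `NA`).
#' @export
covariate_frame <- function(table, variables, schema = cohort_schema(table)) {
  out <- list()
  for (v in variables) {
    entry <- schema_lookup(schema, v)
    out[[v]] <- if (entry$kind == "categorical") {
      as.numeric(table[[v]] == entry$levels[[1]][1])
    } else {
      as.numeric(table[[v]])
    }
  }
  as.data.frame(out, optional = TRUE)
}

#' Diastolic wall strain from posterior-wall thickness
#'
#' Standard definition `(LVPWs - LVPWd) / LVPWs` from the systolic and
#' diastolic left-ventricular posterior wall thicknesses, used as a stiffness
#' surrogate continuous predictor.
#'
#' @param lv_pw_systole,lv_pw_diastole wall thickness in cm.
#' @return strain as a fraction.
#' @export
diastolic_wall_strain <- function(lv_pw_systole, lv_pw_diastole) {
  (lv_pw_systole - lv_pw_diastole) / lv_pw_systole
}

new_logistic_model <- function(coefficients, binary_vars, cutoff, prevalence,
                               complete_case_n, vcov = NULL,
                               diagnostics = list(converged = TRUE,
                                                  iterations = NA_integer_,
                                                  loglik = NA_real_),
                               label = "logistic risk model") {
  structure(list(coefficients = coefficients, binary_vars = binary_vars,
                 cutoff = cutoff, prevalence = prevalence,
                 complete_case_n = complete_case_n, vcov = vcov,
                 diagnostics = diagnostics, label = label),
            class = "logistic_model")
}

#' Model variables (excluding the intercept)
#' @param model a `logistic_model`.
#' @export
model_variables <- function(model) {
  setdiff(names(model$coefficients), "(Intercept)")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(x$label, "\n")
  b0 <- x$coefficients[["(Intercept)"]]
  terms <- character(0)
  for (v in model_variables(x)) {
    b <- x$coefficients[[v]]
    terms <- c(terms, if (v %in% x$binary_vars) {
      sprintf("- (0 or %.2f)_%s", b, v)
    } else {
      sprintf("%s %.2f*%s", if (b >= 0) "-" else "+", abs(b), v)
    })
  }
  cat("  P = 1 / (1 + exp(", sprintf("%.2f ", -b0), paste(terms, collapse = " "),
      "))\n", sep = "")
  cat("  classification cutoff: P >", sprintf("%.3f", x$cutoff),
      " (complete-case n =", x$complete_case_n, ", prevalence",
      sprintf("%.3f", x$prevalence), ")\n")
  invisible(x)
}

#' Fit a logistic outcome model by maximum likelihood
#'
#' Standard binomial GLM fit by iteratively reweighted least squares
#' (coefficient tolerance 1e-8, at most 50 iterations). The classification
#' cutoff defaults to the complete-case outcome prevalence. Quasi-separation
#' (any |coefficient| > 15) is flagged with a warning; a rank-deficient
#' design is rejected naming the aliased columns.
#'
#' @param X data.frame or matrix of numeric covariates, complete cases.
#' @param y binary outcome (0/1), both classes present.
#' @param cutoff classification cutoff; default the outcome prevalence.
#' @return A `logistic_model`.
#' @export
fit_logistic <- function(X, y, cutoff = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 1L) stop("need at least one covariate")
  if (anyNA(X) || anyNA(y)) stop("fit_logistic requires complete cases")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  dat <- cbind(.y = y, X)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  b <- stats::coef(fit)
  names(b) <- c("(Intercept)", names(X))
  if (any(abs(b) > 15))
    warning("possible separation: |coefficient| > 15 for ",
            paste(names(b)[abs(b) > 15], collapse = ", "))
  binary_vars <- names(X)[vapply(X, function(col)
    all(col %in% c(0, 1)), logical(1))]
  prevalence <- mean(y)
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(names(b), names(b))
  new_logistic_model(
    coefficients = b, binary_vars = binary_vars,
    cutoff = cutoff %||% prevalence, prevalence = prevalence,
    complete_case_n = length(y), vcov = vc,
    diagnostics = list(converged = fit$converged, iterations = fit$iter,
                       loglik = as.numeric(stats::logLik(fit))))
}

wald_p <- function(model) {
  se <- sqrt(diag(model$vcov))
  z <- model$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  p[setdiff(names(p), "(Intercept)")]
}

#' Predicted HFpEF probability
#'
#' Evaluates `P = plogis(b0 + sum(b * x))`, which is identically the
#' exponent-subtraction form `P = 1 / (1 + exp(a - sum(...)))` with
#' `a = -b0` used to display the model.
#'
#' @param model a `logistic_model`.
#' @param covariates named numeric vector, list, or data.frame containing
#'   every model variable (rows are patients for a data.frame).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, covariates) {
  vars <- model_variables(model)
  if (is.data.frame(covariates) || is.matrix(covariates)) {
    covariates <- as.data.frame(covariates)
    missing_vars <- setdiff(vars, names(covariates))
    if (length(missing_vars))
      stop("missing covariate(s): ", paste(missing_vars, collapse = ", "))
    eta <- model$coefficients[["(Intercept)"]] +
      as.matrix(covariates[vars]) %*% model$coefficients[vars]
    return(stats::plogis(as.numeric(eta)))
  }
  covariates <- unlist(covariates)
  missing_vars <- setdiff(vars, names(covariates))
  if (length(missing_vars))
    stop("missing covariate(s): ", paste(missing_vars, collapse = ", "))
  stats::plogis(model$coefficients[["(Intercept)"]] +
                  sum(model$coefficients[vars] * covariates[vars]))
}

#' Classify patients at a probability cutoff
#'
#' Predicts progression to HFpEF when the model probability strictly exceeds
#' the cutoff (by default the model's complete-case prevalence), and scores
#' the predictions against supplied labels.
#'
#' @param model a `logistic_model`.
#' @param covariates data.frame of model covariates, one row per patient.
#' @param y observed binary outcomes.
#' @param cutoff probability threshold in (0, 1).
#' @return A `classification_result`: confusion counts, sensitivity
#'   `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy and the cutoff used.
#' @export
classify <- function(model, covariates, y, cutoff = model$cutoff) {
  if (length(y) == 0L) stop("no labelled cases supplied")
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1)")
  p <- predict_probability(model, covariates)
  pred <- as.integer(p > cutoff)
  y <- as.integer(y)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / length(y), cutoff = cutoff),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "Classification at P > %.3f: sens %.1f%%, spec %.1f%%, acc %.1f%% (TP %d FP %d TN %d FN %d)\n",
    x$cutoff, 100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Per-variable odds ratios
#'
#' `exp(|coefficient|)` for binary history variables (the odds multiplier for
#' a positive history) and `exp(coefficient)` per unit for continuous terms.
#'
#' @param model a `logistic_model`.
#' @return named numeric vector of odds ratios.
#' @export
odds_ratios <- function(model) {
  vars <- model_variables(model)
  b <- model$coefficients[vars]
  ifelse(vars %in% model$binary_vars, exp(abs(b)), exp(b)) |>
    stats::setNames(vars)
}

#' Univariate screening and progressive predictor addition
#'
#' The model-building procedure: (1) screen each candidate with a univariate
#' logistic fit, keeping those with Wald p < `alpha`; (2) add survivors in
#' order of univariate significance; (3) after each addition, if an already
#' included variable has become non-significant and its pairwise association
#' with the newcomer (Pearson correlation of the numeric covariates, which is
#' the phi coefficient for a pair of indicators) exceeds `collinearity_r`,
#' drop the less significant of the pair; (4) finally prune until every
#' retained variable stays significant while adjusting for the others. The
#' returned model is refit complete-case on the final variable set.
#'
#' @param table a cohort table.
#' @param outcome name of the outcome column (default `"outcome"`).
#' @param candidates candidate variable names.
#' @param alpha significance level for screening and retention.
#' @param collinearity_r absolute-correlation threshold treated as collinear.
#' @return A `logistic_model`, or (with a warning) an intercept-only model
#'   when no candidate passes screening.
#' @export
select_predictors <- function(table, outcome = "outcome", candidates,
                              alpha = 0.05, collinearity_r = 0.5) {
  schema <- cohort_schema(table)
  missing_vars <- setdiff(candidates, names(table))
  if (length(missing_vars))
    stop("candidate(s) not in table: ", paste(missing_vars, collapse = ", "))
  y_all <- as.integer(table[[outcome]])
  Xall <- covariate_frame(table, candidates, schema)
  screen <- data.frame(variable = candidates, p = NA_real_)
  for (i in seq_along(candidates)) {
    ok <- !is.na(Xall[[i]]) & !is.na(y_all)
    if (sum(ok) < 10L || length(unique(y_all[ok])) < 2L) next
    m <- tryCatch(suppressWarnings(
      fit_logistic(Xall[ok, i, drop = FALSE], y_all[ok])),
      error = function(e) NULL)
    if (!is.null(m)) screen$p[i] <- wald_p(m)[[1]]
  }
  keep <- screen[!is.na(screen$p) & screen$p < alpha, ]
  if (nrow(keep) == 0L) {
    warning("no candidate passed univariate screening at alpha = ", alpha)
    prev <- mean(y_all, na.rm = TRUE)
    return(new_logistic_model(
      coefficients = c("(Intercept)" = stats::qlogis(prev)),
      binary_vars = character(0), cutoff = prev, prevalence = prev,
      complete_case_n = sum(!is.na(y_all)),
      label = "logistic risk model (empty: no predictor survived screening)"))
  }
  keep <- keep[order(keep$p), ]
  included <- character(0)
  refit <- function(vars) {
    ok <- stats::complete.cases(Xall[vars]) & !is.na(y_all)
    suppressWarnings(fit_logistic(Xall[ok, vars, drop = FALSE], y_all[ok]))
  }
  for (v in keep$variable) {
    trial <- c(included, v)
    m <- tryCatch(refit(trial), error = function(e) NULL)
    if (is.null(m)) {
      # perfectly collinear with something already included: keep the
      # earlier (more significant) variable
      next
    }
    p <- wald_p(m)
    repeat {
      drop_candidate <- NULL
      for (w in setdiff(trial, v)) {
        ok <- !is.na(Xall[[w]]) & !is.na(Xall[[v]])
        r <- suppressWarnings(stats::cor(Xall[[w]][ok], Xall[[v]][ok]))
        if (!is.na(p[w]) && p[w] > alpha && !is.na(r) &&
            abs(r) > collinearity_r) {
          drop_candidate <- if (is.na(p[v]) || p[w] >= p[v]) w else v
          break
        }
      }
      if (is.null(drop_candidate)) break
      trial <- setdiff(trial, drop_candidate)
      if (!length(trial)) break
      m <- refit(trial)
      p <- wald_p(m)
      if (!v %in% trial) break
    }
    included <- trial
  }
  # final pruning: every variable significant while adjusting for the others
  while (length(included) > 1L) {
    m <- refit(included)
    p <- wald_p(m)
    if (all(p < alpha)) break
    included <- setdiff(included, names(p)[which.max(p)])
  }
  if (!length(included)) {
    warning("progressive addition eliminated every candidate")
    prev <- mean(y_all, na.rm = TRUE)
    return(new_logistic_model(
      coefficients = c("(Intercept)" = stats::qlogis(prev)),
      binary_vars = character(0), cutoff = prev, prevalence = prev,
      complete_case_n = sum(!is.na(y_all)),
      label = "logistic risk model (empty)"))
  }
  refit(included)
}

#' Alternating two-fold cross-validation of a fixed-variable risk model
#'
#' The cohort is restricted to complete cases on `fixed_variables`, then
#' split in two by assigning alternating members (ordered by patient id
#' within each outcome stratum, so fold sizes per stratum differ by at most
#' one). Coefficients are refitted on each discovery fold in turn and
#' classification accuracy at the discovery-fold prevalence cutoff is
#' reported for both the discovery and the held-out validation fold, in both
#' directions.
#'
#' @param table a cohort table.
#' @param outcome outcome column name.
#' @param fixed_variables the variable set (held fixed across folds, as when
#'   the whole-cohort selection is being validated).
#' @return A `cv_result`: fold assignment, per-direction refitted
#'   coefficients and discovery/validation accuracies.
#' @export
twofold_cv <- function(table, outcome = "outcome", fixed_variables) {
  schema <- cohort_schema(table)
  X <- covariate_frame(table, fixed_variables, schema)
  y <- as.integer(table[[outcome]])
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  ids <- table$patient_id[ok]
  fold <- integer(length(y))
  for (s in unique(y)) {
    idx <- which(y == s)
    if (length(idx) < 2L) stop("outcome stratum with < 2 members")
    idx <- idx[order(ids[idx])]
    fold[idx] <- rep(c(1L, 2L), length.out = length(idx))
  }
  run <- function(discovery) {
    tr <- fold == discovery
    vars <- names(X)
    # a covariate can become constant or aliased inside one fold; drop it
    # there (with a warning) rather than aborting the whole validation
    m <- NULL
    while (length(vars)) {
      m <- tryCatch(
        suppressWarnings(fit_logistic(X[tr, vars, drop = FALSE], y[tr])),
        error = function(e) e)
      if (!inherits(m, "error")) break
      aliased <- vars[vapply(vars, function(v)
        grepl(v, conditionMessage(m), fixed = TRUE), logical(1))]
      if (!length(aliased) || !grepl("aliased", conditionMessage(m)))
        stop(m)
      warning("fold ", discovery, ": dropping aliased covariate(s) ",
              paste(aliased, collapse = ", "))
      vars <- setdiff(vars, aliased)
    }
    if (inherits(m, "error") || is.null(m)) stop("no usable covariates in fold")
    list(discovery_fold = discovery, coefficients = m$coefficients,
         discovery = classify(m, X[tr, , drop = FALSE], y[tr]),
         validation = classify(m, X[!tr, , drop = FALSE], y[!tr]))
  }
  structure(list(fold = stats::setNames(fold, ids),
                 directions = list(run(1L), run(2L)),
                 n = length(y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Alternating two-fold cross-validation (n =", x$n, ")\n")
  for (d in x$directions) {
    cat(sprintf("  discovery fold %d: accuracy %.1f%% | validation %.1f%%\n",
                d$discovery_fold, 100 * d$discovery$accuracy,
                100 * d$validation$accuracy))
  }
  invisible(x)
}

risk_equation <- function(intercept_a, binary = numeric(0),
                          continuous = numeric(0), cutoff, label) {
  # `binary` holds the magnitudes subtracted in the exponent for a positive
  # history; `continuous` holds the signed multipliers as they appear in the
  # exponent. Standard log-odds parameterisation: b0 = -a, b_bin = +binary,
  # b_cont = -continuous.
  b <- c("(Intercept)" = -intercept_a, binary, -continuous)
  new_logistic_model(
    coefficients = b, binary_vars = names(binary), cutoff = cutoff,
    prevalence = cutoff, complete_case_n = NA_integer_, label = label)
}

#' Reference risk equations
#'
#' The three fitted prediction equations shipped as evaluable fixtures: the
#' whole-cohort model (four binary predictors — diabetes, chronic kidney
#' disease, atrial fibrillation, diuretic use — with prevalence cutoff
#' 53.0%), the cluster B model (adds the aortic-valve maximum gradient and
#' diastolic wall strain as continuous terms, cutoff 61.8%) and the cluster C
#' model (chronic kidney disease, diuretic use, age at diastolic-dysfunction
#' diagnosis and end-systolic volume index, cutoff 41.3%).
#'
#' @return A `logistic_model`.
#' @export
whole_cohort_equation <- function() {
  risk_equation(1.94,
                binary = c(diabetes = 1.14, ckd = 1.37, afib = 1.08,
                           diuretic = 1.39),
                cutoff = 0.530,
                label = "Whole-cohort HFpEF risk equation")
}

#' @rdname whole_cohort_equation
#' @export
cluster_b_equation <- function() {
  risk_equation(4.44,
                binary = c(diabetes = 2.30, ckd = 2.30, diuretic = 2.28),
                continuous = c(av_max_gradient = 0.11,
                               diastolic_wall_strain = -13.29),
                cutoff = 0.618,
                label = "Cluster B HFpEF risk equation")
}

#' @rdname whole_cohort_equation
#' @export
cluster_c_equation <- function() {
  risk_equation(3.12,
                binary = c(ckd = 1.23, diuretic = 1.79),
                continuous = c(age_dd = -0.06, esvi = 0.17),
                cutoff = 0.413,
                label = "Cluster C HFpEF risk equation")
}
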