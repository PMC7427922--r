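#' @keywords internal
"_PACKAGE"

# Columns of a cohort table that are never clinical variables: identifiers,
# latent labels, outcomes and censored event times. They are excluded from
# encoding/clustering and never masked by the missingness generator.
RESERVED_COLUMNS <- c("patient_id", "true_cluster", "outcome",
                      "time_to_hfpef", "hfpef_observed",
                      "time_to_death", "death_observed", "age_at_dd")

#' Clinical variable names of a cohort table
#'
#' @param table a cohort table as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @return character vector of variable column names (reserved bookkeeping
#'   columns removed).
#' @export
cohort_variables <- function(table) {
  setdiff(names(table), RESERVED_COLUMNS)
}

cohort_schema <- function(table) {
  sch <- attr(table, "schema")
  if (is.null(sch)) stop("cohort table carries no variable schema")
  sch
}

as_cohort_table <- function(df, schema) {
  attr(df, "schema") <- schema
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "patients,", length(cohort_variables(x)),
      "clinical variables\n")
  if ("outcome" %in% names(x) && !all(is.na(x$outcome)))
    cat("  HFpEF prevalence:",
        sprintf("%.1f%%", 100 * mean(x$outcome, na.rm = TRUE)), "\n")
  if ("true_cluster" %in% names(x) && !all(is.na(x$true_cluster)))
    cat("  latent phenogroups:",
        paste(names(table(x$true_cluster)), table(x$true_cluster),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Moment-matched log-normal: generated mean and SD equal the requested ones.
rlnorm_matched <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic cohort from a specification
#'
#' Draws each patient's numeric variables from per-cluster Gaussians (or
#' moment-matched log-normals for skewed biomarkers) and categorical variables
#' from per-cluster multinomials, recording the latent phenogroup label.
#' Outcome and event-time columns are initialised to `NA`; attach them with
#' [attach_outcomes()]. Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A cohort table (data frame, class `"cohort_table"`) with one row
#'   per patient, carrying its [variable_schema()] as an attribute.
#' @examples
#' spec <- default_cohort_spec(seed = 7)
#' cohort <- generate_cohort(spec)
#' table(cohort$true_cluster)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  sizes <- spec$cluster_sizes
  if (is.null(names(sizes))) names(sizes) <- LETTERS[seq_along(sizes)]
  n <- sum(sizes)
  cl_idx <- rep(seq_along(sizes), sizes)
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (v in spec$numeric_vars) {
    x <- numeric(n)
    for (k in seq_along(sizes)) {
      idx <- which(cl_idx == k)
      if (isTRUE(v$log_normal) && v$sd[k] > 0 && v$mean[k] > 0) {
        x[idx] <- rlnorm_matched(length(idx), v$mean[k], v$sd[k])
      } else {
        x[idx] <- stats::rnorm(length(idx), v$mean[k], v$sd[k])
      }
    }
    df[[v$name]] <- x
  }
  for (v in spec$categorical_vars) {
    x <- character(n)
    for (k in seq_along(sizes)) {
      idx <- which(cl_idx == k)
      x[idx] <- sample(v$levels, length(idx), replace = TRUE,
                       prob = v$probs[k, ])
    }
    df[[v$name]] <- x
  }
  df$true_cluster <- names(sizes)[cl_idx]
  df$outcome <- NA_integer_
  df$time_to_hfpef <- NA_real_
  df$hfpef_observed <- NA
  df$time_to_death <- NA_real_
  df$death_observed <- NA
  df$age_at_dd <- if ("age_dd" %in% names(df)) df$age_dd else
    stats::rnorm(n, 70, 10)
  as_cohort_table(df, spec_schema(spec))
}

#' Attach logistic outcomes and censored event times to a cohort
#'
#' The HFpEF progression indicator is drawn Bernoulli with probability
#' `plogis(intercept + sum(coef * covariate))` evaluated on the (pre-masking)
#' variable values: categorical covariates are indicators of the variable's
#' first level, numeric covariates enter linearly. Progressors receive a
#' time from diastolic-dysfunction diagnosis to HFpEF drawn from the
#' horizon-truncated exponential with their cluster's rate (so every
#' progressor's event is observed inside the administrative window, keeping
#' `outcome == 1` equivalent to an observed HFpEF event); death times are the
#' HFpEF time plus (or, for non-progressors, directly) an exponential
#' residual, administratively censored at `spec$censor_horizon`.
#'
#' @param table a cohort table with latent `true_cluster` labels.
#' @param spec the [cohort_spec()] that generated it.
#' @param seed optional seed; defaults to `spec$seed + 1` so the draw is
#'   independent of the variable draw yet reproducible.
#' @return The cohort table with `outcome`, `time_to_hfpef`,
#'   `hfpef_observed`, `time_to_death` and `death_observed` filled in.
#' @export
attach_outcomes <- function(table, spec, seed = spec$seed + 1L) {
  oc <- spec$outcome_coefficients
  vars <- setdiff(names(oc), "(Intercept)")
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    stop("outcome_coefficients reference unknown variables: ",
         paste(missing_vars, collapse = ", "))
  schema <- cohort_schema(table)
  set.seed(seed)
  n <- nrow(table)
  eta <- rep(if ("(Intercept)" %in% names(oc)) oc[["(Intercept)"]] else 0, n)
  for (v in vars) {
    entry <- schema_lookup(schema, v)
    x <- if (entry$kind == "categorical") {
      as.numeric(table[[v]] == entry$levels[[1]][1])
    } else {
      table[[v]]
    }
    if (anyNA(x)) stop("attach_outcomes requires pre-masking values for '", v, "'")
    eta <- eta + oc[[v]] * x
  }
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  sizes <- spec$cluster_sizes
  if (is.null(names(sizes))) names(sizes) <- LETTERS[seq_along(sizes)]
  k_of <- match(table$true_cluster, names(sizes))
  if (anyNA(k_of)) stop("attach_outcomes requires latent true_cluster labels")
  horizon <- spec$censor_horizon
  rate_h <- spec$hazard_params$hfpef_rate[k_of]
  rate_d <- spec$hazard_params$death_rate[k_of]
  # truncated exponential on [0, horizon] by inverse CDF
  u <- stats::runif(n)
  t_hfpef_event <- -log(1 - u * (1 - exp(-rate_h * horizon))) / rate_h
  t_death_raw <- ifelse(outcome == 1L, t_hfpef_event, 0) + stats::rexp(n, rate_d)
  death_observed <- t_death_raw <= horizon
  time_to_death <- pmin(t_death_raw, horizon)
  hfpef_observed <- outcome == 1L
  time_to_hfpef <- ifelse(hfpef_observed, t_hfpef_event, time_to_death)
  table$outcome <- outcome
  table$time_to_hfpef <- time_to_hfpef
  table$hfpef_observed <- hfpef_observed
  table$time_to_death <- time_to_death
  table$death_observed <- death_observed
  table
}

#' Mask values completely at random (MCAR)
#'
#' Each clinical value is independently set to missing with its variable's
#' rate. Identifier, outcome and event-time columns are never masked.
#'
#' @param table a cohort table.
#' @param rates named numeric vector of masking fractions in \[0, 1\], keyed
#'   by variable name.
#' @param seed integer seed.
#' @return The cohort table with `NA`s injected.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  if (length(rates) == 0L) return(table)
  vars <- cohort_variables(table)
  bad <- setdiff(names(rates), vars)
  if (length(bad))
    stop("missingness rates reference unknown variables: ",
         paste(bad, collapse = ", "))
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0, 1]")
  set.seed(seed)
  for (v in names(rates)) {
    if (rates[[v]] == 0) next
    hit <- stats::runif(nrow(table)) < rates[[v]]
    table[[v]][hit] <- NA
  }
  table
}

#' Append one extreme-valued patient to a cohort
#'
#' Adds a single patient whose LVOT flow measurements sit `z` pooled standard
#' deviations above the cohort mean, emulating the kind of measurement
#' outlier the preprocessing screen ([screen_outliers()]) is designed to
#' remove. All other variables are copied from a donor row.
#'
#' @param table a cohort table.
#' @param variables numeric variables to inflate.
#' @param z how many SDs above the mean to place the values (default 12, so
#'   the patient stays beyond an 8-SD screen even after inflating the SD).
#' @return The cohort table with one extra row (id suffix `"X"`).
#' @export
add_outlier_patient <- function(table,
                                variables = c("lvot_velocity_max",
                                              "lvot_velocity_mean",
                                              "lvot_max_gradient",
                                              "lvot_mean_gradient"),
                                z = 12) {
  stopifnot(nrow(table) >= 1, all(variables %in% names(table)))
  row <- table[nrow(table), , drop = FALSE]
  row$patient_id <- paste0(row$patient_id, "X")
  for (v in variables) {
    x <- table[[v]]
    row[[v]] <- mean(x, na.rm = TRUE) + z * stats::sd(x, na.rm = TRUE)
  }
  out <- rbind(table, row)
  as_cohort_table(out, cohort_schema(table))
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper chaining [generate_cohort()], [attach_outcomes()] and
#' [inject_missingness()], optionally appending the planted measurement
#' outlier so the full screen-encode-impute-cluster pipeline is exercised.
#'
#' @param spec a [cohort_spec()]; defaults to [default_cohort_spec()].
#' @param include_outlier append one extreme patient ([add_outlier_patient()]).
#' @return A cohort table with outcomes, event times and missingness.
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), include_outlier = FALSE) {
  cohort <- generate_cohort(spec)
  cohort <- attach_outcomes(cohort, spec)
  if (include_outlier) cohort <- add_outlier_patient(cohort)
  inject_missingness(cohort, spec$missing_rates, seed = spec$seed + 2L)
}

#' Write / read a cohort as delimited text with a schema sidecar
#'
#' The cohort is written comma-separated with a header row and missing values
#' as empty fields; the schema goes to `<stem>_schema.tsv` (see
#' [write_schema()]). `read_cohort()` accepts the same dialect for user data:
#' any of the reserved outcome/event-time columns may be absent.
#'
#' @param table a cohort table.
#' @param path path of the cohort csv file.
#' @param schema_path path of the schema file; defaults alongside `path`.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a cohort
#'   table.
#' @export
write_cohort <- function(table, path,
                         schema_path = sub("\\.csv$", "_schema.tsv", path)) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  write_schema(cohort_schema(table), schema_path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = sub("\\.csv$", "_schema.tsv", path)) {
  schema <- read_schema(schema_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_vars <- setdiff(schema$name, names(df))
  if (length(missing_vars))
    stop("cohort file lacks schema variables: ",
         paste(missing_vars, collapse = ", "))
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    if (schema$kind[i] == "numeric") {
      df[[v]] <- as.numeric(df[[v]])
    } else {
      obs <- !is.na(df[[v]])
      bad <- setdiff(unique(df[[v]][obs]), schema$levels[[i]])
      if (length(bad))
        stop("variable '", v, "' has undeclared level(s): ",
             paste(bad, collapse = ", "))
      df[[v]] <- as.character(df[[v]])
    }
  }
  if (!"patient_id" %in% names(df))
    df$patient_id <- sprintf("P%04d", seq_len(nrow(df)))
  if (anyDuplicated(df$patient_id)) stop("patient_id values must be unique")
  as_cohort_table(df, schema)
}
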