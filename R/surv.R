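#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator `S(t) = prod(1 - d_i/n_i)` over
#' event times up to `t`; at tied times events are processed before
#' censorings (the standard convention). The median is the smallest time at
#' which `S(t) <= 0.5`, `NA` when the curve never reaches 0.5.
#'
#' @param time nonnegative event/censoring times (years).
#' @param event logical or 0/1; `TRUE` when the event was observed.
#' @return An object of class `"survival_curve"`: `time` (distinct observed
#'   times), `survival`, `at_risk`, `n_events`, `n_censored` per time, plus
#'   `median` and `n`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one sample")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and nonnegative")
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  s <- fit$surv
  med <- if (any(s <= 0.5)) fit$time[which(s <= 0.5)[1]] else NA_real_
  structure(list(time = fit$time, survival = s, at_risk = fit$n.risk,
                 n_events = fit$n.event, n_censored = fit$n.censor,
                 median = med, n = length(time)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_events),
      ", median =",
      if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median), "\n")
  invisible(x)
}

#' Survival curve as a data frame
#' @param x a `survival_curve`.
#' @param ... unused.
#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(time = x$time, survival = x$survival, at_risk = x$at_risk,
             n_events = x$n_events, n_censored = x$n_censored)
}

#' Log-rank test comparing survival distributions
#'
#' Standard observed-minus-expected log-rank chi-square across groups,
#' df = number of groups - 1.
#'
#' @param time event/censoring times.
#' @param event event indicators.
#' @param group group labels (>= 2 groups, >= 1 event overall).
#' @return A `test_result`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events observed in any group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(sd$n) - 1L
  test_result(sd$chisq, df,
              stats::pchisq(sd$chisq, df, lower.tail = FALSE),
              method = "Log-rank test")
}

trajectory_endpoints <- function(table) {
  # Four disease-trajectory endpoints. Patients who never develop HFpEF are
  # censored for the HFpEF endpoints at their last known time alive;
  # HFpEF-to-death endpoints are defined for progressors only.
  prog <- table$hfpef_observed %in% TRUE
  list(
    dd_to_hfpef = data.frame(
      time = table$time_to_hfpef, event = as.integer(prog),
      keep = !is.na(table$time_to_hfpef)),
    age_at_hfpef = data.frame(
      time = table$age_at_dd + table$time_to_hfpef, event = as.integer(prog),
      keep = !is.na(table$time_to_hfpef) & !is.na(table$age_at_dd)),
    hfpef_to_death = data.frame(
      time = table$time_to_death - table$time_to_hfpef,
      event = as.integer(table$death_observed %in% TRUE),
      keep = prog & !is.na(table$time_to_death)),
    age_at_death = data.frame(
      time = table$age_at_dd + table$time_to_death,
      event = as.integer(table$death_observed %in% TRUE),
      keep = !is.na(table$time_to_death) & !is.na(table$age_at_dd)))
}

#' Kaplan-Meier disease-trajectory report
#'
#' For each phenogroup within each stratum, estimates Kaplan-Meier curves
#' and medians for four endpoints — time from diastolic-dysfunction
#' diagnosis to HFpEF, age at HFpEF diagnosis, time from HFpEF to death,
#' and age at death — and computes pairwise log-rank p-values between
#' clusters. Strata: `all` (entire cohort), `gender`, `lvh` (any
#' left-ventricular hypertrophy vs none, from `lvh_grade`), and `outcome`
#' (progressed vs asymptomatic; HFpEF-specific endpoints are then restricted
#' to progressors by construction). Empty strata are reported as absent.
#'
#' @param table a cohort table with outcome and event-time columns.
#' @param assignment a `cluster_assignment` covering the table's patients.
#' @param strata subset of `c("all", "gender", "lvh", "outcome")`.
#' @return A data frame of class `"trajectory_report"`: one row per stratum
#'   x endpoint x cluster with n, events and median; pairwise log-rank
#'   p-values in `attr(, "pairwise")`.
#' @export
trajectory_report <- function(table, assignment,
                              strata = c("all", "gender", "lvh", "outcome")) {
  strata <- match.arg(strata, several.ok = TRUE)
  needed <- c("time_to_hfpef", "hfpef_observed", "time_to_death",
              "death_observed", "age_at_dd")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("cohort table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  cl <- assignment$labels[match(table$patient_id, names(assignment$labels))]
  strata_defs <- list()
  for (s in strata) {
    strata_defs <- c(strata_defs, switch(s,
      all = list(all = rep(TRUE, nrow(table))),
      gender = {
        if (!"gender" %in% names(table)) list() else {
          lv <- unique(stats::na.omit(table$gender))
          stats::setNames(lapply(lv, function(l) table$gender %in% l),
                          paste0("gender:", lv))
        }
      },
      lvh = {
        if (!"lvh_grade" %in% names(table)) list() else list(
          "lvh:absent" = table$lvh_grade %in% "none",
          "lvh:present" = !is.na(table$lvh_grade) & table$lvh_grade != "none")
      },
      outcome = list("outcome:hfpef" = table$outcome %in% 1L,
                     "outcome:asymptomatic" = table$outcome %in% 0L)))
  }
  rows <- list()
  pairwise <- list()
  endpoints <- trajectory_endpoints(table)
  for (sname in names(strata_defs)) {
    in_stratum <- strata_defs[[sname]] & !is.na(cl)
    if (!any(in_stratum)) next
    for (ep in names(endpoints)) {
      d <- endpoints[[ep]]
      use <- in_stratum & d$keep
      if (!any(use)) next
      for (g in levels(cl)) {
        sel <- use & cl == g
        if (!any(sel)) next
        km <- km_estimate(d$time[sel], d$event[sel])
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = sname, endpoint = ep, cluster = g, n = km$n,
          events = sum(km$n_events), median = km$median,
          stringsAsFactors = FALSE)
      }
      present <- levels(cl)[vapply(levels(cl), function(g)
        sum(use & cl == g) > 0 && sum(d$event[use & cl == g]) > 0,
        logical(1))]
      if (length(present) >= 2L) {
        for (i in seq_len(length(present) - 1L)) for (j in (i + 1L):length(present)) {
          gi <- present[i]; gj <- present[j]
          sel <- use & cl %in% c(gi, gj)
          p <- tryCatch(
            logrank_test(d$time[sel], d$event[sel], droplevels(cl[sel]))$p_value,
            error = function(e) NA_real_)
          pairwise[[length(pairwise) + 1L]] <- data.frame(
            stratum = sname, endpoint = ep, cluster1 = gi, cluster2 = gj,
            p_value = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0), endpoint = character(0),
               cluster = character(0), n = integer(0), events = integer(0),
               median = numeric(0))
  attr(out, "pairwise") <- if (length(pairwise)) do.call(rbind, pairwise) else
    data.frame(stratum = character(0), endpoint = character(0),
               cluster1 = character(0), cluster2 = character(0),
               p_value = numeric(0))
  class(out) <- c("trajectory_report", "data.frame")
  out
}
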