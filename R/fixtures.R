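# Reference fixtures: the worked examples with known results that pin the
# package's statistical conventions (continuity correction on 2x2 tables
# only, no minimum expected count, the purity formula, and the shipped risk
# equations). Counts are cluster-by-outcome and outcome-by-category
# contingency tables from the motivating phenomapping cohort.

#' Reference contingency-table fixtures
#'
#' Small count tables with known chi-square p-values, used to pin the
#' package's testing conventions and exercised by [reproduce_fixtures()].
#' `reference_cluster_outcome_counts()` is the 3-phenogroup by HFpEF-outcome
#' table (cluster sizes 7/59/95, HFpEF frequencies 71.4/59.3/42.1%);
#' `reference_mortality_counts()` the 2 x 2 mortality table (26/81 vs 40/81
#' deceased); `reference_dd_severity_counts()` the outcome by
#' diastolic-dysfunction-severity 2 x 3 table;
#' `reference_gender_counts()` the phenogroup by gender 3 x 2 table; and
#' `reference_ckd_counts()` the phenogroup by CKD-stage 3 x 5 table (expected
#' counts below 1 — deliberately kept untrimmed).
#'
#' @return An integer matrix of counts.
#' @export
reference_cluster_outcome_counts <- function() {
  matrix(c(5, 35, 40, 2, 24, 55), nrow = 3,
         dimnames = list(c("A", "B", "C"), c("hfpef", "asymptomatic")))
}

#' @rdname reference_cluster_outcome_counts
#' @export
reference_mortality_counts <- function() {
  matrix(c(26, 40, 55, 41), nrow = 2,
         dimnames = list(c("asymptomatic", "hfpef"), c("deceased", "alive")))
}

#' @rdname reference_cluster_outcome_counts
#' @export
reference_dd_severity_counts <- function() {
  matrix(c(7, 21, 68, 57, 6, 3), nrow = 2,
         dimnames = list(c("asymptomatic", "hfpef"),
                         c("mild", "moderate", "severe")))
}

#' @rdname reference_cluster_outcome_counts
#' @export
reference_gender_counts <- function() {
  matrix(c(4, 28, 20, 3, 31, 75), nrow = 3,
         dimnames = list(c("A", "B", "C"), c("male", "female")))
}

#' @rdname reference_cluster_outcome_counts
#' @export
reference_ckd_counts <- function() {
  matrix(c(0, 18, 44, 1, 8, 23, 3, 10, 13, 1, 5, 5, 0, 9, 6), nrow = 3,
         dimnames = list(c("A", "B", "C"), CKD_STAGES))
}

# Expand a cluster-by-outcome count table into per-patient labels/outcomes so
# the assignment-level purity operation can be exercised on it.
counts_to_assignment <- function(counts) {
  if (is.null(rownames(counts)))
    rownames(counts) <- LETTERS[seq_len(nrow(counts))]
  labels <- factor(rep(rep(rownames(counts), ncol(counts)), as.vector(counts)),
                   levels = rownames(counts))
  outcomes <- rep(rep(c(1L, 0L), each = nrow(counts)), as.vector(counts))
  assign <- structure(list(labels = stats::setNames(
    labels, sprintf("P%03d", seq_along(labels))),
    k = nrow(counts), noise = NULL), class = "cluster_assignment")
  list(assignment = assign, outcomes = outcomes)
}

#' Evaluate every shipped reference fixture
#'
#' Recomputes, through the package's own operations, each fixture with a
#' known reference value: the 3-phenogroup purity (59%), the
#' outcome-homogeneity chi-square p (0.058), the three additional
#' contingency-table p-values that pin the correction conventions (0.038
#' Yates-corrected mortality, 0.011 severity, 0.001 gender, 0.031 CKD), the
#' three shipped risk equations over canonical covariate patterns (including
#' the "2 or more of the 4 factors implies P > 53%" decision rule), and the
#' per-factor odds ratios (the 3-4-fold band).
#'
#' @return A data frame with one row per fixture: `fixture`, `value`,
#'   `reference`, `pass` (agreement at the reference's printed precision).
#' @export
reproduce_fixtures <- function() {
  rows <- list()
  add <- function(fixture, value, reference, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fixture = fixture, value = value, reference = reference, pass = pass,
      stringsAsFactors = FALSE)
  }
  co <- counts_to_assignment(reference_cluster_outcome_counts())
  pur <- 100 * purity(co$assignment, co$outcomes)
  add("purity_3_clusters_pct", pur, 59, round(pur) == 59)
  p_hom <- outcome_homogeneity_test(co$assignment, co$outcomes)$p_value
  add("outcome_homogeneity_p", p_hom, 0.058, round(p_hom, 3) == 0.058)
  p_mort <- chi_square_test(reference_mortality_counts())$p_value
  add("mortality_2x2_p", p_mort, 0.038, round(p_mort, 3) == 0.038)
  p_dd <- chi_square_test(reference_dd_severity_counts())$p_value
  add("dd_severity_2x3_p", p_dd, 0.011, round(p_dd, 3) == 0.011)
  p_gen <- chi_square_test(reference_gender_counts())$p_value
  add("gender_3x2_p", p_gen, 0.001, round(p_gen, 3) == 0.001)
  p_ckd <- suppressWarnings(chi_square_test(reference_ckd_counts())$p_value)
  add("ckd_3x5_p", p_ckd, 0.031, round(p_ckd, 3) == 0.031)
  eq <- whole_cohort_equation()
  vars <- model_variables(eq)
  patterns <- expand.grid(rep(list(c(0, 1)), length(vars)))
  names(patterns) <- vars
  p_pat <- predict_probability(eq, patterns)
  nfac <- rowSums(patterns)
  add("whole_cohort_P_no_factors", p_pat[nfac == 0], 0.126,
      round(p_pat[nfac == 0], 3) == 0.126)
  add("whole_cohort_P_all_factors", p_pat[nfac == 4], 0.954,
      round(p_pat[nfac == 4], 3) == 0.954)
  add("decision_rule_2plus_factors", as.numeric(
    all((p_pat > eq$cutoff) == (nfac >= 2))), 1,
    all((p_pat > eq$cutoff) == (nfac >= 2)))
  ors <- odds_ratios(eq)
  for (v in names(ors))
    add(paste0("odds_ratio_", v), ors[[v]],
        c(diabetes = 3.13, ckd = 3.94, afib = 2.94, diuretic = 4.01)[[v]],
        round(ors[[v]]) %in% c(3, 4))
  pB <- predict_probability(cluster_b_equation(),
                            c(diabetes = 0, ckd = 0, diuretic = 0,
                              av_max_gradient = 0, diastolic_wall_strain = 0))
  add("cluster_b_P_all_zero", pB, stats::plogis(-4.44),
      abs(pB - stats::plogis(-4.44)) < 1e-12)
  pC <- predict_probability(cluster_c_equation(),
                            c(ckd = 0, diuretic = 0, age_dd = 0, esvi = 0))
  add("cluster_c_P_all_zero", pC, 0.042, round(pC, 3) == 0.042)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
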