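#' Grade diastolic-dysfunction severity from mitral inflow and annular velocity
#'
#' Severity is determined solely by the E/A ratio and the average mitral
#' annular early velocity e' (cm/s), on the domain e' <= 9 cm/s:
#' mild when E/A < 1, moderate when 1 <= E/A < 2, severe when E/A >= 2.
#' When e' > 9 cm/s the grading scheme does not apply and `"indeterminate"`
#' is returned rather than a guess.
#'
#' @param e_over_a E/A ratio (early over atrial mitral inflow velocity),
#'   positive.
#' @param e_prime average e' in cm/s, positive.
#' @return character vector with values in
#'   `c("mild", "moderate", "severe", "indeterminate")`.
#' @examples
#' grade_dd_severity(0.8, 8)   # mild
#' grade_dd_severity(2.3, 7)   # severe
#' grade_dd_severity(1.2, 9.5) # indeterminate
#' @export
grade_dd_severity <- function(e_over_a, e_prime) {
  if (any(!is.finite(e_over_a)) || any(!is.finite(e_prime)) ||
      any(e_over_a <= 0) || any(e_prime <= 0))
    stop("e_over_a and e_prime must be finite and positive")
  ifelse(e_prime > 9, "indeterminate",
         ifelse(e_over_a >= 2, "severe",
                ifelse(e_over_a >= 1, "moderate", "mild")))
}

#' Stage chronic kidney disease from the glomerular filtration rate
#'
#' GFR (mL/min/1.73 m2) is mapped to CKD stages with half-open intervals:
#' `[60, Inf)` stage 1-2, `[45, 60)` stage 3a, `[30, 45)` stage 3b,
#' `[15, 30)` stage 4, `(0, 15)` stage 5.
#'
#' @param gfr glomerular filtration rate, positive.
#' @return character vector with values in `CKD_STAGES`.
#' @examples
#' stage_ckd(c(70, 50, 45, 29, 10))
#' @export
stage_ckd <- function(gfr) {
  if (any(!is.finite(gfr)) || any(gfr <= 0))
    stop("gfr must be finite and positive")
  as.character(cut(gfr, breaks = c(0, 15, 30, 45, 60, Inf), right = FALSE,
                   labels = rev(CKD_STAGES)))
}

#' @rdname stage_ckd
#' @format character vector of the five CKD stage labels, mildest first.
#' @export
CKD_STAGES <- c("stage1_2", "stage3a", "stage3b", "stage4", "stage5")
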