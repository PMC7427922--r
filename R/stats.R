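test_result <- function(statistic, df, p_value, method,
                        correction_applied = FALSE, warnings = character(0)) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 correction_applied = correction_applied,
                 warnings = warnings),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 5),
      ", df = ", paste(x$df, collapse = ", "),
      ", p = ", signif(x$p_value, 4),
      if (x$correction_applied) " (continuity corrected)" else "", "\n",
      sep = "")
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) with expected counts
#' from the product of the margins. The Yates continuity correction replaces
#' |O - E| by max(0, |O - E| - 0.5) and, under the default `"auto"` policy,
#' is applied to 2 x 2 tables only — the convention under which the
#' package's reference contingency fixtures reproduce their known p-values.
#' No minimum expected count is enforced; a warning is recorded in the
#' result when any expected count is below 5.
#'
#' @param table an r x c matrix of nonnegative counts (r, c >= 2).
#' @param correction `"auto"` (Yates on 2 x 2 only), `"on"` (force on 2 x 2;
#'   larger tables are never corrected), or `"off"`.
#' @return A `test_result` with `statistic`, `df = (r-1)(c-1)`, `p_value`,
#'   `correction_applied` and any expected-count warnings.
#' @examples
#' chi_square_test(rbind(c(26, 55), c(40, 41)))          # 2x2, Yates applied
#' chi_square_test(rbind(c(5, 2), c(35, 24), c(40, 55))) # 3x2, uncorrected
#' @export
chi_square_test <- function(table, correction = c("auto", "on", "off")) {
  correction <- match.arg(correction)
  O <- as.matrix(table)
  if (nrow(O) < 2L || ncol(O) < 2L) stop("need an r x c table with r, c >= 2")
  if (any(O < 0) || anyNA(O)) stop("counts must be nonnegative")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal total in contingency table")
  E <- outer(rs, cs) / sum(O)
  warnings <- character(0)
  if (any(E < 5))
    warnings <- sprintf("%d of %d expected counts below 5 (min %.2f)",
                        sum(E < 5), length(E), min(E))
  apply_corr <- correction != "off" && nrow(O) == 2L && ncol(O) == 2L
  dev <- abs(O - E)
  if (apply_corr) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              method = "Pearson chi-square",
              correction_applied = apply_corr, warnings = warnings)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects ANOVA, F = MS_between / MS_within with
#' (k - 1, N - k) degrees of freedom, on complete cases. Groups with fewer
#' than 2 observations are dropped with a warning.
#'
#' @param groups list of numeric vectors, one per group.
#' @return A `test_result` (df is the pair c(df1, df2)).
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  usable <- lengths(groups) >= 2L
  warnings <- character(0)
  if (any(!usable)) {
    warnings <- sprintf("%d group(s) with < 2 observations dropped",
                        sum(!usable))
    warning(warnings)
    groups <- groups[usable]
  }
  if (length(groups) < 2L) stop("need at least 2 usable groups")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  test_result(ft$statistic, unname(ft$parameter), ft$p.value,
              method = "One-way ANOVA", warnings = warnings)
}

anova_pieces <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) >= 2L]
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(k = k, n = n, means = means, df_within = N - k,
       ms_within = ssw / (N - k))
}

# Stepwise studentized-range procedure shared by Newman-Keuls and Duncan.
# `crit_p` gives the cumulative probability at which the studentized-range
# quantile is taken for a given span.
range_posthoc <- function(groups, alpha, method, crit_p) {
  pieces <- anova_pieces(groups)
  k <- pieces$k
  if (is.null(names(pieces$means)))
    names(pieces$means) <- names(groups) %||% as.character(seq_len(k))
  if (k < 3L) {
    warning(method, ": fewer than 3 groups; falling back to a pairwise t test")
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    dec <- matrix(tt$p.value < alpha, 1, 1,
                  dimnames = list(names(pieces$means)[1],
                                  names(pieces$means)[2]))
    return(structure(list(method = method, alpha = alpha,
                          means = pieces$means, decisions = dec),
                     class = "posthoc_result"))
  }
  ord <- order(pieces$means)           # ascending
  means <- pieces$means[ord]
  nh <- 1 / mean(1 / pieces$n[ord])    # harmonic mean size (unbalanced)
  se <- sqrt(pieces$ms_within / nh)
  df <- pieces$df_within
  differ <- matrix(NA, k, k, dimnames = list(names(means), names(means)))
  # test spans widest-first; a non-rejected range blocks all inner pairs
  for (span in k:2) {
    for (lo in seq_len(k - span + 1L)) {
      hi <- lo + span - 1L
      if (!is.na(differ[lo, hi])) next   # already blocked as not-different
      q_obs <- (means[hi] - means[lo]) / se
      q_crit <- stats::qtukey(crit_p(span), nmeans = span, df = df)
      if (q_obs >= q_crit) {
        differ[lo, hi] <- TRUE
      } else {
        for (a in lo:hi) for (b in a:hi) if (a < b && is.na(differ[a, b]))
          differ[a, b] <- FALSE
      }
    }
  }
  structure(list(method = method, alpha = alpha, means = means,
                 decisions = differ),
            class = "posthoc_result")
}

#' Newman-Keuls and Duncan stepwise multiple comparisons
#'
#' After a significant ANOVA, group means are ordered and ranges are tested
#' widest-first against studentized-range critical values
#' `q(alpha_span, span, df_within)` with the harmonic mean of the group sizes
#' standing in for a common n. A range that fails to reach significance
#' blocks every pair inside it (stepwise consistency). Newman-Keuls uses the
#' fixed level `alpha` at every span; Duncan relaxes it to the protection
#' level `1 - (1 - alpha)^(span - 1)`, so Duncan's rejections always include
#' Newman-Keuls's.
#'
#' @param groups named list of numeric vectors (complete cases taken).
#' @param alpha nominal significance level.
#' @return A `posthoc_result`: ordered `means` and a `decisions` matrix
#'   (upper triangle, `TRUE` = pair differs) in mean order.
#' @export
newman_keuls <- function(groups, alpha = 0.05) {
  range_posthoc(groups, alpha, "newman_keuls",
                crit_p = function(span) 1 - alpha)
}

#' @rdname newman_keuls
#' @export
duncan_test <- function(groups, alpha = 0.05) {
  range_posthoc(groups, alpha, "duncan",
                crit_p = function(span) (1 - alpha)^(span - 1))
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat("Multiple comparisons (", x$method, ", alpha = ", x$alpha, ")\n", sep = "")
  cat("  means (ascending):",
      paste(names(x$means), signif(x$means, 4), sep = "=", collapse = ", "), "\n")
  d <- x$decisions
  pairs <- which(upper.tri(d) & !is.na(d) & d, arr.ind = TRUE)
  if (nrow(pairs) == 0) cat("  no pairs differ\n")
  else cat("  differing pairs:",
           paste(rownames(d)[pairs[, 1]], colnames(d)[pairs[, 2]],
                 sep = " vs ", collapse = "; "), "\n")
  invisible(x)
}

#' Pairs declared different by a post-hoc procedure
#'
#' @param x a `posthoc_result`.
#' @return data frame of group pairs with a logical `differ` column.
#' @export
posthoc_pairs <- function(x) {
  d <- x$decisions
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(group1 = rownames(d)[idx[, 1]], group2 = colnames(d)[idx[, 2]],
             differ = d[idx], stringsAsFactors = FALSE)
}

fmt_mean_ci <- function(x) {
  # mean +/- 95% CI half-width (t quantile), the convention of the
  # phenogroup comparison tables
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(sprintf("%.2f (n=%d)", mean(x), n))
  hw <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  sprintf("%.2f ± %.2f (n=%d)", mean(x), hw, n)
}

#' Compare every variable across patient groups
#'
#' The phenogroup-comparison report: for each schema variable, categorical
#' variables are tested with [chi_square_test()] (Yates on 2 x 2 only) and
#' summarised as counts with percentages; numeric variables with
#' [one_way_anova()] and summarised as mean +/- 95% confidence interval.
#' When the ANOVA is significant at `alpha` and there are at least 3 groups,
#' Newman-Keuls and Duncan multiple comparisons are appended. Each variable
#' is analysed complete-case with its per-group n reported. No
#' multiple-testing adjustment is applied across variables; every p-value is
#' marginal.
#'
#' @param table a cohort table.
#' @param grouping factor/character vector of group labels, one per patient.
#' @param schema a [variable_schema()]; defaults to the table's own.
#' @param variables variables to compare; default all schema variables.
#' @param alpha significance level gating the post-hoc procedures.
#' @return A data frame of class `"group_comparison"`: one row per variable
#'   with test, statistic, p_value, per-group summaries, and post-hoc
#'   verdicts; the underlying post-hoc objects are kept in
#'   `attr(, "posthoc")`.
#' @export
compare_groups <- function(table, grouping, schema = cohort_schema(table),
                           variables = intersect(schema$name, names(table)),
                           alpha = 0.05) {
  grouping <- factor(grouping)
  if (length(grouping) != nrow(table))
    stop("grouping must cover every patient")
  rows <- list()
  posthoc <- list()
  for (v in variables) {
    if (!v %in% schema$name) {
      warning("variable '", v, "' absent from schema; skipped")
      next
    }
    entry <- schema_lookup(schema, v)
    x <- table[[v]]
    obs <- !is.na(x)
    per_group <- character(nlevels(grouping))
    names(per_group) <- levels(grouping)
    if (entry$kind == "categorical") {
      tab <- base::table(factor(x[obs], levels = entry$levels[[1]]),
                         grouping[obs])
      keep <- rowSums(tab) > 0
      res <- tryCatch(chi_square_test(t(tab[keep, , drop = FALSE])),
                      error = function(e) NULL)
      for (g in levels(grouping)) {
        cnt <- tab[, g]
        per_group[g] <- paste(sprintf("%s:%d (%.1f%%)", rownames(tab), cnt,
                                      100 * cnt / max(1, sum(cnt))),
                              collapse = ", ")
      }
      rows[[v]] <- data.frame(
        variable = v, kind = "categorical", test = "chi-square",
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        n = sum(obs), t(per_group), posthoc = "",
        stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      groups <- split(x[obs], droplevels(grouping[obs]))
      res <- tryCatch(suppressWarnings(one_way_anova(groups)),
                      error = function(e) NULL)
      for (g in levels(grouping))
        per_group[g] <- fmt_mean_ci(x[obs & grouping == g])
      ph <- ""
      if (!is.null(res) && !is.na(res$p_value) && res$p_value < alpha &&
          length(groups) >= 3L) {
        nk <- suppressWarnings(newman_keuls(groups))
        dc <- suppressWarnings(duncan_test(groups))
        posthoc[[v]] <- list(newman_keuls = nk, duncan = dc)
        fmt_ph <- function(p) {
          pr <- posthoc_pairs(p)
          pr <- pr[pr$differ, , drop = FALSE]
          if (!nrow(pr)) "none" else
            paste(pr$group1, pr$group2, sep = "~", collapse = ";")
        }
        ph <- sprintf("NK[%s] Duncan[%s]", fmt_ph(nk), fmt_ph(dc))
      }
      rows[[v]] <- data.frame(
        variable = v, kind = "numeric", test = "anova",
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        n = sum(obs), t(per_group), posthoc = ph,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "posthoc") <- posthoc
  class(out) <- c("group_comparison", "data.frame")
  out
}
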