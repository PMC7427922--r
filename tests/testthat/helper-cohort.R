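# Compact cohort specifications and small oracle utilities shared by the
# tests. Oracles are deliberately written from first principles, independent
# of the package's implementation paths.

# A small 3-phenogroup spec: a handful of variables, well-separated numeric
# means, logistic outcome on two binary factors.
small_spec <- function(seed = 1L, sizes = c(A = 20L, B = 30L, C = 40L),
                       separation = 3) {
  nv <- list(
    list(name = "marker1", mean = c(0, 1, 2) * separation, sd = c(1, 1, 1),
         units = "", log_normal = FALSE),
    list(name = "marker2", mean = c(2, 1, 0) * separation, sd = c(1, 1, 1),
         units = "", log_normal = FALSE),
    list(name = "biomarker", mean = c(500, 300, 100), sd = c(400, 250, 80),
         units = "pg/mL", log_normal = TRUE))
  cv <- list(
    list(name = "ckd", levels = c("yes", "no"),
         probs = rbind(c(0.6, 0.4), c(0.5, 0.5), c(0.35, 0.65))),
    list(name = "diuretic", levels = c("yes", "no"),
         probs = rbind(c(0.6, 0.4), c(0.55, 0.45), c(0.45, 0.55))))
  k <- length(sizes)
  nv <- lapply(nv, function(v) {
    v$mean <- v$mean[seq_len(k)]; v$sd <- v$sd[seq_len(k)]; v
  })
  cv <- lapply(cv, function(v) {
    v$probs <- v$probs[seq_len(k), , drop = FALSE]; v
  })
  cohort_spec(
    cluster_sizes = sizes, numeric_vars = nv, categorical_vars = cv,
    missing_rates = c(biomarker = 0.3, marker2 = 0.1),
    outcome_coefficients = c("(Intercept)" = -1.0, ckd = 1.2, diuretic = 0.9),
    hazard_params = list(hfpef_rate = c(0.4, 0.15, 0.07)[seq_len(k)],
                         death_rate = c(0.08, 0.06, 0.05)[seq_len(k)]),
    censor_horizon = 12, seed = seed)
}

# Adjusted Rand index between two labelings (closed-form pair counting).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force Pearson chi-square (optionally Yates-clamped), written as a
# direct O/E summation independent of the package implementation.
chisq_oracle <- function(O, yates = FALSE) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  dev <- abs(O - E)
  if (yates) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Hand product-limit estimator: walk distinct times, events before
# censorings at ties.
km_oracle <- function(time, event) {
  ut <- sort(unique(time))
  n_at_risk <- integer(length(ut)); d <- integer(length(ut))
  s <- numeric(length(ut)); cur <- 1
  for (i in seq_along(ut)) {
    n_at_risk[i] <- sum(time >= ut[i])
    d[i] <- sum(time == ut[i] & event == 1)
    cur <- cur * (1 - d[i] / n_at_risk[i])
    s[i] <- cur
  }
  list(time = ut, surv = s, at_risk = n_at_risk, events = d)
}

# Log-rank chi-square via per-event-time hypergeometric moments (two or more
# groups), the textbook observed-minus-expected sum.
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  g <- nlevels(group)
  ut <- sort(unique(time[event == 1]))
  O <- numeric(g); E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ni <- vapply(levels(group), function(l) sum(at_risk & group == l),
                 numeric(1))
    di <- vapply(levels(group), function(l)
      sum(at_risk & group == l & event == 1 & time == t), numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      for (a in seq_len(g)) for (b in seq_len(g)) {
        V[a, b] <- V[a, b] + if (a == b)
          d * (ni[a] / n) * (1 - ni[a] / n) * (n - d) / (n - 1)
        else
          -d * ni[a] * ni[b] / n^2 * (n - d) / (n - 1)
      }
    }
  }
  u <- (O - E)[-1]
  stat <- as.numeric(t(u) %*% solve(V[-1, -1, drop = FALSE]) %*% u)
  list(stat = stat, df = g - 1,
       p = pchisq(stat, g - 1, lower.tail = FALSE))
}

# A complete tiny encoded matrix built directly from a numeric matrix.
as_encoded <- function(x) {
  colnames(x) <- colnames(x) %||% paste0("v", seq_len(ncol(x)))
  rownames(x) <- rownames(x) %||% sprintf("P%03d", seq_len(nrow(x)))
  structure(list(
    values = x, mask = !is.na(x),
    column_meta = data.frame(column = colnames(x), variable = colnames(x),
                             level = NA_character_, kind = "numeric",
                             stringsAsFactors = FALSE),
    row_ids = rownames(x)), class = "encoded_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
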