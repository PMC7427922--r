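#' Screen whole patients with extreme numeric values
#'
#' A patient is excluded when, on any screened numeric variable, the absolute
#' distance from the column mean is at least `z_threshold` standard
#' deviations. Means and SDs are computed on the observed values of each
#' column including the candidate, so the screen is a single pass and
#' idempotent at a fixed threshold. Zero-dispersion columns are skipped with
#' a warning.
#'
#' @param table a cohort table.
#' @param z_threshold exclusion threshold in standard deviations (default 8,
#'   the conventional "gross measurement error" cut for this pipeline).
#' @return A list with `table` (retained patients) and `excluded`, a data
#'   frame of excluded patient ids and the offending variables.
#' @export
screen_outliers <- function(table, z_threshold = 8) {
  stopifnot(z_threshold > 0)
  schema <- cohort_schema(table)
  numeric_vars <- intersect(schema$name[schema$kind == "numeric"], names(table))
  offending <- vector("list", nrow(table))
  for (v in numeric_vars) {
    x <- table[[v]]
    obs <- !is.na(x)
    if (sum(obs) < 2L) next
    s <- stats::sd(x[obs])
    if (s == 0) {
      warning("screen_outliers: variable '", v, "' has zero SD; skipped")
      next
    }
    z <- abs(x - mean(x[obs])) / s
    hit <- which(!is.na(z) & z >= z_threshold)
    for (i in hit) offending[[i]] <- c(offending[[i]], v)
  }
  out_idx <- which(lengths(offending) > 0)
  excluded <- data.frame(
    patient_id = table$patient_id[out_idx],
    variables = vapply(offending[out_idx], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  kept <- as_cohort_table(table[setdiff(seq_len(nrow(table)), out_idx), ,
                                drop = FALSE], schema)
  rownames(kept) <- NULL
  list(table = kept, excluded = excluded)
}

#' One-hot encode a mixed-type cohort into a numeric matrix
#'
#' Every categorical variable with L levels becomes L indicator columns (full
#' encoding, not L-1: each level is treated as its own yes/no dichotomy);
#' numeric variables pass through unchanged. Missing values propagate to all
#' of a variable's columns via the observation mask. Outcome, event-time and
#' identifier columns are never encoded.
#'
#' @param table a cohort table.
#' @param schema a [variable_schema()]; defaults to the table's own.
#' @param variables which variables to encode; defaults to every schema
#'   variable present in the table.
#' @return An object of class `"encoded_matrix"`: list with `values` (patient
#'   x column matrix, `NA` where unobserved), `mask` (TRUE = observed),
#'   `column_meta` (source variable and level per column) and `row_ids`.
#' @export
one_hot_encode <- function(table, schema = cohort_schema(table),
                           variables = intersect(schema$name, names(table))) {
  missing_vars <- setdiff(variables, schema$name)
  if (length(missing_vars))
    stop("variables not in schema: ", paste(missing_vars, collapse = ", "))
  bad_reserved <- intersect(variables, RESERVED_COLUMNS)
  if (length(bad_reserved))
    stop("outcome/bookkeeping columns may not be encoded: ",
         paste(bad_reserved, collapse = ", "))
  n <- nrow(table)
  cols <- list()
  meta <- list()
  for (v in variables) {
    entry <- schema_lookup(schema, v)
    if (entry$kind == "numeric") {
      cols[[v]] <- as.numeric(table[[v]])
      meta[[v]] <- data.frame(column = v, variable = v, level = NA_character_,
                              kind = "numeric", stringsAsFactors = FALSE)
    } else {
      lv <- entry$levels[[1]]
      x <- table[[v]]
      obs <- !is.na(x)
      bad <- setdiff(unique(x[obs]), lv)
      if (length(bad))
        stop("variable '", v, "' has value(s) outside declared levels: ",
             paste(bad, collapse = ", "))
      for (l in lv) {
        cn <- paste(v, l, sep = "=")
        val <- as.numeric(x == l)
        val[!obs] <- NA_real_
        cols[[cn]] <- val
        meta[[cn]] <- data.frame(column = cn, variable = v, level = l,
                                 kind = "indicator", stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- table$patient_id
  structure(list(values = values, mask = !is.na(values),
                 column_meta = do.call(rbind, meta),
                 row_ids = table$patient_id),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("Encoded matrix:", nrow(x$values), "patients x", ncol(x$values),
      "columns (", sum(x$column_meta$kind == "numeric"), "numeric,",
      sum(x$column_meta$kind == "indicator"), "indicator )\n")
  cat("  observed:", sprintf("%.1f%%", 100 * mean(x$mask)), "\n")
  invisible(x)
}

#' Iterative SVD imputation of an encoded matrix
#'
#' Missing entries are completed by iterating a truncated singular value
#' decomposition: initialise missing cells at their column means, then
#' repeatedly (i) take the rank-`rank` SVD reconstruction of the current
#' completed matrix and (ii) overwrite only the missing cells with it, until
#' the relative (Frobenius) change of the imputed entries falls below `tol`
#' or `max_iter` is reached. Columns are centred and scaled internally
#' (recomputed from the current completed matrix each iteration, so an
#' exactly low-rank matrix is a fixed point) and restored afterwards;
#' without this, columns on large raw scales would dominate the
#' factorisation. Observed entries are returned exactly unchanged.
#'
#' @param matrix an [one_hot_encode()] result (or compatible list).
#' @param rank rank of the truncated SVD (default 5).
#' @param tol convergence tolerance on the relative change of imputed entries.
#' @param max_iter iteration cap (default 500: the moment-refreshing
#'   iteration converges linearly and typically needs a few hundred sweeps
#'   at `tol = 1e-6` on heavily missing clinical data); non-convergence is
#'   flagged, not fatal.
#' @return An `encoded_matrix` with no missing values; the pre-imputation
#'   mask is kept in `$observed_mask` and a `$converged` flag is attached.
#' @export
impute_svd <- function(matrix, rank = 5L, tol = 1e-6, max_iter = 500L) {
  x <- matrix$values
  mask <- matrix$mask
  n <- nrow(x); p <- ncol(x)
  if (rank < 1L || rank > min(n, p))
    stop("rank must lie in [1, ", min(n, p), "]")
  if (any(colSums(mask) == 0L))
    stop("column(s) entirely missing: ",
         paste(colnames(x)[colSums(mask) == 0L], collapse = ", "))
  out <- matrix
  if (all(mask)) {
    out$observed_mask <- mask
    out$converged <- TRUE
    return(out)
  }
  filled <- x
  init <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(p)) filled[!mask[, j], j] <- init[j]
  converged <- FALSE
  prev <- filled[!mask]
  for (iter in seq_len(max_iter)) {
    ctr <- colMeans(filled)
    scl <- apply(filled, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    z <- sweep(sweep(filled, 2, ctr), 2, scl, "/")
    sv <- svd(z, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    recon <- sweep(sweep(recon, 2, scl, "*"), 2, ctr, "+")
    filled[!mask] <- recon[!mask]
    cur <- filled[!mask]
    denom <- sqrt(sum(prev^2))
    delta <- sqrt(sum((cur - prev)^2)) / max(denom, .Machine$double.eps)
    prev <- cur
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("impute_svd: not converged after ", max_iter, " iterations")
  filled[mask] <- x[mask]  # observed entries exactly preserved
  out$values <- filled
  out$mask <- base::matrix(TRUE, n, p, dimnames = dimnames(x))
  out$observed_mask <- mask
  out$converged <- converged
  out
}

#' Standardise the columns of an encoded matrix
#'
#' @param matrix a complete (imputed) `encoded_matrix`.
#' @param policy `"numeric_only"` (default) scales numeric-provenance columns
#'   to mean 0, SD 1 and leaves indicator columns untouched; `"all"` scales
#'   every column; `"none"` is the identity. The SD uses the population
#'   convention (divisor n). Parameters are recorded so
#'   [invert_standardize()] can reverse the transformation.
#' @return The `encoded_matrix` with a `$scaling` record.
#' @export
standardize_matrix <- function(matrix, policy = c("numeric_only", "all", "none")) {
  policy <- match.arg(policy)
  if (anyNA(matrix$values)) stop("standardize requires a complete matrix")
  x <- matrix$values
  n <- nrow(x)
  which_cols <- switch(policy,
    none = character(0),
    numeric_only = matrix$column_meta$column[matrix$column_meta$kind == "numeric"],
    all = matrix$column_meta$column)
  center <- stats::setNames(rep(0, ncol(x)), colnames(x))
  scale <- stats::setNames(rep(1, ncol(x)), colnames(x))
  for (cn in which_cols) {
    mu <- mean(x[, cn])
    s <- sqrt(mean((x[, cn] - mu)^2))  # population SD (divisor n)
    if (s == 0) {
      warning("standardize: column '", cn, "' has zero SD; left untouched")
      next
    }
    x[, cn] <- (x[, cn] - mu) / s
    center[cn] <- mu
    scale[cn] <- s
  }
  matrix$values <- x
  matrix$scaling <- list(policy = policy, center = center, scale = scale)
  matrix
}

#' @rdname standardize_matrix
#' @export
invert_standardize <- function(matrix) {
  sc <- matrix$scaling
  if (is.null(sc)) return(matrix)
  x <- sweep(sweep(matrix$values, 2, sc$scale[colnames(matrix$values)], "*"),
             2, sc$center[colnames(matrix$values)], "+")
  matrix$values <- x
  matrix$scaling <- NULL
  matrix
}
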