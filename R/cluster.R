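#' Squared Euclidean distance matrix between patients
#'
#' @param matrix a complete (imputed) `encoded_matrix`, or a plain numeric
#'   matrix with patients in rows.
#' @return An object of class `"distance_matrix"`: list with `d` (patient x
#'   patient squared Euclidean distances, exactly symmetric, zero diagonal)
#'   and `row_ids`.
#' @export
distance_matrix <- function(matrix) {
  x <- if (inherits(matrix, "encoded_matrix")) matrix$values else matrix
  if (anyNA(x)) stop("distance_matrix requires a complete (imputed) matrix")
  d <- as.matrix(stats::dist(x, method = "euclidean"))^2
  d <- (d + t(d)) / 2  # enforce exact symmetry
  diag(d) <- 0
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, row_ids = ids), class = "distance_matrix")
}

as_distance_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  if (is.matrix(D)) {
    ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
    return(structure(list(d = D, row_ids = ids), class = "distance_matrix"))
  }
  stop("expected a distance_matrix or numeric matrix")
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard Lance-Williams agglomeration on a precomputed (squared Euclidean)
#' dissimilarity matrix. The default `"ward"` linkage applies the classical
#' Ward update to the squared distances (minimum within-cluster variance
#' increase); `"complete"`, `"average"` (UPGMA) and `"single"` are also
#' available. Ties in the minimum inter-cluster dissimilarity are broken by
#' the lexicographically smallest pair of cluster indices (a cluster keeps
#' the index of its oldest member), which makes the merge sequence fully
#' reproducible.
#'
#' @param D a [distance_matrix()].
#' @param linkage one of `"ward"`, `"complete"`, `"average"`, `"single"`.
#' @return An object of class `"phenomap_dendrogram"`: list with `merge`
#'   (n-1 x 2 matrix in the base-R hclust convention: negative entries are
#'   patients, positive entries earlier merges), `height`, `labels` and
#'   `linkage`.
#' @export
hierarchical_cluster <- function(D, linkage = c("ward", "complete",
                                                "average", "single")) {
  linkage <- match.arg(linkage)
  D <- as_distance_matrix(D)
  n <- nrow(D$d)
  if (n < 2L) stop("need at least 2 patients to cluster")
  W <- D$d
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  ids <- -seq_len(n)       # hclust convention: negative = singleton patient
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  Wwork <- W
  diag(Wwork) <- Inf
  for (m in seq_len(n - 1L)) {
    best <- min(Wwork)
    cand <- which(Wwork == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    merge[m, ] <- sort(c(ids[i], ids[j]))
    height[m] <- best
    ni <- sizes[i]; nj <- sizes[j]
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    dij <- W[i, j]
    for (k in others) {
      nk <- sizes[k]
      newd <- switch(linkage,
        single   = min(W[i, k], W[j, k]),
        complete = max(W[i, k], W[j, k]),
        average  = (ni * W[i, k] + nj * W[j, k]) / (ni + nj),
        ward     = ((ni + nk) * W[i, k] + (nj + nk) * W[j, k] - nk * dij) /
                   (ni + nj + nk))
      W[i, k] <- W[k, i] <- newd
      Wwork[i, k] <- Wwork[k, i] <- newd
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    Wwork[j, ] <- Inf
    Wwork[, j] <- Inf
    ids[i] <- m
  }
  structure(list(merge = merge, height = height, labels = D$row_ids,
                 linkage = linkage),
            class = "phenomap_dendrogram")
}

#' @export
print.phenomap_dendrogram <- function(x, ...) {
  cat("Patient dendrogram:", length(x$labels), "patients,",
      x$linkage, "linkage on squared Euclidean distances\n")
  invisible(x)
}

#' Convert a patient dendrogram to a base-R hclust object
#'
#' @param x a `phenomap_dendrogram`.
#' @param ... unused.
#' @return An object of class `"hclust"` usable with [stats::cutree()] and
#'   [plot()].
#' @export
as.hclust.phenomap_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  # leaf order by left-to-right traversal of the final merge
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(x$merge[node, 1]), expand(x$merge[node, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = expand(n - 1L), labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "squared euclidean"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges. When outcome labels are supplied, clusters are
#' lettered by decreasing HFpEF frequency (cluster `A` has the highest);
#' otherwise by decreasing size.
#'
#' @param dend a `phenomap_dendrogram`.
#' @param k number of clusters, `1 <= k <= n`.
#' @param outcomes optional binary outcome vector (same order as the
#'   dendrogram labels) used to order cluster letters.
#' @return An object of class `"cluster_assignment"`: list with `labels`
#'   (factor of cluster letters named by patient id) and `k`.
#' @export
cut_tree <- function(dend, k, outcomes = NULL) {
  n <- length(dend$labels)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  reps <- integer(n - 1L)  # representative patient of each merge
  for (m in seq_len(n - 1L)) {
    a <- dend$merge[m, 1]; b <- dend$merge[m, 2]
    ra <- if (a < 0) find(-a) else find(reps[a])
    rb <- if (b < 0) find(-b) else find(reps[b])
    reps[m] <- ra
    if (m <= n - k) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  raw <- match(roots, unique(roots))
  assignment_from_raw(raw, dend$labels, k, outcomes)
}

assignment_from_raw <- function(raw, row_ids, k, outcomes = NULL,
                                noise = NULL) {
  stopifnot(length(unique(raw[!is.na(raw)])) == k)
  ord <- if (!is.null(outcomes)) {
    freq <- tapply(outcomes, raw, mean)
    size <- table(raw)[names(freq)]
    names(freq)[order(-freq, -as.numeric(size))]
  } else {
    names(sort(table(raw), decreasing = TRUE))
  }
  letters_k <- if (k <= 26) LETTERS[seq_len(k)] else as.character(seq_len(k))
  labels <- factor(letters_k[match(as.character(raw), ord)],
                   levels = letters_k)
  names(labels) <- row_ids
  structure(list(labels = labels, k = k, noise = noise),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: k =", x$k, "\n")
  print(table(x$labels))
  if (!is.null(x$noise) && any(x$noise))
    cat("  unassigned (noise):", sum(x$noise), "\n")
  invisible(x)
}

#' Density-reachability (eps, min_pts) clustering
#'
#' Classic density-based clustering on the squared Euclidean distances: a
#' patient is a core point when at least `min_pts` patients (itself included)
#' lie within squared distance `eps`; clusters are the connected components
#' of density-reachability, and non-reachable patients are reported as noise
#' (unassigned, `NA` label).
#'
#' @param matrix a complete `encoded_matrix` (or numeric matrix).
#' @param eps neighbourhood radius on the squared-distance scale.
#' @param min_pts minimum neighbourhood size for a core point.
#' @param outcomes optional outcomes for cluster lettering.
#' @return A `cluster_assignment`; noise patients have `NA` labels and are
#'   flagged in `$noise`.
#' @export
density_cluster <- function(matrix, eps, min_pts, outcomes = NULL) {
  if (eps <= 0) stop("eps must be positive")
  if (min_pts < 1) stop("min_pts must be >= 1")
  D <- distance_matrix(matrix)
  d <- D$d
  n <- nrow(d)
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neighbours) >= min_pts
  raw <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(raw[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    raw[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in neighbours[[p]]) {
        if (is.na(raw[q])) {
          raw[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  noise <- is.na(raw)
  k <- max(0L, cl)
  if (k == 0L) {
    labels <- factor(rep(NA_character_, n))
    names(labels) <- D$row_ids
    return(structure(list(labels = labels, k = 0L, noise = noise),
                     class = "cluster_assignment"))
  }
  out <- assignment_from_raw(raw[!noise], D$row_ids[!noise], k,
                             outcomes = outcomes[!noise])
  full <- factor(rep(NA_character_, n), levels = levels(out$labels))
  full[!noise] <- out$labels
  names(full) <- D$row_ids
  structure(list(labels = full, k = k, noise = noise),
            class = "cluster_assignment")
}

#' Cluster purity against a binary outcome
#'
#' purity = (1/N) * sum over clusters of the count of patients sharing the
#' cluster's majority outcome. Equals 1 when every cluster is
#' outcome-homogeneous and is bounded below by the larger marginal outcome
#' frequency.
#'
#' @param assign a `cluster_assignment` (noise-free).
#' @param outcomes binary vector (0/1 or logical), same order/length as the
#'   assignment labels.
#' @return purity as a fraction in \[0, 1\].
#' @export
purity <- function(assign, outcomes) {
  labels <- assign$labels
  if (length(outcomes) != length(labels))
    stop("outcomes must match the assignment length")
  if (anyNA(labels) || anyNA(outcomes))
    stop("purity requires complete labels and outcomes")
  outcomes <- as.integer(outcomes)
  tab <- table(labels, outcomes)
  sum(apply(tab, 1, max)) / length(labels)
}

#' Chi-square test of outcome-frequency homogeneity across clusters
#'
#' Pearson chi-square (no continuity correction) on the k x 2
#' cluster-by-outcome contingency table, df = k - 1. This is the screening
#' statistic used to choose the number of phenogroups.
#'
#' @inheritParams purity
#' @return A `test_result` (see [chi_square_test()]).
#' @export
outcome_homogeneity_test <- function(assign, outcomes) {
  if (assign$k < 2L) stop("need at least 2 clusters")
  tab <- table(assign$labels, factor(as.integer(outcomes), levels = c(0, 1)))
  if (any(rowSums(tab) == 0)) stop("empty cluster in assignment")
  chi_square_test(unclass(unname(tab)), correction = "off")
}

#' Evaluate candidate cluster counts and select one
#'
#' Cuts the dendrogram at every k in `k_range`, computes the per-cluster
#' HFpEF frequencies, the purity and the outcome-homogeneity chi-square, and
#' selects the k with the smallest homogeneity p-value (ties broken towards
#' the smaller, simpler k). All evaluations are returned so the choice can
#' be overridden on qualitative grounds.
#'
#' @param dend a `phenomap_dendrogram`.
#' @param outcomes binary outcome vector in dendrogram label order.
#' @param k_range candidate cluster counts (default 2:5).
#' @return list with `assignment` (the selected cut), `k`, and `evaluations`
#'   (one row per candidate: k, purity, chi2, df, p_value, and per-cluster
#'   outcome frequencies as a comma-separated string).
#' @export
select_k <- function(dend, outcomes, k_range = 2:5) {
  if (is.null(outcomes) || anyNA(outcomes))
    stop("select_k requires complete outcomes")
  n <- length(dend$labels)
  if (any(k_range < 2L | k_range > n)) stop("k_range outside valid cuts")
  rows <- list()
  cuts <- list()
  for (k in k_range) {
    a <- cut_tree(dend, k, outcomes = outcomes)
    tst <- outcome_homogeneity_test(a, outcomes)
    freq <- tapply(as.integer(outcomes), a$labels, mean)
    rows[[as.character(k)]] <- data.frame(
      k = k, purity = purity(a, outcomes), chi2 = tst$statistic,
      df = tst$df, p_value = tst$p_value,
      cluster_sizes = paste(table(a$labels), collapse = "/"),
      outcome_freq = paste(sprintf("%.3f", freq), collapse = "/"),
      stringsAsFactors = FALSE)
    cuts[[as.character(k)]] <- a
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  best <- ev$k[order(ev$p_value, ev$k)][1]
  list(assignment = cuts[[as.character(best)]], k = best, evaluations = ev)
}
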