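test_that("squared Euclidean distances match a double-loop oracle", {
  set.seed(41)
  x <- matrix(rnorm(200), 20, 10)
  D <- distance_matrix(as_encoded(x))
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- sum((x[i, ] - x[j, ])^2)
  expect_lt(max(abs(D$d - oracle)), 1e-9)
  expect_identical(D$d, t(D$d))
  expect_true(all(diag(D$d) == 0))
  # identical rows at distance zero; the 3-4-5 triangle squared
  y <- rbind(c(0, 0), c(0, 0), c(3, 4))
  Dy <- distance_matrix(y)
  expect_equal(Dy$d[1, 2], 0)
  expect_equal(Dy$d[1, 3], 25)
  expect_error(distance_matrix(matrix(c(1, NA), 1)), "complete")
})

test_that("obvious geometry forces the first merges", {
  # two tight pairs far apart: the pairs merge first
  x <- rbind(c(0, 0), c(0.1, 0), c(50, 0), c(50.1, 0))
  dend <- hierarchical_cluster(distance_matrix(x))
  expect_identical(sort(dend$merge[1, ]), c(-2L, -1L))
  expect_identical(sort(dend$merge[2, ]), c(-4L, -3L))
  expect_error(hierarchical_cluster(distance_matrix(x[1, , drop = FALSE])),
               "at least 2")
})

test_that("every linkage reproduces the base-R agglomeration exactly", {
  hclust_method <- c(ward = "ward.D", complete = "complete",
                     average = "average", single = "single")
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 4), n)
    D <- distance_matrix(x)
    for (lk in names(hclust_method)) {
      mine <- hierarchical_cluster(D, lk)
      ref <- hclust(as.dist(D$d), method = hclust_method[[lk]])
      expect_equal(mine$height, ref$height, tolerance = 1e-10)
      for (k in 2:(n - 1)) {
        a <- cut_tree(mine, k)$labels
        b <- cutree(ref, k)
        expect_equal(adjusted_rand(a, b), 1)
      }
    }
  }
  # one larger instance on the default linkage
  x <- matrix(rnorm(40 * 6), 40)
  D <- distance_matrix(x)
  mine <- hierarchical_cluster(D, "ward")
  ref <- hclust(as.dist(D$d), method = "ward.D")
  expect_equal(mine$height, ref$height, tolerance = 1e-8)
  expect_equal(adjusted_rand(cut_tree(mine, 3)$labels, cutree(ref, 3)), 1)
})

test_that("ward merge heights are monotone and the tree converts to hclust", {
  x <- matrix(rnorm(25 * 4), 25)
  dend <- hierarchical_cluster(distance_matrix(x), "ward")
  expect_true(all(diff(dend$height) >= -1e-12))
  h <- as.hclust(dend)
  expect_s3_class(h, "hclust")
  expect_identical(sort(h$order), 1:25)
})

test_that("well-separated planted clusters are recovered", {
  spec <- small_spec(seed = 17, sizes = c(A = 60L, B = 90L, C = 150L),
                     separation = 10)
  spec$missing_rates <- numeric(0)
  cohort <- attach_outcomes(generate_cohort(spec), spec)
  std <- standardize_matrix(impute_svd(one_hot_encode(cohort)), "numeric_only")
  dend <- hierarchical_cluster(distance_matrix(std))
  cut <- cut_tree(dend, 3)
  expect_gte(adjusted_rand(cut$labels, cohort$true_cluster), 0.9)
})

test_that("tree cuts are nested and cover the degenerate k", {
  x <- matrix(rnorm(15 * 3), 15)
  dend <- hierarchical_cluster(distance_matrix(x))
  expect_equal(nlevels(cut_tree(dend, 1)$labels), 1L)
  expect_equal(length(unique(cut_tree(dend, 15)$labels)), 15L)
  expect_error(cut_tree(dend, 0), "k must lie")
  expect_error(cut_tree(dend, 16), "k must lie")
  for (k in 2:14) {
    fine <- cut_tree(dend, k + 1)$labels
    coarse <- cut_tree(dend, k)$labels
    # refinement: patients sharing a fine cluster share the coarse cluster
    expect_true(all(tapply(as.integer(coarse), fine,
                           function(v) length(unique(v))) == 1L))
  }
})

test_that("clusters are lettered by decreasing outcome frequency", {
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 20), 10))
  outcomes <- c(rep(1, 8), rep(0, 2), rep(0, 9), 1)  # freq 0.8 vs 0.1
  dend <- hierarchical_cluster(distance_matrix(x))
  cut <- cut_tree(dend, 2, outcomes = outcomes)
  expect_equal(unname(tapply(outcomes, cut$labels, mean)[["A"]]), 0.8)
  expect_equal(unname(tapply(outcomes, cut$labels, mean)[["B"]]), 0.1)
})

test_that("density clustering finds blobs, noise, and matches reachability", {
  set.seed(51)
  blob1 <- matrix(rnorm(40, 0, 0.2), 20)
  blob2 <- matrix(rnorm(40, 5, 0.2), 20)
  x <- rbind(blob1, blob2)
  a <- density_cluster(x, eps = 1.5, min_pts = 4)
  expect_equal(a$k, 2L)
  expect_false(any(a$noise))
  # uniform scatter at a vanishing radius: everything is noise
  u <- matrix(runif(60, 0, 100), 30)
  b <- density_cluster(u, eps = 1e-6, min_pts = 3)
  expect_equal(b$k, 0L)
  expect_true(all(b$noise))
  expect_error(density_cluster(x, eps = -1, min_pts = 3), "eps")
  expect_error(density_cluster(x, eps = 1, min_pts = 0), "min_pts")
  # reference: core points, their components, and reachable borders
  for (seed in 1:4) {
    set.seed(seed)
    y <- matrix(rnorm(40 * 2, sd = 2), 40)
    eps <- 2
    got <- density_cluster(y, eps = eps, min_pts = 4)
    d <- as.matrix(dist(y))^2
    core <- rowSums(d <= eps) >= 4
    # components of the core-core reachability graph by label propagation
    comp <- ifelse(core, seq_len(40), NA_integer_)
    repeat {
      new <- comp
      for (i in which(core)) {
        nb <- which(core & d[i, ] <= eps)
        new[i] <- min(comp[nb], comp[i])
      }
      if (identical(new, comp)) break
      comp <- new
    }
    # noise: non-core points with no core neighbour
    border <- !core & vapply(seq_len(40), function(i)
      any(core & d[i, ] <= eps), logical(1))
    expect_identical(unname(got$noise), unname(!(core | border)))
    # core partition agrees up to relabeling (ARI undefined for k = 1)
    if (any(core) && length(unique(comp[core])) > 1L &&
        length(unique(got$labels[core])) > 1L)
      expect_equal(adjusted_rand(got$labels[core], comp[core]), 1)
    else if (any(core))
      expect_equal(length(unique(got$labels[core])),
                   length(unique(comp[core])))
    # every border point sits in a cluster containing a core neighbour
    for (i in which(border)) {
      nb <- which(core & d[i, ] <= eps)
      expect_true(got$labels[i] %in% got$labels[nb])
    }
  }
})

test_that("purity equals the per-cluster majority fraction", {
  co <- hfpefmap:::counts_to_assignment(reference_cluster_outcome_counts())
  expect_equal(purity(co$assignment, co$outcomes), 95 / 161)
  # uniform single cluster is pure; a 50/50 split is half pure
  one <- hfpefmap:::counts_to_assignment(matrix(c(10, 0), 1))
  expect_equal(purity(one$assignment, one$outcomes), 1)
  half <- hfpefmap:::counts_to_assignment(matrix(c(5, 5, 5, 5), 2))
  expect_equal(purity(half$assignment, half$outcomes), 0.5)
  # brute-force equality and the marginal-frequency lower bound
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    k <- sample(2:5, 1)
    raw <- sample(k, n, replace = TRUE)
    outc <- rbinom(n, 1, 0.5)
    assign <- hfpefmap:::assignment_from_raw(raw, as.character(1:n),
                                             length(unique(raw)), outc)
    got <- purity(assign, outc)
    brute <- sum(vapply(unique(raw), function(cl)
      max(table(factor(outc[raw == cl], levels = 0:1))), numeric(1))) / n
    expect_equal(got, brute)
    expect_gte(got, max(mean(outc), 1 - mean(outc)) - 1e-12)
  }
})

test_that("purity never decreases along nested cuts of one dendrogram", {
  set.seed(62)
  x <- matrix(rnorm(40 * 3), 40)
  outc <- rbinom(40, 1, 0.5)
  dend <- hierarchical_cluster(distance_matrix(x))
  ps <- vapply(1:10, function(k) purity(cut_tree(dend, k), outc), numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("outcome homogeneity is the uncorrected chi-square on the k x 2 table", {
  co <- hfpefmap:::counts_to_assignment(reference_cluster_outcome_counts())
  res <- outcome_homogeneity_test(co$assignment, co$outcomes)
  expect_equal(round(res$statistic, 3), 5.699)
  expect_equal(round(res$p_value, 3), 0.058)
  expect_false(res$correction_applied)
  # equal frequencies: statistic 0, p 1
  eq <- hfpefmap:::counts_to_assignment(matrix(c(10, 20, 10, 20), 2))
  res0 <- outcome_homogeneity_test(eq$assignment, eq$outcomes)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # 2 x 2 case agrees with the general test with correction disabled
  two <- hfpefmap:::counts_to_assignment(matrix(c(12, 7, 5, 14), 2))
  a <- outcome_homogeneity_test(two$assignment, two$outcomes)
  b <- chi_square_test(matrix(c(12, 7, 5, 14), 2), correction = "off")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("the cluster count with the smallest homogeneity p is selected", {
  spec <- small_spec(seed = 71, sizes = c(A = 50L, B = 55L, C = 55L),
                     separation = 8)
  spec$missing_rates <- numeric(0)
  cohort <- generate_cohort(spec)
  set.seed(72)
  outcomes <- rbinom(nrow(cohort), 1,
                     c(A = 0.85, B = 0.5, C = 0.15)[cohort$true_cluster])
  std <- standardize_matrix(impute_svd(one_hot_encode(cohort)), "numeric_only")
  dend <- hierarchical_cluster(distance_matrix(std))
  sel <- select_k(dend, outcomes, 2:5)
  expect_equal(sel$k, sel$evaluations$k[which.min(sel$evaluations$p_value)])
  expect_equal(nrow(sel$evaluations), 4L)
  expect_true(all(sel$evaluations$purity >= max(mean(outcomes),
                                                1 - mean(outcomes))))
  expect_error(select_k(dend, rep(NA, nrow(cohort))), "complete outcomes")
})
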