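#' Pearson correlation screen of each predictor against Ho
#'
#' Reports, per predictor, the Pearson correlation with observed
#' heterozygosity and the two-sided t-test p-value — the screening step used
#' to check that no predictor is collinear with Ho before the random-forest
#' regression. A constant predictor column yields `NA` with a warning rather
#' than an error.
#'
#' @param table complete-case analysis table (from [extract_at_points()]).
#' @return Data frame with columns `predictor`, `r`, `p`, `n`.
#' @export
correlation_screen <- function(table) {
  vars <- canonical_predictors()
  if (nrow(table) < 3) stop("need at least 3 complete-case localities")
  out <- lapply(vars, function(v) {
    x <- table[[v]]
    if (stats::sd(x) == 0) {
      warning("constant predictor column, correlation undefined: ", v)
      return(data.frame(predictor = v, r = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- stats::cor.test(x, table$ho, method = "pearson", alternative = "two.sided")
    data.frame(predictor = v, r = unname(ct$estimate), p = ct$p.value, n = length(x))
  })
  do.call(rbind, out)
}

#' Principal component analysis of Ho and the predictors
#'
#' Variables are standardized (zero mean, unit variance) before the
#' decomposition. Ho is an active variable by default, matching an analysis
#' of localities "according to observed heterozygosity and the five
#' predictors"; set `include_ho = FALSE` to restrict the PCA to the
#' predictors alone.
#'
#' @param table complete-case analysis table.
#' @param include_ho include `ho` as an active variable (default `TRUE`).
#' @return An object of class `pca_result`: `loadings` (variable x
#'   component), `scores` (locality x component), `explained` (variance
#'   fraction per component, decreasing, summing to 1) and `variables`.
#' @export
run_pca <- function(table, include_ho = TRUE) {
  vars <- c(if (include_ho) "ho", canonical_predictors())
  x <- as.matrix(table[vars])
  if (nrow(x) <= length(vars)) stop("need more localities than active variables")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = fit$rotation, scores = fit$x,
                 explained = explained, variables = vars,
                 center = fit$center, scale = fit$scale),
            class = "pca_result")
}

# within-cluster sum of squared Euclidean distances to centroids
within_inertia <- function(scores, labels) {
  sum(vapply(split(seq_len(nrow(scores)), labels), function(ix) {
    m <- scores[ix, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
}

#' Hierarchical clustering on principal components (HCPC)
#'
#' Ward-linkage agglomerative clustering on Euclidean distances over the
#' retained component scores. Components are retained when they explain at
#' least `1/p` of the variance (the Kaiser rule on standardized data). When
#' `k` is not given it is chosen, over 2..10, at the partition with the
#' largest relative drop of within-cluster inertia relative to one fewer
#' cluster.
#'
#' @param pca a `pca_result` from [run_pca()].
#' @param k optional number of clusters.
#' @return An object of class `cluster_assignment`: `labels`, `k`,
#'   `linkage_heights`, `retained_components`, `tree` (the hclust object).
#' @export
hcpc <- function(pca, k = NULL) {
  n <- nrow(pca$scores)
  if (n < 3) stop("need at least 3 localities to cluster")
  retained <- which(pca$explained >= 1 / length(pca$explained))
  if (length(retained) == 0) retained <- 1L
  sc <- pca$scores[, retained, drop = FALSE]
  tree <- stats::hclust(stats::dist(sc), method = "ward.D2")
  if (is.null(k)) {
    kmax <- min(10L, n - 1L)
    w <- vapply(seq_len(kmax), function(kk) within_inertia(sc, stats::cutree(tree, kk)),
                numeric(1))
    rel_drop <- (w[-length(w)] - w[-1]) / pmax(w[-length(w)], .Machine$double.eps)
    k <- which.max(rel_drop) + 1L   # rel_drop[i] is the drop going to i+1 clusters
  }
  if (k < 1 || k > n) stop("k must be between 1 and the number of localities")
  labels <- if (k == n) seq_len(n) else stats::cutree(tree, k)
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 linkage_heights = tree$height, retained_components = retained,
                 tree = tree),
            class = "cluster_assignment")
}

#' Island-versus-mainland comparison of Ho
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of observed
#' heterozygosity between island and mainland localities: exact null
#' enumeration when both groups have at most 10 records and no ties, the
#' normal approximation with tie correction otherwise.
#'
#' @param table analysis table (or any data frame) with `ho` and
#'   `insularity` columns.
#' @return List with `statistic` (the rank-sum W for the island group),
#'   `p_value`, and the group sizes.
#' @export
island_mainland_test <- function(table) {
  island <- table$ho[table$insularity == "island"]
  mainland <- table$ho[table$insularity == "mainland"]
  if (length(island) == 0) stop("empty group: island")
  if (length(mainland) == 0) stop("empty group: mainland")
  ties <- any(duplicated(c(island, mainland)))
  exact <- length(island) <= 10 && length(mainland) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(island, mainland, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  p <- wt$p.value
  # every observation tied: the null variance is 0 and there is no evidence
  # against the null in either direction
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       n_island = length(island), n_mainland = length(mainland),
       exact = exact)
}
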