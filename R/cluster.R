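# Unsupervised discovery of metabolic subtypes: Ward/Euclidean hierarchical
# clustering over a candidate range of cluster counts, six validity metrics,
# majority-vote model selection, and K-means / random-forest-proximity
# sensitivity clusterings.

#' Pairwise Euclidean distances between samples
#'
#' @param x A [metabolite_matrix()] or numeric matrix (samples in rows).
#' @return A `dist` object.
#' @export
pairwise_euclidean <- function(x) {
  m <- if (inherits(x, "metabolite_matrix")) mm_values(x) else as.matrix(x)
  dist(m, method = "euclidean")
}

#' Agglomerative Ward linkage
#'
#' Hierarchical clustering by the Lance-Williams recurrence with Ward
#' coefficients. The default `"ward.D"` dialect applies the recurrence to
#' the unsquared Euclidean distances; `"ward.D2"` squares them first.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return An `hclust` tree (merge order, heights, labels).
#' @export
ward_linkage <- function(d, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort("distance matrix must be symmetric.")
    d <- stats::as.dist(d)
  }
  hclust(d, method = method)
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last `k - 1` merges; cluster labels are integers assigned by
#' order of first appearance along the sample order.
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return An integer vector of labels named by sample.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) abort(sprintf("k must lie in [1, %d].", n))
  raw <- cutree(tree, k = k)
  labels <- match(raw, unique(raw))
  names(labels) <- names(raw)
  labels
}

#' Cluster validity metrics for a hard partition
#'
#' Computes the six model-selection metrics used to pick the number of
#' subtypes: mean silhouette width (Euclidean; a singleton cluster
#' contributes 0), Dunn index (minimum single-linkage inter-cluster
#' distance over maximum intra-cluster diameter), Calinski-Harabasz
#' pseudo-F `[B/(k-1)]/[W/(n-k)]`, allocation entropy
#' `-sum((n_j/n) log(n_j/n))`, and the sum-of-squares information criteria
#' `BIC = W + log(n) k p` and `AIC = W + 2 k p`, where `W` and `B` are the
#' within- and between-cluster sums of squares about centroids and `p` the
#' number of metabolites.
#'
#' @param x A [metabolite_matrix()] or numeric matrix (samples in rows).
#' @param labels Integer cluster labels.
#' @param d Optional precomputed `dist`; saves recomputation across k.
#' @return A one-row tibble: `k`, `bic`, `aic`, `silhouette`, `dunn`,
#'   `calinski_harabasz`, `entropy`.
#' @export
cluster_metrics <- function(x, labels, d = NULL) {
  m <- if (inherits(x, "metabolite_matrix")) mm_values(x) else as.matrix(x)
  n <- nrow(m)
  p <- ncol(m)
  k <- length(unique(labels))
  if (k < 2 || k > n - 1) abort("metrics need 2 <= k <= n - 1.")
  d <- d %||% dist(m)
  dm <- as.matrix(d)

  sil <- mean(cluster::silhouette(labels, d)[, "sil_width"])

  inter <- Inf
  diam <- 0
  for (a in unique(labels)) {
    ia <- which(labels == a)
    if (length(ia) > 1) diam <- max(diam, max(dm[ia, ia]))
    for (b in unique(labels)) {
      if (b <= a) next
      inter <- min(inter, min(dm[ia, which(labels == b)]))
    }
  }
  dunn <- if (diam == 0) Inf else inter / diam

  centroids <- rowsum(m, labels) / as.vector(table(labels)[as.character(sort(unique(labels)))])
  grand <- colMeans(m)
  w <- sum((m - centroids[labels, , drop = FALSE])^2)
  b_ss <- sum(table(labels)[as.character(sort(unique(labels)))] *
                rowSums(sweep(centroids, 2, grand)^2))
  ch <- (b_ss / (k - 1)) / (w / (n - k))

  pj <- as.vector(table(labels)) / n
  entropy <- -sum(pj * log(pj))

  tibble::tibble(
    k = k,
    bic = w + log(n) * k * p,
    aic = w + 2 * k * p,
    silhouette = sil,
    dunn = dunn,
    calinski_harabasz = ch,
    entropy = entropy
  )
}

#' Majority-vote selection of the number of clusters
#'
#' Each validity metric casts one vote: the k minimising BIC, AIC and
#' entropy, and the k maximising silhouette, Dunn and Calinski-Harabasz.
#' The winner is the k with most votes; ties break toward the smaller k
#' (parsimony).
#'
#' @param metrics A tibble of per-k metric rows from [cluster_metrics()].
#' @return A list with `k_star` and the `votes` tibble (metric, k).
#' @export
select_k <- function(metrics) {
  if (nrow(metrics) < 2) abort("need at least two candidate models.")
  lower <- c("bic", "aic", "entropy")
  higher <- c("silhouette", "dunn", "calinski_harabasz")
  votes <- tibble::tibble(
    metric = c(lower, higher),
    k = c(
      vapply(lower, function(mt) metrics$k[which.min(metrics[[mt]])], 1L),
      vapply(higher, function(mt) metrics$k[which.max(metrics[[mt]])], 1L)
    )
  )
  tab <- table(votes$k)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k_star = min(winners), votes = votes)
}

#' Discover metabolic subtypes by hierarchical clustering
#'
#' The primary subtype-discovery routine: Euclidean distances between
#' samples, Ward linkage, candidate cuts over `k_range`, the six validity
#' metrics per candidate, and majority-vote selection of the optimal
#' model. Clusters of the selected model are lettered "A", "B", ... in
#' decreasing order of their mean standardised metabolite level, so the
#' metabolically elevated cluster is always subtype A.
#'
#' @param x A [metabolite_matrix()] (samples by metabolites).
#' @param k_range Candidate cluster counts (default 2:6).
#' @param linkage Ward dialect passed to [ward_linkage()].
#' @return An object of class `subtype_clustering`: list with `tree`,
#'   `metrics`, `votes`, `k_star`, `labels` (tibble `sample_id`,
#'   `subtype`), and `method = "hierarchical"`.
#' @export
cluster_subtypes <- function(x, k_range = 2:6, linkage = "ward.D") {
  d <- pairwise_euclidean(x)
  tree <- ward_linkage(d, linkage)
  metrics <- purrr::map_dfr(k_range, function(k) {
    cluster_metrics(x, cut_tree(tree, k), d = d)
  })
  sel <- select_k(metrics)
  labels <- cut_tree(tree, sel$k_star)
  new_subtype_clustering(x, labels, method = "hierarchical",
                         tree = tree, metrics = metrics, votes = sel$votes,
                         k_star = sel$k_star)
}

new_subtype_clustering <- function(x, labels, method, tree = NULL,
                                   metrics = NULL, votes = NULL,
                                   k_star = NULL, extra = list()) {
  m <- mm_values(x)
  means <- tapply(rowMeans(m), labels, mean)
  ord <- order(-means)
  letter <- setNames(LETTERS[seq_along(ord)], names(means)[ord])
  out <- list(
    labels = tibble::tibble(
      sample_id = rownames(m),
      subtype = unname(letter[as.character(labels)])
    ),
    k_star = k_star %||% length(unique(labels)),
    metrics = metrics, votes = votes, tree = tree, method = method
  )
  structure(c(out, extra), class = "subtype_clustering")
}

#' @export
print.subtype_clustering <- function(x, ...) {
  cat(sprintf("<subtype_clustering: %s, k = %d>\n", x$method, x$k_star))
  print(table(x$labels$subtype))
  invisible(x)
}

#' @describeIn cluster_subtypes Tidy the sample-level subtype assignments.
#' @param x A `subtype_clustering` object.
#' @param ... Unused.
#' @export
tidy.subtype_clustering <- function(x, ...) x$labels

#' @describeIn cluster_subtypes One-row model summary (k, sizes, votes won).
#' @export
glance.subtype_clustering <- function(x, ...) {
  sizes <- table(x$labels$subtype)
  tibble::tibble(
    method = x$method,
    k = x$k_star,
    n = nrow(x$labels),
    n_subtype_a = as.integer(sizes["A"] %||% NA),
    votes_for_k = if (!is.null(x$votes)) sum(x$votes$k == x$k_star) else NA_integer_
  )
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- m[sample.int(n, 1), , drop = FALSE]
  d2 <- rowSums(sweep(m, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    idx <- if (sum(d2) > 0) {
      sample.int(n, 1, prob = d2 / sum(d2))
    } else {
      sample.int(n, 1)
    }
    centers <- rbind(centers, m[idx, , drop = FALSE])
    d2 <- pmin(d2, rowSums(sweep(m, 2, m[idx, ])^2))
  }
  centers
}

#' K-means sensitivity clustering
#'
#' Lloyd iterations started from k-means++ seedings; the best of
#' `n_restarts` runs by total within-cluster sum of squares is kept.
#' Deterministic given `seed`.
#'
#' @param x A [metabolite_matrix()].
#' @param k Number of clusters.
#' @param n_restarts Independent k-means++ restarts.
#' @param seed Integer seed.
#' @return A `subtype_clustering` object (`method = "kmeans"`, with
#'   `tot_withinss`).
#' @export
kmeans_cluster <- function(x, k = 2, n_restarts = 10, seed = 1) {
  if (k < 2) abort("k must be at least 2.")
  m <- mm_values(x)
  withr::local_seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- NULL
    for (try in 1:20) {
      fit <- tryCatch(
        kmeans(m, centers = kmeanspp_centers(m, k),
               iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed to produce a valid partition.")
  new_subtype_clustering(x, best$cluster, method = "kmeans",
                         k_star = k, extra = list(tot_withinss = best$tot.withinss))
}

#' Random-forest-proximity sensitivity clustering
#'
#' Unsupervised random-forest clustering: a synthetic contrast sample is
#' drawn by independently permuting each metabolite's marginal
#' distribution, an ensemble classifies real versus synthetic, and the
#' proximity of two real samples is the fraction of trees placing them in
#' the same terminal node. Samples are then Ward-clustered on
#' `sqrt(1 - proximity)` and the tree cut at `k`.
#'
#' @param x A [metabolite_matrix()].
#' @param k Number of clusters.
#' @param n_trees Trees in the ensemble; fewer than 50 triggers a
#'   warning because proximities become unstable.
#' @param seed Integer seed.
#' @return A `subtype_clustering` object (`method = "rf"`, with
#'   `proximity` matrix).
#' @export
rf_proximity_cluster <- function(x, k = 2, n_trees = 500, seed = 1) {
  if (k < 2) abort("k must be at least 2.")
  if (n_trees < 50) warn("fewer than 50 trees gives unstable proximities.")
  m <- mm_values(x)
  withr::local_seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(m), y = NULL,
                                    ntree = n_trees, proximity = TRUE)
  prox <- fit$proximity
  diss <- sqrt(pmax(1 - prox, 0))
  tree <- ward_linkage(stats::as.dist(diss))
  labels <- cut_tree(tree, k)
  new_subtype_clustering(x, labels, method = "rf", tree = tree, k_star = k,
                         extra = list(proximity = prox))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' computed from the contingency table; 1 means identical partitions, 0 is
#' the expected agreement of independent labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
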