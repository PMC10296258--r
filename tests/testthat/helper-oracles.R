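# Brute-force oracles written from definitions, independent of the package
# implementation paths they check.

# O(n^3) agglomerative Ward linkage: keep the full dissimilarity matrix,
# merge the closest active pair, update by the Lance-Williams recurrence
# with Ward coefficients on unsquared distances.
naive_ward_heights <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- dm
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    idx <- which(!vapply(active, is.null, TRUE))
    for (a in idx) for (b in idx) {
      if (b <= a) next
      if (D[a, b] < best_d) { best_d <- D[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- best_d
    ni <- sizes[i]; nj <- sizes[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- sizes[k]
      s <- ni + nj + nk
      newd <- (ni + nk) / s * D[i, k] + (nj + nk) / s * D[j, k] -
        nk / s * D[i, j]
      D[i, k] <- D[k, i] <- newd
    }
    sizes[i] <- ni + nj
    active[j] <- list(NULL)
    D[j, ] <- D[, j] <- Inf
  }
  heights
}

# Efron = Breslow when there are no ties: log partial likelihood for a
# single covariate, maximised by grid search.
cox_grid_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  ll <- vapply(grid, function(beta) {
    lp <- x * beta
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      lp[i] - log(sum(exp(lp[risk])))
    }, 1))
  }, 1)
  grid[which.max(ll)]
}

# Two-sided hypergeometric (Fisher-style) p: total probability of tables
# as or less likely than the observed hit count.
hyper_two_sided_p <- function(N, T_, m, k) {
  support <- max(0, m + T_ - N):min(m, T_)
  probs <- stats::dhyper(support, m, N - m, T_)
  sum(probs[probs <= stats::dhyper(k, m, N - m, T_) * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (no ties): doubles the smaller one-sided tail, capped at 1.
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  combos <- utils::combn(length(pooled), nx)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  stats <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * length(y) / 2
  min(1, 2 * min(mean(stats <= obs + 1e-9), mean(stats >= obs - 1e-9)))
}

# Mann-Whitney AUC by pair enumeration with half credit for ties.
auc_enum <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Wrap a bare numeric matrix as a metabolite_matrix.
as_mm <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%03d", seq_len(ncol(m)))
  metabolite_matrix(dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)), tibble::as_tibble(m)
  ))
}

# Small, fast cohort configuration for integration-style tests.
small_cfg <- function(seed = 1, ...) {
  sim_config(
    n_patients = 60, n_metabolites = 40,
    pathway_spec = tibble::tibble(
      pathway = c("pw_a", "pw_b"), size = c(5L, 4L), shift = c(1, 0.8)
    ),
    n_batches = 2, seed = seed, ...
  )
}
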