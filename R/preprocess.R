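# Post-extraction processing of replicate-level LC-MS feature tables:
# CV filter -> triplicate summarisation -> batch correction -> missingness
# filter -> kNN imputation -> log2/Z-score -> dual-mode pooling -> library
# matching. Every operation here is deterministic.

long_to_matrix <- function(data, value_col = "value") {
  wide <- tidyr::pivot_wider(
    data[, c("feature_id", "sample_id", value_col)],
    names_from = "sample_id", values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$feature_id
  m
}

matrix_to_long <- function(m, value_col = "value") {
  tibble::tibble(
    feature_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    !!value_col := as.vector(m)
  )
}

#' Per-feature median coefficient of variation across technical replicates
#'
#' For each (feature, sample) with at least two observed replicates, the CV
#' is the sample SD divided by the mean of the observed replicate
#' intensities; the per-feature summary is the median over samples with a
#' defined CV. Features for which no CV is computable get `NA` and are
#' treated as failing the reproducibility filter.
#'
#' @param raw A replicate-level feature table (long form, columns
#'   `feature_id`, `sample_id`, `replicate`, `intensity`).
#' @return A tibble with `feature_id`, `median_cv`, and `n_cv_samples`,
#'   the number of samples contributing a CV.
#' @examples
#' raw <- tibble::tibble(feature_id = "F1", sample_id = "S1",
#'                       replicate = 1:3, intensity = c(50, 100, 150))
#' feature_cv(raw)$median_cv  # 0.5
#' @export
feature_cv <- function(raw) {
  per_cell <- raw |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::summarise(
      cv = if (dplyr::n() >= 2) sd(.data$intensity) / mean(.data$intensity)
           else NA_real_,
      .by = c("feature_id", "sample_id")
    )
  out <- per_cell |>
    dplyr::summarise(
      median_cv = median(.data$cv, na.rm = TRUE),
      n_cv_samples = sum(!is.na(.data$cv)),
      .by = "feature_id"
    ) |>
    dplyr::mutate(median_cv = ifelse(.data$n_cv_samples == 0, NA_real_,
                                     .data$median_cv))
  dplyr::left_join(tibble::tibble(feature_id = unique(raw$feature_id)), out,
                   by = "feature_id") |>
    tidyr::replace_na(list(n_cv_samples = 0L))
}

#' Remove irreproducible features by median replicate CV
#'
#' Features whose median technical-replicate CV meets or exceeds the
#' threshold (default 0.75, i.e. 75%) are removed; the bound is inclusive.
#' Features with no computable CV are also removed.
#'
#' @inheritParams feature_cv
#' @param threshold Inclusive removal bound on the median CV.
#' @return The filtered replicate-level table; the number of removed
#'   features is reported via a message and the `"n_removed_cv"` attribute.
#' @export
filter_features_by_cv <- function(raw, threshold = 0.75) {
  cv <- feature_cv(raw)
  bad <- cv$feature_id[is.na(cv$median_cv) | cv$median_cv >= threshold]
  out <- dplyr::filter(raw, !.data$feature_id %in% bad)
  inform(sprintf("CV filter: removed %d of %d features (median CV >= %.2f).",
                 length(bad), nrow(cv), threshold))
  attr(out, "n_removed_cv") <- length(bad)
  out
}

#' Median-summarise triplicate injections
#'
#' Each (feature, sample) becomes the median of its observed replicates
#' when at least two of the three are observed, and missing otherwise —
#' so at most one replicate's worth of information is ever tolerated as
#' absent, never fabricated.
#'
#' @inheritParams feature_cv
#' @return A tibble with `feature_id`, `sample_id`, `batch` (if present in
#'   `raw`), and summarised `intensity` (NA when fewer than two replicates
#'   were observed).
#' @export
summarize_triplicates <- function(raw) {
  keys <- intersect(c("feature_id", "sample_id", "batch"), names(raw))
  raw |>
    dplyr::summarise(
      intensity = {
        obs <- .data$intensity[!is.na(.data$intensity)]
        if (length(obs) >= 2) median(obs) else NA_real_
      },
      .by = dplyr::all_of(keys)
    )
}

#' Empirical-Bayes batch-effect correction for log-scale intensities
#'
#' Parametric location/scale adjustment in the ComBat family, operating on
#' summarised log2 intensities. Per feature, batch means and variances are
#' standardised away; with `method = "eb"` the per-batch location and scale
#' estimates are first shrunk toward across-feature priors (normal prior
#' for location, inverse-gamma for scale, moment-matched, solved
#' iteratively), which stabilises small batches. `method = "ml"` applies
#' the unshrunk maximum-likelihood adjustment, which exactly equalises
#' per-batch feature means and variances and is idempotent. Missing
#' entries are ignored during estimation and stay missing.
#'
#' @param data Long tibble with columns `feature_id`, `sample_id`,
#'   `batch`, and `value` (log2 intensity).
#' @param method `"eb"` (default) or `"ml"`.
#' @return The input tibble with `value` batch-corrected.
#' @export
correct_batches <- function(data, method = c("eb", "ml")) {
  method <- match.arg(method)
  stopifnot(all(c("feature_id", "sample_id", "batch", "value") %in% names(data)))
  batches <- dplyr::distinct(data, .data$sample_id, .data$batch)
  if (anyDuplicated(batches$sample_id) > 0) {
    abort("each sample must belong to exactly one batch.")
  }
  sizes <- table(batches$batch)
  if (any(sizes < 2)) {
    abort(sprintf("batch with fewer than 2 samples: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  if (length(sizes) == 1) return(data)

  x <- long_to_matrix(data)
  batch <- batches$batch[match(colnames(x), batches$sample_id)]
  corrected <- if (method == "ml") combat_ml(x, batch) else combat_eb(x, batch)
  out <- matrix_to_long(corrected)
  dplyr::left_join(out, batches, by = "sample_id")[
    , c("feature_id", "sample_id", "batch", "value")]
}

# Unshrunk location/scale adjustment: equalises per-batch feature means and
# variances exactly. Variance denominators are chosen consistently
# (within-batch n-1, pooled n-k) so the map is idempotent.
combat_ml <- function(x, batch) {
  levs <- unique(batch)
  out <- x
  for (g in seq_len(nrow(x))) {
    xs <- x[g, ]
    mu <- tapply(xs, batch, mean, na.rm = TRUE)[as.character(levs)]
    v <- tapply(xs, batch, stats::var, na.rm = TRUE)[as.character(levs)]
    ns <- tapply(!is.na(xs), batch, sum)[as.character(levs)]
    alpha <- sum(ns * mu, na.rm = TRUE) / sum(ns)
    pooled <- sum((ns - 1) * v, na.rm = TRUE) /
      max(sum(ns, na.rm = TRUE) - sum(ns > 0), 1)
    for (b in seq_along(levs)) {
      idx <- which(batch == levs[b] & !is.na(xs))
      if (length(idx) == 0) next
      scale <- if (!is.na(v[b]) && v[b] > 0 && pooled > 0) {
        sqrt(pooled / v[b])
      } else 1
      out[g, idx] <- (xs[idx] - mu[b]) * scale + alpha
    }
  }
  out
}

# Parametric empirical-Bayes variant mirroring the classical ComBat
# estimators (batch-mean model, pooled ML variance, normal/inverse-gamma
# moment-matched priors, iterative posterior solution), extended to
# tolerate missing values by using observed counts per (feature, batch).
combat_eb <- function(x, batch) {
  levs <- unique(batch)
  nb <- length(levs)
  obs <- !is.na(x)
  n_g <- rowSums(obs)

  mu <- sapply(levs, function(b) rowMeans(x[, batch == b, drop = FALSE],
                                          na.rm = TRUE))
  n_gb <- sapply(levs, function(b) rowSums(obs[, batch == b, drop = FALSE]))
  alpha <- rowSums(mu * n_gb, na.rm = TRUE) / n_g
  resid <- x - mu[, match(batch, levs), drop = FALSE]
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / n_g
  if (any(var_pooled <= 0)) {
    abort(sprintf("zero-variance feature(s): %s",
                  paste(rownames(x)[var_pooled <= 0], collapse = ", ")))
  }
  z <- (x - alpha) / sqrt(var_pooled)

  out_z <- z
  for (b in seq_along(levs)) {
    zb <- z[, batch == levs[b], drop = FALSE]
    g_hat <- rowMeans(zb, na.rm = TRUE)
    d_hat <- apply(zb, 1, stats::var, na.rm = TRUE)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat, na.rm = TRUE)
    s2 <- stats::var(d_hat, na.rm = TRUE)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    n_b <- rowSums(!is.na(zb))
    g_star <- g_hat
    d_star <- d_hat
    for (it in 1:100) {
      g_new <- (n_b * t2 * g_hat + d_star * g_bar) / (n_b * t2 + d_star)
      sum2 <- rowSums((zb - g_new)^2, na.rm = TRUE)
      d_new <- (b_prior + 0.5 * sum2) / (n_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_star) / pmax(abs(g_star), 1e-12),
                    abs(d_new - d_star) / pmax(abs(d_star), 1e-12))
      g_star <- g_new
      d_star <- d_new
      if (change < 1e-8) break
    }
    out_z[, batch == levs[b]] <- (zb - g_star) / sqrt(d_star)
  }
  out_z * sqrt(var_pooled) + alpha
}

#' Remove features with excess missingness
#'
#' Features missing in strictly more than `max_missing` (default 20%) of
#' samples are dropped; a feature missing in exactly 20% of samples is
#' retained for imputation.
#'
#' @param data Long tibble with `feature_id`, `sample_id`, `value`.
#' @param max_missing Strict upper bound on the per-feature missing
#'   fraction.
#' @return Filtered tibble; removal count in attribute
#'   `"n_removed_missing"`.
#' @export
filter_missingness <- function(data, max_missing = 0.20) {
  frac <- data |>
    dplyr::summarise(frac = mean(is.na(.data$value)), .by = "feature_id")
  bad <- frac$feature_id[frac$frac > max_missing]
  out <- dplyr::filter(data, !.data$feature_id %in% bad)
  inform(sprintf("missingness filter: removed %d of %d features (> %.0f%% missing).",
                 length(bad), nrow(frac), 100 * max_missing))
  attr(out, "n_removed_missing") <- length(bad)
  out
}

#' k-nearest-neighbour imputation of missing summarised values
#'
#' Missing (feature, sample) entries are filled with the mean of that
#' feature over the sample's k nearest neighbours, where the neighbour
#' distance is the Euclidean distance over the features observed in both
#' samples, computed once on the pre-imputation matrix. Neighbours among
#' the k nearest that lack the feature contribute nothing; if none of the
#' k nearest observes the feature (or a sample shares no observed feature
#' with any other), the feature median is used and a warning is raised.
#'
#' @param data Long tibble with `feature_id`, `sample_id`, `value`.
#' @param k Number of neighbours.
#' @return The tibble with all `value`s observed; the number of imputed
#'   cells is stored in attribute `"n_imputed"`.
#' @export
impute_knn <- function(data, k = 10) {
  extra <- setdiff(names(data), c("feature_id", "sample_id", "value"))
  x <- long_to_matrix(data)                       # features x samples
  n_missing <- sum(is.na(x))
  if (n_missing == 0) {
    attr(data, "n_imputed") <- 0L
    return(data)
  }
  w <- !is.na(x)
  y <- x
  y[!w] <- 0
  c1 <- crossprod(y^2, w)                         # sum_j y_ja^2 w_jb
  d2 <- c1 + t(c1) - 2 * crossprod(y)
  shared <- crossprod(w)                          # features observed in both
  d2[shared == 0] <- Inf
  diag(d2) <- Inf
  d2[d2 < 0] <- 0                                 # numerical guard

  fallback <- FALSE
  feat_median <- apply(x, 1, median, na.rm = TRUE)
  for (i in which(colSums(!w) > 0)) {
    ord <- order(d2[, i])
    ord <- ord[is.finite(d2[ord, i])]
    nb <- head(ord, k)
    for (g in which(!w[, i])) {
      vals <- x[g, nb]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        fallback <- TRUE
        x[g, i] <- feat_median[g]
      } else {
        x[g, i] <- mean(vals)
      }
    }
  }
  if (fallback) {
    warn("some cells had no informative neighbour; feature medians used.")
  }
  out <- matrix_to_long(x)
  if (length(extra) > 0) {
    key <- dplyr::distinct(data, dplyr::pick(dplyr::all_of(c("sample_id", extra))))
    out <- dplyr::left_join(out, key, by = "sample_id")
  }
  attr(out, "n_imputed") <- n_missing
  out
}

#' Metabolite matrix container
#'
#' A wide tibble of standardised values, one row per sample (`sample_id`
#' column first) and one column per metabolite, with the per-metabolite
#' annotation (name, accession, mode, adduct) carried in the
#' `"annotation"` attribute.
#'
#' @param wide Wide tibble with `sample_id` plus metabolite columns.
#' @param annotation Annotation tibble with a `feature_id` column matching
#'   the metabolite columns.
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(wide, annotation = NULL) {
  stopifnot("sample_id" %in% names(wide))
  structure(wide, annotation = annotation,
            class = c("metabolite_matrix", class(tibble::tibble())))
}

#' Extract the numeric sample-by-metabolite matrix
#' @param mm A [metabolite_matrix()].
#' @return A numeric matrix with sample ids as row names.
#' @export
mm_values <- function(mm) {
  m <- as.matrix(mm[, setdiff(names(mm), "sample_id")])
  rownames(m) <- mm$sample_id
  storage.mode(m) <- "double"
  m
}

#' Metabolite annotation of a matrix
#' @param mm A [metabolite_matrix()].
#' @return The annotation tibble stored on the object (or NULL).
#' @export
mm_annotation <- function(mm) attr(mm, "annotation")

#' log2 transformation and Z-score standardisation
#'
#' Per metabolite, values are (optionally) log2 transformed and then
#' standardised by subtracting the metabolite-specific mean and dividing
#' by the metabolite-specific sample standard deviation (n - 1
#' denominator). After standardisation every column has mean 0 and unit
#' SD.
#'
#' @param data Long tibble with `feature_id`, `sample_id`, `value`. With
#'   `log2 = TRUE`, `value` holds positive intensities; with
#'   `log2 = FALSE` it is already on the log2 scale.
#' @param log2 Apply the log2 transform before standardising?
#' @param annotation Optional annotation tibble to attach.
#' @return A [metabolite_matrix()] of Z-scores (samples by metabolites).
#' @examples
#' d <- tibble::tibble(feature_id = "m1", sample_id = c("s1", "s2", "s3"),
#'                     value = c(1, 2, 4))
#' mm_values(log2_zscore(d))[, 1]  # -1, 0, 1
#' @export
log2_zscore <- function(data, log2 = TRUE, annotation = NULL) {
  if (any(is.na(data$value))) abort("missing values must be imputed first.")
  if (log2 && any(data$value <= 0)) abort("intensities must be positive.")
  scaled <- data |>
    dplyr::mutate(value = if (log2) base::log2(.data$value) else .data$value) |>
    dplyr::mutate(
      .sd = sd(.data$value),
      value = (.data$value - mean(.data$value)) /
        ifelse(.data$.sd > 0, .data$.sd, NA_real_),
      .by = "feature_id"
    )
  degenerate <- unique(scaled$feature_id[is.na(scaled$value)])
  if (length(degenerate) > 0) {
    abort(sprintf("zero-variance metabolite(s): %s",
                  paste(degenerate, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(scaled[, c("feature_id", "sample_id", "value")],
                             names_from = "feature_id",
                             values_from = "value")
  metabolite_matrix(wide, annotation)
}

#' Pool two chromatography modes into one metabolite matrix
#'
#' Column-wise concatenation of two standardised matrices measured on the
#' same samples (e.g. HILIC-positive and C18-negative runs), preserving
#' annotations. Sample sets must match exactly and metabolite ids must be
#' disjoint.
#'
#' @param a,b [metabolite_matrix()] objects.
#' @return The pooled [metabolite_matrix()].
#' @export
merge_modes <- function(a, b) {
  if (ncol(b) <= 1) return(a)
  if (ncol(a) <= 1) return(b)
  diff_ab <- setdiff(a$sample_id, b$sample_id)
  diff_ba <- setdiff(b$sample_id, a$sample_id)
  if (length(diff_ab) > 0 || length(diff_ba) > 0) {
    abort(sprintf("sample sets differ: only in first (%s); only in second (%s)",
                  paste(diff_ab, collapse = ", "),
                  paste(diff_ba, collapse = ", ")))
  }
  dup <- intersect(setdiff(names(a), "sample_id"),
                   setdiff(names(b), "sample_id"))
  if (length(dup) > 0) {
    abort(sprintf("duplicate metabolite id(s) across modes: %s",
                  paste(dup, collapse = ", ")))
  }
  b_ord <- b[match(a$sample_id, b$sample_id), ]
  merged <- dplyr::bind_cols(a, b_ord[, setdiff(names(b_ord), "sample_id")])
  ann <- dplyr::bind_rows(mm_annotation(a), mm_annotation(b))
  metabolite_matrix(merged, if (nrow(ann %||% tibble::tibble()) > 0) ann)
}

#' Annotate features against a Level-1 metabolite library
#'
#' A feature matches a library entry measured in the same chromatography
#' mode when the m/z agreement is within `ppm_tol` parts per million of
#' the library mass and the retention times differ by at most `rt_tol_s`
#' seconds (both bounds inclusive). When several entries qualify, the one
#' closest in ppm wins, with retention-time distance as the tie-break.
#' Unmatched features are dropped from downstream analysis.
#'
#' @param features Tibble of feature annotations (`feature_id`, `mz`,
#'   `rt`, `mode`).
#' @param library Library tibble (`name`, `mz`, `rt`, `mode`, `adduct`,
#'   `hmdb_id`).
#' @param ppm_tol Inclusive m/z tolerance in ppm.
#' @param rt_tol_s Inclusive retention-time tolerance in seconds.
#' @return The matched subset of `features` with library columns `name`,
#'   `adduct`, `hmdb_id`, and the match errors `ppm_error`, `rt_error`.
#' @export
match_library <- function(features, library, ppm_tol = 10, rt_tol_s = 30) {
  cand <- dplyr::inner_join(
    features, dplyr::rename(library, lib_mz = "mz", lib_rt = "rt"),
    by = "mode", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      ppm_error = abs(.data$mz - .data$lib_mz) / .data$lib_mz * 1e6,
      rt_error = abs(.data$rt - .data$lib_rt)
    ) |>
    dplyr::filter(.data$ppm_error <= ppm_tol, .data$rt_error <= rt_tol_s)
  cand |>
    dplyr::arrange(.data$ppm_error, .data$rt_error) |>
    dplyr::distinct(.data$feature_id, .keep_all = TRUE) |>
    dplyr::select("feature_id", "mz", "rt", "mode", "name", "adduct",
                  "hmdb_id", "ppm_error", "rt_error") |>
    dplyr::arrange(.data$feature_id)
}

#' Full post-extraction processing pipeline
#'
#' Runs the fixed processing order on a replicate-level feature table:
#' replicate-CV filter, triplicate median summarisation, log2 transform,
#' empirical-Bayes batch correction, missingness filter, k-nearest
#' neighbour imputation and Z-score standardisation — each chromatography
#' mode processed independently — followed by library matching and pooling
#' of the modes. Only library-matched metabolites survive.
#'
#' @param raw Replicate-level feature table (long form) as produced by
#'   [simulate_metabolome()] or [read_feature_table()].
#' @param library Metabolite library tibble.
#' @param cv_threshold Inclusive median-CV removal bound.
#' @param max_missing Strict missingness removal bound.
#' @param k Neighbours for imputation.
#' @param ppm_tol,rt_tol_s Library matching tolerances.
#' @param batch_method Batch-correction flavour, see [correct_batches()].
#' @return A [metabolite_matrix()] of standardised values for the matched
#'   metabolites, with a `"processing_log"` attribute recording counts at
#'   every stage (see [processing_log()]).
#' @export
preprocess_features <- function(raw, library,
                                cv_threshold = 0.75, max_missing = 0.20,
                                k = 10, ppm_tol = 10, rt_tol_s = 30,
                                batch_method = "eb") {
  n_in <- dplyr::n_distinct(raw$feature_id)
  filtered <- filter_features_by_cv(raw, cv_threshold)
  feat_ann <- dplyr::distinct(filtered, .data$feature_id, .data$mz,
                              .data$rt, .data$mode)
  summarized <- summarize_triplicates(filtered)

  per_mode <- lapply(split(feat_ann$feature_id, feat_ann$mode), function(ids) {
    dat <- summarized |>
      dplyr::filter(.data$feature_id %in% ids) |>
      dplyr::mutate(value = base::log2(.data$intensity),
                    intensity = NULL)
    dat <- correct_batches(dat, method = batch_method)
    dat <- filter_missingness(dat, max_missing)
    n_removed_missing <- attr(dat, "n_removed_missing")
    dat <- impute_knn(dat, k)
    list(mm = log2_zscore(dat, log2 = FALSE),
         n_removed_missing = n_removed_missing,
         n_imputed = attr(dat, "n_imputed"),
         n_cells = nrow(dat))
  })

  matched <- match_library(feat_ann, library, ppm_tol, rt_tol_s)
  mms <- lapply(per_mode, function(x) {
    keep <- intersect(names(x$mm), c("sample_id", matched$feature_id))
    mm <- x$mm[, keep]
    metabolite_matrix(mm, matched[matched$feature_id %in% keep, ])
  })
  pooled <- Reduce(merge_modes, mms)

  log <- list(
    n_features_in = n_in,
    n_removed_cv = attr(filtered, "n_removed_cv"),
    n_removed_missing = sum(vapply(per_mode, `[[`, 1, "n_removed_missing")),
    n_imputed_cells = sum(vapply(per_mode, `[[`, 1, "n_imputed")),
    imputed_fraction = sum(vapply(per_mode, `[[`, 1, "n_imputed")) /
      sum(vapply(per_mode, `[[`, 1, "n_cells")),
    n_matched = nrow(matched),
    n_metabolites_out = ncol(pooled) - 1,
    order = c("cv_filter", "summarize", "log2", "batch_correct",
              "missingness_filter", "impute_knn", "zscore", "match", "merge")
  )
  inform(sprintf("preprocess: %d features in, %d metabolites out, %.2f%% imputed.",
                 n_in, log$n_metabolites_out, 100 * log$imputed_fraction))
  attr(pooled, "processing_log") <- log
  pooled
}

#' Processing log of a preprocessed matrix
#' @param mm A [metabolite_matrix()] from [preprocess_features()].
#' @return A list of per-stage counts.
#' @export
processing_log <- function(mm) attr(mm, "processing_log")
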