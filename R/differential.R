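# Post-hoc per-metabolite Wilcoxon rank-sum ranking between the two
# subtypes, Benjamini-Hochberg adjustment, and top-set selection.

#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks are used for ties. The exact enumeration p-value is computed
#' when the combined sample size is at most 12 and no ties are present;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y Numeric value vectors of the two groups (both non-empty).
#' @param exact_max Largest combined size for the exact path.
#' @return A one-row tibble: `statistic` (the rank-sum U of `x`),
#'   `p_value`, `method` ("exact" or "normal").
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  fit <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    method = if (exact) "exact" else "normal"
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Rank metabolites by differential expression between two subtypes
#'
#' Runs a Wilcoxon rank-sum test per metabolite between subtypes A and B,
#' adjusts with Benjamini-Hochberg, ranks by adjusted then raw p-value,
#' and flags the selected top set (see [rank_and_select()]).
#'
#' @param x A [metabolite_matrix()] of standardised values.
#' @param labels Tibble with `sample_id` and `subtype` (e.g.
#'   `tidy(cluster_subtypes(x))`), or a vector of labels aligned with the
#'   matrix rows. Exactly two subtype levels are required.
#' @param adj_p_threshold,top_fraction Passed to [rank_and_select()].
#' @return A tibble, one row per metabolite, with the test statistic, raw
#'   and adjusted p-values, per-subtype mean Z-scores, rank and `selected`
#'   flag, joined to the matrix annotation when available.
#' @export
rank_metabolites <- function(x, labels, adj_p_threshold = 1e-5,
                             top_fraction = 0.20) {
  m <- mm_values(x)
  lab <- if (is.data.frame(labels)) {
    labels$subtype[match(rownames(m), labels$sample_id)]
  } else as.character(labels)
  levs <- sort(unique(lab))
  if (length(levs) != 2) abort("exactly two subtypes are required.")

  res <- purrr::map_dfr(colnames(m), function(j) {
    xa <- m[lab == levs[1], j]
    xb <- m[lab == levs[2], j]
    t <- wilcoxon_rank_sum(xa, xb)
    tibble::tibble(
      feature_id = j,
      statistic = t$statistic,
      p_value = t$p_value,
      mean_z_a = mean(xa),
      mean_z_b = mean(xb)
    )
  })
  res$adj_p <- bh_adjust(res$p_value)
  res <- res[order(res$adj_p, res$p_value), ]
  res$rank <- seq_len(nrow(res))
  res <- rank_and_select(res, adj_p_threshold, top_fraction)
  ann <- mm_annotation(x)
  if (!is.null(ann)) res <- dplyr::left_join(res, ann, by = "feature_id")
  res
}

#' Select the top differentially expressed set
#'
#' Selection is driven by the adjusted p-value threshold (default 1e-5);
#' the implied selected fraction is reported alongside for transparency,
#' since a "top 20%" style cutoff is arbitrary.
#'
#' @param results Tibble with an `adj_p` column.
#' @param adj_p_threshold Strict selection bound on the adjusted p-value.
#' @param top_fraction Reference fraction reported in the attribute
#'   `"selection"` for comparison with the realised fraction.
#' @return `results` with a logical `selected` column; attribute
#'   `"selection"` holds `n_selected`, `fraction`, and the thresholds.
#' @export
rank_and_select <- function(results, adj_p_threshold = 1e-5,
                            top_fraction = 0.20) {
  results$selected <- results$adj_p < adj_p_threshold
  attr(results, "selection") <- list(
    n_selected = sum(results$selected),
    fraction = mean(results$selected),
    adj_p_threshold = adj_p_threshold,
    top_fraction = top_fraction
  )
  results
}
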