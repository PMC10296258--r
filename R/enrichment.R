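# Background-constrained chi-squared pathway enrichment of the selected
# metabolite set against the full analysed panel.

#' Read a GMT pathway-membership file
#'
#' Each line is `pathway<TAB>description<TAB>member<TAB>member...`.
#' Duplicate members within a line are stored once; a line with no members
#' or fewer than three fields is an error naming the line number.
#'
#' @param path Path to a GMT file.
#' @return A tibble with `pathway`, `description`, and list-column
#'   `hmdb_ids`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    members <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (length(fields) < 3 || length(members) == 0) {
      abort(sprintf("malformed GMT line %d: pathway with no members.", i))
    }
    tibble::tibble(pathway = fields[1], description = fields[2],
                   hmdb_ids = list(members))
  })
  dplyr::bind_rows(parsed)
}

#' Write a pathway map as GMT
#'
#' @param pathways Tibble with `pathway`, `description`, list-column
#'   `hmdb_ids`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- purrr::pmap_chr(pathways, function(pathway, description, hmdb_ids, ...) {
    paste(c(pathway, description, hmdb_ids), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Chi-squared over-representation test for one pathway
#'
#' Pearson chi-squared statistic (no continuity correction) on the 2x2
#' table of pathway membership against selection, `[[k, m-k], [T-k,
#' N-m-T+k]]`, with `N` the background panel size, `T` the selected-set
#' size, `m` the pathway members within the background and `k` the pathway
#' members within the selected set. The p-value is the upper tail of the
#' chi-squared distribution with 1 df; the enrichment direction (sign of
#' `k - mT/N`) is reported separately. Tables with any expected cell below
#' 1 are flagged low-count.
#'
#' @param n_background,n_selected,n_pathway,n_hits The margins N, T, m, k.
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `direction`,
#'   `expected_hits`, `low_count`.
#' @examples
#' enrichment_chisq(186, 38, 6, 4)  # chi2 = 8.15, p = 0.004
#' @export
enrichment_chisq <- function(n_background, n_selected, n_pathway, n_hits) {
  N <- n_background; T_ <- n_selected; m <- n_pathway; k <- n_hits
  if (m <= 0 || m >= N || T_ <= 0 || T_ >= N) {
    abort("zero margin: need 0 < m < N and 0 < T < N.")
  }
  if (k > min(m, T_) || k < max(0, m + T_ - N)) {
    abort("`n_hits` is incompatible with the table margins.")
  }
  observed <- c(k, m - k, T_ - k, N - m - T_ + k)
  expected <- c(m * T_, m * (N - T_), (N - m) * T_, (N - m) * (N - T_)) / N
  chi2 <- sum((observed - expected)^2 / expected)
  tibble::tibble(
    chi2 = chi2,
    df = 1L,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
    direction = if (k >= expected[1]) "enriched" else "depleted",
    expected_hits = expected[1],
    low_count = any(expected < 1)
  )
}

#' Enrichment of every pathway in a map
#'
#' One chi-squared over-representation row per pathway with at least one
#' member in the background panel; pathways absent from the background are
#' skipped and reported in a message. Rows are sorted by ascending
#' p-value.
#'
#' @param selected Character vector of selected metabolite accessions
#'   (must be a subset of `background`).
#' @param background Character vector of all analysed accessions.
#' @param pathways Pathway map tibble from [read_gmt()] or
#'   [simulate_pathways()].
#' @return A tibble with `pathway`, `n_background`, `n_selected`,
#'   `n_pathway`, `n_hits`, and the [enrichment_chisq()] columns.
#' @export
enrich_all <- function(selected, background, pathways) {
  selected <- unique(selected)
  background <- unique(background)
  offenders <- setdiff(selected, background)
  if (length(offenders) > 0) {
    abort(sprintf("selected metabolites outside background: %s",
                  paste(offenders, collapse = ", ")))
  }
  N <- length(background)
  T_ <- length(selected)
  if (T_ == 0) abort("selected set is empty (zero margin).")
  if (T_ == N) abort("selected set equals the background (zero margin).")

  rows <- purrr::pmap_dfr(pathways, function(pathway, hmdb_ids, ...) {
    m <- length(intersect(hmdb_ids, background))
    if (m == 0) {
      return(tibble::tibble(pathway = pathway, n_pathway = 0L))
    }
    k <- length(intersect(hmdb_ids, selected))
    dplyr::bind_cols(
      tibble::tibble(pathway = pathway, n_background = N, n_selected = T_,
                     n_pathway = m, n_hits = k),
      enrichment_chisq(N, T_, m, k)
    )
  })
  skipped <- rows$pathway[rows$n_pathway == 0]
  if (length(skipped) > 0) {
    inform(sprintf("skipped %d pathway(s) with no background members: %s",
                   length(skipped), paste(skipped, collapse = ", ")))
  }
  rows <- rows[rows$n_pathway > 0, ]
  rows[order(rows$p_value), ]
}
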