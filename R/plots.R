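# ggplot2 companions for the main result types.

#' Plot validity metrics and their votes across candidate cluster counts
#'
#' One panel per metric with the voted-for k highlighted; the selected
#' model is the majority winner.
#'
#' @param clustering A `subtype_clustering` from [cluster_subtypes()].
#' @return A ggplot object.
#' @export
plot_cluster_metrics <- function(clustering) {
  stopifnot(!is.null(clustering$metrics))
  long <- tidyr::pivot_longer(clustering$metrics, -"k",
                              names_to = "metric", values_to = "value")
  votes <- clustering$votes
  voted <- dplyr::inner_join(long, votes, by = c("metric", "k"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = voted, colour = "red", size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of clusters",
                  y = NULL,
                  title = sprintf("Model selection: k* = %d", clustering$k_star))
}

#' Kaplan-Meier curves by subtype for one stratum
#'
#' @param strat A `stratified_survival` from [stratified_analysis()].
#' @param stratum Stratum name (e.g. "full", "ever_smoker").
#' @param outcome `"os"` or `"pfs"`.
#' @return A ggplot object of the step curves.
#' @export
plot_km <- function(strat, stratum = "full", outcome = "os") {
  st <- strat$strata[[stratum]]
  stopifnot(!is.null(st))
  curves <- purrr::imap_dfr(st[[outcome]]$km, function(cu, subtype) {
    if (is.null(cu)) return(NULL)
    dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1),
      tidy(cu)[, c("time", "survival")]
    ) |>
      dplyr::mutate(subtype = subtype)
  })
  lr <- st[[outcome]]$logrank
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$subtype)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "survival",
                  title = sprintf("%s, %s%s", stratum, toupper(outcome),
                                  if (!is.null(lr)) {
                                    sprintf(" (log-rank p = %.3g)", lr$p_value)
                                  } else ""))
}

#' ROC curves of the three-year logistic models for one stratum
#'
#' @param strat A `stratified_survival` object.
#' @param stratum Stratum name (default "ever_smoker", where the subtype
#'   is prognostic).
#' @return A ggplot object.
#' @export
plot_roc <- function(strat, stratum = "ever_smoker") {
  st <- strat$strata[[stratum]]
  stopifnot(!is.null(st))
  curves <- purrr::imap_dfr(st$logistic, function(md, model) {
    if (is.null(md)) return(NULL)
    r <- roc_auc(stats::fitted(md$fit$fit), md$fit$fit$y)
    dplyr::mutate(r$curve, model = sprintf("%s (AUC %.2f)", model, md$auc))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity,
                                       colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("Three-year mortality, %s", stratum))
}

#' Bar chart of pathway enrichment
#'
#' @param enrichment Result of [enrich_all()].
#' @param top Number of pathways shown.
#' @return A ggplot object of -log10 p by pathway.
#' @export
plot_enrichment <- function(enrichment, top = 10) {
  d <- head(enrichment, top)
  d$pathway <- factor(d$pathway, levels = rev(d$pathway))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_value), y = .data$pathway,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL)
}
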