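# End-to-end orchestration: simulate (or load) -> preprocess -> cluster ->
# rank -> enrich -> survival, with a machine-readable report.

#' Pipeline configuration
#'
#' Collects every stage parameter with the pipeline's default analysis
#' settings: replicate-CV removal at 0.75 (inclusive), missingness
#' removal above 0.20 (strict), k-nearest-neighbour imputation with
#' k = 10, candidate cluster counts 2-6, differential selection at
#' adjusted p < 1e-5, and 10 ppm / 30 s library matching.
#'
#' @param sim A [sim_config()] describing the synthetic cohort (ignored
#'   when `input_dir` points at files on disk).
#' @param input_dir Optional directory holding `clinical.csv`,
#'   `features.tsv`, `samples.csv`, `library.tsv`, `pathways.gmt` as
#'   written by [write_cohort()]; when `NULL` the cohort is simulated.
#' @param cv_threshold,max_missing,impute_k,ppm_tol,rt_tol_s,batch_method
#'   Preprocessing parameters, see [preprocess_features()].
#' @param k_range Candidate cluster counts.
#' @param cluster_method `"hierarchical"`, `"kmeans"`, or `"rf"`.
#' @param adj_p_threshold,top_fraction Differential selection parameters.
#' @param horizon Years for the logistic/ROC comparison.
#' @param seed Seed for the stochastic sensitivity clusterings.
#' @return A list of class `metab_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            cv_threshold = 0.75, max_missing = 0.20,
                            impute_k = 10, ppm_tol = 10, rt_tol_s = 30,
                            batch_method = "eb",
                            k_range = 2:6,
                            cluster_method = c("hierarchical", "kmeans", "rf"),
                            adj_p_threshold = 1e-5, top_fraction = 0.20,
                            horizon = 3, seed = 1) {
  structure(list(
    sim = sim, input_dir = input_dir,
    cv_threshold = cv_threshold, max_missing = max_missing,
    impute_k = impute_k, ppm_tol = ppm_tol, rt_tol_s = rt_tol_s,
    batch_method = batch_method, k_range = k_range,
    cluster_method = match.arg(cluster_method),
    adj_p_threshold = adj_p_threshold, top_fraction = top_fraction,
    horizon = horizon, seed = seed
  ), class = "metab_pipeline_config")
}

resolved_config_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$pathway_spec <- as.data.frame(out$sim$pathway_spec)
  out
}

#' Run the full subtype-discovery pipeline
#'
#' Executes the stages in their fixed order — simulate or load inputs,
#' preprocess the replicate-level features into a standardised metabolite
#' matrix, cluster patients into metabolic subtypes with validity-vote
#' model selection, rank metabolites by differential expression, run
#' pathway enrichment of the selected set against the analysed panel, and
#' evaluate the subtypes against overall and progression-free survival in
#' smoking/HPV strata. Results are returned in one object and optionally
#' written to `out_dir` as CSV/JSON artifacts plus a run log.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `metab_pipeline_result` with elements
#'   `cohort`, `matrix`, `clustering`, `differential`, `enrichment`,
#'   `survival`, and `report` (a plain list; identical across reruns of
#'   the same configuration).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "metab_pipeline_config"))
  t0 <- Sys.time()
  timing <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    timing[[name]] <<- round(as.numeric(Sys.time() - st, units = "secs"), 3)
    value
  }

  cohort <- stage("simulate", {
    if (is.null(config$input_dir)) {
      simulate_cohort(config$sim)
    } else {
      d <- config$input_dir
      structure(list(
        clinical = read_clinical(file.path(d, "clinical.csv")),
        features = read_feature_table(file.path(d, "features.tsv"),
                                      file.path(d, "samples.csv")),
        library = read_library(file.path(d, "library.tsv")),
        pathways = read_gmt(file.path(d, "pathways.gmt")),
        config = NULL
      ), class = "metab_cohort")
    }
  })

  mm <- stage("preprocess", suppressMessages(
    preprocess_features(cohort$features, cohort$library,
                        cv_threshold = config$cv_threshold,
                        max_missing = config$max_missing,
                        k = config$impute_k, ppm_tol = config$ppm_tol,
                        rt_tol_s = config$rt_tol_s,
                        batch_method = config$batch_method)
  ))

  clustering <- stage("cluster", switch(
    config$cluster_method,
    hierarchical = cluster_subtypes(mm, k_range = config$k_range),
    kmeans = kmeans_cluster(mm, k = min(config$k_range), seed = config$seed),
    rf = rf_proximity_cluster(mm, k = min(config$k_range), seed = config$seed)
  ))

  differential <- stage("rank", {
    lab <- tidy(clustering)
    lab$subtype <- ifelse(lab$subtype == "A", "A", "B")  # two-level contrast
    rank_metabolites(mm, lab, adj_p_threshold = config$adj_p_threshold,
                     top_fraction = config$top_fraction)
  })

  enrichment <- stage("enrich", {
    sel <- attr(differential, "selection")
    if (sel$n_selected > 0 && sel$n_selected < nrow(differential) &&
        nrow(cohort$pathways) > 0 && "hmdb_id" %in% names(differential)) {
      suppressMessages(enrich_all(
        selected = differential$hmdb_id[differential$selected],
        background = differential$hmdb_id,
        pathways = cohort$pathways
      ))
    } else {
      NULL
    }
  })

  surv <- stage("survive", {
    joined <- dplyr::left_join(cohort$clinical, tidy(clustering),
                               by = c(id = "sample_id"))
    suppressWarnings(stratified_analysis(joined, horizon = config$horizon))
  })

  sel <- attr(differential, "selection")
  plog <- processing_log(mm)
  report <- list(
    config = resolved_config_list(config),
    preprocessing = plog,
    clustering = list(
      method = clustering$method,
      k_star = clustering$k_star,
      votes = if (!is.null(clustering$votes)) as.data.frame(clustering$votes),
      subtype_sizes = as.list(table(tidy(clustering)$subtype))
    ),
    differential = list(
      n_selected = sel$n_selected,
      selected_fraction = sel$fraction,
      adj_p_threshold = sel$adj_p_threshold
    ),
    enrichment = if (!is.null(enrichment)) {
      as.data.frame(head(enrichment[, c("pathway", "n_pathway", "n_hits",
                                        "chi2", "p_value")], 10))
    },
    survival = as.data.frame(glance(surv))
  )

  result <- structure(list(cohort = cohort, matrix = mm,
                           clustering = clustering,
                           differential = differential,
                           enrichment = enrichment, survival = surv,
                           report = report),
                      class = "metab_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(clustering), file.path(out_dir, "subtypes.csv"))
    if (!is.null(clustering$metrics)) {
      readr::write_csv(clustering$metrics, file.path(out_dir, "cluster_metrics.csv"))
    }
    readr::write_csv(differential, file.path(out_dir, "differential.csv"))
    if (!is.null(enrichment)) {
      readr::write_csv(enrichment, file.path(out_dir, "enrichment.csv"))
    }
    readr::write_csv(tidy(surv), file.path(out_dir, "cox_models.csv"))
    readr::write_csv(glance(surv), file.path(out_dir, "survival_summary.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    run_log <- list(stages = timing,
                    total_secs = round(as.numeric(Sys.time() - t0,
                                                  units = "secs"), 3),
                    finished = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
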