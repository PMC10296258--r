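#' Simulate a metabolite identification library
#'
#' Generates the annotation backbone for the synthetic cohort: one entry
#' per metabolite with a synthetic name, accurate mass, retention time,
#' chromatography mode (HILIC with positive ionisation or C18 with
#' negative ionisation, split roughly 2:1 as in typical dual-mode panels),
#' adduct, and a synthetic HMDB-style accession. All identifiers are
#' synthetic; they resemble but never collide with real HMDB records.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `name`, `mz`, `rt`, `mode`, `adduct`,
#'   `hmdb_id`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "metab_sim_config"))
  n <- config$n_metabolites
  withr::local_seed(stage_seed(config, "library"))
  n_hilic <- round(n * 125 / 186)
  mode <- sample(c(rep("HILIC+", n_hilic), rep("C18-", n - n_hilic)))
  tibble::tibble(
    name = sprintf("SynMet_%03d", seq_len(n)),
    mz = round(runif(n, 85, 1275), 4),
    rt = round(ifelse(mode == "HILIC+", runif(n, 30, 300), runif(n, 10, 250))),
    mode = mode,
    adduct = ifelse(mode == "HILIC+", "(M + H)", "(M - H)"),
    hmdb_id = sprintf("HMDB9%06d", seq_len(n))
  )
}

#' Simulate a pathway membership map
#'
#' Assigns library metabolites to the designated pathways of the
#' configuration's `pathway_spec`. Members are drawn without replacement,
#' so default pathways are disjoint; membership is deterministic given the
#' configuration seed. The default specification includes a 6-member fatty
#' acid biosynthesis pathway, the worked-example pathway used throughout
#' the package documentation.
#'
#' @param config A [sim_config()] object.
#' @param library A metabolite library from [simulate_library()].
#' @return A tibble with columns `pathway`, `description` and a
#'   list-column `hmdb_ids`; the shape returned by [read_gmt()].
#' @export
simulate_pathways <- function(config, library = simulate_library(config)) {
  stopifnot(inherits(config, "metab_sim_config"))
  spec <- config$pathway_spec
  if (nrow(spec) == 0) {
    return(tibble::tibble(pathway = character(), description = character(),
                          hmdb_ids = list()))
  }
  withr::local_seed(stage_seed(config, "pathways"))
  picked <- sample(library$hmdb_id, sum(spec$size))
  ends <- cumsum(spec$size)
  starts <- ends - spec$size + 1
  tibble::tibble(
    pathway = spec$pathway,
    description = "synthetic pathway",
    hmdb_ids = purrr::map2(starts, ends, function(s, e) picked[s:e])
  )
}

#' Simulate replicate-level LC-MS feature intensities
#'
#' Builds the latent patient-by-metabolite signal and degrades it the way
#' an untargeted LC-MS experiment would. Per metabolite, subtype A
#' patients are shifted upward by the pathway-specific mean shift (in
#' latent SD units) if the metabolite belongs to a designated pathway, or
#' by a random `N(0, background_shift_sd^2)` shift otherwise; noise within
#' a pathway is exchangeably correlated at `block_correlation`. The latent
#' log2 signal is placed on a random per-metabolite base abundance, batch
#' shifts are added per (feature, batch), the result is exponentiated to
#' the intensity scale, and three replicate injections are drawn with
#' multiplicative log-normal noise of coefficient of variation
#' `replicate_cv`. Values then go missing with probability increasing as
#' intensity decreases (a logistic in standardised log2 intensity with
#' slope `mnar_strength`, calibrated so the marginal missingness equals
#' `missing_rate`). Feature m/z and retention time are jittered within the
#' matching tolerance of the supplied library.
#'
#' @param clinical A clinical table carrying `true_subtype`.
#' @param pathways A pathway map from [simulate_pathways()].
#' @param config The [sim_config()] object.
#' @param library The metabolite library; defaults to the one implied by
#'   the configuration seed.
#' @return A long tibble with one row per (feature, sample, replicate):
#'   `feature_id`, `mz`, `rt`, `mode`, `sample_id`, `batch`, `replicate`,
#'   `intensity` (NA when missing). The library used is attached as the
#'   `"library"` attribute.
#' @export
simulate_metabolome <- function(clinical, pathways, config,
                                library = simulate_library(config)) {
  stopifnot(inherits(config, "metab_sim_config"))
  if (!"true_subtype" %in% names(clinical)) {
    abort("`clinical` must carry a latent `true_subtype` column.")
  }
  all_members <- unique(unlist(pathways$hmdb_ids))
  missing_acc <- setdiff(all_members, library$hmdb_id)
  if (length(missing_acc) > 0) {
    abort(sprintf("pathway accessions absent from library: %s",
                  paste(missing_acc, collapse = ", ")),
          class = "metabosurv_validation_error")
  }
  n <- nrow(clinical)
  p <- nrow(library)
  withr::local_seed(stage_seed(config, "metabolome"))

  # per-metabolite subtype shift and pathway block
  shift <- rnorm(p, 0, config$background_shift_sd)
  block <- rep(NA_integer_, p)
  for (b in seq_len(nrow(pathways))) {
    idx <- match(pathways$hmdb_ids[[b]], library$hmdb_id)
    blk_shift <- config$pathway_spec$shift[
      match(pathways$pathway[b], config$pathway_spec$pathway)]
    shift[idx] <- blk_shift %||% 0
    block[idx] <- b
  }

  # latent values: mean shift for subtype A + exchangeable block noise
  is_a <- clinical$true_subtype == "A"
  rho <- config$block_correlation
  eps <- matrix(rnorm(n * p), n, p)
  if (any(!is.na(block)) && rho > 0) {
    u <- matrix(rnorm(n * nrow(pathways)), n, nrow(pathways))
    in_block <- which(!is.na(block))
    eps[, in_block] <- sqrt(1 - rho) * eps[, in_block] +
      sqrt(rho) * u[, block[in_block], drop = FALSE]
  }
  latent <- outer(is_a, shift) + eps                  # n x p, SD-unit scale

  # assemble replicate-level log2 intensities
  base <- runif(p, 10, 20)
  batch <- sample(rep(seq_len(config$n_batches), length.out = n))
  gamma <- matrix(rnorm(config$n_batches * p, 0, config$batch_shift_sd),
                  config$n_batches, p)
  log2_core <- sweep(latent, 2, base, `+`) + gamma[batch, , drop = FALSE]

  sigma_rep <- sqrt(log(1 + config$replicate_cv^2))
  reps <- lapply(1:3, function(r) {
    noise <- if (sigma_rep > 0) {
      exp(rnorm(n * p, -sigma_rep^2 / 2, sigma_rep))
    } else 1
    2^log2_core * noise
  })

  # intensity-dependent (MNAR) missingness, calibrated to missing_rate
  if (config$missing_rate > 0) {
    all_log2 <- log2(unlist(reps))
    z <- (all_log2 - mean(all_log2)) / sd(all_log2)
    s <- config$mnar_strength
    a <- uniroot(function(a) mean(plogis(a - s * z)) - config$missing_rate,
                 c(-50, 50))$root
    drop <- runif(length(z)) < plogis(a - s * z)
    for (r in 1:3) {
      m <- matrix(drop[((r - 1) * n * p + 1):(r * n * p)], n, p)
      reps[[r]][m] <- NA
    }
  }

  feat <- tibble::tibble(
    feature_id = sprintf("F%04d", seq_len(p)),
    mz = round(library$mz * (1 + runif(p, -3e-6, 3e-6)), 4),
    rt = round(library$rt + runif(p, -5, 5), 1),
    mode = library$mode
  )
  samples <- tibble::tibble(sample_id = clinical$id, batch = batch)

  long <- purrr::map_dfr(1:3, function(r) {
    tibble::tibble(
      feature_id = rep(feat$feature_id, each = n),
      sample_id = rep(samples$sample_id, p),
      batch = rep(samples$batch, p),
      replicate = r,
      intensity = as.vector(reps[[r]])
    )
  })
  out <- dplyr::left_join(feat, long, by = "feature_id")
  out <- dplyr::arrange(out, .data$feature_id, .data$sample_id, .data$replicate)
  attr(out, "library") <- library
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running the full generator: clinical covariates,
#' survival outcomes, metabolite library, pathway map, and replicate-level
#' feature intensities, all deterministic given the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `metab_cohort` with elements `clinical`,
#'   `features`, `library`, `pathways`, and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 30, n_metabolites = 40,
#'                                      pathway_spec = NULL, seed = 2))
#' names(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "metab_sim_config"))
  clinical <- simulate_survival(simulate_clinical(config), config)
  library <- simulate_library(config)
  pathways <- simulate_pathways(config, library)
  features <- simulate_metabolome(clinical, pathways, config, library)
  structure(list(clinical = clinical, features = features,
                 library = library, pathways = pathways, config = config),
            class = "metab_cohort")
}
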