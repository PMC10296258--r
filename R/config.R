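#' Simulation configuration for a synthetic metabolomics cohort
#'
#' Builds and validates the parameter set that drives the synthetic cohort
#' generator. The defaults describe a two-subtype head-and-neck cancer
#' cohort: 209 patients split 41%/59% into a high-risk subtype A and a
#' low-risk subtype B, 186 annotated metabolites measured in triplicate in
#' two chromatography modes, batch structure and intensity-dependent
#' missingness, and survival in which subtype A carries a threefold hazard
#' among ever-smokers but no excess hazard among never-smokers.
#'
#' @param n_patients Number of patients.
#' @param n_metabolites Number of annotated metabolites across both modes.
#' @param subtype_prevalence Probability that a patient belongs to subtype A.
#' @param pathway_spec Data frame with columns `pathway`, `size`,
#'   `shift` giving, for each designated pathway, its member count and the
#'   per-metabolite mean shift (in latent SD units) of subtype A above B.
#'   Sizes must fit within `n_metabolites`.
#' @param background_shift_sd SD of the random subtype shift given to
#'   metabolites outside the designated pathways.
#' @param block_correlation Exchangeable within-pathway noise correlation,
#'   in `[0, 1)`.
#' @param n_batches Number of analytical batches.
#' @param batch_shift_sd SD of the additive per-(feature, batch) shift on
#'   the log2 scale.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   technical-replicate noise.
#' @param missing_rate Target marginal missingness rate of replicate-level
#'   intensities, in `[0, 1)`.
#' @param mnar_strength Slope of the missingness logit in standardised
#'   log2 intensity; larger values concentrate missingness at low
#'   intensities (0 = missing completely at random).
#' @param smoking_probs Length-3 probability vector (never, former,
#'   current), summing to 1.
#' @param hpv_positive_prob Probability of HPV-related disease.
#' @param age_mean_by_subtype Length-2 vector of mean age (years) for
#'   subtypes A and B.
#' @param age_sd SD of age in years.
#' @param hr_subtypeA_smoker Hazard ratio of subtype A vs B among
#'   ever-smokers.
#' @param hr_subtypeA_never Hazard ratio of subtype A vs B among
#'   never-smokers.
#' @param baseline_3yr_survival Three-year survival of the reference group
#'   (subtype B), in (0, 1).
#' @param censor_window Length-2 vector (min, max) in years of the uniform
#'   administrative censoring window.
#' @param loss_to_followup Fraction of patients lost to follow-up (their
#'   survival columns are `NA` and they are excluded from survival
#'   analyses).
#' @param progression_rate_ratio Progression hazard as a multiple of the
#'   mortality hazard; progression-free survival is the minimum of the
#'   progression and death times.
#' @param covariate_missing_rate Per-item probability that an optional
#'   clinical covariate is missing for a patient.
#' @param seed Integer seed; identical configurations give byte-identical
#'   simulated outputs.
#'
#' @return A validated list of class `metab_sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 40, n_metabolites = 30, seed = 7)
#' cfg$subtype_prevalence
#' @export
sim_config <- function(n_patients = 209,
                       n_metabolites = 186,
                       subtype_prevalence = 0.41,
                       pathway_spec = default_pathway_spec(),
                       background_shift_sd = 0.45,
                       block_correlation = 0.3,
                       n_batches = 4,
                       batch_shift_sd = 0.3,
                       replicate_cv = 0.15,
                       missing_rate = 0.06,
                       mnar_strength = 1,
                       smoking_probs = c(never = 0.39, former = 0.33, current = 0.28),
                       hpv_positive_prob = 0.48,
                       age_mean_by_subtype = c(A = 61.7, B = 57.6),
                       age_sd = 10,
                       hr_subtypeA_smoker = 3,
                       hr_subtypeA_never = 1,
                       baseline_3yr_survival = 0.863,
                       censor_window = c(2.5, 9.5),
                       loss_to_followup = 20 / 209,
                       progression_rate_ratio = 0.5,
                       covariate_missing_rate = 0.025,
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients, n_metabolites = n_metabolites,
    subtype_prevalence = subtype_prevalence,
    pathway_spec = tibble::as_tibble(
      pathway_spec %||%
        tibble::tibble(pathway = character(), size = integer(), shift = numeric())
    ),
    background_shift_sd = background_shift_sd,
    block_correlation = block_correlation,
    n_batches = n_batches, batch_shift_sd = batch_shift_sd,
    replicate_cv = replicate_cv, missing_rate = missing_rate,
    mnar_strength = mnar_strength,
    smoking_probs = smoking_probs, hpv_positive_prob = hpv_positive_prob,
    age_mean_by_subtype = age_mean_by_subtype, age_sd = age_sd,
    hr_subtypeA_smoker = hr_subtypeA_smoker,
    hr_subtypeA_never = hr_subtypeA_never,
    baseline_3yr_survival = baseline_3yr_survival,
    censor_window = censor_window, loss_to_followup = loss_to_followup,
    progression_rate_ratio = progression_rate_ratio,
    covariate_missing_rate = covariate_missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "metab_sim_config")
}

#' Default designated-pathway specification
#'
#' Four metabolic pathways with member counts of 6, 5, 12 and 6 and
#' per-metabolite subtype mean shifts calibrated so that, at the default
#' cohort size, the observed per-subtype mean Z-scores land near +0.4 for
#' subtype A and -0.3 for subtype B.
#'
#' @return A tibble with columns `pathway`, `size`, `shift`.
#' @export
default_pathway_spec <- function() {
  tibble::tibble(
    pathway = c(
      "Fatty acid biosynthesis",
      "Transfer of acetyl groups into mitochondria",
      "Arginine and proline metabolism",
      "Galactose metabolism"
    ),
    size = c(6L, 5L, 12L, 6L),
    shift = c(0.85, 0.75, 0.85, 1.15)
  )
}

config_error <- function(msg) {
  abort(msg, class = "metabosurv_config_error")
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients)) {
    config_error("`n_patients` must be a nonnegative integer.")
  }
  if (!is.numeric(cfg$n_metabolites) || cfg$n_metabolites < 1) {
    config_error("`n_metabolites` must be a positive count.")
  }
  if (!is_prob(cfg$subtype_prevalence) ||
      cfg$subtype_prevalence <= 0 || cfg$subtype_prevalence >= 1) {
    config_error("`subtype_prevalence` must lie strictly in (0, 1).")
  }
  ps <- cfg$pathway_spec
  if (nrow(ps) > 0) {
    if (!all(c("pathway", "size", "shift") %in% names(ps))) {
      config_error("`pathway_spec` needs columns pathway, size, shift.")
    }
    if (any(ps$size < 1)) config_error("pathway sizes must be positive.")
    if (sum(ps$size) > cfg$n_metabolites) {
      config_error("pathway sizes sum beyond `n_metabolites`.")
    }
  }
  for (nm in c("background_shift_sd", "batch_shift_sd", "replicate_cv",
               "mnar_strength", "age_sd", "progression_rate_ratio")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      config_error(sprintf("`%s` must be nonnegative.", nm))
    }
  }
  if (!is_prob(cfg$block_correlation) || cfg$block_correlation >= 1) {
    config_error("`block_correlation` must lie in [0, 1).")
  }
  if (!is_prob(cfg$missing_rate) || cfg$missing_rate >= 1) {
    config_error("`missing_rate` must lie in [0, 1).")
  }
  if (length(cfg$smoking_probs) != 3 || any(cfg$smoking_probs < 0) ||
      abs(sum(cfg$smoking_probs) - 1) > 1e-8) {
    config_error("`smoking_probs` must be a 3-vector summing to 1.")
  }
  if (!is_prob(cfg$hpv_positive_prob)) {
    config_error("`hpv_positive_prob` must lie in [0, 1].")
  }
  if (!is_prob(cfg$loss_to_followup) || cfg$loss_to_followup >= 1) {
    config_error("`loss_to_followup` must lie in [0, 1).")
  }
  if (!is_prob(cfg$covariate_missing_rate) || cfg$covariate_missing_rate >= 1) {
    config_error("`covariate_missing_rate` must lie in [0, 1).")
  }
  if (length(cfg$age_mean_by_subtype) != 2) {
    config_error("`age_mean_by_subtype` must have two entries (A, B).")
  }
  if (!is.numeric(cfg$hr_subtypeA_smoker) || cfg$hr_subtypeA_smoker <= 0 ||
      !is.numeric(cfg$hr_subtypeA_never) || cfg$hr_subtypeA_never <= 0) {
    config_error("hazard ratios must be positive.")
  }
  if (!is.numeric(cfg$baseline_3yr_survival) ||
      cfg$baseline_3yr_survival <= 0 || cfg$baseline_3yr_survival >= 1) {
    config_error("`baseline_3yr_survival` must lie strictly in (0, 1).")
  }
  if (length(cfg$censor_window) != 2 || any(cfg$censor_window <= 0) ||
      cfg$censor_window[1] > cfg$censor_window[2]) {
    config_error("`censor_window` must be an increasing positive (min, max).")
  }
  if (cfg$n_batches < 1) config_error("`n_batches` must be at least 1.")
  invisible(cfg)
}

# Deterministic sub-seed for a named simulation stage, kept within 32-bit
# integer range so set.seed() accepts it on every platform.
stage_seed <- function(cfg, stage) {
  offset <- c(clinical = 11L, pathways = 23L, library = 37L,
              metabolome = 53L, survival = 71L)[[stage]]
  as.integer((as.numeric(cfg$seed) * 7919 + offset) %% .Machine$integer.max)
}
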