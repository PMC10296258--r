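#' Table 1-style clinical vocabulary used by the synthetic generator
#'
#' Category levels and default sampling frequencies for the clinical
#' covariates of a head-and-neck squamous cell carcinoma cohort. The first
#' level of each factor is the reference level used by the survival models.
#' @keywords internal
clinical_vocab <- function() {
  list(
    sex = c(Male = 0.75, Female = 0.25),
    race = c(White = 0.81, Black = 0.19),
    alcohol = c("<1 drink/week" = 0.55, "1+ drink/week" = 0.45),
    marital = c("Married or partnered" = 0.71, Single = 0.29),
    tumor_site = c(Oropharynx = 0.51, "Oral cavity" = 0.15, Larynx = 0.17,
                   Other = 0.17),
    stage = c(I = 0.05, II = 0.08, III = 0.40, IV = 0.47),
    treatment = c(Radiotherapy = 0.22,
                  "Chemoradiotherapy with Cisplatin" = 0.56,
                  "Chemoradiotherapy with Carboplatin and Paclitaxel" = 0.22),
    feeding_tube = c(No = 0.40, Yes = 0.60),
    ecog = c(Active = 0.50, Restricted = 0.37, "Non-working" = 0.13),
    comorbidity = c(Yes = 0.75, No = 0.25)
  )
}

sample_factor <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

clinical_schema <- function() {
  vocab <- clinical_vocab()
  fct <- function(nm) factor(character(), levels = names(vocab[[nm]]))
  tibble::tibble(
    id = character(), true_subtype = character(), age = numeric(),
    sex = fct("sex"), race = fct("race"), bmi = numeric(),
    hpv_status = factor(character(), levels = c("unrelated", "related")),
    smoking = factor(character(), levels = c("never", "former", "current")),
    alcohol = fct("alcohol"), marital = fct("marital"),
    tumor_site = fct("tumor_site"), stage = fct("stage"),
    treatment = fct("treatment"), feeding_tube = fct("feeding_tube"),
    ecog = fct("ecog"), comorbidity = fct("comorbidity"),
    albumin = numeric(), hemoglobin = numeric(), nlr = numeric(),
    plr = numeric(), followed = logical(),
    os_time = numeric(), os_event = integer(),
    pfs_time = numeric(), pfs_event = integer()
  )
}

#' Simulate a clinical table with a latent metabolic subtype
#'
#' Draws one row per patient: a hidden two-level metabolic subtype
#' (`true_subtype`, Bernoulli with the configured prevalence), age from a
#' per-subtype normal, and all remaining demographic, tumour, treatment and
#' laboratory covariates independently from their configured frequencies.
#' Survival columns are created but left `NA` until [simulate_survival()]
#' fills them. A small per-item missingness is injected into the optional
#' covariates so that fully adjusted models must drop incomplete rows, as
#' real registries do.
#'
#' @param config A [sim_config()] object.
#' @return A tibble, one row per patient. `true_subtype` is a latent label
#'   ("A" high-risk, "B" low-risk) that the analysis pipeline never sees.
#' @examples
#' clin <- simulate_clinical(sim_config(n_patients = 50, seed = 1))
#' table(clin$true_subtype)
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "metab_sim_config"))
  n <- config$n_patients
  if (n == 0) return(clinical_schema())
  withr::local_seed(stage_seed(config, "clinical"))
  vocab <- clinical_vocab()

  subtype <- ifelse(rbinom(n, 1, config$subtype_prevalence) == 1, "A", "B")
  age_mean <- ifelse(subtype == "A",
                     config$age_mean_by_subtype[[1]],
                     config$age_mean_by_subtype[[2]])
  clin <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    true_subtype = subtype,
    age = rnorm(n, age_mean, config$age_sd),
    sex = sample_factor(n, vocab$sex),
    race = sample_factor(n, vocab$race),
    bmi = rnorm(n, 27.5, 5.2),
    hpv_status = factor(
      ifelse(rbinom(n, 1, config$hpv_positive_prob) == 1, "related", "unrelated"),
      levels = c("unrelated", "related")
    ),
    smoking = factor(
      sample(c("never", "former", "current"), n, replace = TRUE,
             prob = config$smoking_probs),
      levels = c("never", "former", "current")
    ),
    alcohol = sample_factor(n, vocab$alcohol),
    marital = sample_factor(n, vocab$marital),
    tumor_site = sample_factor(n, vocab$tumor_site),
    stage = sample_factor(n, vocab$stage),
    treatment = sample_factor(n, vocab$treatment),
    feeding_tube = sample_factor(n, vocab$feeding_tube),
    ecog = sample_factor(n, vocab$ecog),
    comorbidity = sample_factor(n, vocab$comorbidity),
    albumin = rnorm(n, 3.95, 0.42),
    hemoglobin = rnorm(n, 13.18, 1.80),
    nlr = pmax(rnorm(n, 3.18, 2.07), 0.2),
    plr = pmax(rnorm(n, 170.3, 98.9), 10),
    followed = NA,
    os_time = NA_real_, os_event = NA_integer_,
    pfs_time = NA_real_, pfs_event = NA_integer_
  )

  # item-level missingness in the optional covariates only
  optional <- c("bmi", "alcohol", "stage", "feeding_tube", "ecog",
                "comorbidity", "albumin", "hemoglobin", "nlr", "plr")
  if (config$covariate_missing_rate > 0) {
    for (col in optional) {
      miss <- rbinom(n, 1, config$covariate_missing_rate) == 1
      clin[[col]][miss] <- NA
    }
  }
  clin
}

#' Simulate survival outcomes with a subtype-by-smoking interaction
#'
#' Event times are exponential. The reference hazard is calibrated so the
#' configured group attains `baseline_3yr_survival` at three years:
#' `lambda = -log(baseline_3yr_survival) / 3`. Subtype A patients have
#' their hazard multiplied by `hr_subtypeA_smoker` if they ever smoked and
#' by `hr_subtypeA_never` otherwise. Progression times are exponential
#' with hazard `progression_rate_ratio * lambda` (same subtype multiplier),
#' and progression-free survival is the minimum of progression and death,
#' so `pfs_time <= os_time` always. Administrative censoring is uniform on
#' `censor_window`; a `loss_to_followup` fraction of patients is flagged
#' unfollowed with `NA` survival columns.
#'
#' @param clinical A clinical table from [simulate_clinical()].
#' @param config The [sim_config()] used to generate it.
#' @return The clinical table with `followed`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event` filled in.
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 3)
#' clin <- simulate_survival(simulate_clinical(cfg), cfg)
#' mean(clin$os_event, na.rm = TRUE)
#' @export
simulate_survival <- function(clinical, config) {
  stopifnot(inherits(config, "metab_sim_config"))
  if (!all(c("true_subtype", "smoking") %in% names(clinical))) {
    abort("`clinical` must carry latent subtype and smoking columns.")
  }
  n <- nrow(clinical)
  if (n == 0) return(clinical)
  withr::local_seed(stage_seed(config, "survival"))

  lambda0 <- -log(config$baseline_3yr_survival) / 3
  ever <- clinical$smoking != "never"
  hr <- ifelse(clinical$true_subtype == "A",
               ifelse(ever, config$hr_subtypeA_smoker, config$hr_subtypeA_never),
               1)
  death <- rexp(n, rate = lambda0 * hr)
  progression <- rexp(n, rate = lambda0 * hr * config$progression_rate_ratio)
  censor <- runif(n, config$censor_window[1], config$censor_window[2])

  clinical$os_time <- pmin(death, censor)
  clinical$os_event <- as.integer(death <= censor)
  pfs_raw <- pmin(progression, death)
  clinical$pfs_time <- pmin(pfs_raw, censor)
  clinical$pfs_event <- as.integer(pfs_raw <= censor)

  clinical$followed <- rbinom(n, 1, 1 - config$loss_to_followup) == 1
  surv_cols <- c("os_time", "os_event", "pfs_time", "pfs_event")
  clinical[!clinical$followed, surv_cols] <- NA
  clinical
}
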