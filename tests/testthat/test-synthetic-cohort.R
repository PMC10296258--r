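# The synthetic cohort generator: calibration of clinical marginals,
# metabolome structure, survival law, and determinism.

test_that("an empty cohort keeps the full clinical column schema", {
  clin <- simulate_clinical(sim_config(n_patients = 0))
  expect_equal(nrow(clin), 0)
  expect_true(all(c("id", "true_subtype", "age", "sex", "race", "bmi",
                    "hpv_status", "smoking", "alcohol", "marital",
                    "tumor_site", "stage", "treatment", "feeding_tube",
                    "ecog", "comorbidity", "albumin", "hemoglobin", "nlr",
                    "plr", "os_time", "os_event", "pfs_time", "pfs_event")
                  %in% names(clin)))
})

test_that("clinical marginals land near their configured frequencies", {
  clin <- simulate_clinical(sim_config(seed = 42))
  expect_equal(nrow(clin), 209)
  expect_lt(abs(mean(clin$true_subtype == "A") - 0.41), 0.07)
  expect_lt(abs(mean(clin$smoking == "never") - 0.39), 0.07)
  expect_lt(abs(mean(clin$hpv_status == "related") - 0.48), 0.07)
})

test_that("large cohorts recover every configured marginal within 0.01", {
  cfg <- sim_config(n_patients = 50000, covariate_missing_rate = 0, seed = 5)
  clin <- simulate_clinical(cfg)
  expect_lt(abs(mean(clin$age[clin$true_subtype == "A"]) - 61.7), 0.2)
  expect_lt(abs(mean(clin$age[clin$true_subtype == "B"]) - 57.6), 0.2)
  expect_lt(abs(mean(clin$true_subtype == "A") - 0.41), 0.01)
  expect_lt(abs(mean(clin$hpv_status == "related") - 0.48), 0.01)
  expect_lt(abs(mean(clin$sex == "Male") - 0.75), 0.01)
  expect_lt(abs(mean(clin$race == "White") - 0.81), 0.01)
  sm <- prop.table(table(clin$smoking))
  expect_true(all(abs(sm - c(0.39, 0.33, 0.28)) < 0.01))
})

test_that("identical configurations give identical cohorts", {
  a <- simulate_cohort(small_cfg(seed = 9))
  b <- simulate_cohort(small_cfg(seed = 9))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$features, b$features)
  expect_identical(a$pathways, b$pathways)
})

test_that("the noise-free limit emits three identical replicates", {
  cfg <- small_cfg(seed = 2, replicate_cv = 0, batch_shift_sd = 0,
                   missing_rate = 0)
  cohort <- simulate_cohort(cfg)
  spread <- cohort$features |>
    dplyr::summarise(d = diff(range(intensity)),
                     .by = c(feature_id, sample_id))
  expect_true(all(spread$d == 0))
})

test_that("pathway maps honour requested sizes and are seed-stable", {
  cfg <- sim_config(
    n_metabolites = 40,
    pathway_spec = tibble::tibble(pathway = c("p1", "p2", "p3", "p4"),
                                  size = c(6L, 5L, 12L, 6L),
                                  shift = rep(0.5, 4)),
    seed = 3
  )
  pw <- simulate_pathways(cfg)
  expect_equal(lengths(pw$hmdb_ids), c(6, 5, 12, 6))
  expect_identical(pw, simulate_pathways(cfg))
  empty <- sim_config(pathway_spec = NULL)
  expect_equal(nrow(simulate_pathways(empty)), 0)
})

test_that("survival times follow the configured exponential law", {
  # no-censoring configuration: S(3) for the reference group and the
  # closed-form S_A(3) = S_B(3)^HR among smokers
  cfg <- sim_config(
    n_patients = 100000, subtype_prevalence = 0.5,
    smoking_probs = c(never = 0, former = 0, current = 1),
    hr_subtypeA_smoker = 3, censor_window = c(900, 1000),
    loss_to_followup = 0, seed = 8
  )
  clin <- simulate_survival(simulate_clinical(cfg), cfg)
  s3_b <- mean(clin$os_time[clin$true_subtype == "B"] > 3)
  s3_a <- mean(clin$os_time[clin$true_subtype == "A"] > 3)
  expect_lt(abs(s3_b - 0.863), 0.005)
  expect_lt(abs(s3_a - 0.863^3), 0.005)

  # hazard-rate recovery: the event-history slope (exponential MLE)
  # matches the configured rate within 2%
  lambda <- -log(0.863) / 3
  b <- clin$true_subtype == "B"
  rate_hat <- sum(clin$os_event[b]) / sum(clin$os_time[b])
  expect_lt(abs(rate_hat / lambda - 1), 0.02)
})

test_that("a null hazard ratio gives well-behaved log-rank p-values", {
  ps <- vapply(1:30, function(s) {
    cfg <- sim_config(n_patients = 100, hr_subtypeA_smoker = 1,
                      hr_subtypeA_never = 1, loss_to_followup = 0, seed = s)
    clin <- simulate_survival(simulate_clinical(cfg), cfg)
    logrank_test(clin$os_time, clin$os_event, clin$true_subtype)$p_value
  }, 1)
  expect_gt(mean(ps), 0.34)
  expect_lt(mean(ps), 0.66)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("survival outputs satisfy their structural invariants", {
  cfg <- sim_config(n_patients = 300, seed = 4)
  clin <- simulate_survival(simulate_clinical(cfg), cfg)
  ok <- clin$followed
  expect_true(all(clin$os_time[ok] > 0))
  expect_true(all(clin$pfs_time[ok] <= clin$os_time[ok]))
  expect_true(all(clin$os_event[ok] %in% 0:1))
  expect_true(all(is.na(clin$os_time[!ok])))
  expect_gt(sum(!ok), 0)
})

test_that("missingness is intensity-dependent at the configured rate", {
  cfg <- small_cfg(seed = 6, missing_rate = 0.1, mnar_strength = 1.5)
  feats <- simulate_metabolome(simulate_clinical(cfg),
                               simulate_pathways(cfg), cfg)
  expect_lt(abs(mean(is.na(feats$intensity)) - 0.1), 0.01)
  # missing cells sit at systematically lower latent intensity: compare
  # each feature's missingness against its base abundance
  per_feat <- feats |>
    dplyr::summarise(fmiss = mean(is.na(intensity)),
                     mu = mean(log2(intensity), na.rm = TRUE),
                     .by = feature_id)
  expect_lt(cor(per_feat$fmiss, per_feat$mu), -0.5)
})

test_that("post-processing Z-shift matches the analytic large-n value", {
  # single designated pathway, all other noise sources off: the observed
  # A-vs-B difference in standardised means converges to
  # delta / sqrt(1 + pi (1 - pi) delta^2)
  delta <- 1
  pi_a <- 0.41
  cfg <- sim_config(
    n_patients = 3000, n_metabolites = 20,
    pathway_spec = tibble::tibble(pathway = "pw", size = 6L, shift = delta),
    background_shift_sd = 0, block_correlation = 0, n_batches = 1,
    batch_shift_sd = 0, replicate_cv = 0, missing_rate = 0, seed = 10
  )
  clin <- simulate_clinical(cfg)
  pw <- simulate_pathways(cfg)
  feats <- simulate_metabolome(clin, pw, cfg)
  mm <- suppressMessages(preprocess_features(feats, attr(feats, "library")))
  ann <- mm_annotation(mm)
  target <- ann$feature_id[ann$hmdb_id %in% pw$hmdb_ids[[1]]]
  m <- mm_values(mm)
  is_a <- clin$true_subtype[match(rownames(m), clin$id)] == "A"
  shift_hat <- mean(colMeans(m[is_a, target]) - colMeans(m[!is_a, target]))
  expect_lt(abs(shift_hat - delta / sqrt(1 + pi_a * (1 - pi_a) * delta^2)),
            0.05)
  # and the sign pattern: designated-pathway metabolites positive in A,
  # negative in B
  expect_true(all(colMeans(m[is_a, target]) > 0))
  expect_true(all(colMeans(m[!is_a, target]) < 0))
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(sim_config(subtype_prevalence = 1.2), class = "metabosurv_config_error")
  expect_error(sim_config(smoking_probs = c(0.5, 0.5, 0.5)), class = "metabosurv_config_error")
  expect_error(sim_config(baseline_3yr_survival = 1.5), class = "metabosurv_config_error")
  expect_error(sim_config(n_metabolites = 5), class = "metabosurv_config_error")

  cfg <- small_cfg()
  clin <- simulate_clinical(cfg)
  bad_pw <- tibble::tibble(pathway = "pw", description = "x",
                           hmdb_ids = list("HMDB_NOT_THERE"))
  expect_error(simulate_metabolome(clin, bad_pw, cfg),
               class = "metabosurv_validation_error")
})
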