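# Kaplan-Meier, log-rank, Cox regression with PH checking, three-year
# logistic/ROC comparison, and the stratified analysis ladder.

test_that("the product-limit estimator matches hand computation", {
  km <- km_curve(1:4, rep(1, 4))
  expect_equal(tidy(km)$survival, c(0.75, 0.5, 0.25, 0))

  km2 <- km_curve(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(survival_at(km2, 1), 0.8)
  expect_equal(survival_at(km2, 3), 0.8 * 2 / 3, tolerance = 1e-9)
  expect_equal(survival_at(km2, 5), 0)

  cens <- km_curve(c(2, 3, 7), c(0, 0, 0))
  expect_equal(survival_at(cens, 7), 1)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")

  withr::with_seed(2, {
    t <- rexp(50); e <- rbinom(50, 1, 0.6)
  })
  s <- tidy(km_curve(t, e))$survival
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("the log-rank statistic matches its O-E/V definition", {
  # duplicated groups: no difference
  t <- c(1, 2, 3); e <- c(1, 0, 1)
  same <- logrank_test(c(t, t), c(e, e), rep(1:2, each = 3))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  tri <- logrank_test(rep(t, 3), rep(e, 3), rep(1:3, each = 3))
  expect_equal(tri$chi2, 0, tolerance = 1e-12)
  expect_equal(tri$df, 2)

  # 6-subject toy against the direct observed-minus-expected computation
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 1, 1, 0, 1)
  group <- c(0, 1, 0, 1, 0, 1)
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  got <- logrank_test(times, events, group)
  expect_equal(got$chi2, o_minus_e^2 / v, tolerance = 1e-10)

  # classical equivalence with the Cox score test on no-tie data
  withr::with_seed(4, {
    tt <- rexp(40); gg <- rep(0:1, 20); ee <- rbinom(40, 1, 0.8)
  })
  lr <- logrank_test(tt, ee, gg)
  sc <- survival::coxph(survival::Surv(tt, ee) ~ gg)
  expect_equal(lr$chi2, unname(summary(sc)$sctest["test"]), tolerance = 1e-6)
})

test_that("Cox coefficients maximise the partial likelihood", {
  withr::with_seed(8, {
    for (i in 1:3) {
      n <- 6 + i
      x <- rbinom(n, 1, 0.5)
      if (length(unique(x)) < 2) x[1:2] <- 0:1
      time <- round(rexp(n, exp(0.8 * x)), 6)  # continuous, no ties
      d <- tibble::tibble(time = time, event = 1, x = x)
      fit <- cox_fit(d, "time", "event", "x")
      beta_star <- cox_grid_beta(d$time, d$event, d$x)
      expect_lt(abs(tidy(fit)$estimate - beta_star), 2e-3)
      expect_equal(tidy(fit)$hr, exp(tidy(fit)$estimate))
    }
  })
})

test_that("Cox fitting reports structure and rejects degenerate designs", {
  withr::with_seed(9, {
    d <- tibble::tibble(time = rexp(30), event = rbinom(30, 1, 0.7),
                        x = rnorm(30), z = rnorm(30))
  })
  d$x[1:3] <- NA
  fit <- cox_fit(d, "time", "event", c("x", "z"))
  expect_equal(glance(fit)$n, 27)
  expect_equal(glance(fit)$n_dropped, 3)
  expect_true(glance(fit)$converged)
  td <- tidy(fit)
  expect_equal(td$conf_low, exp(td$estimate - 1.96 * td$std_error))

  d$const <- 1
  expect_error(cox_fit(d, "time", "event", "const"), "constant covariate: const")
  d$x2 <- d$x
  expect_error(cox_fit(dplyr::filter(d, !is.na(x)), "time", "event",
                       c("x", "x2")), "collinear|rank")
})

test_that("the time-interaction PH check flags planted non-proportionality", {
  withr::with_seed(10, {
    n <- 150
    g <- rep(0:1, each = n / 2)
    # crossing hazards: early-risk group vs late-risk group
    time <- ifelse(g == 1, rweibull(n, 0.5, 1), rweibull(n, 3, 1))
    d <- tibble::tibble(time = time, event = 1, g = g)
  })
  fit <- suppressWarnings(cox_fit(d, "time", "event", "g"))
  p <- ph_test(fit)$p_value
  expect_lt(p, 0.05)

  # proportional data: a single draw should usually look clean
  withr::with_seed(11, {
    d2 <- tibble::tibble(time = rexp(200, exp(0.5 * rep(0:1, 100))),
                         event = 1, g = rep(0:1, 100))
  })
  fit2 <- cox_fit(d2, "time", "event", "g")
  out <- ph_test(fit2, transform = "log")
  expect_true(is.finite(out$p_value))
  expect_equal(out$transform, "log")

  # binary factor covariates are accepted
  d2$g2 <- factor(ifelse(d2$g == 1, "B", "A"))
  fit3 <- cox_fit(d2, "time", "event", "g2")
  expect_true(is.finite(ph_test(fit3)$p_value))
})

test_that("three-year status classifies events, survivors and exclusions", {
  expect_equal(three_year_status(2.5, 1), 1L)
  expect_equal(three_year_status(4.0, 0), 0L)
  expect_true(is.na(three_year_status(2.0, 0)))
  expect_equal(three_year_status(3.5, 1), 0L)  # event after the horizon
  expect_equal(three_year_status(c(2.5, 4, 2), c(1, 0, 0)), c(1L, 0L, NA))
})

test_that("logistic regression matches closed forms and flags separation", {
  # saturated 2x2: exposure coefficient = log odds ratio = log 4
  d <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), c(10, 10, 5, 20)),
    y = rep(c(1, 0, 1, 0), c(10, 10, 5, 20))
  )
  fit <- logistic_fit(y ~ x, d)
  expect_equal(unname(tidy(fit)$estimate[2]), log(4), tolerance = 1e-6)

  # independence: slope exactly zero by symmetry
  d0 <- tibble::tibble(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
  expect_lt(abs(tidy(logistic_fit(y ~ x, d0))$estimate[2]), 1e-6)

  # intercept-only: logit of the mean
  d1 <- tibble::tibble(y = rep(c(0, 1), c(30, 10)))
  expect_equal(tidy(logistic_fit(y ~ 1, d1))$estimate, qlogis(0.25),
               tolerance = 1e-8)

  dsep <- tibble::tibble(x = 1:10, y = rep(0:1, each = 5))
  expect_warning(fs <- logistic_fit(y ~ x, dsep), "separation")
  expect_true(fs$separated)
  expect_error(logistic_fit(y ~ x, tibble::tibble(x = 1:4, y = 1)),
               "both outcome classes")
})

test_that("ROC analysis equals pair enumeration and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  withr::with_seed(14, {
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # with ties
    y <- rbinom(30, 1, 0.5)
  })
  expect_equal(roc_auc(s, y)$auc, auc_enum(s, y), tolerance = 1e-12)
  expect_equal(roc_auc(exp(5 * s), y)$auc, roc_auc(s, y)$auc)
  expect_error(roc_auc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("the stratified ladder reproduces its structure and symmetries", {
  cfg <- sim_config(n_patients = 160, n_metabolites = 20,
                    pathway_spec = NULL, hpv_positive_prob = 1,
                    smoking_probs = c(never = 0, former = 0.5, current = 0.5),
                    covariate_missing_rate = 0, loss_to_followup = 0,
                    seed = 15)
  clin <- simulate_survival(simulate_clinical(cfg), cfg)
  clin$subtype <- clin$true_subtype
  res <- suppressWarnings(stratified_analysis(clin))

  # all ever-smoking HPV-related: those strata duplicate the full cohort
  full_hr <- tidy(res) |>
    dplyr::filter(stratum == "full", outcome == "os", model == "unadjusted",
                  grepl("subtype", term))
  dup_hr <- tidy(res) |>
    dplyr::filter(stratum == "ever_smoker_hpv_related", outcome == "os",
                  model == "unadjusted", grepl("subtype", term))
  expect_equal(full_hr$hr, dup_hr$hr, tolerance = 1e-10)

  g <- glance(res)
  expect_true(all(c("full", "ever_smoker") %in% g$stratum))
  ever <- g[g$stratum == "ever_smoker", ]
  # nested three-year models dominate on training data
  expect_gte(ever$auc_hpv_subtype, ever$auc_subtype_only)
  # hazard ratio direction: subtype A worse among smokers
  expect_gt(dup_hr$hr, 1)
})
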