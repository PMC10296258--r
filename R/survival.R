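# Kaplan-Meier estimation, log-rank testing, Cox proportional-hazards
# modelling with a time-interaction PH check, three-year logistic/ROC
# comparison, and the smoking/HPV-stratified analysis ladder.

#' Kaplan-Meier product-limit curve
#'
#' @param times Positive follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve` wrapping the product-limit fit.
#' @examples
#' km <- km_curve(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
#' survival_at(km, 3)  # 0.5333
#' @export
km_curve <- function(times, events) {
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0) abort("empty input.")
  if (any(times <= 0)) abort("times must be positive.")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1.")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(fit = fit, n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' @describeIn km_curve Evaluate the survival step function at time `t`.
#' @param curve A `km_curve`.
#' @param t Time point(s).
#' @export
survival_at <- function(curve, t) {
  s <- summary(curve$fit, times = t, extend = TRUE)
  unname(s$surv)
}

#' @describeIn km_curve Tidy the step function into a tibble.
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) {
  f <- x$fit
  tibble::tibble(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                 n_censor = f$n.censor, survival = f$surv)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic with the
#' hypergeometric variance at each event time.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param group Group labels (at least two non-empty groups).
#' @return A one-row tibble: `chi2`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2) abort("need at least two non-empty groups.")
  if (sum(events) < 1) abort("need at least one event.")
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1
  tibble::tibble(chi2 = fit$chisq, df = df,
                 p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Efron-tie-corrected partial likelihood maximised by Newton-Raphson
#' (via the survival package); Wald standard errors from the observed
#' information. Rows with a missing covariate are dropped and counted,
#' a covariate constant over the analysed rows is an error naming it, and
#' monotone-likelihood non-convergence is flagged rather than hidden
#' (such strata report extremely wide confidence intervals and should be
#' read as preliminary).
#'
#' @param data A data frame.
#' @param time,event Column names of the follow-up time and 0/1 event
#'   indicator.
#' @param covariates Character vector of covariate column names;
#'   categorical covariates are one-hot encoded with their first factor
#'   level as reference.
#' @param ties Tie-handling method, default `"efron"`.
#' @return An object of class `metab_cox`; see [tidy.metab_cox()] and
#'   [glance.metab_cox()].
#' @export
cox_fit <- function(data, time, event, covariates, ties = "efron") {
  cols <- c(time, event, covariates)
  stopifnot(all(cols %in% names(data)))
  complete <- complete.cases(data[, cols])
  n_dropped <- sum(!complete)
  d <- data[complete, cols]
  if (sum(d[[event]]) < 1) abort("need at least one event.")
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(sprintf("constant covariate: %s", cv))
    }
  }
  fml <- as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")
  ))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (any(is.na(coef(fit)))) {
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  structure(list(fit = fit, data = d, time = time, event = event,
                 covariates = covariates, ties = ties,
                 n = nrow(d), n_events = sum(d[[event]]),
                 n_dropped = n_dropped, converged = !flagged),
            class = "metab_cox")
}

#' @describeIn cox_fit Per-covariate coefficients, hazard ratios, Wald
#'   95% confidence intervals and p-values.
#' @param x A `metab_cox` object.
#' @param ... Unused.
#' @export
tidy.metab_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = exp(co[, "coef"]),
    std_error = co[, "se(coef)"],
    conf_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    conf_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @describeIn cox_fit One-row model summary.
#' @export
glance.metab_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, n_dropped = x$n_dropped,
    log_partial_lik = as.numeric(tail(x$fit$loglik, 1)),
    converged = x$converged
  )
}

#' Proportional-hazards check via a covariate-with-time interaction
#'
#' The data are episode-split at the event times and the model refit with
#' an added time-varying term: the covariate of interest multiplied by
#' time (or log time). The Wald p-value of the interaction coefficient is
#' returned; a small value indicates the covariate's hazard ratio drifts
#' with follow-up time, violating proportionality.
#'
#' @param fit A `metab_cox` object.
#' @param term Covariate to test (default the first covariate). A binary
#'   factor/character covariate is converted to a 0/1 indicator of its
#'   non-reference level.
#' @param transform `"linear"` (default) or `"log"` time.
#' @return A one-row tibble: `interaction_coef`, `p_value`, `transform`.
#' @export
ph_test <- function(fit, term = fit$covariates[1],
                    transform = c("linear", "log")) {
  transform <- match.arg(transform)
  d <- fit$data
  v <- d[[term]]
  d$.x <- if (is.numeric(v)) v else {
    lv <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
    if (length(lv) != 2) abort("PH interaction term must be binary or numeric.")
    as.numeric(as.character(v) == lv[2])
  }
  cuts <- sort(unique(d[[fit$time]][d[[fit$event]] == 1]))
  split <- survival::survSplit(
    as.formula(paste0("Surv(", fit$time, ", ", fit$event, ") ~ .")),
    data = d, cut = cuts, start = "tstart", end = "tstop"
  )
  split$.tt <- if (transform == "log") log(split$tstop) else split$tstop
  split$.xt <- split$.x * split$.tt
  rhs <- paste(c(fit$covariates, ".xt"), collapse = " + ")
  refit <- survival::coxph(
    as.formula(paste0("Surv(tstart, tstop, ", fit$event, ") ~ ", rhs)),
    data = split, ties = fit$ties
  )
  co <- summary(refit)$coefficients
  tibble::tibble(interaction_coef = co[".xt", "coef"],
                 p_value = co[".xt", "Pr(>|z|)"],
                 transform = transform)
}

#' Vital status at a fixed horizon
#'
#' Classifies each subject as dead (event at or before the horizon) or
#' alive (followed beyond the horizon, regardless of later status).
#' Subjects censored before the horizon carry no information about it and
#' are excluded (`NA`).
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param horizon Years (default 3).
#' @return Integer vector: 1 dead, 0 alive, `NA` excluded.
#' @export
three_year_status <- function(times, events, horizon = 3) {
  dplyr::case_when(
    is.na(times) | is.na(events) ~ NA_integer_,
    events == 1 & times <= horizon ~ 1L,
    times > horizon ~ 0L,
    .default = NA_integer_
  )
}

#' Logistic regression fit
#'
#' Binomial GLM fit by iteratively reweighted least squares. Perfect
#' separation is flagged with a warning and the (capped, very large)
#' coefficients returned as-is.
#'
#' @param formula Model formula with a 0/1 response.
#' @param data Data frame; rows with missing model variables are dropped.
#' @return Object of class `metab_logit` wrapping the `glm` fit.
#' @export
logistic_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2) abort("both outcome classes must be present.")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(), na.action = stats::na.omit),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (separated) warn("possible complete separation; coefficients unreliable.")
  structure(list(fit = fit, separated = separated, n = length(y)),
            class = "metab_logit")
}

#' @describeIn logistic_fit Tidy coefficient table.
#' @param x A `metab_logit` object.
#' @param ... Unused.
#' @export
tidy.metab_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"], p_value = s[, "Pr(>|z|)"])
}

#' @describeIn logistic_fit One-row model summary with in-sample AUC.
#' @export
glance.metab_logit <- function(x, ...) {
  y <- x$fit$y
  tibble::tibble(n = x$n, separated = x$separated,
                 auc = roc_auc(stats::fitted(x$fit), y)$auc)
}

#' ROC curve and area under the curve
#'
#' The AUC is the Mann-Whitney concordance probability of the scores with
#' half credit for ties; the curve enumerates all distinct score
#' thresholds.
#'
#' @param scores Numeric classification scores (higher = more positive).
#' @param y Binary outcomes.
#' @return A list of class `metab_roc`: `auc` and `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, y) {
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  if (length(unique(y)) < 2) abort("both outcome classes must be present.")
  r <- pROC::roc(response = y, predictor = scores, direction = "<",
                 quiet = TRUE)
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    curve = tibble::tibble(threshold = r$thresholds,
                           sensitivity = r$sensitivities,
                           specificity = r$specificities)
  ), class = "metab_roc")
}

fully_adjusted_covariates <- function() {
  c("age", "sex", "race", "bmi", "alcohol", "marital", "tumor_site",
    "stage", "treatment", "ecog", "feeding_tube", "comorbidity",
    "albumin", "hemoglobin", "nlr", "plr")
}

# Drop covariates that are constant over the stratum's complete rows, so
# the ladder degrades gracefully in small strata instead of erroring.
usable_covariates <- function(data, covariates) {
  keep <- vapply(covariates, function(cv) {
    v <- data[[cv]]
    length(unique(v[!is.na(v)])) >= 2
  }, TRUE)
  covariates[keep]
}

fit_ladder_model <- function(data, time, event, covariates) {
  tryCatch(
    cox_fit(data, time, event, usable_covariates(data, covariates)),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "metab_cox_failure")
  )
}

#' Smoking/HPV-stratified survival analysis
#'
#' The full prognostic evaluation of a two-level metabolic subtype. For
#' each stratum (full cohort, never-smokers, ever-smokers, and
#' ever-smokers split by HPV status) and each outcome (overall and
#' progression-free survival) it computes Kaplan-Meier curves by subtype
#' with three-year survival estimates, the log-rank test, and a ladder of
#' three Cox models: unadjusted; adjusted for age, sex and HPV status
#' (plus smoking history outside the smoking-defined strata); and fully
#' adjusted for the complete covariate list. It also fits the three
#' three-year logistic models (HPV only, subtype only, HPV plus subtype)
#' with in-sample AUCs, excluding subjects censored before three years.
#' Subtype B is the reference level throughout, so hazard ratios read as
#' subtype A versus B. Unfollowed patients are removed first; strata
#' without events are skipped with a warning.
#'
#' @param data Clinical table joined with a `subtype` column ("A"/"B"),
#'   e.g. `dplyr::left_join(clinical, tidy(fit), by = c(id = "sample_id"))`.
#' @param horizon Horizon (years) for the logistic/ROC comparison.
#' @return An object of class `stratified_survival`; `tidy()` returns the
#'   Cox ladder table, `glance()` the per-stratum summary (3-year
#'   survivals, log-rank p, AUCs).
#' @export
stratified_analysis <- function(data, horizon = 3) {
  stopifnot("subtype" %in% names(data))
  if ("followed" %in% names(data)) {
    data <- data[!is.na(data$followed) & data$followed, ]
  }
  data <- data[!is.na(data$os_time) & !is.na(data$subtype), ]
  data$subtype <- factor(data$subtype, levels = c("B", "A"))

  strata <- list(
    full = rep(TRUE, nrow(data)),
    never_smoker = data$smoking == "never",
    ever_smoker = data$smoking != "never",
    ever_smoker_hpv_related = data$smoking != "never" &
      data$hpv_status == "related",
    ever_smoker_hpv_unrelated = data$smoking != "never" &
      data$hpv_status == "unrelated"
  )
  outcomes <- list(os = c("os_time", "os_event"),
                   pfs = c("pfs_time", "pfs_event"))

  res <- purrr::imap(strata, function(mask, stratum) {
    d <- data[mask & !is.na(mask), ]
    out <- list(n = nrow(d))
    if (nrow(d) == 0 || sum(d$os_event, na.rm = TRUE) == 0) {
      warn(sprintf("stratum %s has no events; skipped.", stratum))
      return(NULL)
    }
    base_adj <- c("age", "sex")
    if (!grepl("hpv", stratum)) base_adj <- c(base_adj, "hpv_status")
    if (stratum %in% c("full", "never_smoker")) {
      # smoking has one level inside never_smoker; usable_covariates drops it
      base_adj <- c(base_adj, "smoking")
    }
    full_adj <- unique(c(base_adj, "hpv_status", fully_adjusted_covariates()))

    for (oc in names(outcomes)) {
      tm <- outcomes[[oc]][1]; ev <- outcomes[[oc]][2]
      km <- lapply(split(d, d$subtype), function(g) {
        if (nrow(g) == 0) return(NULL)
        km_curve(g[[tm]], g[[ev]])
      })
      surv3 <- vapply(km, function(cu) {
        if (is.null(cu)) NA_real_ else survival_at(cu, horizon)
      }, 1)
      lr <- tryCatch(logrank_test(d[[tm]], d[[ev]], d$subtype),
                     error = function(e) NULL)
      models <- list(
        unadjusted = fit_ladder_model(d, tm, ev, "subtype"),
        adjusted = fit_ladder_model(d, tm, ev, c("subtype", base_adj)),
        fully_adjusted = fit_ladder_model(d, tm, ev, c("subtype", full_adj))
      )
      out[[oc]] <- list(km = km, surv3 = surv3, logrank = lr, cox = models)
    }

    d$status3 <- three_year_status(d$os_time, d$os_event, horizon)
    d3 <- d[!is.na(d$status3), ]
    logit_specs <- list(hpv_only = "hpv_status", subtype_only = "subtype",
                        hpv_subtype = c("hpv_status", "subtype"))
    out$logistic <- purrr::map(logit_specs, function(terms) {
      terms <- usable_covariates(d3, terms)
      if (length(terms) == 0 || length(unique(d3$status3)) < 2) return(NULL)
      fit <- logistic_fit(
        as.formula(paste("status3 ~", paste(terms, collapse = " + "))), d3)
      list(fit = fit, auc = glance(fit)$auc)
    })
    out$n_excluded_3yr <- sum(is.na(d$status3))
    out
  })
  structure(list(strata = res, horizon = horizon), class = "stratified_survival")
}

#' @describeIn stratified_analysis Cox-ladder table across strata,
#'   outcomes and models (subtype A vs B rows plus all covariate rows).
#' @param x A `stratified_survival` object.
#' @param ... Unused.
#' @export
tidy.stratified_survival <- function(x, ...) {
  purrr::imap_dfr(x$strata, function(st, stratum) {
    if (is.null(st)) return(NULL)
    purrr::map_dfr(c("os", "pfs"), function(oc) {
      if (is.null(st[[oc]])) return(NULL)
      purrr::imap_dfr(st[[oc]]$cox, function(fit, model) {
        if (inherits(fit, "metab_cox_failure")) return(NULL)
        dplyr::bind_cols(
          tibble::tibble(stratum = stratum, outcome = oc, model = model,
                         n = fit$n, n_events = fit$n_events,
                         n_dropped = fit$n_dropped,
                         converged = fit$converged),
          tidy(fit)
        )
      })
    })
  })
}

#' @describeIn stratified_analysis Per-stratum summary: three-year
#'   survival by subtype, log-rank p, and the three logistic AUCs.
#' @export
glance.stratified_survival <- function(x, ...) {
  purrr::imap_dfr(x$strata, function(st, stratum) {
    if (is.null(st)) return(NULL)
    tibble::tibble(
      stratum = stratum,
      n = st$n,
      surv3_os_a = st$os$surv3[["A"]],
      surv3_os_b = st$os$surv3[["B"]],
      logrank_p_os = if (!is.null(st$os$logrank)) st$os$logrank$p_value else NA,
      logrank_p_pfs = if (!is.null(st$pfs$logrank)) st$pfs$logrank$p_value else NA,
      auc_hpv_only = st$logistic$hpv_only$auc %||% NA_real_,
      auc_subtype_only = st$logistic$subtype_only$auc %||% NA_real_,
      auc_hpv_subtype = st$logistic$hpv_subtype$auc %||% NA_real_,
      n_excluded_3yr = st$n_excluded_3yr
    )
  })
}
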