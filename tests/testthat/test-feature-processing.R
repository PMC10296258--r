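# Deterministic post-extraction processing: CV filtering, triplicate
# summarisation, batch correction, missingness handling, imputation,
# standardisation, pooling and library matching.

rep_table <- function(...) {
  sets <- list(...)
  purrr::imap_dfr(sets, function(s, i) {
    tibble::tibble(feature_id = s$f, sample_id = s$s, replicate = 1:3,
                   intensity = s$v)
  })
}

test_that("replicate CV follows its definition and median summary", {
  raw <- rep_table(
    list(f = "f1", s = "s1", v = c(100, 100, 100)),
    list(f = "f2", s = "s1", v = c(50, 100, 150)),
    # three samples with CVs 0.2, 0.9, 0.8 -> median 0.8
    list(f = "f3", s = "s1", v = c(80, 100, 120)),
    list(f = "f3", s = "s2", v = c(10, 100, 190)),
    list(f = "f3", s = "s3", v = c(20, 100, 180))
  )
  cv <- feature_cv(raw)
  expect_equal(cv$median_cv[cv$feature_id == "f1"], 0)
  expect_equal(cv$median_cv[cv$feature_id == "f2"], 0.5)
  expect_equal(cv$median_cv[cv$feature_id == "f3"], 0.8)

  # a feature with at most one observed replicate anywhere has no CV
  raw1 <- tibble::tibble(feature_id = "f4", sample_id = "s1",
                         replicate = 1:3, intensity = c(5, NA, NA))
  expect_true(is.na(feature_cv(raw1)$median_cv))
})

test_that("the CV filter removes at and above the inclusive 75% bound", {
  raw <- rep_table(
    list(f = "keep", s = "s1", v = c(95, 100, 105)),
    list(f = "at_bound", s = "s1", v = c(25, 100, 175)),   # CV exactly 0.75
    list(f = "above", s = "s1", v = c(10, 100, 190))       # CV 0.9
  )
  kept <- suppressMessages(filter_features_by_cv(raw, 0.75))
  expect_setequal(unique(kept$feature_id), "keep")
  # all-zero-variance features pass untouched
  calm <- rep_table(list(f = "a", s = "s1", v = c(7, 7, 7)))
  expect_equal(nrow(suppressMessages(filter_features_by_cv(calm))), 3)
})

test_that("triplicate summarisation tolerates one missing replicate only", {
  raw <- rep_table(
    list(f = "f1", s = "s1", v = c(1, 2, 3)),
    list(f = "f2", s = "s1", v = c(10, 20, NA)),
    list(f = "f3", s = "s1", v = c(10, NA, NA))
  )
  out <- summarize_triplicates(raw)
  expect_equal(out$intensity[out$feature_id == "f1"], 2)
  expect_equal(out$intensity[out$feature_id == "f2"], 15)
  expect_true(is.na(out$intensity[out$feature_id == "f3"]))
})

make_batch_data <- function(n_feat = 60, n_per_batch = 10, shift_sd = 1,
                            seed = 1) {
  withr::with_seed(seed, {
    shifts <- rnorm(n_feat, 0, shift_sd)
    base <- matrix(rnorm(n_feat * 2 * n_per_batch, 10, 1), n_feat)
    base[, seq_len(n_per_batch)] <- base[, seq_len(n_per_batch)] + shifts
    tibble::tibble(
      feature_id = rep(sprintf("f%02d", seq_len(n_feat)), 2 * n_per_batch),
      sample_id = rep(sprintf("s%02d", seq_len(2 * n_per_batch)),
                      each = n_feat),
      batch = rep(rep(c("b1", "b2"), each = n_per_batch), each = n_feat),
      value = as.vector(base)
    )
  })
}

test_that("batch correction equalises means, is idempotent, and guards input", {
  d <- make_batch_data()
  # single batch: identity
  single <- dplyr::mutate(d, batch = "b1")
  expect_equal(correct_batches(single, "ml")$value, single$value)
  expect_equal(correct_batches(single, "eb")$value, single$value)

  # location oracle: after ML correction, per-batch feature means agree
  # with plain per-batch mean subtraction (equal means within 1e-6)
  out <- correct_batches(d, method = "ml")
  means <- out |>
    dplyr::summarise(m = mean(value), .by = c(feature_id, batch)) |>
    tidyr::pivot_wider(names_from = batch, values_from = m)
  expect_lt(max(abs(means$b1 - means$b2)), 1e-6)

  # idempotence of the ML variant
  twice <- correct_batches(out, method = "ml")
  expect_lt(max(abs(twice$value - out$value)), 1e-6)

  # missing entries are ignored in estimation and stay missing
  d_na <- d
  d_na$value[c(3, 50, 101)] <- NA
  out_na <- correct_batches(d_na, method = "eb")
  expect_identical(which(is.na(out_na$value)), which(is.na(d_na$value)))

  # a batch with fewer than 2 samples errors naming the batch
  tiny <- dplyr::filter(d, !(batch == "b2" & sample_id != "s11"))
  expect_error(correct_batches(tiny), "b2")
})

test_that("empirical-Bayes correction matches the reference ComBat on complete data", {
  skip_if_not_installed("sva")
  d <- make_batch_data(n_feat = 80, n_per_batch = 8, seed = 7)
  mine <- correct_batches(d, method = "eb")
  x <- tidyr::pivot_wider(d[, c("feature_id", "sample_id", "value")],
                          names_from = sample_id, values_from = value)
  m <- as.matrix(x[, -1]); rownames(m) <- x$feature_id
  batch <- d$batch[match(colnames(m), d$sample_id)]
  ref <- suppressMessages(sva::ComBat(dat = m, batch = batch))
  mine_m <- tidyr::pivot_wider(mine[, c("feature_id", "sample_id", "value")],
                               names_from = sample_id, values_from = value)
  mm <- as.matrix(mine_m[, -1])
  expect_lt(max(abs(mm - ref[x$feature_id, colnames(mm)])), 1e-3)
})

test_that("the missingness filter removes strictly above 20%", {
  n <- 100
  d <- tibble::tibble(
    feature_id = rep(c("at20", "above20", "clean"), each = n),
    sample_id = rep(sprintf("s%03d", 1:n), 3),
    value = 1
  )
  d$value[d$feature_id == "at20"][1:20] <- NA      # exactly 20%
  d$value[d$feature_id == "above20"][1:21] <- NA   # 21%
  out <- suppressMessages(filter_missingness(d, 0.20))
  expect_setequal(unique(out$feature_id), c("at20", "clean"))
  full <- suppressMessages(filter_missingness(dplyr::filter(d, feature_id == "clean")))
  expect_equal(nrow(full), n)
})

test_that("kNN imputation uses the nearest neighbour's observed values", {
  # identity when complete
  d0 <- tidyr::expand_grid(feature_id = c("f", "g"),
                           sample_id = c("a", "b")) |>
    dplyr::mutate(value = 1:4)
  expect_equal(impute_knn(d0)$value, d0$value)

  # hand case: C's nearest neighbour over shared features is A (f = 7)
  d1 <- tibble::tibble(
    feature_id = rep(c("f", "g", "h"), 3),
    sample_id = rep(c("A", "B", "C"), each = 3),
    value = c(7, 1, 2,      # A
              50, 9, 12,    # B
              NA, 1.1, 2.2) # C, missing f, near A
  )
  out <- impute_knn(d1, k = 1)
  expect_equal(out$value[out$sample_id == "C" & out$feature_id == "f"], 7)

  # symmetric case: equidistant neighbours -> mean of their values
  d2 <- tibble::tibble(
    feature_id = rep(c("f", "g"), 3),
    sample_id = rep(c("A", "B", "C"), each = 2),
    value = c(4, 1, 10, 1, NA, 1)
  )
  out2 <- impute_knn(d2, k = 2)
  expect_equal(out2$value[out2$sample_id == "C" & out2$feature_id == "f"], 7)

  # no informative neighbour within k -> feature median with a warning
  d3 <- tibble::tibble(
    feature_id = rep(c("f", "g"), 3),
    sample_id = rep(c("A", "B", "C"), each = 2),
    value = c(NA, 1.0, 20, 5, NA, 1.1)  # C's nearest (A) also lacks f
  )
  expect_warning(out3 <- impute_knn(d3, k = 1), "median")
  expect_equal(out3$value[out3$sample_id == "C" & out3$feature_id == "f"], 20)
})

test_that("log2/Z-score standardisation centres and scales each metabolite", {
  d <- tibble::tibble(feature_id = "m1", sample_id = c("s1", "s2", "s3"),
                      value = c(1, 2, 4))
  z <- mm_values(log2_zscore(d))[, "m1"]
  expect_equal(unname(z), c(-1, 0, 1))

  withr::with_seed(3, {
    big <- tidyr::expand_grid(feature_id = sprintf("m%d", 1:5),
                              sample_id = sprintf("s%d", 1:30)) |>
      dplyr::mutate(value = exp(rnorm(dplyr::n())))
  })
  m <- mm_values(log2_zscore(big))
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-9)

  const <- tibble::tibble(feature_id = "flat", sample_id = c("s1", "s2"),
                          value = c(3, 3))
  expect_error(log2_zscore(const), "flat")
})

test_that("mode pooling concatenates matched samples and rejects misuse", {
  mk <- function(samples, feats, seed) {
    withr::with_seed(seed, {
      d <- tidyr::expand_grid(feature_id = feats, sample_id = samples) |>
        dplyr::mutate(value = exp(rnorm(dplyr::n())))
    })
    log2_zscore(d)
  }
  a <- mk(sprintf("s%d", 1:10), sprintf("h%d", 1:5), 1)
  b <- mk(sprintf("s%d", 1:10), sprintf("c%d", 1:3), 2)
  merged <- merge_modes(a, b)
  expect_equal(ncol(merged) - 1, 8)
  expect_equal(merged$sample_id, a$sample_id)

  empty <- metabolite_matrix(tibble::tibble(sample_id = a$sample_id))
  expect_identical(merge_modes(a, empty), a)

  dup <- mk(sprintf("s%d", 1:10), c("h1", "x"), 3)
  expect_error(merge_modes(a, dup), "duplicate")

  other <- mk(sprintf("t%d", 1:10), "y1", 4)
  expect_error(merge_modes(a, other), "sample sets differ")
})

test_that("library matching honours tolerances and the ppm-first tie rule", {
  library_tbl <- tibble::tibble(
    name = c("Glucose", "NearA", "NearB"),
    mz = c(215.0328, 300.0000, 300.0015),
    rt = c(21, 100, 140),
    mode = "C18-",
    adduct = "(M + Cl)",
    hmdb_id = c("HMDB0000122", "HMDB0000001", "HMDB0000002")
  )
  feats <- tibble::tibble(
    feature_id = c("hit", "far", "tie"),
    mz = c(215.0328, 215.1403, 300.0010),  # far is ~500 ppm off
    rt = c(21, 21, 120),                   # tie equidistant in rt (20 s)
    mode = "C18-"
  )
  out <- match_library(feats, library_tbl)
  expect_equal(out$hmdb_id[out$feature_id == "hit"], "HMDB0000122")
  expect_false("far" %in% out$feature_id)
  # equidistant in rt but closer in ppm to NearB (5 ppm vs ~3.3 ppm)
  ppm <- abs(feats$mz[3] - library_tbl$mz[2:3]) / library_tbl$mz[2:3] * 1e6
  expect_equal(out$hmdb_id[out$feature_id == "tie"],
               library_tbl$hmdb_id[2:3][which.min(ppm)])

  # exhaustive agreement with a double-loop matcher on the toy set
  brute <- purrr::map_chr(seq_len(nrow(feats)), function(i) {
    best <- NA_character_; best_key <- c(Inf, Inf)
    for (j in seq_len(nrow(library_tbl))) {
      if (feats$mode[i] != library_tbl$mode[j]) next
      ppm <- abs(feats$mz[i] - library_tbl$mz[j]) / library_tbl$mz[j] * 1e6
      drt <- abs(feats$rt[i] - library_tbl$rt[j])
      if (ppm <= 10 && drt <= 30 &&
          (ppm < best_key[1] || (ppm == best_key[1] && drt < best_key[2]))) {
        best <- library_tbl$hmdb_id[j]; best_key <- c(ppm, drt)
      }
    }
    best
  })
  matched <- brute[!is.na(brute)]
  expect_equal(out$hmdb_id, matched)
})

test_that("the full preprocessing pipeline standardises and logs", {
  cohort <- simulate_cohort(small_cfg(seed = 4))
  mm <- suppressMessages(preprocess_features(cohort$features, cohort$library))
  m <- mm_values(mm)
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-9)
  expect_false(anyNA(m))
  log <- processing_log(mm)
  expect_equal(log$n_features_in, 40)
  expect_equal(log$order[1], "cv_filter")
  expect_true(log$imputed_fraction >= 0 && log$imputed_fraction < 1)
  # determinism of the whole chain
  mm2 <- suppressMessages(preprocess_features(cohort$features, cohort$library))
  expect_identical(mm_values(mm2), m)
})
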