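# Plain-text readers and writers for the pipeline's four input schemas:
# clinical CSV, replicate-level feature TSV (+ sample/batch CSV),
# metabolite library TSV, and pathway GMT.

#' Write a synthetic cohort to disk
#'
#' Emits the four pipeline inputs: `clinical.csv`, `features.tsv` (wide,
#' one row per feature, intensity columns named `<sample>_r<replicate>`),
#' `samples.csv` (sample-to-batch map), `library.tsv`, and
#' `pathways.gmt`.
#'
#' @param cohort A `metab_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "metab_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"), na = "")

  wide <- cohort$features |>
    dplyr::mutate(column = paste0(.data$sample_id, "_r", .data$replicate)) |>
    dplyr::select("feature_id", "mz", "rt", "mode", "column", "intensity") |>
    tidyr::pivot_wider(names_from = "column", values_from = "intensity")
  readr::write_tsv(wide, file.path(dir, "features.tsv"), na = "")

  samples <- dplyr::distinct(cohort$features, .data$sample_id, .data$batch)
  readr::write_csv(samples, file.path(dir, "samples.csv"))
  readr::write_tsv(cohort$library, file.path(dir, "library.tsv"))
  write_gmt(cohort$pathways, file.path(dir, "pathways.gmt"))
  invisible(dir)
}

#' Read a replicate-level feature table
#'
#' @param features_path Wide TSV with `feature_id`, `mz`, `rt`, `mode`
#'   and `<sample>_r<replicate>` intensity columns.
#' @param samples_path CSV mapping `sample_id` to `batch`.
#' @return The long replicate-level tibble used by the preprocessing
#'   functions.
#' @export
read_feature_table <- function(features_path, samples_path) {
  wide <- readr::read_tsv(features_path, show_col_types = FALSE)
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-c("feature_id", "mz", "rt", "mode"),
                        names_to = "column", values_to = "intensity") |>
    tidyr::separate_wider_regex(
      "column", c(sample_id = ".*", "_r", replicate = "[0-9]+")
    ) |>
    dplyr::mutate(replicate = as.integer(.data$replicate))
  dplyr::left_join(long, samples, by = "sample_id")
}

#' Read a clinical table
#'
#' Restores the categorical covariates to their canonical factor levels
#' so reference levels in the survival models are stable.
#'
#' @param path Clinical CSV path.
#' @return A clinical tibble.
#' @export
read_clinical <- function(path) {
  clin <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  vocab <- clinical_vocab()
  for (col in names(vocab)) {
    if (col %in% names(clin)) {
      clin[[col]] <- factor(clin[[col]], levels = names(vocab[[col]]))
    }
  }
  if ("hpv_status" %in% names(clin)) {
    clin$hpv_status <- factor(clin$hpv_status, levels = c("unrelated", "related"))
  }
  if ("smoking" %in% names(clin)) {
    clin$smoking <- factor(clin$smoking, levels = c("never", "former", "current"))
  }
  clin
}

#' Read a metabolite identification library
#' @param path Library TSV with columns `name`, `mz`, `rt`, `mode`,
#'   `adduct`, `hmdb_id`.
#' @return A library tibble.
#' @export
read_library <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Validate a set of pipeline input files
#'
#' Schema checks for the clinical CSV, feature TSV + sample CSV, library
#' TSV and pathway GMT, plus cross-file referential checks (every
#' clinical id present in the feature table, every pathway accession in
#' the library). Problems are reported, never silently fixed.
#'
#' @param clinical_path,features_path,samples_path,library_path,gmt_path
#'   File paths; any may be `NULL` to skip that file.
#' @return A tibble of issues (`file`, `issue`); zero rows means all
#'   checks passed.
#' @export
validate_inputs <- function(clinical_path = NULL, features_path = NULL,
                            samples_path = NULL, library_path = NULL,
                            gmt_path = NULL) {
  issues <- list()
  note <- function(file, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(file = file, issue = issue)
  }

  clin <- NULL
  if (!is.null(clinical_path)) {
    clin <- tryCatch(readr::read_csv(clinical_path, show_col_types = FALSE),
                     error = function(e) { note("clinical", conditionMessage(e)); NULL })
    if (!is.null(clin)) {
      needed <- c("id", "age", "smoking", "hpv_status", "os_time", "os_event")
      miss <- setdiff(needed, names(clin))
      if (length(miss) > 0) {
        note("clinical", paste("missing column(s):", paste(miss, collapse = ", ")))
      }
      if (anyDuplicated(clin$id) > 0) note("clinical", "duplicate patient ids")
    }
  }

  feat <- NULL
  if (!is.null(features_path)) {
    raw <- tryCatch(readr::read_tsv(features_path, show_col_types = FALSE,
                                    col_types = readr::cols(.default = "c")),
                    error = function(e) { note("features", conditionMessage(e)); NULL })
    if (!is.null(raw)) {
      miss <- setdiff(c("feature_id", "mz", "rt", "mode"), names(raw))
      if (length(miss) > 0) {
        note("features", paste("missing column(s):", paste(miss, collapse = ", ")))
      } else {
        value_cols <- setdiff(names(raw), c("feature_id", "mz", "rt", "mode"))
        for (col in value_cols) {
          v <- raw[[col]]
          bad <- which(!is.na(v) & v != "" & is.na(suppressWarnings(as.numeric(v))))
          for (i in head(bad, 5)) {
            note("features", sprintf("non-numeric intensity at row %d, column %s: '%s'",
                                     i, col, v[i]))
          }
        }
        feat <- raw
        if (!is.null(clin) && "id" %in% names(clin)) {
          sample_ids <- unique(sub("_r[0-9]+$", "", value_cols))
          absent <- setdiff(clin$id, sample_ids)
          for (id in absent) {
            note("clinical/features",
                 sprintf("clinical sample %s absent from feature table", id))
          }
        }
      }
    }
  }

  if (!is.null(samples_path)) {
    smp <- tryCatch(readr::read_csv(samples_path, show_col_types = FALSE),
                    error = function(e) { note("samples", conditionMessage(e)); NULL })
    if (!is.null(smp) && length(setdiff(c("sample_id", "batch"), names(smp))) > 0) {
      note("samples", "needs columns sample_id, batch")
    }
  }

  lib <- NULL
  if (!is.null(library_path)) {
    lib <- tryCatch(read_library(library_path),
                    error = function(e) { note("library", conditionMessage(e)); NULL })
    if (!is.null(lib)) {
      miss <- setdiff(c("name", "mz", "rt", "mode", "adduct", "hmdb_id"), names(lib))
      if (length(miss) > 0) {
        note("library", paste("missing column(s):", paste(miss, collapse = ", ")))
      }
    }
  }

  if (!is.null(gmt_path)) {
    pw <- tryCatch(read_gmt(gmt_path),
                   error = function(e) { note("pathways", conditionMessage(e)); NULL })
    if (!is.null(pw) && !is.null(lib) && "hmdb_id" %in% names(lib)) {
      absent <- setdiff(unique(unlist(pw$hmdb_ids)), lib$hmdb_id)
      if (length(absent) > 0) {
        note("pathways/library",
             sprintf("%d pathway accession(s) absent from library (e.g. %s)",
                     length(absent), absent[1]))
      }
    }
  }

  if (length(issues) == 0) {
    tibble::tibble(file = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
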