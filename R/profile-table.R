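#' Sample-by-metabolite profile tables
#'
#' A `metab_profile` holds one study's quantified metabolite concentrations
#' together with the design metadata of a paired crossover intervention:
#' subject, intervention arm (`vehicle` or `alcohol`), collection time in
#' hours after the intervention, the analytical role of the injection
#' (`experimental`, pooled `qc`, or `repeat`), batch and injection order, and
#' the sample's urinary creatinine (mmol/L). Concentrations start as raw
#' instrument quantifications (umol/L) and are expressed as umol/mmol
#' creatinine after [normalize_to_creatinine()].
#'
#' The object is a list with:
#' \describe{
#'   \item{samples}{tibble of per-sample metadata (one row per injection).}
#'   \item{values}{numeric matrix, samples x metabolites, rownames =
#'     `sample_id`.}
#' }
#' plus attributes `normalized` (logical), `transform_state` (one of
#' `"raw"`, `"imputed"`, `"log"`, `"scaled"` — transitions only move forward),
#' `transform_params` (per-metabolite centering/scaling parameters retained
#' for projecting held-out samples) and `dropped_metabolites`.
#'
#' @param samples Tibble with columns `sample_id`, `subject_id`,
#'   `intervention`, `time_h`, `role`, `batch_id`, `injection_order`,
#'   `creatinine`.
#' @param values Numeric matrix of concentrations, rows matching `samples`.
#' @param normalized Logical; `TRUE` once values are umol/mmol creatinine.
#' @param transform_state Preprocessing state of `values`.
#' @param transform_params Retained centering/scaling parameters, or `NULL`.
#' @param require_complete Validate that every (subject, intervention) pair
#'   has exactly one experimental sample at each design time.
#' @return A `metab_profile` object.
#' @export
metab_profile <- function(samples, values,
                          normalized = FALSE,
                          transform_state = c("raw", "imputed", "log", "scaled"),
                          transform_params = NULL,
                          require_complete = FALSE) {
  transform_state <- match.arg(transform_state)
  samples <- tibble::as_tibble(samples)
  required <- c("sample_id", "subject_id", "intervention", "time_h", "role",
                "batch_id", "injection_order", "creatinine")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop_uromet(
      paste0("missing metadata column(s): ", paste(missing_cols, collapse = ", ")),
      class = "uromet_format_error"
    )
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(samples)) {
    stop_uromet("values matrix and samples metadata disagree on sample count",
                class = "uromet_validation_error")
  }
  if (is.null(colnames(values))) {
    stop_uromet("values matrix must carry metabolite column names",
                class = "uromet_format_error")
  }
  rownames(values) <- samples$sample_id
  x <- structure(
    list(samples = samples, values = values),
    normalized = normalized,
    transform_state = transform_state,
    transform_params = transform_params,
    dropped_metabolites = character(),
    class = "metab_profile"
  )
  validate_profile(x, require_complete = require_complete)
  x
}

#' Validate a profile table against the design invariants
#'
#' Checks the structural invariants: known intervention/role levels, design
#' times in 0..4, non-negative concentrations in raw/imputed states, positive
#' creatinine for experimental samples, no duplicated experimental
#' (subject, intervention, time) cell, and (optionally) exactly one
#' experimental sample per (subject, intervention, time) — five per subject
#' and arm.
#'
#' @param x A `metab_profile`.
#' @param require_complete Also require the complete 5-time design.
#' @return `x`, invisibly; structured errors name the offending row/column.
#' @export
validate_profile <- function(x, require_complete = FALSE) {
  s <- x$samples
  if (anyDuplicated(s$sample_id)) {
    stop_uromet("duplicated sample_id values", class = "uromet_validation_error")
  }
  bad_int <- setdiff(unique(s$intervention), c("vehicle", "alcohol"))
  if (length(bad_int) > 0) {
    stop_uromet(paste0("unknown intervention level(s): ", paste(bad_int, collapse = ", ")),
                class = "uromet_validation_error")
  }
  bad_role <- setdiff(unique(s$role), c("experimental", "qc", "repeat"))
  if (length(bad_role) > 0) {
    stop_uromet(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")),
                class = "uromet_validation_error")
  }
  if (!all(s$time_h %in% 0:4)) {
    stop_uromet("time_h outside the design hours 0..4",
                class = "uromet_validation_error")
  }
  state <- attr(x, "transform_state")
  if (state %in% c("raw", "imputed")) {
    neg <- which(x$values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      stop_uromet(
        sprintf("negative concentration at sample '%s', metabolite '%s'",
                rownames(x$values)[neg[1, 1]], colnames(x$values)[neg[1, 2]]),
        class = "uromet_validation_error"
      )
    }
  }
  exper <- s[s$role == "experimental", ]
  if (!attr(x, "normalized")) {
    bad_cr <- exper$sample_id[is.na(exper$creatinine) | exper$creatinine <= 0]
    if (length(bad_cr) > 0) {
      stop_uromet(
        paste0("experimental sample(s) without positive creatinine: ",
               paste(head(bad_cr, 5), collapse = ", ")),
        class = "uromet_validation_error"
      )
    }
  }
  key <- paste(exper$subject_id, exper$intervention, exper$time_h)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_uromet(paste0("duplicate experimental sample for (subject, intervention, time): ", dup),
                class = "uromet_design_error")
  }
  if (require_complete && nrow(exper) > 0) {
    counts <- table(exper$subject_id, exper$intervention)
    if (any(counts != 5)) {
      bad <- which(counts != 5, arr.ind = TRUE)[1, ]
      stop_uromet(
        sprintf("subject '%s' has %d experimental samples in the %s arm (expected 5)",
                rownames(counts)[bad[1]], counts[bad[1], bad[2]],
                colnames(counts)[bad[2]]),
        class = "uromet_design_error"
      )
    }
  }
  invisible(x)
}

#' @export
print.metab_profile <- function(x, ...) {
  cat(sprintf(
    "<metab_profile> %d samples x %d metabolites | normalized: %s | state: %s\n",
    nrow(x$values), ncol(x$values), attr(x, "normalized"), attr(x, "transform_state")
  ))
  roles <- table(x$samples$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.metab_profile <- function(x) dim(x$values)

#' Subset samples of a profile table
#'
#' Filters the sample rows with `dplyr::filter()` semantics while keeping
#' metadata and value matrix aligned.
#'
#' @param x A `metab_profile`.
#' @param ... Logical filter expressions on the metadata columns.
#' @return A `metab_profile` restricted to the matching samples.
#' @export
filter_samples <- function(x, ...) {
  keep <- dplyr::mutate(x$samples, .row = dplyr::row_number())
  keep <- dplyr::filter(keep, ...)
  out <- x
  out$samples <- dplyr::select(keep, -".row")
  out$values <- x$values[keep$.row, , drop = FALSE]
  out
}

reserved_columns <- c("sample_id", "subject_id", "intervention", "time_h",
                      "role", "batch_id", "injection_order",
                      "creatinine_mmol_per_L")

#' Read a wide profile table from CSV/TSV
#'
#' The wide dialect carries the reserved metadata columns first —
#' `sample_id, subject_id, intervention, time_h, role, batch_id,
#' injection_order, creatinine_mmol_per_L` — followed by one column per
#' metabolite. Missing raw values and analytical non-detects are both encoded
#' as 0 and handled downstream by [impute_zeros()].
#'
#' @param path File to read.
#' @param dialect `"wide_csv"` or `"wide_tsv"`.
#' @param normalized Whether values in the file are already umol/mmol Cr.
#' @param require_complete Enforce the complete 5-time design (default TRUE).
#' @return A validated `metab_profile`.
#' @export
read_profile_table <- function(path, dialect = c("wide_csv", "wide_tsv"),
                               normalized = FALSE, require_complete = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_uromet(paste0("file not found: ", path), class = "uromet_format_error")
  }
  reader <- if (dialect == "wide_csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(reserved_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_uromet(
      paste0("missing metadata column(s): ", paste(missing_cols, collapse = ", ")),
      class = "uromet_format_error"
    )
  }
  met_cols <- setdiff(names(df), reserved_columns)
  if (length(met_cols) == 0) {
    stop_uromet("no metabolite columns found after the reserved metadata columns",
                class = "uromet_format_error")
  }
  samples <- tibble::tibble(
    sample_id = as.character(df$sample_id),
    subject_id = as.character(df$subject_id),
    intervention = as.character(df$intervention),
    time_h = as.integer(df$time_h),
    role = as.character(df$role),
    batch_id = as.character(df$batch_id),
    injection_order = as.integer(df$injection_order),
    creatinine = as.numeric(df$creatinine_mmol_per_L)
  )
  values <- as.matrix(df[met_cols])
  metab_profile(samples, values, normalized = normalized,
                require_complete = require_complete)
}

#' Write a profile table in the wide CSV/TSV dialect
#'
#' @param x A `metab_profile`.
#' @param path Destination file.
#' @param dialect `"wide_csv"` or `"wide_tsv"`.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path, dialect = c("wide_csv", "wide_tsv")) {
  dialect <- match.arg(dialect)
  meta <- x$samples
  df <- tibble::tibble(
    sample_id = meta$sample_id,
    subject_id = meta$subject_id,
    intervention = meta$intervention,
    time_h = meta$time_h,
    role = meta$role,
    batch_id = meta$batch_id,
    injection_order = meta$injection_order,
    creatinine_mmol_per_L = meta$creatinine
  )
  df <- dplyr::bind_cols(df, tibble::as_tibble(x$values))
  writer <- if (dialect == "wide_csv") readr::write_csv else readr::write_tsv
  writer(df, path, progress = FALSE)
  invisible(path)
}
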