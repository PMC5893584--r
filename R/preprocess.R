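#' Normalize concentrations to urinary creatinine
#'
#' Divides every raw concentration (umol/L) by the sample's creatinine
#' (mmol/L), yielding umol metabolite per mmol creatinine. This corrects for
#' urine dilution driven by variable water intake; each sample — including QC
#' and repeat injections — is normalized by its own creatinine value.
#'
#' @param x A `metab_profile` with raw (un-normalized) values.
#' @return The table with normalized values and `normalized = TRUE`.
#' @export
normalize_to_creatinine <- function(x) {
  if (attr(x, "normalized")) {
    stop_uromet("table is already creatinine-normalized",
                class = "uromet_normalization_error")
  }
  cr <- x$samples$creatinine
  bad <- which(is.na(cr) | cr <= 0)
  if (length(bad) > 0) {
    stop_uromet(
      paste0("cannot normalize sample(s) with missing/non-positive creatinine: ",
             paste(head(x$samples$sample_id[bad], 5), collapse = ", ")),
      class = "uromet_normalization_error"
    )
  }
  x$values <- x$values / cr
  attr(x, "normalized") <- TRUE
  x
}

#' Replace analytical zeros by half the minimum positive value
#'
#' GC-MS non-detects are encoded as exact zeros. Each zero is replaced by
#' half the minimum positive value of that metabolite across experimental
#' samples, which keeps the subsequent log transform defined while preserving
#' the "below everything observed" meaning of a non-detect. Metabolites that
#' are zero in every experimental sample carry no quantitative information
#' and are dropped with a warning; the dropped names are recorded in the
#' `dropped_metabolites` attribute.
#'
#' @param x A normalized `metab_profile` in the `raw` state.
#' @return The table in the `imputed` state, all values strictly positive.
#' @export
impute_zeros <- function(x) {
  if (attr(x, "transform_state") != "raw") {
    stop_uromet("impute_zeros expects a table in the 'raw' transform state",
                class = "uromet_state_error")
  }
  exper <- x$samples$role == "experimental"
  v <- x$values
  min_pos <- apply(v[exper, , drop = FALSE], 2, function(col) {
    pos <- col[col > 0]
    if (length(pos) == 0) NA_real_ else min(pos)
  })
  all_zero <- names(min_pos)[is.na(min_pos)]
  if (length(all_zero) > 0) {
    rlang::warn(paste0("dropping all-zero metabolite column(s): ",
                       paste(all_zero, collapse = ", ")))
    v <- v[, setdiff(colnames(v), all_zero), drop = FALSE]
    min_pos <- min_pos[setdiff(names(min_pos), all_zero)]
  }
  for (j in seq_len(ncol(v))) {
    zero <- v[, j] == 0
    if (any(zero)) v[zero, j] <- min_pos[j] / 2
  }
  x$values <- v
  attr(x, "transform_state") <- "imputed"
  attr(x, "dropped_metabolites") <- c(attr(x, "dropped_metabolites"), all_zero)
  x
}

#' Log-transform, center and scale metabolite columns
#'
#' Applies the natural-log transform and then column-wise mean centering with
#' the chosen scaling: `auto` (unit variance), `pareto` (divide by the square
#' root of the standard deviation), or `none` (centering only). The
#' per-column mean and divisor are retained in `transform_params` so held-out
#' samples can be projected into the same space with [apply_transform()].
#' Scaling parameters are estimated from experimental samples only; QC and
#' repeat rows are transformed with those parameters but never drive them.
#'
#' Zero-variance columns under `auto` scaling are flagged and excluded (they
#' cannot be standardized and carry no contrast).
#'
#' @param x An imputed `metab_profile`, all values positive.
#' @param scaling One of `"auto"`, `"pareto"`, `"none"`.
#' @return The table in the `scaled` state.
#' @export
transform_scale <- function(x, scaling = c("auto", "pareto", "none")) {
  scaling <- match.arg(scaling)
  if (attr(x, "transform_state") != "imputed") {
    stop_uromet("transform_scale expects a table in the 'imputed' state",
                class = "uromet_state_error")
  }
  if (any(x$values <= 0)) {
    stop_uromet("all values must be positive before the log transform",
                class = "uromet_validation_error")
  }
  lv <- log(x$values)
  exper <- x$samples$role == "experimental"
  mu <- colMeans(lv[exper, , drop = FALSE])
  sdev <- apply(lv[exper, , drop = FALSE], 2, sd)
  div <- switch(scaling,
    auto = sdev,
    pareto = sqrt(sdev),
    none = rep(1, length(sdev))
  )
  flagged <- character()
  if (scaling == "auto") {
    zero_var <- sdev < .Machine$double.eps^0.5
    if (any(zero_var)) {
      flagged <- names(mu)[zero_var]
      rlang::warn(paste0("excluding zero-variance metabolite(s) under auto scaling: ",
                         paste(flagged, collapse = ", ")))
      lv <- lv[, !zero_var, drop = FALSE]
      mu <- mu[!zero_var]
      div <- div[!zero_var]
    }
  } else {
    div[div < .Machine$double.eps^0.5] <- 1
  }
  x$values <- sweep(sweep(lv, 2, mu, `-`), 2, div, `/`)
  attr(x, "transform_state") <- "scaled"
  attr(x, "transform_params") <- list(scaling = scaling, mean = mu, divisor = div)
  attr(x, "dropped_metabolites") <- c(attr(x, "dropped_metabolites"), flagged)
  x
}

#' Project concentrations with retained transform parameters
#'
#' Applies the log/center/scale transform fitted by [transform_scale()] to a
#' matrix of positive concentrations (e.g. held-out samples), reproducing the
#' training-space coordinates exactly for the training rows.
#'
#' @param values Positive concentration matrix with metabolite column names.
#' @param params The `transform_params` attribute of a scaled table.
#' @return The transformed matrix.
#' @export
apply_transform <- function(values, params) {
  cols <- names(params$mean)
  missing_cols <- setdiff(cols, colnames(values))
  if (length(missing_cols) > 0) {
    stop_uromet(paste0("values lack transformed metabolite column(s): ",
                       paste(head(missing_cols, 5), collapse = ", ")),
                class = "uromet_validation_error")
  }
  lv <- log(values[, cols, drop = FALSE])
  sweep(sweep(lv, 2, params$mean, `-`), 2, params$divisor, `/`)
}

#' QC and repeat-injection repeatability diagnostics
#'
#' Summarizes analytical repeatability per metabolite and batch from the
#' pooled-QC and repeat injections of the measurement design. The first five
#' QC injections of each batch condition the column and are excluded; the
#' relative standard deviation (RSD, percent) is computed across the
#' remaining QC injections of the batch. Each repeat injection is paired with
#' the experimental sample of the same (subject, intervention, time) in the
#' same batch and the absolute percent difference is reported; the maximum
#' over a batch's pairs is returned per metabolite.
#'
#' @param x A `metab_profile` containing `qc` and `repeat` rows.
#' @return Tibble with columns `metabolite`, `batch_id`, `qc_rsd_percent`
#'   (NA when fewer than 2 usable QC rows), `repeat_max_abs_diff_percent`.
#' @export
qc_repeatability <- function(x) {
  s <- x$samples
  out <- list()
  for (b in unique(s$batch_id)) {
    in_batch <- s$batch_id == b
    qc_rows <- which(in_batch & s$role == "qc")
    qc_rows <- qc_rows[order(s$injection_order[qc_rows])]
    usable_qc <- if (length(qc_rows) > 5) qc_rows[-(1:5)] else integer()
    if (length(usable_qc) >= 2) {
      qv <- x$values[usable_qc, , drop = FALSE]
      rsd <- 100 * apply(qv, 2, sd) / colMeans(qv)
    } else {
      rsd <- rep(NA_real_, ncol(x$values))
      names(rsd) <- colnames(x$values)
    }
    rep_rows <- which(in_batch & s$role == "repeat")
    max_diff <- rep(NA_real_, ncol(x$values))
    names(max_diff) <- colnames(x$values)
    if (length(rep_rows) > 0) {
      diffs <- matrix(NA_real_, nrow = length(rep_rows), ncol = ncol(x$values))
      for (i in seq_along(rep_rows)) {
        r <- rep_rows[i]
        orig <- which(in_batch & s$role == "experimental" &
                        s$subject_id == s$subject_id[r] &
                        s$intervention == s$intervention[r] &
                        s$time_h == s$time_h[r])
        if (length(orig) == 1) {
          o <- x$values[orig, ]
          diffs[i, ] <- 100 * abs(x$values[r, ] - o) / ifelse(o == 0, NA_real_, o)
        }
      }
      if (any(!is.na(diffs))) {
        max_diff <- apply(diffs, 2, function(col) {
          if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE)
        })
      }
    }
    out[[b]] <- tibble::tibble(
      metabolite = colnames(x$values),
      batch_id = b,
      qc_rsd_percent = unname(rsd),
      repeat_max_abs_diff_percent = unname(max_diff)
    )
  }
  dplyr::bind_rows(out)
}

#' Full preprocessing chain
#'
#' Convenience wrapper: creatinine normalization (if not already applied),
#' zero imputation and log/scale transform.
#'
#' @param x A `metab_profile`.
#' @param scaling Scaling passed to [transform_scale()].
#' @return A list with `scaled` (the transformed table) and `normalized`
#'   (the creatinine-normalized, untransformed table used for fold changes
#'   and per-time summaries).
#' @export
preprocess_profile <- function(x, scaling = "auto") {
  if (!attr(x, "normalized")) x <- normalize_to_creatinine(x)
  imputed <- impute_zeros(x)
  list(normalized = imputed, scaled = transform_scale(imputed, scaling = scaling))
}
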