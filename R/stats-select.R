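#' Signed fold change between two group means
#'
#' The ratio of the comparison mean to the reference mean, reported with a
#' symmetric sign convention: +ratio when the ratio is at least 1, and
#' -1/ratio otherwise, so increases and decreases of equal magnitude get the
#' same |FC|. Computed from arithmetic means of creatinine-normalized
#' (untransformed) concentrations.
#'
#' @param mean_ref Reference-group mean concentration (> 0).
#' @param mean_cmp Comparison-group mean concentration (> 0).
#' @return Signed fold change (|FC| >= 1), full precision.
#' @export
signed_fold_change <- function(mean_ref, mean_cmp) {
  if (any(!is.finite(c(mean_ref, mean_cmp))) || mean_ref <= 0 || mean_cmp <= 0) {
    stop_uromet("fold change requires positive finite means",
                class = "uromet_validation_error")
  }
  ratio <- mean_cmp / mean_ref
  if (ratio >= 1) ratio else -1 / ratio
}

# exact null distribution of the signed-rank statistic on doubled mid-ranks
# (doubling keeps tie mid-ranks integral); returns P(W2 = 0..sum(r2))/2^n
wsr_exact_pmf <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
    f <- f + shifted
  }
  f / 2^length(r2)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Nonparametric paired test on the within-subject differences
#' `x_cmp - x_ref`. Zero differences are dropped (the standard Wilcoxon
#' convention) and ties among the absolute differences get mid-ranks. For
#' n <= `exact_max` usable pairs the p-value comes from the exact permutation
#' distribution of the signed-rank statistic conditional on the observed
#' ranks (all 2^n sign assignments, computed by convolution); above that, the
#' normal approximation with tie correction and continuity correction is
#' used. The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x_ref Reference-time values, one per subject.
#' @param x_cmp Comparison-time values, paired with `x_ref`.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `p_value`, `statistic` (W+, mid-rank scale), `n_used`,
#'   `method` and `degenerate` (TRUE when all differences were zero).
#' @export
wilcoxon_signed_rank <- function(x_ref, x_cmp, exact_max = 25) {
  if (length(x_ref) != length(x_cmp)) {
    stop_uromet("paired vectors must have equal length",
                class = "uromet_validation_error")
  }
  d <- x_cmp - x_ref
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(p_value = 1.0, statistic = 0, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  if (length(nz) < 5) {
    stop_uromet(sprintf("only %d non-zero paired differences (need >= 5)", length(nz)),
                class = "uromet_validation_error")
  }
  n <- length(nz)
  r <- rank(abs(nz))
  w_plus <- sum(r[nz > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    pmf <- wsr_exact_pmf(r2)
    w2 <- as.integer(round(2 * w_plus))
    p_lower <- sum(pmf[seq_len(w2 + 1)])
    p_upper <- sum(pmf[(w2 + 1):length(pmf)])
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p_value = p, statistic = w_plus, n_used = n, method = method,
       degenerate = FALSE)
}

#' Triple-criterion biomarker selection
#'
#' Produces one record per metabolite for a paired time contrast in one
#' intervention arm: the PLS-DA VIP at the contrast, two-sided Wilcoxon
#' signed-rank p-values for the contrast and for time 0 vs 4 h, signed fold
#' changes from arithmetic means of creatinine-normalized concentrations, and
#' per-time means and standard deviations (umol/mmol Cr). A metabolite is
#' selected when all three criteria hold: VIP >= `vip_min`, p <= `p_max` at
#' the contrast, and |FC| >= `abs_fc_min` at the contrast. Records are sorted
#' by VIP, descending. An FDR-adjusted p column (`fdr_0_1`) is included for
#' reference but never gates selection.
#'
#' @param x A creatinine-normalized `metab_profile` (untransformed values;
#'   the imputed state is fine) restricted or restrictable to one arm.
#' @param vip Named VIP vector matching the table's metabolites.
#' @param intervention Arm analysed (default `"alcohol"`).
#' @param contrast Two design times, reference first (default `c(0, 1)`).
#' @param vip_min,p_max,abs_fc_min Selection thresholds (defaults 1.0, 0.05,
#'   1.5).
#' @return Tibble of biomarker records with a logical `selected` column.
#' @export
select_biomarkers <- function(x, vip, intervention = "alcohol",
                              contrast = c(0, 1),
                              vip_min = 1.0, p_max = 0.05, abs_fc_min = 1.5) {
  if (attr(x, "transform_state") %in% c("log", "scaled")) {
    stop_uromet("select_biomarkers needs concentrations, not log/scaled values",
                class = "uromet_state_error")
  }
  mets <- colnames(x$values)
  if (is.null(names(vip)) || !setequal(names(vip), mets)) {
    stop_uromet("VIP vector names do not match the table's metabolites",
                class = "uromet_validation_error")
  }
  arm <- filter_samples(x, .data$role == "experimental",
                        .data$intervention == !!intervention)
  s <- arm$samples
  subjects <- sort(unique(s$subject_id))
  by_time <- function(t) {
    rows <- s$time_h == t
    v <- arm$values[rows, , drop = FALSE]
    v[match(subjects, s$subject_id[rows]), , drop = FALSE]
  }
  v_by_time <- lapply(0:4, by_time)
  names(v_by_time) <- paste0("t", 0:4)
  ref <- v_by_time[[paste0("t", contrast[1])]]
  cmp <- v_by_time[[paste0("t", contrast[2])]]
  t4 <- v_by_time[["t4"]]
  rec <- lapply(mets, function(m) {
    means <- vapply(v_by_time, function(v) mean(v[, m]), numeric(1))
    sds <- vapply(v_by_time, function(v) sd(v[, m]), numeric(1))
    p01 <- wilcoxon_signed_rank(ref[, m], cmp[, m])$p_value
    p04 <- wilcoxon_signed_rank(ref[, m], t4[, m])$p_value
    tibble::tibble(
      metabolite = m,
      vip = unname(vip[m]),
      p_0_1 = p01,
      fc_0_1 = signed_fold_change(mean(ref[, m]), mean(cmp[, m])),
      p_0_4 = p04,
      fc_0_4 = signed_fold_change(mean(ref[, m]), mean(t4[, m])),
      !!!stats::setNames(as.list(means), paste0("mean_", 0:4)),
      !!!stats::setNames(as.list(sds), paste0("sd_", 0:4))
    )
  })
  out <- dplyr::bind_rows(rec)
  out$fdr_0_1 <- stats::p.adjust(out$p_0_1, method = "BH")
  out$selected <- out$vip >= vip_min & out$p_0_1 <= p_max &
    abs(out$fc_0_1) >= abs_fc_min
  dplyr::arrange(out, dplyr::desc(.data$vip))
}

#' Write a Table 1-style biomarker TSV
#'
#' Fold changes are printed to one decimal (the reporting convention);
#' full precision stays in the returned records.
#'
#' @param records Output of [select_biomarkers()].
#' @param path Destination TSV.
#' @param selected_only Write only selected records.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(records, path, selected_only = FALSE) {
  df <- if (selected_only) dplyr::filter(records, .data$selected) else records
  df <- dplyr::mutate(df,
                      fc_0_1 = round(.data$fc_0_1, 1),
                      fc_0_4 = round(.data$fc_0_4, 1))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

band_levels <- c("high_negative", "negative", "neutral", "positive", "high_positive")

band_rho <- function(rho) {
  out <- ifelse(rho >= 0.6, "high_positive",
         ifelse(rho >= 0.2, "positive",
         ifelse(rho > -0.2, "neutral",
         ifelse(rho > -0.6, "negative", "high_negative"))))
  out[is.na(rho)] <- NA_character_
  out
}

#' Spearman correlation matrix with qualitative bands
#'
#' Pairwise Spearman rho (mid-rank ties) over all experimental observations
#' of one arm pooled across the study period, optionally including the
#' sample's collection hour as the pseudo-variable `time`. Each coefficient
#' is banded: high positive (rho >= 0.6), positive (0.2 <= rho < 0.6),
#' neutral (-0.2 < rho < 0.2), negative (-0.6 < rho <= -0.2) and high
#' negative (rho <= -0.6). Constant variables have undefined rho; their
#' entries are NA and listed in `flagged`.
#'
#' @param x A normalized `metab_profile`.
#' @param variables Metabolite subset (default: all).
#' @param include_time Add the collection hour as a variable.
#' @param intervention Arm to pool (default `"alcohol"`).
#' @return List with `rho` (symmetric matrix, unit diagonal), `band`
#'   (character matrix of band labels) and `flagged` (constant variables).
#' @export
spearman_matrix <- function(x, variables = NULL, include_time = TRUE,
                            intervention = "alcohol") {
  arm <- filter_samples(x, .data$role == "experimental",
                        .data$intervention == !!intervention)
  variables <- variables %||% colnames(arm$values)
  v <- arm$values[, variables, drop = FALSE]
  if (include_time) v <- cbind(v, time = arm$samples$time_h)
  if (nrow(v) < 3) {
    stop_uromet("at least 3 observations are required",
                class = "uromet_validation_error")
  }
  const <- apply(v, 2, function(col) max(col) - min(col) == 0)
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  band <- matrix(band_rho(rho), nrow = nrow(rho), dimnames = dimnames(rho))
  list(rho = rho, band = band, flagged = colnames(v)[const])
}

#' Write a correlation matrix in long form
#'
#' @param cm Result of [spearman_matrix()].
#' @param path Destination TSV (columns var1, var2, rho, band).
#' @return `path`, invisibly.
#' @export
write_correlations <- function(cm, path) {
  vars <- colnames(cm$rho)
  long <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  long <- long[match(long$var1, vars) <= match(long$var2, vars), ]
  long$rho <- cm$rho[cbind(long$var1, long$var2)]
  long$band <- cm$band[cbind(long$var1, long$var2)]
  readr::write_tsv(tibble::as_tibble(long), path, progress = FALSE)
  invisible(path)
}

#' Analytic power of the paired two-sided t-test
#'
#' Power for detecting a standardized paired difference d with n pairs at a
#' two-sided level alpha, from the noncentral t distribution with n - 1
#' degrees of freedom and noncentrality d * sqrt(n). At d = 0 the power
#' equals alpha exactly.
#'
#' @param d Standardized effect size (mean difference / SD of differences).
#' @param n Number of pairs (>= 2).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
paired_power <- function(d, n, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_uromet("alpha must be in (0, 1)", class = "uromet_validation_error")
  }
  if (d < 0 || n < 2) {
    stop_uromet("need d >= 0 and n >= 2", class = "uromet_validation_error")
  }
  df <- n - 1
  ncp <- d * sqrt(n)
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp = ncp) + pt(-tc, df, ncp = ncp)
}

#' Monte-Carlo power for paired tests under normal shifts
#'
#' Simulates n paired differences from Normal(d, 1) and estimates the
#' rejection rate of the two-sided paired t-test or Wilcoxon signed-rank test
#' at level alpha.
#'
#' @param d Standardized effect size.
#' @param n Number of pairs.
#' @param alpha Two-sided level.
#' @param test `"t"` or `"wilcoxon"`.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return Estimated power.
#' @export
paired_power_mc <- function(d, n, alpha = 0.05, test = c("t", "wilcoxon"),
                            n_reps = 1e5, seed = 1) {
  test <- match.arg(test)
  set.seed(seed)
  D <- matrix(rnorm(n * n_reps, mean = d, sd = 1), nrow = n)
  if (test == "t") {
    m <- colMeans(D)
    s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
    tstat <- sqrt(n) * m / s
    mean(abs(tstat) > qt(1 - alpha / 2, n - 1))
  } else {
    # exact critical region of W+ at level alpha (no ties a.s.)
    w <- 0:(n * (n + 1) / 2)
    p2 <- pmin(1, 2 * pmin(stats::psignrank(w, n), 1 - stats::psignrank(w - 1, n)))
    crit <- w[p2 <= alpha]
    r <- apply(abs(D), 2, rank)
    wplus <- colSums(r * (D > 0))
    mean(wplus %in% crit)
  }
}
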