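#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end workflow. Defaults equal the standard
#' analysis settings: auto scaling, 2 components for score plots, 3 for the
#' selection model, contrast 0 vs 1 h in the alcohol arm, selection
#' thresholds VIP >= 1.0, p <= 0.05, |FC| >= 1.5, 95% ASCA and 90% unfolded
#' ellipsoids.
#'
#' @param scaling Scaling for [transform_scale()].
#' @param k_plot Components for PCA / score plots.
#' @param k_select Components for the selection PLS-DA.
#' @param contrast Two design times, reference first.
#' @param intervention Analysis arm.
#' @param vip_min,p_max,abs_fc_min Selection thresholds.
#' @param asca_level,unfolded_level Ellipsoid confidence levels.
#' @param n_perm Permutations for the ASCA time-effect test.
#' @param seed Seed for permutation draws.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scaling = "auto", k_plot = 2, k_select = 3,
                            contrast = c(0, 1), intervention = "alcohol",
                            vip_min = 1.0, p_max = 0.05, abs_fc_min = 1.5,
                            asca_level = 0.95, unfolded_level = 0.90,
                            n_perm = 199, seed = 1L) {
  stopifnot(vip_min > 0, p_max > 0, abs_fc_min > 0,
            all(contrast %in% 0:4), length(contrast) == 2)
  structure(
    list(scaling = scaling, k_plot = k_plot, k_select = k_select,
         contrast = contrast, intervention = intervention,
         vip_min = vip_min, p_max = p_max, abs_fc_min = abs_fc_min,
         asca_level = asca_level, unfolded_level = unfolded_level,
         n_perm = n_perm, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis workflow
#'
#' Executes, in order: preprocessing (creatinine normalization, zero
#' imputation, log/scale transform), PCA and PLS-DA on the configured
#' contrast, ASCA over time and participant with a permutation test for the
#' time effect, unfolded PCA with trajectories and bi-plot rankings,
#' triple-criterion biomarker selection, and Spearman correlation of the
#' selected panel over the full period. All module TSVs plus a markdown
#' report are written to `out_dir`.
#'
#' @param x A raw `metab_profile` (or a path to a wide CSV readable by
#'   [read_profile_table()]).
#' @param out_dir Output directory.
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every stage result (`preprocessed`, `pca`,
#'   `plsda`, `asca`, `asca_time`, `perm`, `unfolded`, `biomarkers`,
#'   `correlations`).
#' @export
run_pipeline <- function(x, out_dir, config = pipeline_config()) {
  if (is.character(x)) x <- read_profile_table(x)
  if (nrow(x$values) == 0) {
    stop_uromet("input table has no samples", class = "uromet_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pp <- preprocess_profile(x, scaling = config$scaling)
  arm_scaled <- filter_samples(pp$scaled, .data$role == "experimental",
                               .data$intervention == !!config$intervention)
  # contrast models are scaled within their own sample subset, so every
  # metabolite's 0-vs-t contrast is standardized against contrast variation
  # (not against variation at unrelated hours)
  contrast_tab <- filter_samples(pp$normalized, .data$role == "experimental",
                                 .data$intervention == !!config$intervention,
                                 .data$time_h %in% !!config$contrast)
  contrast_scaled <- transform_scale(contrast_tab, scaling = config$scaling)
  Xc <- contrast_scaled$values
  yc <- factor(contrast_scaled$samples$time_h == config$contrast[2],
               levels = c(FALSE, TRUE), labels = c("reference", "comparison"))
  pca <- fit_pca(Xc, k = config$k_plot)
  plsda <- fit_plsda(Xc, yc, k = config$k_select)
  write_latent_model(pca, file.path(out_dir, "latent"), prefix = "pca_")
  write_latent_model(plsda, file.path(out_dir, "latent"), prefix = "plsda_")

  X_arm <- scale(arm_scaled$values, center = TRUE, scale = FALSE)
  factors <- data.frame(time = arm_scaled$samples$time_h,
                        subject = arm_scaled$samples$subject_id)
  decomp <- asca_decompose(X_arm, factors)
  k_time <- min(config$k_plot, length(unique(factors$time)) - 1)
  sca_time <- asca_sca(decomp, "time", k = k_time, level = config$asca_level)
  perm <- asca_permutation_test(X_arm, factors, "time",
                                n_perm = config$n_perm, seed = config$seed)
  write_asca_ssq(decomp, file.path(out_dir, "effect_ssq.tsv"))
  readr::write_tsv(sca_time$centroids, file.path(out_dir, "asca_time_centroids.tsv"),
                   progress = FALSE)

  U <- unfold(pp$scaled, intervention = config$intervention)
  uf <- unfolded_pca_trajectories(U, k = config$k_plot,
                                  level = config$unfolded_level)
  write_unfolded_outputs(uf, file.path(out_dir, "unfolded"), U = U)

  norm_tab <- pp$normalized
  norm_tab$values <- norm_tab$values[, names(plsda$vip), drop = FALSE]
  bios <- select_biomarkers(norm_tab, plsda$vip,
                            intervention = config$intervention,
                            contrast = config$contrast,
                            vip_min = config$vip_min, p_max = config$p_max,
                            abs_fc_min = config$abs_fc_min)
  write_biomarkers(bios, file.path(out_dir, "biomarkers.tsv"))
  sel <- bios$metabolite[bios$selected]
  cors <- if (length(sel) >= 2) {
    spearman_matrix(norm_tab, variables = sel, include_time = TRUE,
                    intervention = config$intervention)
  } else NULL
  if (!is.null(cors)) write_correlations(cors, file.path(out_dir, "correlations.tsv"))

  write_report(out_dir, x, config, decomp, perm, bios)
  invisible(list(preprocessed = pp, pca = pca, plsda = plsda, asca = decomp,
                 asca_time = sca_time, perm = perm, unfolded = uf,
                 biomarkers = bios, correlations = cors))
}

config_hash <- function(config) {
  s <- paste(vapply(config, function(v) paste(format(v), collapse = ","),
                    character(1)), collapse = "|")
  # small stable polynomial hash; avoids external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_report <- function(out_dir, x, config, decomp, perm, bios) {
  sel <- dplyr::filter(bios, .data$selected)
  tot <- decomp$ssq[["total"]]
  lines <- c(
    "# Urinary organic-acid intervention analysis",
    "",
    sprintf("- samples: %d (%d metabolites)", nrow(x$values), ncol(x$values)),
    sprintf("- package version: %s", as.character(utils::packageVersion("uromet"))),
    sprintf("- seed: %d | config hash: %s", config$seed, config_hash(config)),
    sprintf("- selection thresholds: VIP >= %.2f, p <= %.3f, |FC| >= %.2f",
            config$vip_min, config$p_max, config$abs_fc_min),
    "",
    "## Variation partition (ASCA)",
    "",
    sprintf("- time: %.1f%% | participant: %.1f%% | residual: %.1f%%",
            100 * decomp$ssq[["time"]] / tot, 100 * decomp$ssq[["subject"]] / tot,
            100 * decomp$ssq[["residual"]] / tot),
    sprintf("- permutation p-value for the time effect: %.4g", perm$p_value),
    "",
    sprintf("## Selected biomarkers (%d)", nrow(sel)),
    "",
    "| metabolite | VIP | p (0 vs 1 h) | FC (0 vs 1 h) | p (0 vs 4 h) | FC (0 vs 4 h) |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %.2f | %.3f | %+.1f | %.3f | %+.1f |",
            sel$metabolite, sel$vip, sel$p_0_1, sel$fc_0_1, sel$p_0_4, sel$fc_0_4)
  )
  writeLines(lines, file.path(out_dir, "report.md"))
}
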