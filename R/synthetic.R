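#' Generator configuration for a synthetic crossover study
#'
#' Defaults reproduce the study dimensions this pipeline targets: 12
#' subjects, 120 metabolites, five hourly collections (0..4 h), two
#' interventions (vehicle, alcohol) in a two-period crossover, lognormal
#' creatinine per sample, and optionally the full 25-injection batch layout
#' with pooled-QC and repeat samples.
#'
#' @param n_subjects Number of subjects.
#' @param n_metabolites Number of metabolites.
#' @param times Collection hours.
#' @param include_qc_layout Emit the per-subject batch layout (QC + repeats).
#' @param creatinine_meanlog,creatinine_sdlog Lognormal parameters of the
#'   per-sample creatinine (mmol/L); defaults emulate realistic urine
#'   dilution variation.
#' @param qc_noise_sd Log-scale analytical noise of QC and repeat injections.
#' @param zero_rate Probability that a value is reported as a non-detect 0.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 12, n_metabolites = 120,
                             times = 0:4, include_qc_layout = FALSE,
                             creatinine_meanlog = log(10),
                             creatinine_sdlog = 0.4,
                             qc_noise_sd = 0.05, zero_rate = 0) {
  stopifnot(n_subjects >= 2, n_metabolites >= 1, zero_rate >= 0, zero_rate < 1)
  structure(
    list(n_subjects = n_subjects, n_metabolites = n_metabolites,
         times = as.integer(times),
         interventions = c("vehicle", "alcohol"),
         include_qc_layout = include_qc_layout,
         creatinine_meanlog = creatinine_meanlog,
         creatinine_sdlog = creatinine_sdlog,
         qc_noise_sd = qc_noise_sd, zero_rate = zero_rate),
    class = "generator_config"
  )
}

#' Crossover study design
#'
#' Splits the subjects into two groups whose period-1 interventions differ;
#' every subject receives both interventions across the two periods.
#'
#' @param n_subjects Number of subjects.
#' @return List with `subjects`, `times`, `interventions` and
#'   `crossover_assignment` (named vector: subject -> period-1 intervention).
#' @export
study_design <- function(n_subjects = 12) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  half <- ceiling(n_subjects / 2)
  assignment <- stats::setNames(
    rep(c("vehicle", "alcohol"), c(half, n_subjects - half)), subjects
  )
  list(subjects = subjects, times = 0:4,
       interventions = c("vehicle", "alcohol"),
       crossover_assignment = assignment)
}

#' Planted ground truth for a synthetic study
#'
#' Describes which metabolites respond to the alcohol arm and how. Response
#' shapes interpolate log-linearly between hourly anchors:
#' \describe{
#'   \item{early_peak / late_peak}{log-linear rise from 1 at time 0 to
#'     `peak_fc` at `peak_time`, then geometric decay toward 1 by 4 h.}
#'   \item{persistent_rise}{rise to `peak_fc` at `peak_time`, plateau after.}
#'   \item{monotone_decrease}{log-linear decline from 1 to `peak_fc` (< 1)
#'     at 4 h.}
#' }
#'
#' @param affected Tibble with columns `metabolite`, `shape`, `peak_time`,
#'   `peak_fc`.
#' @param baseline Tibble with columns `metabolite`, `median` (umol/mmol Cr)
#'   and `gsd` (geometric SD); metabolites not listed get defaults drawn at
#'   generation time.
#' @param subject_sd Log-scale between-subject SD.
#' @param noise_sd Log-scale residual SD.
#' @param seed Integer seed recorded with the truth.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(affected, baseline = NULL,
                            subject_sd = 0.35, noise_sd = 0.45, seed = 1L) {
  affected <- tibble::as_tibble(affected)
  stopifnot(all(c("metabolite", "shape", "peak_time", "peak_fc") %in% names(affected)))
  bad_shape <- setdiff(affected$shape,
                       c("early_peak", "late_peak", "persistent_rise",
                         "monotone_decrease"))
  if (length(bad_shape) > 0) {
    stop_uromet(paste0("unknown response shape(s): ", paste(bad_shape, collapse = ", ")),
                class = "uromet_validation_error")
  }
  if (any(affected$peak_fc <= 0)) {
    stop_uromet("peak_fc must be positive", class = "uromet_validation_error")
  }
  dec <- affected$shape == "monotone_decrease"
  if (any(affected$peak_fc[dec] >= 1)) {
    stop_uromet("monotone_decrease requires peak_fc < 1",
                class = "uromet_validation_error")
  }
  stopifnot(subject_sd >= 0, noise_sd >= 0)
  structure(
    list(affected = affected, baseline = baseline,
         subject_sd = subject_sd, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

# multiplicative response of an affected metabolite at hour t in the alcohol
# arm; decay constant 0.45 per hour past the peak on the log scale
response_value <- function(shape, peak_time, peak_fc, t, decay = 0.45) {
  lfc <- log(peak_fc)
  if (shape == "monotone_decrease") {
    return(exp(lfc * t / 4))
  }
  if (t <= peak_time) {
    return(exp(lfc * t / peak_time))
  }
  if (shape == "persistent_rise") {
    return(peak_fc)
  }
  exp(lfc * decay^(t - peak_time))
}

#' Response profile of a truth entry over the design hours
#'
#' @param truth A `synthetic_truth`.
#' @param metabolite Affected metabolite name.
#' @param times Hours (default 0:4).
#' @return Named numeric vector of multiplicative responses.
#' @export
planted_response <- function(truth, metabolite, times = 0:4) {
  row <- truth$affected[truth$affected$metabolite == metabolite, ]
  if (nrow(row) != 1) {
    stop_uromet(paste0("metabolite not in the affected set: ", metabolite),
                class = "uromet_validation_error")
  }
  stats::setNames(
    vapply(times, function(t) response_value(row$shape, row$peak_time, row$peak_fc, t),
           numeric(1)),
    paste0("t", times)
  )
}

#' Ground truth mimicking the published 13-metabolite alcohol response
#'
#' The preset plants 13 affected metabolites whose shapes, peak times and
#' peak fold changes follow the reference time-courses in
#' [table1_reference()]: an early-peaking lactic-like surge (peak FC ~27 at
#' 1 h), a monotone vanillylmandelic-like decrease (FC ~1/8.8 by 4 h), a
#' persistent tiglylglycine-like rise (FC ~7 from 2 h), and so on. Baseline
#' medians equal the reference time-0 means.
#'
#' @param subject_sd,noise_sd Log-scale SDs (defaults calibrated so per-time
#'   CVs match the reference SD/mean ranges).
#' @param seed Seed recorded with the truth.
#' @return A `synthetic_truth` with 13 affected metabolites.
#' @export
table1_preset <- function(subject_sd = 0.35, noise_sd = 0.45, seed = 1L) {
  ref <- table1_reference()
  means <- as.matrix(ref[paste0("mean_", 0:4)])
  rownames(means) <- ref$metabolite
  ratios <- means / means[, 1]
  aff <- lapply(seq_len(nrow(ref)), function(i) {
    m <- ref$metabolite[i]
    r <- ratios[i, ]
    if (all(r <= 1 + 1e-9) && which.min(r) == 5) {
      return(tibble::tibble(metabolite = m, shape = "monotone_decrease",
                            peak_time = 4, peak_fc = unname(r[5])))
    }
    pk <- unname(which.max(r))
    # plateau: response stays within 25% of the peak through 4 h
    if (pk < 5 && all(r[pk:5] > 0.75 * max(r))) {
      return(tibble::tibble(metabolite = m, shape = "persistent_rise",
                            peak_time = pk - 1, peak_fc = unname(max(r))))
    }
    tibble::tibble(metabolite = m,
                   shape = if (pk <= 2) "early_peak" else "late_peak",
                   peak_time = pk - 1, peak_fc = unname(max(r)))
  })
  affected <- dplyr::bind_rows(aff)
  baseline <- tibble::tibble(metabolite = ref$metabolite,
                             median = unname(means[, 1]), gsd = exp(0.5))
  synthetic_truth(affected, baseline, subject_sd = subject_sd,
                  noise_sd = noise_sd, seed = seed)
}

#' The 25-injection batch layout of the measurement design
#'
#' Per subject batch: five conditioning QC injections plus a sixth QC, then
#' vehicle samples interleaved with alcohol repeats and QCs, then alcohol
#' samples interleaved with vehicle repeats and QCs — 11 QC, 5 vehicle, 5
#' alcohol, 2 alcohol-repeat and 2 vehicle-repeat injections. The first two
#' repeats duplicate experimental samples injected later in the batch; the
#' last two duplicate samples injected earlier.
#'
#' @return Character vector of length 25 with entries in
#'   `Q`, `S_V`, `S_A`, `R_A`, `R_V`.
#' @export
batch_layout <- function() {
  c("Q", "Q", "Q", "Q", "Q", "Q",
    "S_V", "S_V", "S_V", "R_A", "Q",
    "S_V", "S_V", "R_A", "Q",
    "S_A", "S_A", "S_A", "R_V", "Q",
    "S_A", "S_A", "R_V", "Q", "Q")
}

#' Generate a synthetic crossover study table
#'
#' Concentrations follow a multiplicative lognormal model:
#' value(subject, metabolite, time, arm) = baseline x subject effect x
#' response(time, arm) x exp(noise), with response = 1 in the vehicle arm and
#' for unaffected metabolites. Normalized values (umol/mmol Cr) are
#' back-computed to raw umol/L through each sample's lognormal creatinine, so
#' the table enters the pipeline un-normalized, exactly as measured data
#' would. With `include_qc_layout`, each subject's batch is emitted in the
#' 25-injection measurement-design order, QC injections carrying the pooled
#' mean profile plus small analytical noise and repeat injections duplicating
#' the matching experimental sample plus the same analytical noise.
#'
#' @param config A `generator_config`.
#' @param truth A `synthetic_truth`; affected metabolites must be within the
#'   metabolite panel.
#' @param seed Integer seed (defaults to `truth$seed`); the output is fully
#'   reproducible given (config, truth, seed).
#' @return List with `table` (a raw `metab_profile`), `truth`, and `layout`
#'   (tibble of the injection order per batch; `NULL` without the QC layout).
#' @export
generate_study <- function(config = generator_config(), truth = table1_preset(),
                           seed = NULL) {
  seed <- seed %||% truth$seed
  set.seed(seed)
  n_m <- config$n_metabolites
  named <- truth$affected$metabolite
  if (length(named) > n_m) {
    stop_uromet("more affected metabolites than the metabolite panel holds",
                class = "uromet_validation_error")
  }
  extra_base <- truth$baseline$metabolite %||% character()
  panel <- unique(c(named, setdiff(extra_base, named)))
  if (length(panel) > n_m) {
    stop_uromet("baseline map lists metabolites beyond the panel size",
                class = "uromet_validation_error")
  }
  fillers <- sprintf("met_%03d", seq_len(n_m))
  panel <- c(panel, setdiff(fillers, panel)[seq_len(n_m - length(panel))])
  bad <- setdiff(named, panel)
  if (length(bad) > 0) {
    stop_uromet(paste0("affected metabolite absent from metabolite set: ",
                       paste(bad, collapse = ", ")),
                class = "uromet_validation_error")
  }
  # baselines: listed ones as given, the rest lognormal around 5 umol/mmol Cr
  med <- stats::setNames(rlnorm(length(panel), log(5), log(2.5)), panel)
  if (!is.null(truth$baseline)) {
    med[truth$baseline$metabolite] <- truth$baseline$median
  }
  design <- study_design(config$n_subjects)
  subjects <- design$subjects
  times <- config$times
  # per (subject, metabolite) random effect, shared across arms and times
  subj_eff <- matrix(rnorm(length(subjects) * length(panel), 0, truth$subject_sd),
                     nrow = length(subjects),
                     dimnames = list(subjects, panel))
  resp <- matrix(1, nrow = length(panel), ncol = length(times),
                 dimnames = list(panel, paste0("t", times)))
  for (i in seq_len(nrow(truth$affected))) {
    a <- truth$affected[i, ]
    resp[a$metabolite, ] <- vapply(
      times, function(t) response_value(a$shape, a$peak_time, a$peak_fc, t),
      numeric(1)
    )
  }
  rows <- list()
  norm_values <- list()
  idx <- 0
  for (s in subjects) {
    for (arm in config$interventions) {
      for (t in times) {
        idx <- idx + 1
        eps <- rnorm(length(panel), 0, truth$noise_sd)
        r <- if (arm == "alcohol") resp[, paste0("t", t)] else rep(1, length(panel))
        norm_values[[idx]] <- med * exp(subj_eff[s, ]) * r * exp(eps)
        rows[[idx]] <- tibble::tibble(
          sample_id = sprintf("%s_%s_t%d", s, arm, t),
          subject_id = s, intervention = arm, time_h = t,
          role = "experimental", batch_id = s
        )
      }
    }
  }
  samples <- dplyr::bind_rows(rows)
  V <- do.call(rbind, norm_values)
  colnames(V) <- panel
  if (config$zero_rate > 0) {
    zero <- matrix(runif(length(V)) < config$zero_rate, nrow = nrow(V))
    V[zero] <- 0
  }
  creat <- rlnorm(nrow(samples), config$creatinine_meanlog, config$creatinine_sdlog)
  samples$creatinine <- creat
  layout <- NULL
  if (config$include_qc_layout) {
    pooled <- colMeans(V)
    pooled_cr <- mean(creat)
    lay <- batch_layout()
    all_rows <- list(); all_vals <- list(); lay_rows <- list()
    for (s in subjects) {
      sub_idx <- which(samples$subject_id == s)
      veh <- sub_idx[samples$intervention[sub_idx] == "vehicle"]
      alc <- sub_idx[samples$intervention[sub_idx] == "alcohol"]
      veh <- sample(veh); alc <- sample(alc)
      # early repeats duplicate alcohol samples injected later; late repeats
      # duplicate vehicle samples injected earlier
      rep_a <- sample(alc, 2); rep_v <- sample(veh, 2)
      v_i <- a_i <- ra_i <- rv_i <- q_i <- 0
      for (pos in seq_along(lay)) {
        kind <- lay[pos]
        if (kind == "Q") {
          q_i <- q_i + 1
          id <- sprintf("%s_qc_%02d", s, q_i)
          val <- pooled * exp(rnorm(length(panel), 0, config$qc_noise_sd))
          meta <- tibble::tibble(sample_id = id, subject_id = s,
                                 intervention = "vehicle", time_h = 0L,
                                 role = "qc", batch_id = s,
                                 injection_order = pos, creatinine = pooled_cr)
        } else if (kind %in% c("S_V", "S_A")) {
          src <- if (kind == "S_V") { v_i <- v_i + 1; veh[v_i] } else { a_i <- a_i + 1; alc[a_i] }
          val <- V[src, ]
          meta <- dplyr::mutate(samples[src, ], injection_order = pos,
                                .before = "creatinine")
        } else {
          src <- if (kind == "R_A") { ra_i <- ra_i + 1; rep_a[ra_i] } else { rv_i <- rv_i + 1; rep_v[rv_i] }
          orig <- samples[src, ]
          val <- V[src, ] * exp(rnorm(length(panel), 0, config$qc_noise_sd))
          meta <- tibble::tibble(sample_id = paste0(orig$sample_id, "_rep"),
                                 subject_id = orig$subject_id,
                                 intervention = orig$intervention,
                                 time_h = orig$time_h, role = "repeat",
                                 batch_id = s, injection_order = pos,
                                 creatinine = orig$creatinine)
        }
        all_rows[[length(all_rows) + 1]] <- meta
        all_vals[[length(all_vals) + 1]] <- val
        lay_rows[[length(lay_rows) + 1]] <- tibble::tibble(
          batch_id = s, injection_order = pos, kind = kind,
          sample_id = meta$sample_id
        )
      }
    }
    samples <- dplyr::bind_rows(all_rows)
    V <- do.call(rbind, all_vals)
    colnames(V) <- panel
    layout <- dplyr::bind_rows(lay_rows)
  } else {
    samples$injection_order <- stats::ave(
      seq_len(nrow(samples)), samples$batch_id, FUN = seq_along
    )
    samples <- dplyr::relocate(samples, "injection_order", .before = "creatinine")
  }
  raw <- V * samples$creatinine
  table <- metab_profile(samples, raw, normalized = FALSE,
                         transform_state = "raw", require_complete = TRUE)
  list(table = table, truth = truth, layout = layout)
}

#' Score recovery of planted effects
#'
#' @param selected Character vector of selected metabolites.
#' @param truth A `synthetic_truth`.
#' @param metabolites Full metabolite panel of the analysed table.
#' @return List with `sensitivity`, `specificity` and `false_discoveries`.
#' @export
score_recovery <- function(selected, truth, metabolites) {
  if (!all(selected %in% metabolites)) {
    stop_uromet("selected set contains unknown metabolites",
                class = "uromet_validation_error")
  }
  affected <- intersect(truth$affected$metabolite, metabolites)
  unaffected <- setdiff(metabolites, affected)
  tp <- length(intersect(selected, affected))
  fp <- length(intersect(selected, unaffected))
  list(
    sensitivity = if (length(affected) == 0) NA_real_ else tp / length(affected),
    specificity = if (length(unaffected) == 0) NA_real_ else
      (length(unaffected) - fp) / length(unaffected),
    false_discoveries = fp
  )
}

#' Write generator outputs: wide CSV, truth JSON and injection layout
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_table(study$table, file.path(dir, "study.csv"), dialect = "wide_csv")
  truth <- study$truth
  jsonlite::write_json(
    list(affected = truth$affected, subject_sd = truth$subject_sd,
         noise_sd = truth$noise_sd, seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(study$layout)) {
    readr::write_tsv(study$layout, file.path(dir, "layout.tsv"), progress = FALSE)
  }
  invisible(dir)
}
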