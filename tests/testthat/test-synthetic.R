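test_that("default configuration reproduces the study dimensions", {
  cfg <- generator_config()
  expect_equal(cfg$n_subjects, 12)
  expect_equal(cfg$n_metabolites, 120)
  expect_equal(cfg$times, 0:4)

  design <- study_design(12)
  assign <- design$crossover_assignment
  expect_equal(sort(as.vector(table(assign))), c(6, 6))
  expect_setequal(names(assign), design$subjects)

  study <- generate_study(generator_config(n_metabolites = 20), table1_preset(seed = 1))
  expect_equal(sum(study$table$samples$role == "experimental"), 120)
  expect_true(all(study$table$values >= 0))
})

test_that("the QC layout emits the exact 25-injection batch pattern", {
  lay <- batch_layout()
  expect_equal(length(lay), 25)
  expect_equal(unname(table(lay)[c("Q", "S_V", "S_A", "R_A", "R_V")]),
               c(11, 5, 5, 2, 2), ignore_attr = TRUE)

  study <- generate_study(generator_config(n_metabolites = 16, include_qc_layout = TRUE),
                          table1_preset(seed = 2))
  for (b in unique(study$layout$batch_id)) {
    batch <- study$layout[study$layout$batch_id == b, ]
    expect_equal(batch$kind[order(batch$injection_order)], lay)
  }
  # repeats duplicate an experimental sample's design cell within the batch
  s <- study$table$samples
  reps <- s[s$role == "repeat", ]
  for (i in seq_len(nrow(reps))) {
    match_orig <- s$role == "experimental" & s$batch_id == reps$batch_id[i] &
      s$subject_id == reps$subject_id[i] &
      s$intervention == reps$intervention[i] & s$time_h == reps$time_h[i]
    expect_equal(sum(match_orig), 1)
  }
})

test_that("noiseless generation reproduces planted fold changes exactly", {
  truth <- table1_preset(subject_sd = 0, noise_sd = 0, seed = 5)
  study <- generate_study(generator_config(n_metabolites = 15), truth)
  norm <- normalize_to_creatinine(study$table)
  arm <- filter_samples(norm, .data$intervention == "alcohol",
                        .data$role == "experimental")
  for (m in truth$affected$metabolite) {
    resp <- planted_response(truth, m)
    m0 <- mean(arm$values[arm$samples$time_h == 0, m])
    m1 <- mean(arm$values[arm$samples$time_h == 1, m])
    planted <- if (resp["t1"] >= 1) resp["t1"] else -1 / resp["t1"]
    expect_equal(signed_fold_change(m0, m1), unname(planted), tolerance = 1e-10)
  }
  # vehicle arm and unaffected metabolites carry no time response
  veh <- filter_samples(norm, .data$intervention == "vehicle",
                        .data$role == "experimental")
  expect_lt(max(apply(veh$values, 2, function(col) diff(range(col / col[1])))),
            1e-12)
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- generator_config(n_metabolites = 16, include_qc_layout = TRUE)
  s1 <- generate_study(cfg, table1_preset(seed = 9))
  s2 <- generate_study(cfg, table1_preset(seed = 9))
  expect_identical(s1$table$values, s2$table$values)
  expect_identical(s1$table$samples, s2$table$samples)
  expect_identical(s1$layout, s2$layout)
  f1 <- withr::local_tempdir(); f2 <- withr::local_tempdir()
  write_study(s1, f1); write_study(s2, f2)
  expect_identical(readLines(file.path(f1, "study.csv")),
                   readLines(file.path(f2, "study.csv")))
  s3 <- generate_study(cfg, table1_preset(seed = 10))
  expect_false(identical(s1$table$values, s3$table$values))
})

test_that("the preset plants the 13 reference response profiles", {
  truth <- table1_preset()
  expect_equal(nrow(truth$affected), 13)
  vma <- truth$affected[truth$affected$metabolite == "vanillylmandelic_acid", ]
  expect_equal(vma$shape, "monotone_decrease")
  expect_lt(vma$peak_fc, 1)
  lactic <- truth$affected[truth$affected$metabolite == "lactic_acid", ]
  expect_equal(lactic$peak_time, 1)
  expect_equal(lactic$peak_fc, 27.4, tolerance = 0.05)
  ntg <- truth$affected[truth$affected$metabolite == "n_tiglylglycine", ]
  expect_equal(ntg$shape, "persistent_rise")
  expect_equal(ntg$peak_fc, 7.0, tolerance = 0.05)
  # baselines equal the reference time-0 means
  ref <- table1_reference()
  expect_equal(truth$baseline$median[match(ref$metabolite, truth$baseline$metabolite)],
               ref$mean_0)
})

test_that("zero inflation hits the configured rate within binomial bounds", {
  cfg <- generator_config(n_metabolites = 50, zero_rate = 0.05)
  study <- generate_study(cfg, table1_preset(seed = 11))
  n <- length(study$table$values)
  frac <- mean(study$table$values == 0)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
})

test_that("recovery scoring counts hits and false discoveries", {
  truth <- table1_preset()
  mets <- c(truth$affected$metabolite, sprintf("met_%03d", 1:7))
  expect_equal(score_recovery(truth$affected$metabolite, truth, mets),
               list(sensitivity = 1, specificity = 1, false_discoveries = 0L))
  expect_equal(score_recovery(character(), truth, mets)$sensitivity, 0)
  expect_equal(score_recovery(character(), truth, mets)$specificity, 1)
  mixed <- c(truth$affected$metabolite[1:5], "met_001")
  out <- score_recovery(mixed, truth, mets)
  expect_equal(out$sensitivity, 5 / 13)
  expect_equal(out$false_discoveries, 1L)
  expect_error(score_recovery("nope", truth, mets), class = "uromet_validation_error")
})

test_that("affected metabolites must be inside the panel", {
  truth <- synthetic_truth(
    tibble::tibble(metabolite = "ghost", shape = "early_peak",
                   peak_time = 1, peak_fc = 3),
    baseline = tibble::tibble(metabolite = sprintf("m%02d", 1:5),
                              median = 5, gsd = 2)
  )
  expect_error(synthetic_truth(tibble::tibble(metabolite = "x", shape = "weird",
                                              peak_time = 1, peak_fc = 2)),
               class = "uromet_validation_error")
  expect_error(synthetic_truth(tibble::tibble(metabolite = "x",
                                              shape = "monotone_decrease",
                                              peak_time = 4, peak_fc = 2)),
               class = "uromet_validation_error")
  expect_error(generate_study(generator_config(n_metabolites = 3), truth),
               class = "uromet_validation_error")
})
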