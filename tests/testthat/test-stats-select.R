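test_that("signed fold change uses the symmetric ratio convention", {
  expect_equal(signed_fold_change(5, 5), 1)
  expect_equal(signed_fold_change(2, 6), 3)
  expect_equal(signed_fold_change(6, 2), -3)
  expect_error(signed_fold_change(0, 5), class = "uromet_validation_error")

  # antisymmetry and |FC| >= 1 on random positive pairs
  set.seed(12)
  for (i in 1:50) {
    a <- rlnorm(1); b <- rlnorm(1)
    fc <- signed_fold_change(a, b)
    expect_gte(abs(fc), 1)
    if (a != b) expect_equal(signed_fold_change(b, a), -fc, tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles degenerate and small-n contracts", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- wilcoxon_signed_rank(x, x)
  expect_equal(same$p_value, 1.0)
  expect_true(same$degenerate)

  expect_error(wilcoxon_signed_rank(1:4, c(2, 3, 4, 5)),
               class = "uromet_validation_error")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), class = "uromet_validation_error")

  # n = 5, all differences positive: two-sided p = 2/32
  out5 <- wilcoxon_signed_rank(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(out5$p_value, 2 / 32)

  # n = 12, all same sign: 2/4096 is the smallest achievable p
  out12 <- wilcoxon_signed_rank(rep(0, 12), seq_len(12))
  expect_equal(out12$p_value, 2 / 4096)
})

test_that("exact p equals full sign-pattern enumeration on random pairs", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    ref <- rnorm(n)
    cmp <- ref + rnorm(n, mean = runif(1, -1, 1))
    expect_equal(wilcoxon_signed_rank(ref, cmp)$p_value,
                 oracle_wsr_enum(ref, cmp), tolerance = 1e-12)
  }
  # ties among |differences| are mid-ranked; enumeration stays the oracle
  for (i in 1:10) {
    n <- sample(6:10, 1)
    ref <- rep(0, n)
    cmp <- sample(c(-2, -1, 1, 1, 2), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(ref, cmp)$p_value,
                 oracle_wsr_enum(ref, cmp), tolerance = 1e-12)
  }
})

test_that("exact p matches stats::wilcox.test when there are no ties", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    ref <- rnorm(n)
    cmp <- ref + rnorm(n, 0.4)
    ours <- wilcoxon_signed_rank(ref, cmp)$p_value
    reference <- stats::wilcox.test(cmp, ref, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, reference, tolerance = 1e-12)
  }
})

test_that("normal approximation is used above the exact cutoff and is close", {
  set.seed(40)
  n <- 40
  ref <- rnorm(n); cmp <- ref + rnorm(n, 0.5)
  out <- wilcoxon_signed_rank(ref, cmp)
  expect_equal(out$method, "normal")
  reference <- stats::wilcox.test(cmp, ref, paired = TRUE, exact = FALSE,
                                  correct = TRUE)$p.value
  expect_equal(out$p_value, reference, tolerance = 1e-10)
})

test_that("selection applies the three gates as a conjunction", {
  study <- generate_study(generator_config(n_metabolites = 16),
                          table1_preset(noise_sd = 0.02, subject_sd = 0.1, seed = 2))
  pp <- preprocess_profile(study$table)
  mets <- colnames(pp$normalized$values)
  # hand-set VIPs: a huge-FC metabolite gated out by VIP < 1
  vip <- stats::setNames(rep(2, length(mets)), mets)
  vip["lactic_acid"] <- 0.9
  recs <- select_biomarkers(pp$normalized, vip)
  expect_false(recs$selected[recs$metabolite == "lactic_acid"])
  lac <- recs[recs$metabolite == "lactic_acid", ]
  expect_lt(lac$p_0_1, 0.05)
  expect_gt(abs(lac$fc_0_1), 1.5)
  # records come sorted by VIP, descending
  expect_true(all(diff(recs$vip) <= 0))
  # fillers with VIP 2 but |FC| ~ 1 fail the fold-change gate
  filler <- recs[grepl("^met_", recs$metabolite), ]
  expect_true(all(!filler$selected[abs(filler$fc_0_1) < 1.5]))

  expect_error(select_biomarkers(pp$normalized, vip[-1]),
               class = "uromet_validation_error")
})

test_that("Spearman matrix matches the naive rank oracle and bands correctly", {
  study <- generate_study(generator_config(n_subjects = 6, n_metabolites = 16),
                          table1_preset(seed = 6))
  pp <- preprocess_profile(study$table)
  cm <- spearman_matrix(pp$normalized, include_time = TRUE)
  arm <- filter_samples(pp$normalized, .data$role == "experimental",
                        .data$intervention == "alcohol")
  v <- cbind(arm$values, time = arm$samples$time_h)
  expect_equal(cm$rho, oracle_spearman(v), tolerance = 1e-12)
  expect_true(isSymmetric(cm$rho))
  expect_true(all(diag(cm$rho) == 1))
  expect_true(all(abs(cm$rho) <= 1 + 1e-12))

  # banding thresholds
  expect_equal(uromet:::band_rho(c(0.7, 0.3, 0, -0.3, -0.7)),
               c("high_positive", "positive", "neutral", "negative",
                 "high_negative"))
  expect_equal(uromet:::band_rho(c(0.6, 0.2, -0.2, -0.6)),
               c("high_positive", "positive", "negative", "high_negative"))
})

test_that("a monotone decrease over time has rho = -1 with time", {
  x <- toy_profile(n_subjects = 3, n_metabolites = 2, creatinine = 1)
  attr(x, "normalized") <- TRUE
  x$values[, 1] <- 100 - 10 * x$samples$time_h # strictly decreasing in time
  cm <- spearman_matrix(x, include_time = TRUE)
  expect_equal(unname(cm$rho["met_01", "time"]), -1)
  expect_equal(unname(cm$band["met_01", "time"]), "high_negative")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  study <- generate_study(generator_config(n_subjects = 5, n_metabolites = 16),
                          table1_preset(seed = 10))
  pp <- preprocess_profile(study$table)
  a <- spearman_matrix(pp$normalized, include_time = FALSE)
  warped <- pp$normalized
  warped$values[, 1] <- exp(warped$values[, 1] / max(warped$values[, 1]))
  warped$values[, 2] <- warped$values[, 2]^3
  b <- spearman_matrix(warped, include_time = FALSE)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("constant variables are flagged as undefined correlations", {
  x <- toy_profile(n_subjects = 2, n_metabolites = 3, creatinine = 1)
  attr(x, "normalized") <- TRUE
  x$values[, 2] <- 4
  cm <- spearman_matrix(x, include_time = FALSE)
  expect_true("met_02" %in% cm$flagged)
  expect_true(all(is.na(cm$rho["met_02", ])))
})

test_that("analytic power behaves like a power function should", {
  expect_equal(paired_power(0, 12), 0.05, tolerance = 1e-12)
  expect_equal(paired_power(0, 8, alpha = 0.10), 0.10, tolerance = 1e-12)
  # monotone in effect size and in sample size
  d_grid <- seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(d_grid, paired_power, numeric(1), n = 12)) > 0))
  n_grid <- c(4, 6, 8, 12, 20, 40)
  expect_true(all(diff(vapply(n_grid, function(n) paired_power(0.9, n), numeric(1))) > 0))
  expect_error(paired_power(0.5, 12, alpha = 1.2), class = "uromet_validation_error")
  expect_error(paired_power(-1, 12), class = "uromet_validation_error")
})

test_that("Monte-Carlo power agrees with the analytic t-test computation", {
  mc <- paired_power_mc(0.9, 12, test = "t", n_reps = 2e4, seed = 3)
  expect_lt(abs(mc - paired_power(0.9, 12)), 0.015)
  # Wilcoxon power under normal shifts is close to (slightly below) the t-test
  w <- paired_power_mc(0.9, 12, test = "wilcoxon", n_reps = 1e4, seed = 4)
  expect_gt(w, 0.6)
  expect_lt(w, paired_power(0.9, 12) + 0.05)
})
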