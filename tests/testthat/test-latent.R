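test_that("PCA matches the covariance-eigendecomposition oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:20, 1); p <- sample(2:20, 1)
    X <- random_centered(n, p, seed)
    k <- min(n - 1, p, 3)
    model <- fit_pca(X, k = k)
    oracle <- oracle_pca_eigen(X)
    expect_equal(model$explained, oracle$explained[seq_len(k)], tolerance = 1e-8)
    expect_equal(abs(model$loadings), abs(oracle$loadings[, seq_len(k)]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PCA satisfies its structural invariants", {
  X <- random_centered(10, 6, seed = 7)
  model <- fit_pca(X, k = 5)
  # orthonormal loadings
  expect_equal(crossprod(model$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # score variances non-increasing
  v <- apply(model$scores, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  # scores reproduce X through the loadings at full rank
  full <- fit_pca(X, k = qr(X)$rank)
  expect_equal(full$scores %*% t(full$loadings), X, tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained fractions sum to 1 over all attainable components
  expect_equal(sum(full$explained), 1, tolerance = 1e-10)
  # sign convention: largest-magnitude loading entry positive
  expect_true(all(apply(model$loadings, 2, function(l) l[which.max(abs(l))]) > 0))
})

test_that("two symmetric samples give a single component explaining everything", {
  X <- rbind(c(1, 2, -1), c(-1, -2, 1))
  colnames(X) <- paste0("v", 1:3)
  model <- fit_pca(X, k = 1)
  expect_equal(model$explained, 1)
  expect_error(fit_pca(X, k = 2), class = "uromet_rank_error")
})

test_that("duplicating every row leaves PCA loadings unchanged", {
  X <- random_centered(6, 4, seed = 3)
  m1 <- fit_pca(X, k = 2)
  m2 <- fit_pca(rbind(X, X), k = 2)
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-8)
})

test_that("PLS-DA separates constructed blobs and collapses under permuted labels", {
  set.seed(5)
  n <- 20
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1] <- X[y == "b", 1] + 10 # 10-sd separation on variable 1
  X <- scale(X, center = TRUE, scale = FALSE)
  model <- fit_plsda(X, y, k = 2)
  s1 <- model$scores[, 1]
  expect_true(max(s1[y == "a"]) < min(s1[y == "b"]) ||
                min(s1[y == "a"]) > max(s1[y == "b"]))

  set.seed(6)
  perm <- fit_plsda(X, sample(y), k = 2)
  expect_lt(perm$explained_y[1], model$explained_y[1])
})

test_that("PLS-DA with no class signal explains (almost) no response variance", {
  set.seed(8)
  A <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
  X <- scale(rbind(A, A), center = TRUE, scale = FALSE)
  y <- rep(c("a", "b"), each = 8)
  # identical class profiles up to negligible jitter
  Xj <- X + matrix(rnorm(length(X), 0, 1e-8), nrow(X))
  model <- fit_plsda(Xj, y, k = 1)
  expect_lt(model$explained_y[1], 1e-6)
  # exactly identical profiles are degenerate
  expect_error(fit_plsda(X, y, k = 1), class = "uromet_rank_error")
  expect_error(fit_plsda(X, rep("a", 16), k = 1), class = "uromet_class_error")
})

test_that("PLS-DA is invariant to swapping the label coding up to global sign", {
  X <- random_centered(12, 6, seed = 10)
  y <- rep(c("ctrl", "trt"), 6)
  m1 <- fit_plsda(X, factor(y, levels = c("ctrl", "trt")), k = 2)
  m2 <- fit_plsda(X, factor(y, levels = c("trt", "ctrl")), k = 2)
  expect_equal(m1$scores, m2$scores, tolerance = 1e-10)
  expect_equal(m1$vip, m2$vip, tolerance = 1e-10)
})

test_that("VIP follows the weight-based definition", {
  # one component, equal |weights|: every VIP is 1
  w <- matrix(c(1, -1, 1, -1) / 2, ncol = 1)
  m <- structure(list(kind = "plsda", weights = w, explained_y = 0.7),
                 class = "latent_model")
  expect_equal(unname(compute_vip(m)), rep(1, 4))

  # one component, weight (1,0,0): VIP = (sqrt(3), 0, 0)
  m$weights <- matrix(c(1, 0, 0), ncol = 1)
  expect_equal(unname(compute_vip(m)), c(sqrt(3), 0, 0))

  # two components with hand-set weights and SSY vs brute-force evaluation
  W <- cbind(c(0.6, 0.8, 0), c(0, 0.6, -0.8))
  m$weights <- W
  m$explained_y <- c(0.5, 0.2)
  expect_equal(unname(compute_vip(m)), oracle_vip(W, c(0.5, 0.2)), tolerance = 1e-10)

  m$explained_y <- c(0, 0)
  expect_error(compute_vip(m), class = "uromet_degenerate_error")
})

test_that("sum of VIP^2 equals the variable count for every fitted model", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(8:16, 1); p <- sample(3:12, 1)
    X <- random_centered(n, p, seed + 100)
    y <- rep(c("a", "b"), length.out = n)
    k <- min(2, p)
    model <- fit_plsda(X, y, k = k)
    expect_equal(sum(model$vip^2), p, tolerance = 1e-8)
  }
})

test_that("VIP agrees with the mixOmics reference on a one-component model", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  X <- random_centered(20, 8, seed = 21)
  y <- rep(c("a", "b"), each = 10)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 1.5
  X <- scale(X, center = TRUE, scale = FALSE)
  ours <- fit_plsda(X, y, k = 1)
  ref <- mixOmics::plsda(X, factor(y), ncomp = 1, scale = FALSE)
  ref_vip <- mixOmics::vip(ref)[, 1]
  expect_equal(unname(ours$vip), unname(ref_vip), tolerance = 1e-6)
})

test_that("multilevel split separates within- and between-subject variation", {
  x <- toy_profile(n_subjects = 3, n_metabolites = 4, seed = 13)
  pp <- preprocess_profile(x)$scaled
  within <- multilevel_split(pp, "within")
  between <- multilevel_split(pp, "between")
  # within-part sums to zero per subject
  for (s in unique(pp$samples$subject_id)) {
    expect_lt(max(abs(colSums(within[pp$samples$subject_id == s, ]))), 1e-10)
  }
  # reconstruction: within + broadcast subject means equals the input
  rec <- within + between[pp$samples$subject_id, ]
  expect_equal(rec, pp$values, tolerance = 1e-12, ignore_attr = TRUE)

  # constant subject offset moves only the between part
  shifted <- pp
  rows <- shifted$samples$subject_id == "S01"
  shifted$values[rows, ] <- shifted$values[rows, ] + 5
  expect_equal(multilevel_split(shifted, "within"), within, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(multilevel_split(shifted, "between"), between)))

  # zero within-subject variation yields an all-zero within part
  flat <- pp
  flat$values <- between[flat$samples$subject_id, ]
  rownames(flat$values) <- flat$samples$sample_id
  expect_lt(max(abs(multilevel_split(flat, "within"))), 1e-12)

  solo <- filter_samples(pp, !(.data$subject_id == "S01" &
                                 .data$sample_id != "S01_alcohol_t0"))
  expect_error(multilevel_split(solo, "within"), class = "uromet_design_error")
})
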