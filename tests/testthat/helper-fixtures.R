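# Small in-code fixtures and independent oracles shared across tests.

# minimal complete profile: n subjects x 5 times x 2 arms, lognormal values
toy_profile <- function(n_subjects = 3, n_metabolites = 4, seed = 42,
                        creatinine = NULL) {
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  grid <- expand.grid(subject_id = subjects,
                      intervention = c("vehicle", "alcohol"),
                      time_h = 0:4, stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$intervention, grid$time_h), ]
  n <- nrow(grid)
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%s_t%d", grid$subject_id, grid$intervention, grid$time_h),
    subject_id = grid$subject_id,
    intervention = grid$intervention,
    time_h = grid$time_h,
    role = "experimental",
    batch_id = grid$subject_id,
    injection_order = stats::ave(seq_len(n), grid$subject_id, FUN = seq_along),
    creatinine = creatinine %||% stats::rlnorm(n, log(10), 0.3)
  )
  values <- matrix(stats::rlnorm(n * n_metabolites, log(5), 0.5),
                   nrow = n,
                   dimnames = list(samples$sample_id,
                                   sprintf("met_%02d", seq_len(n_metabolites))))
  metab_profile(samples, values, require_complete = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# eigendecomposition-of-covariance PCA oracle (independent of svd route)
oracle_pca_eigen <- function(X) {
  n <- nrow(X)
  C <- crossprod(X) / 1 # X assumed centered; raw scatter matrix
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-12
  list(explained = eig$values[keep] / sum(eig$values[eig$values > 0]),
       loadings = eig$vectors[, keep, drop = FALSE])
}

# brute-force two-sided exact signed-rank p by enumerating all 2^n signs
oracle_wsr_enum <- function(x_ref, x_cmp) {
  d <- x_cmp - x_ref
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lower <- mean(w_all <= w_obs)
  p_upper <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lower, p_upper))
}

# naive O(n^2)-style Spearman: Pearson correlation of mid-ranks
oracle_spearman <- function(v) {
  R <- apply(v, 2, rank)
  p <- ncol(v)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- R[, i] - mean(R[, i]); xj <- R[, j] - mean(R[, j])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# spreadsheet-style VIP evaluation from raw weights and per-component SSY
oracle_vip <- function(W, ssy) {
  p <- nrow(W)
  vip <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(ncol(W))) {
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    }
    vip[j] <- sqrt(p * acc / sum(ssy))
  }
  vip
}

# random column-centered matrix of a given size
random_centered <- function(n, p, seed) {
  set.seed(seed)
  scale(matrix(stats::rnorm(n * p), n, p,
               dimnames = list(paste0("s", 1:n), paste0("v", 1:p))),
        center = TRUE, scale = FALSE)[, , drop = FALSE]
}
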