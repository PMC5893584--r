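#' ANOVA-simultaneous component analysis
#'
#' ASCA partitions a column-centered data matrix by the design factors of the
#' study — here time and participant — exactly as an ANOVA partitions
#' variation, and then summarizes each effect matrix by simultaneous
#' component analysis (PCA of the effect matrix). The decomposition is
#' additive: centered data = sum of effect matrices + residual. For a
#' balanced design the effect matrices of different factors are mutually
#' orthogonal and the total sum of squares splits exactly into per-factor and
#' residual sums of squares.
#'
#' @param X Column-centered matrix (samples x variables).
#' @param factors Data frame / tibble with one row per sample and one column
#'   per design factor (e.g. `time`, `subject`).
#' @return An `asca_decomposition`: list with `grand_mean`, `effects` (named
#'   list of effect matrices), `residual`, `ssq` (named vector incl.
#'   `residual` and `total`), and `balanced` (logical).
#' @export
asca_decompose <- function(X, factors) {
  X <- as.matrix(X)
  factors <- as.data.frame(factors)
  if (nrow(factors) != nrow(X)) {
    stop_uromet("factors must have one row per sample",
                class = "uromet_validation_error")
  }
  if (anyNA(factors)) {
    stop_uromet("every sample must carry a level for every factor",
                class = "uromet_validation_error")
  }
  grand <- colMeans(X)
  Xc <- sweep(X, 2, grand, `-`)
  effects <- list()
  balanced <- TRUE
  for (f in names(factors)) {
    lev <- factor(factors[[f]])
    if (any(table(lev) == 0)) {
      stop_uromet(sprintf("factor '%s' has an empty level", f),
                  class = "uromet_design_error")
    }
    counts <- table(lev)
    if (length(unique(counts)) > 1) balanced <- FALSE
    lmeans <- apply(Xc, 2, function(col) tapply(col, lev, mean))
    lmeans <- matrix(lmeans, nrow = nlevels(lev),
                     dimnames = list(levels(lev), colnames(X)))
    eff <- lmeans[as.integer(lev), , drop = FALSE]
    rownames(eff) <- rownames(X)
    effects[[f]] <- eff
  }
  # cross-balance: all factor-level combinations equally replicated
  if (ncol(factors) > 1) {
    cross <- table(factors)
    if (length(unique(as.vector(cross))) > 1) balanced <- FALSE
  }
  residual <- Xc - Reduce(`+`, effects)
  ssq_vec <- vapply(effects, ssq, numeric(1))
  out <- list(
    grand_mean = grand,
    effects = effects,
    residual = residual,
    ssq = c(ssq_vec, residual = ssq(residual), total = ssq(Xc)),
    balanced = balanced,
    factors = factors
  )
  class(out) <- "asca_decomposition"
  if (!balanced) {
    rlang::warn("unbalanced design: effect matrices need not be orthogonal")
  }
  out
}

#' @export
print.asca_decomposition <- function(x, ...) {
  cat("<asca_decomposition>\n")
  tot <- x$ssq[["total"]]
  for (nm in names(x$ssq)) {
    if (nm == "total") next
    cat(sprintf("  %-10s ssq = %.4g (%.1f%%)\n", nm, x$ssq[[nm]],
                100 * x$ssq[[nm]] / tot))
  }
  cat("  balanced:", x$balanced, "\n")
  invisible(x)
}

#' Simultaneous component analysis of one ASCA effect
#'
#' PCA of a factor's effect matrix. The effect matrix is constant within a
#' factor level, so its rank is at most (levels - 1) and the model scores
#' place every sample at its level centroid. Confidence ellipsoids for the
#' centroids are chi-square contours of the centroid's estimated covariance:
#' the within-level scatter of the residual-augmented scores divided by the
#' level's sample count. Optionally (`augment = TRUE`) the returned scores
#' themselves are the residual-augmented projections.
#'
#' @param decomp An `asca_decomposition`.
#' @param factor Factor name present in the decomposition.
#' @param k Number of components (at most levels - 1).
#' @param level Confidence level for the centroid ellipsoids.
#' @param augment Return residual-augmented scores instead of pure effect
#'   scores.
#' @return List with `model` (a `latent_model`), `centroids` (tibble: level,
#'   per-component coordinates, ellipse semi-axes `ellipse_a`, `ellipse_b`
#'   and `ellipse_angle` for the first two components) and
#'   `augmented_scores`.
#' @export
asca_sca <- function(decomp, factor, k = 2, level = 0.95, augment = FALSE) {
  if (!factor %in% names(decomp$effects)) {
    stop_uromet(sprintf("factor '%s' not in decomposition", factor),
                class = "uromet_validation_error")
  }
  eff <- decomp$effects[[factor]]
  lev <- factor(decomp$factors[[factor]])
  max_k <- nlevels(lev) - 1
  if (k > max_k) {
    stop_uromet(
      sprintf("k = %d exceeds the effect-matrix rank bound %d (levels - 1)", k, max_k),
      class = "uromet_rank_error"
    )
  }
  model <- fit_pca(eff, k = k)
  aug <- (eff + decomp$residual) %*% model$loadings
  cents <- list()
  for (l in levels(lev)) {
    rows <- lev == l
    cent <- colMeans(model$scores[rows, , drop = FALSE])
    ell <- list(a = NA_real_, b = NA_real_, angle = NA_real_)
    if (k >= 2 && sum(rows) >= 3) {
      sigma <- stats::cov(aug[rows, 1:2, drop = FALSE]) / sum(rows)
      ell <- ellipse_params(sigma, level)
    }
    cents[[l]] <- tibble::tibble(
      level = l,
      !!!stats::setNames(as.list(cent), colnames(model$scores)),
      ellipse_a = ell$a, ellipse_b = ell$b, ellipse_angle = ell$angle
    )
  }
  if (augment) model$scores <- aug
  list(model = model, centroids = dplyr::bind_rows(cents), augmented_scores = aug)
}

#' Permutation test for an ASCA factor effect
#'
#' Tests the factor's sum of squares against a null built by permuting the
#' tested factor's labels within the levels of the other factor(s), which
#' respects the nesting of time within subject: time labels are shuffled
#' within each subject, so exchangeability is honest for the repeated-
#' measures design. p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param X Column-centered matrix.
#' @param factors Data frame of design factors (as in [asca_decompose()]).
#' @param factor Name of the factor to test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for reproducibility.
#' @return List with `p_value`, `observed` ssq, and the `null` ssq vector.
#' @export
asca_permutation_test <- function(X, factors, factor, n_perm = 199, seed = 1) {
  if (n_perm < 99) {
    stop_uromet("n_perm must be at least 99", class = "uromet_validation_error")
  }
  factors <- as.data.frame(factors)
  observed <- suppressWarnings(asca_decompose(X, factors))$ssq[[factor]]
  others <- setdiff(names(factors), factor)
  strata <- if (length(others) == 0) {
    rep("all", nrow(factors))
  } else {
    interaction(factors[others], drop = TRUE)
  }
  set.seed(seed)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- factors
    idx <- seq_len(nrow(factors))
    for (s in unique(strata)) {
      rows <- which(strata == s)
      idx[rows] <- rows[sample.int(length(rows))]
    }
    perm[[factor]] <- factors[[factor]][idx]
    null[i] <- suppressWarnings(asca_decompose(X, perm))$ssq[[factor]]
  }
  list(
    p_value = (1 + sum(null >= observed)) / (n_perm + 1),
    observed = observed,
    null = null
  )
}

#' Write ASCA effect sums of squares as TSV
#'
#' @param decomp An `asca_decomposition`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_asca_ssq <- function(decomp, path) {
  tot <- decomp$ssq[["total"]]
  nm <- setdiff(names(decomp$ssq), "total")
  readr::write_tsv(
    tibble::tibble(factor = nm, ssq = unname(decomp$ssq[nm]),
                   fraction = unname(decomp$ssq[nm]) / tot),
    path, progress = FALSE
  )
  invisible(path)
}
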