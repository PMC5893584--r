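#' Latent-variable models: PCA and two-class PLS-DA
#'
#' Both fits return a `latent_model`: a list with `kind` (`"pca"` or
#' `"plsda"`), `n_components`, `scores` (samples x components), `loadings`
#' (variables x components), `explained` (fraction of X variation per
#' component) and, for PLS-DA, `weights`, `explained_y` (fraction of response
#' variation per component), `vip` and `class_labels`. Component signs are
#' fixed so the largest-magnitude loading entry of each component is
#' positive, making runs bit-reproducible.
#'
#' @name latent_model
NULL

new_latent_model <- function(kind, scores, loadings, explained, ...) {
  structure(
    c(list(kind = kind, n_components = ncol(scores), scores = scores,
           loadings = loadings, explained = explained), list(...)),
    class = "latent_model"
  )
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model:%s> %d components, %d samples x %d variables\n",
              x$kind, x$n_components, nrow(x$scores), nrow(x$loadings)))
  cat("  explained X:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "), "\n")
  if (!is.null(x$explained_y)) {
    cat("  explained Y:", paste(sprintf("%.1f%%", 100 * x$explained_y), collapse = " "), "\n")
  }
  invisible(x)
}

#' Principal component analysis of a centered matrix
#'
#' Thin SVD of the (already column-centered) preprocessed matrix. Scores are
#' `X %*% loadings`; explained fractions are squared singular values over the
#' total sum of squares, so they sum to 1 over all attainable components.
#'
#' @param X Column-centered numeric matrix (samples x variables).
#' @param k Number of components; must not exceed the matrix rank.
#' @return A `latent_model` of kind `"pca"`.
#' @export
fit_pca <- function(X, k = 2) {
  X <- as.matrix(X)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (k > rank) {
    stop_uromet(sprintf("k = %d exceeds the attainable rank %d", k, rank),
                class = "uromet_rank_error")
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  fixed <- fix_signs(loadings)
  loadings <- fixed$loadings
  scores <- X %*% loadings
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(loadings)
  explained <- (sv$d[seq_len(k)]^2) / sum(sv$d^2)
  new_latent_model("pca", scores, loadings, explained,
                   singular_values = sv$d[seq_len(k)], rank = rank)
}

#' Two-class PLS-DA by NIPALS
#'
#' NIPALS partial least squares on a centered 0/1 indicator response (the
#' chemometrics reference algorithm for discriminant analysis between two
#' groups). Per component the weight vector maximizes covariance between the
#' X scores and the centered class indicator; X and y are deflated by the
#' extracted component. The response variance explained per component
#' (`explained_y`) feeds the VIP computation.
#'
#' @param X Preprocessed (centered) matrix, samples x variables.
#' @param y Two-class labels (factor, character or any two-valued vector),
#'   each class with at least 2 samples.
#' @param k Number of components.
#' @return A `latent_model` of kind `"plsda"` with `vip` filled in.
#' @export
fit_plsda <- function(X, y, k = 2) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) {
    stop_uromet("PLS-DA requires exactly two classes in y",
                class = "uromet_class_error")
  }
  if (any(table(y) < 2)) {
    stop_uromet("each class needs at least 2 samples",
                class = "uromet_class_error")
  }
  rank <- qr(scale(X, center = TRUE, scale = FALSE))$rank
  if (k > rank) {
    stop_uromet(sprintf("k = %d exceeds the attainable rank %d", k, rank),
                class = "uromet_rank_error")
  }
  y01 <- as.numeric(y == levels(y)[2])
  yc <- y01 - mean(y01)
  ssy_total <- ssq(yc)
  n <- nrow(X); p <- ncol(X)
  ssx_total <- ssq(X)
  Xd <- X; yd <- yc
  W <- P <- matrix(0, p, k)
  Tm <- matrix(0, n, k)
  qv <- numeric(k)
  ssy <- ssx <- numeric(k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop_uromet(sprintf("no response covariance left at component %d", a),
                  class = "uromet_rank_error")
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; qv[a] <- q_a
    ssy[a] <- q_a^2 * tt
    ssx[a] <- tt * sum(p_a^2)
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("LV", seq_len(k)))
  dimnames(Tm) <- list(rownames(X), paste0("LV", seq_len(k)))
  fixed <- fix_signs(P, weights = W, scores = Tm)
  qv <- qv * fixed$flips
  model <- new_latent_model(
    "plsda", fixed$scores, fixed$loadings, ssx / ssx_total,
    weights = fixed$weights, y_loadings = qv,
    explained_y = ssy / ssy_total, class_labels = y, rank = rank
  )
  model$vip <- compute_vip(model)
  model
}

#' Variable importance in projection
#'
#' The standard weight-based VIP: for variable j over components a,
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a SSY_a}}
#' with p the number of variables and SSY_a the response variance explained
#' by component a. VIPs are normalized so the mean of VIP^2 equals 1;
#' variables with VIP >= 1 contribute more than an average variable.
#'
#' @param model A fitted `latent_model` of kind `"plsda"`.
#' @return Named numeric vector of VIP scores.
#' @export
compute_vip <- function(model) {
  if (model$kind != "plsda") {
    stop_uromet("VIP is defined for PLS-DA models", class = "uromet_class_error")
  }
  ssy <- model$explained_y
  if (sum(ssy) <= 0) {
    stop_uromet("degenerate model: zero explained response variance",
                class = "uromet_degenerate_error")
  }
  W <- model$weights
  p <- nrow(W)
  wnorm2 <- sweep(W^2, 2, colSums(W^2), `/`)
  vip <- sqrt(p * drop(wnorm2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(W)
  vip
}

#' Split repeated measures into within- and between-subject parts
#'
#' Multilevel decomposition for paired designs: the between part is each
#' subject's mean profile; the within part is each sample minus its subject's
#' mean. Within + broadcast subject means reconstructs the input exactly, so
#' latent fits on either part analyse complementary variation (the within
#' part is what a paired analysis should see).
#'
#' @param x A preprocessed `metab_profile`, or a matrix with `subjects` given.
#' @param scope `"within"` or `"between"`.
#' @param subjects Subject id per row (required when `x` is a matrix).
#' @return For `"within"`, a matrix of the same shape as the input; for
#'   `"between"`, one row per subject (rownames = subject id).
#' @export
multilevel_split <- function(x, scope = c("within", "between"), subjects = NULL) {
  scope <- match.arg(scope)
  if (inherits(x, "metab_profile")) {
    subjects <- x$samples$subject_id
    X <- x$values
  } else {
    X <- as.matrix(x)
    if (is.null(subjects)) {
      stop_uromet("subjects must be supplied with a bare matrix",
                  class = "uromet_validation_error")
    }
  }
  counts <- table(subjects)
  solo <- names(counts)[counts < 2]
  if (length(solo) > 0) {
    stop_uromet(paste0("subject(s) with a single sample: ",
                       paste(solo, collapse = ", ")),
                class = "uromet_design_error")
  }
  subj <- factor(subjects)
  means <- apply(X, 2, function(col) tapply(col, subj, mean))
  if (scope == "between") {
    means <- as.matrix(means)
    rownames(means) <- levels(subj)
    return(means)
  }
  X - means[as.integer(subj), , drop = FALSE]
}

#' Export a latent model as a TSV bundle
#'
#' Writes `scores.tsv`, `loadings.tsv`, `explained.tsv` and, for PLS-DA,
#' `vip.tsv` into a directory, keyed by sample id / metabolite name.
#'
#' @param model A `latent_model`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix.
#' @return The directory, invisibly.
#' @export
write_latent_model <- function(model, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- function(name) file.path(dir, paste0(prefix, name))
  scores <- tibble::as_tibble(model$scores)
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(model$scores)), scores)
  readr::write_tsv(scores, fn("scores.tsv"), progress = FALSE)
  loadings <- tibble::as_tibble(model$loadings)
  loadings <- dplyr::bind_cols(tibble::tibble(metabolite = rownames(model$loadings)), loadings)
  readr::write_tsv(loadings, fn("loadings.tsv"), progress = FALSE)
  expl <- tibble::tibble(component = seq_along(model$explained),
                         explained_x = model$explained)
  if (!is.null(model$explained_y)) expl$explained_y <- model$explained_y
  readr::write_tsv(expl, fn("explained.tsv"), progress = FALSE)
  if (!is.null(model$vip)) {
    readr::write_tsv(tibble::tibble(metabolite = names(model$vip), vip = model$vip),
                     fn("vip.tsv"), progress = FALSE)
  }
  invisible(dir)
}
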