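#' Unfold a cases x time x metabolite tensor into a matrix
#'
#' Batch-wise unfolding for repeated measures: one row per case (subject
#' within the chosen intervention arm) and one column per (metabolite, time)
#' pair, ordered lexicographically by metabolite then time. Each time's
#' columns form a block (`block_index`), so a case's row concatenates its
#' five hourly sub-profiles into a single longitudinal profile that PCA can
#' treat as one observation.
#'
#' @param x A preprocessed `metab_profile` (values already transformed per
#'   metabolite across samples).
#' @param intervention Arm to unfold (`"alcohol"` by default), or `NULL` to
#'   unfold subject-arm combinations jointly as cases.
#' @return An `unfolded_matrix`: numeric matrix with attributes `metabolites`,
#'   `times`, `cases` and `block_index` (named list time -> column indices).
#' @export
unfold <- function(x, intervention = "alcohol") {
  s <- x$samples
  keep <- s$role == "experimental"
  if (!is.null(intervention)) keep <- keep & s$intervention == intervention
  s <- s[keep, ]
  v <- x$values[keep, , drop = FALSE]
  case <- if (is.null(intervention)) {
    paste(s$subject_id, s$intervention, sep = ":")
  } else {
    s$subject_id
  }
  cases <- sort(unique(case))
  times <- sort(unique(s$time_h))
  mets <- colnames(v)
  U <- matrix(NA_real_, nrow = length(cases), ncol = length(mets) * length(times),
              dimnames = list(cases, paste(rep(mets, each = length(times)),
                                           rep(times, times = length(mets)),
                                           sep = "@")))
  for (i in seq_len(nrow(v))) {
    r <- match(case[i], cases)
    cols <- match(paste(mets, s$time_h[i], sep = "@"), colnames(U))
    U[r, cols] <- v[i, ]
  }
  if (anyNA(U)) {
    gap <- which(is.na(U), arr.ind = TRUE)[1, ]
    stop_uromet(
      sprintf("missing (case, time) cell: case '%s', column '%s'",
              cases[gap[1]], colnames(U)[gap[2]]),
      class = "uromet_design_error"
    )
  }
  col_time <- as.integer(sub(".*@", "", colnames(U)))
  block_index <- lapply(stats::setNames(times, paste0("t", times)),
                        function(t) which(col_time == t))
  structure(U, metabolites = mets, times = times, cases = cases,
            block_index = block_index, class = c("unfolded_matrix", "matrix", "array"))
}

#' Refold an unfolded matrix back to long (case, time) x metabolite form
#'
#' Inverse of [unfold()] up to row order: returns a matrix with one row per
#' (case, time) and one column per metabolite.
#'
#' @param U An `unfolded_matrix`.
#' @return Matrix with rownames `case@time`.
#' @export
refold <- function(U) {
  mets <- attr(U, "metabolites")
  times <- attr(U, "times")
  cases <- attr(U, "cases")
  out <- matrix(NA_real_, nrow = length(cases) * length(times), ncol = length(mets),
                dimnames = list(paste(rep(cases, each = length(times)),
                                      rep(times, times = length(cases)), sep = "@"),
                                mets))
  for (ci in seq_along(cases)) {
    for (ti in seq_along(times)) {
      cols <- match(paste(mets, times[ti], sep = "@"), colnames(U))
      out[(ci - 1) * length(times) + ti, ] <- U[ci, cols]
    }
  }
  out
}

#' PCA of the unfolded matrix with per-time trajectories
#'
#' Fits PCA to the column-centered unfolded matrix, so model scores describe
#' between-case variation (all zero when cases are identical). The per-time
#' point of a case is its block score: the projection of the case's time-t
#' sub-profile onto the time-t block of the loadings. Block scores are
#' computed from the uncentered (per-metabolite preprocessed) values, so the
#' per-time centroid — the mean of the case points at that time — carries the
#' time effect, while the scatter around it carries the inter-individual
#' variation. The centered block scores of a case sum exactly to its model
#' score over the time blocks (block-score additivity).
#'
#' @param U An `unfolded_matrix`.
#' @param k Number of components (default 2).
#' @param level Confidence level of the per-time ellipsoids (default 0.90).
#' @return List with `model` (a `latent_model`), `trajectories` (tibble:
#'   case, time_h, one column per component), `centroids` (tibble: time_h,
#'   component coordinates, `ellipse_a`, `ellipse_b`, `ellipse_angle`), and
#'   `block_scores` (centered block scores, cases x times x components).
#' @export
unfolded_pca_trajectories <- function(U, k = 2, level = 0.90) {
  mu <- colMeans(U)
  Uc <- sweep(U, 2, mu, `-`)
  model <- fit_pca(Uc, k = k)
  blocks <- attr(U, "block_index")
  times <- attr(U, "times")
  cases <- attr(U, "cases")
  n_t <- length(times)
  bs <- array(0, dim = c(length(cases), n_t, k),
              dimnames = list(cases, paste0("t", times), colnames(model$scores)))
  offs <- matrix(0, n_t, k, dimnames = list(paste0("t", times), colnames(model$scores)))
  for (ti in seq_len(n_t)) {
    cols <- blocks[[ti]]
    bs[, ti, ] <- Uc[, cols, drop = FALSE] %*% model$loadings[cols, , drop = FALSE]
    offs[ti, ] <- drop(mu[cols] %*% model$loadings[cols, , drop = FALSE])
  }
  traj <- list()
  cents <- list()
  for (ti in seq_len(n_t)) {
    pts <- sweep(matrix(bs[, ti, ], ncol = k), 2, offs[ti, ], `+`)
    colnames(pts) <- colnames(model$scores)
    traj[[ti]] <- dplyr::bind_cols(
      tibble::tibble(case = cases, time_h = times[ti]),
      tibble::as_tibble(pts)
    )
    ell <- list(a = NA_real_, b = NA_real_, angle = NA_real_)
    if (k >= 2 && nrow(pts) >= 3) {
      ell <- ellipse_params(stats::cov(pts[, 1:2, drop = FALSE]), level)
    }
    cents[[ti]] <- dplyr::bind_cols(
      tibble::tibble(time_h = times[ti]),
      tibble::as_tibble(t(colMeans(pts))),
      tibble::tibble(ellipse_a = ell$a, ellipse_b = ell$b, ellipse_angle = ell$angle)
    )
  }
  trajectories <- dplyr::arrange(dplyr::bind_rows(traj), .data$case, .data$time_h)
  list(model = model, trajectories = trajectories,
       centroids = dplyr::bind_rows(cents), block_scores = bs)
}

#' Rank metabolites by squared loadings on the first two components
#'
#' Bi-plot ranking: metabolites are ordered by the sum of squared loadings on
#' components 1 and 2, descending, ties broken lexicographically by name.
#' For an unfolded model, `time_block` restricts the loadings to one time's
#' column block so the ranking is time-resolved.
#'
#' @param model A `latent_model` with at least 2 components.
#' @param top_k How many metabolites to return (default 7).
#' @param time_block Optional time (hour) selecting one block of an unfolded
#'   model's loadings; requires `U` to map columns to blocks.
#' @param U The `unfolded_matrix` the model was fitted to (needed with
#'   `time_block`).
#' @return Tibble with `metabolite`, `rank`, `ss_loadings`, `l1`, `l2`.
#' @export
biplot_rank <- function(model, top_k = 7, time_block = NULL, U = NULL) {
  if (model$n_components < 2) {
    stop_uromet("bi-plot ranking needs at least 2 components",
                class = "uromet_rank_error")
  }
  L <- model$loadings[, 1:2, drop = FALSE]
  if (!is.null(time_block)) {
    if (is.null(U)) {
      stop_uromet("U is required for a time-resolved ranking",
                  class = "uromet_validation_error")
    }
    cols <- attr(U, "block_index")[[paste0("t", time_block)]]
    L <- L[cols, , drop = FALSE]
    rownames(L) <- attr(U, "metabolites")
  }
  ss <- L[, 1]^2 + L[, 2]^2
  ord <- order(-ss, rownames(L))
  n <- length(ss)
  if (top_k > n) {
    rlang::warn(sprintf("top_k = %d exceeds the %d available metabolites; truncating",
                        top_k, n))
    top_k <- n
  }
  sel <- ord[seq_len(top_k)]
  tibble::tibble(
    metabolite = rownames(L)[sel],
    rank = seq_len(top_k),
    ss_loadings = unname(ss[sel]),
    l1 = unname(L[sel, 1]),
    l2 = unname(L[sel, 2])
  )
}

#' Write trajectory, centroid and bi-plot TSVs
#'
#' @param fit Result of [unfolded_pca_trajectories()].
#' @param dir Output directory.
#' @param U The fitted `unfolded_matrix` (for bi-plot rankings per time).
#' @param top_k Metabolites per bi-plot ranking.
#' @return `dir`, invisibly.
#' @export
write_unfolded_outputs <- function(fit, dir, U = NULL, top_k = 7) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(fit$trajectories, file.path(dir, "trajectories.tsv"), progress = FALSE)
  readr::write_tsv(fit$centroids, file.path(dir, "centroids.tsv"), progress = FALSE)
  if (!is.null(U)) {
    ranks <- lapply(attr(U, "times"), function(t) {
      dplyr::mutate(biplot_rank(fit$model, top_k = top_k, time_block = t, U = U),
                    time_h = t, .before = 1)
    })
    readr::write_tsv(dplyr::bind_rows(ranks), file.path(dir, "biplot.tsv"), progress = FALSE)
  }
  invisible(dir)
}
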