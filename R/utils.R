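#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor pt qt sd var qchisq rnorm rlnorm runif median
#' @importFrom utils head
NULL

stop_uromet <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "uromet_error"), ...)
}

# 95%/90% contour of a 2x2 covariance in score space:
# semi-axes sqrt(qchisq(level, 2) * eigenvalues), angle of the major axis.
ellipse_params <- function(sigma, level) {
  stopifnot(nrow(sigma) == 2, ncol(sigma) == 2)
  eig <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  r <- sqrt(qchisq(level, df = 2) * lam)
  ang <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  list(a = r[1], b = r[2], angle = ang)
}

# fix component signs so the largest-magnitude loading entry is positive
fix_signs <- function(loadings, ...) {
  flips <- apply(loadings, 2, function(v) {
    i <- which.max(abs(v))
    if (v[i] < 0) -1 else 1
  })
  out <- list(loadings = sweep(loadings, 2, flips, `*`))
  extra <- list(...)
  for (nm in names(extra)) {
    out[[nm]] <- if (is.null(extra[[nm]])) NULL else sweep(extra[[nm]], 2, flips, `*`)
  }
  out$flips <- flips
  out
}

ssq <- function(x) sum(x^2)
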