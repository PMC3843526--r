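#' Standardize descriptor columns
#'
#' Column-wise z-scoring with the sample standard deviation (n - 1
#' denominator).  When `params` is `NULL` the mean and SD are estimated
#' from `x` (the training rows); otherwise the stored parameters are
#' applied, so test rows are scaled exactly as the training set was.
#' Zero-variance columns are retained and map to 0, keeping bin labels
#' stable across randomization cycles.
#'
#' @param x numeric matrix (rows = compounds, columns = bins).
#' @param params optional list with `center`, `scale`, `zero_var` as
#'   returned in the `params` element of a previous fit.
#' @return list with `x` (standardized matrix) and `params`.
#' @export
standardize <- function(x, params = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(params)) {
    if (nrow(x) < 2) stopf("standardization needs at least 2 rows")
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero_var <- !is.finite(scale) | scale <= 0
    scale[zero_var] <- 1
    params <- list(center = center, scale = scale, zero_var = zero_var)
  } else {
    if (ncol(x) != length(params$center))
      stopf("column count does not match standardization params")
  }
  z <- sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
  if (any(params$zero_var)) z[, params$zero_var] <- 0
  list(x = z, params = params)
}

#' Fit a SIMPLS partial least squares model
#'
#' Implements the SIMPLS algorithm for a univariate response: the
#' cross-product vector `s = X'y` is deflated directly through an
#' orthonormal basis of the loading space, producing mutually orthogonal
#' scores, per-LV weight (projection) vectors and cumulative regression
#' coefficients.  Descriptors are standardized internally (see
#' [standardize()]); the response is centered but not scaled.  The fit is
#' fully deterministic.
#'
#' If `n_lv` exceeds `min(nrow(x) - 1, ncol(x))` or the residual
#' cross-product vanishes earlier, the number of components is truncated
#' with a warning.
#'
#' @param x occupancy rows (numeric matrix; colnames are bin labels).
#' @param y activities, one per row of `x`.
#' @param n_lv requested number of latent variables (>= 1).
#' @param scale standardize the columns of `x` (default `TRUE`, matching
#'   the canonical workflow; raw centering only if `FALSE`).
#' @return an object of class `sdar_pls` with elements `n_lv` (components
#'   actually fitted), `coefficients` (per-bin, on the standardized
#'   scale), `weights` (bins x LV matrix of unit-norm x-weight vectors),
#'   `scores`, `loadings`, `params` (standardization), `y_mean`,
#'   `bin_labels`.
#' @export
simpls_fit <- function(x, y, n_lv, scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("rows of 'x' must match length of 'y'")
  if (!is_count(n_lv) || n_lv < 1) stopf("'n_lv' must be an integer >= 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  m <- nrow(x); n <- ncol(x)
  if (scale) {
    std <- standardize(x)
  } else {
    cm <- colMeans(x)
    std <- list(x = sweep(x, 2, cm, "-"),
                params = list(center = cm, scale = rep(1, n),
                              zero_var = rep(FALSE, n)))
  }
  X <- std$x
  y_mean <- mean(y)
  yc <- y - y_mean

  a_max <- min(m - 1L, n)
  if (n_lv > a_max) {
    warning(sprintf("n_lv = %d exceeds min(m - 1, n) = %d; truncated",
                    n_lv, a_max))
    n_lv <- a_max
  }

  R <- matrix(0, n, n_lv)            # projection weights (scores = X R)
  W <- matrix(0, n, n_lv)            # unit-norm weight vectors, per LV
  P <- matrix(0, n, n_lv)            # x-loadings
  Tt <- matrix(0, m, n_lv)           # orthonormal scores
  V <- matrix(0, n, n_lv)            # orthonormal basis for deflation
  q <- numeric(n_lv)                 # y-loadings
  tol <- .Machine$double.eps^0.5 * max(1, sqrt(sum((crossprod(X, yc))^2)))

  s <- crossprod(X, yc)
  a <- 0L
  for (comp in seq_len(n_lv)) {
    if (sqrt(sum(s^2)) < tol) break
    r <- s
    t <- X %*% r
    t <- t - mean(t)
    normt <- sqrt(sum(t^2))
    if (normt < .Machine$double.eps^0.5) break
    t <- t / normt
    r <- r / normt
    p <- crossprod(X, t)
    v <- p
    if (a > 0) {
      Va <- V[, seq_len(a), drop = FALSE]
      v <- v - Va %*% crossprod(Va, p)
    }
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps^0.5) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    a <- a + 1L
    R[, a] <- r
    W[, a] <- r / sqrt(sum(r^2))
    P[, a] <- p
    V[, a] <- v
    Tt[, a] <- t
    q[a] <- crossprod(yc, t)
  }
  if (a == 0L) {
    # X carries no covariance with y (e.g. constant response): null model
    a <- 0L
    coefs <- matrix(0, n, 1)
  } else {
    if (a < n_lv)
      warning(sprintf("rank exhausted after %d of %d components", a, n_lv))
    coefs <- R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
  }
  keep <- seq_len(max(a, 1L))
  structure(
    list(n_lv = a,
         coefficients = structure(as.numeric(coefs), names = colnames(x)),
         weights = structure(W[, seq_len(max(a, 0L)), drop = FALSE],
                             dimnames = list(colnames(x), NULL)),
         scores = Tt[, seq_len(max(a, 0L)), drop = FALSE],
         loadings = structure(P[, seq_len(max(a, 0L)), drop = FALSE],
                              dimnames = list(colnames(x), NULL)),
         y_loadings = q[seq_len(max(a, 0L))],
         params = std$params, scaled = scale,
         y_mean = y_mean, bin_labels = colnames(x)),
    class = "sdar_pls")
}

#' @export
print.sdar_pls <- function(x, ...) {
  cat(sprintf("<sdar_pls> %d LVs over %d bins\n",
              x$n_lv, length(x$bin_labels)))
  invisible(x)
}

#' Predict activities from a fitted PLS model
#'
#' New rows are aligned to the training bin labels: bins unseen in
#' training are dropped, training bins missing from `x_new` are imputed as
#' zero occupancy.  The stored standardization is applied, the regression
#' coefficients evaluated, and the training activity mean added back.
#'
#' @param model an `sdar_pls` fit.
#' @param x_new occupancy rows (matrix or vector; colnames = bin labels).
#' @return numeric vector of predicted activities.
#' @export
pls_predict <- function(model, x_new) {
  if (!inherits(model, "sdar_pls")) stopf("'model' must be an sdar_pls")
  x_new <- align_bins(x_new, model$bin_labels)
  z <- standardize(x_new, model$params)$x
  as.numeric(z %*% model$coefficients) + model$y_mean
}

#' @export
predict.sdar_pls <- function(object, newdata, ...) pls_predict(object, newdata)

# Align occupancy rows to a reference bin label set: drop unseen bins,
# zero-fill missing ones.  Errors when no bins overlap.
align_bins <- function(x_new, bin_labels) {
  if (is.null(dim(x_new))) {
    x_new <- matrix(x_new, nrow = 1,
                    dimnames = list(NULL, names(x_new)))
  }
  x_new <- as.matrix(x_new)
  if (is.null(colnames(x_new)))
    stopf("new occupancy rows must carry bin labels as column names")
  common <- intersect(bin_labels, colnames(x_new))
  if (length(common) == 0)
    stopf("no overlap between new bins and training bins")
  out <- matrix(0, nrow(x_new), length(bin_labels),
                dimnames = list(rownames(x_new), bin_labels))
  out[, common] <- x_new[, common, drop = FALSE]
  out
}

#' Extract the per-LV weight vector of a PLS model
#'
#' Returns the `lv`-th SIMPLS x-weight vector (unit norm), labeled by bin.
#' These per-LV weights - not loadings, not regression coefficients - are
#' what the interpretation stage ranks for the most positive and most
#' negative bins.
#'
#' @param model an `sdar_pls` fit.
#' @param lv component index, `1 <= lv <= model$n_lv`.
#' @return named numeric vector over bins.
#' @export
extract_lv_weights <- function(model, lv) {
  if (!inherits(model, "sdar_pls")) stopf("'model' must be an sdar_pls")
  if (!is_count(lv) || lv < 1 || lv > model$n_lv)
    stopf("'lv' must be in 1..%d", model$n_lv)
  structure(model$weights[, lv], names = model$bin_labels)
}

#' Serialize a PLS model to JSON
#'
#' Self-describing document holding bin labels, coefficients,
#' standardization parameters and the activity mean.
#'
#' @param model an `sdar_pls` fit.
#' @param path file to write.
#' @export
write_pls_model <- function(model, path) {
  doc <- list(
    type = "sdar_pls", n_lv = model$n_lv, scaled = model$scaled,
    y_mean = model$y_mean, bin_labels = model$bin_labels,
    coefficients = as.numeric(model$coefficients),
    weights = unname(apply(model$weights, 2, as.numeric, simplify = FALSE)),
    standardization = list(center = as.numeric(model$params$center),
                           scale = as.numeric(model$params$scale),
                           zero_var = model$params$zero_var))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
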