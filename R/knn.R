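#' Tanimoto similarity of two occupancy vectors
#'
#' Generalized vector form on raw (non-transformed) bin counts:
#' `T = a.b / (||a||^2 + ||b||^2 - a.b)`.  Equals 1 for identical nonzero
#' vectors, 0 for disjoint support, and is scale-sensitive
#' (`T(a, 2a) < 1`).  Standardized descriptors would make T depend on the
#' training subset, so only raw occupancies are accepted.
#'
#' @param a,b non-negative numeric vectors over the same bin label set.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0), c(1, 0, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stopf("occupancy vectors must share the same bin label set")
  if (any(a < 0) || any(b < 0)) stopf("occupancies must be non-negative")
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom <= 0) stopf("Tanimoto similarity undefined: both vectors zero")
  ab / denom
}

#' Pairwise Tanimoto similarity matrix
#'
#' All-pairs similarity of the rows of an occupancy matrix.  Compounds
#' with an all-zero occupancy row are flagged with a warning and every
#' pair involving them is `NA`.
#'
#' @param occ an `sdar_occupancy` or a numeric matrix of occupancy rows.
#' @return symmetric matrix of class `sdar_similarity` with compound ids
#'   as dimnames.
#' @export
similarity_matrix <- function(occ) {
  x <- if (inherits(occ, "sdar_occupancy")) occ$counts else as.matrix(occ)
  if (nrow(x) < 2) stopf("need at least 2 compounds")
  g <- tcrossprod(x)
  sq <- diag(g)
  tm <- g / (outer(sq, sq, "+") - g)
  zero <- sq == 0
  if (any(zero)) {
    warning(sprintf("%d compound(s) with all-zero occupancy: %s",
                    sum(zero), paste(rownames(x)[zero], collapse = ", ")))
    tm[zero, ] <- NA_real_
    tm[, zero] <- NA_real_
  }
  diag(tm)[!zero] <- 1
  class(tm) <- c("sdar_similarity", class(tm))
  tm
}

#' Export a similarity matrix as square CSV
#'
#' @param sim an `sdar_similarity` matrix.
#' @param path file to write.
#' @export
write_similarity <- function(sim, path) {
  out <- data.frame(compound_id = rownames(sim), unclass(sim),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = 1)
  invisible(path)
}

#' Tanimoto-weighted k-nearest-neighbor prediction
#'
#' Training compounds are ranked by descending Tanimoto similarity to the
#' query; the prediction is the similarity-weighted mean activity of the
#' top `k`: `sum(T_i y_i) / sum(T_i)`.  Ties in similarity are broken by
#' training row order (stable), so results are platform-independent.  If
#' all top-`k` similarities are zero the unweighted mean of those `k`
#' neighbors is returned with a warning.  Query bins unseen in training
#' stay in the vector space and lower the similarity through the query's
#' squared magnitude.
#'
#' @param train_occ training occupancy rows (matrix with bin-label
#'   colnames, rows = compounds).
#' @param train_y training activities.
#' @param query_occ one occupancy row (named vector) or a matrix of rows.
#' @param k number of neighbors, `1 <= k <= nrow(train_occ)`; both odd and
#'   even values are meaningful.
#' @return numeric vector of predictions, one per query row.
#' @export
knn_predict <- function(train_occ, train_y, query_occ, k) {
  train_occ <- as.matrix(train_occ)
  train_y <- as.numeric(train_y)
  if (nrow(train_occ) != length(train_y))
    stopf("training rows must match activities")
  if (!is_count(k) || k < 1 || k > nrow(train_occ))
    stopf("'k' must be an integer in 1..%d", nrow(train_occ))
  if (is.null(dim(query_occ)))
    query_occ <- matrix(query_occ, nrow = 1,
                        dimnames = list(NULL, names(query_occ)))
  query_occ <- as.matrix(query_occ)
  if (ncol(query_occ) != ncol(train_occ)) {
    # align by bin label over the union; unseen bins keep their counts
    if (is.null(colnames(query_occ)) || is.null(colnames(train_occ)))
      stopf("bin label alignment requires column names")
    all_bins <- union(colnames(train_occ), colnames(query_occ))
    pad <- function(m) {
      out <- matrix(0, nrow(m), length(all_bins),
                    dimnames = list(rownames(m), all_bins))
      out[, colnames(m)] <- m
      out
    }
    train_occ <- pad(train_occ)
    query_occ <- pad(query_occ)
  }
  ab <- tcrossprod(query_occ, train_occ)          # q x m dot products
  q2 <- rowSums(query_occ^2)
  t2 <- rowSums(train_occ^2)
  denom <- outer(q2, t2, "+") - ab
  if (any(denom <= 0 & !(ab > 0)))
    stopf("Tanimoto similarity undefined: zero query and training vectors")
  tm <- ab / denom
  vapply(seq_len(nrow(query_occ)), function(qi) {
    tv <- tm[qi, ]
    top <- order(-tv, seq_along(tv))[seq_len(k)]   # stable tie-break
    w <- tv[top]
    if (sum(w) <= 0) {
      warning("all top-k similarities are zero; falling back to unweighted mean")
      return(mean(train_y[top]))
    }
    sum(w * train_y[top]) / sum(w)
  }, numeric(1))
}
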