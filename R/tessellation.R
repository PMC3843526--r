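#' Define a regular tessellation grid
#'
#' The 3D-SDAR space is tessellated by a regular rectangular grid anchored
#' at the origin (0 ppm, 0 ppm, 0 A).  Bins are square in the shift plane
#' (`dx = dy`) and half-open on every axis: a value on a bin edge belongs
#' to the upper bin.
#'
#' @param dx bin width on both chemical-shift axes, ppm.
#' @param dz bin height on the distance axis, Angstrom.
#' @return an object of class `sdar_grid`.
#' @examples
#' grid_spec(10, 0.5)
#' @export
grid_spec <- function(dx, dz) {
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stopf("'dx' must be a single positive number (ppm)")
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz) || dz <= 0)
    stopf("'dz' must be a single positive number (Angstrom)")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dx),
                 dz = as.numeric(dz)),
            class = "sdar_grid")
}

#' @export
print.sdar_grid <- function(x, ...) {
  cat(sprintf("<sdar_grid> %s\n", format(x)))
  invisible(x)
}

#' @export
format.sdar_grid <- function(x, ...) {
  sprintf("%g ppm x %g ppm x %g A", x$dx, x$dy, x$dz)
}

#' Enumerate tessellation grids
#'
#' Cartesian product of shift-plane widths and distance heights, ordered by
#' ascending width then ascending height.  The canonical scan, 2-20 ppm in
#' steps of 2 by 0.5-2.5 A in steps of 0.5, yields 50 grids.
#'
#' @param xy_widths positive ppm widths.
#' @param z_heights positive Angstrom heights.
#' @return list of [grid_spec()] objects.
#' @examples
#' length(enumerate_grids(seq(2, 20, 2), seq(0.5, 2.5, 0.5)))  # 50
#' @export
enumerate_grids <- function(xy_widths = seq(2, 20, by = 2),
                            z_heights = seq(0.5, 2.5, by = 0.5)) {
  if (length(xy_widths) == 0 || length(z_heights) == 0)
    stopf("grid ranges must be non-empty")
  if (any(!is.finite(xy_widths)) || any(xy_widths <= 0) ||
      any(!is.finite(z_heights)) || any(z_heights <= 0))
    stopf("grid widths and heights must be positive")
  xy <- sort(as.numeric(xy_widths))
  z <- sort(as.numeric(z_heights))
  out <- vector("list", length(xy) * length(z))
  n <- 0L
  for (w in xy) for (h in z) {
    n <- n + 1L
    out[[n]] <- grid_spec(w, h)
  }
  out
}

#' Bin index of fingerprint elements
#'
#' Maps elements to integer bin triples `(i, j, k)` with
#' `i = floor(shift_x/dx)`, `j = floor(shift_y/dy)`, `k =
#' floor(distance/dz)`; bins are half-open `[edge, edge + width)`.
#'
#' @param shift_x,shift_y shifts in ppm (>= 0); recycled jointly.
#' @param distance distances in Angstrom (> 0).
#' @param grid a [grid_spec()].
#' @return integer matrix with columns `i`, `j`, `k`.
#' @examples
#' bin_index(116.94, 116.94, 5.52, grid_spec(10, 0.5))  # 11 11 11
#' @export
bin_index <- function(shift_x, shift_y, distance, grid) {
  if (!inherits(grid, "sdar_grid")) stopf("'grid' must be an sdar_grid")
  if (any(shift_x < 0) || any(shift_y < 0))
    stopf("shifts must be >= 0 ppm")
  if (any(distance <= 0))
    stopf("distances must be > 0 Angstrom")
  cbind(i = as.integer(floor(shift_x / grid$dx)),
        j = as.integer(floor(shift_y / grid$dy)),
        k = as.integer(floor(distance / grid$dz)))
}

bin_label <- function(idx) {
  paste(idx[, "i"], idx[, "j"], idx[, "k"], sep = "_")
}

#' Build the occupancy matrix of a tessellated fingerprint set
#'
#' Counts, per compound, the number of fingerprint elements falling in each
#' bin of `grid` (coincident symmetric elements count with multiplicity).
#' Columns are restricted to bins occupied by at least one compound and
#' ordered lexicographically by `(i, j, k)`; the bin triple, not a serial
#' number, identifies a column, so bins are comparable across training
#' subsets and grids of equal granularity.
#'
#' @param fp an `sdar_fingerprint` data.frame (possibly many compounds).
#' @param grid a [grid_spec()].
#' @param compound_ids optional character vector fixing row order;
#'   defaults to order of first appearance in `fp`.
#' @return an object of class `sdar_occupancy`: list with `grid`, `counts`
#'   (m x n integer matrix, rownames = compound ids, colnames = "i_j_k"
#'   labels) and `bins` (data.frame of the n occupied triples).
#' @export
build_occupancy_matrix <- function(fp, grid, compound_ids = NULL) {
  if (is.null(fp) || nrow(fp) == 0) stopf("empty fingerprint input")
  if (!inherits(grid, "sdar_grid")) stopf("'grid' must be an sdar_grid")
  idx <- bin_index(fp$shift_x, fp$shift_y, fp$distance, grid)
  ids <- if (is.null(compound_ids)) unique(fp$compound_id) else compound_ids
  if (!all(fp$compound_id %in% ids))
    stopf("fingerprint contains compounds absent from 'compound_ids'")
  ord <- order(idx[, "i"], idx[, "j"], idx[, "k"])
  ubins <- unique(idx[ord, , drop = FALSE])
  labels <- bin_label(ubins)
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(ubins),
                   dimnames = list(ids, labels))
  tab <- table(factor(fp$compound_id, levels = ids),
               factor(bin_label(idx), levels = labels))
  counts[] <- as.integer(tab)
  structure(list(grid = grid, counts = counts,
                 bins = data.frame(i = ubins[, "i"], j = ubins[, "j"],
                                   k = ubins[, "k"], label = labels,
                                   stringsAsFactors = FALSE)),
            class = "sdar_occupancy")
}

#' @export
print.sdar_occupancy <- function(x, ...) {
  cat(sprintf("<sdar_occupancy> %d compounds x %d occupied bins at %s\n",
              nrow(x$counts), ncol(x$counts), format(x$grid)))
  invisible(x)
}

#' Export an occupancy matrix
#'
#' `format = "wide"` writes one row per compound with "i_j_k" bin labels as
#' column names; `format = "sparse"` writes triplets
#' (compound_id, i, j, k, count) for the nonzero cells.
#'
#' @param occ an `sdar_occupancy`.
#' @param path file to write.
#' @param format `"wide"` or `"sparse"`.
#' @export
write_occupancy <- function(occ, path, format = c("wide", "sparse")) {
  format <- match.arg(format)
  if (format == "wide") {
    out <- data.frame(compound_id = rownames(occ$counts),
                      occ$counts, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = 1)
  } else {
    nz <- which(occ$counts > 0, arr.ind = TRUE)
    out <- data.frame(compound_id = rownames(occ$counts)[nz[, 1]],
                      occ$bins[nz[, 2], c("i", "j", "k")],
                      count = occ$counts[nz])
    out <- out[order(out$compound_id, out$i, out$j, out$k), ]
    utils::write.csv(out, path, row.names = FALSE, quote = 1)
  }
  invisible(path)
}
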