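#' Construct a compound record
#'
#' A compound carries everything the 3D-SDAR fingerprint needs: element
#' symbols, 3D coordinates (Angstrom), one predicted or measured 13C
#' chemical shift per carbon atom (in atom order), and optionally the
#' activity, log(1/EC50).
#'
#' @param id compound identifier (character scalar).
#' @param elements character vector of element symbols, one per atom.
#' @param coordinates numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @param carbon_shifts numeric vector of 13C shifts in ppm, one per carbon
#'   atom, in the order the carbons appear in `elements`.
#' @param activity optional activity value, log(1/EC50).
#' @return an object of class `sdar_compound`.
#' @examples
#' cpd <- compound("toy", rep("C", 3),
#'                 cbind(x = c(0, 1.5, 3), y = 0, z = 0),
#'                 carbon_shifts = c(10, 20, 30))
#' @export
compound <- function(id, elements, coordinates, carbon_shifts,
                     activity = NA_real_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("'id' must be a non-empty character scalar")
  elements <- as.character(elements)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (nrow(coordinates) != length(elements) || ncol(coordinates) != 3L)
    stopf("compound '%s': coordinates must be a %d x 3 matrix",
          id, length(elements))
  if (!all(is.finite(coordinates)))
    stopf("compound '%s': non-finite coordinates", id)
  n_carbon <- sum(elements == "C")
  carbon_shifts <- as.numeric(carbon_shifts)
  if (length(carbon_shifts) != n_carbon)
    stopf("compound '%s': %d carbon atoms but %d shifts",
          id, n_carbon, length(carbon_shifts))
  if (!all(is.finite(carbon_shifts)) || any(carbon_shifts < 0))
    stopf("compound '%s': shifts must be finite and >= 0 ppm", id)
  structure(
    list(id = id, elements = elements, coordinates = coordinates,
         carbon_shifts = carbon_shifts, activity = as.numeric(activity)[1]),
    class = "sdar_compound")
}

#' @export
print.sdar_compound <- function(x, ...) {
  cat(sprintf("<sdar_compound> %s: %d atoms (%d C), activity %s\n",
              x$id, length(x$elements), sum(x$elements == "C"),
              if (is.na(x$activity)) "NA" else format(x$activity)))
  invisible(x)
}

#' Number of fingerprint elements for a carbon count
#'
#' A molecule with `n_carbons` carbon atoms has one fingerprint element per
#' unordered carbon pair, i.e. `n(n-1)/2` elements; a 12-carbon congener
#' core yields 66.
#'
#' @param n_carbons number of carbon atoms (>= 1).
#' @return integer pair count.
#' @examples
#' element_count(12)  # 66
#' @export
element_count <- function(n_carbons) {
  if (!is_count(n_carbons) || n_carbons < 1)
    stopf("'n_carbons' must be a single integer >= 1")
  as.integer(n_carbons * (n_carbons - 1) / 2)
}

#' Build the 3D-SDAR fingerprint of a compound
#'
#' Every unordered pair of carbon atoms contributes one element: the two
#' 13C shifts (canonicalized so `shift_x <= shift_y`) and the Euclidean
#' distance between the carbons.  Elements that coincide because of
#' molecular symmetry are all retained, so downstream bin occupancies count
#' them with multiplicity.  Only carbon atoms participate; heteroatoms act
#' solely through their influence on the input shifts.
#'
#' @param cpd an [compound()] object with at least two carbon atoms.
#' @param mirror if `TRUE`, additionally emit the mirrored element
#'   `(shift_y, shift_x, d)` for every off-diagonal pair, symmetrizing the
#'   shift plane instead of canonicalizing it.  Default `FALSE`
#'   (canonical form, one point per pair).
#' @return a `data.frame` of class `sdar_fingerprint` with columns
#'   `compound_id`, `atom_i`, `atom_j` (indices into the compound's atom
#'   list), `shift_x`, `shift_y` (ppm), `distance` (Angstrom).
#' @examples
#' cpd <- compound("toy", rep("C", 3),
#'                 cbind(c(0, 1.5, 3), 0, 0), c(10, 20, 30))
#' build_fingerprint(cpd)
#' @export
build_fingerprint <- function(cpd, mirror = FALSE) {
  if (!inherits(cpd, "sdar_compound"))
    stopf("'cpd' must be an sdar_compound")
  carbon_idx <- which(cpd$elements == "C")
  nc <- length(carbon_idx)
  if (nc < 2)
    stopf("degenerate compound '%s': fewer than 2 carbon atoms", cpd$id)
  xyz <- cpd$coordinates[carbon_idx, , drop = FALSE]
  shifts <- cpd$carbon_shifts
  pairs <- utils::combn(nc, 2L)
  a <- pairs[1L, ]; b <- pairs[2L, ]
  d <- sqrt(rowSums((xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE])^2))
  if (any(d <= 0))
    stopf("compound '%s': coincident carbon coordinates (zero distance)",
          cpd$id)
  sx <- pmin(shifts[a], shifts[b])
  sy <- pmax(shifts[a], shifts[b])
  fp <- data.frame(
    compound_id = cpd$id,
    atom_i = carbon_idx[a], atom_j = carbon_idx[b],
    shift_x = sx, shift_y = sy, distance = d,
    stringsAsFactors = FALSE)
  if (mirror) {
    off <- fp$shift_x != fp$shift_y
    m <- fp[off, ]
    m[, c("shift_x", "shift_y")] <- m[, c("shift_y", "shift_x")]
    fp <- rbind(fp, m)
    rownames(fp) <- NULL
  }
  class(fp) <- c("sdar_fingerprint", "data.frame")
  fp
}

#' Fingerprints for a list of compounds
#'
#' @param compounds list of [compound()] objects.
#' @param mirror passed to [build_fingerprint()].
#' @return one `sdar_fingerprint` data.frame stacking all compounds.
#' @export
build_fingerprints <- function(compounds, mirror = FALSE) {
  fps <- lapply(compounds, build_fingerprint, mirror = mirror)
  out <- do.call(rbind, fps)
  rownames(out) <- NULL
  class(out) <- c("sdar_fingerprint", "data.frame")
  out
}

#' Export fingerprints as CSV
#'
#' Columns: compound_id, atom_i, atom_j, shift_x_ppm, shift_y_ppm,
#' distance_A.
#'
#' @param fp an `sdar_fingerprint` data.frame.
#' @param path file to write.
#' @export
write_fingerprints <- function(fp, path) {
  out <- data.frame(compound_id = fp$compound_id,
                    atom_i = fp$atom_i, atom_j = fp$atom_j,
                    shift_x_ppm = fp$shift_x, shift_y_ppm = fp$shift_y,
                    distance_A = fp$distance)
  utils::write.csv(out, path, row.names = FALSE, quote = 1)
  invisible(path)
}
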