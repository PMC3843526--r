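#' Pairwise consensus prediction
#'
#' Element-wise arithmetic mean of two members' per-compound predictions.
#' Full precision is retained; use [round_half_up()] for the 2-decimal
#' display convention of printed prediction tables.
#'
#' @param pred_a,pred_b numeric vectors named by compound id, same set.
#' @return named numeric vector of consensus predictions (full precision).
#' @examples
#' consensus_predict(c(a = 7.66), c(a = 7.10))  # 7.38
#' @export
consensus_predict <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b))
    stopf("member predictions differ in length")
  if (!is.null(names(pred_a)) || !is.null(names(pred_b))) {
    if (is.null(names(pred_a)) || is.null(names(pred_b)) ||
        !setequal(names(pred_a), names(pred_b)))
      stopf("member predictions cover different compound sets")
    pred_b <- pred_b[names(pred_a)]
  }
  out <- (as.numeric(pred_a) + as.numeric(pred_b)) / 2
  stats::setNames(out, names(pred_a))
}

#' Percent improvement of a consensus model over its members
#'
#' `100 * (r2_consensus - mean(r2_members)) / mean(r2_members)`, reported
#' to one decimal (half-up).
#'
#' @param r2_consensus hold-out R^2 of the consensus model.
#' @param r2_members the two members' R^2 values (or their mean).
#' @return percent improvement, one decimal.
#' @examples
#' improvement_pct(0.685, 0.620)  # 10.5
#' @export
improvement_pct <- function(r2_consensus, r2_members) {
  mb <- mean(as.numeric(r2_members))
  if (!is.finite(mb) || mb <= 0)
    stopf("mean member R^2 must be positive")
  round_half_up(100 * (r2_consensus - mb) / mb, 1)
}

#' Build a consensus model from two composite models
#'
#' Averages the members' per-compound hold-out predictions (each compound
#' having been predicted many times across cycles) and evaluates the
#' consensus against the observed activities.
#'
#' @param a,b `sdar_composite` objects over the same compounds.
#' @param y named observed activities.
#' @param r2_mode R^2 convention for the reported values.
#' @return object of class `sdar_consensus` with members' R^2, consensus
#'   predictions and R^2, and percent improvement.
#' @export
consensus_model <- function(a, b, y,
                            r2_mode = c("pearson_sq", "one_minus_ss")) {
  r2_mode <- match.arg(r2_mode)
  if (!inherits(a, "sdar_composite") || !inherits(b, "sdar_composite"))
    stopf("members must be sdar_composite objects")
  pa <- a$avg_prediction; pb <- b$avg_prediction
  never <- is.na(pa) | is.na(pb)
  if (any(never)) {
    message(sprintf(
      "%d compound(s) never predicted by a member; excluded: %s",
      sum(never), paste(names(pa)[never], collapse = ", ")))
    pa <- pa[!never]; pb <- pb[!never]
  }
  pred <- consensus_predict(pa, pb)
  y <- stats::setNames(as.numeric(y[names(pred)]), names(pred))
  if (anyNA(y)) stopf("activities missing for some compounds")
  tag <- function(m) sprintf("%s %s", m$engine$engine,
                             if (!is.null(m$grid)) format(m$grid) else "")
  r2m <- c(compute_r2(pa[names(pred)], y, r2_mode),
           compute_r2(pb[names(pred)], y, r2_mode))
  r2c <- compute_r2(pred, y, r2_mode)
  structure(
    list(members = c(tag(a), tag(b)), member_r2 = r2m,
         prediction = pred, r2_consensus = r2c,
         improvement_pct = improvement_pct(r2c, r2m)),
    class = "sdar_consensus")
}

#' @export
print.sdar_consensus <- function(x, ...) {
  cat(sprintf(
    "<sdar_consensus> %s + %s\n  member R2 %.3f / %.3f, consensus R2 %.3f (%+.1f%%)\n",
    x$members[1], x$members[2], x$member_r2[1], x$member_r2[2],
    x$r2_consensus, x$improvement_pct))
  invisible(x)
}

#' Average predictions of more than two composite models
#'
#' Utility extension of pairwise consensus; the canonical analysis is
#' restricted to pairs.
#'
#' @param ... two or more named prediction vectors over the same compounds.
#' @return named numeric vector.
#' @export
consensus_predict_multi <- function(...) {
  preds <- list(...)
  if (length(preds) < 2) stopf("need at least two prediction vectors")
  out <- Reduce(`+`, lapply(preds, function(p) {
    if (!setequal(names(p), names(preds[[1]])))
      stopf("prediction vectors cover different compound sets")
    as.numeric(p[names(preds[[1]])])
  })) / length(preds)
  stats::setNames(out, names(preds[[1]]))
}

#' Extract the top positively and negatively weighted bins
#'
#' From every stored per-cycle PLS model and every latent variable, takes
#' the `n_top` bins with the largest weights (sign "positive") and the
#' `n_top` bins with the smallest weights (sign "negative").  At the
#' canonical settings (100 cycles x 7 LVs x top 10, both signs) this
#' extracts 14000 entries.
#'
#' @param composite an `sdar_composite` run with `keep_models = TRUE`
#'   (PLS engine).
#' @param n_top bins per sign per LV per cycle (default 10).
#' @return data.frame: cycle, lv, bin label, i, j, k, sign, weight.
#' @export
extract_top_bins <- function(composite, n_top = 10) {
  if (!inherits(composite, "sdar_composite") ||
      composite$engine$engine != "PLS" || is.null(composite$models))
    stopf("need a PLS composite run with keep_models = TRUE")
  if (!is_count(n_top) || n_top < 1) stopf("'n_top' must be >= 1")
  shortfall <- 0L
  out <- vector("list", length(composite$models))
  for (cyc in seq_along(composite$models)) {
    w <- composite$models[[cyc]]
    nb <- nrow(w)
    take <- min(n_top, nb)
    if (take < n_top) shortfall <- shortfall + 1L
    per_lv <- vector("list", ncol(w))
    for (lv in seq_len(ncol(w))) {
      ord <- order(w[, lv], decreasing = TRUE)
      pos <- ord[seq_len(take)]
      neg <- rev(ord)[seq_len(take)]
      per_lv[[lv]] <- data.frame(
        cycle = cyc, lv = lv,
        bin = rownames(w)[c(pos, neg)],
        sign = rep(c("positive", "negative"), each = take),
        weight = w[c(pos, neg), lv],
        stringsAsFactors = FALSE)
    }
    out[[cyc]] <- do.call(rbind, per_lv)
  }
  if (shortfall > 0)
    message(sprintf(
      "%d cycle(s) had fewer than %d bins; all available bins taken",
      shortfall, n_top))
  out <- do.call(rbind, out)
  ijk <- do.call(rbind, strsplit(out$bin, "_", fixed = TRUE))
  out$i <- as.integer(ijk[, 1]); out$j <- as.integer(ijk[, 2])
  out$k <- as.integer(ijk[, 3])
  rownames(out) <- NULL
  out
}

#' Rank extracted bins by frequency and select the top fraction
#'
#' Per sign, unique bins are ranked by relative frequency of occurrence
#' (occurrences divided by the total number of extractions of that sign)
#' and the top `ceil(top_fraction * n_unique)` are kept.  Ties are broken
#' by frequency, then lexicographically on the bin triple.  If a bin is
#' selected with both signs the overlap is reported as a finding (message
#' and attribute), not an error.
#'
#' @param extracted data.frame from [extract_top_bins()].
#' @param top_fraction fraction of unique bins to keep per sign
#'   (default 0.2).
#' @return data.frame of class `sdar_bin_attribution`: sign, i, j, k,
#'   bin, count, frequency, rank.
#' @export
rank_and_select_bins <- function(extracted, top_fraction = 0.2) {
  if (is.null(extracted) || nrow(extracted) == 0)
    stopf("empty bin multiset")
  if (top_fraction <= 0 || top_fraction > 1)
    stopf("'top_fraction' must be in (0, 1]")
  sel <- lapply(split(extracted, extracted$sign), function(df) {
    counts <- table(df$bin)
    tab <- df[!duplicated(df$bin), c("bin", "i", "j", "k")]
    tab$count <- as.integer(counts[tab$bin])
    tab$frequency <- tab$count / nrow(df)
    tab <- tab[order(-tab$frequency, tab$i, tab$j, tab$k), ]
    keep <- ceiling(top_fraction * nrow(tab))
    tab <- tab[seq_len(keep), ]
    tab$rank <- seq_len(keep)
    tab$sign <- df$sign[1]
    tab
  })
  out <- do.call(rbind, sel)[, c("sign", "i", "j", "k", "bin",
                                 "count", "frequency", "rank")]
  rownames(out) <- NULL
  overlap <- intersect(out$bin[out$sign == "positive"],
                       out$bin[out$sign == "negative"])
  if (length(overlap) > 0)
    message(sprintf(
      "finding: %d bin(s) selected with both signs: %s",
      length(overlap), paste(overlap, collapse = ", ")))
  attr(out, "sign_overlap") <- overlap
  class(out) <- c("sdar_bin_attribution", "data.frame")
  out
}

#' Back-project selected bins onto supporting atom pairs
#'
#' Maps each selected bin to every (compound, atom pair) whose
#' fingerprint element falls in it on the given grid, ready for export
#' and molecular-graphics overlay downstream.  Symmetric coincident
#' elements yield one row each.
#'
#' @param bins an `sdar_bin_attribution` (or data.frame with sign, i, j,
#'   k, frequency).
#' @param fp `sdar_fingerprint` data.frame of the same compounds.
#' @param grid the [grid_spec()] the composite was built on.
#' @return attribution data.frame: sign, i, j, k, frequency, compound_id,
#'   atom_i, atom_j, shift_x, shift_y, distance.
#' @export
back_project <- function(bins, fp, grid) {
  cols <- c("sign", "i", "j", "k", "frequency", "compound_id",
            "atom_i", "atom_j", "shift_x", "shift_y", "distance")
  if (is.null(bins) || nrow(bins) == 0) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  idx <- bin_index(fp$shift_x, fp$shift_y, fp$distance, grid)
  el_lab <- bin_label(idx)
  hit <- match(el_lab, bins$bin)
  keep <- !is.na(hit)
  out <- data.frame(
    sign = bins$sign[hit[keep]],
    i = bins$i[hit[keep]], j = bins$j[hit[keep]], k = bins$k[hit[keep]],
    frequency = bins$frequency[hit[keep]],
    fp[keep, c("compound_id", "atom_i", "atom_j",
               "shift_x", "shift_y", "distance")],
    stringsAsFactors = FALSE)
  out <- out[order(out$sign, out$i, out$j, out$k, out$compound_id,
                   out$atom_i, out$atom_j), ]
  rownames(out) <- NULL
  out
}

#' Export a bin attribution table
#'
#' @param attribution data.frame from [back_project()].
#' @param path file to write.
#' @export
write_attribution <- function(attribution, path) {
  utils::write.csv(attribution, path, row.names = FALSE, quote = 6)
  invisible(path)
}
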