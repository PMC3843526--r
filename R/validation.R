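#' Create a seeded randomized train/test split plan
#'
#' Draws `n_cycles` hold-out test subsets of size
#' `round(test_fraction * m)` uniformly without replacement, all from a
#' single master seed.  The same arguments always reproduce the identical
#' plan, and the plan object is shared across engines so PLS and KNN see
#' matching training/test subset pairs.  A per-cycle scrambling sub-seed
#' stream is drawn at creation time so Y-scrambling never perturbs the
#' split sequence.
#'
#' @param m number of compounds (>= 5).
#' @param n_cycles number of randomization cycles.
#' @param test_fraction hold-out proportion in (0, 1); the canonical
#'   workflow uses 0.2, i.e. test size 19 of 94.
#' @param seed master integer seed.
#' @return object of class `sdar_split_plan`.
#' @export
make_split_plan <- function(m, n_cycles = 100, test_fraction = 0.2, seed) {
  if (!is_count(m) || m < 5) stopf("'m' must be an integer >= 5")
  if (!is_count(n_cycles) || n_cycles < 1)
    stopf("'n_cycles' must be a positive integer")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stopf("'test_fraction' must be in (0, 1)")
  if (missing(seed) || !is_count(seed)) stopf("an integer 'seed' is required")
  test_size <- round(test_fraction * m)
  if (test_size < 1) stopf("test size rounds to zero; increase test_fraction")
  if (test_size >= m) stopf("test size leaves no training compounds")
  plan <- with_seed(seed, {
    test <- lapply(seq_len(n_cycles),
                   function(i) sort(sample.int(m, test_size)))
    scramble_seeds <- sample.int(2147483646L, n_cycles)
    list(test = test, scramble_seeds = scramble_seeds)
  })
  structure(
    list(m = as.integer(m), n_cycles = as.integer(n_cycles),
         test_fraction = test_fraction, test_size = as.integer(test_size),
         seed = as.integer(seed), test = plan$test,
         scramble_seeds = plan$scramble_seeds),
    class = "sdar_split_plan")
}

#' @export
print.sdar_split_plan <- function(x, ...) {
  cat(sprintf(
    "<sdar_split_plan> %d cycles, %d/%d held out per cycle, seed %d\n",
    x$n_cycles, x$test_size, x$m, x$seed))
  invisible(x)
}

#' Coefficient of determination between predicted and observed activities
#'
#' Two conventions are in circulation and can disagree badly, so both are
#' implemented: `"pearson_sq"` (default) is the squared Pearson
#' correlation, i.e. the R^2 of the best-fit line through a
#' predicted-vs-observed plot; `"one_minus_ss"` is `1 - SSE/SST` and can
#' be negative when predictions are worse than the observed mean.
#'
#' @param predicted,observed numeric vectors, length >= 3.
#' @param mode `"pearson_sq"` or `"one_minus_ss"`.
#' @return R^2 value.
#' @export
compute_r2 <- function(predicted, observed,
                       mode = c("pearson_sq", "one_minus_ss")) {
  mode <- match.arg(mode)
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  if (length(predicted) != length(observed) || length(observed) < 3)
    stopf("need >= 3 aligned (predicted, observed) pairs")
  if (anyNA(predicted) || anyNA(observed))
    stopf("R^2 undefined: missing values in predicted or observed")
  if (stats::sd(observed) == 0)
    stopf("R^2 undefined: observed values are constant")
  if (mode == "pearson_sq") {
    if (stats::sd(predicted) == 0)
      stopf("R^2 (pearson_sq) undefined: predicted values are constant")
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' PLS engine configuration for composite runs
#' @param n_lv number of latent variables (1-10 in the canonical scan).
#' @return engine spec consumed by [run_composite()].
#' @export
pls_engine <- function(n_lv) {
  if (!is_count(n_lv) || n_lv < 1) stopf("'n_lv' must be an integer >= 1")
  structure(list(engine = "PLS", n_lv = as.integer(n_lv)),
            class = "sdar_engine")
}

#' KNN engine configuration for composite runs
#' @param k number of neighbors (1-10 in the canonical scan).
#' @return engine spec consumed by [run_composite()].
#' @export
knn_engine <- function(k) {
  if (!is_count(k) || k < 1) stopf("'k' must be an integer >= 1")
  structure(list(engine = "KNN", k = as.integer(k)), class = "sdar_engine")
}

#' Run a composite model over a split plan
#'
#' One engine (PLS or KNN) on one occupancy matrix, aggregated over all
#' cycles of a split plan.  Each cycle fits on the training rows only
#' (standardization is refit per cycle for PLS), predicts the hold-out
#' subset and records R^2_test.  For PLS, R^2_train and one Y-scrambling
#' replicate per cycle are also recorded: the training activities are
#' permuted under the cycle's scrambling sub-seed, the model refit, and
#' the true test activities predicted, estimating the chance-correlation
#' baseline.  Cycle R^2 values that are undefined (e.g. constant
#' predictions) are stored as `NA`, excluded from the summary means and
#' counted.
#'
#' Summary statistics are means and SDs over cycles, so they include
#' contributions from "good" as well as "bad" randomized models.
#'
#' @param occ an `sdar_occupancy` (or occupancy matrix with bin-label
#'   colnames).
#' @param y activities, one per compound row; if named, names must match
#'   the occupancy rownames.
#' @param plan an [make_split_plan()] object with `m == nrow(occ)`.
#' @param engine [pls_engine()] or [knn_engine()].
#' @param r2_mode reported R^2 convention, see [compute_r2()]; both modes
#'   are stored per cycle regardless.
#' @param keep_models if `TRUE` (default for PLS), store each cycle's
#'   per-LV weight matrix for downstream interpretation.
#' @return object of class `sdar_composite`: per-cycle statistics
#'   (`cycles` data.frame), per-compound averaged prediction and
#'   times-predicted counts, summary means/SDs, the plan, and optionally
#'   the per-cycle weights.
#' @export
run_composite <- function(occ, y, plan, engine,
                          r2_mode = c("pearson_sq", "one_minus_ss"),
                          keep_models = NULL) {
  r2_mode <- match.arg(r2_mode)
  if (!inherits(plan, "sdar_split_plan")) stopf("'plan' must be a split plan")
  if (!inherits(engine, "sdar_engine"))
    stopf("'engine' must come from pls_engine() or knn_engine()")
  x <- if (inherits(occ, "sdar_occupancy")) occ$counts else as.matrix(occ)
  grid <- if (inherits(occ, "sdar_occupancy")) occ$grid else NULL
  if (nrow(x) != plan$m) stopf("plan was made for %d compounds, occupancy has %d",
                               plan$m, nrow(x))
  y <- as.numeric(if (!is.null(names(y)) && !is.null(rownames(x)))
    y[rownames(x)] else y)
  if (length(y) != nrow(x) || anyNA(y))
    stopf("activities must be complete and match the occupancy rows")
  is_pls <- engine$engine == "PLS"
  if (is.null(keep_models)) keep_models <- is_pls

  nc <- plan$n_cycles
  r2_test <- r2_test_p <- r2_test_ss <- rep(NA_real_, nc)
  r2_train <- r2_scr <- rep(NA_real_, nc)
  pred_sum <- numeric(nrow(x))
  pred_cnt <- integer(nrow(x))
  cycle_pred <- vector("list", nc)
  models <- if (keep_models && is_pls) vector("list", nc) else NULL

  safe_r2 <- function(p, o, mode) tryCatch(compute_r2(p, o, mode),
                                           error = function(e) NA_real_)

  for (cyc in seq_len(nc)) {
    te <- plan$test[[cyc]]
    tr <- setdiff(seq_len(plan$m), te)
    if (is_pls) {
      fit <- suppressWarnings(
        simpls_fit(x[tr, , drop = FALSE], y[tr], engine$n_lv))
      pred <- pls_predict(fit, x[te, , drop = FALSE])
      r2_train[cyc] <- safe_r2(pls_predict(fit, x[tr, , drop = FALSE]),
                               y[tr], r2_mode)
      y_scr <- with_seed(plan$scramble_seeds[cyc], sample(y[tr]))
      fit_scr <- suppressWarnings(
        simpls_fit(x[tr, , drop = FALSE], y_scr, engine$n_lv))
      r2_scr[cyc] <- safe_r2(pls_predict(fit_scr, x[te, , drop = FALSE]),
                             y[te], r2_mode)
      if (keep_models) models[[cyc]] <- fit$weights
    } else {
      pred <- knn_predict(x[tr, , drop = FALSE], y[tr],
                          x[te, , drop = FALSE], engine$k)
    }
    r2_test_p[cyc] <- safe_r2(pred, y[te], "pearson_sq")
    r2_test_ss[cyc] <- safe_r2(pred, y[te], "one_minus_ss")
    r2_test[cyc] <- if (r2_mode == "pearson_sq") r2_test_p[cyc] else r2_test_ss[cyc]
    pred_sum[te] <- pred_sum[te] + pred
    pred_cnt[te] <- pred_cnt[te] + 1L
    cycle_pred[[cyc]] <- structure(pred, names = rownames(x)[te])
  }
  n_undef <- sum(is.na(r2_test))
  if (n_undef > 0)
    message(sprintf("%d cycle(s) with undefined R^2_test excluded from means",
                    n_undef))
  avg_pred <- ifelse(pred_cnt > 0, pred_sum / pred_cnt, NA_real_)
  names(avg_pred) <- rownames(x)
  cycles <- data.frame(cycle = seq_len(nc), r2_train = r2_train,
                       r2_test = r2_test, r2_test_pearson = r2_test_p,
                       r2_test_ss = r2_test_ss, r2_scrambling = r2_scr)
  if (!is_pls) cycles$r2_train <- cycles$r2_scrambling <- NULL
  summ <- list(
    r2_test_mean = mean(r2_test, na.rm = TRUE),
    r2_test_sd = stats::sd(r2_test, na.rm = TRUE),
    n_undefined = n_undef)
  if (is_pls) {
    summ$r2_train_mean <- mean(r2_train, na.rm = TRUE)
    summ$r2_scrambling_mean <- mean(r2_scr, na.rm = TRUE)
    summ$r2_scrambling_sd <- stats::sd(r2_scr, na.rm = TRUE)
  }
  structure(
    list(engine = engine, grid = grid,
         hyper = if (is_pls) engine$n_lv else engine$k,
         r2_mode = r2_mode, cycles = cycles,
         avg_prediction = avg_pred, times_predicted = pred_cnt,
         cycle_predictions = cycle_pred, summary = summ,
         plan = plan, models = models,
         bin_labels = colnames(x)),
    class = "sdar_composite")
}

#' @export
print.sdar_composite <- function(x, ...) {
  hy <- if (x$engine$engine == "PLS") sprintf("%d LVs", x$hyper)
        else sprintf("%d neighbors", x$hyper)
  cat(sprintf("<sdar_composite> %s (%s)%s: mean R2_test %.3f (sd %.3f), %d cycles\n",
              x$engine$engine, hy,
              if (!is.null(x$grid)) paste0(" at ", format(x$grid)) else "",
              x$summary$r2_test_mean, x$summary$r2_test_sd,
              x$plan$n_cycles))
  if (!is.null(x$summary$r2_scrambling_mean))
    cat(sprintf("  mean R2_scrambling %.3f, mean R2_train %.3f\n",
                x$summary$r2_scrambling_mean, x$summary$r2_train_mean))
  invisible(x)
}

#' Running mean of per-cycle R^2 at convergence checkpoints
#'
#' Used to decide how many randomization cycles are needed before the
#' composite mean R^2_test settles to its asymptotic value.
#'
#' @param per_cycle_r2 numeric vector of per-cycle R^2 values, in cycle
#'   order (`NA` cycles are skipped in the running mean).
#' @param checkpoints increasing cycle counts, each `<=` available cycles.
#' @return named numeric vector: running mean at each checkpoint.
#' @export
convergence_curve <- function(per_cycle_r2, checkpoints) {
  per_cycle_r2 <- as.numeric(per_cycle_r2)
  if (length(per_cycle_r2) == 0) stopf("empty R^2 sequence")
  if (any(checkpoints < 1) || any(checkpoints > length(per_cycle_r2)))
    stopf("checkpoints must lie in 1..%d", length(per_cycle_r2))
  vapply(checkpoints,
         function(n) mean(per_cycle_r2[seq_len(n)], na.rm = TRUE),
         numeric(1)) |>
    stats::setNames(as.character(checkpoints))
}

#' Matched-pair orthogonality analysis of two composite models
#'
#' Compares per-cycle hold-out R^2 of two composites that share the same
#' split plan (matching training/test subset pairs).  A high correlation
#' of the matched R^2 values means the engines capture the same structural
#' information and consensus averaging cannot help; a low correlation
#' plus many cycles deviating by at least 1 SD of the difference signals
#' partial orthogonality.
#'
#' @param a,b `sdar_composite` objects built on an identical plan.
#' @return object of class `sdar_matched_pairs`: per-cycle pairs and
#'   differences, mean and SD of the difference, count of cycles with
#'   `|delta - mean| >= 1 SD` (split by sign), and the correlation /
#'   squared correlation of the matched R^2 values.
#' @export
matched_pair_analysis <- function(a, b) {
  if (!inherits(a, "sdar_composite") || !inherits(b, "sdar_composite"))
    stopf("inputs must be sdar_composite objects")
  if (!identical(a$plan, b$plan))
    stopf("composites do not share the same split plan")
  if (!identical(a$r2_mode, b$r2_mode))
    stopf("composites report different R^2 modes")
  ra <- a$cycles$r2_test; rb <- b$cycles$r2_test
  ok <- !is.na(ra) & !is.na(rb)
  delta <- ra - rb
  mean_d <- mean(delta[ok]); sd_d <- stats::sd(delta[ok])
  beyond <- ok & abs(delta - mean_d) >= sd_d
  structure(
    list(pairs = data.frame(cycle = a$cycles$cycle, r2_a = ra, r2_b = rb,
                            delta = delta),
         mean_delta = mean_d, sd_delta = sd_d,
         n_beyond_1sd = sum(beyond),
         n_beyond_1sd_a_wins = sum(beyond & delta > mean_d),
         n_beyond_1sd_b_wins = sum(beyond & delta < mean_d),
         cor_matched = stats::cor(ra[ok], rb[ok]),
         r2_matched = stats::cor(ra[ok], rb[ok])^2),
    class = "sdar_matched_pairs")
}

#' @export
print.sdar_matched_pairs <- function(x, ...) {
  cat(sprintf(
    paste0("<sdar_matched_pairs> %d cycles; matched R^2 correlation %.3f ",
           "(R2 %.3f)\n  delta mean %.3f, sd %.3f; %d cycle(s) beyond 1 sd ",
           "(%d + / %d -)\n"),
    nrow(x$pairs), x$cor_matched, x$r2_matched, x$mean_delta, x$sd_delta,
    x$n_beyond_1sd, x$n_beyond_1sd_a_wins, x$n_beyond_1sd_b_wins))
  invisible(x)
}

#' Scan grids and engine hyperparameters
#'
#' For every tessellation grid, runs PLS composites over `lv_range` and
#' KNN composites over `k_range` on a shared split plan, and reports the
#' best (highest mean R^2_test) setting per engine together with its
#' means and SDs - one row per grid.  The full per-setting
#' means are attached as attributes `pls_scan` and `knn_scan`.
#'
#' @param fp an `sdar_fingerprint` data.frame covering all compounds.
#' @param y named activities (names = compound ids).
#' @param grids list of [grid_spec()] objects.
#' @param plan shared [make_split_plan()].
#' @param lv_range PLS latent-variable counts to try.
#' @param k_range KNN neighbor counts to try.
#' @param r2_mode reported R^2 convention.
#' @return data.frame of class `sdar_scan`, one row per grid, with
#'   attribute `best` holding the per-engine argmax rows.
#' @export
scan_hyperparameters <- function(fp, y, grids, plan,
                                 lv_range = 1:10, k_range = 1:10,
                                 r2_mode = c("pearson_sq", "one_minus_ss")) {
  r2_mode <- match.arg(r2_mode)
  if (length(grids) == 0) stopf("empty grid list")
  ids <- names(y)
  if (is.null(ids)) stopf("'y' must be named by compound id")
  rows <- vector("list", length(grids))
  pls_scan <- knn_scan <- list()
  for (gi in seq_along(grids)) {
    grid <- grids[[gi]]
    occ <- build_occupancy_matrix(fp, grid, compound_ids = ids)
    pls_stats <- lapply(lv_range, function(lv) {
      cm <- run_composite(occ, y, plan, pls_engine(lv), r2_mode,
                          keep_models = FALSE)
      data.frame(grid = format(grid), n_lv = lv,
                 r2_test_mean = cm$summary$r2_test_mean,
                 r2_test_sd = cm$summary$r2_test_sd,
                 r2_scr_mean = cm$summary$r2_scrambling_mean,
                 r2_scr_sd = cm$summary$r2_scrambling_sd)
    })
    pls_stats <- do.call(rbind, pls_stats)
    knn_stats <- lapply(k_range, function(k) {
      cm <- run_composite(occ, y, plan, knn_engine(k), r2_mode)
      data.frame(grid = format(grid), k = k,
                 r2_test_mean = cm$summary$r2_test_mean,
                 r2_test_sd = cm$summary$r2_test_sd)
    })
    knn_stats <- do.call(rbind, knn_stats)
    bp <- which.max(pls_stats$r2_test_mean)
    bk <- which.max(knn_stats$r2_test_mean)
    rows[[gi]] <- data.frame(
      bin_size = format(grid), dx = grid$dx, dz = grid$dz,
      optimal_lv = pls_stats$n_lv[bp],
      avg_r2_test_pls = pls_stats$r2_test_mean[bp],
      sd_r2_test_pls = pls_stats$r2_test_sd[bp],
      avg_r2_scr_pls = pls_stats$r2_scr_mean[bp],
      sd_r2_scr_pls = pls_stats$r2_scr_sd[bp],
      optimal_k = knn_stats$k[bk],
      avg_r2_test_knn = knn_stats$r2_test_mean[bk],
      sd_r2_test_knn = knn_stats$r2_test_sd[bk],
      stringsAsFactors = FALSE)
    pls_scan[[gi]] <- pls_stats
    knn_scan[[gi]] <- knn_stats
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pls_scan") <- do.call(rbind, pls_scan)
  attr(out, "knn_scan") <- do.call(rbind, knn_scan)
  attr(out, "best") <- list(
    PLS = out[which.max(out$avg_r2_test_pls), , drop = FALSE],
    KNN = out[which.max(out$avg_r2_test_knn), , drop = FALSE])
  class(out) <- c("sdar_scan", "data.frame")
  out
}

#' Export a hyperparameter scan table
#'
#' One CSV row per grid: bin size, optimal LV count, average/SD hold-out
#' and scrambling R^2 for PLS, optimal neighbor count and average/SD
#' hold-out R^2 for KNN.
#'
#' @param scan an `sdar_scan` table.
#' @param path file to write.
#' @export
write_scan <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE, quote = 1)
  invisible(path)
}
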