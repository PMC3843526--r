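#' Read a modeling dataset from SDF + CSV tables
#'
#' Joins three sources on `compound_id`: per-compound 3D structures (SDF
#' V2000 with explicit 3D coordinates, molecule title = compound id),
#' a per-atom 13C shift table (CSV: `compound_id`, `atom_index`,
#' `shift_ppm`, with `atom_index` referring to the SDF atom order) and an
#' activity table (CSV: `compound_id`, `activity`).  Compounds with a
#' shift-count mismatch are rejected with a per-compound error listing;
#' compounds absent from the activity table are loaded with activity `NA`
#' and reported, so callers can exclude them from modeling.
#'
#' @param structures path to an SDF V2000 file with 3D coordinates.
#' @param shifts path to the shift CSV.
#' @param activities path to the activity CSV.
#' @return list of [compound()] objects.
#' @export
read_dataset <- function(structures, shifts, activities) {
  for (f in c(structures, shifts, activities))
    if (!file.exists(f)) stopf("file not found: %s", f)
  sdf <- ChemmineR::read.SDFset(structures)
  ids <- as.character(ChemmineR::sdfid(sdf))
  if (anyDuplicated(ids)) stopf("duplicate compound ids in SDF")
  shift_tab <- utils::read.csv(shifts, stringsAsFactors = FALSE)
  act_tab <- utils::read.csv(activities, stringsAsFactors = FALSE)
  for (col in c("compound_id", "atom_index", "shift_ppm"))
    if (!col %in% names(shift_tab)) stopf("shift table lacks column '%s'", col)
  for (col in c("compound_id", "activity"))
    if (!col %in% names(act_tab)) stopf("activity table lacks column '%s'", col)

  orphan <- setdiff(unique(shift_tab$compound_id), ids)
  if (length(orphan) > 0)
    message(sprintf("shift table ids absent from SDF (ignored): %s",
                    paste(orphan, collapse = ", ")))
  no_act <- setdiff(ids, act_tab$compound_id)
  if (length(no_act) > 0)
    message(sprintf(
      "no activity for: %s (loaded with activity NA; exclude from modeling)",
      paste(no_act, collapse = ", ")))

  blocks <- ChemmineR::atomblock(sdf)
  errors <- character(0)
  out <- vector("list", length(ids))
  for (ci in seq_along(ids)) {
    ab <- blocks[[ci]]
    elements <- sub("_.*$", "", rownames(ab))
    xyz <- ab[, 1:3, drop = FALSE]
    if (all(xyz[, 3] == 0)) {
      errors <- c(errors, sprintf("%s: no 3D coordinates (all z = 0)", ids[ci]))
      next
    }
    st <- shift_tab[shift_tab$compound_id == ids[ci], ]
    st <- st[order(st$atom_index), ]
    n_carbon <- sum(elements == "C")
    if (nrow(st) != n_carbon) {
      errors <- c(errors, sprintf("%s: %d carbon atoms but %d shifts",
                                  ids[ci], n_carbon, nrow(st)))
      next
    }
    act <- act_tab$activity[match(ids[ci], act_tab$compound_id)]
    out[[ci]] <- tryCatch(
      compound(ids[ci], elements, unname(xyz), st$shift_ppm,
               activity = if (length(act) == 0) NA_real_ else act),
      error = function(e) {
        errors <<- c(errors, conditionMessage(e))
        NULL
      })
  }
  if (length(errors) > 0)
    stopf("dataset validation failed:\n  %s", paste(errors, collapse = "\n  "))
  out
}

#' Write abstract carbon skeletons as SDF V2000
#'
#' Minimal V2000 writer for point-set compounds, e.g. output of
#' [generate_synthetic_dataset()].  The molecule title line carries the
#' compound id.  A linear chain bond block is emitted purely so the files
#' validate in standard SDF tools; the skeletons are abstract point sets
#' and the bonds carry no meaning.  Files written here round-trip through
#' standard SDF readers.
#'
#' @param compounds list of [compound()] objects.
#' @param path file to write.
#' @export
write_sdf_v2000 <- function(compounds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cpd in compounds) {
    n <- length(cpd$elements)
    writeLines(c(
      cpd$id, "  qsdar3d", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, n - 1L),
      sprintf("%10.4f%10.4f%10.4f %-2s  0  0  0  0  0  0  0  0  0  0  0  0",
              cpd$coordinates[, 1], cpd$coordinates[, 2],
              cpd$coordinates[, 3], cpd$elements),
      sprintf("%3d%3d  1  0  0  0  0", seq_len(n - 1L), seq_len(n - 1L) + 1L),
      "M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Write shift and activity tables for a compound list
#'
#' Companion CSVs to [write_sdf_v2000()] in the layout [read_dataset()]
#' expects.
#'
#' @param compounds list of [compound()] objects.
#' @param shifts_path,activities_path files to write.
#' @export
write_tables <- function(compounds, shifts_path, activities_path) {
  sh <- do.call(rbind, lapply(compounds, function(cpd) {
    data.frame(compound_id = cpd$id,
               atom_index = which(cpd$elements == "C"),
               shift_ppm = cpd$carbon_shifts)
  }))
  utils::write.csv(sh, shifts_path, row.names = FALSE, quote = 1)
  act <- data.frame(
    compound_id = vapply(compounds, `[[`, character(1), "id"),
    activity = vapply(compounds, `[[`, numeric(1), "activity"))
  act <- act[!is.na(act$activity), ]
  utils::write.csv(act, activities_path, row.names = FALSE, quote = 1)
  invisible(c(shifts_path, activities_path))
}

#' Packaged AhR binding table
#'
#' The 94-row table of aryl hydrocarbon receptor binders with experimental
#' log(1/EC50) and the four composite-model prediction columns (PLS and
#' KNN at 2 ppm x 2 ppm x 0.5 A and at 10 ppm x 10 ppm x 0.5 A) plus the
#' printed PLS-KNN consensus column (the mean of `knn_2ppm` and
#' `pls_10ppm`).  Four trailing rows repeat an earlier congener name with
#' near-identical values and one row carries a truncated name ("H"); both
#' conditions are flagged, not dropped, so the table keeps its printed
#' 94-row form.
#'
#' @return data.frame with columns `name`, `experimental`, `pls_2ppm`,
#'   `knn_2ppm`, `pls_10ppm`, `knn_10ppm`, `consensus`, `flag`.
#' @export
ahr_table2 <- function() {
  path <- system.file("extdata", "ahr_table2.csv", package = "qsdar3d",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  flag <- ifelse(duplicated(tab$name), "duplicate name", "")
  flag[tab$name == "H"] <- "truncated name"
  tab$flag <- flag
  tab
}

#' Run configuration
#'
#' Serializable bundle of everything a full run needs; `seed` is
#' mandatory.  Round-trips exactly through [write_run_config()] /
#' [read_run_config()].
#'
#' @param structures,shifts,activities input paths (may be `NA` for
#'   synthetic runs).
#' @param xy_widths,z_heights grid scan ranges (ppm, Angstrom).
#' @param n_cycles randomization cycles.
#' @param test_fraction hold-out proportion.
#' @param seed master seed.
#' @param lv_range,k_range engine hyperparameter ranges.
#' @param r2_mode `"pearson_sq"` or `"one_minus_ss"`.
#' @param outdir output directory.
#' @return object of class `sdar_run_config`.
#' @export
run_config <- function(structures = NA_character_, shifts = NA_character_,
                       activities = NA_character_,
                       xy_widths = seq(2, 20, by = 2),
                       z_heights = seq(0.5, 2.5, by = 0.5),
                       n_cycles = 100, test_fraction = 0.2, seed,
                       lv_range = 1:10, k_range = 1:10,
                       r2_mode = "pearson_sq", outdir = ".") {
  if (missing(seed) || !is_count(seed)) stopf("an integer 'seed' is required")
  structure(list(
    structures = structures, shifts = shifts, activities = activities,
    xy_widths = as.numeric(xy_widths), z_heights = as.numeric(z_heights),
    n_cycles = as.integer(n_cycles), test_fraction = as.numeric(test_fraction),
    seed = as.integer(seed), lv_range = as.integer(lv_range),
    k_range = as.integer(k_range), r2_mode = r2_mode,
    outdir = outdir), class = "sdar_run_config")
}

#' @rdname run_config
#' @param config an `sdar_run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc <- lapply(doc, function(x) if (is.null(x)) NA_character_ else x)
  do.call(run_config, doc)
}

#' Write a report of a full modeling run
#'
#' Emits the standard CSV outputs into `outdir`: per-compound averaged
#' predictions (one row per compound, one column per composite and
#' consensus model), the hyperparameter scan table, the consensus summary
#' (member R^2, consensus R^2, percent improvement per pair) and the bin
#' attribution table, plus a run log echoing the seed and configuration.
#' No timestamps are written, so identical runs produce byte-identical
#' files.
#'
#' @param outdir output directory (created if needed).
#' @param y named observed activities (optional).
#' @param composites named list of `sdar_composite` objects (optional).
#' @param consensus list of `sdar_consensus` objects (optional).
#' @param scan an `sdar_scan` table (optional).
#' @param attributions a [back_project()] table (optional).
#' @param config an `sdar_run_config` (optional; echoed in the log).
#' @param seed seed to record when no config is given.
#' @return invisible character vector of files written.
#' @export
write_report <- function(outdir, y = NULL, composites = NULL,
                         consensus = NULL, scan = NULL, attributions = NULL,
                         config = NULL, seed = NULL) {
  if (is.null(composites) && is.null(consensus) && is.null(scan) &&
      is.null(attributions))
    stopf("nothing to report")
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", outdir)
  written <- character(0)
  emit <- function(name) {
    f <- file.path(outdir, name)
    written <<- c(written, f)
    f
  }
  if (!is.null(composites) || !is.null(consensus)) {
    ids <- if (!is.null(composites))
      names(composites[[1]]$avg_prediction)
    else names(consensus[[1]]$prediction)
    pred <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
    if (!is.null(y)) pred$experimental <- as.numeric(y[ids])
    for (nm in names(composites))
      pred[[nm]] <- round_half_up(composites[[nm]]$avg_prediction[ids], 2)
    for (ki in seq_along(consensus)) {
      nm <- paste0("consensus_", ki)
      pred[[nm]] <- round_half_up(consensus[[ki]]$prediction[ids], 2)
    }
    utils::write.csv(pred, emit("predictions.csv"), row.names = FALSE,
                     quote = 1)
  }
  if (!is.null(scan)) write_scan(scan, emit("scan.csv"))
  if (!is.null(consensus)) {
    cons_tab <- do.call(rbind, lapply(consensus, function(cn) {
      data.frame(model_1 = cn$members[1], model_2 = cn$members[2],
                 r2_member_1 = cn$member_r2[1], r2_member_2 = cn$member_r2[2],
                 r2_consensus = cn$r2_consensus,
                 improvement_pct = cn$improvement_pct,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(cons_tab, emit("consensus.csv"), row.names = FALSE,
                     quote = c(1, 2))
  }
  if (!is.null(attributions))
    write_attribution(attributions, emit("attributions.csv"))
  log_lines <- c("qsdar3d run report")
  if (!is.null(config)) {
    log_lines <- c(log_lines, sprintf("seed: %d", config$seed), "config:",
                   jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                    digits = NA, na = "null", pretty = TRUE))
  } else if (!is.null(seed)) {
    log_lines <- c(log_lines, sprintf("seed: %d", seed))
  }
  writeLines(log_lines, emit("run_log.txt"))
  invisible(written)
}
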