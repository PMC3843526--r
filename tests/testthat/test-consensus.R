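test_that("consensus is the exact arithmetic mean with half-up display", {
  expect_equal(unname(round_half_up(consensus_predict(c(a = 7.66), c(a = 7.10)))),
               7.38)
  expect_equal(unname(round_half_up(consensus_predict(c(a = 5.61), c(a = 3.30)))),
               4.46)
  p <- c(x = 5.2, y = 6.1)
  expect_equal(consensus_predict(p, p), p)
  # names align even when ordered differently
  expect_equal(consensus_predict(c(x = 1, y = 3), c(y = 5, x = 3)),
               c(x = 2, y = 4))
  expect_error(consensus_predict(c(x = 1), c(z = 1)), "different compound")
  # exactness at full precision over random inputs
  set.seed(901)
  a <- rnorm(50); b <- rnorm(50)
  names(a) <- names(b) <- paste0("c", 1:50)
  expect_equal(max(abs(consensus_predict(a, b) - (a + b) / 2)), 0)
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(4.455, 2), 4.46)
  expect_equal(round_half_up(6.935, 2), 6.94)
  expect_equal(round_half_up(-4.455, 2), -4.46)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(10.483, 1), 10.5)
})

test_that("percent improvement reproduces the published accounting", {
  expect_equal(improvement_pct(0.685, 0.620), 10.5)
  expect_equal(improvement_pct(0.633, 0.611), 3.6)
  expect_equal(improvement_pct(0.5, 0.5), 0)
  expect_equal(improvement_pct(0.685, c(0.617, 0.622)),
               improvement_pct(0.685, 0.6195))
  expect_error(improvement_pct(0.5, 0), "positive")
})

test_that("consensus of two composites improves or matches the members", {
  ds <- small_synth(n = 40, noise_sd = 0.4, seed = 406)
  occ <- occupancy_of(ds)
  plan <- make_split_plan(40, 30, 0.2, seed = 12)
  cp <- run_composite(occ, ds$activities, plan, pls_engine(5),
                      keep_models = FALSE)
  ck <- run_composite(occ, ds$activities, plan, knn_engine(4))
  cons <- consensus_model(cp, ck, ds$activities)
  expect_equal(cons$prediction,
               (cp$avg_prediction + ck$avg_prediction) / 2)
  expect_equal(cons$improvement_pct,
               improvement_pct(cons$r2_consensus, cons$member_r2))
  # averaging more than two members
  multi <- consensus_predict_multi(cp$avg_prediction, ck$avg_prediction,
                                   cons$prediction)
  expect_equal(unname(multi),
               unname((cp$avg_prediction + ck$avg_prediction +
                         cons$prediction) / 3))
})

test_that("top-bin extraction takes the extremes of every LV weight vector", {
  plan <- make_split_plan(20, 1, 0.5, seed = 13)
  w <- matrix(c(3, -1, 2), 3, 1,
              dimnames = list(c("1_1_1", "2_2_2", "3_3_3"), NULL))
  fake <- structure(list(engine = structure(list(engine = "PLS", n_lv = 1L),
                                            class = "sdar_engine"),
                         models = list(w), plan = plan),
                    class = "sdar_composite")
  picks <- extract_top_bins(fake, n_top = 1)
  expect_equal(picks$bin[picks$sign == "positive"], "1_1_1")  # argmax
  expect_equal(picks$bin[picks$sign == "negative"], "2_2_2")  # argmin
  expect_equal(nrow(picks), 2)
  # 1 cycle x 1 LV x top-10 both signs -> 20 entries when bins suffice
  w10 <- matrix(rnorm(25), 25, 1,
                dimnames = list(sprintf("1_1_%d", 1:25), NULL))
  fake$models <- list(w10)
  expect_equal(nrow(extract_top_bins(fake, 10)), 20)
  # shortfall: fewer bins than n_top takes all and reports
  expect_message(short <- extract_top_bins(fake, 30), "fewer than 30")
  expect_equal(nrow(short), 50)
  expect_error(extract_top_bins(
    structure(list(engine = structure(list(engine = "KNN", k = 1L),
                                      class = "sdar_engine"), models = NULL),
              class = "sdar_composite")), "keep_models")
})

test_that("bin ranking keeps the top fraction per sign deterministically", {
  ext <- data.frame(
    cycle = 1, lv = 1,
    bin = c(rep("1_1_1", 5), rep("2_1_1", 3), rep("3_1_1", 2),
            rep("9_9_9", 4)),
    sign = c(rep("positive", 10), rep("negative", 4)),
    weight = 1,
    i = c(rep(1, 5), rep(2, 3), rep(3, 2), rep(9, 4)),
    j = c(rep(1, 10), rep(9, 4)), k = c(rep(1, 10), rep(9, 4)))
  sel <- rank_and_select_bins(ext, top_fraction = 0.2)
  # ceil(0.2 * 3) = 1 positive bin survives: the most frequent one
  pos <- sel[sel$sign == "positive", ]
  expect_equal(pos$bin, "1_1_1")
  expect_equal(pos$frequency, 0.5)          # 5 of 10 positive extractions
  neg <- sel[sel$sign == "negative", ]
  expect_equal(neg$bin, "9_9_9")
  expect_equal(neg$frequency, 1)
  expect_error(rank_and_select_bins(ext[0, ]), "empty")
  # frequency ties break lexicographically on the bin triple
  tie <- data.frame(cycle = 1, lv = 1,
                    bin = c("2_5_1", "1_9_9"), sign = "positive",
                    weight = 1, i = c(2, 1), j = c(5, 9), k = c(1, 9))
  sel_tie <- rank_and_select_bins(tie, top_fraction = 0.5)
  expect_equal(sel_tie$bin, "1_9_9")
})

test_that("sign overlap in the selection is reported as a finding", {
  both <- data.frame(cycle = 1, lv = 1, bin = "5_5_5",
                     sign = c("positive", "negative"), weight = c(1, -1),
                     i = 5, j = 5, k = 5)
  expect_message(sel <- rank_and_select_bins(both, 1), "both signs")
  expect_equal(attr(sel, "sign_overlap"), "5_5_5")
})

test_that("back-projection recovers the supporting atom pairs", {
  g <- grid_spec(10, 0.5)
  fp <- build_fingerprint(toy3())
  bins <- data.frame(sign = "positive", i = 1, j = 2, k = 3,
                     bin = "1_2_3", frequency = 0.8)
  attr_tab <- back_project(bins, fp, g)
  # the (10, 20, 1.5) element of atoms 1 and 2 lands in bin (1, 2, 3)
  expect_equal(nrow(attr_tab), 1)
  expect_equal(attr_tab$atom_i, 1)
  expect_equal(attr_tab$atom_j, 2)
  expect_equal(attr_tab$compound_id, "toy3")
  # empty selection gives an empty table
  expect_equal(nrow(back_project(bins[0, ], fp, g)), 0)
  # coincident symmetric elements produce one row each
  fp2 <- rbind(fp, fp[1, ])
  expect_equal(nrow(back_project(bins, fp2, g)), 2)
  # round-trip: every attribution row re-bins into its claimed bin
  ds <- small_synth(n = 20, seed = 407)
  fps <- build_fingerprints(ds$compounds)
  occ <- occupancy_of(ds)
  plan <- make_split_plan(20, 5, 0.2, seed = 14)
  cp <- run_composite(occ, ds$activities, plan, pls_engine(3))
  sel <- rank_and_select_bins(extract_top_bins(cp, 5), 0.2)
  proj <- back_project(sel, fps, ds$truth$signal_grid)
  rebinned <- bin_index(proj$shift_x, proj$shift_y, proj$distance,
                        ds$truth$signal_grid)
  expect_equal(unname(rebinned[, "i"]), proj$i)
  expect_equal(unname(rebinned[, "j"]), proj$j)
  expect_equal(unname(rebinned[, "k"]), proj$k)
})
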