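# Shared in-code fixtures for the test suite.

# Three collinear carbons at x = 0, 1.5, 3.0 A with shifts 10, 20, 30 ppm:
# elements (10,20,1.5), (20,30,1.5), (10,30,3.0) by hand enumeration.
toy3 <- function() {
  compound("toy3", rep("C", 3),
           cbind(c(0, 1.5, 3.0), 0, 0), c(10, 20, 30))
}

# Two equivalent aromatic-like carbons 5.52 A apart, both at 116.94 ppm,
# plus a third distinct carbon, echoing a dioxin-core shift pair.
tcdd_like <- function() {
  compound("tcdd_like", rep("C", 3),
           cbind(c(0, 5.52, 2.76), c(0, 0, 1.2), 0),
           c(116.94, 116.94, 140.0))
}

# Random compound with n carbons; optionally a few heteroatoms mixed in.
random_compound <- function(id, n, heteroatoms = 0) {
  elements <- c(rep("C", n), rep("O", heteroatoms))
  ord <- sample(length(elements))
  compound(id, elements[ord],
           matrix(runif(length(elements) * 3, 0, 8), ncol = 3),
           runif(n, 10, 180))
}

# Small planted-signal dataset shared by several tests; coarse distance
# axis keeps the descriptor count near the training-set size so the
# planted linear map is identifiable.
small_synth <- function(n = 50, noise_sd = 0, seed = 401) {
  generate_synthetic_dataset(synthetic_spec(
    n_compounds = n, noise_sd = noise_sd,
    signal_grid = grid_spec(10, 2.5), seed = seed))
}

occupancy_of <- function(ds, grid = ds$truth$signal_grid) {
  fp <- build_fingerprints(ds$compounds)
  build_occupancy_matrix(fp, grid, compound_ids = names(ds$activities))
}

# Minimal composite stand-in for diagnostics that only consume per-cycle
# R^2 sequences and the shared plan.
fake_composite <- function(r2, plan, r2_mode = "pearson_sq") {
  structure(list(engine = structure(list(engine = "PLS", n_lv = 1L),
                                    class = "sdar_engine"),
                 grid = NULL, hyper = 1L, r2_mode = r2_mode,
                 cycles = data.frame(cycle = seq_along(r2), r2_test = r2),
                 plan = plan),
            class = "sdar_composite")
}
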