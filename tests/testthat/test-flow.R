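make_events <- function(cd45, cd3 = cd45, cd4 = 10, cd8 = 10,
                        scatter = 300, is_bead = FALSE) {
  n <- max(lengths(list(cd45, cd3, cd4, cd8, scatter, is_bead)))
  tibble::tibble(event_id = seq_len(n), is_bead = rep_len(is_bead, n),
                 scatter_side = rep_len(scatter, n),
                 cd45 = rep_len(cd45, n), cd3 = rep_len(cd3, n),
                 cd4 = rep_len(cd4, n), cd8 = rep_len(cd8, n))
}

test_that("gating reproduces the generator's truth labels exactly", {
  tissue <- homogeneous_tissue(seed = 7)
  for (s in c(1, 2, 3)) {
    tube <- flow_run(tissue, flow_sim_config(seed = s))
    counts <- gate_counts(tube)
    truth <- attr(tube, "truth_counts")
    get_node <- function(node) counts$count[counts$node == node]
    expect_identical(get_node("beads"), as.integer(truth[["bead"]]))
    expect_identical(get_node("t_cells"), as.integer(truth[["T_total"]]))
    expect_identical(get_node("cd4"), as.integer(truth[["T_CD4"]]))
    expect_identical(get_node("cd8"), as.integer(truth[["T_CD8"]]))
    expect_identical(get_node("lymphocytes"),
                     as.integer(truth[["T_total"]] + truth[["non_T"]]))
  }
})

test_that("events below the CD45 threshold are excluded everywhere", {
  ev <- make_events(cd45 = rep(10, 50), cd3 = 5000, cd4 = 5000)
  counts <- gate_counts(ev)
  for (node in c("lymphocytes", "t_cells", "cd4", "cd8")) {
    expect_equal(counts$count[counts$node == node], 0)
  }
})

test_that("double positives are excluded from both subsets, reported apart", {
  ev <- dplyr::bind_rows(
    make_events(cd45 = rep(5000, 4), cd3 = 5000, cd4 = 5000, cd8 = 5000),
    make_events(cd45 = rep(5000, 3), cd3 = 5000, cd4 = 5000, cd8 = 10),
    make_events(cd45 = rep(5000, 2), cd3 = 5000, cd4 = 10, cd8 = 5000),
    make_events(cd45 = rep(5000, 1), cd3 = 5000, cd4 = 10, cd8 = 10)
  )
  counts <- gate_counts(ev)
  get_node <- function(node) counts$count[counts$node == node]
  expect_equal(get_node("double_positive"), 4)
  expect_equal(get_node("cd4"), 3)
  expect_equal(get_node("cd8"), 2)
  expect_equal(get_node("double_negative"), 1)
  # partition of the CD3 gate
  expect_equal(get_node("cd4") + get_node("cd8") + get_node("double_positive") +
                 get_node("double_negative"), get_node("t_cells"))
})

test_that("gate hierarchy is monotone on simulated tubes", {
  tube <- flow_run(homogeneous_tissue(seed = 7), flow_sim_config(seed = 8))
  counts <- gate_counts(tube)
  get_node <- function(node) counts$count[counts$node == node]
  expect_lte(get_node("t_cells"), get_node("lymphocytes"))
  expect_lte(get_node("lymphocytes"), get_node("non_bead"))
  expect_equal(get_node("non_bead") + get_node("beads"), get_node("total"))
})

test_that("empty event tables warn and return zero counts", {
  empty <- make_events(cd45 = 10)[0, ]
  expect_warning(counts <- gate_counts(empty), "empty")
  expect_true(all(counts$count == 0))
})

test_that("the bead-ratio formula gives absolute concentrations", {
  expect_equal(trucount_concentration(500, 1000, 1040), 520)
  expect_equal(trucount_concentration(0, 1000, 1040), 0)
  expect_error(trucount_concentration(500, 0, 1040), "bead")
  # scale invariance: acquiring twice as much changes nothing
  expect_equal(trucount_concentration(1000, 2000, 1040),
               trucount_concentration(500, 1000, 1040))
})

test_that("the bead-ratio estimator is unbiased for a known concentration", {
  tissue <- homogeneous_tissue(seed = 7)
  cfg0 <- flow_sim_config()
  true_conc <- sum(tissue$in_core) * cfg0$recovery_fraction /
    cfg0$suspension_volume_ul
  ests <- sapply(1:50, function(s) {
    tube <- flow_run(tissue, flow_sim_config(seed = s))
    counts <- gate_counts(tube)
    trucount_concentration(counts$count[counts$node == "t_cells"],
                           counts$count[counts$node == "beads"],
                           tube$beads_per_ul)
  })
  expect_equal(mean(ests), true_conc, tolerance = 0.02)
})

test_that("per-biopsy and per-mm3 conversion matches the reported yields", {
  out <- per_biopsy_and_density(174.939, 1000, 1, 24)
  expect_equal(out$cells_per_biopsy, 174939)
  expect_equal(round(out$cells_per_mm3), 7289)
  # single biopsy, unit volume identity
  unit <- per_biopsy_and_density(5, 1, 1, 1)
  expect_equal(unit$cells_per_biopsy, 5)
  zero <- per_biopsy_and_density(0, 1000, 30, 24)
  expect_equal(zero$cells_per_biopsy, 0)
  expect_equal(zero$cells_per_mm3, 0)
  expect_error(per_biopsy_and_density(5, 1000, 0), "n_biopsies")
})

test_that("subset percentages split CD4/CD8 to the nearest integer", {
  p <- subset_percentages(4549, 2708)
  expect_equal(p$cd4_pct, 63)
  expect_equal(p$cd8_pct, 37)
  expect_equal(subset_percentages(1, 1)$cd4_pct, 50)
  expect_equal(subset_percentages(10, 0)$cd4_pct, 100)
  expect_equal(subset_percentages(10, 0)$cd8_pct, 0)
  expect_error(subset_percentages(0, 0), "undefined")
})
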