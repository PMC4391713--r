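test_that("tissue generation is a pure function of config and seed", {
  sim <- tissue_sim(seed = 3)
  a <- generate_tissue(sim)
  b <- generate_tissue(sim)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_tissue(tissue_sim(seed = 4))
  expect_false(nrow(a) == nrow(c) && identical(a$x, c$x))
})

test_that("zero density yields an empty table", {
  sim <- tissue_sim(lamina_propria_mm3 = 0, epithelium_mm3 = 0,
                    epithelium_depth_mm = 0, aggregates_per_section = 0,
                    seed = 1)
  expect_equal(nrow(generate_tissue(sim)), 0)
})

test_that("cell counts follow the Poisson mean at the study density", {
  tissue <- homogeneous_tissue(seed = 7)
  n_core <- sum(tissue$in_core)
  lambda <- 37400 * 24
  expect_lt(abs(n_core - lambda), 4 * sqrt(lambda))
})

test_that("compartment labels are conserved and aggregates are denser", {
  sim <- tissue_sim(seed = 9)
  tissue <- generate_tissue(sim)
  expect_equal(sum(table(tissue$compartment)), nrow(tissue))
  expect_setequal(unique(tissue$compartment),
                  c("epithelium", "lamina_propria", "lymphoid_aggregate"))
  # marker split close to the configured 57/40/3
  split <- prop.table(table(tissue$marker))
  expect_equal(unname(split[["CD4"]]), 0.57, tolerance = 0.01)
  expect_equal(unname(split[["CD8"]]), 0.40, tolerance = 0.01)
})

test_that("section counts recover the generating density within 5%", {
  tissue <- homogeneous_tissue(seed = 7)
  regions <- section_counts(tissue, n_regions = 30, seed = 13)
  expect_true(all(regions$count == round(regions$count)))
  est <- estimate_densities(regions)
  expect_equal(est$density_mm3, 37400, tolerance = 0.05)
})

test_that("empty tissue gives all-zero section counts", {
  sim <- tissue_sim(lamina_propria_mm3 = 0, epithelium_mm3 = 0,
                    epithelium_depth_mm = 0, aggregates_per_section = 0,
                    seed = 1)
  tissue <- generate_tissue(sim)
  attr(tissue, "sim") <- sim
  regions <- section_counts(tissue, n_regions = 5, seed = 1)
  expect_true(all(regions$count == 0))
})

test_that("a single cell appears in expected_sections sections on average", {
  model <- sectioning_model()
  spec <- section_spec()
  t_mm <- spec$thickness_um / 1000
  appearances <- sapply(1:400, function(s) {
    z <- withr::with_seed(s, runif(1, 0.4, 0.6))
    tissue <- tibble::tibble(x = 0.5, y = 0.5, z = z,
                             compartment = "lamina_propria", marker = "CD4",
                             in_core = TRUE)
    attr(tissue, "sim") <- tissue_sim(dims_mm = c(1, 1, 1), seed = 1)
    # count this cell across every section by full-face regions
    half_vis <- (model$diameter_um / 2 - model$min_cap_depth_um) / 1000
    sum(sapply(seq_len(round(1 / t_mm)) - 1, function(k) {
      (z + half_vis) > k * t_mm && (z - half_vis) < (k + 1) * t_mm
    }))
  })
  expect_equal(mean(appearances), expected_sections(model), tolerance = 0.03)
})

test_that("counter_pair reduces to identity without noise and reproduces the gain", {
  true_counts <- seq(100, 1000, by = 25)
  clean <- counter_pair(true_counts, manual_cv = 0, automated_cv = 0,
                        automated_gain = 1, seed = 1)
  expect_identical(clean$manual, clean$automated)
  fit <- ols_concordance(clean, manual, automated)
  expect_equal(fit$r_squared, 1)

  gained <- counter_pair(true_counts, manual_cv = 0, automated_cv = 0,
                         automated_gain = 1.04, seed = 1)
  fit2 <- ols_concordance(gained, manual, automated)
  expect_equal(fit2$slope, 1.04, tolerance = 1e-10)
})

test_that("flow run is deterministic, conservative, and recovers recovery 1", {
  tissue <- homogeneous_tissue(seed = 7)
  cfg <- flow_sim_config(seed = 5)
  t1 <- flow_run(tissue, cfg)
  t2 <- flow_run(tissue, cfg)
  expect_identical(as.data.frame(t1$events), as.data.frame(t2$events))
  # never emits more cells than the tissue contains
  expect_lte(sum(!t1$events$is_bead & grepl("^T_", t1$events$truth)),
             sum(tissue$in_core))

  full <- flow_run(tissue, flow_sim_config(recovery_fraction = 1,
                                           acquisition_fraction = 1,
                                           sample_volume_ul = 1000,
                                           seed = 5))
  yields <- quantify_tube(full)
  expect_equal(yields$cells_per_mm3[yields$marker == "CD3"],
               sum(tissue$in_core) / 24, tolerance = 0.01)
})

test_that("empty tissue yields a beads-only tube", {
  sim <- tissue_sim(lamina_propria_mm3 = 0, epithelium_mm3 = 0,
                    epithelium_depth_mm = 0, aggregates_per_section = 0,
                    seed = 1)
  tube <- flow_run(generate_tissue(sim), flow_sim_config(seed = 2))
  expect_true(all(tube$events$is_bead))
  expect_gt(nrow(tube$events), 0)
})

test_that("the flow branch measures what was recovered, not what is resident", {
  tissue <- homogeneous_tissue(seed = 7)
  tube <- flow_run(tissue, flow_sim_config(recovery_fraction = 0.20, seed = 17))
  yields <- quantify_tube(tube)
  true_density <- sum(tissue$in_core) / 24
  expect_equal(yields$cells_per_mm3[yields$marker == "CD3"],
               true_density * 0.20, tolerance = 0.06)
})
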