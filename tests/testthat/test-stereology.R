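test_that("areal density divides counts by region area", {
  cases <- list(
    list(count = 0, area = 2.0, expected = 0.0),
    list(count = 502, area = 1.0, expected = 502.0),
    list(count = 10, area = 0.25, expected = 40.0)
  )
  for (cs in cases) {
    out <- areal_density(region_row(cs$count, cs$area))
    expect_equal(out$areal_density, cs$expected)
  }
  expect_error(areal_density(region_row(5, area = 0)), "area")
  expect_error(areal_density(region_row(5, area = -1)), "area")
  expect_error(areal_density(region_row(-2)), "count")
})

test_that("region averaging gives unweighted mean and SD/sqrt(n) SEM", {
  three_same <- dplyr::bind_rows(lapply(1:3, function(i) region_row(100)))
  avg <- average_regions(three_same)
  expect_equal(avg$mean_areal, 100)
  expect_equal(avg$sem_areal, 0)
  expect_equal(avg$n_regions, 3L)

  spread <- dplyr::bind_rows(region_row(90), region_row(100), region_row(110))
  avg <- average_regions(spread)
  expect_equal(avg$mean_areal, 100)
  expect_equal(avg$sem_areal, 10 / sqrt(3), tolerance = 1e-10)
  expect_equal(round(avg$sem_areal, 4), 5.7735)

  single <- average_regions(region_row(42, area = 0.5))
  expect_equal(single$mean_areal, 84)
  expect_true(is.na(single$sem_areal))

  mixed <- dplyr::bind_rows(region_row(10, marker = "CD4"),
                            region_row(20, marker = "CD8"))
  expect_equal(nrow(average_regions(mixed)), 2) # markers never pooled

  expect_error(average_regions(region_row(1)[0, ]), "empty")
})

test_that("volumetric conversion is x slices_per_mm / appearance_factor", {
  expect_equal(areal_to_volumetric(0), 0)
  expect_equal(areal_to_volumetric(1), 250 / 3.356)
  expect_equal(round(areal_to_volumetric(1), 4), 74.4934)
  expect_equal(signif(areal_to_volumetric(502), 3), 37400)
  expect_error(section_spec(appearance_factor = 0.5), "appearance_factor")
  expect_error(areal_to_volumetric(-1), ">= 0")
})

test_that("areal to volumetric conversion round-trips to machine precision", {
  set.seed(11)
  for (i in 1:20) {
    spec <- section_spec(thickness_um = runif(1, 2, 10),
                         appearance_factor = runif(1, 1, 5))
    areal <- runif(1, 0, 1000)
    back <- areal_to_volumetric(areal, spec) * spec$appearance_factor /
      spec$slices_per_mm
    expect_equal(back, areal, tolerance = 1e-12)
  }
})

test_that("spherical cell volume follows (pi/6) d^3", {
  expect_equal(round(cell_volume(cell_morphology(12)), 2), 904.78)
  expect_equal(cell_volume(12, rounded = TRUE), 905)
  expect_equal(cell_volume(2), 4.18879, tolerance = 1e-5)
  expect_equal(cell_volume(0), 0)
  morph <- cell_morphology(12)
  expect_lt(abs(morph$volume_um3 - pi / 6 * 12^3), 0.5)
})

test_that("volume fraction converts density x cell volume to percent", {
  expect_equal(round(volume_fraction(37400, 905), 2), 3.38)
  expect_equal(round(volume_fraction(33700, 905), 2), 3.05)
  expect_equal(volume_fraction(0, 905), 0)
  # linear in both arguments
  expect_equal(volume_fraction(2 * 37400, 905), 2 * volume_fraction(37400, 905))
  expect_equal(volume_fraction(37400, 2 * 905), 2 * volume_fraction(37400, 905))
  # physically sensible packings stay below 100%
  set.seed(5)
  d <- runif(50, 0, 5e4)
  v <- runif(50, 100, 2000)
  keep <- d * v * 1e-9 <= 1
  expect_true(all(volume_fraction(d[keep], v[keep]) <= 100))
})

test_that("mucosal shell volume matches the annular-cylinder formula", {
  sig <- shell_volume(segment_geometry("sigmoid", 350, 35))$volume_mm3
  rec <- shell_volume(segment_geometry("rectum", 50, 50))$volume_mm3
  expect_equal(sig, 350 * pi * (19^2 - 17.5^2))
  expect_gt(sig, 60160); expect_lt(sig, 60220)
  expect_gt(rec, 12100); expect_lt(rec, 12170)
  flat <- shell_volume(segment_geometry("x", 10, 10, mucosal_thickness_mm = 0))
  expect_equal(flat$volume_mm3, 0)
  expect_error(segment_geometry("x", -1, 10), "positive")
})

test_that("shell volume agrees with Monte-Carlo rejection sampling within 1%", {
  geom <- segment_geometry("sigmoid", 350, 35)
  analytic <- shell_volume(geom)$volume_mm3
  set.seed(99)
  n <- 1e6
  r_out <- geom$outer_radius_mm
  x <- runif(n, -r_out, r_out)
  y <- runif(n, -r_out, r_out)
  r2 <- x^2 + y^2
  inside <- r2 <= r_out^2 & r2 >= geom$inner_radius_mm^2
  mc <- mean(inside) * (2 * r_out)^2 * geom$length_mm
  expect_equal(mc, analytic, tolerance = 0.01)
})

test_that("segment totals reproduce the reported extrapolations", {
  sig_v <- shell_volume(segment_geometry("sigmoid", 350, 35))$volume_mm3
  rec_v <- shell_volume(segment_geometry("rectum", 50, 50))$volume_mm3
  expect_equal(signif(total_cells(37400, sig_v), 3), 2.25e9)
  expect_equal(signif(total_cells(33700, rec_v), 3), 4.09e8)
  expect_equal(signif(total_cells(37400, sig_v) + total_cells(33700, rec_v), 3),
               2.66e9)
  expect_equal(total_cells(0, sig_v), 0)
})

test_that("subset densities scale the parent by the dual-label fraction", {
  expect_equal(subset_density(37400, 0.57), 21318)
  expect_equal(subset_density(37400, 0.40), 14960)
  expect_equal(subset_density(37400, 0), 0)
  expect_error(subset_density(100, 1.2), "0, 1")
  expect_error(subset_density(100, -0.1), "0, 1")
})

test_that("the two extrapolation routes agree internally and flag external fractions", {
  dens <- tibble::tibble(site = "sigmoid", marker = "CD3", density_mm3 = 37400)
  out <- extrapolate_totals(dens)
  expect_false(out$routes_disagree)
  expect_equal(out$total_by_density, out$total_by_fraction, tolerance = 1e-10)
  # a reported fraction inconsistent with its density trips the flag
  dens2 <- tibble::tibble(site = "sigmoid", marker = "CD4",
                          density_mm3 = 21300, volume_fraction_pct = 2.07)
  out2 <- extrapolate_totals(dens2)
  expect_true(out2$routes_disagree)
})

test_that("estimate_densities summarises across samples with SD/sqrt(n) SEM", {
  regions <- dplyr::bind_rows(
    region_row(400, sample_id = "a"), region_row(420, sample_id = "a"),
    region_row(500, sample_id = "b"), region_row(520, sample_id = "b")
  )
  est <- estimate_densities(regions)
  expect_equal(nrow(est), 1)
  expect_equal(est$n_samples, 2L)
  per_sample <- c(areal_to_volumetric(410), areal_to_volumetric(510))
  expect_equal(est$density_mm3, mean(per_sample))
  expect_equal(est$sem_mm3, sd(per_sample) / sqrt(2))
  expect_equal(est$provenance, "IHC-manual")
})

test_that("site-level density is the unweighted mean over compartments", {
  regions <- dplyr::bind_rows(
    region_row(100, compartment = "epithelium"),
    region_row(300, compartment = "lamina_propria")
  )
  est <- estimate_densities(regions)
  expect_equal(est$density_mm3, areal_to_volumetric(200))
})
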