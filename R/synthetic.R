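#' Synthetic biopsy tissue configuration
#'
#' Describes a virtual mucosal biopsy block populated by a homogeneous
#' Poisson point process of T lymphocytes per compartment. The default
#' block is the nominal 8 x 3 x 1 mm biopsy (24 mm^3). Compartments:
#' an epithelial band of configurable depth along the y axis, spherical
#' lymphoid aggregates of elevated density placed Poisson-randomly, and
#' lamina propria everywhere else. Setting `epithelium_depth_mm = 0` and
#' `aggregates_per_section = 0` yields a homogeneous block at the lamina
#' propria density.
#'
#' @param dims_mm Block dimensions in mm, `c(x, y, z)`; sections are cut
#'   perpendicular to z. Default `c(8, 3, 1)`.
#' @param lamina_propria_mm3 Lamina propria T-cell density, cells/mm^3.
#'   Default 37,400 (the sigmoid CD3 regime).
#' @param epithelium_mm3 Epithelial band density, cells/mm^3. Default
#'   20,000 (sparser intraepithelial population).
#' @param epithelium_depth_mm Depth of the epithelial band from the y = 0
#'   face, mm. Default 0.25.
#' @param aggregate_multiplier Density inside lymphoid aggregates relative
#'   to lamina propria. Default 3.
#' @param aggregate_radius_mm Aggregate sphere radius, mm. Default 0.15.
#' @param aggregates_per_section Expected number of aggregates intersecting
#'   any one section; sets the aggregate placement intensity. Default 1.33.
#' @param cell_diameter_um Cell diameter, um. Default 12.
#' @param marker_split Named proportions of CD4 / CD8 / other among CD3+
#'   cells; must sum to 1. Default `c(CD4 = 0.57, CD8 = 0.40, other = 0.03)`.
#' @param seed Integer seed; the generated tissue is a pure function of the
#'   configuration and seed.
#' @return A `tissue_sim` configuration list.
#' @export
tissue_sim <- function(dims_mm = c(8, 3, 1),
                       lamina_propria_mm3 = 37400,
                       epithelium_mm3 = 20000,
                       epithelium_depth_mm = 0.25,
                       aggregate_multiplier = 3,
                       aggregate_radius_mm = 0.15,
                       aggregates_per_section = 1.33,
                       cell_diameter_um = 12,
                       marker_split = c(CD4 = 0.57, CD8 = 0.40, other = 0.03),
                       seed = 1) {
  if (any(dims_mm <= 0)) abort_config("Block dimensions must be positive.")
  if (lamina_propria_mm3 < 0 || epithelium_mm3 < 0) {
    abort_config("Densities must be non-negative.")
  }
  if (epithelium_depth_mm < 0 || epithelium_depth_mm > dims_mm[2]) {
    abort_config("`epithelium_depth_mm` must lie in [0, dims_mm[2]].")
  }
  if (abs(sum(marker_split) - 1) > 1e-8) {
    abort_config("`marker_split` proportions must sum to 1.")
  }
  structure(
    list(dims_mm = dims_mm,
         lamina_propria_mm3 = lamina_propria_mm3,
         epithelium_mm3 = epithelium_mm3,
         epithelium_depth_mm = epithelium_depth_mm,
         aggregate_multiplier = aggregate_multiplier,
         aggregate_radius_mm = aggregate_radius_mm,
         aggregates_per_section = aggregates_per_section,
         cell_diameter_um = cell_diameter_um,
         marker_split = marker_split,
         seed = as.integer(seed)),
    class = "tissue_sim"
  )
}

#' Generate a synthetic 3D cell table
#'
#' Draws cell positions per compartment from homogeneous Poisson point
#' processes at the configured densities, assigns CD4/CD8/other marker
#' labels multinomially, and flags whether each cell centre lies inside the
#' biopsy block. A guard margin of one cell diameter surrounds the block so
#' that section counts near the faces are unbiased (cells whose centres lie
#' just outside the block can still contribute profiles).
#'
#' @param sim A [tissue_sim()] configuration.
#' @return A tibble with columns `x`, `y`, `z` (mm), `compartment`,
#'   `marker` and `in_core` (centre inside the block). The configuration is
#'   attached as attribute `"sim"`.
#' @examples
#' tissue <- generate_tissue(tissue_sim(seed = 42))
#' nrow(tissue)
#' @export
generate_tissue <- function(sim) {
  stopifnot(inherits(sim, "tissue_sim"))
  g <- sim$cell_diameter_um / 1000  # guard margin, mm
  lo <- -g
  hi <- sim$dims_mm + g
  ext <- hi - lo

  withr::with_seed(sim$seed, {
    # base field: epithelium band vs lamina propria, over the extended box
    depth <- sim$epithelium_depth_mm
    vol_epi <- ext[1] * ext[3] * (depth + g)  # y in [-g, depth)
    vol_lp <- ext[1] * ext[3] * (ext[2] - (depth + g))
    draw_uniform <- function(n, y_range) {
      tibble(
        x = runif(n, lo, sim$dims_mm[1] + g),
        y = runif(n, y_range[1], y_range[2]),
        z = runif(n, lo, sim$dims_mm[3] + g)
      )
    }
    n_epi <- if (depth > 0) rpois(1, sim$epithelium_mm3 * vol_epi) else 0L
    n_lp <- rpois(1, sim$lamina_propria_mm3 * vol_lp)
    cells <- bind_rows(
      if (n_epi > 0) mutate(draw_uniform(n_epi, c(-g, depth)),
                            compartment = "epithelium"),
      if (n_lp > 0) mutate(draw_uniform(n_lp, c(depth, sim$dims_mm[2] + g)),
                           compartment = "lamina_propria")
    )
    if (!"x" %in% names(cells)) {
      cells <- tibble(x = double(), y = double(), z = double(),
                      compartment = character())
    }

    # lymphoid aggregates: Poisson number of spheres at an intensity giving
    # the configured expected aggregates per section, each topped up with
    # extra cells to reach multiplier x lamina propria density
    r_agg <- sim$aggregate_radius_mm
    if (sim$aggregates_per_section > 0 && r_agg > 0) {
      n_agg <- rpois(1, sim$aggregates_per_section * sim$dims_mm[3] / (2 * r_agg))
      if (n_agg > 0) {
        centres <- matrix(runif(3 * n_agg) , ncol = 3) %*% diag(sim$dims_mm)
        extra_rate <- (sim$aggregate_multiplier - 1) * sim$lamina_propria_mm3
        vol_sphere <- 4 / 3 * pi * r_agg^3
        extra <- purrr::map(seq_len(n_agg), function(i) {
          m <- rpois(1, extra_rate * vol_sphere)
          if (m == 0) return(NULL)
          # uniform in sphere by radius^(1/3) scaling
          u <- matrix(rnorm(3 * m), ncol = 3)
          u <- u / sqrt(rowSums(u^2)) * r_agg * runif(m)^(1 / 3)
          tibble(x = centres[i, 1] + u[, 1],
                 y = centres[i, 2] + u[, 2],
                 z = centres[i, 3] + u[, 3],
                 compartment = "lymphoid_aggregate")
        })
        cells <- bind_rows(cells, purrr::compact(extra))
        # relabel base cells falling inside any aggregate sphere
        if (nrow(cells) > 0) {
          inside <- rep(FALSE, nrow(cells))
          for (i in seq_len(n_agg)) {
            d2 <- (cells$x - centres[i, 1])^2 + (cells$y - centres[i, 2])^2 +
              (cells$z - centres[i, 3])^2
            inside <- inside | d2 <= r_agg^2
          }
          cells$compartment[inside] <- "lymphoid_aggregate"
        }
      }
    }

    n <- nrow(cells)
    cells$marker <- if (n > 0) {
      sample(names(sim$marker_split), n, replace = TRUE,
             prob = sim$marker_split)
    } else character()
    cells$in_core <- n > 0 &
      cells$x >= 0 & cells$x <= sim$dims_mm[1] &
      cells$y >= 0 & cells$y <= sim$dims_mm[2] &
      cells$z >= 0 & cells$z <= sim$dims_mm[3]
    attr(cells, "sim") <- sim
    cells
  })
}

#' Count visible cell profiles in random regions of random sections
#'
#' Virtually sections the tissue block perpendicular to z into
#' thickness-`t` slices, draws random rectangular regions of interest of
#' the given area on random sections, and counts, per region, the cell
#' profiles visible under the sectioning model (a cell contributes a
#' profile to every section overlapping its axial extent trimmed by the
#' visibility threshold at each pole).
#'
#' @param tissue A tibble from [generate_tissue()].
#' @param spec A [section_spec()]; its thickness defines the slice grid.
#' @param model A [sectioning_model()]; its cap-depth threshold defines
#'   profile visibility.
#' @param region_area_mm2 Area of each rectangular region of interest.
#' @param n_regions Number of regions to draw.
#' @param marker Which marker to count: `"CD3"` and `"CD45"` count every
#'   cell (all generated cells are CD45+CD3+ T lymphocytes); `"CD4"`,
#'   `"CD8"` or `"other"` count that subset.
#' @param sample_id,site,method Metadata stamped on the output rows.
#' @param seed Integer seed for region placement.
#' @return A region-count tibble (columns `sample_id`, `site`, `marker`,
#'   `compartment`, `area_mm2`, `count`, `method`) ready for
#'   [estimate_densities()].
#' @export
section_counts <- function(tissue, spec = section_spec(),
                           model = sectioning_model(), region_area_mm2 = 1,
                           n_regions = 30, marker = "CD3",
                           sample_id = "sim1", site = "sigmoid",
                           method = "manual", seed = 1) {
  sim <- attr(tissue, "sim")
  dims <- if (!is.null(sim)) sim$dims_mm else c(max(tissue$x), max(tissue$y), max(tissue$z))
  if (region_area_mm2 > dims[1] * dims[2]) {
    abort_input("`region_area_mm2` exceeds the section face area.")
  }
  t_mm <- spec$thickness_um / 1000
  n_sections <- max(1, floor(dims[3] / t_mm))
  half_vis <- (model$diameter_um / 2 - model$min_cap_depth_um) / 1000
  if (half_vis < 0) abort_input("No visible profile: h >= d/2.")

  keep <- if (marker %in% c("CD3", "CD45")) rep(TRUE, nrow(tissue)) else tissue$marker == marker
  cx <- tissue$x[keep]; cy <- tissue$y[keep]; cz <- tissue$z[keep]

  withr::with_seed(seed, {
    sec <- sample.int(n_sections, n_regions, replace = TRUE) - 1L
    w <- sqrt(region_area_mm2) * 2^runif(n_regions, -0.5, 0.5)
    w <- pmin(w, dims[1])
    hgt <- pmin(region_area_mm2 / w, dims[2])
    w <- region_area_mm2 / hgt
    x0 <- runif(n_regions, 0, dims[1] - w)
    y0 <- runif(n_regions, 0, dims[2] - hgt)
    counts <- integer(n_regions)
    for (i in seq_len(n_regions)) {
      z_lo <- sec[i] * t_mm
      z_hi <- z_lo + t_mm
      counts[i] <- sum(
        cx >= x0[i] & cx <= x0[i] + w[i] &
          cy >= y0[i] & cy <= y0[i] + hgt[i] &
          (cz + half_vis) > z_lo & (cz - half_vis) < z_hi
      )
    }
    tibble(
      sample_id = sample_id, site = site, marker = marker,
      compartment = "combined", area_mm2 = w * hgt,
      count = counts, method = method
    )
  })
}

#' Paired manual/automated counts with calibrated measurement noise
#'
#' Simulates the two enumeration methods counting the same regions:
#' multiplicative lognormal measurement noise per region (mean-corrected so
#' each method is unbiased up to its gain), a constant gain factor on the
#' automated method, and Poisson discreteness for small expected counts
#' (below `poisson_floor` the count is drawn from a Poisson; above, it is
#' rounded).
#'
#' @param true_counts Vector of true per-region counts.
#' @param manual_cv Coefficient of variation of manual counting noise.
#'   Default 0.05.
#' @param automated_cv Coefficient of variation of automated counting
#'   noise. Default 0.10.
#' @param automated_gain Multiplicative bias of the automated method.
#'   Default 1.04.
#' @param poisson_floor Expected-count threshold below which counts are
#'   Poisson-sampled. Default 30.
#' @param seed Integer seed.
#' @return A tibble with columns `true`, `manual`, `automated`.
#' @export
counter_pair <- function(true_counts, manual_cv = 0.05, automated_cv = 0.10,
                         automated_gain = 1.04, poisson_floor = 30,
                         seed = 1) {
  if (manual_cv < 0 || automated_cv < 0) abort_input("CVs must be >= 0.")
  n <- length(true_counts)
  noisy <- function(mu, cv) {
    if (cv == 0) return(mu)
    sdl <- sqrt(log(1 + cv^2))
    mu * exp(rnorm(n, 0, sdl) - sdl^2 / 2)
  }
  discretise <- function(m) {
    small <- m < poisson_floor
    out <- round(m)
    if (any(small)) out[small] <- rpois(sum(small), m[small])
    out
  }
  withr::with_seed(seed, {
    m_manual <- noisy(true_counts, manual_cv)
    m_auto <- noisy(true_counts * automated_gain, automated_cv)
    tibble(true = true_counts,
           manual = discretise(m_manual),
           automated = discretise(m_auto))
  })
}

#' Simulate a manual-vs-automated concordance study
#'
#' Draws true per-region counts with lognormal biological spread across
#' regions/subjects and applies [counter_pair()] noise, emulating a study
#' where the same fields are enumerated by eye and by algorithm.
#'
#' @param n_pairs Number of paired regions. Default 30 (three fields per
#'   site from five subjects at two sites).
#' @param median_count Median true count per region. Default 500.
#' @param sdlog_true Biological spread of true counts on the log scale.
#'   Default 0.35.
#' @param seed Integer seed.
#' @param ... Passed to [counter_pair()].
#' @return A tibble with `true`, `manual`, `automated`.
#' @export
simulate_concordance <- function(n_pairs = 30, median_count = 500,
                                 sdlog_true = 0.35, seed = 1, ...) {
  true_counts <- withr::with_seed(derive_seed(seed, "truth"), {
    rlnorm(n_pairs, log(median_count), sdlog_true)
  })
  counter_pair(true_counts, seed = derive_seed(seed, "pair"), ...)
}

#' Flow-run simulation configuration
#'
#' Parameters of the virtual isolation + TruCount acquisition: the fraction
#' of tissue cells surviving digestion and staining (recovery), the bead
#' tube, aliquoting volumes, fluorescence intensity model, and contaminant
#' populations that make hierarchical gating non-trivial.
#'
#' @param recovery_fraction Fraction of tissue cells recovered into the
#'   suspension. Default 0.20.
#' @param cd4_fraction,cd8_fraction Subset proportions used only when the
#'   tissue table carries no marker labels. Defaults 0.57 / 0.40.
#' @param separation Ratio of positive to negative mean fluorescence
#'   intensity. Default 30.
#' @param negative_mean Mean intensity of a negative channel. Default 100.
#' @param intensity_sdlog Lognormal sdlog of each intensity channel.
#'   Default 0.35.
#' @param bead_count Beads per tube. Default 50,000.
#' @param sample_volume_ul Suspension aliquot added to the tube, ul.
#'   Default 100.
#' @param suspension_volume_ul Total suspension volume, ul. Default 1,000.
#' @param n_biopsies Biopsies pooled into the suspension. Default 1.
#' @param acquisition_fraction Fraction of tube contents acquired by the
#'   cytometer; applies equally to cells and beads, so the bead-ratio
#'   estimate is invariant to it. Default 0.25.
#' @param non_t_fraction CD45+CD3- contaminant events as a fraction of T
#'   cells in the tube. Default 0.3.
#' @param debris_fraction CD45- debris events as a fraction of T cells in
#'   the tube. Default 0.5.
#' @param seed Integer seed.
#' @return A `flow_sim_config` list.
#' @export
flow_sim_config <- function(recovery_fraction = 0.20,
                            cd4_fraction = 0.57, cd8_fraction = 0.40,
                            separation = 30, negative_mean = 100,
                            intensity_sdlog = 0.35,
                            bead_count = 50000, sample_volume_ul = 100,
                            suspension_volume_ul = 1000, n_biopsies = 1,
                            acquisition_fraction = 0.25,
                            non_t_fraction = 0.3, debris_fraction = 0.5,
                            seed = 1) {
  if (recovery_fraction <= 0 || recovery_fraction > 1) {
    abort_config("`recovery_fraction` must lie in (0, 1].")
  }
  if (cd4_fraction + cd8_fraction > 1) {
    abort_config("Subset fractions must sum to at most 1.")
  }
  if (bead_count < 1) abort_config("`bead_count` must be >= 1.")
  if (sample_volume_ul <= 0 || suspension_volume_ul <= 0 ||
      sample_volume_ul > suspension_volume_ul) {
    abort_config("Need 0 < sample_volume_ul <= suspension_volume_ul.")
  }
  structure(
    list(recovery_fraction = recovery_fraction,
         cd4_fraction = cd4_fraction, cd8_fraction = cd8_fraction,
         separation = separation, negative_mean = negative_mean,
         intensity_sdlog = intensity_sdlog,
         bead_count = bead_count, sample_volume_ul = sample_volume_ul,
         suspension_volume_ul = suspension_volume_ul,
         n_biopsies = n_biopsies,
         acquisition_fraction = acquisition_fraction,
         non_t_fraction = non_t_fraction,
         debris_fraction = debris_fraction,
         seed = as.integer(seed)),
    class = "flow_sim_config"
  )
}

#' Simulate a TruCount flow run on a synthetic tissue
#'
#' Thins the tissue's cells binomially at the recovery fraction (the cells
#' that survive digestion and staining), aliquots them into a bead tube,
#' applies acquisition thinning equally to cells and beads, and draws
#' fluorescence intensities from well-separated lognormal positive /
#' negative populations. Contaminant CD45+CD3- lymphocytes and CD45-
#' debris are added so that the CD45/scatter and CD3 gates do real work.
#'
#' @param tissue A tibble from [generate_tissue()] (only `in_core` cells
#'   are digested).
#' @param cfg A [flow_sim_config()].
#' @return A `trucount_tube` list: `events` tibble (`event_id`, `is_bead`,
#'   `scatter_side`, `cd45`, `cd3`, `cd4`, `cd8`, plus a `truth` label
#'   column), `beads_per_ul`, `sample_volume_ul`, `suspension_volume_ul`,
#'   `n_biopsies`, and the true per-subset event counts as attribute
#'   `"truth_counts"`.
#' @export
flow_run <- function(tissue, cfg = flow_sim_config()) {
  stopifnot(inherits(cfg, "flow_sim_config"))
  if (!"in_core" %in% names(tissue)) tissue$in_core <- TRUE
  core <- tissue[tissue$in_core, , drop = FALSE]

  withr::with_seed(cfg$seed, {
    markers <- if ("marker" %in% names(core)) {
      core$marker
    } else {
      probs <- c(CD4 = cfg$cd4_fraction, CD8 = cfg$cd8_fraction,
                 other = 1 - cfg$cd4_fraction - cfg$cd8_fraction)
      sample(names(probs), nrow(core), replace = TRUE, prob = probs)
    }
    n_core <- nrow(core)
    recovered <- if (n_core > 0) which(runif(n_core) < cfg$recovery_fraction) else integer()
    in_tube <- recovered[runif(length(recovered)) <
                           cfg$sample_volume_ul / cfg$suspension_volume_ul]
    acquired <- in_tube[runif(length(in_tube)) < cfg$acquisition_fraction]
    t_markers <- if (length(markers) > 0) markers[acquired] else character()
    n_t <- length(acquired)

    n_beads <- rbinom(1, cfg$bead_count, cfg$acquisition_fraction)
    n_nont <- rpois(1, cfg$non_t_fraction * n_t)
    n_debris <- rpois(1, cfg$debris_fraction * n_t)

    pos_mean <- cfg$negative_mean * cfg$separation
    intensity <- function(n, positive) {
      rlnorm(n, log(ifelse(positive, pos_mean, cfg$negative_mean)),
             cfg$intensity_sdlog)
    }
    scatter <- function(n, mean_val) rlnorm(n, log(mean_val), 0.2)

    t_events <- tibble(
      is_bead = rep(FALSE, n_t),
      scatter_side = scatter(n_t, 300),
      cd45 = intensity(n_t, TRUE),
      cd3 = intensity(n_t, TRUE),
      cd4 = intensity(n_t, t_markers == "CD4"),
      cd8 = intensity(n_t, t_markers == "CD8"),
      truth = paste0("T_", t_markers)
    )
    nont_events <- tibble(
      is_bead = rep(FALSE, n_nont),
      scatter_side = scatter(n_nont, 300),
      cd45 = intensity(n_nont, TRUE),
      cd3 = intensity(n_nont, FALSE),
      cd4 = intensity(n_nont, FALSE),
      cd8 = intensity(n_nont, FALSE),
      truth = "non_T"
    )
    debris_events <- tibble(
      is_bead = rep(FALSE, n_debris),
      scatter_side = scatter(n_debris, 40),
      cd45 = intensity(n_debris, FALSE),
      cd3 = intensity(n_debris, FALSE),
      cd4 = intensity(n_debris, FALSE),
      cd8 = intensity(n_debris, FALSE),
      truth = "debris"
    )
    bead_events <- tibble(
      is_bead = rep(TRUE, n_beads),
      scatter_side = scatter(n_beads, 1200),
      cd45 = intensity(n_beads, TRUE),
      cd3 = intensity(n_beads, TRUE),
      cd4 = intensity(n_beads, TRUE),
      cd8 = intensity(n_beads, TRUE),
      truth = "bead"
    )
    events <- bind_rows(t_events, nont_events, debris_events, bead_events)
    events <- events[sample.int(nrow(events)), , drop = FALSE]
    events$event_id <- seq_len(nrow(events))
    events <- select(events, "event_id", "is_bead", "scatter_side",
                     "cd45", "cd3", "cd4", "cd8", "truth")

    tube <- structure(
      list(events = events,
           beads_per_ul = cfg$bead_count / cfg$sample_volume_ul,
           bead_count = cfg$bead_count,
           sample_volume_ul = cfg$sample_volume_ul,
           suspension_volume_ul = cfg$suspension_volume_ul,
           n_biopsies = cfg$n_biopsies),
      class = "trucount_tube"
    )
    attr(tube, "truth_counts") <- c(
      T_total = n_t,
      T_CD4 = sum(t_markers == "CD4"),
      T_CD8 = sum(t_markers == "CD8"),
      non_T = n_nont, debris = n_debris, bead = n_beads
    )
    tube
  })
}
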