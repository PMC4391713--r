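#' Sectioning specification for areal-to-volumetric conversion
#'
#' Bundles the physical sectioning parameters that convert a per-section
#' areal density (cells/mm^2) into a volumetric density (cells/mm^3):
#' the section thickness, the number of slices cut from 1 mm of tissue,
#' and the appearance-correction factor (the average number of consecutive
#' sections in which a single cell appears, an Abercrombie-family
#' correction).
#'
#' @param thickness_um Section thickness in micrometres. Default 4.
#' @param slices_per_mm Number of sections per millimetre of tissue depth.
#'   Defaults to `1000 / thickness_um` (250 for 4 um sections).
#' @param appearance_factor Average number of sections in which one cell
#'   appears; profile counts are divided by this. Default 3.356, the value
#'   for a 12 um cell cut into 4 um sections with the default visibility
#'   threshold (see [calibrate_visibility()]).
#' @return A `section_spec` list with the three fields.
#' @seealso [volumetric_density()], [sectioning_model()]
#' @examples
#' section_spec()                 # the 4 um / x250 / /3.356 convention
#' section_spec(thickness_um = 5) # 200 slices/mm
#' @export
section_spec <- function(thickness_um = 4,
                         slices_per_mm = 1000 / thickness_um,
                         appearance_factor = 3.356) {
  if (thickness_um <= 0) abort_config("`thickness_um` must be positive.")
  if (slices_per_mm <= 0) abort_config("`slices_per_mm` must be positive.")
  if (appearance_factor < 1) {
    abort_config("`appearance_factor` must be >= 1 (a cell appears in at least one section).")
  }
  structure(
    list(thickness_um = thickness_um,
         slices_per_mm = slices_per_mm,
         appearance_factor = appearance_factor),
    class = "section_spec"
  )
}

#' Cell morphology: diameter and derived spherical volume
#'
#' @param diameter_um Average cell diameter in micrometres. Default 12,
#'   the size of an activated T lymphocyte.
#' @return A `cell_morphology` list with `diameter_um` and the derived
#'   sphere volume `volume_um3` = (pi/6) d^3.
#' @examples
#' cell_morphology()$volume_um3  # 904.78, conventionally reported as 905
#' @export
cell_morphology <- function(diameter_um = 12) {
  if (diameter_um < 0) abort_config("`diameter_um` must be non-negative.")
  structure(
    list(diameter_um = diameter_um,
         volume_um3 = pi / 6 * diameter_um^3),
    class = "cell_morphology"
  )
}

#' Per-cell volume of a spherical cell
#'
#' @param morph A [cell_morphology()] object, or a numeric diameter in um.
#' @param rounded If `TRUE`, round to the nearest integer um^3 (the
#'   reporting convention); default `FALSE` returns the exact value.
#' @return Volume in um^3.
#' @examples
#' cell_volume(cell_morphology(12))            # 904.7787
#' cell_volume(12, rounded = TRUE)             # 905
#' @export
cell_volume <- function(morph, rounded = FALSE) {
  if (is.numeric(morph)) morph <- cell_morphology(morph)
  v <- morph$volume_um3
  if (rounded) round(v) else v
}

#' Gut-segment geometry as an annular cylinder
#'
#' Describes a gut segment as a cylindrical shell: the mucosa is the annulus
#' between the lumen (inner radius) and the muscular layers (inner radius +
#' mucosal thickness).
#'
#' @param name Segment name, e.g. `"sigmoid"`.
#' @param length_mm Segment length in mm.
#' @param inner_diameter_mm Luminal diameter in mm.
#' @param mucosal_thickness_mm Mucosal thickness in mm (up to but not
#'   including muscular layers). Default 1.5.
#' @return A one-row tibble with the geometry and derived radii.
#' @examples
#' segment_geometry("sigmoid", 350, 35)
#' segment_geometry("rectum", 50, 50)
#' @export
segment_geometry <- function(name, length_mm, inner_diameter_mm,
                             mucosal_thickness_mm = 1.5) {
  if (length_mm <= 0 || inner_diameter_mm <= 0) {
    abort_input("Segment length and inner diameter must be positive.")
  }
  if (mucosal_thickness_mm < 0) {
    abort_input("`mucosal_thickness_mm` must be non-negative.")
  }
  tibble(
    name = name,
    length_mm = length_mm,
    inner_diameter_mm = inner_diameter_mm,
    mucosal_thickness_mm = mucosal_thickness_mm,
    inner_radius_mm = inner_diameter_mm / 2,
    outer_radius_mm = inner_diameter_mm / 2 + mucosal_thickness_mm
  )
}

#' Default rectosigmoid segment geometries
#'
#' Sigmoid colon 350 mm long, 35 mm inner diameter; rectum 50 mm long,
#' 50 mm inner diameter; mucosal thickness 1.5 mm for both.
#'
#' @return A two-row tibble of [segment_geometry()] rows.
#' @export
default_segments <- function() {
  bind_rows(
    segment_geometry("sigmoid", 350, 35),
    segment_geometry("rectum", 50, 50)
  )
}

region_sites <- c("sigmoid", "rectum")
region_markers <- c("CD3", "CD4", "CD8", "CD45", "other")
region_compartments <- c("epithelium", "lamina_propria", "lymphoid_aggregate",
                         "combined")
region_methods <- c("manual", "automated")

#' Validate a region-count table
#'
#' Checks the tibble of circumscribed counting regions: one row per region
#' of interest on an immunostained section, with its area, labeled-cell
#' count, marker, tissue compartment and counting method. Site, marker and
#' method names are normalised (case-insensitively) to the canonical
#' vocabulary.
#'
#' @param regions A data frame with columns `sample_id`, `site`, `marker`,
#'   `compartment`, `area_mm2`, `count`, `method`.
#' @return The validated tibble (invisibly coerced), with normalised enums.
#' @export
validate_regions <- function(regions) {
  required <- c("sample_id", "site", "marker", "compartment",
                "area_mm2", "count", "method")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    abort_input(paste0("Region table is missing columns: ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  regions <- as_tibble(regions)
  regions$site <- tolower(trimws(as.character(regions$site)))
  regions$compartment <- tolower(trimws(as.character(regions$compartment)))
  regions$method <- tolower(trimws(as.character(regions$method)))
  regions$marker <- normalise_marker(regions$marker)

  check_enum <- function(x, allowed, what) {
    bad <- which(!x %in% allowed)
    if (length(bad) > 0) {
      abort_input(sprintf("Row %d: unknown %s '%s' (allowed: %s).",
                          bad[1], what, x[bad[1]],
                          paste(allowed, collapse = ", ")))
    }
  }
  check_enum(regions$site, region_sites, "site")
  check_enum(regions$marker, region_markers, "marker")
  check_enum(regions$compartment, region_compartments, "compartment")
  check_enum(regions$method, region_methods, "method")

  bad_area <- which(!is.finite(regions$area_mm2) | regions$area_mm2 <= 0)
  if (length(bad_area) > 0) {
    abort_input(sprintf("Row %d: `area_mm2` must be positive (got %s).",
                        bad_area[1], regions$area_mm2[bad_area[1]]))
  }
  bad_count <- which(!is.finite(regions$count) | regions$count < 0 |
                       regions$count != round(regions$count))
  if (length(bad_count) > 0) {
    abort_input(sprintf("Row %d: `count` must be a non-negative integer (got %s).",
                        bad_count[1], regions$count[bad_count[1]]))
  }
  regions
}

normalise_marker <- function(x) {
  x <- trimws(as.character(x))
  up <- toupper(x)
  out <- ifelse(up %in% toupper(region_markers),
                region_markers[match(up, toupper(region_markers))], x)
  ifelse(tolower(out) == "other", "other", out)
}

#' Areal density of labeled cells per region
#'
#' Normalises each circumscribed region's labeled-cell count to cells/mm^2
#' by dividing the count by the region-of-interest area.
#'
#' @param regions A region-count data frame (see [validate_regions()]).
#' @return The input tibble with an added `areal_density` column
#'   (cells/mm^2).
#' @examples
#' r <- tibble::tibble(sample_id = "s1", site = "sigmoid", marker = "CD3",
#'                     compartment = "combined", area_mm2 = 2, count = 100,
#'                     method = "manual")
#' areal_density(r)$areal_density  # 50
#' @export
areal_density <- function(regions) {
  regions <- validate_regions(regions)
  mutate(regions, areal_density = .data$count / .data$area_mm2)
}

#' Average per-region areal densities within a sample
#'
#' Averages the 3-5 regions of interest per sample, marker, compartment and
#' counting method: unweighted mean of per-region areal densities, with the
#' standard error of the mean (sample SD / sqrt(n); absent for n = 1).
#'
#' @param regions A region-count data frame; `areal_density` is computed if
#'   absent.
#' @return A tibble with one row per sample/site/marker/compartment/method
#'   and columns `mean_areal`, `sem_areal`, `n_regions`.
#' @export
average_regions <- function(regions) {
  if (nrow(as.data.frame(regions)) == 0) {
    abort_input("Region table is empty; nothing to average.")
  }
  if (!"areal_density" %in% names(regions)) regions <- areal_density(regions)
  regions |>
    group_by(.data$sample_id, .data$site, .data$marker, .data$compartment,
             .data$method) |>
    summarise(
      mean_areal = mean(.data$areal_density),
      sem_areal = if (n() >= 2) sd(.data$areal_density) / sqrt(n()) else NA_real_,
      n_regions = n(),
      .groups = "drop"
    )
}

#' Convert areal density to volumetric density
#'
#' Multiplies cells/mm^2 by the number of slices per mm of tissue depth and
#' divides by the appearance-correction factor, yielding cells/mm^3. With
#' defaults this is the x250 / /3.356 convention for 4 um sections of 12 um
#' cells.
#'
#' @param areal Areal density in cells/mm^2 (numeric vector).
#' @param spec A [section_spec()].
#' @return Volumetric density in cells/mm^3.
#' @examples
#' areal_to_volumetric(502)  # ~37,396 cells/mm^3
#' @export
areal_to_volumetric <- function(areal, spec = section_spec()) {
  if (any(areal < 0, na.rm = TRUE)) abort_input("Areal density must be >= 0.")
  areal * spec$slices_per_mm / spec$appearance_factor
}

#' Volumetric density table from averaged areal densities
#'
#' @param averaged Output of [average_regions()] (or any tibble with
#'   `mean_areal` and optional `sem_areal`).
#' @param spec A [section_spec()].
#' @return The tibble with added `density_mm3` and `sem_mm3` columns; the
#'   SEM is converted with the same linear factor.
#' @export
volumetric_density <- function(averaged, spec = section_spec()) {
  averaged |>
    mutate(
      density_mm3 = areal_to_volumetric(.data$mean_areal, spec),
      sem_mm3 = .data$sem_areal * spec$slices_per_mm / spec$appearance_factor
    )
}

#' Full in-situ density estimation pipeline
#'
#' Runs areal normalisation, per-sample region averaging and volumetric
#' conversion, then summarises across samples. Compartment-level densities
#' are computed independently; a sample's site-level value is the unweighted
#' mean over its compartments (compartment volume weights are unknown).
#' Across samples, the estimate is the mean with SEM = sample SD / sqrt(n
#' samples).
#'
#' @param regions A region-count data frame.
#' @param spec A [section_spec()].
#' @return A tibble of density estimates with columns `site`, `marker`,
#'   `method`, `density_mm3`, `sem_mm3`, `n_samples`, `n_regions` and
#'   `provenance` (`"IHC-manual"` or `"IHC-automated"`).
#' @examples
#' tissue <- generate_tissue(tissue_sim(seed = 1))
#' regions <- section_counts(tissue, n_regions = 12, seed = 2)
#' estimate_densities(regions)
#' @export
estimate_densities <- function(regions, spec = section_spec()) {
  per_sample <- regions |>
    average_regions() |>
    volumetric_density(spec) |>
    group_by(.data$sample_id, .data$site, .data$marker, .data$method) |>
    summarise(density_mm3 = mean(.data$density_mm3),
              n_regions = sum(.data$n_regions), .groups = "drop")
  per_sample |>
    group_by(.data$site, .data$marker, .data$method) |>
    summarise(
      n_samples = n(),
      sem_mm3 = if (n() >= 2) sd(.data$density_mm3) / sqrt(n()) else NA_real_,
      density_mm3 = mean(.data$density_mm3),
      n_regions = sum(.data$n_regions),
      .groups = "drop"
    ) |>
    mutate(provenance = paste0("IHC-", .data$method)) |>
    select("site", "marker", "method", "density_mm3", "sem_mm3",
           "n_samples", "n_regions", "provenance")
}

#' Volume fraction occupied by a cell population
#'
#' The percentage of tissue volume occupied by cells of a given volumetric
#' density: 100 x density (cells/mm^3) x per-cell volume (um^3) x 1e-9
#' (um^3 to mm^3).
#'
#' @param density Volumetric density in cells/mm^3.
#' @param cell_vol_um3 Per-cell volume in um^3 (e.g. [cell_volume()]).
#' @return Volume fraction in percent. Conventionally reported to two
#'   decimals.
#' @examples
#' volume_fraction(37400, cell_volume(12))  # 3.38%
#' @export
volume_fraction <- function(density, cell_vol_um3 = cell_volume(cell_morphology())) {
  if (any(density < 0, na.rm = TRUE) || any(cell_vol_um3 < 0, na.rm = TRUE)) {
    abort_input("Density and cell volume must be >= 0.")
  }
  100 * density * cell_vol_um3 * 1e-9
}

#' Mucosal shell volume of a gut segment
#'
#' Volume of the annular cylinder between the luminal surface and the
#' muscular layers: length x pi x (outer_radius^2 - inner_radius^2), all in
#' millimetres.
#'
#' @param geom A [segment_geometry()] tibble (one or more rows).
#' @return The tibble with an added `volume_mm3` column.
#' @examples
#' shell_volume(segment_geometry("sigmoid", 350, 35))$volume_mm3  # ~60,201
#' @export
shell_volume <- function(geom) {
  if (any(geom$length_mm <= 0) || any(geom$inner_diameter_mm <= 0)) {
    abort_input("Segment dimensions must be positive.")
  }
  mutate(geom, volume_mm3 = .data$length_mm * pi *
           (.data$outer_radius_mm^2 - .data$inner_radius_mm^2))
}

#' Total cells in a compartment
#'
#' @param density Volumetric density in cells/mm^3.
#' @param volume_mm3 Compartment volume in mm^3.
#' @return Total cell count (density x volume). Conventionally reported to
#'   three significant figures.
#' @examples
#' signif(total_cells(37400, 60201), 3)  # 2.25e9
#' @export
total_cells <- function(density, volume_mm3) {
  if (any(density < 0, na.rm = TRUE) || any(volume_mm3 < 0, na.rm = TRUE)) {
    abort_input("Density and volume must be >= 0.")
  }
  density * volume_mm3
}

#' Density of a subset from its parent population
#'
#' Scales a parent density by a subset proportion measured by dual-label
#' counting of double positives (e.g. CD3+CD4+ as a fraction of CD3+).
#'
#' @param parent_density Parent volumetric density in cells/mm^3.
#' @param fraction Subset proportion in `[0, 1]`.
#' @return Subset density in cells/mm^3.
#' @examples
#' subset_density(37400, 0.57)  # 21,318 -- CD4 subset of sigmoid CD3
#' @export
subset_density <- function(parent_density, fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    abort_input("`fraction` must lie in [0, 1].")
  }
  parent_density * fraction
}

#' Extrapolate whole-segment cell totals by two routes
#'
#' Computes each segment's total cell count two ways: directly as density x
#' shell volume, and indirectly as volume-fraction / per-cell-volume x shell
#' volume. The two routes are algebraically identical when the same density
#' feeds both; they are reported side by side and flagged when they disagree
#' by more than 2% (which happens when a published volume fraction is
#' internally inconsistent with its density).
#'
#' @param densities A tibble with columns `site` and `density_mm3` (and
#'   optionally `volume_fraction_pct` to drive the second route from an
#'   externally reported fraction).
#' @param segments A [segment_geometry()] tibble; matched to `site` by
#'   `name`.
#' @param morph A [cell_morphology()].
#' @return A tibble with per-site totals by both routes, the shell volume,
#'   and a `routes_disagree` flag.
#' @export
extrapolate_totals <- function(densities, segments = default_segments(),
                               morph = cell_morphology()) {
  seg <- shell_volume(segments) |> select(site = "name", "volume_mm3")
  out <- densities |>
    left_join(seg, by = "site") |>
    mutate(
      total_by_density = total_cells(.data$density_mm3, .data$volume_mm3),
      volume_fraction_pct = if ("volume_fraction_pct" %in% names(densities)) {
        .data$volume_fraction_pct
      } else {
        volume_fraction(.data$density_mm3, cell_volume(morph))
      },
      total_by_fraction = .data$volume_fraction_pct / 100 * .data$volume_mm3 /
        (cell_volume(morph) * 1e-9),
      routes_disagree = abs(.data$total_by_fraction - .data$total_by_density) >
        0.02 * .data$total_by_density
    )
  out
}
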