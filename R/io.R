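#' Read a region-count CSV
#'
#' Reads and validates a table of circumscribed counting regions with
#' header `sample_id,site,marker,compartment,area_mm2,count,method`.
#' Enum columns are normalised case-insensitively; malformed rows are
#' rejected with their row number.
#'
#' @param path Path to the CSV file.
#' @return A validated region-count tibble.
#' @export
read_region_csv <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Region CSV not found: ", path))
  regions <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      site = readr::col_character(),
      marker = readr::col_character(),
      compartment = readr::col_character(),
      area_mm2 = readr::col_double(),
      count = readr::col_double(),
      method = readr::col_character()
    )
  )
  if (nrow(regions) == 0) abort_input("Region CSV contains no data rows.")
  validate_regions(regions)
}

#' Write a region-count CSV
#' @param regions A region-count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(regions, path) {
  readr::write_csv(validate_regions(regions), path)
  invisible(path)
}

#' Write / read a density-estimate CSV
#'
#' Tidy round-trip of [estimate_densities()] output.
#'
#' @param densities A density-estimate tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_density_csv <- function(densities, path) {
  readr::write_csv(densities, path)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Density CSV not found: ", path))
  readr::read_csv(path, col_types = readr::cols())
}

#' Read a flow event CSV and tube metadata into a TruCount tube
#'
#' Event CSV header: `event_id,is_bead,scatter_side,cd45,cd3,cd4,cd8`.
#' Tube metadata JSON keys: `beads_per_ul`, `sample_volume_ul`,
#' `suspension_volume_ul`, `n_biopsies`.
#'
#' @param event_path Path to the event CSV.
#' @param tube_path Path to the tube metadata JSON.
#' @return A `trucount_tube` list.
#' @export
read_event_csv <- function(event_path, tube_path) {
  if (!file.exists(event_path)) {
    abort_input(paste0("Event CSV not found: ", event_path))
  }
  if (!file.exists(tube_path)) {
    abort_input(paste0("Tube metadata JSON not found: ", tube_path))
  }
  events <- readr::read_csv(
    event_path,
    col_types = readr::cols(
      event_id = readr::col_integer(),
      is_bead = readr::col_logical(),
      scatter_side = readr::col_double(),
      cd45 = readr::col_double(),
      cd3 = readr::col_double(),
      cd4 = readr::col_double(),
      cd8 = readr::col_double(),
      .default = readr::col_character()
    )
  )
  neg <- which(events$scatter_side < 0 | events$cd45 < 0 | events$cd3 < 0 |
                 events$cd4 < 0 | events$cd8 < 0)
  if (length(neg) > 0) {
    abort_input(sprintf("Row %d: event intensities must be non-negative.", neg[1]))
  }
  meta <- jsonlite::read_json(tube_path, simplifyVector = TRUE)
  for (key in c("beads_per_ul", "sample_volume_ul", "suspension_volume_ul")) {
    if (is.null(meta[[key]])) {
      abort_input(paste0("Tube metadata is missing key: ", key))
    }
  }
  if (meta$beads_per_ul <= 0) abort_input("`beads_per_ul` must be positive.")
  structure(
    list(events = events,
         beads_per_ul = meta$beads_per_ul,
         bead_count = meta$beads_per_ul * meta$sample_volume_ul,
         sample_volume_ul = meta$sample_volume_ul,
         suspension_volume_ul = meta$suspension_volume_ul,
         n_biopsies = meta$n_biopsies %||% 1),
    class = "trucount_tube"
  )
}

#' Write a TruCount tube to an event CSV and metadata JSON
#'
#' @param tube A `trucount_tube`.
#' @param event_path,tube_path Output paths.
#' @return `event_path`, invisibly.
#' @export
write_event_csv <- function(tube, event_path, tube_path) {
  stopifnot(inherits(tube, "trucount_tube"))
  events <- tube$events
  events$truth <- NULL
  readr::write_csv(events, event_path)
  jsonlite::write_json(
    list(beads_per_ul = tube$beads_per_ul,
         sample_volume_ul = tube$sample_volume_ul,
         suspension_volume_ul = tube$suspension_volume_ul,
         n_biopsies = tube$n_biopsies),
    tube_path, auto_unbox = TRUE, digits = NA
  )
  invisible(event_path)
}

#' Pipeline configuration
#'
#' Collects the file paths and physical parameters for a full analysis
#' run. All referenced input files must exist at run time.
#'
#' @param region_csv Path to the region-count CSV (required).
#' @param event_csv,tube_json Paths to the flow event CSV and tube
#'   metadata JSON; both or neither.
#' @param section A [section_spec()].
#' @param cell A [cell_morphology()].
#' @param segments A [segment_geometry()] tibble.
#' @param gates A [gate_set()].
#' @param biopsy_volume_mm3 Nominal biopsy volume for flow density
#'   conversion. Default 24.
#' @param seed Top-level seed recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(region_csv, event_csv = NULL, tube_json = NULL,
                            section = section_spec(),
                            cell = cell_morphology(),
                            segments = default_segments(),
                            gates = gate_set(),
                            biopsy_volume_mm3 = 24, seed = 1) {
  if (is.null(region_csv) || !file.exists(region_csv)) {
    abort_config(paste0("Config field `region_csv`: file not found: ",
                        region_csv %||% "<missing>"))
  }
  if (xor(is.null(event_csv), is.null(tube_json))) {
    abort_config("Config fields `event_csv` and `tube_json` must be supplied together.")
  }
  if (!is.null(event_csv) && !file.exists(event_csv)) {
    abort_config(paste0("Config field `event_csv`: file not found: ", event_csv))
  }
  if (!is.null(tube_json) && !file.exists(tube_json)) {
    abort_config(paste0("Config field `tube_json`: file not found: ", tube_json))
  }
  structure(
    list(region_csv = region_csv, event_csv = event_csv,
         tube_json = tube_json, section = section, cell = cell,
         segments = segments, gates = gates,
         biopsy_volume_mm3 = biopsy_volume_mm3, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' JSON keys: `region_csv`, `event_csv`, `tube_json`,
#' `section{thickness_um, slices_per_mm, appearance_factor}`,
#' `cell{diameter_um}`,
#' `segments[{name, length_mm, inner_diameter_mm, mucosal_thickness_mm}]`,
#' `gates{cd45, cd3, cd4, cd8, scatter_low, scatter_high}`,
#' `biopsy_volume_mm3`, `seed`. Missing sections fall back to package
#' defaults; relative paths are resolved against the JSON file's
#' directory.
#'
#' @param path Path to the config JSON.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("Config JSON not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  section <- if (!is.null(raw$section)) {
    do.call(section_spec, raw$section)
  } else section_spec()
  cell <- if (!is.null(raw$cell)) {
    cell_morphology(raw$cell$diameter_um)
  } else cell_morphology()
  segments <- if (!is.null(raw$segments)) {
    seg <- as_tibble(raw$segments)
    purrr::pmap(seg, segment_geometry) |> bind_rows()
  } else default_segments()
  gates <- if (!is.null(raw$gates)) do.call(gate_set, raw$gates) else gate_set()
  pipeline_config(
    region_csv = resolve(raw$region_csv),
    event_csv = resolve(raw$event_csv),
    tube_json = resolve(raw$tube_json),
    section = section, cell = cell, segments = segments, gates = gates,
    biopsy_volume_mm3 = raw$biopsy_volume_mm3 %||% 24,
    seed = raw$seed %||% 1
  )
}

#' Run the full quantification pipeline
#'
#' Orchestrates the end-to-end analysis: in-situ densification (areal ->
#' averaged -> volumetric), volume fractions and whole-segment totals by
#' both extrapolation routes, flow-cytometric absolute counting (when an
#' event table is configured), the flow-vs-in-situ recovery comparison,
#' and manual-vs-automated concordance statistics (when both counting
#' methods are present). Writes a tidy density CSV and JSON reports to
#' `out_dir`; re-running the same configuration reproduces the bundle
#' byte for byte.
#'
#' @param config A [pipeline_config()] or a path to a config JSON.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `densities`, `totals`, `flow`,
#'   `recovery`, `concordance` and `discrepancies`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  regions <- read_region_csv(config$region_csv)
  densities <- estimate_densities(regions, config$section)
  write_density_csv(densities, file.path(out_dir, "density_estimates.csv"))

  dens_for_totals <- if (any(densities$method == "manual")) {
    filter(densities, .data$method == "manual")
  } else densities
  totals <- extrapolate_totals(dens_for_totals, config$segments, config$cell)
  jsonlite::write_json(totals, file.path(out_dir, "totals.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  flow <- NULL
  recovery <- NULL
  if (!is.null(config$event_csv)) {
    tube <- read_event_csv(config$event_csv, config$tube_json)
    flow <- quantify_tube(tube, config$gates, config$biopsy_volume_mm3)
    ihc <- densities |> filter(.data$method == "manual")
    shared <- intersect(flow$marker, ihc$marker)
    if (length(shared) > 0) {
      recovery <- purrr::map(shared, function(m) {
        compare_recovery(
          flow$cells_per_mm3[flow$marker == m],
          ihc$density_mm3[ihc$marker == m][1],
          marker = m
        )
      }) |> bind_rows()
    }
    jsonlite::write_json(flow, file.path(out_dir, "flow_yields.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(recovery)) {
      jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  concordance <- NULL
  per_sample <- regions |>
    average_regions() |>
    volumetric_density(config$section) |>
    group_by(.data$sample_id, .data$site, .data$marker, .data$method) |>
    summarise(density_mm3 = mean(.data$density_mm3), .groups = "drop")
  if (all(c("manual", "automated") %in% per_sample$method)) {
    pairs <- per_sample |>
      tidyr::pivot_wider(names_from = "method", values_from = "density_mm3") |>
      filter(!is.na(.data$manual) & !is.na(.data$automated))
    if (nrow(pairs) >= 3) {
      fit <- ols_concordance(pairs, manual, automated)
      concordance <- c(
        as.list(glance(fit)),
        as.list(paired_t(pairs$manual, pairs$automated))
      )
      jsonlite::write_json(concordance,
                           file.path(out_dir, "concordance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  discrepancies <- reference_discrepancies()
  jsonlite::write_json(discrepancies,
                       file.path(out_dir, "discrepancies.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(densities = densities, totals = totals, flow = flow,
                 recovery = recovery, concordance = concordance,
                 discrepancies = discrepancies))
}
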