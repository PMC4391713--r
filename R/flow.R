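#' Fixed-threshold gate set for lymphocyte subset enumeration
#'
#' Scalar intensity thresholds and a side-scatter window implementing the
#' standard hierarchy: viable lymphocytes by CD45 and side scatter, T cells
#' by CD3, then mutually exclusive CD4 / CD8 subsets.
#'
#' @param cd45,cd3,cd4,cd8 Positivity thresholds per channel. Defaults 550
#'   (the geometric midpoint between the synthetic negative and positive
#'   intensity means).
#' @param scatter_low,scatter_high Side-scatter window for the lymphocyte
#'   gate.
#' @return A `gate_set` list.
#' @export
gate_set <- function(cd45 = 550, cd3 = 550, cd4 = 550, cd8 = 550,
                     scatter_low = 100, scatter_high = 900) {
  if (scatter_low >= scatter_high) {
    abort_config("`scatter_low` must be below `scatter_high`.")
  }
  structure(
    list(cd45 = cd45, cd3 = cd3, cd4 = cd4, cd8 = cd8,
         scatter_low = scatter_low, scatter_high = scatter_high),
    class = "gate_set"
  )
}

#' Hierarchically gate a TruCount event table
#'
#' Applies the gating hierarchy to an event table: bead events are
#' identified first; among non-bead events, viable lymphocytes are
#' CD45-positive within the scatter window; T cells are additionally
#' CD3-positive; CD4 and CD8 subsets are single positives (double positives
#' are excluded from both subsets and reported separately).
#'
#' @param tube A `trucount_tube` (from [flow_run()] or [read_event_csv()]),
#'   or a bare event data frame.
#' @param gates A [gate_set()].
#' @return A tibble with one row per gate node (`total`, `beads`,
#'   `non_bead`, `lymphocytes`, `t_cells`, `cd4`, `cd8`,
#'   `double_positive`, `double_negative`) and its event `count`.
#' @export
gate_counts <- function(tube, gates = gate_set()) {
  events <- if (inherits(tube, "trucount_tube")) tube$events else as_tibble(tube)
  if (nrow(events) == 0) {
    warn("Event table is empty; all gate counts are zero.")
    counts <- rep(0L, 9)
  } else {
    bead <- as.logical(events$is_bead)
    lymph <- !bead & events$cd45 > gates$cd45 &
      events$scatter_side >= gates$scatter_low &
      events$scatter_side <= gates$scatter_high
    tcell <- lymph & events$cd3 > gates$cd3
    cd4p <- tcell & events$cd4 > gates$cd4
    cd8p <- tcell & events$cd8 > gates$cd8
    counts <- c(
      nrow(events), sum(bead), sum(!bead), sum(lymph), sum(tcell),
      sum(cd4p & !cd8p), sum(cd8p & !cd4p), sum(cd4p & cd8p),
      sum(tcell & !cd4p & !cd8p)
    )
  }
  tibble(
    node = c("total", "beads", "non_bead", "lymphocytes", "t_cells",
             "cd4", "cd8", "double_positive", "double_negative"),
    count = as.integer(counts)
  )
}

#' Bead-ratio absolute concentration
#'
#' The TruCount formula: cells/ul = (antibody-positive cell events / total
#' bead events) x beads per ul. Because acquisition thins cells and beads
#' equally, the ratio is invariant to how much of the tube is acquired.
#'
#' @param positive_events Gated positive cell events.
#' @param bead_events Bead events.
#' @param beads_per_ul Known bead concentration of the tube.
#' @return Absolute concentration in cells/ul.
#' @examples
#' trucount_concentration(500, 1000, 1040)  # 520 cells/ul
#' @export
trucount_concentration <- function(positive_events, bead_events, beads_per_ul) {
  if (any(bead_events <= 0)) {
    abort_input("`bead_events` must be positive: the bead ratio is undefined without bead events.")
  }
  positive_events / bead_events * beads_per_ul
}

#' Convert a concentration to per-biopsy and per-mm^3 yields
#'
#' Scales a suspension concentration up to the whole suspension, divides by
#' the number of pooled biopsies, and converts to a tissue density using
#' the nominal biopsy volume.
#'
#' @param cells_per_ul Concentration in the cell suspension.
#' @param suspension_volume_ul Total suspension volume, ul.
#' @param n_biopsies Number of biopsies pooled into the suspension.
#' @param biopsy_volume_mm3 Volume of one biopsy, mm^3. Default 24 (the
#'   nominal 8 x 3 x 1 mm block); the displacement-measured 20.2 mm^3 may
#'   be supplied instead.
#' @return A one-row tibble with `cells_per_ul`, `cells_per_biopsy`,
#'   `cells_per_mm3`, `n_biopsies`, `biopsy_volume_mm3`.
#' @examples
#' per_biopsy_and_density(174.939, 1000, 1, 24)  # 7,289 cells/mm^3
#' @export
per_biopsy_and_density <- function(cells_per_ul, suspension_volume_ul,
                                   n_biopsies = 1, biopsy_volume_mm3 = 24) {
  if (n_biopsies < 1) abort_input("`n_biopsies` must be >= 1.")
  if (suspension_volume_ul <= 0 || biopsy_volume_mm3 <= 0) {
    abort_input("Volumes must be positive.")
  }
  cells_per_biopsy <- cells_per_ul * suspension_volume_ul / n_biopsies
  tibble(
    cells_per_ul = cells_per_ul,
    cells_per_biopsy = cells_per_biopsy,
    cells_per_mm3 = cells_per_biopsy / biopsy_volume_mm3,
    n_biopsies = as.integer(n_biopsies),
    biopsy_volume_mm3 = biopsy_volume_mm3
  )
}

#' Quantify a TruCount tube end to end
#'
#' Gates the tube, converts each marker's positive-event count to an
#' absolute concentration by the bead ratio, and reports per-biopsy and
#' per-mm^3 yields for CD3, CD4 and CD8.
#'
#' @param tube A `trucount_tube`.
#' @param gates A [gate_set()].
#' @param biopsy_volume_mm3 Nominal biopsy volume for the density
#'   conversion. Default 24.
#' @return A tibble with one row per marker and the [per_biopsy_and_density()]
#'   columns plus `provenance = "flow"`.
#' @export
quantify_tube <- function(tube, gates = gate_set(), biopsy_volume_mm3 = 24) {
  stopifnot(inherits(tube, "trucount_tube"))
  counts <- gate_counts(tube, gates)
  get_node <- function(node) counts$count[counts$node == node]
  markers <- c(CD3 = "t_cells", CD4 = "cd4", CD8 = "cd8")
  purrr::imap(markers, function(node, marker) {
    conc <- trucount_concentration(get_node(node), get_node("beads"),
                                   tube$beads_per_ul)
    per_biopsy_and_density(conc, tube$suspension_volume_ul,
                           tube$n_biopsies, biopsy_volume_mm3) |>
      mutate(marker = marker)
  }) |>
    bind_rows() |>
    mutate(provenance = "flow") |>
    select("marker", "cells_per_ul", "cells_per_biopsy", "cells_per_mm3",
           "n_biopsies", "biopsy_volume_mm3", "provenance")
}

#' CD4 / CD8 subset percentages
#'
#' Expresses the CD4 and CD8 yields as percentages of their sum, reported
#' to the nearest integer (raw values retained).
#'
#' @param cd4,cd8 CD4 and CD8 yields in any common unit (e.g. cells/mm^3).
#' @return A one-row tibble with `cd4_pct`, `cd8_pct` (rounded) and
#'   `cd4_pct_raw`, `cd8_pct_raw`.
#' @examples
#' subset_percentages(4549, 2708)  # 63% / 37%
#' @export
subset_percentages <- function(cd4, cd8) {
  if (cd4 + cd8 <= 0) {
    abort_input("CD4 and CD8 yields are both zero; percentages are undefined.")
  }
  p4 <- 100 * cd4 / (cd4 + cd8)
  tibble(cd4_pct = round(p4), cd8_pct = round(100 - p4),
         cd4_pct_raw = p4, cd8_pct_raw = 100 - p4)
}
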