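#' Serial-sectioning model for spherical cells
#'
#' Geometric model of a spherical cell of diameter `d` cut by an ungapped
#' grid of sections of thickness `t`. A section shows a countable profile
#' only if it cuts at least `min_cap_depth` (h) into the sphere at either
#' pole; h = 0 means every grazing cap is counted. The expected number of
#' sections showing a profile is what the appearance-correction factor
#' divides out.
#'
#' @param diameter_um Cell diameter d in um. Default 12.
#' @param thickness_um Section thickness t in um. Default 4.
#' @param min_cap_depth_um Visibility threshold h in um: minimum depth a
#'   section must cut into the sphere for its profile to be counted. Must
#'   satisfy 0 <= h < d/2. Default is calibrated so that
#'   `expected_sections()` equals 3.356 (see [calibrate_visibility()]).
#' @return A `sectioning_model` list.
#' @seealso [expected_sections()], [simulate_sections()],
#'   [min_profile_radius()]
#' @export
sectioning_model <- function(diameter_um = 12, thickness_um = 4,
                             min_cap_depth_um = calibrate_visibility(
                               diameter_um, thickness_um, 3.356)) {
  if (diameter_um <= 0) abort_config("`diameter_um` must be positive.")
  if (thickness_um <= 0) abort_config("`thickness_um` must be positive.")
  if (min_cap_depth_um < 0 || min_cap_depth_um >= diameter_um / 2) {
    abort_config("`min_cap_depth_um` must satisfy 0 <= h < diameter/2.")
  }
  structure(
    list(diameter_um = diameter_um,
         thickness_um = thickness_um,
         min_cap_depth_um = min_cap_depth_um),
    class = "sectioning_model"
  )
}

#' Expected number of sections in which one cell appears
#'
#' A sphere of diameter d with visibility threshold h presents a countable
#' profile over an axial interval of length d - 2h. With the section grid at
#' uniform random phase relative to the cell centre, the expected number of
#' thickness-t cells of the grid intersected by that interval is
#' (d + t - 2h) / t.
#'
#' @param model A [sectioning_model()].
#' @return Expected section count (dimensionless, >= 1).
#' @examples
#' expected_sections(sectioning_model(12, 4, 0))       # 4
#' expected_sections(sectioning_model(12, 4, 1.288))   # 3.356
#' @export
expected_sections <- function(model) {
  d <- model$diameter_um
  t <- model$thickness_um
  h <- model$min_cap_depth_um
  if (h >= d / 2) abort_input("No visible profile: h >= d/2.")
  (d + t - 2 * h) / t
}

#' Calibrate the visibility threshold to a target appearance factor
#'
#' Inverts (d + t - 2h)/t = target for h, the minimum cap depth that makes
#' the expected per-cell section count equal the target correction factor.
#'
#' @param diameter_um Cell diameter d in um.
#' @param thickness_um Section thickness t in um.
#' @param target_factor Target expected-sections value, in
#'   `[1, (d + t)/t]`.
#' @return Minimum cap depth h in um: `(d + t - target * t) / 2`.
#' @examples
#' calibrate_visibility(12, 4, 3.356)  # 1.288 um
#' @export
calibrate_visibility <- function(diameter_um, thickness_um, target_factor) {
  upper <- (diameter_um + thickness_um) / thickness_um
  if (target_factor < 1 || target_factor > upper) {
    abort_input(sprintf(
      "`target_factor` must lie in [1, %.4g] for d = %g, t = %g.",
      upper, diameter_um, thickness_um))
  }
  (diameter_um + thickness_um - target_factor * thickness_um) / 2
}

#' Minimum visible profile radius equivalent to a cap-depth threshold
#'
#' A section cutting depth h into a sphere of diameter d shows a circular
#' profile of radius sqrt(d*h - h^2); requiring cap depth >= h is the same
#' visibility criterion as requiring profile radius >= this value.
#'
#' @param model A [sectioning_model()].
#' @return Minimum countable profile radius in um.
#' @export
min_profile_radius <- function(model) {
  h <- model$min_cap_depth_um
  sqrt(model$diameter_um * h - h^2)
}

#' Monte-Carlo validation of the expected section count
#'
#' Places sphere centres at axial positions uniform over one section period
#' and counts, for each sphere, the sections whose overlap with the
#' sphere's visible axial extent (trimmed by h at each pole) is positive.
#' Deterministic for a fixed seed.
#'
#' @param model A [sectioning_model()].
#' @param n_cells Number of simulated spheres.
#' @param seed Integer seed.
#' @return A tibble with `expected_sections` (analytic), `mc_mean`, `mc_se`,
#'   `n_sim` and `seed`.
#' @examples
#' simulate_sections(sectioning_model(12, 4, 0), n_cells = 1e4, seed = 1)
#' @export
simulate_sections <- function(model, n_cells = 1e5, seed = 1) {
  if (n_cells < 1) abort_input("`n_cells` must be >= 1.")
  d <- model$diameter_um
  t <- model$thickness_um
  h <- model$min_cap_depth_um
  counts <- withr::with_seed(seed, {
    z <- runif(n_cells, 0, t)     # centre phase within one section period
    lo <- z - d / 2 + h           # visible axial extent [lo, hi]
    hi <- z + d / 2 - h
    # sections are [k t, (k+1) t); count indices with positive overlap
    floor(hi / t) - floor(lo / t) + 1 -
      (hi %% t == 0) # boundary touch contributes zero overlap
  })
  tibble(
    expected_sections = expected_sections(model),
    mc_mean = mean(counts),
    mc_se = sd(counts) / sqrt(n_cells),
    n_sim = as.integer(n_cells),
    seed = as.integer(seed)
  )
}
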