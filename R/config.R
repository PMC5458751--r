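#' Configuration for the synthetic confocal stack generator
#'
#' Bundles every parameter of the simulated imaging experiment: voxel
#' sampling, region-of-interest (ROI) geometry, the axonal tree to draw,
#' varicosity counts and classes, AIS tube geometry, presynaptic-marker
#' probabilities per varicosity class, and the intensity model.  Defaults
#' reproduce the P16 study condition (the developmental peak of arbor
#' complexity): 290 branch points and 263 varicosities of which 109 lie on
#' AISs distributed over 29 cartridges, in a 100 x 100 um ROI through a
#' 60 um slice.
#'
#' Detection-relevant defaults respect the selection criteria applied
#' downstream: varicosity full widths below 3 um (x-y) and 3.5 um (z), peak
#' brightness at least twice the adjacent shaft, and AIS tubes whose
#' bounding boxes exceed 10 um in height and 2 um in width.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(seed, config)`.
#' @param voxel_size_xy_um,voxel_size_z_um Voxel pitch in um.
#' @param roi_um ROI width and height in um (x-y plane).
#' @param slice_depth_um Slice thickness (z extent) in um.
#' @param n_branch_points Exact number of axonal bifurcation points to place.
#' @param n_varicosities_total Total varicosities; `round(frac_on_ais *
#'   n_varicosities_total)` of them are AIS-class.
#' @param frac_on_ais Fraction of varicosities apposed to AIS tubes.
#' @param n_ais_tubes Number of AnkG-like vertical tubes.
#' @param ais_length_um,ais_width_um Tube length (> 10) and full width (> 2).
#' @param marker_prob_ais,marker_prob_off Probability that a varicosity of
#'   each class carries a presynaptic-marker punctum.
#' @param varicosity_diam_xy_um,varicosity_diam_z_um Nominal blob full
#'   widths at half maximum (um); must satisfy the < 3 / < 3.5 criteria.
#' @param varicosity_brightness_ratio Raw peak-to-shaft intensity ratio of
#'   generated varicosities (>= 2 so they pass detection).
#' @param noise_sd Additive Gaussian noise SD (12-bit intensity units);
#'   0 gives a noiseless stack.
#' @param background_level Baseline intensity. In the marker channel the
#'   neuropil sits at `0.8 * background_level` while the somatic cytosol is
#'   flat at `background_level`, emulating the diffuse cytosolic marker
#'   signal against which puncta are thresholded.
#' @param shaft_intensity Peak shaft intensity above background.
#' @param ais_intensity AIS-channel tube core intensity above background.
#' @param marker_intensity Marker punctum peak amplitude above field level.
#'
#' @return An object of class `gen_config` (a validated list).
#' @export
gen_config <- function(seed = 1L,
                       voxel_size_xy_um = 0.2,
                       voxel_size_z_um = 0.5,
                       roi_um = c(100, 100),
                       slice_depth_um = 60,
                       n_branch_points = 290L,
                       n_varicosities_total = 263L,
                       frac_on_ais = 109 / 263,
                       n_ais_tubes = 29L,
                       ais_length_um = 15,
                       ais_width_um = 2.5,
                       marker_prob_ais = 0.90,
                       marker_prob_off = 0.15,
                       varicosity_diam_xy_um = 2.0,
                       varicosity_diam_z_um = 2.5,
                       varicosity_brightness_ratio = 2.5,
                       noise_sd = 20,
                       background_level = 100,
                       shaft_intensity = 1000,
                       ais_intensity = 1200,
                       marker_intensity = 800) {
  cfg <- list(
    seed = as.integer(seed),
    voxel_size_xy_um = voxel_size_xy_um,
    voxel_size_z_um = voxel_size_z_um,
    roi_um = as.numeric(roi_um),
    slice_depth_um = slice_depth_um,
    n_branch_points = as.integer(n_branch_points),
    n_varicosities_total = as.integer(n_varicosities_total),
    frac_on_ais = frac_on_ais,
    n_ais_tubes = as.integer(n_ais_tubes),
    ais_length_um = ais_length_um,
    ais_width_um = ais_width_um,
    marker_prob_ais = marker_prob_ais,
    marker_prob_off = marker_prob_off,
    varicosity_diam_xy_um = varicosity_diam_xy_um,
    varicosity_diam_z_um = varicosity_diam_z_um,
    varicosity_brightness_ratio = varicosity_brightness_ratio,
    noise_sd = noise_sd,
    background_level = background_level,
    shaft_intensity = shaft_intensity,
    ais_intensity = ais_intensity,
    marker_intensity = marker_intensity
  )
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
  cfg
}

validate_gen_config <- function(cfg) {
  lens <- c("voxel_size_xy_um", "voxel_size_z_um", "slice_depth_um",
            "ais_length_um", "ais_width_um", "varicosity_diam_xy_um",
            "varicosity_diam_z_um")
  for (f in lens) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_config("field '", f, "' must be a positive length")
    }
  }
  if (length(cfg$roi_um) != 2 || any(cfg$roi_um <= 0)) {
    stop_config("roi_um must be a positive (width, height) pair")
  }
  if (cfg$frac_on_ais < 0 || cfg$frac_on_ais > 1) {
    stop_config("frac_on_ais must lie in [0, 1]")
  }
  for (f in c("marker_prob_ais", "marker_prob_off")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_config(f, " must lie in [0, 1]")
  }
  if (cfg$n_branch_points < 0 || cfg$n_varicosities_total < 0 ||
      cfg$n_ais_tubes < 0) {
    stop_config("counts must be non-negative")
  }
  n_ais <- round(cfg$frac_on_ais * cfg$n_varicosities_total)
  if (n_ais > 0 && cfg$n_ais_tubes == 0) {
    stop_config("frac_on_ais requests AIS varicosities but n_ais_tubes = 0")
  }
  if (cfg$ais_length_um <= 10) {
    stop_config("ais_length_um must exceed 10 um (bounding-box filter)")
  }
  if (cfg$ais_width_um <= 2) {
    stop_config("ais_width_um must exceed 2 um (bounding-box filter)")
  }
  if (cfg$varicosity_diam_xy_um >= 3 || cfg$varicosity_diam_z_um >= 3.5) {
    stop_config("varicosity diameters must satisfy the < 3 um (x-y) and ",
                "< 3.5 um (z) selection criteria")
  }
  if (cfg$varicosity_brightness_ratio < 2) {
    stop_config("varicosity_brightness_ratio must be >= 2 so generated ",
                "varicosities pass the brightness criterion")
  }
  if (cfg$noise_sd < 0) stop_config("noise_sd must be non-negative")
  invisible(cfg)
}

#' Configuration for the synthetic electron-microscopy image generator
#'
#' Describes one varicosity profile: a roughly circular membrane outline
#' containing non-overlapping elliptical synaptic vesicles and dark
#' immunogold particles.  `vesicle_aspect_ratio` 1 gives round
#' (excitatory-like) vesicles; values > 1 give the flattened "jellybean"
#' shape typical of GABAergic vesicles.
#'
#' @param seed Integer seed.
#' @param nm_per_px Pixel pitch in nm.
#' @param profile_diameter_nm Profile diameter; must exceed the 200 nm
#'   varicosity-qualification rule.
#' @param n_vesicles Number of vesicles to pack into the profile.
#' @param vesicle_aspect_ratio Major/minor axis ratio (>= 1).
#' @param vesicle_mean_diameter_nm Equivalent-circle vesicle diameter.
#' @param gold_particle_count,gold_diameter_nm Immunogold disc count and size.
#'
#' @return An object of class `em_gen_config`.
#' @export
em_gen_config <- function(seed = 1L,
                          nm_per_px = 2,
                          profile_diameter_nm = 600,
                          n_vesicles = 20L,
                          vesicle_aspect_ratio = 2,
                          vesicle_mean_diameter_nm = 40,
                          gold_particle_count = 8L,
                          gold_diameter_nm = 20) {
  cfg <- list(
    seed = as.integer(seed),
    nm_per_px = nm_per_px,
    profile_diameter_nm = profile_diameter_nm,
    n_vesicles = as.integer(n_vesicles),
    vesicle_aspect_ratio = vesicle_aspect_ratio,
    vesicle_mean_diameter_nm = vesicle_mean_diameter_nm,
    gold_particle_count = as.integer(gold_particle_count),
    gold_diameter_nm = gold_diameter_nm
  )
  class(cfg) <- "em_gen_config"
  if (cfg$profile_diameter_nm <= 200) {
    stop_config("profile_diameter_nm must exceed 200 nm")
  }
  if (cfg$vesicle_aspect_ratio < 1) {
    stop_config("vesicle_aspect_ratio must be >= 1")
  }
  if (cfg$nm_per_px <= 0 || cfg$vesicle_mean_diameter_nm <= 0 ||
      cfg$gold_diameter_nm <= 0) {
    stop_config("all lengths must be positive")
  }
  if (cfg$n_vesicles < 0 || cfg$gold_particle_count < 0) {
    stop_config("counts must be non-negative")
  }
  cfg
}
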