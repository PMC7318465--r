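#' Pipeline configuration
#'
#' Collects every tunable of the quantification pipeline in one validated
#' object. All area settings are in square micrometers and are converted to
#' pixels internally via the field's calibration.
#'
#' @param dapi_threshold foreground cutoff for the nuclear channel, as a
#'   fraction of the per-image dynamic range (`0 < f < 1`); a pixel is nuclear
#'   foreground iff `I >= min + f * (max - min)`.
#' @param nucleus_area_range_um2 closed interval of admissible nuclear
#'   cross-section areas. The default 40-300 um^2 brackets typical
#'   granule-cell and cultured-cell (HEK293) nuclei.
#' @param nucleus_circularity_range closed interval within `[0, 1]` for the
#'   shape gate `4*pi*A/P^2` (1 = disc).
#' @param exclude_border_nuclei drop nuclei touching the field border (their
#'   area and intensity are censored).
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param focus_area_range_um2 closed interval of admissible focus areas.
#'   The default 0.2-3.0 um^2 corresponds to published nuclear-stress-body
#'   diameters of roughly 0.5-2 um.
#' @param rats_p gradient exponent of the RATS weights (`w = g^p`).
#' @param rats_noise_sigma gradient noise floor `sigma_g`; gradients at or
#'   below `lambda * sigma_g` carry zero weight.
#' @param rats_lambda noise multiplier `lambda`.
#' @param rats_min_leaf_px stop subdividing RATS regions once their edge is
#'   at most this many pixels (>= 2).
#' @param zscore_ddof degrees-of-freedom correction for the Z-score standard
#'   deviation (1 = sample sd).
#' @param alpha significance level for group tests.
#' @param projection_method Z-stack collapse method, `"max"` or `"mean"`.
#' @param background_radius_px rolling-ball radius for background
#'   subtraction, or `NULL` to skip it (the default; synthetic fields carry
#'   no shading).
#' @param seed integer seed for any stochastic step.
#' @return an object of class `PipelineConfig` (a validated list).
#' @export
pipeline_config <- function(dapi_threshold = 0.25,
                            nucleus_area_range_um2 = c(40, 300),
                            nucleus_circularity_range = c(0.3, 1.0),
                            exclude_border_nuclei = TRUE,
                            connectivity = 8,
                            focus_area_range_um2 = c(0.2, 3.0),
                            rats_p = 2,
                            rats_noise_sigma = 0.02,
                            rats_lambda = 3,
                            rats_min_leaf_px = 16,
                            zscore_ddof = 1,
                            alpha = 0.05,
                            projection_method = c("max", "mean"),
                            background_radius_px = NULL,
                            seed = 1L) {
  projection_method <- match.arg(projection_method)
  if (!(dapi_threshold > 0 && dapi_threshold < 1))
    stop_input("dapi_threshold must be in (0, 1)")
  check_interval(nucleus_area_range_um2, "nucleus_area_range_um2")
  check_interval(nucleus_circularity_range, "nucleus_circularity_range")
  if (nucleus_circularity_range[1] < 0 || nucleus_circularity_range[2] > 1)
    stop_input("nucleus_circularity_range must lie within [0, 1]")
  check_interval(focus_area_range_um2, "focus_area_range_um2")
  if (!connectivity %in% c(4, 8)) stop_input("connectivity must be 4 or 8")
  stopifnot(rats_p > 0, rats_noise_sigma >= 0, rats_lambda >= 0)
  if (rats_min_leaf_px < 2) stop_input("rats_min_leaf_px must be >= 2")
  stopifnot(zscore_ddof >= 0, alpha > 0, alpha < 1)
  if (!is.null(background_radius_px)) stopifnot(background_radius_px >= 1)
  structure(
    list(dapi_threshold = dapi_threshold,
         nucleus_area_range_um2 = nucleus_area_range_um2,
         nucleus_circularity_range = nucleus_circularity_range,
         exclude_border_nuclei = isTRUE(exclude_border_nuclei),
         connectivity = as.integer(connectivity),
         focus_area_range_um2 = focus_area_range_um2,
         rats_p = rats_p,
         rats_noise_sigma = rats_noise_sigma,
         rats_lambda = rats_lambda,
         rats_min_leaf_px = as.integer(rats_min_leaf_px),
         zscore_ddof = as.integer(zscore_ddof),
         alpha = alpha,
         projection_method = projection_method,
         background_radius_px = background_radius_px,
         seed = as.integer(seed)),
    class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds any subset of [pipeline_config()]'s arguments; omitted keys
#' take their defaults and unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_input("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `PipelineConfig`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
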