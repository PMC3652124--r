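#' Load and validate a run configuration
#'
#' A single YAML file configures a whole experiment: `phantom:`,
#' `geometry:`, `recon:`, `segmentation:`, `ct:` (noise and frame offset),
#' `counts:` and `seed:` sections. Unknown keys are rejected by name; every
#' omitted value takes the package default, and the fully materialized
#' configuration is what [write_manifest()] echoes, so two runs with equal
#' manifests are equal runs.
#'
#' @param path YAML configuration file; an empty or missing-section file
#'   yields all defaults.
#' @return A named list with entries `phantom` ([phantom_spec()]),
#'   `geometry` ([sinogram_geometry()]), `recon` ([recon_config()]),
#'   `segmentation` ([segment_policy()]), `curve` ([calibration_curve()]),
#'   `ct_offset` ([rigid_transform()]), `noise_sd_hu`, `total_counts`,
#'   `seed`.
#' @export
load_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else list()
  if (is.null(cfg)) cfg <- list()
  known <- c("phantom", "geometry", "recon", "segmentation", "calibration",
             "ct", "total_counts", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration sections: ", paste(bad, collapse = ", "))
  take <- function(section, fields, builder) {
    s <- cfg[[section]]
    if (is.null(s)) s <- list()
    extra <- setdiff(names(s), fields)
    if (length(extra))
      stop(sprintf("unknown keys in '%s': %s", section,
                   paste(extra, collapse = ", ")))
    do.call(builder, s)
  }
  phantom <- if (is.null(cfg$phantom)) rat_phantom()
             else as_phantom_spec(cfg$phantom)
  geometry <- take("geometry", c("n_angles", "n_bins", "bin_width_mm"),
                   sinogram_geometry)
  recon <- take("recon", c("n_subsets", "n_iterations", "init_value",
                           "ac_mode"), recon_config)
  segmentation <- take("segmentation", c("method", "fraction", "percentile"),
                       segment_policy)
  curve <- if (is.null(cfg$calibration)) default_calibration()
           else if (!is.null(cfg$calibration$points_file))
             fit_calibration(read_calibration_points(cfg$calibration$points_file))
           else do.call(calibration_curve, cfg$calibration)
  ct <- cfg$ct
  if (is.null(ct)) ct <- list()
  extra <- setdiff(names(ct), c("noise_sd_hu", "offset_rotation_deg",
                                "offset_translation_mm"))
  if (length(extra)) stop("unknown keys in 'ct': ",
                          paste(extra, collapse = ", "))
  ct_offset <- if (is.null(ct$offset_rotation_deg) &&
                   is.null(ct$offset_translation_mm)) default_ct_offset()
    else inplane_transform(ct$offset_rotation_deg %||% 0,
                           ct$offset_translation_mm %||% c(0, 0, 0))
  list(phantom = phantom, geometry = geometry, recon = recon,
       segmentation = segmentation, curve = curve, ct_offset = ct_offset,
       noise_sd_hu = ct$noise_sd_hu %||% 0,
       total_counts = cfg$total_counts %||% 2e6,
       seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the materialized
#' configuration, the package version, the seed, and any extra results the
#' caller attaches (fitted curves, estimated transforms as 4x4 homogeneous
#' matrices).
#'
#' @param config a configuration list from [load_config()].
#' @param path output JSON path.
#' @param extra named list appended under `results`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  strip <- function(x) {
    if (inherits(x, "rigid_transform")) return(as_homogeneous(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  manifest <- list(package = "petac",
                   version = as.character(utils::packageVersion("petac")),
                   config = strip(config), results = strip(extra))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
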