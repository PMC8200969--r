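# Run configuration: one nested list mirroring each module's parameters,
# loadable from YAML. Unknown keys are rejected (typos must not silently
# fall back to defaults) and every batch run writes the fully-resolved
# configuration next to its outputs.

#' Default run configuration
#'
#' @return nested list with sections `calibration`, `rois`, `pores`,
#'   `roughness`, `redness`, `fluctuation`, `synthetic`, plus global `seed`
#'   and `log_level`. ROI entries are 4-integer vectors
#'   `(row_start, row_stop, col_start, col_stop)`, 0-based half-open.
#' @export
default_config <- function() {
  lay <- patch_layout(c(256L, 256L))
  roi_vec <- function(r) c(r$row_start, r$row_stop, r$col_start, r$col_stop)
  list(
    calibration = list(tip_roi = roi_vec(lay$tip), nominal_reflectance = 0.5),
    rois = list(cheek = roi_vec(lay$cheek),
                eye_to_cheek = roi_vec(lay$eye_to_cheek)),
    pores = list(dog_sigma_small = 1.5, dog_sigma_large = 6, binarize_k = 3.5,
                 min_area = 9, max_area = 2000, circularity_min = 0.6,
                 min_contrast = 0.02),
    roughness = list(band = c(0.02, 0.15), sigma_illum = 30),
    redness = list(band = c(0.005, 0.05), w_brightness = 1, w_variation = 1),
    fluctuation = list(adjust = TRUE, baseline = "week-4"),
    synthetic = list(n_subjects = 47, missingness = 0.05,
                     image_size = c(256, 256)),
    seed = 1,
    log_level = "info")
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user))
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                  paste0(path, k, "."))
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file, overlays it onto [default_config()], and rejects
#' unknown keys. `NULL` returns the defaults unchanged.
#'
#' @param path YAML config path, or `NULL`.
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

write_resolved_config <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config.resolved.yaml"))
}

config_pore_params <- function(cfg) {
  p <- cfg$pores
  pore_params(p$dog_sigma_small, p$dog_sigma_large, p$binarize_k,
              p$min_area, p$max_area, p$circularity_min, p$min_contrast)
}

config_roi <- function(v, label) {
  roi(v[1], v[2], v[3], v[4], label = label)
}
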