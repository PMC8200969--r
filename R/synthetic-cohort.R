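# Longitudinal cohort simulator emulating the two-study design: 8 weeks
# (4 baseline + 4 treatment), three sessions a day, with the additive model
#
#   value = mu + b_s + tau_t + delta_t * 1[week >= 1] + eps
#
# b_s ~ N(0, sigma_subject^2) per subject, eps ~ N(0, sigma_noise^2) per
# session. tau orders the timepoints (pore/roughness: morning-wake largest;
# redness: evening largest); delta is the treatment shift per timepoint.
# Sessions are dropped independently with the missingness probability, and
# in image mode each surviving session is rendered as a synthetic patch.

default_metric_models <- function() {
  list(
    pore_area = list(mu = 100, tau = c(8, 0, 2), delta = c(-8, -3, -3),
                     sigma_subject = 10, sigma_noise = 4),
    roughness = list(mu = 50, tau = c(4, 0, 1), delta = c(-4, -1, -1),
                     sigma_subject = 6, sigma_noise = 2),
    redness   = list(mu = 40, tau = c(1, 0, 6), delta = c(-1, -1, -5),
                     sigma_subject = 8, sigma_noise = 3))
}

#' Cohort simulation parameters
#'
#' @param n_subjects number of subjects (default 47, the per-study completer
#'   count the simulator emulates).
#' @param metric_models named list (per metric) of `mu`, `tau` (length-3
#'   timepoint offsets in the order morning_wake, morning_wash,
#'   evening_wash), `delta` (length-3 treatment offsets), `sigma_subject`,
#'   `sigma_noise`. See `dermaflux:::default_metric_models()` for the
#'   defaults.
#' @param missingness independent per-session drop probability.
#' @param days study days simulated (default all of 1..56).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 47L,
                          metric_models = default_metric_models(),
                          missingness = 0.05,
                          days = 1:56,
                          seed = 1L) {
  stopifnot(n_subjects >= 1L, missingness >= 0, missingness < 1,
            all(days %in% 1:56))
  stopifnot(all(METRICS %in% names(metric_models)))
  for (m in METRICS) {
    mm <- metric_models[[m]]
    stopifnot(length(mm$tau) == 3L, length(mm$delta) == 3L,
              mm$sigma_subject >= 0, mm$sigma_noise >= 0)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 metric_models = metric_models,
                 missingness = missingness,
                 days = sort(unique(as.integer(days))),
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Simulate a longitudinal cohort
#'
#' In `values` mode, emits the linear-model session values directly as a
#' metric-record table. In `images` mode, each session's three generating
#' values are additionally mapped to patch parameters (pore value to a pore
#' count at fixed radius, roughness value to texture RMS, redness value to a
#' hemoglobin shift plus blotch field), rendered at `image_size`, and written
#' as 16-bit PPM files with a sidecar CSV, so the whole analysis pipeline can
#' be closed-loop tested. Everything is reproducible from `params$seed`.
#'
#' @param params a [cohort_params()].
#' @param mode `"values"` or `"images"`.
#' @param out_dir output directory for image mode.
#' @param image_size rendered patch size, default `c(256, 256)`.
#' @return `values` mode: metric-record data frame (ground-truth values).
#'   `images` mode: list with `records` (the generating values), `sidecar`
#'   (data frame naming one image file per session), `layout` (tip and
#'   analysis ROIs used), and `dir`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            mode = c("values", "images"),
                            out_dir = NULL, image_size = c(256L, 256L)) {
  stopifnot(inherits(params, "cohort_params"))
  mode <- match.arg(mode)
  set.seed(params$seed)
  subjects <- sprintf("S%03d", seq_len(params$n_subjects))
  grid <- expand.grid(timepoint = TIMEPOINTS, study_day = params$days,
                      subject_id = subjects, stringsAsFactors = FALSE)
  grid <- grid[c("subject_id", "study_day", "timepoint")]
  grid$week_index <- week_from_day(grid$study_day)
  # sessions drop out as a whole (all metrics share the captured image)
  keep <- stats::runif(nrow(grid)) >= params$missingness
  grid <- grid[keep, , drop = FALSE]
  tp_idx <- match(grid$timepoint, TIMEPOINTS)
  treated <- as.numeric(grid$week_index >= 1)

  recs <- lapply(METRICS, function(m) {
    mm <- params$metric_models[[m]]
    b_s <- stats::rnorm(params$n_subjects, 0, mm$sigma_subject)
    names(b_s) <- subjects
    eps <- stats::rnorm(nrow(grid), 0, mm$sigma_noise)
    value <- mm$mu + b_s[grid$subject_id] + mm$tau[tp_idx] +
      mm$delta[tp_idx] * treated + eps
    data.frame(subject_id = grid$subject_id, study_day = grid$study_day,
               week_index = grid$week_index, timepoint = grid$timepoint,
               face_side = NA_character_, metric = m, value_au = value)
  })
  records <- metric_records(do.call(rbind, recs))
  rownames(records) <- NULL
  if (mode == "values") return(records)

  if (is.null(out_dir)) stop("image mode needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- patch_layout(image_size)
  wide <- stats::reshape(records[c("subject_id", "study_day", "timepoint",
                                   "metric", "value_au")],
                         idvar = c("subject_id", "study_day", "timepoint"),
                         timevar = "metric", direction = "wide")
  sidecar <- data.frame(file = character(nrow(wide)),
                        subject_id = wide$subject_id,
                        study_day = wide$study_day,
                        timepoint = wide$timepoint,
                        face_side = "left",
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(wide))) {
    pp <- session_patch_params(
      pore_au = wide$value_au.pore_area[i],
      roughness_au = wide$value_au.roughness[i],
      redness_au = wide$value_au.redness[i],
      layout = layout,
      seed = (params$seed * 1000L + i) %% .Machine$integer.max)
    g <- generate_patch(pp)
    fn <- sprintf("%s_d%02d_%s.ppm", wide$subject_id[i], wide$study_day[i],
                  wide$timepoint[i])
    write_image(g$image, file.path(out_dir, fn), bit_depth = 16L)
    sidecar$file[i] <- fn
  }
  utils::write.csv(sidecar, file.path(out_dir, "sidecar.csv"),
                   row.names = FALSE)
  list(records = records, sidecar = sidecar, layout = layout, dir = out_dir)
}

#' Standard layout of a rendered patch
#'
#' Gray tip in the top-left corner; below it the analysis area splits into a
#' left eye-to-cheek region (roughness; rendered pore-free, as pores sit at
#' the cheek) and a right cheek region (pores, redness).
#'
#' @param size `(H, W)` of the rendered patch.
#' @return list with [roi()]s `tip`, `cheek`, `eye_to_cheek`.
#' @export
patch_layout <- function(size = c(256L, 256L)) {
  h <- size[1]; w <- size[2]
  stopifnot(h >= 128L, w >= 128L)
  tip <- roi(4L, 36L, 4L, 36L, label = "gray_tip")
  a_r0 <- 48L
  mid <- w %/% 2L
  list(tip = tip,
       cheek = roi(a_r0, h - 8L, mid, w - 8L, label = "cheek"),
       eye_to_cheek = roi(a_r0, h - 8L, 8L, mid, label = "eye_to_cheek"),
       size = c(h, w))
}

# Map one session's generating metric values onto physical patch parameters.
# Each map is affine and monotone, so image-mode metrics preserve ordering.
# Slopes trade recoverability against cross-talk: pore density is kept sparse
# (~6% coverage at 100 au) because the robust binarization threshold assumes
# pores are outliers of the response distribution, and the texture slope is
# kept small because the threshold scales with texture RMS and would
# otherwise bleed roughness variation into the detected pore area.
session_patch_params <- function(pore_au, roughness_au, redness_au, layout,
                                 seed,
                                 pore_radius = 4,
                                 capture_gains = c(1.12, 1.0, 0.92)) {
  ck <- layout$cheek
  n_pores <- max(0L, round(pore_au * 0.3))                 # 100 au -> 30 pores
  texture_rms <- max(0, roughness_au * 0.03 / 50)          # 50 au -> 0.03 RMS
  h_shift <- (redness_au - 40) / 100                       # 1 au -> 0.01 h units
  patch_params(size = layout$size,
               n_pores = n_pores,
               pore_radius_px = c(pore_radius, 0),
               texture_rms = texture_rms,
               texture_rms_cheek = 0.03,
               blotch_rms = 0.02,
               h_shift = h_shift,
               pore_region = layout$cheek,
               tip_roi = layout$tip,
               tip_reflectance = 0.5,
               gains = capture_gains,
               bit_depth = 16L,
               seed = seed)
}
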