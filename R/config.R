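#' Pipeline configuration
#'
#' Bundles the geometric and algorithmic parameters shared across the
#' pipeline: patch geometry (a 70 um x 70 um patch corresponds to
#' 200 x 200 pixels at the default optics), the background window used for
#' fluorescence normalization, the mobility median-filter window, the
#' dead-call variance threshold, classifier debouncing persistence and the
#' manual-comparison frame tolerance.
#'
#' All frame indices produced by the pipeline are 0-based; times in minutes
#' are `index * frame_interval`.
#'
#' @param patch_size_px Side of the square per-incubator crop, pixels.
#' @param patch_size_um Side of the crop in micrometres; together with
#'   `patch_size_px` this fixes the pixel size (um/px).
#' @param bg_window_um Background window (width, height) in micrometres,
#'   anchored at the top rows of the patch; default 70 x 7 um.
#' @param dead_variance_threshold Variance of the filtered mobility trace
#'   below which an embryo is called Dead. `NULL` (default) means
#'   self-calibrate from the Empty incubators of the same run
#'   (3 x their 95th-percentile variance).
#' @param median_filter_window Odd window (frames) for the mobility median
#'   filter.
#' @param persistence_frames Number of consecutive frames a classifier call
#'   must persist before a transition is accepted.
#' @param tolerance_frames Frame tolerance used when comparing automated and
#'   manual transition calls.
#' @param trap_width_px,trap_height_px Expected outer incubator dimensions in
#'   pixels, used to filter detection candidates.
#' @param incubator_pitch_px Expected centre-to-centre incubator spacing.
#' @param seed Integer seed recorded with the config.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$patch_size_px
pipeline_config <- function(patch_size_px = 200L,
                            patch_size_um = 70,
                            bg_window_um = c(70, 7),
                            dead_variance_threshold = NULL,
                            median_filter_window = 5L,
                            persistence_frames = 3L,
                            tolerance_frames = 5L,
                            trap_width_px = 48L,
                            trap_height_px = 68L,
                            incubator_pitch_px = 220L,
                            seed = 1L) {
  stopifnot(patch_size_px > 0, patch_size_um > 0, all(bg_window_um > 0),
            median_filter_window >= 1, tolerance_frames >= 0,
            persistence_frames >= 1)
  if (median_filter_window %% 2 == 0)
    stop("`median_filter_window` must be odd", call. = FALSE)
  cfg <- structure(list(
    patch_size_px = as.integer(patch_size_px),
    patch_size_um = patch_size_um,
    bg_window_um = bg_window_um,
    dead_variance_threshold = dead_variance_threshold,
    median_filter_window = as.integer(median_filter_window),
    persistence_frames = as.integer(persistence_frames),
    tolerance_frames = as.integer(tolerance_frames),
    trap_width_px = as.integer(trap_width_px),
    trap_height_px = as.integer(trap_height_px),
    incubator_pitch_px = as.integer(incubator_pitch_px),
    seed = as.integer(seed)
  ), class = "pipeline_config")
  cfg
}

#' Pixel size implied by a configuration
#'
#' @param config A [pipeline_config()].
#' @return Micrometres per pixel.
#' @export
config_pixel_size <- function(config) {
  config$patch_size_um / config$patch_size_px
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}
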