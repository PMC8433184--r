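#' Time-lapse image sequence
#'
#' Container for a multi-channel time-lapse acquired at one stage position:
#' one `height x width x time` numeric array per channel, a constant frame
#' interval in minutes and a pixel size in micrometres. Intensities are
#' nonnegative; the pipeline itself is unit-agnostic (any nonnegative
#' integer or float imagery is accepted).
#'
#' @param channels Named list of 3-D arrays (`height x width x frames`),
#'   names from `"brightfield"`, `"gfp"`.
#' @param frame_interval Minutes between consecutive frames (> 0); 5 min for
#'   brightfield-only runs, 10 min for dual brightfield/fluorescence runs.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param position_id Identifier of the stage position.
#'
#' @return An object of class `time_lapse_sequence`.
#' @export
time_lapse_sequence <- function(channels, frame_interval, pixel_size,
                                position_id = "pos0") {
  if (!is.list(channels) || is.null(names(channels)) ||
      !all(nzchar(names(channels))))
    stop("`channels` must be a named list of 3-D arrays", call. = FALSE)
  if (!all(names(channels) %in% c("brightfield", "gfp")))
    stop("channel labels must be 'brightfield' and/or 'gfp'", call. = FALSE)
  dims <- lapply(channels, dim)
  for (d in dims) {
    if (length(d) != 3) stop("each channel must be height x width x frames",
                             call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
    stop("all channels must share identical dimensions and frame counts",
         call. = FALSE)
  stopifnot(frame_interval > 0, pixel_size > 0)
  structure(list(
    channels = channels,
    frame_interval = frame_interval,
    pixel_size = pixel_size,
    position_id = position_id
  ), class = "time_lapse_sequence")
}

#' @export
print.time_lapse_sequence <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<time_lapse_sequence> %s | %d x %d px, %d frames, %g min/frame, %g um/px, channels: %s\n",
    x$position_id, d[1], d[2], d[3], x$frame_interval, x$pixel_size,
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a sequence
#' @param sequence A [time_lapse_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(sequence) {
  dim(sequence$channels[[1]])[3]
}

#' Extract one frame
#'
#' @param sequence A [time_lapse_sequence()].
#' @param frame 0-based acquisition index.
#' @param channel Channel label.
#' @return A `height x width` matrix.
#' @export
get_frame <- function(sequence, frame, channel = "brightfield") {
  stopifnot(inherits(sequence, "time_lapse_sequence"))
  if (!channel %in% names(sequence$channels))
    stop("channel not present: ", channel, call. = FALSE)
  nt <- n_frames(sequence)
  if (frame < 0 || frame >= nt)
    stop("frame index out of range [0, ", nt - 1, "]", call. = FALSE)
  sequence$channels[[channel]][, , frame + 1]
}

#' Write a time-lapse sequence to disk
#'
#' One multi-page 16-bit TIFF per channel (page index = time index) named
#' `<position>_<channel>.tiff`, plus a JSON metadata sidecar with the frame
#' interval, pixel size and channel list. Intensities must lie in `[0, 1]`
#' (16-bit normalized); values are stored on the 16-bit grid, so a sequence
#' whose values are multiples of 1/65535 round-trips exactly.
#'
#' @param sequence A [time_lapse_sequence()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_sequence <- function(sequence, dir) {
  stopifnot(inherits(sequence, "time_lapse_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rng <- range(unlist(lapply(sequence$channels, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("save_sequence() stores 16-bit normalized imagery; ",
         "intensities must lie in [0, 1]", call. = FALSE)
  for (ch in names(sequence$channels)) {
    arr <- sequence$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t])
    tiff::writeTIFF(pages,
                    file.path(dir, paste0(sequence$position_id, "_", ch, ".tiff")),
                    bits.per.sample = 16L, compression = "none")
  }
  meta <- list(position_id = sequence$position_id,
               channels = names(sequence$channels),
               frame_interval = sequence$frame_interval,
               pixel_size = sequence$pixel_size)
  jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a time-lapse sequence
#'
#' Reads multi-page TIFF stacks (one file or several per channel; pages are
#' appended in lexicographic file order, preserving acquisition order). When
#' the directory contains a `sequence.json` sidecar written by
#' [save_sequence()], metadata defaults are taken from it.
#'
#' @param path Directory containing the stacks.
#' @param channel_map Named character vector mapping channel labels to file
#'   glob patterns, e.g. `c(brightfield = "*_brightfield.tiff")`.
#' @param frame_interval,pixel_size,position_id Metadata; override the
#'   sidecar when given.
#' @return A [time_lapse_sequence()].
#' @export
load_sequence <- function(path,
                          channel_map = NULL,
                          frame_interval = NULL,
                          pixel_size = NULL,
                          position_id = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  meta <- NULL
  sidecar <- file.path(path, "sequence.json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  position_id <- position_id %||% meta$position_id %||% "pos0"
  frame_interval <- frame_interval %||% meta$frame_interval
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(frame_interval) || is.null(pixel_size))
    stop("frame_interval and pixel_size must be given when no sidecar exists",
         call. = FALSE)
  if (is.null(channel_map)) {
    chs <- meta$channels %||% "brightfield"
    channel_map <- stats::setNames(paste0("*_", chs, ".tiff"), chs)
  }
  channels <- list()
  for (ch in names(channel_map)) {
    files <- sort(Sys.glob(file.path(path, channel_map[[ch]])))
    if (length(files) == 0)
      stop("no files match pattern for channel '", ch, "'", call. = FALSE)
    pages <- list()
    for (f in files) {
      pg <- tiff::readTIFF(f, all = TRUE)
      if (!is.list(pg)) pg <- list(pg)
      pages <- c(pages, pg)
    }
    dims <- unique(vapply(pages, function(p) paste(dim(p), collapse = "x"), ""))
    if (length(dims) != 1)
      stop("inconsistent frame dimensions in channel '", ch, "'", call. = FALSE)
    channels[[ch]] <- array(unlist(pages),
                            dim = c(dim(pages[[1]]), length(pages)))
  }
  nts <- vapply(channels, function(a) dim(a)[3], integer(1))
  if (length(unique(nts)) != 1)
    stop("channels have mismatched frame counts", call. = FALSE)
  time_lapse_sequence(channels, frame_interval, pixel_size, position_id)
}
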