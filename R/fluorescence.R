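# Background-normalized embryo fluorescence.
#
# I_SBR = I_ROI / I_BG per frame, where I_ROI is the nonzero median of the
# masked fluorescence patch (the mask is built once from an embryo-free
# brightfield patch and dilated) and I_BG is the mean of a top-anchored
# background window spanning the full patch width and 7 um of height.
# Normalizing each frame by its own background window cancels frame-to-
# frame illumination (lamp intensity) variation, which is the point of the
# ratio.

#' Build the incubator mask from an embryo-free patch
#'
#' Thresholds the trap walls of an embryo-free brightfield patch (Otsu),
#' closes the gate opening, fills the enclosed region and keeps its largest
#' interior component, then dilates ("extends") the mask by
#' `dilation_radius` so the embryo boundary is not clipped when the mask is
#' mapped onto the fluorescence channel.
#'
#' @param empty_patch 2-D intensity matrix of an embryo-free incubator.
#' @param dilation_radius Dilation radius in px (0 = undilated threshold
#'   output).
#' @param closing_size Diameter of the disc used to seal the trap's gate
#'   opening before hole filling; must exceed the gate width.
#' @return A binary matrix of class `incubator_mask` (1 = embryo-region
#'   interior) with attribute `dilation_radius`.
#' @export
build_mask <- function(empty_patch, dilation_radius = 2L, closing_size = 19L) {
  stopifnot(is.matrix(empty_patch))
  if (diff(range(empty_patch)) < 1e-12)
    stop("mask error: uniform patch, nothing to threshold", call. = FALSE)
  rng <- range(empty_patch)
  norm <- (empty_patch - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  walls <- as.matrix(EBImage::closing((norm < thr) * 1,
                                      EBImage::makeBrush(closing_size, "disc")))
  filled <- as.matrix(EBImage::fillHull(walls))
  interior <- (filled > 0 & walls == 0) * 1
  lab <- EBImage::bwlabel(interior)
  if (max(lab) == 0)
    stop("mask error: no enclosed interior found", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  mask <- matrix(as.numeric(lab == which.max(sizes)),
                 nrow(empty_patch), ncol(empty_patch))
  if (dilation_radius > 0)
    mask <- as.matrix(EBImage::dilate(
      mask, EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, "disc")))
  if (sum(mask) == 0) stop("mask error: empty mask", call. = FALSE)
  structure(mask, class = c("incubator_mask", class(mask)),
            dilation_radius = as.integer(dilation_radius))
}

# top-anchored background window rows for a patch under `config`
.bg_window_rows <- function(patch, config) {
  px_size <- config_pixel_size(config)
  h <- max(1L, round(config$bg_window_um[2] / px_size))
  seq_len(min(h, nrow(patch)))
}

#' Quantify embryo fluorescence in one frame
#'
#' `I_ROI` is the median of the nonzero values of `fluo_patch * mask`;
#' `I_BG` is the mean of the background window (full patch width, 7 um
#' high, anchored at the top rows); `I_SBR = I_ROI / I_BG`.
#'
#' @param fluo_patch 2-D fluorescence intensity matrix, same shape as
#'   `mask`.
#' @param mask An [build_mask()] output (or binary matrix). Must not
#'   intersect the background window.
#' @param config A [pipeline_config()].
#' @return One-row tibble: `i_roi`, `i_bg`, `i_sbr`, `flag` (`NA` or
#'   `"empty_roi"` when the masked region has no nonzero pixels).
#' @export
quantify_frame <- function(fluo_patch, mask, config = pipeline_config()) {
  stopifnot(is.matrix(fluo_patch), all(dim(fluo_patch) == dim(mask)))
  rows <- .bg_window_rows(fluo_patch, config)
  if (any(mask[rows, ] > 0))
    stop("background window intersects the mask", call. = FALSE)
  i_bg <- mean(fluo_patch[rows, ])
  if (i_bg <= 0) stop("division error: background window mean is 0",
                      call. = FALSE)
  masked <- fluo_patch * as.numeric(mask)
  nz <- masked[masked > 0]
  if (length(nz) == 0)
    return(tibble::tibble(i_roi = NA_real_, i_bg = i_bg, i_sbr = NA_real_,
                          flag = "empty_roi"))
  i_roi <- median(nz)
  tibble::tibble(i_roi = i_roi, i_bg = i_bg, i_sbr = i_roi / i_bg,
                 flag = NA_character_)
}

#' Quantify embryo fluorescence over a patch series
#'
#' One measurement per frame up to `end_frame` (exclusive; defaults to the
#' series end — callers typically pass the hatch frame). Each frame is
#' normalized by its own background window.
#'
#' @param fluo_series A [patch_series()] of the fluorescence channel.
#' @param mask An [build_mask()] output.
#' @param config A [pipeline_config()].
#' @param end_frame Optional 0-based exclusive bound on frames measured.
#' @return Tibble with `frame` (0-based), `minutes`, `i_roi`, `i_bg`,
#'   `i_sbr`, `flag`.
#' @export
quantify_series <- function(fluo_series, mask, config = pipeline_config(),
                            end_frame = NULL) {
  stopifnot(inherits(fluo_series, "patch_series"))
  nt <- dim(fluo_series$frames)[3]
  n <- if (is.null(end_frame) || is.na(end_frame)) nt
       else min(as.integer(end_frame), nt)
  out <- dplyr::bind_rows(lapply(seq_len(n), function(t)
    quantify_frame(fluo_series$frames[, , t], mask, config)))
  out$frame <- seq_len(n) - 1L
  out$minutes <- out$frame * fluo_series$frame_interval
  out[, c("frame", "minutes", "i_roi", "i_bg", "i_sbr", "flag")]
}

#' Population mean fluorescence profile
#'
#' Per-frame mean and standard error of `i_sbr` across embryos still
#' present at that frame: embryos whose measurement series was truncated
#' (e.g. at hatch) simply drop out of later frames. At `n = 1` the SEM is
#' reported as 0 and flagged via the `n` column.
#'
#' @param per_embryo List of [quantify_series()] tibbles, one per embryo.
#' @param horizon_frames Number of frames to report (default: longest
#'   series). The initial 300 min of embryogenesis corresponds to
#'   `horizon_frames = 30` at a 10-min frame interval.
#' @return A tibble of class `fluo_profile`: `frame`, `minutes`, `mean_sbr`,
#'   `sem_sbr`, `n`.
#' @export
population_mean_profile <- function(per_embryo, horizon_frames = NULL) {
  if (length(per_embryo) == 0 || all(vapply(per_embryo, nrow, 0L) == 0))
    stop("no measurements supplied", call. = FALSE)
  fi <- {
    m <- per_embryo[[which(vapply(per_embryo, nrow, 0L) > 0)[1]]]
    if (nrow(m) > 1) diff(m$minutes[1:2]) else 1
  }
  horizon <- horizon_frames %||% max(vapply(per_embryo, nrow, 0L))
  rows <- lapply(seq_len(horizon) - 1L, function(f) {
    v <- unlist(lapply(per_embryo, function(m) m$i_sbr[m$frame == f]))
    v <- v[!is.na(v)]
    tibble::tibble(frame = f, minutes = f * fi,
                   mean_sbr = if (length(v)) mean(v) else NA_real_,
                   sem_sbr = if (length(v) > 1) sd(v) / sqrt(length(v))
                             else if (length(v) == 1) 0 else NA_real_,
                   n = length(v))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fluo_profile", class(out))
  out
}
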