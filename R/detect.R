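# Incubator localization.
#
# Incubator traps are located once per stage position from a single
# brightfield frame: Canny edge map -> morphological closing -> hole fill
# -> connected components -> area/aspect filtering -> centroid. A matched
# -filter fallback covers frames where component filtering is inconclusive.
# Coordinates are 0-based with x = column, y = row, everywhere.

# shift a matrix by (dr, dc), padding with `fill`
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, percentile-derived
# hysteresis thresholds.
canny_edges <- function(img, sigma = 2, high_quantile = 0.995,
                        low_fraction = 0.4) {
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(sm, kx))
  gy <- as.matrix(EBImage::filter2(sm, t(kx)))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-9) return(matrix(0, nrow(img), ncol(img)))
  # quantize gradient direction into 4 bins and suppress non-maxima
  ang <- atan2(gy, gx)
  bin <- (round(ang / (pi / 4)) %% 4)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- mag
  for (b in 0:3) {
    o <- offs[[as.character(b)]]
    nb1 <- .shift_mat(mag, o[1], o[2])
    nb2 <- .shift_mat(mag, -o[1], -o[2])
    sup <- bin == b & (mag < nb1 | mag < nb2)
    nms[sup] <- 0
  }
  # percentile-derived strong threshold, capped at a fraction of the
  # gradient peak so dense edge maps (many structures per frame) keep
  # strong anchors on every edge segment
  hi <- min(max(quantile(mag, high_quantile), 0.1 * max(mag)),
            0.35 * max(mag))
  lo <- low_fraction * hi
  weak <- nms >= lo
  strong <- nms >= hi
  if (!any(strong)) return(matrix(0, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(as.numeric(lab %in% keep), nrow(img), ncol(img))
}

# matched-filter fallback: correlate with a synthetic trap-wall template
.template_locations <- function(frame, config) {
  tw <- config$trap_width; th <- config$trap_height
  w <- config$trap_width %/% 10L
  tmpl <- matrix(0, th, tw)
  tmpl[c(seq_len(w), th - seq_len(w) + 1L), ] <- 1
  tmpl[, c(seq_len(w), tw - seq_len(w) + 1L)] <- 1
  tmpl <- tmpl - mean(tmpl)
  resp <- as.matrix(EBImage::filter2(frame - mean(frame), tmpl / sqrt(sum(tmpl^2))))
  resp <- abs(resp)
  thr <- 0.6 * max(resp)
  half <- config$incubator_pitch %/% 3L
  locs <- list()
  r <- resp
  while (max(r) >= thr && length(locs) < 4L * 64L) {
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    locs[[length(locs) + 1L]] <- ij
    rr <- max(1, ij[1] - half):min(nrow(r), ij[1] + half)
    cc <- max(1, ij[2] - half):min(ncol(r), ij[2] + half)
    r[rr, cc] <- 0
  }
  if (length(locs) == 0) return(NULL)
  do.call(rbind, locs)
}

#' Detect embryo incubators in a frame
#'
#' Runs once per stage position on a single (typically first) brightfield
#' frame. The edge-based pipeline is Canny edges, morphological closing,
#' hole filling, connected components, then filtering by area and bounding
#' -box dimensions against the expected trap geometry in `config`; each
#' surviving component contributes the centre of its bounding box as the
#' incubator centroid. If no component survives, a matched-filter fallback
#' against a synthetic trap template is used. Returns an empty tibble (not
#' an error) when nothing is found, including on degenerate all-constant
#' frames.
#'
#' @param frame 2-D intensity matrix.
#' @param config A [pipeline_config()] carrying `trap_width_px`,
#'   `trap_height_px` and `incubator_pitch_px`.
#' @return Tibble with columns `index` (0-based ordinal along x), `x`, `y`
#'   (0-based centroid pixel coordinates, x = column).
#' @export
detect_incubators <- function(frame, config = pipeline_config()) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  empty <- tibble::tibble(index = integer(), x = numeric(), y = numeric())
  if (diff(range(frame)) < 1e-12) return(empty)
  edges <- canny_edges(frame)
  cand <- NULL
  if (any(edges > 0)) {
    closed <- EBImage::closing(edges, EBImage::makeBrush(11, "disc"))
    filled <- EBImage::fillHull(closed)
    lab <- EBImage::bwlabel(filled)
    nlab <- max(lab)
    tw <- config$trap_width_px; th <- config$trap_height_px
    for (k in seq_len(nlab)) {
      px <- which(lab == k, arr.ind = TRUE)
      h <- diff(range(px[, 1])) + 1L
      w <- diff(range(px[, 2])) + 1L
      area <- nrow(px)
      # area bound tolerates partially fragmented wall rings (an intact
      # ring is ~2 x perimeter x edge thickness; a filled trap far more)
      if (w >= 0.5 * tw && w <= 1.8 * tw &&
          h >= 0.5 * th && h <= 1.8 * th &&
          area >= 0.15 * tw * th && area <= 3 * tw * th) {
        cand <- rbind(cand, c(mean(range(px[, 1])), mean(range(px[, 2]))))
      }
    }
  }
  if (is.null(cand)) cand <- .template_locations(frame, config)
  if (is.null(cand)) return(empty)
  # merge fragments of the same trap: centroids closer than half a pitch
  ord <- order(cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  merged <- list(cand[1, ])
  if (nrow(cand) > 1) {
    for (k in 2:nrow(cand)) {
      last <- merged[[length(merged)]]
      if (abs(cand[k, 2] - last[2]) < config$incubator_pitch_px / 2)
        merged[[length(merged)]] <- (last + cand[k, ]) / 2
      else merged[[length(merged) + 1L]] <- cand[k, ]
    }
  }
  cand <- do.call(rbind, merged)
  tibble::tibble(index = seq_len(nrow(cand)) - 1L,
                 x = cand[, 2] - 1,    # 0-based
                 y = cand[, 1] - 1)
}

#' Per-incubator patch series
#'
#' @param frames `height x width x frames` array cropped around one
#'   incubator.
#' @param frame_interval Minutes per frame.
#' @param channel Channel label.
#' @param origin 0-based (x, y) of the crop window's top-left corner in the
#'   source frame.
#' @return An object of class `patch_series`.
#' @export
patch_series <- function(frames, frame_interval, channel = "brightfield",
                         origin = c(0, 0)) {
  stopifnot(length(dim(frames)) == 3)
  structure(list(frames = frames, frame_interval = frame_interval,
                 channel = channel, origin = origin),
            class = "patch_series")
}

#' @export
print.patch_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<patch_series> %s: %d x %d px, %d frames, origin (%g, %g)\n",
              x$channel, d[1], d[2], d[3], x$origin[1], x$origin[2]))
  invisible(x)
}

#' Crop the patch series of one incubator
#'
#' Extracts a `patch_size_px`-square patch centred on the incubator at
#' every timepoint (70 um x 70 um, i.e. 200 x 200 px at the default
#' optics). Crops that would overhang a frame border are shifted inward so
#' the full square fits; the same window is used for every timepoint and
#' channel, so brightfield and fluorescence patches are co-registered.
#'
#' @param sequence A [time_lapse_sequence()].
#' @param loc One-row location (list/tibble row with `x`, `y`, 0-based).
#' @param config A [pipeline_config()].
#' @param channel Channel to crop.
#' @return A [patch_series()].
#' @export
crop_patch_series <- function(sequence, loc, config = pipeline_config(),
                              channel = "brightfield") {
  stopifnot(inherits(sequence, "time_lapse_sequence"))
  arr <- sequence$channels[[channel]]
  if (is.null(arr)) stop("channel not present: ", channel, call. = FALSE)
  p <- config$patch_size_px
  H <- dim(arr)[1]; W <- dim(arr)[2]
  if (p > H || p > W)
    stop("patch_size_px exceeds frame dimensions", call. = FALSE)
  x <- round(loc$x); y <- round(loc$y)
  if (x < 0 || x >= W || y < 0 || y >= H)
    stop("location outside frame bounds", call. = FALSE)
  x0 <- min(max(x - p %/% 2L, 0L), W - p)    # 0-based, shifted inward
  y0 <- min(max(y - p %/% 2L, 0L), H - p)
  patch_series(arr[(y0 + 1L):(y0 + p), (x0 + 1L):(x0 + p), , drop = FALSE],
               frame_interval = sequence$frame_interval,
               channel = channel, origin = c(x0, y0))
}
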