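# Frame-differencing mobility analysis.
#
# The mobility trace is the per-frame-pair mean absolute pixel difference
# between consecutive incubator patches. A static (dead or empty) incubator
# yields a flat trace; twitching produces a sustained step, and the first
# upward crossing of the reduced (hatch-cropped, median-filtered) trace
# through its own mean marks the twitching onset.

#' Mobility trace
#'
#' @param values Nonnegative numeric vector, one value per consecutive
#'   frame pair (length = frames - 1).
#' @param frame_interval Minutes per frame.
#' @param filtered Optional median-filtered copy (same length).
#' @return An object of class `mobility_trace`.
#' @export
mobility_trace <- function(values, frame_interval = 5, filtered = NULL) {
  stopifnot(length(values) >= 1, all(values >= 0))
  if (!is.null(filtered) && length(filtered) != length(values))
    stop("`filtered` must have the same length as `values`", call. = FALSE)
  structure(list(values = as.numeric(values),
                 frame_interval = frame_interval,
                 filtered = if (!is.null(filtered)) as.numeric(filtered)),
            class = "mobility_trace")
}

#' @export
print.mobility_trace <- function(x, ...) {
  cat(sprintf("<mobility_trace> %d frame pairs, %g min/frame%s\n",
              length(x$values), x$frame_interval,
              if (is.null(x$filtered)) "" else ", median-filtered"))
  invisible(x)
}

#' @export
tidy.mobility_trace <- function(x, ...) {
  tibble::tibble(pair = seq_along(x$values) - 1L,
                 minutes = (seq_along(x$values) - 1L) * x$frame_interval,
                 raw = x$values,
                 filtered = if (is.null(x$filtered)) NA_real_ else x$filtered)
}

#' Compute the mobility trace of a patch series
#'
#' For each pair of consecutive patches, subtracts them pixel by pixel (in
#' signed double arithmetic, so unsigned imagery cannot underflow) and
#' averages the absolute differences over the patch.
#'
#' @param series A [patch_series()] or a `height x width x frames` array
#'   with at least 2 frames.
#' @return A [mobility_trace()] of length `frames - 1`.
#' @export
#' @examples
#' a <- array(0, c(4, 4, 3)); a[1, 1, 2] <- 8
#' compute_mobility(a)$values   # 0.5, 0.5
compute_mobility <- function(series) {
  arr <- if (inherits(series, "patch_series")) series$frames else series
  fi <- if (inherits(series, "patch_series")) series$frame_interval else 5
  if (length(dim(arr)) != 3)
    stop("`series` must be a 3-D array (height x width x frames)", call. = FALSE)
  nt <- dim(arr)[3]
  if (nt < 2) stop("mobility needs at least 2 frames", call. = FALSE)
  storage.mode(arr) <- "double"
  d <- abs(arr[, , -1, drop = FALSE] - arr[, , -nt, drop = FALSE])
  mobility_trace(apply(d, 3, mean), frame_interval = fi)
}

#' Median-filter a mobility trace
#'
#' Sliding-window median with edge replication; output length equals input
#' length. The filtered copy is stored in the `filtered` field.
#'
#' @param trace A [mobility_trace()].
#' @param window Odd window length in frame pairs (default 5).
#' @return The trace with `filtered` populated.
#' @export
median_filter_trace <- function(trace, window = 5L) {
  stopifnot(inherits(trace, "mobility_trace"))
  if (window %% 2 == 0 || window < 1)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  v <- trace$values
  if (window > length(v))
    stop("`window` exceeds trace length", call. = FALSE)
  h <- (window - 1L) %/% 2L
  padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
  filt <- vapply(seq_along(v),
                 function(i) median(padded[i:(i + 2L * h)]),
                 numeric(1))
  trace$filtered <- filt
  trace
}

#' Population variance of a mobility trace
#'
#' Variance (dividing by n) of the filtered values when present, else the
#' raw values. A constant trace — e.g. a static dead embryo or an empty
#' incubator imaged without noise — has variance exactly 0.
#'
#' @param trace A [mobility_trace()].
#' @return Nonnegative scalar.
#' @export
trace_variance <- function(trace) {
  stopifnot(inherits(trace, "mobility_trace"))
  pop_var(trace$filtered %||% trace$values)
}

#' Detect the twitching onset from a mobility trace
#'
#' Builds the reduced mobility trace — the filtered trace cropped at the
#' hatch transition when a hatch frame is known, else the full (noncropped)
#' trace, as used for late-hatching embryos — and returns the first upward
#' crossing of its arithmetic mean: the smallest index `i >= 1` with
#' `values[i] >= mean` and `values[i - 1] < mean`. Indices are 0-based
#' positions in the trace (pair `i` spans frames `i` and `i + 1`).
#'
#' @param trace A median-filtered [mobility_trace()].
#' @param hatch_frame Optional 0-based hatch frame; the reduced trace keeps
#'   pairs `0 .. hatch_frame - 1`.
#' @return 0-based crossing index, or `NA_integer_` when no crossing exists
#'   (e.g. a constant trace).
#' @export
#' @examples
#' tr <- mobility_trace(c(0, 0, 0, 10, 10, 10))
#' detect_twitch(median_filter_trace(tr, 1))   # 3
detect_twitch <- function(trace, hatch_frame = NULL) {
  stopifnot(inherits(trace, "mobility_trace"))
  v <- trace$filtered %||% trace$values
  if (!is.null(hatch_frame) && !is.na(hatch_frame)) {
    if (hatch_frame < 1) stop("reduced trace is empty", call. = FALSE)
    v <- v[seq_len(min(hatch_frame, length(v)))]
  }
  if (length(v) == 0) stop("reduced trace is empty", call. = FALSE)
  m <- mean(v)
  hit <- which(v >= m & c(TRUE, v[-length(v)] < m))
  hit <- hit[hit > 1]          # crossing needs a predecessor below the mean
  if (length(hit) == 0) return(NA_integer_)
  as.integer(hit[1] - 1L)      # 0-based
}
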