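# Per-embryo decision protocol.
#
# Combines classifier calls and the mobility trace into one record per
# incubator, in this order: (1) embryo presence at the series start, else
# Empty; (2) variance of the median-filtered mobility trace against the
# dead threshold, else Dead; (3) hatch detection — no hatch within the
# recording means the Late Hatching path; (4) twitch onset from the
# reduced (hatch-cropped) trace, or the noncropped trace for late
# hatchers; (5) bean detection before the twitch frame — unresolved means
# Unclear, otherwise Normal. Interval phenotypes are frame differences
# times the frame interval, exactly.

.EMBRYO_STATES <- c("Normal", "Dead", "Unclear", "LateHatching", "Empty")

.empty_record <- function(incubator = NA_integer_) {
  tibble::tibble(incubator = as.integer(incubator),
                 state = NA_character_,
                 bean_frame = NA_integer_, twitch_frame = NA_integer_,
                 hatch_frame = NA_integer_,
                 bean_to_twitch_min = NA_real_, twitch_to_hatch_min = NA_real_,
                 trace_variance = NA_real_, error = NA_character_)
}

#' Phenotype a single embryo incubator
#'
#' Executes the full decision protocol on one per-incubator patch series
#' and returns a one-row record carrying the state label, the transition
#' frames (0-based), the derived stage intervals in minutes and the
#' trace-variance evidence.
#'
#' @param series A [patch_series()] (brightfield).
#' @param model A [train_classifier()] model.
#' @param config A [pipeline_config()]; `dead_variance_threshold` must be
#'   numeric here (either set explicitly or resolved by [phenotype_chip()]'s
#'   self-calibration).
#' @param incubator Incubator index recorded in the output.
#' @return One-row tibble (an embryo record).
#' @export
phenotype_embryo <- function(series, model, config = pipeline_config(),
                             incubator = 0L) {
  stopifnot(inherits(series, "patch_series"),
            inherits(model, "stage_classifier"))
  if (dim(series$frames)[3] < 2)
    stop("series must have at least 2 frames", call. = FALSE)
  if (nrow(series$frames) != ncol(series$frames))
    stop("model/patch geometry mismatch", call. = FALSE)

  rec <- .empty_record(incubator)
  fi <- series$frame_interval
  cls <- classify_series(model, series)
  labels <- cls$label

  mob <- compute_mobility(series)
  w <- min(config$median_filter_window, length(mob$values))
  if (w %% 2 == 0) w <- w - 1L
  trace <- median_filter_trace(mob, w)
  rec$trace_variance <- trace_variance(trace)

  # (1) embryo presence at the series start (majority over the first
  # persistence_frames frames, debouncing single misclassifications)
  k <- min(config$persistence_frames, length(labels))
  if (mean(labels[seq_len(k)] == "Empty") > 0.5) {
    rec$state <- "Empty"
    return(rec)
  }

  # (2) dead call from mobility-trace variance
  thr <- config$dead_variance_threshold
  if (is.null(thr))
    stop("dead_variance_threshold unresolved; set it in the config or use ",
         "phenotype_chip() for self-calibration", call. = FALSE)
  if (rec$trace_variance < thr) {
    rec$state <- "Dead"
    return(rec)
  }

  # (3) hatch detection
  hatch <- .hatch_from_labels(labels, config$persistence_frames)
  rec$hatch_frame <- hatch

  # (4) twitch onset on the reduced (or noncropped, for late hatchers) trace
  twitch_idx <- detect_twitch(trace, hatch_frame = hatch)
  twitch <- if (is.na(twitch_idx)) NA_integer_ else twitch_idx + 1L
  rec$twitch_frame <- twitch

  # (5) bean transition before the twitch frame
  bean <- .bean_from_labels(labels, config$persistence_frames,
                            end_frame = twitch)
  rec$bean_frame <- bean

  rec$state <- if (is.na(hatch)) "LateHatching"
               else if (is.na(bean) || is.na(twitch)) "Unclear"
               else "Normal"
  if (rec$state == "Unclear") rec$bean_frame <- NA_integer_
  if (!is.na(rec$bean_frame) && !is.na(twitch))
    rec$bean_to_twitch_min <- (twitch - rec$bean_frame) * fi
  if (!is.na(twitch) && !is.na(hatch))
    rec$twitch_to_hatch_min <- (hatch - twitch) * fi
  rec
}

# 3 x the 95th percentile of Empty-incubator trace variance, floored at a
# tiny positive value so an exactly-static embryo is always below it
.calibrate_dead_threshold <- function(empty_variances) {
  if (length(empty_variances) == 0) return(NULL)
  max(3 * quantile(empty_variances, 0.95, names = FALSE), 1e-12)
}

#' Phenotype every incubator of a chip position
#'
#' Crops one patch series per detected location and runs
#' [phenotype_embryo()] on each, independently (results do not depend on
#' the order of locations). When `config$dead_variance_threshold` is
#' `NULL`, the threshold is self-calibrated from the incubators the
#' classifier calls Empty at the series start: 3 times the 95th percentile
#' of their trace variances. Per-incubator failures are captured in the
#' `error` column instead of aborting the batch.
#'
#' @param sequence A [time_lapse_sequence()].
#' @param locations Tibble of incubator locations (`index`, `x`, `y`),
#'   from [detect_incubators()].
#' @param model A [train_classifier()] model.
#' @param config A [pipeline_config()].
#' @return Tibble of embryo records, one row per location, ordered by
#'   location index.
#' @export
phenotype_chip <- function(sequence, locations, model,
                           config = pipeline_config()) {
  stopifnot(inherits(sequence, "time_lapse_sequence"))
  if (nrow(locations) == 0) return(.empty_record()[0, ])
  series_list <- lapply(seq_len(nrow(locations)), function(i)
    crop_patch_series(sequence, locations[i, ], config))

  cfg <- config
  if (is.null(cfg$dead_variance_threshold)) {
    k <- cfg$persistence_frames
    vars_empty <- numeric()
    for (s in series_list) {
      labels <- classify_series(model, s)$label
      kk <- min(k, length(labels))
      if (mean(labels[seq_len(kk)] == "Empty") > 0.5) {
        tr <- median_filter_trace(compute_mobility(s),
                                  cfg$median_filter_window)
        vars_empty <- c(vars_empty, trace_variance(tr))
      }
    }
    cfg$dead_variance_threshold <-
      .calibrate_dead_threshold(vars_empty) %||% 1e-12
  }

  recs <- lapply(seq_along(series_list), function(i) {
    tryCatch(
      phenotype_embryo(series_list[[i]], model, cfg,
                       incubator = locations$index[i]),
      error = function(e) {
        r <- .empty_record(locations$index[i])
        r$error <- conditionMessage(e)
        r
      })
  })
  dplyr::arrange(dplyr::bind_rows(recs), .data$incubator)
}

#' Compare automated and manual embryo records
#'
#' For each transition (bean, twitch, hatch) reports the fraction of
#' embryos whose automated and manual frames agree exactly (zero
#' tolerance) and within `tolerance_frames` (|auto - manual| <= tolerance),
#' plus a state-label confusion matrix. Records are aligned by incubator
#' index; only embryos where both calls carry the transition enter that
#' transition's denominator.
#'
#' @param auto,manual Record tibbles with matching `incubator` indices.
#' @param tolerance_frames Frame tolerance (default 5).
#' @return A list of class `phenotype_agreement`: `transitions` (tibble:
#'   transition, n, agreement_zero_tol, agreement_tol), `confusion`
#'   (contingency table auto x manual) and `tolerance_frames`.
#' @export
compare_to_manual <- function(auto, manual, tolerance_frames = 5L) {
  if (nrow(auto) == 0 || nrow(manual) == 0)
    stop("record lists must be nonempty", call. = FALSE)
  if (nrow(auto) != nrow(manual) ||
      !all(sort(auto$incubator) == sort(manual$incubator)))
    stop("records must be aligned by incubator index", call. = FALSE)
  a <- dplyr::arrange(auto, .data$incubator)
  m <- dplyr::arrange(manual, .data$incubator)
  one <- function(col) {
    da <- a[[col]]; dm <- m[[col]]
    both <- !is.na(da) & !is.na(dm)
    n <- sum(both)
    tibble::tibble(
      transition = sub("_frame", "", col),
      n = n,
      agreement_zero_tol = if (n) mean(da[both] == dm[both]) else NA_real_,
      agreement_tol = if (n)
        mean(abs(da[both] - dm[both]) <= tolerance_frames) else NA_real_)
  }
  structure(list(
    transitions = dplyr::bind_rows(lapply(
      c("bean_frame", "twitch_frame", "hatch_frame"), one)),
    confusion = table(auto = factor(a$state, .EMBRYO_STATES),
                      manual = factor(m$state, .EMBRYO_STATES)),
    tolerance_frames = as.integer(tolerance_frames)),
    class = "phenotype_agreement")
}

#' @export
print.phenotype_agreement <- function(x, ...) {
  cat(sprintf("<phenotype_agreement> tolerance %d frames\n",
              x$tolerance_frames))
  print(x$transitions)
  cat("state confusion (auto rows x manual cols):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.phenotype_agreement <- function(x, ...) x$transitions

#' Validate embryo-record state invariants
#'
#' Checks, for every row, the structural constraints each state imposes on
#' the transition fields (Empty: none present; Dead: no twitch/hatch;
#' Normal: bean < twitch < hatch all present; LateHatching: twitch present,
#' hatch absent; Unclear: bean absent) and that intervals equal frame
#' differences times the frame interval.
#'
#' @param records Record tibble.
#' @param frame_interval Minutes per frame.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_records <- function(records, frame_interval) {
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!is.null(r$error) && !is.na(r$error)) next
    bad <- switch(r$state,
      Empty = !all(is.na(c(r$bean_frame, r$twitch_frame, r$hatch_frame))),
      Dead = !all(is.na(c(r$twitch_frame, r$hatch_frame))),
      Normal = anyNA(c(r$bean_frame, r$twitch_frame, r$hatch_frame)) ||
        !(r$bean_frame < r$twitch_frame && r$twitch_frame < r$hatch_frame),
      LateHatching = is.na(r$twitch_frame) || !is.na(r$hatch_frame),
      Unclear = !is.na(r$bean_frame),
      TRUE)
    if (isTRUE(bad))
      stop("record ", r$incubator, " violates ", r$state, " invariants",
           call. = FALSE)
    if (!is.na(r$bean_to_twitch_min) &&
        r$bean_to_twitch_min != (r$twitch_frame - r$bean_frame) * frame_interval)
      stop("record ", r$incubator, ": bean_to_twitch interval mismatch",
           call. = FALSE)
    if (!is.na(r$twitch_to_hatch_min) &&
        r$twitch_to_hatch_min != (r$hatch_frame - r$twitch_frame) * frame_interval)
      stop("record ", r$incubator, ": twitch_to_hatch interval mismatch",
           call. = FALSE)
  }
  invisible(TRUE)
}
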