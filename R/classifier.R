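# Three-class developmental stage classifier.
#
# Patches are classified as Empty (no embryo in the incubator), PreBean or
# Bean. The classifier is a compact single-hidden-layer softmax network
# over per-patch min-max-normalized images downscaled to a small square;
# class imbalance is handled by inverse-frequency case weighting. "Embryo
# present" means a PreBean or Bean call. Per-frame label sequences drive
# the bean (PreBean -> Bean switch) and hatch (embryo no longer present)
# transition detectors, debounced by a persistence requirement.

.STAGE_CLASSES <- c("Empty", "PreBean", "Bean")

# min-max normalize and downscale one patch to a feature vector
.patch_features <- function(patch, input_dim) {
  rng <- range(patch)
  p <- if (diff(rng) > 0) (patch - rng[1]) / diff(rng) else patch * 0
  as.numeric(EBImage::resize(p, w = input_dim, h = input_dim))
}

.features_matrix <- function(patches, input_dim) {
  t(vapply(patches, .patch_features, numeric(input_dim^2),
           input_dim = input_dim))
}

#' Train the stage classifier
#'
#' Fits the patch classifier on a labeled training set (three classes:
#' Empty, PreBean, Bean; imbalanced counts allowed). A stratified 20% split
#' is held out and the held-out accuracy is stored on the model. Training
#' is fully reproducible for a fixed seed: the same split, the same
#' initialization and therefore identical parameters.
#'
#' @param dataset Tibble with columns `label` (factor/character over the
#'   three classes) and `patch` (list of square matrices), as produced by
#'   [make_training_set()]. At least 2 classes and 10 patches per present
#'   class are required.
#' @param epochs Maximum optimizer iterations.
#' @param seed Integer seed.
#' @param input_dim Downscaled patch side used as network input.
#' @param hidden Hidden units.
#' @return An object of class `stage_classifier`.
#' @export
train_classifier <- function(dataset, epochs = 150L, seed = 1L,
                             input_dim = 20L, hidden = 12L) {
  if (nrow(dataset) == 0) stop("empty training set", call. = FALSE)
  lab <- factor(as.character(dataset$label), levels = .STAGE_CLASSES)
  if (anyNA(lab)) stop("labels must be Empty/PreBean/Bean", call. = FALSE)
  present <- levels(droplevels(lab))
  if (length(present) < 2)
    stop("training needs at least 2 classes", call. = FALSE)
  if (any(table(lab)[present] < 10))
    stop("training needs >= 10 patches per present class", call. = FALSE)

  .with_seed(seed, {
    # stratified 80/20 split
    holdout <- unlist(lapply(split(seq_along(lab), lab), function(ix) {
      if (length(ix) == 0) return(integer())
      sample(ix, max(1L, round(0.2 * length(ix))))
    }))
    tr <- setdiff(seq_along(lab), holdout)

    x <- .features_matrix(dataset$patch, input_dim)
    y <- nnet::class.ind(lab)
    wts <- (1 / table(lab)[as.character(lab)])
    wts <- as.numeric(wts / mean(wts[tr]))

    net <- nnet::nnet(x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                      size = hidden, softmax = TRUE, weights = wts[tr],
                      maxit = epochs, decay = 1e-3,
                      MaxNWts = 100000L, trace = FALSE)

    pred <- .STAGE_CLASSES[max.col(predict(net, x[holdout, , drop = FALSE]))]
    acc <- mean(pred == as.character(lab[holdout]))

    structure(list(net = net,
                   classes = .STAGE_CLASSES,
                   input_dim = as.integer(input_dim),
                   hidden = as.integer(hidden),
                   preprocess = "minmax",
                   seed = as.integer(seed),
                   holdout_accuracy = acc,
                   n_train = length(tr),
                   n_holdout = length(holdout)),
              class = "stage_classifier")
  })
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf(
    "<stage_classifier> %dx%d input, %d hidden units, classes %s\n  held-out accuracy %.3f (n = %d)\n",
    x$input_dim, x$input_dim, x$hidden, paste(x$classes, collapse = "/"),
    x$holdout_accuracy, x$n_holdout))
  invisible(x)
}

#' @export
glance.stage_classifier <- function(x, ...) {
  tibble::tibble(holdout_accuracy = x$holdout_accuracy,
                 n_train = x$n_train, n_holdout = x$n_holdout,
                 input_dim = x$input_dim, hidden = x$hidden, seed = x$seed)
}

#' Classify one patch
#'
#' @param model A [train_classifier()] model.
#' @param patch Square single-channel matrix.
#' @return Named probability vector over Empty/PreBean/Bean (nonnegative,
#'   summing to 1); the argmax is the predicted label and "embryo present"
#'   means PreBean or Bean.
#' @export
classify_patch <- function(model, patch) {
  stopifnot(inherits(model, "stage_classifier"))
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stop("`patch` must be a square matrix", call. = FALSE)
  p <- predict(model$net, rbind(.patch_features(patch, model$input_dim)))
  stats::setNames(as.numeric(p), model$classes)
}

#' Classify every frame of a patch series
#'
#' @param model A [train_classifier()] model.
#' @param series A [patch_series()].
#' @return Tibble with `frame` (0-based), per-class probabilities and the
#'   argmax `label`.
#' @export
classify_series <- function(model, series) {
  stopifnot(inherits(model, "stage_classifier"),
            inherits(series, "patch_series"))
  arr <- series$frames
  if (nrow(arr) != ncol(arr))
    stop("model/patch geometry mismatch: patches must be square", call. = FALSE)
  nt <- dim(arr)[3]
  feats <- t(vapply(seq_len(nt),
                    function(t) .patch_features(arr[, , t], model$input_dim),
                    numeric(model$input_dim^2)))
  pr <- predict(model$net, feats)
  out <- tibble::as_tibble(stats::setNames(as.data.frame(pr),
                                           paste0("p_", tolower(model$classes))))
  out$frame <- seq_len(nt) - 1L
  out$label <- model$classes[max.col(pr)]
  out[, c("frame", paste0("p_", tolower(model$classes)), "label")]
}

# first 0-based start of a run of >= persistence consecutive TRUEs
.first_persistent <- function(flag, persistence) {
  n <- length(flag)
  if (persistence > n) return(NA_integer_)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (flag[i]) run + 1L else 0L
    if (run >= persistence) return(as.integer(i - persistence))  # 0-based start
  }
  NA_integer_
}

.hatch_from_labels <- function(labels, persistence) {
  .first_persistent(labels == "Empty", persistence)
}

.bean_from_labels <- function(labels, persistence, end_frame = NULL) {
  if (!is.null(end_frame) && !is.na(end_frame))
    labels <- labels[seq_len(min(end_frame, length(labels)))]
  bean_start <- .first_persistent(labels == "Bean", persistence)
  if (is.na(bean_start)) return(NA_integer_)
  if (bean_start == 0L) return(NA_integer_)    # already bean at frame 0
  pre <- labels[seq_len(bean_start)]
  pre_run <- .first_persistent(pre == "PreBean", min(persistence, length(pre)))
  if (is.na(pre_run)) return(NA_integer_)      # no clear pre-bean phase
  bean_start
}

#' Detect the hatching frame
#'
#' The hatch transition is the first frame from which the embryo is no
#' longer present according to the classifier: the earliest frame `h` such
#' that frames `h .. h + persistence - 1` all classify Empty. When no such
#' run occurs before the end of the sequence the embryo has not hatched
#' within the recording (the Late Hatching precondition) and `NA` is
#' returned.
#'
#' @param model A [train_classifier()] model.
#' @param series A [patch_series()] whose first frames contain an embryo.
#' @param persistence Consecutive Empty frames required (>= 1).
#' @return 0-based frame index or `NA_integer_`.
#' @export
detect_hatch_frame <- function(model, series, persistence = 3L) {
  if (persistence < 1) stop("persistence must be >= 1", call. = FALSE)
  .hatch_from_labels(classify_series(model, series)$label, persistence)
}

#' Detect the pre-bean to bean transition frame
#'
#' Returns the first frame where the classification switches from PreBean
#' to Bean and persists for at least `persistence` frames, searching only
#' frames before `end_frame` (the twitching frame) when given. Returns
#' `NA` ("unclear") when no persistent PreBean phase precedes the first
#' Bean run — the embryo was already past the bean stage at the start of
#' the recording, or never clearly reached it.
#'
#' @inheritParams detect_hatch_frame
#' @param end_frame Optional 0-based exclusive search bound.
#' @return 0-based frame index or `NA_integer_` (unclear).
#' @export
detect_bean_frame <- function(model, series, persistence = 3L,
                              end_frame = NULL) {
  if (persistence < 1) stop("persistence must be >= 1", call. = FALSE)
  .bean_from_labels(classify_series(model, series)$label, persistence,
                    end_frame)
}

#' Save / load a stage classifier checkpoint
#'
#' The checkpoint is a single plain-text file: a JSON header (architecture,
#' class ordering, preprocessing, seed) followed by the flattened network
#' weights, so the label ordering round-trips with the parameters.
#'
#' @param model A [train_classifier()] model.
#' @param path Checkpoint file path.
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   returns the restored `stage_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "stage_classifier"))
  header <- list(classes = model$classes, input_dim = model$input_dim,
                 hidden = model$hidden, preprocess = model$preprocess,
                 seed = model$seed, holdout_accuracy = model$holdout_accuracy,
                 n_train = model$n_train, n_holdout = model$n_holdout,
                 n = model$net$n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  writeLines(sprintf("%.17g", model$net$wts), con)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path, call. = FALSE)
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  wts <- as.numeric(lines[-1])
  # rebuild an nnet skeleton with the stored weights
  n <- header$n
  skel <- .with_seed(0L,
    nnet::nnet(matrix(stats::rnorm(6 * n[1]), 6, n[1]),
               nnet::class.ind(factor(rep(header$classes, 2))),
               size = n[2], softmax = TRUE, maxit = 1, trace = FALSE,
               MaxNWts = 100000L))
  stopifnot(length(skel$wts) == length(wts))
  skel$wts <- wts
  structure(list(net = skel, classes = header$classes,
                 input_dim = header$input_dim, hidden = header$hidden,
                 preprocess = header$preprocess, seed = header$seed,
                 holdout_accuracy = header$holdout_accuracy,
                 n_train = header$n_train, n_holdout = header$n_holdout),
            class = "stage_classifier")
}
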