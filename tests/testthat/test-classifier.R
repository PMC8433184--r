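# Stage classifier training, application and transition detection.

# assemble a patch series from class-conditional rendered patches
label_series <- function(labels, seed = 31) {
  cfg <- sim_chip_config(noise_sigma = 0, seed = seed)
  pool <- make_training_set(cfg, 3, seed = seed)
  pick <- function(lab) {
    ix <- which(pool$label == lab)
    pool$patch[[ix[1]]]
  }
  arr <- array(0, c(200, 200, length(labels)))
  for (t in seq_along(labels)) arr[, , t] <- pick(labels[t])
  patch_series(arr, frame_interval = 5)
}

test_that("training is reproducible and reports held-out accuracy", {
  m1 <- fixture_model(0)
  cfg <- sim_chip_config(noise_sigma = 0, seed = 101)
  ts <- make_training_set(cfg, 120, seed = 102)
  m2 <- train_classifier(ts, epochs = 120, seed = 103)
  expect_identical(m1$net$wts, m2$net$wts)          # identical parameters
  expect_gte(m1$holdout_accuracy, 0.99)
  expect_equal(glance(m1)$n_holdout, m1$n_holdout)
})

test_that("degenerate training sets are rejected", {
  cfg <- sim_chip_config(noise_sigma = 0, seed = 1)
  ts <- make_training_set(cfg, 12, seed = 2)
  expect_error(train_classifier(ts[ts$label == "Empty", ]), "2 classes")
  expect_error(train_classifier(ts[0, ]), "empty")
  expect_error(train_classifier(ts[c(1:12, 13:17), ]), ">= 10 patches")
})

test_that("classification returns a proper probability vector, deterministically", {
  model <- fixture_model(0)
  ts <- make_training_set(sim_chip_config(noise_sigma = 0, seed = 55), 2,
                          seed = 56)
  for (i in seq_len(nrow(ts))) {
    pr <- classify_patch(model, ts$patch[[i]])
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-6)
    expect_equal(names(which.max(pr)), as.character(ts$label[i]))
  }
  p <- ts$patch[[1]]
  expect_identical(classify_patch(model, p), classify_patch(model, p))
  expect_error(classify_patch(model, matrix(0, 10, 20)), "square")
})

test_that("hatch detection requires a persistent empty run", {
  model <- fixture_model(0)
  labs <- c(rep("Bean", 60), rep("Empty", 20))
  expect_equal(detect_hatch_frame(model, label_series(labs), 3), 60L)

  # a single spurious Empty classification does not trigger hatching
  labs2 <- rep("Bean", 50); labs2[31] <- "Empty"
  expect_true(is.na(detect_hatch_frame(model, label_series(labs2), 3)))

  labs3 <- rep("Bean", 20)                # embryo present throughout
  expect_true(is.na(detect_hatch_frame(model, label_series(labs3), 3)))
  expect_error(detect_hatch_frame(model, label_series(labs3), 0), ">= 1")
})

test_that("bean detection needs a persistent pre-bean phase before bean", {
  model <- fixture_model(0)
  labs <- c(rep("PreBean", 20), rep("Bean", 30))
  expect_equal(detect_bean_frame(model, label_series(labs), 3), 20L)
  # search window bounded by the twitch frame
  expect_true(is.na(detect_bean_frame(model, label_series(labs), 3,
                                      end_frame = 18)))

  expect_true(is.na(detect_bean_frame(model, label_series(rep("Bean", 30)), 3)))
  expect_true(is.na(detect_bean_frame(model, label_series(rep("PreBean", 30)), 3)))
})

test_that("planted transitions are recovered within one frame on clean patches", {
  model <- fixture_model(0)
  cfg <- sim_chip_config(n_incubators = 1, frame_count = 80, noise_sigma = 0,
                         seed = 71)
  sim <- simulate_chip(cfg, list(sim_embryo_spec("Normal", 20, 40, 70)))
  ps <- crop_patch_series(sim$sequence, sim$locations[1, ], pipeline_config())
  expect_lte(abs(detect_bean_frame(model, ps, 3, end_frame = 40) - 20), 1)
  expect_lte(abs(detect_hatch_frame(model, ps, 3) - 70), 1)
})

test_that("checkpoints round-trip the label ordering and predictions", {
  model <- fixture_model(0)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_classifier(model, path)
  back <- load_classifier(path)
  expect_identical(back$classes, model$classes)
  ts <- make_training_set(sim_chip_config(noise_sigma = 0, seed = 77), 2,
                          seed = 78)
  for (p in ts$patch)
    expect_equal(classify_patch(back, p), classify_patch(model, p))
})
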