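# Ground-truthed synthetic chip generator.

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- sim_chip_config(n_incubators = 2, frame_count = 8, seed = 5)
  specs <- list(sim_embryo_spec("Normal", 2, 4, 7), sim_embryo_spec("Empty"))
  a <- simulate_chip(cfg, specs)
  b <- simulate_chip(cfg, specs)
  expect_identical(a$sequence$channels, b$sequence$channels)
  expect_identical(a$truth, b$truth)

  ts1 <- make_training_set(cfg, 5, seed = 9)
  ts2 <- make_training_set(cfg, 5, seed = 9)
  expect_identical(ts1, ts2)
})

test_that("spec invariants are enforced at construction", {
  expect_error(sim_embryo_spec("Normal", 10, 5, 20), "inconsistent")
  expect_error(sim_embryo_spec("LateHatching", twitch_frame = 5,
                               hatch_frame = 10), "inconsistent")
  expect_error(sim_embryo_spec("Dead", bean_frame = 3), "inconsistent")
  expect_error(sim_embryo_spec("Normal", 2, 4, 7, fluo_ratio = 0.5), ">= 1")
  cfg <- sim_chip_config(n_incubators = 1, frame_count = 5)
  expect_error(simulate_chip(cfg, list()), "one embryo spec per incubator")
  expect_error(simulate_chip(cfg, list(sim_embryo_spec("Normal", 2, 4, 7))),
               "before frame_count")
})

test_that("noise-free Empty and Dead incubators are constant in time", {
  sim <- fixture_chip(noise_sigma = 0)
  pc <- pipeline_config()
  for (i in c(2, 3)) {   # Dead, Empty (1-based positions in the fixture)
    ps <- crop_patch_series(sim$sequence, sim$locations[i, ], pc)
    first <- ps$frames[, , 1]
    expect_true(all(apply(ps$frames, 3, identical, first)))
  }
})

test_that("an Empty incubator equals the embryo-free template exactly", {
  cfg <- sim_chip_config(n_incubators = 2, frame_count = 3, noise_sigma = 0,
                         seed = 13)
  sim <- simulate_chip(cfg, list(sim_embryo_spec("Empty"),
                                 sim_embryo_spec("Dead")))
  # the empty incubator's patch must match a pure-template rendering
  tmpl <- simulate_chip(cfg, list(sim_embryo_spec("Empty"),
                                  sim_embryo_spec("Empty")))
  pc <- pipeline_config()
  p1 <- crop_patch_series(sim$sequence, sim$locations[1, ], pc)
  p2 <- crop_patch_series(tmpl$sequence, tmpl$locations[1, ], pc)
  expect_identical(p1$frames, p2$frames)
})

test_that("twitching raises mobility relative to the pre-twitch phase", {
  cfg <- sim_chip_config(n_incubators = 1, frame_count = 80, noise_sigma = 0,
                         seed = 17)
  sim <- simulate_chip(cfg, list(sim_embryo_spec("Normal", 10, 40, 75)))
  ps <- crop_patch_series(sim$sequence, sim$locations[1, ], pipeline_config())
  mob <- compute_mobility(ps)$values
  expect_gt(mean(mob[41:74]), mean(mob[1:40]))
  # static except at the bean transition pair (frames 9 -> 10)
  expect_equal(mean(mob[c(1:9, 11:39)]), 0)
})

test_that("training sets have the requested size, labels and separability", {
  cfg <- sim_chip_config(noise_sigma = 0, seed = 19)
  ts <- make_training_set(cfg, 10, seed = 23)
  expect_equal(nrow(ts), 30)
  expect_equal(as.integer(table(ts$label)), c(10, 10, 10))
  expect_true(all(vapply(ts$patch, function(p) all(dim(p) == c(200, 200)),
                         TRUE)))
  # imbalanced counts mirror the three-class training design
  ts2 <- make_training_set(cfg, c(4, 10, 6), seed = 23)
  expect_equal(as.integer(table(ts2$label)), c(4, 10, 6))

  # a plain pixel-sum statistic separates Empty from embryo-present patches
  sums <- vapply(ts$patch, sum, numeric(1))
  empty <- ts$label == "Empty"
  expect_lt(max(sums[!empty]), min(sums[empty]))
})

test_that("random cohort specs honour the mix and frame bounds", {
  specs <- random_embryo_specs(64, seed = 3)
  states <- vapply(specs, function(s) s$state, "")
  expect_equal(sum(states == "Normal"), 32)
  expect_equal(sum(states == "Dead"), 8)
  expect_equal(sum(states == "Empty"), 8)
  for (s in specs) {
    fr <- c(s$bean_frame, s$twitch_frame, s$hatch_frame)
    expect_true(all(fr < 144, na.rm = TRUE))
  }
  expect_identical(vapply(random_embryo_specs(64, seed = 3),
                          function(s) s$state, ""), states)
})
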