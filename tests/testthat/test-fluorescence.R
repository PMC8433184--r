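# Masked, background-normalized fluorescence quantification.

# small handcrafted mask: 1 in a central block, away from the top window
toy_mask <- function(n = 200) {
  m <- matrix(0, n, n)
  m[80:120, 80:120] <- 1
  m
}

test_that("I_SBR identities hold exactly", {
  pc <- pipeline_config()
  m <- toy_mask()

  # uniform patch: ratio of equal intensities is 1
  u <- matrix(0.37, 200, 200)
  expect_equal(quantify_frame(u, m, pc)$i_sbr, 1)

  # masked pixels 300, background window 100 -> I_SBR = 3
  p <- matrix(100, 200, 200)
  p[80:120, 80:120] <- 300
  q <- quantify_frame(p, m, pc)
  expect_equal(q$i_roi, 300)
  expect_equal(q$i_bg, 100)
  expect_equal(q$i_sbr, 3)

  # global scaling by k > 0 cancels in the ratio
  for (k in c(0.25, 7, 1000))
    expect_equal(quantify_frame(p * k, m, pc)$i_sbr, 3)
})

test_that("quantification errors and flags are raised as specified", {
  pc <- pipeline_config()
  m <- toy_mask()
  z <- matrix(0, 200, 200)
  expect_error(quantify_frame(z, m, pc), "background window mean is 0")

  p <- matrix(1, 200, 200)
  p[80:120, 80:120] <- 0                      # masked region all zero
  expect_equal(quantify_frame(p, m, pc)$flag, "empty_roi")

  bad <- matrix(0, 200, 200); bad[1:30, 1:30] <- 1   # mask touches window
  expect_error(quantify_frame(p, bad, pc), "intersects")

  expect_error(build_mask(matrix(0.5, 200, 200)), "uniform")
})

test_that("the mask recovers the trap interior and dilation only grows it", {
  cfg <- sim_chip_config(n_incubators = 1, frame_count = 2, noise_sigma = 0,
                         seed = 61)
  sim <- simulate_chip(cfg, list(sim_embryo_spec("Empty")))
  pc <- pipeline_config()
  patch <- crop_patch_series(sim$sequence, sim$locations[1, ], pc)$frames[, , 1]
  gt <- sim_interior_mask(cfg)

  m0 <- build_mask(patch, dilation_radius = 0)
  jac <- sum(m0 * gt) / sum((m0 + gt) > 0)
  expect_gte(jac, 0.95)
  # wall pixels (intensity well below fluid) are excluded
  expect_equal(sum(m0[patch < 0.3]), 0)

  m2 <- build_mask(patch, dilation_radius = 2)
  expect_true(all(m2[m0 == 1] == 1))
  expect_gt(sum(m2), sum(m0))
})

test_that("planted fluorescence ratios are recovered", {
  pc <- pipeline_config()
  for (noise in c(0, 0.01)) {
    cfg <- sim_chip_config(n_incubators = 5, frame_count = 3,
                           channels = c("brightfield", "gfp"),
                           noise_sigma = noise, seed = 63)
    ratios <- c(1, 1.2, 2, 5)
    specs <- c(list(sim_embryo_spec("Empty")),
               lapply(ratios, function(r) sim_embryo_spec("Dead", fluo_ratio = r)))
    sim <- simulate_chip(cfg, specs)
    empty_bf <- crop_patch_series(sim$sequence, sim$locations[1, ], pc)$frames[, , 1]
    mask <- build_mask(empty_bf)
    tol <- if (noise == 0) 0.02 else 0.05
    for (i in seq_along(ratios)) {
      fl <- crop_patch_series(sim$sequence, sim$locations[i + 1, ], pc,
                              channel = "gfp")
      got <- mean(quantify_series(fl, mask, pc)$i_sbr)
      expect_lt(abs(got / ratios[i] - 1), tol)
    }
  }
})

test_that("series quantification respects end_frame and per-frame normalization", {
  pc <- pipeline_config()
  m <- toy_mask()
  base <- matrix(100, 200, 200); base[80:120, 80:120] <- 300
  arr <- array(rep(base, 40), c(200, 200, 40))
  arr[, , 7] <- base * 2          # lamp flicker: background and embryo double
  ps <- patch_series(arr, frame_interval = 10, channel = "gfp")

  q <- quantify_series(ps, m, pc, end_frame = 30)
  expect_equal(nrow(q), 30)       # exactly 30 measurements
  expect_equal(unique(q$i_sbr), 3)   # ratio invariant to the flicker
  expect_equal(q$minutes, q$frame * 10)

  qa <- quantify_series(ps, m, pc)
  expect_equal(nrow(qa), 40)
})

test_that("population profiles average across present embryos with dropout", {
  mk <- function(v) tibble::tibble(frame = seq_along(v) - 1L,
                                   minutes = (seq_along(v) - 1L) * 10,
                                   i_roi = v, i_bg = 1, i_sbr = v,
                                   flag = NA_character_)
  prof <- population_mean_profile(list(mk(c(1, 1)), mk(c(3, 3))))
  expect_equal(prof$mean_sbr, c(2, 2))

  # an embryo hatching at frame 10 contributes to frames < 10 only
  long <- mk(rep(2, 20)); short <- mk(rep(4, 10))
  prof2 <- population_mean_profile(list(long, short), horizon_frames = 20)
  expect_equal(prof2$n, c(rep(2, 10), rep(1, 10)))
  expect_equal(prof2$mean_sbr, c(rep(3, 10), rep(2, 10)))

  one <- population_mean_profile(list(mk(c(5, 5))))
  expect_equal(one$sem_sbr, c(0, 0))   # n = 1 convention, flagged by n column
  expect_equal(one$n, c(1, 1))

  expect_error(population_mean_profile(list()), "no measurements")
})
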