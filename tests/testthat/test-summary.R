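# Cohort aggregation and the normalized clustergram.

mk_records <- function(states, b2t = NA_real_, t2h = NA_real_) {
  n <- length(states)
  tibble::tibble(incubator = seq_len(n) - 1L, state = states,
                 bean_frame = NA_integer_, twitch_frame = NA_integer_,
                 hatch_frame = NA_integer_,
                 bean_to_twitch_min = rep_len(b2t, n),
                 twitch_to_hatch_min = rep_len(t2h, n),
                 trace_variance = 0, error = NA_character_)
}

test_that("cohort fractions follow the state definitions", {
  recs <- mk_records(c(rep("Dead", 4), rep("Normal", 3), rep("Unclear", 2),
                       "LateHatching"))
  s <- summarize_cohort(recs, "x")
  expect_equal(s$dead_fraction, 0.40)
  expect_equal(s$normal_over_alive, 0.50)     # 3 / (3 + 1 + 2)
  expect_equal(s$n_total, 10)

  # Empty incubators hold no embryo: excluded from every denominator
  s2 <- summarize_cohort(dplyr::bind_rows(recs, mk_records(rep("Empty", 5))), "x")
  expect_equal(s2$dead_fraction, 0.40)
  expect_equal(s2$n_total, 10)
  expect_equal(s2$n_empty, 5)

  s3 <- summarize_cohort(mk_records(rep("Empty", 3)), "x")
  expect_true(s3$empty_cohort)
})

test_that("interval statistics cover Normal embryos only, SEM = sd/sqrt(n)", {
  recs <- dplyr::bind_rows(
    mk_records(rep("Normal", 4), b2t = c(90, 100, 110, 100),
               t2h = c(300, 300, 300, 300)),
    mk_records("Unclear", b2t = 999, t2h = 999))
  s <- summarize_cohort(recs, "x")
  expect_equal(s$bean_to_twitch_mean, 100)
  expect_equal(s$bean_to_twitch_sem, sd(c(90, 100, 110, 100)) / 2)
  expect_equal(s$twitch_to_hatch_mean, 300)
  expect_equal(s$twitch_to_hatch_sem, 0)      # identical intervals
})

test_that("summaries match an independent tally on random cohorts", {
  set.seed(7)
  states <- c("Normal", "Dead", "Unclear", "LateHatching", "Empty")
  for (k in 1:25) {
    n <- sample(5:40, 1)
    st <- sample(states, n, replace = TRUE)
    b2t <- ifelse(st == "Normal", sample(50:150, n, replace = TRUE), NA)
    recs <- mk_records(st)
    recs$bean_to_twitch_min <- as.numeric(b2t)
    s <- summarize_cohort(recs, "rnd")

    # literal counting oracle
    emb <- st[st != "Empty"]
    expect_identical(s$n_total, length(emb))
    if (length(emb) > 0)
      expect_equal(s$dead_fraction, sum(emb == "Dead") / length(emb))
    alive <- sum(emb %in% c("Normal", "LateHatching", "Unclear"))
    if (alive > 0)
      expect_equal(s$normal_over_alive, sum(emb == "Normal") / alive)
    iv <- b2t[!is.na(b2t)]
    if (length(iv) > 0) {
      expect_equal(s$bean_to_twitch_mean, sum(iv) / length(iv))
      if (length(iv) > 1)
        expect_equal(s$bean_to_twitch_sem,
                     sqrt(sum((iv - mean(iv))^2) / (length(iv) - 1)) /
                       sqrt(length(iv)))
    }
  }
})

test_that("fractions are invariant to record order", {
  recs <- mk_records(sample(c("Normal", "Dead", "Unclear", "Empty"), 20,
                            replace = TRUE))
  a <- summarize_cohort(recs, "x")
  b <- summarize_cohort(recs[sample(nrow(recs)), ], "x")
  expect_equal(a, b)
})

test_that("clustergram rows are population z-scores with constant rows zeroed", {
  smry <- dplyr::bind_rows(
    summarize_cohort(mk_records(c("Dead", "Normal"),
                                b2t = c(NA, 10), t2h = c(NA, 100)), "a"),
    summarize_cohort(mk_records(c("Normal", "Normal"),
                                b2t = 20, t2h = 100), "b"))
  cg <- build_clustergram(smry)
  # bean_to_twitch means are (10, 20) -> z-scores (-1, +1), population SD
  expect_equal(sort(cg$z["bean_to_twitch_mean", ]), c(a = -1, b = 1))
  # twitch_to_hatch is constant across conditions -> all zeros, sorted last
  expect_equal(unname(cg$z["twitch_to_hatch_mean", ]), c(0, 0))
  expect_equal(tail(cg$row_order, 1), "twitch_to_hatch_mean")
  # every non-constant row: mean 0, unit population variance
  for (r in rownames(cg$z)) {
    z <- cg$z[r, ]
    if (any(z != 0)) {
      expect_lt(abs(mean(z)), 1e-9)
      expect_lt(abs(mean((z - mean(z))^2) - 1), 1e-9)
    }
  }
})

test_that("two identical conditions give an all-zero clustergram", {
  one <- summarize_cohort(mk_records(c("Normal", "Dead"), b2t = c(10, NA),
                                     t2h = c(100, NA)), "a")
  two <- one; two$condition <- "b"
  cg <- build_clustergram(dplyr::bind_rows(one, two))
  expect_true(all(cg$z == 0))
  expect_error(build_clustergram(one), "at least 2")
})

test_that("column ordering is invariant to input permutation", {
  set.seed(11)
  smry <- dplyr::bind_rows(lapply(c("c1", "c2", "c3", "c4"), function(cond) {
    st <- sample(c("Normal", "Dead", "Unclear"), 20, replace = TRUE)
    recs <- mk_records(st)
    recs$bean_to_twitch_min <- ifelse(st == "Normal",
                                      sample(60:140, 20, replace = TRUE), NA)
    recs$twitch_to_hatch_min <- ifelse(st == "Normal",
                                       sample(200:400, 20, replace = TRUE), NA)
    summarize_cohort(recs, cond)
  }))
  a <- build_clustergram(smry)
  b <- build_clustergram(smry[c(3, 1, 4, 2), ])
  expect_identical(a$col_order, b$col_order)
  expect_identical(a$row_order, b$row_order)
  expect_identical(a$z, b$z)
})
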