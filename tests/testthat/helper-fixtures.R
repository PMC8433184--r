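# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a compact trained classifier (120 patches/class is plenty for the
# synthetic appearance model; heavier 300/class models are trained in the
# acceptance tests)
fixture_model <- function(noise_sigma = 0) {
  key <- paste0("model_", noise_sigma)
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_chip_config(noise_sigma = noise_sigma, seed = 101)
    ts <- make_training_set(cfg, 120, seed = 102)
    .fixtures[[key]] <- train_classifier(ts, epochs = 120, seed = 103)
  }
  .fixtures[[key]]
}

# a 6-incubator mixed-state chip covering every embryo state
fixture_chip_specs <- function() {
  list(
    sim_embryo_spec("Normal", bean_frame = 20, twitch_frame = 40,
                    hatch_frame = 100),
    sim_embryo_spec("Dead"),
    sim_embryo_spec("Empty"),
    sim_embryo_spec("Unclear", twitch_frame = 30, hatch_frame = 90),
    sim_embryo_spec("LateHatching", bean_frame = 25, twitch_frame = 45),
    sim_embryo_spec("Normal", bean_frame = 30, twitch_frame = 50,
                    hatch_frame = 120))
}

fixture_chip <- function(noise_sigma = 0, seed = 7, frame_count = 144L) {
  key <- paste0("chip_", noise_sigma, "_", seed, "_", frame_count)
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_chip_config(noise_sigma = noise_sigma, seed = seed,
                           frame_count = frame_count)
    .fixtures[[key]] <- simulate_chip(cfg, fixture_chip_specs())
  }
  .fixtures[[key]]
}

# phenotype a cohort of n embryos simulated in fields of 6, one field in
# memory at a time; returns truth and records joined by a global index
run_cohort <- function(n, noise_sigma, seed, model,
                       config = pipeline_config()) {
  specs <- random_embryo_specs(n, seed = seed)
  truth_all <- list(); recs_all <- list()
  done <- 0L
  field <- 0L
  while (done < n) {
    take <- min(6L, n - done)
    cfg <- sim_chip_config(n_incubators = take, noise_sigma = noise_sigma,
                           seed = seed + 1000L + field)
    sim <- simulate_chip(cfg, specs[(done + 1L):(done + take)])
    locs <- detect_incubators(get_frame(sim$sequence, 0), config)
    recs <- phenotype_chip(sim$sequence, locs, model, config)
    truth <- sim$truth
    truth$incubator <- truth$incubator + done
    recs$incubator <- recs$incubator + done
    truth_all[[field + 1L]] <- truth
    recs_all[[field + 1L]] <- recs
    done <- done + take
    field <- field + 1L
    rm(sim); gc(FALSE)
  }
  list(truth = dplyr::bind_rows(truth_all),
       records = dplyr::bind_rows(recs_all))
}
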