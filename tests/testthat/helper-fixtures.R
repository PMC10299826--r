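# Shared fixtures: trained estimates, pooled cohort runs, and a synthetic
# arena layout.  Everything is generated in code under fixed seeds.

fixture_learned <- function(name = "P1") {
  train_weights(build_protocol(name))
}

# Pool run_test() tables over several master seeds.
pool_runs <- function(variant, test = "easy", params = model_params(),
                      learned = fixture_learned(), seeds = 1:20,
                      spec = test_spec(test)) {
  do.call(rbind, lapply(seeds, function(s) {
    run_test(spec, params, variant, learned, seed = s * 1000L)
  }))
}

fixture_layout <- function() {
  stimulus_layout(c("S100", "S0"), x = c(0.30, 0.70), y = c(0.40, 0.40))
}

# Hand-buildable event table with known tallies.
fixture_events <- function() {
  data.frame(
    bee_id = c(1, 1, 1, 1, 2, 2, 2, 2),
    test_id = "easy",
    stimulus_id = c("S100", "S100", "S0", "S0", "S100", "S0", "S100", "S0"),
    response = c("accept", "reject", "accept", "reject",
                 "accept", "reject", "accept", "reject"),
    response_time = c(0.4, 1.2, 2.0, 0.9, 0.6, 1.1, 3.0, 0.7),
    stringsAsFactors = FALSE
  )
}
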