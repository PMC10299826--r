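test_that("parameter validation enforces the model's structural constraints", {
  expect_s3_class(model_params(), "model_params")
  expect_error(model_params(theta = 0.05), "baseline")
  expect_error(model_params(w1a = 0.1, w2a = 0.8), "w1a > w2a")
  expect_error(model_params(dt = 0), "dt")
  expect_error(model_params(alpha = 1.5), "alpha")
  # weight ordering is irrelevant when learning is silenced
  expect_s3_class(model_params(alpha = 0, w1a = 0.1, w2a = 0.8),
                  "model_params")
})

test_that("command output floors at the baseline activity", {
  expect_identical(command_output(-0.5), 0.1)
  expect_identical(command_output(0.1), 0.1)
  expect_identical(command_output(2.3), 2.3)
  expect_equal(command_output(c(-1, 0, 0.05, 0.7)), c(0.1, 0.1, 0.1, 0.7))
})

test_that("learning drives interpolate between the binary colour channels", {
  p <- model_params(alpha = 0.8, I = 1)
  hi <- learning_drive(1, p)
  expect_equal(hi$rL1, 0)
  expect_equal(hi$rL2, 0.8)
  lo <- learning_drive(0, p)
  expect_equal(lo$rL1, 0.8)
  expect_equal(lo$rL2, 0)
  off <- learning_drive(0.5, ablate(p, "no_learning"))
  expect_equal(off$rL1, 0)
  expect_equal(off$rL2, 0)
  expect_error(learning_drive(1.2, p), "\\[0, 1\\]")
})

test_that("a single step reproduces drift arithmetic", {
  p <- model_params(sigma = 0, k = 0, I = 1, dt = 0.01)
  st <- step_accumulators(list(t = 0, Pa = 0, Pr = 0), p, "race",
                          xi1 = 0, xi2 = 0)
  expect_equal(st$Pa, 0.01)
  expect_equal(st$t, 0.01)

  pq <- model_params(sigma = 0, I = 0)
  st2 <- step_accumulators(list(t = 0, Pa = 0, Pr = 0), pq, "race",
                           xi1 = 0, xi2 = 0)
  expect_equal(st2$Pa, 0)
  expect_equal(st2$Pr, 0)
})

test_that("noiseless leaky integration converges to the I/k equilibrium", {
  # closed form of the linear ODE: Pa(t) = (I/k)(1 - exp(-k t))
  p <- model_params(sigma = 0, k = 1, I = 1, dt = 0.001, theta = 5, t_max = 12)
  st <- list(t = 0, Pa = 0, Pr = 0)
  for (i in 1:12000) {
    st <- step_accumulators(st, p, "race", xi1 = 0, xi2 = 0)
  }
  expect_equal(st$Pa, 1, tolerance = 1e-4)

  # the recorded trace tracks the closed form throughout
  out <- simulate_trial(model_params(sigma = 0, k = 1, I = 1, dt = 0.01,
                                     theta = 0.95, t_max = 10),
                        "race", seed = 1, trace = TRUE)
  tr <- out$trace
  expect_equal(tr$Pa, 1 - exp(-tr$t), tolerance = 5e-3)
})

test_that("trial simulation is deterministic and honours the stopping rules", {
  p <- model_params()
  a <- simulate_trial(p, "full", q_hat = 1, seed = 42, trace = TRUE)
  b <- simulate_trial(p, "full", q_hat = 1, seed = 42, trace = TRUE)
  expect_identical(a$response, b$response)
  expect_identical(a$decision_time, b$decision_time)
  expect_identical(a$trace, b$trace)

  # quiescent input: forced decision at t_max with A = R = baseline -> reject
  quiet <- simulate_trial(model_params(sigma = 0, I = 0), "race", seed = 1)
  expect_identical(quiet$response, "reject")
  expect_true(quiet$forced)
  expect_equal(quiet$decision_time, 10)

  # symmetric noiseless drift, threshold just above baseline: both commands
  # cross together and the tie resolves to reject
  tie <- simulate_trial(model_params(sigma = 0, theta = 0.11, I = 1, k = 1),
                        "race", seed = 1)
  expect_identical(tie$response, "reject")
  expect_false(tie$forced)

  # decision_time never exceeds t_max
  expect_lte(a$decision_time, p$t_max)
})

test_that("noiseless decision times are step-size robust", {
  base <- list(sigma = 0, k = 1, I = 1, theta = 0.8, t_max = 10)
  t_coarse <- do.call(simulate_trial,
                      list(do.call(model_params, c(base, dt = 0.01)),
                           "race", 0.5, 1))$decision_time
  t_fine <- do.call(simulate_trial,
                    list(do.call(model_params, c(base, dt = 0.005)),
                         "race", 0.5, 1))$decision_time
  expect_lt(abs(t_coarse - t_fine), 0.01)
  # and both near the exact crossing of the closed form: -log(1 - theta)
  expect_equal(t_fine, -log(0.2), tolerance = 0.02)
})

test_that("the batched simulator agrees with stepwise single-trial dynamics", {
  p <- model_params(t_max = 2)
  for (variant in c("race", "cross", "learning", "full")) {
    set.seed(99)
    batch <- beechoice:::.simulate_batch(1L, p, variant, q_hat = 0.3)
    single <- simulate_trial(p, variant, q_hat = 0.3, seed = 99)
    expect_identical(batch$response, single$response)
    expect_identical(batch$decision_time, single$decision_time)
    expect_identical(batch$forced, single$forced)
  }
})

test_that("parameter blow-up is reported, not silently propagated", {
  p <- model_params(k = 1e8, sigma = 0, theta = Inf)
  expect_error(simulate_trial(p, "race", seed = 1), "non-finite")
})

test_that("parameters round-trip through YAML and JSON configs", {
  p <- model_params(sigma = 0.25, theta = 1.2)
  fy <- withr::local_tempfile(fileext = ".yaml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_model_params(p, fy)
  write_model_params(p, fj)
  expect_equal(read_model_params(fy), p)
  expect_equal(read_model_params(fj), p)

  writeLines("sigma: 0.2\nbogus: 1", fy)
  expect_error(read_model_params(fy), "unknown parameter")
})
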