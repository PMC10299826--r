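test_that("events are categorised and tallied correctly", {
  ev <- categorise_events(fixture_events(), high_stimulus = "S100")
  expect_equal(ev$category,
               c("CA", "IR", "IA", "CR", "CA", "CR", "CA", "CR"))

  counts <- count_responses(ev)
  expect_equal(unclass(counts)[], c(nCA = 3L, nIA = 1L, nCR = 3L, nIR = 1L))

  bee1 <- count_responses(ev, bee = 1)
  expect_equal(sum(bee1), 4L)
  expect_equal(bee1[["nCA"]], 1L)

  empty <- count_responses(ev[0, ])
  expect_equal(sum(empty), 0L)

  # category contradicting the recorded response is refused, naming the row
  bad <- ev
  bad$category[2] <- "CA"   # row 2 is a rejection
  expect_error(count_responses(bad), "row\\(s\\): 2")
})

test_that("MCC matches its endpoints and the correlation oracle", {
  expect_identical(mcc(response_counts(5, 0, 5, 0)), 1)
  expect_identical(mcc(response_counts(0, 5, 0, 5)), -1)
  expect_identical(mcc(response_counts(6, 6, 4, 4)), 0)
  # zero marginal: conventional 0
  expect_identical(mcc(response_counts(5, 0, 0, 3)), 0)
  expect_identical(mcc(response_counts(0, 0, 0, 0)), 0)

  # oracle: MCC is the Pearson correlation of the two binary indicators
  # (response = accept, stimulus = higher-ranked) over the expanded table
  mcc_oracle <- function(nCA, nIA, nCR, nIR) {
    accepted <- c(rep(1, nCA + nIA), rep(0, nCR + nIR))
    was_high <- c(rep(1, nCA), rep(0, nIA), rep(0, nCR), rep(1, nIR))
    suppressWarnings(stats::cor(accepted, was_high))
  }
  set.seed(11)
  for (i in 1:50) {
    n <- as.list(stats::rpois(4, 5))
    got <- mcc(response_counts(n[[1]], n[[2]], n[[3]], n[[4]]))
    expect_gte(got, -1)
    expect_lte(got, 1)
    want <- mcc_oracle(n[[1]], n[[2]], n[[3]], n[[4]])
    if (!is.na(want)) expect_equal(got, want, tolerance = 1e-12)
    # swapping correctness labels flips the sign
    expect_equal(mcc(response_counts(n[[2]], n[[1]], n[[4]], n[[3]])), -got,
                 tolerance = 1e-12)
  }
})

test_that("hit and false-positive rates follow the acceptance/rejection split", {
  r <- response_rates(response_counts(8, 2, 6, 4))
  expect_equal(r$hit_rate, 0.8)
  expect_equal(r$false_positive_rate, 0.4)
  expect_false(r$edge_corrected)

  # clamp policy moves a unit rate to 1 - 1/(2N)
  r2 <- response_rates(response_counts(5, 0, 5, 5))
  expect_equal(r2$hit_rate, 1 - 1 / 10)
  expect_true(r2$edge_corrected)

  # log-linear alternative adds 0.5 per cell
  r3 <- response_rates(response_counts(5, 0, 5, 5), edge_policy = "loglinear")
  expect_equal(r3$hit_rate, 5.5 / 6)

  # textbook false-alarm definition is selectable and labelled
  r4 <- response_rates(response_counts(8, 2, 6, 4),
                       fp_definition = "noise_trials")
  expect_equal(r4$false_positive_rate, 2 / 8)
  expect_equal(r4$fp_definition, "noise_trials")

  expect_error(response_rates(response_counts(0, 0, 5, 5)), "no acceptances")
  expect_error(response_rates(response_counts(5, 5, 0, 0)), "no rejections")
})

test_that("d-prime and criterion match the inverse-normal oracle", {
  # hit = fp = 0.5 is the exact null
  s0 <- sdt_summary(response_counts(5, 5, 5, 5))
  expect_equal(s0$d_prime, 0)
  expect_equal(s0$decision_criterion, 0)

  # frozen from an independent high-precision inverse-normal evaluation:
  # Z(0.84) = 0.994457883209753
  s <- sdt_summary(response_counts(84, 16, 84, 16))
  expect_equal(s$d_prime, 1.988915766419506, tolerance = 1e-12)
  expect_equal(s$decision_criterion, 0, tolerance = 1e-12)

  # antisymmetry about 0.5
  s_flip <- sdt_summary(response_counts(16, 84, 16, 84))
  expect_equal(s_flip$d_prime, -1.988915766419506, tolerance = 1e-12)

  # d' strictly increasing in hit rate, strictly decreasing in fp rate
  hits <- seq(0.55, 0.95, by = 0.1)
  d_by_hit <- vapply(round(hits * 100), function(h) {
    sdt_summary(response_counts(h, 100 - h, 60, 40))$d_prime
  }, numeric(1))
  expect_true(all(diff(d_by_hit) > 0))
  d_by_fp <- vapply(round(hits * 100), function(f) {
    sdt_summary(response_counts(60, 40, 100 - f, f))$d_prime
  }, numeric(1))
  expect_true(all(diff(d_by_fp) < 0))
})

test_that("conditional accuracy functions bin and summarise response times", {
  ev <- data.frame(
    bee_id = 1, test_id = "easy",
    stimulus_id = c("S100", "S100", "S0", "S100"),
    response = "accept",
    response_time = c(0.2, 0.3, 0.7, 0.8),
    stringsAsFactors = FALSE
  )
  ev <- categorise_events(ev, "S100")   # CA, CA, IA, CA
  curve <- caf(ev, "accept", bin_width = 0.5, min_count = 1)
  expect_equal(curve$n_total, c(2L, 2L))
  expect_equal(curve$prop_correct, c(1.0, 0.5))
  # bin totals conserve the event count of that type
  expect_equal(sum(curve$n_total), sum(ev$category %in% c("CA", "IA")))

  # bins under min_count are reported but undefined
  curve2 <- caf(ev, "accept", bin_width = 0.5, min_count = 3)
  expect_true(all(is.na(curve2$prop_correct)))

  expect_error(caf(ev, "reject"), "no events")
})

test_that("CAF trends recover planted accuracy-time relationships", {
  make_curve <- function(props, n = 10) {
    ev <- do.call(rbind, lapply(seq_along(props), function(b) {
      k <- round(props[b] * n)
      data.frame(bee_id = 1, test_id = "t",
                 stimulus_id = c(rep("H", k), rep("L", n - k)),
                 response = "accept",
                 response_time = (b - 1) * 0.5 + seq(0.05, 0.45, length.out = n))
    }))
    caf(categorise_events(ev, "H"), "accept", min_count = 3)
  }
  expect_equal(caf_trend(make_curve(c(0.9, 0.8, 0.7, 0.6, 0.5)))$rho, -1)
  expect_equal(caf_trend(make_curve(c(0.5, 0.6, 0.7, 0.8, 0.9)))$rho, 1)
  expect_equal(caf_trend(make_curve(c(0.7, 0.7, 0.7)))$rho, 0)
  expect_error(caf_trend(make_curve(c(0.9, 0.5))), "at least 3")

  # accuracy planted to decline with a logistic in time: negative trend
  set.seed(21)
  times <- stats::runif(600, 0, 4)
  p_correct <- stats::plogis(2 - 1.5 * times)
  ev <- data.frame(bee_id = 1, test_id = "t",
                   stimulus_id = ifelse(stats::runif(600) < p_correct, "H", "L"),
                   response = "accept", response_time = times)
  trend <- caf_trend(caf(categorise_events(ev, "H"), "accept"))
  expect_lt(trend$rho, 0)
})

test_that("first-choice latency is the per-group minimum", {
  ev <- fixture_events()
  lat <- first_choice_latency(ev, by = "bee")
  expect_equal(lat$first_latency[match(c(1, 2), lat$bee_id)], c(0.4, 0.6))
  expect_error(first_choice_latency(ev[0, ]), "no events")
})

test_that("choice events round-trip through delimited text", {
  ev <- fixture_events()
  f <- withr::local_tempfile(fileext = ".csv")
  write_choice_events(categorise_events(ev, "S100"), f)
  back <- read_choice_events(f, high_stimulus = "S100")
  expect_equal(back$response, ev$response)
  expect_equal(back$response_time, ev$response_time)
  expect_true("category" %in% names(back))
  expect_error(read_choice_events(f, high_stimulus = c(a = "x", b = "y")),
               "test_id|entry")
})
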