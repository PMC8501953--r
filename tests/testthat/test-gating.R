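test_that("compensation with the identity matrix is a no-op", {
  ev <- toy_events(c(1, 2, 3), channel = "a")
  ev$mean_b <- c(4, 5, 6)
  ev <- as_event_table(ev)
  comp <- compensation_matrix(diag(2), channels = c("a", "b"))
  expect_equal(compensate(ev, comp), ev)
})

test_that("a hand-solved 2x2 spillover is inverted exactly", {
  # observed = M %*% true with 20% spill of channel b into a:
  # observed (1.2, 1.0) must compensate to (1.0, 1.0)
  ev <- data.frame(droplet_id = 1L, duration_samples = 10L,
                   mean_a = 1.2, mean_b = 1.0)
  comp <- compensation_matrix(matrix(c(1, 0, 0.2, 1), 2),
                              channels = c("a", "b"))
  out <- compensate(as_event_table(ev), comp)
  expect_equal(out$mean_a, 1.0)
  expect_equal(out$mean_b, 1.0)
})

test_that("compensation inverts the simulator's spillover on noiseless events", {
  ct <- matrix(c(1, 0.1, 0.15, 1), 2, byrow = TRUE)
  m0 <- mixture_model(seed = 91, noise_sd = 0)
  m <- mixture_model(seed = 91, noise_sd = 0, crosstalk = ct)
  clean <- simulate_event_table(m0, 500)$events
  mixed <- simulate_event_table(m, 500)$events
  comp <- compensation_matrix(ct, channels = c("ERBB2", "stain"))
  restored <- compensate(mixed, comp)
  expect_equal(restored$mean_ERBB2, clean$mean_ERBB2, tolerance = 1e-10)
  expect_equal(restored$mean_stain, clean$mean_stain, tolerance = 1e-10)
})

test_that("estimate_compensation recovers a known spillover within 1%", {
  set.seed(7)
  n <- 1000
  # observed = M %*% true: 20% of channel b spills into a
  truth <- matrix(c(1, 0.2, 0, 1), 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("a", "b")))
  make_control <- function(pos) {
    sig <- matrix(0, n, 2, dimnames = list(NULL, c("a", "b")))
    sig[, pos] <- runif(n, 800, 1200)
    obs <- sig %*% t(truth) + matrix(rnorm(2 * n, 0, 1), n, 2)
    df <- data.frame(droplet_id = seq_len(n), duration_samples = 10L)
    df$mean_a <- obs[, 1]
    df$mean_b <- obs[, 2]
    as_event_table(df)
  }
  est <- estimate_compensation(list(a = make_control("a"), b = make_control("b")))
  expect_lt(abs(est$matrix["a", "b"] - 0.2), 0.01 * 0.2 + 1e-3)
  expect_lt(abs(est$matrix["b", "a"] - 0.0), 1e-2)
  expect_equal(diag(est$matrix), c(a = 1, b = 1))
})

test_that("zero-spillover controls give the identity matrix", {
  set.seed(8)
  mk <- function(pos) {
    df <- data.frame(droplet_id = 1:200, duration_samples = 10L)
    df$mean_a <- if (pos == "a") runif(200, 900, 1100) else 0
    df$mean_b <- if (pos == "b") runif(200, 900, 1100) else 0
    as_event_table(df)
  }
  est <- estimate_compensation(list(a = mk("a"), b = mk("b")))
  expect_equal(unname(est$matrix), diag(2))
})

test_that("size gate trims floor(trim * n) events from each duration tail", {
  ev100 <- toy_events(rep(1, 100), durations = sample(1000:1099))
  expect_equal(nrow(size_gate(ev100, 0.08)), 84)
  expect_equal(size_gate(ev100, 0), ev100)
  ev25 <- toy_events(rep(1, 25), durations = sample(500:524))
  expect_equal(nrow(size_gate(ev25, 0.08)), 21)  # floor(2.0) = 2 per tail
  # survivors are the middle of the duration distribution, order preserved
  kept <- size_gate(ev100, 0.08)
  rng <- range(kept$duration_samples)
  expect_equal(rng, c(1008, 1091))
  expect_equal(kept$droplet_id, ev100$droplet_id[ev100$droplet_id %in% kept$droplet_id])
  expect_error(size_gate(ev100, 0.5), "trim")
})

test_that("cell gate partitions events at fold x median stain", {
  ev <- toy_events(c(rep(100, 90), rep(1000, 10)), channel = "stain")
  parts <- cell_gate(ev, gate_config(stain_fold = 2.8))
  expect_equal(nrow(parts$cells), 10)
  expect_equal(nrow(parts$empties), 90)
  expect_equal(parts$cutoff, 280)
  expect_equal(nrow(parts$cells) + nrow(parts$empties), nrow(ev))
  expect_setequal(c(parts$cells$droplet_id, parts$empties$droplet_id),
                  ev$droplet_id)
  # identical stain everywhere: nothing exceeds fold x median
  flat <- toy_events(rep(100, 50), channel = "stain")
  expect_equal(nrow(cell_gate(flat)$cells), 0)
})

test_that("down-sampling is exact, reproducible and identity when n >= size", {
  ev <- toy_events(runif(50000))
  expect_identical(downsample_events(ev, 60000, seed = 1), ev)
  a <- downsample_events(ev, 10000, seed = 3)
  b <- downsample_events(ev, 10000, seed = 3)
  expect_equal(nrow(a), 10000)
  expect_equal(anyDuplicated(a$droplet_id), 0)
  expect_identical(a, b)
  expect_false(identical(a, downsample_events(ev, 10000, seed = 4)))
})

test_that("amplification threshold is fold x empty-population median", {
  ev <- toy_events(rep(100, 11), channel = "FAM")
  expect_equal(amplification_threshold(ev, "FAM", fold = 2.8), 280)
  expect_equal(amplification_threshold(ev, "FAM", fold = 1.0001), 100 * 1.0001)
  even <- toy_events(c(90, 110), channel = "FAM")  # even-size median = 100
  expect_equal(amplification_threshold(even, "FAM", fold = 2.8), 280)
  expect_error(amplification_threshold(ev[0, ], "FAM"), "no events")
})

test_that("threshold from simulated empties separates the two fluorescence modes", {
  m <- mixture_model(seed = 101)
  sim <- simulate_event_table(m, 20000)
  parts <- cell_gate(sim$events)
  thr <- amplification_threshold(parts$empties, "ERBB2")
  # empty baseline is 100, amplified signal 1100: cutoff must fall between
  expect_gt(thr, 150)
  expect_lt(thr, 1000)
})

test_that("positivity calls and summaries follow the thresholds", {
  ev <- toy_events(c(300, 100, 290, 50), channel = "FAM")
  calls <- classify_positive(ev, c(FAM = 280))
  expect_equal(calls$call_FAM, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(percent_positive(calls, "FAM"), 0.5)
  none <- classify_positive(ev, c(FAM = 1e6))
  expect_equal(percent_positive(none, "FAM"), 0)
  # invariance under row permutation
  perm <- calls[sample(nrow(calls)), ]
  expect_equal(percent_positive(perm, "FAM"), 0.5)
  expect_error(classify_positive(ev, c(HEX = 1)), "HEX")
  expect_error(percent_positive(calls[0, ], "FAM"), "0 events")
})

test_that("quadrant counts partition the table", {
  ev <- toy_events(c(1, 1, 1, 0, 0), channel = "x")
  ev$mean_y <- c(0, 0, 0, 1, 1)
  ev <- as_event_table(ev)
  calls <- classify_positive(ev, c(x = 0.5, y = 0.5))
  q <- quadrant_counts(calls, "x", "y")
  expect_equal(unname(q), c(0, 3, 2, 0))
  expect_equal(sum(q), nrow(ev))
  empty_q <- quadrant_counts(calls[0, ], "x", "y")
  expect_equal(unname(empty_q), c(0, 0, 0, 0))
})

test_that("calls on simulated data agree with ground-truth marker states", {
  m <- mixture_model(p_positive = 0.5, seed = 111)
  sim <- simulate_event_table(m, 20000)
  parts <- cell_gate(sim$events)
  thr <- amplification_threshold(parts$empties, "ERBB2")
  calls <- classify_positive(parts$cells, c(ERBB2 = thr))
  truth <- sim$truth[match(calls$droplet_id, sim$truth$droplet_id), ]
  # 10x signal over baseline with sd-5 noise: calls mirror true states
  expect_gt(mean(calls$call_ERBB2 == truth$ERBB2), 0.999)
})
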