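mz <- make_maze()

test_that("identical seeds give identical sessions", {
  a <- simulate_session(seed = 11, n_units = 10, n_trials = c(3, 3, 3), lfp = TRUE)
  b <- simulate_session(seed = 11, n_units = 10, n_trials = c(3, 3, 3), lfp = TRUE)
  expect_identical(a$position, b$position)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp$v, b$lfp$v)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
})

test_that("degenerate trial counts are rejected", {
  expect_error(simulate_behavior(mz, n_trials = c(0, 0, 0)), "at least 3")
  expect_error(simulate_behavior(mz, n_trials = c(5, 5)), "3 elements")
})

test_that("behavior schedule places the learning point after replacement", {
  beh <- simulate_behavior(mz, n_trials = c(pre = 12, learning = 26, post = 12),
                           seed = 1)
  expect_equal(beh$ground_truth$reward_replacement_trial, 13L)
  expect_equal(beh$ground_truth$learning_point_trial, 39L)
  expect_equal(length(beh$ground_truth$phase_of_trial), 50L)
  # timestamps nondecreasing, constant sample rate
  expect_true(all(diff(beh$position$t) > 0))
  expect_lt(diff(range(diff(beh$position$t))), 1e-9)
})

test_that("zero peak rate gives an empty train; negative peak errors", {
  beh <- simulate_behavior(mz, n_trials = c(3, 3, 3), seed = 2)
  tun <- data.frame(unit = 1L, type = "stable", group = NA, path = "S-C1",
                    center = 30, sigma = 10, peak = 0)
  class(tun) <- c("tuning_spec", "data.frame")
  spk <- simulate_spikes(beh, tun, mz, baseline_rate = 0, seed = 1)
  expect_length(spk$spikes[[1]], 0L)

  tun$peak <- -1
  expect_error(simulate_spikes(beh, tun, mz, seed = 1), "negative peak")
})

test_that("empirical rate map peak matches the programmed tuning", {
  beh <- simulate_behavior(mz, n_trials = c(22, 3, 3), seed = 6)
  tun <- data.frame(unit = 1L, type = "stable", group = NA, path = "S-C1",
                    center = 30, sigma = 10, peak = 15)
  class(tun) <- c("tuning_spec", "data.frame")
  spk <- simulate_spikes(beh, tun, mz, baseline_rate = 0, seed = 7)
  s <- structure(list(maze = mz, position = beh$position, trials = beh$trials,
                      spikes = spk$spikes, lfp = NULL), class = "rk_session")
  rm <- compute_rate_map(s, 1)
  at_center <- rm$rate[rm$path == "S-C1"][abs(rm$center[rm$path == "S-C1"] - 30) < 3]
  expect_gt(max(at_center, na.rm = TRUE), 15 * 0.7)
  expect_lt(max(at_center, na.rm = TRUE), 15 * 1.3)
})

test_that("empirical mean rate converges to the programmed tuning with T", {
  tun <- data.frame(unit = 1L, type = "stable", group = NA, path = "S-C1",
                    center = 30, sigma = 10, peak = 15)
  class(tun) <- c("tuning_spec", "data.frame")
  rel_err <- function(n_pre, seed) {
    beh <- simulate_behavior(mz, n_trials = c(n_pre, 3, 3), seed = seed)
    spk <- simulate_spikes(beh, tun, mz, baseline_rate = 0, seed = seed + 1)
    # expected spikes: integral of the tuning over the actual trajectory
    smp <- beh$samples
    sel <- smp$running & !is.na(smp$path) & smp$path == "S-C1"
    lam <- 15 * exp(-(smp$lin[sel] - 30)^2 / 200)
    expected <- sum(lam) * 0.02
    abs(length(spk$spikes[[1]]) - expected) / expected
  }
  e1 <- rel_err(6, 31)
  e4 <- rel_err(24, 31)
  expect_lt(e4, 0.12)
  expect_lt(e4, e1 * 1.5 + 0.02)  # error shrinks (noisy ~ 1/sqrt(T))
})

test_that("context units express fields on analogous paths", {
  s <- fix50()
  tun <- s$ground_truth$tuning
  u <- tun$unit[tun$type == "context" & tun$group == "checkpoint"][1]
  flds <- unit_fields(tun[tun$unit == u, ], s$maze, "learning")
  expect_setequal(flds$path, c("S-C1", "S-C2", "G-C2"))
  # destination-aligned: same distance to destination on every path
  d <- vapply(seq_len(nrow(flds)), function(i)
    path_length(s$maze, flds$path[i]) - flds$center[i], numeric(1))
  expect_lt(diff(range(d)), 1e-9)
})

test_that("replay schedules outside immobility are rejected", {
  beh <- simulate_behavior(mz, n_trials = c(3, 3, 3), seed = 4)
  tun <- make_tuning(mz, 12, seed = 1)
  spk <- simulate_spikes(beh, tun, mz, seed = 2)
  seg <- beh$segments[1, ]  # a running segment
  bad <- data.frame(event = 1L, trial = seg$trial, phase = "pre", window = "pre",
                    area = "field", t_start = (seg$t_start + seg$t_end) / 2,
                    duration = 0.2, path = "S-C1", direction = "forward")
  expect_error(simulate_lfp_and_replays(beh, spk, bad, mz, lfp = FALSE),
               "immobility")
})

test_that("make_tuning respects composition and bounds", {
  tun <- make_tuning(mz, 60, seed = 9)
  expect_equal(nrow(tun), 60L)
  expect_true(all(tun$type %in% c("stable", "context", "on", "off", "nonplace")))
  pl <- tun[tun$type %in% c("stable", "on", "off"), ]
  expect_true(all(pl$center >= 0 &
                    pl$center <= vapply(pl$path, function(p) path_length(mz, p),
                                        numeric(1))))
  # context groups populated in ratio ~3:2
  gr <- table(tun$group)
  expect_true(all(c("checkpoint", "goal") %in% names(gr)))
})
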