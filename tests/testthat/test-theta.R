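test_that("theta cycles are recovered from a pure sinusoid", {
  fs <- 1250
  tt <- seq_len(10 * fs) / fs
  lfp <- data.frame(t = tt, v = sin(2 * pi * 8 * tt))
  attr(lfp, "fs") <- fs
  cyc <- detect_theta_cycles(lfp, speed = rep(30, 11), speed_t = 0:10)
  expect_gte(nrow(cyc), 77)
  expect_lte(nrow(cyc), 80)
  expect_equal(median(cyc$duration), 0.125, tolerance = 0.01)
  expect_true(all(diff(cyc$t_start) > 0))
})

test_that("cycle segmentation enforces duration bounds, immobility and length", {
  fs <- 1250
  tt <- seq_len(10 * fs) / fs
  lfp <- data.frame(t = tt, v = sin(2 * pi * 8 * tt))
  attr(lfp, "fs") <- fs
  # immobile animal: every cycle rejected
  cyc0 <- detect_theta_cycles(lfp, speed = rep(0, 11), speed_t = 0:10)
  expect_equal(nrow(cyc0), 0L)
  # all surviving noise cycles respect the duration bounds
  set.seed(3)
  lfpn <- data.frame(t = tt, v = stats::rnorm(length(tt)))
  attr(lfpn, "fs") <- fs
  cycn <- detect_theta_cycles(lfpn, speed = rep(30, 11), speed_t = 0:10)
  if (nrow(cycn)) {
    expect_true(all(cycn$duration >= 1 / 12 & cycn$duration <= 1 / 5))
  }
  short <- lfp[1:100, ]
  attr(short, "fs") <- fs
  expect_error(detect_theta_cycles(short, rep(30, 11), 0:10), "shorter")
})

test_that("synthetic session cycle count tracks theta frequency x running time", {
  s <- fix_lfp()
  speed <- position_speed(s$position)
  cyc <- detect_theta_cycles(s$lfp, speed, s$position$t)
  run_s <- sum(speed > 4) * median(diff(s$position$t))
  expect_gt(nrow(cyc) / run_s, 8 * 0.9)
  expect_lt(nrow(cyc) / run_s, 8 * 1.1)
})

test_that("quadrant score matrix obeys its exact identities", {
  rc <- seq(-49, 49, by = 2)  # 50 rows, no zero-centered row
  nr <- length(rc)
  # symmetric about the current position -> 0
  M <- matrix(stats::runif(12), nr, 12, byrow = TRUE)
  expect_equal(quadrant_score_matrix(M, rc), 0, tolerance = 1e-12)

  # ideal forward sweep: behind-early, ahead-late -> 1
  M2 <- matrix(0, nr, 12)
  M2[rc < 0, 1:6] <- 1
  M2[rc > 0, 7:12] <- 1
  expect_equal(quadrant_score_matrix(M2, rc), 1)

  # time reversal negates the score
  set.seed(1)
  M3 <- matrix(stats::runif(nr * 12), nr, 12)
  expect_equal(quadrant_score_matrix(M3[, 12:1], rc),
               -quadrant_score_matrix(M3, rc), tolerance = 1e-12)

  # uniform additive offset: the quadrant contrast (numerator) is invariant,
  # so sign and zeros are preserved even though the normalized score shrinks
  s3 <- quadrant_score_matrix(M3, rc)
  s3off <- quadrant_score_matrix(M3 + 5, rc)
  expect_equal(sign(s3off), sign(s3))
  expect_equal(quadrant_score_matrix(M2 + 3, rc) > 0, TRUE)
  expect_equal(quadrant_score_matrix(M + 3, rc), 0, tolerance = 1e-12)

  expect_true(is.na(quadrant_score_matrix(matrix(0, nr, 12), rc)))
})

test_that("quadrant_score runs end-to-end on a session with LFP", {
  s <- fix_lfp()
  qs <- quadrant_score(s, "C1-G", phases = c("pre", "learning"))
  expect_gt(qs$n_windows, 20)
  expect_true(is.finite(qs$score))
  expect_lte(abs(qs$score), 1)
  # too few cycles -> NA score
  qs2 <- quadrant_score(s, "C1-G", phases = "pre", min_cycles = 1e6)
  expect_true(is.na(qs2$score))
})
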