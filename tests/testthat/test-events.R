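test_that("SWR detector finds an injected ripple burst with correct onset", {
  fs <- 1250
  set.seed(4)
  n <- 60 * fs
  tt <- seq_len(n) / fs
  v <- replaykit:::pink_noise(n)
  t0 <- 30; dur <- 0.07
  idx <- which(tt >= t0 & tt <= t0 + dur)
  win <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
  v[idx] <- v[idx] + 5 * win * sin(2 * pi * 200 * (tt[idx] - t0))
  lfp <- data.frame(t = tt, v = v)
  attr(lfp, "fs") <- fs
  swr <- detect_swr(lfp, speed = rep(0, 61), speed_t = 0:60)
  hit <- swr[swr$t_start < t0 + dur & swr$t_end > t0, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$t_start - t0), 0.012)

  expect_error(detect_swr(lfp[1:5, ], rep(0, 61), 0:60), "empty LFP")
  expect_error(detect_swr(lfp, rep(30, 61), 0:60), "no immobility")
})

test_that("SWR false-positive rate on pure noise is below 1 per minute", {
  fs <- 1250
  set.seed(9)
  n <- 120 * fs
  lfp <- data.frame(t = seq_len(n) / fs, v = replaykit:::pink_noise(n))
  attr(lfp, "fs") <- fs
  swr <- detect_swr(lfp, speed = rep(0, 121), speed_t = 0:120)
  expect_lte(nrow(swr), 2L)  # 2 minutes of noise
})

stationary_session <- function(spikes, t_end = 60, moving = FALSE) {
  mz <- make_maze()
  tt <- seq(0, t_end, by = 0.02)
  if (moving) {
    xy <- path_point(mz, "return", (tt * 25) %% path_length(mz, "return"))
    pos <- data.frame(t = tt, x = xy[, 1], y = xy[, 2])
  } else {
    pos <- data.frame(t = tt, x = mz$s_anchor[1], y = mz$s_anchor[2])
  }
  structure(list(maze = mz, position = pos,
                 trials = data.frame(trial = 1L, t_start = 0, t_end = t_end,
                                     phase = "pre"),
                 spikes = spikes, lfp = NULL), class = "rk_session")
}

test_that("synchronous-event detection isolates an injected burst", {
  set.seed(12)
  base <- lapply(1:30, function(u) sort(stats::runif(4, 0, 60)))
  burst <- lapply(seq_along(base), function(u)
    sort(c(base[[u]], 30 + stats::runif(1, 0, 0.08))))
  s <- stationary_session(burst)
  ev <- detect_synchronous_events(s)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$t_start - 30), 0.08)
  expect_gte(ev$n_units, 30 * 0.1)
  expect_equal(ev$area, "start")

  # the same burst during running is excluded
  s_run <- stationary_session(burst, moving = TRUE)
  expect_error(detect_synchronous_events(s_run), "no immobility")

  expect_error(detect_synchronous_events(stationary_session(base[1:5])),
               "at least 10 units")
})

test_that("homogeneous Poisson population stays under the 0.4 Hz bound", {
  set.seed(13)
  spikes <- lapply(1:40, function(u) sort(stats::runif(60, 0, 60)))  # 1 Hz each
  s <- stationary_session(spikes)
  ev <- detect_synchronous_events(s)
  expect_lt(nrow(ev) / 60, 0.4)
})

test_that("event rate maps conserve counts and exposure", {
  s <- fix_small()
  ev <- fixture("small_events", function() detect_synchronous_events(fix_small()))
  erm <- event_rate_maps(ev, s)
  expect_equal(sum(erm$table$n_events), nrow(ev))
  speed <- position_speed(s$position)
  dt <- median(diff(s$position$t))
  expect_equal(sum(erm$table$exposure_s), sum(speed < 4) * dt, tolerance = 0.01)
  expect_true(all(erm$map$rate_hz >= 0, na.rm = TRUE))
  # no events -> all-zero map
  erm0 <- event_rate_maps(ev[0, ], s)
  expect_true(all(erm0$map$n_events == 0))
})

test_that("reprate concentrates, ties break deterministically", {
  st <- eq_states(10)
  post <- matrix(0, 5, nrow(st))
  post[, st$path == "S-C2"] <- 1 / sum(st$path == "S-C2")
  dp <- make_dp(post, st, n_spikes = rep(1, 5))
  rr <- reprate(dp)
  expect_equal(unname(rr$reprate[["S-C2"]]), 1)
  expect_equal(rr$represented, "S-C2")

  unif <- matrix(1 / nrow(st), 5, nrow(st))
  rr2 <- reprate(make_dp(unif, st, n_spikes = rep(1, 5)))
  expect_true(all(abs(rr2$reprate - 0.2) < 1e-12))
  expect_equal(rr2$represented, sort(unique(st$path))[1])

  expect_error(reprate(make_dp(unif[0, , drop = FALSE], st)), "empty posterior")
})

test_that("weighted correlation: exact identities and the brute-force oracle", {
  D <- diag(5)
  expect_equal(weighted_corr(D), 1)
  expect_equal(weighted_corr(D[5:1, ]), -1)

  set.seed(6)
  for (k in 1:50) {
    P <- matrix(stats::runif(20), 4, 5)
    tv <- sort(stats::runif(4)); xv <- sort(stats::runif(5))
    r <- weighted_corr(P, tv, xv)
    expect_equal(r, wcorr_brute(P, tv, xv), tolerance = 1e-12)
    # exact time reversal: reverse rows and mirror the time coordinates
    tv_rev <- sort(max(tv) + min(tv) - tv)
    expect_equal(weighted_corr(P[4:1, ], tv_rev, xv), -r, tolerance = 1e-12)
  }

  # equal weights on a subset of cells = plain Pearson of the coordinates
  set.seed(7)
  M <- matrix(0, 6, 6)
  cells <- which(matrix(stats::runif(36) < 0.4, 6, 6), arr.ind = TRUE)
  M[cells] <- 0.37
  expect_equal(weighted_corr(M), stats::cor(cells[, 1], cells[, 2]),
               tolerance = 1e-12)

  # zero variance -> NA
  expect_true(is.na(weighted_corr(matrix(1, 1, 5))))
  expect_true(is.na(weighted_corr(matrix(c(1, 0, 0, 0), 2, 2)[, 1, drop = FALSE])))
})

test_that("sequence threshold is |r| >= 0.5 with sign-based direction", {
  st <- eq_states(10)
  on_path <- st$path == "S-C1"
  mk_post <- function(w_diag) {
    post <- matrix(1e-6, 10, nrow(st))
    for (i in 1:10) post[i, which(on_path)[i]] <- w_diag
    post <- post + 0.08
    post / rowSums(post)
  }
  for (w in c(0.05, 0.3, 3)) {
    dp <- make_dp(mk_post(w), st, n_spikes = rep(1, 10))
    sc <- sequence_score(dp, path = "S-C1", n_shuffles = 0)
    expect_equal(sc$is_sequential, abs(sc$r) >= 0.5)
    if (sc$is_sequential) expect_equal(sc$direction, if (sc$r > 0) "forward" else "reverse")
    else expect_equal(sc$direction, "none")
  }
  # deterministic under a fixed seed
  dp <- make_dp(mk_post(3), st, n_spikes = rep(1, 10))
  a <- sequence_score(dp, path = "S-C1", n_shuffles = 100, seed = 5)
  b <- sequence_score(dp, path = "S-C1", n_shuffles = 100, seed = 5)
  expect_identical(a, b)
  expect_gt(a$rZ, 2)
})

test_that("trajectory events require a long low-jump MAP sweep", {
  st <- eq_states(20)
  on_path <- which(st$path == "S-C2")
  static <- matrix(1e-9, 8, nrow(st))
  static[, on_path[10]] <- 1
  expect_false(trajectory_events(make_dp(static / rowSums(static), st,
                                         n_spikes = rep(1, 8)), path = "S-C2"))

  sweep_ <- matrix(1e-9, 16, nrow(st))
  for (i in 1:16) sweep_[i, on_path[2 + i]] <- 1
  expect_true(trajectory_events(make_dp(sweep_ / rowSums(sweep_), st,
                                        n_spikes = rep(1, 16)), path = "S-C2"))
})

test_that("repZ is reproducible and detects a strong injected replay", {
  # heterogeneous population: identity shuffle scrambles path tuning
  s <- fix_small()
  inj <- s$ground_truth$events
  ev <- inj[which.max(inj$n_participants), ]
  enc <- fix_small_enc()
  edges <- seq(ev$t_start, ev$t_start + ev$duration, by = 0.02)
  cnt <- bin_spike_counts(s$spikes, edges)
  z1 <- repz(cnt, enc, n_shuffles = 200, seed = 9)
  z2 <- repz(cnt, enc, n_shuffles = 200, seed = 9)
  expect_identical(z1, z2)
  expect_gt(z1$repZ[[ev$path]], 2)
  expect_equal(z1$represented, ev$path)
  expect_warning(repz(cnt, enc, n_shuffles = 50, seed = 1), "100 shuffles")
})

test_that("participation and PCC behave on the clean fixture", {
  cl <- fix_clean()
  sc <- fixture("clean_scored", function() {
    cl <- fix_clean()
    score_events(cl$session, cl$sched, cl$enc, n_shuffles = 100, seed = 3)
  })
  sub <- sc[1:20, ]
  pp <- participation_and_pcc(cl$session, sub, cl$enc,
                              classes = rep("stable", 30),
                              n_shuffles = 50, seed = 2)
  expect_true(all(pp$units$participation >= 0.9))  # full participation injected
  # carriers of the injected sequences contribute positively
  expect_gt(pp$by_class$mean_pcc, 0)
  expect_lt(pp$by_class$p_value, 0.05)
})

test_that("ensemble correlations: identity, anti-overlap, masking", {
  set.seed(20)
  sp <- lapply(1:12, function(u) numeric(0))
  # two identical events (units 1-6), one disjoint event (units 7-12)
  for (u in 1:6) sp[[u]] <- c(10.01 + u * 0.002, 20.01 + u * 0.002)
  for (u in 7:12) sp[[u]] <- 30.01 + (u - 6) * 0.002
  s <- stationary_session(sp, t_end = 40)
  ev <- data.frame(event = 1:3, t_start = c(10, 20, 30), t_end = c(10.2, 20.2, 30.2),
                   trial = c(1L, 1L, 1L))
  ec <- ensemble_correlations(s, ev)
  expect_equal(ec$event_cor[1, 2], 1, tolerance = 1e-12)
  expect_lte(ec$event_cor[1, 3], 0)
  expect_error(ensemble_correlations(s, ev[1, ]), "at least 2")
})
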