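mz <- make_maze()

test_that("rate maps are occupancy-normalized and mass-conserving", {
  s <- fix_small()
  binning <- make_binning(s$maze, 2)
  ss <- ratemap_suffstats(s, binning)
  rms <- rate_map_set(ss)
  expect_true(all(rms$rate >= 0, na.rm = TRUE))
  # integrating rate x occupancy recovers the assigned spike count (< 5%)
  tot_assigned <- sum(rms$counts)
  integ <- sum(sweep(rms$rate, 2, rms$smoothed_occ, "*"), na.rm = TRUE)
  expect_lt(abs(integ - tot_assigned) / tot_assigned, 0.05)
})

test_that("zero spikes give an all-zero map; uniform firing a flat map", {
  s <- fix_small()
  s0 <- s
  s0$spikes[[1]] <- numeric(0)
  rm0 <- compute_rate_map(s0, 1)
  expect_true(all(rm0$rate == 0, na.rm = TRUE))

  set.seed(8)
  s5 <- s
  s5$spikes[[2]] <- sort(stats::runif(round(5 * max(s$position$t)), 0,
                                      max(s$position$t)))
  rm5 <- compute_rate_map(s5, 2)
  occ_ok <- !is.na(rm5$rate) & rm5$occ > 1
  expect_lt(abs(mean(rm5$rate[occ_ok]) - 5), 1.2)
})

test_that("field detection finds constructed bumps and rejects flat maps", {
  binning <- make_binning(mz, 2)
  ns <- nrow(binning$states)
  mk_rms <- function(r) {
    structure(list(rate = matrix(r, 1), occ = rep(1, ns), smoothed_occ = rep(1, ns),
                   mask = rep(FALSE, ns), binning = binning,
                   counts = matrix(0, 1, ns), sigma_bins = 0),
              class = "rate_map_set")
  }
  idx <- which(binning$states$path == "S-C1")
  ctr <- binning$states$center[idx]

  flat <- rep(0.3, ns)
  expect_equal(nrow(detect_fields(mk_rms(flat), 1)), 0L)

  bump <- rep(0, ns)
  bump[idx] <- 10 * exp(-(ctr - 30)^2 / (2 * 36))
  f1 <- detect_fields(mk_rms(bump), 1, peak_floor = 1, frac = 0.2)
  expect_equal(nrow(f1), 1L)
  expect_lt(abs(f1$peak_pos - 30), 2.1)

  two <- rep(0, ns)
  two[idx] <- 10 * exp(-(ctr - 15)^2 / 32) + 8 * exp(-(ctr - 45)^2 / 32)
  f2 <- detect_fields(mk_rms(two), 1, peak_floor = 1, frac = 0.2)
  expect_equal(nrow(f2), 2L)

  # diffuse whole-path firing is not a field
  wide <- rep(0, ns); wide[idx] <- 3
  expect_equal(nrow(detect_fields(mk_rms(wide), 1, peak_floor = 1)), 0L)
})

test_that("stable units' detected peaks sit at the programmed centers", {
  s <- fix50()
  binning <- make_binning(s$maze, 2)
  ss <- ratemap_suffstats(s, binning)
  rms <- rate_map_set(ss)
  tun <- s$ground_truth$tuning
  st_units <- tun$unit[tun$type == "stable"][1:5]
  for (u in st_units) {
    f <- detect_fields(rms, u)
    f <- f[f$path == tun$path[tun$unit == u], ]
    if (!nrow(f)) next
    err <- min(abs(f$peak_pos - tun$center[tun$unit == u]))
    expect_lte(err, 2 * binning$bin_cm + 2)
  }
})

test_that("joint classification covers stable/context/on/off and errors", {
  fa <- data.frame(unit = 1, path = "S-C1", peak_rate = 8,
                   peak_pos = 40, start = 30, end = 50)
  fb <- fa
  jc <- joint_classify(fa, fb, mz)
  expect_equal(jc$pairs$label, "stable")
  expect_equal(jc$units$label, "stable")

  # 10 cm before C1 on S-C1 vs 10 cm before C2 on S-C2 -> context
  fb2 <- data.frame(unit = 1, path = "S-C2", peak_rate = 8,
                    peak_pos = path_length(mz, "S-C2") - 10,
                    start = 0, end = 0)
  fa2 <- data.frame(unit = 1, path = "S-C1", peak_rate = 8,
                    peak_pos = path_length(mz, "S-C1") - 10,
                    start = 0, end = 0)
  jc2 <- joint_classify(fa2, fb2, mz)
  expect_equal(jc2$pairs$label, "context")

  # field in phase A only -> off; B only -> on
  none <- fa[0, ]
  expect_equal(joint_classify(fa, none, mz)$units$label, "off")
  expect_equal(joint_classify(none, fb, mz)$units$label, "on")

  bad <- fa; bad$path <- "nonsense"
  expect_error(joint_classify(bad, fb, mz), "unknown path")
})

test_that("population vector matrix has unit diagonal and null off-diagonal", {
  binning <- make_binning(mz, 5)
  ns <- nrow(binning$states)
  set.seed(5)
  mk <- function() {
    structure(list(rate = matrix(stats::rexp(20 * ns), 20),
                   occ = rep(1, ns), smoothed_occ = rep(1, ns),
                   mask = rep(FALSE, ns), binning = binning,
                   counts = matrix(0, 20, ns), sigma_bins = 0),
              class = "rate_map_set")
  }
  pv <- population_vector_matrix(list(a = mk()))
  expect_equal(unname(diag(pv$cor)), rep(1, ns), tolerance = 1e-12)
  expect_true(isSymmetric(unname(pv$cor)))
  off <- pv$cor[upper.tri(pv$cor)]
  expect_lt(abs(mean(off, na.rm = TRUE)), 3 / sqrt(20))

  expect_error(population_vector_matrix(list(a = {
    r <- mk(); r$rate <- r$rate[1, , drop = FALSE]; r
  })), "2 units")
})
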