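mz <- make_maze()

test_that("discretize_trajectory collapses duplicates and annotates visits", {
  still <- data.frame(t = seq(0, 1, 0.02), x = 50, y = 50)
  d <- discretize_trajectory(still, mz)
  expect_length(d$cells, 1L)

  run <- data.frame(t = seq(0, 4, 0.02), x = 50,
                    y = seq(11, 89, length.out = 201))
  d2 <- discretize_trajectory(run, mz)
  expect_length(d2$cells, 5L)  # one lattice column, five cells

  expect_error(discretize_trajectory(still[1, ], mz), "2 position")
})

test_that("pre-phase trials visit S, C1, G in order", {
  s <- fix_small()
  tr <- s$trials[1, ]
  p <- s$position[s$position$t >= tr$t_start & s$position$t < tr$t_end, ]
  d <- discretize_trajectory(p, mz)
  lm <- d$visits$landmark
  expect_equal(lm[seq_len(3)], c("S", "C1", "G"))
})

test_that("classify_paths labels canonical segments and the return leg", {
  # S -> C1 -> G -> (alleyway) -> S built from the path templates
  seqs <- rbind(path_point(mz, "S-C1", seq(0, path_length(mz, "S-C1"), 1)),
                path_point(mz, "C1-G", seq(0, path_length(mz, "C1-G"), 1)),
                path_point(mz, "return", seq(0, path_length(mz, "return"), 1)))
  pos <- data.frame(t = seq_len(nrow(seqs)) * 0.02, x = seqs[, 1], y = seqs[, 2])
  seg <- classify_paths(discretize_trajectory(pos, mz), mz)
  expect_equal(seg$label, c("S-C1", "C1-G", "return"))

  # S -> C2 -> G
  seqs2 <- rbind(path_point(mz, "S-C2", seq(0, path_length(mz, "S-C2"), 1)),
                 path_point(mz, "C2-G", seq(0, path_length(mz, "C2-G"), 1)))
  pos2 <- data.frame(t = seq_len(nrow(seqs2)) * 0.02, x = seqs2[, 1], y = seqs2[, 2])
  seg2 <- classify_paths(discretize_trajectory(pos2, mz), mz)
  expect_equal(seg2$label, c("S-C2", "C2-G"))

  # S -> G directly through the field: not among the five named paths
  direct <- data.frame(t = seq(0, 6, 0.02),
                       x = 50, y = seq(-10, 110, length.out = 301))
  seg3 <- classify_paths(discretize_trajectory(direct, mz), mz)
  expect_equal(unique(seg3$label), "other")
})

test_that("learning_point handles step input, null case and edge errors", {
  eff_lab <- list(c("S-C2", "C2-G"))
  other_lab <- list(c("S-C1", "C1-G", "return"))
  labels <- c(rep(other_lab, 5), rep(eff_lab, 5))
  lc <- learning_point(labels, replacement_trial = 4, window = 5)
  expect_equal(lc$learning_point, 6L)  # first trial of the efficient block
  expect_true(all(lc$moving_average >= 0 & lc$moving_average <= 1))

  lc2 <- learning_point(rep(other_lab, 10), replacement_trial = 4, window = 5)
  expect_null(lc2$learning_point)

  expect_error(learning_point(labels, 4, window = 11), "window larger")
  expect_error(learning_point(labels, 4, window = 4), "odd")
})

test_that("trajectory_distance is a metric matching the brute-force oracle", {
  expect_equal(trajectory_distance(c("a", "b"), c("a", "b")), 0L)
  expect_equal(trajectory_distance(c("a", "b"), c("a", "x", "b")), 1L)
  expect_error(trajectory_distance(character(0), "a"), "nonempty")

  set.seed(42)
  alph <- letters[1:4]
  for (k in 1:40) {
    a <- sample(alph, sample(1:6, 1), replace = TRUE)
    b <- sample(alph, sample(1:6, 1), replace = TRUE)
    c_ <- sample(alph, sample(1:6, 1), replace = TRUE)
    dab <- trajectory_distance(a, b)
    expect_equal(dab, lev_recursive(a, b))
    expect_equal(dab, trajectory_distance(b, a))                       # symmetry
    expect_equal(dab, as.integer(utils::adist(paste(a, collapse = ""),
                                              paste(b, collapse = ""))))
    expect_lte(dab, trajectory_distance(a, c_) + trajectory_distance(c_, b))
    expect_true(dab >= 0)
    if (identical(a, b)) expect_equal(dab, 0L)
  }
})

test_that("prob_behavior_change covers degenerate and alternating cases", {
  lab_eff <- c("S-C2", "C2-G")
  same <- rep(list(c("a", "b", "c")), 5)
  labs <- rep(list(lab_eff), 5)
  expect_equal(prob_behavior_change(same, labs), 0)

  alt <- rep(list(c("a", "b", "c"), c("x", "y", "z")), 3)
  expect_equal(prob_behavior_change(alt, rep(list(lab_eff), 6)), 1)

  expect_null(prob_behavior_change(same[1], labs[1]))
  expect_null(prob_behavior_change(same, rep(list(c("S-C1")), 5)))
})

test_that("path proportions sum to one and named paths dominate", {
  s <- fix_small()
  ts <- trial_summaries(s)
  pr <- path_proportions(ts$labels)
  expect_equal(sum(pr), 1)
  five <- sum(pr[c("S-C1", "C1-G", "G-C2", "S-C2", "C2-G")])
  expect_gt(five / (five + pr[["other"]]), 0.9)
  # string length equals the path-string length by construction
  expect_true(all(ts$summary$string_length ==
                    vapply(ts$cells, length, integer(1))))
})

test_that("learning point recovered on the synthetic session", {
  s <- fix_small()
  ts <- trial_summaries(s)
  lc <- learning_point(ts$labels, s$ground_truth$reward_replacement_trial)
  expect_false(is.null(lc$learning_point))
  expect_lte(abs(lc$learning_point - s$ground_truth$learning_point_trial), 3)
})
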