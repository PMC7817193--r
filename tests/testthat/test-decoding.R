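mk_enc <- function(lambda, centers = NULL, path = "S-C1") {
  ns <- ncol(lambda)
  if (is.null(centers)) centers <- seq_len(ns) * 2 - 1
  list(lambda = lambda,
       states = data.frame(path = path, bin = seq_len(ns), center = centers,
                           state = seq_len(ns)),
       eps = 0, bin_cm = 2)
}

test_that("decode reproduces the closed-form two-state example", {
  # one unit, lambda = (1, 3) Hz, tau = 0.5 s, n = 2, flat prior:
  # P(2)/P(1) = (3/1)^2 * exp(-0.5 * (3 - 1)) = 9 * exp(-1)
  enc <- mk_enc(matrix(c(1, 3), 1))
  dp <- decode(matrix(2L, 1, 1), enc, tau = 0.5)
  ratio <- 9 * exp(-1)
  expect_equal(unname(dp$posterior[1, 2]), ratio / (1 + ratio), tolerance = 1e-12)
  # independent arithmetic for the printed value
  expect_equal(ratio / (1 + ratio), 0.7680307, tolerance = 1e-6)
})

test_that("zero spikes with equal total rates give a uniform posterior", {
  enc <- mk_enc(matrix(c(1, 3, 3, 1), 2))  # colSums equal
  dp <- decode(matrix(0L, 2, 1), enc, tau = 0.1)
  expect_equal(unname(dp$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("flat likelihood returns the prior; zero-rate state gets zero mass", {
  enc <- mk_enc(matrix(1, 1, 4))
  prior <- c(0.4, 0.3, 0.2, 0.1)
  dp <- decode(matrix(3L, 1, 1), enc, tau = 0.2, prior = prior)
  expect_equal(unname(dp$posterior[1, ]), prior, tolerance = 1e-12)

  enc0 <- mk_enc(matrix(c(0, 2), 1))  # true zero rate, no floor
  dp0 <- decode(matrix(1L, 1, 1), enc0, tau = 0.1)
  expect_equal(unname(dp0$posterior[1, 1]), 0)
})

test_that("log-space decoding equals direct computation on small instances", {
  set.seed(2)
  for (k in 1:20) {
    lam <- matrix(stats::rexp(3 * 5, 0.2), 3, 5)
    n <- matrix(stats::rpois(3, 2), 3, 1)
    tau <- stats::runif(1, 0.05, 0.5)
    dp <- decode(n, mk_enc(lam), tau = tau)
    direct <- apply(lam, 2, function(l) prod(l^n[, 1])) * exp(-tau * colSums(lam))
    direct <- direct / sum(direct)
    expect_equal(unname(dp$posterior[1, ]), unname(direct), tolerance = 1e-9)
  }
})

test_that("decode validates inputs and fit_encoder guards degenerate maps", {
  enc <- mk_enc(matrix(1, 1, 2))
  expect_error(decode(matrix(-1L, 1, 1), enc, tau = 0.1), "non-negative")
  expect_error(decode(matrix(1L, 1, 1), enc, tau = 0), "tau > 0")

  s <- fix_small()
  ss <- ratemap_suffstats(s, make_binning(s$maze, 5))
  rms <- rate_map_set(ss)
  rms$mask[] <- TRUE
  expect_error(fit_encoder(rms), "all states masked")
})

test_that("encoder matches generative tuning within Monte-Carlo error", {
  s <- fix50()
  enc <- fixture("fix50_enc", function() {
    fit_encoder(rate_map_set(ratemap_suffstats(s, make_binning(s$maze, 2))))
  })
  tun <- s$ground_truth$tuning
  st <- tun[tun$type == "stable", ][1:4, ]
  for (i in seq_len(nrow(st))) {
    sel <- enc$states$path == st$path[i] &
      abs(enc$states$center - st$center[i]) < 4
    if (!any(sel)) next
    lam_hat <- max(enc$lambda[st$unit[i], sel])
    expect_gt(lam_hat, 0.4 * st$peak[i])
    expect_lt(lam_hat, 1.6 * st$peak[i])
  }
})

test_that("decoding error shrinks as the population grows", {
  s <- fix50()
  sub <- function(n) {
    s2 <- s
    s2$spikes <- s$spikes[seq_len(n)]
    s2
  }
  e10 <- loo_position_error(sub(10), bin_s = 0.2, bin_cm = 5)$median_cm
  e40 <- loo_position_error(sub(40), bin_s = 0.2, bin_cm = 5)$median_cm
  expect_lt(e40, e10)
})
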