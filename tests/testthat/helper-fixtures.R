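# Shared lazily-built fixtures, cached for the whole test run. Everything is
# generated in code (no stored data); seeds are fixed so results are frozen.

rk_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(rk_cache[[name]])) assign(name, build(), envir = rk_cache)
  get(name, envir = rk_cache)
}

# small spike-only session for module tests
fix_small <- function() fixture("small", function() {
  simulate_session(seed = 3, n_units = 30,
                   n_trials = c(pre = 4, learning = 6, post = 4), lfp = FALSE)
})

# small session with LFP for SWR/theta tests
fix_lfp <- function() fixture("lfp", function() {
  simulate_session(seed = 5, n_units = 25,
                   n_trials = c(pre = 4, learning = 5, post = 4), lfp = TRUE)
})

# the 50-unit session at the task's stated trial schedule (decoder +
# classification criteria)
fix50 <- function() fixture("fix50", function() {
  simulate_session(seed = 1, n_units = 50, lfp = FALSE)
})

fix_small_enc <- function() fixture("small_enc", function() {
  s <- fix_small()
  ss <- ratemap_suffstats(s, make_binning(s$maze, 5))
  fit_encoder(rate_map_set(ss))
})

# clean-replay fixture: 30 units tiling S-C2, 100 scheduled events
# (alternating reverse/forward), injected with full participation
fix_clean <- function() fixture("clean", function() {
  mz <- make_maze()
  beh <- simulate_behavior(mz, n_trials = c(4, 6, 14), seed = 21)
  L <- path_length(mz, "S-C2")
  tun <- data.frame(unit = 1:30, type = "stable", group = NA_character_,
                    path = "S-C2", center = seq(0.04, 0.96, length.out = 30) * L,
                    sigma = 8, peak = 15)
  class(tun) <- c("tuning_spec", "data.frame")
  spk <- simulate_spikes(beh, tun, mz, seed = 22)
  pz <- beh$pauses
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(pz))) for (off in c(0.12, 0.55, 1.0)) {
    if (k >= 100L) break
    if (pz$t_start[i] + off + 0.32 > pz$t_end[i] - 0.05) next
    k <- k + 1L
    rows[[k]] <- data.frame(
      trial = pz$trial[i], phase = "x", window = "x", area = pz$area[i],
      t_start = pz$t_start[i] + off, duration = 0.25, path = "S-C2",
      direction = if (k %% 2L == 0L) "forward" else "reverse")
  }
  sched <- cbind(event = seq_len(k), do.call(rbind, rows))
  sched$t_end <- sched$t_start + sched$duration
  inj <- simulate_lfp_and_replays(beh, spk,
                                  sched[, setdiff(names(sched), "t_end")],
                                  mz, seed = 23, lfp = FALSE, p_participate = 1)
  session <- structure(list(maze = mz, position = beh$position,
                            trials = beh$trials, spikes = inj$spikes,
                            lfp = NULL,
                            ground_truth = list(tuning = tun)),
                       class = "rk_session")
  enc <- fit_encoder(rate_map_set(ratemap_suffstats(session, make_binning(mz, 5))))
  list(session = session, sched = sched, enc = enc)
})

# time-mirror every scheduled event's spikes within its window
mirror_events <- function(session, sched) {
  s2 <- session
  for (e in seq_len(nrow(sched))) {
    t0 <- sched$t_start[e]; t1 <- sched$t_end[e]
    s2$spikes <- lapply(s2$spikes, function(sp) {
      inw <- sp >= t0 & sp <= t1
      sp[inw] <- t0 + t1 - sp[inw]
      sort(sp)
    })
  }
  s2
}

# independent oracles -------------------------------------------------------

# brute-force recursive Levenshtein (exponential; strings <= 6 only)
lev_recursive <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(lev_recursive(a[-1], b) + 1L,
      lev_recursive(a, b[-1]) + 1L,
      lev_recursive(a[-1], b[-1]) + (a[1] != b[1]))
}

# brute-force weighted correlation by explicit loops
wcorr_brute <- function(P, tvals = seq_len(nrow(P)), xvals = seq_len(ncol(P))) {
  W <- 0; st <- 0; sx <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    W <- W + P[i, j]; st <- st + P[i, j] * tvals[i]; sx <- sx + P[i, j] * xvals[j]
  }
  mt <- st / W; mx <- sx / W
  ctx <- 0; ctt <- 0; cxx <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    ctx <- ctx + P[i, j] * (tvals[i] - mt) * (xvals[j] - mx)
    ctt <- ctt + P[i, j] * (tvals[i] - mt)^2
    cxx <- cxx + P[i, j] * (xvals[j] - mx)^2
  }
  ctx / sqrt(ctt * cxx)
}

# decoded_posterior stub from an explicit posterior matrix
make_dp <- function(post, states, n_spikes = NULL) {
  structure(list(posterior = post, states = states, tau = 0.02,
                 map_state = apply(post, 1, which.max),
                 n_spikes = n_spikes),
            class = "decoded_posterior")
}

# equal-size 5-path state table (spec's symmetric-reprate example)
eq_states <- function(nbins = 10L) {
  paths <- c("S-C1", "C1-G", "G-C2", "S-C2", "C2-G")
  st <- do.call(rbind, lapply(paths, function(p)
    data.frame(path = p, bin = seq_len(nbins),
               center = seq_len(nbins) * 2 - 1)))
  st$state <- seq_len(nrow(st))
  st
}
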