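#' Simulate task behavior on the lattice maze
#'
#' Generates position samples for a full session with three learning phases:
#' \describe{
#'   \item{pre}{reward at C1; trials traverse S-C1, C1-G, then the return
#'     alleyway.}
#'   \item{learning}{reward relocated to C2; trial-and-error trials traverse
#'     S-C1, C1-G, G-C2, C2-G, return (the animal still visits C1 first,
#'     finds no reward, and reaches C2 via the goal).}
#'   \item{post}{the efficient strategy S-C2, C2-G, return.}
#' }
#' The ground-truth learning point is the first post-phase trial (the switch
#' to the efficient trajectory). The reward-replacement trial is the first
#' learning-phase trial.
#'
#' Running speed is constant per path traversal with lognormal jitter across
#' traversals; immobility pauses (lognormal duration, configurable median)
#' are inserted at the start box, at each visited checkpoint, and at the
#' goal — the locations where synchronous events occur.
#'
#' @param maze a `maze_spec` from [make_maze()].
#' @param n_trials named or positional integer vector `c(pre, learning, post)`,
#'   each >= 3.
#' @param seed integer RNG seed; identical seeds give identical sessions.
#' @param run_speed nominal running speed, cm/s.
#' @param speed_sdlog lognormal sd of the per-traversal speed factor.
#' @param fs_pos position sampling rate, Hz.
#' @param pause_median median immobility pause duration, s.
#' @param pause_sdlog lognormal sd of pause durations.
#' @param pos_noise sd of Gaussian position measurement noise, cm.
#' @return list with elements
#'   `position` (t, x, y — the measured stream),
#'   `trials` (trial, t_start, t_end, phase),
#'   `samples` (ground-truth per-sample state: t, x, y, trial, path, lin,
#'    running, area),
#'   `segments` (trial, path, t_start, t_end — ground-truth traversals),
#'   `pauses` (trial, area, t_start, t_end),
#'   `ground_truth` (phase_of_trial, learning_point_trial,
#'    reward_replacement_trial).
#' @export
simulate_behavior <- function(maze, n_trials = c(pre = 12L, learning = 26L, post = 12L),
                              seed = 1L, run_speed = 25, speed_sdlog = 0.08,
                              fs_pos = 50, pause_median = 3, pause_sdlog = 0.4,
                              pos_noise = 0.5) {
  stopifnot(inherits(maze, "maze_spec"))
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 3L) stop("n_trials must have 3 elements (pre, learning, post)")
  if (any(n_trials < 3L)) stop("need at least 3 trials per phase")
  set.seed(as.integer(seed))

  phase_of_trial <- rep(c("pre", "learning", "post"), n_trials)
  n_tot <- sum(n_trials)
  routes <- list(
    pre      = c("S-C1", "C1-G", "return"),
    learning = c("S-C1", "C1-G", "G-C2", "C2-G", "return"),
    post     = c("S-C2", "C2-G", "return")
  )
  pause_area_after <- c("S-C1" = "c1", "C1-G" = "goal", "G-C2" = "c2",
                        "C2-G" = "goal", "S-C2" = "c2", "return" = "start")

  dt <- 1 / fs_pos
  t_cur <- 0
  seg_rows <- list(); pause_rows <- list(); trial_rows <- list()
  smp <- list()

  emit_pause <- function(trial, area, xy, dur) {
    n <- max(2L, round(dur * fs_pos))
    tt <- t_cur + seq_len(n) * dt
    data.frame(t = tt, x = xy[1], y = xy[2], trial = trial,
               path = NA_character_, lin = NA_real_, running = FALSE, area = area)
  }

  for (tr in seq_len(n_tot)) {
    phase <- phase_of_trial[tr]
    t_trial_start <- t_cur
    # pause in the start box before running
    dur <- max(1, stats::rlnorm(1, log(pause_median), pause_sdlog))
    p <- emit_pause(tr, "start", maze$s_anchor, dur)
    smp[[length(smp) + 1L]] <- p
    pause_rows[[length(pause_rows) + 1L]] <-
      data.frame(trial = tr, area = "start", t_start = t_cur, t_end = t_cur + nrow(p) * dt)
    t_cur <- t_cur + nrow(p) * dt

    for (pth in routes[[phase]]) {
      L <- maze$paths[[pth]]$length
      v <- run_speed * stats::rlnorm(1, 0, speed_sdlog)
      n <- max(2L, ceiling(L / v * fs_pos))
      s <- seq_len(n) / n * L
      xy <- path_point(maze, pth, s)
      tt <- t_cur + seq_len(n) * dt
      smp[[length(smp) + 1L]] <- data.frame(
        t = tt, x = xy[, 1], y = xy[, 2], trial = tr,
        path = pth, lin = s, running = TRUE, area = NA_character_)
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(trial = tr, path = pth, t_start = t_cur, t_end = t_cur + n * dt)
      t_cur <- t_cur + n * dt
      # arrival pause (not after the return leg's S arrival: next trial's
      # start pause covers it)
      if (pth != "return") {
        area <- pause_area_after[[pth]]
        anchor <- switch(area, c1 = maze$c1_xy, c2 = maze$c2_xy,
                         goal = maze$g_anchor, start = maze$s_anchor)
        dur <- max(1, stats::rlnorm(1, log(pause_median), pause_sdlog))
        p <- emit_pause(tr, area, anchor, dur)
        smp[[length(smp) + 1L]] <- p
        pause_rows[[length(pause_rows) + 1L]] <-
          data.frame(trial = tr, area = area, t_start = t_cur, t_end = t_cur + nrow(p) * dt)
        t_cur <- t_cur + nrow(p) * dt
      }
    }
    trial_rows[[length(trial_rows) + 1L]] <-
      data.frame(trial = tr, t_start = t_trial_start, t_end = t_cur, phase = phase)
  }

  samples <- do.call(rbind, smp)
  rownames(samples) <- NULL
  noise <- matrix(stats::rnorm(2L * nrow(samples), 0, pos_noise), ncol = 2)
  position <- data.frame(t = samples$t,
                         x = samples$x + noise[, 1],
                         y = samples$y + noise[, 2])

  list(
    position = position,
    trials = do.call(rbind, trial_rows),
    samples = samples,
    segments = do.call(rbind, seg_rows),
    pauses = do.call(rbind, pause_rows),
    ground_truth = list(
      phase_of_trial = phase_of_trial,
      reward_replacement_trial = n_trials[1] + 1L,
      learning_point_trial = n_trials[1] + n_trials[2] + 1L
    )
  )
}

#' Running speed from a position stream
#'
#' Positions are boxcar-smoothed before differentiation and the central
#' difference is taken over `lag` samples on each side, so that tracking
#' noise (sub-cm jitter at 50 Hz) does not masquerade as running; the
#' standard preprocessing for immobility gating.
#' @param position data.frame with columns t, x, y.
#' @param smooth_bins boxcar width (samples) applied to x and y.
#' @param lag half-width (samples) of the central difference.
#' @return numeric vector of speeds (cm/s), same length as the stream.
#' @export
position_speed <- function(position, smooth_bins = 5L, lag = 5L) {
  t <- position$t; x <- position$x; y <- position$y
  n <- length(t)
  if (n < 2L * lag + 1L) return(rep(0, n))
  if (smooth_bins > 1L) {
    k <- rep(1 / smooth_bins, smooth_bins)
    sm <- function(v) {
      out <- as.numeric(stats::filter(v, k, sides = 2))
      out[is.na(out)] <- v[is.na(out)]
      out
    }
    x <- sm(x); y <- sm(y)
  }
  v <- numeric(n)
  i <- (lag + 1L):(n - lag)
  dtc <- t[i + lag] - t[i - lag]
  v[i] <- sqrt((x[i + lag] - x[i - lag])^2 + (y[i + lag] - y[i - lag])^2) / dtc
  v[seq_len(lag)] <- v[lag + 1L]
  v[(n - lag + 1L):n] <- v[n - lag]
  pmax(v, 0)
}
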