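#' Draw a phase-dependent replay schedule for a simulated session
#'
#' Events are placed inside immobility pauses (where synchronous events
#' occur) as a Poisson process at a phase-dependent rate. Each event gets a
#' path whose distribution depends on the phase window: in the pre phase the
#' experienced paths (S-C1, C1-G, return) dominate; in the first two thirds
#' of the learning phase the trial-and-error paths G-C2/C2-G dominate; in
#' the last third the majority content switches to the never-yet-exploited
#' efficient path S-C2; after learning S-C2/C2-G dominate. Direction is
#' forward/reverse with equal probability.
#'
#' @param behavior output of [simulate_behavior()].
#' @param maze the `maze_spec`.
#' @param rates events per second of immobility per phase,
#'   `c(pre, learning, post)`.
#' @param content optional named list of path-probability vectors for windows
#'   `pre, learn1, learn2, learn3, post` (defaults as described).
#' @param run_speed,compression nominal running speed (cm/s) and replay time
#'   compression factor; event duration = path length / (speed * compression),
#'   clamped to `[0.06, 0.4]` s.
#' @param p_forward probability of forward direction.
#' @param seed integer seed.
#' @return data.frame: event, trial, phase, window, area, t_start, duration,
#'   path, direction.
#' @export
make_replay_schedule <- function(behavior, maze,
                                 rates = c(pre = 0.15, learning = 0.35, post = 0.30),
                                 content = NULL, run_speed = 25, compression = 15,
                                 p_forward = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  labs <- path_labels()
  default_content <- list(
    pre    = c("S-C1" = .30, "C1-G" = .30, "G-C2" = .05, "S-C2" = .05, "C2-G" = .05, "return" = .25),
    learn1 = c("S-C1" = .10, "C1-G" = .10, "G-C2" = .30, "S-C2" = .10, "C2-G" = .30, "return" = .10),
    learn2 = c("S-C1" = .10, "C1-G" = .10, "G-C2" = .30, "S-C2" = .10, "C2-G" = .30, "return" = .10),
    learn3 = c("S-C1" = .08, "C1-G" = .09, "G-C2" = .15, "S-C2" = .45, "C2-G" = .15, "return" = .08),
    post   = c("S-C1" = .08, "C1-G" = .09, "G-C2" = .15, "S-C2" = .30, "C2-G" = .30, "return" = .08)
  )
  if (is.null(content)) content <- default_content
  stopifnot(all(vapply(content, function(p) all(labs %in% names(p)), logical(1))))

  phase_of_trial <- behavior$ground_truth$phase_of_trial
  lt <- which(phase_of_trial == "learning")
  third_of <- function(tr) {
    k <- findInterval(match(tr, lt) - 1L, length(lt) * c(1, 2) / 3) + 1L
    paste0("learn", pmin(k, 3L))
  }
  pauses <- behavior$pauses
  rows <- list()
  for (i in seq_len(nrow(pauses))) {
    pz <- pauses[i, ]
    phase <- phase_of_trial[pz$trial]
    window <- if (phase == "learning") third_of(pz$trial) else phase
    avail <- pz$t_end - pz$t_start - 0.3
    if (avail <= 0.1) next
    n_ev <- stats::rpois(1, rates[[phase]] * avail)
    if (n_ev == 0L) next
    tt <- sort(stats::runif(n_ev, pz$t_start + 0.15, pz$t_end - 0.15))
    if (n_ev > 1L) tt <- tt[c(TRUE, diff(tt) >= 0.45)]
    pr <- content[[window]][labs]
    for (t0 in tt) {
      pth <- sample(labs, 1, prob = pr)
      dur <- min(max(path_length(maze, pth) / (run_speed * compression), 0.06), 0.4)
      if (t0 + dur > pz$t_end - 0.05) next
      rows[[length(rows) + 1L]] <- data.frame(
        trial = pz$trial, phase = phase, window = window, area = pz$area,
        t_start = t0, duration = dur, path = pth,
        direction = if (stats::runif(1) < p_forward) "forward" else "reverse")
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial = integer(), phase = character(), window = character(),
                      area = character(), t_start = numeric(), duration = numeric(),
                      path = character(), direction = character())
  } else {
    out <- out[order(out$t_start), ]
  }
  out <- cbind(event = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Synthesize LFP and inject time-compressed replay spike sequences
#'
#' The LFP is 1/f (pink) background noise plus a theta oscillation gated by
#' running, plus a Hann-windowed ripple-band oscillation burst at each
#' scheduled event. For each scheduled replay, units with a field on the
#' event's path emit spikes ordered by their field positions, linearly
#' time-compressed into the event window (reversed order for
#' direction = "reverse"), with small Gaussian jitter.
#'
#' @param behavior output of [simulate_behavior()].
#' @param spk output of [simulate_spikes()].
#' @param schedule data.frame from [make_replay_schedule()]; every event must
#'   lie within an immobility pause.
#' @param maze the `maze_spec`.
#' @param fs_lfp LFP sampling rate, Hz (>= 1000).
#' @param theta_freq,theta_amp theta component frequency (Hz) and amplitude
#'   (in background-sd units).
#' @param ripple_freq ripple burst center frequency, Hz (150-250).
#' @param ripple_amp ripple burst amplitude (background-sd units).
#' @param p_participate per-unit probability of joining an event it has a
#'   field for.
#' @param spike_jitter sd of spike-time jitter within events, s.
#' @param seed integer seed.
#' @return list with `lfp` (data.frame t, v), `spikes` (per-unit vectors with
#'   replay spikes merged in), and `events` (the schedule augmented with
#'   per-event participant counts).
#' @export
simulate_lfp_and_replays <- function(behavior, spk, schedule, maze,
                                     fs_lfp = 1250, theta_freq = 8, theta_amp = 1.2,
                                     ripple_freq = 200, ripple_amp = 3,
                                     p_participate = 0.9, spike_jitter = 0.008,
                                     seed = 1L, lfp = TRUE) {
  set.seed(as.integer(seed))
  stopifnot(ripple_freq >= 150, ripple_freq <= 250)
  pauses <- behavior$pauses
  if (nrow(schedule) > 0) {
    ok <- vapply(seq_len(nrow(schedule)), function(i) {
      any(schedule$t_start[i] >= pauses$t_start &
            schedule$t_start[i] + schedule$duration[i] <= pauses$t_end)
    }, logical(1))
    if (!all(ok)) stop("replay schedule outside immobility pauses")
  }

  phase_of_trial <- behavior$ground_truth$phase_of_trial
  tuning <- spk$tuning
  spikes <- spk$spikes
  n_part <- integer(nrow(schedule))

  for (e in seq_len(nrow(schedule))) {
    ev <- schedule[e, ]
    L <- path_length(maze, ev$path)
    phase <- phase_of_trial[ev$trial]
    for (i in seq_len(nrow(tuning))) {
      flds <- unit_fields(tuning[i, ], maze, phase)
      f <- flds[flds$path == ev$path, ]
      if (nrow(f) == 0L || stats::runif(1) > p_participate) next
      frac <- min(max(f$center[1] / L, 0.02), 0.98)
      if (ev$direction == "reverse") frac <- 1 - frac
      tspk <- ev$t_start + frac * ev$duration + stats::rnorm(1, 0, spike_jitter)
      tspk <- min(max(tspk, ev$t_start), ev$t_start + ev$duration)
      add <- tspk
      if (stats::runif(1) < 0.3) add <- c(add, min(tspk + 0.006, ev$t_start + ev$duration))
      spikes[[i]] <- c(spikes[[i]], add)
      n_part[e] <- n_part[e] + 1L
    }
  }
  spikes <- lapply(spikes, function(s) {
    s <- sort(s)
    if (length(s) > 1L) s <- s[c(TRUE, diff(s) >= 0.002)]
    s
  })

  lfp_df <- NULL
  if (isTRUE(lfp)) {
    t_end <- max(behavior$samples$t)
    n <- ceiling(t_end * fs_lfp)
    v <- pink_noise(n)
    tt <- seq_len(n) / fs_lfp
    # theta during running
    run_gate <- stats::approx(behavior$samples$t, as.numeric(behavior$samples$running),
                              xout = tt, method = "constant", rule = 2)$y
    v <- v + theta_amp * run_gate * sin(2 * pi * theta_freq * tt)
    for (e in seq_len(nrow(schedule))) {
      ev <- schedule[e, ]
      idx <- which(tt >= ev$t_start & tt <= ev$t_start + ev$duration)
      if (!length(idx)) next
      ph <- 2 * pi * ripple_freq * (tt[idx] - ev$t_start)
      win <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1)))
      v[idx] <- v[idx] + ripple_amp * win * sin(ph)
    }
    keep <- tt <= t_end
    lfp_df <- data.frame(t = tt[keep], v = v[keep])
    attr(lfp_df, "fs") <- fs_lfp
  }

  events <- schedule
  events$n_participants <- n_part
  list(lfp = lfp_df, spikes = spikes, events = events)
}

#' 1/f ("pink") noise via spectral shaping, unit variance
#' @param n number of samples.
#' @return numeric vector.
#' @keywords internal
pink_noise <- function(n) {
  N <- stats::nextn(n, c(2, 3, 5))   # composite padding keeps the FFT fast
  w <- stats::rnorm(N)
  W <- stats::fft(w)
  f <- c(1, seq_len(N - 1))
  f <- pmin(f, N - f + 1)            # two-sided frequency index
  W <- W / sqrt(f)
  v <- Re(stats::fft(W, inverse = TRUE)) / N
  as.numeric(scale(v[seq_len(n)]))
}
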