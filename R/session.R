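#' Simulate a complete ground-truth-annotated recording session
#'
#' Convenience wrapper chaining [make_maze()], [simulate_behavior()],
#' [make_tuning()], [simulate_spikes()], [make_replay_schedule()] and
#' [simulate_lfp_and_replays()]. All sub-generator seeds are derived
#' deterministically from `seed`, so identical seeds give identical
#' sessions.
#'
#' @param seed master integer seed.
#' @param n_units number of units.
#' @param n_trials `c(pre, learning, post)` trial counts.
#' @param maze optional `maze_spec` (default [make_maze()]).
#' @param lfp logical; set `FALSE` to skip LFP synthesis (faster when only
#'   spike-based analyses are needed).
#' @param tuning optional pre-built `tuning_spec`.
#' @param schedule optional pre-built replay schedule.
#' @param ... passed to [simulate_spikes()] (e.g. `precess = FALSE`).
#' @return object of class `rk_session`: maze, position, trials, spikes
#'   (list per unit), lfp (or NULL), and `ground_truth` (tuning, samples,
#'   segments, pauses, events, phase_of_trial, learning_point_trial,
#'   reward_replacement_trial).
#' @export
simulate_session <- function(seed = 1L, n_units = 50L,
                             n_trials = c(pre = 12L, learning = 26L, post = 12L),
                             maze = make_maze(), lfp = TRUE,
                             tuning = NULL, schedule = NULL,
                             rates = c(pre = 0.15, learning = 0.35, post = 0.30),
                             content = NULL, ...) {
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 5L)
  beh <- simulate_behavior(maze, n_trials = n_trials, seed = sub[1])
  if (is.null(tuning)) tuning <- make_tuning(maze, n_units = n_units, seed = sub[2])
  spk <- simulate_spikes(beh, tuning, maze, seed = sub[3], ...)
  if (is.null(schedule))
    schedule <- make_replay_schedule(beh, maze, rates = rates, content = content,
                                     seed = sub[4])
  inj <- simulate_lfp_and_replays(beh, spk, schedule, maze, seed = sub[5], lfp = lfp)

  structure(list(
    maze = maze,
    position = beh$position,
    trials = beh$trials,
    spikes = inj$spikes,
    lfp = inj$lfp,
    ground_truth = list(
      tuning = tuning,
      samples = beh$samples,
      segments = beh$segments,
      pauses = beh$pauses,
      events = inj$events,
      phase_of_trial = beh$ground_truth$phase_of_trial,
      reward_replacement_trial = beh$ground_truth$reward_replacement_trial,
      learning_point_trial = beh$ground_truth$learning_point_trial,
      theta = spk$theta
    )
  ), class = "rk_session")
}

#' @export
print.rk_session <- function(x, ...) {
  cat(sprintf("<rk_session> %d units, %d trials (%s), %.0f s, %d injected events, LFP: %s\n",
              length(x$spikes), nrow(x$trials),
              paste(table(factor(x$trials$phase, c("pre", "learning", "post"))), collapse = "/"),
              max(x$position$t), nrow(x$ground_truth$events),
              if (is.null(x$lfp)) "no" else "yes"))
  invisible(x)
}
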