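#' Discretize a trajectory into a lattice-cell path string
#'
#' Maps each position sample to a symbolic cell code — `"S"` (start box),
#' `"G"` (goal box), `"A"` (alleyway), or `"L<i>"` for lattice cell `i` —
#' and collapses consecutive duplicates. Landmark visits (S, G, C1, C2) are
#' annotated with their entry times.
#'
#' @param position data.frame t, x, y for one trial.
#' @param maze a `maze_spec`.
#' @return list with `cells` (character path string), `cell_t` (entry time
#'   per string element), and `visits` (data.frame landmark, t).
#' @export
discretize_trajectory <- function(position, maze) {
  if (nrow(position) < 2L) stop("need at least 2 position samples")
  reg <- region_of(maze, position$x, position$y)
  idx <- lattice_cell_index(maze, position$x, position$y)
  code <- ifelse(reg == "start", "S",
          ifelse(reg == "goal", "G",
          ifelse(reg == "alleyway", "A", paste0("L", idx))))
  r <- rle(code)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  cells <- r$values
  cell_t <- position$t[starts]

  c1code <- paste0("L", (maze$c1_cell[1] - 1L) * maze$lattice_rows + maze$c1_cell[2])
  c2code <- paste0("L", (maze$c2_cell[1] - 1L) * maze$lattice_rows + maze$c2_cell[2])
  lm <- ifelse(cells == "S", "S",
        ifelse(cells == "G", "G",
        ifelse(cells == c1code, "C1",
        ifelse(cells == c2code, "C2", NA_character_))))
  keep <- !is.na(lm)
  visits <- data.frame(landmark = lm[keep], t = cell_t[keep])
  if (nrow(visits) > 1L) {
    dup <- c(FALSE, visits$landmark[-1] == visits$landmark[-nrow(visits)])
    visits <- visits[!dup, ]
  }
  rownames(visits) <- NULL
  list(cells = cells, cell_t = cell_t, visits = visits)
}

#' Classify inter-landmark segments into canonical path labels
#'
#' Consecutive landmark visits define segments labeled by their endpoints:
#' the five analyzed paths S-C1, C1-G, G-C2, S-C2, C2-G, plus `return` for
#' a G-to-S segment that crosses the alleyway. Anything else is `other`.
#'
#' @param disc output of [discretize_trajectory()].
#' @param maze a `maze_spec`.
#' @return data.frame: from, to, label, t_start, t_end (0 rows if fewer than
#'   two landmark visits).
#' @export
classify_paths <- function(disc, maze) {
  v <- disc$visits
  if (nrow(v) < 2L)
    return(data.frame(from = character(), to = character(), label = character(),
                      t_start = numeric(), t_end = numeric()))
  from <- v$landmark[-nrow(v)]; to <- v$landmark[-1]
  t0 <- v$t[-nrow(v)]; t1 <- v$t[-1]
  key <- paste(from, to, sep = ">")
  lab <- unname(c("S>C1" = "S-C1", "C1>G" = "C1-G", "G>C2" = "G-C2",
                  "S>C2" = "S-C2", "C2>G" = "C2-G")[key])
  lab[is.na(lab)] <- "other"
  # G -> S via the peripheral alleyway is the return path
  gs <- which(from == "G" & to == "S")
  for (i in gs) {
    in_seg <- disc$cell_t >= t0[i] & disc$cell_t <= t1[i]
    if (any(disc$cells[in_seg] == "A")) lab[i] <- "return"
  }
  data.frame(from = from, to = to, label = lab, t_start = t0, t_end = t1)
}

#' Per-trial behavioral summaries
#'
#' @param session an `rk_session` (or any list with position, trials, maze).
#' @return list with `summary` (data.frame trial, phase, duration_s,
#'   distance_cm, string_length, n_paths), `labels` (per-trial character
#'   vectors of path labels, return leg included) and `cells` (per-trial
#'   path strings).
#' @export
trial_summaries <- function(session) {
  trials <- session$trials; maze <- session$maze; pos <- session$position
  labels <- vector("list", nrow(trials)); cells <- vector("list", nrow(trials))
  out <- trials[, c("trial", "phase")]
  out$duration_s <- trials$t_end - trials$t_start
  out$distance_cm <- NA_real_; out$string_length <- NA_integer_; out$n_paths <- NA_integer_
  for (i in seq_len(nrow(trials))) {
    sel <- pos$t >= trials$t_start[i] & pos$t < trials$t_end[i]
    p <- pos[sel, ]
    disc <- discretize_trajectory(p, maze)
    seg <- classify_paths(disc, maze)
    labels[[i]] <- seg$label
    cells[[i]] <- disc$cells
    out$distance_cm[i] <- sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
    out$string_length[i] <- length(disc$cells)
    out$n_paths[i] <- nrow(seg)
  }
  list(summary = out, labels = labels, cells = cells)
}

#' Path-label proportions over a set of trials
#' @param labels list of per-trial label vectors (as from [trial_summaries()]).
#' @return named proportions over the six canonical labels plus `other`;
#'   sums to 1.
#' @export
path_proportions <- function(labels) {
  all_lab <- unlist(labels)
  lv <- c(path_labels(), "other")
  tab <- table(factor(all_lab, levels = lv))
  p <- as.numeric(tab) / max(sum(tab), 1L)
  names(p) <- lv
  p
}

#' Learning curve and learning point
#'
#' A trial is "efficient" iff its labeled path sequence, after dropping the
#' return leg, is exactly `S-C2, C2-G`. The learning curve is a centered
#' moving average (partial windows at the edges) of the efficiency
#' indicator; the learning point is the first trial at or after the
#' reward-replacement trial whose moving average reaches 0.5 and stays at
#' or above 0.5 through the end of the session (NULL if never).
#'
#' @param labels per-trial list of path-label vectors.
#' @param replacement_trial index of the reward-replacement trial.
#' @param window moving-average window in trials (odd, >= 3).
#' @return list: efficiency, moving_average, window, learning_point
#'   (integer or NULL).
#' @export
learning_point <- function(labels, replacement_trial, window = 5L) {
  n <- length(labels)
  if (window > n) stop("window larger than trial count")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  eff <- vapply(labels, function(l) {
    l <- l[l != "return"]
    identical(l, c("S-C2", "C2-G"))
  }, logical(1))
  half <- (window - 1L) %/% 2L
  ma <- vapply(seq_len(n), function(i) {
    mean(eff[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  ok <- ma >= 0.5
  sustained <- rev(cumprod(rev(ok))) == 1
  cand <- which(sustained & seq_len(n) >= replacement_trial)
  list(efficiency = as.numeric(eff), moving_average = ma, window = window,
       learning_point = if (length(cand)) cand[1] else NULL)
}

#' Levenshtein distance between two lattice-cell path strings
#'
#' Standard dynamic-programming edit distance (insertions, deletions,
#' substitutions, unit cost) on symbolic cell codes. Satisfies the metric
#' axioms.
#'
#' @param a,b character vectors (path strings).
#' @return non-negative integer.
#' @export
trajectory_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("path strings must be nonempty")
  na <- length(a); nb <- length(b)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Probability of behavioral change across successive trials
#'
#' From the first trial containing path S-C2 onward, the fraction of
#' successive-trial pairs whose trajectory edit distance is at least
#' `threshold`.
#'
#' @param cells per-trial list of path strings.
#' @param labels per-trial list of path labels.
#' @param threshold integer distance threshold.
#' @return probability in `[0, 1]`, or NULL if fewer than two qualifying
#'   trials.
#' @export
prob_behavior_change <- function(cells, labels, threshold = 2L) {
  first <- which(vapply(labels, function(l) "S-C2" %in% l, logical(1)))[1]
  if (is.na(first) || first > length(cells) - 1L) return(NULL)
  idx <- first:length(cells)
  d <- vapply(seq_len(length(idx) - 1L), function(k) {
    trajectory_distance(cells[[idx[k]]], cells[[idx[k + 1L]]])
  }, numeric(1))
  mean(d >= threshold)
}
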