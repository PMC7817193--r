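#' Decode one candidate event in fine time bins
#'
#' @param session an `rk_session`.
#' @param encoder from [fit_encoder()].
#' @param t_start,t_end event window, s.
#' @param bin_s fine bin width, s.
#' @return a `decoded_posterior` (see [decode()]), or NULL if the window is
#'   shorter than one bin.
#' @export
decode_event <- function(session, encoder, t_start, t_end, bin_s = 0.02) {
  if (t_end - t_start < bin_s) return(NULL)
  edges <- seq(t_start, t_end, by = bin_s)
  if (length(edges) < 2L) return(NULL)
  cnt <- bin_spike_counts(session$spikes, edges)
  dp <- decode(cnt, encoder, tau = bin_s)
  dp$n_spikes <- colSums(cnt)
  dp
}

# restrict a decoded posterior to its occupied (>= 1 spike) time bins;
# zero-spike bins carry only the exposure term and no sequence content
occupied_bins <- function(dp) {
  if (is.null(dp$n_spikes)) return(dp)
  keep <- dp$n_spikes > 0
  dp$posterior <- dp$posterior[keep, , drop = FALSE]
  dp$map_state <- dp$map_state[keep]
  dp$n_spikes <- dp$n_spikes[keep]
  dp
}

#' Representation rates per path and the represented path
#'
#' The reprate of a path is the mean over occupied event time bins (bins
#' with at least one spike, when spike counts are attached by
#' [decode_event()]) of the total posterior mass on that path's states;
#' the represented path is the argmax. Exact ties are broken by the larger
#' maximum single-bin path mass, then lexicographically, so results are
#' deterministic.
#'
#' @param dp a `decoded_posterior` for the event.
#' @return list: `reprate` (named numeric over paths), `represented` (path
#'   label).
#' @export
reprate <- function(dp) {
  if (is.null(dp) || nrow(dp$posterior) == 0L) stop("empty posterior")
  dp <- occupied_bins(dp)
  if (nrow(dp$posterior) == 0L) stop("no occupied time bins")
  paths <- unique(dp$states$path)
  mass <- vapply(paths, function(p) {
    sel <- dp$states$path == p
    mean(rowSums(dp$posterior[, sel, drop = FALSE]))
  }, numeric(1))
  mx <- max(mass)
  cand <- paths[mass >= mx - 1e-12]
  if (length(cand) > 1L) {
    peak <- vapply(cand, function(p) {
      sel <- dp$states$path == p
      max(rowSums(dp$posterior[, sel, drop = FALSE]))
    }, numeric(1))
    cand <- cand[peak >= max(peak) - 1e-12]
    cand <- sort(cand)
  }
  list(reprate = mass, represented = cand[1])
}

#' Shuffle-normalized representation rates (repZ)
#'
#' Null distribution: the tuning-curve assignment is permuted across units
#' (unit-identity shuffle), the event is re-decoded, and reprates are
#' recomputed. repZ(path) = (observed - null mean) / null sd; paths with a
#' degenerate null sd are NA.
#'
#' @param counts units x bins spike counts of the event.
#' @param encoder fitted encoder.
#' @param bin_s fine bin width, s.
#' @param n_shuffles number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @return list: `repZ` (named numeric), `observed`, `represented`.
#' @export
repz <- function(counts, encoder, bin_s = 0.02, n_shuffles = 500L, seed = 1L) {
  if (n_shuffles < 100L) warning("fewer than 100 shuffles")
  with_counts <- function(cnt, enc) {
    dp <- decode(cnt, enc, tau = bin_s)
    dp$n_spikes <- colSums(cnt)
    dp
  }
  obs <- reprate(with_counts(counts, encoder))
  set.seed(as.integer(seed))
  paths <- unique(encoder$states$path)
  null <- matrix(NA_real_, n_shuffles, length(paths),
                 dimnames = list(NULL, paths))
  enc2 <- encoder
  for (s in seq_len(n_shuffles)) {
    enc2$lambda <- encoder$lambda[sample(nrow(encoder$lambda)), , drop = FALSE]
    null[s, ] <- reprate(with_counts(counts, enc2))$reprate[paths]
  }
  mu <- colMeans(null); sdv <- apply(null, 2, stats::sd)
  z <- (obs$reprate[paths] - mu) / sdv
  z[sdv == 0] <- NA_real_
  list(repZ = z, observed = obs$reprate, represented = obs$represented)
}

#' Posterior-weighted time-position correlation
#'
#' With weights `w(t, x)` equal to the posterior matrix, the weighted
#' correlation is `cov_w(t, x) / sqrt(cov_w(t, t) * cov_w(x, x))` using
#' weighted means and covariances. Returns NA when either marginal weighted
#' variance is zero.
#'
#' @param P time-bins x position-bins weight (posterior) matrix.
#' @param tvals time coordinates of the rows (default 1..nrow).
#' @param xvals position coordinates of the columns (default 1..ncol).
#' @return correlation in `[-1, 1]`, or NA.
#' @export
weighted_corr <- function(P, tvals = seq_len(nrow(P)), xvals = seq_len(ncol(P))) {
  W <- sum(P)
  if (W <= 0) return(NA_real_)
  Tm <- matrix(tvals, nrow(P), ncol(P))
  Xm <- matrix(xvals, nrow(P), ncol(P), byrow = TRUE)
  mt <- sum(P * Tm) / W
  mx <- sum(P * Xm) / W
  ctx <- sum(P * (Tm - mt) * (Xm - mx)) / W
  ctt <- sum(P * (Tm - mt)^2) / W
  cxx <- sum(P * (Xm - mx)^2) / W
  if (ctt <= 0 || cxx <= 0) return(NA_real_)
  max(min(ctx / sqrt(ctt * cxx), 1), -1)
}

#' Sequence score, sequential-event flag, and replay direction
#'
#' The posterior is restricted to the represented path. The weighted
#' correlation r between time and position gives the direction: positions
#' ordered start-to-destination, so r > 0 means the decoded progression
#' matches the travel direction (forward) and r < 0 means reverse. The
#' sequential-event criterion is `|r| >= 0.5`. The sequence score rZ
#' z-scores `|r|` against a column-cycle shuffle null (independent circular
#' shift of each time bin's position distribution).
#'
#' @param dp a `decoded_posterior` for the event.
#' @param path path to score (default: represented path).
#' @param n_shuffles shuffle count.
#' @param seed integer seed.
#' @param r_threshold sequential-event threshold on `|r|`.
#' @return list: r, rZ, is_sequential, direction
#'   (`"forward"`/`"reverse"`/`"none"`), path.
#' @export
sequence_score <- function(dp, path = NULL, n_shuffles = 500L, seed = 1L,
                           r_threshold = 0.5) {
  if (is.null(path)) path <- reprate(dp)$represented
  dp <- occupied_bins(dp)
  sel <- dp$states$path == path
  P <- dp$posterior[, sel, drop = FALSE]
  xv <- dp$states$center[sel]
  r <- weighted_corr(P, xvals = xv)
  if (is.na(r))
    return(list(r = NA_real_, rZ = NA_real_, is_sequential = FALSE,
                direction = "none", path = path))
  rz <- NA_real_
  if (n_shuffles > 0L) {
    set.seed(as.integer(seed))
    nr <- numeric(n_shuffles)
    nc <- ncol(P)
    for (s in seq_len(n_shuffles)) {
      sh <- sample.int(nc, nrow(P), replace = TRUE) - 1L
      Ps <- P
      for (i in seq_len(nrow(P))) if (sh[i] > 0L)
        Ps[i, ] <- P[i, c((nc - sh[i] + 1L):nc, 1L:(nc - sh[i]))]
      nr[s] <- abs(weighted_corr(Ps, xvals = xv))
    }
    nr <- nr[is.finite(nr)]
    sdn <- stats::sd(nr)
    rz <- if (length(nr) < 10L || sdn == 0) NA_real_ else (abs(r) - mean(nr)) / sdn
  }
  seq_ok <- abs(r) >= r_threshold
  list(r = r, rZ = rz, is_sequential = seq_ok,
       direction = if (!seq_ok) "none" else if (r > 0) "forward" else "reverse",
       path = path)
}

#' Trajectory-event classification from the MAP trace
#'
#' The MAP position per time bin (posterior restricted to `path`) must
#' contain a run of at least `min_run` bins with per-step jumps no larger
#' than `max_jump_frac` of the path length, spanning at least
#' `min_span_frac` of the path.
#'
#' @param dp a `decoded_posterior`.
#' @param path path label (default: represented path).
#' @param min_span_frac minimum spanned fraction of the path.
#' @param max_jump_frac maximum per-step jump as a fraction of path length.
#' @param min_run minimum run length in bins.
#' @return logical.
#' @export
trajectory_events <- function(dp, path = NULL, min_span_frac = 0.3,
                              max_jump_frac = 0.2, min_run = 3L) {
  if (is.null(path)) path <- reprate(dp)$represented
  dp <- occupied_bins(dp)
  sel <- dp$states$path == path
  P <- dp$posterior[, sel, drop = FALSE]
  xv <- dp$states$center[sel]
  mp <- xv[apply(P, 1, which.max)]
  L <- max(xv) + diff(xv[1:2]) / 2
  if (length(mp) < min_run) return(FALSE)
  ok <- abs(diff(mp)) <= max_jump_frac * L
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= (min_run - 1L))) {
    span <- diff(range(mp[starts[k]:(ends[k] + 1L)]))
    if (span >= min_span_frac * L) return(TRUE)
  }
  FALSE
}

#' Score a table of candidate events
#'
#' Runs the full per-event pipeline: fine-bin decoding, reprates and the
#' represented path, optional repZ, the weighted correlation r and sequence
#' score rZ on the represented path, forward/reverse classification, and
#' the trajectory-event flag.
#'
#' @param session an `rk_session`.
#' @param events event table ([detect_synchronous_events()] format; only
#'   t_start/t_end are required).
#' @param encoder fitted encoder.
#' @param bin_s fine decoding bin, s.
#' @param n_shuffles shuffles for rZ.
#' @param n_shuffles_repz shuffles for repZ (0 skips repZ).
#' @param seed integer seed (per-event seeds are derived deterministically).
#' @return the events table augmented with reprate_<path> columns,
#'   rep_path, repZ, r, rZ, is_sequential, direction, is_trajectory_event.
#' @export
score_events <- function(session, events, encoder, bin_s = 0.02,
                         n_shuffles = 500L, n_shuffles_repz = 0L, seed = 1L) {
  paths <- unique(encoder$states$path)
  n <- nrow(events)
  rp <- matrix(NA_real_, n, length(paths), dimnames = list(NULL, paths))
  rep_path <- character(n); rvec <- rep(NA_real_, n); rz <- rep(NA_real_, n)
  seq_ok <- logical(n); dir <- rep("none", n); traj <- logical(n)
  repz_rep <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dp <- decode_event(session, encoder, events$t_start[i], events$t_end[i],
                       bin_s = bin_s)
    if (is.null(dp) || sum(dp$n_spikes > 0) < 3L) { rep_path[i] <- NA; next }
    rr <- reprate(dp)
    rp[i, ] <- rr$reprate[paths]
    rep_path[i] <- rr$represented
    sc <- sequence_score(dp, path = rr$represented, n_shuffles = n_shuffles,
                         seed = seed + i)
    rvec[i] <- sc$r; rz[i] <- sc$rZ; seq_ok[i] <- sc$is_sequential
    dir[i] <- sc$direction
    traj[i] <- trajectory_events(dp, path = rr$represented)
    if (n_shuffles_repz > 0L) {
      edges <- seq(events$t_start[i], events$t_end[i], by = bin_s)
      cnt <- bin_spike_counts(session$spikes, edges)
      rz_all <- repz(cnt, encoder, bin_s = bin_s, n_shuffles = n_shuffles_repz,
                     seed = seed + i)
      repz_rep[i] <- rz_all$repZ[[rr$represented]]
    }
  }
  out <- events
  colnames(rp) <- paste0("reprate_", paths)
  out <- cbind(out, rp)
  out$rep_path <- rep_path
  out$repZ <- repz_rep
  out$r <- rvec; out$rZ <- rz
  out$is_sequential <- seq_ok; out$direction <- dir
  out$is_trajectory_event <- traj
  out
}

#' Participation rates and per-cell contributions (PCC)
#'
#' Participation rate: fraction of events in which a unit fires at least
#' one spike. PCC: for sequential events containing the unit, the drop in
#' the event's sequence score when the unit's spikes are removed
#' (leave-one-unit-out delta rZ), averaged per unit. Per-class aggregation
#' reports the mean PCC and a one-sample t statistic against zero.
#'
#' @param session an `rk_session`.
#' @param scored scored events from [score_events()].
#' @param encoder fitted encoder.
#' @param classes per-unit class labels (e.g. from [joint_classify()]).
#' @param bin_s fine bin, s.
#' @param n_shuffles shuffles for the leave-one-out rZ (smaller than the
#'   headline rZ for tractability).
#' @param seed integer seed.
#' @return list: `units` (unit, class, participation, pcc, n_events),
#'   `by_class` (class, mean_pcc, t_stat, p_value, n).
#' @export
participation_and_pcc <- function(session, scored, encoder, classes = NULL,
                                  bin_s = 0.02, n_shuffles = 100L, seed = 1L) {
  n_units <- length(session$spikes)
  n_ev <- nrow(scored)
  fired <- matrix(FALSE, n_units, n_ev)
  for (i in seq_len(n_ev)) {
    fired[, i] <- vapply(session$spikes, function(s)
      any(s >= scored$t_start[i] & s < scored$t_end[i]), logical(1))
  }
  particip <- rowMeans(fired)

  pcc <- rep(NA_real_, n_units); nev_u <- integer(n_units)
  seq_idx <- which(scored$is_sequential)
  for (i in seq_idx) {
    edges <- seq(scored$t_start[i], scored$t_end[i], by = bin_s)
    if (length(edges) < 4L) next
    cnt <- bin_spike_counts(session$spikes, edges)
    dp <- decode(cnt, encoder, tau = bin_s)
    dp$n_spikes <- colSums(cnt)
    pth <- scored$rep_path[i]
    base <- sequence_score(dp, path = pth, n_shuffles = n_shuffles, seed = seed + i)
    if (!is.finite(base$rZ)) next
    for (u in which(fired[, i])) {
      cnt2 <- cnt; cnt2[u, ] <- 0L
      dp2 <- decode(cnt2, encoder, tau = bin_s)
      dp2$n_spikes <- colSums(cnt2)
      alt <- sequence_score(dp2, path = pth, n_shuffles = n_shuffles, seed = seed + i)
      if (!is.finite(alt$rZ)) next
      d <- base$rZ - alt$rZ
      pcc[u] <- if (is.na(pcc[u])) d else pcc[u] + d
      nev_u[u] <- nev_u[u] + 1L
    }
  }
  pcc <- ifelse(nev_u > 0, pcc / nev_u, NA_real_)
  units <- data.frame(unit = seq_len(n_units),
                      class = if (is.null(classes)) NA_character_ else classes,
                      participation = particip, pcc = pcc, n_events = nev_u)
  by_class <- NULL
  if (!is.null(classes)) {
    by_class <- do.call(rbind, lapply(split(units, units$class), function(g) {
      v <- g$pcc[is.finite(g$pcc)]
      tt <- if (length(v) >= 3L && stats::sd(v) > 0) stats::t.test(v, mu = 0) else NULL
      data.frame(class = g$class[1], mean_pcc = mean(v), n = length(v),
                 t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value)
    }))
    rownames(by_class) <- NULL
  }
  list(units = units, by_class = by_class)
}

#' Event-pair and trial-pair ensemble correlations
#'
#' Each event is vectorized as its per-unit spike counts; Pearson
#' correlations are computed between all event pairs, and the trial-pair
#' matrix averages event-pair correlations spanning each trial pair.
#'
#' @param session an `rk_session`.
#' @param events event table.
#' @return list: `event_cor` (events x events), `trial_cor` (trials x
#'   trials), `counts` (units x events).
#' @export
ensemble_correlations <- function(session, events) {
  if (nrow(events) < 2L) stop("need at least 2 events")
  n_ev <- nrow(events)
  cnt <- matrix(0, length(session$spikes), n_ev)
  for (i in seq_len(n_ev)) {
    cnt[, i] <- vapply(session$spikes, function(s)
      sum(s >= events$t_start[i] & s < events$t_end[i]), numeric(1))
  }
  sdv <- apply(cnt, 2, stats::sd)
  C <- matrix(NA_real_, n_ev, n_ev)
  ok <- sdv > 0
  if (sum(ok) >= 2L) C[ok, ok] <- stats::cor(cnt[, ok, drop = FALSE])
  trials <- sort(unique(events$trial))
  TC <- matrix(NA_real_, length(trials), length(trials),
               dimnames = list(trials, trials))
  for (a in seq_along(trials)) for (b in seq_along(trials)) {
    ia <- which(events$trial == trials[a]); ib <- which(events$trial == trials[b])
    vals <- C[ia, ib, drop = FALSE]
    if (a == b) vals[lower.tri(vals, diag = TRUE)] <- NA
    TC[a, b] <- mean(vals, na.rm = TRUE)
  }
  list(event_cor = C, trial_cor = TC, counts = cnt)
}
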