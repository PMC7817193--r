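#' Linearized-position binning shared by rate maps and the decoder
#'
#' Every canonical path is its own 1D axis, discretized into `bin_cm` bins;
#' the decoder state space is the concatenation of all path bins.
#'
#' @param maze a `maze_spec`.
#' @param bin_cm bin size in cm.
#' @param paths which paths to include (default all six).
#' @return list with `states` (data.frame state, path, bin, center) and
#'   per-path bin edges.
#' @export
make_binning <- function(maze, bin_cm = 2, paths = path_labels()) {
  edges <- lapply(paths, function(p) {
    L <- path_length(maze, p)
    seq(0, ceiling(L / bin_cm) * bin_cm, by = bin_cm)
  })
  names(edges) <- paths
  states <- do.call(rbind, lapply(paths, function(p) {
    e <- edges[[p]]
    data.frame(path = p, bin = seq_len(length(e) - 1L),
               center = (e[-1] + e[-length(e)]) / 2)
  }))
  states$state <- seq_len(nrow(states))
  list(states = states, edges = edges, bin_cm = bin_cm, paths = paths)
}

#' Analysis-side linearized run samples
#'
#' Segments each trial with [classify_paths()] (no ground truth used),
#' projects positions within each canonical-path segment onto that path's
#' axis, and attaches the running speed.
#'
#' @param session an `rk_session` (or equivalent list).
#' @return data.frame: t, trial, phase, path, lin, speed.
#' @export
linearized_samples <- function(session) {
  pos <- session$position; maze <- session$maze; trials <- session$trials
  speed <- position_speed(pos)
  out <- list()
  for (i in seq_len(nrow(trials))) {
    sel <- which(pos$t >= trials$t_start[i] & pos$t < trials$t_end[i])
    if (length(sel) < 2L) next
    p <- pos[sel, ]
    disc <- discretize_trajectory(p, maze)
    seg <- classify_paths(disc, maze)
    seg <- seg[seg$label %in% path_labels(), ]
    for (k in seq_len(nrow(seg))) {
      ssel <- sel[p$t >= seg$t_start[k] & p$t <= seg$t_end[k]]
      if (!length(ssel)) next
      lin <- linearize_position(maze, seg$label[k], pos$x[ssel], pos$y[ssel])$lin
      out[[length(out) + 1L]] <- data.frame(
        t = pos$t[ssel], trial = trials$trial[i], phase = trials$phase[i],
        path = seg$label[k], lin = lin, speed = speed[ssel])
    }
  }
  do.call(rbind, out)
}

gauss_kernel <- function(sigma_bins) {
  if (sigma_bins <= 0) return(1)
  r <- ceiling(3 * sigma_bins)
  k <- exp(-(-r:r)^2 / (2 * sigma_bins^2))
  k / sum(k)
}

# smooth columns of a states-long vector/matrix independently within each path
smooth_states <- function(x, binning, sigma_bins) {
  k <- gauss_kernel(sigma_bins)
  if (length(k) == 1L) return(x)
  one <- function(v) {
    out <- v
    for (p in binning$paths) {
      idx <- which(binning$states$path == p)
      out[idx] <- conv_same(v[idx], k)
    }
    out
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

# centered ("same") convolution with an odd symmetric kernel, via
# power-of-2 zero-padded FFT so arbitrary signal lengths stay fast
conv_same <- function(v, k) {
  n <- length(v); m <- length(k)
  if (m == 1L) return(v * k)
  r <- (m - 1L) %/% 2L
  N <- stats::nextn(n + m - 1L, 2)
  V <- stats::fft(c(v, rep(0, N - n)))
  K <- stats::fft(c(k, rep(0, N - m)))
  full <- Re(stats::fft(V * K, inverse = TRUE)) / N
  full[(r + 1L):(r + n)]
}

#' Per-trial sufficient statistics for rate maps
#'
#' Unsmoothed spike counts and occupancy per decoder state for each trial;
#' rate maps for any subset of trials are then assembled by summing and
#' smoothing, which makes leave-one-out refits cheap.
#'
#' @param session an `rk_session`.
#' @param binning from [make_binning()].
#' @param lin precomputed [linearized_samples()] (optional).
#' @param speed_threshold immobility exclusion, cm/s.
#' @return list: counts (units x states x trials array), occ (states x
#'   trials), binning, trials, dt (occupancy per sample, s).
#' @export
ratemap_suffstats <- function(session, binning, lin = NULL, speed_threshold = 4) {
  if (is.null(lin)) lin <- linearized_samples(session)
  lin <- lin[lin$speed > speed_threshold, ]
  n_units <- length(session$spikes)
  n_states <- nrow(binning$states)
  trial_ids <- session$trials$trial
  n_trials <- length(trial_ids)
  dt <- stats::median(diff(session$position$t))

  state_of <- function(path, linpos) {
    s <- binning$states
    off <- vapply(binning$paths, function(p) s$state[s$path == p][1] - 1L, numeric(1))
    b <- pmin(pmax(floor(linpos / binning$bin_cm) + 1L, 1L),
              vapply(binning$paths, function(p) sum(s$path == p), numeric(1))[path])
    off[path] + b
  }
  lin$state <- state_of(lin$path, lin$lin)

  occ <- matrix(0, n_states, n_trials)
  tb <- table(factor(lin$state, levels = seq_len(n_states)),
              factor(lin$trial, levels = trial_ids))
  occ[] <- as.numeric(tb) * dt

  counts <- array(0, dim = c(n_units, n_states, n_trials))
  # spike -> state via nearest run sample in time (within half a sample step)
  ord <- order(lin$t)
  lt <- lin$t[ord]; lstate <- lin$state[ord]; ltrial <- lin$trial[ord]
  for (u in seq_len(n_units)) {
    st <- session$spikes[[u]]
    if (!length(st)) next
    pos_idx <- findInterval(st, lt)
    lo <- pmax(pos_idx, 1L); hi <- pmin(pos_idx + 1L, length(lt))
    d_lo <- abs(st - lt[lo]); d_hi <- abs(lt[hi] - st)
    nearest <- ifelse(d_hi < d_lo, hi, lo)
    ok <- pmin(d_lo, d_hi) <= dt
    if (!any(ok)) next
    tr <- match(ltrial[nearest[ok]], trial_ids)
    stt <- lstate[nearest[ok]]
    tb <- tabulate((tr - 1L) * n_states + stt, nbins = n_states * n_trials)
    counts[u, , ] <- matrix(tb, n_states, n_trials)
  }
  list(counts = counts, occ = occ, binning = binning,
       trials = session$trials, dt = dt)
}

#' Assemble smoothed rate maps from sufficient statistics
#'
#' @param ss from [ratemap_suffstats()].
#' @param trials trial ids to include (default all).
#' @param sigma_bins Gaussian smoothing sd in bins.
#' @param min_occ occupancy mask threshold, s.
#' @return object of class `rate_map_set`: rate (units x states), occ,
#'   mask (states with occupancy below threshold), binning, counts
#'   (unsmoothed unit x state totals).
#' @export
rate_map_set <- function(ss, trials = NULL, sigma_bins = 2, min_occ = 0.1) {
  trial_ids <- ss$trials$trial
  sel <- if (is.null(trials)) seq_along(trial_ids) else match(trials, trial_ids)
  occ <- rowSums(ss$occ[, sel, drop = FALSE])
  if (all(occ == 0)) stop("zero occupancy everywhere")
  cnt <- apply(ss$counts[, , sel, drop = FALSE], c(1, 2), sum)
  # FFT convolution of nonnegative series; clamp out roundoff negatives
  so <- pmax(smooth_states(occ, ss$binning, sigma_bins), 0)
  sc <- pmax(smooth_states(cnt, ss$binning, sigma_bins), 0)
  rate <- sweep(sc, 2, pmax(so, 1e-12), "/")
  mask <- occ < min_occ
  rate[, mask] <- NA_real_
  structure(list(rate = rate, occ = occ, smoothed_occ = so, mask = mask,
                 binning = ss$binning, counts = cnt, sigma_bins = sigma_bins),
            class = "rate_map_set")
}

#' Occupancy-normalized rate map for one unit
#'
#' Convenience wrapper around the sufficient-statistics machinery for a
#' single unit; see [rate_map_set()] for the population version.
#'
#' @param session an `rk_session`.
#' @param unit unit index.
#' @param trials trial subset (default all).
#' @param bin_cm,sigma_bins,speed_threshold,min_occ see [rate_map_set()].
#' @return data.frame: path, bin, center, occ, rate (NA where masked).
#' @export
compute_rate_map <- function(session, unit, trials = NULL, bin_cm = 2,
                             sigma_bins = 2, speed_threshold = 4, min_occ = 0.1) {
  binning <- make_binning(session$maze, bin_cm)
  ss <- ratemap_suffstats(session, binning, speed_threshold = speed_threshold)
  rms <- rate_map_set(ss, trials = trials, sigma_bins = sigma_bins, min_occ = min_occ)
  out <- rms$binning$states
  out$occ <- rms$occ
  out$rate <- rms$rate[unit, ]
  out
}

#' Detect place fields on a unit's rate map
#'
#' Fields are maximal contiguous bin runs (within one path) whose rate is at
#' least `max(frac * unit peak, abs_floor)`; a field is kept if its peak
#' rate reaches `peak_floor`, it spans at least `min_bins` bins and at most
#' `max_width_cm` (a run covering most of a path is diffuse firing, not a
#' place field). Multiple fields per unit (and per path) are allowed.
#'
#' @param rms a `rate_map_set`.
#' @param unit unit index.
#' @param peak_floor minimum field peak rate, Hz.
#' @param frac bin-inclusion threshold as a fraction of the unit's peak.
#' @param abs_floor absolute bin-inclusion floor, Hz.
#' @param min_bins minimum field extent in bins.
#' @param max_width_cm maximum field extent, cm.
#' @return data.frame: unit, path, peak_rate, peak_pos, start, end (cm).
#' @export
detect_fields <- function(rms, unit, peak_floor = 2, frac = 0.2,
                          abs_floor = 0.5, min_bins = 3L, max_width_cm = 60) {
  r <- rms$rate[unit, ]
  r[is.na(r)] <- 0
  pk <- max(r)
  out <- list()
  if (pk >= peak_floor) {
    thr <- max(frac * pk, abs_floor)
    st <- rms$binning$states
    for (p in rms$binning$paths) {
      idx <- which(st$path == p)
      above <- r[idx] >= thr
      rl <- rle(above)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
      for (k in which(rl$values & rl$lengths >= min_bins)) {
        ii <- idx[starts[k]:ends[k]]
        if (max(r[ii]) < peak_floor) next
        if (length(ii) * rms$binning$bin_cm > max_width_cm) next
        pkpos <- st$center[ii[which.max(r[ii])]]
        out[[length(out) + 1L]] <- data.frame(
          unit = unit, path = p, peak_rate = max(r[ii]), peak_pos = pkpos,
          start = st$center[ii[1]] - rms$binning$bin_cm / 2,
          end = st$center[ii[length(ii)]] + rms$binning$bin_cm / 2)
      }
    }
  }
  if (!length(out))
    return(data.frame(unit = integer(), path = character(), peak_rate = numeric(),
                      peak_pos = numeric(), start = numeric(), end = numeric()))
  do.call(rbind, out)
}

#' Detect fields for every unit
#' @inheritParams detect_fields
#' @return one data.frame over all units.
#' @export
detect_fields_all <- function(rms, ...) {
  do.call(rbind, lapply(seq_len(nrow(rms$rate)), function(u) detect_fields(rms, u, ...)))
}

#' Joint classification of place fields across two phases
#'
#' Field pairs across phases are labeled `stable` (same path, peak positions
#' within `tol` cm), `context` (fields on analogous paths of one
#' correspondence group at matching destination-aligned positions —
#' distance-to-destination within `tol`), or `unrelated`. Fields without any
#' counterpart in the other phase are `off` (phase A only) or `on` (phase B
#' only). Per-unit summary labels apply context priority: a unit with any
#' context pair is `context`, else any stable pair makes it `stable`, else
#' `off`/`on`/`none`.
#'
#' @param fields_a,fields_b field tables from [detect_fields_all()] for
#'   phases A (earlier) and B (later).
#' @param maze a `maze_spec`.
#' @param tol matching tolerance, cm.
#' @return list: `pairs` (unit, path_a, path_b, pos_a, pos_b, label),
#'   `units` (unit, any_stable, any_context, label).
#' @export
joint_classify <- function(fields_a, fields_b, maze, tol = 10) {
  known <- path_labels()
  if (nrow(fields_a) && !all(fields_a$path %in% known)) stop("unknown path label")
  if (nrow(fields_b) && !all(fields_b$path %in% known)) stop("unknown path label")
  corr <- path_correspondence()
  group_of <- function(p) {
    g <- names(corr)[vapply(corr, function(v) p %in% v, logical(1))]
    if (length(g)) g else NA_character_
  }
  units <- sort(unique(c(fields_a$unit, fields_b$unit)))
  pair_rows <- list(); unit_rows <- list()
  for (u in units) {
    fa <- fields_a[fields_a$unit == u, ]; fb <- fields_b[fields_b$unit == u, ]
    any_stable <- FALSE; any_context <- FALSE
    if (nrow(fa) && nrow(fb)) {
      for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(fb))) {
        pa <- fa$path[i]; pb <- fb$path[j]
        lab <- "unrelated"
        if (pa == pb && abs(fa$peak_pos[i] - fb$peak_pos[j]) <= tol) {
          lab <- "stable"; any_stable <- TRUE
        } else if (pa != pb) {
          ga <- group_of(pa)
          if (!is.na(ga) && identical(ga, group_of(pb))) {
            da <- path_length(maze, pa) - fa$peak_pos[i]
            db <- path_length(maze, pb) - fb$peak_pos[j]
            if (abs(da - db) <= tol) { lab <- "context"; any_context <- TRUE }
          }
        }
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          unit = u, path_a = pa, path_b = pb,
          pos_a = fa$peak_pos[i], pos_b = fb$peak_pos[j], label = lab)
      }
    }
    label <- if (any_context) "context" else if (any_stable) "stable"
      else if (nrow(fa) && !nrow(fb)) "off"
      else if (!nrow(fa) && nrow(fb)) "on" else "none"
    unit_rows[[length(unit_rows) + 1L]] <- data.frame(
      unit = u, any_stable = any_stable, any_context = any_context, label = label)
  }
  list(pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else NULL,
       units = if (length(unit_rows)) do.call(rbind, unit_rows) else
         data.frame(unit = integer(), any_stable = logical(),
                    any_context = logical(), label = character()))
}

#' Population-vector correlation matrix across location bins
#'
#' The population vector at a location bin is the vector of all units'
#' rates there. Returns the Pearson correlation for every pair of (phase,
#' path, bin) columns; bins masked in either map, or with zero variance,
#' give NA.
#'
#' @param rms_list named list of `rate_map_set` objects (one per phase).
#' @return list: `cor` (matrix), `states` (data.frame phase, path, bin,
#'   center describing the columns).
#' @export
population_vector_matrix <- function(rms_list) {
  stopifnot(length(rms_list) >= 1L)
  cols <- list(); meta <- list()
  for (ph in names(rms_list)) {
    rms <- rms_list[[ph]]
    if (nrow(rms$rate) < 2L) stop("need at least 2 units")
    m <- rms$rate
    meta[[ph]] <- cbind(phase = ph, rms$binning$states)
    cols[[ph]] <- m
  }
  M <- do.call(cbind, cols)
  suppressWarnings(C <- stats::cor(M, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- NA_real_
  list(cor = C, states = do.call(rbind, meta))
}
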