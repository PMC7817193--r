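#' Segment the LFP into theta cycles during running
#'
#' Zero-phase band-pass (default 6-10 Hz), cycles cut trough-to-trough
#' (or peak-to-peak with `reference = "peak"`). Cycles with durations
#' outside `dur_range` or occurring during immobility are discarded.
#'
#' @param lfp data.frame t, v with attribute `fs` (or pass `fs`).
#' @param speed,speed_t running speed samples and their times.
#' @param fs LFP sampling rate, Hz (>= 250).
#' @param band theta band, Hz.
#' @param reference `"trough"` or `"peak"` cycle boundaries.
#' @param dur_range admissible cycle durations, s.
#' @param speed_threshold running gate, cm/s.
#' @return data.frame: t_start, t_end, duration.
#' @export
detect_theta_cycles <- function(lfp, speed, speed_t, fs = attr(lfp, "fs"),
                                band = c(6, 10), reference = c("trough", "peak"),
                                dur_range = c(1 / 12, 1 / 5), speed_threshold = 4) {
  reference <- match.arg(reference)
  if (is.null(fs)) fs <- 1 / stats::median(diff(lfp$t))
  stopifnot(fs >= 250)
  if (nrow(lfp) < 2 * fs / band[1]) stop("LFP shorter than 2 theta cycles")
  v <- fir_bandpass(lfp$v, fs, band[1], band[2], taps = round(2 * fs / band[1]) * 2 + 1)
  if (reference == "peak") v <- -v
  n <- length(v)
  tr <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n] & v[2:(n - 1)] < 0) + 1L
  if (length(tr) < 2L) return(data.frame(t_start = numeric(), t_end = numeric(),
                                         duration = numeric()))
  out <- data.frame(t_start = lfp$t[tr[-length(tr)]], t_end = lfp$t[tr[-1]])
  out$duration <- out$t_end - out$t_start
  out <- out[out$duration >= dur_range[1] & out$duration <= dur_range[2], ]
  mid <- (out$t_start + out$t_end) / 2
  run <- stats::approx(speed_t, speed, xout = mid, rule = 2)$y > speed_threshold
  out <- out[run, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quadrant score of an averaged theta-window posterior matrix
#'
#' `M` has relative position on the rows (ordered by `row_centers`, cm,
#' negative = behind the animal) and time within the two-cycle window on
#' the columns (early to late). Quadrants are taken about the center
#' (current position, window midpoint); rows or columns centered exactly on
#' zero/midline are excluded. With quadrants QI (early-ahead), QII
#' (early-behind), QIII (late-behind), QIV (late-ahead), the score
#' `((QII + QIV) - (QI + QIII)) / (QI + QII + QIII + QIV)` is positive for
#' forward sweeps (behind-early to ahead-late) and lies in `[-1, 1]`.
#'
#' @param M matrix (position bins x time bins) of averaged posterior mass.
#' @param row_centers relative-position bin centers, cm.
#' @return scalar score (NA if the matrix has no mass).
#' @export
quadrant_score_matrix <- function(M, row_centers) {
  stopifnot(nrow(M) == length(row_centers))
  nc <- ncol(M)
  early <- seq_len(floor(nc / 2))
  late <- (ceiling(nc / 2) + 1L):nc
  if (nc %% 2 == 1L) late <- late[late != (nc + 1L) / 2]
  behind <- which(row_centers < 0)
  ahead <- which(row_centers > 0)
  QI <- sum(M[ahead, early], na.rm = TRUE)
  QII <- sum(M[behind, early], na.rm = TRUE)
  QIII <- sum(M[behind, late], na.rm = TRUE)
  QIV <- sum(M[ahead, late], na.rm = TRUE)
  tot <- QI + QII + QIII + QIV
  if (tot <= 0) return(NA_real_)
  ((QII + QIV) - (QI + QIII)) / tot
}

#' Theta-sequence quadrant score for one path and phase
#'
#' Decodes running periods on `path` in fine time bins, aligns the decoded
#' posterior of every qualifying theta cycle to (current position, cycle
#' phase), averages the aligned matrices, and scores the average with
#' [quadrant_score_matrix()]. The window is a single cycle with the
#' quadrant center at the cycle midpoint: with trough-referenced cycles a
#' forward sweep runs behind (early half) to ahead (late half), which a
#' two-cycle window split at the cycle boundary would cancel by
#' construction. (Displays of two concatenated cycles can be produced by
#' tiling the matrix.)
#'
#' @param session an `rk_session` (LFP required).
#' @param path path label.
#' @param phases phase(s) whose trials are used.
#' @param encoder a fitted encoder covering the session (e.g. from all
#'   trials); if NULL one is fit internally at `bin_cm`.
#' @param cycles optional precomputed [detect_theta_cycles()] output.
#' @param bin_s decoding bin width, s.
#' @param window_cm relative-position half-window, cm.
#' @param rel_bin_cm relative-position bin size, cm.
#' @param n_cols time columns across the cycle.
#' @param min_cycles minimum number of qualifying windows (else score NA).
#' @param bin_cm state bin size when fitting the encoder internally.
#' @param speed_threshold running gate, cm/s.
#' @param lin optional precomputed [linearized_samples()].
#' @return list: score, n_windows, matrix, row_centers.
#' @export
quadrant_score <- function(session, path, phases = c("pre", "learning", "post"),
                           encoder = NULL, cycles = NULL, bin_s = 0.02,
                           window_cm = 50, rel_bin_cm = 2, n_cols = 12L,
                           min_cycles = 20L, bin_cm = 5, speed_threshold = 4,
                           lin = NULL) {
  if (is.null(session$lfp)) stop("session has no LFP")
  if (is.null(lin)) lin <- linearized_samples(session)
  speed_t <- session$position$t
  speed <- position_speed(session$position)
  if (is.null(cycles))
    cycles <- detect_theta_cycles(session$lfp, speed, speed_t,
                                  speed_threshold = speed_threshold)
  if (is.null(encoder)) {
    binning <- make_binning(session$maze, bin_cm)
    ss <- ratemap_suffstats(session, binning, lin = lin,
                            speed_threshold = speed_threshold)
    encoder <- fit_encoder(rate_map_set(ss))
  }
  trials_ph <- session$trials$trial[session$trials$phase %in% phases]
  lp <- lin[lin$path == path & lin$trial %in% trials_ph & lin$speed > speed_threshold, ]
  if (nrow(lp) < 10L)
    return(list(score = NA_real_, n_windows = 0L, matrix = NULL, row_centers = NULL))

  r_edges <- seq(-window_cm, window_cm, by = rel_bin_cm)
  r_ctr <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  acc <- matrix(0, length(r_ctr), n_cols)
  cnt <- matrix(0, length(r_ctr), n_cols)
  on_path <- encoder$states$path == path
  state_pos <- encoder$states$center[on_path]
  n_win <- 0L

  brk <- c(0, which(diff(lp$t) > 0.5), nrow(lp))
  for (k in seq_len(length(brk) - 1L)) {
    seg <- lp[(brk[k] + 1L):brk[k + 1L], ]
    if (nrow(seg) < 5L) next
    t0 <- min(seg$t); t1 <- max(seg$t)
    cyc <- cycles[cycles$t_start >= t0 & cycles$t_end <= t1, ]
    if (nrow(cyc) < 2L) next
    edges <- seq(t0, t1, by = bin_s)
    if (length(edges) < 3L) next
    cntm <- bin_spike_counts(session$spikes, edges)
    dp <- decode(cntm, encoder, tau = bin_s)
    tctr <- (edges[-1] + edges[-length(edges)]) / 2
    true_pos <- stats::approx(seg$t, seg$lin, xout = tctr, rule = 2)$y
    postp <- dp$posterior[, on_path, drop = FALSE]
    # cycles fully inside this segment
    for (c1 in seq_len(nrow(cyc))) {
      w0 <- cyc$t_start[c1]; w1 <- cyc$t_end[c1]
      bsel <- which(tctr >= w0 & tctr < w1)
      if (length(bsel) < 4L) next
      coln <- pmin(floor((tctr[bsel] - w0) / (w1 - w0) * n_cols) + 1L, n_cols)
      for (bi in seq_along(bsel)) {
        b <- bsel[bi]
        rel <- state_pos - true_pos[b]
        inw <- rel >= -window_cm & rel < window_cm
        if (!any(inw)) next
        rowi <- findInterval(rel[inw], r_edges, rightmost.closed = TRUE)
        mass <- postp[b, inw]
        agg <- rowsum(mass, rowi)
        add <- numeric(length(r_ctr))
        add[as.integer(rownames(agg))] <- agg
        acc[, coln[bi]] <- acc[, coln[bi]] + add
        cnt[, coln[bi]] <- cnt[, coln[bi]] + 1
      }
      n_win <- n_win + 1L
    }
  }
  if (n_win < min_cycles)
    return(list(score = NA_real_, n_windows = n_win, matrix = NULL, row_centers = r_ctr))
  M <- acc / pmax(cnt, 1)
  list(score = quadrant_score_matrix(M, r_ctr), n_windows = n_win,
       matrix = M, row_centers = r_ctr)
}
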